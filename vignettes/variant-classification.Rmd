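---
title: "Hierarchical variant classification: model, windows and design notes"
author: "VariantHierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical variant classification: model, windows and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantHierarchy)
```

# The model

`VariantHierarchy` classifies query variants — substitutions, insertions
and deletions on a region of interest — by positional overlap against
user-supplied annotation, walking a fixed decision tree from coarse to fine
context: known-variant/repeat collocation, intergenic vs genic, promoter /
downstream / intronic / exonic per transcript, splice-site windows, UTR/CDS
subregions, and finally codon-level consequences with a predicted mutant
protein. The hierarchy is deliberately *lossless*: rather than electing one
"most severe" consequence, every level and every overlapping gene and
transcript is reported, and downstream consumers sort or filter.

## Coordinates

Everything lives in a 0-space-based frame local to the region of interest:
positions count the *spaces between residues*, from 0 to the region length
$s$, so an interval $(b, e)$ covers residues $b{+}1 .. e$ and a degenerate
interval $b = e$ is an insertion point. This makes substitutions,
insertions and deletions describable by one span convention, at the cost of
a genuine ambiguity: an insertion point lying exactly on a feature boundary
touches both neighbours. The package resolves the ambiguity conservatively
— the insertion attaches to *both* flanking features and both
classifications are reported. Overlap is strict for non-degenerate
intervals (`spanOverlap(5,6, 6,10)` is `FALSE`: adjacent, not overlapping)
and closed for insertion points.

Internally the feature tables are indexed as `IRanges` (residues $b{+}1..e$;
insertion-point features map to the two flanking residues so the
both-sides rule survives indexing), and per-variant queries evaluate the
same predicate against the index's endpoint vectors.

## Windows and their boundary conventions

Three window parameters drive the context labels
(`classifierParams()`; all run-time configurable):

| parameter        | default | meaning |
|------------------|---------|---------|
| `promoterWindow` | 1000 bases | upstream-promoter region before the first exon, and (same width) downstream-transcript region after the last exon, in coding orientation |
| `donorWindow`    | 10 bases   | intronic bases immediately 3' of an exon labelled 5' splice site |
| `acceptorWindow` | 6 bases    | intronic bases immediately 5' of the next exon labelled 3' splice site |
| `flankLen`       | 50 bases   | flanking sequence reported per variant |

Splice offsets are 1-based from the exon boundary — the first intronic base
is offset 1 — and the windows are *closed*: offset exactly equal to the
window is still inside. The same convention holds for the promoter window
(the 1000th upstream base is labelled; the 1001st is not), and all three
boundaries are pinned by sweep tests. "First exon" is resolved on the
transcript's strand, so the promoter of a minus-strand transcript lies to
the *right* of its rightmost exon, and in a very short intron the donor and
acceptor windows may both cover a position, in which case both labels
attach.

The *reported* distance-to-exon is the 0-space gap between the variant span
and the exon boundary (a SNP abutting the exon has distance 0, the 500th
upstream base has distance 499). The window *test*, by contrast, asks
whether the variant's nearest base is among the window's bases — the two
conventions differ by one and are easy to conflate; the sweep tests fix
both.

Variants spanning several categories (e.g. a deletion across an
exon/intron boundary) receive *every* touched label plus an
`exon_intron_boundary` note; the tree is written for point-like variants
and multi-labelling is the lossless generalisation. Transcripts without a
CDS yield `noncoding_exon` for exonic variants and no protein effect.

## Protein-level consequences

For a variant touching the CDS of a coding transcript:

* The CDS is the concatenation of exon ∩ CDS-span pieces in coding order
  (reverse-complemented for minus-strand transcripts); a single genomic CDS
  span per transcript is stored, Ensembl-style, and per-exon coding pieces
  are derived. CDS base $i$ maps to codon $\lceil i/3 \rceil$.
* The mutant CDS is rebuilt by splicing the plus-strand allele into the
  genomic sequence and re-extracting the *same* exon structure with
  coordinates mapped through the edit — so a deletion spanning into an
  intron removes only its exonic bases from the CDS, and an insertion lands
  at its point (an insertion exactly on an exon's 3' boundary joins that
  exon; on the 5' boundary it stays intronic — a documented tie-break).
* Substitutions whose affected coding bases stay within one codon are
  called `synonymous`/`nonsynonymous` by the standard genetic code
  (stop↔stop counts as synonymous). Multi-codon block substitutions get no
  substitution class, a `multi_codon_substitution` note, and a predicted
  protein. Codons containing ambiguity codes translate to `X` and suppress
  the call with an `ambiguous_codon` note.
* Non-synonymous changes are `unconserved` when their BLOSUM30 entry is
  negative and `conserved` otherwise (score ≥ 0); any shift *to* a stop
  codon is unconserved before the matrix is consulted. The matrix ships as
  an NCBI-format text file (`inst/extdata/BLOSUM30.txt`) parsed at load, so
  another matrix (e.g. BLOSUM62) can be substituted via `--matrix`; stop is
  not a matrix row — the stop rule precedes lookup. A substitution that
  *destroys* the stop codon has no matrix entry either: both classes are
  omitted and the `stop_lost` note carries the information.
* Indels are `frameshift` when the net *coding* length change is not a
  multiple of 3, `amino_acid_indel` otherwise. The net change is measured
  on the rebuilt CDS, not the raw allele, so a deletion reaching into an
  intron is judged by the coding bases it actually removes.
* The predicted protein is the translation of the mutant CDS from the
  original start, truncated at the first stop. If the first codon is no
  longer `ATG` the protein is empty with a `start_lost` note; if no stop
  occurs within the mutant CDS, translation continues through the spliced
  3' UTR to the next stop or the transcript end, with a `stop_lost` note.
  Translation beyond the transcript's last exon is not attempted — the
  annotation gives no sequence contract past it.
* Impacted domains are Pfam intervals (1-based inclusive amino-acid
  coordinates) overlapping the affected codon range; for frameshifts the
  affected range extends from the first affected codon to the end of the
  reference protein, since everything downstream is rewritten. Domain
  overlap for the *first* affected codon only would understate frameshifts;
  the downstream-range choice is the conservative one.

# The synthetic-fixture generator

`generateFixture()` builds deterministic annotated toy regions: i.i.d.
uniform ACGT background, CDSs assembled codon-wise (an `ATG`, uniform sense
codons, one terminal stop) so that by construction every CDS has length
divisible by 3, no internal stop, and a stored protein equal to the
translation of its spliced CDS. Defaults (two genes, one per strand;
introns 40–80 bases; UTRs 15–50; 40–80 codons; ≥ 1300-base intergenic pads;
1700 bases upstream of gene 1) are chosen so that the decision tree's
windows are all exercised and separable: pads exceed the 1000-base promoter
window, introns exceed the combined splice windows, and the upstream pad
leaves room for a full 1–1500 promoter sweep. `intronLength` can be lowered
to 8 for window-collision experiments. Seeds are explicit arguments
everywhere and global random state is saved and restored.

What the generator does *not* emulate: realistic base composition or codon
bias, overlapping genes, alternative transcripts of one gene (multi-
transcript genes are exercised by hand-built annotation in the tests),
non-coding genes, or sequencing artefacts. Passing tests therefore
demonstrate the correctness of the classification *logic* under clean
annotation, not robustness to messy real-world gene models.

`generateVariantPanel()` places at least one variant on every leaf of the
decision tree — promoter distances {1, 500, 1000, 1001}, donor offsets
{1, 10, 11}, acceptor offsets {1, 6, 7}, UTRs, synonymous / conserved /
unconserved / stop-gain substitutions found by scanning the fixture's
codons against the genetic code and BLOSUM30, in-frame and frameshift
deletions, a domain hit — each with its expected labels computed by
construction. `oracleLabel()` is an independent brute-force position
labeler (straight-line loops, naive window arithmetic, no code shared with
the classifier); the test suite asserts exact agreement with
`classifyVariant()` over every position × allele single-base substitution
of three seeded fixtures (one of the problem sizes kept deliberately
modest: regions of ≈ 6 kb).

# Report formats

The *normalized* writer emits one block per variant with depth-encoded tab
indentation (variant header 0; known/repeat/intergenic 1; gene 1;
transcript 2; region label 3; splice/exon sublabel 4; protein facts 5).
The *denormalized* writer emits one line per (variant × gene × transcript)
branch with a fixed 24-column schema (26 with flanks), empty strings for
inapplicable cells and comma-joined multi-valued cells; intergenic variants
contribute exactly one line, so the file's line count equals
$\sum_v \max(1, \sum_{g \ni v} |\text{transcripts}(g)|)$. Whether to emit
one line per gene or per transcript was an open choice; per-transcript
matches the per-transcript classification rule. The flat file carries no
header row (the schema is fixed and documented); re-parsing it reconstructs
exactly the label facts of the trees, and both laws are asserted in the
tests. Predicted proteins are written in full — they are a primary output,
not an annotation.

# Numerical and degenerate-input choices

* Non-ACGTN reference characters are masked to `N` (counted in a warning)
  rather than rejected, keeping the classifier total over references with
  IUPAC codes; codons containing `N` translate to `X`.
* Mixed-length events (span 3 replaced by a 1-base allele, say) are typed
  by the pure length rule — here, deletion — and flagged `complex`.
* Row-level input errors (inverted spans, no-op rows, out-of-range
  coordinates, non-DNA alleles) reject the row with a reason, never the
  run; the CLI exits 0 if at least one variant classified, 2 if none, 1 on
  fatal input errors (missing files, hard annotation violations).
* A CDS whose concatenated length is not a multiple of 3 is a validator
  *warning*, not an error — real annotation contains such transcripts and
  the classifier still operates on them.
* Known-variant collocation is positional overlap only; the input format
  carries no alleles to match against.
* Ties: an insertion point on an exon boundary attaches to both features
  for *labelling*; for mutant-CDS reconstruction it joins the piece whose
  interior or right boundary contains it (deterministic, documented above).

# Problem sizes in the test suite

The suites run on fixtures of ~6 kb with 1–3 genes: the
classifier-vs-oracle agreement check covers all positions × 4 alleles of
three fixtures (~72k classifications), the protein suite covers every
synonymous and stop-gain single-base substitution of one transcript plus
indel panels, and the sweeps cover 1500 promoter and 20 splice offsets.
These sizes were chosen as the smallest that exercise every window boundary
and both strands exhaustively.

# Known limitations

* One region of interest per run; no whole-genome indexing, no network
  annotation retrieval (the GFF3/BED adapter replaces it).
* No VCF ingestion (a VCF row converts trivially, but indel
  left-normalization is the caller's responsibility) and no VCF/JSON
  emitters.
* No ranked "most severe consequence" summary; the hierarchy is the
  output.
* Standard genetic code only; no selenocysteine or plastid codes.
* The conservation call is a single-matrix heuristic — quick, but naive
  relative to alignment-based deleteriousness scores; treat it as a first
  triage.
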