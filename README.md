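# VariantHierarchy

Hierarchical, annotation-driven classification of sequence variants on a
region of interest, with protein-level consequence prediction.

## The problem

Resequencing projects produce long lists of putative variants —
substitutions, insertions, deletions — against a well-annotated reference.
Assessing which of them matter is naturally hierarchical: a SNP in a gene is
more interesting than an intergenic one, an exonic SNP more than an intronic
one, and a coding change that truncates the protein more than a synonymous
one, while the intron/exon distinction is moot for a variant that is already
intergenic. `VariantHierarchy` walks each query variant through a decision
tree of genomic feature contexts and reports *every* level of classification
it can assign, so that variants can be sorted and prioritised in a
spreadsheet or by a line-based parser.

For each variant the tree assesses, in order:

1. **collocation** with a known (dbSNP) variant and/or an annotated repeat —
   positional overlap, assessed before any gene context;
2. **intergenic** vs **genic** — a variant overlapping no gene envelope and
   no promoter/downstream window is intergenic; otherwise it is classified
   independently against every overlapping gene and, within each gene,
   against every alternative transcript;
3. **upstream promoter region** / **downstream transcript region** — within
   1,000 bases (configurable) of the transcript's first/last exon in coding
   orientation, with the distance to the nearest exon;
4. **intronic**, with **5' splice site** (within 10 intronic bases
   downstream of an exon, coding orientation) and **3' splice site** (within
   6 intronic bases upstream of the next exon) windows, both closed and
   1-based from the exon boundary;
5. **exonic**, split into **5' UTR**, **CDS**, **3' UTR** at the transcript's
   CDS span (a `noncoding_exon` label for transcripts without a CDS);
6. for CDS variants, the codon-level consequence: position mapped into CDS
   and amino-acid coordinates; **synonymous** / **non-synonymous** for
   single-codon substitutions; non-synonymous changes scored **conserved**
   (BLOSUM30 ≥ 0) or **unconserved** (BLOSUM30 < 0, or any shift to a stop
   codon); indels classified **frameshift** (net coding-length change not a
   multiple of 3) or **amino acid indel**; **impacted protein domains**
   (Pfam intervals overlapping the affected amino-acid range, extended to
   the protein end for frameshifts); and the full **predicted mutant
   protein**, translated from the mutant spliced CDS and truncated at the
   first stop (with `start_lost` / `stop_lost` notes where applicable).

Flanking sequence around each variant is reported for assay design.

## Coordinates

All positions are **0-space-based** in the local frame of the region of
interest: an interval `(b, e)` covers residues `b+1 .. e` of the region, and
`b == e` is an insertion point *between* residues — which makes indel
description uniform. An insertion point sitting exactly on a feature
boundary attaches to the features on both sides, and both classifications
are reported. The reference-allele length is `end − begin`, so variant type
is inferred by comparing it with the assayed-allele length: equal → (block)
substitution, longer allele → insertion, shorter → deletion.

## Inputs

1. **Reference FASTA** — the region of interest (first record used).
2. **Annotation TSV** — all features in local 0-space coordinates, one row
   per feature, seven columns:

   ```
   feature_type  feature_id  parent_id  begin  end  strand  attributes
   ```

   `feature_type` ∈ `gene`, `transcript`, `exon`, `cds` (one genomic
   translation-start/stop span per transcript), `domain` (begin/end are
   1-based inclusive *amino-acid* coordinates, `attributes` carries
   `name=<Pfam id>`), `repeat` (`name=` attribute), `known_variant`
   (`feature_id` is the dbSNP id). Example:

   ```
   feature_type	feature_id	parent_id	begin	end	strand	attributes
   gene	gX		0	100	+	
   transcript	tX	gX	0	100	+	
   exon		tX	0	40	+	
   exon		tX	60	100	+	
   cds		tX	10	90	+	
   domain		tX	2	10		name=PF00001
   repeat			5	25		name=AluY
   known_variant	rs42		15	16		
   ```

   `gff3ToAnnotation()` (or `inst/scripts/annotation_adapter.R`) generates
   this file from standard GFF3 (+ optional BED repeats / known variants),
   projecting genomic coordinates into the local frame.
3. **Variants TSV** — `variant_id  begin  end  orientation  allele`
   (header optional; allele `-` or empty = pure deletion; a `-` orientation
   means the allele is given on the minus strand and is
   reverse-complemented internally; coordinates are always plus-strand).

## Outputs

* `<prefix>.normalized.txt` — one block per variant, each fact indented
  with exactly as many tabs as its hierarchy depth, so a spreadsheet shows
  equal classification levels at equal indentation.
* `<prefix>.denormalized.tsv` — one line per (variant × gene × transcript)
  branch for line-based parsers; 24 fixed columns
  (`variant_id, begin, end, variant_type, known_ids, repeat_names, gene_id,
  transcript_id, gene_context, distance_to_exon, transcript_region,
  splice_site, exon_region, impacted_domains, cds_position, aa_position,
  ref_codon, alt_codon, ref_aa, alt_aa, substitution_class,
  conservation_class, indel_class, predicted_protein`) plus `left_flank`
  and `right_flank` unless `--no-flanks` is given. Both outputs carry the
  same information.

## Worked example

The package ships a deterministic fixture generator, so the example is
fully self-contained:

```r
library(VariantHierarchy)

fx <- generateFixture(fixtureSpec(seed = 1))   # annotated toy region
writeFixture(fx, "demo")                       # demo/region.fa, demo/annotation.tsv
panel <- generateVariantPanel(fx)              # one variant per tree leaf
sel <- panel[panel$variant_id %in%
             c("promoter_500", "donor_10", "cds_stop_gain"), ]
writeVariantsTsv(
  lapply(seq_len(nrow(sel)), function(i)
    queryVariant(sel$variant_id[i], sel$begin[i], sel$end[i], "+",
                 sel$allele[i])),
  "demo/variants.tsv")

runClassifier(c("--fasta", "demo/region.fa",
                "--annotation", "demo/annotation.tsv",
                "--variants", "demo/variants.tsv",
                "--out-prefix", "demo/out", "--flank-len", "10"))
```

`demo/out.normalized.txt` then contains (tabs shown as indentation):

```
variant_id	begin	end	variant_type	plus_allele	left_flank	right_flank
promoter_500	1200	1201	substitution	C	CTTGCGTGTA	TGTACGGCTC
	gene	g1
		transcript	t1
			upstream_promoter	distance=499
donor_10	1779	1780	substitution	A	CCGATCAGGC	AATTTTCGTT
	gene	g1
		transcript	t1
			intronic	distance=9
				five_prime_splice_site
cds_stop_gain	1739	1740	substitution	T	AAGGTCCAGG	AGAGTAACTG
	gene	g1
		transcript	t1
			exonic
				CDS
					cds_position	16
					aa_position	6
					codon_change	CAG/TAG
					amino_acid_change	Q/*
					substitution_class	nonsynonymous
					conservation_class	unconserved
					predicted_protein	MARSR
```

Reading it: the first SNP sits 499 gap bases (the 500th base) upstream of
`t1`'s first exon, inside the 1,000-base promoter window; the second is the
10th intronic base after an exon — the last base still inside the donor
splice-site window; the third changes codon 6 (`CAG` → `TAG`), a
glutamine-to-stop gain — non-synonymous, unconserved by the stop rule — and
the predicted mutant protein `MARSR` is the reference protein truncated
after five residues. The same facts appear flat, one line per transcript
branch, in `demo/out.denormalized.tsv`.

Interactively, `classifyVariant()` returns a `ClassificationTree` S4 object
whose `show()` method prints the same hierarchy, and accessors
(`labelSet()`, `geneBranches()`, `knownIds()`, …) expose it
programmatically.

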