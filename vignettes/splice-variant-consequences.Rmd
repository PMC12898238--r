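---
title: "Splice-acceptor variant consequences: models, conventions and limits"
author: "splicecase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-acceptor variant consequences: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecase)
```

## The problem

A single-nucleotide substitution at the −2 position of a splice acceptor
destroys the intron-terminal AG that the U2 spliceosome requires. In a
haploinsufficient tumor-suppressor gene such as *NF1* (58 exons, autosomal
dominant inheritance), the consequence of one such allele can be a whole
disease. Yet the interesting biology is mostly *secondary*: where does
splicing move, what happens to the reading frame, is the transcript
degraded, can the allele be corrected? Standard splice predictors score the
primary event but stop there. `splicecase` implements the downstream
arithmetic as a small, fully tested pipeline operating on desk-scale
sequence slices.

The pipeline has four stages, run individually or through `run_case()`:

1. **Variant resolution** — HGVS c. parsing against an exon/CDS model, and
   classification against splice-site registers (acceptor −1/−2, donor
   +1/+2, exonic, deep intronic).
2. **Primary splicing effect** — the cryptic-acceptor scan.
3. **Secondary consequences** — transcript reconstruction, frame/PTC
   analysis, NMD prediction, truncated-peptide properties, CpG deltas and
   per-read methylation aggregation.
4. **Editing-tool selection** — base-editor placement with bystander-edit
   hazards, simplified prime-editing design, and strategy ranking.

## The cryptic-acceptor model

When the canonical AG of intron *i* is disrupted, the model activates the
**nearest downstream exonic AG**: the new exon begins immediately after the
chosen AG, so `deletion_length` equals the exonic position of the AG's
second base. This "next available AG" rule is deliberate minimalism; no
branch-point or polypyrimidine strength scoring is attempted (such scoring
belongs to dedicated splice-strength models, which are out of scope). Two
distance conventions circulate for the same event and are both reported to
prevent off-by-two confusion:

* `deletion_length` — exonic bases removed (16 in the worked *NF1*-like
  example);
* `distance_from_variant` — inclusive base count from the acceptor−2
  variant to the AG's second base (18 in the same example: 2 intronic + 16
  exonic bases).

A cryptic AG whose second base would sit at exonic position 1 cannot exist
after an acceptor−2 substitution: the AG's first base would have to be the
intron's −1 base, which the canonical acceptor fixes as G. Offsets
therefore start at 2, and `scan_cryptic_acceptor()` scans fully exonic
dinucleotides only. An optional `include_upstream` flag additionally
reports the nearest upstream *intronic* AG (a partial intron-retention
acceptor), clearly labeled as such.

The scan window defaults to 100 exonic nucleotides (`max_scan_nt`); an
exon without an AG in the window is a valid `found = FALSE` result, not an
error.

## Reading-frame analysis

`analyze_frame()` compares the mutant CDS (start codon to transcript 3'
end, since a frameshift forfeits the annotated stop) against the wild-type
CDS:

* `frame_offset = deletion_length mod 3`; a non-zero offset is a
  frameshift.
* `novel_aa_count` — residues after the last wild-type-identical residue
  and before the first stop, computed on the peptides (a residue-wise
  common prefix), so a chance silent codon at the junction is counted as
  wild-type, not novel.
* `ptc_cds_pos` — the first base of the mutant stop codon in mutant CDS
  coordinates; it is reported as a PTC only when its wild-type-equivalent
  position (`ptc_cds_pos + deletion_length`) precedes the wild-type stop.
* `wildtype_exon_aa_lost_after_ptc` — whole wild-type amino-acid codons of
  the affected exon lying strictly downstream of the PTC's wild-coordinate
  footprint (`ptc_cds_pos + 2 + deletion_length`). Whether a published
  truncation count includes the junction codon is usually unstated; this
  package counts whole codons of the affected exon only, and documents
  that choice here rather than guessing.
* A per-frame stop map of the mutant CDS is emitted for figure-style
  reporting of all three frames.

In-frame deletions (offset 0) report `novel_aa_count = 0` and the number
of residues deleted instead.

## NMD prediction

The classic exon-junction rule with the literature's 55-nt threshold
(configurable): a PTC at least 55 nt upstream of the **last** exon–exon
junction of the *mutant* transcript is NMD-positive; PTCs in the last exon
and single-exon transcripts are NMD-negative. Distance is measured from
the first base of the stop codon in mutant mRNA coordinates. The rule is a
well-supported heuristic, not a degradation-rate model; `rule_detail`
records the measured distance so borderline calls are auditable.

## Peptide mass

Average (not monoisotopic) residue masses with one water, reported in kDa,
matching how truncated-protein sizes are quoted in the clinical
literature. The empty peptide returns the mass of water. The residue table
is pinned in the package source.

## CpG deltas and methylation

An SNV can only change the two dinucleotides overlapping its position, so
`cpg_delta()` inspects exactly those, before and after substitution, on
the plus strand (CpG is strand-symmetric). Created/destroyed sites are
reported as the genomic position of the cytosine. Per-read methylation
calls are consumed as a table of binary calls (`methylation_fraction()`
counts distinct reads and rejects duplicates); calling 5mC from raw
signal is out of scope. `homopolymer_runs()` reports maximal single-base
runs (the poly-T acceptor context); general repeat annotation is not
attempted.

## Editing feasibility

### Windows and chemistry

A `NucleaseSpec` carries an IUPAC PAM/TAM motif, which side of the
protospacer it binds, the spacer length, the editing window and the
chemistry (CBE: C→T, ABE: A→G, on the protospacer strand). **Window
positions are counted from the protospacer 5' end** — PAM-proximal for
Cas12a, PAM-distal for SpCas9 — which is how editor windows are quoted in
the base-editing literature. The shipped defaults are a Cas12a CBE (TTTV,
spacer 23, window 8–14) and SpCas9 CBE/ABE (NGG, spacer 20, window 4–8);
they are a documented catalog choice, versioned in
`inst/extdata/nuclease_catalog.json`, and every scan records the catalog's
MD5 in the report provenance so results are reproducible against a stated
catalog.

`scan_editor_sites()` matches motifs on both strands within ±20 bases of
the target (the flank is configurable) and keeps a placement only when
(a) the therapeutic correction — alt back to ref, e.g. G>A on the plus
strand, which is C>T for a minus-strand CBE — matches the chemistry on
the protospacer strand, and (b) the target sits inside the editing
window. PAMs are reported in plus-strand orientation (a minus-strand TTTV
prints as BAAA), alongside both the window position of the target and its
distance to the nearest PAM base, again to keep the two circulating
distance conventions explicit.

### Bystanders

Every same-chemistry base inside the window other than the target is an
unavoidable co-edit. Bystanders are classified against a local
pathogenic-variant table (exact contig/pos/ref/alt match; no live
database queries, for determinism); any pathogenic match makes the
placement *hazardous*. `rank_strategies()` then orders clean base editors
first, prime editors second, hazardous base editors last — reproducing,
as a rule outcome, the clinical logic that prime editing is the only
viable route when the acceptor's neighboring guanine is itself a
pathogenic G>A site.

### Prime editing

`design_prime_edit()` is deliberately simplified: all NGG placements on
either strand whose nick (between protospacer positions 17/18, 3 nt from
the PAM) lies within `max_nick_to_edit` (default 30) nt 5' of the target,
with fixed PBS length (13) and an RT template covering nick-to-edit + the
edited base + a 10-nt 3' homology arm. Replicating a full pegRNA scorer
(secondary structure, efficiency models) is a non-goal; candidates are
ordered by nick-to-edit distance only.

## Expression statistics

* `expression_zscore()` — z = (value − mean)/sd against a control cohort,
  two-tailed p from the standard normal. Published figures sometimes give
  an empirical-looking percentile alongside normal-theory Z/p; both
  percentiles are computed and labeled (`percentile_empirical` requires
  raw controls) and neither is asserted to be "the" method.
* `low_expression_filter()` — a gene is dropped when *strictly more than*
  90% of samples are at or below TPM 1; the boundary gene (exactly 90%)
  is retained, matching the rule's wording. TPM matrices are assumed
  pre-normalized; batch correction is out of scope.
* `ddct()` — replicates averaged per (sample, gene); ΔCt = target −
  reference; ΔΔCt against the calibrator; relative expression `2^-ΔΔCt`
  with the calibrator at exactly 1, percent change, and a replicate
  standard error propagated in quadrature through both ΔCt terms and onto
  the linear scale.
* `group_compare()` — textbook pooled-variance Student's t (two groups)
  or one-way ANOVA from sums of squares (more), with Bonferroni-adjusted
  pairwise post hoc tests; the published pedigree analysis names "post
  hoc tests" without specifying one, so the conservative default is used
  and documented.

## What the synthetic generators emulate

`make_splice_case()` builds a multi-exon gene with canonical GT–AG
introns, a pyrimidine tract and a 20-bp poly-T run upstream of the first
acceptor, and an acceptor−2 A>G variant whose consequences are *planted*:
the first exonic AG at a chosen offset, a shifted frame meeting its first
stop after exactly `novel_aa` codons, and `truncation_aa` whole wild-type
codons beyond the stop's footprint. Filler regions use a stop-free,
T-free codon alphabet (no stop codon can arise in any frame without a T),
which is what makes exact stop placement possible; accidental AG or PAM
motifs inside scanned windows are excluded by construction (pyrimidine
prefixes, A/T backgrounds with no AAA runs) plus a deterministic patch
pass. `make_editing_case()` plants one minus-strand Cas12a TAM with a
chosen target window position and bystander count. Cohort, Ct and
methylation generators plant Gaussian TPM cohorts, a known fold change
and exact read counts.

Every generator is deterministic under its seed and leaves the caller's
RNG stream untouched. What passing round-trip tests show is that the
*engines invert the generators exactly* under these idealized conditions;
they do not show robustness to real-genome complications — degenerate
splice signals, competing cryptic sites of similar strength, repeat-rich
contexts, mapping artifacts — which the generators intentionally do not
model.

`nf1_case()` deserves a special note: it is a **synthetic
reconstruction** of the published *NF1* c.61-2A>G locus geometry at its
real GRCh38 coordinates (variant at chr17:31,155,981, exon 2 at
31,155,983, the CpG-forming cytosine at 31,155,980, the 20-bp poly-T, the
16-nt cryptic offset, the BAAA TAM nine bases downstream, the pathogenic
neighboring guanine). It is not GRCh38 sequence; everything outside the
planted features is filler. It exists so the worked example and the
acceptance checks run without any reference download.

## Numerical and degenerate-input choices

* qPCR noise in `make_ct_table()` is Gaussian per Ct *measurement* (every
  well of every gene and sample), the standard model of replicate
  scatter; with triplicates the ΔΔCt standard deviation is 2σ/√3.
* Coordinates are 1-based inclusive at every interface; any half-open
  arithmetic is internal. Minus-strand models store plus-strand
  coordinates and emit reverse-complemented transcripts; HGVS alleles are
  transcript-strand, `Variant` alleles plus-strand.
* Problem sizes in the shipped tests: 200 planted splice cases (offsets
  2–60), 100 planted editing cases, 1000 random 60-nt motif windows
  against a k-mer-expansion oracle, 1000 simulated Ct tables — sizes
  chosen to exercise every offset/window register while keeping the suite
  quick on one CPU.
* Degenerate inputs fail loudly and early: indels are rejected at
  `variant()`, a deletion consuming its whole exon at reconstruction,
  zero control SD and zero-variance group comparisons at the statistics
  layer, duplicate (read, site) methylation calls at aggregation.

## Known limitations

* Acceptor variants only drive the cryptic scan (donor variants are
  classified but not rescanned); single-variant analyses, SNVs only.
* Nearest-AG is a model, not a predictor: a real spliceosome may choose a
  weaker, farther acceptor or skip the exon entirely. The package reports
  what the model implies, with the conventions stated above.
* The nuclease catalog is a snapshot; editing windows differ between
  engineered editor variants, and users with different editors should
  ship their own catalog file.
* The 55-nt NMD rule has documented exceptions (long 3' UTRs,
  start-proximal PTCs); `rule_detail` exposes the distance so such cases
  can be flagged downstream.
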