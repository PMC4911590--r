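---
title: "Methods: genome-wide characterization of a two-domain kinase family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide characterization of a two-domain kinase family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cipkfam)
```

# Scope and model

`cipkfam` re-implements, as reusable and tested components, the standard
analysis chain used to characterize a plant gene family defined by domain
co-occurrence — here the CBL-interacting protein kinases (CIPKs), whose
members carry an N-terminal serine/threonine kinase domain and a C-terminal
NAF domain (the module through which calcineurin B-like calcium sensors
activate the kinase). The chain is:

1. **Family identification.** A protein is a member iff it has at least one
   retained hit for *every* required domain label (default `NAF` +
   `Pkinase`). Real `hmmscan` per-domain tables can be ingested; for
   self-contained work a PSSM scanner over two fixed 20-mer consensus
   motifs stands in for the profile-HMM search. The stand-in is not a Pfam
   model and is not meant to detect real NAF domains; it preserves exactly
   the co-occurrence logic that defines membership.
2. **Protein statistics.** Molecular weight is the sum of average residue
   masses plus one water; the isoelectric point is the unique root of the
   Henderson–Hasselbalch net charge, found by bisection on pH ∈ [0, 14] to
   1e-4, with a Bjellqvist-style pKa set (N-term 7.5, C-term 3.55, D 4.05,
   E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0). Net charge is strictly
   decreasing in pH, so the root is unique and bisection cannot miss it.
   `X` residues take the mean residue mass for MW and carry no charge.
3. **Gene structure.** Exon counts come from the exon features of the
   representative transcript (the mRNA with the longest total CDS);
   introns = exons − 1. Genes with fewer than 3 introns form the
   intron-poor clade and genes with more than 8 the intron-rich clade —
   the thresholds used throughout the CIPK literature. Counts of 3–8 get
   an explicit `intermediate` label so that classification partitions all
   of ℕ; no soybean CIPK gene falls there, but arbitrary inputs may.
4. **Phylogeny.** Distances between aligned proteins are proportions of
   differing residues with *pairwise deletion* (sites gapped in either row
   are dropped per pair), optionally Poisson-corrected, d = −ln(1 − p).
   Trees are built by canonical Saitou–Nei neighbor joining. Bootstrap
   resamples alignment columns with replacement, rebuilds distances and
   tree per replicate, and maps the percentage of replicates containing
   each bipartition onto the internal edges of the *original* tree (the
   behavior of the mainstream desktop tools), not onto a consensus tree.
5. **Duplication.** Tandem arrays: two or more family genes on one
   chromosome linked when the gap (end of the upstream gene to start of
   the downstream one) is below 100 kb and, when a full annotation is
   supplied, at most five non-family genes lie strictly between them.
   Segmental duplications are read off an externally provided table of
   paired duplicated blocks; a gene counts as "in a duplicated block" when
   its span is contained in either side, whether or not a family partner
   sits on the mate side — this matches the gene-wise bookkeeping used in
   published family surveys.
6. **Expression.** Microarray drought responses per developmental stage
   are classified by the sign of the log2(drought/control) ratio
   (threshold 0 by default, since published up/down tallies state no
   cutoff). qRT-PCR quantification follows 2^−ΔΔCt: per biological
   replicate ΔCt = Ct_target − Ct_reference within the same sample;
   ΔΔCt = ΔCt_treated − mean(ΔCt_control); the reported fold is the
   arithmetic mean of per-replicate folds with SE = sd/√n.

# Design choices where the procedure was open

* **Gap measurement for tandem arrays.** "Separated by less than a 100-kb
  region" is ambiguous; we measure end-of-upstream to start-of-downstream.
  On the packaged 52-gene soybean catalog this choice reproduces exactly
  the six published tandem pairs and no extras.
* **NJ tie-breaking.** When several pairs minimize the Q criterion, the
  lowest index pair after lexicographic ordering of ids is joined. This
  makes the tree a pure function of the distance matrix, invariant to
  input row order. Negative branch lengths are clamped to zero (a common
  convention); the cumulative clamped deficit is retained as an attribute
  so it is never silently lost.
* **Statistical test for ΔΔCt.** The two-sample test compares treated and
  control ΔCt values — the log2 scale, where replicate variation is
  approximately Gaussian and variance-stabilized — rather than the folds
  themselves. Student's equal-variance t is the default; Welch is an
  option. The ΔΔCt baseline averages the control replicates (per-replicate
  pairing of treated vs control replicates is not assumed).
* **Stress contrast.** Fold changes compare drought to the watered control
  collected at the same timepoint; at day 0 the two coincide, so day-0
  folds are 1 by construction. Comparing each timepoint to day 0 instead
  is possible by relabelling the condition column.
* **E-value threshold.** For real hmmscan tables the default per-domain
  cutoff is E ≤ 1e-5 (configurable); PSSM hits are thresholded on score
  (half the maximum attainable score by default) and carry `NA` E-values.

# The synthetic-data generator

`generate_family()` and `generate_expression()` produce fixtures with a
YAML truth record so every downstream stage can be checked against planted
ground truth without genome or GEO downloads.

The family generator's defaults mirror the published soybean study design:
52 members whose planted intron counts are the catalog's own per-gene
counts (35 intron-poor, 17 intron-rich), 20 chromosomes, six tandem
clusters of two genes with intergenic gaps drawn below 70 kb, and
segmental pairs placed on distinct chromosomes inside paired 50-kb-margin
blocks. Eleven segmental pairs are planted by default — a scaled-down
stand-in for block assignments that, in the real analysis, depend entirely
on an external synteny resource and are therefore a property of that
input, not of this code. Member proteins descend from
`n_seed_groups` (default 4) independent ancestral sequences by recursive
bifurcation with per-branch mutation of non-motif positions (rate 0.04 per
position per branch), so each seed group forms a resolvable clade with
internal structure rather than an unresolved star; all intron-poor members
descend from the last group, mirroring the intron-poor subgroup of the
real family. Both domain motifs are planted into every member (mutated at
`motif_mutation_rate`, default 0.05), and single-domain decoys carry
exactly one. All proteins share one length (default 420 aa), so the
emitted FASTA is column-aligned as written and can feed the phylogeny
stage directly.

The expression generator plants a two-stage microarray pattern whose
defaults reproduce the published overlap structure over 48 probed genes
(20 up/28 down at the vegetative stage, 33 up/15 down at the reproductive
stage; 18 consistently up, 13 consistently down, 17 opposite), and a Ct
table with a reference-gene baseline of 20 cycles, per-gene target
baselines of 22–29 cycles, three biological replicates, and independent
Gaussian noise (default SD 0.3 cycles, a typical replicate SD) on every Ct
measurement. For cells with a nonzero planted effect the drought Ct shift
is calibrated by the lognormal-mean term ln(2)/2 · Var(ΔΔCt) so that the
*expectation* of the recovered fold (arithmetic mean of per-replicate
2^−ΔΔCt) equals the planted fold; unaffected cells get no shift at all and
remain an exact null for the replicate t-test.

What the generator does **not** emulate: insertions/deletions and
alignment uncertainty (member sequences are gap-free and equal-length),
realistic substitution processes (mutations are uniform over residues, so
the fixtures cannot support dN/dS-style analyses), probe-level microarray
noise and normalization, and technical qPCR replicates (only biological
replicates are drawn). Passing the planted-truth tests therefore
demonstrates the correctness of the bookkeeping and statistics on clean
inputs, not robustness to alignment error or platform artifacts.

# Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive everywhere (GFF3 convention); BED
  export shifts to 0-based half-open. Reversed coordinate pairs are
  normalized with a warning — the packaged soybean catalog itself contains
  one reversed span and one zero-width span as printed, which
  `validate_catalog()` flags without guessing the intended values.
* A pair of alignment rows with no ungapped site in common has an
  undefined distance and is an error; during bootstrap such a replicate is
  redrawn (up to 10 times) rather than silently patched. A p-distance of
  1 cannot be Poisson-corrected (saturation) and errors likewise.
* Fewer than two replicates in a ΔΔCt cell yields no p-value and is
  flagged rather than dropped.
* All stochastic steps (generator, bootstrap) take explicit integer seeds;
  a fixed seed gives byte-identical fixture files and identical report
  bundles.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale: the 52-row
packaged catalog for all count reproductions; synthetic families of 4–52
members; NJ-vs-least-squares brute force on additive matrices of up to 7
taxa (all 945 topologies enumerated, with branch lengths fit by ordinary
least squares on the path–edge incidence); 200-replicate bootstrap replay
on 5–6 taxa; 200 Monte-Carlo seeds for noisy fold recovery; and 1000
simulated null tables for the size of the replicate t-test. These sizes
make every check exact or tightly bounded while keeping a full run in the
order of a minute.

# Known limitations

* The PSSM scanner reports one maximal-scoring window per motif; proteins
  with duplicated domains are still counted once per label, which is all
  the membership rule needs.
* `assign_subgroups()` labels each unanchored leaf from the smallest
  bipartition side containing it and anchors of exactly one subgroup. On
  trees where a group is an unresolved star, the attachment point of a
  neighboring clade is noise-driven and single leaves can be captured by
  the wrong anchor; the generator's hierarchical within-group structure
  avoids this regime, but real families with very low divergence may not.
* Published block-level counts (e.g. how many genes fall into how many
  duplicated blocks) are properties of the external synteny table supplied
  as input; the package reproduces them only when that table is provided.
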