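---
title: "Methods: shell-gene classification, locus assembly and co-regulation in ccmshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shell-gene classification, locus assembly and co-regulation in ccmshell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmshell)
```

## The problem

β-cyanobacteria fix CO₂ inside β-carboxysomes, icosahedral protein
organelles whose shells are tiled by hexameric BMC-H proteins (the CcmK
paralog family), trimeric BMC-T proteins (CcmO, CcmP) and pentameric
BMC-P vertices (CcmL). The genes are split between one *main carboxysome
locus* (MCL) — the operon-like unit `ccmK2 [ccmK1] ccmL ccmM ccmN
[ccmO]` — and a variable set of *satellite loci* elsewhere in the
genome. Three questions drive the toolchain in this package:

1. Which CcmK class does each shell protein belong to (CcmK1–6, CcmO,
   outgroups)?
2. How are shell genes organized into loci, and where does `ccmO` sit —
   terminal in the MCL or relocated to a satellite locus?
3. Do satellite shell genes escape the transcriptional co-regulation of
   the MCL?

The statistical layer quantifies class co-occurrence across a genome
cohort (observed/expected ratios with χ² tests) and co-regulation
(mean pairwise Pearson correlation with MCL genes).

## Profile classification

Each class is represented by a position-specific scoring profile built
from a seed alignment (`build_profile()`). Columns with more than 50%
gaps are treated as insert columns and discarded. Emission log-odds are

$$ s_j(a) = \log_2 \frac{(c_{j,a} + \alpha)/(n_j + 20\alpha)}{q_a} $$

with Laplace pseudocount α = 1 and background *q* estimated from the
pooled seed residues. Query sequences are scored by best local alignment
against the match columns under affine gap penalties (open 4 bits,
extend 0.5 bits) and assigned to the arg-max class
(`assign_class()`).

Design choices, and why:

* **Bit scores instead of e-values.** The reference workflow ranks
  profile-HMM hits by e-value; e-value calibration depends on database
  size and an extreme-value fit that is under-determined at desk scale.
  The raw local-alignment bit score is monotone in −log e-value at fixed
  database size, so the arg-max class is identical.
* **Match states only.** Single-domain ~100-aa families separated by
  large between-class divergence do not need insert-state emission
  modelling; affine gap penalties absorb length variation.
* **Normalisation.** `normalized_score` is bits per profile match
  column. Normalising by the columns of the best local path would let a
  short spurious 2-column hit on an unrelated sequence report a high
  per-column rate; per-profile-column rates make unrelated sequences
  score near 0 (empirically ≤ 0.5 bits/column for background draws).
* **Ties and ambiguity.** Ties break alphabetically (deterministic);
  margins under 1 bit are flagged `ambiguous`. A sequence at the local
  floor (0 bits) on every profile is `Unclassified`.
* **CcmK1 vs CcmK2** cannot be separated by profile (they form one
  mixed superclass) and are split purely by residue length: 100–107 aa
  → CcmK2, 108–118 aa → CcmK1 (the CcmK1 C-terminal extension).
  Lengths outside 100–118 are flagged rather than forced.
* **CcmK5/CcmK6 and their starred subclasses** were originally defined
  by tree inspection, not by profile scoring. They are supported as
  ordinary profiles whenever seed alignments are supplied (the synthetic
  generator ships archetypes for both); no quantitative rule for the
  starred subclasses is invented.

## Locus assembly

Coordinates are ordinal gene indices (0-based per replicon), not base
pairs: every published distance rule is in gene units ("10 open reading
frames"). `ordinals_from_positions()` converts GFF-like start
coordinates when needed. Replicons are treated as linear — circularity
is a documented limitation — and strand is read but ignored (no strand
rule exists).

Two gap rules, both counted in *intervening non-carboxysome genes*
(ordinal difference − 1):

* genes within `satellite_distance = 10` of another carboxysome gene
  belong to the same locus region (a satellite is a gene with *no*
  other carboxysome gene within 10 ORFs); the boundary is inclusive —
  exactly 10 intervening genes still links — and exposed as a config
  flag because the prose is ambiguous at exactly 10;
* inside a region, the maximal run with gaps ≤ `max_insert = 1` forms
  the locus *core* used for the signature: single non-carboxysome
  insertions do not interrupt the MCL. The grammatically ambiguous
  source rule is read as *tolerating* single insertions (settable to 0),
  because real MCLs do contain them.

Genes at gaps 2–10 join the region but stay outside the core and are
flagged `loosely_associated`; this preserves both printed rules without
inventing a third threshold. RubisCO genes (`rbcL`/`rbcS`) can flank the
MCL but never define a locus, so they are excluded from the
carboxysome label set.

The MCL is the unique locus whose core has ≥ 1 `ccmK1/2` gene and all
of `ccmL`, `ccmM`, `ccmN` (`ccmK2/L/M/N` is the minimum genetic unit).
Two candidates raise an integrity error; zero flags the genome non-β.
Atypical gene orders (a K gene downstream of L/M/N, or non-terminal
`ccmO`) warn rather than error, because rare real genomes have them.

## Co-occurrence statistics

From a binary genome × class presence matrix: coverage `n_c` and
percent (rounded half away from zero, 1 dp), expected co-occurrence
`E = n_a n_b / N` under independence, ratio `O/E` (2 dp, half away from
zero — this rounding convention reproduces published tables as
printed), and a Pearson χ² (df = 1) on the 2×2 presence table. No Yates
correction by default (exposed as a flag). Classes at 0% or 100%
coverage have a degenerate margin: the χ² is reported NA while the
ratio is still defined (1.00 for a full-coverage class).

## Co-regulation with the MCL

Expression matrices (genes × ≥ 3 conditions) are linearized first
(`2^x` for log2 data), then pairwise Pearson correlations are computed.
For focal `ccmO`, the partner set is the MCL ccmKs plus `ccmL`, `ccmM`,
`ccmN` — never `ccmO` itself. For focal `ccmK1/2` and `ccmK3/4` the
partner set is "the remaining MCL genes", read as excluding the focal
genes themselves (flag `exclude_focal_pairs`), and always excluding
RubisCO genes. Values are averaged over partners per focal gene, then
over focal genes; group means over datasets are rounded half away from
zero to 2 dp. Datasets from the same species stay separate;
species-level averaging is a reporting option only. One published
aggregate labelled a "mean across four species" actually equals the
dataset-level mean over the six MCL-ccmO datasets; the dataset-level
mean is what `aggregate_groups()` computes, and the discrepancy is
documented here rather than resolved.

## What the synthetic generator emulates — and what it does not

`generate_genomes()` draws each genome as one linear replicon of
140–180 genes carrying one MCL, a `ccmP` satellite, and optional
satellites, with defaults fixed to the empirical 227-genome class
frequencies: K3/K4 pair 206/227 (drawn as a *single* Bernoulli event —
the pair strictly co-occurs), K5 marginal 10/227 drawn only in genomes
lacking K3/4 (exclusion exact, not probabilistic), K6 25/227,
satellite `ccmO` 89/227. MCL ccmK copy number is 1/2/3 with weights
5/192/30 of 227 (five genomes lack `ccmK1`; the 3-copy share is a
package choice, stated once here). Loci are separated by more than
`satellite_distance` filler genes via exact slack allocation, so
placement never needs rejection loops and is fully seeded.

`generate_sequences()` draws from deterministic, mutually unrelated
class archetypes (uniform residue composition; BMC-H ~100 aa, BMC-T
~215 aa) with point mutations at a configurable rate, and
`generate_seed_alignments()` emulates curated seed sets (12 homologs at
5% divergence; reference seed sets held 7–29). This gives the
*between-class* signal the classifier needs, but **no phylogeny**: there
is no tree-structured mutation process, no rate heterogeneity, no
within-class subfamily structure. A green classifier-recovery test
therefore establishes that scoring and arg-max assignment work, not
that real CcmK5* -like subclasses would be resolved.

`generate_expression()` uses a Gaussian single-factor model:
`x_g = 10 + sqrt(ρ_g) f + sqrt(1 − ρ_g) ε_g`, so two genes with
loadings ρ_a, ρ_b correlate at `sqrt(ρ_a ρ_b)`. MCL genes share
ρ = 0.8 (matching the observed ~0.79 ccmK1/2 co-regulation), satellite
`ccmO` loads 0, and ccmK3/K4/ccmP load 0.22 so their correlation with
the MCL is ~0.42, the observed moderate value. Real transcriptomes are
counts with mean–variance coupling and condition structure; none of
that is modelled, so expression tests establish the estimator, not
distributional robustness. The log2 output option writes
`log2(x + 1)` (shift 1 avoids log 0); correlations are invariant to the
implied affine map after linearization.

## Numerical conventions and degenerate inputs

* Rounding for reported tables is half away from zero
  (`round_half_away()`), not banker's rounding.
* QC: sequences with *strictly* more than 20% `X` are dropped; exactly
  20% is kept.
* Identity denominators exclude gap–gap and gap–residue positions
  (common convention; the delegated tool never stated one).
* Redundancy filtering is greedy in input order (matching interactive
  tool behaviour); non-transitive chains mean the result is not a
  clique — documented, deterministic.
* Neighbor joining is delegated to `ape::nj()` behind validation;
  negative branch lengths are clamped to 0 with a warning. p-distances
  do not guarantee additivity, so monophyly checks on real-like data are
  heuristics.
* Information content is relative entropy against a background with
  α = 1 pseudocount; exact logo-server conventions (whose scale bars can
  exceed log₂ 20) are out of scope.
* All CLI outputs embed a config hash and the seed; fixed-seed runs are
  byte-identical.

## Known limitations

External-tool stages of the original workflow — MAFFT alignment, TrimAL
trimming, PhyML maximum-likelihood trees, BLASTP homolog retrieval,
structure-based conservation and electrostatics — are out of scope;
their desk-scale surrogates (gap-fraction trimming, p-distance NJ) are
deliberately simpler and should not be used for publication-grade
phylogenetics. Cohort-scale headline numbers (138 vs 89 ccmO positions,
2.5 mean satellites) require the real 227-genome dataset; the package
demonstrates recovery of the *generating parameters* from synthetic
cohorts instead.
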