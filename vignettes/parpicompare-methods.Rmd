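---
title: "Methods: genomic scars, enrichment surrogacy, and biomarker comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic scars, enrichment surrogacy, and biomarker comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parpicompare)
```

# The problem and the modelling idea

PARP inhibitors exploit synthetic lethality with defective homologous
recombination: a cell that cannot repair double-strand breaks accurately
dies when its backup single-strand repair (PARP1/PARP2) is also blocked.
In breast, ovarian, prostate and pancreatic cancer the approved patient
selection markers are *BRCA* alterations and genomic-scar HRD scores. In
colorectal cancer *BRCA* mutations are rare, and which marker should
select patients is unsettled.

Absent trial data, a retrospective comparison can use transcriptional
*surrogacy*: a gene set assembled from PARPi-perturbation experiments
(genes that move when cell lines are treated with olaparib, rucaparib,
veliparib or talazoparib) should be enriched in the expression profiles
of the patient subset that a good biomarker labels as drug-favorable.
Each candidate biomarker therefore becomes a two-class phenotype, its
enrichment score (ES) against the compiled PARPi response set becomes
its effect size, and candidates are compared through those effect sizes.
This package implements the three layers of that design:

1. scar scores and phenotype construction from copy-number segments;
2. a self-contained GSEA (ranking, ES, permutation inference);
3. two comparative statistics between biomarkers — a Fisher-z
   differential-ES test and the gene set enrichment fraction (GSEF)
   signed-rank comparison.

# Genomic scar scores

All scores consume a `segment_profile`: one sample's non-overlapping
copy-number segments (1-based inclusive coordinates; lengths are
`end − start + 1`) on a genome build. The packaged hg19 table supplies
chromosome lengths and centromere intervals; the p arm is
`[1, cen_start]`, the q arm `[cen_end + 1, length]`.

**LST** (large-scale state transitions), default parameters
`min_segment_mb = 10`, `smoothing_mb = 3`: per chromosome arm, segments
are clipped to the arm, segments shorter than 3 Mb are removed with
equal-state flanks merged (iterated to a fixed point), and every
remaining breakpoint whose two flanking segments each span ≥ 10 Mb and
differ in copy state is counted. Copy-state equality is exact integer
equality of (major, minor) allele copy numbers when the profile carries
them, otherwise |Δ log2| ≤ 0.1. Because arms are processed separately, a
state change coinciding with the centromere gap is never counted. The
10 Mb / 3 Mb constants are the conventional parameterization of this
score; both are exposed as arguments.

**TAI** (telomeric allelic imbalance), default `min_mb = 11`: runs of
segments with major ≠ minor are merged into regions; a region counts
when it spans ≥ 11 Mb, reaches a telomere, and does not cross the
centromere. Telomere contact is judged against the outermost *assayed*
position of the chromosome, since segment data rarely reach the literal
chromosome ends.

**LOH**, default `min_mb = 15`: merged regions with minor copy number 0
and major ≥ 1, strictly longer than 15 Mb, that do not span their entire
assayed chromosome (whole-chromosome loss is a different lesion class
and excluded by convention).

**HRD** is exactly LST + TAI + LOH and errors when any component is
unavailable — without allele-specific copy number (e.g. no ASCAT-style
calls) TAI and LOH cannot be derived, and the package deliberately
refuses to fabricate them.

**FGA**, default `log2_threshold = 0.2` (the cBioPortal convention): the
length fraction of assayed genome with |log2 ratio| above threshold.
Chromosomes absent from a profile enter neither numerator nor
denominator.

**Aneuploidy**, defaults `arm_fraction = 0.5`, same log2 threshold: the
number of arms on which at least half the assayed length is altered in
one direction (gained or lost, considered separately, so a half-gained
half-lost arm does not count). The conventional 39 autosomal arms are
scored — acrocentric p arms (13p, 14p, 15p, 21p, 22p) and sex
chromosomes excluded by default, both configurable.

**Dichotomization.** Continuous scores become GSEA phenotypes via
`dichotomize_score()` (threshold, "high"/"low") or `median_split()`
(ties to "low"). The LST literature dichotomizes at study-specific
cut-points; no universal constant exists, so the package takes the
threshold as an explicit argument rather than hard-coding one, and the
pipeline log records whatever was used. A split that puts every sample
in one class is flagged degenerate and refused by the phenotype
permutation machinery rather than silently producing a vacuous null.

# Expression normalization

`fractional_rank_normalize()` applies the two-step rank-based inverse
normal transform per gene: average-rank fractional ranks, then
`qnorm(rank / (n + 1))`. The `n + 1` offset keeps quantiles finite for
all ranks; alternatives (e.g. Blom's 3/8 offsets) change values by a
strictly monotone amount and therefore change none of the rank-based
downstream statistics, which is why the simplest offset is the default.
Constant genes map to 0 for every sample. Missing values are rejected
outright — imputation is out of scope and silently propagating NAs
through ranking would corrupt the ES.

# The GSEA core

**Ranking.** Signal-to-noise `s2n = (μ_A − μ_B)/(σ_A + σ_B)` with each
class σ floored at `max(0.2·|μ|, 0.2)`, requiring ≥ 3 samples per class.
Ties in the metric are broken lexicographically by gene id, making the
ranking — and everything conditioned on it, including permutation
inference — fully deterministic.

**Enrichment score.** The running sum increments by
`|s2n|^p / Σ_hits |s2n|^p` at gene-set members and decrements by
`1/(N − N_hit)` elsewhere; ES is the signed maximum deviation. The
default `weight_p = 1` is the standard weighted statistic; `p = 0`
recovers the classic Kolmogorov–Smirnov form. One numerical subtlety is
worth stating: with rational increments the maximal positive and
maximal negative deviations can tie exactly in magnitude. The package
resolves that tie to the positive deviation, using a 1e-9 relative
tolerance so that the choice cannot be flipped by floating-point
accumulation order. The brute-force oracle used in the test suite
applies the identical rule, so implementation and oracle are compared
on mathematics, not on rounding noise.

**Permutation null.** Phenotype permutation shuffles class labels over
samples without stratification and recomputes ranking + ES per shuffle
(preserving inter-gene correlation — the preferred null when class sizes
permit); gene-set permutation keeps the observed ranking and draws
random member sets of the same size. Both are seed-reproducible, and the
caller's RNG state is saved and restored.

**Inference.** With observed `es`, the nominal p value is computed among
same-sign null ES values with an add-one correction,
`p = (r + 1)/(n_same + 1)`, so p is never exactly zero; values below the
permutation resolution print as `"<0.001"` at 1000 permutations.
`NES = es / mean(|same-sign null ES|)`. With a single gene set per run
there is no multi-set FDR family, and the FDR q value equals the nominal
p value by construction; the package runs one compiled set per
phenotype, which is why its result tables show identical p and q
columns. The leading edge is the set members at or before the running
sum extremum for positive ES (at or after it for negative ES).

# Comparative statistics

**Differential ES.** ES behaves like a correlation-type effect size in
[−1, 1], so two independent ES values are compared on the Fisher-z
scale: `z = (atanh(es₁) − atanh(es₂))/√(1/(n₁−3) + 1/(n₂−3))`, two-sided
normal p. The sample sizes are each biomarker's *classifiable* n — the
samples actually carrying a label for that biomarker — which is why the
two n's in a comparison generally differ. p values are BH-adjusted over
the family of comparisons run together (one family per cohort in the
pipeline). An ES of exactly ±1 (every set member outranking every
non-member) has no finite Fisher-z image; the pipeline isolates such a
comparison as a per-pair failure in the run log instead of clamping it
to a made-up value. Note that the standard BH step-up is monotone but
not idempotent; the package makes no idempotence claim.

**GSEF.** For each drug gene module m and biomarker b, the gene set
enrichment fraction is `|m ∩ leading_edge(b)| / |m|`. Two biomarkers are
compared by the Wilcoxon signed-rank test on their paired per-module
fractions: zero differences are dropped (Wilcoxon's original rule), tied
absolute differences receive average ranks, and the two-sided p value is
exact for up to 25 informative pairs — from the full sign-assignment
distribution of the rank sum, computed by convolution so ties are
handled exactly — with a normal approximation (continuity and tie
corrected) above. If all differences are zero the comparison is reported
as degenerate and non-significant rather than erroring. One interpretive
caveat: the signed-rank test detects *consistency*, not magnitude — many
modules each missing one or two genes from one biomarker's leading edge
can reach small p values even when the fractions are nearly equal, so
the per-module fraction table should be read alongside the test.

# What the synthetic cohorts emulate — and what they do not

The generator produces the statistical structure the analysis assumes,
with exact ground truth:

- *Expression*: i.i.d. standard normal baseline; the planted gene set is
  mean-shifted by `enrichment_shift` SD units in the positive class.
  Defaults (120 samples split 50/50, 1000 genes, 50-gene planted set,
  1 SD shift) are the cohort scale used throughout the test suite.
  Heavier-tailed noise is unnecessary for the rank-based pipeline — the
  inverse-normal normalization destroys marginal scale — and i.i.d.
  noise is the one clearly *unrealistic* choice: real cohorts carry
  gene-gene correlation, which inflates ES variance. Phenotype
  permutation preserves whatever correlation the input has, so the
  calibration demonstrated on synthetic nulls shows the inference
  machinery is correct, not that real-data p values are immune to
  correlation structure.
- *Biomarkers*: labels copied from the enrichment classes with per-sample
  flip probability `(1 − association)/2`, giving a one-parameter sweep
  from perfect surrogate (1) to independent label (0).
- *Segments*: on the hg19 autosomal arms, each sample receives exactly
  `k_lst` qualifying LST breakpoints (alternating balanced states
  (1,1) ↔ (2,2), all segments ≥ 11 Mb), `k_tai` telomere-bounded
  imbalanced regions and `k_loh` interstitial copy-neutral LOH regions
  (each buffered by 8 Mb neutral flanks so their boundaries never
  qualify as LSTs), decoy sub-3 Mb blips that the smoothing step must
  remove, and — when `fga_target` is set — filler segments with neutral
  integer copy state but |log2| above the FGA threshold, sized to land
  the genome-altered fraction on target. Each arm hosts at most one
  feature, so planted counts cannot interact and the scorers recover
  them exactly; geometric infeasibility (too many events for the arm
  table) errors instead of silently under-planting.
- Not emulated: purity/ploidy mixtures, clonal structure, realistic
  breakpoint processes, platform noise on log2 ratios. The generator
  validates the *scoring rules*, not segmentation upstream of them.

# Problem sizes and numerical tolerances used in the test suite

The suite checks the ES implementation against a brute-force
prefix-loop oracle on 1000 random instances (N ≤ 200); calibrates the
nominal p value on 200 null cohorts (60 vs 60, 99 permutations) against
the exact central 95% binomial band for a 5% rate; requires recovery of
a 1 SD planted 50-gene signal (q < 0.05 at 1000 permutations) in at
least 19 of 20 seeded cohorts; and requires exact recovery of planted
scar counts on 100 profiles with FGA within ±0.02 of target. The
published-value check reproduces the eleven differential-ES z-statistics
derivable from printed per-cohort ES/sample-size pairs to ±0.02 — the
slack that 3-decimal rounding of the printed ES inputs induces — and
excludes the one tabulated z value that is not reproducible from its own
printed inputs. Exact and approximate signed-rank paths are required to
agree within 0.01 in p at 22 pairs.

# Known limitations

- TAI and LOH (hence HRD) require allele-specific copy number; profiles
  without it get `NA`, mirroring the practical situation where ASCAT
  output is unavailable for a cohort.
- The differential-ES test assumes the two ES values come from
  independent sample subsets; applied to two biomarkers labelling
  overlapping patients it is anti-conservative to an unknown degree, a
  caveat inherited from the underlying difference-of-correlations form.
- Single-gene-set inference only; scoring a collection with cross-set
  FDR is out of scope.
- The CMS → two/three-tier recoding maps CMS3 to MSS / Epithelial-CIN;
  CMS3's tier assignment is the one genuinely ambiguous cell in the
  published scheme (CMS3 tumours are epithelial-metabolic with elevated
  but not MSI-level mutation rates), and the choice here follows the
  majority-CIN character of CMS3. It is a single lookup table, easily
  overridden upstream of `make_phenotype()`.
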