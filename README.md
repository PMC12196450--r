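# parpicompare

Comparing candidate predictive biomarkers of PARP-inhibitor (PARPi)
response in colorectal cancer, using gene-set enrichment as the response
surrogate and genomic scar scores as the reference biomarker family.

PARP inhibitors are approved in breast, ovarian, prostate and pancreatic
cancer on the back of homologous recombination deficiency (HRD) and
*BRCA* biomarkers, but *BRCA* mutations are rare in colorectal cancer and
the right predictive biomarker there is an open question. A practical way
to compare candidates on retrospective cohorts is to treat the enrichment
of a PARPi-perturbation gene set as a stand-in for drug response, score
every candidate biomarker by how strongly its "favorable" patient subset
is enriched, and then test whether any candidate's enrichment differs
from that of a reference genomic scar score. `parpicompare` implements
that workflow end-to-end:

- **Genomic scar scores** from copy-number segment (SEG) files on hg19:
  large-scale state transitions (LST — breakpoints between adjacent
  segments each ≥ 10 Mb, per chromosome arm, after smoothing away
  segments < 3 Mb), telomeric allelic imbalance (TAI), loss of
  heterozygosity (LOH), their aggregate HRD = LST + TAI + LOH, fraction
  genome altered (FGA), and an arm-level aneuploidy score.
- **GSEA from scratch**: signal-to-noise gene ranking
  `(μ_A − μ_B)/(σ_A + σ_B)` with σ floored at `max(0.2·|μ|, 0.2)`, the
  weighted running-sum enrichment score (ES), phenotype or gene-set
  permutation nulls, normalized ES, permutation p values and FDR q, and
  leading-edge gene extraction.
- **Differential enrichment-score test**: treating ES as a
  correlation-like effect size,
  `z = (atanh(ES₁) − atanh(ES₂)) / √(1/(n₁−3) + 1/(n₂−3))`,
  with two-sided normal p values and Benjamini–Hochberg adjustment over
  the family of biomarker comparisons.
- **GSEF comparison**: per-module gene set enrichment fractions
  (|module ∩ leading edge| / |module|) compared between two biomarkers
  with a Wilcoxon signed-rank test (exact permutation distribution up to
  25 informative pairs, normal approximation with continuity and tie
  corrections above).
- **A synthetic cohort generator** that plants known scar counts in
  segment profiles, a known mean-shifted gene set in an expression
  matrix, and biomarker labels with a controllable association to the
  planted signal — so every stage of the pipeline is testable with exact
  ground truth and no external downloads.
- **Format I/O**: SEG, GCT v1.2, two-class CLS, GMT; a packaged hg19
  chromosome/centromere table.

## Worked example

A synthetic 120-sample cohort with a 50-gene response set shifted by
0.4 SD in the positive class; MSI tags that class with 0.9 association,
TP53 with 0.4; segment profiles carry class-specific planted scars.

```r
library(parpicompare)

spec <- cohort_spec(
  n_samples = 120, n_genes = 1000, planted_gene_set_size = 50,
  enrichment_shift = 0.4,
  biomarker_specs = list(MSI  = list(association = 0.9),
                         TP53 = list(association = 0.4)),
  segment_spec = list(
    pos = list(k_lst = 4,  k_tai = 1, k_loh = 2, fga_target = 0.25),
    neg = list(k_lst = 16, k_tai = 5, k_loh = 6, fga_target = 0.45)),
  seed = 20)

sim  <- simulate_expression(spec)
prof <- simulate_segments(spec, ifelse(sim$labels$labels == "pos", "pos", "neg"))
head(score_profiles(prof[1:4]))
#>   sample_id lst tai loh hrd  fga aneuploidy
#> 1      S001   4   1   2   7 0.25          8
#> 2      S002  16   5   6  27 0.45         18
#> 3      S003  16   5   6  27 0.45         15
#> 4      S004   4   1   2   7 0.25          9

norm <- fractional_rank_normalize(sim$matrix)
biom <- simulate_biomarkers(spec, sim$labels)
mods <- simulate_drug_modules(sim$gene_set, rownames(sim$matrix),
                              module_size_range = c(20, 50), seed = 20)

bundle <- run_biomarker_comparison(
  norm, c(list(LST = sim$labels), biom), sim$gene_set,
  reference = "LST", modules = mods, n_perm = 1000, seed = 20)
bundle
#> <biomarker_comparison>
#>  biomarker gene_set_size    es   nes   nominal_p       fdr_q   n
#>        LST            50 0.837 2.854 0.001926782 0.001926782 120
#>        MSI            50 0.828 2.769 0.001855288 0.001855288 120
#>       TP53            50 0.640 2.196 0.001956947 0.001956947 120
#>
#> Differential ES vs reference:
#>  biomarker_pair n_ref n_other    es_ref  es_other    z adjusted_p
#>     LST vs. MSI   120     120 0.8370244 0.8277895 0.23    0.81800
#>    LST vs. TP53   120     120 0.8370244 0.6396162 3.47    0.00104
```

Reading the output: each biomarker's subset enriches the planted response
set (all q < 0.05), exactly as planted. The differential test cannot
distinguish LST from the well-associated MSI (z = 0.23, adjusted
p = 0.82) but flags the weakly associated TP53 as carrying significantly
less of the signal (z = 3.47, adjusted p ≈ 0.001). The returned bundle
also holds the per-module GSEF table and Wilcoxon results
(`bundle$gsef`), per-biomarker leading-edge gene lists, and an
append-only run log recording every seed, threshold and permutation
type.

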