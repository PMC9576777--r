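---
title: "Methods: proteome-wide MR with pQTL instruments"
author: "pqtlmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR with pQTL instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pqtlmr)
```

# The inference problem

`pqtlmr` estimates the causal effect of a circulating protein on a
disease outcome from two independent GWAS: one of plasma protein levels
(the exposure; effects in SD units per effect-allele copy) and one of the
outcome (log-odds for binary traits). Genetic variants associated with
the protein — pQTLs — act as instrumental variables. The MR assumptions
are the usual three: the instrument is associated with the exposure; it
shares no unmeasured confounder with the outcome; and it affects the
outcome only through the exposure (no horizontal pleiotropy). The whole
battery of estimators and sensitivity tests exists because the third
assumption is unverifiable variant by variant: concordance across
methods with different failure modes is the practical evidence.

cis-pQTLs (within ±1 Mb of the gene encoding the protein) are treated as
the more trustworthy instruments, because a variant acting in or near
its own gene has a plausible direct mechanism; trans instruments are
added in a secondary pass and never promote a protein on their own. A
configurable exclusion list lets known highly pleiotropic loci (the
classic example is the ABO region) annotate trans-inclusive results.

# Harmonization

Exposure and outcome files are joined on rsid — the one identifier
reliably present across GWAS summary releases — with a chrom/pos
consistency check whenever both files carry coordinates (1-based, closed
intervals throughout). Outcome records coded on the opposite allele are
sign-flipped (and `eaf` mapped to `1 − eaf`); records coded on the other
strand are complemented first. Palindromic variants (A/T, C/G) cannot be
strand-resolved from alleles alone, so the default policy drops them;
the alternative `infer_by_eaf` policy keeps a palindromic variant only
when both frequencies lie outside (0.42, 0.58) and uses frequency
concordance to resolve the strand. 0.42 is deliberately conservative:
closer to 0.5, sampling noise in the frequencies would flip strands
silently. Indels are matched by exact allele-string equality; no
left-alignment normalization is attempted (a documented limitation).

# Instrument selection

LD clumping re-implements the standard greedy algorithm on a supplied LD
correlation matrix: candidates at P ≤ 5×10⁻⁸ are visited from the
smallest p-value; each index variant absorbs all remaining candidates
with r² ≥ 0.1 within ±1 Mb. Ties at identical p-values break by genomic
order then rsid, so results are independent of row order. Variants
missing from the LD matrix are excluded rather than assumed independent.
The LD matrix is an input (from a reference panel or
`simulate_ld()`); the package does not compute LD from genotypes.

Instrument strength uses the summary-data approximations
F = (β̂/σ̂)² and R² = F/(F + n − 2). These are the standard forms when
only summary statistics are available; the per-variant R² from this
formula matches an individual-level regression in the test suite.
Cis/trans classification anchors the ±1 Mb window on the gene body
(closed interval `[start − 1 Mb, end + 1 Mb]`); anchoring on the TSS
would shift the boundary by at most the gene length and is not offered,
to keep one convention.

# The estimator battery

The fitting function `mr_fit()` dispatches by `method`; `"auto"` encodes
the screening rule (Wald ratio for 1 IV, fixed-effect IVW for 2–3,
multiplicative random effects above 3). Numerical conventions, all of
which matter for reproducing results:

- **Wald SE** is first-order delta (`σ_Y/|β̂_X|`), ignoring exposure-side
  noise; the second-order form is available behind `second_order = TRUE`.
- **Multiplicative random effects** scale the fixed-effect SE by
  max(1, √(Q/df)) — the truncation at 1 means the random-effects SE is
  never smaller than the fixed one.
- **MR-Egger** first orients every pair so β̂_X ≥ 0 (flipping both
  effects jointly); the estimator is not invariant to allele orientation
  and this is the established convention. Its SEs carry the same
  truncated multiplicative over-dispersion with df = n − 2.
- **Correlated-IVW** builds Ω_jk = σ_Yjσ_Ykr_jk and solves by Cholesky
  whitening; if the smallest eigenvalue of Ω falls below 1e-8 the
  diagonal is inflated by 1e-6 once, and a singular system after that is
  an error, not a silent fix.
- **MR-PRESSO** uses leave-one-out IVW residual sums with parametric
  simulation from the observed SEs; p-values have Monte-Carlo resolution
  1/(n_sim + 1) and the seed is a required argument. The distortion test
  resamples random instrument subsets of the outlier count; the original
  release's distortion construction is under-documented, so this part is
  an approximation of the published description.
- **Contamination mixture** defaults: ψ = 1.5 × SD of the per-variant
  ratio estimates (falling back to 1.5 × max ratio SE when a single
  instrument makes the SD undefined), and a 2001-point grid spanning the
  ratio-estimate range widened by 3 × max SE. Its CI inverts the profile
  likelihood at the χ²₁(0.95) cut and can be non-contiguous in
  principle; the reported interval is the range of the accepted grid.
- P-values are two-sided normal throughout, except the contamination
  mixture (profile-likelihood inversion).

# Colocalization

Per-variant evidence is the Wakefield log approximate Bayes factor with
effect-prior SD W = 0.15 for quantitative traits (SD units) and 0.2 for
binary traits (log-odds) — the conventional values, configurable in
`coloc_config()`. Regions are the ±1 Mb window around the lead pQTL,
filtered to MAF ≥ 0.01 (MAF = min(eaf, 1 − eaf)) and INFO ≥ 0.8.

Pairwise analysis enumerates H0–H4 with priors p1 = p2 = 1e-4 and
p12 = 1e-5 (uniform mode) or p12 = p1(1 − γ) with γ = 0.98
(conservative mode; 1 in 500,000 variants causal for two traits). The
multi-trait posterior assumes a single causal variant shared by all m
traits: the shared configuration at variant i has likelihood
∏_t ABF_ti and prior p·f^(m−1) (f = 1 − γ conservative, p12/p1
uniform), normalized against the factorized per-trait evidence
∏_t(1 + p·S_t) with the all-shared term's prior corrected. For m = 2
this is algebraically identical to the exact H0–H4 enumeration, which is
how the approximation is anchored in the tests (brute-force enumeration
oracle, agreement to 1e-10). When the full set fails PP ≥ 0.7, a greedy
search repeatedly removes the trait whose exclusion most increases the
posterior and recurses on both parts, emitting maximal passing clusters.
This replaces the branch-and-bound machinery of full multi-trait
colocalization software; it serves the same decision rule (clusters, PP
threshold, per-variant share) but does not reproduce that algorithm's
regional/alignment probability decomposition. Increasing γ can only
decrease the posterior, and the single-causal-variant assumption is a
real limitation: a region with two causal variants for one trait can
fail to colocalize even when one of them is shared.

# Mediation

All mediation arithmetic happens on the log-odds (linear) scale — the
product method is only coherent there — and odds ratios are converted by
natural log on input. The indirect effect is β_EM·β_MO with delta-method
SE; the proportion mediated is indirect/total. A delta-method CI for the
proportion is reported but flagged unstable when |β_EO/σ_EO| < 2: a
ratio with a weakly determined denominator has no well-behaved normal
CI. Sign-mismatch and |proportion| > 1 raise flags rather than errors,
since both occur in real screens and mean "do not interpret as a
fraction".

# Phenome-wide screen

Phenotypes with fewer than 500 cases are excluded ("fewer than" read
literally: 500 cases is retained). The significance threshold is
layered Bonferroni, family α divided by (number of proteins × number of
retained phenotypes), recomputed from the supplied manifests — never
hard-coded. Direction classification compares the sign of the phenotype
effect with the sign of the protein's reference effect on stroke: same
sign is "beneficial" (a hypothetical intervention helping stroke helps
this phenotype too), opposite "deleterious", and a zero effect on either
side "not_applicable".

# The synthetic-data generator

`simulate_region()` emulates the summary-data regime directly: an AR(1)
LD matrix r_jk = ρ^|j−k|, joint effects b on the exposure giving
marginal expectations Rb, and estimates drawn from MVN(Rb, DRD) with
per-variant SEs from the standard GWAS approximation
σ_j = 1/√(2 maf_j(1−maf_j) n) (binary outcomes additionally scaled by
1/√(case_frac(1−case_frac))). Defaults mirror the study conditions the
package targets: a 4,994-sample exposure (pQTL) GWAS and a binary
outcome GWAS of 40,585 cases / 406,111 controls. Pleiotropy is injected
on the marginal outcome scale (mean_y = θ·mean_x + α_j, α_j drawn
balanced or directional) — the regime the Egger-intercept property
assumes for clumped, approximately independent instruments. Truth
records carry θ, b, and the pleiotropy draws so estimators are scored
against stored truth, never re-derived quantities.

What the generator does **not** emulate: realistic human LD structure
(AR(1) has no haplotype blocks), winner's curse in instrument discovery,
sample overlap between exposure and outcome GWAS, and the latent-liability
calibration of binary-trait effect sizes (the logistic SE approximation
is asymptotic). Passing tests therefore demonstrate the estimators'
internal correctness and calibration under the stated generative model,
not robustness to those real-data features.

## Simulation design choices in the validation suite

Two recovery checks need deliberately strong instruments, and the
reasons are statistical, not incidental:

- Two-sample IVW is attenuated toward the null by roughly a factor
  1/F per unit of instrument weakness (regression dilution from noise in
  β̂_X). With an outcome GWAS of MEGASTROKE scale the Monte-Carlo error
  of a 500-replicate mean is tiny, so the recovery scenario uses
  lead-cis-pQTL-scale effects (0.4–1.0 SD per allele, per-IV F in the
  hundreds to thousands) where the residual attenuation is below the
  Monte-Carlo resolution. Such effect sizes are routine for lead
  cis-pQTLs on affinity-proteomics platforms.
- The Egger intercept estimates the mean directional pleiotropic effect
  only under the NO-Measurement-Error approximation; its recovery
  scenario therefore uses a large exposure GWAS (n = 100,000) and a wide
  instrument-strength spread (0.1–0.8 SD) so that dilution leakage from
  the slope into the intercept is negligible.

Problem sizes used by the validation suite (chosen once for the package):
1,000 null replicates for IVW type-I error; 500 replicates for IVW and
Egger recovery; 300 replicates for mediation-chain recovery; 60-replicate
batches for colocalization detection and screen-null behaviour; 40
replicates × 5 protein-level verdicts for the end-to-end pipeline check.
The end-to-end check scores per-protein verdict accuracy: because the
decision procedure requires four gates each at α = 0.05, even a
perfectly clean causal protein fails some sensitivity gate at the gates'
nominal size — that is a property of the screening procedure itself, and
the accuracy measure reflects the verdicts a user actually reads.

# Known limitations

- Single mediator per decomposition; no multivariable-MR direct-effect
  estimation.
- No Steiger directionality filtering (reverse MR plays that role).
- No liftover, multi-allelic decomposition, or VCF ingestion; summary
  statistics enter as delimited text.
- The colocalization subset search is greedy and can in principle split
  a true cluster sub-optimally; the pairwise path is exact.
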