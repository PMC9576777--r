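#' Simulate an AR(1) LD correlation matrix with allele frequencies
#'
#' LD between variants decays geometrically with index distance:
#' `r[j, k] = ld_rho^|j - k|`, which is symmetric, unit-diagonal and
#' positive definite for `0 <= ld_rho < 1`. Minor allele frequencies are
#' drawn uniformly from `maf_range`.
#'
#' @param n_variants Number of variants.
#' @param ld_rho AR(1) correlation parameter in `[0, 1)`.
#' @param maf_range MAF range, default `c(0.05, 0.5)`.
#' @param seed Integer seed (mandatory).
#' @return List with `r` (matrix with rsid dimnames `snp_1..n`), `maf`, and
#'   `variants` (rsid/chrom/pos table; positions 5 kb apart on chromosome 1).
#' @export
simulate_ld <- function(n_variants, ld_rho, maf_range = c(0.05, 0.5), seed) {
  stopifnot(ld_rho >= 0, ld_rho < 1, n_variants >= 1)
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  idx <- seq_len(n_variants)
  r <- ld_rho^abs(outer(idx, idx, "-"))
  rsid <- paste0("snp_", idx)
  dimnames(r) <- list(rsid, rsid)
  maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
  list(r = r, maf = maf,
       variants = data.frame(rsid = rsid, chrom = "1",
                             pos = 1e6 + (idx - 1L) * 5000L,
                             stringsAsFactors = FALSE))
}

# draw one MVN vector with mean mu and covariance D R D using the upper
# Cholesky factor of R (precomputed by callers that loop)
mvn_draw <- function(mu, d, chol_r) {
  mu + d * drop(crossprod(chol_r, stats::rnorm(length(mu))))
}

assoc_from_draws <- function(variants, beta, se, maf, trait_id, trait_type,
                             n) {
  data.frame(rsid = variants$rsid, chrom = variants$chrom,
             pos = variants$pos, effect_allele = "A", other_allele = "G",
             eaf = maf, beta = beta, se = se,
             pvalue = pmax(two_sided_p(beta / se), .Machine$double.xmin),
             info = 1, n = n, trait_id = trait_id, trait_type = trait_type,
             stringsAsFactors = FALSE)
}

#' Simulate LD-correlated GWAS summary statistics for one region
#'
#' Emulates the two-sample summary-data regime directly, without
#' individual-level genotypes. Joint (causal) variant effects `b` on the
#' exposure give marginal expectations `R b`; exposure estimates are drawn
#' from `MVN(R b, D R D)` with `D = diag(se_x)` and
#' `se_xj = 1 / sqrt(2 maf_j (1 - maf_j) n_exposure)` (SD-unit trait).
#' Marginal outcome expectations are `theta * (R b)` plus per-variant
#' pleiotropic effects; outcome SEs use the asymptotic logistic
#' approximation for binary traits,
#' `se_yj = 1 / sqrt(2 maf_j (1 - maf_j) n_outcome case_frac (1 - case_frac))`.
#'
#' Defaults mirror the data structure of a plasma-proteome MR study: a
#' ~5,000-sample exposure (pQTL) GWAS and a large binary stroke outcome
#' GWAS (40,585 cases / 406,111 controls).
#'
#' @param n_variants Region size (default 20).
#' @param ld_rho AR(1) LD parameter (default 0.5).
#' @param maf_range MAF range.
#' @param causal_index,causal_beta Indices and joint effect sizes (SD units
#'   per allele) of causal variants on the exposure. Default: one causal
#'   variant of effect 0.15 in the region centre.
#' @param theta True causal effect of the exposure on the outcome.
#' @param pleiotropy `list(type = "none" | "balanced" | "directional",
#'   mean = , sd = )`; per-variant pleiotropic outcome effects drawn
#'   `N(mean, sd^2)` (`mean = 0` for balanced) and added to the marginal
#'   outcome expectations.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param case_frac Case fraction for a binary outcome.
#' @param outcome_type `"binary"` or `"quantitative"`.
#' @param seed Integer seed (mandatory).
#' @return Object of class `synthetic_region`: list with `ld` (see
#'   [simulate_ld()]), `exposure` and `outcome` association-record tables,
#'   and `truth` (`theta`, `b`, `causal_index`, `pleiotropy` draws) —
#'   sufficient to score any estimator against the generating model.
#' @export
simulate_region <- function(n_variants = 20, ld_rho = 0.5,
                            maf_range = c(0.05, 0.5),
                            causal_index = ceiling(n_variants / 2),
                            causal_beta = 0.15, theta = 0,
                            pleiotropy = list(type = "none"),
                            n_exposure = 4994,
                            n_outcome = 446696,
                            case_frac = 40585 / 446696,
                            outcome_type = "binary", seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(causal_index) == length(causal_beta) ||
              length(causal_beta) == 1,
            all(causal_index >= 1), all(causal_index <= n_variants))
  ld <- simulate_ld(n_variants, ld_rho, maf_range, seed)
  b <- numeric(n_variants)
  b[causal_index] <- causal_beta
  mean_x <- drop(ld$r %*% b)
  se_x <- 1 / sqrt(2 * ld$maf * (1 - ld$maf) * n_exposure)
  se_y <- if (outcome_type == "binary")
    1 / sqrt(2 * ld$maf * (1 - ld$maf) * n_outcome *
               case_frac * (1 - case_frac))
  else 1 / sqrt(2 * ld$maf * (1 - ld$maf) * n_outcome)
  alpha <- switch(pleiotropy$type,
                  none = numeric(n_variants),
                  balanced = stats::rnorm(n_variants, 0, pleiotropy$sd),
                  directional = stats::rnorm(n_variants, pleiotropy$mean,
                                             pleiotropy$sd),
                  stop("unknown pleiotropy type"))
  mean_y <- theta * mean_x + alpha
  ch <- if (ld_rho > 0) chol(ld$r) else NULL
  draw <- function(mu, d) {
    if (is.null(ch)) mu + d * stats::rnorm(length(mu)) else mvn_draw(mu, d, ch)
  }
  bx <- draw(mean_x, se_x)
  by <- draw(mean_y, se_y)
  structure(list(
    ld = ld,
    exposure = assoc_from_draws(ld$variants, bx, se_x, ld$maf, "exposure",
                                "quantitative", n_exposure),
    outcome = assoc_from_draws(ld$variants, by, se_y, ld$maf, "outcome",
                               outcome_type, n_outcome),
    truth = list(theta = theta, b = b, causal_index = causal_index,
                 pleiotropy = alpha, mean_x = mean_x, mean_y = mean_y),
    config = list(n_variants = n_variants, ld_rho = ld_rho,
                  n_exposure = n_exposure, n_outcome = n_outcome,
                  case_frac = case_frac, outcome_type = outcome_type,
                  seed = seed)),
    class = "synthetic_region")
}

#' Simulate harmonized instrument-level pairs directly
#'
#' Fast path for estimator validation: `n_iv` approximately independent
#' instruments (post-clumping regime) with true exposure effects
#' `causal_beta`, outcome effects `theta * beta_x + alpha_j`, and noisy
#' estimates on both sides. Returns a ready-made harmonized-pair table.
#'
#' @param n_iv Number of instruments.
#' @param causal_beta True exposure effects (recycled to `n_iv`).
#' @param theta True causal effect.
#' @param pleiotropy As in [simulate_region()].
#' @param n_exposure,n_outcome,case_frac,outcome_type As in
#'   [simulate_region()].
#' @param maf_range MAF range for the instruments.
#' @param seed Integer seed (mandatory).
#' @return Harmonized-pair data.frame with attribute `"truth"`.
#' @export
simulate_pairs <- function(n_iv = 10, causal_beta = 0.15, theta = 0,
                           pleiotropy = list(type = "none"),
                           n_exposure = 4994, n_outcome = 446696,
                           case_frac = 40585 / 446696,
                           outcome_type = "binary",
                           maf_range = c(0.1, 0.5), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  maf <- stats::runif(n_iv, maf_range[1], maf_range[2])
  b <- rep_len(causal_beta, n_iv)
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * n_exposure)
  se_y <- if (outcome_type == "binary")
    1 / sqrt(2 * maf * (1 - maf) * n_outcome * case_frac * (1 - case_frac))
  else 1 / sqrt(2 * maf * (1 - maf) * n_outcome)
  alpha <- switch(pleiotropy$type,
                  none = numeric(n_iv),
                  balanced = stats::rnorm(n_iv, 0, pleiotropy$sd),
                  directional = stats::rnorm(n_iv, pleiotropy$mean,
                                             pleiotropy$sd),
                  stop("unknown pleiotropy type"))
  out <- data.frame(
    rsid = paste0("snp_", seq_len(n_iv)), chrom = "1",
    pos = 1e6 + (seq_len(n_iv) - 1L) * 5e5,
    effect_allele = "A", other_allele = "G",
    beta_x = stats::rnorm(n_iv, b, se_x), se_x = se_x,
    pvalue_x = NA_real_, eaf = maf,
    beta_y = stats::rnorm(n_iv, theta * b + alpha, se_y), se_y = se_y,
    pvalue_y = NA_real_, eaf_y = maf,
    flipped = FALSE, palindromic = FALSE, stringsAsFactors = FALSE)
  out$pvalue_x <- two_sided_p(out$beta_x / out$se_x)
  out$pvalue_y <- two_sided_p(out$beta_y / out$se_y)
  attr(out, "truth") <- list(theta = theta, b = b, pleiotropy = alpha)
  out
}

#' Simulate a multi-trait colocalization scenario
#'
#' Builds a `regional_assoc` with planted causal structure:
#' `"coloc_shared"` drives all traits from one causal variant,
#' `"coloc_distinct"` assigns disjoint causal variants to trait subsets,
#' `"null"` has no associated variant anywhere. Per-trait joint effects are
#' scaled so the lead variant's expected |z| is `z_lead`.
#'
#' @param scenario `"coloc_shared"`, `"coloc_distinct"` or `"null"`.
#' @param n_traits Number of traits (>= 2).
#' @param n_variants Region size (default 20).
#' @param ld_rho AR(1) LD parameter.
#' @param z_lead Expected lead-variant z-score per trait (default 8).
#' @param trait_groups For `"coloc_distinct"`: integer vector of length
#'   `n_traits` assigning traits to causal-variant groups; default splits
#'   them in two halves.
#' @param n_per_trait Per-trait GWAS sample size (default 50000).
#' @param seed Integer seed (mandatory).
#' @return A `regional_assoc` with attribute `"truth"` (scenario, causal
#'   indices per trait).
#' @export
simulate_coloc_scenario <- function(scenario = c("coloc_shared",
                                                 "coloc_distinct", "null"),
                                    n_traits = 2, n_variants = 20,
                                    ld_rho = 0.5, z_lead = 8,
                                    trait_groups = NULL,
                                    n_per_trait = 50000, seed) {
  scenario <- match.arg(scenario)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_traits >= 2)
  ld <- simulate_ld(n_variants, ld_rho, c(0.05, 0.5), seed)
  se <- 1 / sqrt(2 * ld$maf * (1 - ld$maf) * n_per_trait)
  causal <- switch(scenario,
    coloc_shared = rep(ceiling(n_variants / 2), n_traits),
    coloc_distinct = {
      if (is.null(trait_groups))
        trait_groups <- rep(1:2, length.out = n_traits)
      ng <- length(unique(trait_groups))
      # well-separated causal positions, one per group
      pos <- round(seq(0.25, 0.75, length.out = ng) * n_variants)
      pos[trait_groups]
    },
    null = rep(NA_integer_, n_traits))
  ch <- if (ld_rho > 0) chol(ld$r) else NULL
  assoc <- list()
  for (t in seq_len(n_traits)) {
    b <- numeric(n_variants)
    if (!is.na(causal[t])) b[causal[t]] <- z_lead * se[causal[t]]
    mu <- drop(ld$r %*% b)
    est <- if (is.null(ch)) mu + se * stats::rnorm(n_variants) else
      mvn_draw(mu, se, ch)
    assoc[[paste0("trait_", t)]] <-
      assoc_from_draws(ld$variants, est, se, ld$maf, paste0("trait_", t),
                       "quantitative", n_per_trait)
  }
  region <- regional_assoc(assoc, lead_rsid = ld$variants$rsid[
    if (all(is.na(causal))) 1L else causal[1]],
    window_bp = Inf, maf_min = 0, info_min = 0)
  attr(region, "truth") <- list(scenario = scenario, causal_index = causal)
  region
}

#' Simulate a full mediation chain as three two-sample MR datasets
#'
#' Plants an exposure -> mediator -> outcome chain with an additional direct
#' exposure effect: the total exposure effect on the outcome is
#' `direct_eo + beta_em * beta_mo` by construction, so the true proportion
#' mediated is `beta_em * beta_mo / (direct_eo + beta_em * beta_mo)`.
#' Exposure and mediator instruments come from disjoint regions.
#'
#' @param beta_em,beta_mo,direct_eo Chain parameters (defaults 0.2, 0.5,
#'   0.1: true proportion mediated 0.5).
#' @param n_iv_e,n_iv_m Instrument counts for exposure and mediator.
#' @param iv_beta Per-instrument effect size on its own trait (SD units).
#' @param n_exposure,n_mediator,n_outcome,case_frac GWAS sample sizes;
#'   outcome is binary.
#' @param seed Integer seed (mandatory).
#' @return List of class `mediation_chain` with harmonized-pair tables
#'   `eo` (exposure instruments on outcome), `em` (exposure instruments on
#'   mediator), `mo` (mediator instruments on outcome) and `truth`.
#' @export
simulate_mediation_chain <- function(beta_em = 0.2, beta_mo = 0.5,
                                     direct_eo = 0.1, n_iv_e = 10,
                                     n_iv_m = 10, iv_beta = 0.15,
                                     n_exposure = 4994, n_mediator = 60000,
                                     n_outcome = 446696,
                                     case_frac = 40585 / 446696, seed) {
  if (missing(seed)) stop("seed is mandatory")
  total_eo <- direct_eo + beta_em * beta_mo
  em <- simulate_pairs(n_iv_e, iv_beta, theta = beta_em,
                       n_exposure = n_exposure, n_outcome = n_mediator,
                       outcome_type = "quantitative", seed = seed)
  eo <- simulate_pairs(n_iv_e, iv_beta, theta = total_eo,
                       n_exposure = n_exposure, n_outcome = n_outcome,
                       case_frac = case_frac, outcome_type = "binary",
                       seed = seed + 1L)
  # the exposure-side draws of the E->M and E->O datasets come from the same
  # discovery GWAS: reuse the E->M exposure estimates
  eo$beta_x <- em$beta_x; eo$se_x <- em$se_x; eo$pvalue_x <- em$pvalue_x
  mo <- simulate_pairs(n_iv_m, iv_beta, theta = beta_mo,
                       n_exposure = n_mediator, n_outcome = n_outcome,
                       case_frac = case_frac, outcome_type = "binary",
                       seed = seed + 2L)
  mo$rsid <- paste0("med_", mo$rsid)
  structure(list(eo = eo, em = em, mo = mo,
                 truth = list(beta_em = beta_em, beta_mo = beta_mo,
                              direct_eo = direct_eo, total_eo = total_eo,
                              proportion = beta_em * beta_mo / total_eo)),
            class = "mediation_chain")
}
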