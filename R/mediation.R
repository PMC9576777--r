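#' Indirect effect by the product method with delta-method SE
#'
#' Indirect (mediated) effect of an exposure on an outcome through one
#' mediator, from two-step MR estimates: `indirect = beta_EM * beta_MO`,
#' with first-order delta-method standard error
#' `sqrt(beta_EM^2 se_MO^2 + beta_MO^2 se_EM^2)` and a normal CI. All inputs
#' must be on the linear (log-odds for binary traits) scale.
#'
#' @param beta_em,se_em Exposure-to-mediator effect and SE.
#' @param beta_mo,se_mo Mediator-to-outcome effect and SE.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `indirect`, `se`, `ci_low`, `ci_high`, `pvalue`.
#' @export
product_indirect <- function(beta_em, se_em, beta_mo, se_mo,
                             conf_level = 0.95) {
  stopifnot(se_em > 0, se_mo > 0)
  ind <- beta_em * beta_mo
  se <- sqrt(beta_em^2 * se_mo^2 + beta_mo^2 * se_em^2)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(indirect = ind, se = se, ci_low = ind - zq * se,
       ci_high = ind + zq * se,
       pvalue = if (se > 0) two_sided_p(ind / se) else NA_real_)
}

#' Proportion of a total effect that is mediated
#'
#' `proportion = indirect / beta_EO` on the log-odds (linear) scale.
#' Flags are raised when the indirect and total effects have opposite signs
#' (`sign_mismatch`: the "proportion" is then not interpretable as a
#' fraction) and when its magnitude exceeds 1 (`proportion_out_of_range`).
#'
#' @param indirect Indirect effect (see [product_indirect()]).
#' @param beta_eo Total exposure-to-outcome effect (nonzero).
#' @return List with `proportion` and logical `flags`
#'   (`sign_mismatch`, `proportion_out_of_range`).
#' @export
proportion_mediated <- function(indirect, beta_eo) {
  if (beta_eo == 0) stop("undefined proportion: total effect is zero")
  prop <- indirect / beta_eo
  list(proportion = prop,
       flags = c(sign_mismatch = indirect != 0 && prop < 0,
                 proportion_out_of_range = abs(prop) > 1))
}

#' Two-step MR mediation decomposition
#'
#' Combines the three MR estimates of a mediation triangle — total effect
#' `beta_EO` (exposure on outcome), `beta_EM` (exposure on mediator),
#' `beta_MO` (mediator on outcome) — into the indirect effect (product
#' method), its delta-method SE and CI, and the proportion mediated. Binary
#' effects enter as log odds ratios; use `log()` on ORs first. A
#' delta-method CI for the proportion itself is reported and flagged
#' unstable when the total effect is weakly determined
#' (`|beta_EO/se_EO| < 2`).
#'
#' @param beta_eo,se_eo Total effect and SE (SE may be `NA` when only the
#'   point decomposition is wanted).
#' @param beta_em,se_em,beta_mo,se_mo Two-step effects and SEs.
#' @param conf_level Confidence level.
#' @return Object of class `mediation`: all inputs plus `indirect`,
#'   `se_indirect`, `ci_indirect`, `p_indirect`, `direct`
#'   (`beta_eo - indirect`), `proportion`, `se_proportion`,
#'   `ci_proportion`, `flags`.
#' @examples
#' # printed worked example: OR 1.03 exposure->mediator, 2.04
#' # mediator->outcome, total OR 1.089 -> 24.7% mediated
#' m <- mediate(log(1.089), NA, log(1.03), NA, log(2.04), NA)
#' round(100 * m$proportion, 1)
#' @export
mediate <- function(beta_eo, se_eo, beta_em, se_em, beta_mo, se_mo,
                    conf_level = 0.95) {
  have_se <- is.finite(se_em) && is.finite(se_mo)
  if (have_se) {
    pr <- product_indirect(beta_em, se_em, beta_mo, se_mo, conf_level)
  } else {
    pr <- list(indirect = beta_em * beta_mo, se = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_)
  }
  pm <- proportion_mediated(pr$indirect, beta_eo)
  se_prop <- ci_prop <- NA_real_
  unstable <- NA
  if (have_se && is.finite(se_eo)) {
    # delta method on the ratio, treating numerator and denominator
    # estimates as independent (two-sample summary data)
    v <- pr$se^2 / beta_eo^2 + pr$indirect^2 * se_eo^2 / beta_eo^4
    se_prop <- sqrt(v)
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci_prop <- pm$proportion + c(-1, 1) * zq * se_prop
    unstable <- abs(beta_eo / se_eo) < 2
  }
  structure(list(beta_eo = beta_eo, se_eo = se_eo,
                 beta_em = beta_em, se_em = se_em,
                 beta_mo = beta_mo, se_mo = se_mo,
                 indirect = pr$indirect, se_indirect = pr$se,
                 ci_indirect = c(pr$ci_low, pr$ci_high),
                 p_indirect = pr$pvalue,
                 direct = beta_eo - pr$indirect,
                 proportion = pm$proportion, se_proportion = se_prop,
                 ci_proportion = ci_prop,
                 flags = c(pm$flags, proportion_ci_unstable = unstable),
                 conf_level = conf_level),
            class = "mediation")
}

#' @export
print.mediation <- function(x, digits = 4, ...) {
  cat("Two-step MR mediation decomposition (log-odds scale)\n")
  cat(sprintf("  total  beta_EO = %.*g\n", digits, x$beta_eo))
  cat(sprintf("  step   beta_EM = %.*g, beta_MO = %.*g\n",
              digits, x$beta_em, digits, x$beta_mo))
  if (is.finite(x$se_indirect))
    cat(sprintf("  indirect = %.*g (SE %.*g, %d%% CI [%.*g, %.*g])\n",
                digits, x$indirect, digits, x$se_indirect,
                round(100 * x$conf_level),
                digits, x$ci_indirect[1], digits, x$ci_indirect[2]))
  else cat(sprintf("  indirect = %.*g\n", digits, x$indirect))
  cat(sprintf("  proportion mediated = %.1f%%\n", 100 * x$proportion))
  fl <- x$flags[!is.na(x$flags) & x$flags]
  if (length(fl)) cat("  flags:", paste(names(fl), collapse = ", "), "\n")
  invisible(x)
}
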