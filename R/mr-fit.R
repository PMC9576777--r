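#' Fit a two-sample Mendelian randomization estimator
#'
#' The central fitting function of the package. Given a table of harmonized
#' variant-level effects on an exposure and an outcome, estimates the causal
#' effect of a one-SD higher exposure on the outcome (log-odds for binary
#' outcomes) by one of the summary-data MR estimators:
#'
#' * `"wald"` — single-instrument Wald ratio, `beta_y / beta_x`, first-order
#'   delta-method SE `|se_y / beta_x|`.
#' * `"ivw_fixed"` / `"ivw_mre"` — inverse-variance-weighted meta-analysis of
#'   per-variant ratios, equivalent to weighted regression of `beta_y` on
#'   `beta_x` through the origin with weights `1/se_y^2`; the multiplicative
#'   random-effects variant inflates the SE by `max(1, sqrt(Q/df))`.
#' * `"ivw_correlated"` — generalized IVW accounting for LD between
#'   instruments through the residual covariance
#'   `Omega[j,k] = se_yj * se_yk * r[j,k]`.
#' * `"egger"` — weighted regression with an unconstrained intercept; the
#'   slope estimates the causal effect, the intercept tests directional
#'   pleiotropy. Requires >= 3 instruments; pairs are first oriented so all
#'   `beta_x >= 0`.
#' * `"conmix"` — contamination-mixture profile likelihood classifying each
#'   instrument as valid or invalid around candidate effect values.
#' * `"auto"` — the decision rule used for primary screening: Wald ratio for
#'   one instrument, fixed-effect IVW for 2-3, multiplicative random-effects
#'   IVW for more.
#'
#' Cochran's Q heterogeneity statistic (with `I^2 = max(0, (Q - df)/Q)`) is
#' attached for all multi-instrument IVW-family fits.
#'
#' @param pairs Harmonized pairs (see [harmonize()]), or any data.frame with
#'   columns `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @param method Estimator, see above. Default `"auto"`.
#' @param ld Signed LD correlation matrix for the instruments (required for
#'   `"ivw_correlated"`), in the row order of `pairs` or with rsid dimnames.
#' @param second_order For `"wald"`: use the second-order delta SE
#'   `sqrt(se_y^2/beta_x^2 + beta_y^2 se_x^2/beta_x^4)` instead of the
#'   first-order one.
#' @param psi For `"conmix"`: SD of invalid-instrument pleiotropy; default
#'   1.5 times the SD of the per-variant ratio estimates.
#' @param theta_grid For `"conmix"`: grid of candidate effects; default 2001
#'   points spanning the ratio-estimate range widened by 3 max SE.
#' @param conf_level Confidence level for the reported interval (default
#'   0.95).
#'
#' @return An object of class `mr_fit`: a list with `method`, `theta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `n_snps`, `heterogeneity` (list `q`,
#'   `df`, `p_q`, `i2`; `NULL` for single-instrument fits), `pleiotropy`
#'   (Egger intercept, its SE and p; Egger only), `valid` (conmix only:
#'   logical vector of instruments classed valid at the estimate), `profile`
#'   (conmix only: grid and profile log-likelihood) and the input `data`.
#' @examples
#' p <- data.frame(beta_x = c(0.5, 0.4, 0.6), se_x = 0.05,
#'                 beta_y = c(0.15, 0.12, 0.18), se_y = 0.02)
#' fit <- mr_fit(p)
#' summary(fit)
#' @export
mr_fit <- function(pairs, method = c("auto", "wald", "ivw_fixed", "ivw_mre",
                                     "ivw_correlated", "egger", "conmix"),
                   ld = NULL, second_order = FALSE, psi = NULL,
                   theta_grid = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  bx <- pairs$beta_x; bxse <- pairs$se_x
  by <- pairs$beta_y; byse <- pairs$se_y
  n <- length(bx)
  if (n < 1L) stop("empty instrument set")
  stopifnot(all(byse > 0))
  if (method == "auto")
    method <- if (n == 1L) "wald" else if (n <= 3L) "ivw_fixed" else "ivw_mre"
  fit <- switch(method,
    wald = mr_wald_core(bx, bxse, by, byse, second_order),
    ivw_fixed = mr_ivw_core(bx, by, byse, random = FALSE),
    ivw_mre = mr_ivw_core(bx, by, byse, random = TRUE),
    ivw_correlated = mr_ivw_corr_core(bx, by, byse, ld, pairs$rsid),
    egger = mr_egger_core(bx, bxse, by, byse),
    conmix = mr_conmix_core(bx, by, byse, psi, theta_grid, conf_level)
  )
  fit$method <- method
  fit$n_snps <- n
  if (is.null(fit$ci_low)) {
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    fit$ci_low <- fit$theta - zq * fit$se
    fit$ci_high <- fit$theta + zq * fit$se
  }
  fit$conf_level <- conf_level
  fit$data <- pairs
  class(fit) <- "mr_fit"
  fit
}

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

mr_wald_core <- function(bx, bxse, by, byse, second_order = FALSE) {
  if (length(bx) != 1L) stop("Wald ratio requires exactly one instrument")
  if (bx == 0) stop("undefined estimate: exposure effect is zero")
  theta <- by / bx
  se <- if (second_order)
    sqrt(byse^2 / bx^2 + by^2 * bxse^2 / bx^4) else abs(byse / bx)
  list(theta = theta, se = se, pvalue = two_sided_p(theta / se),
       heterogeneity = NULL)
}

het_stats <- function(q, df) {
  list(q = q, df = df,
       p_q = if (df >= 1) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_,
       i2 = if (q > 0) max(0, (q - df) / q) else 0)
}

mr_ivw_core <- function(bx, by, byse, random = FALSE) {
  if (all(bx == 0)) stop("undefined estimate: all exposure effects are zero")
  w <- 1 / byse^2
  s2 <- sum(w * bx^2)
  theta <- sum(w * bx * by) / s2
  se <- sqrt(1 / s2)
  q <- sum(w * (by - theta * bx)^2)
  df <- length(bx) - 1L
  if (random && df >= 1) se <- se * max(1, sqrt(q / df))
  list(theta = theta, se = se, pvalue = two_sided_p(theta / se),
       heterogeneity = if (df >= 1) het_stats(q, df) else NULL)
}

mr_ivw_corr_core <- function(bx, by, byse, ld, rsid = NULL) {
  if (is.null(ld)) stop("ivw_correlated requires an LD matrix")
  r <- if (is.list(ld) && !is.null(ld$r)) ld$r else ld
  if (!is.null(rownames(r)) && !is.null(rsid) && all(rsid %in% rownames(r)))
    r <- r[rsid, rsid, drop = FALSE]
  if (nrow(r) != length(bx)) stop("LD matrix does not match instruments")
  omega <- outer(byse, byse) * r
  ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) {
    omega <- omega + diag(1e-6, nrow(omega))
    ev_min <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0)
      stop("instrument covariance singular after regularization (min ",
           "eigenvalue ", format(ev_min), ")")
  }
  ch <- chol(omega)
  # whiten: solve(t(ch)) %*% v without forming the inverse
  wx <- backsolve(ch, bx, transpose = TRUE)
  wy <- backsolve(ch, by, transpose = TRUE)
  s2 <- sum(wx^2)
  theta <- sum(wx * wy) / s2
  se <- sqrt(1 / s2)
  q <- sum((wy - theta * wx)^2)
  list(theta = theta, se = se, pvalue = two_sided_p(theta / se),
       heterogeneity = het_stats(q, length(bx) - 1L))
}

mr_egger_core <- function(bx, bxse, by, byse) {
  n <- length(bx)
  if (n < 3L) stop("insufficient instruments: MR-Egger requires >= 3")
  flip <- bx < 0          # Egger is orientation-sensitive; fix beta_x >= 0
  by <- ifelse(flip, -by, by)
  bx <- ifelse(flip, -bx, bx)
  w <- 1 / byse^2
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  det <- sw * sxx - swx^2
  slope <- (sw * sxy - swx * swy) / det
  intercept <- (swy - slope * swx) / sw
  resid <- by - intercept - slope * bx
  rss <- sum(w * resid^2)
  phi <- max(1, rss / (n - 2))             # over-dispersion, truncated at 1
  se_slope <- sqrt(phi * sw / det)
  se_int <- sqrt(phi * sxx / det)
  list(theta = slope, se = se_slope,
       pvalue = two_sided_p(slope / se_slope),
       heterogeneity = het_stats(rss, n - 2L),
       pleiotropy = list(egger_intercept = intercept, se = se_int,
                         p_intercept = two_sided_p(intercept / se_int)))
}

mr_conmix_core <- function(bx, by, byse, psi = NULL, theta_grid = NULL,
                           conf_level = 0.95) {
  n <- length(bx)
  if (n < 1L) stop("insufficient instruments")
  ratio <- by / bx
  ratio_se <- byse / abs(bx)
  if (is.null(psi)) {
    psi <- 1.5 * stats::sd(ratio)
    if (!is.finite(psi) || psi <= 0) psi <- 1.5 * max(ratio_se)
  }
  if (psi <= 0) stop("psi must be positive")
  if (is.null(theta_grid)) {
    pad <- 3 * max(ratio_se)
    theta_grid <- seq(min(ratio) - pad, max(ratio) + pad, length.out = 2001L)
  }
  if (!length(theta_grid)) stop("empty theta grid")
  ll_at <- function(theta) {
    lv <- stats::dnorm(ratio, theta, ratio_se, log = TRUE)
    li <- stats::dnorm(ratio, 0, sqrt(ratio_se^2 + psi^2), log = TRUE)
    sum(pmax(lv, li))
  }
  ll <- vapply(theta_grid, ll_at, numeric(1))
  best <- which.max(ll)
  theta <- theta_grid[best]
  crit <- stats::qchisq(conf_level, 1)
  inside <- 2 * (ll[best] - ll) <= crit
  ci <- range(theta_grid[inside])
  lv <- stats::dnorm(ratio, theta, ratio_se, log = TRUE)
  li <- stats::dnorm(ratio, 0, sqrt(ratio_se^2 + psi^2), log = TRUE)
  p0 <- stats::pchisq(2 * (ll[best] - ll_at(0)), 1, lower.tail = FALSE)
  list(theta = theta, se = diff(ci) / (2 * stats::qnorm(1 - (1 - conf_level) / 2)),
       ci_low = ci[1], ci_high = ci[2], pvalue = p0,
       heterogeneity = NULL, valid = lv >= li, psi = psi,
       profile = list(theta = theta_grid, loglik = ll))
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR estimate (%s, %d SNP%s)\n", x$method, x$n_snps,
              if (x$n_snps == 1) "" else "s"))
  cat(sprintf("  theta = %.*g (SE %.*g), %d%% CI [%.*g, %.*g], p = %.3g\n",
              digits, x$theta, digits, x$se,
              round(100 * x$conf_level), digits, x$ci_low, digits, x$ci_high,
              x$pvalue))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, exponentiate = FALSE, ...) {
  structure(list(fit = object, exponentiate = exponentiate),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (x$exponentiate)
    cat(sprintf("  OR = %.*g, %d%% CI [%.*g, %.*g]\n",
                digits, exp(f$theta), round(100 * f$conf_level),
                digits, exp(f$ci_low), digits, exp(f$ci_high)))
  h <- f$heterogeneity
  if (!is.null(h))
    cat(sprintf("  Cochran Q = %.3f on %d df (p = %.3g), I2 = %.1f%%\n",
                h$q, h$df, h$p_q, 100 * h$i2))
  pl <- f$pleiotropy
  if (!is.null(pl))
    cat(sprintf("  Egger intercept = %.*g (SE %.*g), p = %.3g\n",
                digits, pl$egger_intercept, digits, pl$se, pl$p_intercept))
  if (!is.null(f$valid))
    cat(sprintf("  conmix: %d/%d instruments classed valid (psi = %.3g)\n",
                sum(f$valid), f$n_snps, f$psi))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (!is.null(object$pleiotropy))
    c(intercept = object$pleiotropy$egger_intercept, theta = object$theta)
  else c(theta = object$theta)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  if (!is.null(object$profile)) {
    crit <- stats::qchisq(level, 1)
    ll <- object$profile$loglik
    inside <- 2 * (max(ll) - ll) <= crit
    ci <- range(object$profile$theta[inside])
  } else {
    zq <- stats::qnorm(1 - (1 - level) / 2)
    ci <- object$theta + c(-1, 1) * zq * object$se
  }
  m <- matrix(ci, nrow = 1,
              dimnames = list("theta",
                              sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2))))
  m
}

#' Scatter plot of a two-sample MR fit
#'
#' Plots per-variant outcome effects against exposure effects with +/- 1 SE
#' bars and the fitted causal slope (and Egger intercept when present).
#'
#' @param x An `mr_fit` object.
#' @param ... Passed to [plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  plot(d$beta_x, d$beta_y, pch = 19,
       xlab = "SNP effect on exposure (SD)",
       ylab = "SNP effect on outcome",
       main = sprintf("MR fit (%s)", x$method), ...)
  segments(d$beta_x, d$beta_y - d$se_y, d$beta_x, d$beta_y + d$se_y,
           col = "grey60")
  segments(d$beta_x - d$se_x, d$beta_y, d$beta_x + d$se_x, d$beta_y,
           col = "grey60")
  a <- if (!is.null(x$pleiotropy)) x$pleiotropy$egger_intercept else 0
  abline(a = a, b = x$theta, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Primary-analysis estimator dispatch
#'
#' Applies the screening decision rule: Wald ratio for a single instrument,
#' fixed-effect IVW for 2-3 instruments, multiplicative random-effects IVW
#' for more than 3.
#'
#' @inheritParams mr_fit
#' @return An `mr_fit` object (its `method` records which estimator ran).
#' @export
select_primary <- function(pairs, conf_level = 0.95) {
  mr_fit(pairs, method = "auto", conf_level = conf_level)
}

#' Run the full estimator battery with sensitivity statistics
#'
#' Convenience wrapper producing the primary estimate plus every sensitivity
#' analysis the instrument count supports: MR-Egger (>= 3 instruments),
#' MR-PRESSO global test (>= 4), contamination mixture (>= 2), and, when an
#' LD matrix is supplied, correlated-instrument IVW.
#'
#' @inheritParams mr_fit
#' @param n_sim,seed Passed to [mr_presso()].
#' @return A list of class `mr_battery` with elements `primary`, `egger`,
#'   `presso`, `conmix`, `ivw_correlated` (absent ones `NULL`); use
#'   [as.data.frame.mr_battery()] for a one-row summary table.
#' @export
mr_battery <- function(pairs, ld = NULL, n_sim = 1000, seed = 1) {
  n <- nrow(pairs)
  out <- list(primary = select_primary(pairs))
  out$egger <- if (n >= 3) mr_fit(pairs, "egger")
  out$presso <- if (n >= 4) mr_presso(pairs, n_sim = n_sim, seed = seed)
  out$conmix <- if (n >= 2) mr_fit(pairs, "conmix")
  out$ivw_correlated <- if (!is.null(ld) && n >= 2)
    mr_fit(pairs, "ivw_correlated", ld = ld)
  class(out) <- "mr_battery"
  out
}

#' @export
print.mr_battery <- function(x, ...) {
  print(x$primary)
  if (!is.null(x$egger)) {
    cat("Sensitivity: ")
    print(summary(x$egger))
  }
  if (!is.null(x$presso))
    cat(sprintf("MR-PRESSO global p = %.3g (%d outlier(s))\n",
                x$presso$p_global, length(x$presso$outliers)))
  invisible(x)
}

#' One-row summary of an estimator battery
#'
#' @param x An `mr_battery` object.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @return One-row data.frame with the primary estimate, heterogeneity,
#'   Egger-intercept and PRESSO statistics (NA where a test did not run).
#' @export
as.data.frame.mr_battery <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  p <- x$primary
  h <- p$heterogeneity
  data.frame(
    method = p$method, n_snps = p$n_snps, theta = p$theta, se = p$se,
    ci_low = p$ci_low, ci_high = p$ci_high, pvalue = p$pvalue,
    q = if (is.null(h)) NA_real_ else h$q,
    p_q = if (is.null(h)) NA_real_ else h$p_q,
    i2 = if (is.null(h)) NA_real_ else h$i2,
    egger_intercept = if (is.null(x$egger)) NA_real_ else
      x$egger$pleiotropy$egger_intercept,
    p_egger_intercept = if (is.null(x$egger)) NA_real_ else
      x$egger$pleiotropy$p_intercept,
    p_presso_global = if (is.null(x$presso)) NA_real_ else x$presso$p_global,
    n_presso_outliers = if (is.null(x$presso)) NA_integer_ else
      length(x$presso$outliers),
    stringsAsFactors = FALSE
  )
}
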