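test_that("Wald ratio follows the first-order delta formula", {
  p <- make_pairs(0.5, 0.05, 0.1, 0.02)
  f <- mr_fit(p, "wald")
  expect_equal(f$theta, 0.2)
  expect_equal(f$se, 0.04)
  expect_equal(f$ci_low, 0.2 - qnorm(0.975) * 0.04)
  # null outcome effect: estimate 0, p = 1
  f0 <- mr_fit(make_pairs(0.5, 0.05, 0, 0.02), "wald")
  expect_equal(f0$theta, 0)
  expect_equal(f0$pvalue, 1)
  expect_error(mr_fit(make_pairs(0, 0.05, 0.1, 0.02), "wald"), "undefined")
})

test_that("second-order Wald SE adds the exposure-noise term predictably", {
  bx <- 0.5; bxse <- 0.05; by <- 0.1; byse <- 0.02
  p <- make_pairs(bx, bxse, by, byse)
  se1 <- mr_fit(p, "wald")$se
  se2 <- mr_fit(p, "wald", second_order = TRUE)$se
  expect_equal(se2, sqrt(byse^2 / bx^2 + by^2 * bxse^2 / bx^4))
  expect_gt(se2, se1)
  expect_equal(se2^2 - se1^2, by^2 * bxse^2 / bx^4)
})

test_that("single-instrument IVW is identical to the Wald ratio", {
  p <- make_pairs(0.4, 0.03, 0.12, 0.025)
  w <- mr_fit(p, "wald")
  i <- mr_fit(p, "ivw_fixed")
  expect_equal(i$theta, w$theta, tolerance = 1e-12)
  expect_equal(i$se, w$se, tolerance = 1e-12)
})

test_that("exact proportional effects give Q = 0 and equal fixed/MRE SEs", {
  bx <- c(0.2, 0.35, 0.5, 0.65)
  p <- make_pairs(bx, 0.05, 0.3 * bx, 0.02)
  ff <- mr_fit(p, "ivw_fixed")
  fm <- mr_fit(p, "ivw_mre")
  expect_equal(ff$theta, 0.3, tolerance = 1e-12)
  expect_equal(ff$heterogeneity$q, 0, tolerance = 1e-20)
  expect_equal(ff$heterogeneity$i2, 0)
  expect_equal(fm$se, ff$se, tolerance = 1e-12)
})

test_that("IVW equals an independent weighted least-squares fit through the origin", {
  p <- simulate_pairs(5, seq(0.2, 0.6, length.out = 5), theta = 0.25,
                      seed = 31)
  f <- mr_fit(p, "ivw_fixed")
  o <- lm(beta_y ~ 0 + beta_x, data = p, weights = 1 / p$se_y^2)
  expect_equal(f$theta, unname(coef(o)), tolerance = 1e-12)
  # fixed-effect SE is the WLS SE with residual scale fixed at 1
  se_wls <- sqrt(1 / sum(p$beta_x^2 / p$se_y^2))
  expect_equal(f$se, se_wls, tolerance = 1e-12)
  # MRE scales by the dispersion, never below the fixed SE
  fm <- mr_fit(p, "ivw_mre")
  expect_gte(fm$se, f$se)
})

test_that("correlated-instrument IVW reduces to fixed IVW under identity LD and collapses duplicates", {
  p <- simulate_pairs(4, seq(0.2, 0.5, length.out = 4), theta = 0.3,
                      seed = 17)
  ld <- diag(4); dimnames(ld) <- list(p$rsid, p$rsid)
  expect_equal(mr_fit(p, "ivw_correlated", ld = ld)$theta,
               mr_fit(p, "ivw_fixed")$theta, tolerance = 1e-12)
  expect_equal(mr_fit(p, "ivw_correlated", ld = ld)$se,
               mr_fit(p, "ivw_fixed")$se, tolerance = 1e-12)
  # duplicated instrument contributes no information
  one <- make_pairs(0.5, 0.05, 0.15, 0.02)
  dup <- make_pairs(c(0.5, 0.5), 0.05, c(0.15, 0.15), 0.02)
  eps <- 1e-6
  ld2 <- matrix(c(1, 1 - eps, 1 - eps, 1), 2)
  dimnames(ld2) <- list(dup$rsid, dup$rsid)
  fd <- mr_fit(dup, "ivw_correlated", ld = ld2)
  fw <- mr_fit(one, "wald")
  expect_equal(fd$theta, fw$theta, tolerance = 1e-6)
  expect_equal(fd$se, fw$se, tolerance = 1e-2)
})

test_that("MR-Egger recovers exact linear data and reduces to IVW without pleiotropy", {
  bx <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  p <- make_pairs(bx, 0.05, 0.01 + 0.2 * bx, 0.02)
  f <- mr_fit(p, "egger")
  expect_equal(f$theta, 0.2, tolerance = 1e-12)
  expect_equal(f$pleiotropy$egger_intercept, 0.01, tolerance = 1e-12)
  # zero intercept & equal weights: slope equals IVW... only with the
  # intercept constrained; unconstrained slope still matches on exact data
  p0 <- make_pairs(bx, 0.05, 0.2 * bx, 0.02)
  expect_equal(mr_fit(p0, "egger")$theta,
               mr_fit(p0, "ivw_fixed")$theta, tolerance = 1e-12)
  expect_equal(mr_fit(p0, "egger")$pleiotropy$egger_intercept, 0,
               tolerance = 1e-12)
  expect_error(mr_fit(make_pairs(c(0.2, 0.3), 0.05, c(0.1, 0.1), 0.02),
                      "egger"), "insufficient")
})

test_that("Egger matches a weighted lm fit with truncated over-dispersion", {
  p <- simulate_pairs(8, seq(0.2, 0.9, length.out = 8), theta = 0.2,
                      pleiotropy = list(type = "balanced", sd = 0.05),
                      seed = 23)
  f <- mr_fit(p, "egger")
  o <- lm(beta_y ~ beta_x, data = p, weights = 1 / p$se_y^2)
  expect_equal(f$theta, unname(coef(o)["beta_x"]), tolerance = 1e-10)
  expect_equal(f$pleiotropy$egger_intercept,
               unname(coef(o)["(Intercept)"]), tolerance = 1e-10)
  sig <- summary(o)$sigma
  se_lm <- summary(o)$coefficients["beta_x", "Std. Error"]
  expect_equal(f$se, se_lm / sig * max(1, sig), tolerance = 1e-10)
})

test_that("Egger is invariant to allele re-orientation of individual variants", {
  p <- simulate_pairs(6, seq(0.2, 0.7, length.out = 6), theta = 0.3,
                      seed = 5)
  p2 <- p
  p2$beta_x[c(2, 5)] <- -p2$beta_x[c(2, 5)]
  p2$beta_y[c(2, 5)] <- -p2$beta_y[c(2, 5)]
  f1 <- mr_fit(p, "egger"); f2 <- mr_fit(p2, "egger")
  expect_equal(f1$theta, f2$theta, tolerance = 1e-12)
  expect_equal(f1$pleiotropy$egger_intercept,
               f2$pleiotropy$egger_intercept, tolerance = 1e-12)
})

test_that("contamination mixture finds the homogeneous effect and profiles mixtures", {
  bx <- rep(0.5, 6)
  p <- make_pairs(bx, 0.01, 0.3 * bx, 0.002)
  f <- mr_fit(p, "conmix")
  expect_equal(f$theta, 0.3, tolerance = 0.005)
  expect_true(all(f$valid))
  # split population: two local maxima in the profile, mode at either
  p2 <- make_pairs(rep(0.5, 10), 0.01,
                   c(rep(0.15, 5), rep(0, 5)), 0.002)
  f2 <- mr_fit(p2, "conmix", psi = 0.2)
  ll <- f2$profile$loglik
  local_max <- which(diff(sign(diff(ll))) == -2) + 1
  modes <- f2$profile$theta[local_max]
  expect_true(any(abs(modes - 0.3) < 0.02))
  expect_true(any(abs(modes - 0) < 0.02))
  expect_equal(sum(f2$valid), 5)
  # single instrument degenerates to the Wald ratio as the grid refines
  p1 <- make_pairs(0.5, 0.05, 0.1, 0.02)
  f1 <- mr_fit(p1, "conmix", psi = 0.1,
               theta_grid = seq(0.1, 0.3, length.out = 20001))
  expect_equal(f1$theta, 0.2, tolerance = 1e-4)
})

test_that("the primary dispatch rule follows the instrument count", {
  mk <- function(n) simulate_pairs(n, 0.4, theta = 0.2, seed = n)
  expect_equal(mr_fit(mk(1), "auto")$method, "wald")
  expect_equal(mr_fit(mk(2), "auto")$method, "ivw_fixed")
  expect_equal(mr_fit(mk(3), "auto")$method, "ivw_fixed")
  expect_equal(mr_fit(mk(4), "auto")$method, "ivw_mre")
  expect_equal(select_primary(mk(5))$method, "ivw_mre")
  expect_error(mr_fit(mk(5)[0, ]), "empty")
})

test_that("estimates are scale-equivariant in exposure and outcome units", {
  p <- simulate_pairs(6, seq(0.2, 0.7, length.out = 6), theta = 0.25,
                      seed = 13)
  k <- 2.5
  for (m in c("ivw_fixed", "ivw_mre", "egger")) {
    base <- mr_fit(p, m)
    px <- p; px$beta_x <- k * px$beta_x; px$se_x <- k * px$se_x
    expect_equal(mr_fit(px, m)$theta, base$theta / k, tolerance = 1e-10,
                 label = paste(m, "exposure scaling"))
    py <- p; py$beta_y <- k * py$beta_y; py$se_y <- k * py$se_y
    expect_equal(mr_fit(py, m)$theta, base$theta * k, tolerance = 1e-10,
                 label = paste(m, "outcome scaling"))
  }
})

test_that("odds-ratio reporting is the exact exponential of the log-scale estimate", {
  p <- simulate_pairs(4, 0.4, theta = 0.2, seed = 3)
  f <- mr_fit(p)
  s <- summary(f, exponentiate = TRUE)
  expect_output(print(s), sprintf("OR = %.4g", exp(f$theta)))
  expect_identical(exp(f$theta), exp(1)^f$theta)
})

test_that("fit objects print, summarise, and expose coefficients and intervals", {
  p <- simulate_pairs(5, 0.4, theta = 0.2, seed = 8)
  f <- mr_fit(p)
  expect_output(print(f), "Two-sample MR estimate")
  expect_named(coef(f), "theta")
  ci <- confint(f)
  expect_equal(unname(ci[1, ]), c(f$ci_low, f$ci_high), tolerance = 1e-12)
  fe <- mr_fit(p, "egger")
  expect_named(coef(fe), c("intercept", "theta"))
  b <- mr_battery(p, n_sim = 200, seed = 4)
  row <- as.data.frame(b)
  expect_equal(nrow(row), 1)
  expect_false(any(is.na(c(row$theta, row$p_q, row$p_egger_intercept,
                           row$p_presso_global))))
})
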