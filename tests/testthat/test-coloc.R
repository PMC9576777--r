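test_that("Wakefield log-ABF matches a directly coded Gaussian marginal-likelihood ratio", {
  beta <- 0.1; se <- 0.02; w <- 0.2
  # oracle: log[ N(beta; 0, se^2 + w^2) / N(beta; 0, se^2) ]
  oracle <- dnorm(beta, 0, sqrt(se^2 + w^2), log = TRUE) -
    dnorm(beta, 0, se, log = TRUE)
  expect_equal(wakefield_labf(beta, se, w), oracle, tolerance = 1e-12)
  # null estimate: evidence for the null, negative log-ABF
  r <- w^2 / (w^2 + se^2)
  expect_equal(wakefield_labf(0, se, w), 0.5 * log1p(-r))
  expect_lt(wakefield_labf(0, se, w), 0)
  # degenerate prior: no evidence either way
  expect_equal(wakefield_labf(0.1, 0.02, 1e-8), 0, tolerance = 1e-10)
})

test_that("pairwise posteriors match exhaustive enumeration on small regions", {
  set.seed(19)
  for (rep in 1:5) {
    q <- sample(3:5, 1)
    assoc <- list(
      t1 = make_assoc(paste0("s", 1:q), pos = 1:q * 1000,
                      beta = rnorm(q, 0, 0.08), se = 0.02, trait_id = "t1"),
      t2 = make_assoc(paste0("s", 1:q), pos = 1:q * 1000,
                      beta = rnorm(q, 0, 0.08), se = 0.02, trait_id = "t2"))
    region <- regional_assoc(assoc, maf_min = 0, info_min = 0)
    cfg <- coloc_config()
    res <- pairwise_coloc(region, cfg)
    oracle <- enumerate_pairwise_coloc(
      wakefield_labf(region$beta[, 1], region$se[, 1], cfg$sd_quant),
      wakefield_labf(region$beta[, 2], region$se[, 2], cfg$sd_quant),
      cfg$p_single, cfg$p_single, cfg$p12)
    expect_equal(unname(res$pp), unname(oracle), tolerance = 1e-10)
    expect_equal(sum(res$pp), 1, tolerance = 1e-8)
    expect_equal(sum(res$variant_share), 1, tolerance = 1e-8)
  }
})

test_that("one-sided evidence lands on H1 and a shared strong signal on H4", {
  q <- 12
  strong <- c(rep(0, 5), 0.16, rep(0, 6))   # z = 8 at variant 6
  a1 <- make_assoc(paste0("s", 1:q), pos = 1:q * 1000, beta = strong,
                   se = 0.02, trait_id = "t1")
  null2 <- make_assoc(paste0("s", 1:q), pos = 1:q * 1000, beta = 0,
                      se = 0.02, trait_id = "t2")
  r_h1 <- pairwise_coloc(regional_assoc(list(t1 = a1, t2 = null2),
                                        maf_min = 0))
  expect_gt(r_h1$pp["H1"], 0.5)
  r_h4 <- pairwise_coloc(regional_assoc(list(t1 = a1, t2 = a1),
                                        maf_min = 0))
  expect_gt(r_h4$pp_coloc, 0.95)
  expect_equal(r_h4$candidate_variant, "s6")
})

test_that("regional filters drop low-MAF and low-INFO variants around the lead", {
  a <- make_assoc(paste0("s", 1:5), pos = c(1e6, 1.2e6, 1.4e6, 1.6e6, 4e6),
                  beta = c(0.2, 0.1, 0.05, 0.02, 0.01), se = 0.02,
                  eaf = c(0.3, 0.005, 0.3, 0.3, 0.3),
                  info = c(1, 1, 0.5, 1, 1))
  region <- regional_assoc(list(t1 = a, t2 = a))
  # s2 fails MAF, s3 fails INFO, s5 is outside the 1 Mb window
  expect_setequal(region$variants$rsid, c("s1", "s4"))
})

test_that("the multi-trait posterior agrees with pairwise H4 for two traits", {
  region <- simulate_coloc_scenario("coloc_shared", n_traits = 2,
                                    z_lead = 6, seed = 29)
  for (mode in c("uniform", "conservative")) {
    cfg <- coloc_config(prior_mode = mode)
    pw <- pairwise_coloc(region, cfg)
    cl <- multitrait_coloc(region, cfg)
    expect_equal(attr(cl, "full_pp"), pw$pp_coloc, tolerance = 1e-10)
  }
})

test_that("raising gamma never raises the colocalization posterior", {
  region <- simulate_coloc_scenario("coloc_shared", n_traits = 3,
                                    z_lead = 5, seed = 37)
  pps <- vapply(c(0.9, 0.95, 0.98, 0.995), function(g) {
    cl <- multitrait_coloc(region, coloc_config("conservative", gamma = g))
    attr(cl, "full_pp")
  }, numeric(1))
  expect_true(all(diff(pps) <= 1e-12))
})

test_that("planted shared and distinct causal variants are resolved into clusters", {
  shared <- simulate_coloc_scenario("coloc_shared", n_traits = 4,
                                    z_lead = 8, seed = 41)
  cl <- multitrait_coloc(shared)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$trait_subset, paste0("trait_", 1:4))
  expect_gte(cl[[1]]$pp_coloc, 0.7)
  truth <- attr(shared, "truth")
  expect_equal(cl[[1]]$candidate_variant,
               shared$variants$rsid[truth$causal_index[1]])

  distinct <- simulate_coloc_scenario("coloc_distinct", n_traits = 4,
                                      z_lead = 8, seed = 43)
  cl2 <- multitrait_coloc(distinct)
  expect_length(cl2, 2)
  groups <- lapply(cl2, `[[`, "trait_subset")
  expect_setequal(vapply(groups, paste, "", collapse = "+"),
                  c("trait_1+trait_3", "trait_2+trait_4"))
  # pairwise view of a distinct pair: H3 dominant
  sub <- distinct
  sub$beta <- sub$beta[, c(1, 2)]; sub$se <- sub$se[, c(1, 2)]
  sub$trait_ids <- sub$trait_ids[1:2]; sub$trait_types <- sub$trait_types[1:2]
  pw <- pairwise_coloc(sub)
  expect_gt(pw$pp["H3"], 0.5)

  null <- simulate_coloc_scenario("null", n_traits = 2, seed = 47)
  expect_gt(pairwise_coloc(null)$pp["H0"], 0.9)
})

test_that("shared-variant colocalization is detected in most replicates at lead z of 8", {
  reps <- 60
  hit <- vapply(seq_len(reps), function(i) {
    region <- simulate_coloc_scenario("coloc_shared", n_traits = 2,
                                      z_lead = 8, seed = 5000 + i)
    length(multitrait_coloc(region)) == 1
  }, logical(1))
  expect_gte(mean(hit), 0.8)
})
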