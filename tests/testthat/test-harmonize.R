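test_that("summary statistics survive a write/read round trip with dialect mapping", {
  x <- make_assoc(c("rs1", "rs2", "rs3"), beta = c(0.2, -0.1, 0.05))
  f <- tempfile(fileext = ".tsv")
  y <- x
  names(y)[names(y) == "beta"] <- "Effect"
  names(y)[names(y) == "se"] <- "StdErr"
  write.table(y, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_summary_stats(f, dialect = c(beta = "Effect", se = "StdErr"))
  expect_equal(nrow(back), 3)
  expect_equal(back$beta, x$beta)
  expect_equal(back$se, x$se)
  expect_identical(attr(back, "rejected")$reason, character(0))
  expect_error(read_summary_stats(f, dialect = c(beta = "nope")),
               "not present")
  unlink(f)
})

test_that("rows violating invariants are rejected with a reason, or error in strict mode", {
  x <- make_assoc(c("rs1", "rs2"), beta = 0.1)
  x$se[2] <- 0
  f <- tempfile(fileext = ".tsv")
  write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ok <- read_summary_stats(f), "failed validation")
  expect_equal(ok$rsid, "rs1")
  expect_equal(attr(ok, "rejected")$reason, "se not > 0")
  expect_error(read_summary_stats(f, drop_invalid = FALSE), "invalid")
  unlink(f)
})

test_that("missing required columns are a configuration error", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(rsid = "rs1", beta = 0.1), f, row.names = FALSE)
  expect_error(read_summary_stats(f), "missing required column")
  unlink(f)
})

test_that("outcome coded on the other allele is sign- and frequency-flipped", {
  ex <- make_assoc("rs1", effect_allele = "A", other_allele = "G",
                   beta = 0.2, eaf = 0.8)
  ou <- make_assoc("rs1", effect_allele = "G", other_allele = "A",
                   beta = 0.3, eaf = 0.1, trait_id = "y")
  h <- harmonize(ex, ou)
  expect_equal(h$beta_y, -0.3)
  expect_equal(h$eaf_y, 0.9)
  expect_true(h$flipped)
  # identical coding: untouched
  h2 <- harmonize(ex, make_assoc("rs1", effect_allele = "A",
                                 other_allele = "G", beta = 0.3, eaf = 0.8))
  expect_equal(h2$beta_y, 0.3)
  expect_false(h2$flipped)
})

test_that("palindromic variants follow the policy", {
  ex <- make_assoc("rs1", effect_allele = "A", other_allele = "T",
                   eaf = 0.5)
  ou <- make_assoc("rs1", effect_allele = "A", other_allele = "T",
                   eaf = 0.5)
  h <- harmonize(ex, ou, palindrome_policy = "drop")
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "exclusions")$reason, "palindromic")
  # inferable: both frequencies far from 0.5 and concordant -> retained
  ex2 <- make_assoc("rs1", effect_allele = "A", other_allele = "T",
                    eaf = 0.1, beta = 0.2)
  ou2 <- make_assoc("rs1", effect_allele = "A", other_allele = "T",
                    eaf = 0.12, beta = 0.3)
  h2 <- harmonize(ex2, ou2, palindrome_policy = "infer_by_eaf")
  expect_equal(h2$beta_y, 0.3)
  # discordant frequencies imply the other strand: flipped
  ou3 <- make_assoc("rs1", effect_allele = "A", other_allele = "T",
                    eaf = 0.88, beta = 0.3)
  h3 <- harmonize(ex2, ou3, palindrome_policy = "infer_by_eaf")
  expect_equal(h3$beta_y, -0.3)
  expect_equal(h3$eaf_y, 0.12)
  # ambiguous frequency -> dropped even under inference
  ou4 <- make_assoc("rs1", effect_allele = "A", other_allele = "T",
                    eaf = 0.5, beta = 0.3)
  h4 <- harmonize(ex2, ou4, palindrome_policy = "infer_by_eaf")
  expect_equal(nrow(h4), 0)
})

test_that("incompatible allele sets and position mismatches are excluded with reasons", {
  ex <- make_assoc(c("rs1", "rs2"), effect_allele = "A", other_allele = "G")
  ou <- make_assoc(c("rs1", "rs2"), effect_allele = c("A", "A"),
                   other_allele = c("C", "G"))
  ou$pos[2] <- 999999
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 0)
  reasons <- attr(h, "exclusions")
  expect_setequal(reasons$reason,
                  c("incompatible_alleles", "position_mismatch"))
})

test_that("strand-complement coding harmonizes to the same pairs", {
  set.seed(1)
  ex <- make_assoc(paste0("rs", 1:6), effect_allele = "A",
                   other_allele = "G", beta = rnorm(6, 0, 0.1), eaf = 0.3)
  ou <- make_assoc(paste0("rs", 1:6), effect_allele = "A",
                   other_allele = "G", beta = rnorm(6, 0, 0.1), eaf = 0.3,
                   trait_id = "y")
  h_same <- harmonize(ex, ou)
  ou_comp <- ou
  ou_comp$effect_allele <- "T"   # complement of A
  ou_comp$other_allele <- "C"    # complement of G
  h_comp <- harmonize(ex, ou_comp)
  expect_equal(h_comp$beta_y, h_same$beta_y)
  expect_equal(h_comp$eaf_y, h_same$eaf_y)
})

test_that("harmonization is an involution and swap-coding the whole outcome file is a no-op", {
  set.seed(2)
  n <- 8
  ex <- make_assoc(paste0("rs", 1:n), effect_allele = "A",
                   other_allele = "G", beta = rnorm(n, 0, 0.1),
                   eaf = runif(n, 0.1, 0.9))
  ou <- make_assoc(paste0("rs", 1:n), effect_allele = "A",
                   other_allele = "G", beta = rnorm(n, 0, 0.1),
                   eaf = runif(n, 0.1, 0.9), trait_id = "y")
  h1 <- harmonize(ex, ou)
  # re-feed the harmonized outcome side as an outcome file
  ou2 <- ou
  ou2$beta <- h1$beta_y
  ou2$eaf <- h1$eaf_y
  h2 <- harmonize(ex, ou2)
  expect_equal(h2$beta_y, h1$beta_y, tolerance = 1e-15)
  expect_false(any(h2$flipped))
  # flip every outcome row's allele coding: identical harmonized pairs
  ou3 <- ou
  ou3$effect_allele <- ou$other_allele
  ou3$other_allele <- ou$effect_allele
  ou3$beta <- -ou$beta
  ou3$eaf <- 1 - ou$eaf
  h3 <- harmonize(ex, ou3)
  expect_equal(h3$beta_y, h1$beta_y)
  expect_equal(h3$eaf_y, h1$eaf_y)
})
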