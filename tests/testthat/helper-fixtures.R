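# shared fixture builders and independent oracles used across test files

make_assoc <- function(rsid, chrom = "1", pos = seq_along(rsid) * 1000,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.02, pvalue = NULL,
                       info = 1, n = 5000, trait_id = "x",
                       trait_type = "quantitative") {
  k <- length(rsid)
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta / se))
  data.frame(rsid = rsid, chrom = rep_len(chrom, k), pos = rep_len(pos, k),
             effect_allele = rep_len(effect_allele, k),
             other_allele = rep_len(other_allele, k),
             eaf = rep_len(eaf, k), beta = rep_len(beta, k),
             se = rep_len(se, k), pvalue = rep_len(pvalue, k),
             info = rep_len(info, k), n = rep_len(n, k),
             trait_id = rep_len(trait_id, k),
             trait_type = rep_len(trait_type, k), stringsAsFactors = FALSE)
}

make_pairs <- function(beta_x, se_x, beta_y, se_y,
                       rsid = paste0("snp_", seq_along(beta_x))) {
  data.frame(rsid = rsid, chrom = "1", pos = seq_along(beta_x) * 1e5,
             effect_allele = "A", other_allele = "G",
             beta_x = beta_x, se_x = rep_len(se_x, length(beta_x)),
             pvalue_x = NA_real_, eaf = 0.3,
             beta_y = beta_y, se_y = rep_len(se_y, length(beta_x)),
             pvalue_y = NA_real_, eaf_y = 0.3,
             flipped = FALSE, palindromic = FALSE, stringsAsFactors = FALSE)
}

# independent brute-force oracle for two-trait colocalization: enumerate
# every configuration (c1, c2) of causal-variant assignments, c = 0 meaning
# no association, and sum plain-scale ABF products per hypothesis
enumerate_pairwise_coloc <- function(labf1, labf2, p1, p2, p12) {
  q <- length(labf1)
  abf1 <- exp(labf1); abf2 <- exp(labf2)
  h <- c(H0 = 1, H1 = 0, H2 = 0, H3 = 0, H4 = 0)
  for (c1 in 0:q) for (c2 in 0:q) {
    if (c1 == 0 && c2 == 0) next
    lik <- (if (c1 > 0) abf1[c1] else 1) * (if (c2 > 0) abf2[c2] else 1)
    if (c1 > 0 && c2 == 0) h["H1"] <- h["H1"] + p1 * lik
    else if (c1 == 0 && c2 > 0) h["H2"] <- h["H2"] + p2 * lik
    else if (c1 != c2) h["H3"] <- h["H3"] + p1 * p2 * lik
    else h["H4"] <- h["H4"] + p12 * lik
  }
  h / sum(h)
}

# independent generalized-least-squares oracle using explicit inversion
gls_ivw_oracle <- function(bx, by, byse, r) {
  omega <- outer(byse, byse) * r
  oi <- solve(omega)
  theta <- drop(t(bx) %*% oi %*% by) / drop(t(bx) %*% oi %*% bx)
  se <- 1 / sqrt(drop(t(bx) %*% oi %*% bx))
  c(theta = theta, se = se)
}
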