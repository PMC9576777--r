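#' Wakefield approximate Bayes factor (log scale)
#'
#' Log approximate Bayes factor comparing association vs null for one
#' variant-trait pair from its marginal estimate and SE, under a normal
#' effect prior with SD `prior_sd`: with shrinkage
#' `r = prior_sd^2 / (prior_sd^2 + se^2)` and `z = beta/se`,
#' `log ABF = 0.5 log(1 - r) + 0.5 r z^2`.
#'
#' @param beta,se Marginal effect and standard error (vectorized; `se > 0`).
#' @param prior_sd Prior SD of the true effect (`> 0`); conventional values
#'   are 0.15 for quantitative traits (SD units) and 0.2 for binary traits
#'   (log-odds).
#' @return Log ABF (natural log), same length as `beta`.
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), all(prior_sd > 0))
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * log1p(-r) + 0.5 * r * (beta / se)^2
}

#' Colocalization configuration
#'
#' @param prior_mode `"uniform"` (default, the cited coloc defaults:
#'   `p1 = p2 = 1e-4`, `p12 = 1e-5`) or `"conservative"` (trait-level
#'   structure: per-variant single-trait prior `p_single` and, for each
#'   additional colocalizing trait, factor `1 - gamma`; with the defaults,
#'   `1e-4 * 0.02 = 2e-6` per variant for two traits).
#' @param p_single Prior probability a variant is associated with one trait.
#' @param p12 Shared-variant prior for two traits under uniform mode.
#' @param gamma Conservative-mode trait-coupling parameter (default 0.98).
#' @param sd_quant,sd_binary Wakefield effect-prior SDs by trait type.
#' @param pp_threshold Posterior probability above which a trait set is
#'   declared colocalized (default 0.7).
#' @return List of class `coloc_config`.
#' @export
coloc_config <- function(prior_mode = c("uniform", "conservative"),
                         p_single = 1e-4, p12 = 1e-5, gamma = 0.98,
                         sd_quant = 0.15, sd_binary = 0.2,
                         pp_threshold = 0.7) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(p_single > 0, p_single < 1, gamma > 0, gamma < 1,
            p12 > 0, p12 < p_single)
  structure(list(prior_mode = prior_mode, p_single = p_single, p12 = p12,
                 gamma = gamma, sd_quant = sd_quant, sd_binary = sd_binary,
                 pp_threshold = pp_threshold),
            class = "coloc_config")
}

#' Assemble a regional multi-trait association object
#'
#' Aligns per-trait association records on a shared variant list (same
#' alleles and orientation assumed — harmonize first) and applies the
#' regional filters: variants within `window_bp` of the lead variant,
#' minor allele frequency at least `maf_min` (MAF taken as
#' `min(eaf, 1 - eaf)`), and imputation INFO at least `info_min` (variants
#' with missing INFO are kept).
#'
#' @param assoc_list Named list of association-record data.frames, one per
#'   trait, each covering the region.
#' @param trait_types Character vector (`"binary"`/`"quantitative"`) per
#'   trait; defaults to the `trait_type` column of each table.
#' @param lead_rsid Lead variant anchoring the window; default the variant
#'   with the smallest p-value in the first trait.
#' @param window_bp Window half-width around the lead (default 1 Mb).
#' @param maf_min,info_min Regional filters (defaults 0.01 and 0.8).
#' @return Object of class `regional_assoc`: list with `variants`
#'   (data.frame `rsid`, `chrom`, `pos`), matrices `beta` and `se`
#'   (variants x traits), `trait_ids`, `trait_types`.
#' @export
regional_assoc <- function(assoc_list, trait_types = NULL, lead_rsid = NULL,
                           window_bp = 1e6, maf_min = 0.01, info_min = 0.8) {
  stopifnot(length(assoc_list) >= 1)
  if (is.null(names(assoc_list)))
    names(assoc_list) <- paste0("trait", seq_along(assoc_list))
  first <- assoc_list[[1]]
  if (is.null(lead_rsid))
    lead_rsid <- first$rsid[which.min(first$pvalue)]
  lead <- first[first$rsid == lead_rsid, ]
  if (nrow(lead) != 1) stop("lead variant not found in first trait")
  shared <- Reduce(intersect, lapply(assoc_list, `[[`, "rsid"))
  first <- first[match(shared, first$rsid), ]
  keep <- abs(first$pos - lead$pos) <= window_bp &
    as.character(first$chrom) == as.character(lead$chrom) &
    pmin(first$eaf, 1 - first$eaf) >= maf_min
  for (a in assoc_list) {
    a <- a[match(shared, a$rsid), ]
    keep <- keep & (!is.finite(a$info) | a$info >= info_min) &
      pmin(a$eaf, 1 - a$eaf) >= maf_min
  }
  shared <- shared[keep]
  if (length(shared) < 1) stop("no variants left after regional filters")
  beta <- vapply(assoc_list,
                 function(a) a$beta[match(shared, a$rsid)],
                 numeric(length(shared)))
  se <- vapply(assoc_list,
               function(a) a$se[match(shared, a$rsid)],
               numeric(length(shared)))
  beta <- matrix(beta, ncol = length(assoc_list),
                 dimnames = list(shared, names(assoc_list)))
  se <- matrix(se, ncol = length(assoc_list),
               dimnames = list(shared, names(assoc_list)))
  if (is.null(trait_types))
    trait_types <- vapply(assoc_list, function(a)
      if ("trait_type" %in% names(a) && !is.na(a$trait_type[1]))
        a$trait_type[1] else "quantitative", character(1))
  first <- assoc_list[[1]]
  structure(list(
    variants = data.frame(rsid = shared,
                          chrom = first$chrom[match(shared, first$rsid)],
                          pos = first$pos[match(shared, first$rsid)],
                          stringsAsFactors = FALSE),
    beta = beta, se = se, trait_ids = names(assoc_list),
    trait_types = unname(trait_types)),
    class = "regional_assoc")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

region_labf <- function(region, config) {
  sds <- ifelse(region$trait_types == "binary", config$sd_binary,
                config$sd_quant)
  labf <- region$beta
  for (t in seq_along(sds))
    labf[, t] <- wakefield_labf(region$beta[, t], region$se[, t], sds[t])
  labf
}

#' Pairwise (two-trait) colocalization
#'
#' Enumerates the five colocalization hypotheses for two traits over a
#' region under the single-causal-variant-per-trait assumption: H0 no
#' association, H1/H2 association with one trait only, H3 both traits
#' associated through different variants, H4 both through a shared variant.
#' Posteriors combine per-variant Wakefield ABFs with per-variant priors
#' `p1 = p2 = p_single` and shared prior `p12` (under conservative mode
#' `p12 = p_single * (1 - gamma)`).
#'
#' @param region A `regional_assoc` restricted to two traits.
#' @param config A [coloc_config()].
#' @return Object of class `coloc_result`: `trait_subset`, `pp` (named
#'   vector H0-H4 summing to 1), `pp_coloc` (= PP H4), `candidate_variant`
#'   (top shared variant), `variant_share` (per-variant posterior share of
#'   H4, summing to 1).
#' @export
pairwise_coloc <- function(region, config = coloc_config()) {
  stopifnot(inherits(region, "regional_assoc"), ncol(region$beta) == 2)
  labf <- region_labf(region, config)
  q <- nrow(labf)
  p1 <- config$p_single
  p12 <- if (config$prior_mode == "conservative")
    config$p_single * (1 - config$gamma) else config$p12
  l1 <- logsumexp(labf[, 1]) + log(p1)
  l2 <- logsumexp(labf[, 2]) + log(p1)
  both <- labf[, 1] + labf[, 2]
  l4 <- logsumexp(both) + log(p12)
  # H3: distinct variants = all cross pairs minus the diagonal
  l3 <- if (q >= 2) {
    all_pairs <- logsumexp(labf[, 1]) + logsumexp(labf[, 2])
    diag_part <- logsumexp(both)
    # log(exp(all) - exp(diag)), guarded against cancellation
    d <- diag_part - all_pairs
    if (d >= 0) -Inf else all_pairs + log1p(-exp(d))
  } else {
    warning("single variant in region: H3 undefined, omitted")
    -Inf
  }
  l3 <- l3 + 2 * log(p1)
  lh <- c(H0 = 0, H1 = l1, H2 = l2, H3 = l3, H4 = l4)
  pp <- exp(lh - logsumexp(lh))
  share <- exp(both - logsumexp(both))
  structure(list(trait_subset = region$trait_ids,
                 pp = pp, pp_coloc = unname(pp["H4"]),
                 candidate_variant = region$variants$rsid[which.max(share)],
                 variant_share = share),
            class = "coloc_result")
}

#' Multi-trait colocalization with greedy subset search
#'
#' Posterior probability that all supplied traits share one causal variant,
#' under a single-causal-variant product-of-ABF model: the shared
#' configuration at variant i has likelihood `prod_t ABF[i, t]` and prior
#' `p_single * f^(m-1)` per variant (`f = 1 - gamma` in conservative mode, a
#' flat `p12/p_single` analogue in uniform mode), normalized against the
#' factorized per-trait evidence so that for two traits the result is
#' exactly the pairwise H4 posterior. When the full set fails the
#' `pp_threshold`, a greedy subset search repeatedly removes the trait whose
#' exclusion maximally increases the colocalization posterior and recurses
#' on both parts, emitting every maximal trait cluster that passes.
#'
#' This is a deliberate simplification of branch-and-bound multi-trait
#' colocalization: it serves the same decision rule (clusters with
#' PP >= 0.7 and a per-variant posterior share) and is validated against
#' exhaustive enumeration in the two-trait case.
#'
#' @param region A `regional_assoc` with >= 2 traits.
#' @param config A [coloc_config()].
#' @return List of `coloc_result` clusters (possibly empty) with attribute
#'   `"full_pp"`, the colocalization posterior of the full trait set.
#' @export
multitrait_coloc <- function(region, config = coloc_config()) {
  stopifnot(inherits(region, "regional_assoc"), ncol(region$beta) >= 2)
  labf <- region_labf(region, config)
  res <- coloc_subset_search(labf, region, config,
                             seq_along(region$trait_ids))
  attr(res$clusters, "full_pp") <- res$full_pp
  res$clusters
}

coloc_pp_subset <- function(labf, config, traits) {
  m <- length(traits)
  p <- config$p_single
  f <- if (config$prior_mode == "conservative") 1 - config$gamma else
    config$p12 / config$p_single
  l_shared <- logsumexp(rowSums(labf[, traits, drop = FALSE]))
  log_prior_sh <- log(p) + (m - 1) * log(f)
  # factorized evidence: prod_t (1 + p * S_t), with the all-shared
  # configuration's prior corrected from p^m to the structured prior
  log_fact <- sum(vapply(traits, function(t)
    log1p(p * exp(logsumexp(labf[, t]))), numeric(1)))
  num <- log_prior_sh + l_shared
  corr <- m * log(p) + l_shared
  # denominator = exp(log_fact) + exp(num) - exp(corr); num >= corr always
  # (prior_sh >= p^m needs f >= p, true for defaults) -- compute stably
  den <- logsumexp(c(log_fact, num)) # then subtract corr term
  d <- corr - den
  den <- if (d >= 0) log_fact else den + log1p(-exp(d))
  list(pp = exp(num - den),
       share = {
    rs <- rowSums(labf[, traits, drop = FALSE])
    exp(rs - logsumexp(rs))
  })
}

coloc_subset_search <- function(labf, region, config, traits,
                                full_pp = NULL) {
  make_cluster <- function(traits, r) {
    structure(list(trait_subset = region$trait_ids[traits],
                   pp_coloc = r$pp,
                   candidate_variant =
                     region$variants$rsid[which.max(r$share)],
                   variant_share = r$share),
              class = "coloc_result")
  }
  # greedily peel off the trait whose exclusion most increases the
  # posterior until the retained set colocalizes or is exhausted, then
  # recurse on the peeled-off traits
  removed <- integer(0)
  current <- traits
  repeat {
    r <- coloc_pp_subset(labf, config, current)
    if (is.null(full_pp)) full_pp <- r$pp
    if (r$pp >= config$pp_threshold) {
      clusters <- list(make_cluster(current, r))
      break
    }
    if (length(current) <= 2) {
      clusters <- list()
      removed <- c(removed, current) # failed pair may split across groups
      break
    }
    pp_wo <- vapply(seq_along(current), function(i)
      coloc_pp_subset(labf, config, current[-i])$pp, numeric(1))
    drop_i <- which.max(pp_wo)
    removed <- c(removed, current[drop_i])
    current <- current[-drop_i]
  }
  if (length(removed) >= 2 && length(removed) < length(traits)) {
    rec <- coloc_subset_search(labf, region, config, sort(removed), full_pp)
    clusters <- c(clusters, rec$clusters)
  }
  list(clusters = clusters, full_pp = full_pp)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization of:", paste(x$trait_subset, collapse = ", "), "\n")
  if (!is.null(x$pp)) {
    cat("  PP(H0..H4):", paste(sprintf("%.3f", x$pp), collapse = " "), "\n")
  }
  cat(sprintf("  PP(colocalization) = %.3f; top variant %s (share %.2f)\n",
              x$pp_coloc, x$candidate_variant, max(x$variant_share)))
  invisible(x)
}
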