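#' Filter phenotypes by case count
#'
#' Binary phenotypes with fewer than `min_cases` cases are excluded for lack
#' of statistical power (a phenotype with exactly `min_cases` cases is
#' retained).
#'
#' @param metas data.frame of phenotype metadata with at least
#'   `phenotype_id` and `n_cases`.
#' @param min_cases Minimum case count (default 500).
#' @return Retained rows; attribute `"excluded"` holds the dropped rows.
#' @export
filter_phenotypes <- function(metas, min_cases = 500) {
  keep <- metas$n_cases >= min_cases
  out <- metas[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- metas[!keep, , drop = FALSE]
  out
}

#' Classify a phenotype effect as beneficial or deleterious
#'
#' Direction classification relative to the protein's effect on stroke: if a
#' hypothetical intervention raising the protein moves the phenotype risk in
#' the same direction as it moves stroke risk, the additional effect is
#' `"beneficial"` (treating the protein for stroke helps this phenotype
#' too); opposite directions are `"deleterious"`. A zero reference or
#' phenotype effect gives `"not_applicable"`.
#'
#' @param effect_on_phenotype,effect_on_stroke Signed log-scale effects
#'   (vectorized over the phenotype effect).
#' @return Character vector of `"beneficial"`, `"deleterious"`,
#'   `"not_applicable"`.
#' @export
classify_direction <- function(effect_on_phenotype, effect_on_stroke) {
  s <- sign(effect_on_phenotype) * sign(effect_on_stroke)
  out <- ifelse(is.na(s) | s == 0, "not_applicable",
                ifelse(s > 0, "beneficial", "deleterious"))
  out
}

#' Phenome-wide MR screen
#'
#' Runs the primary MR estimator for each (protein, phenotype) pair across a
#' phenome, applies the layered Bonferroni threshold
#' `alpha_family / (n_proteins * n_phenotypes)` (phenotype count taken after
#' case filtering), and classifies each estimate as beneficial or
#' deleterious relative to the protein's reference effect on stroke.
#'
#' @param pairs_by_protein Nested list: for each protein, a named list of
#'   harmonized-pair tables, one per phenotype (see [harmonize()]). An
#'   entry that is `NULL` or has zero rows yields a row with a missing
#'   estimate and reason `"no_overlapping_instruments"`.
#' @param phenotype_meta Phenotype metadata (see [filter_phenotypes()]).
#' @param stroke_effects Named numeric vector: each protein's signed
#'   log-scale reference effect on stroke. Proteins without a reference get
#'   `direction_class = "not_applicable"`.
#' @param alpha_family Family-wise error rate before correction (0.05).
#' @param min_cases Case-count filter (default 500).
#' @return data.frame of class `phemr_screen`: one row per retained
#'   (protein, phenotype) with the estimate, `significant`,
#'   `direction_class` and `reason`; attributes `"threshold"` (the layered
#'   Bonferroni p cut-off) and `"excluded_phenotypes"`.
#' @export
run_screen <- function(pairs_by_protein, phenotype_meta, stroke_effects,
                       alpha_family = 0.05, min_cases = 500) {
  metas <- filter_phenotypes(phenotype_meta, min_cases)
  n_prot <- length(pairs_by_protein)
  n_phen <- nrow(metas)
  if (n_prot < 1 || n_phen < 1) stop("empty screen")
  threshold <- alpha_family / (n_prot * n_phen)
  rows <- list()
  for (prot in names(pairs_by_protein)) {
    ref <- if (prot %in% names(stroke_effects)) stroke_effects[[prot]] else
      NA_real_
    for (ph in metas$phenotype_id) {
      pp <- pairs_by_protein[[prot]][[ph]]
      if (is.null(pp) || nrow(pp) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = prot, phenotype_id = ph, method = NA_character_,
          n_snps = 0L, theta = NA_real_, se = NA_real_, pvalue = NA_real_,
          significant = FALSE, direction_class = "not_applicable",
          reason = "no_overlapping_instruments", stringsAsFactors = FALSE)
        next
      }
      fit <- select_primary(pp)
      sig <- fit$pvalue <= threshold
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = prot, phenotype_id = ph, method = fit$method,
        n_snps = fit$n_snps, theta = fit$theta, se = fit$se,
        pvalue = fit$pvalue, significant = sig,
        direction_class = if (is.na(ref)) "not_applicable" else
          classify_direction(fit$theta, ref),
        reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "excluded_phenotypes") <- attr(metas, "excluded")
  class(out) <- c("phemr_screen", class(out))
  out
}

#' @export
print.phemr_screen <- function(x, ...) {
  sig <- x[!is.na(x$significant) & x$significant, , drop = FALSE]
  cat(sprintf("Phe-MR screen: %d protein-phenotype tests, threshold p <= %.3g\n",
              nrow(x), attr(x, "threshold")))
  cat(sprintf("  %d significant (%d beneficial, %d deleterious)\n",
              nrow(sig), sum(sig$direction_class == "beneficial"),
              sum(sig$direction_class == "deleterious")))
  invisible(x)
}
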