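#' Bonferroni thresholds of the screening pipeline
#'
#' Derives every significance threshold from the manifest counts rather
#' than hard-coding them: `alpha / n` at each layer. With the default
#' counts (308 proteins, 7 risk factors, 6 selected proteins x 784
#' phenotypes) these are `1.62e-4`, `0.007` (1 d.p. `0.0071`) and
#' `1.06e-5`.
#'
#' @param n_proteins Proteins tested in the primary MR.
#' @param n_risk_factors Risk factors in the two-step MR.
#' @param n_proteins_selected,n_phenotypes Layers of the phenome-wide
#'   screen correction.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `alpha_primary`, `alpha_riskfactor`, `alpha_screen`
#'   and a `provenance` character vector recording each denominator.
#' @export
mr_thresholds <- function(n_proteins = 308, n_risk_factors = 7,
                          n_proteins_selected = 6, n_phenotypes = 784,
                          alpha = 0.05) {
  stopifnot(n_proteins >= 1, n_risk_factors >= 1, n_proteins_selected >= 1,
            n_phenotypes >= 1)
  list(
    alpha_primary = alpha / n_proteins,
    alpha_riskfactor = alpha / n_risk_factors,
    alpha_screen = alpha / (n_proteins_selected * n_phenotypes),
    provenance = c(
      alpha_primary = sprintf("%g/%d", alpha, n_proteins),
      alpha_riskfactor = sprintf("%g/%d", alpha, n_risk_factors),
      alpha_screen = sprintf("%g/%d/%d", alpha, n_proteins_selected,
                             n_phenotypes)))
}

battery_row <- function(pairs, ld = NULL, n_sim = 600, seed = 1) {
  as.data.frame(mr_battery(pairs, ld = ld, n_sim = n_sim, seed = seed))
}

apply_gates <- function(row, alpha_primary, gate_alpha = 0.05) {
  # sensitivity gates that could not run (too few instruments) pass with
  # annotation, mirroring the conditional application of each test
  pass_na <- function(p, ge) is.na(p) | (if (ge) p >= gate_alpha else FALSE)
  row$pass_causal <- !is.na(row$pvalue) & row$pvalue <= alpha_primary
  row$pass_q <- pass_na(row$p_q, TRUE)
  row$pass_egger_intercept <- pass_na(row$p_egger_intercept, TRUE)
  row$pass_presso_global <- pass_na(row$p_presso_global, TRUE)
  row$verdict <- row$pass_causal & row$pass_q & row$pass_egger_intercept &
    row$pass_presso_global
  row
}

#' Primary proteome-to-outcome MR screen
#'
#' Runs the estimator battery for every (protein, outcome) pair, twice: once
#' restricted to cis instruments and once with cis and trans instruments
#' together. Each row carries the four decision gates — causal-estimate
#' p-value at the Bonferroni threshold, Cochran-Q p >= 0.05, Egger-intercept
#' p >= 0.05 and MR-PRESSO global p >= 0.05 — and a joint verdict. Proteins
#' passing in cis-only mode are flagged `primary_hit`; trans-inclusive rows
#' whose instruments touch a flagged pleiotropic locus are annotated (never
#' auto-promoted).
#'
#' @param panel Named list per protein; each element a named list per
#'   outcome of harmonized-pair tables carrying a `cis` column (`"cis"` /
#'   `"trans"` or logical).
#' @param thresholds Output of [mr_thresholds()]; `alpha_primary` is used.
#'   Defaults to `mr_thresholds(n_proteins = length(panel))`.
#' @param gate_alpha Level of the sensitivity gates (default 0.05).
#' @param flagged_loci Character vector of rsids at known pleiotropic loci.
#' @param n_sim_presso,seed MR-PRESSO settings.
#' @return data.frame, one row per (protein, outcome, mode) with estimates,
#'   sensitivity statistics, gates, `verdict` and `primary_hit`.
#' @export
run_primary_mr <- function(panel, thresholds = NULL, gate_alpha = 0.05,
                           flagged_loci = character(),
                           n_sim_presso = 600, seed = 1) {
  if (!length(panel)) stop("empty protein panel")
  if (is.null(thresholds))
    thresholds <- mr_thresholds(n_proteins = length(panel))
  rows <- list()
  for (prot in names(panel)) {
    outs <- panel[[prot]]
    if (!length(outs)) stop("protein ", prot, " has an empty outcome manifest")
    for (oc in names(outs)) {
      pairs <- outs[[oc]]
      cis_flag <- if (is.logical(pairs$cis)) pairs$cis else
        pairs$cis == "cis"
      for (mode in c("cis", "cis_trans")) {
        sub <- if (mode == "cis") pairs[cis_flag, , drop = FALSE] else pairs
        if (!nrow(sub)) next
        row <- battery_row(sub, n_sim = n_sim_presso, seed = seed)
        row <- apply_gates(row, thresholds$alpha_primary, gate_alpha)
        row <- cbind(data.frame(protein_id = prot, outcome_id = oc,
                                mode = mode, stringsAsFactors = FALSE), row)
        row$flagged_pleiotropic_locus <- mode == "cis_trans" &&
          any(sub$rsid %in% flagged_loci)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$primary_hit <- out$mode == "cis" & out$verdict
  attr(out, "alpha_primary") <- thresholds$alpha_primary
  out
}

#' Reverse-direction MR of outcomes onto hit proteins
#'
#' For each primary hit, instruments the outcome and estimates its effect on
#' the protein; hits whose reverse estimate passes the primary threshold are
#' flagged as possibly driven by reverse causation.
#'
#' @param reverse_panel Named list per protein of named lists per outcome of
#'   harmonized pairs with the outcome as exposure and the protein as
#'   outcome. Missing or empty entries yield rows marked untestable.
#' @param hits data.frame with `protein_id`, `outcome_id` (e.g. the
#'   `primary_hit` rows of [run_primary_mr()]).
#' @param alpha_primary Significance threshold for the reverse estimate.
#' @return data.frame: one row per hit with the reverse estimate,
#'   `reverse_flag`, and `untestable` where no outcome instruments exist.
#' @export
run_reverse_mr <- function(reverse_panel, hits, alpha_primary) {
  if (!nrow(hits)) return(data.frame())
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    prot <- hits$protein_id[i]; oc <- hits$outcome_id[i]
    pairs <- reverse_panel[[prot]][[oc]]
    if (is.null(pairs) || !nrow(pairs))
      return(data.frame(protein_id = prot, outcome_id = oc,
                        theta = NA_real_, se = NA_real_, pvalue = NA_real_,
                        n_snps = 0L, reverse_flag = FALSE, untestable = TRUE,
                        stringsAsFactors = FALSE))
    fit <- select_primary(pairs)
    data.frame(protein_id = prot, outcome_id = oc, theta = fit$theta,
               se = fit$se, pvalue = fit$pvalue, n_snps = fit$n_snps,
               reverse_flag = fit$pvalue <= alpha_primary,
               untestable = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-step MR with mediation decomposition
#'
#' Step 1 estimates each risk factor's effect on the outcome (gate:
#' `alpha_riskfactor`); step 2 estimates each hit protein's effect on each
#' risk factor (gate: `alpha_primary`). Mediation is decomposed only for
#' (protein, risk factor, outcome) triples where both steps pass and a
#' total effect is available — mirroring a screen restricted to proteins
#' with evidence in both MRs.
#'
#' @param step1_panel Named list per risk factor of harmonized pairs
#'   (risk-factor instruments on the outcome).
#' @param step2_panel Named list per protein of named lists per risk factor
#'   (protein instruments on the risk factor).
#' @param total_effects data.frame `protein_id`, `theta`, `se`: each
#'   protein's total effect on the outcome from the primary MR.
#' @param thresholds Output of [mr_thresholds()].
#' @return List with `step1`, `step2` estimate tables and `mediation`
#'   (data.frame of qualifying triples with indirect effect, SE, CI and
#'   proportion mediated; zero rows when nothing qualifies).
#' @export
run_two_step <- function(step1_panel, step2_panel, total_effects,
                         thresholds = mr_thresholds(
                           n_risk_factors = length(step1_panel))) {
  step1 <- do.call(rbind, lapply(names(step1_panel), function(rf) {
    fit <- select_primary(step1_panel[[rf]])
    data.frame(risk_factor = rf, theta = fit$theta, se = fit$se,
               pvalue = fit$pvalue, n_snps = fit$n_snps,
               pass = fit$pvalue <= thresholds$alpha_riskfactor,
               stringsAsFactors = FALSE)
  }))
  step2 <- do.call(rbind, lapply(names(step2_panel), function(prot) {
    do.call(rbind, lapply(names(step2_panel[[prot]]), function(rf) {
      fit <- select_primary(step2_panel[[prot]][[rf]])
      data.frame(protein_id = prot, risk_factor = rf, theta = fit$theta,
                 se = fit$se, pvalue = fit$pvalue, n_snps = fit$n_snps,
                 pass = fit$pvalue <= thresholds$alpha_primary,
                 stringsAsFactors = FALSE)
    }))
  }))
  med_rows <- list()
  if (!is.null(step2) && nrow(step2)) {
    for (i in which(step2$pass)) {
      rf <- step2$risk_factor[i]; prot <- step2$protein_id[i]
      s1 <- step1[step1$risk_factor == rf, ]
      tot <- total_effects[total_effects$protein_id == prot, ]
      if (!nrow(s1) || !s1$pass || !nrow(tot)) next
      m <- mediate(tot$theta[1], tot$se[1], step2$theta[i], step2$se[i],
                   s1$theta, s1$se)
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        protein_id = prot, risk_factor = rf,
        beta_eo = m$beta_eo, beta_em = m$beta_em, beta_mo = m$beta_mo,
        indirect = m$indirect, se_indirect = m$se_indirect,
        ci_low = m$ci_indirect[1], ci_high = m$ci_indirect[2],
        proportion = m$proportion,
        sign_mismatch = unname(m$flags["sign_mismatch"]),
        stringsAsFactors = FALSE)
    }
  }
  mediation <- if (length(med_rows)) do.call(rbind, med_rows) else
    data.frame(protein_id = character(), risk_factor = character(),
               proportion = numeric(), stringsAsFactors = FALSE)
  list(step1 = step1, step2 = step2, mediation = mediation,
       thresholds = thresholds)
}

#' Assemble a machine-readable results bundle
#'
#' Collects the pipeline stage tables into one structure, records the
#' threshold provenance of every gate, marks skipped stages explicitly, and
#' (optionally) writes each table as TSV. Given identical inputs and seeds
#' the bundle — and the files — are byte-identical across runs.
#'
#' @param primary,reverse,two_step,screen Stage outputs (any may be `NULL`:
#'   the report marks the stage `"skipped"`).
#' @param thresholds Output of [mr_thresholds()].
#' @param dir Output directory for TSV artifacts; `NULL` (default) skips
#'   writing.
#' @return List of class `mr_report` with `stages` (tables or the string
#'   `"skipped"`), `thresholds` and `summary` counts.
#' @export
run_report <- function(primary = NULL, reverse = NULL, two_step = NULL,
                       screen = NULL, thresholds = mr_thresholds(),
                       dir = NULL) {
  stage_or_skip <- function(x) if (is.null(x)) "skipped" else x
  stages <- list(primary = stage_or_skip(primary),
                 reverse = stage_or_skip(reverse),
                 two_step = stage_or_skip(two_step),
                 screen = stage_or_skip(screen))
  summary <- list(
    n_primary_hits = if (is.null(primary)) NA_integer_ else
      sum(primary$primary_hit),
    n_reverse_flagged = if (is.null(reverse) || !nrow(reverse)) NA_integer_
      else sum(reverse$reverse_flag),
    n_mediated = if (is.null(two_step)) NA_integer_ else
      nrow(two_step$mediation),
    n_screen_significant = if (is.null(screen)) NA_integer_ else
      sum(screen$significant, na.rm = TRUE))
  rep <- structure(list(stages = stages, thresholds = thresholds,
                        summary = summary),
                   class = "mr_report")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(stages)) {
      x <- stages[[nm]]
      if (is.character(x)) next
      tabs <- if (is.data.frame(x)) stats::setNames(list(x), nm) else
        stats::setNames(x[vapply(x, is.data.frame, logical(1))],
                        paste0(nm, "_", names(x)[vapply(x, is.data.frame,
                                                        logical(1))]))
      for (tn in names(tabs))
        utils::write.table(tabs[[tn]], file.path(dir, paste0(tn, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  rep
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR pipeline report\n")
  cat("  thresholds:",
      paste(names(x$thresholds$provenance), x$thresholds$provenance,
            sep = " = ", collapse = "; "), "\n")
  for (nm in names(x$stages))
    cat(sprintf("  stage %-9s %s\n", nm,
                if (is.character(x$stages[[nm]])) "skipped" else "present"))
  s <- x$summary
  cat(sprintf("  primary hits: %s; reverse-flagged: %s; mediated: %s; screen hits: %s\n",
              s$n_primary_hits, s$n_reverse_flagged, s$n_mediated,
              s$n_screen_significant))
  invisible(x)
}
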