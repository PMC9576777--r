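#' Read GWAS summary statistics from a delimited file
#'
#' Reads tab- or comma-delimited summary statistics (gzip-transparent) and
#' validates them into the standard association-record layout used throughout
#' the package: one row per variant-trait association with columns `rsid`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pvalue`, `info`, `n`, `trait_id`, `trait_type`.
#'
#' @param path Path to a delimited text file with a header row. Files ending
#'   in `.gz` are decompressed transparently.
#' @param dialect Named character vector or list mapping the standard column
#'   names (above) to the column names used in the file. Columns not named in
#'   the dialect are assumed to already use standard names. `info` and `n`
#'   may be absent (filled with `NA`).
#' @param trait_id,trait_type Used to fill the trait columns when the file
#'   does not carry them. `trait_type` must be `"binary"` or
#'   `"quantitative"`.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param drop_invalid If `TRUE` (default) rows failing validation (e.g.
#'   `se <= 0`, `eaf` outside `[0, 1]`, non-ACGT alleles) are dropped with a
#'   warning and reported in the `"rejected"` attribute of the result; if
#'   `FALSE` any invalid row is an error.
#'
#' @return A `data.frame` of validated association records. Attribute
#'   `"rejected"` holds the invalid rows together with a `reason` column.
#' @seealso [harmonize()], [validate_assoc()]
#' @export
read_summary_stats <- function(path, dialect = NULL, trait_id = NULL,
                               trait_type = NULL, sep = NULL,
                               drop_invalid = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    con <- file(path, "r")
    on.exit(close(con))
    hdr <- readLines(con, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  std <- c("rsid", "chrom", "pos", "effect_allele", "other_allele", "eaf",
           "beta", "se", "pvalue", "info", "n", "trait_id", "trait_type")
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    bad <- setdiff(names(dialect), std)
    if (length(bad)) stop("unknown standard column(s) in dialect: ",
                          paste(bad, collapse = ", "))
    missing_src <- setdiff(unname(dialect), names(raw))
    if (length(missing_src))
      stop("column(s) named in dialect not present in file: ",
           paste(missing_src, collapse = ", "))
    for (k in names(dialect)) names(raw)[names(raw) == dialect[[k]]] <- k
  }
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pvalue")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         " (supply a dialect mapping)")
  for (opt in c("info", "n")) if (!opt %in% names(raw)) raw[[opt]] <- NA_real_
  if (!"trait_id" %in% names(raw))
    raw$trait_id <- if (is.null(trait_id)) NA_character_ else trait_id
  if (!"trait_type" %in% names(raw))
    raw$trait_type <- if (is.null(trait_type)) NA_character_ else trait_type
  raw <- raw[std]
  raw$chrom <- as.character(raw$chrom)
  raw$effect_allele <- toupper(as.character(raw$effect_allele))
  raw$other_allele <- toupper(as.character(raw$other_allele))
  for (num in c("pos", "eaf", "beta", "se", "pvalue", "info", "n"))
    raw[[num]] <- suppressWarnings(as.numeric(raw[[num]]))
  validate_assoc(raw, drop_invalid = drop_invalid)
}

#' Validate association records
#'
#' Checks the row-level invariants of an association record table:
#' positive finite `se`, finite `beta`, `pvalue` in (0, 1], `eaf` in
#' \[0, 1\], `pos >= 1`, distinct A/C/G/T alleles, `info` in \[0, 1\] when
#' present.
#'
#' @param x A data.frame in the standard association-record layout.
#' @param drop_invalid Drop failing rows with a warning (`TRUE`) or raise an
#'   error (`FALSE`).
#' @return `x` with invalid rows removed; attribute `"rejected"` carries the
#'   removed rows and the first failed check per row (`reason`).
#' @export
validate_assoc <- function(x, drop_invalid = TRUE) {
  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- why
  }
  flag(!is.finite(x$beta), "non-numeric beta")
  flag(!is.finite(x$se) | x$se <= 0, "se not > 0")
  flag(!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1,
       "pvalue outside (0,1]")
  flag(!is.finite(x$eaf) | x$eaf < 0 | x$eaf > 1, "eaf outside [0,1]")
  flag(!is.finite(x$pos) | x$pos < 1, "pos < 1")
  ok_allele <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  flag(!ok_allele(x$effect_allele) | !ok_allele(x$other_allele),
       "allele not A/C/G/T string")
  flag(x$effect_allele == x$other_allele, "identical alleles")
  flag(is.finite(x$info) & (x$info < 0 | x$info > 1), "info outside [0,1]")
  bad <- !is.na(reason)
  if (any(bad)) {
    if (!drop_invalid)
      stop("invalid summary-statistic rows: ",
           paste(unique(reason[bad]), collapse = "; "))
    warning(sum(bad), " row(s) failed validation and were dropped")
  }
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  rejected <- x[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  attr(out, "rejected") <- rejected
  out
}

# DNA complement for strand checks; multi-base alleles complemented basewise
# (not reversed: GWAS summary files report plus/minus strand flips, not
# reverse complements of the reported string).
comp_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) comp_allele(a1) == a2

#' Harmonize exposure and outcome summary statistics to shared effect alleles
#'
#' Matches exposure and outcome association records on rsid and re-expresses
#' the outcome effect for the exposure's effect allele, so that downstream
#' two-sample MR sees both effects per copy of the same allele. When the
#' outcome's effect allele equals the exposure's other allele the outcome
#' beta is negated and its frequency replaced by `1 - eaf`. Outcome records
#' whose allele pair is the strand complement of the exposure pair are
#' complemented first. Palindromic variants (A/T or C/G), whose strand cannot
#' be resolved from the alleles, are handled by `palindrome_policy`.
#'
#' @param exposure,outcome Association-record data.frames (see
#'   [read_summary_stats()]).
#' @param palindrome_policy `"drop"` (default) excludes palindromic variants;
#'   `"infer_by_eaf"` keeps those whose effect-allele frequency is far enough
#'   from 0.5 on both sides to infer strand, and drops the rest.
#' @param eaf_threshold Frequency bound for strand inference: a palindromic
#'   variant is resolvable only when both frequencies lie outside the
#'   interval (`eaf_threshold`, `1 - eaf_threshold`). Default 0.42.
#' @param check_position If `TRUE` (default) variants whose chrom/pos differ
#'   between the two files (when both report them) are excluded.
#'
#' @return A data.frame of harmonized pairs: `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta_x`, `se_x`, `pvalue_x`, `eaf`,
#'   `beta_y`, `se_y`, `pvalue_y`, `eaf_y`, `flipped`, `palindromic`.
#'   Attribute `"exclusions"` is a data.frame (`rsid`, `reason`) logging
#'   every variant not emitted and why.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "infer_by_eaf"),
                      eaf_threshold = 0.42, check_position = TRUE) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (anyDuplicated(exposure$rsid) || anyDuplicated(outcome$rsid))
    stop("duplicate rsids within a file; resolve before harmonizing")
  excl <- list()
  note <- function(rsid, reason)
    excl[[length(excl) + 1L]] <<- data.frame(rsid = rsid, reason = reason,
                                             stringsAsFactors = FALSE)
  only_x <- setdiff(exposure$rsid, outcome$rsid)
  if (length(only_x)) note(only_x, "absent_from_outcome")
  m <- match(exposure$rsid, outcome$rsid)
  keep <- !is.na(m)
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[m[keep], , drop = FALSE]

  if (check_position) {
    both <- !is.na(ex$chrom) & !is.na(ou$chrom) &
      is.finite(ex$pos) & is.finite(ou$pos)
    mism <- both & (ex$chrom != ou$chrom | ex$pos != ou$pos)
    if (any(mism)) {
      note(ex$rsid[mism], "position_mismatch")
      ex <- ex[!mism, , drop = FALSE]; ou <- ou[!mism, , drop = FALSE]
    }
  }

  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  flip_same <- comp_allele(ou$effect_allele) == ex$effect_allele &
    comp_allele(ou$other_allele) == ex$other_allele
  flip_swap <- comp_allele(ou$effect_allele) == ex$other_allele &
    comp_allele(ou$other_allele) == ex$effect_allele
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  compatible <- same | swapped | flip_same | flip_swap
  if (any(!compatible)) {
    note(ex$rsid[!compatible], "incompatible_alleles")
    ok <- compatible
    ex <- ex[ok, , drop = FALSE]; ou <- ou[ok, , drop = FALSE]
    same <- same[ok]; swapped <- swapped[ok]; pal <- pal[ok]
  }
  # for palindromic variants same/swapped and the strand-flipped versions
  # coincide; orientation must come from frequency, handled below
  flipped <- !same & swapped | (!same & !swapped & !pal &
                                  comp_allele(ou$effect_allele) ==
                                  ex$other_allele)

  beta_y <- ifelse(flipped, -ou$beta, ou$beta)
  eaf_y <- ifelse(flipped, 1 - ou$eaf, ou$eaf)

  drop_pal <- rep(FALSE, nrow(ex))
  if (any(pal)) {
    if (palindrome_policy == "drop") {
      drop_pal <- pal
      if (any(pal)) note(ex$rsid[pal], "palindromic")
    } else {
      lo <- eaf_threshold; hi <- 1 - eaf_threshold
      clear <- function(f) is.finite(f) & (f < lo | f > hi)
      resolvable <- pal & clear(ex$eaf) & clear(eaf_y)
      # discordant frequency sides imply the outcome file is on the other
      # strand: the allele labels swap, so flip sign and frequency again
      discord <- resolvable & (sign(ex$eaf - 0.5) != sign(eaf_y - 0.5))
      beta_y[discord] <- -beta_y[discord]
      eaf_y[discord] <- 1 - eaf_y[discord]
      flipped[discord] <- !flipped[discord]
      drop_pal <- pal & !resolvable
      if (any(drop_pal)) note(ex$rsid[drop_pal], "palindromic_eaf_ambiguous")
    }
  }
  keep <- !drop_pal
  out <- data.frame(
    rsid = ex$rsid[keep], chrom = ex$chrom[keep], pos = ex$pos[keep],
    effect_allele = ex$effect_allele[keep], other_allele = ex$other_allele[keep],
    beta_x = ex$beta[keep], se_x = ex$se[keep], pvalue_x = ex$pvalue[keep],
    eaf = ex$eaf[keep],
    beta_y = beta_y[keep], se_y = ou$se[keep], pvalue_y = ou$pvalue[keep],
    eaf_y = eaf_y[keep],
    flipped = flipped[keep], palindromic = pal[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(rsid = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

#' Write a harmonized-pair table (and its exclusion log) to TSV
#'
#' @param pairs Output of [harmonize()].
#' @param path Output TSV path; the exclusion log, if non-empty, is written
#'   next to it with suffix `.exclusions.tsv`.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  excl <- attr(pairs, "exclusions")
  if (!is.null(excl) && nrow(excl))
    utils::write.table(excl, paste0(sub("\\.tsv$", "", path),
                                    ".exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
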