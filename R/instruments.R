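#' Greedy LD clumping of association records
#'
#' Selects approximately independent index variants the way PLINK-style
#' clumping does: candidates at `pvalue <= p_threshold` are visited in order
#' of increasing p-value; each visit retains the best remaining variant as an
#' index and removes every remaining candidate within `window_bp` of it whose
#' squared correlation with it is at least `r2_threshold`. Ties at equal
#' p-value are broken by chromosome, position, then rsid, so the result does
#' not depend on input row order.
#'
#' @param assocs Association-record data.frame for one trait (needs `rsid`,
#'   `chrom`, `pos`, `pvalue`).
#' @param ld Square correlation matrix (signed r, not r^2) with rsid
#'   dimnames, covering the candidate variants. Candidates absent from `ld`
#'   are excluded with a warning rather than assumed independent.
#' @param p_threshold Inclusion p-value threshold (default `5e-8`).
#' @param r2_threshold Squared-correlation threshold at or above which a
#'   variant joins an index variant's clump (default 0.1).
#' @param window_bp Half-width of the clumping window in base pairs
#'   (default 1 Mb). Variants farther than this from the index stay
#'   candidates regardless of LD.
#' @return The rows of `assocs` retained as index variants, in selection
#'   order. Attribute `"dropped_missing_ld"` lists candidate rsids absent
#'   from the LD matrix.
#' @export
ld_clump <- function(assocs, ld, p_threshold = 5e-8, r2_threshold = 0.1,
                     window_bp = 1e6) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  r <- if (is.list(ld) && !is.null(ld$r)) ld$r else ld
  if (is.null(rownames(r))) stop("LD matrix must carry rsid dimnames")
  cand <- assocs[assocs$pvalue <= p_threshold, , drop = FALSE]
  missing_ld <- setdiff(cand$rsid, rownames(r))
  if (length(missing_ld)) {
    warning(length(missing_ld),
            " candidate variant(s) absent from LD matrix; excluded")
    cand <- cand[!cand$rsid %in% missing_ld, , drop = FALSE]
  }
  ord <- order(cand$pvalue, cand$chrom, cand$pos, cand$rsid)
  cand <- cand[ord, , drop = FALSE]
  picked <- integer(0)
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    picked <- c(picked, i)
    alive[i] <- FALSE
    near <- alive & cand$chrom == cand$chrom[i] &
      abs(cand$pos - cand$pos[i]) <= window_bp
    if (any(near)) {
      r2 <- r[cand$rsid[near], cand$rsid[i]]^2
      alive[which(near)[r2 >= r2_threshold]] <- FALSE
    }
  }
  out <- cand[picked, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_missing_ld") <- missing_ld
  out
}

#' Classify variants as cis or trans relative to a gene
#'
#' A pQTL is cis when it lies on the same chromosome as the gene encoding
#' the target protein and within `window_bp` of the gene body (closed
#' interval `[start - window_bp, end + window_bp]`, 1-based coordinates);
#' otherwise trans.
#'
#' @param chrom,pos Variant coordinates (vectorized).
#' @param region List or one-row data.frame with `chrom`, `start`, `end`
#'   (and optionally `gene_id`) for the encoding gene.
#' @param window_bp Window half-width, default 1 Mb.
#' @return Character vector of `"cis"` / `"trans"`.
#' @export
classify_cis_trans <- function(chrom, pos, region, window_bp = 1e6) {
  stopifnot(region$start <= region$end)
  ifelse(as.character(chrom) == as.character(region$chrom) &
           pos >= region$start - window_bp & pos <= region$end + window_bp,
         "cis", "trans")
}

#' Instrument strength from summary statistics
#'
#' Summary-data approximations of per-variant instrument strength:
#' `f_stat = (beta/se)^2` and the variance in the exposure explained,
#' `r2 = F / (F + n - 2)`.
#'
#' @param beta,se,n Marginal effect, its standard error (> 0), and the
#'   exposure GWAS sample size. Vectorized. A missing `n` yields `NA` for
#'   `r2` while `f_stat` is still computed.
#' @return data.frame with columns `f_stat`, `r2`.
#' @export
instrument_strength <- function(beta, se, n = NA_real_) {
  stopifnot(all(se > 0))
  f <- (beta / se)^2
  r2 <- ifelse(is.finite(n) & n > 1, f / (f + n - 2), NA_real_)
  data.frame(f_stat = f, r2 = r2)
}

#' Build the instrument set for one protein
#'
#' Runs LD clumping on a protein's pQTL associations, annotates each retained
#' index variant as cis or trans relative to the encoding gene, and computes
#' per-instrument strength. The total variance explained sums per-instrument
#' R^2 (adequate for the approximately independent variants clumping emits).
#'
#' @param protein_id Protein identifier.
#' @param assocs pQTL association records for the protein.
#' @param ld LD correlation matrix (see [ld_clump()]).
#' @param gene_region Encoding-gene region (see [classify_cis_trans()]).
#' @param p_threshold,r2_threshold,window_bp Clumping settings.
#' @return An object of class `instrument_set`: list with `protein_id`,
#'   `instruments` (clumped records plus `cis`, `f_stat`, `r2`) and
#'   `total_r2`.
#' @export
build_instruments <- function(protein_id, assocs, ld, gene_region,
                              p_threshold = 5e-8, r2_threshold = 0.1,
                              window_bp = 1e6) {
  idx <- ld_clump(assocs, ld, p_threshold, r2_threshold, window_bp)
  idx$cis <- classify_cis_trans(idx$chrom, idx$pos, gene_region, window_bp)
  st <- instrument_strength(idx$beta, idx$se, idx$n)
  idx$f_stat <- st$f_stat
  idx$r2 <- st$r2
  structure(list(protein_id = protein_id, instruments = idx,
                 total_r2 = sum(st$r2, na.rm = TRUE)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set for", x$protein_id, "\n")
  cat(sprintf("  %d instrument(s): %d cis, %d trans\n",
              nrow(x$instruments), sum(x$instruments$cis == "cis"),
              sum(x$instruments$cis == "trans")))
  cat(sprintf("  total R^2 explained: %.4f; min per-IV F: %.1f\n",
              x$total_r2, min(x$instruments$f_stat)))
  invisible(x)
}

#' Read an LD matrix from a delimited file
#'
#' Expects a square matrix with a header row and first column both holding
#' rsids (row/column order must agree).
#'
#' @param path Delimited file (tab default).
#' @param sep Field separator.
#' @return Numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path, sep = "\t") {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                   row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("LD file is not a square rsid-labelled matrix")
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix is not symmetric")
  m
}
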