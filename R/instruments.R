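# Instrument selection: greedy LD clumping at a p-value / r-squared threshold
# and instrument-strength diagnostics.

#' Construct an LD matrix object
#'
#' @param r2 square symmetric matrix of squared correlations in \[0, 1\].
#' @param variant_ids row/column variant ids (defaults to dimnames).
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, variant_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(variant_ids)) stop("ld_matrix: variant ids required", call. = FALSE)
  if (nrow(r2) != ncol(r2)) stop("ld_matrix: matrix must be square", call. = FALSE)
  if (any(r2 < 0 | r2 > 1)) stop("ld_matrix: r2 values must lie in [0,1]", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("ld_matrix: diagonal must be 1", call. = FALSE)
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("ld_matrix: matrix must be symmetric", call. = FALSE)
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Expects a tab-separated file whose first row and first column hold variant
#' ids and whose body holds squared correlations.
#'
#' @param path file path.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, header = TRUE, row.names = 1,
                                   sep = "\t", check.names = FALSE))
  ld_matrix(m)
}

#' Write an LD matrix to TSV
#' @param ld an `ld_matrix`.
#' @param path output path.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(SNP = ld$variant_ids, ld$r2, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Select independent instruments by greedy LD clumping
#'
#' Candidates are variants with `P < p_threshold`. They are ranked by
#' ascending p-value (ties broken by chromosome then position); the best
#' remaining candidate is accepted and every remaining candidate with
#' `r2 >= r2_threshold` against it is discarded, until none remain. Pairs
#' absent from the LD matrix (e.g. across chromosomes) are treated as
#' independent only when *both* variants are present in the matrix;
#' sub-threshold variants missing from the matrix entirely are excluded with
#' a warning rather than assumed independent.
#'
#' @param records a `kinmr_assoc` table.
#' @param ld an `ld_matrix` covering the candidate variants.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param r2_threshold maximum squared correlation between retained
#'   instruments (default 0.001).
#' @return An object of class `instrument_set`: list with `trait_id`,
#'   `records` (retained rows, genomic order), `p_threshold`, `r2_threshold`.
#' @export
ld_clump <- function(records, ld, p_threshold = 5e-8, r2_threshold = 0.001) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- as.data.frame(records)
  cand <- df[df$P < p_threshold, , drop = FALSE]
  missing <- setdiff(cand$SNP, ld$variant_ids)
  if (length(missing)) {
    warning(sprintf("ld_clump: %d sub-threshold variant(s) absent from the LD matrix were excluded: %s",
                    length(missing), paste(utils::head(missing, 5), collapse = ", ")))
    cand <- cand[!(cand$SNP %in% missing), , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    warning("ld_clump: no variant passes the p-value threshold")
    return(structure(list(trait_id = df$trait_id[1],
                          records = df[0, , drop = FALSE],
                          p_threshold = p_threshold, r2_threshold = r2_threshold),
                     class = "instrument_set"))
  }
  chr_num <- suppressWarnings(as.numeric(cand$CHR))
  cand <- cand[order(cand$P, ifelse(is.na(chr_num), Inf, chr_num), cand$CHR, cand$POS), , drop = FALSE]
  r2 <- ld$r2[cand$SNP, cand$SNP, drop = FALSE]
  n <- nrow(cand)
  status <- rep("pending", n)
  for (i in seq_len(n)) {
    if (status[i] != "pending") next
    status[i] <- "kept"
    status[status == "pending" & r2[i, ] >= r2_threshold] <- "discarded"
  }
  kept <- cand[status == "kept", , drop = FALSE]
  chr_k <- suppressWarnings(as.numeric(kept$CHR))
  kept <- kept[order(ifelse(is.na(chr_k), Inf, chr_k), kept$CHR, kept$POS), , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("kinmr_assoc", "data.frame")
  structure(list(trait_id = df$trait_id[1], records = kept,
                 p_threshold = p_threshold, r2_threshold = r2_threshold),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for '%s': %d variant(s) at P < %g, r2 < %g\n",
              x$trait_id, nrow(x$records), x$p_threshold, x$r2_threshold))
  invisible(x)
}

#' Per-variant and mean instrument F-statistics
#'
#' The single-SNP F-statistic is (beta / se)^2, the square of the
#' instrument's z-score; the mean across instruments is the usual summary
#' reported to judge weak-instrument bias (rule of thumb: mean F > 10).
#'
#' @param set an `instrument_set` (or a `kinmr_assoc` table).
#' @return list with `f` (named per-variant vector) and `mean_f`.
#' @export
instrument_strength <- function(set) {
  rec <- if (inherits(set, "instrument_set")) set$records else as.data.frame(set)
  if (nrow(rec) == 0) stop("instrument_strength: empty instrument set", call. = FALSE)
  f <- (rec$BETA / rec$SE)^2
  names(f) <- rec$SNP
  list(f = f, mean_f = mean(f))
}
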