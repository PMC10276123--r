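# GWAS summary statistics: read, validate, write, harmonize.
#
# The canonical container throughout the package is an "assoc table": a
# data.frame with one row per variant and the ten schema columns
# SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N plus a trait_id attribute/column.

.SUMSTATS_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
.VALID_ALLELES <- c("A", "C", "G", "T")

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) .complement(ea) == oa

#' Build a validated association table
#'
#' Constructs the package's canonical per-variant association container from
#' vectors, applying the same invariant checks as [read_summary_stats()].
#' Effect sizes (`beta`) are per copy of the effect allele: SD units for
#' quantitative traits, change in the coded family-history outcome or
#' log-odds for disease traits.
#'
#' @param snp character variant ids (rsID or chr:pos:ref:alt).
#' @param chr chromosome labels (coerced to character).
#' @param pos 1-based positions.
#' @param ea,oa effect and other allele, single upper-case bases A/C/G/T.
#' @param eaf effect-allele frequency in \[0, 1\].
#' @param beta,se per-allele effect and its standard error (se > 0).
#' @param p association p-value in (0, 1\].
#' @param n sample size (>= 1).
#' @param trait_id label of the trait the effects refer to.
#' @return A data.frame of class `kinmr_assoc` with columns
#'   `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N, trait_id`.
#' @export
assoc_table <- function(snp, chr, pos, ea, oa, eaf, beta, se, p, n, trait_id) {
  df <- data.frame(
    SNP = as.character(snp), CHR = as.character(chr), POS = as.integer(pos),
    EA = toupper(as.character(ea)), OA = toupper(as.character(oa)),
    EAF = as.numeric(eaf), BETA = as.numeric(beta), SE = as.numeric(se),
    P = as.numeric(p), N = as.numeric(n),
    trait_id = trait_id, stringsAsFactors = FALSE
  )
  .validate_assoc(df)
  class(df) <- c("kinmr_assoc", "data.frame")
  df
}

.validate_assoc <- function(df, where = "association table") {
  bad <- list(
    "EA/OA not a single base A/C/G/T" = !(df$EA %in% .VALID_ALLELES) | !(df$OA %in% .VALID_ALLELES),
    "EA equals OA" = df$EA == df$OA,
    "EAF outside [0,1]" = !is.finite(df$EAF) | df$EAF < 0 | df$EAF > 1,
    "SE <= 0" = !is.finite(df$SE) | df$SE <= 0,
    "P outside (0,1]" = !is.finite(df$P) | df$P <= 0 | df$P > 1,
    "POS < 1" = !is.finite(df$POS) | df$POS < 1,
    "N < 1" = !is.finite(df$N) | df$N < 1
  )
  msgs <- character(0)
  for (reason in names(bad)) {
    idx <- which(bad[[reason]])
    if (length(idx)) {
      msgs <- c(msgs, sprintf("%s at row(s) %s", reason,
                              paste(utils::head(idx, 10), collapse = ", ")))
    }
  }
  if (length(msgs)) {
    stop(sprintf("validation error in %s: %s", where,
                 paste(msgs, collapse = "; ")), call. = FALSE)
  }
  invisible(df)
}

# chromosome sort key: numeric chromosomes first in numeric order, then others
.chr_order <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  key1 <- ifelse(is.na(num), Inf, num)
  order(key1, chr)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab-separated file whose header contains the ten schema columns
#' `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N` (any order). Rows violating
#' the record invariants raise a validation error naming the offending rows.
#' Duplicate variant ids are resolved by keeping the row with the lowest
#' p-value (a message reports how many were dropped). Records are returned
#' sorted by (chromosome, position).
#'
#' @param path file path.
#' @param trait_id trait label attached to every record.
#' @return A `kinmr_assoc` data.frame.
#' @export
read_summary_stats <- function(path, trait_id) {
  if (!file.exists(path)) stop(sprintf("I/O error: no such file '%s'", path), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.SUMSTATS_COLS, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("schema error in '%s': missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(
    SNP = raw$SNP, CHR = raw$CHR, POS = as.integer(raw$POS),
    EA = toupper(raw$EA), OA = toupper(raw$OA),
    EAF = as.numeric(raw$EAF), BETA = as.numeric(raw$BETA),
    SE = as.numeric(raw$SE), P = as.numeric(raw$P), N = as.numeric(raw$N),
    trait_id = trait_id, stringsAsFactors = FALSE
  )
  .validate_assoc(df, where = sprintf("'%s'", path))
  if (anyDuplicated(df$SNP)) {
    df <- df[order(df$P), , drop = FALSE]
    ndup <- sum(duplicated(df$SNP))
    df <- df[!duplicated(df$SNP), , drop = FALSE]
    message(sprintf("read_summary_stats: dropped %d duplicate variant id(s), keeping lowest p", ndup))
  }
  df <- df[.chr_order(df$CHR), , drop = FALSE]
  df <- df[order(match(df$CHR, unique(df$CHR)), df$POS), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("kinmr_assoc", "data.frame")
  df
}

#' Write a GWAS summary-statistics file
#'
#' Writes records in the fixed schema column order with full floating-point
#' precision, so that a read/write round trip reproduces the numbers exactly.
#'
#' @param records a `kinmr_assoc` data.frame (or compatible data.frame).
#' @param path output path.
#' @export
write_summary_stats <- function(records, path) {
  df <- as.data.frame(records)[, .SUMSTATS_COLS, drop = FALSE]
  # %.17g guarantees a lossless decimal representation of a double
  for (col in c("EAF", "BETA", "SE", "P", "N")) {
    df[[col]] <- sprintf("%.17g", as.numeric(df[[col]]))
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop(sprintf("I/O error writing '%s': %s", path,
                                conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

# Align one table's per-variant effects onto reference alleles.
# Returns list(beta, eaf, drop_reason) vectors in the order of `ref`.
.align_to_reference <- function(ref, tab, palindrome_policy, eaf_tolerance) {
  idx <- match(ref$SNP, tab$SNP)
  ea <- tab$EA[idx]; oa <- tab$OA[idx]
  beta <- tab$BETA[idx]; eaf <- tab$EAF[idx]; se <- tab$SE[idx]
  p <- tab$P[idx]; n <- tab$N[idx]
  drop <- rep(NA_character_, nrow(ref))
  pal <- .is_palindromic(ref$EA, ref$OA)

  same    <- ea == ref$EA & oa == ref$OA
  swapped <- ea == ref$OA & oa == ref$EA
  csame   <- .complement(ea) == ref$EA & .complement(oa) == ref$OA
  cswap   <- .complement(ea) == ref$OA & .complement(oa) == ref$EA

  flip <- rep(FALSE, nrow(ref))
  incompatible <- !(same | swapped | csame | cswap)
  drop[incompatible] <- "incompatible_alleles"
  flip[(swapped | cswap) & !pal & !incompatible] <- TRUE

  if (any(pal & !incompatible)) {
    which_pal <- which(pal & !incompatible)
    if (palindrome_policy == "drop") {
      drop[which_pal] <- "palindromic"
    } else { # infer-by-eaf
      amb <- abs(ref$EAF[which_pal] - 0.5) <= eaf_tolerance |
             abs(eaf[which_pal] - 0.5) <= eaf_tolerance
      drop[which_pal[amb]] <- "palindromic_ambiguous_eaf"
      inf <- which_pal[!amb]
      # frequencies on discordant sides of 0.5 imply opposite strand labelling
      flip[inf] <- (ref$EAF[inf] < 0.5) != (eaf[inf] < 0.5)
    }
  }
  beta[flip] <- -beta[flip]
  eaf[flip] <- 1 - eaf[flip]
  list(beta = beta, se = se, eaf = eaf, p = p, n = n, drop = drop)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Restricts to the variants common to every table and expresses all effects
#' on the first exposure's effect allele. Where another table's allele pair is
#' swapped (or strand-flipped) relative to the reference, its beta sign is
#' flipped and its effect-allele frequency complemented. Palindromic variants
#' (A/T, C/G), for which strand cannot be resolved from alleles, are handled
#' by `palindrome_policy`: `"drop"` removes them; `"infer-by-eaf"` aligns by
#' allele frequency when both frequencies lie outside
#' `0.5 +/- eaf_tolerance`, and removes them otherwise. Variants with
#' incompatible allele pairs are removed with a logged reason.
#'
#' @param exposures a single `kinmr_assoc` table or a list of them (K >= 1),
#'   each with a distinct `trait_id`.
#' @param outcome a `kinmr_assoc` table for the outcome trait.
#' @param palindrome_policy `"drop"` (default) or `"infer-by-eaf"`.
#' @param eaf_tolerance half-width of the ambiguity window around 0.5
#'   (default 0.08).
#' @return An object of class `harmonized_set`: a list with `exposure_ids`,
#'   `outcome_id`, `variants` (data.frame `SNP, CHR, POS, EA, OA`),
#'   `bx`/`bx_se` (n x K matrices), `by`/`by_se` (vectors), `eaf`, `n_outcome`
#'   and a `drops` data.frame (`SNP`, `reason`).
#' @export
harmonize <- function(exposures, outcome, palindrome_policy = c("drop", "infer-by-eaf"),
                      eaf_tolerance = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (is.data.frame(exposures)) exposures <- list(exposures)
  exp_ids <- vapply(exposures, function(e) e$trait_id[1], character(1))
  if (anyDuplicated(exp_ids)) {
    stop("harmonize: duplicate exposure trait_ids: ",
         paste(exp_ids[duplicated(exp_ids)], collapse = ", "), call. = FALSE)
  }
  tabs <- c(exposures, list(outcome))
  common <- Reduce(intersect, lapply(tabs, function(t) t$SNP))
  if (length(common) == 0) stop("harmonize: no variant common to all input tables", call. = FALSE)

  ref <- as.data.frame(exposures[[1]])
  ref <- ref[ref$SNP %in% common, , drop = FALSE]
  ref <- ref[order(match(ref$CHR, unique(ref$CHR)), ref$POS), , drop = FALSE]

  K <- length(exposures)
  nref <- nrow(ref)
  bx <- matrix(NA_real_, nref, K, dimnames = list(ref$SNP, exp_ids))
  bx_se <- bx
  bx[, 1] <- ref$BETA; bx_se[, 1] <- ref$SE
  drop_reason <- rep(NA_character_, nref)

  # palindromic reference variants under the drop policy are removed even for K = 1
  pal <- .is_palindromic(ref$EA, ref$OA)
  if (palindrome_policy == "drop") drop_reason[pal] <- "palindromic"
  if (palindrome_policy == "infer-by-eaf") {
    drop_reason[pal & abs(ref$EAF - 0.5) <= eaf_tolerance] <- "palindromic_ambiguous_eaf"
  }

  aligned_out <- NULL
  others <- if (K >= 2) 2:K else integer(0)
  for (k in others) {
    al <- .align_to_reference(ref, as.data.frame(exposures[[k]]),
                              palindrome_policy, eaf_tolerance)
    bx[, k] <- al$beta; bx_se[, k] <- al$se
    drop_reason <- ifelse(is.na(drop_reason), al$drop, drop_reason)
  }
  aligned_out <- .align_to_reference(ref, as.data.frame(outcome),
                                     palindrome_policy, eaf_tolerance)
  drop_reason <- ifelse(is.na(drop_reason), aligned_out$drop, drop_reason)

  keep <- is.na(drop_reason)
  drops <- data.frame(SNP = ref$SNP[!keep], reason = drop_reason[!keep],
                      stringsAsFactors = FALSE)
  if (!any(keep)) stop("harmonize: every common variant was dropped during allele alignment",
                       call. = FALSE)
  out <- list(
    exposure_ids = exp_ids,
    outcome_id = outcome$trait_id[1],
    variants = data.frame(SNP = ref$SNP[keep], CHR = ref$CHR[keep],
                          POS = ref$POS[keep], EA = ref$EA[keep],
                          OA = ref$OA[keep], stringsAsFactors = FALSE),
    bx = bx[keep, , drop = FALSE],
    bx_se = bx_se[keep, , drop = FALSE],
    by = unname(aligned_out$beta[keep]),
    by_se = unname(aligned_out$se[keep]),
    eaf = ref$EAF[keep],
    n_outcome = unname(aligned_out$n[keep]),
    drops = drops
  )
  class(out) <- "harmonized_set"
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %d variant(s), exposures [%s] vs outcome '%s'\n",
              nrow(x$variants), paste(x$exposure_ids, collapse = ", "), x$outcome_id))
  if (nrow(x$drops)) cat(sprintf("  dropped %d variant(s): %s\n", nrow(x$drops),
                                 paste(unique(x$drops$reason), collapse = ", ")))
  invisible(x)
}

#' Write a harmonization drop log
#'
#' @param h a `harmonized_set`.
#' @param path output TSV path (columns `SNP`, `reason`).
#' @export
write_drop_log <- function(h, path) {
  utils::write.table(h$drops, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Internal: assemble a harmonized_set directly from already-aligned scans
# (used by the simulator pipeline where all tables share one effect allele).
.harmonized_from_aligned <- function(exposures, outcome) {
  if (is.data.frame(exposures)) exposures <- list(exposures)
  exp_ids <- vapply(exposures, function(e) e$trait_id[1], character(1))
  common <- Reduce(intersect, c(lapply(exposures, `[[`, "SNP"), list(outcome$SNP)))
  ref <- as.data.frame(exposures[[1]])
  ref <- ref[ref$SNP %in% common, , drop = FALSE]
  bx <- vapply(exposures, function(e) e$BETA[match(ref$SNP, e$SNP)],
               numeric(nrow(ref)))
  bx_se <- vapply(exposures, function(e) e$SE[match(ref$SNP, e$SNP)],
                  numeric(nrow(ref)))
  bx <- matrix(bx, nrow(ref), length(exposures), dimnames = list(ref$SNP, exp_ids))
  bx_se <- matrix(bx_se, nrow(ref), length(exposures), dimnames = list(ref$SNP, exp_ids))
  oi <- match(ref$SNP, outcome$SNP)
  out <- list(
    exposure_ids = exp_ids, outcome_id = outcome$trait_id[1],
    variants = ref[, c("SNP", "CHR", "POS", "EA", "OA")],
    bx = bx, bx_se = bx_se,
    by = outcome$BETA[oi], by_se = outcome$SE[oi],
    eaf = ref$EAF, n_outcome = outcome$N[oi],
    drops = data.frame(SNP = character(0), reason = character(0))
  )
  class(out) <- "harmonized_set"
  out
}
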