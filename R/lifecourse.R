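# Multivariable MR over lifecourse exposures, total/direct/indirect effect
# decomposition, three-exposure mediation, and de-attenuation of
# proxy-reported (family-history) outcome estimates by the genotypic sharing
# coefficient.

#' Multivariable MR fit
#'
#' Weighted multiple regression of the SNP-outcome effects on the K columns
#' of SNP-exposure effects, no intercept, weights 1 / by_se^2. Each
#' exposure's coefficient is its *direct* (conditional) effect, accounting
#' for the other exposures in the model. SEs carry the multiplicative
#' random-effects factor `sqrt(max(1, Q / (n - K)))`. A per-exposure
#' conditional instrument-strength statistic is reported: the mean squared
#' standardized residual of each exposure's effects after projecting out the
#' other exposures' effects (values near or below ~10 flag conditionally
#' weak instruments).
#'
#' @param h a `harmonized_set`; K = 1 reproduces [ivw()] exactly.
#' @return An object of class `mvmr_fit`: list with `exposure_ids`, `fits`
#'   (one `mr_fit` per exposure), `conditional_f`, `n_snps`,
#'   `heterogeneity_q`, `heterogeneity_df`.
#' @export
mvmr_fit <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  bx <- h$bx; by <- h$by; w <- 1 / h$by_se^2
  K <- ncol(bx); n <- nrow(bx)
  if (n <= K) stop(sprintf("mvmr_fit: insufficient instruments (%d SNPs for %d exposures)",
                           n, K), call. = FALSE)
  # an exposure with no instrument signal at all contributes nothing to the
  # joint model: drop it from the solve and report an NA fit for it
  zero_cols <- colSums(bx != 0) == 0
  if (any(zero_cols)) {
    hk <- h
    hk$bx <- bx[, !zero_cols, drop = FALSE]
    hk$bx_se <- h$bx_se[, !zero_cols, drop = FALSE]
    hk$exposure_ids <- h$exposure_ids[!zero_cols]
    sub <- mvmr_fit(hk)
    fits <- stats::setNames(vector("list", K), h$exposure_ids)
    cond_f <- stats::setNames(rep(NA_real_, K), h$exposure_ids)
    for (id in hk$exposure_ids) {
      fits[[id]] <- sub$fits[[id]]
      cond_f[id] <- sub$conditional_f[id]
    }
    for (id in h$exposure_ids[zero_cols]) {
      fits[[id]] <- .new_mr_fit("mvmr", id, h$outcome_id, NA_real_, NA_real_,
                                NA_real_, n, q = sub$heterogeneity_q,
                                q_df = sub$heterogeneity_df)
    }
    return(structure(list(exposure_ids = h$exposure_ids, fits = fits,
                          conditional_f = cond_f, n_snps = n,
                          heterogeneity_q = sub$heterogeneity_q,
                          heterogeneity_df = sub$heterogeneity_df),
                     class = "mvmr_fit"))
  }
  xtwx <- crossprod(bx, w * bx)
  cond <- rcond(xtwx)
  if (!is.finite(cond) || cond < 1e-10) {
    cors <- stats::cor(bx)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop(sprintf("mvmr_fit: exposure effect columns are collinear (worst pair: '%s' and '%s', cor = %.4f)",
                 colnames(bx)[worst[1]], colnames(bx)[worst[2]],
                 cors[worst[1], worst[2]]), call. = FALSE)
  }
  coefs <- solve(xtwx, crossprod(bx, w * by))[, 1]
  resid <- by - as.vector(bx %*% coefs)
  q <- sum(w * resid^2)
  q_df <- n - K
  scale2 <- max(1, q / q_df)
  se <- sqrt(diag(solve(xtwx)) * scale2)
  p <- 2 * stats::pnorm(-abs(coefs / se))

  cond_f <- vapply(seq_len(K), function(k) {
    if (K == 1) return(mean((bx[, 1] / h$bx_se[, 1])^2))
    others <- bx[, -k, drop = FALSE]
    r <- stats::lm.fit(others, bx[, k])$residuals
    mean((r / h$bx_se[, k])^2)
  }, numeric(1))
  names(cond_f) <- h$exposure_ids

  fits <- lapply(seq_len(K), function(k) {
    .new_mr_fit("mvmr", h$exposure_ids[k], h$outcome_id, coefs[k], se[k], p[k],
                n, q = q, q_df = q_df)
  })
  names(fits) <- h$exposure_ids
  structure(list(exposure_ids = h$exposure_ids, fits = fits,
                 conditional_f = cond_f, n_snps = n,
                 heterogeneity_q = q, heterogeneity_df = q_df),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("Multivariable MR fit: %d exposures, %d SNPs (Q = %.2f on %d df)\n",
              length(x$exposure_ids), x$n_snps, x$heterogeneity_q,
              as.integer(x$heterogeneity_df)))
  for (id in x$exposure_ids) {
    f <- x$fits[[id]]
    cat(sprintf("  %-24s b = %+.4f (SE %.4f), p = %.3g, cond. F = %.1f\n",
                id, f$estimate, f$se, f$pval, x$conditional_f[id]))
  }
  invisible(x)
}

#' Total/direct/indirect lifecourse effect decomposition
#'
#' Pairs the univariable (total) estimate of an early-life exposure with its
#' multivariable (direct) estimate and derives the indirect effect — the
#' part transmitted through the later-life exposure — in two ways:
#' \describe{
#'   \item{difference}{`total - direct`, SE `sqrt(se_total^2 + se_direct^2)`
#'     (conservative: the covariance between the two estimates is not
#'     identifiable from summary output and is ignored).}
#'   \item{product}{(effect of early on later exposure) x (direct effect of
#'     the later exposure on the outcome), with first-order delta-method SE.}
#' }
#' The two coincide in expectation under a linear structural model;
#' divergence is itself a diagnostic.
#'
#' @param total an `mr_fit`: univariable estimate of the early exposure on
#'   the outcome.
#' @param mv an `mvmr_fit` containing the early and later exposures.
#' @param path_effect an `mr_fit`: univariable estimate of the early
#'   exposure on the *later exposure*.
#' @param later_id id of the later exposure inside `mv` (default: the first
#'   exposure in `mv` that is not the early one).
#' @return An object of class `lifecourse_result`.
#' @export
decompose <- function(total, mv, path_effect, later_id = NULL) {
  early <- total$exposure_id
  if (!(early %in% mv$exposure_ids)) {
    stop(sprintf("decompose: exposure '%s' absent from the multivariable fit", early),
         call. = FALSE)
  }
  if (path_effect$exposure_id != early) {
    stop("decompose: path_effect must have the same early exposure as `total`",
         call. = FALSE)
  }
  if (is.null(later_id)) later_id <- setdiff(mv$exposure_ids, early)[1]
  if (is.na(later_id) || !(later_id %in% mv$exposure_ids)) {
    stop("decompose: later exposure not found in the multivariable fit", call. = FALSE)
  }
  if (path_effect$outcome_id != later_id) {
    stop(sprintf("decompose: path_effect outcome ('%s') must be the later exposure ('%s')",
                 path_effect$outcome_id, later_id), call. = FALSE)
  }
  direct <- mv$fits[[early]]
  if (direct$outcome_id != total$outcome_id) {
    stop("decompose: total and multivariable fits refer to different outcomes",
         call. = FALSE)
  }
  later_direct <- mv$fits[[later_id]]
  ind_diff <- total$estimate - direct$estimate
  ind_diff_se <- sqrt(total$se^2 + direct$se^2)
  ind_prod <- path_effect$estimate * later_direct$estimate
  ind_prod_se <- sqrt(path_effect$estimate^2 * later_direct$se^2 +
                      later_direct$estimate^2 * path_effect$se^2)
  structure(list(
    exposure_id = early, outcome_id = total$outcome_id,
    later_exposure_id = later_id,
    total = total, direct = direct, later_direct = later_direct,
    path_effect = path_effect,
    indirect_difference = list(estimate = ind_diff, se = ind_diff_se),
    indirect_product = list(estimate = ind_prod, se = ind_prod_se),
    sharing_adjusted = FALSE
  ), class = "lifecourse_result")
}

#' @export
print.lifecourse_result <- function(x, ...) {
  cat(sprintf("Lifecourse decomposition: %s -> %s (via %s)%s\n",
              x$exposure_id, x$outcome_id, x$later_exposure_id,
              if (x$sharing_adjusted) " [sharing-adjusted]" else ""))
  cat(sprintf("  total    %+.4f (SE %.4f)\n", x$total$estimate, x$total$se))
  cat(sprintf("  direct   %+.4f (SE %.4f)\n", x$direct$estimate, x$direct$se))
  cat(sprintf("  indirect %+.4f (SE %.4f, difference) / %+.4f (SE %.4f, product)\n",
              x$indirect_difference$estimate, x$indirect_difference$se,
              x$indirect_product$estimate, x$indirect_product$se))
  invisible(x)
}

#' Three-exposure mediation analysis
#'
#' Fits the K = 3 multivariable model (early exposure, later exposure,
#' mediator — e.g. childhood body size, adult body size, lifetime smoking)
#' and reports, for each of the first two exposures, how its K = 2 direct
#' estimate changes when the mediator is added: the attenuation attributable
#' to the mediated pathway.
#'
#' @param h3 a `harmonized_set` with exactly 3 exposures, ordered
#'   (early, later, mediator).
#' @return list with `fit2` (K = 2 `mvmr_fit`), `fit3` (K = 3 `mvmr_fit`)
#'   and `attenuation`, a data.frame with columns `exposure`, `b_without`,
#'   `b_with`, `difference`, `pct_change`.
#' @export
mediation_mvmr <- function(h3) {
  stopifnot(inherits(h3, "harmonized_set"))
  if (ncol(h3$bx) != 3) stop("mediation_mvmr: requires exactly 3 exposures (early, later, mediator)",
                             call. = FALSE)
  h2 <- h3
  h2$bx <- h3$bx[, 1:2, drop = FALSE]
  h2$bx_se <- h3$bx_se[, 1:2, drop = FALSE]
  h2$exposure_ids <- h3$exposure_ids[1:2]
  fit2 <- mvmr_fit(h2)
  fit3 <- mvmr_fit(h3)
  att <- data.frame(
    exposure = h3$exposure_ids[1:2],
    b_without = vapply(fit2$fits[1:2], `[[`, numeric(1), "estimate"),
    b_with = vapply(fit3$fits[1:2], `[[`, numeric(1), "estimate"),
    stringsAsFactors = FALSE
  )
  att$difference <- att$b_with - att$b_without
  att$pct_change <- ifelse(att$b_without != 0,
                           100 * att$difference / abs(att$b_without), NA_real_)
  rownames(att) <- NULL
  list(fit2 = fit2, fit3 = fit3, attenuation = att)
}

#' De-attenuate a proxy-outcome estimate by the genotypic sharing coefficient
#'
#' When the outcome is a relative's disease rather than the genotyped
#' person's own, the expected genetic association — and hence the MR
#' estimate on the log-odds (or linear) scale — is attenuated by the
#' expected genotypic correlation s between the index person and the
#' relative (s = 0.5 for first-degree relatives, 1 for self-reported
#' outcomes). This divides the estimate, SE and CI bounds by s; odds ratios
#' are obtained by exponentiating the adjusted log-odds, e.g. a
#' parental-proxy OR of 1.97 adjusts to exp(2 ln 1.97) = 3.88.
#'
#' @param fit an `mr_fit` (or `mvmr_fit`, adjusted per exposure) on a
#'   proxy-reported outcome.
#' @param s sharing coefficient in (0, 1].
#' @return A fit of the same class, method label suffixed
#'   `" (sharing-adjusted)"`.
#' @export
deattenuate_proxy <- function(fit, s = 0.5) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0 || s > 1) {
    stop("deattenuate_proxy: sharing coefficient s must lie in (0, 1]", call. = FALSE)
  }
  if (inherits(fit, "mvmr_fit")) {
    fit$fits <- lapply(fit$fits, deattenuate_proxy, s = s)
    return(fit)
  }
  stopifnot(inherits(fit, "mr_fit"))
  fit$estimate <- fit$estimate / s
  fit$se <- fit$se / s
  fit$ci_low <- fit$ci_low / s
  fit$ci_high <- fit$ci_high / s
  fit$sharing_s <- s
  if (!grepl("sharing-adjusted", fit$method)) {
    fit$method <- paste0(fit$method, " (sharing-adjusted)")
  }
  fit
}

#' Apply sharing adjustment to a lifecourse decomposition
#'
#' Returns a copy of the decomposition in which every estimate (total,
#' direct, both indirect variants) is divided by the sharing coefficient;
#' the original is retained unchanged.
#'
#' @param res a `lifecourse_result`.
#' @param s sharing coefficient in (0, 1].
#' @return An adjusted `lifecourse_result` with `sharing_adjusted = TRUE`
#'   and the unadjusted result stored in `$unadjusted`.
#' @export
adjust_lifecourse <- function(res, s = 0.5) {
  stopifnot(inherits(res, "lifecourse_result"))
  adj <- res
  adj$total <- deattenuate_proxy(res$total, s)
  adj$direct <- deattenuate_proxy(res$direct, s)
  adj$later_direct <- deattenuate_proxy(res$later_direct, s)
  # the path effect (exposure on exposure, measured in the index person) is
  # not proxy-attenuated; only outcome-side estimates are rescaled
  adj$indirect_difference <- lapply(res$indirect_difference, function(v) v / s)
  adj$indirect_product <- lapply(res$indirect_product, function(v) v / s)
  adj$sharing_adjusted <- TRUE
  adj$sharing_s <- s
  adj$unadjusted <- res
  adj
}
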