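# Univariable two-sample MR estimators: IVW, MR-Egger, weighted median,
# Wald ratio; odds-ratio conversion; Benjamini-Hochberg FDR gating.
#
# All estimators consume a harmonized_set with K = 1 exposure. P-values use
# the standard normal reference, the convention for summary-data MR.

.Z95 <- stats::qnorm(0.975)

.new_mr_fit <- function(method, exposure_id, outcome_id, estimate, se, pval,
                        n_snps, intercept = NULL, intercept_se = NULL,
                        intercept_pval = NULL, q = NA_real_, q_df = NA_real_,
                        extra = list()) {
  estimate <- unname(estimate); se <- unname(se); pval <- unname(pval)
  fit <- c(list(
    method = method, exposure_id = exposure_id, outcome_id = outcome_id,
    estimate = estimate, se = se,
    ci_low = estimate - .Z95 * se, ci_high = estimate + .Z95 * se,
    pval = pval, n_snps = n_snps,
    intercept = if (is.null(intercept)) NULL else unname(intercept),
    intercept_se = if (is.null(intercept_se)) NULL else unname(intercept_se),
    intercept_pval = if (is.null(intercept_pval)) NULL else unname(intercept_pval),
    heterogeneity_q = unname(q), heterogeneity_df = unname(q_df)
  ), extra)
  class(fit) <- "mr_fit"
  fit
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("MR fit [%s]: %s -> %s\n", x$method, x$exposure_id, x$outcome_id))
  cat(sprintf("  b = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, nSNP = %d\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept = %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  if (is.finite(x$heterogeneity_q)) {
    cat(sprintf("  Cochran's Q = %.2f on %d df\n", x$heterogeneity_q,
                as.integer(x$heterogeneity_df)))
  }
  invisible(x)
}

.check_uni <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (ncol(h$bx) != 1) stop("estimator requires a single-exposure harmonized set (K = 1)",
                            call. = FALSE)
  if (any(h$by_se <= 0)) stop("all outcome SEs must be positive", call. = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure effects
#' through the origin, with weights 1 / by_se^2:
#' `b = sum(w bx by) / sum(w bx^2)`. The fixed-effect SE is
#' `sqrt(1 / sum(w bx^2))`; under the default multiplicative random-effects
#' model it is inflated by `sqrt(max(1, Q / (n - 1)))`, where Q is Cochran's
#' heterogeneity statistic — the SE is never deflated below the fixed-effect
#' value. With one SNP this reduces to the Wald ratio.
#'
#' @param h a `harmonized_set` with one exposure.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An `mr_fit`.
#' @export
ivw <- function(h, model = c("random", "fixed")) {
  model <- match.arg(model)
  .check_uni(h)
  bx <- h$bx[, 1]; by <- h$by; w <- 1 / h$by_se^2
  n <- length(bx)
  if (all(bx == 0)) stop("ivw: degenerate instruments (all exposure effects zero)",
                         call. = FALSE)
  swx2 <- sum(w * bx^2)
  est <- sum(w * bx * by) / swx2
  se_fixed <- sqrt(1 / swx2)
  q <- sum(w * (by - est * bx)^2)
  q_df <- n - 1
  scale <- if (model == "random" && n > 1) sqrt(max(1, q / q_df)) else 1
  se <- se_fixed * scale
  p <- 2 * stats::pnorm(-abs(est / se))
  .new_mr_fit("ivw", h$exposure_ids[1], h$outcome_id, est, se, p, n,
              q = q, q_df = q_df, extra = list(model = model))
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome on SNP-exposure effects with a free
#' intercept (weights 1 / by_se^2). Rows are first oriented so that every
#' exposure effect is non-negative (flipping the outcome effect with it); the
#' slope is the causal estimate and the intercept captures directional
#' pleiotropy. SEs carry the multiplicative random-effects factor
#' `sqrt(max(1, Q_egger / (n - 2)))`.
#'
#' @param h a `harmonized_set` with one exposure and at least 3 variants.
#' @return An `mr_fit` with `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(h) {
  .check_uni(h)
  bx <- h$bx[, 1]; by <- h$by; w <- 1 / h$by_se^2
  n <- length(bx)
  if (n < 3) stop("mr_egger: insufficient instruments (need >= 3 SNPs)", call. = FALSE)
  neg <- bx < 0
  bx[neg] <- -bx[neg]; by[neg] <- -by[neg]
  if (stats::var(bx) < .Machine$double.eps) {
    stop("mr_egger: zero variance in exposure effects (collinear with intercept)",
         call. = FALSE)
  }
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coefs
  q <- sum(w * resid^2)
  q_df <- n - 2
  scale2 <- max(1, q / q_df)
  vc <- solve(xtwx) * scale2
  se <- sqrt(diag(vc))
  z <- coefs / se
  p <- 2 * stats::pnorm(-abs(z))
  .new_mr_fit("egger", h$exposure_ids[1], h$outcome_id,
              estimate = coefs["slope", 1], se = se["slope"],
              pval = p["slope", 1], n_snps = n,
              intercept = coefs["intercept", 1], intercept_se = se["intercept"],
              intercept_pval = p["intercept", 1], q = q, q_df = q_df)
}

# weighted-median point estimate from ratio estimates and weights
.weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2     # midpoint convention
  if (cw[1] >= 0.5) return(r[1])
  n <- length(r)
  if (cw[n] <= 0.5) return(r[n])
  k <- max(which(cw < 0.5))
  if (cw[k + 1] == cw[k]) return(r[k + 1])
  r[k] + (r[k + 1] - r[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
}

#' Weighted median estimator
#'
#' Forms per-SNP ratio estimates `r_j = by_j / bx_j` with inverse-variance
#' weights `w_j = bx_j^2 / by_se_j^2` and returns the weighted 50th
#' percentile (midpoint convention, linear interpolation between bracketing
#' ratios). Consistent when at least half the weight comes from valid
#' instruments. The SE is a parametric bootstrap: `(bx_j, by_j)` are
#' resampled from normal distributions centred at the observed values with
#' their reported SEs, and the SD of the resampled medians is returned.
#'
#' @param h a `harmonized_set` with one exposure and >= 3 variants; no
#'   exposure effect may be exactly zero.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap, recorded in the fit.
#' @return An `mr_fit` (with `seed` and `n_boot` recorded).
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  .check_uni(h)
  bx <- h$bx[, 1]; bx_se <- h$bx_se[, 1]; by <- h$by; by_se <- h$by_se
  n <- length(bx)
  if (n < 3) stop("weighted_median: insufficient instruments (need >= 3 SNPs)",
                  call. = FALSE)
  if (any(bx == 0)) stop("weighted_median: undefined ratio (some bx = 0); prefilter instruments",
                         call. = FALSE)
  est <- .weighted_median_point(by / bx, bx^2 / by_se^2)
  boot <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    vapply(seq_len(n_boot), function(i) {
      bxs <- stats::rnorm(n, bx, bx_se)
      bys <- stats::rnorm(n, by, by_se)
      bxs[bxs == 0] <- .Machine$double.eps
      .weighted_median_point(bys / bxs, bxs^2 / by_se^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  p <- if (se > 0) 2 * stats::pnorm(-abs(est / se)) else NA_real_
  .new_mr_fit("weighted_median", h$exposure_ids[1], h$outcome_id, est, se, p, n,
              extra = list(seed = seed, n_boot = n_boot))
}

#' Single-SNP Wald ratio
#'
#' @param bx,bx_se SNP-exposure effect and SE (bx must be nonzero).
#' @param by,by_se SNP-outcome effect and SE.
#' @param exposure_id,outcome_id trait labels.
#' @return An `mr_fit` with estimate `by / bx` and first-order SE
#'   `|by_se / bx|`.
#' @export
wald_ratio <- function(bx, bx_se, by, by_se,
                       exposure_id = "exposure", outcome_id = "outcome") {
  if (bx == 0) stop("wald_ratio: bx must be nonzero", call. = FALSE)
  est <- by / bx
  se <- abs(by_se / bx)
  p <- 2 * stats::pnorm(-abs(est / se))
  .new_mr_fit("wald_ratio", exposure_id, outcome_id, est, se, p, 1L,
              q = 0, q_df = 0)
}

#' Convert a log-odds MR fit to the odds-ratio scale
#'
#' @param fit an `mr_fit` whose estimate is on the log-odds scale.
#' @return list with `or`, `or_ci_low`, `or_ci_high` (exponentials of the
#'   estimate and estimate +/- 1.96 SE).
#' @export
to_odds_ratio <- function(fit) {
  list(or = exp(fit$estimate),
       or_ci_low = exp(fit$estimate - .Z95 * fit$se),
       or_ci_high = exp(fit$estimate + .Z95 * fit$se))
}

#' Benjamini-Hochberg FDR gate
#'
#' Step-up procedure: sort the m p-values ascending, find the largest k with
#' `p_(k) <= k q / m`, and pass every test with `p <= p_(k)`.
#'
#' @param pvals p-values in (0, 1].
#' @param q target false-discovery rate (default 0.05).
#' @return An object of class `fdr_decision`: list with `pvals`, `q`,
#'   `passed` (logical, input order), `threshold_p` (largest accepted
#'   p-value; 0 when nothing passes).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("bh_fdr: empty p-value vector", call. = FALSE)
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("bh_fdr: p-values must lie in (0,1]", call. = FALSE)
  }
  m <- length(pvals)
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) * q / m)
  threshold_p <- if (length(ok)) ps[max(ok)] else 0
  structure(list(pvals = pvals, q = q, passed = pvals <= threshold_p,
                 threshold_p = threshold_p),
            class = "fdr_decision")
}
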