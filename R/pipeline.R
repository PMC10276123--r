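# End-to-end orchestration: clump -> univariable MR (IVW / Egger / weighted
# median) -> FDR gate -> multivariable MR -> lifecourse decomposition and
# mediation -> sharing adjustment -> report tables.

#' Run configuration
#'
#' @param exposure_early,exposure_late paths to summary-statistics files for
#'   the early-life and later-life exposures (must be distinct traits).
#' @param exposure_mediator optional path for a third, mediator exposure
#'   (e.g. lifetime smoking).
#' @param outcomes data.frame with columns `name` (outcome label), `path`
#'   (summary-statistics file) and `sharing` (genotypic sharing coefficient
#'   in (0, 1]: 0.5 for parental proxy reports, 1 for own-disease outcomes).
#' @param ld path to the LD matrix TSV.
#' @param p_threshold,r2_threshold clumping thresholds (defaults 5e-8, 0.001).
#' @param fdr_q FDR gate level (default 0.05).
#' @param fdr_pooling `"per-exposure"` (BH across outcomes within each
#'   exposure, default) or `"global"` (one family pooling all
#'   exposure-outcome IVW tests).
#' @param ivw_model `"random"` or `"fixed"`.
#' @param palindrome_policy,eaf_tolerance harmonization settings, see
#'   [harmonize()].
#' @param n_boot,seed weighted-median bootstrap settings.
#' @param out_dir directory for report tables.
#' @return A validated `run_config` list.
#' @export
run_config <- function(exposure_early, exposure_late, exposure_mediator = NULL,
                       outcomes, ld, p_threshold = 5e-8, r2_threshold = 0.001,
                       fdr_q = 0.05, fdr_pooling = c("per-exposure", "global"),
                       ivw_model = c("random", "fixed"),
                       palindrome_policy = c("drop", "infer-by-eaf"),
                       eaf_tolerance = 0.08, n_boot = 1000, seed = 1L,
                       out_dir = tempfile("kinmr_run_")) {
  fdr_pooling <- match.arg(fdr_pooling)
  ivw_model <- match.arg(ivw_model)
  palindrome_policy <- match.arg(palindrome_policy)
  if (identical(exposure_early, exposure_late)) {
    stop("run_config: early and late exposures must be distinct", call. = FALSE)
  }
  outcomes <- as.data.frame(outcomes)
  stopifnot(all(c("name", "path", "sharing") %in% names(outcomes)))
  if (any(outcomes$sharing <= 0 | outcomes$sharing > 1)) {
    stop("run_config: sharing coefficients must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    exposure_early = exposure_early, exposure_late = exposure_late,
    exposure_mediator = exposure_mediator, outcomes = outcomes, ld = ld,
    p_threshold = p_threshold, r2_threshold = r2_threshold,
    fdr_q = fdr_q, fdr_pooling = fdr_pooling, ivw_model = ivw_model,
    palindrome_policy = palindrome_policy, eaf_tolerance = eaf_tolerance,
    n_boot = as.integer(n_boot), seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' Read a run configuration from a flat key-value file
#'
#' The file holds `key: value` lines (`#` comments allowed). Scalar keys
#' mirror the [run_config()] arguments; outcomes are given as paired
#' `outcome_<name>: <path>` and `sharing_<name>: <s>` keys.
#'
#' @param path config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3]
  if (length(bad)) stop(sprintf("config parse error at: '%s'", bad[1]), call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  named <- stats::setNames(as.list(vals), keys)

  out_names <- sub("^outcome_", "", grep("^outcome_", keys, value = TRUE))
  outcomes <- data.frame(
    name = out_names,
    path = vapply(out_names, function(n) named[[paste0("outcome_", n)]], character(1)),
    sharing = vapply(out_names, function(n) {
      s <- named[[paste0("sharing_", n)]]
      if (is.null(s)) 0.5 else as.numeric(s)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  getv <- function(key, default, cast = identity) {
    if (is.null(named[[key]])) default else cast(named[[key]])
  }
  run_config(
    exposure_early = named[["exposure_early"]],
    exposure_late = named[["exposure_late"]],
    exposure_mediator = named[["exposure_mediator"]],
    outcomes = outcomes, ld = named[["ld"]],
    p_threshold = getv("p_threshold", 5e-8, as.numeric),
    r2_threshold = getv("r2_threshold", 0.001, as.numeric),
    fdr_q = getv("fdr_q", 0.05, as.numeric),
    fdr_pooling = getv("fdr_pooling", "per-exposure"),
    ivw_model = getv("ivw_model", "random"),
    palindrome_policy = getv("palindrome_policy", "drop"),
    eaf_tolerance = getv("eaf_tolerance", 0.08, as.numeric),
    n_boot = getv("n_boot", 1000, as.integer),
    seed = getv("seed", 1L, as.integer),
    out_dir = getv("out_dir", tempfile("kinmr_run_"))
  )
}

.stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.fit_row <- function(fit, fdr_pass = NA) {
  or <- to_odds_ratio(fit)
  data.frame(
    exposure = fit$exposure_id, outcome = fit$outcome_id,
    method = fit$method, nsnp = fit$n_snps,
    b = fit$estimate, se = fit$se, ci_low = fit$ci_low, ci_high = fit$ci_high,
    pval = fit$pval, or = or$or, or_lci = or$or_ci_low, or_uci = or$or_ci_high,
    egger_intercept = if (is.null(fit$intercept)) NA_real_ else fit$intercept,
    egger_intercept_p = if (is.null(fit$intercept_pval)) NA_real_ else fit$intercept_pval,
    q_stat = fit$heterogeneity_q, fdr_pass = fdr_pass,
    stringsAsFactors = FALSE
  )
}

#' Run the full lifecourse MR pipeline
#'
#' Stages, in fixed order: read and validate inputs; LD-clump each exposure;
#' univariable MR (IVW, MR-Egger, weighted median) of every exposure on
#' every outcome; Benjamini-Hochberg FDR gate on the IVW p-values;
#' multivariable MR (union of the early and late exposures' instruments,
#' jointly re-harmonized) for gated outcomes only; total/direct/indirect
#' decomposition of the early exposure's effect; three-exposure mediation
#' where a mediator is configured; sharing adjustment of all outcome-side
#' estimates. All tables are written under `cfg$out_dir`; re-running the
#' same config on the same inputs reproduces them byte-for-byte.
#'
#' Robust estimators that cannot run (e.g. fewer than 3 instruments) appear
#' as explicit missing rows, never silent drops.
#'
#' @param cfg a `run_config`.
#' @return An object of class `study_report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  .stage_msg("read", "loading exposures, outcomes and LD matrix")
  exp_paths <- c(early = cfg$exposure_early, late = cfg$exposure_late)
  if (!is.null(cfg$exposure_mediator)) exp_paths["mediator"] <- cfg$exposure_mediator
  exp_full <- lapply(exp_paths, function(p) read_summary_stats(p, trait_id = p))
  # trait ids: use file base names without extension for readability
  for (role in names(exp_full)) {
    exp_full[[role]]$trait_id <- sub("\\.[^.]*$", "", basename(exp_paths[[role]]))
  }
  out_tabs <- lapply(seq_len(nrow(cfg$outcomes)), function(i) {
    read_summary_stats(cfg$outcomes$path[i], trait_id = cfg$outcomes$name[i])
  })
  names(out_tabs) <- cfg$outcomes$name
  ld <- read_ld_matrix(cfg$ld)

  .stage_msg("clump", "selecting instruments at P < %g, r2 < %g",
             cfg$p_threshold, cfg$r2_threshold)
  instr <- lapply(exp_full, ld_clump, ld = ld,
                  p_threshold = cfg$p_threshold, r2_threshold = cfg$r2_threshold)
  for (role in names(instr)) {
    .stage_msg("clump", "%s: %d instrument(s)", role, nrow(instr[[role]]$records))
  }

  .stage_msg("uni-mr", "univariable estimators for every exposure-outcome pair")
  uni <- list()
  rows <- list()
  for (role in names(instr)) {
    for (on in names(out_tabs)) {
      h <- harmonize(instr[[role]]$records, out_tabs[[on]],
                     palindrome_policy = cfg$palindrome_policy,
                     eaf_tolerance = cfg$eaf_tolerance)
      fits <- list(ivw = ivw(h, model = cfg$ivw_model))
      fits$egger <- tryCatch(mr_egger(h), error = function(e) NULL)
      fits$weighted_median <- tryCatch(
        weighted_median(h, n_boot = cfg$n_boot, seed = cfg$seed),
        error = function(e) NULL)
      uni[[role]][[on]] <- fits
      for (mth in c("ivw", "egger", "weighted_median")) {
        if (is.null(fits[[mth]])) {
          rows[[length(rows) + 1]] <- data.frame(
            exposure = exp_full[[role]]$trait_id[1], outcome = on, method = mth,
            nsnp = nrow(h$variants), b = NA_real_, se = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
            or = NA_real_, or_lci = NA_real_, or_uci = NA_real_,
            egger_intercept = NA_real_, egger_intercept_p = NA_real_,
            q_stat = NA_real_, fdr_pass = NA, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1]] <- .fit_row(fits[[mth]])
        }
      }
    }
  }

  .stage_msg("fdr", "Benjamini-Hochberg gate at q = %g (%s pooling)",
             cfg$fdr_q, cfg$fdr_pooling)
  gate <- list()
  if (cfg$fdr_pooling == "per-exposure") {
    for (role in names(uni)) {
      p <- vapply(uni[[role]], function(f) f$ivw$pval, numeric(1))
      dec <- bh_fdr(p, q = cfg$fdr_q)
      gate[[role]] <- stats::setNames(dec$passed, names(uni[[role]]))
    }
  } else {
    keys <- expand.grid(role = names(uni), on = names(out_tabs),
                        stringsAsFactors = FALSE)
    p <- mapply(function(r, o) uni[[r]][[o]]$ivw$pval, keys$role, keys$on)
    dec <- bh_fdr(p, q = cfg$fdr_q)
    for (i in seq_len(nrow(keys))) {
      gate[[keys$role[i]]][keys$on[i]] <- dec$passed[i]
    }
  }
  res_tab <- do.call(rbind, rows)
  for (i in seq_len(nrow(res_tab))) {
    role <- names(exp_full)[vapply(exp_full, function(e) e$trait_id[1] == res_tab$exposure[i],
                                   logical(1))][1]
    if (res_tab$method[i] == "ivw") res_tab$fdr_pass[i] <- gate[[role]][[res_tab$outcome[i]]]
  }

  # multivariable stage: only outcomes the FDR gate lets through
  gated_outcomes <- names(out_tabs)[vapply(names(out_tabs), function(on) {
    any(vapply(names(gate), function(r) isTRUE(gate[[r]][[on]]), logical(1)))
  }, logical(1))]
  .stage_msg("mvmr", "gated outcomes: %s",
             if (length(gated_outcomes)) paste(gated_outcomes, collapse = ", ") else "(none)")

  early_id <- exp_full$early$trait_id[1]
  late_id <- exp_full$late$trait_id[1]
  union2 <- union(instr$early$records$SNP, instr$late$records$SNP)
  sub2 <- lapply(exp_full[c("early", "late")],
                 function(e) e[e$SNP %in% union2, , drop = FALSE])
  path_h <- harmonize(instr$early$records,
                      exp_full$late, # late exposure as outcome of the early one
                      palindrome_policy = cfg$palindrome_policy,
                      eaf_tolerance = cfg$eaf_tolerance)
  path_fit <- ivw(path_h, model = cfg$ivw_model)

  mvmr <- list(); lifecourse <- list(); mediation <- list()
  for (on in gated_outcomes) {
    h2 <- harmonize(sub2, out_tabs[[on]],
                    palindrome_policy = cfg$palindrome_policy,
                    eaf_tolerance = cfg$eaf_tolerance)
    mv <- mvmr_fit(h2)
    mvmr[[on]] <- mv
    total <- uni$early[[on]]$ivw
    dec <- decompose(total, mv, path_fit, later_id = late_id)
    s <- cfg$outcomes$sharing[cfg$outcomes$name == on][1]
    lifecourse[[on]] <- adjust_lifecourse(dec, s = s)
    if (!is.null(cfg$exposure_mediator)) {
      union3 <- union(union2, instr$mediator$records$SNP)
      sub3 <- lapply(exp_full[c("early", "late", "mediator")],
                     function(e) e[e$SNP %in% union3, , drop = FALSE])
      h3 <- harmonize(sub3, out_tabs[[on]],
                      palindrome_policy = cfg$palindrome_policy,
                      eaf_tolerance = cfg$eaf_tolerance)
      med <- mediation_mvmr(h3)
      med$fit3_adjusted <- deattenuate_proxy(med$fit3, s = s)
      mediation[[on]] <- med
    }
  }

  .stage_msg("report", "writing tables under %s", cfg$out_dir)
  utils::write.table(.format_table(res_tab), file.path(cfg$out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lc_tab <- .lifecourse_table(lifecourse, gate, early_id)
  utils::write.table(.format_table(lc_tab), file.path(cfg$out_dir, "lifecourse.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  provenance <- list(
    package = "kinmr",
    version = as.character(utils::packageVersion("kinmr")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")]
  )
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(
    config = cfg, instruments = instr, univariable = uni,
    results_table = res_tab, fdr_gate = gate, mvmr = mvmr,
    lifecourse = lifecourse, lifecourse_table = lc_tab,
    mediation = mediation, path_fit = path_fit
  ), class = "study_report")
}

# stable full-precision text rendering of numeric columns
.format_table <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.10g", df[[col]])
  }
  df
}

.lifecourse_table <- function(lifecourse, gate, early_id) {
  if (!length(lifecourse)) {
    return(data.frame(exposure = character(0), outcome = character(0)))
  }
  do.call(rbind, lapply(names(lifecourse), function(on) {
    a <- lifecourse[[on]]; r <- a$unadjusted
    data.frame(
      exposure = r$exposure_id, outcome = on,
      total_b = r$total$estimate, total_se = r$total$se, total_p = r$total$pval,
      direct_b = r$direct$estimate, direct_se = r$direct$se, direct_p = r$direct$pval,
      indirect_diff_b = r$indirect_difference$estimate,
      indirect_diff_se = r$indirect_difference$se,
      indirect_prod_b = r$indirect_product$estimate,
      indirect_prod_se = r$indirect_product$se,
      sharing_s = a$sharing_s,
      adj_total_b = a$total$estimate, adj_total_se = a$total$se,
      adj_direct_b = a$direct$estimate, adj_direct_se = a$direct$se,
      adj_indirect_diff_b = a$indirect_difference$estimate,
      adj_indirect_prod_b = a$indirect_product$estimate,
      fdr_gate_passed = TRUE,
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d exposure role(s) x %d outcome(s); %d outcome(s) passed the FDR gate\n",
              length(x$univariable), nrow(x$config$outcomes), length(x$mvmr)))
  cat(sprintf("  tables under %s\n", x$config$out_dir))
  invisible(x)
}

#' Compare proxy-outcome and direct-outcome study reports
#'
#' For every exposure-outcome key present in both reports, takes the
#' univariable IVW estimates and forms the ratio proxy / direct on the
#' log-odds scale with a first-order delta-method SE, flagging whether the
#' ratio's 95% CI covers the sharing coefficient configured for that
#' outcome in the proxy report. Under the halving law the ratio should be
#' ~0.5 for first-degree-relative proxies.
#'
#' @param report_proxy,report_direct `study_report`s sharing exposure and
#'   outcome labels.
#' @return data.frame with columns `exposure`, `outcome`, `proxy_b`,
#'   `direct_b`, `ratio`, `ratio_se`, `ratio_lci`, `ratio_uci`, `sharing_s`,
#'   `covers_sharing`.
#' @export
compare_proxy_vs_direct <- function(report_proxy, report_direct) {
  key <- function(rep) {
    ivw_rows <- rep$results_table[rep$results_table$method == "ivw", ]
    paste(ivw_rows$exposure, ivw_rows$outcome, sep = "\r")
  }
  kp <- key(report_proxy); kd <- key(report_direct)
  shared <- intersect(kp, kd)
  if (!length(shared)) stop("compare_proxy_vs_direct: no shared exposure-outcome keys",
                            call. = FALSE)
  tp <- report_proxy$results_table[report_proxy$results_table$method == "ivw", ][match(shared, kp), ]
  td <- report_direct$results_table[report_direct$results_table$method == "ivw", ][match(shared, kd), ]
  ratio <- tp$b / td$b
  ratio_se <- abs(ratio) * sqrt((tp$se / tp$b)^2 + (td$se / td$b)^2)
  s <- report_proxy$config$outcomes$sharing[match(tp$outcome, report_proxy$config$outcomes$name)]
  z <- stats::qnorm(0.975)
  out <- data.frame(
    exposure = tp$exposure, outcome = tp$outcome,
    proxy_b = tp$b, direct_b = td$b,
    ratio = ratio, ratio_se = ratio_se,
    ratio_lci = ratio - z * ratio_se, ratio_uci = ratio + z * ratio_se,
    sharing_s = s, stringsAsFactors = FALSE
  )
  out$covers_sharing <- out$ratio_lci <= s & s <= out$ratio_uci
  out
}

#' Forest-style plot of total and direct estimates
#'
#' One panel per outcome: points and 95% CIs on the odds-ratio scale for the
#' univariable (total) and multivariable (direct) estimates of each
#' exposure.
#'
#' @param report a `study_report` with at least one gated outcome.
#' @param path output file (PDF).
#' @return Invisibly, `path`.
#' @export
render_forest <- function(report, path) {
  if (!length(report$lifecourse)) stop("render_forest: report has no lifecourse results",
                                       call. = FALSE)
  outs <- names(report$lifecourse)
  grDevices::pdf(path, width = 7, height = 2.2 * length(outs) + 1)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(outs), 1), mar = c(4, 14, 2, 2))
  for (on in outs) {
    r <- report$lifecourse[[on]]$unadjusted
    fits <- list(
      "early total (uni IVW)" = r$total,
      "early direct (MVMR)" = r$direct,
      "late direct (MVMR)" = r$later_direct
    )
    ors <- lapply(fits, to_odds_ratio)
    xs <- vapply(ors, `[[`, numeric(1), "or")
    lo <- vapply(ors, `[[`, numeric(1), "or_ci_low")
    hi <- vapply(ors, `[[`, numeric(1), "or_ci_high")
    ylim <- c(0.5, length(fits) + 0.5)
    xlim <- range(c(lo, hi, 1))
    graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n", log = "x",
                   xlab = "Odds ratio (95% CI)", ylab = "", main = on)
    graphics::abline(v = 1, lty = 2, col = "grey50")
    yy <- rev(seq_along(fits))
    graphics::segments(lo, yy, hi, yy)
    graphics::points(xs, yy, pch = 15, col = c("goldenrod3", "goldenrod4", "purple4"))
    graphics::axis(2, at = yy, labels = names(fits), las = 1, cex.axis = 0.8)
  }
  invisible(path)
}
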