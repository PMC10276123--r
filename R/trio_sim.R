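# Family-trio simulator: Mendelian transmission of unlinked SNPs, lifecourse
# exposures (childhood -> adult -> mediator), liability-threshold parental
# disease, UK-Biobank-style family-history outcome coding (0/1/2 affected
# parents, or single-parent binary), and per-SNP association scans producing
# GWAS summary statistics in the package schema.
#
# The disease liability uses *standard logistic* noise, so that the theta_*
# parameters are log-odds per unit of parental exposure and a logistic
# per-SNP scan is correctly specified; linear (0/1 or 0/1/2) scans of the
# same outcomes remain valid up to a scale constant, and ratios of slopes
# (the halving law) are scale-free.

#' Simulation configuration
#'
#' Defines the generative model for a cohort of independent mother/father/
#' offspring trios:
#' \itemize{
#'   \item Parent genotypes: per SNP, two Hardy-Weinberg alleles at a
#'     frequency drawn uniformly from `maf_range`; offspring inherit one
#'     uniformly chosen allele from each parent (so offspring-parent dosage
#'     correlation is 0.5 per SNP).
#'   \item Childhood exposure = G beta_child + noise scaled to the target
#'     heritability `h2_child`.
#'   \item Adult exposure = `kappa` x childhood + G beta_adult_specific +
#'     noise scaled so the total genetic fraction of variance is `h2_adult`.
#'   \item Mediator = `mediator_gamma` x adult + G beta_mediator_specific +
#'     unit normal noise. (The mediator needs genetic effects of its own to
#'     be separable from the adult exposure in a joint model, as lifetime
#'     smoking has in practice.)
#'   \item Parental disease: liability = theta_child x childhood +
#'     theta_adult x adult + theta_mediator x mediator + standard logistic
#'     noise; disease = liability above the realized (1 - prevalence)
#'     quantile pooled over parents, fixing prevalence per replicate.
#'   \item Family history: `family_history_count` = mother + father disease
#'     (0/1/2); single-parent binaries for sex-specific endpoints.
#' }
#' Per-SNP effect vectors left `NULL` are drawn `N(0, 0.15^2)` from the
#' config seed (`beta_mediator_specific` defaults to all-zero unless
#' `theta_mediator` or `mediator_gamma` is nonzero).
#'
#' @param n_trios number of trios.
#' @param n_snps number of unlinked SNPs.
#' @param maf_range minor-allele-frequency range, subset of (0, 0.5].
#' @param beta_child,beta_adult_specific,beta_mediator_specific per-SNP
#'   effect vectors (length `n_snps`) or `NULL`.
#' @param kappa persistence of the childhood exposure into adulthood.
#' @param h2_child,h2_adult target heritabilities in (0, 1).
#' @param theta_child,theta_adult,theta_mediator log-odds liability effects
#'   of the parental exposures on parental disease.
#' @param mediator_gamma effect of the adult exposure on the mediator.
#' @param prevalence parental disease prevalence in (0, 1).
#' @param missing_frac fraction of families whose parental reports are
#'   missing ("do not know" responses); those families' family-history
#'   outcomes are NA and are dropped by [assoc_scan()]. Default 0.
#' @param seed RNG seed; identical configs give bit-identical cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_trios = 10000, n_snps = 50, maf_range = c(0.1, 0.5),
                       beta_child = NULL, beta_adult_specific = NULL,
                       beta_mediator_specific = NULL,
                       kappa = 0.5, h2_child = 0.3, h2_adult = 0.3,
                       theta_child = 0, theta_adult = 0.5, theta_mediator = 0,
                       mediator_gamma = 0, prevalence = 0.3,
                       missing_frac = 0, seed = 1L) {
  stopifnot(n_trios >= 1, n_snps >= 1)
  if (!(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2])) {
    stop("sim_config: maf_range must be an ordered pair within (0, 0.5]", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) stop("sim_config: prevalence must lie in (0,1)", call. = FALSE)
  if (missing_frac < 0 || missing_frac >= 1) stop("sim_config: missing_frac must lie in [0,1)", call. = FALSE)
  if (h2_child <= 0 || h2_child >= 1 || h2_adult <= 0 || h2_adult >= 1) {
    stop("sim_config: heritabilities must lie in (0,1)", call. = FALSE)
  }
  for (nm in c("beta_child", "beta_adult_specific", "beta_mediator_specific")) {
    b <- get(nm)
    if (!is.null(b) && length(b) != n_snps) {
      stop(sprintf("sim_config: %s must have length n_snps (%d)", nm, n_snps), call. = FALSE)
    }
  }
  structure(list(
    n_trios = as.integer(n_trios), n_snps = as.integer(n_snps),
    maf_range = maf_range, beta_child = beta_child,
    beta_adult_specific = beta_adult_specific,
    beta_mediator_specific = beta_mediator_specific,
    kappa = kappa, h2_child = h2_child, h2_adult = h2_adult,
    theta_child = theta_child, theta_adult = theta_adult,
    theta_mediator = theta_mediator, mediator_gamma = mediator_gamma,
    prevalence = prevalence, missing_frac = missing_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# exposure phenotypes for one person from their genotype matrix and shared
# noise SDs; noise drawn inside so call order fixes reproducibility
.person_phenotypes <- function(G, cfg, sd_e_child, sd_e_adult) {
  n <- nrow(G)
  child <- as.vector(G %*% cfg$beta_child) + stats::rnorm(n, 0, sd_e_child)
  adult <- cfg$kappa * child + as.vector(G %*% cfg$beta_adult_specific) +
    stats::rnorm(n, 0, sd_e_adult)
  mediator <- cfg$mediator_gamma * adult +
    as.vector(G %*% cfg$beta_mediator_specific) + stats::rnorm(n)
  data.frame(childhood_exposure = child, adult_exposure = adult,
             mediator = mediator)
}

#' Simulate a trio cohort
#'
#' Draws the cohort described by [sim_config()]. Fully reproducible from the
#' config seed. Errors if the heritability targets are infeasible given the
#' effect vectors (the kappa-transmitted childhood noise already exceeds the
#' environmental variance budget for the adult exposure), reporting the
#' achievable bound.
#'
#' @param cfg a `sim_config`.
#' @return An object of class `trio_cohort`: list with `geno`
#'   (`$mother`, `$father`, `$offspring` dosage matrices), `pheno`
#'   (per-person data.frames; parents additionally have `disease` and
#'   `liability`), `family_history_count`, `mother_disease`,
#'   `father_disease`, `either_parent_disease`, `snp_info` (SNP id, CHR,
#'   POS, EA, OA, maf) and the `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  n <- cfg$n_trios; m <- cfg$n_snps

  if (is.null(cfg$beta_child)) cfg$beta_child <- stats::rnorm(m, 0, 0.15)
  if (is.null(cfg$beta_adult_specific)) cfg$beta_adult_specific <- stats::rnorm(m, 0, 0.15)
  if (is.null(cfg$beta_mediator_specific)) {
    cfg$beta_mediator_specific <-
      if (cfg$theta_mediator != 0 || cfg$mediator_gamma != 0) stats::rnorm(m, 0, 0.15)
      else rep(0, m)
  }

  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  draw_parent <- function() {
    matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  }
  Gm <- draw_parent()
  Gf <- draw_parent()
  # Mendelian transmission: one allele from each parent; a parent with
  # dosage g transmits the effect allele with probability g/2
  Go <- matrix(stats::rbinom(n * m, 1L, Gm / 2), n, m) +
        matrix(stats::rbinom(n * m, 1L, Gf / 2), n, m)

  # noise SDs targeting the heritabilities, from realized parental genetic values
  Gpool <- rbind(Gm, Gf)
  g_child <- as.vector(Gpool %*% cfg$beta_child)
  var_gc <- stats::var(g_child)
  if (var_gc <= 0) stop("simulate_cohort: childhood genetic variance is zero; cannot target h2_child",
                        call. = FALSE)
  var_e_child <- var_gc * (1 - cfg$h2_child) / cfg$h2_child
  g_adult <- cfg$kappa * g_child + as.vector(Gpool %*% cfg$beta_adult_specific)
  var_ga <- stats::var(g_adult)
  if (var_ga <= 0) stop("simulate_cohort: adult genetic variance is zero; cannot target h2_adult",
                        call. = FALSE)
  env_budget <- var_ga * (1 - cfg$h2_adult) / cfg$h2_adult
  var_e_adult <- env_budget - cfg$kappa^2 * var_e_child
  if (var_e_adult < 0) {
    h2_max <- var_ga / (var_ga + cfg$kappa^2 * var_e_child)
    stop(sprintf("simulate_cohort: h2_adult = %.3f infeasible; childhood noise carried by kappa already exceeds the environmental budget (achievable h2_adult <= %.3f)",
                 cfg$h2_adult, h2_max), call. = FALSE)
  }

  ph_m <- .person_phenotypes(Gm, cfg, sqrt(var_e_child), sqrt(var_e_adult))
  ph_f <- .person_phenotypes(Gf, cfg, sqrt(var_e_child), sqrt(var_e_adult))
  ph_o <- .person_phenotypes(Go, cfg, sqrt(var_e_child), sqrt(var_e_adult))

  liab <- function(ph) {
    cfg$theta_child * ph$childhood_exposure +
      cfg$theta_adult * ph$adult_exposure +
      cfg$theta_mediator * ph$mediator +
      stats::rlogis(n)
  }
  lm_ <- liab(ph_m); lf_ <- liab(ph_f)
  thr <- stats::quantile(c(lm_, lf_), probs = 1 - cfg$prevalence, names = FALSE)
  ph_m$liability <- lm_; ph_f$liability <- lf_
  ph_m$disease <- as.integer(lm_ > thr)
  ph_f$disease <- as.integer(lf_ > thr)

  fh_missing <- if (cfg$missing_frac > 0) {
    stats::runif(n) < cfg$missing_frac
  } else rep(FALSE, n)

  ids <- sprintf("snp_%04d", seq_len(m))
  dimnames(Gm) <- dimnames(Gf) <- dimnames(Go) <- list(NULL, ids)
  snp_info <- data.frame(SNP = ids, CHR = "1", POS = seq_len(m) * 1000L,
                         EA = "A", OA = "G", maf = maf, stringsAsFactors = FALSE)

  structure(list(
    geno = list(mother = Gm, father = Gf, offspring = Go),
    pheno = list(mother = ph_m, father = ph_f, offspring = ph_o),
    family_history_count = ifelse(fh_missing, NA_integer_,
                                  ph_m$disease + ph_f$disease),
    mother_disease = ifelse(fh_missing, NA_integer_, ph_m$disease),
    father_disease = ifelse(fh_missing, NA_integer_, ph_f$disease),
    either_parent_disease = ifelse(fh_missing, NA_integer_,
                                   as.integer(ph_m$disease | ph_f$disease)),
    snp_info = snp_info,
    config = cfg
  ), class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("Trio cohort: %d trios x %d SNPs; parental disease prevalence %.3f\n",
              x$config$n_trios, x$config$n_snps,
              mean(c(x$mother_disease, x$father_disease))))
  invisible(x)
}

# resolve a trait selector to a numeric vector
.cohort_trait <- function(cohort, genotype_source, trait) {
  person_traits <- c("childhood_exposure", "adult_exposure", "mediator",
                     "liability")
  if (trait %in% person_traits) return(cohort$pheno[[genotype_source]][[trait]])
  switch(trait,
    own_disease = {
      if (genotype_source == "offspring") {
        stop("assoc_scan: offspring have no simulated disease; use a family-history trait",
             call. = FALSE)
      }
      cohort$pheno[[genotype_source]]$disease
    },
    family_history_count = cohort$family_history_count,
    mother_disease = cohort$mother_disease,
    father_disease = cohort$father_disease,
    either_parent_disease = cohort$either_parent_disease,
    stop(sprintf("assoc_scan: unknown trait '%s'", trait), call. = FALSE)
  )
}

.BINARY_TRAITS <- c("own_disease", "mother_disease", "father_disease",
                    "either_parent_disease")

#' Per-SNP association scan
#'
#' Regresses a trait on each SNP's allele dosage in turn and emits one
#' summary-statistics record per SNP. The linear model is ordinary least
#' squares (slope, SE, t-based p); the logistic model is maximum-likelihood
#' logistic regression (log-odds slope, SE, Wald p), available only for
#' binary traits. Monomorphic SNPs yield a record with missing beta/SE and a
#' logged skip. The effect-allele frequency is computed from the chosen
#' genotype matrix.
#'
#' @param cohort a `trio_cohort`.
#' @param genotype_source `"offspring"`, `"mother"` or `"father"` — whose
#'   genotypes to scan. Using offspring genotypes against a parental disease
#'   trait is the GWAS-by-proxy design.
#' @param trait one of `"childhood_exposure"`, `"adult_exposure"`,
#'   `"mediator"`, `"liability"` (of the genotype-source person),
#'   `"own_disease"` (parents only), `"family_history_count"`,
#'   `"mother_disease"`, `"father_disease"`, `"either_parent_disease"`.
#' @param model `"linear"` or `"logistic"`.
#' @param trait_id label for the emitted records (default
#'   `<genotype_source>:<trait>`).
#' @return A `kinmr_assoc` data.frame (one row per SNP).
#' @export
assoc_scan <- function(cohort, genotype_source = c("offspring", "mother", "father"),
                       trait, model = c("linear", "logistic"),
                       trait_id = NULL) {
  stopifnot(inherits(cohort, "trio_cohort"))
  genotype_source <- match.arg(genotype_source)
  model <- match.arg(model)
  G <- cohort$geno[[genotype_source]]
  y <- .cohort_trait(cohort, genotype_source, trait)
  if (model == "logistic" && !(trait %in% .BINARY_TRAITS)) {
    stop(sprintf("assoc_scan: logistic model requested for non-binary trait '%s'", trait),
         call. = FALSE)
  }
  keep <- !is.na(y)
  if (!all(keep)) {
    G <- G[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- nrow(G); m <- ncol(G)
  eaf <- colMeans(G) / 2
  mono <- eaf == 0 | eaf == 1
  beta <- se <- pv <- rep(NA_real_, m)

  if (model == "linear") {
    gc <- sweep(G, 2, colMeans(G))
    yc <- y - mean(y)
    sxx <- colSums(gc^2)
    sxy <- as.vector(crossprod(gc, yc))
    ok <- !mono & sxx > 0
    beta[ok] <- sxy[ok] / sxx[ok]
    syy <- sum(yc^2)
    s2 <- (syy - beta[ok]^2 * sxx[ok]) / (n - 2)
    se[ok] <- sqrt(s2 / sxx[ok])
    tstat <- beta[ok] / se[ok]
    pv[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    for (j in seq_len(m)) {
      if (mono[j]) next
      fit <- stats::glm.fit(cbind(1, G[, j]), y,
                            family = stats::binomial())
      cf <- fit$coefficients[2]
      # Wald SE from the Fisher information at the MLE
      X <- cbind(1, G[, j])
      p_hat <- fit$fitted.values
      info <- crossprod(X, X * (p_hat * (1 - p_hat)))
      vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
      beta[j] <- cf
      se[j] <- sqrt(vc[2, 2])
      pv[j] <- 2 * stats::pnorm(-abs(cf / se[j]))
    }
  }
  if (any(mono)) {
    message(sprintf("assoc_scan: skipped %d monomorphic SNP(s)", sum(mono)))
  }
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
  df <- data.frame(
    SNP = cohort$snp_info$SNP, CHR = cohort$snp_info$CHR,
    POS = cohort$snp_info$POS, EA = cohort$snp_info$EA,
    OA = cohort$snp_info$OA, EAF = eaf, BETA = beta, SE = se, P = pv,
    N = n,
    trait_id = if (is.null(trait_id)) paste0(genotype_source, ":", trait) else trait_id,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  class(df) <- c("kinmr_assoc", "data.frame")
  df
}

#' Emit a simulated study as summary-statistics files
#'
#' Writes, under `out_dir`: exposure scans of the offspring genotypes
#' (childhood, adult, mediator), proxy-outcome scans of the offspring
#' genotypes (family-history count, linear; mother-only and father-only
#' binary, logistic), a direct-outcome scan of the father's genotypes
#' against his own disease (logistic), and the identity LD matrix of the
#' simulated unlinked SNPs — all in the package's summary-statistics schema.
#'
#' @param cohort a `trio_cohort`.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a named character vector of the files written.
#' @export
emit_study <- function(cohort, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop(sprintf("I/O error: cannot create directory '%s'", out_dir), call. = FALSE)
  scans <- list(
    exposure_childhood = assoc_scan(cohort, "offspring", "childhood_exposure",
                                    "linear", trait_id = "childhood_size"),
    exposure_adult = assoc_scan(cohort, "offspring", "adult_exposure",
                                "linear", trait_id = "adult_size"),
    exposure_mediator = assoc_scan(cohort, "offspring", "mediator",
                                   "linear", trait_id = "mediator"),
    outcome_family_history = assoc_scan(cohort, "offspring", "family_history_count",
                                        "linear", trait_id = "family_history_count"),
    outcome_mother_binary = assoc_scan(cohort, "offspring", "mother_disease",
                                       "logistic", trait_id = "mother_disease"),
    outcome_father_binary = assoc_scan(cohort, "offspring", "father_disease",
                                       "logistic", trait_id = "father_disease"),
    outcome_parent_direct = assoc_scan(cohort, "father", "own_disease",
                                       "logistic", trait_id = "parent_own_disease")
  )
  files <- character(0)
  for (nm in names(scans)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_summary_stats(scans[[nm]], path)
    files[nm] <- path
  }
  ld <- ld_matrix(diag(nrow(cohort$snp_info)),
                  variant_ids = cohort$snp_info$SNP)
  files["ld"] <- file.path(out_dir, "ld_identity.tsv")
  write_ld_matrix(ld, files["ld"])
  invisible(files)
}
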