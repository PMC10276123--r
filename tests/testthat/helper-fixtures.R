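# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route (lm/glm/p.adjust/recursive search) from the
# package's own linear-algebra implementations.

make_assoc <- function(snp = sprintf("rs%d", seq_along(beta)),
                       chr = "1", pos = seq_along(beta) * 100L,
                       ea = "A", oa = "G", eaf = 0.3,
                       beta, se = 0.05, p = NULL, n = 10000,
                       trait_id = "trait") {
  m <- length(beta)
  se <- rep_len(se, m)
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  assoc_table(snp, rep_len(chr, m), pos, rep_len(ea, m), rep_len(oa, m),
              rep_len(eaf, m), beta, se, pmin(pmax(p, 1e-300), 1),
              rep_len(n, m), trait_id)
}

# harmonized set built directly (already-aligned effects)
make_h <- function(bx, by, bx_se = 0.01, by_se = 0.05,
                   exposure_ids = NULL, outcome_id = "outcome") {
  bx <- as.matrix(bx)
  K <- ncol(bx); n <- nrow(bx)
  if (is.null(exposure_ids)) exposure_ids <- paste0("exp", seq_len(K))
  bx_se <- matrix(rep_len(bx_se, n * K), n, K)
  colnames(bx) <- colnames(bx_se) <- exposure_ids
  structure(list(
    exposure_ids = exposure_ids, outcome_id = outcome_id,
    variants = data.frame(SNP = sprintf("rs%d", seq_len(n)), CHR = "1",
                          POS = seq_len(n) * 100L, EA = "A", OA = "G",
                          stringsAsFactors = FALSE),
    bx = bx, bx_se = bx_se, by = as.numeric(by),
    by_se = rep_len(by_se, n), eaf = rep(0.3, n), n_outcome = rep(10000, n),
    drops = data.frame(SNP = character(0), reason = character(0))
  ), class = "harmonized_set")
}

# weighted-least-squares oracles via stats::lm
oracle_ivw_fixed <- function(bx, by, by_se) {
  fit <- lm(by ~ 0 + bx, weights = 1 / by_se^2)
  s <- summary(fit)
  list(estimate = unname(coef(fit)[1]),
       se = unname(s$coefficients[1, 2] / s$sigma))
}

oracle_egger <- function(bx, by, by_se) {
  neg <- bx < 0
  bx[neg] <- -bx[neg]; by[neg] <- -by[neg]
  fit <- lm(by ~ bx, weights = 1 / by_se^2)
  s <- summary(fit)
  scale <- sqrt(max(1, s$sigma^2))
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       slope_se = unname(s$coefficients[2, 2] / s$sigma * scale),
       intercept_se = unname(s$coefficients[1, 2] / s$sigma * scale))
}

oracle_mvmr <- function(bx, by, by_se) {
  fit <- lm(by ~ 0 + bx, weights = 1 / by_se^2)
  s <- summary(fit)
  K <- ncol(bx); n <- nrow(bx)
  scale <- sqrt(max(1, s$sigma^2))
  list(estimate = unname(coef(fit)),
       se = unname(s$coefficients[, 2] / s$sigma * scale))
}

# independent greedy-clump oracle: recursive, set-based, no index arithmetic
oracle_clump <- function(records, r2, p_threshold, r2_threshold) {
  cand <- records[records$P < p_threshold, , drop = FALSE]
  pick <- character(0)
  pool <- cand$SNP[order(cand$P, cand$POS)]
  while (length(pool)) {
    best <- pool[1]
    pick <- c(pick, best)
    pool <- setdiff(pool, pool[r2[best, pool] >= r2_threshold])
  }
  sort(pick)
}

# small random LD matrix with block structure, valid (PSD via correlation of
# random block-correlated normals)
random_block_ld <- function(m, n_blocks = 4) {
  blocks <- sort(sample(seq_len(n_blocks), m, replace = TRUE))
  z <- matrix(rnorm(200 * m), 200, m)
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    common <- rnorm(200)
    lambda <- runif(1, 0.3, 0.95)
    z[, idx] <- sqrt(lambda) * common + sqrt(1 - lambda) * z[, idx]
  }
  r2 <- cor(z)^2
  diag(r2) <- 1
  dimnames(r2) <- list(sprintf("rs%d", seq_len(m)), sprintf("rs%d", seq_len(m)))
  r2
}
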