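# univariable estimators, OR conversion, FDR gate

test_that("ivw: single SNP is the Wald ratio; exact line has Q = 0", {
  h1 <- make_h(bx = 0.2, by = 0.1, by_se = 0.05)
  expect_equal(ivw(h1)$estimate, 0.5)

  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_h(bx, by = 0.7 * bx, by_se = c(0.05, 0.04, 0.03, 0.05))
  fit <- ivw(h)
  expect_equal(fit$estimate, 0.7)
  expect_equal(fit$heterogeneity_q, 0)
  expect_error(ivw(make_h(c(0, 0), c(0.1, 0.2))), "degenerate")
})

test_that("ivw matches the weighted-least-squares oracle to 1e-10", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(2:60, 1)
    bx <- rnorm(n, 0, 0.1); by_se <- runif(n, 0.01, 0.1)
    by <- 0.5 * bx + rnorm(n, 0, by_se)
    if (all(bx == 0)) next
    h <- make_h(bx, by, by_se = by_se)
    want <- oracle_ivw_fixed(bx, by, by_se)
    fixed <- ivw(h, model = "fixed")
    expect_equal(fixed$estimate, want$estimate, tolerance = 1e-10)
    expect_equal(fixed$se, want$se, tolerance = 1e-10)
    # random-effects SE is the fixed SE inflated by sqrt(max(1, Q/(n-1))), never below it
    rand <- ivw(h, model = "random")
    expect_equal(rand$estimate, want$estimate, tolerance = 1e-10)
    expect_gte(rand$se, fixed$se - 1e-15)
    expect_equal(rand$se,
                 want$se * sqrt(max(1, rand$heterogeneity_q / (n - 1))),
                 tolerance = 1e-10)
  }
})

test_that("ivw recovers a known causal effect in simulation", {
  set.seed(31)
  n <- 100
  bx <- rnorm(n, 0, 0.1); by_se <- rep(0.02, n)
  by <- 0.5 * bx + rnorm(n, 0, by_se)
  fit <- ivw(make_h(bx, by, by_se = by_se))
  expect_lt(abs(fit$estimate - 0.5), 3 * fit$se)
})

test_that("mr_egger: exact affine relation, minimum df, collinearity", {
  bx <- c(0.1, 0.2, 0.3, 0.5)
  h <- make_h(bx, by = 0.05 + 0.4 * bx, by_se = c(0.05, 0.03, 0.04, 0.05))
  fit <- mr_egger(h)
  expect_equal(fit$estimate, 0.4)
  expect_equal(fit$intercept, 0.05)
  expect_equal(fit$heterogeneity_q, 0)

  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.05, 0.1))), "insufficient")
  expect_error(mr_egger(make_h(rep(0.2, 4), rnorm(4))), "zero variance")
})

test_that("mr_egger matches the intercept-regression oracle and orients bx >= 0", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(3:40, 1)
    bx <- rnorm(n, 0, 0.1); by_se <- runif(n, 0.01, 0.1)
    by <- 0.02 + 0.4 * bx + rnorm(n, 0, by_se)
    if (var(abs(bx)) < 1e-12) next
    fit <- mr_egger(make_h(bx, by, by_se = by_se))
    want <- oracle_egger(bx, by, by_se)
    expect_equal(fit$estimate, want$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(fit$se, want$slope_se, tolerance = 1e-10)
    expect_equal(fit$intercept_se, want$intercept_se, tolerance = 1e-10)
  }
})

test_that("egger intercept is near zero under balanced pleiotropy; zero intercept matches IVW", {
  set.seed(51)
  n <- 80
  bx <- abs(rnorm(n, 0.1, 0.03)); by_se <- rep(0.02, n)
  by <- 0.3 * bx + rnorm(n, 0, by_se) # no directional pleiotropy
  fit <- mr_egger(make_h(bx, by, by_se = by_se))
  expect_lt(abs(fit$intercept), 3 * fit$intercept_se)

  # data exactly through the origin: intercept 0 and slope equals fixed IVW
  h0 <- make_h(c(0.1, 0.2, 0.4), by = 0.6 * c(0.1, 0.2, 0.4),
               by_se = c(0.03, 0.05, 0.02))
  e0 <- mr_egger(h0)
  expect_equal(e0$intercept, 0, tolerance = 1e-12)
  expect_equal(e0$estimate, ivw(h0, model = "fixed")$estimate, tolerance = 1e-12)
})

test_that("weighted median: exact small fixtures and degenerate dispersion", {
  # 3 equal-weight ratios -> the middle one
  h <- make_h(c(0.1, 0.1, 0.1), by = c(0.02, 0.05, 0.09), by_se = 0.05)
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$estimate, 0.5)

  # hand-computed 3-SNP fixture with unequal weights:
  # ratios (0.1, 0.3, 0.8), normalized weights (0.2, 0.3, 0.5)
  # midpoint cumulative weights (0.10, 0.35, 0.75); 0.5 interpolates to
  # 0.3 + (0.5-0.35)/(0.75-0.35) * (0.8-0.3) = 0.4875
  bx <- rep(1, 3); by <- c(0.1, 0.3, 0.8)
  by_se <- 1 / sqrt(c(0.2, 0.3, 0.5))
  expect_equal(weighted_median(make_h(bx, by, by_se = by_se),
                               n_boot = 50, seed = 1)$estimate, 0.4875)

  # identical ratios: estimate exact, bootstrap SE shrinks with by_se
  h_tight <- make_h(c(0.1, 0.2, 0.3), by = 0.3 * c(0.1, 0.2, 0.3),
                    bx_se = 1e-6, by_se = 1e-6)
  fit <- weighted_median(h_tight, n_boot = 100, seed = 2)
  expect_equal(fit$estimate, 0.3)
  expect_lt(fit$se, 1e-4)

  expect_error(weighted_median(make_h(c(0, 0.1, 0.2), c(0, 0.1, 0.2))),
               "undefined ratio")
  expect_error(weighted_median(make_h(c(0.1, 0.2), c(0.1, 0.2))), "insufficient")
})

test_that("weighted median is robust where IVW is biased (30% invalid instruments)", {
  set.seed(61)
  wins <- 0
  for (rep in 1:200) {
    n <- 20
    bx <- runif(n, 0.05, 0.2); by_se <- rep(0.01, n)
    pleio <- c(rep(0.05, 6), rep(0, 14)) # 30% share a pleiotropic pathway
    by <- 0.5 * bx + pleio + rnorm(n, 0, by_se)
    h <- make_h(bx, by, bx_se = 1e-8, by_se = by_se)
    wm <- weighted_median(h, n_boot = 2, seed = rep)$estimate
    iv <- ivw(h)$estimate
    if (abs(wm - 0.5) < abs(iv - 0.5)) wins <- wins + 1
  }
  expect_gte(wins, 160)
})

test_that("weighted median is reproducible from its seed and bounded by the ratios", {
  set.seed(71)
  bx <- rnorm(10, 0.1, 0.02); by <- 0.4 * bx + rnorm(10, 0, 0.02)
  h <- make_h(bx, by, by_se = 0.02)
  a <- weighted_median(h, n_boot = 200, seed = 5)
  b <- weighted_median(h, n_boot = 200, seed = 5)
  expect_identical(a$se, b$se)
  r <- by / bx
  expect_gte(a$estimate, min(r))
  expect_lte(a$estimate, max(r))
})

test_that("wald_ratio base cases", {
  fit <- wald_ratio(0.2, 0.01, 0.1, 0.05)
  expect_equal(fit$estimate, 0.5)
  expect_equal(fit$se, 0.25)
  expect_equal(wald_ratio(0.2, 0.01, 0, 0.05)$estimate, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "nonzero")
})

test_that("odds-ratio conversion is exponential and monotone", {
  f0 <- wald_ratio(1, 0.01, 0, 1e-6)
  expect_equal(to_odds_ratio(f0)$or, 1.0)

  f <- wald_ratio(1, 0.01, log(1.43), 1e-10)
  expect_equal(to_odds_ratio(f)$or, 1.43, tolerance = 1e-6)

  ors <- sapply(c(-0.5, 0, 0.3, 1.2),
                function(b) to_odds_ratio(wald_ratio(1, 0.01, b, 0.1))$or)
  expect_true(all(diff(ors) > 0))
})

test_that("all estimators are equivariant under exposure rescaling", {
  set.seed(81)
  bx <- rnorm(12, 0.1, 0.03); by <- 0.4 * bx + rnorm(12, 0, 0.02)
  h <- make_h(bx, by, by_se = 0.02)
  for (c_ in c(0.5, 2, 10)) {
    hc <- make_h(c_ * bx, by, bx_se = 0.01 * c_, by_se = 0.02)
    expect_equal(ivw(hc)$estimate, ivw(h)$estimate / c_, tolerance = 1e-12)
    expect_equal(mr_egger(hc)$estimate, mr_egger(h)$estimate / c_, tolerance = 1e-12)
    expect_equal(weighted_median(hc, n_boot = 2, seed = 1)$estimate,
                 weighted_median(h, n_boot = 2, seed = 1)$estimate / c_,
                 tolerance = 1e-12)
  }
})

test_that("bh_fdr implements the step-up rule", {
  expect_false(any(bh_fdr(rep(1, 5))$passed))
  expect_true(bh_fdr(0.001)$passed)
  # hand-run step-up: largest k with p_(k) <= 0.01 k is k = 4
  dec <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.2), q = 0.05)
  expect_identical(dec$passed, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(dec$threshold_p, 0.04)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "0,1")
})

test_that("bh_fdr agrees with the p.adjust oracle and passes a down-set", {
  set.seed(91)
  for (rep in 1:50) {
    m <- sample(1:200, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    dec <- bh_fdr(p, q)
    expect_identical(dec$passed, p.adjust(p, "BH") <= q)
    if (any(dec$passed)) {
      expect_true(all(p[p <= max(p[dec$passed])] <= dec$threshold_p))
      expect_true(all(dec$passed[order(p)] == sort(dec$passed, decreasing = TRUE)))
    }
  }
})

test_that("bh_fdr false-positive rate under the global null is consistent with q", {
  set.seed(101)
  hits <- replicate(500, any(bh_fdr(runif(200), q = 0.05)$passed))
  # P(any rejection | global null) = q for independent uniforms
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})
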