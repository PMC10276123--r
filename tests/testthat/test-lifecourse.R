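# multivariable MR, decomposition, mediation, sharing de-attenuation

test_that("mvmr_fit solves an exact system with zero residual Q", {
  set.seed(12)
  bx1 <- rnorm(20, 0, 0.1); bx2 <- rnorm(20, 0, 0.1)
  by <- 0.0 * bx1 + 0.6 * bx2
  h <- make_h(cbind(bx1, bx2), by, exposure_ids = c("child", "adult"))
  fit <- mvmr_fit(h)
  expect_equal(fit$fits$child$estimate, 0, tolerance = 1e-12)
  expect_equal(fit$fits$adult$estimate, 0.6, tolerance = 1e-12)
  expect_equal(fit$heterogeneity_q, 0, tolerance = 1e-18)
})

test_that("mvmr_fit matches the weighted multiple-regression oracle", {
  set.seed(22)
  for (rep in 1:30) {
    n <- sample(5:50, 1); K <- sample(2:3, 1)
    bx <- matrix(rnorm(n * K, 0, 0.1), n, K)
    by_se <- runif(n, 0.01, 0.1)
    by <- bx %*% runif(K, -0.5, 0.5) + rnorm(n, 0, by_se)
    h <- make_h(bx, by, by_se = by_se)
    fit <- mvmr_fit(h)
    want <- oracle_mvmr(bx, by, by_se)
    got_b <- vapply(fit$fits, `[[`, numeric(1), "estimate")
    got_se <- vapply(fit$fits, `[[`, numeric(1), "se")
    expect_equal(unname(got_b), want$estimate, tolerance = 1e-10)
    expect_equal(unname(got_se), want$se, tolerance = 1e-10)
  }
})

test_that("mvmr_fit nests ivw: K = 1 identical, zero second column ignored", {
  set.seed(32)
  bx <- rnorm(15, 0.1, 0.05); by <- 0.4 * bx + rnorm(15, 0, 0.03)
  h1 <- make_h(bx, by, by_se = 0.03)
  uni <- ivw(h1)
  m1 <- mvmr_fit(h1)
  expect_equal(m1$fits[[1]]$estimate, uni$estimate, tolerance = 1e-14)
  expect_equal(m1$fits[[1]]$se, uni$se, tolerance = 1e-14)

  h2 <- make_h(cbind(a = bx, b = rep(0, 15)), by, by_se = 0.03,
               exposure_ids = c("a", "b"))
  m2 <- mvmr_fit(h2)
  expect_equal(m2$fits$a$estimate, uni$estimate, tolerance = 1e-14)
  expect_true(is.na(m2$fits$b$estimate))
})

test_that("mvmr_fit errors on collinear columns and too few SNPs", {
  bx <- rnorm(10, 0.1, 0.05)
  h <- make_h(cbind(bx, bx), rnorm(10), exposure_ids = c("x1", "x2"))
  expect_error(mvmr_fit(h), "collinear.*x[12].*x[12]")
  h3 <- make_h(cbind(bx, 2 * bx, -bx), rnorm(10),
               exposure_ids = c("x1", "x2", "x3"))
  expect_error(mvmr_fit(h3), "collinear")
  expect_error(mvmr_fit(make_h(cbind(c(0.1, 0.2), c(0.3, 0.1)), c(0.1, 0.2))),
               "insufficient")
})

test_that("decompose: identities, frozen arithmetic, id checks", {
  set.seed(42)
  bx1 <- rnorm(30, 0, 0.1); bx2 <- 0.53 * bx1 + rnorm(30, 0, 0.08)
  by <- 0.68 * bx2
  h2 <- make_h(cbind(bx1, bx2), by, exposure_ids = c("child", "adult"),
               outcome_id = "disease")
  mv <- mvmr_fit(h2)
  total <- ivw(make_h(bx1, by, exposure_ids = "child", outcome_id = "disease"))
  path <- ivw(make_h(bx1, bx2, by_se = 0.01, exposure_ids = "child",
                     outcome_id = "adult"))
  res <- decompose(total, mv, path)
  # difference identity holds exactly by construction
  expect_equal(res$indirect_difference$estimate,
               total$estimate - mv$fits$child$estimate, tolerance = 1e-15)
  expect_equal(res$indirect_product$estimate,
               path$estimate * mv$fits$adult$estimate, tolerance = 1e-15)

  # degenerate case: direct == total
  same <- decompose(total,
                    structure(list(exposure_ids = c("child", "adult"),
                                   fits = list(child = total, adult = mv$fits$adult),
                                   conditional_f = c(child = 1, adult = 1),
                                   n_snps = 30, heterogeneity_q = 0,
                                   heterogeneity_df = 28), class = "mvmr_fit"),
                    path)
  expect_equal(same$indirect_difference$estimate, 0)

  # frozen arithmetic from the stated formulas
  t2 <- total; t2$estimate <- 0.36; t2$se <- 0.1
  mv2 <- mv
  mv2$fits$child$estimate <- 0.0; mv2$fits$child$se <- 0.1
  mv2$fits$adult$estimate <- 0.68
  p2 <- path; p2$estimate <- 0.53
  r2 <- decompose(t2, mv2, p2)
  expect_equal(r2$indirect_difference$estimate, 0.36)
  expect_equal(r2$indirect_product$estimate, 0.3604)
  expect_equal(r2$indirect_difference$se, sqrt(0.1^2 + 0.1^2))

  bad_path <- path; bad_path$exposure_id <- "other"
  expect_error(decompose(total, mv, bad_path), "same early exposure")
  bad_total <- total; bad_total$outcome_id <- "elsewhere"
  expect_error(decompose(bad_total, mv, path), "different outcomes")
})

test_that("difference and product indirect effects agree under full mediation", {
  set.seed(52)
  n <- 150
  bx1 <- rnorm(n, 0, 0.1)
  bx2 <- 0.5 * bx1 + rnorm(n, 0, 0.08)
  by_se <- rep(0.02, n)
  by <- 0.6 * bx2 + rnorm(n, 0, by_se) # childhood acts only through adult
  h2 <- make_h(cbind(bx1, bx2), by, exposure_ids = c("child", "adult"),
               outcome_id = "disease")
  mv <- mvmr_fit(h2)
  total <- ivw(make_h(bx1, by, by_se = by_se, exposure_ids = "child",
                      outcome_id = "disease"))
  path <- ivw(make_h(bx1, bx2, by_se = 0.08, exposure_ids = "child",
                     outcome_id = "adult"))
  res <- decompose(total, mv, path)
  d <- res$indirect_difference; p <- res$indirect_product
  overlap <- abs(d$estimate - p$estimate) < 1.96 * sqrt(d$se^2 + p$se^2)
  expect_true(overlap)
  # and the direct effect of childhood is null
  expect_lt(abs(mv$fits$child$estimate), 3 * mv$fits$child$se)
})

test_that("mediation: an irrelevant mediator leaves K=2 estimates unchanged", {
  set.seed(62)
  n <- 40
  bx1 <- rnorm(n, 0, 0.1); bx2 <- rnorm(n, 0, 0.1)
  by_se <- rep(0.02, n)
  by <- 0.3 * bx1 + 0.5 * bx2 + rnorm(n, 0, by_se)
  w <- 1 / by_se^2
  # construct a mediator column w-orthogonal to bx1, bx2 and the outcome
  raw <- rnorm(n, 0, 0.1)
  X <- cbind(bx1, bx2, by)
  proj <- X %*% solve(crossprod(X, w * X), crossprod(X, w * raw))
  bxm <- raw - as.vector(proj)
  h3 <- make_h(cbind(bx1, bx2, bxm), by, by_se = by_se,
               exposure_ids = c("child", "adult", "med"))
  med <- mediation_mvmr(h3)
  expect_equal(med$attenuation$b_without, med$attenuation$b_with,
               tolerance = 1e-10)
  expect_equal(med$fit3$fits$med$estimate, 0, tolerance = 1e-10)
})

test_that("mediation recovers the mediated pathway and errors on collinearity", {
  set.seed(72)
  n <- 150
  bx1 <- rnorm(n, 0, 0.1)
  bx2 <- 0.5 * bx1 + rnorm(n, 0, 0.08)
  bxm <- 0.6 * bx2 + rnorm(n, 0, 0.08) # mediator downstream of adult
  by_se <- rep(0.02, n)
  by <- 0.5 * bxm + rnorm(n, 0, by_se) # outcome only via the mediator
  h3 <- make_h(cbind(bx1, bx2, bxm), by, by_se = by_se,
               exposure_ids = c("child", "adult", "med"))
  med <- mediation_mvmr(h3)
  att <- med$attenuation
  # without the mediator, adult carries the effect; with it, adult attenuates
  expect_gt(att$b_without[att$exposure == "adult"], 0.2)
  expect_lt(abs(att$b_with[att$exposure == "adult"]),
            3 * med$fit3$fits$adult$se)
  expect_lt(abs(med$fit3$fits$med$estimate - 0.5), 3 * med$fit3$fits$med$se)

  hc <- make_h(cbind(bx1, bx2, bx2), by, by_se = by_se,
               exposure_ids = c("child", "adult", "med"))
  expect_error(mediation_mvmr(hc), "collinear")
  expect_error(mediation_mvmr(make_h(cbind(bx1, bx2), by, by_se = by_se)),
               "exactly 3")
})

test_that("deattenuate_proxy rescales by the sharing coefficient", {
  fit <- wald_ratio(1, 0.01, 0.34, 0.05)
  adj <- deattenuate_proxy(fit, s = 0.5)
  expect_equal(adj$estimate, 0.68)
  expect_equal(adj$se, 0.1)
  expect_equal(adj$ci_low, fit$ci_low / 0.5)
  expect_match(adj$method, "sharing-adjusted")

  expect_equal(deattenuate_proxy(fit, s = 1)$estimate, fit$estimate)
  # round trip: multiplying back by s recovers the original numbers
  expect_equal(adj$estimate * 0.5, fit$estimate)
  expect_equal(adj$se * 0.5, fit$se)
  expect_error(deattenuate_proxy(fit, s = 0), "0, 1")
  expect_error(deattenuate_proxy(fit, s = 1.2), "0, 1")
})

test_that("adjust_lifecourse rescales outcome-side estimates and keeps the original", {
  set.seed(82)
  bx1 <- rnorm(30, 0, 0.1); bx2 <- 0.5 * bx1 + rnorm(30, 0, 0.08)
  by <- 0.6 * bx2 + rnorm(30, 0, 0.02)
  mv <- mvmr_fit(make_h(cbind(bx1, bx2), by, by_se = 0.02,
                        exposure_ids = c("child", "adult"),
                        outcome_id = "disease"))
  total <- ivw(make_h(bx1, by, by_se = 0.02, exposure_ids = "child",
                      outcome_id = "disease"))
  path <- ivw(make_h(bx1, bx2, by_se = 0.08, exposure_ids = "child",
                     outcome_id = "adult"))
  res <- decompose(total, mv, path)
  adj <- adjust_lifecourse(res, s = 0.5)
  expect_true(adj$sharing_adjusted)
  expect_equal(adj$total$estimate, 2 * res$total$estimate)
  expect_equal(adj$direct$estimate, 2 * res$direct$estimate)
  expect_equal(adj$indirect_difference$estimate,
               2 * res$indirect_difference$estimate)
  # identity survives adjustment
  expect_equal(adj$total$estimate - adj$direct$estimate,
               adj$indirect_difference$estimate, tolerance = 1e-12)
  expect_identical(adj$unadjusted$total$estimate, res$total$estimate)
})
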