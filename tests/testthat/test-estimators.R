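test_that("the Wald ratio divides effects and propagates sign, SE and p", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(-0.1, 0.01, 0.05, 0.01)$beta, -0.5)
  z <- wald_ratio(0.2, 0.02, 0, 0.01)
  expect_equal(z$beta, 0)
  expect_equal(z$pval, 1)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01), "degenerate")
  # second-order delta SE adds the exposure term
  w2 <- wald_ratio(0.1, 0.01, 0.05, 0.01, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.01^2 / 0.1^4))
  expect_gt(w2$se, w$se)
})

test_that("IVW reduces to simple cases and matches the zero-intercept WLS oracle", {
  # two identical ratios with equal weights: se shrinks by sqrt(2)
  h2 <- harmonized_set(c("a", "b"), c(0.1, 0.1), 0.01, c(0.05, 0.05), 0.01)
  f <- mr_ivw(h2, "fixed")
  expect_equal(f$beta, 0.5)
  expect_equal(f$se, (0.01 / 0.1) / sqrt(2))

  # one SNP reduces to the Wald ratio
  h1 <- harmonized_set("a", 0.1, 0.01, 0.05, 0.02)
  expect_equal(mr_ivw(h1)$beta, wald_ratio(0.1, 0.01, 0.05, 0.02)$beta)
  expect_equal(mr_ivw(h1)$se, wald_ratio(0.1, 0.01, 0.05, 0.02)$se)

  # heterogeneous SNPs equal the generic WLS oracle
  h <- make_test_set(J = 5, beta = 0.4, seed = 11)
  or <- wls_oracle(h$beta_x, h$beta_y, 1 / h$se_y^2, intercept = FALSE)
  expect_equal(mr_ivw(h, "fixed")$beta, unname(or$coef["slope"]), tolerance = 1e-12)

  # random-effects SE never undercuts the fixed SE
  expect_gte(mr_ivw(h, "multiplicative_random")$se, mr_ivw(h, "fixed")$se)

  expect_error(mr_egger(h2), "at least 3")
})

test_that("MR-Egger matches the free-intercept WLS oracle and fits exact lines exactly", {
  # exact linear data: slope and intercept recovered with zero residuals
  x <- c(0.05, 0.1, 0.15, 0.2)
  h <- harmonized_set(letters[1:4], x, 0.01, 0.02 + 0.3 * x, 0.01)
  fit <- mr_egger(h)
  expect_equal(fit$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.02, tolerance = 1e-10)

  # zero-intercept data: slope equals fixed IVW when the intercept is dropped
  h0 <- harmonized_set(letters[1:4], x, 0.01, 0.3 * x, 0.01)
  expect_equal(mr_egger(h0)$beta, mr_ivw(h0, "fixed")$beta, tolerance = 1e-10)

  # simulated data: slope, intercept and SEs match the normal-equations oracle
  hs <- make_test_set(J = 10, beta = 0.5, seed = 21)
  flip <- sign(hs$beta_x)
  or <- wls_oracle(hs$beta_x * flip, hs$beta_y * flip, 1 / hs$se_y^2)
  fit2 <- mr_egger(hs)
  expect_equal(fit2$beta, unname(or$coef["slope"]), tolerance = 1e-10)
  expect_equal(fit2$intercept, unname(or$coef["intercept"]), tolerance = 1e-10)
  expect_equal(fit2$se, unname(or$se["slope"]), tolerance = 1e-10)
  expect_equal(fit2$intercept_se, unname(or$se["intercept"]), tolerance = 1e-10)
})

test_that("the weighted median obeys its quantile definition", {
  # equal weights: plain median
  h <- harmonized_set(letters[1:3], c(1, 1, 1), 0.01, c(0.1, 0.2, 0.9), 0.1)
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$beta, 0.2)

  # a centrally placed ratio carrying 60% of the weight is returned exactly
  w <- c(0.2, 0.6, 0.2)               # target weights beta_x^2 / se_y^2
  bx <- sqrt(w) * 0.1
  hmaj <- harmonized_set(letters[1:3], bx, 0.01, bx * c(0.1, 0.5, 0.9), 0.1)
  expect_equal(mr_weighted_median(hmaj, n_boot = 10, seed = 1)$beta, 0.5)

  # unequal weights match the CDF-inversion oracle
  set.seed(31)
  J <- 7
  bx <- runif(J, 0.05, 0.2)
  hs <- harmonized_set(sprintf("s%d", 1:J), bx, 0.01,
                       bx * runif(J, 0.2, 0.8), runif(J, 0.05, 0.2))
  expect_equal(mr_weighted_median(hs, n_boot = 10, seed = 1)$beta,
               weighted_median_oracle(hs$beta_y / hs$beta_x,
                                      hs$beta_x^2 / hs$se_y^2),
               tolerance = 1e-12)

  # bootstrap SE is bit-reproducible under (n_boot, seed)
  a <- mr_weighted_median(hs, n_boot = 200, seed = 99)
  b <- mr_weighted_median(hs, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, mr_weighted_median(hs, n_boot = 200, seed = 100)$se))
})

test_that("maximum likelihood matches its analytic limits and a grid-search oracle", {
  # tiny exposure SE: collapses to fixed-effect IVW
  h <- make_test_set(J = 15, beta = 0.3, seed = 41, se_x = 1e-8, se_y = 0.02)
  expect_equal(mr_maxlik(h)$beta, mr_ivw(h, "fixed")$beta, tolerance = 1e-4)

  # general case: dense grid search over the profile likelihood
  hg <- make_test_set(J = 20, beta = 0.3, seed = 42, se_x = 0.01, se_y = 0.02)
  fit <- mr_maxlik(hg)
  grid_b <- maxlik_grid_oracle(hg, fit$beta, 0.05)
  expect_equal(fit$beta, grid_b, tolerance = 1e-5)
})

test_that("MR-RAPS matches the IVW limit, resists an outlier, and respects symmetry", {
  # l2 loss, no overdispersion, tiny exposure SE: fixed-effect IVW
  h <- make_test_set(J = 15, beta = 0.3, seed = 51, se_x = 1e-8, se_y = 0.02)
  expect_equal(mr_raps(h, loss = "l2", overdispersion = FALSE)$beta,
               mr_ivw(h, "fixed")$beta, tolerance = 1e-4)

  # huber beats l2 on a gross outlier (known simulated truth 0.3)
  ho <- make_test_set(J = 20, beta = 0.3, seed = 52, se_x = 0.005, se_y = 0.01)
  ho$beta_y[7] <- ho$beta_y[7] + 0.2
  b_huber <- mr_raps(ho, loss = "huber", overdispersion = FALSE)$beta
  b_l2 <- mr_raps(ho, loss = "l2", overdispersion = FALSE)$beta
  expect_lt(abs(b_huber - 0.3), abs(b_l2 - 0.3))

  # ratios symmetric around zero: estimate ~ 0
  hsym <- harmonized_set(sprintf("s%d", 1:6),
                         rep(0.1, 6), 0.01,
                         c(0.03, -0.03, 0.02, -0.02, 0.01, -0.01), 0.02)
  expect_lt(abs(mr_raps(hsym)$beta), 0.01)

  # estimated overdispersion is non-negative and grows with planted pleiotropy
  hp <- make_test_set(J = 30, beta = 0.3, seed = 53, se_x = 0.002, se_y = 0.005)
  set.seed(1)
  hp$beta_y <- hp$beta_y + rnorm(30, 0, 0.05)
  expect_gt(attr(mr_raps(hp), "tau2"), 0)
})

test_that("every estimator is invariant to jointly flipping an instrument's signs", {
  h <- make_test_set(J = 12, beta = 0.4, seed = 61)
  hf <- h
  flip <- c(2, 5, 9)
  hf$beta_x[flip] <- -hf$beta_x[flip]
  hf$beta_y[flip] <- -hf$beta_y[flip]
  expect_equal(mr_ivw(hf)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(hf)$beta, mr_egger(h)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hf, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(h, n_boot = 10, seed = 1)$beta,
               tolerance = 1e-12)
  expect_equal(mr_maxlik(hf)$beta, mr_maxlik(h)$beta, tolerance = 1e-8)
  expect_equal(mr_raps(hf)$beta, mr_raps(h)$beta, tolerance = 1e-8)
})

test_that("fixed-effect IVW variance never exceeds any single Wald-ratio variance", {
  for (s in 1:5) {
    h <- make_test_set(J = 8, beta = 0.5, seed = 70 + s)
    se_ivw <- mr_ivw(h, "fixed")$se
    se_single <- h$se_y / abs(h$beta_x)
    expect_true(all(se_ivw <= se_single + 1e-15))
  }
})

test_that("estimates and the consolidated table expose the OR scale consistently", {
  h <- make_test_set(J = 10, beta = 0.5, seed = 81)
  fit <- mr_ivw(h)
  expect_equal(fit$odds_ratio, exp(fit$beta))
  expect_true(fit$ci_low <= fit$beta && fit$beta <= fit$ci_high)
  tab <- mr_all(h, n_boot = 50, seed = 1)
  expect_equal(nrow(tab), 5L)
  expect_true(all(is.na(tab$intercept[tab$method != "MR-Egger"])))
  expect_false(is.na(tab$intercept[tab$method == "MR-Egger"]))
})
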