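# Independent oracles used to cross-check the estimators. These go through
# generic linear algebra (solve on the normal equations) and stats::approx,
# never through the package's own code paths.

# Weighted least squares via explicit normal equations; SEs carry the same
# multiplicative overdispersion convention (never deflating below 1).
wls_oracle <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(intercept = 1, slope = x) else cbind(slope = x)
  XtWX <- t(X) %*% (w * X)
  coef <- drop(solve(XtWX, t(X) %*% (w * y)))
  resid <- y - drop(X %*% coef)
  rss <- sum(w * resid^2)
  J <- length(y)
  p <- ncol(X)
  phi <- if (J > p) max(1, rss / (J - p)) else 1
  se <- sqrt(phi * diag(solve(XtWX)))
  list(coef = coef, se = se, rss = rss)
}

# Interpolated weighted median via inversion of the piecewise-linear
# weighted CDF with stats::approx.
weighted_median_oracle <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

# Dense grid argmax of the profile log-likelihood, written from the model
# definition (independent normals with a shared slope).
maxlik_grid_oracle <- function(h, center, half_width, n_grid = 20001) {
  grid <- seq(center - half_width, center + half_width, length.out = n_grid)
  ll <- vapply(grid, function(b) {
    -0.5 * sum((h$beta_y - b * h$beta_x)^2 / (h$se_y^2 + b^2 * h$se_x^2))
  }, numeric(1))
  grid[which.max(ll)]
}

# A standard simulated harmonized set for estimator tests.
make_test_set <- function(J = 10, beta = 0.5, seed = 1, se_x = 0.01, se_y = 0.02) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    gamma <- runif(J, 0.05, 0.15)
    bx <- rnorm(J, gamma, se_x)
    by <- rnorm(J, beta * gamma, se_y)
    harmonized_set(sprintf("rs%03d", seq_len(J)), bx, rep(se_x, J), by, rep(se_y, J))
  })
}
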