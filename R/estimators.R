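new_mr_estimate <- function(method, beta, se, n_snp, pval = NULL,
                            intercept = NULL, intercept_se = NULL,
                            intercept_pval = NULL) {
  z975 <- stats::qnorm(0.975)
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  out <- list(method = method, beta = beta, se = se,
              ci_low = beta - z975 * se, ci_high = beta + z975 * se,
              pval = pval, n_snp = as.integer(n_snp))
  out$odds_ratio <- exp(out$beta)
  out$or_ci_low <- exp(out$ci_low)
  out$or_ci_high <- exp(out$ci_high)
  out$intercept <- intercept
  out$intercept_se <- intercept_se
  out$intercept_pval <- intercept_pval
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("  OR = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$odds_ratio, x$or_ci_low, x$or_ci_high))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high,
             odds_ratio = x$odds_ratio, or_ci_low = x$or_ci_low,
             or_ci_high = x$or_ci_high, pval = x$pval,
             intercept = if (is.null(x$intercept)) NA_real_ else x$intercept,
             intercept_se = if (is.null(x$intercept_se)) NA_real_ else x$intercept_se,
             intercept_pval = if (is.null(x$intercept_pval)) NA_real_ else x$intercept_pval,
             stringsAsFactors = FALSE)
}

#' Wald ratio for a single instrument
#'
#' Per-SNP causal estimate: the outcome effect divided by the exposure
#' effect, `beta_y / beta_x`. The default standard error is the
#' first-order delta approximation `se_y / |beta_x|`; the second-order
#' option adds the term propagating the exposure uncertainty,
#' `sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)`.
#'
#' @param beta_x,se_x exposure effect and SE (`beta_x` must be nonzero).
#' @param beta_y,se_y outcome effect and SE.
#' @param second_order use the second-order delta SE.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (beta_x == 0) stop("degenerate instrument: beta_x = 0")
  b <- beta_y / beta_x
  se <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
  new_mr_estimate("Wald ratio", b, se, 1L)
}

ivw_weights <- function(h) h$beta_x^2 / h$se_y^2

wald_ratios <- function(h) h$beta_y / h$beta_x

#' Inverse-variance weighted estimator
#'
#' Combines the per-SNP Wald ratios with inverse-variance weights
#' `w_j = beta_x_j^2 / se_y_j^2`: `beta = sum(w * ratio) / sum(w)`,
#' algebraically identical to the zero-intercept weighted least-squares
#' regression of `beta_y` on `beta_x` with weights `1 / se_y^2`.
#' Under `"fixed"` effects `se = 1 / sqrt(sum(w))`; the default
#' `"multiplicative_random"` model inflates it by
#' `sqrt(max(1, Q / (J - 1)))` where `Q` is Cochran's heterogeneity
#' statistic, so the random-effects SE never undercuts the fixed one.
#' A single SNP delegates to [wald_ratio()].
#'
#' @param h a [harmonized_set()] (or data frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y`).
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate`.
#' @export
mr_ivw <- function(h, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  h <- as_harmonized_set(h)
  J <- nrow(h)
  if (J == 1L) return(wald_ratio(h$beta_x, h$se_x, h$beta_y, h$se_y))
  w <- ivw_weights(h)
  r <- wald_ratios(h)
  b <- sum(w * r) / sum(w)
  se <- 1 / sqrt(sum(w))
  method <- "IVW (fixed)"
  if (effects_model == "multiplicative_random") {
    q <- sum(w * (r - b)^2)
    se <- se * sqrt(max(1, q / (J - 1)))
    method <- "IVW (multiplicative random effects)"
  }
  new_mr_estimate(method, b, se, J)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with an unconstrained intercept (weights `1 / se_y^2`), after
#' orienting every instrument so `beta_x >= 0` (flipping the paired
#' `beta_y` sign), the orientation under which the estimator is
#' identified. The slope estimates the causal effect; a nonzero intercept
#' indicates directional horizontal pleiotropy, and its p-value is the
#' pleiotropy test. Standard errors carry the multiplicative
#' overdispersion factor `sqrt(max(1, RSS / (J - 2)))`.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with `intercept`, `intercept_se`,
#'   `intercept_pval` populated.
#' @export
mr_egger <- function(h) {
  h <- as_harmonized_set(h)
  J <- nrow(h)
  if (J < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(h$beta_x)
  flip[flip == 0] <- 1
  x <- h$beta_x * flip
  y <- h$beta_y * flip
  w <- 1 / h$se_y^2
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  rss <- sum(w * (y - intercept - slope * x)^2)
  phi <- max(1, rss / (J - 2))
  se_slope <- sqrt(phi * sw / det)
  se_int <- sqrt(phi * sxx / det)
  new_mr_estimate("MR-Egger", slope, se_slope, J,
                  intercept = intercept, intercept_se = se_int,
                  intercept_pval = 2 * stats::pnorm(-abs(intercept / se_int)))
}

weighted_median_value <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  n <- length(r)
  if (cw[n] <= 0.5) return(r[n])
  below <- max(which(cw <= 0.5))
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

#' Weighted median estimator
#'
#' Consistent when instruments carrying at least half of the total weight
#' are valid. Sorts the Wald ratios and returns the value at which the
#' normalized cumulative inverse-variance weights
#' (`w_j = beta_x_j^2 / se_y_j^2`, offset by half of each weight) cross
#' one half, linearly interpolating between the bracketing ratios. The
#' standard error comes from a seeded parametric bootstrap: each
#' replicate redraws `beta_x` and `beta_y` from normals centred on the
#' observed values and recomputes the weighted median.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed integer seed making the bootstrap reproducible.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 42L) {
  h <- as_harmonized_set(h)
  J <- nrow(h)
  if (J < 3L) stop("weighted median requires at least 3 instruments")
  b <- weighted_median_value(wald_ratios(h), ivw_weights(h))
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, h$beta_x, h$se_x)
      by <- stats::rnorm(J, h$beta_y, h$se_y)
      ok <- bx != 0
      weighted_median_value(by[ok] / bx[ok], bx[ok]^2 / h$se_y[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  new_mr_estimate("Weighted median", b, se, J)
}

profile_loglik <- function(b, h) {
  -0.5 * sum((h$beta_y - b * h$beta_x)^2 / (h$se_y^2 + b^2 * h$se_x^2))
}

#' Maximum-likelihood estimator
#'
#' Models each observed pair `(beta_x_j, beta_y_j)` as independent normals
#' centred on a latent SNP effect `xi_j` and `b * xi_j` with the reported
#' standard errors, and maximizes the likelihood over `b` after profiling
#' out the nuisance `xi_j` analytically. The profile log-likelihood is
#' `-(1/2) * sum((beta_y - b beta_x)^2 / (se_y^2 + b^2 se_x^2))`,
#' maximized numerically from the IVW starting value; the SE comes from
#' the observed information (numerical second derivative) at the optimum.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate`.
#' @export
mr_maxlik <- function(h) {
  h <- as_harmonized_set(h)
  J <- nrow(h)
  if (J < 2L) stop("maximum likelihood requires at least 2 instruments")
  b0 <- mr_ivw(h, "fixed")$beta
  width <- max(1, 100 * mr_ivw(h, "fixed")$se, 10 * abs(b0))
  opt <- stats::optimize(function(b) -profile_loglik(b, h),
                         interval = c(b0 - width, b0 + width), tol = 1e-10)
  b <- opt$minimum
  eps <- max(1e-6, 1e-6 * abs(b))
  info <- -(profile_loglik(b + eps, h) - 2 * profile_loglik(b, h) +
              profile_loglik(b - eps, h)) / eps^2
  if (!is.finite(info) || info <= 0) stop("maximum likelihood did not converge")
  new_mr_estimate("Maximum likelihood", b, sqrt(1 / info), J)
}

huber_psi <- function(t, cc) pmin(pmax(t, -cc), cc)
huber_dpsi <- function(t, cc) as.numeric(abs(t) <= cc)

#' Robust adjusted profile score (MR-RAPS)
#'
#' Accounts for idiosyncratic (balanced) pleiotropy by adding an
#' overdispersion variance `tau^2` to each SNP's profile residual and
#' solving the robustified profile-score equation
#' `sum(psi(t_j) * dt_j/db) = 0` with
#' `t_j = (beta_y_j - b beta_x_j) / sqrt(se_y_j^2 + b^2 se_x_j^2 + tau^2)`.
#' `psi` is the identity (`"l2"`) or the Huber score with tuning constant
#' 1.345 (default `"huber"`). With `overdispersion = TRUE` (default),
#' `tau^2 >= 0` is estimated jointly from the second estimating equation
#' `sum(t_j psi(t_j)) = J * E[Z psi(Z)]`. The SE is the M-estimation
#' sandwich treating `tau^2` as known at its estimate.
#'
#' @inheritParams mr_ivw
#' @param loss `"huber"` (default) or `"l2"`.
#' @param overdispersion estimate `tau^2` jointly (default `TRUE`).
#' @param tuning Huber tuning constant (default 1.345).
#' @param max_iter iteration cap for the alternating solver.
#' @return An `mr_estimate` with the estimated `tau2` attached as an
#'   attribute.
#' @export
mr_raps <- function(h, loss = c("huber", "l2"), overdispersion = TRUE,
                    tuning = 1.345, max_iter = 200L) {
  loss <- match.arg(loss)
  h <- as_harmonized_set(h)
  J <- nrow(h)
  if (J < 3L) stop("MR-RAPS requires at least 3 instruments")
  psi <- if (loss == "huber") function(t) huber_psi(t, tuning) else identity
  dpsi <- if (loss == "huber") function(t) huber_dpsi(t, tuning) else function(t) rep(1, length(t))
  # E[Z psi(Z)] under N(0,1): 1 for l2, 2*Phi(c)-1 for Huber
  delta <- if (loss == "huber") 2 * stats::pnorm(tuning) - 1 else 1

  tj <- function(b, tau2) {
    (h$beta_y - b * h$beta_x) / sqrt(h$se_y^2 + b^2 * h$se_x^2 + tau2)
  }
  dt_db <- function(b, tau2) {
    s2 <- h$se_y^2 + b^2 * h$se_x^2 + tau2
    s <- sqrt(s2)
    -h$beta_x / s - tj(b, tau2) * b * h$se_x^2 / s2
  }
  score_b <- function(b, tau2) sum(psi(tj(b, tau2)) * dt_db(b, tau2))
  score_tau <- function(b, tau2) {
    t <- tj(b, tau2)
    sum(t * psi(t)) - J * delta
  }
  solve_b <- function(b0, tau2) {
    step <- max(10 * mr_ivw(h, "fixed")$se, 0.1 * abs(b0), 1e-3)
    lo <- b0 - step; hi <- b0 + step
    for (k in 1:60) {
      if (sign(score_b(lo, tau2)) != sign(score_b(hi, tau2))) break
      lo <- lo - step; hi <- hi + step
      step <- step * 1.5
    }
    if (sign(score_b(lo, tau2)) == sign(score_b(hi, tau2))) {
      stop("MR-RAPS: no root in search bracket for the causal effect")
    }
    stats::uniroot(score_b, c(lo, hi), tau2 = tau2, tol = 1e-12)$root
  }
  solve_tau <- function(b) {
    if (score_tau(b, 0) <= 0) return(0)
    hi <- stats::var(h$beta_y - b * h$beta_x) + max(h$se_y^2)
    for (k in 1:60) {
      if (score_tau(b, hi) < 0) break
      hi <- hi * 2
    }
    if (score_tau(b, hi) >= 0) stop("MR-RAPS: overdispersion search did not bracket")
    stats::uniroot(function(t2) score_tau(b, t2), c(0, hi), tol = 1e-12)$root
  }

  b <- mr_ivw(h, "fixed")$beta
  tau2 <- 0
  for (it in seq_len(max_iter)) {
    b_new <- solve_b(b, tau2)
    tau2_new <- if (overdispersion) solve_tau(b_new) else 0
    done <- abs(b_new - b) < 1e-10 && abs(tau2_new - tau2) < 1e-12
    b <- b_new; tau2 <- tau2_new
    if (done) break
    if (it == max_iter) stop("MR-RAPS did not converge in ", max_iter, " iterations")
  }
  t <- tj(b, tau2)
  d <- dt_db(b, tau2)
  A <- sum(dpsi(t) * d^2)
  B <- sum(psi(t)^2 * d^2)
  se <- sqrt(B) / A
  method <- sprintf("MR-RAPS (%s%s)", loss,
                    if (overdispersion) ", overdispersed" else "")
  out <- new_mr_estimate(method, b, se, J)
  attr(out, "tau2") <- tau2
  out
}

#' Run all five estimators
#'
#' Convenience wrapper producing a tidy table mirroring a forest-plot
#' layout: one row per method with effect, SE, odds ratio, CI and p-value
#' (plus the Egger intercept columns).
#'
#' @inheritParams mr_ivw
#' @param n_boot,seed passed to [mr_weighted_median()].
#' @param effects_model passed to [mr_ivw()].
#' @return Data frame, one row per estimator.
#' @export
mr_all <- function(h, effects_model = "multiplicative_random",
                   n_boot = 1000, seed = 42L) {
  h <- as_harmonized_set(h)
  fits <- list(mr_ivw(h, effects_model),
               mr_weighted_median(h, n_boot = n_boot, seed = seed),
               mr_egger(h),
               mr_maxlik(h),
               mr_raps(h))
  do.call(rbind, lapply(fits, as.data.frame))
}
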