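#' Cochran's Q heterogeneity test
#'
#' Measures heterogeneity among the per-SNP Wald ratios around the
#' fixed-effect IVW estimate: `Q = sum(w_j * (ratio_j - b_ivw)^2)` with
#' the IVW weights `w_j = beta_x_j^2 / se_y_j^2`, referred to a chi-square
#' distribution on `J - 1` degrees of freedom. `Q` equals the weighted
#' residual sum of squares of the zero-intercept regression of `beta_y` on
#' `beta_x` with weights `1 / se_y^2`. Excess heterogeneity suggests
#' pleiotropy or invalid instruments.
#'
#' @inheritParams mr_ivw
#' @return List with `q`, `df`, `pval` (class `q_result`).
#' @export
cochran_q <- function(h) {
  h <- as_harmonized_set(h)
  J <- nrow(h)
  if (J < 2L) stop("Cochran's Q requires at least 2 instruments")
  w <- ivw_weights(h)
  r <- wald_ratios(h)
  b <- sum(w * r) / sum(w)
  q <- sum(w * (r - b)^2)
  structure(list(q = q, df = J - 1L,
                 pval = stats::pchisq(q, df = J - 1L, lower.tail = FALSE)),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept triple from [mr_egger()]: a nonzero intercept
#' indicates directional horizontal pleiotropy (intercept p < 0.05 is the
#' conventional flag).
#'
#' @inheritParams mr_ivw
#' @return List with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  list(intercept = fit$intercept, se = fit$intercept_se,
       pval = fit$intercept_pval)
}

#' Leave-one-out analysis
#'
#' Recomputes the IVW estimate excluding each SNP in turn, to reveal
#' whether any single instrument drives the overall result.
#'
#' @inheritParams mr_ivw
#' @param effects_model IVW variant used for each reduced fit.
#' @return Data frame (class `loo_result`) with one row per left-out SNP:
#'   `left_out_snp`, `beta`, `se`, `pval`; the full-set estimate is in
#'   `attr(x, "full")`.
#' @export
leave_one_out <- function(h, effects_model = "multiplicative_random") {
  h <- as_harmonized_set(h)
  J <- nrow(h)
  if (J < 3L) stop("leave-one-out requires at least 3 instruments")
  rows <- lapply(seq_len(J), function(j) {
    fit <- mr_ivw(h[-j, , drop = FALSE], effects_model)
    data.frame(left_out_snp = h$snp_id[j], beta = fit$beta, se = fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- mr_ivw(h, effects_model)
  class(out) <- c("loo_result", "data.frame")
  out
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precisions (`1 / se`), plus the IVW
#' and (when three or more SNPs) MR-Egger estimates as reference lines.
#' Asymmetry of the scatter around the reference suggests directional
#' pleiotropy. Plotting is left to the caller; the returned data frame is
#' plot-ready.
#'
#' @inheritParams mr_ivw
#' @return Data frame (class `funnel_data`) with `snp_id`, `ratio`,
#'   `precision`; reference estimates in `attr(x, "reference")`.
#' @export
funnel_data <- function(h) {
  h <- as_harmonized_set(h)
  r <- wald_ratios(h)
  se_r <- h$se_y / abs(h$beta_x)
  out <- data.frame(snp_id = h$snp_id, ratio = r, precision = 1 / se_r,
                    stringsAsFactors = FALSE)
  ref <- c(ivw = mr_ivw(h)$beta,
           egger = if (nrow(h) >= 3L) mr_egger(h)$beta else NA_real_)
  attr(out, "reference") <- ref
  class(out) <- c("funnel_data", "data.frame")
  out
}

# Zero-intercept WLS slope with weights 1/se_y^2 (the fixed-effect IVW),
# expressed through running sums so leave-one-out variants are O(1).
ivw_loo_betas <- function(x, y, w) {
  s_xy <- sum(w * x * y)
  s_xx <- sum(w * x^2)
  (s_xy - w * x * y) / (s_xx - w * x^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments.
#' The observed statistic is the residual sum of squares of the
#' leave-one-out-predicted outcome effects,
#' `RSS = sum_j (beta_y_j - b_(-j) * beta_x_j)^2`, where `b_(-j)` is the
#' fixed-effect IVW slope excluding SNP j. Its null distribution is built
#' by simulating `n_sim` datasets with
#' `beta_y*_j ~ N(b_(-j) * beta_x_j, se_y_j)` and
#' `beta_x*_j ~ N(beta_x_j, se_x_j)` and recomputing RSS identically:
#'
#' * global test: empirical p of the observed RSS;
#' * outlier test: per-SNP empirical p of each squared residual against
#'   its own simulated distribution, flagged when the Bonferroni-adjusted
#'   p falls below `outlier_alpha`;
#' * distortion test: the shift between the raw IVW estimate and the
#'   outlier-removed estimate is compared against shifts from removing
#'   random subsets of the same size.
#'
#' Per-SNP simulation streams are derived from `seed` and the SNP
#' identifier, so the result is reproducible and invariant to row order.
#'
#' @inheritParams mr_ivw
#' @param n_sim number of simulated null datasets (default 1000).
#' @param seed master seed for the simulation streams.
#' @param outlier_alpha familywise threshold for flagging outliers after
#'   Bonferroni adjustment (default 0.05).
#' @param n_distortion random subset draws for the distortion test.
#' @return A `presso_result` list: `global_rss`, `global_pval`,
#'   `outlier_indices`, `outlier_snps`, `outlier_pvals`, `raw_beta`,
#'   `raw_se`, `raw_pval`, and — when outliers were flagged —
#'   `corrected_beta`, `corrected_se`, `corrected_pval`,
#'   `distortion_pval`; plus `n_sim` and `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 42L, outlier_alpha = 0.05,
                      n_distortion = 1000) {
  h <- as_harmonized_set(h)
  J <- nrow(h)
  if (J < 4L) stop("MR-PRESSO requires at least 4 instruments")
  x <- h$beta_x; y <- h$beta_y
  w <- 1 / h$se_y^2

  b_loo <- ivw_loo_betas(x, y, w)
  resid_obs <- y - b_loo * x
  rss_obs <- sum(resid_obs^2)

  # per-SNP simulation streams keyed by snp_id (order-invariant)
  xs <- matrix(NA_real_, n_sim, J)
  ys <- matrix(NA_real_, n_sim, J)
  for (j in seq_len(J)) {
    draws <- with_seed(snp_stream_seed(seed, h$snp_id[j]), {
      list(x = stats::rnorm(n_sim, x[j], h$se_x[j]),
           y = stats::rnorm(n_sim, b_loo[j] * x[j], h$se_y[j]))
    })
    xs[, j] <- draws$x
    ys[, j] <- draws$y
  }

  # vectorized leave-one-out IVW across simulated datasets
  wmat <- matrix(w, n_sim, J, byrow = TRUE)
  s_xy <- (xs * ys * wmat) %*% rep(1, J)
  s_xx <- (xs^2 * wmat) %*% rep(1, J)
  b_loo_sim <- (as.vector(s_xy) - xs * ys * wmat) /
    (as.vector(s_xx) - xs^2 * wmat)
  resid_sim <- ys - b_loo_sim * xs
  rss_sim <- rowSums(resid_sim^2)

  # add-one Monte Carlo p-values (never exactly zero at finite n_sim)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  per_snp_p <- (1 + colSums(sweep(resid_sim^2, 2, resid_obs^2, ">="))) /
    (n_sim + 1)
  p_adj <- pmin(1, per_snp_p * J)
  flagged <- which(p_adj < outlier_alpha)

  raw <- mr_ivw(h)
  out <- list(global_rss = rss_obs, global_pval = global_pval,
              outlier_indices = flagged, outlier_snps = h$snp_id[flagged],
              outlier_pvals = per_snp_p[flagged],
              per_snp_pvals = stats::setNames(per_snp_p, h$snp_id),
              raw_beta = raw$beta, raw_se = raw$se, raw_pval = raw$pval,
              n_sim = n_sim, seed = seed)
  if (length(flagged)) {
    if (length(flagged) == J) {
      stop("MR-PRESSO flagged every instrument; corrected estimate undefined")
    }
    corrected <- mr_ivw(h[-flagged, , drop = FALSE])
    out$corrected_beta <- corrected$beta
    out$corrected_se <- corrected$se
    out$corrected_pval <- corrected$pval
    n_out <- length(flagged)
    obs_shift <- abs(out$corrected_beta - out$raw_beta)
    ids_sorted <- sort(h$snp_id)
    shifts <- with_seed(snp_stream_seed(seed, "distortion"), {
      vapply(seq_len(n_distortion), function(k) {
        drop_ids <- sample(ids_sorted, n_out)
        mr_ivw(h[!h$snp_id %in% drop_ids, , drop = FALSE])$beta - out$raw_beta
      }, numeric(1))
    })
    out$distortion_pval <- (1 + sum(abs(shifts) >= obs_shift)) /
      (n_distortion + 1)
  }
  structure(out, class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.4g, p = %.4g (%d simulations)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (length(x$outlier_indices)) {
    cat("Outliers: ", paste(x$outlier_snps, collapse = ", "), "\n", sep = "")
    cat(sprintf("Raw beta = %.4f (p = %.3g); corrected beta = %.4f (p = %.3g); distortion p = %.3g\n",
                x$raw_beta, x$raw_pval, x$corrected_beta, x$corrected_pval,
                x$distortion_pval))
  } else {
    cat(sprintf("No outliers flagged. Raw beta = %.4f (p = %.3g)\n",
                x$raw_beta, x$raw_pval))
  }
  invisible(x)
}
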