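#' Indirect (mediated) effect by the product method
#'
#' Sum over mediators of the product of the exposure-to-mediator effect
#' (`beta1`) and the mediator-to-outcome effect (`beta2`), all on the log
#' scale: `sum(beta1 * beta2)`.
#'
#' @param beta1 per-mediator exposure-to-mediator effects.
#' @param beta2 per-mediator mediator-to-outcome effects (same length).
#' @return The summed product.
#' @export
indirect_effect <- function(beta1, beta2) {
  if (length(beta1) != length(beta2)) {
    stop("beta1 and beta2 must have the same length")
  }
  sum(beta1 * beta2)
}

#' Proportion of the total effect that is mediated
#'
#' `E = indirect / (beta3 + indirect)` where `beta3` is the direct effect
#' of the exposure on the outcome; the denominator reconstitutes the total
#' effect as direct plus indirect. When the indirect and total effects
#' have opposite signs the proportion is not interpretable as a share
#' ("inconsistent mediation") and the result carries attribute
#' `inconsistent = TRUE`.
#'
#' @param indirect summed product of mediator-path effects
#'   ([indirect_effect()]).
#' @param beta3 direct (mediator-adjusted) effect on the log scale.
#' @return The proportion (unitless; multiply by 100 for percent), with
#'   attribute `inconsistent`.
#' @export
proportion_mediated <- function(indirect, beta3) {
  total <- beta3 + indirect
  if (total == 0) stop("undefined proportion: direct + indirect effect is zero")
  p <- indirect / total
  attr(p, "inconsistent") <- indirect != 0 && sign(indirect) != sign(total)
  p
}

#' Mediated proportion from printed odds ratios
#'
#' Convenience wrapper for published results reported as odds ratios:
#' log-transforms the total-effect OR and the two mediator-path ORs,
#' forms the indirect effect by the product method, recovers the direct
#' effect as total minus indirect, and returns the mediated proportion.
#'
#' @param or_total OR of the exposure on the outcome (total effect).
#' @param or_exposure_mediator OR (or exponentiated effect) of the
#'   exposure on the mediator.
#' @param or_mediator_outcome OR of the mediator on the outcome.
#' @return List with `beta1`, `beta2`, `total_effect`, `indirect_effect`,
#'   `beta3`, `proportion`, `percent`.
#' @examples
#' # a total-effect OR of 1.15 with mediator-path ORs 1.08 and 1.35
#' proportion_from_or(1.15, 1.08, 1.35)$percent
#' @export
proportion_from_or <- function(or_total, or_exposure_mediator,
                               or_mediator_outcome) {
  stopifnot(or_total > 0, or_exposure_mediator > 0, or_mediator_outcome > 0)
  beta1 <- log(or_exposure_mediator)
  beta2 <- log(or_mediator_outcome)
  total <- log(or_total)
  ind <- indirect_effect(beta1, beta2)
  beta3 <- total - ind
  p <- proportion_mediated(ind, beta3)
  list(beta1 = beta1, beta2 = beta2, total_effect = total,
       indirect_effect = ind, beta3 = beta3,
       proportion = as.numeric(p), percent = 100 * as.numeric(p),
       inconsistent = attr(p, "inconsistent"))
}

estimator_by_name <- function(method) {
  switch(method,
         ivw = mr_ivw,
         ivw_fixed = function(h, ...) mr_ivw(h, "fixed"),
         weighted_median = mr_weighted_median,
         egger = mr_egger,
         maxlik = mr_maxlik,
         raps = mr_raps,
         stop("unknown estimator: ", method))
}

#' Two-step mediation Mendelian randomization
#'
#' Decomposes the total effect of an exposure on an outcome into a direct
#' component and an indirect component carried by one or more mediators.
#' Step one estimates each exposure-to-mediator effect (`beta1`), step two
#' each mediator-to-outcome effect (`beta2`); their summed product is the
#' indirect effect. The total effect comes from the exposure-to-outcome
#' instrument set. By default the direct effect `beta3` is recovered as
#' total minus indirect (`decompose_mode = "total_minus_indirect"`), so
#' direct + indirect = total holds exactly; alternatively an externally
#' estimated direct effect (for example from a multivariable model) can be
#' supplied via `beta3` with `decompose_mode = "external"`. The mediated
#' proportion is `indirect / (beta3 + indirect)`. A first-order
#' delta-method SE propagates the three legs' standard errors assuming
#' independence (an approximation: the legs share no samples but the
#' mediators are treated as uncorrelated).
#'
#' @param h_exposure_mediator a [harmonized_set()] (or list of them, one
#'   per mediator) for the exposure-to-mediator leg(s).
#' @param h_mediator_outcome matching set(s) for the mediator-to-outcome
#'   leg(s).
#' @param h_exposure_outcome set for the total-effect leg.
#' @param method estimator used on every leg: `"ivw"` (default),
#'   `"ivw_fixed"`, `"weighted_median"`, `"egger"`, `"maxlik"`, `"raps"`.
#' @param decompose_mode `"total_minus_indirect"` (default) or
#'   `"external"`.
#' @param beta3,se_beta3 externally supplied direct effect (and optional
#'   SE) used when `decompose_mode = "external"`.
#' @param mediator_names optional labels.
#' @param ... passed to the leg estimator.
#' @return A `mediation_result` list: `beta1`, `se1`, `beta2`, `se2`,
#'   `beta3`, `total_effect`, `se_total`, `indirect_effect`, `proportion`,
#'   `percent`, `se_proportion`, `inconsistent`, plus the per-leg
#'   `mr_estimate` objects.
#' @export
two_step_mediation <- function(h_exposure_mediator, h_mediator_outcome,
                               h_exposure_outcome,
                               method = "ivw",
                               decompose_mode = c("total_minus_indirect", "external"),
                               beta3 = NULL, se_beta3 = NULL,
                               mediator_names = NULL, ...) {
  decompose_mode <- match.arg(decompose_mode)
  est <- estimator_by_name(method)
  as_list <- function(x) if (inherits(x, "harmonized_set") || is.data.frame(x)) list(x) else x
  hx <- as_list(h_exposure_mediator)
  hm <- as_list(h_mediator_outcome)
  if (length(hx) != length(hm)) {
    stop("need one mediator-to-outcome set per exposure-to-mediator set")
  }
  K <- length(hx)
  if (is.null(mediator_names)) mediator_names <- paste0("mediator_", seq_len(K))

  run_leg <- function(h, leg) {
    tryCatch(est(h, ...), error = function(e) {
      stop("estimation failed on leg '", leg, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  fits1 <- lapply(seq_len(K), function(k) {
    run_leg(hx[[k]], paste0("exposure->", mediator_names[k]))
  })
  fits2 <- lapply(seq_len(K), function(k) {
    run_leg(hm[[k]], paste0(mediator_names[k], "->outcome"))
  })
  fit_total <- run_leg(h_exposure_outcome, "exposure->outcome")

  b1 <- vapply(fits1, `[[`, numeric(1), "beta")
  s1 <- vapply(fits1, `[[`, numeric(1), "se")
  b2 <- vapply(fits2, `[[`, numeric(1), "beta")
  s2 <- vapply(fits2, `[[`, numeric(1), "se")
  total <- fit_total$beta
  se_total <- fit_total$se

  ind <- indirect_effect(b1, b2)
  var_ind <- sum(b2^2 * s1^2 + b1^2 * s2^2)

  if (decompose_mode == "total_minus_indirect") {
    beta3 <- total - ind
    p <- proportion_mediated(ind, beta3)  # = ind / total
    # E = I / T with I, T from disjoint instrument sets
    se_p <- sqrt(var_ind / total^2 + ind^2 * se_total^2 / total^4)
  } else {
    if (is.null(beta3)) stop("decompose_mode 'external' requires beta3")
    p <- proportion_mediated(ind, beta3)
    denom <- beta3 + ind
    v3 <- if (is.null(se_beta3)) 0 else se_beta3^2
    se_p <- sqrt((beta3^2 * var_ind + ind^2 * v3) / denom^4)
  }

  structure(list(mediators = mediator_names,
                 beta1 = stats::setNames(b1, mediator_names),
                 se1 = stats::setNames(s1, mediator_names),
                 beta2 = stats::setNames(b2, mediator_names),
                 se2 = stats::setNames(s2, mediator_names),
                 beta3 = beta3, total_effect = total, se_total = se_total,
                 indirect_effect = ind, proportion = as.numeric(p),
                 percent = 100 * as.numeric(p), se_proportion = se_p,
                 inconsistent = attr(p, "inconsistent"),
                 method = method, decompose_mode = decompose_mode,
                 fits = list(step1 = fits1, step2 = fits2, total = fit_total)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step mediation MR (", x$method, ", ", x$decompose_mode, ")\n", sep = "")
  for (k in seq_along(x$mediators)) {
    cat(sprintf("  %s: beta1 = %.4f (SE %.4f), beta2 = %.4f (SE %.4f)\n",
                x$mediators[k], x$beta1[k], x$se1[k], x$beta2[k], x$se2[k]))
  }
  cat(sprintf("  total = %.4f, indirect = %.4f, direct = %.4f\n",
              x$total_effect, x$indirect_effect, x$beta3))
  cat(sprintf("  mediated proportion = %.1f%% (SE %.1f pp)%s\n",
              x$percent, 100 * x$se_proportion,
              if (isTRUE(x$inconsistent)) " [inconsistent mediation]" else ""))
  invisible(x)
}
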