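#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Describes a two-sample MR data-generating process: per-SNP true
#' exposure effects, a causal effect of the exposure on the outcome, an
#' optional fraction of pleiotropic (invalid) instruments, allele
#' frequencies including an optional palindromic fraction, optional block
#' LD, and an optional mediation system.
#'
#' Observed effects are drawn around the truth with the standardized-trait
#' standard error `se_j = 1 / sqrt(2 n p_j (1 - p_j))`; for a binary trait
#' (log-odds scale) the SE is additionally inflated by
#' `1 / sqrt(phi (1 - phi))` with `phi` the case fraction.
#'
#' @param n_snp number of instruments.
#' @param true_beta causal effect of exposure on outcome.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param maf_range minor-allele-frequency bounds, in (0, 0.5].
#' @param gamma_mean,gamma_sd normal distribution of the true per-SNP
#'   exposure effects (effect alleles oriented trait-increasing, so the
#'   mean is positive).
#' @param frac_invalid fraction of instruments with a pleiotropic path to
#'   the outcome.
#' @param pleiotropy_mean,pleiotropy_sd pleiotropic effect distribution
#'   (`mean = 0` gives balanced, nonzero directional pleiotropy).
#' @param inside_violation_cor correlation between pleiotropic effects and
#'   instrument strength (0 = InSIDE assumption holds, the default).
#' @param frac_palindromic fraction of SNPs assigned A/T or C/G alleles.
#' @param ld_blocks optional list `list(n_blocks, block_size, r2_within)`
#'   describing block LD; requires `n_snp = n_blocks * block_size`.
#' @param mediator_spec optional list `list(beta1, beta2, direct)` for
#'   [simulate_mediation_system()].
#' @param outcome_type,exposure_type `"continuous"` or `"binary"`.
#' @param case_fraction_outcome,case_fraction_exposure case fractions used
#'   when the respective trait is binary.
#' @param seed integer seed; identical configs yield identical data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snp = 100, true_beta = 0.1,
                       n_exposure = 1e6, n_outcome = 1e6,
                       maf_range = c(0.05, 0.5),
                       gamma_mean = 0.05, gamma_sd = 0.02,
                       frac_invalid = 0,
                       pleiotropy_mean = 0, pleiotropy_sd = 0.01,
                       inside_violation_cor = 0,
                       frac_palindromic = 0,
                       ld_blocks = NULL, mediator_spec = NULL,
                       outcome_type = "continuous",
                       exposure_type = "continuous",
                       case_fraction_outcome = 0.1,
                       case_fraction_exposure = 0.1,
                       seed = 1L) {
  stopifnot(n_snp >= 1, frac_invalid >= 0, frac_invalid <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            frac_palindromic >= 0, frac_palindromic <= 1,
            abs(inside_violation_cor) <= 1)
  if (!is.null(ld_blocks)) {
    stopifnot(all(c("n_blocks", "block_size", "r2_within") %in% names(ld_blocks)))
    if (ld_blocks$n_blocks * ld_blocks$block_size != n_snp) {
      stop("n_snp must equal n_blocks * block_size")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

sim_snp_ids <- function(J) sprintf("rs%06d", seq_len(J))

se_for_trait <- function(n, maf, type, case_fraction) {
  se <- 1 / sqrt(2 * n * maf * (1 - maf))
  if (type == "binary") se <- se / sqrt(case_fraction * (1 - case_fraction))
  se
}

#' Simulate an exposure-outcome summary-statistic pair
#'
#' Generates matched GWAS summary tables for an exposure and an outcome
#' over shared variants. Per SNP j: a minor-allele frequency is drawn
#' uniformly from `maf_range`; a true exposure effect
#' `gamma_j ~ N(gamma_mean, gamma_sd^2)`; a pleiotropic effect `alpha_j`
#' equal to 0 for valid SNPs and drawn from
#' `N(pleiotropy_mean, pleiotropy_sd^2)` for the invalid fraction (with
#' optional correlation with `gamma_j` to violate the InSIDE assumption);
#' the true outcome effect is `true_beta * gamma_j + alpha_j`. Observed
#' betas are drawn around the truth with the analytic standard errors, and
#' p-values follow from the observed z-scores. Alleles are assigned with
#' the configured palindromic fraction and are identical (pre-aligned)
#' between the two tables.
#'
#' @param config a [sim_config()].
#' @return List with `exposure` and `outcome` [summary_table()]s and a
#'   `truth` list carrying every latent quantity (`gamma`, `alpha`,
#'   `Gamma`, `maf`, `se_x`, `se_y`, `valid`, `true_beta`).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    J <- config$n_snp
    ids <- sim_snp_ids(J)
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    gamma <- stats::rnorm(J, config$gamma_mean, config$gamma_sd)
    valid <- rep(TRUE, J)
    n_inv <- round(config$frac_invalid * J)
    if (n_inv > 0) valid[sample.int(J, n_inv)] <- FALSE
    alpha <- numeric(J)
    if (n_inv > 0) {
      rho <- config$inside_violation_cor
      z <- stats::rnorm(n_inv)
      g_std <- (gamma[!valid] - config$gamma_mean) /
        max(config$gamma_sd, .Machine$double.eps)
      alpha[!valid] <- config$pleiotropy_mean +
        config$pleiotropy_sd * (rho * g_std + sqrt(1 - rho^2) * z)
    }
    Gamma <- config$true_beta * gamma + alpha

    se_x <- se_for_trait(config$n_exposure, maf, config$exposure_type,
                         config$case_fraction_exposure)
    se_y <- se_for_trait(config$n_outcome, maf, config$outcome_type,
                         config$case_fraction_outcome)
    beta_x <- stats::rnorm(J, gamma, se_x)
    beta_y <- stats::rnorm(J, Gamma, se_y)

    # allele assignment: shared frame, optional palindromic fraction
    pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    nonpal_pairs <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                         c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
    n_pal <- round(config$frac_palindromic * J)
    is_pal <- rep(FALSE, J)
    if (n_pal > 0) is_pal[sample.int(J, n_pal)] <- TRUE
    ea <- oa <- character(J)
    for (j in seq_len(J)) {
      pr <- if (is_pal[j]) pal_pairs[[sample.int(4, 1)]] else nonpal_pairs[[sample.int(8, 1)]]
      ea[j] <- pr[1]; oa[j] <- pr[2]
    }

    if (!is.null(config$ld_blocks)) {
      chrom <- rep(1L, J)
      pos <- (seq_len(J) - 1L) * 10000L + 1L
    } else {
      chrom <- rep_len(1:22, J)
      pos <- sample.int(1e8, J)
    }

    mk_table <- function(beta, se, n, trait, type) {
      summary_table(data.frame(
        snp_id = ids, chrom = chrom, pos = pos,
        effect_allele = ea, other_allele = oa, eaf = maf,
        beta = beta, se = se,
        pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300), n = n,
        stringsAsFactors = FALSE), trait_name = trait, trait_type = type)
    }
    list(exposure = mk_table(beta_x, se_x, config$n_exposure, "exposure",
                             config$exposure_type),
         outcome = mk_table(beta_y, se_y, config$n_outcome, "outcome",
                            config$outcome_type),
         truth = list(gamma = gamma, alpha = alpha, Gamma = Gamma, maf = maf,
                      se_x = se_x, se_y = se_y, valid = valid,
                      true_beta = config$true_beta, config = config))
  })
}

#' Harmonized set straight from a simulated pair
#'
#' The simulator emits both tables on a shared, pre-aligned allele frame,
#' so the harmonized instrument set is a direct column binding. Useful for
#' estimator studies that do not exercise the harmonization path.
#'
#' @param sim result of [simulate_pair()].
#' @return A [harmonized_set()].
#' @export
sim_harmonized <- function(sim) {
  shared <- intersect(sim$exposure$snp_id, sim$outcome$snp_id)
  ex <- sim$exposure[match(shared, sim$exposure$snp_id), ]
  ou <- sim$outcome[match(shared, sim$outcome$snp_id), ]
  harmonized_set(shared, ex$beta, ex$se, ou$beta, ou$se, ex$eaf, ou$eaf)
}

#' Simulate a block-diagonal LD matrix
#'
#' Builds the r-squared matrix implied by `config$ld_blocks`: unit
#' diagonal, the stated within-block value inside each block, zero
#' elsewhere. SNP ids and positions match [simulate_pair()] under the same
#' config, with consecutive SNPs 10 kb apart so whole blocks fall within
#' the default clumping window.
#'
#' @param config a [sim_config()] with `ld_blocks` set.
#' @return An [ld_matrix()].
#' @export
simulate_ld <- function(config) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$ld_blocks))
  bl <- config$ld_blocks
  J <- config$n_snp
  ids <- sim_snp_ids(J)
  r2 <- matrix(0, J, J, dimnames = list(ids, ids))
  for (b in seq_len(bl$n_blocks)) {
    idx <- ((b - 1) * bl$block_size + 1):(b * bl$block_size)
    r2[idx, idx] <- bl$r2_within
  }
  diag(r2) <- 1
  ld_matrix(r2)
}

#' Simulate a three-leg mediation system
#'
#' Generates exposure-to-mediator, mediator-to-outcome, and
#' exposure-to-outcome summary-statistic pairs consistent with a mediation
#' truth in which the total effect equals `direct + sum(beta1 * beta2)`.
#' Each leg uses an independent instrument set (independent seeds derived
#' from `config$seed`).
#'
#' @param config a [sim_config()] with `mediator_spec = list(beta1,
#'   beta2, direct)`; `beta1`/`beta2` may be vectors for several
#'   mediators.
#' @return List with `xm`, `my` (lists of simulated pairs, one per
#'   mediator), `xy` (the total-effect pair) and `truth` (including the
#'   true mediated `proportion`).
#' @export
simulate_mediation_system <- function(config) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$mediator_spec))
  spec <- config$mediator_spec
  stopifnot(all(c("beta1", "beta2", "direct") %in% names(spec)),
            length(spec$beta1) == length(spec$beta2))
  K <- length(spec$beta1)
  total <- spec$direct + sum(spec$beta1 * spec$beta2)

  leg_config <- function(true_beta, seed_offset) {
    cfg <- config
    cfg$true_beta <- true_beta
    cfg$mediator_spec <- NULL
    cfg$seed <- (config$seed * 1009L + seed_offset) %% 2147483629L
    cfg
  }
  xm <- lapply(seq_len(K), function(k) {
    simulate_pair(leg_config(spec$beta1[k], k))
  })
  my <- lapply(seq_len(K), function(k) {
    simulate_pair(leg_config(spec$beta2[k], 100L + k))
  })
  xy <- simulate_pair(leg_config(total, 1000L))
  list(xm = xm, my = my, xy = xy,
       truth = list(beta1 = spec$beta1, beta2 = spec$beta2,
                    direct = spec$direct, total = total,
                    indirect = sum(spec$beta1 * spec$beta2),
                    proportion = sum(spec$beta1 * spec$beta2) / total))
}

#' Write a simulated pair as the TSV dialect the readers consume
#'
#' @param sim result of [simulate_pair()].
#' @param dir output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_simulated_pair <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"))
  for (nm in names(paths)) {
    d <- as.data.frame(sim[[nm]])
    names(d) <- c("SNP", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n")
    utils::write.table(d, paths[[nm]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
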