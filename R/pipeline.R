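#' Assemble a study configuration
#'
#' Normalizes a configuration list (or YAML file) for [run_mr_study()].
#' Expected structure (paths are resolved relative to the working
#' directory):
#'
#' ```yaml
#' exposure: {path: exposure.tsv, trait_name: FT4, trait_type: continuous}
#' outcome:  {path: outcome.tsv, trait_name: gallstones, trait_type: binary}
#' mediators:
#'   - {path: ldl.tsv, trait_name: LDL-C, trait_type: continuous}
#' criteria: {p_threshold: 5.0e-8, clump_r2: 0.001, clump_window_kb: 10000,
#'            confounder_traits: [BMI]}
#' ld_path: ld.tsv            # optional
#' annotations_path: ann.tsv  # optional
#' estimators: {effects_model: multiplicative_random, n_boot: 1000}
#' sensitivity: {n_sim: 1000, outlier_alpha: 0.05}
#' seed: 1
#' output_dir: mr_out
#' ```
#'
#' Each table entry accepts an optional `column_map`. Every stochastic
#' component (weighted-median bootstrap, MR-PRESSO) uses the master
#' `seed`, recorded in the manifest.
#'
#' @param config a list with the structure above, or a path to a YAML file.
#' @return A validated `study_config` list.
#' @export
study_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$exposure), !is.null(config$outcome))
  crit <- config$criteria %||% list()
  config$criteria <- instrument_criteria(
    p_threshold = crit$p_threshold %||% 5e-8,
    clump_r2 = crit$clump_r2 %||% 0.001,
    clump_window_kb = crit$clump_window_kb %||% 10000,
    confounder_traits = crit$confounder_traits %||% character())
  config$estimators <- utils::modifyList(
    list(effects_model = "multiplicative_random", n_boot = 1000),
    config$estimators %||% list())
  config$sensitivity <- utils::modifyList(
    list(n_sim = 1000, outlier_alpha = 0.05, n_distortion = 1000),
    config$sensitivity %||% list())
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = "study_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config_table <- function(entry) {
  read_summary_table(entry$path, trait_name = entry$trait_name,
                     trait_type = entry$trait_type %||% "continuous",
                     column_map = unlist(entry$column_map))
}

select_instruments <- function(table, config, ld, annotations) {
  counts <- c(input = nrow(table))
  sig <- select_significant(table, config$criteria$p_threshold)
  counts["not_significant"] <- nrow(table) - nrow(sig)
  cl <- clump(sig, ld, config$criteria)
  counts["clumped_out"] <- nrow(sig) - nrow(cl)
  fin <- filter_confounders(cl, annotations, config$criteria$confounder_traits)
  counts["confounder_removed"] <- nrow(cl) - nrow(fin)
  counts["retained"] <- nrow(fin)
  list(table = fin, counts = counts)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full two-sample MR study
#'
#' Orchestrates the whole flow from one configuration: instrument
#' selection (significance, clumping, confounder filtering) on the
#' exposure, harmonization against the outcome, instrument strength, all
#' five estimators (both IVW variants labeled), the sensitivity suite
#' (Cochran's Q, Egger intercept, leave-one-out, funnel data, MR-PRESSO
#' when four or more instruments remain), and — when mediators are
#' configured — two-step mediation with the mediated proportion. Results
#' are written as TSV/JSON under `output_dir` together with a manifest
#' recording seeds and the SNP counts dropped at each filter; the run is
#' deterministic given the config, so a rerun reproduces the bundle
#' byte for byte.
#'
#' @param config a [study_config()], a plain list, or a YAML path.
#' @return Invisibly, a list with `instruments`, `harmonized`, `strength`,
#'   `estimates`, `sensitivity`, `mediation` (or `NULL`), `manifest`.
#' @export
run_mr_study <- function(config) {
  config <- if (inherits(config, "study_config")) config else study_config(config)
  out_dir <- config$output_dir %||% "mr_output"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  ld <- run_stage("ld", if (!is.null(config$ld_path)) read_ld_matrix(config$ld_path) else NULL)
  annotations <- run_stage("annotations",
    if (!is.null(config$annotations_path)) read_annotations(config$annotations_path) else NULL)

  exposure <- run_stage("read_exposure", read_config_table(config$exposure))
  outcome <- run_stage("read_outcome", read_config_table(config$outcome))

  sel <- run_stage("instrument_selection",
                   select_instruments(exposure, config, ld, annotations))
  if (nrow(sel$table) == 0L) stop("stage 'instrument_selection' failed: no instruments retained")

  h <- run_stage("harmonize", harmonize(sel$table, outcome))
  counts <- sel$counts
  counts["dropped_palindromic"] <- attr(h, "n_dropped_palindromic")
  counts["dropped_incompatible"] <- attr(h, "n_dropped_incompatible")
  counts["missing_in_outcome"] <- counts["retained"] -
    nrow(h) - counts["dropped_palindromic"] - counts["dropped_incompatible"]
  counts["harmonized"] <- nrow(h)

  strength <- run_stage("instrument_strength", tryCatch(
    instrument_strength(sel$table[sel$table$snp_id %in% h$snp_id, ]),
    error = function(e) NULL))

  est_cfg <- config$estimators
  estimates <- run_stage("estimators", {
    rows <- list(as.data.frame(mr_ivw(h, "fixed")),
                 as.data.frame(mr_ivw(h, "multiplicative_random")))
    if (nrow(h) >= 3L) {
      rows <- c(rows, list(
        as.data.frame(mr_weighted_median(h, n_boot = est_cfg$n_boot,
                                         seed = config$seed)),
        as.data.frame(mr_egger(h)),
        as.data.frame(mr_maxlik(h)),
        as.data.frame(mr_raps(h))))
    } else if (nrow(h) >= 2L) {
      rows <- c(rows, list(as.data.frame(mr_maxlik(h))))
    }
    do.call(rbind, rows)
  })
  write_tsv(estimates, file.path(out_dir, "estimates.tsv"))

  sens <- run_stage("sensitivity", {
    s <- list()
    if (nrow(h) >= 2L) s$q <- cochran_q(h)
    if (nrow(h) >= 3L) {
      s$egger_intercept <- egger_intercept_test(h)
      s$loo <- leave_one_out(h, est_cfg$effects_model)
      write_tsv(as.data.frame(s$loo), file.path(out_dir, "leave_one_out.tsv"))
    }
    s$funnel <- funnel_data(h)
    write_tsv(as.data.frame(s$funnel), file.path(out_dir, "funnel.tsv"))
    if (nrow(h) >= 4L) {
      s$presso <- mr_presso(h, n_sim = config$sensitivity$n_sim,
                            seed = config$seed,
                            outlier_alpha = config$sensitivity$outlier_alpha,
                            n_distortion = config$sensitivity$n_distortion)
      presso_row <- data.frame(
        global_rss = s$presso$global_rss, global_pval = s$presso$global_pval,
        n_outliers = length(s$presso$outlier_indices),
        outlier_snps = paste(s$presso$outlier_snps, collapse = ","),
        raw_beta = s$presso$raw_beta, raw_pval = s$presso$raw_pval,
        corrected_beta = s$presso$corrected_beta %||% NA_real_,
        corrected_pval = s$presso$corrected_pval %||% NA_real_,
        distortion_pval = s$presso$distortion_pval %||% NA_real_,
        n_sim = s$presso$n_sim, seed = s$presso$seed)
      write_tsv(presso_row, file.path(out_dir, "presso.tsv"))
    }
    s
  })

  mediation <- NULL
  med_counts <- list()
  if (!is.null(config$mediators) && length(config$mediators)) {
    mediation <- run_stage("mediation", {
      hx_list <- list(); hm_list <- list(); med_names <- character()
      for (m in config$mediators) {
        med_table <- read_config_table(m)
        med_names <- c(med_names, attr(med_table, "trait_name"))
        # leg 1: exposure instruments against the mediator
        hx_list <- c(hx_list, list(harmonize(sel$table, med_table)))
        # leg 2: mediator instruments against the outcome
        med_sel <- select_instruments(med_table, config, ld, annotations)
        med_counts[[attr(med_table, "trait_name")]] <- med_sel$counts
        hm_list <- c(hm_list, list(harmonize(med_sel$table, outcome)))
      }
      two_step_mediation(hx_list, hm_list, h,
                         method = "ivw", mediator_names = med_names,
                         effects_model = est_cfg$effects_model)
    })
    med_df <- data.frame(mediator = mediation$mediators,
                         beta1 = mediation$beta1, beta2 = mediation$beta2,
                         stringsAsFactors = FALSE)
    med_summary <- list(
      mediators = med_df, beta3 = mediation$beta3,
      total_effect = mediation$total_effect,
      indirect_effect = mediation$indirect_effect,
      proportion_percent = round(mediation$percent, 1),
      se_proportion = mediation$se_proportion,
      inconsistent = isTRUE(mediation$inconsistent))
    jsonlite::write_json(med_summary, file.path(out_dir, "mediation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    seed = config$seed,
    criteria = unclass(config$criteria),
    counts = as.list(counts),
    mediator_counts = lapply(med_counts, as.list),
    f_stat = if (!is.null(strength)) strength$f_stat else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(instruments = sel$table, harmonized = h, strength = strength,
                 estimates = estimates, sensitivity = sens,
                 mediation = mediation, manifest = manifest))
}
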