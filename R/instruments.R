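#' Instrument selection criteria
#'
#' Bundles the thresholds used to select independent, genome-wide
#' significant instruments: the significance cutoff, the LD-clumping
#' r-squared threshold and window, and trait names whose associated SNPs
#' are excluded as potential confounders.
#'
#' @param p_threshold significance cutoff; SNPs with `pval < p_threshold`
#'   (strict) are retained. Default `5e-8`, genome-wide significance.
#' @param clump_r2 LD r-squared above which the less significant SNP of a
#'   pair is discarded. Default 0.001.
#' @param clump_window_kb clumping window in kilobases (center-to-center).
#'   Default 10000.
#' @param confounder_traits character vector of trait names; SNPs
#'   annotated to any of them are removed by [filter_confounders()].
#' @return An `instrument_criteria` list.
#' @export
instrument_criteria <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                                clump_window_kb = 10000,
                                confounder_traits = character()) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_window_kb > 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 confounder_traits = as.character(confounder_traits)),
            class = "instrument_criteria")
}

#' Retain genome-wide significant SNPs
#'
#' @param table a [summary_table()].
#' @param p_threshold strict upper bound on the p-value (a SNP with
#'   `pval == p_threshold` is excluded).
#' @return The filtered `summary_table`, row order preserved. May be empty.
#' @export
select_significant <- function(table, p_threshold = 5e-8) {
  stopifnot(is.data.frame(table), p_threshold > 0, p_threshold < 1)
  keep <- table$pval < p_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    message("select_significant: no SNPs below p = ", format(p_threshold))
  }
  out
}

#' LD matrix container
#'
#' A symmetric matrix of squared allelic correlations with unit diagonal,
#' used by [clump()]. SNPs absent from the matrix are treated as unlinked.
#'
#' @param r2 square numeric matrix with row/column names set to SNP ids.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(r2) {
  r2 <- as.matrix(r2)
  stopifnot(nrow(r2) == ncol(r2),
            !is.null(rownames(r2)), identical(rownames(r2), colnames(r2)))
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("r2 diagonal must be 1")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric")
  structure(list(snp_ids = rownames(r2), r2 = r2), class = "ld_matrix")
}

#' Read an LD matrix from a square TSV
#'
#' Expects a header row of SNP ids and a first column of SNP ids.
#'
#' @param path file path.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  ld_matrix(as.matrix(raw))
}

#' Greedy LD clumping
#'
#' Prunes correlated instruments keeping the most significant SNP per
#' region: repeatedly take the remaining SNP with the smallest p-value
#' (ties broken by lexicographic `snp_id`), then discard every remaining
#' SNP on the same chromosome whose r-squared with it exceeds
#' `criteria$clump_r2` and whose position lies within
#' `criteria$clump_window_kb` kilobases (center-to-center). SNP pairs
#' absent from `ld` are treated as unlinked; the result is independent of
#' input row order.
#'
#' @param table a [summary_table()] with `chrom`/`pos` populated for the
#'   window test.
#' @param ld an [ld_matrix()], or `NULL` to treat all SNPs as unlinked.
#' @param criteria an [instrument_criteria()].
#' @return The retained SNPs as a `summary_table`, in selection order
#'   (decreasing significance).
#' @export
clump <- function(table, ld = NULL, criteria = instrument_criteria()) {
  stopifnot(is.data.frame(table))
  if (nrow(table) <= 1L) return(table)
  ids <- table$snp_id
  r2 <- if (is.null(ld)) NULL else ld$r2
  # deterministic processing order: p-value, then lexicographic id
  ord <- order(table$pval, ids)
  remaining <- ord
  picked <- integer(0)
  win_bp <- criteria$clump_window_kb * 1000
  while (length(remaining)) {
    i <- remaining[1]
    picked <- c(picked, i)
    remaining <- remaining[-1]
    if (!length(remaining)) break
    drop <- vapply(remaining, function(j) {
      same_chr <- !is.na(table$chrom[i]) && !is.na(table$chrom[j]) &&
        table$chrom[i] == table$chrom[j]
      if (!same_chr) return(FALSE)
      within <- !is.na(table$pos[i]) && !is.na(table$pos[j]) &&
        abs(table$pos[i] - table$pos[j]) <= win_bp
      if (!within) return(FALSE)
      rij <- 0
      if (!is.null(r2) && ids[i] %in% rownames(r2) && ids[j] %in% rownames(r2)) {
        rij <- r2[ids[i], ids[j]]
      }
      rij > criteria$clump_r2
    }, logical(1))
    remaining <- remaining[!drop]
  }
  out <- table[picked, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove SNPs associated with confounding traits
#'
#' Drops instruments annotated to any trait in `confounder_traits` (for
#' example secondary-phenotype lookups flagging adiposity or glycemic
#' associations when gallstone disease is the outcome). Annotations come
#' from a user-supplied table rather than a live phenotype-database query.
#'
#' @param table a [summary_table()].
#' @param annotations data frame with columns `snp_id` and `trait` (zero
#'   or more rows per SNP).
#' @param confounder_traits trait names to exclude on (case-insensitive).
#' @return The filtered `summary_table`.
#' @export
filter_confounders <- function(table, annotations, confounder_traits) {
  stopifnot(is.data.frame(table))
  if (length(confounder_traits) == 0L || is.null(annotations) ||
      nrow(annotations) == 0L) {
    return(table)
  }
  stopifnot(all(c("snp_id", "trait") %in% names(annotations)))
  bad_ids <- unique(annotations$snp_id[
    tolower(annotations$trait) %in% tolower(confounder_traits)])
  keep <- !table$snp_id %in% bad_ids
  if (any(!keep)) {
    message("filter_confounders: removed ", sum(!keep),
            " SNP(s) annotated to confounder traits")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a SNP-to-trait annotation table
#'
#' Two-column TSV (`snp_id`, `trait`) mapping instruments to secondary
#' phenotypes, used by [filter_confounders()].
#'
#' @param path file path.
#' @return Data frame with columns `snp_id`, `trait`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "trait") %in% names(ann)))
  ann
}

#' Per-SNP variance explained from a t-statistic
#'
#' Partial r-squared of one instrument for its trait, computed from the
#' marginal association alone: with `t = beta / se`, returns
#' `t^2 / (t^2 + n - 2)`. Works without allele frequencies or trait
#' variance.
#'
#' @param beta,se per-allele effect and its standard error (vectorized).
#' @param n GWAS sample size, must exceed 2.
#' @return Variance-explained fraction(s) in \[0, 1).
#' @export
per_snp_r2 <- function(beta, se, n) {
  if (any(n <= 2)) stop("per_snp_r2 requires n > 2")
  if (any(se <= 0)) stop("per_snp_r2 requires se > 0")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Per-SNP variance explained from allele frequency
#'
#' Alternative to [per_snp_r2()] when the effect-allele frequency is known
#' and the trait is standardized (unit variance): `2 p (1 - p) beta^2`.
#'
#' @param beta per-allele effect on the standardized trait.
#' @param eaf effect-allele frequency in (0, 1).
#' @return Variance-explained fraction(s).
#' @export
per_snp_r2_af <- function(beta, eaf) {
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must lie in (0, 1)")
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' `F = R2 * (N - 1 - K) / ((1 - R2) * K)` where `R2` is the total
#' variance in the exposure explained by the `K` instruments and `N` is
#' the exposure GWAS sample size. `F >= 10` is the conventional bound
#' below which weak-instrument bias becomes a concern.
#'
#' @param r2_total aggregate variance explained, in \[0, 1).
#' @param n exposure sample size.
#' @param k number of instruments.
#' @return The F statistic.
#' @export
f_statistic <- function(r2_total, n, k) {
  if (any(r2_total < 0 | r2_total >= 1)) stop("r2_total must lie in [0, 1)")
  if (any(n <= k + 1) || any(k < 1)) stop("require n > k + 1 and k >= 1")
  r2_total * (n - 1 - k) / ((1 - r2_total) * k)
}

#' Summarize instrument strength
#'
#' Computes per-SNP variance explained (t-statistic formula), their total,
#' and the aggregate F statistic for a set of exposure instruments.
#'
#' @param table a [summary_table()] of selected instruments.
#' @param n exposure GWAS sample size; taken from the table's `n` column
#'   (median) when omitted.
#' @return List with `r2_total`, `n`, `k`, `f_stat`, `per_snp_r2`,
#'   `per_snp_f` (class `instrument_strength`).
#' @export
instrument_strength <- function(table, n = NULL) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  if (is.null(n)) {
    n <- stats::median(table$n, na.rm = TRUE)
    if (is.na(n)) stop("sample size unavailable: supply n")
  }
  r2 <- per_snp_r2(table$beta, table$se, n)
  k <- nrow(table)
  r2_tot <- sum(r2)
  structure(list(r2_total = r2_tot, n = n, k = k,
                 f_stat = f_statistic(r2_tot, n, k),
                 per_snp_r2 = stats::setNames(r2, table$snp_id),
                 per_snp_f = stats::setNames(
                   f_statistic(r2, n, 1L), table$snp_id)),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: K = %d, N = %s, R2 = %.4g, F = %.3f\n",
              x$k, format(x$n, big.mark = ","), x$r2_total, x$f_stat))
  cat(sprintf("per-SNP F range: %.3f - %.3f\n",
              min(x$per_snp_f), max(x$per_snp_f)))
  invisible(x)
}
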