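DEFAULT_COLUMN_MAP <- c(
  snp_id = "SNP", chrom = "chr", pos = "pos",
  effect_allele = "effect_allele", other_allele = "other_allele",
  eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n"
)

REQUIRED_FIELDS <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
OPTIONAL_FIELDS <- c("chrom", "pos", "eaf", "n")

#' Construct a GWAS summary-statistic table
#'
#' A `summary_table` is a data frame with one row per SNP carrying the
#' per-variant association statistics for a single trait: identifier,
#' genomic location, effect/other alleles, effect-allele frequency, effect
#' size (log-odds for binary traits, SD or native units for continuous
#' traits), its standard error, p-value and sample size.
#'
#' Rows violating the record invariants (identical alleles, non-ACGT
#' alleles, `se <= 0`, `pval` outside (0, 1], `eaf` outside \[0, 1\],
#' `pos < 1`) are dropped with a message; the number dropped is stored in
#' `attr(x, "n_dropped_invalid")`. Alleles are upper-cased. SNP identifiers
#' must be unique after filtering.
#'
#' @param data data frame with (at least) columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`; optionally
#'   `chrom`, `pos`, `eaf`, `n`.
#' @param trait_name label for the trait.
#' @param trait_type `"continuous"` or `"binary"` (binary effects are
#'   interpreted as log odds ratios downstream).
#' @return A `summary_table` (data frame subclass) with attributes
#'   `trait_name`, `trait_type`, `n_dropped_invalid`.
#' @seealso [read_summary_table()] to build one from a TSV file.
#' @export
summary_table <- function(data, trait_name, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(REQUIRED_FIELDS, names(data))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (f in OPTIONAL_FIELDS) {
    if (!f %in% names(data)) data[[f]] <- NA
  }
  data <- data[c(REQUIRED_FIELDS[1], "chrom", "pos",
                 "effect_allele", "other_allele", "eaf",
                 "beta", "se", "pval", "n")]
  data$snp_id <- as.character(data$snp_id)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (f in c("pos", "eaf", "beta", "se", "pval", "n")) {
    data[[f]] <- suppressWarnings(as.numeric(data[[f]]))
  }

  ok <- !is.na(data$snp_id) &
    data$effect_allele %in% c("A", "C", "G", "T") &
    data$other_allele %in% c("A", "C", "G", "T") &
    data$effect_allele != data$other_allele &
    !is.na(data$beta) & is.finite(data$beta) &
    !is.na(data$se) & data$se > 0 &
    !is.na(data$pval) & data$pval > 0 & data$pval <= 1 &
    (is.na(data$eaf) | (data$eaf >= 0 & data$eaf <= 1)) &
    (is.na(data$pos) | data$pos >= 1) &
    (is.na(data$n) | data$n > 0)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(trait_name, ": dropped ", n_dropped, " row(s) failing record validation")
  }
  data <- data[ok, , drop = FALSE]
  if (nrow(data) == 0L) stop("no valid summary records for trait '", trait_name, "'")
  if (anyDuplicated(data$snp_id)) {
    stop("duplicate snp_id values in summary table for trait '", trait_name, "'")
  }
  rownames(data) <- NULL
  structure(data,
            trait_name = trait_name, trait_type = trait_type,
            n_dropped_invalid = n_dropped,
            class = c("summary_table", "data.frame"))
}

#' Read a GWAS summary-statistic TSV
#'
#' Reads a tab-separated file with a header row and maps its columns onto
#' the standard fields via `column_map` (a named character vector,
#' `standard_field = "file column"`). Unmapped standard fields fall back to
#' the default column names `SNP, chr, pos, effect_allele, other_allele,
#' eaf, beta, se, pval, n`.
#'
#' @param path path to a tab-separated file with header.
#' @param trait_name trait label stored on the result.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param column_map named character vector overriding the default
#'   field-to-column mapping, e.g. `c(snp_id = "rsid", pval = "p")`.
#' @inherit summary_table return
#' @export
read_summary_table <- function(path, trait_name,
                               trait_type = c("continuous", "binary"),
                               column_map = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  map <- DEFAULT_COLUMN_MAP
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad)) stop("unknown field(s) in column_map: ", paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_req <- REQUIRED_FIELDS[!map[REQUIRED_FIELDS] %in% names(raw)]
  if (length(missing_req)) {
    stop("column(s) ", paste(map[missing_req], collapse = ", "),
         " not found in ", path)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in names(map)) {
    if (map[[f]] %in% names(raw)) out[[f]] <- raw[[map[[f]]]]
  }
  summary_table(out, trait_name = trait_name, trait_type = trait_type)
}

#' @export
print.summary_table <- function(x, ...) {
  cat("GWAS summary table: ", attr(x, "trait_name"),
      " (", attr(x, "trait_type"), "), ", nrow(x), " SNPs\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP has alleles that are reverse
#' complements of each other, i.e. the pair is \{A,T\} or \{C,G\}; the
#' reported strand cannot be resolved from the alleles alone.
#'
#' @param effect_allele,other_allele single-character allele vectors, each
#'   element one of A, C, G, T (case-insensitive).
#' @return Logical vector.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a1 <- toupper(effect_allele)
  a2 <- toupper(other_allele)
  if (!all(a1 %in% c("A", "C", "G", "T")) || !all(a2 %in% c("A", "C", "G", "T"))) {
    stop("alleles must be one of A, C, G, T")
  }
  a2 == complement_allele(a1)
}

complement_allele <- function(a) chartr("ACGT", "TGCA", a)

#' Construct a harmonized exposure-outcome instrument set
#'
#' Container for exposure and outcome effects expressed on a common effect
#' allele, the input to every MR estimator. Usually produced by
#' [harmonize()]; this constructor is useful for simulated or externally
#' harmonized data.
#'
#' @param snp_id variant identifiers.
#' @param beta_x,se_x exposure effects and standard errors.
#' @param beta_y,se_y outcome effects and standard errors.
#' @param eaf_x,eaf_y optional effect-allele frequencies.
#' @param n_dropped_palindromic,n_dropped_incompatible audit counts carried
#'   as attributes.
#' @return A `harmonized_set` (data frame subclass).
#' @export
harmonized_set <- function(snp_id, beta_x, se_x, beta_y, se_y,
                           eaf_x = NA_real_, eaf_y = NA_real_,
                           n_dropped_palindromic = 0L,
                           n_dropped_incompatible = 0L) {
  d <- data.frame(snp_id = as.character(snp_id),
                  beta_x = as.numeric(beta_x), se_x = as.numeric(se_x),
                  beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
                  eaf_x = as.numeric(eaf_x), eaf_y = as.numeric(eaf_y),
                  stringsAsFactors = FALSE)
  if (nrow(d) < 1L) stop("harmonized set must contain at least one SNP")
  if (any(d$se_x <= 0) || any(d$se_y <= 0)) stop("all standard errors must be > 0")
  structure(d,
            n_dropped_palindromic = as.integer(n_dropped_palindromic),
            n_dropped_incompatible = as.integer(n_dropped_incompatible),
            class = c("harmonized_set", "data.frame"))
}

as_harmonized_set <- function(h) {
  if (inherits(h, "harmonized_set")) return(h)
  stopifnot(is.data.frame(h),
            all(c("snp_id", "beta_x", "se_x", "beta_y", "se_y") %in% names(h)))
  harmonized_set(h$snp_id, h$beta_x, h$se_x, h$beta_y, h$se_y,
                 if ("eaf_x" %in% names(h)) h$eaf_x else NA_real_,
                 if ("eaf_y" %in% names(h)) h$eaf_y else NA_real_)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instrument set: ", nrow(x), " SNPs",
      " (dropped: ", attr(x, "n_dropped_palindromic"), " palindromic, ",
      attr(x, "n_dropped_incompatible"), " incompatible)\n", sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations onto the exposure's effect alleles for
#' every SNP shared between the two tables. For each shared SNP:
#' if the outcome alleles match the exposure alleles as reported, the pair
#' is kept as-is; if they match with effect and other allele swapped, the
#' outcome beta sign is flipped (and `eaf_y` becomes `1 - eaf_y`); if they
#' match only after strand complementation, complementation is applied
#' first and the same rules follow. Palindromic (A/T, C/G) SNPs cannot be
#' strand-resolved from alleles and are handled by `palindrome_policy`;
#' SNPs whose alleles cannot be reconciled at all are dropped and counted.
#'
#' @param exposure,outcome `summary_table` objects sharing at least one
#'   `snp_id`.
#' @param palindrome_policy `"drop"` (default) removes every palindromic
#'   SNP; `"infer_by_frequency"` keeps palindromic SNPs whose effect-allele
#'   frequency on both sides is outside `freq_window` and aligns them by
#'   minor allele; `"keep"` trusts the reported strands.
#' @param freq_window ambiguity band for frequency inference; palindromic
#'   SNPs with either frequency inside it (or missing) are dropped.
#' @return A [harmonized_set()] with drop counts in its attributes.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop", "infer_by_frequency", "keep"),
                      freq_window = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "summary_table") || is.data.frame(exposure),
            inherits(outcome, "summary_table") || is.data.frame(outcome))
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0L) stop("no shared SNPs between exposure and outcome")
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  n_pal <- 0L
  n_inc <- 0L
  keep <- logical(length(shared))
  beta_y <- ou$beta
  eaf_y <- if ("eaf" %in% names(ou)) ou$eaf else rep(NA_real_, nrow(ou))
  eaf_x <- if ("eaf" %in% names(ex)) ex$eaf else rep(NA_real_, nrow(ex))

  for (i in seq_along(shared)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    pal <- is_palindromic(e1, e2)
    if (pal) {
      if (!(identical(sort(c(o1, o2)), sort(c(e1, e2))))) {
        n_inc <- n_inc + 1L
        next
      }
      if (palindrome_policy == "drop") {
        n_pal <- n_pal + 1L
        next
      }
      if (palindrome_policy == "infer_by_frequency") {
        fx <- eaf_x[i]; fy <- if (o1 == e1) eaf_y[i] else 1 - eaf_y[i]
        ambiguous <- is.na(fx) || is.na(fy) ||
          (fx >= freq_window[1] && fx <= freq_window[2]) ||
          (fy >= freq_window[1] && fy <= freq_window[2])
        if (ambiguous) {
          n_pal <- n_pal + 1L
          next
        }
        # align by minor allele: if the frequency comparison disagrees the
        # outcome's reported effect allele is on the opposite strand sense
        same_as_reported <- (fx < 0.5) == (fy < 0.5)
        if (o1 == e1) {
          if (!same_as_reported) {
            beta_y[i] <- -beta_y[i]
            eaf_y[i] <- 1 - eaf_y[i]
          }
        } else {
          # reported swapped: start from the flipped orientation
          if (same_as_reported) {
            beta_y[i] <- -beta_y[i]
            eaf_y[i] <- 1 - eaf_y[i]
          }
        }
        keep[i] <- TRUE
        next
      }
      # policy "keep": fall through to plain allele matching
    }
    if (o1 == e1 && o2 == e2) {
      keep[i] <- TRUE
    } else if (o1 == e2 && o2 == e1) {
      beta_y[i] <- -beta_y[i]
      eaf_y[i] <- 1 - eaf_y[i]
      keep[i] <- TRUE
    } else {
      c1 <- complement_allele(o1); c2 <- complement_allele(o2)
      if (c1 == e1 && c2 == e2) {
        keep[i] <- TRUE
      } else if (c1 == e2 && c2 == e1) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
        keep[i] <- TRUE
      } else {
        n_inc <- n_inc + 1L
      }
    }
  }

  if (!any(keep)) stop("no SNPs survive harmonization")
  harmonized_set(shared[keep],
                 ex$beta[keep], ex$se[keep],
                 beta_y[keep], ou$se[keep],
                 eaf_x[keep], eaf_y[keep],
                 n_dropped_palindromic = n_pal,
                 n_dropped_incompatible = n_inc)
}

#' Write a harmonized set as TSV for audit
#'
#' @param h a [harmonized_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized_set <- function(h, path) {
  h <- as_harmonized_set(h)
  utils::write.table(as.data.frame(h), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
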