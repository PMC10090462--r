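make_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

base_rows <- function() {
  data.frame(SNP = c("rs1", "rs2", "rs3"), chr = 1, pos = c(100, 200, 300),
             effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
             eaf = c(0.2, 0.3, 0.4), beta = c(0.1, -0.2, 0.05),
             se = c(0.01, 0.02, 0.01), pval = c(1e-9, 1e-12, 1e-8), n = 10000,
             stringsAsFactors = FALSE)
}

test_that("reading a well-formed TSV passes rows through and normalizes alleles", {
  tab <- read_summary_table(make_tsv(base_rows()), "trait", "continuous")
  expect_s3_class(tab, "summary_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "n_dropped_invalid"), 0L)

  lower <- base_rows()
  lower$effect_allele[1] <- "a"; lower$other_allele[1] <- "t"
  tab2 <- read_summary_table(make_tsv(lower), "trait", "continuous")
  expect_equal(tab2$effect_allele[1], "A")
  expect_equal(tab2$other_allele[1], "T")
  expect_equal(nrow(tab2), 3L)
})

test_that("invalid rows are dropped with a count; empty and misconfigured input error", {
  bad <- base_rows()
  bad$se[2] <- 0
  expect_message(tab <- read_summary_table(make_tsv(bad), "trait", "continuous"),
                 "dropped 1")
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "n_dropped_invalid"), 1L)

  all_bad <- base_rows()
  all_bad$se <- 0
  expect_error(suppressMessages(
    read_summary_table(make_tsv(all_bad), "trait", "continuous")), "no valid")

  nocol <- base_rows()
  nocol$se <- NULL
  expect_error(read_summary_table(make_tsv(nocol), "trait", "continuous"),
               "not found")
})

test_that("custom column maps are honored", {
  renamed <- base_rows()
  names(renamed)[names(renamed) == "SNP"] <- "rsid"
  names(renamed)[names(renamed) == "pval"] <- "p"
  tab <- read_summary_table(make_tsv(renamed), "trait", "continuous",
                            column_map = c(snp_id = "rsid", pval = "p"))
  expect_equal(tab$snp_id, c("rs1", "rs2", "rs3"))
})

test_that("palindrome detection follows the A/T, C/G definition", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_equal(is_palindromic(c("a", "c"), c("t", "a")), c(TRUE, FALSE))
  expect_error(is_palindromic("A", "N"), "alleles")
})

two_tables <- function(out_ea = "A", out_oa = "G", out_beta = 0.05,
                       exp_ea = "A", exp_oa = "G") {
  ex <- summary_table(data.frame(
    snp_id = "rs1", effect_allele = exp_ea, other_allele = exp_oa,
    eaf = 0.3, beta = 0.1, se = 0.01, pval = 1e-9), "x", "continuous")
  ou <- summary_table(data.frame(
    snp_id = "rs1", effect_allele = out_ea, other_allele = out_oa,
    eaf = 0.3, beta = out_beta, se = 0.02, pval = 1e-4), "y", "continuous")
  list(ex = ex, ou = ou)
}

test_that("harmonization aligns, flips, complements and drops as specified", {
  # identity alignment
  t1 <- two_tables("A", "G")
  h1 <- harmonize(t1$ex, t1$ou)
  expect_equal(h1$beta_y, 0.05)
  # swapped alleles flip the outcome sign
  t2 <- two_tables("G", "A")
  h2 <- harmonize(t2$ex, t2$ou)
  expect_equal(h2$beta_y, -0.05)
  expect_equal(h2$eaf_y, 0.7)
  # strand complement resolves before declaring incompatibility
  t3 <- two_tables("T", "C")  # complement of A/G
  h3 <- harmonize(t3$ex, t3$ou)
  expect_equal(h3$beta_y, 0.05)
  # complement + swap flips
  t4 <- two_tables("C", "T")
  h4 <- harmonize(t4$ex, t4$ou)
  expect_equal(h4$beta_y, -0.05)
  # irreconcilable alleles drop with a count (needs a surviving SNP too)
  ex <- summary_table(data.frame(
    snp_id = c("rs1", "rs2"), effect_allele = c("A", "A"),
    other_allele = c("G", "G"), beta = 0.1, se = 0.01, pval = 1e-9),
    "x", "continuous")
  ou <- summary_table(data.frame(
    snp_id = c("rs1", "rs2"), effect_allele = c("A", "A"),
    other_allele = c("G", "C"), beta = 0.05, se = 0.02, pval = 1e-4),
    "y", "continuous")
  h5 <- harmonize(ex, ou)
  expect_equal(nrow(h5), 1L)
  expect_equal(attr(h5, "n_dropped_incompatible"), 1L)
})

test_that("palindromic SNPs are dropped by default and kept only under confident frequency inference", {
  pal <- two_tables("A", "T", exp_ea = "A", exp_oa = "T")
  expect_error(harmonize(pal$ex, pal$ou), "no SNPs survive")

  ex <- summary_table(data.frame(
    snp_id = c("rs1", "rs2"), effect_allele = c("A", "A"),
    other_allele = c("T", "G"), eaf = c(0.1, 0.3),
    beta = 0.1, se = 0.01, pval = 1e-9), "x", "continuous")
  ou <- summary_table(data.frame(
    snp_id = c("rs1", "rs2"), effect_allele = c("A", "A"),
    other_allele = c("T", "G"), eaf = c(0.1, 0.3),
    beta = 0.05, se = 0.02, pval = 1e-4), "y", "continuous")
  h <- harmonize(ex, ou)
  expect_equal(h$snp_id, "rs2")
  expect_equal(attr(h, "n_dropped_palindromic"), 1L)

  # frequency inference keeps a clearly-minor palindromic SNP, as-is when
  # the minor allele agrees
  h2 <- harmonize(ex, ou, palindrome_policy = "infer_by_frequency")
  expect_equal(nrow(h2), 2L)
  expect_equal(h2$beta_y[h2$snp_id == "rs1"], 0.05)

  # disagreeing minor allele flips the outcome
  ou_flip <- summary_table(data.frame(
    snp_id = c("rs1", "rs2"), effect_allele = c("A", "A"),
    other_allele = c("T", "G"), eaf = c(0.9, 0.3),
    beta = 0.05, se = 0.02, pval = 1e-4), "y", "continuous")
  h3 <- harmonize(ex, ou_flip, palindrome_policy = "infer_by_frequency")
  expect_equal(h3$beta_y[h3$snp_id == "rs1"], -0.05)

  # ambiguous frequency is dropped even under inference
  ex_mid <- ex; ex_mid$eaf[1] <- 0.5
  h4 <- harmonize(ex_mid, ou, palindrome_policy = "infer_by_frequency")
  expect_equal(h4$snp_id, "rs2")
})

test_that("harmonization is idempotent and sign-flip consistent, and counts reconcile", {
  sim <- simulate_pair(sim_config(n_snp = 30, seed = 4, frac_palindromic = 0.2))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_equal(nrow(h) + attr(h, "n_dropped_palindromic") +
                 attr(h, "n_dropped_incompatible"),
               length(intersect(sim$exposure$snp_id, sim$outcome$snp_id)))

  # idempotence: re-harmonizing tables already on one frame changes nothing
  keep <- sim$outcome$snp_id %in% h$snp_id
  h2 <- harmonize(sim$exposure[sim$exposure$snp_id %in% h$snp_id, ],
                  sim$outcome[keep, ])
  expect_equal(h2$beta_y, h$beta_y)
  expect_equal(h2$beta_x, h$beta_x)

  # flipping the outcome's recorded alleles and negating beta is a no-op
  flipped <- sim$outcome
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h3 <- harmonize(sim$exposure, flipped)
  expect_equal(h3$snp_id, h$snp_id)
  expect_equal(h3$beta_y, h$beta_y)
})

test_that("harmonized sets round-trip through the audit TSV", {
  h <- make_test_set(J = 5)
  path <- tempfile(fileext = ".tsv")
  write_harmonized_set(h, path)
  back <- read.delim(path)
  expect_equal(back$beta_x, h$beta_x)
  expect_equal(back$beta_y, h$beta_y)
})
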