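test_that("a well-formed table round-trips exactly through read", {
  df <- data.frame(
    snp_id = c("rs1", "rs2", "rs3"), chrom = c("1", "2", "10"),
    pos = c(1000000, 2000000, 3000000),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    eaf = c(0.2, 0.5, 0.81), beta = c(0.01, -0.02, 0.0000312),
    se = c(0.005, 0.004, 0.01), pvalue = c(0.045, 6e-7, 0.9),
    n = c(10000, 10000, 12000), stringsAsFactors = FALSE
  )
  path <- write_summary_tsv(df, tempfile(fileext = ".tsv"))
  tab <- suppressWarnings(read_summary_table(path, trait_name = "demo"))
  expect_s3_class(tab, "trait_table")
  expect_equal(nrow(tab), 3)
  expect_identical(tab$snp_id, df$snp_id)
  expect_equal(tab$beta, df$beta)
  expect_equal(tab$se, df$se)
  expect_equal(tab$eaf, df$eaf)
  expect_equal(attr(tab, "trait_name"), "demo")
})

test_that("rows with unparseable se are dropped with a logged count", {
  df <- data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"), other_allele = c("G", "T", "A"),
    beta = c(0.01, -0.02, 0.03), se = c("0.005", "NA", "0.01"),
    stringsAsFactors = FALSE
  )
  path <- write_summary_tsv(df, tempfile(fileext = ".tsv"))
  expect_message(tab <- read_summary_table(path, trait_name = "demo"),
                 "dropped")
  expect_equal(nrow(tab), 2)
  expect_identical(tab$snp_id, c("rs1", "rs3"))
})

test_that("lower-case alleles are upper-cased on read", {
  df <- data.frame(
    snp_id = c("rs1", "rs2"),
    effect_allele = c("a", "c"), other_allele = c("t", "g"),
    beta = c(0.1, 0.2), se = c(0.01, 0.01), stringsAsFactors = FALSE
  )
  path <- write_summary_tsv(df, tempfile(fileext = ".tsv"))
  tab <- read_summary_table(path, trait_name = "demo")
  expect_identical(tab$effect_allele, c("A", "C"))
  expect_identical(tab$other_allele, c("T", "G"))
})

test_that("indel allele codes are rejected rows, SNVs kept", {
  df <- data.frame(
    snp_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "D", "AT"), other_allele = c("G", "I", "A"),
    beta = c(0.1, 0.2, 0.3), se = c(0.01, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
  path <- write_summary_tsv(df, tempfile(fileext = ".tsv"))
  expect_message(tab <- read_summary_table(path, trait_name = "demo"),
                 "alleles")
  expect_identical(tab$snp_id, "rs1")
})

test_that("missing mandatory columns and empty files are hard errors", {
  df <- data.frame(snp_id = "rs1", effect_allele = "A",
                   beta = 0.1, se = 0.01, stringsAsFactors = FALSE)
  path <- write_summary_tsv(df, tempfile(fileext = ".tsv"))
  expect_error(read_summary_table(path, trait_name = "x"), "other_allele")

  empty <- tempfile(fileext = ".tsv")
  writeLines("snp_id\teffect_allele\tother_allele\tbeta\tse", empty)
  expect_error(read_summary_table(empty, trait_name = "x"), "empty")
})

test_that("column_map remaps source column names and csv is autodetected", {
  df <- data.frame(
    rsid = c("rs1", "rs2"), A1 = c("A", "C"), A2 = c("G", "T"),
    b = c(0.1, -0.2), stderr = c(0.01, 0.02), p = c(0.001, 0.5),
    stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  tab <- suppressWarnings(read_summary_table(path, column_map = c(
    snp_id = "rsid", effect_allele = "A1", other_allele = "A2",
    beta = "b", se = "stderr", pvalue = "p"), trait_name = "demo"))
  expect_equal(tab$beta, c(0.1, -0.2))
  expect_equal(tab$pvalue, c(0.001, 0.5))
})

test_that("an inconsistent p-value triggers a validation warning, not an error", {
  df <- data.frame(
    snp_id = c("rs1", "rs2"),
    effect_allele = c("A", "C"), other_allele = c("G", "T"),
    beta = c(0.1, 0.1), se = c(0.01, 0.01),
    pvalue = c(2 * pnorm(-10), 0.5), # rs2 wildly inconsistent with z = 10
    stringsAsFactors = FALSE
  )
  path <- write_summary_tsv(df, tempfile(fileext = ".tsv"))
  expect_warning(tab <- read_summary_table(path, trait_name = "demo"),
                 "inconsistent")
  expect_equal(nrow(tab), 2)
})

test_that("write_results emits TSVs plus a manifest and round-trips values", {
  out <- file.path(tempdir(), "res_roundtrip")
  est <- data.frame(method = c("ivw", "egger"), beta = c(0.123456789012345, -2e-6),
                    se = c(0.01, 0.5), stringsAsFactors = FALSE)
  man <- write_results(list(estimates = est), out, config = list(a = 1))
  expect_equal(man$files$row_count, 2)
  expect_true(file.exists(file.path(out, "estimates.tsv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  back <- read.delim(file.path(out, "estimates.tsv"))
  expect_equal(back$beta, est$beta)
  expect_equal(back$se, est$se)

  # empty table set: manifest with empty file list, no crash
  man2 <- write_results(list(), file.path(tempdir(), "res_empty"))
  expect_equal(man2$n_tables, 0)
  expect_equal(nrow(man2$files), 0)
})

test_that("trait tables survive a full write/read round trip", {
  tab <- make_trait(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                    beta = c(0.123456789, -3.2e-7), se = c(0.01, 0.02),
                    eaf = c(0.25, 0.5), pvalue = c(1e-9, 0.2))
  out <- file.path(tempdir(), "res_trait")
  write_results(list(trait = as.data.frame(tab)), out)
  back <- suppressWarnings(read_summary_table(file.path(out, "trait.tsv"),
                                              trait_name = "trait"))
  expect_equal(back$beta, tab$beta)
  expect_equal(back$se, tab$se)
  expect_equal(back$pvalue, tab$pvalue)
  expect_identical(back$snp_id, tab$snp_id)
})
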