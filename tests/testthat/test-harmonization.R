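test_that("select_instruments applies a strict p-value cut in order", {
  tab <- make_trait(c("rs1", "rs2", "rs3"), rep("A", 3), rep("G", 3),
                    beta = c(0.1, 0.1, 0.1), se = rep(0.01, 3),
                    pvalue = c(1e-9, 1e-7, 1e-5))
  expect_identical(select_instruments(tab, 5e-8)$snp_id, "rs1")
  expect_identical(select_instruments(tab, 5e-6)$snp_id, c("rs1", "rs2"))
  expect_warning(empty <- select_instruments(tab, 1e-12), "no variants")
  expect_equal(nrow(empty), 0)
})

test_that("selection is monotone in the threshold and matches a brute-force scan", {
  set.seed(101)
  n <- 100
  tab <- make_trait(sprintf("rs%03d", 1:n), rep("A", n), rep("G", n),
                    beta = rnorm(n), se = runif(n, 0.01, 0.1),
                    pvalue = runif(n))
  for (thr in c(0.01, 0.2, 0.5)) {
    got <- select_instruments(tab, thr)$snp_id
    expect_identical(got, tab$snp_id[tab$pvalue < thr])
  }
  s1 <- select_instruments(tab, 0.1)$snp_id
  s2 <- select_instruments(tab, 0.4)$snp_id
  expect_true(all(s1 %in% s2))
})

test_that("distance clumping keeps the lowest-p index and drops in-window rivals", {
  tab <- make_trait(c("a", "b"), c("A", "A"), c("G", "G"),
                    beta = c(0.1, 0.1), se = c(0.01, 0.01),
                    pvalue = c(1e-10, 1e-9), chrom = "1",
                    pos = c(1000000, 2000000))
  out <- clump(tab, window_kb = 10000)
  expect_identical(out$snp_id, "a")

  # different chromosomes are never clumped together
  tab2 <- make_trait(c("a", "b"), c("A", "A"), c("G", "G"),
                     beta = c(0.1, 0.1), se = c(0.01, 0.01),
                     pvalue = c(1e-10, 1e-9), chrom = c("1", "2"),
                     pos = c(1000000, 1000000))
  expect_equal(nrow(clump(tab2)), 2)

  # single variant clumps to itself
  expect_equal(nrow(clump(tab[1, ])), 1)
})

test_that("an ld table makes within-window independent pairs survive", {
  tab <- make_trait(c("a", "b", "c"), rep("A", 3), rep("G", 3),
                    beta = rep(0.1, 3), se = rep(0.01, 3),
                    pvalue = c(1e-10, 1e-9, 1e-8), chrom = "1",
                    pos = c(1e6, 2e6, 3e6))
  ld <- data.frame(snp_a = "a", snp_b = "b", r2 = 0.9)
  out <- clump(tab, ld_table = ld)
  # b is correlated with index a and removed; c is absent from the table
  # hence treated as independent
  expect_identical(out$snp_id, c("a", "c"))
})

test_that("clump output is a subset with every removed variant near a retained index", {
  set.seed(77)
  n <- 60
  tab <- make_trait(sprintf("rs%03d", 1:n), rep("A", n), rep("G", n),
                    beta = rnorm(n), se = runif(n, 0.005, 0.02),
                    pvalue = runif(n)^4,
                    chrom = as.character(sample(1:4, n, replace = TRUE)),
                    pos = sample(1:2000, n) * 1e4)
  kept <- clump(tab, window_kb = 5000)
  expect_true(all(kept$snp_id %in% tab$snp_id))
  removed <- tab[!tab$snp_id %in% kept$snp_id, ]
  for (i in seq_len(nrow(removed))) {
    near <- kept$chrom == removed$chrom[i] &
      abs(kept$pos - removed$pos[i]) <= 5000 * 1000
    expect_true(any(near))
  }
})

test_that("harmonize flips swapped alleles and reflects the frequency", {
  exp <- make_trait("rs1", "A", "G", beta = 0.10, se = 0.01, eaf = 0.3)
  out <- make_trait("rs1", "G", "A", beta = -0.05, se = 0.02, eaf = 0.7,
                    trait_name = "Y")
  h <- harmonize(exp, out)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$eaf_outcome, 0.3)
  expect_identical(h$action, "flipped")
})

test_that("opposite-strand reports are complemented before alignment", {
  exp <- make_trait("rs1", "A", "G", beta = 0.10, se = 0.01, eaf = 0.3)
  same <- make_trait("rs1", "T", "C", beta = 0.04, se = 0.02, eaf = 0.3,
                     trait_name = "Y")
  h <- harmonize(exp, same)
  expect_equal(h$beta_outcome, 0.04)
  expect_identical(h$action, "kept")

  swapped <- make_trait("rs1", "C", "T", beta = 0.04, se = 0.02, eaf = 0.7,
                        trait_name = "Y")
  h2 <- harmonize(exp, swapped)
  expect_equal(h2$beta_outcome, -0.04)
  expect_equal(h2$eaf_outcome, 0.3)
})

test_that("palindromic variants follow the policy", {
  exp <- make_trait("rs1", "A", "T", beta = 0.10, se = 0.01, eaf = 0.30)
  out <- make_trait("rs1", "A", "T", beta = 0.06, se = 0.02, eaf = 0.72,
                    trait_name = "Y")
  # drop policy always excludes
  expect_warning(h <- harmonize(exp, out, palindrome_policy = "drop"),
                 "dropped")
  expect_equal(nrow(h), 0)
  expect_identical(attr(h, "dropped")$action, "dropped_palindromic")

  # frequency inference: minor alleles disagree -> strand flip, sign flips
  h2 <- harmonize(exp, out, palindrome_policy = "infer_by_frequency",
                  palindrome_eaf_window = 0.08)
  expect_equal(h2$beta_outcome, -0.06)
  expect_equal(h2$eaf_outcome, 0.28)
  expect_identical(h2$action, "flipped")

  # ambiguous frequency near 0.5 is dropped even under inference
  amb <- make_trait("rs1", "A", "T", beta = 0.06, se = 0.02, eaf = 0.52,
                    trait_name = "Y")
  expect_warning(h3 <- harmonize(exp, amb), "dropped")
  expect_equal(nrow(h3), 0)
})

test_that("incompatible allele pairs are dropped and disjoint tables error", {
  exp <- make_trait(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                    beta = c(0.1, 0.1), se = c(0.01, 0.01), eaf = 0.3)
  out <- make_trait(c("rs1", "rs2"), c("A", "A"), c("C", "G"),
                    beta = c(0.05, 0.05), se = c(0.02, 0.02), eaf = 0.3,
                    trait_name = "Y")
  h <- harmonize(exp, out)
  expect_identical(h$snp_id, "rs2")
  expect_identical(attr(h, "dropped")$action, "dropped_incompatible")

  out2 <- make_trait("rs9", "A", "G", beta = 0.05, se = 0.02,
                     trait_name = "Y")
  expect_error(harmonize(exp, out2), "no shared variants")
})

test_that("harmonization is involution-safe", {
  set.seed(5)
  n <- 12
  alleles <- cbind(c("A", "C", "G", "T")[sample(1:4, n, replace = TRUE)])
  other <- vapply(alleles, function(a) {
    setdiff(c("A", "C", "G", "T"), a)[sample(1:3, 1)]
  }, "")
  exp <- make_trait(sprintf("rs%02d", 1:n), alleles, other,
                    beta = rnorm(n, 0.1, 0.02), se = runif(n, 0.005, 0.02),
                    eaf = runif(n, 0.1, 0.4))
  out <- make_trait(sprintf("rs%02d", 1:n), alleles, other,
                    beta = rnorm(n, 0.02, 0.01), se = runif(n, 0.005, 0.02),
                    eaf = runif(n, 0.1, 0.4), trait_name = "Y")
  h1 <- harmonize(exp, out)
  # rebuild tables from the harmonized rows and harmonize again
  exp2 <- make_trait(h1$snp_id, h1$effect_allele, h1$other_allele,
                     beta = h1$beta_exposure, se = h1$se_exposure,
                     eaf = h1$eaf_exposure)
  out2 <- make_trait(h1$snp_id, h1$effect_allele, h1$other_allele,
                     beta = h1$beta_outcome, se = h1$se_outcome,
                     eaf = h1$eaf_outcome, trait_name = "Y")
  h2 <- harmonize(exp2, out2)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
  expect_true(all(h2$action == "kept"))
})
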