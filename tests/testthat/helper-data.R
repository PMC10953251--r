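# Fixture builders shared across test files. All fixtures are built in
# code; nothing binary is stored.

make_hd <- function(bx, by, sex = rep(0.01, length(bx)),
                    sey = rep(0.01, length(bx)),
                    eaf = rep(0.3, length(bx)), n = 100000,
                    exposure = "X", outcome = "Y") {
  harmonized_data(data.frame(
    snp_id = sprintf("s%02d", seq_along(bx)),
    beta_exposure = bx, se_exposure = sex,
    beta_outcome = by, se_outcome = sey,
    eaf_exposure = eaf, eaf_outcome = eaf,
    n_exposure = n, n_outcome = n,
    stringsAsFactors = FALSE
  ), exposure_name = exposure, outcome_name = outcome)
}

make_trait <- function(snp_id, effect_allele, other_allele, beta, se,
                       eaf = NA, pvalue = NA, chrom = "1",
                       pos = seq_along(snp_id) * 1e6, n = 100000,
                       trait_name = "trait", trait_type = "binary") {
  # fixtures often carry deliberately arbitrary p-values; silence the
  # p-vs-z consistency warning here so tests assert it only where intended
  suppressWarnings(trait_table(data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
    stringsAsFactors = FALSE
  ), trait_name = trait_name, trait_type = trait_type))
}

# Random small harmonized dataset for oracle-equivalence checks.
random_hd <- function(n, seed) {
  set.seed(seed)
  bx <- (0.05 + abs(rnorm(n, 0.1, 0.05))) * sample(c(-1, 1), n, replace = TRUE)
  sey <- runif(n, 0.005, 0.05)
  by <- 0.2 * bx + rnorm(n, 0, sey)
  sex <- runif(n, 0.005, 0.02)
  make_hd(bx, by, sex = sex, sey = sey)
}

write_summary_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
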