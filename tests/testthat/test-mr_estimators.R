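test_that("Wald ratios divide outcome by exposure effects", {
  h <- make_hd(0.1, 0.05, sey = 0.01)
  r <- ratio_estimates(h)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$se, 0.1)

  # sign flips of both betas leave the ratio unchanged
  h2 <- make_hd(-0.1, -0.05, sey = 0.01)
  expect_equal(ratio_estimates(h2)$ratio, 0.5)

  set.seed(31)
  bx <- rnorm(5, 0.1, 0.02)
  by <- rnorm(5, 0.02, 0.01)
  sey <- runif(5, 0.005, 0.02)
  r5 <- ratio_estimates(make_hd(bx, by, sey = sey))
  expect_equal(r5$ratio, by / bx)
  expect_equal(r5$se, sey / abs(bx))

  expect_error(ratio_estimates(make_hd(c(0.1, 0), c(0.1, 0.1))), "s02")
})

test_that("IVW on a single variant is exactly the Wald ratio", {
  h <- make_hd(0.1, 0.05, sey = 0.01)
  est <- mr_ivw(h, model = "fixed")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$or, exp(0.5))
  expect_error(mr_ivw(h, model = "multiplicative_random"), "at least 2")
})

test_that("IVW matches the weighted-normal-equations oracle", {
  h <- make_hd(c(0.1, 0.2, 0.15), c(0.02, 0.03, 0.025),
               sey = c(0.01, 0.01, 0.02))
  o <- oracle_wls_origin(h$beta_exposure, h$beta_outcome, h$se_outcome)
  fixed <- mr_ivw(h, model = "fixed")
  expect_equal(fixed$beta, o$beta, tolerance = 1e-12)
  expect_equal(fixed$se, o$se_fixed, tolerance = 1e-12)
  random <- mr_ivw(h, model = "multiplicative_random")
  expect_equal(random$beta, o$beta, tolerance = 1e-12)
  expect_equal(random$se, o$se_random, tolerance = 1e-12)
})

test_that("Egger recovers an exact affine relationship with zero residual", {
  bx <- c(0.05, 0.10, 0.20)
  by <- 0.01 + 0.2 * bx
  h <- make_hd(bx, by, sey = rep(0.01, 3))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.2, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.01, tolerance = 1e-10)
})

test_that("Egger matches the with-intercept normal-equations oracle", {
  h <- random_hd(10, seed = 44)
  o <- oracle_egger(h$beta_exposure, h$beta_outcome, h$se_outcome)
  est <- mr_egger(h)
  expect_equal(est$beta, o$slope, tolerance = 1e-10)
  expect_equal(est$se, o$slope_se, tolerance = 1e-10)
  expect_equal(est$egger_intercept, o$intercept, tolerance = 1e-10)
  expect_equal(est$egger_intercept_se, o$intercept_se, tolerance = 1e-10)
  expect_error(mr_egger(make_hd(c(0.1, 0.2), c(0.02, 0.03))), "3")
})

test_that("weighted median interpolates the 50% weight point", {
  # equal weights, ratios {0.1, 0.4, 0.9}: the middle ratio carries the
  # cumulative-weight midpoint
  h <- make_hd(rep(1, 3), c(0.1, 0.4, 0.9), sey = rep(0.01, 3))
  est <- mr_weighted_median(h, n_boot = 0)
  expect_equal(est$beta, 0.4)

  # all ratios equal c -> estimate c
  h2 <- make_hd(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20), sey = rep(0.01, 3))
  expect_equal(mr_weighted_median(h2, n_boot = 0)$beta, 0.5)
})

test_that("weighted median matches the brute-force weighted-quantile oracle", {
  for (s in 1:5) {
    h <- random_hd(sample(3:10, 1), seed = 200 + s)
    r <- ratio_estimates(h)
    expect_equal(mr_weighted_median(h, n_boot = 0)$beta,
                 oracle_weighted_median(r$ratio, 1 / r$se^2),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap standard errors are reproducible under a fixed seed", {
  h <- random_hd(8, seed = 3)
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  c <- mr_weighted_median(h, n_boot = 200, seed = 100)
  expect_false(identical(a$se, c$se))
  m1 <- mr_mode(h, n_boot = 100, seed = 7)
  m2 <- mr_mode(h, n_boot = 100, seed = 7)
  expect_identical(m1$se, m2$se)
})

test_that("mode estimators find the dominant ratio cluster", {
  # all ratios equal
  h0 <- make_hd(c(0.1, 0.2, 0.4), c(0.03, 0.06, 0.12), sey = rep(0.01, 3))
  expect_equal(mr_mode(h0, weighted = TRUE, n_boot = 0)$beta, 0.3)
  expect_equal(mr_mode(h0, weighted = FALSE, n_boot = 0)$beta, 0.3)

  # cluster at 0.2 with one outlying ratio at 0.9
  h <- make_hd(rep(1, 4), c(0.2, 0.21, 0.19, 0.9), sey = rep(0.01, 4))
  est <- mr_mode(h, weighted = FALSE, n_boot = 0)
  oracle <- oracle_mode(c(0.2, 0.21, 0.19, 0.9), rep(1, 4))
  grid_step <- (diff(range(c(0.2, 0.21, 0.19, 0.9))) + 2 * 0.02) / 1999
  expect_lt(abs(est$beta - oracle), 5 * grid_step)
  expect_lt(abs(est$beta - 0.2), 0.05)
})

test_that("a dominant weight pulls the weighted mode relative to the simple mode", {
  ratios <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  sey <- c(0.05, 0.05, 0.05, 0.002, 0.05) # SNP at 0.7 has enormous weight
  h <- make_hd(rep(1, 5), ratios, sey = sey)
  wm <- mr_mode(h, weighted = TRUE, n_boot = 0)$beta
  sm <- mr_mode(h, weighted = FALSE, n_boot = 0)$beta
  expect_lt(abs(wm - 0.7), abs(sm - 0.7))
  # both match the independent dense-grid oracle to grid resolution
  o_w <- oracle_mode(ratios, 1 / sey^2)
  expect_lt(abs(wm - o_w), 0.01)
})

test_that("all estimators are equivariant under allele reorientation", {
  h <- random_hd(10, seed = 15)
  flip <- rep(1, 10)
  flip[c(2, 5, 9)] <- -1
  df <- as.data.frame(h)
  df$beta_exposure <- df$beta_exposure * flip
  df$beta_outcome <- df$beta_outcome * flip
  h_flip <- harmonized_data(df, "X", "Y")
  expect_equal(mr_ivw(h_flip)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h_flip)$beta, mr_egger(h)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(h_flip, n_boot = 0)$beta,
               mr_weighted_median(h, n_boot = 0)$beta, tolerance = 1e-12)
  expect_equal(mr_mode(h_flip, n_boot = 0)$beta,
               mr_mode(h, n_boot = 0)$beta, tolerance = 1e-12)
})

test_that("the five-method panel has the documented shape and policies", {
  h <- random_hd(10, seed = 21)
  est <- mr_estimate_all(h, n_boot = 50, seed = 1)
  expect_identical(est$method, c("ivw", "egger", "weighted_median",
                                 "weighted_mode", "simple_mode"))
  expect_true(all(est$computable))
  expect_true(all(is.finite(est$beta)))
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$or_low, exp(est$ci_low))

  # 2 variants: only fixed-effect IVW computable
  est2 <- mr_estimate_all(make_hd(c(0.1, 0.2), c(0.02, 0.04)))
  expect_identical(est2$computable, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(is.finite(est2$beta[1]))
  empty <- harmonized_data(data.frame(
    snp_id = character(0), beta_exposure = numeric(0),
    se_exposure = numeric(0), beta_outcome = numeric(0),
    se_outcome = numeric(0)), "X", "Y")
  expect_error(mr_estimate_all(empty), "empty")
})

test_that("under a simulated null every estimator sits within 3 SE of zero", {
  sim <- simulate_pair(sim_config(n_snps = 50, true_effect = 0), seed = 555)
  h <- harmonize(sim$exposure, sim$outcome)
  est <- mr_estimate_all(h, n_boot = 200, seed = 1)
  expect_true(all(abs(est$beta) <= 3 * est$se))
})
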