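# Synthetic two-sample GWAS summary statistics with known causal structure.
# SEs follow the standard 1/sqrt(2 N f (1-f)) approximation for a
# standardized trait, so the instrument-strength formulas downstream behave
# as they do on real summary data.

#' Configuration for the synthetic GWAS generator
#'
#' Defaults describe a realistic large-biobank two-sample design: 50
#' independent instruments, effect-allele frequencies uniform on
#' \[0.05, 0.95\], per-variant exposure effects drawn from a positive-
#' truncated Normal(0.08, 0.02), and GWAS sample sizes of 450,000 — a
#' combination whose per-variant F statistics span roughly 20 to 1500.
#'
#' @param n_snps Number of instruments.
#' @param true_effect Causal effect of exposure on outcome (log-odds
#'   scale); in mediation simulations this is the *direct* effect.
#' @param mediator_paths Optional `c(b_xz, b_zy)`: exposure-to-mediator
#'   and mediator-to-outcome path coefficients.
#' @param gamma_mean,gamma_sd Mean/SD of the per-variant exposure effect
#'   (truncated positive).
#' @param eaf_range Range of effect-allele frequencies, inside (0, 1).
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes governing the
#'   standard errors.
#' @param pleiotropy_model `"none"`, `"balanced"` (mean-zero direct
#'   effects), `"directional"` (nonzero mean) or `"inside_violating"`
#'   (pleiotropy correlated with instrument strength).
#' @param pleiotropy_mean,pleiotropy_sd Pleiotropy distribution
#'   parameters.
#' @param prop_invalid Fraction of variants carrying pleiotropy
#'   (default 1: all of them, when a pleiotropy model is active).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50, true_effect = 0,
                       mediator_paths = NULL,
                       gamma_mean = 0.08, gamma_sd = 0.02,
                       eaf_range = c(0.05, 0.95),
                       n_exposure = 450000, n_outcome = 450000,
                       n_mediator = n_outcome,
                       pleiotropy_model = c("none", "balanced",
                                            "directional",
                                            "inside_violating"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       prop_invalid = 1) {
  pleiotropy_model <- match.arg(pleiotropy_model)
  stopifnot(n_snps >= 1, gamma_sd >= 0, pleiotropy_sd >= 0,
            length(eaf_range) == 2, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2],
            n_exposure >= 1, n_outcome >= 1,
            prop_invalid >= 0, prop_invalid <= 1)
  if (!is.null(mediator_paths)) stopifnot(length(mediator_paths) == 2)
  structure(list(n_snps = as.integer(n_snps), true_effect = true_effect,
                 mediator_paths = mediator_paths,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 eaf_range = eaf_range,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 n_mediator = n_mediator,
                 pleiotropy_model = pleiotropy_model,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 prop_invalid = prop_invalid),
            class = "sim_config")
}

rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

# SNP ids, chromosomes and positions spaced far enough apart (20 Mb) that
# distance clumping keeps every variant.
snp_coords <- function(n, offset = 0) {
  idx <- seq_len(n) + offset
  list(snp_id = sprintf("rs%06d", idx),
       chrom = as.character(1 + (idx - 1) %% 22),
       pos = 1e6 + ((idx - 1) %/% 22) * 2e7)
}

clamp_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

assemble_trait <- function(coords, eaf, beta, se, n, trait_name,
                           trait_type = "binary") {
  trait_table(data.frame(
    snp_id = coords$snp_id, chrom = coords$chrom, pos = coords$pos,
    effect_allele = "A", other_allele = "G",
    eaf = eaf, beta = beta, se = se,
    pvalue = clamp_p(beta / se), n = n,
    stringsAsFactors = FALSE
  ), trait_name = trait_name, trait_type = trait_type, validate = FALSE)
}

draw_pleiotropy <- function(cfg, gamma) {
  n <- cfg$n_snps
  alpha <- numeric(n)
  if (cfg$pleiotropy_model == "none") return(list(alpha = alpha,
                                                  invalid = integer(0)))
  k <- round(cfg$prop_invalid * n)
  invalid <- if (k > 0) sample(n, k) else integer(0)
  if (k > 0) {
    alpha[invalid] <- switch(
      cfg$pleiotropy_model,
      balanced = stats::rnorm(k, 0, cfg$pleiotropy_sd),
      directional = stats::rnorm(k, cfg$pleiotropy_mean, cfg$pleiotropy_sd),
      inside_violating = {
        # pleiotropy correlated (rho = 0.8) with instrument strength
        g <- gamma[invalid]
        z <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else rep(0, k)
        cfg$pleiotropy_mean + cfg$pleiotropy_sd *
          (0.8 * z + sqrt(1 - 0.8^2) * stats::rnorm(k))
      })
  }
  list(alpha = alpha, invalid = sort(invalid))
}

#' Simulate a two-sample exposure-outcome GWAS pair
#'
#' Per variant: draws a frequency and a true exposure effect, sets the
#' exposure standard error to \eqn{1/\sqrt{2 N_{exp} f (1-f)}}, observes
#' the exposure beta with that sampling noise, composes the true outcome
#' effect as `true_effect * gamma + alpha` (alpha per the pleiotropy
#' model) and observes it with the outcome-side noise. P-values use the
#' normal approximation. The truth record stores every latent quantity.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; identical seeds give identical tables.
#' @return List with `exposure` and `outcome` [trait_table()]s and a
#'   `truth` list (gamma, alpha, per-variant SEs, invalid set, true
#'   effect).
#' @export
simulate_pair <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n_snps
    coords <- snp_coords(n)
    eaf <- stats::runif(n, config$eaf_range[1], config$eaf_range[2])
    gamma <- rtnorm_pos(n, config$gamma_mean, config$gamma_sd)
    se_x <- 1 / sqrt(2 * config$n_exposure * eaf * (1 - eaf))
    bx <- stats::rnorm(n, gamma, se_x)
    pl <- draw_pleiotropy(config, gamma)
    true_out <- config$true_effect * gamma + pl$alpha
    se_y <- 1 / sqrt(2 * config$n_outcome * eaf * (1 - eaf))
    by <- stats::rnorm(n, true_out, se_y)
    list(
      exposure = assemble_trait(coords, eaf, bx, se_x, config$n_exposure,
                                "sim_exposure"),
      outcome = assemble_trait(coords, eaf, by, se_y, config$n_outcome,
                               "sim_outcome"),
      truth = list(true_effect = config$true_effect, gamma = gamma,
                   alpha = pl$alpha, invalid = pl$invalid,
                   eaf = eaf, se_x = se_x, se_y = se_y,
                   true_outcome_effect = true_out, seed = seed)
    )
  })
}

#' Simulate an exposure-mediator-outcome GWAS triple
#'
#' Generates distinct instrument sets for the exposure and the mediator
#' and composes effects along the mediation graph: exposure variants act
#' on the mediator through the exposure (`b_xz * gamma`) and on the
#' outcome both directly (`true_effect * gamma`) and through the mediator
#' (`b_xz * b_zy * gamma`); mediator variants act on the outcome only
#' through the mediator (`b_zy * delta`). All three tables cover the
#' union of variants, each observed with its own sampling noise.
#'
#' @param config A [sim_config()] with `mediator_paths = c(b_xz, b_zy)`;
#'   `true_effect` is the direct exposure-outcome effect.
#' @param seed RNG seed.
#' @return List with `exposure`, `mediator`, `outcome` trait tables and a
#'   `truth` record including the generating total, direct, indirect
#'   effects and proportion mediated.
#' @export
simulate_mediation_triple <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$mediator_paths)) {
    stop2("simulate_mediation_triple: config$mediator_paths required")
  }
  b_xz <- config$mediator_paths[1]
  b_zy <- config$mediator_paths[2]
  b_direct <- config$true_effect
  with_seed(seed, {
    n <- config$n_snps
    coords <- snp_coords(2 * n)
    eaf <- stats::runif(2 * n, config$eaf_range[1], config$eaf_range[2])
    gamma <- c(rtnorm_pos(n, config$gamma_mean, config$gamma_sd),
               numeric(n))                         # exposure instruments
    delta <- c(numeric(n),
               rtnorm_pos(n, config$gamma_mean, config$gamma_sd))
                                                   # mediator's own variants
    true_x <- gamma
    true_z <- b_xz * gamma + delta
    true_y <- b_direct * gamma + b_zy * true_z

    se_x <- 1 / sqrt(2 * config$n_exposure * eaf * (1 - eaf))
    se_z <- 1 / sqrt(2 * config$n_mediator * eaf * (1 - eaf))
    se_y <- 1 / sqrt(2 * config$n_outcome * eaf * (1 - eaf))
    bx <- stats::rnorm(2 * n, true_x, se_x)
    bz <- stats::rnorm(2 * n, true_z, se_z)
    by <- stats::rnorm(2 * n, true_y, se_y)
    total <- b_direct + b_xz * b_zy
    list(
      exposure = assemble_trait(coords, eaf, bx, se_x, config$n_exposure,
                                "sim_exposure"),
      mediator = assemble_trait(coords, eaf, bz, se_z, config$n_mediator,
                                "sim_mediator", trait_type = "continuous"),
      outcome = assemble_trait(coords, eaf, by, se_y, config$n_outcome,
                               "sim_outcome"),
      truth = list(direct = b_direct, b_xz = b_xz, b_zy = b_zy,
                   total = total,
                   indirect = b_xz * b_zy,
                   proportion_mediated = if (total != 0)
                     b_xz * b_zy / total else NA_real_,
                   gamma = gamma, delta = delta, eaf = eaf,
                   seed = seed)
    )
  })
}
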