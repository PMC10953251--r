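# Study orchestration: bidirectional univariable MR, mediator screening,
# and MVMR mediation from one configuration object.

#' Build a study configuration
#'
#' @param traits Named list of traits. Each element is either a
#'   [trait_table()] or a file path readable by [read_summary_table()]
#'   (optionally a `list(path=, column_map=, trait_type=)`).
#' @param exposure,outcome Names (in `traits`) of the primary exposure
#'   and outcome.
#' @param mediators Character vector of candidate mediator trait names.
#' @param p_threshold Instrument p-value threshold; either one value or a
#'   named vector with per-trait overrides (unnamed traits fall back to
#'   the first value).
#' @param clump_r2,clump_kb,ld_table Clumping settings ([clump()]).
#' @param palindrome_policy,palindrome_window Harmonization settings
#'   ([harmonize()]).
#' @param ivw_model IVW variant used throughout.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param mediator_alpha Significance level of the mediator admission
#'   rule (step-1 IVW p and step-2 MVMR mediator p must both fall below
#'   it).
#' @param seed Base RNG seed; per-branch seeds are derived
#'   deterministically from it.
#' @param out_dir Optional directory; when set, [run_study()] writes all
#'   result tables and a manifest there.
#' @return List of class `study_config`.
#' @export
study_config <- function(traits, exposure, outcome,
                         mediators = character(),
                         p_threshold = 5e-8,
                         clump_r2 = 0.001, clump_kb = 10000,
                         ld_table = NULL,
                         palindrome_policy = "infer_by_frequency",
                         palindrome_window = 0.08,
                         ivw_model = "multiplicative_random",
                         n_boot = 1000, presso_n_sim = 1000,
                         mediator_alpha = 0.05,
                         seed = 1, out_dir = NULL) {
  stopifnot(is.list(traits), !is.null(names(traits)),
            exposure %in% names(traits), outcome %in% names(traits),
            all(mediators %in% names(traits)))
  structure(list(traits = traits, exposure = exposure, outcome = outcome,
                 mediators = mediators, p_threshold = p_threshold,
                 clump_r2 = clump_r2, clump_kb = clump_kb,
                 ld_table = ld_table,
                 palindrome_policy = palindrome_policy,
                 palindrome_window = palindrome_window,
                 ivw_model = ivw_model, n_boot = n_boot,
                 presso_n_sim = presso_n_sim,
                 mediator_alpha = mediator_alpha,
                 seed = seed, out_dir = out_dir),
            class = "study_config")
}

config_trait <- function(config, name) {
  x <- config$traits[[name]]
  if (inherits(x, "trait_table")) return(x)
  if (is.character(x)) {
    return(read_summary_table(x, trait_name = name))
  }
  if (is.list(x) && !is.null(x$path)) {
    return(read_summary_table(x$path, column_map = x$column_map,
                              trait_name = name,
                              trait_type = x$trait_type %||% "binary"))
  }
  stop2("study_config: trait '", name,
        "' must be a trait_table, a path, or list(path=, ...)")
}

trait_threshold <- function(config, name) {
  p <- config$p_threshold
  if (!is.null(names(p)) && name %in% names(p)) return(unname(p[[name]]))
  unname(p[[1]])
}

# Deterministic per-branch seed below 2^31.
branch_seed <- function(base, label) {
  (as.numeric(base) * 1000 + sum(utf8ToInt(label)) %% 1000) %% 2^31
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop2("[stage: ", name, "] ", conditionMessage(e))
  })
}

# Serializable description of the configuration (trait tables reduced to
# row counts) used for the manifest hash.
config_fingerprint <- function(config) {
  tr <- lapply(config$traits, function(x) {
    if (inherits(x, "trait_table")) {
      list(rows = nrow(x), name = attr(x, "trait_name"),
           checksum = sum(x$beta) + sum(x$se))
    } else x
  })
  c(list(traits = tr),
    config[setdiff(names(config), c("traits", "out_dir"))])
}

#' Univariable two-sample MR for one exposure-outcome pair
#'
#' Runs the full single-pair workflow: instrument selection, clumping,
#' harmonization, instrument-strength QC, the five-estimator panel and
#' the sensitivity report. Counts of variants surviving each stage are
#' recorded.
#'
#' @param config A [study_config()].
#' @param exposure_name,outcome_name Trait names from the configuration.
#' @return List of class `mr_univariable` with elements `estimates`,
#'   `sensitivity`, `strength`, `dataset`, `counts`.
#' @export
run_univariable <- function(config, exposure_name, outcome_name) {
  stopifnot(inherits(config, "study_config"))
  exposure <- stage("read", config_trait(config, exposure_name))
  outcome <- stage("read", config_trait(config, outcome_name))
  sel <- stage("select", select_instruments(
    exposure, trait_threshold(config, exposure_name)))
  cl <- stage("clump", clump(sel, r2_threshold = config$clump_r2,
                             window_kb = config$clump_kb,
                             ld_table = config$ld_table))
  dat <- stage("harmonize", harmonize(
    cl, outcome, palindrome_policy = config$palindrome_policy,
    palindrome_eaf_window = config$palindrome_window))
  strength <- stage("qc", tryCatch(strength_table(dat),
                                   error = function(e) NULL))
  seed <- branch_seed(config$seed, paste(exposure_name, outcome_name))
  est <- stage("estimate", mr_estimate_all(
    dat, ivw_model = config$ivw_model, n_boot = config$n_boot, seed = seed))
  sens <- stage("sensitivity", if (nrow(dat) >= 2) {
    sensitivity_report(dat, n_sim = config$presso_n_sim, seed = seed,
                       model = config$ivw_model)
  } else NULL)
  counts <- c(input = nrow(exposure), selected = nrow(sel),
              clumped = nrow(cl), harmonized = nrow(dat))
  message(sprintf("[%s -> %s] variants: input %d, selected %d, clumped %d, harmonized %d",
                  exposure_name, outcome_name, counts[1], counts[2],
                  counts[3], counts[4]))
  structure(list(exposure = exposure_name, outcome = outcome_name,
                 estimates = est, sensitivity = sens, strength = strength,
                 dataset = dat, counts = counts),
            class = "mr_univariable")
}

#' Two-step MR mediation analysis for one mediator
#'
#' Step 1 estimates the exposure-to-mediator effect by univariable IVW;
#' step 2 fits multivariable MR of the outcome on exposure and mediator
#' jointly, giving the mediator-adjusted direct effect and the
#' exposure-adjusted mediator effect. Together with the univariable
#' total effect these feed [mediation_decompose()].
#'
#' @param config A [study_config()].
#' @param mediator_name Mediator trait name.
#' @param total Optional precomputed `mr_univariable` result for the
#'   primary exposure-outcome pair (recomputed if omitted).
#' @return List of class `mr_mediation` with elements `mediation`
#'   (a `mediation_result`), `step1`, `mvmr`, `total`.
#' @export
run_mediation <- function(config, mediator_name, total = NULL) {
  stopifnot(inherits(config, "study_config"),
            mediator_name %in% names(config$traits))
  if (is.null(total)) {
    total <- run_univariable(config, config$exposure, config$outcome)
  }
  step1 <- stage("step1", run_univariable(config, config$exposure,
                                          mediator_name))
  exposure <- config_trait(config, config$exposure)
  mediator <- config_trait(config, mediator_name)
  outcome <- config_trait(config, config$outcome)
  thresholds <- stats::setNames(
    c(trait_threshold(config, config$exposure),
      trait_threshold(config, mediator_name)),
    c(config$exposure, mediator_name))
  mv_dat <- stage("mvmr_build", build_mvmr_dataset(
    stats::setNames(list(exposure, mediator),
                    c(config$exposure, mediator_name)),
    outcome, p_threshold = thresholds,
    r2_threshold = config$clump_r2, window_kb = config$clump_kb,
    ld_table = config$ld_table,
    palindrome_policy = config$palindrome_policy,
    palindrome_eaf_window = config$palindrome_window))
  mv <- stage("mvmr_fit", mvmr_ivw(mv_dat))
  total_ivw <- total$estimates[total$estimates$method == "ivw", ]
  step1_ivw <- step1$estimates[step1$estimates$method == "ivw", ]
  direct <- mv[mv$exposure == config$exposure, ]
  z_to_y <- mv[mv$exposure == mediator_name, ]
  med <- mediation_decompose(total_ivw, direct, step1_ivw, z_to_y)
  structure(list(mediator = mediator_name, mediation = med,
                 step1 = step1, mvmr = mv, mvmr_dataset = mv_dat,
                 total = total),
            class = "mr_mediation")
}

#' Run the full bidirectional MR and mediation study
#'
#' Executes, from one configuration: univariable MR in both directions
#' between the primary exposure and outcome; an exposure-to-mediator
#' screen and a mediator-to-outcome screen for every candidate mediator;
#' and, for mediators with causal support in both steps (step-1 IVW p and
#' step-2 MVMR mediator-coefficient p below `mediator_alpha`), the MVMR
#' mediation decomposition. A branch that fails is recorded in the
#' manifest and the remaining branches continue. When `out_dir` is set,
#' all result tables plus a JSON manifest (with the configuration hash
#' and seed) are written.
#'
#' @param config A [study_config()].
#' @return List of class `mr_study` with elements `forward`, `reverse`,
#'   `mediator_screens`, `mediations`, `estimates_table`,
#'   `sensitivity_table`, `mediation_table`, `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  failures <- list()
  run_branch <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      failures[[label]] <<- conditionMessage(e)
      message("branch '", label, "' failed: ", conditionMessage(e))
      NULL
    })
  }

  forward <- run_branch("forward",
                        run_univariable(config, config$exposure,
                                        config$outcome))
  reverse <- run_branch("reverse",
                        run_univariable(config, config$outcome,
                                        config$exposure))

  screens <- list()
  mediations <- list()
  admitted <- character()
  for (m in config$mediators) {
    to_med <- run_branch(paste0("screen_", m),
                         run_univariable(config, config$exposure, m))
    med_to_out <- run_branch(paste0("mediator_mr_", m),
                             run_univariable(config, m, config$outcome))
    screens[[m]] <- list(exposure_to_mediator = to_med,
                         mediator_to_outcome = med_to_out)
    if (is.null(to_med)) next
    step1_p <- to_med$estimates$pvalue[to_med$estimates$method == "ivw"]
    if (!is.finite(step1_p) || step1_p >= config$mediator_alpha) next
    med_run <- run_branch(paste0("mediation_", m),
                          run_mediation(config, m, total = forward))
    if (is.null(med_run)) next
    step2_p <- med_run$mvmr$pvalue[med_run$mvmr$exposure == m]
    if (is.finite(step2_p) && step2_p < config$mediator_alpha) {
      mediations[[m]] <- med_run
      admitted <- c(admitted, m)
    }
  }

  est_tab <- do.call(rbind, c(
    lapply(Filter(Negate(is.null), list(forward, reverse)),
           function(x) x$estimates),
    lapply(Filter(Negate(is.null), screens), function(s) {
      do.call(rbind, lapply(Filter(Negate(is.null), unname(s)),
                            function(x) x$estimates))
    })
  ))
  sens_rows <- lapply(Filter(Negate(is.null), list(forward, reverse)),
                      function(x) if (!is.null(x$sensitivity))
                        as.data.frame(x$sensitivity) else NULL)
  for (s in screens) {
    for (x in s) {
      if (!is.null(x) && !is.null(x$sensitivity)) {
        sens_rows <- c(sens_rows, list(as.data.frame(x$sensitivity)))
      }
    }
  }
  sens_tab <- do.call(rbind, Filter(Negate(is.null), sens_rows))
  med_tab <- if (length(mediations) > 0) {
    do.call(rbind, lapply(names(mediations), function(m) {
      cbind(data.frame(mediator = m, stringsAsFactors = FALSE),
            as.data.frame(mediations[[m]]$mediation))
    }))
  } else NULL

  manifest <- list(
    config_hash = config_hash(config_fingerprint(config)),
    seed = config$seed,
    branches_run = c("forward", "reverse",
                     as.vector(rbind(paste0("screen_", config$mediators),
                                     paste0("mediator_mr_",
                                            config$mediators)))),
    mediators_admitted = admitted,
    failures = failures
  )
  if (!is.null(config$out_dir)) {
    tables <- list(estimates = est_tab)
    if (!is.null(sens_tab)) tables$sensitivity <- sens_tab
    if (!is.null(med_tab)) tables$mediation <- med_tab
    written <- write_results(tables, config$out_dir,
                             config = config_fingerprint(config))
    manifest$files <- written$files
  }
  structure(list(forward = forward, reverse = reverse,
                 mediator_screens = screens, mediations = mediations,
                 estimates_table = est_tab, sensitivity_table = sens_tab,
                 mediation_table = med_tab, manifest = manifest),
            class = "mr_study")
}
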