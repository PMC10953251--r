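# Heterogeneity, pleiotropy, leave-one-out and outlier diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' For the IVW model, Q is the weighted sum of squared deviations of the
#' per-variant Wald ratios from the fixed-effect IVW estimate, with
#' weights \eqn{1/se_j^2} on the ratio scale (algebraically identical to
#' the weighted residual sum of squares of the origin-constrained fit);
#' degrees of freedom n - 1. For MR-Egger, Q is the weighted residual sum
#' of squares of the with-intercept fit on n - 2 degrees of freedom.
#' P-values come from the chi-square distribution; p < 0.05 is the usual
#' flag for significant heterogeneity.
#'
#' @param dataset A `harmonized_data` object.
#' @param method `"ivw"` (needs >= 2 variants) or `"egger"` (>= 3).
#' @return List with `q`, `df`, `p`.
#' @export
cochran_q <- function(dataset, method = c("ivw", "egger")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "harmonized_data"))
  n <- nrow(dataset)
  if (method == "ivw") {
    if (n < 2) stop2("cochran_q: IVW Q requires at least 2 variants")
    r <- ratio_estimates(dataset)
    w <- 1 / r$se^2
    fitted <- ivw_kernel(dataset$beta_exposure, dataset$beta_outcome,
                         dataset$se_outcome)$beta
    q <- sum(w * (r$ratio - fitted)^2)
    df <- n - 1
  } else {
    if (n < 3) stop2("cochran_q: Egger Q requires at least 3 variants")
    f <- egger_fit(dataset)
    q <- sum(f$weights * f$residuals^2)
    df <- n - 2
  }
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept row of the MR-Egger fit — the same fit
#' underlying [mr_egger()], so the values are identical by construction.
#' A nonzero intercept is evidence of directional horizontal pleiotropy.
#'
#' @param dataset A `harmonized_data` object with at least 3 variants.
#' @return List with `intercept`, `se`, `p` (t-test on n - 2 df).
#' @export
egger_intercept_test <- function(dataset) {
  stopifnot(inherits(dataset, "harmonized_data"))
  f <- egger_fit(dataset)
  list(intercept = f$intercept, se = f$intercept_se,
       p = 2 * stats::pt(-abs(f$intercept / f$intercept_se), f$df))
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate with each variant excluded in turn and
#' flags any exclusion that moves the estimate outside the full-data 95%
#' confidence interval — evidence that a single variant drives the
#' result.
#'
#' @param dataset A `harmonized_data` object with at least 2 variants.
#' @param model IVW model for the refits (and the full-data CI).
#' @return data.frame with `snp_id`, `beta_without`, `se_without`,
#'   `outside_ci`; attribute `full_estimate` holds the all-variant fit.
#' @export
leave_one_out <- function(dataset,
                          model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "harmonized_data"))
  n <- nrow(dataset)
  if (n < 2) stop2("leave_one_out: at least 2 variants required")
  full <- mr_ivw(dataset, model = model)
  out <- data.frame(snp_id = dataset$snp_id,
                    beta_without = NA_real_, se_without = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    sub <- dataset[-j, , drop = FALSE]
    sub <- harmonized_data(as.data.frame(sub),
                           attr(dataset, "exposure_name"),
                           attr(dataset, "outcome_name"))
    est <- if (nrow(sub) == 1) mr_ivw(sub, model = "fixed")
           else mr_ivw(sub, model = model)
    out$beta_without[j] <- est$beta
    out$se_without[j] <- est$se
  }
  out$outside_ci <- out$beta_without < full$ci_low |
    out$beta_without > full$ci_high
  attr(out, "full_estimate") <- full
  out
}

#' MR-PRESSO style pleiotropy residual sum of squares and outlier test
#'
#' A simulation-based test for horizontal pleiotropy. Each variant's
#' observed residual sum of squares (RSS) contribution is its squared,
#' variance-standardized deviation from the IVW prediction fitted with
#' that variant left out. The observed global RSS is compared against
#' `n_sim` parametric simulations drawn under the no-pleiotropy model
#' (betas resampled from their sampling distributions around the
#' leave-one-out fitted values), giving an empirical global p-value.
#' Per-variant empirical p-values, Bonferroni-corrected at
#' `significance`, flag outliers; a distortion test compares the all-
#' variant and outlier-removed IVW estimates against the distortion
#' expected from removing the same number of variants at random.
#'
#' @param dataset A `harmonized_data` object with at least 4 variants.
#' @param n_sim Number of parametric simulations (default 1000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param significance Outlier significance level before Bonferroni
#'   correction (default 0.05).
#' @param model IVW model used for the corrected estimate.
#' @return List with `global_rss`, `global_p`, `outliers` (snp ids),
#'   `outlier_p` (per-variant), `distortion_p` (`NA` when no outliers),
#'   and `corrected_estimate` (IVW after outlier removal; equals the
#'   plain IVW estimate when nothing is flagged).
#' @export
mr_presso <- function(dataset, n_sim = 1000, seed = 1, significance = 0.05,
                      model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "harmonized_data"))
  n <- nrow(dataset)
  if (n < 4) stop2("mr_presso: at least 4 variants required")
  bx <- dataset$beta_exposure
  by <- dataset$beta_outcome
  sex <- dataset$se_exposure
  sey <- dataset$se_outcome
  w <- 1 / sey^2

  loo_beta <- function(BX, BY) {
    # leave-one-out IVW slopes; BX, BY are n_sim x n matrices (or vectors)
    if (is.null(dim(BX))) {
      sxx <- sum(w * BX^2); sxy <- sum(w * BX * BY)
      (sxy - w * BX * BY) / (sxx - w * BX^2)
    } else {
      sxx <- drop(BX^2 %*% w); sxy <- drop((BX * BY) %*% w)
      (sxy - sweep(BX * BY, 2, w, "*")) / (sxx - sweep(BX^2, 2, w, "*"))
    }
  }

  b_loo <- loo_beta(bx, by)
  rss_j <- w * (by - b_loo * bx)^2
  rss_obs <- sum(rss_j)

  sims <- with_seed(seed, {
    BXs <- matrix(stats::rnorm(n_sim * n, mean = rep(bx, each = n_sim),
                               sd = rep(sex, each = n_sim)), n_sim, n)
    BYs <- matrix(stats::rnorm(n_sim * n, mean = rep(b_loo * bx, each = n_sim),
                               sd = rep(sey, each = n_sim)), n_sim, n)
    Bs <- loo_beta(BXs, BYs)
    RSSs <- sweep((BYs - Bs * BXs)^2, 2, w, "*")
    list(global = rowSums(RSSs), per_snp = RSSs)
  })

  global_p <- (sum(sims$global >= rss_obs) + 1) / (n_sim + 1)
  outlier_p <- vapply(seq_len(n), function(j) {
    (sum(sims$per_snp[, j] >= rss_j[j]) + 1) / (n_sim + 1)
  }, numeric(1))
  flagged <- which(outlier_p < significance / n)

  if (length(flagged) >= n - 1) {
    # too few clean variants left to re-estimate; report flags only
    warn2("mr_presso: ", length(flagged), " of ", n,
          " variants flagged; corrected estimate uses the full set")
    corrected <- mr_ivw(dataset, model = model)
    distortion_p <- NA_real_
  } else if (length(flagged) > 0) {
    keep <- setdiff(seq_len(n), flagged)
    sub <- harmonized_data(as.data.frame(dataset[keep, , drop = FALSE]),
                           attr(dataset, "exposure_name"),
                           attr(dataset, "outcome_name"))
    corrected <- mr_ivw(sub, model = if (length(keep) >= 2) model
                                     else "fixed")
    b_all <- mr_ivw(dataset, model = model)$beta
    d_obs <- (b_all - corrected$beta) / abs(corrected$beta)
    d_null <- with_seed(seed + 1, {
      vapply(seq_len(n_sim), function(i) {
        drop_i <- sample(n, length(flagged))
        kk <- ivw_kernel(bx[-drop_i], by[-drop_i], sey[-drop_i])
        (b_all - kk$beta) / abs(kk$beta)
      }, numeric(1))
    })
    distortion_p <- (sum(abs(d_null) >= abs(d_obs)) + 1) / (n_sim + 1)
  } else {
    corrected <- mr_ivw(dataset, model = model)
    distortion_p <- NA_real_
  }

  list(global_rss = rss_obs, global_p = global_p,
       outliers = dataset$snp_id[flagged], outlier_p = outlier_p,
       distortion_p = distortion_p, corrected_estimate = corrected)
}

#' Assemble the full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q (IVW and, when possible, Egger), the MR-Egger
#' intercept test, the leave-one-out table, and — with at least 4
#' variants — the MR-PRESSO global/outlier/distortion tests.
#'
#' @param dataset A `harmonized_data` object with at least 2 variants.
#' @param n_sim,seed,significance Passed to [mr_presso()].
#' @param model IVW model for the leave-one-out refits.
#' @return List of class `sensitivity_report`.
#' @export
sensitivity_report <- function(dataset, n_sim = 1000, seed = 1,
                               significance = 0.05,
                               model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "harmonized_data"))
  n <- nrow(dataset)
  if (n < 2) stop2("sensitivity_report: at least 2 variants required")
  q_ivw <- cochran_q(dataset, "ivw")
  q_egger <- if (n >= 3) cochran_q(dataset, "egger") else NULL
  intercept <- if (n >= 3) egger_intercept_test(dataset) else NULL
  loo <- leave_one_out(dataset, model = model)
  presso <- if (n >= 4) {
    mr_presso(dataset, n_sim = n_sim, seed = seed,
              significance = significance, model = model)
  } else NULL
  structure(list(
    exposure = attr(dataset, "exposure_name"),
    outcome = attr(dataset, "outcome_name"),
    n_snps = n,
    q_ivw = q_ivw, q_egger = q_egger,
    egger_intercept = intercept,
    loo_table = loo,
    presso = presso
  ), class = "sensitivity_report")
}

#' Flatten a sensitivity report to a one-row summary table
#'
#' @param x A `sensitivity_report`.
#' @param ... Unused.
#' @return One-row data.frame mirroring the usual supplementary-table
#'   layout (Q statistics, intercept, global pleiotropy p, outlier count).
#' @export
as.data.frame.sensitivity_report <- function(x, ...) {
  data.frame(
    exposure = x$exposure, outcome = x$outcome, n_snps = x$n_snps,
    q_egger = x$q_egger$q %||% NA_real_,
    q_egger_p = x$q_egger$p %||% NA_real_,
    q_ivw = x$q_ivw$q, q_ivw_p = x$q_ivw$p,
    egger_intercept = x$egger_intercept$intercept %||% NA_real_,
    egger_intercept_p = x$egger_intercept$p %||% NA_real_,
    presso_global_p = if (is.null(x$presso)) NA_real_ else x$presso$global_p,
    n_outliers = if (is.null(x$presso)) NA_integer_
                 else length(x$presso$outliers),
    stringsAsFactors = FALSE
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report: ", x$exposure, " -> ", x$outcome,
      " (", x$n_snps, " variants)\n", sep = "")
  cat(sprintf("  Cochran Q (IVW):   Q = %.3f, df = %d, p = %.4g\n",
              x$q_ivw$q, x$q_ivw$df, x$q_ivw$p))
  if (!is.null(x$q_egger)) {
    cat(sprintf("  Cochran Q (Egger): Q = %.3f, df = %d, p = %.4g\n",
                x$q_egger$q, x$q_egger$df, x$q_egger$p))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  Egger intercept:   %.4f (se %.4f), p = %.4g\n",
                x$egger_intercept$intercept, x$egger_intercept$se,
                x$egger_intercept$p))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("  MR-PRESSO: global p = %.4g, %d outlier(s)\n",
                x$presso$global_p, length(x$presso$outliers)))
  }
  cat("  Leave-one-out exclusions outside full-data CI:",
      sum(x$loo_table$outside_ci), "\n")
  invisible(x)
}
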