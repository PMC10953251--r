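# Two-sample MR estimators. All operate on a harmonized_data object and
# return a one-row data.frame in a common layout so method results can be
# stacked into the estimate tables the reporting layer writes.

mr_estimate_row <- function(method, n_snps, beta, se, pvalue,
                            ci_low, ci_high,
                            egger_intercept = NA_real_,
                            egger_intercept_se = NA_real_,
                            egger_intercept_p = NA_real_,
                            computable = TRUE) {
  data.frame(method = method, n_snps = n_snps,
             beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
             or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high),
             egger_intercept = egger_intercept,
             egger_intercept_se = egger_intercept_se,
             egger_intercept_p = egger_intercept_p,
             computable = computable,
             stringsAsFactors = FALSE)
}

not_computable_row <- function(method, n_snps) {
  mr_estimate_row(method, n_snps, NA_real_, NA_real_, NA_real_,
                  NA_real_, NA_real_, computable = FALSE)
}

label_estimates <- function(df, dataset) {
  cbind(data.frame(exposure = attr(dataset, "exposure_name"),
                   outcome = attr(dataset, "outcome_name"),
                   stringsAsFactors = FALSE), df)
}

#' Per-variant Wald ratio estimates
#'
#' The ratio estimate for variant \eqn{j} is
#' \eqn{\theta_j = \beta_{Yj}/\beta_{Xj}} with first-order standard error
#' \eqn{se_{Yj}/|\beta_{Xj}|}. These ratios are the shared kernel of the
#' median- and mode-based estimators and of the heterogeneity statistics.
#'
#' @param dataset A `harmonized_data` object; all exposure betas must be
#'   nonzero.
#' @return data.frame with columns `snp_id`, `ratio`, `se`, in input order.
#' @export
ratio_estimates <- function(dataset) {
  stopifnot(inherits(dataset, "harmonized_data"))
  zero <- dataset$beta_exposure == 0
  if (any(zero)) {
    stop2("ratio_estimates: zero exposure beta for SNP(s): ",
          paste(dataset$snp_id[zero], collapse = ", "))
  }
  data.frame(snp_id = dataset$snp_id,
             ratio = dataset$beta_outcome / dataset$beta_exposure,
             se = dataset$se_outcome / abs(dataset$beta_exposure),
             stringsAsFactors = FALSE)
}

# Fixed-effect IVW slope and components, used by several diagnostics.
ivw_kernel <- function(bx, by, sey) {
  w <- 1 / sey^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  q <- sum(w * (by - beta * bx)^2)
  list(beta = beta, se_fixed = sqrt(1 / sxx), q = q, sxx = sxx)
}

#' Inverse-variance weighted causal estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin, weights \eqn{1/se_Y^2}. Under the default multiplicative
#' random-effects model the standard error is inflated by
#' \eqn{\sqrt{\max(1, Q/(n-1))}} where Q is Cochran's heterogeneity
#' statistic; the fixed-effect model uses the unscaled SE. P-values use
#' the normal approximation; the 95% CI is \eqn{\beta \pm 1.96\,se}.
#'
#' @param dataset A `harmonized_data` object.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return One-row estimate data.frame (beta, se, CI, p, OR columns).
#' @export
mr_ivw <- function(dataset, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "harmonized_data"))
  n <- nrow(dataset)
  min_n <- if (model == "fixed") 1L else 2L
  if (n < min_n) {
    stop2("mr_ivw: at least ", min_n, " variant(s) required for model '",
          model, "'")
  }
  k <- ivw_kernel(dataset$beta_exposure, dataset$beta_outcome,
                  dataset$se_outcome)
  se <- if (model == "fixed") {
    k$se_fixed
  } else {
    k$se_fixed * sqrt(max(1, k$q / (n - 1)))
  }
  p <- 2 * stats::pnorm(-abs(k$beta / se))
  label_estimates(
    mr_estimate_row("ivw", n, k$beta, se, p,
                    k$beta - 1.96 * se, k$beta + 1.96 * se),
    dataset)
}

# Weighted with-intercept regression of by on bx after orienting every
# variant to a non-negative exposure beta. Shared by mr_egger() and the
# intercept test.
egger_fit <- function(dataset) {
  n <- nrow(dataset)
  if (n < 3) stop2("MR-Egger requires at least 3 variants")
  flip <- ifelse(dataset$beta_exposure < 0, -1, 1)
  bx <- flip * dataset$beta_exposure
  by <- flip * dataset$beta_outcome
  w <- 1 / dataset$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # floor the multiplicative overdispersion scale at 1
  scale_div <- min(1, sm$sigma)
  co <- stats::coef(sm)
  list(
    n = n, df = n - 2,
    slope = co["bx", "Estimate"],
    slope_se = co["bx", "Std. Error"] / scale_div,
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = co["(Intercept)", "Std. Error"] / scale_div,
    residuals = stats::residuals(fit),
    weights = w
  )
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas *with* an
#' unconstrained intercept (weights \eqn{1/se_Y^2}), after orienting each
#' variant so its exposure beta is non-negative. The slope is the
#' pleiotropy-adjusted causal estimate; a nonzero intercept indicates
#' directional horizontal pleiotropy. Standard errors use multiplicative
#' residual scaling floored at 1, with t-distribution inference on
#' n - 2 degrees of freedom.
#'
#' @param dataset A `harmonized_data` object with at least 3 variants.
#' @return One-row estimate data.frame including intercept columns.
#' @export
mr_egger <- function(dataset) {
  stopifnot(inherits(dataset, "harmonized_data"))
  f <- egger_fit(dataset)
  tq <- stats::qt(0.975, f$df)
  p_slope <- 2 * stats::pt(-abs(f$slope / f$slope_se), f$df)
  p_int <- 2 * stats::pt(-abs(f$intercept / f$intercept_se), f$df)
  label_estimates(
    mr_estimate_row("egger", f$n, f$slope, f$slope_se, p_slope,
                    f$slope - tq * f$slope_se, f$slope + tq * f$slope_se,
                    egger_intercept = f$intercept,
                    egger_intercept_se = f$intercept_se,
                    egger_intercept_p = p_int),
    dataset)
}

# Interpolated weighted median of values b with weights w: cumulative
# weights are assigned at w_j/2 offsets (standard weighted-percentile
# convention) and the 50% point is linearly interpolated.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(b[1])
  m <- length(b)
  if (cw[m] <= 0.5) return(b[m])
  stats::approx(cw, b, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE shared by the median and mode estimators:
# resample each variant's betas from their normal sampling distributions,
# recompute the point estimate, take the SD across replicates.
bootstrap_se <- function(dataset, point_fun, n_boot, seed) {
  if (n_boot == 0) return(NA_real_)
  n <- nrow(dataset)
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, dataset$beta_exposure, dataset$se_exposure)
      by <- stats::rnorm(n, dataset$beta_outcome, dataset$se_outcome)
      point_fun(bx, by, dataset$se_outcome)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-variant Wald ratios with normalized
#' inverse-variance weights \eqn{1/se_j^2}; consistent when variants
#' carrying at least half of the weight are valid instruments. The
#' standard error comes from a seeded parametric bootstrap (betas
#' resampled from their sampling distributions).
#'
#' @param dataset A `harmonized_data` object with at least 3 variants.
#' @param n_boot Bootstrap replicates for the SE (default 1000); 0 skips
#'   the bootstrap and reports `NA` SE/p (point estimate only).
#' @param seed RNG seed for the bootstrap.
#' @return One-row estimate data.frame.
#' @export
mr_weighted_median <- function(dataset, n_boot = 1000, seed = 1) {
  stopifnot(inherits(dataset, "harmonized_data"))
  n <- nrow(dataset)
  if (n < 3) stop2("mr_weighted_median: at least 3 variants required")
  r <- ratio_estimates(dataset)
  point <- weighted_median_point(r$ratio, 1 / r$se^2)
  pf <- function(bx, by, sey) {
    weighted_median_point(by / bx, bx^2 / sey^2)
  }
  se <- bootstrap_se(dataset, pf, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(point / se))
  label_estimates(
    mr_estimate_row("weighted_median", n, point, se, p,
                    point - 1.96 * se, point + 1.96 * se),
    dataset)
}

# Mode of the weighted kernel density over ratios b with weights w.
# Bandwidth: modified Silverman rule on the ratios, scaled by `factor`.
mode_point <- function(b, w, factor, grid_n = 2000) {
  w <- w / sum(w)
  if (length(unique(b)) == 1) return(b[1])
  s <- stats::sd(b)
  m <- stats::mad(b)
  h <- factor * 0.9 * min(s, if (m > 0) m else s) * length(b)^(-1 / 5)
  if (!is.finite(h) || h <= 0) h <- factor * s * length(b)^(-1 / 5)
  grid <- seq(min(b) - h, max(b) + h, length.out = grid_n)
  dens <- as.vector(stats::dnorm(outer(grid, b, "-") / h) %*% w) / h
  grid[which.max(dens)]
}

#' Mode-based causal estimate (weighted or simple mode)
#'
#' The causal estimate is the argmax of a normal-kernel density over the
#' per-variant Wald ratios, evaluated on a fine grid; the weighted
#' variant uses normalized inverse-variance weights, the simple variant
#' uniform weights. The bandwidth is `bandwidth_factor` times a modified
#' Silverman rule (0.9 min(sd, mad) n^(-1/5)) on the ratios. Consistent
#' when the largest group of variants sharing a ratio are the valid ones.
#'
#' @param dataset A `harmonized_data` object with at least 3 variants.
#' @param weighted Use inverse-variance weights (`TRUE`, weighted mode)
#'   or uniform weights (`FALSE`, simple mode).
#' @param bandwidth_factor Multiplier on the Silverman bandwidth
#'   (default 1).
#' @param n_boot,seed Parametric-bootstrap settings as in
#'   [mr_weighted_median()].
#' @return One-row estimate data.frame.
#' @export
mr_mode <- function(dataset, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1) {
  stopifnot(inherits(dataset, "harmonized_data"))
  n <- nrow(dataset)
  if (n < 3) stop2("mr_mode: at least 3 variants required")
  r <- ratio_estimates(dataset)
  w <- if (weighted) 1 / r$se^2 else rep(1, n)
  point <- mode_point(r$ratio, w, bandwidth_factor)
  pf <- function(bx, by, sey) {
    rat <- by / bx
    wb <- if (weighted) bx^2 / sey^2 else rep(1, length(bx))
    mode_point(rat, wb, bandwidth_factor)
  }
  se <- bootstrap_se(dataset, pf, n_boot, seed)
  p <- if (is.na(se)) NA_real_ else 2 * stats::pnorm(-abs(point / se))
  label_estimates(
    mr_estimate_row(if (weighted) "weighted_mode" else "simple_mode",
                    n, point, se, p,
                    point - 1.96 * se, point + 1.96 * se),
    dataset)
}

#' Run the full panel of five MR estimators
#'
#' Computes IVW, MR-Egger, weighted median, weighted mode and simple mode
#' on one harmonized dataset, in that order. With only one or two
#' variants, only the fixed-effect IVW estimate is computable and the
#' remaining methods are returned as not-computable rows.
#'
#' @param dataset A `harmonized_data` object.
#' @param ivw_model IVW variant passed to [mr_ivw()].
#' @param n_boot,seed Bootstrap settings for the median/mode estimators.
#' @param bandwidth_factor Mode bandwidth multiplier.
#' @return data.frame with one row per method; `computable` marks rows
#'   whose method could run at this variant count.
#' @export
mr_estimate_all <- function(dataset,
                            ivw_model = c("multiplicative_random", "fixed"),
                            n_boot = 1000, seed = 1, bandwidth_factor = 1) {
  ivw_model <- match.arg(ivw_model)
  stopifnot(inherits(dataset, "harmonized_data"))
  n <- nrow(dataset)
  if (n == 0) stop2("mr_estimate_all: empty dataset")
  if (n < 3) {
    rows <- rbind(
      mr_ivw(dataset, model = "fixed")[, -(1:2)],
      not_computable_row("egger", n),
      not_computable_row("weighted_median", n),
      not_computable_row("weighted_mode", n),
      not_computable_row("simple_mode", n)
    )
    return(label_estimates(rows, dataset))
  }
  rows <- rbind(
    mr_ivw(dataset, model = ivw_model)[, -(1:2)],
    mr_egger(dataset)[, -(1:2)],
    mr_weighted_median(dataset, n_boot = n_boot, seed = seed)[, -(1:2)],
    mr_mode(dataset, weighted = TRUE, bandwidth_factor = bandwidth_factor,
            n_boot = n_boot, seed = seed)[, -(1:2)],
    mr_mode(dataset, weighted = FALSE, bandwidth_factor = bandwidth_factor,
            n_boot = n_boot, seed = seed)[, -(1:2)]
  )
  label_estimates(rows, dataset)
}
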