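#' Variance in a trait explained by one variant
#'
#' Computes the per-variant proportion of phenotypic variance explained,
#' \deqn{R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2 N f(1-f)\,SE^2},}
#' where \eqn{f} is the effect-allele frequency, \eqn{\beta} and \eqn{SE}
#' the per-allele effect and its standard error, and \eqn{N} the GWAS
#' sample size. Algebraically the frequency factor cancels
#' (\eqn{R^2 = \beta^2/(\beta^2 + N\,SE^2)}); the full form is computed as
#' written. Vectorized over all arguments.
#'
#' @param beta Per-allele effect estimate.
#' @param se Positive standard error of `beta`.
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param n GWAS sample size.
#' @return R-squared values in \[0, 1).
#' @export
variance_explained <- function(beta, se, eaf, n) {
  if (any(!is.finite(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stop2("variance_explained: eaf must be strictly inside (0,1)")
  }
  if (any(se <= 0)) stop2("variance_explained: se must be positive")
  if (any(n <= 0)) stop2("variance_explained: n must be positive")
  num <- 2 * beta^2 * eaf * (1 - eaf)
  num / (num + se^2 * 2 * n * eaf * (1 - eaf))
}

#' Instrument-strength F statistic
#'
#' \deqn{F = \frac{R^2 (N - k - 1)}{k (1 - R^2)}} for variance explained
#' \eqn{R^2}, sample size \eqn{N} and \eqn{k} instruments. An F of at
#' least 10 conventionally indicates low weak-instrument bias.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n Sample size; must exceed `k + 1`.
#' @param k Number of instruments (default 1, per-variant F).
#' @return Non-negative F statistics.
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0) || any(r2 >= 1)) {
    stop2("f_statistic: r2 must lie in [0,1)")
  }
  if (any(n <= k + 1)) stop2("f_statistic: n must exceed k + 1")
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Per-instrument strength table for a harmonized dataset
#'
#' Computes each retained variant's exposure R-squared and F statistic
#' (k = 1) and flags weak instruments (F < 10). The minimum and maximum F
#' across instruments — the range usually quoted in MR reports — are
#' attached as attributes. Optionally a pooled F over all instruments
#' (k = number of instruments, R-squared summed) is attached too.
#'
#' @param dataset A `harmonized_data` object with `eaf_exposure` present.
#' @param n Exposure GWAS sample size; a single value or per-row vector.
#'   Defaults to the dataset's `n_exposure` column.
#' @param pooled Also compute the pooled F statistic (default `FALSE`).
#' @return data.frame with columns `snp_id`, `r2`, `f_stat`, `weak_flag`,
#'   and attributes `f_min`, `f_max` (and `pooled_f` when requested).
#'   Rows with missing frequency or sample size get `NA` strength values.
#' @export
strength_table <- function(dataset, n = NULL, pooled = FALSE) {
  stopifnot(inherits(dataset, "harmonized_data"))
  if (nrow(dataset) == 0) stop2("strength_table: empty dataset")
  n <- n %||% dataset$n_exposure
  if (is.null(n) || all(is.na(n))) {
    stop2("strength_table: exposure sample size 'n' is required")
  }
  n <- rep_len(n, nrow(dataset))
  eaf <- dataset$eaf_exposure
  ok <- !is.na(eaf) & eaf > 0 & eaf < 1 & !is.na(n)
  r2 <- rep(NA_real_, nrow(dataset))
  f <- rep(NA_real_, nrow(dataset))
  if (any(ok)) {
    r2[ok] <- variance_explained(dataset$beta_exposure[ok],
                                 dataset$se_exposure[ok], eaf[ok], n[ok])
    f[ok] <- f_statistic(r2[ok], n[ok], k = 1)
  }
  if (any(!ok)) {
    warn2("strength_table: ", sum(!ok),
          " variant(s) missing eaf or n; strength reported as NA")
  }
  out <- data.frame(snp_id = dataset$snp_id, r2 = r2, f_stat = f,
                    weak_flag = !is.na(f) & f < 10,
                    stringsAsFactors = FALSE)
  attr(out, "f_min") <- if (any(ok)) min(f[ok]) else NA_real_
  attr(out, "f_max") <- if (any(ok)) max(f[ok]) else NA_real_
  if (pooled && any(ok)) {
    r2_tot <- sum(r2[ok])
    n_pool <- stats::median(n[ok])
    k_pool <- sum(ok)
    attr(out, "pooled_f") <- if (n_pool > k_pool + 1 && r2_tot < 1) {
      f_statistic(r2_tot, n_pool, k = k_pool)
    } else NA_real_
  }
  out
}
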