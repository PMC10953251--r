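# Multivariable MR and the two-step mediation decomposition.

#' Assemble a multivariable MR dataset
#'
#' Builds the joint instrument set for multivariable MR: instruments are
#' selected and clumped within each exposure, the union is taken, and
#' every table (all exposures and the outcome) is harmonized to the first
#' exposure's effect allele. Variants missing from any table — or lost to
#' allele incompatibility — are dropped with a logged count.
#'
#' @param exposure_tables Named list of two or more [trait_table()]
#'   objects; the first is the primary exposure.
#' @param outcome_table Outcome [trait_table()].
#' @param p_threshold Instrument p-value threshold(s); a single value or
#'   one per exposure (recycled by name when named).
#' @param r2_threshold,window_kb,ld_table Clumping settings, see
#'   [clump()].
#' @param palindrome_policy,palindrome_eaf_window See [harmonize()].
#' @return A data.frame of class `mvmr_data` with per-variant columns
#'   `beta_<exposure>` / `se_<exposure>` for every exposure plus
#'   `beta_outcome`, `se_outcome`; attributes `exposure_names`,
#'   `outcome_name`.
#' @export
build_mvmr_dataset <- function(exposure_tables, outcome_table,
                               p_threshold = 5e-8,
                               r2_threshold = 0.001, window_kb = 10000,
                               ld_table = NULL,
                               palindrome_policy = "infer_by_frequency",
                               palindrome_eaf_window = 0.08) {
  stopifnot(is.list(exposure_tables), length(exposure_tables) >= 2,
            inherits(outcome_table, "trait_table"))
  exp_names <- names(exposure_tables) %||%
    vapply(exposure_tables, attr, "", "trait_name")
  if (is.null(names(exposure_tables))) names(exposure_tables) <- exp_names

  thresholds <- if (length(p_threshold) == 1) {
    stats::setNames(rep(p_threshold, length(exp_names)), exp_names)
  } else if (!is.null(names(p_threshold))) {
    p_threshold[exp_names]
  } else {
    stats::setNames(rep_len(p_threshold, length(exp_names)), exp_names)
  }

  instruments <- unique(unlist(lapply(exp_names, function(nm) {
    sel <- select_instruments(exposure_tables[[nm]], thresholds[[nm]])
    if (nrow(sel) == 0) return(character(0))
    clump(sel, r2_threshold = r2_threshold, window_kb = window_kb,
          ld_table = ld_table)$snp_id
  })))
  if (length(instruments) == 0) {
    stop2("build_mvmr_dataset: no instruments selected for any exposure")
  }

  all_tables <- c(exposure_tables, list(.outcome = outcome_table))
  present <- Reduce(intersect, lapply(all_tables, function(t) t$snp_id))
  keep_ids <- instruments[instruments %in% present]
  n_dropped <- length(instruments) - length(keep_ids)
  if (n_dropped > 0) {
    message("build_mvmr_dataset: ", n_dropped,
            " instrument(s) missing from at least one table, dropped")
  }
  if (length(keep_ids) < 2) {
    stop2("build_mvmr_dataset: fewer than 2 instruments shared across ",
          "all tables")
  }

  ref <- exposure_tables[[1]]
  ref <- ref[match(keep_ids, ref$snp_id), , drop = FALSE]
  out <- data.frame(snp_id = ref$snp_id, stringsAsFactors = FALSE)
  out[[paste0("beta_", exp_names[1])]] <- ref$beta
  out[[paste0("se_", exp_names[1])]] <- ref$se
  drop_mask <- rep(FALSE, nrow(ref))
  for (nm in c(exp_names[-1], ".outcome")) {
    tab <- all_tables[[nm]]
    sub <- tab[match(keep_ids, tab$snp_id), , drop = FALSE]
    al <- align_to_reference(ref, sub, palindrome_policy,
                             palindrome_eaf_window)
    drop_mask <- drop_mask | startsWith(al$action, "dropped")
    label <- if (nm == ".outcome") "outcome" else nm
    out[[paste0("beta_", label)]] <- al$beta
    out[[paste0("se_", label)]] <- sub$se
  }
  if (any(drop_mask)) {
    message("build_mvmr_dataset: ", sum(drop_mask),
            " instrument(s) dropped during cross-table harmonization")
    out <- out[!drop_mask, , drop = FALSE]
  }
  if (nrow(out) < 2) {
    stop2("build_mvmr_dataset: fewer than 2 instruments after harmonization")
  }
  rownames(out) <- NULL
  structure(out,
            exposure_names = exp_names,
            outcome_name = attr(outcome_table, "trait_name"),
            class = c("mvmr_data", "data.frame"))
}

#' Multivariable IVW regression
#'
#' Weighted multiple least squares of the outcome betas on the matrix of
#' exposure betas, no intercept, weights \eqn{1/se_{outcome}^2}. Each
#' coefficient is the direct effect of that exposure conditional on the
#' others. Standard errors come from the weighted normal equations with
#' multiplicative residual scaling floored at 1; p-values use the normal
#' approximation. Exposures whose beta column is collinear with the
#' others receive `NA` coefficients with a warning; a hard error is
#' raised only when the first (primary) exposure is aliased.
#'
#' @param dataset An `mvmr_data` object with more rows than exposures.
#' @return data.frame with one row per exposure: beta, se, CI, p, OR
#'   columns and `n_snps`.
#' @export
mvmr_ivw <- function(dataset) {
  stopifnot(inherits(dataset, "mvmr_data"))
  exp_names <- attr(dataset, "exposure_names")
  p <- length(exp_names)
  n <- nrow(dataset)
  if (n <= p) {
    stop2("mvmr_ivw: need more variants (", n, ") than exposures (", p, ")")
  }
  first <- exp_names[1]
  labels <- c(first, exp_names[-1])
  X <- as.matrix(dataset[, paste0("beta_", labels), drop = FALSE])
  y <- dataset$beta_outcome
  w <- 1 / dataset$se_outcome^2
  fit <- stats::lm.wfit(x = X, y = y, w = w)
  coefs <- fit$coefficients
  aliased <- is.na(coefs)
  if (aliased[1]) {
    stop2("mvmr_ivw: primary exposure '", first,
          "' is collinear with the others")
  }
  if (any(aliased)) {
    warn2("mvmr_ivw: collinear exposure(s) dropped to NA: ",
          paste(labels[aliased], collapse = ", "))
  }
  used <- which(!aliased)
  Xu <- X[, used, drop = FALSE]
  XtWX <- crossprod(Xu * sqrt(w))
  xinv <- solve(XtWX)
  resid <- y - Xu %*% coefs[used]
  dfree <- n - length(used)
  sigma2 <- sum(w * resid^2) / dfree
  se <- rep(NA_real_, p)
  se[used] <- sqrt(diag(xinv)) * sqrt(max(1, sigma2))
  beta <- as.numeric(coefs)
  pv <- 2 * stats::pnorm(-abs(beta / se))
  data.frame(exposure = labels,
             outcome = attr(dataset, "outcome_name"),
             n_snps = n,
             beta = beta, se = se,
             ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
             pvalue = pv,
             or = exp(beta), or_low = exp(beta - 1.96 * se),
             or_high = exp(beta + 1.96 * se),
             stringsAsFactors = FALSE)
}

# Pull (beta, se) out of whatever estimate representation is passed in.
coef_of <- function(x) {
  if (is.data.frame(x)) {
    list(beta = x$beta[1], se = x$se[1])
  } else if (is.list(x) && all(c("beta", "se") %in% names(x))) {
    list(beta = x$beta, se = x$se)
  } else {
    stop2("expected an estimate data.frame or a list(beta, se)")
  }
}

#' Decompose a total causal effect into direct and indirect parts
#'
#' Given the total effect of exposure on outcome, the mediator-adjusted
#' direct effect, the exposure-to-mediator effect and the
#' (exposure-adjusted) mediator-to-outcome effect — all on the log-odds
#' scale — computes both forms of the indirect effect: the product of
#' coefficients \eqn{\beta_{XZ}\beta_{ZY}} (with delta-method standard
#' error \eqn{\sqrt{\beta_{XZ}^2 se_{ZY}^2 + \beta_{ZY}^2 se_{XZ}^2}})
#' and the difference \eqn{\beta_{XY} - \beta_{XY1}}. The proportion
#' mediated is product-indirect over total; it is reported as `NA`
#' (flagged non-interpretable) when the total and indirect effects have
#' opposite signs or the total is numerically zero.
#'
#' @param total Total-effect estimate (data.frame row or `list(beta, se)`).
#' @param direct Mediator-adjusted direct-effect estimate.
#' @param x_to_z Exposure-to-mediator estimate.
#' @param z_to_y Mediator-to-outcome (direct) estimate.
#' @return List of class `mediation_result`.
#' @export
mediation_decompose <- function(total, direct, x_to_z, z_to_y) {
  tt <- coef_of(total); dd <- coef_of(direct)
  xz <- coef_of(x_to_z); zy <- coef_of(z_to_y)
  indirect_product <- xz$beta * zy$beta
  indirect_product_se <- sqrt(xz$beta^2 * zy$se^2 + zy$beta^2 * xz$se^2)
  indirect_difference <- tt$beta - dd$beta
  interpretable <- abs(tt$beta) >= 1e-12 &&
    sign(tt$beta) == sign(indirect_product)
  proportion <- if (interpretable) indirect_product / tt$beta else NA_real_
  structure(list(
    total_effect = tt$beta, total_se = tt$se,
    direct_effect = dd$beta, direct_se = dd$se,
    exposure_to_mediator = xz$beta, exposure_to_mediator_se = xz$se,
    mediator_effect = zy$beta, mediator_effect_se = zy$se,
    indirect_product = indirect_product,
    indirect_product_se = indirect_product_se,
    indirect_difference = indirect_difference,
    proportion_mediated = proportion,
    proportion_interpretable = interpretable
  ), class = "mediation_result")
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(
    total_beta = x$total_effect, total_se = x$total_se,
    total_or = exp(x$total_effect),
    direct_beta = x$direct_effect, direct_se = x$direct_se,
    direct_or = exp(x$direct_effect),
    indirect_beta = x$indirect_product, indirect_se = x$indirect_product_se,
    indirect_difference = x$indirect_difference,
    proportion_mediated = x$proportion_mediated,
    stringsAsFactors = FALSE
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation decomposition (log-odds scale)\n")
  cat(sprintf("  total    %8.4f (se %.4f)  OR %.3f\n",
              x$total_effect, x$total_se, exp(x$total_effect)))
  cat(sprintf("  direct   %8.4f (se %.4f)  OR %.3f\n",
              x$direct_effect, x$direct_se, exp(x$direct_effect)))
  cat(sprintf("  indirect %8.4f (product, se %.4f); %8.4f (difference)\n",
              x$indirect_product, x$indirect_product_se,
              x$indirect_difference))
  if (x$proportion_interpretable) {
    cat(sprintf("  proportion mediated %.3f\n", x$proportion_mediated))
  } else {
    cat("  proportion mediated: not interpretable",
        "(opposite signs or null total)\n")
  }
  invisible(x)
}
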