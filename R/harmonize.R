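#' Select genome-wide significant instruments
#'
#' Filters a trait table to variants with association p-value strictly
#' below a threshold, preserving the original row order. Typical
#' thresholds are `5e-8` (genome-wide significance) or the relaxed
#' `5e-6` used when few variants reach the stricter cut.
#'
#' @param table A [trait_table()].
#' @param p_threshold Significance threshold in (0, 1).
#' @return A [trait_table()] restricted to significant variants (possibly
#'   zero rows, with a warning).
#' @export
select_instruments <- function(table, p_threshold) {
  stopifnot(inherits(table, "trait_table"))
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold >= 1) {
    stop2("select_instruments: p_threshold must be a single value in (0,1)")
  }
  keep <- !is.na(table$pvalue) & table$pvalue < p_threshold
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn2("select_instruments: no variants pass p < ", p_threshold,
          " for trait '", attr(table, "trait_name"), "'")
  }
  rownames(out) <- NULL
  structure(out, trait_name = attr(table, "trait_name"),
            trait_type = attr(table, "trait_type"),
            class = class(table))
}

#' Greedy LD clumping of candidate instruments
#'
#' Repeatedly takes the lowest-p unclaimed variant as an index SNP and
#' removes every unclaimed variant on the same chromosome within
#' `window_kb` of it whose pairwise r-squared with the index exceeds
#' `r2_threshold`. Without an LD table every within-window pair is treated
#' as correlated (r-squared 1), i.e. pure distance clumping; with a
#' supplied table, pairs absent from it are treated as independent
#' (r-squared 0). Ties on p-value are broken by (chromosome, position).
#'
#' @param table A [trait_table()] whose variants carry `chrom` and `pos`.
#' @param r2_threshold LD r-squared cutoff (default 0.001).
#' @param window_kb Window around each index SNP, in kilobases
#'   (default 10000, i.e. 10 Mb).
#' @param ld_table Optional data.frame with columns `snp_a`, `snp_b`, `r2`
#'   (symmetric lookup), or a path to such a TSV.
#' @return A [trait_table()] of index SNPs sorted by chromosome, position.
#' @export
clump <- function(table, r2_threshold = 0.001, window_kb = 10000,
                  ld_table = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (nrow(table) == 0) return(table)
  if (any(is.na(table$chrom)) || any(is.na(table$pos))) {
    stop2("clump: all variants must carry chrom and pos")
  }
  if (is.character(ld_table)) {
    ld_table <- utils::read.table(ld_table, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  ld_lookup <- NULL
  if (!is.null(ld_table)) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld_table)))
    ld_lookup <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(ld_table))) {
      a <- ld_table$snp_a[i]; b <- ld_table$snp_b[i]
      assign(paste(a, b, sep = "\r"), ld_table$r2[i], envir = ld_lookup)
      assign(paste(b, a, sep = "\r"), ld_table$r2[i], envir = ld_lookup)
    }
  }
  pair_r2 <- function(a, b) {
    if (is.null(ld_lookup)) return(1.0)
    key <- paste(a, b, sep = "\r")
    if (exists(key, envir = ld_lookup, inherits = FALSE)) {
      get(key, envir = ld_lookup)
    } else 0.0
  }

  key <- chrom_order_key(table$chrom)
  ord <- order(table$pvalue, is.na(key), key, table$chrom, table$pos)
  claimed <- rep(FALSE, nrow(table))
  index <- logical(nrow(table))
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (claimed[i]) next
    index[i] <- TRUE
    claimed[i] <- TRUE
    near <- !claimed &
      table$chrom == table$chrom[i] &
      abs(table$pos - table$pos[i]) <= window_bp
    for (j in which(near)) {
      if (pair_r2(table$snp_id[i], table$snp_id[j]) > r2_threshold) {
        claimed[j] <- TRUE
      }
    }
  }
  out <- table[index, , drop = FALSE]
  key_out <- chrom_order_key(out$chrom)
  out <- out[order(is.na(key_out), key_out, out$chrom, out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_name = attr(table, "trait_name"),
            trait_type = attr(table, "trait_type"),
            class = class(table))
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic_pair <- function(a1, a2) ALLELE_COMPLEMENT[a1] == a2

# Align one table's rows (already subset and ordered to match `ref`) to the
# reference effect/other alleles. Returns per-row action and the aligned
# beta/eaf. Shared kernel of harmonize() and the MVMR assembly.
align_to_reference <- function(ref, other, palindrome_policy,
                               palindrome_eaf_window) {
  n <- nrow(ref)
  action <- character(n)
  beta <- other$beta
  eaf <- other$eaf
  for (i in seq_len(n)) {
    e1 <- ref$effect_allele[i]; e2 <- ref$other_allele[i]
    o1 <- other$effect_allele[i]; o2 <- other$other_allele[i]
    if (is_palindromic_pair(e1, e2)) {
      # Palindromic variant: letters cannot resolve the strand.
      if (!setequal(c(o1, o2), c(e1, e2))) {
        action[i] <- "dropped_incompatible"
        next
      }
      if (identical(palindrome_policy, "drop")) {
        action[i] <- "dropped_palindromic"
        next
      }
      # infer_by_frequency: align letters first, then use minor-allele
      # agreement; ambiguous frequencies near 0.5 are dropped.
      b <- beta[i]; f <- eaf[i]
      flipped_letters <- FALSE
      if (o1 != e1) { # same pair, swapped roles
        b <- -b
        f <- if (is.na(f)) NA_real_ else 1 - f
        flipped_letters <- TRUE
      }
      fe <- ref$eaf[i]
      if (is.na(fe) || is.na(f) ||
          abs(fe - 0.5) < palindrome_eaf_window ||
          abs(f - 0.5) < palindrome_eaf_window) {
        action[i] <- "dropped_palindromic"
        next
      }
      if ((fe < 0.5) != (f < 0.5)) {
        # Discordant minor alleles: the other study reports the opposite
        # strand, which for a palindrome swaps effect and other allele.
        b <- -b
        f <- 1 - f
        flipped_letters <- !flipped_letters
      }
      beta[i] <- b
      eaf[i] <- f
      action[i] <- if (flipped_letters) "flipped" else "kept"
      next
    }
    # Non-palindromic: try direct, swapped, and strand-complemented matches.
    c1 <- unname(ALLELE_COMPLEMENT[o1]); c2 <- unname(ALLELE_COMPLEMENT[o2])
    if (o1 == e1 && o2 == e2) {
      action[i] <- "kept"
    } else if (o1 == e2 && o2 == e1) {
      beta[i] <- -beta[i]
      eaf[i] <- if (is.na(eaf[i])) NA_real_ else 1 - eaf[i]
      action[i] <- "flipped"
    } else if (c1 == e1 && c2 == e2) {
      action[i] <- "kept" # opposite strand, same orientation
    } else if (c1 == e2 && c2 == e1) {
      beta[i] <- -beta[i]
      eaf[i] <- if (is.na(eaf[i])) NA_real_ else 1 - eaf[i]
      action[i] <- "flipped"
    } else {
      action[i] <- "dropped_incompatible"
    }
  }
  list(action = action, beta = beta, eaf = eaf)
}

#' Harmonize exposure and outcome tables to a common effect allele
#'
#' For every variant shared between the two tables, the outcome
#' association is re-expressed relative to the exposure's effect allele:
#' swapped allele roles flip the outcome beta's sign (and reflect its
#' frequency), opposite-strand reports are complemented first, and
#' palindromic variants (A/T, C/G) are either dropped or resolved by
#' minor-allele frequency agreement. Incompatible allele pairs are
#' dropped. Only retained variants appear in the result; dropped ones are
#' recorded in the `"dropped"` attribute.
#'
#' @param exposure,outcome [trait_table()] objects keyed by `snp_id`.
#' @param palindrome_policy `"infer_by_frequency"` (default) resolves
#'   palindromic variants whose frequencies are informative;
#'   `"drop"` always discards them.
#' @param palindrome_eaf_window Half-width around 0.5 inside which a
#'   frequency is considered uninformative (default 0.08).
#'
#' @return A data.frame of class `harmonized_data`: one row per retained
#'   variant with `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, frequencies, sample sizes and the per-row
#'   `action` (`kept` or `flipped`). Attributes: `exposure_name`,
#'   `outcome_name`, `dropped` (data.frame of excluded variants and why).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_frequency", "drop"),
                      palindrome_eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "trait_table"), inherits(outcome, "trait_table"))
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0) {
    stop2("harmonize: no shared variants between '",
          attr(exposure, "trait_name"), "' and '",
          attr(outcome, "trait_name"), "'")
  }
  exp_df <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  out_df <- outcome[match(shared, outcome$snp_id), , drop = FALSE]
  # preserve exposure-table order among shared SNPs
  ord <- order(match(exp_df$snp_id, exposure$snp_id))
  exp_df <- exp_df[ord, , drop = FALSE]
  out_df <- out_df[ord, , drop = FALSE]

  al <- align_to_reference(exp_df, out_df, palindrome_policy,
                           palindrome_eaf_window)
  keep <- !startsWith(al$action, "dropped")
  res <- data.frame(
    snp_id = exp_df$snp_id,
    chrom = exp_df$chrom,
    pos = exp_df$pos,
    effect_allele = exp_df$effect_allele,
    other_allele = exp_df$other_allele,
    beta_exposure = exp_df$beta,
    se_exposure = exp_df$se,
    eaf_exposure = exp_df$eaf,
    pvalue_exposure = exp_df$pvalue,
    n_exposure = exp_df$n,
    beta_outcome = al$beta,
    se_outcome = out_df$se,
    eaf_outcome = al$eaf,
    n_outcome = out_df$n,
    action = al$action,
    stringsAsFactors = FALSE
  )
  dropped <- res[!keep, c("snp_id", "action"), drop = FALSE]
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  rownames(dropped) <- NULL
  if (nrow(res) == 0) {
    warn2("harmonize: every shared variant was dropped")
  }
  harmonized_data(res,
                  exposure_name = attr(exposure, "trait_name"),
                  outcome_name = attr(outcome, "trait_name"),
                  dropped = dropped)
}

#' Construct a harmonized exposure-outcome dataset directly
#'
#' Low-level constructor used by [harmonize()] and useful for building
#' datasets in simulations or tests. Rows must already share one effect
#' allele across both studies.
#'
#' @param df data.frame with at least `snp_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param exposure_name,outcome_name Trait labels.
#' @param dropped Optional data.frame of excluded variants.
#' @return A `harmonized_data` object.
#' @export
harmonized_data <- function(df, exposure_name, outcome_name,
                            dropped = NULL) {
  needed <- c("snp_id", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop2("harmonized_data: missing column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  if (any(df$se_exposure <= 0, na.rm = TRUE) ||
      any(df$se_outcome <= 0, na.rm = TRUE)) {
    stop2("harmonized_data: standard errors must be positive")
  }
  if ("action" %in% names(df) && any(startsWith(df$action, "dropped"))) {
    stop2("harmonized_data: retained rows cannot carry a dropped action")
  }
  if (!"action" %in% names(df)) df$action <- rep("kept", nrow(df))
  structure(df,
            exposure_name = as.character(exposure_name),
            outcome_name = as.character(outcome_name),
            dropped = dropped %||%
              data.frame(snp_id = character(), action = character(),
                         stringsAsFactors = FALSE),
            class = c("harmonized_data", "data.frame"))
}

#' @export
print.harmonized_data <- function(x, ...) {
  cat("Harmonized dataset: ", attr(x, "exposure_name"), " -> ",
      attr(x, "outcome_name"), ", ", nrow(x), " variants (",
      nrow(attr(x, "dropped")), " dropped)\n", sep = "")
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
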