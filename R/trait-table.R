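#' Construct a trait table of per-variant GWAS associations
#'
#' A trait table holds one row per variant for a single GWAS trait:
#' identifiers, alleles, effect-allele frequency, effect estimate, standard
#' error, p-value and sample size. It is the common currency of all
#' instrument-selection and harmonization steps.
#'
#' @param df data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and optionally `chrom`, `pos`, `eaf`,
#'   `pvalue`, `n`. Missing optional columns are added as `NA`.
#' @param trait_name Character label for the trait.
#' @param trait_type `"binary"` (betas on the log-odds scale) or
#'   `"continuous"` (SD units).
#' @param validate Run invariant checks and row filtering (default `TRUE`).
#'
#' @return A data.frame of class `trait_table` with attributes
#'   `trait_name` and `trait_type`.
#' @export
trait_table <- function(df, trait_name, trait_type = c("binary", "continuous"),
                        validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(df))
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0) {
    stop2("trait_table: missing mandatory column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  optional <- c("chrom", "pos", "eaf", "pvalue", "n")
  for (col in setdiff(optional, names(df))) df[[col]] <- NA
  df <- df[, c(mandatory[1], "chrom", "pos", mandatory[2:3],
               "eaf", "beta", "se", "pvalue", "n")]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- suppressWarnings(as.numeric(df$pos))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$n <- suppressWarnings(as.numeric(df$n))

  if (validate) df <- validate_trait_rows(df, trait_name)
  rownames(df) <- NULL
  structure(df,
            trait_name = as.character(trait_name),
            trait_type = trait_type,
            class = c("trait_table", "data.frame"))
}

# Row-level policy checks: drop unusable rows (with a message), warn on
# p-values inconsistent with beta/se.
validate_trait_rows <- function(df, trait_name) {
  n0 <- nrow(df)
  if (n0 == 0) stop2("trait_table: no data rows for trait '", trait_name, "'")
  if (anyDuplicated(df$snp_id)) {
    stop2("trait_table: duplicated snp_id in trait '", trait_name, "'")
  }

  bad_num <- is.na(df$beta) | is.na(df$se) | df$se <= 0
  valid_allele <- df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T") &
    df$effect_allele != df$other_allele
  bad_eaf <- !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)
  drop <- bad_num | !valid_allele | bad_eaf
  if (any(drop)) {
    message(sum(drop), " of ", n0, " rows dropped for trait '", trait_name,
            "' (unparseable beta/se: ", sum(bad_num),
            ", non-SNV or invalid alleles: ", sum(!valid_allele),
            ", eaf outside [0,1]: ", sum(bad_eaf), ")")
    df <- df[!drop, , drop = FALSE]
  }
  if (nrow(df) == 0) stop2("trait_table: all rows invalid for trait '",
                           trait_name, "'")

  ok_p <- !is.na(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1
  if (any(ok_p)) {
    z_obs <- abs(df$beta[ok_p] / df$se[ok_p])
    z_p <- stats::qnorm(df$pvalue[ok_p] / 2, lower.tail = FALSE)
    comparable <- is.finite(z_p) & z_obs > 0
    ratio <- z_p[comparable] / z_obs[comparable]
    inconsistent <- sum(ratio > 2 | ratio < 0.5)
    if (inconsistent > 0) {
      warn2(inconsistent, " row(s) in trait '", trait_name,
            "' have a p-value inconsistent with |beta/se| by more than a ",
            "factor of 2 (normal approximation)")
    }
  }
  df
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table: ", attr(x, "trait_name"),
      " (", attr(x, "trait_type"), "), ",
      nrow(x), " variants\n", sep = "")
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Read a GWAS summary-statistic table from delimited text
#'
#' Reads a headered TSV (or CSV, auto-detected from the `.csv` extension)
#' of per-variant associations. Column names in the source file are mapped
#' onto the standard fields via `column_map`. Rows with unparseable
#' beta/se, non-SNV alleles (indels, `D`/`I` codes) or out-of-range
#' frequencies are dropped with a logged count; allele letters are
#' upper-cased.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping standard field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to source column names. Fields absent
#'   from the map are looked up under their standard name.
#' @param trait_name Label for the trait.
#' @param trait_type `"binary"` or `"continuous"`.
#'
#' @return A [trait_table()].
#' @export
read_summary_table <- function(path, column_map = NULL, trait_name,
                               trait_type = c("binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop2("read_summary_table: file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character",
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0) stop2("read_summary_table: empty file: ", path)

  std <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pvalue", "n")
  map <- stats::setNames(std, std)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), std)
    if (length(bad) > 0) {
      stop2("read_summary_table: unknown standard field(s) in column_map: ",
            paste(bad, collapse = ", "))
    }
    map[names(column_map)] <- unname(column_map)
  }
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  for (field in mandatory) {
    if (!map[[field]] %in% names(raw)) {
      stop2("read_summary_table: mandatory column '", map[[field]],
            "' (field '", field, "') not found in ", path)
    }
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in std) {
    src <- map[[field]]
    df[[field]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  trait_table(df, trait_name = trait_name, trait_type = trait_type)
}

#' Write result tables and a JSON run manifest
#'
#' Each table is written as a TSV (fixed column order, full numeric
#' precision, scientific notation for magnitudes below `1e-4`); a
#' `manifest.json` records filenames, row counts and a hash of the run
#' configuration.
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional list describing the run; hashed into the manifest.
#'
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, out_dir, config = list()) {
  stopifnot(is.list(tables))
  if (length(tables) > 0 && is.null(names(tables))) {
    stop2("write_results: tables must be named")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2) != 0) {
    stop2("write_results: output directory not writable: ", out_dir)
  }
  files <- data.frame(name = character(), file = character(),
                      row_count = integer(), stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    fname <- paste0(nm, ".tsv")
    write_tsv_table(tab, file.path(out_dir, fname))
    files <- rbind(files, data.frame(name = nm, file = fname,
                                     row_count = nrow(tab),
                                     stringsAsFactors = FALSE))
  }
  manifest <- list(files = files, config_hash = config_hash(config),
                   n_tables = length(tables))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_tsv_table <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- format_numeric(out[[col]])
    } else {
      v <- as.character(out[[col]])
      v[is.na(v)] <- "NA"
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
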