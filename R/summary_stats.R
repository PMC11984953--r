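# Two-context GWAS summary-statistic tables: validation and TSV round trip.

SUMMARY_REQUIRED <- c("variant_id", "beta_a", "se_a", "beta_b", "se_b")
SUMMARY_OPTIONAL <- c("pval_a", "block_id")

# Validates a summary-stat data.frame; errors cite the offending row/column.
validate_summary_records <- function(records) {
  if (!is.data.frame(records)) gxe_stop("summary statistics must be a data.frame")
  miss <- setdiff(SUMMARY_REQUIRED, names(records))
  if (length(miss)) {
    gxe_stop(sprintf("missing required column(s): %s",
                     paste(miss, collapse = ", ")), "gxe_bad_table")
  }
  num_cols <- intersect(c("beta_a", "se_a", "beta_b", "se_b", SUMMARY_OPTIONAL),
                        names(records))
  for (col in num_cols) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      gxe_stop(sprintf("column %s is not numeric (first bad row: %s)",
                       col, ifelse(is.na(bad), "?", bad)), "gxe_bad_table")
    }
  }
  for (col in c("se_a", "se_b")) {
    bad <- which(!is.na(records[[col]]) & records[[col]] <= 0)
    if (length(bad)) {
      gxe_stop(sprintf("non-positive %s on row %d", col, bad[1L]),
               "gxe_bad_table")
    }
  }
  if ("pval_a" %in% names(records)) {
    p <- records$pval_a
    bad <- which(!is.na(p) & (p <= 0 | p > 1))
    if (length(bad)) {
      gxe_stop(sprintf("pval_a outside (0, 1] on row %d", bad[1L]),
               "gxe_bad_table")
    }
  }
  invisible(records)
}

#' Read a two-context GWAS summary-statistic table
#'
#' Reads a tab-separated file with header columns `variant_id`, `beta_a`,
#' `se_a`, `beta_b`, `se_b` and optionally `pval_a` (focal-context p-value)
#' and `block_id` (integer LD-block label). Types and standard-error
#' positivity are validated; errors name the offending row and column.
#'
#' @param path Path to the TSV file.
#' @return A validated `data.frame` of summary-statistic records.
#' @seealso [write_summary_table()], [classify_loci()]
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) gxe_stop(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  df$variant_id <- as.character(df$variant_id)
  validate_summary_records(df)
}

#' Write a two-context GWAS summary-statistic table
#'
#' Serialises a summary-statistic `data.frame` as TSV with 15 significant
#' digits, so that a write/read round trip preserves values to better than
#' 1e-12 relative error.
#'
#' @param records A `data.frame` as accepted by [read_summary_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(records, path) {
  validate_summary_records(records)
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && col != "block_id") {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
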