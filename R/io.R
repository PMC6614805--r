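#' Schema-checked TSV read/write
#'
#' The package's single tabular dialect: tab-delimited, UTF-8, `.` decimal
#' point, with a header row. `write_table_tsv()` rounds numeric columns to
#' 6 significant digits so written files round-trip stably;
#' `read_table_tsv()` verifies that all required columns are present
#' (extra columns pass through untouched) and errors with the expected
#' schema otherwise.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param digits significant digits for numeric columns.
#' @return `write_table_tsv()` returns `path` invisibly;
#'   `read_table_tsv()` returns a data.frame.
#' @export
write_table_tsv <- function(df, path, digits = 6L) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_tsv
#' @param schema character vector of required column names (`NULL` skips
#'   the check).
#' @export
read_table_tsv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    missing <- setdiff(schema, names(df))
    if (length(missing))
      stop(sprintf("missing column(s) %s; expected schema: %s",
                   paste(missing, collapse = ", "),
                   paste(schema, collapse = ", ")))
  }
  df
}

#' Write or read a pool-counts table
#'
#' TSV with columns `sequence`, `reads`, `fraction`, `rpm`, `rank` (floats
#' at 6 significant digits).
#'
#' @param pool a [count_pool()] result.
#' @param path file path.
#' @return `write_pool_counts()`: `path` invisibly; `read_pool_counts()`:
#'   a `pool_counts` object.
#' @export
write_pool_counts <- function(pool, path) {
  stopifnot(inherits(pool, "pool_counts"))
  write_table_tsv(pool$entries[, c("sequence", "reads", "fraction", "rpm", "rank")],
                  path)
}

#' @rdname write_pool_counts
#' @param pool_id pool label for the reconstructed object.
#' @export
read_pool_counts <- function(path, pool_id = basename(path)) {
  df <- read_table_tsv(path, schema = c("sequence", "reads", "fraction",
                                        "rpm", "rank"))
  structure(
    list(pool_id = pool_id, total_reads = sum(df$reads),
         random_length = unique(nchar(df$sequence))[1L], entries = df),
    class = "pool_counts"
  )
}

#' Write a family trajectory table
#'
#' TSV with columns `round_id`, `family_fraction`, `median_fraction`.
#'
#' @param trajectory an [enrichment_trajectory()] result.
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "family_trajectory"))
  write_table_tsv(as.data.frame(trajectory), path)
}
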