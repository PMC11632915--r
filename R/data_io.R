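# Training-table I/O and the curation filters applied before fitting.

training_columns <- c("cell_line", "let_d", "alpha_x", "beta_x",
                      "alpha_c", "beta_c", "photon_source_kvp")

new_training_dataset <- function(df, filter_log = NULL) {
  df$record_id <- seq_len(nrow(df))
  structure(df, filter_log = filter_log,
            class = c("cirbe_dataset", "data.frame"))
}

#' Read a training table from CSV
#'
#' One row per cell-line/LET combination. Required columns: `cell_line`
#' (identifier), `let_d` \[keV um^-1\], photon LQM `alpha_x` \[Gy^-1\] and
#' `beta_x` \[Gy^-2\], carbon-ion LQM `alpha_c` and `beta_c`, and
#' `photon_source_kvp`, the reference photon source energy on a
#' kVp-equivalent scale (megavoltage sources are recorded as 1000 x MV so
#' the "at least 200 kVp" curation rule is a single numeric threshold).
#' An optional `source` provenance column is carried through.
#'
#' @param path CSV path (UTF-8, header required).
#' @return A `cirbe_dataset` data.frame (unfiltered; `beta_c` may still be
#'   negative at this stage).
#' @export
read_training_csv <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(training_columns, names(df))
  if (length(missing_cols)) {
    schema_error(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  num_cols <- setdiff(training_columns, "cell_line")
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        schema_error(sprintf(
          "column '%s' is not numeric at data row(s) %s (file line %s)",
          col, paste(bad, collapse = ", "),
          paste(bad + 1L, collapse = ", ")))
      }
      df[[col]] <- vn
    }
    if (anyNA(df[[col]])) {
      schema_error(sprintf("column '%s' contains missing values at row(s) %s",
                           col, paste(which(is.na(df[[col]])), collapse = ", ")))
    }
  }
  if (any(df$let_d <= 0)) schema_error("'let_d' must be positive")
  if (any(df$alpha_x < 0) || any(df$beta_x < 0)) {
    schema_error("photon LQM parameters must be non-negative")
  }
  if (any(df$alpha_x == 0 & df$beta_x == 0)) {
    schema_error("degenerate photon curve (alpha_x = beta_x = 0)")
  }
  new_training_dataset(df)
}

#' Write a training table to CSV
#'
#' Full double precision is written so that a write/read round trip is
#' lossless well beyond 12 significant digits.
#'
#' @param dataset A `cirbe_dataset` (or compatible data.frame).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_training_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df$record_id <- NULL
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the training-data curation filters
#'
#' Removes, in order: (1) records whose reference photon source is below
#' 200 kVp-equivalent, so that low-energy x-ray sources with RBE > 1
#' relative to megavoltage references do not distort the trends;
#' (2) records with LET_d above 350 keV um^-1, beyond the clinically
#' relevant range and where dosimetric uncertainty is large; (3) records
#' with negative reported beta_C, which make endpoint doses complex.
#' Boundary conventions: exactly 200 kVp, exactly 350 keV um^-1, and
#' beta_C = 0 are all retained. A record removed by an earlier rule is
#' not re-counted by a later one. Filtering is idempotent.
#'
#' @param dataset A `cirbe_dataset`.
#' @return The filtered dataset; `attr(., "filter_log")` counts removals
#'   per rule.
#' @export
apply_curation_filters <- function(dataset) {
  df <- as.data.frame(dataset)
  r1 <- df$photon_source_kvp < 200
  r2 <- !r1 & df$let_d > 350
  r3 <- !r1 & !r2 & df$beta_c < 0
  log <- list(photon_source_below_200kvp = sum(r1),
              let_above_350 = sum(r2),
              negative_beta_c = sum(r3),
              retained = sum(!(r1 | r2 | r3)))
  out <- df[!(r1 | r2 | r3), , drop = FALSE]
  rownames(out) <- NULL
  out$record_id <- NULL
  new_training_dataset(out, filter_log = log)
}

#' @export
print.cirbe_dataset <- function(x, ...) {
  log <- attr(x, "filter_log")
  cat(sprintf("training dataset: %d record(s), %d cell line(s)\n",
              nrow(x), length(unique(x$cell_line))))
  if (!is.null(log)) {
    cat(sprintf("  filtered: %d photon-source, %d high-LET, %d negative-beta removed\n",
                log$photon_source_below_200kvp, log$let_above_350,
                log$negative_beta_c))
  }
  NextMethod()
}

#' Write a filter log to JSON
#'
#' @param dataset A filtered `cirbe_dataset`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_filter_log <- function(dataset, path) {
  log <- attr(dataset, "filter_log")
  if (is.null(log)) usage_error("dataset has no filter log; run apply_curation_filters()")
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
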