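# Raven-style selection tables: tab-separated, one header line, with the
# conventional column names ("Begin Time (s)", "Low Freq (Hz)", ...). The
# reader maps them onto the package's snake_case fields and keeps any other
# columns verbatim so a round trip is lossless.

.raven_map <- c(
  "Selection" = "selection",
  "Begin Time (s)" = "begin_s",
  "End Time (s)" = "end_s",
  "Low Freq (Hz)" = "low_hz",
  "High Freq (Hz)" = "high_hz",
  "Class" = "class")

#' Read a Raven-style selection table
#'
#' @param path tab-separated selection table with a header line. CRLF line
#'   endings are accepted.
#' @return data.frame with `selection`, `begin_s`, `end_s`, `low_hz`,
#'   `high_hz` and, when present, `class`; unknown columns are preserved
#'   under syntactic names with the original header stored in an attribute.
#' @export
read_selection_table <- function(path) {
  .check(file.exists(path), "no such file: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .check(ncol(df) >= 2, "malformed selection table header in %s", path)
  orig <- names(df)
  known <- .raven_map[orig]
  names(df) <- ifelse(is.na(known), make.names(orig), known)
  for (col in c("begin_s", "end_s", "low_hz", "high_hz")) {
    if (col %in% names(df)) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      .check(!anyNA(v) || all(is.na(df[[col]])),
             "non-numeric values in column mapped to %s", col)
      df[[col]] <- v
    }
  }
  if (all(c("begin_s", "end_s") %in% names(df)) && nrow(df) > 0) {
    .check(all(df$begin_s < df$end_s), "selection with begin_s >= end_s")
  }
  attr(df, "original_names") <- orig
  df
}

#' Write a Raven-style selection table
#'
#' @param records data.frame with at least `begin_s`, `end_s`, `low_hz`,
#'   `high_hz`; a `selection` column is added when absent. Extra columns are
#'   written after the standard ones under their own names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(records, path) {
  .check(all(c("begin_s", "end_s", "low_hz", "high_hz") %in% names(records)),
         "records must have begin_s, end_s, low_hz, high_hz")
  if (!"selection" %in% names(records)) {
    records$selection <- seq_len(nrow(records))
  }
  inv <- stats::setNames(names(.raven_map), .raven_map)
  std <- c("selection", "begin_s", "end_s", "low_hz", "high_hz",
           intersect("class", names(records)))
  extra <- setdiff(names(records), std)
  out <- records[, c(std, extra), drop = FALSE]
  names(out) <- ifelse(names(out) %in% names(inv), inv[names(out)], names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
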