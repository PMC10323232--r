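#' Read / write event tables as CSV
#'
#' The CSV schema is `x,y,t,class,probability` with a mandatory header;
#' round trips are lossless. Unknown class strings are a format error naming
#' the offending row.
#'
#' @param path CSV file.
#' @param events an [event_set()].
#' @return `read_events_csv` returns an `epi_events`; `write_events_csv`
#'   returns `path` invisibly.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "t", "class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_format("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    bad <- which(!df$class %in% EVENT_CLASSES)
    if (length(bad) > 0)
      stop_format("unknown class '", df$class[bad[1]], "' in row ", bad[1])
  }
  as_event_set(df)
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  df <- as.data.frame(events)[c("x", "y", "t", "class", "probability")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
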