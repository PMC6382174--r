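# Time-series file interchange: delimited text, one row per time point, one
# column per channel, optional single header row of channel labels.

#' Read / write a multichannel time series as delimited text
#'
#' Comma- or tab-delimited text with one row per time point and one column
#' per channel; an optional single header row carries channel labels.
#'
#' @param path File path.
#' @param ts Numeric time-series matrix.
#' @param delim Field delimiter (`","` or `"\t"`); guessed from the first
#'   line when reading.
#' @param header Whether the file has (or should be written with) a header
#'   row of channel labels.
#' @return `read_timeseries` returns a numeric matrix (channel labels as
#'   column names when present); `write_timeseries` returns `path`
#'   invisibly.
#' @export
read_timeseries <- function(path, delim = NULL, header = NULL) {
  first <- readr::read_lines(path, n_max = 1)
  if (is.null(delim)) {
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  if (is.null(header)) {
    fields <- strsplit(first, delim, fixed = TRUE)[[1]]
    header <- anyNA(suppressWarnings(as.numeric(fields)))
  }
  df <- readr::read_delim(path, delim = delim, col_names = header,
                          col_types = readr::cols(.default = readr::col_double()),
                          show_col_types = FALSE)
  m <- as.matrix(df)
  if (!header) colnames(m) <- NULL
  check_finite_matrix(m, "time series")
  m
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, path, delim = ",", header = !is.null(colnames(ts))) {
  ts <- as.matrix(ts)
  check_finite_matrix(ts, "ts")
  df <- tibble::as_tibble(ts, .name_repair = "minimal")
  if (!header) {
    readr::write_delim(df, path, delim = delim, col_names = FALSE)
  } else {
    if (is.null(colnames(ts))) colnames(df) <- paste0("ch", seq_len(ncol(ts)))
    readr::write_delim(df, path, delim = delim, col_names = TRUE)
  }
  invisible(path)
}
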