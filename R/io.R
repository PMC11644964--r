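# CSV I/O for two-column glucose traces ("Time,BGL" dialect).

#' Read a CGM series from CSV
#'
#' Reads a two-column CSV (timestamp, glucose in mmol/L). The header row
#' (`Time,BGL`) is optional. Timestamps default to the unpadded
#' month/day/year 24-hour dialect common in CGM exports, e.g.
#' `11/2/2020 20:23`. Out-of-order rows are re-sorted with a warning that
#' reports how many rows were out of place; duplicate timestamps are an
#' error (silent aggregation would hide sensor faults).
#'
#' @param path path to the CSV file.
#' @param timestamp_format `strptime` format for the first column
#'   (default `"%m/%d/%Y %H:%M"`; seconds variants are tried automatically
#'   when the format fails for every row).
#' @param tz time zone for parsed timestamps (default `"UTC"`).
#' @return A validated [cgm_series()] tibble.
#' @examples
#' s <- read_cgm_csv(system.file("extdata", "cgm_sample.csv", package = "glucast"))
#' nrow(s)
#' @export
read_cgm_csv <- function(path, timestamp_format = "%m/%d/%Y %H:%M", tz = "UTC") {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "glucast_io_error")
  }
  raw <- readr::read_csv(path, col_names = c("time", "glucose"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) > 0 && is_header_row(raw[1, ])) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0L) {
    abort("no records in CSV data section.", class = "glucast_io_error")
  }
  ts <- as.POSIXct(strptime(raw$time, timestamp_format, tz = tz))
  if (all(is.na(ts))) {
    # tolerate a seconds-bearing variant of the same dialect
    ts <- as.POSIXct(strptime(raw$time, paste0(timestamp_format, ":%S"), tz = tz))
  }
  if (anyNA(ts)) {
    row <- which(is.na(ts))[1]
    abort(sprintf("row %d: cannot parse timestamp %s with format %s.",
                  row, shQuote(raw$time[row]), shQuote(timestamp_format)),
          class = "glucast_parse_error")
  }
  g <- suppressWarnings(as.numeric(raw$glucose))
  if (anyNA(g)) {
    row <- which(is.na(g))[1]
    abort(sprintf("row %d: non-numeric glucose value %s.",
                  row, shQuote(raw$glucose[row])),
          class = "glucast_parse_error")
  }
  if (anyDuplicated(ts)) {
    abort("duplicate timestamps in CSV.", class = "glucast_validation_error")
  }
  n_out_of_order <- sum(diff(as.numeric(ts)) < 0)
  if (n_out_of_order > 0) {
    ord <- order(ts)
    ts <- ts[ord]
    g <- g[ord]
    warn(sprintf("re-sorted %d out-of-order row(s) by timestamp.", n_out_of_order),
         class = "glucast_sort_warning")
  }
  cgm_series(ts, g)
}

is_header_row <- function(row) {
  is.na(suppressWarnings(as.numeric(row$glucose)))
}

#' Write a CGM series to CSV
#'
#' Writes the `Time,BGL` dialect read by [read_cgm_csv()]; a read of the
#' written file reproduces the series exactly (timestamps are written with
#' seconds only when some reading needs them).
#'
#' @param series a [cgm_series()] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(series, path) {
  series <- validate_cgm(series)
  fmt <- if (all(as.numeric(series$time) %% 60 == 0)) {
    "%m/%d/%Y %H:%M"
  } else {
    "%m/%d/%Y %H:%M:%S"
  }
  out <- tibble(Time = unpad_datetime(series$time, fmt), BGL = series$glucose)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Table-style unpadded month/day and hour, e.g. "11/2/2020 20:23".
unpad_datetime <- function(t, fmt) {
  s <- format(t, fmt, tz = "UTC")
  sub("^0", "", gsub("/0", "/", s))
}

#' Bundled 12-reading CGM sample
#'
#' A small example trace from a public single-patient type 1 diabetes CGM
#' dataset: 12 readings at roughly 15-minute spacing (with a day-long sensor
#' gap after the first), values 6.5-9.5 mmol/L. Used throughout the
#' documentation and tests as a minimal realistic input.
#'
#' @return A [cgm_series()] tibble with 12 rows.
#' @examples
#' cgm_sample()
#' @export
cgm_sample <- function() {
  read_cgm_csv(system.file("extdata", "cgm_sample.csv", package = "glucast",
                           mustWork = TRUE))
}
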