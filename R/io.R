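# Plain-CSV exchange formats.  Timestamps are ISO-8601 UTC throughout.

fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_time <- function(s) {
  t <- as.POSIXct(s, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                 "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  t
}

#' Read and write the exchange CSV formats
#'
#' Fix files have columns `seal_id,timestamp,lon,lat,lc`; dive files
#' `seal_id,start,end,max_depth_m`; wet/dry files
#' `seal_id,date,hour,percent_dry`.  Timestamps are written as ISO-8601 UTC.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return Readers return a `data.frame` with parsed `POSIXct`/`Date` columns;
#'   writers return `path` invisibly.
#' @name exchange_csv
NULL

#' @rdname exchange_csv
#' @export
write_fixes <- function(x, path) {
  y <- x[, c("seal_id", "timestamp", "lon", "lat", "lc")]
  y$timestamp <- fmt_time(y$timestamp)
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname exchange_csv
#' @export
read_fixes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(seal_id = "character", lc = "character"))
  x$timestamp <- parse_time(x$timestamp)
  x
}

#' @rdname exchange_csv
#' @export
write_dives <- function(x, path) {
  y <- x[, c("seal_id", "start", "end", "max_depth_m")]
  y$start <- fmt_time(y$start)
  y$end <- fmt_time(y$end)
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname exchange_csv
#' @export
read_dives <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(seal_id = "character"))
  x$start <- parse_time(x$start)
  x$end <- parse_time(x$end)
  x
}

#' @rdname exchange_csv
#' @export
write_drytimes <- function(x, path) {
  y <- x[, c("seal_id", "date", "hour", "percent_dry")]
  y$date <- format(y$date, "%Y-%m-%d")
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname exchange_csv
#' @export
read_drytimes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(seal_id = "character"))
  x$date <- as.Date(x$date)
  x
}

#' Write planted ground truth as JSON
#'
#' Serialises each seal's behaviour schedule and planted monthly budget (not
#' the full true path) for fixture exchange.
#'
#' @param truth List of `sim_truth` objects (as in [simulate_study()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  payload <- lapply(truth, function(tr) {
    sch <- tr$schedule
    if (!is.null(sch)) {
      sch$start <- fmt_time(sch$start)
      sch$end <- fmt_time(sch$end)
    }
    list(seal_id = tr$seal_id, schedule = sch, true_budget = tr$true_budget)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
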