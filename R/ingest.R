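#' Read raw station-level hourly records from delimited text
#'
#' Parses a CSV/TSV of station measurements into a canonical record table
#' with instants in UTC. Timestamps may carry an explicit offset
#' (`2018-01-12T03:00:00+0800`, with or without a colon); rows without one
#' are interpreted at `default_offset_hours`. Unparseable rows are counted
#' and reported, never silently dropped.
#'
#' @param path Path to a delimited text file.
#' @param columns Named list mapping the canonical fields `station_id`,
#'   `city_id`, `timestamp`, `value` to column names in the file.
#' @param sep Field separator (default `,`).
#' @param default_offset_hours UTC offset assumed for offset-less timestamps.
#' @return A data frame with columns `station_id`, `city_id`, `time`
#'   (POSIXct, UTC) and `value` (numeric, `NA` for missing measurements),
#'   with attribute `rejects` giving the number of unparseable rows and
#'   attribute `reject_rows` their original indices.
#' @export
load_station_records <- function(path,
                                 columns = list(station_id = "station_id",
                                                city_id = "city_id",
                                                timestamp = "timestamp",
                                                value = "value"),
                                 sep = ",",
                                 default_offset_hours = 0) {
  if (!file.exists(path)) stop("cannot read station file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  need <- c("station_id", "city_id", "timestamp", "value")
  miss <- setdiff(need, names(columns))
  if (length(miss)) stop("format_spec is missing mappings for: ",
                         paste(miss, collapse = ", "))
  absent <- setdiff(unlist(columns[need]), names(raw))
  if (length(absent)) stop("required column(s) not in file: ",
                           paste(absent, collapse = ", "))
  ts <- parse_timestamps(raw[[columns$timestamp]], default_offset_hours)
  val <- suppressWarnings(as.numeric(raw[[columns$value]]))
  val[trimws(raw[[columns$value]]) %in% c("", "NA", "NaN")] <- NA_real_
  bad <- is.na(ts)
  out <- data.frame(station_id = raw[[columns$station_id]][!bad],
                    city_id = raw[[columns$city_id]][!bad],
                    time = ts[!bad],
                    value = val[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "rejects") <- sum(bad)
  attr(out, "reject_rows") <- which(bad)
  out
}

# ISO-8601-ish parser: offset forms +hhmm / +hh:mm / Z, 'T' or space separator
parse_timestamps <- function(x, default_offset_hours = 0) {
  x <- trimws(x)
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  out <- rep(as.POSIXct(NA), length(x))
  todo <- rep(TRUE, length(x))
  for (fmt in c("%Y-%m-%dT%H:%M:%S%z", "%Y-%m-%d %H:%M:%S%z",
                "%Y-%m-%dT%H:%M%z",    "%Y-%m-%d %H:%M%z")) {
    if (!any(todo)) break
    p <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
    hit <- !is.na(p)
    out[todo][hit] <- p[hit]
    todo[todo] <- !hit
  }
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M",    "%Y-%m-%d %H:%M")) {
    if (!any(todo)) break
    p <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
    hit <- !is.na(p)
    out[todo][hit] <- p[hit] - default_offset_hours * 3600
    todo[todo] <- !hit
  }
  out
}

#' Write station records in the package's CSV dialect
#'
#' The inverse of [load_station_records()]: timestamps are written as
#' wall-clock ISO-8601 with an explicit offset, values at full double
#' precision so a write-then-read round trip is lossless.
#'
#' @param records Record data frame (`station_id`, `city_id`, `time`, `value`).
#' @param path Output path.
#' @param tz_offset_hours Offset used to express the timestamps.
#' @export
write_station_records <- function(records, path, tz_offset_hours = 0) {
  off <- sprintf("%+03d00", tz_offset_hours)
  df <- data.frame(
    station_id = records$station_id,
    city_id = records$city_id,
    timestamp = paste0(format(records$time + tz_offset_hours * 3600,
                              "%Y-%m-%dT%H:%M:%S", tz = "UTC"), off),
    value = ifelse(is.na(records$value), "",
                   format(records$value, digits = 17, trim = TRUE)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read the site table
#'
#' @param path CSV with columns `city_id`, `lat`, `lon`, `tz_offset_hours`,
#'   `country` (extra columns such as planar `x_km`/`y_km` are kept).
#' @return Validated data frame.
#' @export
read_site_table <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_site_table(st)
}

validate_site_table <- function(st) {
  need <- c("city_id", "lat", "lon", "tz_offset_hours")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("site table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(st$city_id)) stop("site table city_id values must be unique")
  if (any(abs(st$lat) > 90, na.rm = TRUE)) stop("latitude out of range [-90, 90]")
  if (any(abs(st$lon) > 180, na.rm = TRUE)) stop("longitude out of range [-180, 180]")
  st
}

#' Quality-control filter for raw station records
#'
#' Applies the standard hourly PM screening rules: implausible exact zeros
#' are removed, extreme values above 1000 ug/m3 (strictly greater) are
#' removed as outliers, exact duplicate (station, timestamp, value) records
#' collapse to a single survivor, and conflicting duplicates (same station
#' and timestamp, different values) are all dropped as unresolvable. Missing
#' measurements (`NA`) are removed from the record stream and reappear as
#' gaps on the hourly grid; nothing is ever imputed. The report itemises
#' every removal class so that counts reconcile with the input size.
#'
#' @param records Record data frame from [load_station_records()].
#' @return A list with elements `records` (the retained rows) and `report`
#'   (named integer vector: `n_input`, `n_missing`, `n_zero`, `n_outlier`,
#'   `n_duplicate`, `n_conflict`, `n_retained`).
#' @export
qc_filter <- function(records) {
  n_input <- nrow(records)
  miss <- is.na(records$value)
  n_missing <- sum(miss)
  r <- records[!miss, , drop = FALSE]

  zero <- r$value == 0
  n_zero <- sum(zero)
  r <- r[!zero, , drop = FALSE]

  out <- r$value > 1000
  n_outlier <- sum(out)
  r <- r[!out, , drop = FALSE]

  key <- paste(r$station_id, as.numeric(r$time), sep = "\r")
  full <- paste(key, r$value, sep = "\r")
  dup_exact <- duplicated(full)
  n_duplicate <- sum(dup_exact)
  r <- r[!dup_exact, , drop = FALSE]
  key <- key[!dup_exact]
  conflict <- key %in% key[duplicated(key)]
  n_conflict <- sum(conflict)
  r <- r[!conflict, , drop = FALSE]

  if (nrow(r) == 0L) stop("empty after QC: no records survived filtering")
  report <- c(n_input = n_input, n_missing = n_missing, n_zero = n_zero,
              n_outlier = n_outlier, n_duplicate = n_duplicate,
              n_conflict = n_conflict, n_retained = nrow(r))
  rownames(r) <- NULL
  list(records = r, report = report)
}

#' Average stations to one hourly series per city
#'
#' Each hourly slot gets the arithmetic mean over the stations reporting
#' that hour; hours with no station reporting are missing. No station
#' weighting or interpolation is applied.
#'
#' @param records QC'd record data frame.
#' @param city_id City to aggregate.
#' @param tz_offset_hours Timezone the resulting series is labelled in.
#' @param qc_log Optional QC report to carry as provenance.
#' @return A [site_series()] spanning the city's first to last reported hour.
#' @export
average_stations <- function(records, city_id, tz_offset_hours = 0,
                             qc_log = NULL) {
  r <- records[records$city_id == city_id, , drop = FALSE]
  if (nrow(r) == 0L) stop("unknown city_id: ", city_id)
  hrs <- floor(as.numeric(r$time) / 3600)
  h0 <- min(hrs); h1 <- max(hrs)
  vals <- rep(NA_real_, h1 - h0 + 1)
  means <- tapply(r$value, hrs, mean)
  vals[as.numeric(names(means)) - h0 + 1] <- as.numeric(means)
  site_series(city_id,
              as.POSIXct(h0 * 3600, origin = "1970-01-01", tz = "UTC"),
              vals, tz_offset_hours, qc_log)
}
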