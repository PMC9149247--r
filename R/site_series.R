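#' Hourly city-level concentration series
#'
#' A `site_series` is the unit the correlation and Granger machinery works
#' on: one city's hourly concentrations on a strictly regular grid, with
#' missing hours as `NA` (never imputed). Instants are stored in UTC; the
#' timezone offset is metadata used only to derive wall-clock labels, so
#' relabelling a series to another offset never touches the data.
#'
#' @param city_id City identifier.
#' @param start `POSIXct` instant (UTC) of the first hourly slot. Timestamps
#'   label the left edge of each hourly interval.
#' @param values Numeric vector of hourly concentrations (ug/m3), `NA` for
#'   missing hours.
#' @param tz_offset_hours Integer UTC offset of the wall clock the series is
#'   expressed in (e.g. 8 for China Standard Time).
#' @param qc_log Named integer vector of quality-control removal counts
#'   (see [qc_filter()]).
#' @return An object of class `site_series`.
#' @export
site_series <- function(city_id, start, values, tz_offset_hours = 0L,
                        qc_log = NULL) {
  stopifnot(length(city_id) == 1L, inherits(start, "POSIXct"),
            is.numeric(values), length(tz_offset_hours) == 1L)
  if (as.numeric(start) %% 3600 != 0)
    stop("'start' must be aligned to a whole hour")
  retained <- values[!is.na(values)]
  if (any(retained <= 0 | retained > 1000))
    stop("site_series values must lie in (0, 1000] ug/m3; run qc_filter() first")
  structure(
    list(city_id = as.character(city_id),
         start = as.POSIXct(as.numeric(start), origin = "1970-01-01", tz = "UTC"),
         values = as.numeric(values),
         tz_offset_hours = as.integer(tz_offset_hours),
         qc_log = qc_log),
    class = "site_series")
}

# integer hour index (hours since epoch) of each slot
series_hours <- function(x) {
  as.numeric(x$start) / 3600 + seq_along(x$values) - 1
}

#' @export
length.site_series <- function(x) length(x$values)

#' Wall-clock timestamps of a series
#'
#' @param x A `site_series`.
#' @return `POSIXct` vector; printing these in UTC gives the wall-clock
#'   labels in the series' own timezone.
#' @export
wall_times <- function(x) {
  stopifnot(inherits(x, "site_series"))
  x$start + x$tz_offset_hours * 3600 + (seq_along(x$values) - 1) * 3600
}

#' @export
as.data.frame.site_series <- function(x, ...) {
  off <- sprintf("%+03d00", x$tz_offset_hours)
  data.frame(
    city_id = x$city_id,
    timestamp = paste0(format(wall_times(x), "%Y-%m-%dT%H:%M:%S", tz = "UTC"), off),
    value = x$values,
    stringsAsFactors = FALSE)
}

#' @export
print.site_series <- function(x, ...) {
  n <- length(x$values)
  miss <- sum(is.na(x$values))
  cat(sprintf("<site_series> city '%s': %d hourly slots (UTC%+d), %d missing (%.1f%%)\n",
              x$city_id, n, x$tz_offset_hours, miss, 100 * miss / max(n, 1)))
  cat(sprintf("  span %s .. %s (wall clock)\n",
              format(wall_times(x)[1], "%Y-%m-%d %H:%M", tz = "UTC"),
              format(wall_times(x)[n], "%Y-%m-%d %H:%M", tz = "UTC")))
  if (!is.null(x$qc_log)) {
    cat("  qc:", paste(names(x$qc_log), x$qc_log, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Re-express a series in another timezone
#'
#' Only the wall-clock labels change: the underlying instants and values are
#' untouched, mirroring the harmonisation step in which Korean and Japanese
#' series (UTC+9) are relabelled to China Standard Time (UTC+8), shifting
#' every label one hour earlier.
#'
#' @param series A `site_series`.
#' @param target_offset_hours Integer UTC offset to relabel to.
#' @return The series with `tz_offset_hours` updated.
#' @export
align_timezone <- function(series, target_offset_hours) {
  stopifnot(inherits(series, "site_series"))
  series$tz_offset_hours <- as.integer(target_offset_hours)
  series
}

#' Restrict a series to one calendar month
#'
#' The month is taken in the series' own wall clock. Slots the series does
#' not cover come back as `NA`, so a January window always has 744 slots.
#' A completeness fraction is attached; windows below the threshold are
#' flagged unusable rather than erroring, so callers can report them.
#'
#' @param series A `site_series`.
#' @param year,month Calendar month to extract.
#' @param completeness_min Minimum fraction of non-missing hours for the
#'   window to be usable (default 0.75).
#' @return A `site_series` covering exactly that month, with attributes
#'   `completeness`, `usable` and `window`.
#' @export
window_series <- function(series, year, month, completeness_min = 0.75) {
  stopifnot(inherits(series, "site_series"))
  wall_start <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", year, month), tz = "UTC")
  nxt <- if (month == 12L) c(year + 1L, 1L) else c(year, month + 1L)
  wall_end <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", nxt[1], nxt[2]), tz = "UTC")
  # instant of the wall-clock month start in this series' zone
  inst_start <- wall_start - series$tz_offset_hours * 3600
  n_slots <- as.numeric(difftime(wall_end, wall_start, units = "hours"))
  h0 <- as.numeric(inst_start) / 3600
  hs <- series_hours(series)
  idx <- h0 + seq_len(n_slots) - 1 - hs[1] + 1  # positions in series$values
  vals <- rep(NA_real_, n_slots)
  ok <- idx >= 1 & idx <= length(series$values)
  vals[ok] <- series$values[idx[ok]]
  out <- site_series(series$city_id, inst_start, vals,
                     series$tz_offset_hours, series$qc_log)
  comp <- mean(!is.na(vals))
  attr(out, "completeness") <- comp
  attr(out, "usable") <- comp >= completeness_min
  attr(out, "window") <- c(year = as.integer(year), month = as.integer(month))
  out
}
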