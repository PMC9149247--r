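#' Define a synthetic advection scenario
#'
#' Builds the configuration for a ground-truth simulator of multi-city
#' hourly pollutant series. The physical picture is deliberately minimal —
#' the statistical framework only needs a lagged, attenuated common signal:
#' cities sit on a plane; each calendar-month window has one wind vector;
#' an autocorrelated plume signal originates at the most-upwind city (or a
#' designated source) and reaches each downwind city after
#' distance / speed hours, attenuated exponentially with distance; every
#' city adds its own AR(1) noise; and the raw station stream is corrupted
#' with the pathologies real agency feeds show (missing hours, exact
#' zeros, duplicate records, implausible outliers above 1000 ug/m3).
#'
#' @param sites Data frame with `city_id`, planar `x_km`, `y_km` (east /
#'   north), and `lat`, `lon` for export. Missing lat/lon are synthesised
#'   from the planar coordinates.
#' @param wind Data frame with one row per window: `year`, `month`,
#'   `dir_deg` (bearing the wind blows TOWARD, degrees clockwise from
#'   north), `speed_kmh`, and optional `source_city` (default: the most
#'   upwind city that window).
#' @param signal_mean,signal_sd,signal_phi Plume signal: AR(1) with this
#'   marginal mean/sd (ug/m3) and coefficient.
#' @param noise_sd,noise_phi Per-city AR(1) measurement/local noise.
#' @param base Ambient baseline added everywhere (ug/m3).
#' @param decay_per_km Exponential attenuation rate of the plume with
#'   downwind distance.
#' @param corridor_km Maximum perpendicular offset from the wind axis for a
#'   city to receive the plume.
#' @param stations_per_city,station_sd Station replication and iid
#'   station-level noise.
#' @param missing_frac,outlier_rate,zero_rate,dup_rate Pathology injection
#'   rates (fractions of record rows), all in [0, 1).
#' @param tz_offset_hours Timezone the records are stamped in.
#' @return Object of class `driftnet_scenario`.
#' @export
synthetic_scenario <- function(sites, wind,
                               signal_mean = 50, signal_sd = 25,
                               signal_phi = 0.95,
                               noise_sd = 6, noise_phi = 0.8,
                               base = 30, decay_per_km = 5e-4,
                               corridor_km = 75,
                               stations_per_city = 2, station_sd = 2,
                               missing_frac = 0.02, outlier_rate = 0.002,
                               zero_rate = 0.002, dup_rate = 0.002,
                               tz_offset_hours = 8) {
  if (is.null(sites) || nrow(sites) == 0)
    stop("scenario needs at least one city")
  if (is.null(wind) || nrow(wind) == 0)
    stop("scenario needs at least one wind window")
  stopifnot(all(c("city_id", "x_km", "y_km") %in% names(sites)),
            all(c("year", "month", "dir_deg", "speed_kmh") %in% names(wind)))
  if (any(wind$speed_kmh <= 0)) stop("wind speeds must be > 0")
  if (decay_per_km < 0) stop("decay rate must be >= 0")
  fr <- c(missing_frac, outlier_rate, zero_rate, dup_rate)
  if (any(fr < 0 | fr >= 1)) stop("injection fractions must lie in [0, 1)")
  if (is.null(sites$lat)) sites$lat <- 36 + sites$y_km / 111
  if (is.null(sites$lon)) sites$lon <- 114 + sites$x_km / 90
  if (is.null(sites$tz_offset_hours)) sites$tz_offset_hours <- tz_offset_hours
  if (is.null(sites$country)) sites$country <- "SYN"
  if (is.null(wind$source_city)) wind$source_city <- NA_character_
  structure(
    list(sites = sites, wind = wind,
         signal = list(mean = signal_mean, sd = signal_sd, phi = signal_phi),
         noise = list(sd = noise_sd, phi = noise_phi),
         base = base, decay_per_km = decay_per_km, corridor_km = corridor_km,
         stations_per_city = stations_per_city, station_sd = station_sd,
         inject = list(missing = missing_frac, outlier = outlier_rate,
                       zero = zero_rate, dup = dup_rate),
         tz_offset_hours = tz_offset_hours),
    class = "driftnet_scenario")
}

#' @export
print.driftnet_scenario <- function(x, ...) {
  cat(sprintf("<driftnet_scenario> %d cities, %d window(s), %d station(s)/city\n",
              nrow(x$sites), nrow(x$wind), x$stations_per_city))
  cat(sprintf("  plume AR(1): mean %g, sd %g, phi %g; noise sd %g; decay %g /km\n",
              x$signal$mean, x$signal$sd, x$signal$phi, x$noise$sd,
              x$decay_per_km))
  cat(sprintf("  pathologies: missing %.1f%%, outliers %.2f%%, zeros %.2f%%, dups %.2f%%\n",
              100 * x$inject$missing, 100 * x$inject$outlier,
              100 * x$inject$zero, 100 * x$inject$dup))
  invisible(x)
}

# stationary AR(1) with given marginal sd
ar1_series <- function(n, phi, sd_marginal) {
  if (sd_marginal == 0) return(rep(0, n))
  innov_sd <- sd_marginal * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                           method = "recursive",
                           init = stats::rnorm(1, 0, sd_marginal)))
}

month_hours <- function(year, month) {
  nxt <- if (month == 12L) c(year + 1L, 1L) else c(year, month + 1L)
  s <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", year, month), tz = "UTC")
  e <- as.POSIXct(sprintf("%04d-%02d-01 00:00:00", nxt[1], nxt[2]), tz = "UTC")
  as.numeric(difftime(e, s, units = "hours"))
}

# per-window geometry: arrival lag (h), attenuation and connectivity per city
window_geometry <- function(scenario, wrow) {
  s <- scenario$sites
  rad <- wrow$dir_deg * pi / 180
  wx <- sin(rad); wy <- cos(rad)
  src <- wrow$source_city
  if (is.na(src)) {
    proj <- s$x_km * wx + s$y_km * wy
    src <- s$city_id[which.min(proj)]
  }
  i0 <- match(src, s$city_id)
  if (is.na(i0)) stop("source city not in site table: ", src)
  dx <- s$x_km - s$x_km[i0]; dy <- s$y_km - s$y_km[i0]
  along <- dx * wx + dy * wy
  perp <- abs(-dx * wy + dy * wx)
  connected <- (s$city_id == src) |
    (along > 0 & perp <= scenario$corridor_km)
  lag_exact <- ifelse(connected, pmax(along, 0) / wrow$speed_kmh, NA_real_)
  list(source = src,
       connected = connected,
       lag = as.integer(round(lag_exact)),
       lag_exact = lag_exact,
       atten = ifelse(connected, exp(-scenario$decay_per_km * pmax(along, 0)),
                      0))
}

#' Simulate a scenario
#'
#' Generates the raw station-level record stream (in exactly the CSV
#' dialect [load_station_records()] reads), the ground-truth matrix of
#' pairwise transport lags and directions, the clean city-level series
#' before station noise and corruption, and a log of every injected
#' pathology. Fixing the seed makes the output fully reproducible.
#'
#' @param object A `driftnet_scenario`.
#' @param nsim Must be 1.
#' @param seed Integer seed (fanned out internally).
#' @param ... Unused.
#' @return Object of class `driftnet_simulation`: `records`, `truth` (one
#'   row per ordered city pair per window: `year`, `month`, `source`,
#'   `target`, `connected`, `lag_hours`, `lag_exact_hours`), `sites`,
#'   `clean` (named list of `site_series`), `injection` (counts), and the
#'   scenario.
#' @export
simulate.driftnet_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (nsim != 1) stop("nsim > 1 is not supported; vary 'seed' instead")
  if (!is.null(seed)) set.seed(seed)
  sc <- object
  s <- sc$sites
  ncity <- nrow(s)
  off <- sc$tz_offset_hours

  win_start <- vapply(seq_len(nrow(sc$wind)), function(i) {
    as.numeric(as.POSIXct(sprintf("%04d-%02d-01 00:00:00",
                                  sc$wind$year[i], sc$wind$month[i]),
                          tz = "UTC")) / 3600 - off
  }, numeric(1))
  win_len <- mapply(month_hours, sc$wind$year, sc$wind$month)
  ord <- order(win_start)

  grid0 <- min(win_start)
  gridN <- max(win_start + win_len) - 1
  clean_mat <- matrix(NA_real_, nrow = gridN - grid0 + 1, ncol = ncity,
                      dimnames = list(NULL, s$city_id))

  rec_list <- list()
  truth_list <- list()
  inj <- c(missing = 0L, outlier = 0L, zero = 0L, dup = 0L)

  for (w in ord) {
    H <- win_len[w]
    geo <- window_geometry(sc, sc$wind[w, ])
    Lmax <- max(c(0L, geo$lag[geo$connected]), na.rm = TRUE)
    plume <- pmax(sc$signal$mean +
                    ar1_series(H + Lmax, sc$signal$phi, sc$signal$sd), 0)
    vals <- matrix(NA_real_, nrow = H, ncol = ncity)
    for (ci in seq_len(ncity)) {
      contrib <- if (geo$connected[ci])
        geo$atten[ci] * plume[(Lmax - geo$lag[ci]) + seq_len(H)] else 0
      vals[, ci] <- pmax(sc$base + contrib +
                           ar1_series(H, sc$noise$phi, sc$noise$sd), 0.5)
    }
    rows0 <- win_start[w] - grid0 + 1
    clean_mat[rows0:(rows0 + H - 1), ] <- vals

    # truth: ordered pairs sharing the plume, downstream lagging upstream
    tw <- expand.grid(source = s$city_id, target = s$city_id,
                      stringsAsFactors = FALSE)
    tw <- tw[tw$source != tw$target, ]
    ia <- match(tw$source, s$city_id); ib <- match(tw$target, s$city_id)
    conn <- geo$connected[ia] & geo$connected[ib] & geo$lag[ib] > geo$lag[ia]
    tw$year <- sc$wind$year[w]; tw$month <- sc$wind$month[w]
    tw$connected <- conn
    tw$lag_hours <- ifelse(conn, geo$lag[ib] - geo$lag[ia], NA_integer_)
    tw$lag_exact_hours <- ifelse(conn, geo$lag_exact[ib] - geo$lag_exact[ia],
                                 NA_real_)
    truth_list[[length(truth_list) + 1L]] <- tw

    # station records for this window
    times <- as.POSIXct((win_start[w] + 0:(H - 1)) * 3600,
                        origin = "1970-01-01", tz = "UTC")
    st_rec <- do.call(rbind, lapply(seq_len(ncity), function(ci) {
      do.call(rbind, lapply(seq_len(sc$stations_per_city), function(sj) {
        v <- vals[, ci]
        if (sc$station_sd > 0)
          v <- pmax(v + stats::rnorm(H, 0, sc$station_sd), 0.5)
        data.frame(station_id = sprintf("%s_s%d", s$city_id[ci], sj),
                   city_id = s$city_id[ci], time = times, value = v,
                   stringsAsFactors = FALSE)
      }))
    }))

    # inject pathologies on disjoint record sets
    N <- nrow(st_rec)
    n_miss <- stats::rbinom(1, N, sc$inject$missing)
    n_out <- stats::rbinom(1, N, sc$inject$outlier)
    n_zero <- stats::rbinom(1, N, sc$inject$zero)
    n_dup <- stats::rbinom(1, N, sc$inject$dup)
    pick <- sample.int(N, min(N, n_miss + n_out + n_zero + n_dup))
    i_miss <- pick[seq_len(n_miss)]
    i_out <- pick[n_miss + seq_len(n_out)]
    i_zero <- pick[n_miss + n_out + seq_len(n_zero)]
    i_dup <- pick[n_miss + n_out + n_zero + seq_len(n_dup)]
    st_rec$value[i_out] <- stats::runif(n_out, 1200, 3000)
    st_rec$value[i_zero] <- 0
    if (n_dup > 0)
      st_rec <- rbind(st_rec, st_rec[i_dup, , drop = FALSE])
    if (n_miss > 0)
      st_rec <- st_rec[-i_miss, , drop = FALSE]
    inj <- inj + c(missing = n_miss, outlier = n_out, zero = n_zero,
                   dup = n_dup)
    rec_list[[length(rec_list) + 1L]] <- st_rec
  }

  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  clean <- lapply(s$city_id, function(cid) {
    site_series(cid,
                as.POSIXct(grid0 * 3600, origin = "1970-01-01", tz = "UTC"),
                clean_mat[, cid], off)
  })
  names(clean) <- s$city_id
  structure(
    list(records = records,
         truth = do.call(rbind, truth_list),
         sites = s, clean = clean, injection = inj, scenario = sc),
    class = "driftnet_simulation")
}

#' @export
print.driftnet_simulation <- function(x, ...) {
  cat(sprintf("<driftnet_simulation> %d records, %d cities, %d window(s)\n",
              nrow(x$records), nrow(x$sites), nrow(x$scenario$wind)))
  cat("  injected:", paste(names(x$injection), x$injection, sep = "=",
                           collapse = " "), "\n")
  cat(sprintf("  true directed links: %d of %d ordered pairs\n",
              sum(x$truth$connected), nrow(x$truth)))
  invisible(x)
}

#' A linear source-to-sink transport chain
#'
#' Cities equally spaced along the west-east axis with wind blowing along
#' it, giving adjacent-pair transport lags of `spacing_km / speed_kmh`
#' hours — the package's standard recovery benchmark (5 cities 300 km
#' apart at 50 km/h: adjacent lags 6 h, pairwise lags 6-24 h).
#'
#' @param n_cities Number of cities in the chain.
#' @param spacing_km Distance between neighbours.
#' @param speed_kmh Wind speed.
#' @param year,months Calendar windows to simulate.
#' @param dir_deg Wind bearing (90 = eastward, along the chain).
#' @param ... Passed on to [synthetic_scenario()].
#' @return A `driftnet_scenario`.
#' @export
chain_scenario <- function(n_cities = 5, spacing_km = 300, speed_kmh = 50,
                           year = 2018, months = 1, dir_deg = 90, ...) {
  sites <- data.frame(city_id = sprintf("city%d", seq_len(n_cities)),
                      x_km = (seq_len(n_cities) - 1) * spacing_km,
                      y_km = 0, stringsAsFactors = FALSE)
  wind <- data.frame(year = year, month = months, dir_deg = dir_deg,
                     speed_kmh = speed_kmh)
  synthetic_scenario(sites, wind, ...)
}

#' A two-window scenario with seasonal wind reversal
#'
#' The same chain of cities with eastward wind in January and westward
#' wind in July, emulating the winter/summer monsoon reversal that flips
#' the direction of transboundary transport between windows.
#'
#' @inheritParams chain_scenario
#' @param ... Passed on to [synthetic_scenario()].
#' @return A `driftnet_scenario` with January and July windows.
#' @export
reversal_scenario <- function(n_cities = 5, spacing_km = 300, speed_kmh = 50,
                              year = 2018, ...) {
  sites <- data.frame(city_id = sprintf("city%d", seq_len(n_cities)),
                      x_km = (seq_len(n_cities) - 1) * spacing_km,
                      y_km = 0, stringsAsFactors = FALSE)
  wind <- data.frame(year = year, month = c(1L, 7L),
                     dir_deg = c(90, 270), speed_kmh = speed_kmh)
  synthetic_scenario(sites, wind, ...)
}

#' Score recovered networks against simulation ground truth
#'
#' @param networks A `driftnet_network` or list of them (one per window).
#' @param truth Truth data frame from [simulate.driftnet_scenario()].
#' @param lag_tolerance Edges whose |recovered - true| lag is within this
#'   many hours count as lag-accurate (reported alongside the MAE).
#' @return Object of class `recovery_metrics`: `direction_accuracy`
#'   (fraction of true directed links recovered with the right arrow),
#'   `lag_mae_hours` (mean absolute lag error over matched edges),
#'   `lag_within_tol`, `false_edges` (edges between pairs not linked in
#'   either direction), `n_true_links`, `n_matched`, `n_edges`.
#' @export
evaluate_recovery <- function(networks, truth, lag_tolerance = 1) {
  if (inherits(networks, "driftnet_network")) networks <- list(networks)
  net_cities <- unique(unlist(lapply(networks, `[[`, "nodes")))
  truth_cities <- unique(c(truth$source, truth$target))
  if (!length(intersect(net_cities, truth_cities)))
    stop("network and truth share no cities")
  n_true <- 0L; n_match <- 0L; n_false <- 0L; n_edges <- 0L
  lag_err <- numeric(0)
  for (net in networks) {
    y <- net$window["year"]; m <- net$window["month"]
    tw <- truth[truth$year == y & truth$month == m, , drop = FALSE]
    flagged <- tw[tw$connected, , drop = FALSE]
    n_true <- n_true + nrow(flagged)
    e <- net$edges
    n_edges <- n_edges + nrow(e)
    if (nrow(e) == 0) next
    ek <- paste(e$source, e$target)
    fk <- paste(flagged$source, flagged$target)
    anyk <- c(fk, paste(flagged$target, flagged$source))
    hit <- match(fk, ek)
    matched <- which(!is.na(hit))
    n_match <- n_match + length(matched)
    lag_err <- c(lag_err,
                 abs(e$lag_hours[hit[matched]] - flagged$lag_hours[matched]))
    n_false <- n_false + sum(!(ek %in% anyk))
  }
  structure(
    list(direction_accuracy = if (n_true) n_match / n_true else NA_real_,
         lag_mae_hours = if (length(lag_err)) mean(lag_err) else NA_real_,
         lag_within_tol = if (length(lag_err))
           mean(lag_err <= lag_tolerance) else NA_real_,
         false_edges = n_false, n_true_links = n_true,
         n_matched = n_match, n_edges = n_edges,
         lag_tolerance = lag_tolerance),
    class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat("<recovery_metrics>\n")
  cat(sprintf("  direction accuracy: %.3f (%d / %d true links)\n",
              x$direction_accuracy, x$n_matched, x$n_true_links))
  cat(sprintf("  lag MAE: %s h (%.0f%% within %g h)\n",
              ifelse(is.na(x$lag_mae_hours), "NA",
                     sprintf("%.2f", x$lag_mae_hours)),
              100 * ifelse(is.na(x$lag_within_tol), 0, x$lag_within_tol),
              x$lag_tolerance))
  cat(sprintf("  false edges: %d (of %d recovered)\n", x$false_edges,
              x$n_edges))
  invisible(x)
}
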