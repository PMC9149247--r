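#' Default analysis configuration
#'
#' All tunables of the pipeline in one validated list: lag grid, minimum
#' overlap, significance level, Granger settings, window completeness
#' threshold and multiple-testing mode. Every run embeds the resolved
#' configuration in its outputs.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of settings.
#' @export
default_config <- function(...) {
  cfg <- list(tau_min = -168, tau_max = 168, step = 1,
              min_overlap = 30, alpha = 0.05,
              max_lag = 24, criterion = "aic", fixed_lag = NULL,
              difference = FALSE,
              completeness_min = 0.75,
              multiplicity = "none")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (!cfg$multiplicity %in% c("none", "bh"))
    stop("unknown multiplicity method: ", cfg$multiplicity)
  cfg
}

#' Build the directed interaction network for one monthly window
#'
#' Runs the full two-step framework over every unordered city pair:
#' lag-scanned correlation, the two-test significance gate, direction
#' candidate from the sign of `T_delay`, and Granger confirmation.
#' Swap symmetry of the cross-correlation makes one pass per unordered
#' pair sufficient. Pairs whose maximum sits on the lag-grid boundary are
#' excluded from edges. Cities whose window falls below the completeness
#' threshold are dropped from the node set.
#'
#' @param series_by_city Named list of `site_series` (full-span; windowing
#'   happens here), or of pre-windowed series when `year`/`month` is `NULL`.
#' @param year,month Calendar window to analyse.
#' @param config See [default_config()].
#' @return Object of class `driftnet_network`: `window`, `nodes`, `edges`
#'   (data frame), `pairs` (all pair-level statistics) and `config`.
#' @export
build_network <- function(series_by_city, year = NULL, month = NULL,
                          config = default_config()) {
  stopifnot(is.list(series_by_city), length(names(series_by_city)) ==
              length(series_by_city))
  if (!is.null(year)) {
    win <- lapply(series_by_city, window_series, year = year, month = month,
                  completeness_min = config$completeness_min)
  } else {
    win <- series_by_city
    year <- NA_integer_; month <- NA_integer_
  }
  usable <- vapply(win, function(s) isTRUE(attr(s, "usable")) ||
                     is.null(attr(s, "usable")), logical(1))
  win <- win[usable]
  cities <- sort(names(win))
  if (length(cities) < 2)
    stop("insufficient sites: need >= 2 cities with usable windows, have ",
         length(cities))

  pair_rows <- list()
  edge_rows <- list()
  cmb <- utils::combn(cities, 2)
  for (j in seq_len(ncol(cmb))) {
    c1 <- cmb[1, j]; c2 <- cmb[2, j]
    lc <- tryCatch(
      lag_correlation(win[[c1]], win[[c2]], config$tau_min, config$tau_max,
                      config$step, config$min_overlap, config$alpha),
      error = function(e) e)
    if (inherits(lc, "error")) {
      pair_rows[[j]] <- data.frame(
        city_1 = c1, city_2 = c2, P_max = NA_real_, T_delay = NA_integer_,
        n_max = NA_integer_, P_zero = NA_real_, p_r = NA_real_,
        p_fisher = NA_real_, significant = FALSE, boundary = FALSE,
        granger_p = NA_real_, granger_p_reverse = NA_real_,
        confirmed = FALSE, bidirectional = FALSE, anomaly = FALSE,
        note = conditionMessage(lc), stringsAsFactors = FALSE)
      next
    }
    row <- data.frame(
      city_1 = c1, city_2 = c2, P_max = lc$P_max, T_delay = lc$T_delay,
      n_max = lc$n_max, P_zero = lc$P_zero, p_r = lc$p_r,
      p_fisher = lc$p_fisher, significant = lc$significant,
      boundary = lc$boundary,
      granger_p = NA_real_, granger_p_reverse = NA_real_,
      confirmed = FALSE, bidirectional = FALSE, anomaly = FALSE,
      note = "", stringsAsFactors = FALSE)
    if (lc$significant && lc$T_delay != 0 && !lc$boundary) {
      dec <- tryCatch(
        confirm_direction(lc, win[[c1]], win[[c2]], config$max_lag,
                          config$alpha, config$criterion, config$fixed_lag,
                          config$difference),
        error = function(e) e)
      if (inherits(dec, "error")) {
        row$note <- conditionMessage(dec)
      } else {
        row$granger_p <- dec$forward$p_value
        row$granger_p_reverse <- dec$reverse$p_value
        row$confirmed <- dec$confirmed
        row$bidirectional <- dec$bidirectional
        row$anomaly <- dec$anomaly
        if (dec$confirmed) {
          edge_rows[[length(edge_rows) + 1L]] <- data.frame(
            source = dec$source, target = dec$target,
            year = year, month = month,
            strength = dec$strength, lag_hours = dec$lag_hours,
            p_r = lc$p_r, p_fisher = lc$p_fisher,
            granger_p = dec$forward$p_value,
            bidirectional = dec$bidirectional,
            stringsAsFactors = FALSE)
        }
      }
    }
    pair_rows[[j]] <- row
  }
  pairs <- do.call(rbind, pair_rows)
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else empty_edges()
  net <- structure(
    list(window = c(year = as.integer(year), month = as.integer(month)),
         nodes = cities, edges = edges, pairs = pairs, config = config),
    class = "driftnet_network")
  adjust_multiplicity(net, config$multiplicity)
}

empty_edges <- function() {
  data.frame(source = character(), target = character(),
             year = integer(), month = integer(),
             strength = numeric(), lag_hours = numeric(),
             p_r = numeric(), p_fisher = numeric(), granger_p = numeric(),
             bidirectional = logical(), stringsAsFactors = FALSE)
}

#' Re-gate edges under a multiple-testing correction
#'
#' Method `"none"` reproduces the uncorrected behaviour and returns the
#' network unchanged. Method `"bh"` applies a Benjamini-Hochberg step-up to
#' the Fisher-gate p-values across all lagged pairs in the window and keeps
#' only edges whose adjusted p-value still clears `alpha`; since adjusted
#' p-values are never smaller than raw ones, the corrected edge set is a
#' subset of the uncorrected one.
#'
#' @param network A `driftnet_network`.
#' @param method `"none"` or `"bh"`.
#' @return The (possibly re-gated) network; with BH the pairs table gains a
#'   `p_fisher_adj` column.
#' @export
adjust_multiplicity <- function(network, method = c("none", "bh")) {
  stopifnot(inherits(network, "driftnet_network"))
  if (!is.character(method) || !method[1] %in% c("none", "bh"))
    stop("unknown multiplicity method: ", method[1])
  method <- method[1]
  if (method == "none") return(network)
  p <- network$pairs
  tested <- !is.na(p$p_fisher)
  p$p_fisher_adj <- NA_real_
  p$p_fisher_adj[tested] <- stats::p.adjust(p$p_fisher[tested], method = "BH")
  network$pairs <- p
  e <- network$edges
  if (nrow(e)) {
    ekey <- paste(pmin(e$source, e$target), pmax(e$source, e$target))
    pkey <- paste(pmin(p$city_1, p$city_2), pmax(p$city_1, p$city_2))
    adj <- p$p_fisher_adj[match(ekey, pkey)]
    network$edges <- e[!is.na(adj) & adj < network$config$alpha, , drop = FALSE]
    rownames(network$edges) <- NULL
  }
  network
}

#' @export
print.driftnet_network <- function(x, ...) {
  cat(sprintf("<driftnet_network> window %04d-%02d: %d cities, %d directed edges\n",
              x$window["year"], x$window["month"], length(x$nodes),
              nrow(x$edges)))
  if (nrow(x$edges)) {
    e <- x$edges
    for (i in seq_len(min(nrow(e), 12L)))
      cat(sprintf("  %s -> %s  (P_max = %.3f, lag = %g h, Granger p = %.3g)%s\n",
                  e$source[i], e$target[i], e$strength[i], e$lag_hours[i],
                  e$granger_p[i], if (e$bidirectional[i]) " [bidir]" else ""))
    if (nrow(e) > 12L) cat("  ...", nrow(e) - 12L, "more\n")
  }
  invisible(x)
}

#' @export
summary.driftnet_network <- function(object, ...) {
  p <- object$pairs
  cat(sprintf("Window %04d-%02d: %d cities, %d pairs scanned\n",
              object$window["year"], object$window["month"],
              length(object$nodes), nrow(p)))
  cat(sprintf("  significant after two-test gate: %d (boundary maxima: %d, lag-zero: %d)\n",
              sum(p$significant, na.rm = TRUE),
              sum(p$boundary, na.rm = TRUE),
              sum(p$significant & p$T_delay == 0, na.rm = TRUE)))
  cat(sprintf("  Granger-confirmed edges: %d (bidirectional: %d, reverse-only anomalies: %d)\n",
              nrow(object$edges), sum(p$bidirectional, na.rm = TRUE),
              sum(p$anomaly, na.rm = TRUE)))
  cat(sprintf("  config: alpha = %g, lag grid [%d, %d] h, max Granger lag %d (%s), multiplicity %s\n",
              object$config$alpha, object$config$tau_min, object$config$tau_max,
              object$config$max_lag, object$config$criterion,
              object$config$multiplicity))
  invisible(object)
}

#' @export
plot.driftnet_network <- function(x, site_table = NULL, ...) {
  if (is.null(site_table))
    stop("plotting needs a site_table with coordinates")
  st <- validate_site_table(site_table)
  graphics::plot(st$lon, st$lat, pch = 19, xlab = "lon", ylab = "lat",
                 main = sprintf("Window %04d-%02d", x$window["year"],
                                x$window["month"]), ...)
  graphics::text(st$lon, st$lat, st$city_id, pos = 3, cex = 0.7)
  e <- x$edges
  if (nrow(e)) {
    i1 <- match(e$source, st$city_id); i2 <- match(e$target, st$city_id)
    graphics::arrows(st$lon[i1], st$lat[i1], st$lon[i2], st$lat[i2],
                     length = 0.1, col = "red3")
  }
  invisible(x)
}

#' Export a network as an edge-list CSV or GeoJSON
#'
#' The CSV writes all edge fields at full double precision, so identical
#' inputs and configuration yield byte-identical files and a
#' write-then-read round trip is lossless. The GeoJSON form emits one
#' LineString feature per edge from source to target coordinates, with the
#' edge fields as properties.
#'
#' @param network A `driftnet_network`.
#' @param path Output file path.
#' @param site_table Required for GeoJSON: coordinates per city.
#' @param format `"csv"` or `"geojson"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, site_table = NULL,
                           format = c("csv", "geojson")) {
  format <- match.arg(format)
  e <- network$edges
  if (format == "csv") {
    df <- e
    for (nm in names(df)) if (is.numeric(df[[nm]]))
      df[[nm]] <- format_full(df[[nm]])
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                       eol = "\n")
  } else {
    st <- validate_site_table(site_table)
    missing_city <- setdiff(unique(c(e$source, e$target)), st$city_id)
    if (length(missing_city))
      stop("site table lacks coordinates for: ",
           paste(missing_city, collapse = ", "))
    feats <- lapply(seq_len(nrow(e)), function(i) {
      i1 <- match(e$source[i], st$city_id); i2 <- match(e$target[i], st$city_id)
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = list(c(st$lon[i1], st$lat[i1]),
                                              c(st$lon[i2], st$lat[i2]))),
           properties = as.list(e[i, , drop = FALSE]))
    })
    gj <- list(type = "FeatureCollection", features = feats)
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, trim = TRUE)
  }, character(1))
  out
}

#' Read an edge-list CSV written by [export_network()]
#'
#' @param path Path to the CSV.
#' @return Edge data frame with the same column types as
#'   `driftnet_network$edges`.
#' @export
read_edge_csv <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(e) == 0) return(empty_edges())
  e$bidirectional <- as.logical(e$bidirectional)
  e
}
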