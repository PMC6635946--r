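#' Default Movebank-style column mapping
#'
#' Maps internal fix fields to CSV column names. Override entries to
#' read other dialects; `x`/`y` name projected coordinates and
#' `lon`/`lat` geographic ones (at least one pair must resolve).
#'
#' @return Named list of column names.
#' @export
movebank_dialect <- function() {
  list(
    animal_id = "individual-local-identifier",
    timestamp = "timestamp",
    x = "utm-easting",
    y = "utm-northing",
    lon = "location-long",
    lat = "location-lat",
    hdop = "gps:hdop",
    n_sats = "gps:satellite-count",
    height = "height-above-msl",
    speed = "ground-speed"
  )
}

#' Read GPS fixes from a Movebank-style CSV
#'
#' Parses and type-checks fixes. Rows whose timestamp or coordinates do
#' not parse are quarantined (returned in the `rejects` attribute and
#' optionally written to a file), never silently dropped.
#'
#' @param path CSV file path.
#' @param dialect Column mapping, see [movebank_dialect()].
#' @param rejects_path Optional path; unparseable raw rows are written
#'   there as CSV.
#' @return Data frame of fixes (`animal_id`, `timestamp`, `x`, `y`, and
#'   any of `hdop`, `n_sats`, `height`, `speed` present in the file),
#'   ordered by animal then time, with attribute `rejects`.
#' @export
read_fixes <- function(path, dialect = movebank_dialect(), rejects_path = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp")
  for (f in need) {
    if (!dialect[[f]] %in% names(raw))
      stop("required column '", dialect[[f]], "' (", f, ") missing from ", path)
  }
  has_xy <- all(c(dialect$x, dialect$y) %in% names(raw))
  has_ll <- all(c(dialect$lon, dialect$lat) %in% names(raw))
  if (!has_xy && !has_ll)
    stop("neither projected (", dialect$x, "/", dialect$y, ") nor geographic (",
         dialect$lon, "/", dialect$lat, ") coordinate columns found")
  if (nrow(raw) == 0L) {
    out <- data.frame(animal_id = character(), timestamp = as.POSIXct(character()),
                      x = numeric(), y = numeric(), stringsAsFactors = FALSE)
    attr(out, "rejects") <- raw
    return(out)
  }
  # per-element parsing: a single malformed timestamp must not poison
  # the rest of the column
  ts_raw <- as.character(raw[[dialect$timestamp]])
  ts <- rep(as.POSIXct(NA), length(ts_raw))
  best_n <- 0L
  for (f in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%d %H:%M:%OS",
              "%Y-%m-%dT%H:%M:%OS")) {
    cand <- as.POSIXct(strptime(ts_raw, f, tz = "UTC"), tz = "UTC")
    n <- sum(!is.na(cand))
    if (n > best_n) {
      ts <- cand
      best_n <- n
    }
  }
  if (has_xy) {
    x <- suppressWarnings(as.numeric(raw[[dialect$x]]))
    y <- suppressWarnings(as.numeric(raw[[dialect$y]]))
  } else {
    x <- suppressWarnings(as.numeric(raw[[dialect$lon]]))
    y <- suppressWarnings(as.numeric(raw[[dialect$lat]]))
  }
  ok <- !is.na(ts) & !is.na(x) & !is.na(y)
  out <- data.frame(
    animal_id = as.character(raw[[dialect$animal_id]])[ok],
    timestamp = ts[ok], x = x[ok], y = y[ok],
    stringsAsFactors = FALSE
  )
  for (f in c("hdop", "n_sats", "height", "speed")) {
    col <- dialect[[f]]
    if (!is.null(col) && col %in% names(raw))
      out[[f]] <- suppressWarnings(as.numeric(raw[[col]]))[ok]
  }
  out <- out[order(out$animal_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  rejects <- raw[!ok, , drop = FALSE]
  if (!is.null(rejects_path) && nrow(rejects) > 0)
    utils::write.csv(rejects, rejects_path, row.names = FALSE)
  attr(out, "rejects") <- rejects
  out
}

#' Per-fix movement speed from coordinates
#'
#' Speed of fix i is the Euclidean displacement from fix i-1 divided by
#' the elapsed time; the first fix inherits the speed of its following
#' segment.
#'
#' @param fixes Time-ordered data frame of one animal's fixes with
#'   columns `timestamp`, `x`, `y` (>= 2 rows).
#' @return Numeric vector of speeds, m/s.
#' @export
compute_speeds <- function(fixes) {
  n <- nrow(fixes)
  if (n < 2L) stop("compute_speeds needs at least 2 fixes")
  dt <- diff(as.numeric(fixes$timestamp))
  if (any(dt <= 0)) stop("non-increasing timestamps (zero or negative dt)")
  d <- sqrt(diff(fixes$x)^2 + diff(fixes$y)^2)
  v <- d / dt
  c(v[1], v)
}

#' Default GPS quality-control thresholds
#'
#' A fix fails when HDOP exceeds `max_hdop`, the satellite count is
#' below `min_sats`, height exceeds `max_height` (m ASL), or speed
#' exceeds `max_speed` (m/s). Comparisons are strict, so boundary
#' values are retained.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(max_hdop = 8, min_sats = 3, max_height = 100, max_speed = 8)
}

#' Filter fixes by GPS quality and post-capture exclusion
#'
#' Applies the four quality thresholds plus removal of fixes recorded
#' within `exclusion_hours` after any capture event of the same animal
#' (post-sedation recovery) and, optionally, inside per-animal trapping
#' windows. Speed comes from the file's `speed` column where present
#' and non-missing, otherwise it is recomputed per animal with
#' [compute_speeds()]. Each removed fix is logged with the first
#' matching reason in the order bad_hdop, low_satellites, high_altitude,
#' high_speed, post_capture, trapping_window.
#'
#' @param fixes Data frame of fixes (possibly several animals).
#' @param thresholds See [qc_thresholds()].
#' @param capture_events Data frame (`animal_id`, `capture_time`) or
#'   NULL.
#' @param exclusion_hours Hours excluded after each capture (default 8).
#' @param exclusion_windows Optional data frame (`animal_id`, `start`,
#'   `end`) of trapping windows to exclude.
#' @return List with `retained` (fixes) and `log` (data frame
#'   `animal_id`, `timestamp`, `reason`); the two partition the input.
#' @export
filter_fixes <- function(fixes, thresholds = qc_thresholds(),
                         capture_events = NULL, exclusion_hours = 8,
                         exclusion_windows = NULL) {
  n <- nrow(fixes)
  if (n == 0L) {
    return(list(retained = fixes,
                log = data.frame(animal_id = character(),
                                 timestamp = as.POSIXct(character()),
                                 reason = character())))
  }
  if (exclusion_hours < 0) stop("exclusion_hours must be >= 0")

  speed <- if (!is.null(fixes$speed)) fixes$speed else rep(NA_real_, n)
  need <- is.na(speed)
  if (any(need)) {
    for (id in unique(fixes$animal_id)) {
      sel <- which(fixes$animal_id == id)
      if (length(sel) >= 2L) {
        v <- compute_speeds(fixes[sel, , drop = FALSE])
        speed[sel][is.na(speed[sel])] <- v[is.na(speed[sel])]
      } else {
        speed[sel][is.na(speed[sel])] <- 0
      }
    }
  }

  hdop <- if (!is.null(fixes$hdop)) fixes$hdop else rep(NA_real_, n)
  sats <- if (!is.null(fixes$n_sats)) fixes$n_sats else rep(NA_real_, n)
  height <- if (!is.null(fixes$height)) fixes$height else rep(NA_real_, n)

  post_capture <- rep(FALSE, n)
  if (!is.null(capture_events) && nrow(capture_events) > 0) {
    for (k in seq_len(nrow(capture_events))) {
      ev <- capture_events$capture_time[k]
      post_capture <- post_capture |
        (fixes$animal_id == capture_events$animal_id[k] &
           fixes$timestamp >= ev &
           fixes$timestamp < ev + exclusion_hours * 3600)
    }
  }
  trapping <- rep(FALSE, n)
  if (!is.null(exclusion_windows) && nrow(exclusion_windows) > 0) {
    for (k in seq_len(nrow(exclusion_windows))) {
      trapping <- trapping |
        (fixes$animal_id == exclusion_windows$animal_id[k] &
           fixes$timestamp >= exclusion_windows$start[k] &
           fixes$timestamp <= exclusion_windows$end[k])
    }
  }

  reason <- rep(NA_character_, n)
  rule <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }
  rule(hdop > thresholds$max_hdop, "bad_hdop")
  rule(sats < thresholds$min_sats, "low_satellites")
  rule(height > thresholds$max_height, "high_altitude")
  rule(speed > thresholds$max_speed, "high_speed")
  rule(post_capture, "post_capture")
  rule(trapping, "trapping_window")

  removed <- !is.na(reason)
  list(
    retained = {
      r <- fixes[!removed, , drop = FALSE]
      rownames(r) <- NULL
      r
    },
    log = data.frame(
      animal_id = fixes$animal_id[removed],
      timestamp = fixes$timestamp[removed],
      reason = reason[removed],
      stringsAsFactors = FALSE
    )
  )
}
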