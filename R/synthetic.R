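#' Generate a synthetic animal population
#'
#' @param n_animals Number of animals (>= 1).
#' @param sex_ratio Expected female fraction, in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @param t0 Reference capture instant (POSIXct UTC); individual capture
#'   times are staggered uniformly over the two weeks after `t0`.
#' @return Data frame with columns `animal_id`, `sex` ("F"/"M"),
#'   `capture_time`.
#' @export
generate_population <- function(n_animals, sex_ratio = 0.5, seed = 1L,
                                t0 = as.POSIXct("2016-06-01 00:00:00", tz = "UTC")) {
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (sex_ratio < 0 || sex_ratio > 1) stop("sex_ratio must be in [0, 1]")
  with_seed(seed, {
    data.frame(
      animal_id = sprintf("A%03d", seq_len(n_animals)),
      sex = ifelse(stats::runif(n_animals) < sex_ratio, "F", "M"),
      capture_time = t0 + stats::runif(n_animals, 0, 14 * 86400),
      stringsAsFactors = FALSE
    )
  })
}

#' Define a known-truth selection scenario
#'
#' Ground truth for the habitat-biased trajectory generator: per-class
#' log selection strengths for day and night (reference scale: 0 means
#' no preference relative to availability), gamma step-length
#' parameters, turning-angle concentration and the number of candidate
#' endpoints evaluated per move.
#'
#' Turns are wrapped-normal; `turn_concentration` is the mean resultant
#' length rho in `[0, 1)` (0 = uniform turns, values near 1 = nearly
#' straight paths). The default rho = 0.578 corresponds to a circular
#' standard deviation of about 60 degrees.
#'
#' @param beta_day,beta_night Numeric 7-vectors of log selection
#'   strengths for classes 1..7 (class 7, waterbody, is never available
#'   regardless of its coefficient).
#' @param step_shape,step_scale Gamma step-length parameters (scale in
#'   metres); defaults shape 1.5, scale 30 m, plausible for a
#'   medium-sized herbivore at 15-min fixes.
#' @param turn_concentration Mean resultant length of the wrapped-normal
#'   turning-angle distribution, `[0, 1)`.
#' @param n_candidates Candidate endpoints per move.
#' @return An object of class `selection_scenario`.
#' @export
selection_scenario <- function(beta_day = rep(0, 7), beta_night = rep(0, 7),
                               step_shape = 1.5, step_scale = 30,
                               turn_concentration = 0.578,
                               n_candidates = 20L) {
  if (length(beta_day) != 7L || length(beta_night) != 7L)
    stop("beta_day and beta_night must have length 7")
  if (step_scale <= 0) stop("step_scale must be > 0")
  if (turn_concentration < 0 || turn_concentration >= 1)
    stop("turn_concentration must be in [0, 1)")
  structure(
    list(
      beta_day = as.numeric(beta_day), beta_night = as.numeric(beta_night),
      step_shape = step_shape, step_scale = step_scale,
      turn_concentration = turn_concentration,
      n_candidates = as.integer(n_candidates)
    ),
    class = "selection_scenario"
  )
}

# wrapped-normal turning angles with mean 0 and mean resultant length
# rho; sigma = sqrt(-2 log rho). rho = 0 degenerates to uniform turns.
rwrapped_normal <- function(n, rho) {
  if (rho <= 0) return(stats::runif(n, -pi, pi))
  sigma <- sqrt(-2 * log(rho))
  a <- stats::rnorm(n, 0, sigma)
  ((a + pi) %% (2 * pi)) - pi
}

#' Simulate a habitat-biased trajectory with known selection
#'
#' Step-selection-style generator: at each move, `n_candidates`
#' candidate endpoints are drawn from the gamma step-length and
#' wrapped-normal turning-angle distributions, and one is chosen with
#' probability proportional to `exp(beta[class])`, where `beta` is the
#' day or night coefficient vector according to the solar classification
#' of the step's timestamp. Candidates falling on waterbody or nodata
#' cells get probability zero; if every candidate is invalid the
#' candidate set is redrawn (up to 100 times, then an error is
#' signalled). Because the bias acts on candidate steps rather than on
#' points, recovered use-availability coefficients match the generator
#' in sign and rank, not in numerical value.
#'
#' @param landscape A [landscape_raster()].
#' @param scenario A [selection_scenario()].
#' @param start Length-2 numeric `(x, y)`, metres; must lie on a
#'   non-water, non-nodata cell.
#' @param t0 First fix instant (POSIXct UTC).
#' @param fix_interval Minutes between fixes (default 15).
#' @param n_steps Number of moves (>= 1); the trajectory has
#'   `n_steps + 1` fixes.
#' @param site_lat,site_lon Nominal site coordinates (degrees) used for
#'   the day/night classification of step timestamps.
#' @param seed Integer RNG seed.
#' @param depression_angle Dawn/dusk solar depression, degrees.
#' @return Data frame with columns `timestamp`, `x`, `y`, `diel`;
#'   attribute `scenario` carries the generating truth.
#' @export
simulate_biased_trajectory <- function(landscape, scenario, start, t0,
                                       fix_interval = 15, n_steps,
                                       site_lat = -38.5, site_lon = 145.25,
                                       seed = 1L, depression_angle = 6) {
  if (n_steps < 1) stop("n_steps must be >= 1")
  cls0 <- class_at(landscape, start[1], start[2])
  if (cls0 == 0L || cls0 == 7L) stop("start must lie on a non-water, non-nodata cell")
  times <- t0 + seq(0, n_steps) * fix_interval * 60
  diel <- classify_day_night(times, site_lat, site_lon, depression_angle)
  x <- numeric(n_steps + 1)
  y <- numeric(n_steps + 1)
  x[1] <- start[1]
  y[1] <- start[2]
  with_seed(seed, {
    heading <- stats::runif(1, -pi, pi)
    for (i in seq_len(n_steps)) {
      beta <- if (diel[i + 1] == "day") scenario$beta_day else scenario$beta_night
      chosen <- NULL
      for (attempt in seq_len(100L)) {
        len <- stats::rgamma(scenario$n_candidates, shape = scenario$step_shape,
                             scale = scenario$step_scale)
        turn <- rwrapped_normal(scenario$n_candidates, scenario$turn_concentration)
        h <- heading + turn
        cx <- x[i] + len * cos(h)
        cy <- y[i] + len * sin(h)
        cls <- class_at(landscape, cx, cy)
        wgt <- exp(beta[pmax(cls, 1L)])
        wgt[cls == 0L | cls == 7L] <- 0
        if (any(wgt > 0)) {
          j <- sample.int(scenario$n_candidates, 1L, prob = wgt)
          chosen <- list(x = cx[j], y = cy[j], h = h[j])
          break
        }
      }
      if (is.null(chosen))
        stop("no valid candidate endpoint after 100 redraws at step ", i)
      x[i + 1] <- chosen$x
      y[i + 1] <- chosen$y
      heading <- chosen$h
    }
  })
  out <- data.frame(timestamp = times, x = x, y = y, diel = diel,
                    stringsAsFactors = FALSE)
  attr(out, "scenario") <- scenario
  out
}

#' Specify GPS contamination
#'
#' @param frac_bad_hdop,frac_low_sats,frac_high_altitude,frac_speed_spike
#'   Fractions of fixes (each in `[0, 1]`) planted with, respectively,
#'   HDOP above 8, fewer than 3 satellites, height above 100 m ASL, and
#'   a positional displacement implying speed above 8 m/s.
#' @param gps_error_sd Gaussian positional error, metres.
#' @return An object of class `contamination_spec`.
#' @export
contamination_spec <- function(frac_bad_hdop = 0, frac_low_sats = 0,
                               frac_high_altitude = 0, frac_speed_spike = 0,
                               gps_error_sd = 0) {
  fr <- c(frac_bad_hdop, frac_low_sats, frac_high_altitude, frac_speed_spike)
  if (any(fr < 0 | fr > 1)) stop("contamination fractions must be in [0, 1]")
  if (gps_error_sd < 0) stop("gps_error_sd must be >= 0")
  structure(
    list(frac_bad_hdop = frac_bad_hdop, frac_low_sats = frac_low_sats,
         frac_high_altitude = frac_high_altitude,
         frac_speed_spike = frac_speed_spike, gps_error_sd = gps_error_sd),
    class = "contamination_spec"
  )
}

#' Degrade a truth trajectory to raw GPS fixes
#'
#' Adds Gaussian positional noise, then plants each defect category in a
#' disjoint random subset of `ceiling(fraction * n)` fixes: HDOP drawn
#' above 8, satellite count below 3, height above 100 m, or a positional
#' displacement large enough that the recomputed speed from the
#' preceding fix exceeds 8 m/s. Clean fixes receive in-range quality
#' metadata. The returned truth table flags every planted defect.
#'
#' @param truth Trajectory data frame from
#'   [simulate_biased_trajectory()] (columns `timestamp`, `x`, `y`).
#' @param spec A [contamination_spec()].
#' @param animal_id Identifier stamped on the fixes.
#' @param seed Integer RNG seed.
#' @return List with `fixes` (data frame: `animal_id`, `timestamp`, `x`,
#'   `y`, `hdop`, `n_sats`, `height`) and `truth_flags` (data frame of
#'   logical columns `bad_hdop`, `low_sats`, `high_altitude`,
#'   `speed_spike` plus `any_bad`).
#' @export
degrade_to_gps <- function(truth, spec, animal_id = "A001", seed = 1L) {
  n <- nrow(truth)
  if (n == 0L) stop("truth trajectory is empty")
  with_seed(seed, {
    x <- truth$x + stats::rnorm(n, 0, spec$gps_error_sd)
    y <- truth$y + stats::rnorm(n, 0, spec$gps_error_sd)
    n_bad <- function(f) if (f > 0) ceiling(f * n) else 0L
    pool <- sample.int(n) # disjoint category assignment
    take <- function(k) {
      idx <- head(pool, k)
      pool <<- tail(pool, length(pool) - k)
      idx
    }
    i_hdop <- take(n_bad(spec$frac_bad_hdop))
    i_sats <- take(n_bad(spec$frac_low_sats))
    i_alt <- take(n_bad(spec$frac_high_altitude))
    # displacement spikes on the first fix are undetectable by a
    # preceding-segment speed rule, so spikes avoid index 1
    i_spike <- setdiff(take(n_bad(spec$frac_speed_spike)), 1L)
    while (length(i_spike) < n_bad(spec$frac_speed_spike) && length(pool) > 0) {
      extra <- setdiff(take(1L), 1L)
      i_spike <- c(i_spike, extra)
    }

    hdop <- stats::runif(n, 0.6, 5)
    hdop[i_hdop] <- stats::runif(length(i_hdop), 8.5, 20)
    n_sats <- sample(4:11, n, replace = TRUE)
    n_sats[i_sats] <- sample(0:2, length(i_sats), replace = TRUE)
    height <- stats::runif(n, 0, 80)
    height[i_alt] <- stats::runif(length(i_alt), 150, 600)
    # displace each spike relative to its (possibly itself displaced)
    # predecessor so the recomputed incoming speed is guaranteed > 8 m/s
    for (i in sort(i_spike)) {
      dt <- as.numeric(difftime(truth$timestamp[i], truth$timestamp[i - 1L],
                                units = "secs"))
      dist_needed <- 8 * dt * stats::runif(1, 1.5, 3)
      ang <- stats::runif(1, -pi, pi)
      x[i] <- x[i - 1L] + dist_needed * cos(ang)
      y[i] <- y[i - 1L] + dist_needed * sin(ang)
    }
    flags <- data.frame(
      bad_hdop = seq_len(n) %in% i_hdop,
      low_sats = seq_len(n) %in% i_sats,
      high_altitude = seq_len(n) %in% i_alt,
      speed_spike = seq_len(n) %in% i_spike
    )
    flags$any_bad <- Reduce(`|`, flags)
    list(
      fixes = data.frame(
        animal_id = animal_id, timestamp = truth$timestamp,
        x = x, y = y, hdop = hdop, n_sats = n_sats, height = height,
        stringsAsFactors = FALSE
      ),
      truth_flags = flags
    )
  })
}

#' Write fixes as Movebank-style CSV
#'
#' @param fixes Data frame with columns `animal_id`, `timestamp`, `x`,
#'   `y` and optionally `hdop`, `n_sats`, `height`, `speed`.
#' @param path Output CSV path.
#' @export
write_fixes_csv <- function(fixes, path) {
  out <- data.frame(
    `individual-local-identifier` = fixes$animal_id,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    `utm-easting` = fixes$x,
    `utm-northing` = fixes$y,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!is.null(fixes$hdop)) out$`gps:hdop` <- fixes$hdop
  if (!is.null(fixes$n_sats)) out$`gps:satellite-count` <- fixes$n_sats
  if (!is.null(fixes$height)) out$`height-above-msl` <- fixes$height
  if (!is.null(fixes$speed)) out$`ground-speed` <- fixes$speed
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
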