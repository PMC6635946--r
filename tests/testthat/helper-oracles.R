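# Independent oracles and small fixture builders used across the suite.

# --- brute-force convex hull (gift wrapping / Jarvis march) ------------
# Independent of grDevices::chull; returns hull vertices in CCW order.
oracle_hull <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (length(hull) == 1L) setdiff(seq_len(n), cur) else seq_len(n)[-cur]
    best <- cand[1]
    for (k in cand[-1]) {
      cr <- (pts[best, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
        (pts[best, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      if (cr > 1e-12) {
        best <- k
      } else if (abs(cr) <= 1e-12) {
        # collinear: keep the farther point
        d_best <- sum((pts[best, ] - pts[cur, ])^2)
        d_k <- sum((pts[k, ] - pts[cur, ])^2)
        if (d_k > d_best) best <- k
      }
    }
    cur <- best
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# independent polygon area (triangle fan from the first vertex)
oracle_area <- function(poly) {
  a <- 0
  for (i in 2:(nrow(poly) - 1)) {
    v1 <- poly[i, ] - poly[1, ]
    v2 <- poly[i + 1, ] - poly[1, ]
    a <- a + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  abs(a)
}

# --- brute-force Euclidean distance transform --------------------------
oracle_edt <- function(mask, cell_size = 1) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  src <- which(mask, arr.ind = TRUE)
  d <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      d[i, j] <- sqrt(min((src[, 1] - i)^2 + (src[, 2] - j)^2))
    }
  }
  d * cell_size
}

# --- hand-rolled IRLS weighted logistic regression ---------------------
# Independent of glm(); Newton-Raphson on the weighted binomial
# log-likelihood.
oracle_irls <- function(X, y, w, tol = 1e-10, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- w * mu * (1 - mu)
    score <- t(X) %*% (w * (y - mu))
    H <- t(X) %*% (X * W)
    step <- solve(H, score)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# --- frozen NOAA dawn/dusk oracle (fractional-year formula set) --------
# Civil twilight (6 degree depression) events, UTC clock times of the
# UTC day; date boundaries are resolved at comparison time by testing
# the adjacent days too.
solar_oracle_cases <- list(
  list(lat = -38.5, lon = 145.25, date = "2016-06-21", dawn = "21:06:20", dusk = "07:34:23"),
  list(lat = -38.5, lon = 145.25, date = "2016-12-21", dawn = "18:19:22", dusk = "10:14:28"),
  list(lat = -38.5, lon = 145.25, date = "2016-03-20", dawn = "19:54:54", dusk = "08:58:36"),
  list(lat = -38.5, lon = 145.25, date = "2016-09-22", dawn = "19:43:12", dusk = "08:40:47"),
  list(lat = -38.5, lon = 145.25, date = "2017-01-15", dawn = "18:38:36", dusk = "10:15:34"),
  list(lat = 0.0, lon = 0.0, date = "2016-03-20", dawn = "05:43:56", dusk = "18:31:46"),
  list(lat = 51.5, lon = -0.1, date = "2016-06-21", dawn = "02:54:49", dusk = "21:09:04"),
  list(lat = 51.5, lon = -0.1, date = "2016-12-21", dawn = "07:23:25", dusk = "16:33:57"),
  list(lat = 35.7, lon = 139.7, date = "2016-04-10", dawn = "19:50:33", dusk = "09:35:37"),
  list(lat = -54.8, lon = -68.3, date = "2016-12-21", dawn = "06:54:22", dusk = "02:08:57")
)

# minutes between a computed POSIXct event and the nearest of the
# oracle clock time placed on the day before / of / after the case date
oracle_event_gap_min <- function(computed, case_date, clock) {
  cands <- as.POSIXct(paste(as.Date(case_date) + (-1:1), clock), tz = "UTC")
  min(abs(as.numeric(difftime(computed, cands, units = "mins"))))
}

# --- fixture builders --------------------------------------------------

# i.i.d. per-cell class raster (no spatial patches, no water)
iid_landscape <- function(n_rows = 40, n_cols = 40, cell_size = 10,
                          probs = c(0.4, 0.3, 0.2, 0.1), seed = 1) {
  cls <- withr::with_seed(seed,
    matrix(sample(seq_along(probs), n_rows * n_cols, replace = TRUE,
                  prob = probs), n_rows, n_cols)
  )
  landscape_raster(cls, cell_size = cell_size)
}

# two-block landscape: left half class a, right half class b
split_landscape <- function(n = 40, cell_size = 10, a = 1L, b = 2L) {
  cls <- matrix(b, n, n)
  cls[, seq_len(n %/% 2)] <- a
  landscape_raster(cls, cell_size = cell_size)
}

# a noon (UTC) timestamp at lon 0: daylight at mid-latitudes
midday_utc <- function(date = "2016-06-01") {
  as.POSIXct(paste(date, "12:00:00"), tz = "UTC")
}

# quick synthetic study for model-level tests: records from a null or
# biased generator on a patchy landscape
make_study_records <- function(n_animals = 4, n_steps = 200, seed = 1,
                               beta_day = rep(0, 7), beta_night = rep(0, 7),
                               weight_scheme = "none",
                               n_rows = 60, n_cols = 60,
                               animal_intercepts = NULL) {
  landscape <- generate_landscape(n_rows, n_cols, cell_size = 20, seed = seed)
  animals <- generate_population(n_animals, 0.5, seed = seed + 1)
  scen <- selection_scenario(beta_day = beta_day, beta_night = beta_night)
  seeds <- dielrsf:::child_seeds(seed + 2, n_animals)
  ok <- which(landscape$classes != 7L & landscape$classes != 0L, arr.ind = TRUE)
  starts <- withr::with_seed(seed + 3,
    ok[sample.int(nrow(ok), n_animals, replace = TRUE), , drop = FALSE])
  observed <- list()
  simulated <- list()
  for (i in seq_len(n_animals)) {
    ctr <- cell_centers(landscape, starts[i, 1], starts[i, 2])
    tr <- simulate_biased_trajectory(
      landscape, scen, start = c(ctr$x, ctr$y),
      t0 = as.POSIXct("2016-06-10 00:00:00", tz = "UTC"),
      fix_interval = 15, n_steps = n_steps, seed = seeds[i]
    )
    id <- animals$animal_id[i]
    observed[[id]] <- tr
    region <- availability_region(mcp(tr[, c("x", "y")]), landscape)
    simulated[[id]] <- simulate_crw(empirical_steps(tr), region,
                                    n_walks = 5, seed = seeds[i] + 1)
  }
  records <- build_case_control(observed, simulated, animals,
                                weight_scheme = weight_scheme)
  stack <- distance_stack(landscape)
  records <- annotate_records(records, landscape, stack)
  if (!is.null(animal_intercepts)) {
    # thin used records per animal to induce per-animal prevalence
    # heterogeneity (a crude random-intercept signal)
    keep <- rep(TRUE, nrow(records))
    for (i in seq_len(n_animals)) {
      id <- animals$animal_id[i]
      p_keep <- stats::plogis(animal_intercepts[i])
      used_i <- which(records$animal_id == id & records$case == 1L)
      drop_n <- round((1 - p_keep) * length(used_i))
      if (drop_n > 0) {
        keep[withr::with_seed(seed + 20 + i,
                              sample(used_i, drop_n))] <- FALSE
      }
    }
    records <- records[keep, , drop = FALSE]
  }
  list(records = records, landscape = landscape, stack = stack,
       animals = animals)
}
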