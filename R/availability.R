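#' 100% minimum convex polygon
#'
#' Convex hull of all points (no peeling) with its shoelace area; the
#' simplest home-range estimate.
#'
#' @param points Matrix or data frame with columns x, y (>= 3
#'   non-collinear points).
#' @return List with `polygon` (counter-clockwise vertex matrix, open
#'   ring) and `area` (m^2).
#' @export
mcp <- function(points) {
  pts <- as.matrix(points[, 1:2])
  if (nrow(pts) < 3L) stop("mcp needs at least 3 points")
  idx <- grDevices::chull(pts[, 1], pts[, 2]) # clockwise order
  poly <- pts[rev(idx), , drop = FALSE]       # counter-clockwise
  a <- shoelace_area(poly)
  if (a <= 0) stop("degenerate hull: points are collinear")
  list(polygon = poly, area = a)
}

# signed shoelace area of an open CCW ring, returned positive
shoelace_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# is each point inside (or on) a convex CCW polygon?
point_in_convex <- function(poly, x, y) {
  inside <- rep(TRUE, length(x))
  nv <- nrow(poly)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (x - poly[i, 1])
    inside <- inside & (cross >= -1e-9)
  }
  inside
}

# Euclidean distance from points to a convex polygon (0 inside)
dist_to_convex <- function(poly, x, y) {
  d <- rep(Inf, length(x))
  nv <- nrow(poly)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[j, 1]; by <- poly[j, 2]
    vx <- bx - ax; vy <- by - ay
    tt <- ((x - ax) * vx + (y - ay) * vy) / (vx^2 + vy^2)
    tt <- pmin(pmax(tt, 0), 1)
    d <- pmin(d, sqrt((x - (ax + tt * vx))^2 + (y - (ay + tt * vy))^2))
  }
  d[point_in_convex(poly, x, y)] <- 0
  d
}

#' Build an animal's availability region
#'
#' The 100% MCP dilated outward by half the square root of its area,
#' with waterbody (class 7) and nodata cells excluded. A point belongs
#' to the region iff its distance to the hull is at most the buffer
#' distance and its containing landscape cell is neither water nor
#' nodata nor outside the extent.
#'
#' @param hull Result of [mcp()] (or list with `polygon`, `area`).
#' @param landscape A [landscape_raster()] covering or overlapping the
#'   buffered hull.
#' @return An object of class `availability_region`: `hull`,
#'   `buffer_distance` (m), `landscape`, `mask` (logical cell matrix of
#'   region membership by cell centre), `area` (rasterised, m^2),
#'   `bbox`.
#' @export
availability_region <- function(hull, landscape) {
  b <- 0.5 * sqrt(hull$area)
  nr <- landscape$n_rows
  nc <- landscape$n_cols
  rc <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ctr <- cell_centers(landscape, rc$row, rc$col)
  inside <- dist_to_convex(hull$polygon, ctr$x, ctr$y) <= b
  cls <- landscape$classes[cbind(rc$row, rc$col)]
  ok <- inside & cls != 7L & cls != 0L
  mask <- matrix(FALSE, nr, nc)
  mask[cbind(rc$row, rc$col)] <- ok
  if (!any(mask)) stop("availability region is empty (buffered hull entirely water/nodata)")
  bbox <- c(
    xmin = min(hull$polygon[, 1]) - b, xmax = max(hull$polygon[, 1]) + b,
    ymin = min(hull$polygon[, 2]) - b, ymax = max(hull$polygon[, 2]) + b
  )
  poly <- hull$polygon
  nxt <- c(2:nrow(poly), 1)
  structure(
    list(hull = hull, buffer_distance = b, landscape = landscape,
         mask = mask, area = sum(mask) * landscape$cell_size^2, bbox = bbox,
         # precomputed edge table for fast membership tests
         edges = list(ax = poly[, 1], ay = poly[, 2],
                      vx = poly[nxt, 1] - poly[, 1],
                      vy = poly[nxt, 2] - poly[, 2],
                      vv = (poly[nxt, 1] - poly[, 1])^2 +
                        (poly[nxt, 2] - poly[, 2])^2)),
    class = "availability_region"
  )
}

#' Point membership in an availability region
#'
#' @param region An [availability_region()].
#' @param x,y Numeric coordinate vectors (metres).
#' @return Logical vector.
#' @export
region_contains <- function(region, x, y) {
  e <- region$edges
  nv <- length(e$ax)
  m <- length(x)
  X <- matrix(x, nv, m, byrow = TRUE)
  Y <- matrix(y, nv, m, byrow = TRUE)
  dx <- X - e$ax
  dy <- Y - e$ay
  inside <- colSums(e$vx * dy - e$vy * dx >= -1e-9) == nv
  tt <- (dx * e$vx + dy * e$vy) / e$vv
  tt[tt < 0] <- 0
  tt[tt > 1] <- 1
  ex <- dx - tt * e$vx
  ey <- dy - tt * e$vy
  d2 <- ex * ex + ey * ey
  dmin2 <- d2[cbind(max.col(-t(d2), ties.method = "first"), seq_len(m))]
  cls <- class_at(region$landscape, x, y)
  (inside | dmin2 <= region$buffer_distance^2) & cls != 7L & cls != 0L
}

#' Empirical step lengths and turning angles
#'
#' For n fixes: n-1 step lengths and n-2 signed turning angles (left
#' turns positive) wrapped to (-pi, pi]. A zero-length step has no
#' defined heading; the adjacent turning angle is treated as 0
#' (heading inherited) and excluded from the turning-angle multiset.
#'
#' @param trajectory Time-ordered data frame with columns `timestamp`,
#'   `x`, `y` (>= 3 fixes).
#' @return Object of class `step_series`: `step_lengths` (m),
#'   `turning_angles` (radians), `timestamps`.
#' @export
empirical_steps <- function(trajectory) {
  n <- nrow(trajectory)
  if (n < 3L) stop("empirical_steps needs at least 3 fixes")
  dx <- diff(trajectory$x)
  dy <- diff(trajectory$y)
  len <- sqrt(dx^2 + dy^2)
  headings <- atan2(dy, dx)
  # carry the last defined heading across zero-length steps
  for (i in seq_along(headings)[-1]) {
    if (len[i] == 0) headings[i] <- headings[i - 1]
  }
  turns <- diff(headings)
  turns <- ((turns + pi) %% (2 * pi)) - pi
  turns[turns == -pi] <- pi
  degenerate <- (len[-length(len)] == 0) | (len[-1] == 0)
  structure(
    list(step_lengths = len,
         turning_angles = turns[!degenerate],
         # (angle, following step length) pairs for joint resampling
         pairs = data.frame(angle = turns[!degenerate],
                            length = len[-1][!degenerate]),
         timestamps = trajectory$timestamp),
    class = "step_series"
  )
}

# uniform start point by rejection sampling in the region's bounding box
sample_start <- function(region, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    x <- stats::runif(1, region$bbox["xmin"], region$bbox["xmax"])
    y <- stats::runif(1, region$bbox["ymin"], region$bbox["ymax"])
    if (region_contains(region, x, y)) return(c(x, y))
  }
  stop("could not draw a start point inside the availability region")
}

#' Simulate correlated random walks inside an availability region
#'
#' Each walk reproduces the source trajectory's fix count and exact
#' timestamps. The start point is uniform over the region, the initial
#' heading uniform on (-pi, pi], and each subsequent step draws a step
#' length and a turning angle independently, with replacement, from the
#' empirical multisets. A proposed point outside the region triggers a
#' redraw (up to 100 pairs); if exhausted, the angle alone is redrawn
#' with the smallest observed step length (logged in the `fallbacks`
#' attribute); if still infeasible an error is signalled. Deterministic
#' per seed, with per-walk child seeds so results do not depend on
#' iteration order.
#'
#' @param steps A [empirical_steps()] result.
#' @param region An [availability_region()].
#' @param n_walks Number of walks (default 5).
#' @param seed Integer RNG seed.
#' @param joint Resample empirical (turning angle, following step
#'   length) pairs together instead of independently (default FALSE).
#' @return List of data frames (`timestamp`, `x`, `y`), one per walk,
#'   each with attribute `drawn_lengths`.
#' @export
simulate_crw <- function(steps, region, n_walks = 5L, seed = 1L,
                         joint = FALSE) {
  if (length(steps$step_lengths) == 0L) stop("empty step series")
  n_fix <- length(steps$timestamps)
  seeds <- child_seeds(seed, n_walks)
  lens <- steps$step_lengths
  turns <- steps$turning_angles
  if (length(turns) == 0L) turns <- 0
  min_len <- min(lens)
  lapply(seq_len(n_walks), function(w) {
    with_seed(seeds[w], {
      x <- numeric(n_fix)
      y <- numeric(n_fix)
      drawn <- numeric(n_fix - 1L)
      st <- sample_start(region)
      x[1] <- st[1]
      y[1] <- st[2]
      heading <- stats::runif(1, -pi, pi)
      n_fallback <- 0L
      for (i in seq_len(n_fix - 1L)) {
        # 100 (length, angle) redraws: a small first batch (most steps
        # accept immediately), then the remainder
        if (joint && nrow(steps$pairs) > 0) {
          j <- sample.int(nrow(steps$pairs), 4L, replace = TRUE)
          l <- steps$pairs$length[j]
          a <- steps$pairs$angle[j]
        } else {
          l <- lens[sample.int(length(lens), 4L, replace = TRUE)]
          a <- turns[sample.int(length(turns), 4L, replace = TRUE)]
        }
        h <- heading + a
        px <- x[i] + l * cos(h)
        py <- y[i] + l * sin(h)
        hit <- which(region_contains(region, px, py))
        if (length(hit) == 0L) {
          if (joint && nrow(steps$pairs) > 0) {
            j <- sample.int(nrow(steps$pairs), 96L, replace = TRUE)
            l <- steps$pairs$length[j]
            a <- steps$pairs$angle[j]
          } else {
            l <- lens[sample.int(length(lens), 96L, replace = TRUE)]
            a <- turns[sample.int(length(turns), 96L, replace = TRUE)]
          }
          h <- heading + a
          px <- x[i] + l * cos(h)
          py <- y[i] + l * sin(h)
          hit <- which(region_contains(region, px, py))
        }
        if (length(hit) == 0L) {
          # fallback: smallest observed step, angle redrawn
          n_fallback <- n_fallback + 1L
          a <- turns[sample.int(length(turns), 100L, replace = TRUE)]
          h <- heading + a
          l <- rep(min_len, 100L)
          px <- x[i] + l * cos(h)
          py <- y[i] + l * sin(h)
          hit <- which(region_contains(region, px, py))
        }
        if (length(hit) == 0L)
          stop("CRW retry budget exhausted at fix ", i,
               ": availability region over-constrained")
        j <- hit[1L]
        x[i + 1] <- px[j]
        y[i + 1] <- py[j]
        heading <- h[j]
        drawn[i] <- l[j]
      }
      out <- data.frame(timestamp = steps$timestamps, x = x, y = y)
      attr(out, "drawn_lengths") <- drawn
      attr(out, "n_fallback") <- n_fallback
      out
    })
  })
}

#' Assemble the use-availability case-control table
#'
#' Observed fixes become case 1 records with weight 1; simulated walk
#' points become case 0 records carrying their source animal's id, with
#' weight 1 (`weight_scheme = "none"`) or `n_used / n_available`
#' (`"equalize"`, which makes the weighted totals equal). The diel class
#' is attached from each record's own timestamp.
#'
#' @param observed Named list of trajectories (data frames `timestamp`,
#'   `x`, `y`), one per animal; names are animal ids.
#' @param simulated Named list (same names) of walk lists from
#'   [simulate_crw()].
#' @param animals Data frame (`animal_id`, `sex`) of animal attributes.
#' @param weight_scheme `"none"` or `"equalize"`.
#' @param site_lat,site_lon Site coordinates for the diel
#'   classification.
#' @param depression_angle Dawn/dusk depression, degrees.
#' @return Data frame of location records: `animal_id`, `case`, `x`,
#'   `y`, `timestamp`, `diel`, `sex`, `weight`.
#' @export
build_case_control <- function(observed, simulated, animals,
                               weight_scheme = c("none", "equalize"),
                               site_lat = -38.5, site_lon = 145.25,
                               depression_angle = 6) {
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(all(names(observed) %in% animals$animal_id))
  missing_sim <- setdiff(names(observed), names(simulated))
  if (length(missing_sim) > 0)
    stop("animals with used but no available records: ",
         paste(missing_sim, collapse = ", "))
  rows <- list()
  for (id in names(observed)) {
    obs <- observed[[id]]
    sims <- simulated[[id]]
    sex <- animals$sex[match(id, animals$animal_id)]
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = id, case = 1L, x = obs$x, y = obs$y,
      timestamp = obs$timestamp, sex = sex, stringsAsFactors = FALSE
    )
    for (wk in sims) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, case = 0L, x = wk$x, y = wk$y,
        timestamp = wk$timestamp, sex = sex, stringsAsFactors = FALSE
      )
    }
  }
  rec <- do.call(rbind, rows)
  rec$diel <- classify_day_night(rec$timestamp, site_lat, site_lon,
                                 depression_angle)
  n_used <- sum(rec$case == 1L)
  n_avail <- sum(rec$case == 0L)
  rec$weight <- 1
  if (weight_scheme == "equalize" && n_avail > 0)
    rec$weight[rec$case == 0L] <- n_used / n_avail
  rownames(rec) <- NULL
  rec
}
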