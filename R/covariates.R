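#' @name landscape_covariates
#' @title Habitat annotation and model covariates
#'
#' @description Exact Euclidean distance transforms from each landscape
#' class, annotation of location records with habitat class and the
#' seven distances, and covariate preparation: Pearson correlation
#' screen, spline curvature screen for polynomial degree, z-score
#' standardisation with a reusable recipe, and presentation-range
#' distance caps.
NULL

# 1D squared-distance transform (lower envelope of parabolas),
# Felzenszwalb-Huttenlocher; f = squared distances (large finite for
# "no source").
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# exact Euclidean distance (cell units) to the nearest TRUE cell
edt_cells <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  BIG <- 1e15
  # pass 1: per column, squared distance along rows to nearest TRUE
  g <- matrix(BIG, nr, nc)
  for (j in seq_len(nc)) {
    col <- mask[, j]
    if (!any(col)) next
    near <- rep(NA_integer_, nr)
    last <- NA_integer_
    up <- rep(NA_integer_, nr)
    for (i in seq_len(nr)) {
      if (col[i]) last <- i
      up[i] <- last
    }
    last <- NA_integer_
    down <- rep(NA_integer_, nr)
    for (i in rev(seq_len(nr))) {
      if (col[i]) last <- i
      down[i] <- last
    }
    du <- ifelse(is.na(up), BIG, (seq_len(nr) - up)^2)
    dd <- ifelse(is.na(down), BIG, (seq_len(nr) - down)^2)
    g[, j] <- pmin(du, dd)
  }
  # pass 2: per row, add squared distance along columns
  d <- matrix(0, nr, nc)
  for (i in seq_len(nr)) d[i, ] <- dt1d(g[i, ])
  sqrt(d)
}

#' Distance grid to one landscape class
#'
#' Exact Euclidean distance from every cell centre to the nearest cell
#' centre of the given class (two-pass exact distance transform); zero
#' on the class's own cells.
#'
#' @param landscape A [landscape_raster()].
#' @param class_code Integer class code 1--7; must be present in the
#'   raster.
#' @return Numeric matrix of distances, metres.
#' @export
distance_to_class <- function(landscape, class_code) {
  mask <- landscape$classes == as.integer(class_code)
  if (!any(mask))
    stop("class ", class_code, " absent from raster: distance undefined")
  edt_cells(mask) * landscape$cell_size
}

#' Distance grids for all seven classes
#'
#' @param landscape A [landscape_raster()].
#' @return Object of class `distance_stack`: named list of 7 distance
#'   matrices (`dist_1` .. `dist_7`), metres, plus the source geometry.
#' @export
distance_stack <- function(landscape) {
  grids <- lapply(1:7, function(k) distance_to_class(landscape, k))
  names(grids) <- paste0("dist_", 1:7)
  structure(list(grids = grids, landscape = landscape),
            class = "distance_stack")
}

#' Annotate location records with habitat class and distances
#'
#' @param records Data frame with columns `x`, `y` (all inside the
#'   raster extent).
#' @param landscape A [landscape_raster()].
#' @param stack A [distance_stack()] aligned to `landscape`.
#' @return `records` with added `habitat_class` and `dist_1` ..
#'   `dist_7` columns.
#' @export
annotate_records <- function(records, landscape, stack) {
  rc <- cell_of(landscape, records$x, records$y)
  if (anyNA(rc$row)) stop(sum(is.na(rc$row)), " record(s) outside the raster extent")
  ij <- cbind(rc$row, rc$col)
  records$habitat_class <- landscape$classes[ij]
  for (k in 1:7) records[[paste0("dist_", k)]] <- stack$grids[[k]][ij]
  records
}

#' Pearson correlation screen of distance covariates
#'
#' Flags feature pairs whose distances correlate with |r| > 0.7 over
#' all records. Advisory only: pairs are reported, never dropped.
#'
#' @param records Annotated records (>= 3 rows).
#' @param threshold Absolute-correlation flag level (default 0.7).
#' @return Data frame of all pairs: `feature_a`, `feature_b`, `r`,
#'   `flagged` (NA r for zero-variance features, reported not flagged).
#' @export
correlation_screen <- function(records, threshold = 0.7) {
  if (nrow(records) < 3L) stop("correlation screen needs >= 3 records")
  cols <- paste0("dist_", 1:7)
  cols <- cols[cols %in% names(records)]
  out <- list()
  for (a in seq_along(cols)) {
    for (b in seq_along(cols)) {
      if (b <= a) next
      va <- records[[cols[a]]]
      vb <- records[[cols[b]]]
      r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_ else
        stats::cor(va, vb)
      out[[length(out) + 1L]] <- data.frame(
        feature_a = cols[a], feature_b = cols[b], r = r,
        flagged = !is.na(r) && abs(r) > threshold
      )
    }
  }
  do.call(rbind, out)
}

# 3-df binomial smoothing spline of case on d, evaluated with standard
# errors on an n-point grid over the observed range; classifies the
# smooth's shape. The smooth counts as non-monotone only when both its
# total rise and total fall exceed twice the mean pointwise standard
# error, so noise wiggle around a flat or monotone trend does not
# register as curvature.
smooth_response <- function(d, case, weights = NULL, n_grid = 100L) {
  if (is.null(weights)) weights <- rep(1, length(d))
  df <- data.frame(case = case, d = d, w = weights)
  fit <- suppressWarnings(
    mgcv::gam(case ~ s(d, k = 4, fx = TRUE), family = stats::binomial(),
              weights = w, data = df)
  )
  grid <- seq(min(d), max(d), length.out = n_grid)
  pr <- stats::predict(fit, newdata = data.frame(d = grid), se.fit = TRUE)
  eta <- as.numeric(pr$fit)
  dd <- diff(eta)
  rise <- sum(dd[dd > 0])
  fall <- -sum(dd[dd < 0])
  noise <- 2 * mean(as.numeric(pr$se.fit))
  monotone <- min(rise, fall) <= noise
  turning_point <- NA_real_
  if (!monotone) {
    # interior extremum of the dominant hump/dip
    i <- if (eta[which.max(abs(eta - eta[1]))] >= eta[1]) which.max(eta)
         else which.min(eta)
    if (i > 1 && i < n_grid) turning_point <- grid[i]
  }
  list(grid = grid, eta = eta, se = as.numeric(pr$se.fit),
       monotone = monotone, turning_point = turning_point)
}

#' Curvature screen: polynomial degree for one distance covariate
#'
#' Fits a binomial additive model of case status on a 3-df cubic spline
#' basis of the distance (weighted as the main model) and inspects the
#' fitted smooth on a 100-point grid: an interior sign change of its
#' first difference (non-monotonicity) selects a second-order
#' polynomial, otherwise first order. A flat smooth counts as monotone.
#' Non-convergence falls back to degree 1 with a warning.
#'
#' @param records Annotated records with `case` and `weight` columns.
#' @param feature Class code 1--7.
#' @return Integer 1 or 2.
#' @export
curvature_screen <- function(records, feature) {
  d <- records[[paste0("dist_", feature)]]
  if (stats::sd(d) == 0) stop("feature has no variation")
  sm <- tryCatch(
    smooth_response(d, records$case, records$weight),
    error = function(e) {
      warning("curvature screen fit failed (", conditionMessage(e),
              "); defaulting to degree 1")
      NULL
    }
  )
  if (is.null(sm)) return(1L)
  if (sm$monotone) 1L else 2L
}

#' Default polynomial degrees for the distance covariates
#'
#' Second-order for woodland/scrub, farmland, coastal, wetland and
#' road distances; first-order for housing and waterbody.
#'
#' @return Named integer vector over classes 1..7.
#' @export
default_degrees <- function() {
  stats::setNames(c(2L, 2L, 2L, 2L, 1L, 2L, 1L), paste0("dist_", 1:7))
}

#' Build a standardisation recipe from the record pool
#'
#' Centres (means) and scales (standard deviations) of the seven
#' distance covariates over the combined used + available pool, plus
#' the polynomial degree per feature. Stored so that prediction-time
#' grids and maps reuse the training transform.
#'
#' @param records Annotated records (used and available together).
#' @param degrees Named integer vector of polynomial degrees (default
#'   [default_degrees()]; or computed per feature with
#'   [curvature_screen()]).
#' @return Object of class `covariate_recipe`.
#' @export
covariate_recipe <- function(records, degrees = default_degrees()) {
  cols <- paste0("dist_", 1:7)
  center <- vapply(cols, function(cc) mean(records[[cc]]), numeric(1))
  scale <- vapply(cols, function(cc) stats::sd(records[[cc]]), numeric(1))
  if (any(scale <= 0)) stop("zero-variance distance covariate: ",
                            paste(cols[scale <= 0], collapse = ", "))
  structure(list(center = center, scale = scale,
                 degrees = degrees[cols]),
            class = "covariate_recipe")
}

#' Standardise values with a stored centre and scale
#'
#' @param values Numeric vector.
#' @param center,scale Centre and scale (scale > 0).
#' @return z-scores `(values - center) / scale`.
#' @export
standardize <- function(values, center, scale) {
  if (scale <= 0) stop("scale must be > 0")
  (values - center) / scale
}

#' Apply a recipe: add standardised covariate columns
#'
#' Adds `z_1` .. `z_7` columns (and squared terms are formed on the
#' standardised scale at model-fit time).
#'
#' @param records Annotated records.
#' @param recipe A [covariate_recipe()].
#' @return `records` with `z_*` columns.
#' @export
apply_recipe <- function(records, recipe) {
  for (k in 1:7) {
    cc <- paste0("dist_", k)
    records[[paste0("z_", k)]] <-
      standardize(records[[cc]], recipe$center[[cc]], recipe$scale[[cc]])
  }
  records
}

#' Presentation cap for a distance covariate
#'
#' The first interior extremum of the 3-df fitted smooth of case on
#' distance, capped at `max_cap` metres. Used only to bound
#' distance-response curves and axes, never to alter the data a model
#' is fitted to.
#'
#' @param records Annotated records with `case` and `weight`.
#' @param feature Class code 1--7.
#' @param cap_rule `"min_of_both"` (default), `"turning_point"` or
#'   `"fixed_500"`.
#' @param max_cap Fixed maximum, metres (default 500).
#' @return Cap in metres.
#' @export
distance_cap <- function(records, feature,
                         cap_rule = c("min_of_both", "turning_point", "fixed_500"),
                         max_cap = 500) {
  cap_rule <- match.arg(cap_rule)
  if (cap_rule == "fixed_500") return(max_cap)
  d <- records[[paste0("dist_", feature)]]
  sm <- smooth_response(d, records$case, records$weight)
  tp <- sm$turning_point
  if (cap_rule == "turning_point") {
    if (is.na(tp)) max_cap else tp
  } else {
    min(c(tp, max_cap), na.rm = TRUE)
  }
}

#' Cap values for presentation
#'
#' @param values Numeric vector of distances, metres.
#' @param cap Cap in metres (from [distance_cap()]).
#' @return `pmin(values, cap)`.
#' @export
cap_distance <- function(values, cap) pmin(values, cap)

#' Write a distance grid as ESRI ASCII
#'
#' @param stack A [distance_stack()].
#' @param class_code Class 1--7.
#' @param path Output path.
#' @export
write_distance_grid <- function(stack, class_code, path) {
  ls <- stack$landscape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ls$n_cols), paste("nrows", ls$n_rows),
    paste("xllcorner", ls$origin_x), paste("yllcorner", ls$origin_y),
    paste("cellsize", ls$cell_size), paste("NODATA_value", -9999)
  ), con)
  m <- stack$grids[[paste0("dist_", class_code)]]
  writeLines(apply(round(m, 3), 1L, paste, collapse = " "), con)
  invisible(path)
}
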