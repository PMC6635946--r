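#' Landscape class codes
#'
#' Integer codes of the seven landscape features used throughout the
#' package, plus 0 for nodata (outside the mapped extent). Waterbody
#' (code 7) is the only class treated as unsuitable habitat.
#'
#' @format Named integer vector of length 7.
#' @export
landscape_classes <- c(
  woodland_scrub = 1L,
  farmland       = 2L,
  coastal        = 3L,
  wetland        = 4L,
  housing        = 5L,
  road           = 6L,
  waterbody      = 7L
)

#' Construct a categorical landscape raster
#'
#' A `landscape_raster` is a regular square-celled grid of integer
#' habitat codes 0--7 (0 = nodata). Row 1 is the top of the map; the
#' origin is the lower-left corner of the grid, so cell (r, c) covers
#' the half-open intervals
#' `[origin_x + (c-1)*cell_size, origin_x + c*cell_size)` in x and
#' `[origin_y + (n_rows-r)*cell_size, origin_y + (n_rows-r+1)*cell_size)`
#' in y.
#'
#' @param classes Integer matrix of class codes in `0:7`.
#' @param origin_x,origin_y Lower-left corner, metres.
#' @param cell_size Cell edge length, metres (> 0).
#' @return An object of class `landscape_raster`.
#' @export
landscape_raster <- function(classes, origin_x = 0, origin_y = 0, cell_size) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (anyNA(classes) || any(classes < 0L | classes > 7L))
    stop("classes must be integer codes in 0..7 with no NA")
  structure(
    list(
      origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
      cell_size = as.numeric(cell_size),
      n_rows = nrow(classes), n_cols = ncol(classes),
      classes = classes
    ),
    class = "landscape_raster"
  )
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat(sprintf(
    "landscape_raster: %d x %d cells, %g m resolution, origin (%g, %g)\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y
  ))
  tab <- table(factor(x$classes, levels = 0:7))
  names(tab) <- c("nodata", names(landscape_classes))
  print(tab[tab > 0])
  invisible(x)
}

#' Locate the cell containing a point
#'
#' Half-open cell membership: a point on the left/bottom edge of a cell
#' belongs to that cell. Points outside the extent get NA.
#'
#' @param landscape A [landscape_raster()].
#' @param x,y Numeric vectors of planar coordinates (metres).
#' @return Data frame with columns `row`, `col` (NA outside the extent).
#' @export
cell_of <- function(landscape, x, y) {
  cs <- landscape$cell_size
  col <- floor((x - landscape$origin_x) / cs) + 1
  row_from_bottom <- floor((y - landscape$origin_y) / cs)
  row <- landscape$n_rows - row_from_bottom
  bad <- col < 1 | col > landscape$n_cols | row < 1 | row > landscape$n_rows |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Habitat class at point locations
#'
#' @inheritParams cell_of
#' @return Integer vector of class codes; 0 (nodata) for points outside
#'   the extent.
#' @export
class_at <- function(landscape, x, y) {
  cs <- landscape$cell_size
  col <- floor((x - landscape$origin_x) / cs) + 1
  row <- landscape$n_rows - floor((y - landscape$origin_y) / cs)
  ok <- col >= 1 & col <= landscape$n_cols & row >= 1 &
    row <= landscape$n_rows & is.finite(x) & is.finite(y)
  out <- integer(length(x))
  out[ok] <- landscape$classes[(col[ok] - 1) * landscape$n_rows + row[ok]]
  out
}

#' Cell-centre coordinates
#'
#' @param landscape A [landscape_raster()].
#' @param rows,cols Integer cell indices (row 1 = top).
#' @return Data frame with columns `x`, `y` (metres).
#' @export
cell_centers <- function(landscape, rows, cols) {
  cs <- landscape$cell_size
  data.frame(
    x = landscape$origin_x + (cols - 0.5) * cs,
    y = landscape$origin_y + (landscape$n_rows - rows + 0.5) * cs
  )
}

#' Write a landscape raster as ESRI ASCII grid
#'
#' @param landscape A [landscape_raster()].
#' @param path Output file path.
#' @param nodata Code written for nodata cells (default 0, the internal
#'   nodata code).
#' @export
write_ascii_grid <- function(landscape, path, nodata = 0L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", landscape$n_cols),
    paste("nrows", landscape$n_rows),
    paste("xllcorner", landscape$origin_x),
    paste("yllcorner", landscape$origin_y),
    paste("cellsize", landscape$cell_size),
    paste("NODATA_value", nodata)
  ), con)
  m <- landscape$classes
  m[m == 0L] <- as.integer(nodata)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid as a landscape raster
#'
#' @param path File written by [write_ascii_grid()] or any integer-coded
#'   ESRI ASCII grid with codes 0--7.
#' @return A [landscape_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], what = integer(), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- 0L
  landscape_raster(m,
    origin_x = hdr$xllcorner %||% 0, origin_y = hdr$yllcorner %||% 0,
    cell_size = hdr$cellsize
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Moving-average smoothing of a white-noise field; `passes` box-blur
# sweeps give smooth blobs whose scale grows with `radius`.
smooth_field <- function(n_rows, n_cols, radius = 3L, passes = 3L) {
  f <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  for (p in seq_len(passes)) {
    g <- matrix(0, n_rows, n_cols)
    w <- 0
    for (dr in -radius:radius) {
      rs <- pmin(pmax(seq_len(n_rows) + dr, 1L), n_rows)
      g <- g + f[rs, , drop = FALSE]
      w <- w + 1
    }
    f <- g / w
    g <- matrix(0, n_rows, n_cols)
    for (dc in -radius:radius) {
      cs <- pmin(pmax(seq_len(n_cols) + dc, 1L), n_cols)
      g <- g + f[, cs, drop = FALSE]
    }
    f <- g / w
  }
  f
}

#' Generate a patchy synthetic landscape
#'
#' Builds a categorical raster emulating a fragmented coastal landscape:
#' patchy area classes (woodland/scrub, farmland, coastal, wetland,
#' housing) from thresholded smoothed Gaussian noise, one-cell-wide road
#' polylines, and contiguous waterbody blobs. Every class with positive
#' weight is guaranteed at least one cell. Deterministic for a fixed
#' seed.
#'
#' @param n_rows,n_cols Grid dimensions (both >= 10).
#' @param cell_size Cell edge, metres.
#' @param class_weights Nonnegative 7-vector of expected area shares for
#'   codes 1..7 (normalised internally; sum must be positive).
#' @param seed Integer RNG seed.
#' @return A [landscape_raster()].
#' @export
generate_landscape <- function(n_rows, n_cols, cell_size = 20,
                               class_weights = c(3, 4, 1, 1, 1.5, 0.5, 1),
                               seed = 1L) {
  if (n_rows < 10 || n_cols < 10) stop("n_rows and n_cols must be >= 10")
  if (length(class_weights) != 7L || any(class_weights < 0))
    stop("class_weights must be 7 nonnegative values")
  if (sum(class_weights) <= 0) stop("class_weights must have positive sum")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  w <- class_weights / sum(class_weights)
  m <- matrix(0L, n_rows, n_cols)

  # area classes 1-5 from one smoothed field, split at weight quantiles
  area_codes <- which(w[1:5] > 0)
  f <- smooth_field(n_rows, n_cols, radius = max(2L, round(min(n_rows, n_cols) / 20)))
  if (length(area_codes) > 0) {
    wa <- w[area_codes] / sum(w[area_codes])
    qs <- stats::quantile(f, probs = cumsum(wa)[-length(wa)])
    m[] <- area_codes[findInterval(f, qs) + 1L]
  }

  # waterbodies: top quantile of a second field -> contiguous blobs
  if (w[7] > 0) {
    fw <- smooth_field(n_rows, n_cols, radius = max(2L, round(min(n_rows, n_cols) / 15)))
    thr <- stats::quantile(fw, probs = 1 - w[7])
    m[fw >= thr] <- 7L
  }

  # roads: 1-cell-wide polylines crossing the grid
  if (w[6] > 0) {
    n_road_cells_target <- max(n_cols, round(w[6] * n_rows * n_cols))
    n_roads <- max(1L, round(n_road_cells_target / max(n_rows, n_cols)))
    for (k in seq_len(n_roads)) {
      horizontal <- (k %% 2L == 1L)
      if (horizontal) {
        r <- sample.int(n_rows, 1L)
        drift <- cumsum(sample(c(-1L, 0L, 0L, 1L), n_cols, replace = TRUE))
        rr <- pmin(pmax(r + drift, 1L), n_rows)
        m[cbind(rr, seq_len(n_cols))] <- 6L
      } else {
        cc0 <- sample.int(n_cols, 1L)
        drift <- cumsum(sample(c(-1L, 0L, 0L, 1L), n_rows, replace = TRUE))
        cc <- pmin(pmax(cc0 + drift, 1L), n_cols)
        m[cbind(seq_len(n_rows), cc)] <- 6L
      }
    }
  }

  # guarantee presence of every positive-weight class
  for (code in which(w > 0)) {
    if (!any(m == code)) {
      idx <- which(m %in% setdiff(1:5, code))
      if (length(idx) == 0L) idx <- seq_along(m)
      m[idx[sample.int(length(idx), 1L)]] <- code
    }
  }

  landscape_raster(m, cell_size = cell_size)
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run `expr` under `seed` without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  expr
}

# derive n child seeds from a root seed by fixed splitting; children are
# independent of the iteration order in which they are consumed
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
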