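#' Day/night selection index per habitat class
#'
#' Population-level predicted probability (random intercept at zero)
#' that a location of each habitat class at each time of day is a used
#' rather than available point, with delta-method 95% CIs and the
#' day - night difference. Values above the availability baseline (1/6
#' under a 1:5 used:available design with unit weights) indicate
#' selection.
#'
#' @param model A use-family `fitted_rsf`.
#' @param level Confidence level (default 0.95).
#' @return Data frame: `habitat`, `time`, `prob`, `lwr`, `upr`, and a
#'   `delta` column (day - night, repeated per class).
#' @export
selection_index <- function(model, level = 0.95) {
  if (model$family != "use") stop("selection_index needs a use-family model")
  habs <- model$xlev$habitat
  times <- model$xlev$time %||% "day"
  grid <- expand.grid(habitat = habs, time = times,
                      stringsAsFactors = FALSE)
  pr <- predict_rsf(model, grid, se = TRUE, level = level)
  out <- cbind(grid, pr[, c("prob", "lwr", "upr")])
  if (all(c("day", "night") %in% times)) {
    day <- stats::setNames(out$prob[out$time == "day"],
                           out$habitat[out$time == "day"])
    night <- stats::setNames(out$prob[out$time == "night"],
                             out$habitat[out$time == "night"])
    out$delta <- as.numeric(day[out$habitat] - night[out$habitat])
  } else {
    out$delta <- NA_real_
  }
  out
}

#' Habitat-suitability map from the landscape use model
#'
#' Assigns every raster cell the population-level predicted probability
#' for its habitat class at the requested time of day. Waterbody,
#' nodata and classes unseen in training are masked (NA). Optionally
#' resampled (nearest neighbour) to another cell size.
#'
#' @param model A use-family `fitted_rsf`.
#' @param landscape A [landscape_raster()].
#' @param time_class `"day"` or `"night"`.
#' @param resolution Output cell size in metres (default: the
#'   landscape's own).
#' @return Object of class `suitability_map`: `prob` matrix in [0,1]
#'   (NA masked), `landscape` geometry fields, `time_class`,
#'   `model_structure`.
#' @export
predict_use_map <- function(model, landscape, time_class = "day",
                            resolution = NULL) {
  if (model$family != "use") stop("predict_use_map needs a use-family model")
  habs <- model$xlev$habitat
  lut <- rep(NA_real_, 7)
  pr <- predict_rsf(model, data.frame(habitat = habs, time = time_class,
                                      stringsAsFactors = FALSE))
  lut[match(habs, names(landscape_classes))] <- pr$prob
  cls <- landscape$classes
  prob <- matrix(NA_real_, nrow(cls), ncol(cls))
  ok <- cls >= 1L & cls <= 6L
  prob[ok] <- lut[cls[ok]]
  out_ls <- landscape
  if (!is.null(resolution) && resolution != landscape$cell_size) {
    res <- resample_nearest(prob, landscape, resolution)
    prob <- res$grid
    out_ls <- res$landscape
  }
  structure(
    list(prob = prob, origin_x = out_ls$origin_x, origin_y = out_ls$origin_y,
         cell_size = out_ls$cell_size, time_class = time_class,
         model_structure = model$structure),
    class = "suitability_map"
  )
}

# nearest-neighbour resample of a value grid to a new cell size over
# the same extent
resample_nearest <- function(grid, landscape, new_cell) {
  width <- landscape$n_cols * landscape$cell_size
  height <- landscape$n_rows * landscape$cell_size
  nc <- max(1L, round(width / new_cell))
  nr <- max(1L, round(height / new_cell))
  src_r <- pmin(pmax(ceiling((seq_len(nr) - 0.5) * landscape$n_rows / nr), 1L),
                landscape$n_rows)
  src_c <- pmin(pmax(ceiling((seq_len(nc) - 0.5) * landscape$n_cols / nc), 1L),
                landscape$n_cols)
  list(
    grid = grid[src_r, src_c, drop = FALSE],
    landscape = list(origin_x = landscape$origin_x,
                     origin_y = landscape$origin_y,
                     cell_size = new_cell, n_rows = nr, n_cols = nc)
  )
}

#' Distance-response curves from the landscape distance model
#'
#' Predicted probability of use versus raw distance to one feature, for
#' each time x sex panel, all other features held at their pooled means
#' (z = 0). The grid runs from 0 to the presentation cap. The
#' availability baseline under unit weights and a 1:5 design is 1/6.
#'
#' @param model A distance-family `fitted_rsf` (carries its recipe).
#' @param feature Class code 1--7.
#' @param cap Presentation cap in metres (e.g. from [distance_cap()];
#'   default 500).
#' @param n_grid Grid points (default 100).
#' @param level Confidence level for the delta-method band.
#' @return Data frame: `distance`, `time`, `sex`, `prob`, `lwr`,
#'   `upr`, plus attribute `baseline` = 1/6.
#' @export
predict_distance_curves <- function(model, feature, cap = 500, n_grid = 100L,
                                    level = 0.95) {
  if (model$family != "distance")
    stop("predict_distance_curves needs a distance-family model")
  recipe <- model$recipe
  times <- model$xlev$time %||% "day"
  sexes <- model$xlev$sex %||% "F"
  dist_grid <- seq(0, cap, length.out = n_grid)
  panels <- expand.grid(time = times, sex = sexes, stringsAsFactors = FALSE)
  out <- list()
  for (p in seq_len(nrow(panels))) {
    nd <- data.frame(matrix(0, n_grid, 7))
    names(nd) <- paste0("z_", 1:7)
    cc <- paste0("dist_", feature)
    nd[[paste0("z_", feature)]] <-
      standardize(dist_grid, recipe$center[[cc]], recipe$scale[[cc]])
    nd$time <- panels$time[p]
    nd$sex <- panels$sex[p]
    pr <- predict_rsf(model, nd, se = TRUE, level = level)
    out[[p]] <- data.frame(distance = dist_grid, time = panels$time[p],
                           sex = panels$sex[p], prob = pr$prob,
                           lwr = pr$lwr, upr = pr$upr,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "baseline") <- 1 / 6
  res
}

#' Habitat-suitability map from the landscape distance model
#'
#' Standardises every cell's seven feature distances with the training
#' recipe, expands the polynomial terms and predicts the probability of
#' use at the given time and sex. Waterbody and nodata cells are
#' masked.
#'
#' @param model A distance-family `fitted_rsf`.
#' @param stack A [distance_stack()] aligned to the training landscape.
#' @param time_class `"day"` or `"night"`.
#' @param sex `"F"` or `"M"`.
#' @return A `suitability_map` (see [predict_use_map()]).
#' @export
predict_distance_map <- function(model, stack, time_class = "day", sex = "F") {
  if (model$family != "distance")
    stop("predict_distance_map needs a distance-family model")
  recipe <- model$recipe
  ls <- stack$landscape
  nd <- data.frame(matrix(0, ls$n_rows * ls$n_cols, 7))
  names(nd) <- paste0("z_", 1:7)
  for (k in 1:7) {
    cc <- paste0("dist_", k)
    nd[[paste0("z_", k)]] <-
      standardize(as.numeric(stack$grids[[cc]]),
                  recipe$center[[cc]], recipe$scale[[cc]])
  }
  nd$time <- time_class
  nd$sex <- sex
  pr <- predict_rsf(model, nd)
  prob <- matrix(pr$prob, ls$n_rows, ls$n_cols)
  prob[ls$classes == 7L | ls$classes == 0L] <- NA_real_
  structure(
    list(prob = prob, origin_x = ls$origin_x, origin_y = ls$origin_y,
         cell_size = ls$cell_size, time_class = time_class,
         model_structure = model$structure),
    class = "suitability_map"
  )
}

#' Write a suitability map as ESRI ASCII grid
#'
#' @param map A `suitability_map`.
#' @param path Output path.
#' @export
write_suitability_grid <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  m <- map$prob
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", map$origin_x), paste("yllcorner", map$origin_y),
    paste("cellsize", map$cell_size), paste("NODATA_value", -9999)
  ), con)
  m[is.na(m)] <- -9999
  writeLines(apply(round(m, 5), 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Render a suitability map to PNG
#'
#' @param map A `suitability_map`.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @export
plot_suitability_png <- function(map, path, width = 800, height = 800) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  m <- map$prob
  # image() draws column-major from bottom-left; flip rows (row 1 = top)
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(z, zlim = c(0, 1), col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = nrow(m) / ncol(m),
                  main = sprintf("habitat suitability (%s)", map$time_class))
  invisible(path)
}
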