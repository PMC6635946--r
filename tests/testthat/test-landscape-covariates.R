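test_that("distance transform: zero on class, 3-4-5 geometry, absent class errors", {
  cls <- matrix(2L, 10, 10)
  cls[1, 1] <- 1L
  ls <- landscape_raster(cls, cell_size = 10)
  d <- distance_to_class(ls, 1)
  expect_equal(d[1, 1], 0)
  expect_equal(d[4, 5], 50) # (3, 4) cells away x 10 m
  expect_error(distance_to_class(ls, 3), "absent")
})

test_that("distance transform equals brute force on random rasters", {
  for (rep in 1:20) {
    ls <- withr::with_seed(rep, {
      nr <- sample(10:50, 1)
      nc <- sample(10:50, 1)
      cls <- matrix(sample(1:7, nr * nc, replace = TRUE,
                           prob = c(0.5, 0.2, 0.1, 0.05, 0.05, 0.05, 0.05)),
                    nr, nc)
      landscape_raster(cls, cell_size = sample(c(1, 10, 20), 1))
    })
    k <- withr::with_seed(rep + 100, sample(1:7, 1))
    if (!any(ls$classes == k)) k <- ls$classes[1, 1]
    expect_equal(distance_to_class(ls, k),
                 oracle_edt(ls$classes == k, ls$cell_size),
                 tolerance = 1e-12)
  }
})

test_that("distance grids obey the triangle inequality between cells", {
  ls <- withr::with_seed(5, landscape_raster(
    matrix(sample(1:3, 900, replace = TRUE), 30, 30), cell_size = 10))
  d <- distance_to_class(ls, 2)
  idx <- withr::with_seed(6, cbind(sample(30, 50, TRUE), sample(30, 50, TRUE)))
  for (a in 1:25) {
    p <- idx[a, ]; q <- idx[a + 25, ]
    sep <- sqrt(sum((p - q)^2)) * ls$cell_size
    expect_lte(abs(d[p[1], p[2]] - d[q[1], q[2]]), sep + 1e-9)
  }
})

test_that("record annotation matches a per-point brute-force lookup", {
  ls <- withr::with_seed(9, landscape_raster(
    matrix(sample(1:7, 400, replace = TRUE), 20, 20), cell_size = 10))
  stack <- distance_stack(ls)
  rec <- withr::with_seed(10, data.frame(
    x = stats::runif(40, 0, 200), y = stats::runif(40, 0, 200)))
  ann <- annotate_records(rec, ls, stack)
  # brute force: scan all cells for the container, all class cells for distance
  for (i in seq_len(nrow(ann))) {
    row <- 20 - floor(ann$y[i] / 10)
    col <- floor(ann$x[i] / 10) + 1
    expect_equal(ann$habitat_class[i], ls$classes[row, col])
    for (k in c(1, 6)) {
      src <- which(ls$classes == k, arr.ind = TRUE)
      dmin <- min(sqrt((src[, 1] - row)^2 + (src[, 2] - col)^2)) * 10
      expect_equal(ann[[paste0("dist_", k)]][i], dmin, tolerance = 1e-9)
    }
  }
  # records on a road cell have road distance zero
  on_road <- ann[ann$habitat_class == 6L, ]
  if (nrow(on_road) > 0) expect_true(all(on_road$dist_6 == 0))
  # two records in the same cell share annotations
  rc <- cell_of(ls, ann$x, ann$y)
  key <- paste(rc$row, rc$col)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    pair <- which(key == dup[1])
    expect_equal(ann[pair[1], grep("dist_", names(ann))],
                 ann[pair[2], grep("dist_", names(ann))],
                 ignore_attr = TRUE)
  }
  expect_error(annotate_records(data.frame(x = -5, y = 10), ls, stack),
               "outside")
})

test_that("correlation screen flags |r| > 0.7 including negative, reports zero variance", {
  n <- 1000
  base <- withr::with_seed(11, stats::runif(n, 0, 400))
  rec <- data.frame(dist_1 = base, dist_2 = 500 - base,
                    dist_3 = withr::with_seed(12, stats::runif(n, 0, 400)),
                    dist_4 = rep(100, n))
  out <- correlation_screen(rec)
  r12 <- out[out$feature_a == "dist_1" & out$feature_b == "dist_2", ]
  expect_equal(r12$r, -1)
  expect_true(r12$flagged)
  r13 <- out[out$feature_a == "dist_1" & out$feature_b == "dist_3", ]
  expect_lt(abs(r13$r), 0.7)
  expect_false(r13$flagged)
  r14 <- out[out$feature_a == "dist_1" & out$feature_b == "dist_4", ]
  expect_true(is.na(r14$r))
  expect_false(isTRUE(r14$flagged))
})

# simulate case-control style data with a known logit form in distance
curvature_fixture <- function(form = c("linear", "quadratic", "constant"),
                              n = 2000, seed = 1) {
  form <- match.arg(form)
  withr::with_seed(seed, {
    d <- stats::runif(n, 0, 500)
    eta <- switch(form,
      linear = -1 + 0.006 * d,
      quadratic = -1 + 0.02 * d - 0.00004 * d^2, # optimum at 250 m
      constant = rep(-0.5, n)
    )
    data.frame(case = stats::rbinom(n, 1, stats::plogis(eta)),
               dist_1 = d, weight = 1)
  })
}

test_that("curvature screen separates linear from quadratic responses", {
  expect_equal(curvature_screen(curvature_fixture("linear", seed = 21), 1), 1L)
  expect_equal(curvature_screen(curvature_fixture("quadratic", seed = 22), 1), 2L)
  expect_equal(curvature_screen(curvature_fixture("constant", seed = 23), 1), 1L)
  expect_error(curvature_screen(data.frame(case = c(0, 1), dist_1 = c(1, 1),
                                           weight = 1), 1),
               "variation")
})

test_that("standardisation centres, scales, and round-trips through the recipe", {
  rec <- withr::with_seed(31, {
    r <- data.frame(matrix(stats::runif(700, 0, 400), 100, 7))
    names(r) <- paste0("dist_", 1:7)
    r
  })
  recipe <- covariate_recipe(rec)
  z <- apply_recipe(rec, recipe)
  for (k in 1:7) {
    expect_lt(abs(mean(z[[paste0("z_", k)]])), 1e-10)
    expect_lt(abs(stats::sd(z[[paste0("z_", k)]]) - 1), 1e-10)
  }
  # shift invariance
  shifted <- rec
  shifted$dist_1 <- shifted$dist_1 + 123
  recipe2 <- covariate_recipe(shifted)
  expect_equal(apply_recipe(shifted, recipe2)$z_1, z$z_1, tolerance = 1e-12)
  # recipe reuse on new data is the training transform
  new_vals <- c(0, 100, 400)
  expect_equal(standardize(new_vals, recipe$center[["dist_1"]],
                           recipe$scale[["dist_1"]]),
               (new_vals - mean(rec$dist_1)) / stats::sd(rec$dist_1))
  # destandardize identity
  zz <- standardize(rec$dist_3, recipe$center[["dist_3"]], recipe$scale[["dist_3"]])
  back <- zz * recipe$scale[["dist_3"]] + recipe$center[["dist_3"]]
  expect_equal(back, rec$dist_3, tolerance = 1e-9)
  expect_error(standardize(1:3, 0, 0), "scale")
})

test_that("default polynomial degrees follow the housing/waterbody exception", {
  deg <- default_degrees()
  expect_equal(unname(deg[c("dist_1", "dist_2", "dist_3", "dist_4", "dist_6")]),
               rep(2L, 5))
  expect_equal(unname(deg[c("dist_5", "dist_7")]), rep(1L, 2))
})

test_that("distance caps use the smooth's turning point, bounded at 500 m", {
  expect_equal(distance_cap(curvature_fixture("linear", seed = 41), 1), 500)
  cap <- distance_cap(curvature_fixture("quadratic", n = 5000, seed = 42), 1)
  expect_lt(abs(cap - 250), 80) # interior optimum near 250 m
  expect_equal(distance_cap(curvature_fixture("linear", seed = 43), 1,
                            cap_rule = "fixed_500"), 500)
  expect_equal(cap_distance(c(10, 200, 499), 500), c(10, 200, 499))
  expect_equal(cap_distance(c(100, 700), 500), c(100, 500))
})
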