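test_that("mcp reproduces simple hulls and ignores interior points", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  h <- mcp(sq)
  expect_equal(h$area, 1)
  h2 <- mcp(rbind(sq, c(0.5, 0.5), c(0.2, 0.7)))
  expect_equal(h2$area, 1)
  expect_equal(nrow(h2$polygon), 4)
  expect_error(mcp(rbind(c(0, 0), c(1, 1))), "3 points")
  expect_error(mcp(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("mcp matches a brute-force gift-wrapping hull on random sets", {
  for (rep in 1:50) {
    pts <- withr::with_seed(rep, {
      n <- sample(5:30, 1)
      cbind(stats::runif(n, 0, 100), stats::runif(n, 0, 100))
    })
    h <- mcp(pts)
    oh <- oracle_hull(pts)
    # same vertex set and same area by an independent formula
    expect_setequal(
      apply(round(h$polygon, 9), 1, paste, collapse = ","),
      apply(round(oh, 9), 1, paste, collapse = ",")
    )
    expect_equal(h$area, oracle_area(oh), tolerance = 1e-9)
  }
})

test_that("buffer distance is half the root of the MCP area", {
  # right triangle with area 10,000 m^2
  h <- mcp(rbind(c(0, 0), c(200, 0), c(0, 100)))
  expect_equal(h$area, 10000)
  ls <- landscape_raster(matrix(1L, 40, 40), origin_x = -200, origin_y = -200,
                         cell_size = 20)
  region <- availability_region(h, ls)
  expect_equal(region$buffer_distance, 50)
})

test_that("without water the region is exactly the buffered hull", {
  ls <- landscape_raster(matrix(2L, 50, 50), cell_size = 10)
  h <- mcp(rbind(c(150, 150), c(350, 150), c(350, 350), c(150, 350)))
  region <- availability_region(h, ls)
  b <- region$buffer_distance
  rc <- expand.grid(row = 1:50, col = 1:50)
  ctr <- cell_centers(ls, rc$row, rc$col)
  inside <- dielrsf:::dist_to_convex(h$polygon, ctr$x, ctr$y) <= b
  expect_equal(as.vector(region$mask)[order(rc$row, rc$col)][order(order(rc$row, rc$col))],
               as.vector(region$mask)) # self-consistency guard
  expect_equal(sum(region$mask), sum(inside))
  expect_equal(region$area, sum(inside) * 100)
})

test_that("water inside the buffered hull is excluded from the region area", {
  cls <- matrix(1L, 50, 50)
  cls[20:25, 20:25] <- 7L # water blob inside the hull
  ls <- landscape_raster(cls, cell_size = 10)
  h <- mcp(rbind(c(100, 100), c(400, 100), c(400, 400), c(100, 400)))
  region <- availability_region(h, ls)
  rc <- expand.grid(row = 1:50, col = 1:50)
  ctr <- cell_centers(ls, rc$row, rc$col)
  inside <- dielrsf:::dist_to_convex(h$polygon, ctr$x, ctr$y) <=
    region$buffer_distance
  water <- cls[cbind(rc$row, rc$col)] == 7L
  expect_equal(region$area, sum(inside & !water) * 100)
  # a point inside the water blob (rows 20:25 from the top = y 250..310)
  expect_false(any(region_contains(region, 205, 255)))
})

test_that("step series follow the stated length and angle conventions", {
  t0 <- as.POSIXct("2016-06-01", tz = "UTC")
  tr <- data.frame(timestamp = t0 + 0:2 * 900,
                   x = c(0, 3, 6), y = c(0, 4, 8))
  s <- empirical_steps(tr)
  expect_equal(s$step_lengths, c(5, 5))
  expect_equal(s$turning_angles, 0)

  left <- data.frame(timestamp = t0 + 0:2 * 900,
                     x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(empirical_steps(left)$turning_angles, pi / 2)

  rev <- data.frame(timestamp = t0 + 0:2 * 900,
                    x = c(0, 1, 0), y = c(0, 0, 0))
  expect_equal(empirical_steps(rev)$turning_angles, pi)

  expect_error(empirical_steps(tr[1:2, ]), "3 fixes")
})

test_that("zero-length steps are excluded from the turning-angle multiset", {
  t0 <- as.POSIXct("2016-06-01", tz = "UTC")
  tr <- data.frame(timestamp = t0 + 0:3 * 900,
                   x = c(0, 1, 1, 2), y = c(0, 0, 0, 0))
  s <- empirical_steps(tr)
  expect_equal(s$step_lengths, c(1, 0, 1))
  # both turns are adjacent to the zero-length step: none retained
  expect_length(s$turning_angles, 0)
})

crw_fixture <- function(seed = 1, n_steps = 120) {
  ls <- iid_landscape(60, 60, cell_size = 10, seed = seed)
  ctr <- cell_centers(ls, 30, 30)
  tr <- simulate_biased_trajectory(ls, selection_scenario(),
                                   start = c(ctr$x, ctr$y),
                                   t0 = midday_utc(), n_steps = n_steps,
                                   seed = seed + 1)
  region <- availability_region(mcp(tr[, c("x", "y")]), ls)
  list(tr = tr, region = region, steps = empirical_steps(tr))
}

test_that("CRWs reproduce fix counts and timestamps and stay in the region", {
  fx <- crw_fixture(seed = 51)
  walks <- simulate_crw(fx$steps, fx$region, n_walks = 5, seed = 7)
  expect_length(walks, 5)
  for (w in walks) {
    expect_equal(nrow(w), nrow(fx$tr))
    expect_identical(w$timestamp, fx$tr$timestamp)
    expect_true(all(region_contains(fx$region, w$x, w$y)))
    # resampling by construction: every drawn length is observed
    expect_true(all(attr(w, "drawn_lengths") %in% fx$steps$step_lengths))
    # path-length conservation
    seg <- sqrt(diff(w$x)^2 + diff(w$y)^2)
    expect_equal(sum(seg), sum(attr(w, "drawn_lengths")), tolerance = 1e-9)
  }
  # determinism and seed sensitivity
  again <- simulate_crw(fx$steps, fx$region, n_walks = 5, seed = 7)
  expect_identical(walks[[3]]$x, again[[3]]$x)
  other <- simulate_crw(fx$steps, fx$region, n_walks = 5, seed = 8)
  expect_false(identical(walks[[1]]$x, other[[1]]$x))
})

test_that("joint resampling draws observed (angle, length) pairs", {
  fx <- crw_fixture(seed = 55, n_steps = 80)
  walks <- simulate_crw(fx$steps, fx$region, n_walks = 2, seed = 13,
                        joint = TRUE)
  pair_key <- paste(round(fx$steps$pairs$length, 9))
  for (w in walks) {
    drawn <- attr(w, "drawn_lengths")
    expect_true(all(round(drawn, 9) %in% pair_key))
  }
})

test_that("simulated step lengths match the observed distribution when unconstrained", {
  # a huge single-class landscape: the buffered hull never binds
  ls <- landscape_raster(matrix(1L, 100, 100), origin_x = -5000,
                         origin_y = -5000, cell_size = 100)
  t0 <- midday_utc()
  tr <- withr::with_seed(61, {
    n <- 200
    data.frame(timestamp = t0 + (0:n) * 900,
               x = cumsum(c(0, stats::rnorm(n, 0, 30))),
               y = cumsum(c(0, stats::rnorm(n, 0, 30))))
  })
  region <- availability_region(mcp(tr[, c("x", "y")]), ls)
  steps <- empirical_steps(tr)
  walks <- simulate_crw(steps, region, n_walks = 50, seed = 9)
  drawn <- unlist(lapply(walks, attr, "drawn_lengths"))
  expect_gt(length(drawn), 9999)
  ks <- suppressWarnings(stats::ks.test(drawn, steps$step_lengths))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sum(vapply(walks, function(w) attr(w, "n_fallback"),
                          numeric(1))), 0)
})

test_that("case-control assembly weights, ids and diel classes are correct", {
  t0 <- as.POSIXct("2016-06-10 02:00:00", tz = "UTC") # local day at the site
  obs <- list(A = data.frame(timestamp = t0 + 0:99 * 900,
                             x = stats::runif(100), y = stats::runif(100)))
  sim <- list(A = lapply(1:5, function(i)
    data.frame(timestamp = t0 + 0:99 * 900,
               x = stats::runif(100), y = stats::runif(100))))
  animals <- data.frame(animal_id = "A", sex = "F")
  rec <- build_case_control(obs, sim, animals, weight_scheme = "none")
  expect_equal(sum(rec$case == 1), 100)
  expect_equal(sum(rec$case == 0), 500)
  expect_true(all(rec$weight == 1))
  expect_true(all(rec$animal_id == "A"))
  expect_true(all(rec$diel %in% c("day", "night")))

  req <- build_case_control(obs, sim, animals, weight_scheme = "equalize")
  expect_equal(unique(req$weight[req$case == 0]), 0.2)
  expect_equal(sum(req$weight[req$case == 1]),
               sum(req$weight[req$case == 0]))

  expect_error(build_case_control(obs, list(), animals),
               "no available records")
})

test_that("the five-to-one availability ratio holds per animal", {
  fx <- crw_fixture(seed = 71, n_steps = 60)
  obs <- list(A001 = fx$tr)
  sim <- list(A001 = simulate_crw(fx$steps, fx$region, 5, seed = 3))
  animals <- data.frame(animal_id = "A001", sex = "M")
  rec <- build_case_control(obs, sim, animals)
  n_used <- sum(rec$case == 1)
  expect_equal(sum(rec$case == 0), 5 * n_used)
})
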