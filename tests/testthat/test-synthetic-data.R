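test_that("generated landscapes honour the class-weight contract", {
  ls <- generate_landscape(100, 100, cell_size = 20,
                           class_weights = rep(1, 7), seed = 1)
  expect_setequal(sort(unique(as.vector(ls$classes))), 1:7)

  # degenerate mixture: all mass on one class
  ls1 <- generate_landscape(50, 50, cell_size = 20,
                            class_weights = c(1, 0, 0, 0, 0, 0, 0), seed = 2)
  expect_true(all(ls1$classes[ls1$classes != 0L] == 1L))

  # determinism
  a <- generate_landscape(40, 40, cell_size = 10, seed = 9)
  b <- generate_landscape(40, 40, cell_size = 10, seed = 9)
  expect_identical(a$classes, b$classes)

  expect_error(generate_landscape(5, 50, 20), "n_rows")
  expect_error(generate_landscape(50, 50, 20, class_weights = rep(0, 7)),
               "positive sum")
})

test_that("population generation respects counts and sex ratio bounds", {
  pop <- generate_population(48, 22 / 48, seed = 3)
  expect_equal(nrow(pop), 48)
  expect_true(all(pop$sex %in% c("F", "M")))
  expect_true(all(generate_population(20, 0, seed = 1)$sex == "M"))
  expect_true(all(generate_population(20, 1, seed = 1)$sex == "F"))
  expect_error(generate_population(10, 1.5), "sex_ratio")
})

test_that("null selection walks sample habitat in proportion to candidate availability", {
  # i.i.d. fine-grained raster so availability within the walk's reach
  # equals the global class mix
  probs <- c(0.4, 0.3, 0.2, 0.1)
  ls <- iid_landscape(80, 80, cell_size = 10, probs = probs, seed = 5)
  scen <- selection_scenario() # all betas zero
  ctr <- cell_centers(ls, 40, 40)
  tr <- simulate_biased_trajectory(ls, scen, start = c(ctr$x, ctr$y),
                                   t0 = midday_utc(), n_steps = 5000,
                                   seed = 11)
  cls <- class_at(ls, tr$x[-1], tr$y[-1])
  obs <- table(factor(cls, levels = 1:4))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("strong bias makes the preferred class dominate endpoints", {
  # one large class-1 patch with a class-2 band along the right edge
  cls <- matrix(1L, 60, 60)
  cls[, 50:60] <- 2L
  ls <- landscape_raster(cls, cell_size = 10)
  scen <- selection_scenario(beta_day = c(5, rep(0, 6)),
                             beta_night = c(5, rep(0, 6)))
  ctr <- cell_centers(ls, 30, 25) # centre of the class-1 patch
  tr <- simulate_biased_trajectory(ls, scen, start = c(ctr$x, ctr$y),
                                   t0 = midday_utc(), n_steps = 600,
                                   seed = 21)
  cls <- class_at(ls, tr$x[-1], tr$y[-1])
  expect_gte(mean(cls == 1L), 0.9)
})

test_that("single-step trajectories have two fixes at the exact interval", {
  ls <- iid_landscape(20, 20, cell_size = 10, seed = 2)
  ctr <- cell_centers(ls, 10, 10)
  tr <- simulate_biased_trajectory(ls, selection_scenario(),
                                   start = c(ctr$x, ctr$y),
                                   t0 = midday_utc(), fix_interval = 15,
                                   n_steps = 1, seed = 1)
  expect_equal(nrow(tr), 2)
  expect_equal(as.numeric(difftime(tr$timestamp[2], tr$timestamp[1],
                                   units = "mins")), 15)
})

test_that("trajectory generation refuses water starts and never visits water", {
  cls <- matrix(1L, 30, 30)
  cls[10:20, 10:20] <- 7L
  ls <- landscape_raster(cls, cell_size = 10)
  water_ctr <- cell_centers(ls, 15, 15)
  expect_error(
    simulate_biased_trajectory(ls, selection_scenario(),
                               start = c(water_ctr$x, water_ctr$y),
                               t0 = midday_utc(), n_steps = 5, seed = 1),
    "non-water"
  )
  ctr <- cell_centers(ls, 3, 3)
  tr <- simulate_biased_trajectory(ls, selection_scenario(),
                                   start = c(ctr$x, ctr$y),
                                   t0 = midday_utc(), n_steps = 400, seed = 4)
  expect_false(any(class_at(ls, tr$x, tr$y) %in% c(0L, 7L)))
})

test_that("degradation with zero contamination is the identity", {
  ls <- iid_landscape(20, 20, seed = 3)
  ctr <- cell_centers(ls, 10, 10)
  tr <- simulate_biased_trajectory(ls, selection_scenario(),
                                   start = c(ctr$x, ctr$y),
                                   t0 = midday_utc(), n_steps = 20, seed = 5)
  deg <- degrade_to_gps(tr, contamination_spec(), seed = 6)
  expect_equal(deg$fixes$x, tr$x)
  expect_equal(deg$fixes$y, tr$y)
  expect_false(any(deg$truth_flags$any_bad))
})

test_that("planted defects match their specified fractions and are real", {
  ls <- iid_landscape(40, 40, seed = 7)
  ctr <- cell_centers(ls, 20, 20)
  tr <- simulate_biased_trajectory(ls, selection_scenario(),
                                   start = c(ctr$x, ctr$y),
                                   t0 = midday_utc(), n_steps = 999, seed = 8)
  n <- nrow(tr) # 1000 fixes

  all_hdop <- degrade_to_gps(tr, contamination_spec(frac_bad_hdop = 1),
                             seed = 9)
  expect_true(all(all_hdop$fixes$hdop > 8))

  spec <- contamination_spec(frac_bad_hdop = 0.05, frac_low_sats = 0.05,
                             frac_high_altitude = 0.05,
                             frac_speed_spike = 0.1, gps_error_sd = 5)
  deg <- degrade_to_gps(tr, spec, seed = 10)
  fl <- deg$truth_flags
  # ceiling-rounding contract per category
  expect_equal(sum(fl$bad_hdop), ceiling(0.05 * n))
  expect_equal(sum(fl$low_sats), ceiling(0.05 * n))
  expect_equal(sum(fl$high_altitude), ceiling(0.05 * n))
  expect_equal(sum(fl$speed_spike), ceiling(0.1 * n))
  # categories are disjoint
  expect_lte(max(fl$bad_hdop + fl$low_sats + fl$high_altitude +
                   fl$speed_spike), 1)
  # planted values actually violate the thresholds; clean ones do not
  expect_true(all(deg$fixes$hdop[fl$bad_hdop] > 8))
  expect_true(all(deg$fixes$hdop[!fl$bad_hdop] <= 8))
  expect_true(all(deg$fixes$n_sats[fl$low_sats] < 3))
  expect_true(all(deg$fixes$height[fl$high_altitude] > 100))
  # recomputed speeds: every planted spike exceeds 8 m/s against its
  # preceding neighbour
  v <- compute_speeds(deg$fixes)
  expect_true(all(v[fl$speed_spike] > 8))
  # non-spike fixes not adjacent to a spike stay below the threshold
  spike_idx <- which(fl$speed_spike)
  shadow <- unique(pmin(pmax(c(spike_idx - 1L, spike_idx, spike_idx + 1L), 1L), n))
  expect_true(all(v[-shadow] <= 8))
})

test_that("identical seeds reproduce trajectories and contamination exactly", {
  ls <- iid_landscape(30, 30, seed = 1)
  ctr <- cell_centers(ls, 15, 15)
  t1 <- simulate_biased_trajectory(ls, selection_scenario(),
                                   start = c(ctr$x, ctr$y),
                                   t0 = midday_utc(), n_steps = 50, seed = 42)
  t2 <- simulate_biased_trajectory(ls, selection_scenario(),
                                   start = c(ctr$x, ctr$y),
                                   t0 = midday_utc(), n_steps = 50, seed = 42)
  expect_identical(t1$x, t2$x)
  d1 <- degrade_to_gps(t1, contamination_spec(frac_bad_hdop = 0.1,
                                              gps_error_sd = 3), seed = 7)
  d2 <- degrade_to_gps(t2, contamination_spec(frac_bad_hdop = 0.1,
                                              gps_error_sd = 3), seed = 7)
  expect_identical(d1$fixes, d2$fixes)
})
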