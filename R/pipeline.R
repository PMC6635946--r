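#' Default run configuration
#'
#' Defaults reproduce the analysis settings: QC thresholds HDOP 8,
#' 3 satellites, 100 m height, 8 m/s speed, 8 h post-capture exclusion;
#' 5 CRWs per animal; unit weights; 500 m presentation cap; 20 m output
#' maps; civil-twilight (6 degree) dawn/dusk at the nominal site.
#' Synthetic-study fields control the generator when no fixes file is
#' supplied.
#'
#' @param ... Named overrides of any default.
#' @return Named list (class `rsf_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    fixes_csv = NULL,            # path to a Movebank-style CSV, or NULL to synthesise
    site_lat = -38.5,
    site_lon = 145.25,
    depression_angle = 6,
    qc = qc_thresholds(),
    exclusion_hours = 8,
    n_walks = 5,
    weight_scheme = "none",
    cap_rule = "min_of_both",
    max_cap = 500,
    map_resolution = 20,
    use_structures = c("null", "additive", "time_interaction"),
    fit_distance_family = TRUE,
    distance_structures = c("null", "additive", "time_interaction",
                            "time_sex_interaction"),
    degrees = NULL,              # NULL = default recipe degrees
    seed = 1L,
    # synthetic-study settings (used when fixes_csv is NULL)
    synth = list(
      n_rows = 80, n_cols = 80, cell_size = 20,
      class_weights = c(3, 4, 1, 1, 1.5, 0.5, 1),
      n_animals = 10, sex_ratio = 22 / 48, n_steps = 500,
      fix_interval = 15,
      beta_day = rep(0, 7), beta_night = rep(0, 7),
      contamination = list(frac_bad_hdop = 0, frac_low_sats = 0,
                           frac_high_altitude = 0, frac_speed_spike = 0,
                           gps_error_sd = 0)
    )
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  required <- c("site_lat", "site_lon", "depression_angle", "n_walks",
                "weight_scheme", "seed")
  missing <- required[!required %in% names(cfg) |
                        vapply(cfg[required], is.null, logical(1))]
  if (length(missing) > 0)
    stop("config missing required field(s): ", paste(missing, collapse = ", "))
  class(cfg) <- "rsf_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys override [default_config()] entries.
#' @return An `rsf_config` list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(y)) {
    if (nm %in% c("qc", "synth") && is.list(y[[nm]])) {
      for (k in names(y[[nm]])) cfg[[nm]][[k]] <- y[[nm]][[k]]
    } else {
      cfg[[nm]] <- y[[nm]]
    }
  }
  cfg
}

#' Synthesise a complete study: landscape, animals, trajectories, fixes
#'
#' Generates the inputs the pipeline expects from the configuration's
#' `synth` block: a patchy landscape, an animal population, one
#' habitat-biased trajectory per animal (starting 9 h after capture, so
#' clear of the post-sedation exclusion window) and degraded GPS fixes
#' with planted defects per the contamination settings.
#'
#' @param cfg An `rsf_config` (see [default_config()]).
#' @param seed Integer root seed.
#' @return List: `landscape`, `animals`, `trajectories` (truth),
#'   `fixes`, `truth_flags`.
#' @export
synthesize_study <- function(cfg, seed) {
  s <- cfg$synth
  landscape <- generate_landscape(s$n_rows, s$n_cols, s$cell_size,
                                  s$class_weights, seed = seed)
  animals <- generate_population(s$n_animals, s$sex_ratio, seed = seed + 1L)
  scen <- selection_scenario(beta_day = s$beta_day, beta_night = s$beta_night)
  seeds <- child_seeds(seed + 2L, s$n_animals)
  ok <- which(landscape$classes != 7L & landscape$classes != 0L,
              arr.ind = TRUE)
  starts <- with_seed(seed + 3L,
                      ok[sample.int(nrow(ok), s$n_animals, replace = TRUE), ,
                         drop = FALSE])
  fixes <- list()
  flags <- list()
  trajectories <- list()
  for (i in seq_len(s$n_animals)) {
    ctr <- cell_centers(landscape, starts[i, 1], starts[i, 2])
    tr <- simulate_biased_trajectory(
      landscape, scen, start = c(ctr$x, ctr$y),
      t0 = animals$capture_time[i] + 9 * 3600, # clear of the 8 h window
      fix_interval = s$fix_interval, n_steps = s$n_steps,
      site_lat = cfg$site_lat, site_lon = cfg$site_lon,
      seed = seeds[i], depression_angle = cfg$depression_angle
    )
    trajectories[[animals$animal_id[i]]] <- tr
    deg <- degrade_to_gps(tr, do.call(contamination_spec, s$contamination),
                          animal_id = animals$animal_id[i],
                          seed = seeds[i] + 1L)
    fixes[[i]] <- deg$fixes
    flags[[i]] <- deg$truth_flags
  }
  list(landscape = landscape, animals = animals,
       trajectories = trajectories,
       fixes = do.call(rbind, fixes), truth_flags = flags)
}

#' Run the full circadian RSF pipeline
#'
#' Executes every stage in order: synthesise (or read) fixes, quality
#' control, per-animal availability regions and CRW simulation,
#' case-control assembly with diel classification, habitat/distance
#' annotation, covariate recipe, model fitting and AICc ranking for the
#' landscape use family (and optionally the distance family), selection
#' indices and suitability maps. With `out_dir` set, tables, grids and
#' a manifest are written.
#'
#' @param config An `rsf_config` (see [default_config()]); a YAML path
#'   is also accepted.
#' @param seed Integer root seed (overrides `config$seed`).
#' @param out_dir Optional output directory.
#' @param landscape Optional externally supplied [landscape_raster()]
#'   (required when `config$fixes_csv` is used).
#' @param animals Optional animal attribute table
#'   (`animal_id`, `sex`, `capture_time`) when fixes come from a file.
#' @return List: `landscape`, `animals`, `qc` (retained + log),
#'   `records`, `recipe`, `use_models`, `use_ranking`, `best_use`,
#'   `selection_index`, `maps`, and (if fitted) `distance_models`,
#'   `distance_ranking`, plus `manifest`.
#' @export
run_pipeline <- function(config = default_config(), seed = NULL,
                         out_dir = NULL, landscape = NULL, animals = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(seed)) seed <- config$seed
  seed <- as.integer(seed)

  # stage 1: inputs
  truth_flags <- NULL
  if (is.null(config$fixes_csv)) {
    syn <- synthesize_study(config, seed)
    landscape <- syn$landscape
    animals <- syn$animals
    fixes <- syn$fixes
    truth_flags <- syn$truth_flags
  } else {
    if (is.null(landscape) || is.null(animals))
      stop("external fixes require 'landscape' and 'animals' arguments")
    fixes <- read_fixes(config$fixes_csv)
  }

  # stage 2: quality control
  qc <- filter_fixes(fixes, thresholds = config$qc,
                     capture_events = animals[, c("animal_id", "capture_time")],
                     exclusion_hours = config$exclusion_hours)
  clean <- qc$retained

  # stage 3: availability (MCP + buffer, water removed; 5 CRWs)
  ids <- unique(clean$animal_id)
  observed <- list()
  simulated <- list()
  walk_seeds <- child_seeds(seed + 10L, length(ids))
  for (i in seq_along(ids)) {
    tr <- clean[clean$animal_id == ids[i], , drop = FALSE]
    if (nrow(tr) < 3L) next
    hull <- mcp(tr[, c("x", "y")])
    region <- availability_region(hull, landscape)
    steps <- empirical_steps(tr)
    observed[[ids[i]]] <- tr
    simulated[[ids[i]]] <- simulate_crw(steps, region,
                                        n_walks = config$n_walks,
                                        seed = walk_seeds[i])
  }

  # stage 4: case-control records with diel class
  records <- build_case_control(observed, simulated, animals,
                                weight_scheme = config$weight_scheme,
                                site_lat = config$site_lat,
                                site_lon = config$site_lon,
                                depression_angle = config$depression_angle)

  # stage 5: annotation + covariates
  stack <- distance_stack(landscape)
  records <- annotate_records(records, landscape, stack)
  degrees <- config$degrees %||% default_degrees()
  recipe <- covariate_recipe(records, degrees = degrees)
  records <- apply_recipe(records, recipe)
  corr <- correlation_screen(records)

  # stage 6: use-family model set
  random <- select_random_structure(records, "use",
                                    structure = utils::tail(config$use_structures, 1))
  use_models <- lapply(config$use_structures, function(st)
    fit_use_model(records, st, random))
  names(use_models) <- config$use_structures
  use_ranking <- rank_models(use_models)
  best_use <- use_models[[use_ranking$model[1]]]

  # stage 7: distance-family model set (optional)
  distance_models <- NULL
  distance_ranking <- NULL
  if (isTRUE(config$fit_distance_family)) {
    distance_models <- lapply(config$distance_structures, function(st)
      fit_distance_model(records, st, recipe, random))
    names(distance_models) <- config$distance_structures
    distance_ranking <- rank_models(distance_models)
  }

  # stage 8: predictions
  sel_index <- selection_index(best_use)
  maps <- list(
    day = predict_use_map(best_use, landscape, "day",
                          resolution = config$map_resolution),
    night = predict_use_map(best_use, landscape, "night",
                            resolution = config$map_resolution)
  )

  manifest <- list(
    seed = seed,
    n_input_fixes = nrow(fixes),
    n_retained = nrow(clean),
    n_removed = nrow(qc$log),
    n_used = sum(records$case == 1L),
    n_available = sum(records$case == 0L),
    n_animals_modelled = length(observed),
    weight_scheme = config$weight_scheme,
    random_structure = random,
    best_use_model = use_ranking$model[1]
  )

  out <- list(landscape = landscape, animals = animals, qc = qc,
              records = records, recipe = recipe, correlation = corr,
              use_models = use_models, use_ranking = use_ranking,
              best_use = best_use, selection_index = sel_index,
              maps = maps, distance_models = distance_models,
              distance_ranking = distance_ranking,
              truth_flags = truth_flags, manifest = manifest)
  if (!is.null(out_dir)) write_run_outputs(out, config, out_dir)
  out
}

# write tables, grids and the manifest for a completed run
write_run_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$qc$log, file.path(out_dir, "qc_rejects.csv"),
                   row.names = FALSE)
  rec <- result$records
  rec$timestamp <- format(rec$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(rec, file.path(out_dir, "location_records.csv"),
                   row.names = FALSE)
  utils::write.csv(result$use_ranking, file.path(out_dir, "use_ranking.csv"),
                   row.names = FALSE)
  if (!is.null(result$distance_ranking))
    utils::write.csv(result$distance_ranking,
                     file.path(out_dir, "distance_ranking.csv"),
                     row.names = FALSE)
  utils::write.csv(result$selection_index,
                   file.path(out_dir, "selection_index.csv"), row.names = FALSE)
  coefs <- data.frame(term = names(result$best_use$beta),
                      estimate = result$best_use$beta,
                      se = result$best_use$se)
  coefs$lwr <- coefs$estimate - 1.96 * coefs$se
  coefs$upr <- coefs$estimate + 1.96 * coefs$se
  utils::write.csv(coefs, file.path(out_dir, "use_coefficients.csv"),
                   row.names = FALSE)
  write_ascii_grid(result$landscape, file.path(out_dir, "landscape.asc"))
  write_suitability_grid(result$maps$day,
                         file.path(out_dir, "suitability_day.asc"))
  write_suitability_grid(result$maps$night,
                         file.path(out_dir, "suitability_night.asc"))
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- result$manifest
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Availability-baseline calibration under a no-preference scenario
#'
#' Generates a null synthetic study (all selection coefficients zero),
#' runs quality control, builds the five-CRW availability design with
#' unit weights, fits the landscape use model and returns the
#' population-level predicted probability averaged over all records.
#' With a 1:5 used:available design this baseline is 1/6 (the 0.17
#' cutoff above which a habitat is selected); the helper exists to
#' verify that calibration on synthetic data.
#'
#' @param seed Integer seed for the replicate.
#' @param config An `rsf_config`; its `synth$beta_day`/`beta_night`
#'   are forced to zero.
#' @param random Random-effect structure for the fit (default
#'   `"intercept_by_id"`).
#' @return List: `mean_prob`, `n_records`, `model`.
#' @export
availability_baseline <- function(seed, config = default_config(),
                                  random = "intercept_by_id") {
  config$weight_scheme <- "none"
  config$synth$beta_day <- rep(0, 7)
  config$synth$beta_night <- rep(0, 7)
  syn <- synthesize_study(config, seed)
  qc <- filter_fixes(syn$fixes, thresholds = config$qc,
                     capture_events = syn$animals[, c("animal_id", "capture_time")],
                     exclusion_hours = config$exclusion_hours)
  clean <- qc$retained
  ids <- unique(clean$animal_id)
  observed <- list()
  simulated <- list()
  walk_seeds <- child_seeds(seed + 10L, length(ids))
  for (i in seq_along(ids)) {
    tr <- clean[clean$animal_id == ids[i], , drop = FALSE]
    region <- availability_region(mcp(tr[, c("x", "y")]), syn$landscape)
    observed[[ids[i]]] <- tr
    simulated[[ids[i]]] <- simulate_crw(empirical_steps(tr), region,
                                        n_walks = config$n_walks,
                                        seed = walk_seeds[i])
  }
  records <- build_case_control(observed, simulated, syn$animals,
                                weight_scheme = "none",
                                site_lat = config$site_lat,
                                site_lon = config$site_lon,
                                depression_angle = config$depression_angle)
  stack <- distance_stack(syn$landscape)
  records <- annotate_records(records, syn$landscape, stack)
  model <- fit_use_model(records, "time_interaction", random)
  pr <- predict_rsf(model, records)
  list(mean_prob = mean(pr$prob), n_records = nrow(records), model = model)
}
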