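## Config-driven orchestration of the full chain:
## simulate -> demand -> land-use suitability -> allocation -> SDM ->
## impact, with a reproducibility manifest. One master seed per run;
## stage seeds are derived deterministically from it and recorded.

#' Default pipeline configuration
#'
#' Returns the fully defaulted configuration used by [run_scenario()];
#' any subset of keys can be overridden by a YAML document passed to
#' [validate_config()]. The defaults describe the shipped demo study:
#' a 100 x 100 landscape with 8 land-use classes, 20 synthetic species,
#' and two scenarios of contrasting severity (0.3 vs 1.0) over decadal
#' steps 2020-2070.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  cls <- landuse_classes()
  list(
    seed = 42,
    output_dir = "cluesdm_output",
    grid = list(n_rows = 100, n_cols = 100, cell_area = 1,
                nodata_code = -9999),
    landscape = list(correlation_length = 8, protected_fraction = 0.1),
    classes = list(codes = cls$code, names = cls$name,
                   static = cls$name[cls$static]),
    transitions = default_transitions(),
    elasticities = list(urban = 1.0, cropland = 0.8, herbaceous = 0.6,
                        shrubland = 0.6, open_forest = 0.7,
                        closed_forest = 0.9, wetlands = 1.0, barren = 1.0),
    demand = list(base_year = 2020, horizon = 50, step = 10,
                  base_population = 1e6, pop_growth_rate = 0.008),
    climate = list(n_members = 15, anomaly_sd = 1, member_sd = 0.3,
                   correlation_length = 10, quantile = "median"),
    landuse_model = list(sample_n = 8000, folds = 10,
                         correlation_threshold = 0.7, tol = 0.001,
                         max_iter = 2000),
    sdm = list(n_background = 2000, folds = 5, min_records = 20,
               min_year = 1950, max_year = 2018, auc_threshold = 0.7,
               importance_threshold = 1, n_perm = 3, regularization = 1,
               alpha = 0.5,
               landuse_predictors = c("cropland", "urban", "closed_forest")),
    species = list(n_species = 20, n_presences = 300, p_landuse = 0.5,
                   niche_width = 0.45, biased = TRUE),
    impact = list(dispersal_mode = "bioregion_adjacent",
                  loss_thresholds = c(0.5, 0.1, 0.95)),
    scenarios = list(low = list(severity = 0.3),
                     high = list(severity = 1.0))
  )
}

#' Default allowed land-use transitions
#'
#' For each class, the classes it may convert to (itself always allowed).
#' Urban land is irreversible; closed-canopy forest opens before it can
#' convert further; the static classes never change.
#'
#' @return named list of character vectors (class names).
#' @export
default_transitions <- function() {
  list(
    urban = c("urban"),
    cropland = c("cropland", "herbaceous", "shrubland", "urban"),
    herbaceous = c("herbaceous", "cropland", "shrubland", "open_forest",
                   "urban"),
    shrubland = c("shrubland", "cropland", "herbaceous", "open_forest",
                  "urban"),
    open_forest = c("open_forest", "closed_forest", "shrubland",
                    "cropland", "urban"),
    closed_forest = c("closed_forest", "open_forest"),
    wetlands = c("wetlands"),
    barren = c("barren")
  )
}

## Recursively overlay user values on defaults, rejecting unknown keys.
## The scenario set and the transition table are replaced wholesale (a
## partial transition table would silently inherit rows); other nested
## lists merge key by key.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (path %in% c("$scenarios", "$transitions")) return(user)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s) at %s: %s", path,
                 paste(unknown, collapse = ", ")))
  }
  out <- defaults
  for (nm in names(user)) {
    out[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                              paste0(path, "$", nm))
  }
  out
}

#' Validate and default a pipeline configuration
#'
#' Overlays a (possibly partial) configuration document on the documented
#' defaults, rejects unknown keys, and checks cross-references and bounds:
#' class codes/names aligned, static classes and transition entries inside
#' the class list, elasticities in `[0, 1]` for every class, positive
#' severities, and a demand step that divides the horizon.
#'
#' @param document nested list (e.g. from `yaml::read_yaml()`), a YAML
#'   file path, or `NULL` for pure defaults.
#' @return validated config list.
#' @export
validate_config <- function(document = NULL) {
  if (is.character(document)) document <- yaml::read_yaml(document)
  cfg <- merge_config(default_config(), document)
  cls <- cfg$classes
  if (length(cls$codes) != length(cls$names)) {
    stop("config error at $classes: codes and names differ in length")
  }
  bad <- setdiff(cls$static, cls$names)
  if (length(bad)) {
    stop("config error at $classes$static: unknown class ",
         paste(bad, collapse = ", "))
  }
  tr <- cfg$transitions
  if (!setequal(names(tr), cls$names)) {
    stop(sprintf(
      "config error at $transitions: transition list has %d classes but the class list has %d",
      length(tr), length(cls$names)))
  }
  for (nm in names(tr)) {
    bad <- setdiff(tr[[nm]], cls$names)
    if (length(bad)) {
      stop(sprintf("config error at $transitions$%s: unknown class %s",
                   nm, paste(bad, collapse = ", ")))
    }
  }
  el <- cfg$elasticities
  if (!setequal(names(el), cls$names)) {
    stop("config error at $elasticities: must name every class exactly once")
  }
  elv <- unlist(el)
  if (any(elv < 0 | elv > 1)) {
    stop("config error at $elasticities: values must lie in [0, 1]")
  }
  if (cfg$demand$horizon %% cfg$demand$step != 0) {
    stop("config error at $demand: step must divide horizon")
  }
  for (sc in names(cfg$scenarios)) {
    sev <- cfg$scenarios[[sc]]$severity
    if (is.null(sev) || sev < 0) {
      stop(sprintf("config error at $scenarios$%s: severity must be >= 0", sc))
    }
  }
  if (!cfg$impact$dispersal_mode %in% c("unlimited", "bioregion_adjacent")) {
    stop("config error at $impact$dispersal_mode: must be 'unlimited' or 'bioregion_adjacent'")
  }
  cfg
}

## Transition matrix (codes x codes, logical) from the config lists.
config_transition_matrix <- function(cfg) {
  cls <- cfg$classes
  K <- length(cls$codes)
  m <- matrix(FALSE, K, K,
              dimnames = list(as.character(cls$codes),
                              as.character(cls$codes)))
  for (nm in names(cfg$transitions)) {
    i <- as.character(cls$codes[match(nm, cls$names)])
    j <- as.character(cls$codes[match(cfg$transitions[[nm]], cls$names)])
    m[i, j] <- TRUE
    m[i, i] <- TRUE
  }
  m
}

#' Land-use indicator layers from a class map
#'
#' One 0/1 matrix per requested class, named `lu_<class name>` — the form
#' in which land use enters the SDM covariate stack.
#'
#' @param land_use integer class-code matrix.
#' @param cfg validated config (for the class table).
#' @param classes class names to expand (default: the configured SDM
#'   land-use predictors).
#' @return named list of 0/1 matrices.
#' @export
landuse_indicators <- function(land_use, cfg,
                               classes = cfg$sdm$landuse_predictors) {
  codes <- cfg$classes$codes[match(classes, cfg$classes$names)]
  out <- lapply(codes, function(k) {
    matrix(as.integer(land_use == k), nrow(land_use), ncol(land_use))
  })
  names(out) <- paste0("lu_", classes)
  out
}

## md5 of an R object via its canonical JSON serialization.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run one scenario of the integrated pipeline
#'
#' Executes all stages in dependency order: synthetic landscape;
#' CGE-style demand trajectory and per-class demand table; land-use
#' suitability fits and decadal CLUE-S allocation; pseudo-GCM climate
#' ensemble and its quartiles; synthetic species, effort estimation,
#' bias-corrected background and SDM fitting with CV-AUC gating,
#' permutation-importance pruning and MaxSSS thresholding; and the
#' direct/indirect/combined impact assessment. All declared outputs are
#' written under `output_dir/<scenario>` and listed with checksums in a
#' run manifest. All randomness derives from the config's master seed,
#' so a re-run with the same config reproduces identical checksums.
#'
#' @param config validated config (see [validate_config()]).
#' @param scenario_name name of an entry of `config$scenarios`.
#' @param output_dir output root (default `config$output_dir`).
#' @param resume if `TRUE` and a manifest with a matching config hash
#'   already exists for this scenario, skip recomputation and return it.
#' @return list of class `scenario_run`: `scenario`, `severity`,
#'   `landscape`, `demand_table`, `landuse` (maps + audit), `sdm_table`
#'   (per-species QC), `records` (range-change records), `cohort`,
#'   `loss_maps`, `change_intensity`, `manifest`.
#' @export
run_scenario <- function(config, scenario_name,
                         output_dir = config$output_dir, resume = FALSE) {
  if (!scenario_name %in% names(config$scenarios)) {
    stop("unknown scenario: ", scenario_name)
  }
  scen <- config$scenarios[[scenario_name]]
  out_dir <- file.path(output_dir, scenario_name)
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg_hash <- object_hash(config)
  if (resume && file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(man$config_hash, unname(cfg_hash)) &&
        all(file.exists(file.path(out_dir, names(man$checksums))))) {
      message("scenario ", scenario_name, " already complete; skipping")
      return(invisible(structure(list(scenario = scenario_name,
                                      manifest = man),
                                 class = "scenario_run")))
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  master <- as.integer(config$seed)
  seeds <- list(landscape = master + 1L, climate = master + 2L,
                demand = master + 3L, suitability = master + 4L,
                species = master + 5L, sdm = master + 6L,
                allocation = master + 7L)
  grid <- grid_spec(config$grid$n_rows, config$grid$n_cols,
                    config$grid$cell_area, config$grid$nodata_code)
  cls <- config$classes
  class_code <- stats::setNames(cls$codes, cls$names)
  static_codes <- class_code[cls$static]

  ## --- landscape (shared across scenarios: seed does not involve severity)
  landscape <- simulate_landscape(
    grid, correlation_length = config$landscape$correlation_length,
    protected_fraction = config$landscape$protected_fraction,
    seed = seeds$landscape)
  base_counts <- vapply(cls$codes, function(k) {
    sum(landscape$land_use == k)
  }, numeric(1))
  base_areas <- stats::setNames(base_counts * grid$cell_area, cls$names)
  total_area <- sum(base_areas)

  ## --- demand
  dem <- config$demand
  traj <- generate_demand_trajectory(
    base_areas, scenario_severity = scen$severity, horizon = dem$horizon,
    step = dem$step, base_year = dem$base_year,
    base_population = dem$base_population,
    pop_growth_rate = dem$pop_growth_rate, seed = seeds$demand)

  ## --- land-use suitability
  lum <- config$landuse_model
  suit_models <- fit_suitability_models(
    landscape, classes = cls$codes, n = lum$sample_n,
    threshold = lum$correlation_threshold, folds = lum$folds,
    seed = seeds$suitability)
  suit_present <- lapply(suit_models, predict_suitability,
                         covariates = landscape$covariates)
  residual_classes <- setdiff(cls$names,
                              c("cropland", "urban", cls$static))
  mean_suit <- vapply(residual_classes, function(nm) {
    mean(suit_present[[as.character(class_code[nm])]])
  }, numeric(1))

  class_roles <- stats::setNames(rep("residual", length(cls$names)),
                                 cls$names)
  class_roles["cropland"] <- "cropland"
  class_roles["urban"] <- "urban"
  class_roles[cls$static] <- "static"
  demand_table <- build_demand_table(
    cropland_demand(traj$sectors, base_areas[["cropland"]]),
    urban_demand(traj$population, base_areas[["urban"]]),
    base_areas, class_roles, mean_suit, total_area)

  ## --- climate ensemble and future covariates
  clim_layers <- c("clim1", "clim2", "clim3")
  ens <- generate_climate_ensemble(
    landscape$covariates[clim_layers], grid,
    n_members = config$climate$n_members, severity = scen$severity,
    anomaly_sd = config$climate$anomaly_sd,
    member_sd = config$climate$member_sd,
    correlation_length = config$climate$correlation_length,
    seed = seeds$climate)
  quart <- ensemble_quartiles(ens)
  future_climate <- quart[[config$climate$quantile]]

  ## per-step suitability under linearly interpolated climate
  steps <- sort(unique(demand_table$timestep))
  horizon_end <- steps[length(steps)]
  suitability_by_step <- lapply(steps, function(t) {
    frac <- (t - steps[1]) / (horizon_end - steps[1])
    covs <- landscape$covariates
    for (v in clim_layers) {
      covs[[v]] <- covs[[v]] + frac * (future_climate[[v]] - covs[[v]])
    }
    lapply(suit_models, predict_suitability, covariates = covs)
  })
  names(suitability_by_step) <- as.character(steps)

  ## --- allocation
  demand_codes <- demand_table
  demand_codes$class <- class_code[demand_table$class]
  lu_series <- run_decadal_series(
    landscape$land_use, suitability_by_step, demand_codes,
    config_transition_matrix(config),
    stats::setNames(unlist(config$elasticities)[cls$names],
                    as.character(class_code[cls$names])),
    landscape$protected, grid, static_classes = static_codes,
    tol = lum$tol, max_iter = lum$max_iter,
    seed = seeds$allocation)
  final_lu <- lu_series$maps[[as.character(horizon_end)]]

  ## --- species and SDMs
  sdm_cfg <- config$sdm
  lu_names <- paste0("lu_", sdm_cfg$landuse_predictors)
  present_stack <- c(landscape$covariates,
                     landuse_indicators(landscape$land_use, config))
  future_stack <- c(landscape$covariates,
                    landuse_indicators(final_lu, config))
  for (v in clim_layers) future_stack[[v]] <- future_climate[[v]]

  pool <- generate_species_pool(
    config$species$n_species, clim_layers, lu_names,
    p_landuse = config$species$p_landuse,
    n_presences = config$species$n_presences,
    niche_width = config$species$niche_width, seed = seeds$species)
  species <- lapply(seq_along(pool), function(i) {
    generate_species_occurrences(
      pool[[i]], present_stack, grid, effort = landscape$effort,
      n = config$species$n_presences, biased = config$species$biased,
      species_id = names(pool)[i],
      year_range = c(sdm_cfg$min_year, sdm_cfg$max_year),
      seed = seeds$species + 100L * i)
  })
  occurrences <- do.call(rbind, lapply(species, `[[`, "occurrences"))
  filt <- filter_records(occurrences, sdm_cfg$min_year, sdm_cfg$max_year,
                         min_n = sdm_cfg$min_records)
  effort_hat <- estimate_effort(
    filt$records, landscape$covariates[c("access", "elevation")], grid)
  background <- sample_background(effort_hat, grid,
                                  n = sdm_cfg$n_background,
                                  seed = seeds$sdm)
  sdm_predictors <- c(clim_layers, "elevation", "access", lu_names)

  fits <- list(); qc_rows <- list()
  for (i in seq_along(species)) {
    sid <- species[[i]]$species_id
    recs <- filt$records[filt$records$species_id == sid, ]
    if (!nrow(recs)) next
    pres_cells <- cell_from_xy(recs$x, recs$y, grid)
    cv <- cv_auc(pres_cells, background$cell, present_stack,
                 predictors = sdm_predictors, k = sdm_cfg$folds,
                 auc_threshold = sdm_cfg$auc_threshold,
                 regularization = sdm_cfg$regularization,
                 alpha = sdm_cfg$alpha, seed = seeds$sdm + 10L * i)
    fit <- cv$fit
    fit$species_id <- sid
    if (cv$retained) {
      pruned <- permutation_importance(fit, present_stack,
                                       n_perm = sdm_cfg$n_perm,
                                       threshold = sdm_cfg$importance_threshold,
                                       seed = seeds$sdm + 10L * i + 1L)
      fit <- pruned$fit
      fit$species_id <- sid
      sc <- sdm_training_scores(fit, present_stack)
      fit$maxsss <- as.numeric(maxsss_threshold(sc$presence, sc$background))
      fits[[sid]] <- fit
    }
    qc_rows[[sid]] <- data.frame(
      species_id = sid, n_records = nrow(recs),
      mean_auc = cv$mean_auc,
      t(stats::setNames(cv$fold_aucs,
                        paste0("auc_fold", seq_along(cv$fold_aucs)))),
      status = if (cv$retained) "retained" else "discarded",
      stringsAsFactors = FALSE)
  }
  sdm_table <- do.call(rbind, qc_rows)
  rownames(sdm_table) <- NULL

  ## --- impact assessment
  records <- list()
  pres_ranges <- list(); fut_ranges <- list(direct = list(),
                                            indirect = list(),
                                            combined = list())
  for (sid in names(fits)) {
    fit <- fits[[sid]]
    occ <- filt$records[filt$records$species_id == sid, ]
    mask <- dispersal_mask(landscape$bioregions, occ, grid,
                           mode = config$impact$dispersal_mode)
    present_pred <- predict_sdm(fit, present_stack)
    pr <- binary_range(present_pred, fit$maxsss, mask)
    if (pr$count == 0) next   # empty present range: excluded from change
    preds <- treatment_predictions(fit, present_stack, future_stack,
                                   lu_names)
    pres_ranges[[sid]] <- pr$range
    for (tr in names(preds)) {
      fr <- binary_range(preds[[tr]], fit$maxsss, mask)
      ch <- range_change(pr$count, fr$count)
      records[[length(records) + 1L]] <- data.frame(
        species_id = sid, scenario = scenario_name, treatment = tr,
        n_present = pr$count, n_future = fr$count, ratio = ch$ratio,
        log_ratio = ifelse(is.na(ch$log_ratio), NA_real_, ch$log_ratio),
        extirpated = ch$extirpated,
        mask_mode = config$impact$dispersal_mode,
        stringsAsFactors = FALSE)
      fut_ranges[[tr]][[sid]] <- fr$range
    }
  }
  records <- do.call(rbind, records)
  cohort <- summarize_cohort(records,
                             unlist(config$impact$loss_thresholds))
  loss_maps <- lapply(fut_ranges, function(fr) {
    loss_proportion_map(pres_ranges[names(fr)], fr)
  })
  change_int <- change_intensity_map(landscape$land_use, final_lu,
                                     factor = 3)

  ## --- outputs and manifest
  utils::write.csv(traj$sectors, file.path(out_dir, "sector_demand.csv"),
                   row.names = FALSE)
  utils::write.csv(traj$population, file.path(out_dir, "population.csv"),
                   row.names = FALSE)
  utils::write.csv(demand_table, file.path(out_dir, "demand_table.csv"),
                   row.names = FALSE)
  utils::write.csv(lu_series$audit, file.path(out_dir, "allocation_audit.csv"),
                   row.names = FALSE)
  utils::write.csv(occurrences, file.path(out_dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(sdm_table, file.path(out_dir, "sdm_qc.csv"),
                   row.names = FALSE)
  utils::write.csv(records, file.path(out_dir, "range_change_records.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$summary, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  for (t in names(lu_series$maps)) {
    write_ascii_grid(lu_series$maps[[t]], grid,
                     file.path(out_dir, sprintf("landuse_%s.asc", t)))
  }
  for (tr in names(loss_maps)) {
    write_ascii_grid(loss_maps[[tr]],
                     grid_spec(nrow(loss_maps[[tr]]), ncol(loss_maps[[tr]]),
                               nodata_code = grid$nodata_code),
                     file.path(out_dir, sprintf("loss_proportion_%s.asc", tr)))
  }
  write_ascii_grid(change_int,
                   grid_spec(nrow(change_int), ncol(change_int),
                             nodata_code = grid$nodata_code),
                   file.path(out_dir, "change_intensity.asc"))
  fit_dir <- file.path(out_dir, "sdm_fits")
  if (!dir.exists(fit_dir)) dir.create(fit_dir)
  for (sid in names(fits)) {
    write_sdm_fit(fits[[sid]], file.path(fit_dir, paste0(sid, ".json")))
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  checksums <- tools::md5sum(files)
  names(checksums) <- substring(files, nchar(out_dir) + 2)
  manifest <- list(
    scenario = scenario_name, severity = scen$severity,
    config_hash = unname(cfg_hash), seeds = seeds,
    software_version = as.character(utils::packageVersion("cluesdm")),
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  structure(
    list(scenario = scenario_name, severity = scen$severity,
         grid = grid, landscape = landscape, demand_table = demand_table,
         landuse = lu_series, fits = fits, sdm_table = sdm_table,
         records = records, cohort = cohort, loss_maps = loss_maps,
         change_intensity = change_int, manifest = manifest,
         output_dir = out_dir),
    class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> %s (severity %.2f)\n", x$scenario,
              if (is.null(x$severity)) NA else x$severity))
  if (!is.null(x$sdm_table)) {
    cat(sprintf("  species retained: %d / %d\n",
                sum(x$sdm_table$status == "retained"), nrow(x$sdm_table)))
  }
  invisible(x)
}

#' Run every configured scenario
#'
#' @param config validated config.
#' @param output_dir output root.
#' @param resume passed to [run_scenario()].
#' @return named list of `scenario_run`s.
#' @export
run_all_scenarios <- function(config, output_dir = config$output_dir,
                              resume = FALSE) {
  runs <- lapply(names(config$scenarios), function(sc) {
    run_scenario(config, sc, output_dir = output_dir, resume = resume)
  })
  names(runs) <- names(config$scenarios)
  runs
}
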