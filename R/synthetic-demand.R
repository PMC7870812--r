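## CGE-style synthetic demand trajectories. The economic model itself is
## out of scope; what the allocator needs is its output surface: a sector
## table of relative output and land-requirement changes with harvested-
## area shares, and an urban population series. Sector outputs drift
## downwards with climate severity (crop sectors shrink under strong
## forcing) while land requirements stay flat or rise slightly (falling
## land productivity means more land per unit output).

#' Generate a synthetic sector demand table and population series
#'
#' All drifts scale linearly with `scenario_severity` and ramp linearly in
#' time, so severity 0 is an exact null scenario (all relative changes 0,
#' population constant). Two severities can emulate a low/high forcing
#' contrast (e.g. 0.3 vs 1.0).
#'
#' @param base_areas named vector of base-year areas per land-use class
#'   (used only for reporting/feasibility context; may be `NULL`).
#' @param scenario_severity scalar >= 0.
#' @param horizon total span in years (e.g. 50).
#' @param step timestep in years (must divide horizon).
#' @param base_year first calendar year.
#' @param sectors sector names.
#' @param base_population population at base year (> 0).
#' @param pop_growth_rate annual urban population growth rate at
#'   severity 1 (scaled by severity).
#' @param output_drift_range,landreq_drift_range ranges from which per-
#'   sector end-of-horizon drifts are drawn (at severity 1). Defaults give
#'   output declines of up to ~20% and land-requirement changes that are
#'   flat to slightly positive.
#' @param seed integer RNG seed.
#' @return list with `sectors` (data.frame `sector`, `timestep`,
#'   `d_output`, `d_land_req`, `share`) and `population` (data.frame
#'   `timestep`, `population`).
#' @export
generate_demand_trajectory <- function(base_areas = NULL, scenario_severity,
                                       horizon = 50, step = 10,
                                       base_year = 2020,
                                       sectors = c("wheat", "rice",
                                                   "coarse_grains",
                                                   "oil_seeds",
                                                   "plant_fibres",
                                                   "horticulture"),
                                       base_population = 1e6,
                                       pop_growth_rate = 0.008,
                                       output_drift_range = c(-0.20, -0.02),
                                       landreq_drift_range = c(0.005, 0.05),
                                       seed = 1) {
  if (scenario_severity < 0) stop("scenario_severity must be >= 0")
  if (horizon %% step != 0) stop("step must divide horizon")
  if (!is.null(base_areas) && any(base_areas < 0)) {
    stop("base_areas must be non-negative")
  }
  years <- base_year + seq(0, horizon, by = step)
  ns <- length(sectors)
  draws <- with_seed(seed, {
    share <- stats::rgamma(ns, shape = 2)
    list(share = share / sum(share),
         out_drift = stats::runif(ns, output_drift_range[1], output_drift_range[2]),
         land_drift = stats::runif(ns, landreq_drift_range[1], landreq_drift_range[2]))
  })
  frac <- (years - base_year) / horizon
  tab <- do.call(rbind, lapply(seq_along(years), function(i) {
    data.frame(sector = sectors, timestep = years[i],
               d_output = scenario_severity * draws$out_drift * frac[i],
               d_land_req = scenario_severity * draws$land_drift * frac[i],
               share = draws$share, stringsAsFactors = FALSE)
  }))
  check_sector_table(tab)
  pop <- data.frame(
    timestep = years,
    population = base_population *
      (1 + scenario_severity * pop_growth_rate)^(years - base_year)
  )
  list(sectors = tab, population = pop)
}

#' Validate a sector change table
#'
#' Checks that shares at every timestep are non-negative and sum to 1
#' within 1e-9, and that timesteps are consistent across sectors.
#'
#' @param sectors data.frame with columns `sector`, `timestep`,
#'   `d_land_req`, `share` (other columns allowed).
#' @return `sectors`, invisibly.
#' @export
check_sector_table <- function(sectors) {
  req <- c("sector", "timestep", "d_land_req", "share")
  miss <- setdiff(req, names(sectors))
  if (length(miss)) stop("sector table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(sectors$share < 0)) stop("sector shares must be non-negative")
  sums <- tapply(sectors$share, sectors$timestep, sum)
  off <- abs(sums - 1) > 1e-9
  if (any(off)) {
    stop(sprintf("harvested-area shares must sum to 1 at every timestep (off at %s)",
                 paste(names(sums)[off], collapse = ", ")))
  }
  invisible(sectors)
}
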