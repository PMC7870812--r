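## Demand downscaling: sector-level relative land-requirement changes,
## population growth and residual-class suitability are converted into an
## absolute per-class area demand series for the allocator.

#' Cropland area demand from sector land-requirement changes
#'
#' At each timestep the sector-level relative changes in land requirements
#' are averaged with their harvested-area shares as weights,
#' `w_t = sum_s share_s * d_land_req_{s,t}`, and applied to the base-year
#' cropland area: `demand_t = base_cropland * (1 + w_t)`. Anchoring to the
#' base-year (current) area, rather than chaining multiplicatively across
#' decades, keeps a direct proportional link between land-requirement
#' change and agricultural area; chaining is available via `chained`.
#'
#' @param sectors sector table (see [check_sector_table()]).
#' @param base_cropland base-year cropland area (>= 0).
#' @param chained logical; if `TRUE`, apply each step's incremental change
#'   to the previous step's demand instead of the base year.
#' @return data.frame with columns `timestep`, `area`.
#' @export
cropland_demand <- function(sectors, base_cropland, chained = FALSE) {
  check_sector_table(sectors)
  if (base_cropland < 0) stop("base_cropland must be >= 0")
  steps <- sort(unique(sectors$timestep))
  w <- vapply(steps, function(t) {
    s <- sectors[sectors$timestep == t, ]
    sum(s$share * s$d_land_req)
  }, numeric(1))
  if (chained) {
    area <- base_cropland * cumprod(c(1, (1 + w[-1]) / (1 + w[-length(w)])))
  } else {
    area <- base_cropland * (1 + w)
  }
  neg <- area < 0
  if (any(neg)) {
    stop(sprintf("cropland demand negative at timestep %s",
                 paste(steps[neg], collapse = ", ")))
  }
  data.frame(timestep = steps, area = area)
}

#' Urban area demand from population growth
#'
#' Urban population density is assumed steady through time, so urban area
#' scales with population: `demand_t = base_urban * pop_t / pop_0`.
#'
#' @param population data.frame with columns `timestep`, `population`.
#' @param base_urban base-year urban area.
#' @return data.frame with columns `timestep`, `area`.
#' @export
urban_demand <- function(population, base_urban) {
  if (any(population$population <= 0)) stop("population must be positive")
  pop <- population[order(population$timestep), ]
  data.frame(timestep = pop$timestep,
             area = base_urban * pop$population / pop$population[1])
}

#' Split a residual area among classes proportional to mean suitability
#'
#' The residual `R = total_area - sum(fixed_demands)` is divided among the
#' residual classes in proportion to their mean predicted suitability in
#' the landscape; the outputs sum to `R` exactly.
#'
#' @param total_area total area to account for.
#' @param fixed_demands named vector of areas already committed (may be
#'   empty).
#' @param residual_classes names of classes receiving the residual.
#' @param mean_suitability named non-negative vector covering
#'   `residual_classes`.
#' @return named vector of areas for `residual_classes`, summing to `R`.
#' @export
residual_demand <- function(total_area, fixed_demands = numeric(),
                            residual_classes, mean_suitability) {
  fx <- sum(fixed_demands)
  # a negative total is allowed only when splitting a pure change
  # (no fixed demands), as build_demand_table does for residual deltas
  if (fx > total_area + 1e-9 * max(1, abs(total_area)) &&
      (length(fixed_demands) > 0 || total_area >= 0)) {
    stop(sprintf("fixed demands (%g) exceed total area (%g) by %g",
                 fx, total_area, fx - total_area))
  }
  s <- mean_suitability[residual_classes]
  if (any(is.na(s))) stop("mean_suitability missing for some residual class")
  if (any(s < 0)) stop("mean suitabilities must be non-negative")
  if (sum(s) == 0) stop("residual suitabilities are all zero")
  r <- total_area - fx
  out <- r * s / sum(s)
  # force exact conservation against rounding
  if (length(out)) out[length(out)] <- r - sum(out[-length(out)])
  stats::setNames(as.numeric(out), residual_classes)
}

#' Build a per-class area demand table for the allocator
#'
#' Combines the cropland and urban demand series with static-class areas
#' and a residual split. Residual-class demands are anchored at their
#' base-year areas; only the *change* in the residual total (driven by
#' cropland/urban expansion or contraction) is redistributed among the
#' residual classes in proportion to their mean suitability. Under a
#' zero-change scenario the table therefore reproduces the base-year areas
#' exactly at every timestep. Class totals sum to `total_area` at each
#' timestep (checked to 1e-6 relative).
#'
#' @param cropland,urban data.frames (`timestep`, `area`) on identical
#'   timesteps.
#' @param base_areas named vector of base-year areas for every class.
#' @param class_roles named character vector mapping class name to one of
#'   `"cropland"`, `"urban"`, `"residual"`, `"static"`.
#' @param mean_suitability named vector covering the residual classes.
#' @param total_area total modelled land area.
#' @return data.frame of class demand per timestep (`timestep`, `class`,
#'   `area`).
#' @export
build_demand_table <- function(cropland, urban, base_areas, class_roles,
                               mean_suitability, total_area) {
  if (!identical(cropland$timestep, urban$timestep)) {
    stop("cropland and urban series have misaligned timesteps")
  }
  classes <- names(class_roles)
  miss <- setdiff(classes, names(base_areas))
  if (length(miss)) stop("base_areas missing class(es): ",
                         paste(miss, collapse = ", "))
  crop_cls <- classes[class_roles == "cropland"]
  urb_cls <- classes[class_roles == "urban"]
  res_cls <- classes[class_roles == "residual"]
  sta_cls <- classes[class_roles == "static"]
  if (length(crop_cls) != 1 || length(urb_cls) != 1) {
    stop("exactly one cropland and one urban class are required")
  }
  static_total <- sum(base_areas[sta_cls])
  r0 <- total_area - base_areas[[crop_cls]] - base_areas[[urb_cls]] - static_total
  rows <- lapply(seq_along(cropland$timestep), function(i) {
    t <- cropland$timestep[i]
    r_t <- total_area - cropland$area[i] - urban$area[i] - static_total
    if (r_t < -1e-9 * total_area) {
      stop(sprintf("fixed demands exceed total area at timestep %s", t))
    }
    delta <- residual_demand(r_t - r0, numeric(), res_cls, mean_suitability)
    areas <- c(
      stats::setNames(cropland$area[i], crop_cls),
      stats::setNames(urban$area[i], urb_cls),
      base_areas[res_cls] + delta,
      base_areas[sta_cls]
    )
    if (any(areas < 0)) {
      stop(sprintf("negative class demand at timestep %s for %s", t,
                   paste(names(areas)[areas < 0], collapse = ", ")))
    }
    data.frame(timestep = t, class = names(areas), area = as.numeric(areas),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sums <- tapply(out$area, out$timestep, sum)
  if (any(abs(sums - total_area) > 1e-6 * total_area)) {
    stop("internal error: demand table does not conserve total area")
  }
  rownames(out) <- NULL
  out
}
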