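## Synthetic species with known suitability truth, and effort-biased
## occurrence sampling.

#' Evaluate a linear + quadratic suitability truth over a stack
#'
#' The truth is a Gaussian-niche style model on the logit scale:
#' `eta = intercept + sum_j (b_j x_j + c_j x_j^2)`, suitability
#' `= plogis(eta)`.
#'
#' @param model list with `intercept`, `linear` (named vector), `quadratic`
#'   (named vector; names are layer names, may be empty).
#' @param covariates named list of matrices.
#' @return matrix of suitabilities in `[0, 1]`.
#' @export
true_suitability <- function(model, covariates) {
  eta <- matrix(model$intercept, nrow(covariates[[1]]), ncol(covariates[[1]]))
  for (v in names(model$linear)) {
    if (is.null(covariates[[v]])) stop("missing layer: ", v)
    eta <- eta + model$linear[[v]] * covariates[[v]]
  }
  for (v in names(model$quadratic)) {
    if (is.null(covariates[[v]])) stop("missing layer: ", v)
    eta <- eta + model$quadratic[[v]] * covariates[[v]]^2
  }
  stats::plogis(eta)
}

#' Sample presence-only occurrences for a species with known truth
#'
#' Cells are drawn with replacement with probability proportional to the
#' species' true suitability, optionally multiplied by a sampling-effort
#' surface (`biased = TRUE`), emulating opportunistic presence-only data.
#' Record coordinates are cell centres; observation years are drawn
#' uniformly from `year_range`.
#'
#' @param true_model suitability truth, as in [true_suitability()].
#' @param covariates named list of matrices.
#' @param grid a [grid_spec()].
#' @param effort non-negative effort matrix (required when `biased`).
#' @param n number of occurrence records (>= 1).
#' @param biased logical; multiply sampling weight by effort.
#' @param species_id identifier string.
#' @param year_range integer range for observation years.
#' @param seed integer RNG seed.
#' @return list of class `synthetic_species`: `species_id`,
#'   `true_coefficients`, `n_presences`, `occurrences` (data.frame
#'   `species_id`, `x`, `y`, `year`), `cells`.
#' @export
generate_species_occurrences <- function(true_model, covariates, grid,
                                         effort = NULL, n, biased = FALSE,
                                         species_id = "sp1",
                                         year_range = c(1950, 2018),
                                         seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  suit <- true_suitability(true_model, covariates)
  w <- as.vector(suit)
  if (biased) {
    if (is.null(effort)) stop("biased sampling requires an effort surface")
    check_grid_matrix(effort, grid, "effort")
    if (any(effort < 0, na.rm = TRUE)) stop("effort must be non-negative")
    if (all(effort == 0 | is.na(effort))) {
      stop("effort is zero everywhere; cannot sample biased occurrences")
    }
    w <- w * as.vector(effort)
  }
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("sampling weights are zero everywhere")
  res <- with_seed(seed, {
    cells <- sample.int(n_cells(grid), n, replace = TRUE, prob = w)
    years <- sample(seq(year_range[1], year_range[2]), n, replace = TRUE)
    list(cells = cells, years = years)
  })
  xy <- xy_from_cell(res$cells, grid)
  structure(
    list(species_id = species_id, true_coefficients = true_model,
         n_presences = n,
         occurrences = data.frame(species_id = species_id, x = xy$x,
                                  y = xy$y, year = res$years,
                                  stringsAsFactors = FALSE),
         cells = res$cells),
    class = "synthetic_species"
  )
}

#' Generate a pool of synthetic species with Gaussian climate niches
#'
#' Each species gets a niche centred at a random point in the space of two
#' randomly chosen climate layers (quadratic terms negative, so suitability
#' peaks at the optimum), plus, with probability `p_landuse`, a linear
#' association with a land-use indicator layer — making some species
#' sensitive to land-use change (the indirect impact pathway).
#'
#' @param n_species number of species.
#' @param climate_layers names of candidate climate layers.
#' @param landuse_layers names of candidate land-use indicator layers
#'   (may be empty).
#' @param p_landuse probability a species responds to land use.
#' @param n_presences records per species (single value or vector).
#' @param niche_width niche breadth in covariate SD units (default 0.45,
#'   a restricted climatic niche that yields informative occurrence data).
#' @param seed integer RNG seed.
#' @return list of truth models (as in [true_suitability()]), one per
#'   species, named `sp01`, `sp02`, ...
#' @export
generate_species_pool <- function(n_species, climate_layers,
                                  landuse_layers = character(),
                                  p_landuse = 0.5, n_presences = 300,
                                  niche_width = 0.45, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n_species), function(i) {
      drivers <- sample(climate_layers, min(2, length(climate_layers)))
      opt <- stats::runif(length(drivers), -1, 1)
      a <- 1 / (2 * niche_width^2)
      linear <- stats::setNames(2 * a * opt, drivers)
      quadratic <- stats::setNames(rep(-a, length(drivers)), drivers)
      # peak suitability on the logit scale in [1, 2] (plogis: 0.73-0.88),
      # so occurrence data carry a clear climatic signal
      intercept <- stats::runif(1, 1, 2) - sum(a * opt^2)
      if (length(landuse_layers) && stats::runif(1) < p_landuse) {
        lu <- sample(landuse_layers, 1)
        linear <- c(linear, stats::setNames(stats::runif(1, 1, 2.5), lu))
      }
      list(intercept = intercept, linear = linear, quadratic = quadratic)
    })
  }) -> pool
  names(pool) <- sprintf("sp%02d", seq_len(n_species))
  pool
}
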