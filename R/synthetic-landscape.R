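#' Generate a spatially autocorrelated covariate field
#'
#' Draws a Gaussian white-noise field and smooths it with a Gaussian kernel
#' of scale `correlation_length` via circular (toroidal) FFT convolution,
#' then standardizes to zero mean and unit variance. With
#' `correlation_length = 0` the field is i.i.d. noise. The toroidal wrap
#' avoids edge artefacts in the autocorrelation structure.
#'
#' @param grid a [grid_spec()].
#' @param correlation_length kernel scale in cells (>= 0).
#' @param seed integer RNG seed; identical inputs give bit-identical output.
#' @return matrix of standardized values.
#' @export
generate_covariate_field <- function(grid, correlation_length, seed) {
  if (!is.numeric(correlation_length) || length(correlation_length) != 1 ||
      is.na(correlation_length) || correlation_length < 0) {
    stop("correlation_length must be a single non-negative number")
  }
  nr <- grid$n_rows; nc <- grid$n_cols
  z <- with_seed(seed, matrix(stats::rnorm(nr * nc), nr, nc))
  if (correlation_length > 0) {
    dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
    dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
    k <- exp(-outer(dr^2, dc^2, "+") / (2 * correlation_length^2))
    k <- k / sum(k)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  }
  z <- z - mean(z)
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  z
}

#' Generate an initial land-use map from a multinomial logistic truth
#'
#' Each cell's class is drawn from a multinomial logistic (softmax) model
#' whose per-class linear predictors are built from the covariate stack and
#' `class_coefficients`. The coefficients are returned alongside the map so
#' downstream suitability fits can be checked against generator truth.
#'
#' @param covariates named list of covariate matrices.
#' @param class_coefficients named list (one element per class code, names
#'   coercible to integer codes); each element is a named numeric vector of
#'   coefficients with an `"(Intercept)"` entry, remaining names referencing
#'   covariate layers.
#' @param grid a [grid_spec()].
#' @param seed integer RNG seed.
#' @return list with `land_use` (integer matrix of class codes) and
#'   `truth` (the coefficient list).
#' @export
generate_initial_landuse <- function(covariates, class_coefficients, grid, seed) {
  check_stack(covariates, grid)
  codes <- as.integer(names(class_coefficients))
  if (any(is.na(codes))) stop("class_coefficients names must be integer class codes")
  n <- n_cells(grid)
  eta <- matrix(0, n, length(codes))
  for (k in seq_along(codes)) {
    b <- class_coefficients[[k]]
    vars <- setdiff(names(b), "(Intercept)")
    bad <- setdiff(vars, names(covariates))
    if (length(bad)) {
      stop(sprintf("class %d coefficients reference missing layer(s): %s",
                   codes[k], paste(bad, collapse = ", ")))
    }
    e <- rep(if ("(Intercept)" %in% names(b)) b[["(Intercept)"]] else 0, n)
    for (v in vars) e <- e + b[[v]] * as.vector(covariates[[v]])
    eta[, k] <- e
  }
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p <- p / rowSums(p)
  cls <- with_seed(seed, {
    u <- stats::runif(n)
    cp <- t(apply(p, 1, cumsum))
    1L + as.integer(rowSums(cp < u))
  })
  lu <- matrix(codes[pmin(cls, length(codes))], grid$n_rows, grid$n_cols)
  list(land_use = lu, truth = class_coefficients)
}

#' Default synthetic land-use class table
#'
#' Eight classes following the common reclassification of global land cover
#' used in regional land-use change studies: urban, cropland, herbaceous
#' ground vegetation, shrubland, open canopy forest, closed canopy forest,
#' wetlands, barren. Whether wetlands and barren land form one or two
#' classes is ambiguous in some classifications; the default here keeps
#' them separate (8 classes) and the list is fully configurable.
#'
#' @return data.frame with columns `code`, `name`, `static` (logical:
#'   excluded from allocation competition).
#' @export
landuse_classes <- function() {
  data.frame(
    code = 1:8,
    name = c("urban", "cropland", "herbaceous", "shrubland",
             "open_forest", "closed_forest", "wetlands", "barren"),
    static = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

## Default multinomial truth for the 8 classes on the standard synthetic
## covariates (clim1..clim3, elevation, access). Intercepts tuned so all
## classes occur at plausible frequencies (urban rare, vegetation common).
default_class_models <- function() {
  list(
    `1` = c("(Intercept)" = -2.5, access = 2.0),                       # urban
    `2` = c("(Intercept)" = 0.3, clim1 = 0.8, elevation = -0.5,
            access = 0.5),                                             # cropland
    `3` = c("(Intercept)" = 0.4, clim1 = -0.3, clim2 = 0.5),           # herbaceous
    `4` = c("(Intercept)" = 0.2, clim2 = -0.6, elevation = 0.4),       # shrubland
    `5` = c("(Intercept)" = 0.1, clim3 = 0.6, elevation = 0.3),        # open forest
    `6` = c("(Intercept)" = 0.0, clim1 = 0.5, clim3 = 0.7,
            access = -0.6),                                            # closed forest
    `7` = c("(Intercept)" = -1.8, clim2 = 0.8, elevation = -0.8),      # wetlands
    `8` = c("(Intercept)" = -1.6, clim1 = -0.9, elevation = 0.9)       # barren
  )
}

#' Generate a bioregion raster by smooth-field quantile slicing
#'
#' Bioregions are contiguous-ish labelled regions obtained by slicing two
#' independent smooth fields into a checkerboard of quantile bins, giving
#' `n_x * n_y` labelled regions with irregular boundaries.
#'
#' @param grid a [grid_spec()].
#' @param n_x,n_y number of quantile bins along each latent field.
#' @param correlation_length smoothness of the latent fields.
#' @param seed integer RNG seed.
#' @return integer matrix of region labels `1..(n_x*n_y)`.
#' @export
generate_bioregions <- function(grid, n_x = 3, n_y = 3,
                                correlation_length = 15, seed = 1) {
  f1 <- generate_covariate_field(grid, correlation_length, seed)
  f2 <- generate_covariate_field(grid, correlation_length, seed + 1L)
  bin <- function(f, k) {
    q <- stats::quantile(f, probs = seq(0, 1, length.out = k + 1))
    cut(as.vector(f), breaks = q, include.lowest = TRUE, labels = FALSE)
  }
  lab <- (bin(f1, n_x) - 1L) * n_y + bin(f2, n_y)
  matrix(as.integer(lab), grid$n_rows, grid$n_cols)
}

#' Simulate a complete synthetic landscape
#'
#' Builds the full set of inputs the pipeline needs: autocorrelated
#' covariates (three climate layers, elevation, accessibility), a land-use
#' map drawn from a known multinomial-logistic truth, a protected-area
#' mask, bioregions, and a sampling-effort surface driven by accessibility
#' and elevation (more effort near accessible, low-lying cells — the usual
#' roadside/population bias in opportunistic occurrence data).
#'
#' @param grid a [grid_spec()].
#' @param class_models per-class coefficient list (default
#'   `default_class_models()`).
#' @param correlation_length covariate field smoothness in cells.
#' @param protected_fraction fraction of cells protected (top of a smooth
#'   latent field, so protected areas are spatially clumped).
#' @param effort_coefficients named vector for the log-linear effort truth.
#' @param seed integer RNG seed.
#' @return list of class `landscape`: `grid`, `covariates`, `land_use`,
#'   `truth`, `protected`, `bioregions`, `effort`,
#'   `effort_coefficients`.
#' @export
simulate_landscape <- function(grid,
                               class_models = default_class_models(),
                               correlation_length = 8,
                               protected_fraction = 0.1,
                               effort_coefficients = c(access = 2, elevation = -0.5),
                               seed = 1) {
  seed <- as.integer(seed)
  cov_names <- c("clim1", "clim2", "clim3", "elevation", "access")
  covariates <- stats::setNames(lapply(seq_along(cov_names), function(i) {
    generate_covariate_field(grid, correlation_length, seed + 10L * i)
  }), cov_names)
  lu <- generate_initial_landuse(covariates, class_models, grid, seed + 100L)
  pa_field <- generate_covariate_field(grid, correlation_length * 1.5, seed + 200L)
  thr <- stats::quantile(pa_field, 1 - protected_fraction)
  protected <- matrix(as.integer(pa_field >= thr), grid$n_rows, grid$n_cols)
  bioregions <- generate_bioregions(grid, seed = seed + 300L)
  eta <- matrix(0, grid$n_rows, grid$n_cols)
  for (v in names(effort_coefficients)) {
    eta <- eta + effort_coefficients[[v]] * covariates[[v]]
  }
  effort <- exp(eta)
  effort <- effort / sum(effort)
  structure(
    list(grid = grid, covariates = covariates, land_use = lu$land_use,
         truth = lu$truth, protected = protected, bioregions = bioregions,
         effort = effort, effort_coefficients = effort_coefficients),
    class = "landscape"
  )
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d; covariates: %s; classes: %s\n",
              x$grid$n_rows, x$grid$n_cols,
              paste(names(x$covariates), collapse = ", "),
              paste(sort(unique(as.vector(x$land_use))), collapse = " ")))
  invisible(x)
}

#' Generate a pseudo-GCM climate ensemble for a future horizon
#'
#' Each ensemble member shares a common anomaly field (the forced signal)
#' plus a member-specific smooth perturbation (structural disagreement
#' between models), both scaled by `severity`, added to the present-day
#' climate layers. With `severity = 0` every member equals the present
#' climate exactly.
#'
#' @param present named list of present-day climate matrices.
#' @param grid a [grid_spec()].
#' @param n_members number of pseudo-GCMs.
#' @param severity scenario severity scalar (>= 0); scales both the shared
#'   anomaly and inter-member spread.
#' @param anomaly_sd magnitude of the shared anomaly at severity 1,
#'   in units of the (standardized) climate layers.
#' @param member_sd magnitude of member perturbations at severity 1.
#' @param correlation_length smoothness of anomaly fields.
#' @param seed integer RNG seed.
#' @return list of members; each member is a named list of matrices with
#'   the layer names of `present`.
#' @export
generate_climate_ensemble <- function(present, grid, n_members = 15,
                                      severity = 1, anomaly_sd = 1,
                                      member_sd = 0.3,
                                      correlation_length = 10, seed = 1) {
  check_stack(present, grid)
  seed <- as.integer(seed)
  lapply(seq_len(n_members), function(m) {
    stats::setNames(lapply(seq_along(present), function(i) {
      shared <- generate_covariate_field(grid, correlation_length,
                                         seed + 1000L * i)
      pert <- generate_covariate_field(grid, correlation_length,
                                       seed + 1000L * i + m)
      present[[i]] + severity * (anomaly_sd * shared + member_sd * pert)
    }), names(present))
  })
}

#' Cell-wise quartiles across a climate ensemble
#'
#' For every cell and layer, computes the first, second and third quartile
#' of the values across ensemble members, using linear interpolation
#' between closest ranks (the default sample-quantile convention), stated
#' here because ensembles commonly have even member counts.
#'
#' @param ensemble list of members, each a named list of matrices sharing
#'   layer names and dimensions.
#' @return list with stacks `q1`, `median`, `q3`.
#' @export
ensemble_quartiles <- function(ensemble) {
  if (!is.list(ensemble) || length(ensemble) < 1) {
    stop("ensemble must contain at least one member")
  }
  layer_names <- names(ensemble[[1]])
  for (m in ensemble) {
    if (!identical(names(m), layer_names)) {
      stop("ensemble members have mismatched layer names")
    }
  }
  nr <- nrow(ensemble[[1]][[1]]); nc <- ncol(ensemble[[1]][[1]])
  M <- length(ensemble)
  one_layer <- function(nm) {
    vals <- vapply(ensemble, function(m) as.vector(m[[nm]]), numeric(nr * nc))
    vals <- matrix(vals, nrow = nr * nc, ncol = M)
    q <- apply(vals, 1, stats::quantile, probs = c(0.25, 0.5, 0.75),
               type = 7, names = FALSE)
    list(q1 = matrix(q[1, ], nr, nc), median = matrix(q[2, ], nr, nc),
         q3 = matrix(q[3, ], nr, nc))
  }
  per_layer <- lapply(layer_names, one_layer)
  names(per_layer) <- layer_names
  list(q1 = lapply(per_layer, `[[`, "q1"),
       median = lapply(per_layer, `[[`, "median"),
       q3 = lapply(per_layer, `[[`, "q3"))
}
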