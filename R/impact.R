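## Impact assessment: thresholded present/future predictions under three
## treatments are turned into per-species range-change statistics, cohort
## summaries and per-cell loss-proportion maps. Treatments isolate the
## pathways of climate change: "direct" swaps in future climate while
## holding land use at present, "indirect" swaps in future land use while
## holding climate at present, and "combined" swaps in both.

#' Dispersal mask from bioregions and occurrence records
#'
#' Under `"unlimited"` dispersal the mask covers every valid cell. Under
#' `"bioregion_adjacent"` it covers the bioregions containing at least one
#' record plus bioregions sharing a boundary with those; adjacency between
#' region labels is 8-neighbour (queen) cell contact by default, or
#' 4-neighbour (rook) via `adjacency`.
#'
#' @param bioregions integer region-label matrix (`NA` = nodata).
#' @param occurrences data.frame with `x`, `y`.
#' @param grid a [grid_spec()].
#' @param mode `"unlimited"` or `"bioregion_adjacent"`.
#' @param adjacency `"queen"` (default) or `"rook"`.
#' @return integer 0/1 matrix.
#' @export
dispersal_mask <- function(bioregions, occurrences, grid,
                           mode = c("unlimited", "bioregion_adjacent"),
                           adjacency = c("queen", "rook")) {
  mode <- match.arg(mode)
  adjacency <- match.arg(adjacency)
  check_grid_matrix(bioregions, grid, "bioregions")
  valid <- !is.na(bioregions)
  if (mode == "unlimited") {
    return(matrix(as.integer(valid), grid$n_rows, grid$n_cols))
  }
  cells <- cell_from_xy(occurrences$x, occurrences$y, grid)
  occ_regions <- unique(bioregions[cells[!is.na(cells)]])
  occ_regions <- occ_regions[!is.na(occ_regions)]
  if (!length(occ_regions)) stop("all occurrences fall on nodata cells")
  shifts <- list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  if (adjacency == "queen") {
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  nr <- grid$n_rows; nc <- grid$n_cols
  pairs <- list()
  for (s in shifts) {
    r1 <- max(1, 1 + s[1]):min(nr, nr + s[1])
    c1 <- max(1, 1 + s[2]):min(nc, nc + s[2])
    a <- bioregions[r1, c1, drop = FALSE]
    b <- bioregions[r1 - s[1], c1 - s[2], drop = FALSE]
    diff <- !is.na(a) & !is.na(b) & a != b
    if (any(diff)) pairs[[length(pairs) + 1L]] <- cbind(a[diff], b[diff])
  }
  adj <- unique(do.call(rbind, c(pairs, list(matrix(integer(), 0, 2)))))
  neighbours <- unique(adj[adj[, 1] %in% occ_regions, 2])
  keep <- union(occ_regions, neighbours)
  matrix(as.integer(valid & bioregions %in% keep), nr, nc)
}

#' Threshold a prediction into a binary range
#'
#' A cell is suitable iff its predicted relative likelihood is at or above
#' the threshold and the dispersal mask allows it.
#'
#' @param prediction matrix of relative likelihoods.
#' @param threshold finite threshold (e.g. from [maxsss_threshold()]).
#' @param mask optional 0/1 matrix; `NULL` = no mask.
#' @return list with `range` (integer 0/1 matrix) and `count` (number of
#'   suitable cells).
#' @export
binary_range <- function(prediction, threshold, mask = NULL) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  suitable <- !is.na(prediction) & prediction >= threshold
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(prediction))) stop("mask grid mismatch")
    suitable <- suitable & !is.na(mask) & mask == 1
  }
  rng <- matrix(as.integer(suitable), nrow(prediction), ncol(prediction))
  list(range = rng, count = sum(rng))
}

#' Range change between present and future suitable-cell counts
#'
#' @param present_count present suitable cells (> 0; species with empty
#'   present ranges must be excluded upstream).
#' @param future_count future suitable cells (>= 0).
#' @return list: `ratio` (future/present), `log_ratio` (natural log;
#'   `NA` when extirpated), `extirpated` (future count 0).
#' @export
range_change <- function(present_count, future_count) {
  if (present_count <= 0) {
    stop("present range is empty; species must be excluded from change estimation")
  }
  ratio <- future_count / present_count
  list(ratio = ratio,
       log_ratio = if (future_count > 0) log(ratio) else NA_real_,
       extirpated = future_count == 0)
}

#' Predictions under the direct, indirect and combined treatments
#'
#' Builds three covariate stacks by recombining present and future layer
#' sources — direct: future climate with present land use; indirect:
#' present climate with future land use; combined: future for both — and
#' predicts each with the same fitted model (the same threshold applies to
#' all three downstream).
#'
#' @param fit an `sdm_fit`.
#' @param present named list of present-day layers (all predictors).
#' @param future named list of future layers (same names).
#' @param landuse_layers names of the land-use-derived layers within the
#'   stacks (possibly none of them used by the fit).
#' @return named list of prediction matrices: `direct`, `indirect`,
#'   `combined`.
#' @export
treatment_predictions <- function(fit, present, future, landuse_layers) {
  for (tr in c("present", "future")) {
    stack <- if (tr == "present") present else future
    miss <- setdiff(fit$predictors, names(stack))
    if (length(miss)) {
      stop(sprintf("%s stack missing layer(s): %s", tr,
                   paste(miss, collapse = ", ")))
    }
  }
  swap <- function(base, donor, layers) {
    for (nm in intersect(layers, names(base))) base[[nm]] <- donor[[nm]]
    base
  }
  direct <- swap(future, present, landuse_layers)
  indirect <- swap(present, future, landuse_layers)
  list(direct = predict_sdm(fit, direct),
       indirect = predict_sdm(fit, indirect),
       combined = predict_sdm(fit, future))
}

#' Per-cell proportion of species losing suitable range
#'
#' For each cell, the numerator counts species suitable there at present
#' but not in the future, and the denominator counts species suitable
#' there at present; cells where no species is present-suitable are
#' `NA`. A whole-cohort denominator (all retained species) is available
#' via `denominator = "all"`.
#'
#' @param present_ranges,future_ranges lists of 0/1 matrices, parallel by
#'   species.
#' @param denominator `"present_suitable"` (default) or `"all"`.
#' @return matrix of proportions in `[0, 1]` (or `NA`).
#' @export
loss_proportion_map <- function(present_ranges, future_ranges,
                                denominator = c("present_suitable", "all")) {
  denominator <- match.arg(denominator)
  if (!length(present_ranges)) stop("at least one species is required")
  if (length(present_ranges) != length(future_ranges)) {
    stop("present and future range lists differ in length")
  }
  num <- den <- matrix(0, nrow(present_ranges[[1]]), ncol(present_ranges[[1]]))
  for (i in seq_along(present_ranges)) {
    p <- present_ranges[[i]]; f <- future_ranges[[i]]
    num <- num + (p == 1 & f == 0)
    den <- den + if (denominator == "present_suitable") (p == 1) else 1
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Cohort summary of range-change records
#'
#' Per scenario x treatment: the mean multiplicative range change across
#' species, counts of species losing at least each threshold fraction of
#' their present range, and the species lists for the 10% and 95% tiers.
#' Extirpated species (ratio 0) fall in every loss tier.
#'
#' @param records data.frame with columns `species_id`, `scenario`,
#'   `treatment`, `ratio` (and optionally `extirpated`).
#' @param loss_thresholds loss fractions to count (default 0.5, 0.1,
#'   0.95).
#' @return list: `summary` (data.frame with `scenario`, `treatment`,
#'   `n_species`, `mean_ratio`, one `n_loss_geXX` column per threshold)
#'   and `species_lists` (nested list by scenario/treatment with `ge10`
#'   and `ge95` species vectors).
#' @export
summarize_cohort <- function(records, loss_thresholds = c(0.5, 0.1, 0.95)) {
  if (!nrow(records)) stop("records must be non-empty")
  groups <- unique(records[, c("scenario", "treatment")])
  rows <- list(); lists <- list()
  for (i in seq_len(nrow(groups))) {
    sc <- groups$scenario[i]; tr <- groups$treatment[i]
    r <- records[records$scenario == sc & records$treatment == tr, ]
    row <- data.frame(scenario = sc, treatment = tr, n_species = nrow(r),
                      mean_ratio = mean(r$ratio), stringsAsFactors = FALSE)
    for (thr in loss_thresholds) {
      row[[sprintf("n_loss_ge%02.0f", 100 * thr)]] <- sum(r$ratio <= 1 - thr)
    }
    rows[[i]] <- row
    lists[[sc]][[tr]] <- list(
      ge10 = r$species_id[r$ratio <= 0.9],
      ge95 = r$species_id[r$ratio <= 0.05]
    )
  }
  list(summary = do.call(rbind, rows), species_lists = lists)
}
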