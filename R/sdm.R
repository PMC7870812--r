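## Presence-background species distribution modelling. The model is an
## elastic-net penalized logistic regression of presences against
## background points on linear + quadratic features of the predictors --
## the standard re-expression of a maximum-entropy model restricted to
## those feature classes. Background points are drawn in proportion to an
## estimated sampling-effort surface, which cancels the effect of
## opportunistic observer bias on the fitted response.

#' Filter occurrence records by year window and minimum sample size
#'
#' Records outside `[min_year, max_year]` are dropped; species with fewer
#' than `min_n` remaining records are excluded entirely.
#'
#' @param occurrences data.frame with columns `species_id`, `x`, `y`,
#'   `year`.
#' @param min_year,max_year inclusive year window (default 1950-2018).
#' @param min_n minimum records per species after windowing (default 20;
#'   a species with exactly `min_n` records is retained).
#' @return list with `records` (filtered data.frame) and `counts`
#'   (data.frame `species_id`, `n_total`, `n_window`, `retained`).
#' @export
filter_records <- function(occurrences, min_year = 1950, max_year = 2018,
                           min_n = 20) {
  req <- c("species_id", "x", "y", "year")
  miss <- setdiff(req, names(occurrences))
  if (length(miss)) stop("occurrence table missing column(s): ",
                         paste(miss, collapse = ", "))
  in_window <- occurrences$year >= min_year & occurrences$year <= max_year
  kept <- occurrences[in_window, , drop = FALSE]
  ids <- unique(occurrences$species_id)
  counts <- data.frame(
    species_id = ids,
    n_total = as.integer(table(factor(occurrences$species_id, ids))),
    n_window = as.integer(table(factor(kept$species_id, ids))),
    stringsAsFactors = FALSE
  )
  counts$retained <- counts$n_window >= min_n
  records <- kept[kept$species_id %in% counts$species_id[counts$retained], ,
                  drop = FALSE]
  rownames(records) <- NULL
  list(records = records, counts = counts)
}

#' Estimate a sampling-effort surface from pooled occurrence records
#'
#' Per-cell record counts (all species pooled) are regressed on the
#' driver layers with a log-link Poisson model; the fitted mean surface,
#' normalized to sum to one, is the relative sampling effort.
#'
#' @param all_records occurrence data.frame (`x`, `y` used).
#' @param drivers named list of driver matrices (demographic/topographic
#'   accessibility proxies).
#' @param grid a [grid_spec()].
#' @return object of class `effort_surface`: `effort` (matrix summing to
#'   1), `coefficients`, `se`, `drivers`.
#' @export
estimate_effort <- function(all_records, drivers, grid) {
  check_stack(drivers, grid)
  cells <- cell_from_xy(all_records$x, all_records$y, grid)
  cells <- cells[!is.na(cells)]
  if (!length(cells)) stop("no on-grid records; cannot estimate effort")
  counts <- tabulate(cells, nbins = n_cells(grid))
  if (all(counts == 0)) stop("all per-cell record counts are zero")
  dat <- data.frame(count = counts)
  for (v in names(drivers)) dat[[v]] <- as.vector(drivers[[v]])
  fit <- stats::glm(count ~ ., data = dat, family = stats::poisson())
  mu <- matrix(stats::fitted(fit), grid$n_rows, grid$n_cols)
  sm <- summary(fit)$coefficients
  structure(
    list(effort = mu / sum(mu), coefficients = stats::coef(fit),
         se = sm[, "Std. Error"], drivers = names(drivers)),
    class = "effort_surface"
  )
}

#' Sample background points proportional to sampling effort
#'
#' Cells are drawn with replacement with probability proportional to the
#' effort surface; zero-effort cells are never sampled. Coordinates are
#' cell centres.
#'
#' @param effort an `effort_surface` or a non-negative matrix.
#' @param grid a [grid_spec()].
#' @param n number of background points (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame with columns `x`, `y`, `cell`.
#' @export
sample_background <- function(effort, grid, n = 10000, seed = 1) {
  if (inherits(effort, "effort_surface")) effort <- effort$effort
  check_grid_matrix(effort, grid, "effort")
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  w <- as.vector(effort)
  w[is.na(w)] <- 0
  if (any(w < 0)) stop("effort must be non-negative")
  if (sum(w) <= 0) stop("effort is zero everywhere")
  cells <- with_seed(seed, sample.int(n_cells(grid), as.integer(n),
                                      replace = TRUE, prob = w))
  xy <- xy_from_cell(cells, grid)
  data.frame(x = xy$x, y = xy$y, cell = cells)
}

## Linear + quadratic feature expansion of raw predictor columns.
## Zero-variance features are dropped (with a warning at fit time).
sdm_features <- function(x, predictors) {
  x <- as.matrix(x[, predictors, drop = FALSE])
  feats <- cbind(x, x^2)
  colnames(feats) <- c(predictors, paste0(predictors, "_sq"))
  feats
}

#' Fit a penalized presence-background SDM
#'
#' Logistic regression of presence (1) vs background (0) on linear +
#' quadratic features of the predictors, with an elastic-net penalty whose
#' strength is chosen by internal cross-validation and scaled by
#' `regularization`. Predictions are relative likelihoods in `[0, 1]`;
#' they are used for ranking and thresholding, so any monotone rescaling
#' downstream is inconsequential.
#'
#' @param presence_cells,background_cells linear cell indices of presence
#'   and background points.
#' @param covariates named list of predictor matrices.
#' @param predictors predictor layer names (default all layers).
#' @param regularization multiplier on the CV-chosen penalty (default 1).
#' @param alpha elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @param species_id identifier carried in the fit.
#' @param seed integer RNG seed (CV fold assignment).
#' @return object of class `sdm_fit`: `species_id`, `predictors`,
#'   `feature_names`, `coefficients` (named, incl. `(Intercept)`),
#'   `lambda`, `alpha`, `regularization`, `presence_cells`,
#'   `background_cells`, `seed`.
#' @export
fit_sdm <- function(presence_cells, background_cells, covariates,
                    predictors = names(covariates), regularization = 1,
                    alpha = 0.5, species_id = "sp", seed = 1) {
  if (length(presence_cells) < 5) stop("too few presences to fit an SDM")
  cells <- c(presence_cells, background_cells)
  y <- c(rep(1L, length(presence_cells)), rep(0L, length(background_cells)))
  x <- stack_values(covariates, cells, predictors)
  feats <- sdm_features(as.data.frame(x), predictors)
  keep <- apply(feats, 2, function(v) stats::var(v) > 0)
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(feats)[!keep], collapse = ", "))
    feats <- feats[, keep, drop = FALSE]
  }
  cvfit <- with_seed(seed, {
    foldid <- sample(rep_len(1:5, length(y)))
    glmnet::cv.glmnet(feats, y, family = "binomial", alpha = alpha,
                      foldid = foldid)
  })
  # the conservative "one standard error" penalty: stronger shrinkage
  # suppresses uninformative features, which the permutation-importance
  # stage then prunes cleanly
  lambda <- cvfit$lambda.1se * regularization
  fit <- glmnet::glmnet(feats, y, family = "binomial", alpha = alpha,
                        lambda = lambda)
  beta <- as.matrix(stats::coef(fit))[, 1]
  structure(
    list(species_id = species_id, predictors = predictors,
         feature_names = colnames(feats), coefficients = beta,
         lambda = lambda, alpha = alpha, regularization = regularization,
         presence_cells = presence_cells,
         background_cells = background_cells, seed = seed),
    class = "sdm_fit"
  )
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s; predictors: %s; lambda = %.4g\n",
              x$species_id, paste(x$predictors, collapse = ", "), x$lambda))
  invisible(x)
}

## Linear predictor of an sdm_fit on a feature matrix.
sdm_eta <- function(fit, feats) {
  b <- fit$coefficients
  eta <- rep(b[["(Intercept)"]], nrow(feats))
  for (nm in intersect(names(b), colnames(feats))) {
    eta <- eta + b[[nm]] * feats[, nm]
  }
  eta
}

#' Predict an SDM over a covariate stack
#'
#' @param fit an `sdm_fit`.
#' @param covariates named list of matrices containing every predictor of
#'   the fit.
#' @return matrix of relative likelihoods in `[0, 1]`; `NA` propagates.
#' @export
predict_sdm <- function(fit, covariates) {
  miss <- setdiff(fit$predictors, names(covariates))
  if (length(miss)) {
    stop("covariate stack missing layer(s): ", paste(miss, collapse = ", "))
  }
  nr <- nrow(covariates[[1]]); nc <- ncol(covariates[[1]])
  x <- vapply(fit$predictors, function(v) as.vector(covariates[[v]]),
              numeric(nr * nc))
  feats <- sdm_features(as.data.frame(x), fit$predictors)
  matrix(stats::plogis(sdm_eta(fit, feats)), nr, nc)
}

## Scores of a fit at its own training points.
sdm_training_scores <- function(fit, covariates) {
  cells <- c(fit$presence_cells, fit$background_cells)
  x <- stack_values(covariates, cells, fit$predictors)
  feats <- sdm_features(as.data.frame(x), fit$predictors)
  s <- stats::plogis(sdm_eta(fit, feats))
  list(presence = s[seq_along(fit$presence_cells)],
       background = s[-seq_along(fit$presence_cells)])
}

#' Area under the ROC curve for presence vs background scores
#'
#' The probability that a randomly chosen presence outscores a randomly
#' chosen background point, with ties counted one half — the normalized
#' Mann-Whitney U statistic.
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  n_p <- length(presence_scores); n_b <- length(background_scores)
  if (n_p == 0 || n_b == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  u <- sum(r[seq_len(n_p)]) - n_p * (n_p + 1) / 2
  u / (n_p * n_b)
}

#' MaxSSS threshold: maximize sensitivity + specificity
#'
#' Sweeps the observed scores as candidate thresholds (background points
#' standing in for absences) and returns the threshold at which
#' sensitivity + specificity is maximal; cells scoring at or above the
#' threshold count as suitable. Among tied candidates the smallest is
#' returned (the most inclusive suitable range).
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return threshold, with attributes `sensitivity`, `specificity`.
#' @export
maxsss_threshold <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores)) {
    stop("both score sets must be non-empty")
  }
  cand <- sort(unique(c(presence_scores, background_scores)))
  sens <- vapply(cand, function(t) mean(presence_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(background_scores < t), numeric(1))
  ss <- sens + spec
  best <- which.max(ss)   # first (= smallest) maximizer
  if (length(cand) == 1L) {
    warning("all scores identical; MaxSSS threshold is degenerate")
  }
  structure(cand[best], sensitivity = sens[best], specificity = spec[best])
}

#' Fivefold cross-validated AUC of a presence-background model
#'
#' Presences are split into `k` random folds; for each fold the model is
#' refit on the remaining presences (background points are shared across
#' folds) and test AUC computed on the held-out presences against the
#' background. The final model, fit on all records, is gated on the mean
#' fold AUC.
#'
#' @param presence_cells,background_cells linear cell indices.
#' @param covariates named list of predictor matrices.
#' @param predictors predictor names.
#' @param k number of folds (presences must number at least `k`).
#' @param auc_threshold retention gate on the mean fold AUC (default 0.7).
#' @param regularization,alpha passed to [fit_sdm()].
#' @param seed integer RNG seed.
#' @return list: `fold_aucs`, `mean_auc`, `retained`, `fit` (final model
#'   on all records).
#' @export
cv_auc <- function(presence_cells, background_cells, covariates,
                   predictors = names(covariates), k = 5,
                   auc_threshold = 0.7, regularization = 1, alpha = 0.5,
                   seed = 1) {
  n_p <- length(presence_cells)
  if (n_p < k) stop(sprintf("%d presences cannot fill %d folds", n_p, k))
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n_p)))
  score_at <- function(fit, cells) {
    x <- stack_values(covariates, cells, fit$predictors)
    stats::plogis(sdm_eta(fit, sdm_features(as.data.frame(x), fit$predictors)))
  }
  fold_aucs <- vapply(seq_len(k), function(f) {
    train <- presence_cells[fold != f]
    test <- presence_cells[fold == f]
    fit_f <- fit_sdm(train, background_cells, covariates, predictors,
                     regularization = regularization, alpha = alpha,
                     seed = seed + f)
    auc(score_at(fit_f, test), score_at(fit_f, background_cells))
  }, numeric(1))
  final <- fit_sdm(presence_cells, background_cells, covariates, predictors,
                   regularization = regularization, alpha = alpha,
                   seed = seed)
  list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
       retained = mean(fold_aucs) >= auc_threshold, fit = final)
}

#' Permutation importance and pruning of SDM predictors
#'
#' Importance of a predictor is the mean drop in training AUC when its raw
#' values are permuted across the training points (linear and quadratic
#' features move together), averaged over `n_perm` permutations, floored
#' at zero, and normalized so the importances sum to 100. Predictors below
#' `threshold` percent are dropped and the model refit once on the
#' survivors.
#'
#' @param fit an `sdm_fit`.
#' @param covariates named list of predictor matrices.
#' @param n_perm permutations per predictor (>= 1).
#' @param threshold importance percentage below which a predictor is
#'   dropped (default 1).
#' @param seed integer RNG seed.
#' @return list: `importance` (named vector summing to 100), `dropped`,
#'   `fit` (pruned refit, or the input fit if nothing was dropped).
#' @export
permutation_importance <- function(fit, covariates, n_perm = 5,
                                   threshold = 1, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  cells <- c(fit$presence_cells, fit$background_cells)
  n_pres <- length(fit$presence_cells)
  x <- as.data.frame(stack_values(covariates, cells, fit$predictors))
  base_feats <- sdm_features(x, fit$predictors)
  base_s <- stats::plogis(sdm_eta(fit, base_feats))
  base_auc <- auc(base_s[seq_len(n_pres)], base_s[-seq_len(n_pres)])
  drops <- with_seed(seed, {
    vapply(fit$predictors, function(v) {
      mean(vapply(seq_len(n_perm), function(j) {
        xp <- x
        xp[[v]] <- sample(xp[[v]])
        s <- stats::plogis(sdm_eta(fit, sdm_features(xp, fit$predictors)))
        base_auc - auc(s[seq_len(n_pres)], s[-seq_len(n_pres)])
      }, numeric(1)))
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) {
    warning("no predictor changes training AUC under permutation; ",
            "keeping all predictors")
    imp <- stats::setNames(rep(100 / length(drops), length(drops)),
                           names(drops))
    return(list(importance = imp, dropped = character(), fit = fit))
  }
  imp <- 100 * drops / sum(drops)
  dropped <- names(imp)[imp < threshold]
  if (length(dropped) == length(imp)) {
    warning("all predictors below the importance threshold; ",
            "keeping the single most important")
    dropped <- setdiff(names(imp), names(imp)[which.max(imp)])
  }
  if (!length(dropped)) {
    return(list(importance = imp, dropped = character(), fit = fit))
  }
  keep <- setdiff(fit$predictors, dropped)
  refit <- fit_sdm(fit$presence_cells, fit$background_cells, covariates,
                   predictors = keep, regularization = fit$regularization,
                   alpha = fit$alpha, species_id = fit$species_id,
                   seed = fit$seed)
  list(importance = imp, dropped = dropped, fit = refit)
}

#' Serialize an SDM fit to JSON
#'
#' @param fit an `sdm_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdm_fit <- function(fit, path) {
  obj <- unclass(fit)
  obj$coefficients <- as.list(obj$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an SDM fit from JSON
#'
#' @param path JSON file written by [write_sdm_fit()].
#' @return an `sdm_fit`.
#' @export
read_sdm_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$presence_cells <- as.integer(obj$presence_cells)
  obj$background_cells <- as.integer(obj$background_cells)
  structure(obj, class = "sdm_fit")
}
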