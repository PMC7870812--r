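## Per-class land-use suitability: one-vs-rest logistic regressions fitted
## to randomly sampled pixels, with a Spearman correlation filter and
## cross-validated Lasso predictor selection, then an unpenalized refit on
## the retained set. Predictions give each class's potential suitability
## surface for the allocator.

#' Sample pixels from a landscape for suitability fitting
#'
#' Uniform random sample without replacement over valid (non-nodata)
#' cells, returning covariate values and the observed land-use class.
#'
#' @param landscape a `landscape` (see [simulate_landscape()]) or a list
#'   with `grid`, `covariates`, `land_use`.
#' @param n sample size (default 15000).
#' @param seed integer RNG seed.
#' @return data.frame with columns `cell`, `class`, and one column per
#'   covariate layer.
#' @export
sample_pixels <- function(landscape, n = 15000, seed = 1) {
  grid <- landscape$grid
  valid <- which(!is.na(landscape$land_use) &
                   landscape$land_use != grid$nodata_code)
  if (n > length(valid)) {
    stop(sprintf("n = %d exceeds the %d valid cells; use n <= %d",
                 n, length(valid), length(valid)))
  }
  cells <- with_seed(seed, sample(valid, n))
  vals <- stack_values(landscape$covariates, cells)
  out <- data.frame(cell = cells, class = landscape$land_use[cells])
  cbind(out, as.data.frame(vals))
}

#' Drop highly correlated predictors by iterated Spearman filtering
#'
#' While any predictor pair has `|rho| >=` the threshold (Spearman rank
#' correlation), the pair with the largest `|rho|` is examined and the
#' member whose highest `|rho|` against the *other remaining* predictors
#' is larger is dropped — keeping the predictor that carries more
#' independent information. Ties are broken by column order (the earlier
#' column is kept). Constant predictors have undefined rank correlation
#' and are treated as correlation 0 with a warning.
#'
#' @param x data.frame or matrix of predictor columns.
#' @param threshold absolute Spearman correlation at or above which a pair
#'   is considered redundant (default 0.7).
#' @return character vector of retained predictor names, in input order.
#' @export
filter_correlated <- function(x, threshold = 0.7) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) return(names(x))
  if (nrow(x) < 3) stop("need at least 3 rows to estimate rank correlations")
  constant <- vapply(x, function(v) stats::var(v) == 0 || all(is.na(v)),
                     logical(1))
  rho <- suppressWarnings(stats::cor(x, method = "spearman",
                                     use = "pairwise.complete.obs"))
  if (any(constant)) {
    warning("constant predictor(s) treated as correlation 0: ",
            paste(names(x)[constant], collapse = ", "))
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 0
  rho <- abs(rho)
  keep <- names(x)
  repeat {
    if (length(keep) < 2) break
    sub <- rho[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx < threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- keep[hit[1]]; b <- keep[hit[2]]
    others <- setdiff(keep, c(a, b))
    ma <- if (length(others)) max(rho[a, others]) else -Inf
    mb <- if (length(others)) max(rho[b, others]) else -Inf
    drop <- if (ma > mb) a
            else if (mb > ma) b
            else keep[max(match(c(a, b), keep))]   # tie: keep earlier column
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Fit a one-vs-rest suitability model for one land-use class
#'
#' Binomial logistic regression of class membership against the retained
#' predictors. An L1 (Lasso) penalty path is evaluated by k-fold
#' cross-validation; predictors with zero coefficient at the
#' minimum-deviance penalty are discarded, and the model is refit
#' unpenalized (`stats::glm`) on the survivors so coefficients and their
#' standard errors are directly interpretable.
#'
#' @param samples pixel sample from [sample_pixels()].
#' @param class land-use class code to model.
#' @param predictors candidate predictor names (e.g. the output of
#'   [filter_correlated()]); defaults to all covariate columns.
#' @param folds number of CV folds for the penalty choice.
#' @param seed integer RNG seed (fold assignment).
#' @return object of class `suitability_model`: `class`,
#'   `retained_predictors`, `coefficients`, `se`, `lambda`,
#'   `lambda_path`, `fit` (the glm refit), `folds`, `seed`.
#' @export
fit_class_suitability <- function(samples, class, predictors = NULL,
                                  folds = 10, seed = 1) {
  if (is.null(predictors)) {
    predictors <- setdiff(names(samples), c("cell", "class"))
  }
  y <- as.integer(samples$class == class)
  if (sum(y) < 10) {
    stop(sprintf("class %s has %d positive pixels; at least 10 are required",
                 class, sum(y)))
  }
  x <- as.matrix(samples[, predictors, drop = FALSE])
  cvfit <- with_seed(seed, {
    foldid <- sample(rep_len(seq_len(folds), nrow(x)))
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1, foldid = foldid)
  })
  beta <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[, 1]
  retained <- setdiff(names(beta)[beta != 0], "(Intercept)")
  if (!length(retained)) retained <- predictors[1]  # degenerate: keep one
  dat <- data.frame(y = y, samples[, retained, drop = FALSE])
  refit <- stats::glm(y ~ ., data = dat, family = stats::binomial())
  sm <- summary(refit)$coefficients
  structure(
    list(class = class, retained_predictors = retained,
         coefficients = stats::coef(refit), se = sm[, "Std. Error"],
         lambda = cvfit$lambda.min, lambda_path = cvfit$lambda,
         fit = refit, folds = folds, seed = seed),
    class = "suitability_model"
  )
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf("<suitability_model> class %s; predictors: %s; lambda = %.4g\n",
              x$class, paste(x$retained_predictors, collapse = ", "),
              x$lambda))
  invisible(x)
}

#' Predict a suitability surface from a fitted class model
#'
#' Cell-wise inverse-logit of the linear predictor over the covariate
#' stack; `NA` cells propagate.
#'
#' @param model a `suitability_model`.
#' @param covariates named list of matrices containing every retained
#'   predictor.
#' @return matrix of suitabilities in `[0, 1]`.
#' @export
predict_suitability <- function(model, covariates) {
  miss <- setdiff(model$retained_predictors, names(covariates))
  if (length(miss)) {
    stop("covariate stack is missing layer(s): ", paste(miss, collapse = ", "))
  }
  b <- model$coefficients
  eta <- matrix(b[["(Intercept)"]],
                nrow(covariates[[1]]), ncol(covariates[[1]]))
  for (v in model$retained_predictors) eta <- eta + b[[v]] * covariates[[v]]
  stats::plogis(eta)
}

#' Fit suitability models for every land-use class
#'
#' Convenience wrapper: samples pixels once, applies the correlation
#' filter, and fits one model per class present in the sample.
#'
#' @param landscape a `landscape`.
#' @param classes class codes to fit (default: all classes in the map).
#' @param n pixel sample size.
#' @param threshold Spearman filter threshold.
#' @param folds CV folds for the Lasso.
#' @param seed integer RNG seed.
#' @return named list of `suitability_model`s (names = class codes).
#' @export
fit_suitability_models <- function(landscape, classes = NULL, n = 15000,
                                   threshold = 0.7, folds = 10, seed = 1) {
  samples <- sample_pixels(landscape, n = n, seed = seed)
  if (is.null(classes)) classes <- sort(unique(samples$class))
  predictors <- filter_correlated(
    samples[, setdiff(names(samples), c("cell", "class")), drop = FALSE],
    threshold = threshold
  )
  models <- lapply(seq_along(classes), function(i) {
    fit_class_suitability(samples, classes[i], predictors = predictors,
                          folds = folds, seed = seed + i)
  })
  names(models) <- as.character(classes)
  models
}
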