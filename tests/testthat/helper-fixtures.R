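# Shared fixtures and independent oracles used across test files.

# Brute-force lag-1 (rook) Moran's I, written as an explicit loop over
# neighbour pairs -- independent of any vectorized shortcut.
moran_i_bruteforce <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  x <- m - mean(m)
  num <- 0; w <- 0
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (r < nr) { num <- num + x[r, c] * x[r + 1, c]; w <- w + 1 }
      if (c < nc) { num <- num + x[r, c] * x[r, c + 1]; w <- w + 1 }
    }
  }
  # symmetric weights: each pair counted once above, twice in the formula
  (length(m) / (2 * w)) * (2 * num / sum(x^2))
}

# Lag-1 correlation between horizontally adjacent cells.
lag1_cor <- function(m) {
  stats::cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
}

# Small landscape used by several suites.
small_landscape <- function(seed = 7, nr = 60, nc = 60) {
  simulate_landscape(grid_spec(nr, nc), seed = seed)
}

# Two-class landscape whose one-vs-rest logistic truth equals the class-2
# coefficients (class 1 is the zero reference), for recovery tests.
two_class_landscape <- function(seed, nr = 150, nc = 120,
                                beta = c("(Intercept)" = -0.4, clim1 = 0.8,
                                         clim2 = -0.5, elevation = 0.4,
                                         access = 0.3)) {
  grid <- grid_spec(nr, nc)
  cov_names <- c("clim1", "clim2", "elevation", "access")
  covs <- stats::setNames(lapply(seq_along(cov_names), function(i) {
    generate_covariate_field(grid, 6, seed + 10L * i)
  }), cov_names)
  lu <- generate_initial_landuse(
    covs, list(`1` = c("(Intercept)" = 0), `2` = beta), grid, seed + 99L)
  list(grid = grid, covariates = covs, land_use = lu$land_use, truth = beta)
}

# Independent re-implementation of the correlation-filter rule, operating
# directly on a correlation matrix: among the pair with the highest
# absolute correlation, drop the member whose maximum against the other
# remaining predictors is larger (ties keep the earlier column).
filter_rule_oracle <- function(rho, threshold) {
  rho <- abs(rho); diag(rho) <- 0
  keep <- colnames(rho)
  repeat {
    if (length(keep) < 2) break
    sub <- rho[keep, keep, drop = FALSE]
    if (max(sub) < threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    rest <- setdiff(keep, c(a, b))
    ma <- if (length(rest)) max(rho[a, rest]) else -Inf
    mb <- if (length(rest)) max(rho[b, rest]) else -Inf
    drop <- if (ma > mb) a else if (mb > ma) b
            else keep[max(match(c(a, b), keep))]
    keep <- setdiff(keep, drop)
  }
  keep
}

# Brute-force AUC by enumerating every presence/background pair.
auc_bruteforce <- function(p, b) {
  tot <- 0
  for (x in p) for (y in b) {
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  tot / (length(p) * length(b))
}

# Brute-force MaxSSS: sweep every observed score, return the best
# sensitivity + specificity achievable.
maxsss_bruteforce <- function(p, b) {
  cand <- sort(unique(c(p, b)))
  best <- -Inf
  for (t in cand) {
    ss <- mean(p >= t) + mean(b < t)
    if (ss > best) best <- ss
  }
  best
}

# Random allocation problem with a demand that is achievable by
# construction (a random legal reassignment of unprotected cells).
random_allocation_problem <- function(seed, nr = 100, nc = 100) {
  set.seed(seed)
  K <- sample(3:6, 1)
  codes <- seq_len(K)
  grid <- grid_spec(nr, nc)
  suits <- stats::setNames(lapply(codes, function(k) {
    0.5 + 0.2 * generate_covariate_field(grid, 5, seed * 100 + k) +
      matrix(stats::runif(nr * nc, -0.1, 0.1), nr, nc)
  }), as.character(codes))
  current <- matrix(sample(codes, nr * nc, TRUE), nr, nc)
  trans <- matrix(stats::runif(K * K) < 0.6, K, K,
                  dimnames = list(codes, codes))
  diag(trans) <- TRUE
  protected <- matrix(as.integer(stats::runif(nr * nc) < 0.1), nr, nc)
  elas <- stats::setNames(stats::runif(K), as.character(codes))
  tgt <- current
  idx <- which(protected == 0)
  flip <- sample(idx, round(length(idx) * stats::runif(1, 0.05, 0.3)))
  for (i in flip) {
    opts <- codes[trans[current[i], ]]
    tgt[i] <- opts[sample.int(length(opts), 1)]
  }
  demand <- vapply(codes, function(k) sum(tgt == k), numeric(1))
  names(demand) <- codes
  list(grid = grid, current = current, suitability = suits,
       transitions = trans, protected = protected, elasticities = elas,
       demand = demand, codes = codes)
}

# Small pipeline config for fast end-to-end tests.
small_config <- function(out_dir, seed = 11, scenarios = NULL) {
  doc <- list(
    seed = seed, output_dir = out_dir,
    grid = list(n_rows = 50, n_cols = 50),
    landuse_model = list(sample_n = 2000, folds = 5),
    sdm = list(n_background = 800, n_perm = 2),
    species = list(n_species = 6, n_presences = 200),
    climate = list(n_members = 5)
  )
  if (!is.null(scenarios)) doc$scenarios <- scenarios
  validate_config(doc)
}
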