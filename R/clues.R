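## CLUE-S style competitive allocation. Land-use demand per class is
## realized spatially by iteratively assigning each cell the class with
## the highest adjusted score
##
##   score_u(cell) = suitability_u(cell) + stay_bonus + term_u
##
## where the stay bonus (conversion elasticity of the current class,
## scaled to the suitability spread) rewards keeping the current class,
## and the per-class iteration terms term_u are raised for classes whose
## allocated area falls short of demand and lowered for classes exceeding
## it, until every class's allocation matches demand within tolerance.
## Transitions are restricted by a boolean transition matrix, protected
## cells never change, and static classes sit outside the competition.

#' Build a 0/1 protection mask from a protected-area category raster
#'
#' @param pa_raster integer matrix of protected-area category codes
#'   (`NA` allowed).
#' @param categories category codes that freeze a cell (e.g. the strict
#'   reserve categories I and II); an empty list masks nothing.
#' @return integer 0/1 matrix (`NA` where `pa_raster` is `NA`).
#' @export
mask_protected <- function(pa_raster, categories) {
  m <- matrix(0L, nrow(pa_raster), ncol(pa_raster))
  if (length(categories)) m[pa_raster %in% categories] <- 1L
  m[is.na(pa_raster)] <- NA_integer_
  m
}

#' Allocate one timestep of land-use demand
#'
#' @param current integer matrix of class codes (`NA` = nodata).
#' @param suitability named list of suitability matrices, names = class
#'   codes, covering every competing class.
#' @param demand named vector of per-class area demand (same units as
#'   `grid$cell_area * cells`); names = class codes; must cover every
#'   class and sum to the valid area within `tol`.
#' @param transitions K x K logical matrix, dimnames = class codes;
#'   `transitions[i, j]` allows conversion from class i to class j.
#'   The diagonal must be `TRUE`.
#' @param elasticities named vector in `[0, 1]` per class; 1 = hardest to
#'   convert away from.
#' @param protected 0/1 matrix; cells with 1 keep their class
#'   unconditionally.
#' @param grid a [grid_spec()].
#' @param static_classes class codes excluded from competition entirely
#'   (their cells are frozen and no cell may convert into them).
#' @param tol convergence tolerance as a fraction of each class's demand
#'   (absolute floor of one cell).
#' @param max_iter iteration cap; non-convergence is an error.
#' @param seed integer seed for the tie-breaking class permutation.
#' @return integer matrix of allocated class codes, with attribute
#'   `audit` (list: `iterations`, `allocated`, `demand_cells`,
#'   `deviation`).
#' @export
allocate_timestep <- function(current, suitability, demand, transitions,
                              elasticities, protected, grid,
                              static_classes = integer(), tol = 0.001,
                              max_iter = 1000, seed = 1) {
  check_grid_matrix(current, grid, "current land use")
  check_grid_matrix(protected, grid, "protected mask")
  codes <- as.integer(names(demand))
  if (any(is.na(codes))) stop("demand names must be class codes")
  if (is.null(dimnames(transitions))) {
    stop("transitions must carry class codes as dimnames")
  }
  if (!all(diag(transitions[as.character(codes), as.character(codes)]))) {
    stop("transition matrix diagonal must be TRUE (a class may keep itself)")
  }
  if (any(elasticities < 0 | elasticities > 1)) {
    stop("elasticities must lie in [0, 1]")
  }
  valid <- !is.na(current) & current != grid$nodata_code
  map_codes <- unique(current[valid])
  if (!all(map_codes %in% codes)) {
    stop("map contains class codes absent from demand: ",
         paste(setdiff(map_codes, codes), collapse = ", "))
  }
  demand_cells <- demand / grid$cell_area
  n_valid <- sum(valid)
  if (abs(sum(demand_cells) - n_valid) > max(tol * n_valid, 1)) {
    stop(sprintf("demand (%.1f cells) does not match the %d valid cells",
                 sum(demand_cells), n_valid))
  }
  tol_cells <- pmax(tol * demand_cells, 1)

  counts0 <- vapply(codes, function(k) sum(current[valid] == k), numeric(1))
  names(counts0) <- names(demand)
  if (all(abs(counts0 - demand_cells) <= tol_cells)) {
    out <- current
    attr(out, "audit") <- list(iterations = 0L, allocated = counts0,
                               demand_cells = demand_cells,
                               deviation = demand_cells - counts0)
    return(out)
  }

  dyn <- setdiff(codes, as.integer(static_classes))
  dyn_chr <- as.character(dyn)
  miss <- setdiff(dyn_chr, names(suitability))
  if (length(miss)) {
    stop("suitability stack missing class(es): ", paste(miss, collapse = ", "))
  }
  frozen <- (protected == 1) | (current %in% as.integer(static_classes))
  active <- which(valid & !frozen)
  cur <- current[active]
  if (any(cur %in% as.integer(static_classes))) {
    stop("internal error: static-class cell in competition")
  }
  n_act <- length(active)
  K <- length(dyn)
  S <- vapply(dyn_chr, function(k) suitability[[k]][active], numeric(n_act))
  S <- matrix(S, nrow = n_act, ncol = K, dimnames = list(NULL, dyn_chr))

  frozen_counts <- vapply(codes, function(k) {
    sum(current[valid][frozen[valid]] == k)
  }, numeric(1))
  names(frozen_counts) <- names(demand)
  target <- demand_cells[dyn_chr] - frozen_counts[dyn_chr]
  if (any(target < -0.5)) {
    bad <- dyn_chr[target < -0.5]
    stop(sprintf("demand for class %s is below its frozen (protected/static) area",
                 paste(bad, collapse = ", ")))
  }
  target <- pmax(target, 0)

  cur_col <- match(cur, dyn)
  allowed <- transitions[as.character(cur), dyn_chr, drop = FALSE]
  allowed <- matrix(as.logical(allowed), nrow = n_act, ncol = K)
  allowed[cbind(seq_len(n_act), cur_col)] <- TRUE
  reachable <- colSums(allowed)
  infeasible <- target > reachable + 1e-9
  if (any(infeasible)) {
    stop(sprintf(
      "infeasible demand: class %s needs %.0f cells but only %.0f are reachable",
      paste(dyn_chr[infeasible], collapse = ", "),
      max(target[infeasible]), min(reachable[infeasible])))
  }
  # cells whose only allowed destination is their current class set a
  # floor on that class's allocation
  stuck <- rowSums(allowed) == 1L
  min_alloc <- vapply(seq_len(K), function(j) sum(stuck & cur_col == j),
                      numeric(1))
  under <- target < min_alloc - 1e-9
  if (any(under)) {
    stop(sprintf(
      "infeasible demand: class %s is demanded %.0f cells but %.0f of its cells cannot convert to any other class",
      paste(dyn_chr[under], collapse = ", "),
      min(target[under]), max(min_alloc[under])))
  }

  spread <- diff(range(S))
  if (spread == 0) spread <- 1
  base <- S
  base[!allowed] <- -Inf
  base[cbind(seq_len(n_act), cur_col)] <-
    base[cbind(seq_len(n_act), cur_col)] +
    elasticities[as.character(cur)] * spread

  perm <- with_seed(seed, sample.int(K))
  term <- stats::setNames(numeric(K), dyn_chr)
  tol_dyn <- tol_cells[dyn_chr]
  ## Each pass recomputes the competitive assignment, then adjusts the
  ## iteration term of the class whose allocation deviates most from
  ## demand by the exact score margin that flips the needed number of
  ## cells. The terms act as competitive prices: a class short of demand
  ## bids itself up past the k-th smallest margin among the cells it
  ## could win; an over-allocated class backs off below the k-th
  ## smallest margin among the cells it holds. Placing the new price at
  ## the midpoint between the k-th and (k+1)-th sorted margins flips
  ## exactly k cells, which prevents exchange cycles between classes.
  tiny <- spread * 1e-9
  assign_idx <- NULL
  for (it in seq_len(max_iter)) {
    score <- sweep(base, 2, term, "+")
    choice <- max.col(score[, perm, drop = FALSE], ties.method = "first")
    assign_idx <- perm[choice]
    alloc <- tabulate(assign_idx, nbins = K)
    dev <- target - alloc
    if (all(abs(dev) <= tol_dyn)) {
      out <- current
      out[active] <- dyn[assign_idx]
      allocated <- frozen_counts
      allocated[dyn_chr] <- allocated[dyn_chr] + alloc
      attr(out, "audit") <- list(iterations = it, allocated = allocated,
                                 demand_cells = demand_cells,
                                 deviation = demand_cells - allocated)
      return(out)
    }
    u <- which.max(abs(dev) - tol_dyn)
    k <- max(1L, round(abs(dev[u])))
    top <- score[cbind(seq_len(n_act), assign_idx)]
    if (dev[u] > 0) {
      could <- which(assign_idx != u & allowed[, u])
      margins <- sort(top[could] - score[could, u])
    } else {
      holds <- which(assign_idx == u)
      alt <- score[holds, , drop = FALSE]
      alt[, u] <- -Inf
      margins <- top[holds] - apply(alt, 1, max)
      margins <- sort(margins[is.finite(margins)])
    }
    k <- min(k, length(margins))
    if (k > 0) {
      nxt <- if (k < length(margins)) margins[k + 1] else margins[k] + 2 * tiny
      move <- (margins[k] + nxt) / 2
      if (move <= margins[k]) move <- margins[k] + tiny
      term[u] <- term[u] + sign(dev[u]) * move
    }
  }
  worst <- which.max(abs(target - tabulate(assign_idx, nbins = K)))
  stop(sprintf(
    "allocation did not converge in %d iterations; worst class %s deviates by %.0f cells",
    max_iter, dyn_chr[worst],
    abs(target - tabulate(assign_idx, nbins = K))[worst]))
}

#' Run a chained decadal allocation series
#'
#' Allocates each timestep of a demand table in order, starting from the
#' previous map, and records a per-step audit of iterations and
#' deviations.
#'
#' @param initial integer class-code matrix for the first timestep.
#' @param suitability_by_step named list (by timestep, as character) of
#'   suitability stacks; a single unnamed stack is reused for all steps.
#' @param demand_table data.frame (`timestep`, `class`, `area`) with
#'   class given as class code.
#' @param transitions,elasticities,protected,grid,static_classes,tol,max_iter,seed
#'   passed to [allocate_timestep()].
#' @return list with `maps` (named list of matrices, one per timestep,
#'   first = `initial`) and `audit` (data.frame: `timestep`, `class`,
#'   `allocated`, `demand`, `deviation`, `iterations`).
#' @export
run_decadal_series <- function(initial, suitability_by_step, demand_table,
                               transitions, elasticities, protected, grid,
                               static_classes = integer(), tol = 0.001,
                               max_iter = 1000, seed = 1) {
  steps <- sort(unique(demand_table$timestep))
  maps <- list()
  maps[[as.character(steps[1])]] <- initial
  audit <- list()
  cur <- initial
  for (i in seq_along(steps)[-1]) {
    t <- steps[i]
    dt <- demand_table[demand_table$timestep == t, ]
    demand <- stats::setNames(dt$area, dt$class)
    suit <- if (!is.null(names(suitability_by_step)) &&
                as.character(t) %in% names(suitability_by_step)) {
      suitability_by_step[[as.character(t)]]
    } else suitability_by_step
    res <- tryCatch(
      allocate_timestep(cur, suit, demand, transitions, elasticities,
                        protected, grid, static_classes = static_classes,
                        tol = tol, max_iter = max_iter,
                        seed = seed + i),
      error = function(e) stop(sprintf("allocation failed at timestep %s: %s",
                                       t, conditionMessage(e)), call. = FALSE)
    )
    ad <- attr(res, "audit")
    audit[[length(audit) + 1L]] <- data.frame(
      timestep = t, class = names(ad$allocated),
      allocated = as.numeric(ad$allocated),
      demand = as.numeric(ad$demand_cells),
      deviation = as.numeric(ad$deviation),
      iterations = ad$iterations, stringsAsFactors = FALSE)
    attr(res, "audit") <- NULL
    maps[[as.character(t)]] <- res
    cur <- res
  }
  list(maps = maps, audit = do.call(rbind, audit))
}

#' Aggregate land-use change into a coarse change-intensity map
#'
#' Divides the grid into `factor` x `factor` blocks and reports, per
#' block, the fraction of its cells whose class differs between the two
#' maps. Edge blocks use their actual (smaller) cell counts.
#'
#' @param lu_a,lu_b integer class-code matrices on the same grid.
#' @param factor aggregation factor (>= 1).
#' @return matrix of change fractions, `ceiling(n_rows/factor)` x
#'   `ceiling(n_cols/factor)`.
#' @export
change_intensity_map <- function(lu_a, lu_b, factor = 3) {
  if (!all(dim(lu_a) == dim(lu_b))) stop("maps have mismatched grids")
  if (factor < 1) stop("factor must be >= 1")
  nr <- nrow(lu_a); nc <- ncol(lu_a)
  br <- (seq_len(nr) - 1L) %/% factor + 1L
  bc <- (seq_len(nc) - 1L) %/% factor + 1L
  nbr <- max(br); nbc <- max(bc)
  block <- outer(br, bc, function(r, c) (c - 1L) * nbr + r)
  ok <- !is.na(lu_a) & !is.na(lu_b)
  changed <- (lu_a != lu_b) & ok
  num <- tabulate(block[changed], nbins = nbr * nbc)
  den <- tabulate(block[ok], nbins = nbr * nbc)
  out <- num / den
  out[den == 0] <- NA_real_
  matrix(out, nbr, nbc)
}
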