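two_class_toy <- function() {
  grid <- grid_spec(5, 5)
  set.seed(77)
  suit2 <- matrix(sample(seq(0.05, 0.95, length.out = 25)), 5, 5)
  current <- matrix(1L, 5, 5)
  current[1, 1] <- 2L; current[5, 5] <- 2L
  protected <- matrix(0L, 5, 5)
  protected[2, 2] <- 1L; protected[3, 4] <- 1L
  # class 2 cannot be abandoned, so growth comes only from class-1 flips
  trans <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2,
                  dimnames = list(1:2, 1:2))
  list(grid = grid, current = current, protected = protected,
       suitability = list(`1` = matrix(0.5, 5, 5), `2` = suit2),
       transitions = trans,
       # equal, firm elasticities: no cell flips without demand pressure
       elasticities = c(`1` = 0.6, `2` = 0.6))
}

test_that("allocation with demand equal to current areas is a fixed point", {
  toy <- two_class_toy()
  counts <- c(`1` = sum(toy$current == 1), `2` = sum(toy$current == 2))
  out <- allocate_timestep(toy$current, toy$suitability, counts,
                           toy$transitions, toy$elasticities,
                           toy$protected, toy$grid, seed = 1)
  expect_identical(unclass(out)[, ], toy$current[, ])
})

test_that("a 3-cell conversion matches exhaustive maximum-suitability enumeration", {
  toy <- two_class_toy()
  demand <- c(`1` = sum(toy$current == 1) - 3, `2` = sum(toy$current == 2) + 3)
  out <- allocate_timestep(toy$current, toy$suitability, demand,
                           toy$transitions, toy$elasticities,
                           toy$protected, toy$grid, seed = 1)
  # oracle: enumerate every legal set of 3 class-1 cells to convert and
  # maximize the total suitability of the resulting map
  convertible <- which(toy$current == 1 & toy$protected == 0)
  best_val <- -Inf; best_map <- NULL
  for (combo in asplit(combn(convertible, 3), 2)) {
    map <- toy$current
    map[combo] <- 2L
    val <- sum(ifelse(map == 1, toy$suitability[["1"]],
                      toy$suitability[["2"]]))
    if (val > best_val) { best_val <- val; best_map <- map }
  }
  expect_identical(unclass(out)[, ], best_map[, ])
})

test_that("protected cells never change even under extreme demand pressure", {
  toy <- two_class_toy()
  # the protected class-1 cells get the worst possible standing
  toy$suitability[["1"]][2, 2] <- 0
  toy$suitability[["2"]][2, 2] <- 1
  n_conv <- sum(toy$current == 1 & toy$protected == 0)
  demand <- c(`1` = sum(toy$current == 1) - n_conv,
              `2` = sum(toy$current == 2) + n_conv)
  out <- allocate_timestep(toy$current, toy$suitability, demand,
                           toy$transitions, toy$elasticities,
                           toy$protected, toy$grid, seed = 1)
  expect_identical(out[2, 2], 1L)
  expect_identical(out[3, 4], 1L)
  expect_true(all(out[toy$current == 1 & toy$protected == 0] == 2L))
})

test_that("infeasible demands are rejected before iterating", {
  grid <- grid_spec(4, 4)
  current <- matrix(c(rep(1L, 6), rep(2L, 6), rep(3L, 4)), 4, 4)
  suits <- list(`1` = matrix(0.5, 4, 4), `2` = matrix(0.5, 4, 4),
                `3` = matrix(0.5, 4, 4))
  prot <- matrix(0L, 4, 4)
  elas <- c(`1` = 0.5, `2` = 0.5, `3` = 0.5)
  # class 3 cells cannot leave, so demanding fewer than their count fails
  trans <- matrix(c(TRUE, TRUE, FALSE,
                    TRUE, TRUE, FALSE,
                    FALSE, FALSE, TRUE), 3, 3, byrow = TRUE,
                  dimnames = list(1:3, 1:3))
  expect_error(
    allocate_timestep(current, suits, c(`1` = 8, `2` = 6, `3` = 2), trans,
                      elas, prot, grid, seed = 1),
    "cannot convert")
  # class 1 cells cannot reach class 2, so class-2 growth fails
  trans2 <- matrix(c(TRUE, FALSE, FALSE,
                     FALSE, TRUE, FALSE,
                     FALSE, TRUE, TRUE), 3, 3, byrow = TRUE,
                   dimnames = list(1:3, 1:3))
  expect_error(
    allocate_timestep(current, suits, c(`1` = 3, `2` = 11, `3` = 2),
                      trans2, elas, prot, grid, seed = 1),
    "reachable")
})

test_that("allocation invariants hold on random landscapes", {
  for (s in 1:6) {
    prob <- random_allocation_problem(s, nr = 50, nc = 50)
    out <- allocate_timestep(prob$current, prob$suitability, prob$demand,
                             prob$transitions, prob$elasticities,
                             prob$protected, prob$grid, seed = s)
    audit <- attr(out, "audit")
    # conservation of valid cells
    expect_identical(sum(!is.na(out)), sum(!is.na(prob$current)))
    # demand satisfaction within 0.1% or one cell
    expect_true(all(abs(audit$deviation) <=
                      pmax(0.001 * audit$demand_cells, 1)))
    # transition legality and protection
    chg <- which(out != prob$current)
    if (length(chg)) {
      expect_true(all(prob$transitions[cbind(as.character(prob$current[chg]),
                                             as.character(out[chg]))]))
    }
    frozen <- prob$protected == 1
    expect_identical(out[frozen], prob$current[frozen])
    # determinism
    out2 <- allocate_timestep(prob$current, prob$suitability, prob$demand,
                              prob$transitions, prob$elasticities,
                              prob$protected, prob$grid, seed = s)
    expect_identical(out[, ], out2[, ])
  }
})

test_that("raising a class's elasticity never increases conversions away from it", {
  for (s in 1:5) {
    prob <- random_allocation_problem(s + 100, nr = 50, nc = 50)
    u <- prob$codes[1]
    lo <- prob$elasticities
    lo[as.character(u)] <- 0.2
    hi <- prob$elasticities
    hi[as.character(u)] <- 0.9
    away <- function(el) {
      out <- allocate_timestep(prob$current, prob$suitability, prob$demand,
                               prob$transitions, el, prob$protected,
                               prob$grid, seed = s)
      sum(prob$current == u & out != u)
    }
    expect_lte(away(hi), away(lo))
  }
})

test_that("decadal series chain, audit, and conservation behave", {
  prob <- random_allocation_problem(5, nr = 40, nc = 40)
  counts <- vapply(prob$codes, function(k) sum(prob$current == k), numeric(1))
  steps <- seq(2020, 2060, 10)
  # stationary chain: constant demand keeps every map identical
  dt0 <- do.call(rbind, lapply(steps, function(t) {
    data.frame(timestep = t, class = prob$codes, area = counts)
  }))
  ser0 <- run_decadal_series(prob$current, prob$suitability, dt0,
                             prob$transitions, prob$elasticities,
                             prob$protected, prob$grid, seed = 3)
  for (m in ser0$maps) expect_identical(m[, ], prob$current[, ])
  # growing first-class demand: its cell count is non-decreasing
  grow <- vapply(seq_along(steps), function(i) {
    counts[1] + (i - 1) * 15
  }, numeric(1))
  dt1 <- do.call(rbind, lapply(seq_along(steps), function(i) {
    area <- counts
    area[1] <- grow[i]
    gain <- grow[i] - counts[1]
    donors <- which.max(counts[-1]) + 1
    area[donors] <- area[donors] - gain
    data.frame(timestep = steps[i], class = prob$codes, area = area)
  }))
  ser1 <- run_decadal_series(prob$current, prob$suitability, dt1,
                             prob$transitions, prob$elasticities,
                             prob$protected, prob$grid, seed = 3)
  n1 <- vapply(ser1$maps, function(m) sum(m == prob$codes[1]), numeric(1))
  expect_true(all(diff(n1) >= 0))
  totals <- vapply(ser1$maps, function(m) sum(!is.na(m)), numeric(1))
  expect_true(all(totals == totals[1]))
  expect_true(all(c("timestep", "class", "allocated", "demand",
                    "deviation", "iterations") %in% names(ser1$audit)))
})

test_that("protection masks and change-intensity aggregation are exact", {
  pa <- matrix(c(1L, 2L, 3L, NA, 1L, 4L), 2, 3)
  expect_identical(mask_protected(pa, integer()),
                   matrix(c(0L, 0L, 0L, NA, 0L, 0L), 2, 3))
  m <- mask_protected(pa, c(1, 2))
  expect_identical(m, matrix(c(1L, 1L, 0L, NA, 1L, 0L), 2, 3))
  # identity maps aggregate to zero
  a <- matrix(sample(1:3, 36, TRUE), 6, 6)
  expect_true(all(change_intensity_map(a, a, 3) == 0))
  # one changed cell in a full 3x3 block
  b <- a
  b[2, 2] <- a[2, 2] %% 3 + 1
  ci <- change_intensity_map(a, b, 3)
  expect_equal(ci[1, 1], 1 / 9)
  expect_true(all(ci[-1] == 0))
  # complete change saturates at one, with edge blocks at their own size
  d <- a %% 3 + 1
  ci2 <- change_intensity_map(a, d, 4)
  expect_true(all(ci2 == 1))
  expect_identical(dim(ci2), c(2L, 2L))
  expect_error(change_intensity_map(a, matrix(1, 2, 2)), "mismatch")
})
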