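test_that("dispersal masks cover occupied and adjacent bioregions", {
  grid <- grid_spec(9, 9)
  # 3x3 arrangement of 3x3 square bioregions, labelled 1..9
  br <- matrix(0L, 9, 9)
  for (i in 0:2) for (j in 0:2) {
    br[i * 3 + 1:3, j * 3 + 1:3] <- i * 3 + j + 1L
  }
  centre <- data.frame(x = 4.5, y = 4.5)   # inside region 5
  m_unl <- dispersal_mask(br, centre, grid, mode = "unlimited")
  expect_true(all(m_unl == 1))
  # queen adjacency from the centre region reaches all nine regions
  m_q <- dispersal_mask(br, centre, grid, mode = "bioregion_adjacent")
  expect_true(all(m_q == 1))
  # rook adjacency leaves out the corner regions
  m_r <- dispersal_mask(br, centre, grid, mode = "bioregion_adjacent",
                        adjacency = "rook")
  corner_regions <- c(1, 3, 7, 9)
  expect_true(all(m_r[br %in% corner_regions] == 0))
  expect_true(all(m_r[!br %in% corner_regions] == 1))
  # records in a corner region only: its queen neighbours plus itself
  corner <- data.frame(x = 0.5, y = 0.5)   # region 1
  m_c <- dispersal_mask(br, corner, grid, mode = "bioregion_adjacent")
  expect_setequal(unique(br[m_c == 1]), c(1L, 2L, 4L, 5L))
  # records everywhere saturate the grid
  allx <- expand.grid(x = c(1.5, 4.5, 7.5), y = c(1.5, 4.5, 7.5))
  expect_true(all(dispersal_mask(br, allx, grid,
                                 mode = "bioregion_adjacent") == 1))
  expect_error(dispersal_mask(br, data.frame(x = -3, y = -3), grid,
                              mode = "bioregion_adjacent"), "nodata")
})

test_that("binary ranges threshold and mask correctly", {
  pred <- matrix(c(0.9, 0.7, 0.5, 0.3,
                   0.8, 0.2, 0.55, 0.1,
                   0.4, 0.45, 0.6, 0.05,
                   0.2, 0.3, 0.35, 0.15), 4, 4, byrow = TRUE)
  # hand count: 6 cells at or above 0.5
  br <- binary_range(pred, 0.5)
  expect_identical(br$count, sum(pred >= 0.5))
  expect_identical(br$count, 6L)
  expect_identical(binary_range(pred, 1.01)$count, 0L)
  expect_identical(binary_range(pred, min(pred))$count, 16L)
  mask <- matrix(0L, 4, 4); mask[1, ] <- 1L
  expect_identical(binary_range(pred, 0.5, mask)$count, 3L)
  expect_error(binary_range(pred, 0.5, matrix(1, 2, 2)), "mismatch")
  expect_error(binary_range(pred, Inf), "finite")
})

test_that("range change handles decline, stasis, and extirpation", {
  rc1 <- range_change(100, 100)
  expect_equal(rc1$ratio, 1); expect_equal(rc1$log_ratio, 0)
  rc2 <- range_change(100, 50)
  expect_equal(rc2$ratio, 0.5)
  expect_equal(rc2$log_ratio, log(0.5), tolerance = 1e-12)
  rc3 <- range_change(100, 0)
  expect_true(rc3$extirpated)
  expect_equal(rc3$ratio, 0)
  expect_true(is.na(rc3$log_ratio))
  expect_error(range_change(0, 10), "empty")
})

test_that("treatments recombine climate and land-use layer sources", {
  fx <- small_landscape(seed = 17, nr = 40, nc = 40)
  cfg <- validate_config()
  lu_layers <- paste0("lu_", cfg$sdm$landuse_predictors)
  present <- c(fx$covariates, landuse_indicators(fx$land_use, cfg))
  # a contrived future: shifted climate, land use flipped in a block
  future <- present
  future$clim1 <- future$clim1 + 1
  lu_fut <- fx$land_use
  lu_fut[1:10, 1:10] <- 2L
  future[lu_layers] <- landuse_indicators(lu_fut, cfg)
  truth <- list(intercept = 0.5, linear = c(clim1 = 1, lu_cropland = 1.5),
                quadratic = c(clim1 = -1))
  sp <- generate_species_occurrences(truth, present, fx$grid, n = 200,
                                     seed = 18)
  bg <- sample_background(matrix(1, 40, 40), fx$grid, 800, seed = 19)
  fit <- fit_sdm(sp$cells, bg$cell, present,
                 predictors = c("clim1", "clim2", "lu_cropland"), seed = 20)
  # future identical to present: all three treatments identical
  tr0 <- treatment_predictions(fit, present, present, lu_layers)
  expect_equal(tr0$direct, tr0$indirect, tolerance = 1e-15)
  expect_equal(tr0$direct, tr0$combined, tolerance = 1e-15)
  tr <- treatment_predictions(fit, present, future, lu_layers)
  # combined and direct differ only where land use changed
  diff_cells <- which(tr$combined != tr$direct)
  lu_changed <- which(fx$land_use != lu_fut)
  expect_true(all(diff_cells %in% lu_changed))
  # a model that ignores land use: indirect equals the present prediction
  fit_clim <- fit_sdm(sp$cells, bg$cell, present,
                      predictors = c("clim1", "clim2"), seed = 21)
  tr2 <- treatment_predictions(fit_clim, present, future, lu_layers)
  expect_equal(tr2$indirect, predict_sdm(fit_clim, present),
               tolerance = 1e-15)
  # with future == present climate, combined equals indirect
  future_lu_only <- present
  future_lu_only[lu_layers] <- future[lu_layers]
  tr3 <- treatment_predictions(fit, present, future_lu_only, lu_layers)
  expect_equal(tr3$combined, tr3$indirect, tolerance = 1e-15)
  expect_error(treatment_predictions(fit, present[-1], future, lu_layers),
               "clim1")
})

test_that("loss-proportion maps count present-suitable species per cell", {
  p1 <- matrix(c(1, 1, 0, 0), 2, 2)
  p2 <- matrix(c(1, 0, 1, 0), 2, 2)
  f1 <- matrix(c(0, 1, 0, 0), 2, 2)   # species 1 loses cell [1,1]
  f2 <- matrix(c(1, 0, 1, 0), 2, 2)   # species 2 keeps everything
  lp <- loss_proportion_map(list(p1, p2), list(f1, f2))
  expect_equal(lp[1, 1], 0.5)      # two present, one lost
  expect_equal(lp[2, 1], 0)        # one present, none lost
  expect_equal(lp[1, 2], 0)
  expect_true(is.na(lp[2, 2]))     # nobody present-suitable
  # no species changes: all zeros where defined
  lp0 <- loss_proportion_map(list(p1, p2), list(p1, p2))
  expect_true(all(lp0[!is.na(lp0)] == 0))
  vals <- lp[!is.na(lp)]
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("cohort summaries aggregate ratios and loss tiers", {
  rec <- data.frame(
    species_id = c("a", "b", "c"), scenario = "s", treatment = "direct",
    ratio = c(0.4, 0.8, 1.2))
  out <- summarize_cohort(rec)
  expect_equal(out$summary$mean_ratio, 0.8)
  expect_identical(out$summary$n_loss_ge50, 1L)
  expect_identical(out$summary$n_loss_ge10, 2L)
  expect_identical(out$summary$n_loss_ge95, 0L)
  expect_setequal(out$species_lists$s$direct$ge10, c("a", "b"))
  # single species: cohort mean equals its ratio
  one <- summarize_cohort(rec[1, ])
  expect_equal(one$summary$mean_ratio, 0.4)
  # an extirpated species lands in every tier
  rec2 <- rbind(rec, data.frame(species_id = "x", scenario = "s",
                                treatment = "direct", ratio = 0))
  out2 <- summarize_cohort(rec2)
  expect_identical(out2$summary$n_loss_ge95, 1L)
  expect_true("x" %in% out2$species_lists$s$direct$ge95)
  # null cohort
  null <- summarize_cohort(data.frame(species_id = "a", scenario = "s",
                                      treatment = "t", ratio = 1))
  expect_equal(null$summary$mean_ratio, 1)
  expect_identical(null$summary$n_loss_ge10, 0L)
})
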