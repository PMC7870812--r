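test_that("record filtering applies the year window and minimum-count rule", {
  occ <- rbind(
    data.frame(species_id = "a", x = 0.5, y = 0.5, year = 1960:1978),  # 19
    data.frame(species_id = "b", x = 0.5, y = 0.5, year = 1999:2018),  # 20
    data.frame(species_id = "c", x = 0.5, y = 0.5,
               year = c(rep(1949, 6), 1960:1978))                      # 25, 19 in window
  )
  out <- filter_records(occ, min_year = 1950, max_year = 2018, min_n = 20)
  expect_identical(sort(unique(out$records$species_id)), "b")
  counts <- out$counts
  expect_identical(counts$n_window[counts$species_id == "a"], 19L)
  expect_identical(counts$n_window[counts$species_id == "c"], 19L)
  expect_false(counts$retained[counts$species_id == "a"])
  expect_true(counts$retained[counts$species_id == "b"])
  expect_identical(counts$n_total[counts$species_id == "c"], 25L)
  # records dated after the window are dropped too
  occ2 <- data.frame(species_id = "d", x = 0.5, y = 0.5,
                     year = c(rep(2019, 30), rep(2000, 5)))
  expect_identical(nrow(filter_records(occ2)$records), 0L)
})

test_that("effort estimation recovers a log-linear driver response", {
  grid <- grid_spec(50, 50)
  driver <- generate_covariate_field(grid, 4, seed = 2)
  # records generated proportional to exp(2 * driver)
  w <- exp(2 * driver)
  set.seed(3)
  cells <- sample.int(2500, 20000, replace = TRUE, prob = as.vector(w))
  xy <- xy_from_cell(cells, grid)
  recs <- data.frame(species_id = "pool", x = xy$x, y = xy$y, year = 2000)
  eff <- estimate_effort(recs, list(driver = driver), grid)
  est <- eff$coefficients[["driver"]]
  se <- eff$se[["driver"]]
  expect_lt(abs(est - 2), 1.96 * se + 0.05)
  expect_equal(sum(eff$effort), 1, tolerance = 1e-9)
  # flat drivers + uniform records: near-uniform fitted effort
  set.seed(4)
  cells_u <- sample.int(2500, 10000, replace = TRUE)
  xy_u <- xy_from_cell(cells_u, grid)
  recs_u <- data.frame(x = xy_u$x, y = xy_u$y)
  eff_u <- estimate_effort(recs_u, list(flat = matrix(0, 50, 50)), grid)
  expect_lt(max(eff_u$effort) / min(eff_u$effort), 1.2)
  expect_error(
    estimate_effort(data.frame(x = -5, y = -5),
                    list(flat = matrix(0, 50, 50)), grid),
    "no on-grid")
})

test_that("background sampling follows the effort surface", {
  grid <- grid_spec(40, 40)
  # uniform effort: quadrant counts uniform
  bg <- sample_background(matrix(1, 40, 40), grid, n = 10000, seed = 5)
  expect_gt(chisq.test(table(bg$x >= 20, bg$y >= 20))$p.value, 0.01)
  # 2:1 effort split
  eff <- matrix(1, 40, 40); eff[, 1:20] <- 2
  bg2 <- sample_background(eff, grid, n = 10000, seed = 5)
  ci <- binom.test(sum(bg2$x < 20), 10000, 2 / 3)$conf.int
  expect_true(2 / 3 >= ci[1] && 2 / 3 <= ci[2])
  # zero-effort cells are never drawn
  eff0 <- matrix(1, 40, 40); eff0[1:10, ] <- 0
  bg3 <- sample_background(eff0, grid, n = 5000, seed = 6)
  expect_true(all(bg3$y >= 10))
})

test_that("AUC equals brute-force pair enumeration with ties at one half", {
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(auc(c(3, 4, 5), c(0, 1, 2)), 1)
  expect_equal(auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  set.seed(11)
  for (i in 1:25) {
    p <- sample(round(runif(sample(2:30, 1)), 2), replace = TRUE)
    b <- sample(round(runif(sample(2:30, 1)), 2), replace = TRUE)
    expect_equal(auc(p, b), auc_bruteforce(p, b), tolerance = 1e-12)
  }
  expect_error(auc(numeric(), 1), "non-empty")
})

test_that("MaxSSS maximizes sensitivity plus specificity over observed scores", {
  # separable: sens + spec reaches 2
  th <- maxsss_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(attr(th, "sensitivity") + attr(th, "specificity"), 2)
  expect_true(th > 0.2 && th <= 0.8)
  # the textbook sweep
  th2 <- maxsss_threshold(c(0.9, 0.6, 0.4), c(0.5, 0.3, 0.1))
  ss2 <- attr(th2, "sensitivity") + attr(th2, "specificity")
  expect_equal(ss2, maxsss_bruteforce(c(0.9, 0.6, 0.4), c(0.5, 0.3, 0.1)))
  set.seed(12)
  for (i in 1:25) {
    p <- round(runif(sample(2:25, 1)), 2)
    b <- round(runif(sample(2:25, 1)), 2)
    th <- maxsss_threshold(p, b)
    expect_equal(attr(th, "sensitivity") + attr(th, "specificity"),
                 maxsss_bruteforce(p, b), tolerance = 1e-12)
  }
  expect_warning(maxsss_threshold(c(0.5, 0.5), c(0.5)), "degenerate")
})

test_that("AUC and the MaxSSS-selected set are invariant to monotone transforms", {
  set.seed(13)
  p <- runif(40); b <- runif(60)
  f <- function(x) qlogis(pmin(pmax(x, 1e-6), 1 - 1e-6)) * 3 + 1
  expect_equal(auc(p, b), auc(f(p), f(b)), tolerance = 1e-12)
  th <- maxsss_threshold(p, b)
  th_f <- maxsss_threshold(f(p), f(b))
  all_scores <- c(p, b)
  expect_identical(all_scores >= as.numeric(th),
                   f(all_scores) >= as.numeric(th_f))
})

sdm_fixture <- function(seed, n_pres = 500, biased = FALSE) {
  grid <- grid_spec(60, 60)
  covs <- list(clim1 = generate_covariate_field(grid, 6, seed),
               clim2 = generate_covariate_field(grid, 6, seed + 1),
               access = generate_covariate_field(grid, 6, seed + 2))
  truth <- list(intercept = 1.5, linear = c(clim1 = 1.2, clim2 = -0.8),
                quadratic = c(clim1 = -1.8, clim2 = -1.8))
  effort <- exp(2 * covs$access)
  sp <- generate_species_occurrences(truth, covs, grid,
                                     effort = if (biased) effort,
                                     n = n_pres, biased = biased,
                                     seed = seed + 3)
  bg <- sample_background(if (biased) effort else matrix(1, 60, 60),
                          grid, n = 2000, seed = seed + 4)
  list(grid = grid, covs = covs, truth = truth, species = sp,
       background = bg)
}

test_that("the penalized presence-background fit recovers a known suitability surface", {
  fx <- sdm_fixture(seed = 101)
  fit <- fit_sdm(fx$species$cells, fx$background$cell, fx$covs, seed = 7)
  pred <- predict_sdm(fit, fx$covs)
  truth <- true_suitability(fx$truth, fx$covs)
  rho <- cor(as.vector(pred), as.vector(truth), method = "spearman")
  expect_gt(rho, 0.9)
  expect_true(all(pred >= 0 & pred <= 1))
  # doubling the background barely moves the cross-validated AUC
  cv1 <- cv_auc(fx$species$cells, fx$background$cell, fx$covs, seed = 8)
  bg2 <- sample_background(matrix(1, 60, 60), fx$grid, 4000, seed = 9)
  cv2 <- cv_auc(fx$species$cells, bg2$cell, fx$covs, seed = 8)
  expect_lt(abs(cv1$mean_auc - cv2$mean_auc), 0.02)
})

test_that("zero-variance features are dropped with a warning", {
  fx <- sdm_fixture(seed = 103, n_pres = 100)
  covs <- c(fx$covs, list(const = matrix(1, 60, 60)))
  expect_warning(
    fit_sdm(fx$species$cells, fx$background$cell, covs, seed = 2),
    "zero-variance")
})

test_that("cross-validated AUC separates signal from shuffled labels", {
  fx <- sdm_fixture(seed = 105)
  cv <- cv_auc(fx$species$cells, fx$background$cell, fx$covs, seed = 3)
  expect_length(cv$fold_aucs, 5)
  expect_true(all(cv$fold_aucs >= 0 & cv$fold_aucs <= 1))
  expect_equal(cv$mean_auc, mean(cv$fold_aucs))
  expect_true(cv$retained)
  # shuffling point labels destroys the signal
  all_cells <- c(fx$species$cells, fx$background$cell)
  set.seed(4)
  shuffled <- sample(all_cells)
  cv0 <- cv_auc(shuffled[seq_along(fx$species$cells)],
                shuffled[-seq_along(fx$species$cells)], fx$covs, seed = 5)
  expect_lt(abs(cv0$mean_auc - 0.5), 0.05)
  expect_false(cv0$retained)
  expect_error(cv_auc(fx$species$cells[1:3], fx$background$cell, fx$covs,
                      k = 5, seed = 1), "folds")
})

test_that("permutation importance normalizes to 100 and prunes noise", {
  fx <- sdm_fixture(seed = 107)
  covs <- c(fx$covs,
            list(noise = generate_covariate_field(fx$grid, 6, 999)))
  fit <- fit_sdm(fx$species$cells, fx$background$cell, covs, seed = 6)
  pi <- permutation_importance(fit, covs, n_perm = 3, seed = 7)
  expect_equal(sum(pi$importance), 100, tolerance = 1e-6)
  expect_lt(pi$importance[["noise"]], 1)
  expect_true("noise" %in% pi$dropped)
  expect_false("noise" %in% pi$fit$predictors)
  # a single informative predictor takes all the importance
  fit1 <- fit_sdm(fx$species$cells, fx$background$cell,
                  covs["clim1"], seed = 8)
  pi1 <- permutation_importance(fit1, covs["clim1"], n_perm = 3, seed = 9)
  expect_equal(unname(pi1$importance), 100, tolerance = 1e-9)
})

test_that("SDM fits survive a JSON round trip", {
  fx <- sdm_fixture(seed = 109, n_pres = 80)
  fit <- fit_sdm(fx$species$cells, fx$background$cell, fx$covs,
                 species_id = "roundtrip", seed = 2)
  path <- tempfile(fileext = ".json")
  write_sdm_fit(fit, path)
  back <- read_sdm_fit(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_identical(back$predictors, fit$predictors)
  p1 <- predict_sdm(fit, fx$covs)
  p2 <- predict_sdm(back, fx$covs)
  expect_equal(p1, p2, tolerance = 1e-12)
})
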