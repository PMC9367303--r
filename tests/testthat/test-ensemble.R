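test_that("ensemble weighting follows the Somers'-D rule", {
  runs <- list(list(d = 0.6, model = NULL), list(d = 0.9, model = NULL),
               list(d = 0.49, model = NULL))
  ens <- build_ensemble(runs, d_threshold = 0.5)
  expect_length(ens$runs, 2)              # the 0.49 run is excluded
  expect_equal(sum(ens$weights), 1)
  expect_equal(ens$weights, c(0.6, 0.9) / 1.5)
  # weighted average of member predictions {0.2, 0.7} -> 0.50
  expect_equal(sum(ens$weights * c(0.2, 0.7)), 0.50, tolerance = 1e-12)

  one <- build_ensemble(runs[2], d_threshold = 0.5)
  expect_equal(one$weights, 1)
  expect_error(build_ensemble(runs[3], d_threshold = 0.5), "no skillful")
})

test_that("ensemble maps are convex combinations of member maps", {
  env <- small_env(5, nx = 25, ny = 30)
  set.seed(6)
  suit <- true_suitability(env)
  pop <- place_groups(suit, env$grid, 3, seed = 8)
  idx <- sample(nrow(pop), 30)
  fit <- run_esm(cbind(pop$x[idx], pop$y[idx]), env, n_background = 300,
                 replicates = 1, splits = 3, seed = 9)
  hsi <- fit$hsi
  expect_true(all(hsi[env$sea] >= 0 & hsi[env$sea] <= 1))

  # member predictions bracket the ensemble cell-wise
  layers <- env$layers
  vals <- vapply(layers, as.vector, numeric(length(layers[[1]])))
  ok <- complete.cases(vals)
  member <- vapply(fit$ensemble$runs, function(r)
    predict(r$model, vals[ok, r$model$vars, drop = FALSE]),
    numeric(sum(ok)))
  lo <- apply(member, 1, min); hi <- apply(member, 1, max)
  expect_true(all(hsi[ok] >= lo - 1e-9 & hsi[ok] <= hi + 1e-9))

  # determinism of the whole stage
  fit2 <- run_esm(cbind(pop$x[idx], pop$y[idx]), env, n_background = 300,
                  replicates = 1, splits = 3, seed = 9)
  expect_identical(fit$hsi, fit2$hsi)
  expect_identical(fit$contributions, fit2$contributions)

  # predict_map demands every needed layer
  expect_error(predict_map(fit$ensemble, layers[1]), "missing layer")
})

test_that("variable contributions normalize to 100 and match hand arithmetic", {
  runs <- list(list(d = 0.8, pair = c("A", "B")),
               list(d = 0.4, pair = c("A", "C")))
  ct <- variable_contribution(runs, c("A", "B", "C"))
  # scores {A: 0.6, B: 0.8, C: 0.4} -> {33.3, 44.4, 22.2} percent
  expect_equal(unname(ct), 100 * c(0.6, 0.8, 0.4) / 1.8, tolerance = 1e-12)
  expect_equal(sum(ct), 100)

  # balanced pairs with equal D: 20 percent each
  nm <- c("a", "b", "c", "d", "e")
  runs_eq <- lapply(enumerate_pairs(nm), function(p) list(d = 0.7, pair = p))
  expect_equal(unname(variable_contribution(runs_eq, nm)), rep(20, 5))

  # variable absent from every run contributes zero
  ct0 <- variable_contribution(runs, c("A", "B", "C", "Z"))
  expect_identical(unname(ct0[["Z"]]), 0)
})

test_that("the Continuous Boyce Index ranks calibration correctly", {
  hsi <- matrix(seq(0.01, 1, length.out = 200), 10, 20)
  set.seed(1)
  top <- sample(hsi[hsi >= quantile(hsi, 0.9)], 30, replace = TRUE)
  cbi_top <- boyce_index(hsi, top)
  expect_gte(cbi_top, 0.9)
  # reversing the map flips the sign
  expect_equal(boyce_index(1 - hsi, 1 - top), -cbi_top, tolerance = 1e-12)

  # uniform presences: near zero on average
  cb <- vapply(1:20, function(s) {
    set.seed(s)
    boyce_index(hsi, sample(as.vector(hsi), 100, replace = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(cb)), 0.3)

  # constant map is degenerate
  flat <- boyce_index(matrix(0.5, 10, 10), rep(0.5, 10))
  expect_identical(as.numeric(flat), 0)
  expect_true(attr(flat, "degenerate"))
})

test_that("annual map summaries obey mean/CV arithmetic", {
  m1 <- matrix(0.2, 4, 4); m2 <- matrix(0.4, 4, 4)
  s <- annual_mean_and_cv(list(m1, m2))
  expect_equal(s$mean[1, 1], 0.3)
  expect_equal(s$cv[1, 1], sd(c(0.2, 0.4)) / 0.3, tolerance = 1e-12)
  expect_equal(round(s$cv[1, 1], 4), 0.4714)
  # identical maps -> CV 0; mean bounded by per-year extremes
  s2 <- annual_mean_and_cv(list(m1, m1, m1))
  expect_true(all(s2$cv == 0))
  expect_true(all(s$mean >= pmin(m1, m2) & s$mean <= pmax(m1, m2)))
  expect_error(annual_mean_and_cv(list(m1)), "at least 2")
  expect_error(annual_mean_and_cv(list(m1, matrix(0, 2, 2))), "mismatched")
})

test_that("the ensemble does not catastrophically underperform its members", {
  env <- small_env(11, nx = 30, ny = 60)
  set.seed(12)
  suit <- true_suitability(env)
  pop <- place_groups(suit, env$grid, 3, seed = 13)
  tr_idx <- sample(nrow(pop), 40)
  ev_idx <- sample(setdiff(seq_len(nrow(pop)), tr_idx), 30)
  fit <- run_esm(cbind(pop$x[tr_idx], pop$y[tr_idx]), env,
                 n_background = 400, replicates = 1, splits = 4, seed = 14)

  rc <- xy_to_rowcol(env$grid, pop$x[ev_idx], pop$y[ev_idx])
  cell <- (rc[, "col"] - 1L) * env$grid$ny + rc[, "row"]
  cbi_ens <- boyce_index(fit$hsi, as.vector(fit$hsi)[cell])

  layers <- env$layers
  vals <- vapply(layers, as.vector, numeric(length(layers[[1]])))
  ok <- complete.cases(vals)
  member_cbi <- vapply(fit$ensemble$runs, function(r) {
    mp <- rep(NA_real_, nrow(vals))
    mp[ok] <- predict(r$model, vals[ok, r$model$vars, drop = FALSE])
    as.numeric(boyce_index(matrix(mp, env$grid$ny), mp[cell]))
  }, numeric(1))
  expect_gte(cbi_ens, max(member_cbi) - 0.1)
})
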