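test_that("environment generation is deterministic and structured", {
  g <- grid_spec(40, 120)
  e1 <- make_environment(g, seed = 7)
  e2 <- make_environment(g, seed = 7)
  expect_identical(e1$layers, e2$layers)
  expect_error(make_environment(grid_spec(10, 10)), "too small")

  # chlorophyll is negatively coupled to SST over sea cells by construction
  sea <- e1$sea
  r <- cor(e1$layers$chla[sea], e1$layers$sst[sea])
  expect_lt(r, 0)
  expect_true(all(e1$layers$chla[sea] > 0))
  expect_true(all(e1$layers$slope[sea] >= 0))
  expect_true(all(e1$layers$bathymetry[sea] >= 0))
  # land masked identically in all layers
  for (l in e1$layers) expect_identical(is.na(l), !sea)

  flat <- make_environment(g, seed = 7, flat_bathymetry = TRUE)
  expect_true(all(flat$layers$slope[flat$sea] == 0))
})

test_that("true suitability respects the imposed response shapes", {
  env <- small_env(3)
  truth <- suitability_truth()
  s <- true_suitability(env, truth)
  expect_true(all(s[env$sea] >= 0 & s[env$sea] <= 1))

  # monotone increasing in chla, holding everything else fixed
  env2 <- env
  cell <- which(env$sea)[100]
  env2$layers$chla[cell] <- env$layers$chla[cell] + 1
  expect_gt(true_suitability(env2, truth)[cell], s[cell])
  # decreasing in SST and depth
  env3 <- env
  env3$layers$sst[cell] <- env$layers$sst[cell] + 1
  expect_lt(true_suitability(env3, truth)[cell], s[cell])
  env4 <- env
  env4$layers$bathymetry[cell] <- env$layers$bathymetry[cell] + 10
  expect_lt(true_suitability(env4, truth)[cell], s[cell])

  # all coefficients zero -> constant surface
  s0 <- true_suitability(env, suitability_truth(0, 0, 0, 0, 0, 0))
  expect_true(all(abs(s0[env$sea] - 0.5) < 1e-12))

  # cell-wise values match a direct hand-coded evaluation at 5 cells
  cells <- which(env$sea)[c(5, 50, 500, 1500, 3000)]
  b <- truth$coef
  by_hand <- plogis(
    b[["intercept"]] + b[["chla"]] * env$layers$chla[cells] +
      b[["sst"]] * env$layers$sst[cells] +
      b[["depth"]] * env$layers$bathymetry[cells] +
      b[["slope"]] * env$layers$slope[cells] +
      b[["ammonium"]] * env$layers$ammonium[cells])
  expect_equal(s[cells], by_hand, tolerance = 1e-12)
})

test_that("group placement follows the Poisson and group-size laws", {
  # zero-truncated Poisson(0.70): mean = 0.70 / (1 - exp(-0.70)) = 1.390
  set.seed(11)
  draws <- rztpois(1e5, 0.70)
  m_true <- 0.70 / (1 - exp(-0.70))
  expect_equal(m_true, 1.390, tolerance = 5e-4)
  expect_true(all(draws >= 1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m_true), 3 * se)

  # expected count: suitability 1 over 100 km^2, scale 1 -> Poisson(100)
  g <- grid_spec(10, 10)
  suit <- matrix(1, 10, 10)
  pop <- place_groups(suit, g, intensity_scale = 1, seed = 5)
  expect_lt(abs(nrow(pop) - 100), 3 * 10)
  expect_true(all(pop$x >= 0 & pop$x <= 10 & pop$y >= 0 & pop$y <= 10))

  expect_identical(nrow(place_groups(suit, g, 0, seed = 1)), 0L)
  expect_identical(place_groups(suit, g, 1, seed = 9),
                   place_groups(suit, g, 1, seed = 9))
})

test_that("transect layout follows the equal-coverage design", {
  sc <- survey_scenario()
  # 185 km alongshore at 18.52 km spacing, half-spacing offset -> 10 lines
  env <- make_environment(grid_spec(40, 185), seed = 1)
  tr <- make_transects(env, sc)
  expect_identical(nrow(tr), 10L)
  expect_equal(diff(tr$y_km), rep(sc$spacing_km, 9))
  # 20 nm = 37.04 km unclipped length
  expect_equal(tr$length_km, rep(37.04, 10), tolerance = 1e-9)
  # spacing wider than the alongshore extent still yields one transect
  env_small <- make_environment(grid_spec(40, 16), seed = 1)
  expect_identical(nrow(make_transects(env_small, sc)), 1L)
})

test_that("survey detection follows g0-thinned half-normal truth", {
  sc <- survey_scenario(sigma_km = 0.12, g0 = 0.364, W_km = 0.3)
  tr <- data.frame(transect_id = "T1", y_km = 5, x_start = 0, x_end = 100,
                   length_km = 100)
  set.seed(21)
  n <- 10000L
  pop <- data.frame(x = runif(n, 0, 100),
                    y = 5 + runif(n, -sc$W_km, sc$W_km),
                    size = rep(1L, n))
  sv <- simulate_survey(pop, tr, sc, seed = 22)
  y <- sv$sightings$perp_distance_km

  # overall detected fraction ~ g0 * mu / W (distance uniform in the strip)
  mu <- integrate(function(u) exp(-u^2 / (2 * sc$sigma_km^2)),
                  0, sc$W_km)$value
  p_exp <- sc$g0 * mu / sc$W_km
  expect_lt(abs(length(y) / n - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))

  # binned distance distribution matches g(y) (chi-square GOF, alpha 0.01)
  brk <- seq(0, sc$W_km, length.out = 7)
  p_bin <- vapply(seq_len(6), function(i)
    integrate(function(u) exp(-u^2 / (2 * sc$sigma_km^2)),
              brk[i], brk[i + 1])$value / mu, numeric(1))
  obs <- table(cut(y, brk, include.lowest = TRUE))
  expect_gt(suppressWarnings(chisq.test(as.vector(obs), p = p_bin)$p.value),
            0.01)

  # limit case: g0 = 1, sigma huge -> every in-strip group recorded
  sc1 <- survey_scenario(sigma_km = 1e6, g0 = 1, W_km = 0.3)
  sv1 <- simulate_survey(pop, tr, sc1, seed = 1)
  expect_identical(nrow(sv1$sightings), n)

  # zero groups -> zero sightings; determinism
  empty <- pop[0, ]
  expect_identical(nrow(simulate_survey(empty, tr, sc, seed = 1)$sightings),
                   0L)
  expect_identical(simulate_survey(pop, tr, sc, seed = 3)$sightings,
                   simulate_survey(pop, tr, sc, seed = 3)$sightings)
})
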