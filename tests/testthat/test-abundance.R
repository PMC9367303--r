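test_that("size-bias regression matches hand-computed least squares", {
  # a detection model with spread in g(y)
  y <- hn_distances(200, seed = 12)
  m <- fit_detection_function(y, "half-normal", "none", W = 0.3)

  d5 <- c(0.02, 0.08, 0.14, 0.20, 0.28)
  s5 <- c(4L, 3L, 2L, 2L, 1L)
  sightings <- data.frame(perp_distance_km = d5, group_size = s5)
  est <- expected_group_size(sightings, m, alpha = 0.15)

  # normal-equations arithmetic, independent of lm()
  g <- detection_prob(m, d5)
  ls <- log(s5)
  b_hat <- sum((g - mean(g)) * (ls - mean(ls))) / sum((g - mean(g))^2)
  a_hat <- mean(ls) - b_hat * mean(g)
  resid <- ls - a_hat - b_hat * g
  s2 <- sum(resid^2) / (length(ls) - 2)
  expect_equal(est$slope, b_hat, tolerance = 1e-10)
  if (est$used_expected)
    expect_equal(est$expected_mean, exp(a_hat + b_hat + s2 / 2),
                 tolerance = 1e-10)

  # all group sizes 1: observed mean, no regression effect
  ones <- data.frame(perp_distance_km = d5, group_size = rep(1L, 5))
  e1 <- expected_group_size(ones, m)
  expect_identical(e1$expected_mean, 1)
  expect_false(e1$used_expected)
})

test_that("slope test keeps its nominal size when size is independent of distance", {
  y <- hn_distances(500, seed = 13)
  m <- fit_detection_function(y, "half-normal", "none", W = 0.3)
  set.seed(14)
  used <- logical(1000)
  for (r in seq_len(1000)) {
    d <- sample(y, 30)
    s <- rztpois(30, 0.70)
    est <- expected_group_size(
      data.frame(perp_distance_km = d, group_size = s), m, alpha = 0.15)
    used[r] <- est$used_expected
  }
  # nominal type-I error 15%; allow 3 binomial SEs around it
  expect_gte(mean(!used), 0.85 - 3 * sqrt(0.15 * 0.85 / 1000))
})

test_that("density estimator implements D = n E[s] / (2 L mu g0)", {
  m <- esw_stub(0.15990)
  sg <- data.frame(perp_distance_km = rep(0.1, 16), group_size = rep(1L, 16))
  est <- estimate_density(sg, effort_km = 1482.4, area_km2 = 25052.52,
                          model = m, group_size = 1.42, g0 = 0.364,
                          stratum = "2013")
  # 16 * 1.42 / (2 * 1482.4 * 0.1599 * 0.364) = 22.72 / 172.56 = 0.1317
  expect_equal(est$density, 22.72 / (2 * 1482.4 * 0.1599 * 0.364),
               tolerance = 1e-12)
  expect_equal(round(est$density, 4), 0.1317)
  expect_equal(est$abundance, est$density * 25052.52)

  # doubling g0 halves the density exactly
  est2 <- estimate_density(sg, 1482.4, 25052.52, m, 1.42, g0 = 0.728)
  expect_equal(est2$density, est$density / 2, tolerance = 1e-12)

  # no sightings -> zero density and abundance
  e0 <- estimate_density(sg[0, ], 100, 1000, m, 1.4, g0 = 0.364)
  expect_identical(e0$density, 0)
  expect_identical(e0$abundance, 0)
  expect_error(estimate_density(sg, 1482.4, 25052.52, m, 1.42, g0 = 0),
               "g0")
})

test_that("strata combine by effort weighting", {
  m <- esw_stub(0.15990)
  mk <- function(D, L, st) {
    n <- 10
    e <- estimate_density(
      data.frame(perp_distance_km = rep(0.1, n), group_size = rep(1L, n)),
      effort_km = L, area_km2 = 1000, model = m, group_size = 1, g0 = 1,
      stratum = st)
    e$density <- D          # impose the target density, keep the structure
    e$abundance <- D * e$area_km2
    e
  }
  D <- c(0.048, 0.120, 0.128, 0.066, 0.086)
  L <- c(1445.3, 1482.4, 1482.4, 1408.3, 1482.4)
  ests <- Map(mk, D, L, as.character(2011:2015))
  comb <- combine_strata(ests, total_area = 25052.52)
  expect_equal(comb$density, sum(D * L) / sum(L), tolerance = 1e-12)
  expect_equal(round(comb$density, 3), 0.090)

  # single stratum: combined equals that stratum
  one <- combine_strata(ests[2], total_area = 1000)
  expect_equal(one$density, ests[[2]]$density)
  # equal efforts: unweighted mean
  eq <- Map(mk, D, rep(100, 5), as.character(2011:2015))
  expect_equal(combine_strata(eq, 1)$density, mean(D), tolerance = 1e-12)
})

test_that("availability correction rescales density and abundance", {
  m <- esw_stub(0.2)
  sg <- data.frame(perp_distance_km = rep(0.1, 20), group_size = rep(1L, 20))
  e <- estimate_density(sg, 500, 10000, m, 1, g0 = 1)
  expect_equal(apply_g0(e, 1)$density, e$density)
  e$abundance <- 1000
  expect_equal(round(apply_g0(e, 0.364)$abundance), 2747)
  # ratio between two corrections is exactly the g0 ratio
  ea <- apply_g0(e, 0.364); eb <- apply_g0(e, 0.45)
  expect_equal(ea$density / eb$density, 0.45 / 0.364, tolerance = 1e-12)
  expect_error(apply_g0(e, 0), "g0")
})

test_that("bootstrap is deterministic and degenerates to CV 0", {
  m <- esw_stub(0.15, W = 0.3)
  # four identical transects: resampling cannot change the estimate
  eff <- data.frame(transect_id = paste0("T", 1:4), stratum = "A",
                    length_km = 37.04)
  sg <- data.frame(transect_id = rep(paste0("T", 1:4), each = 3),
                   stratum = "A",
                   perp_distance_km = rep(c(0.05, 0.12, 0.2), 4),
                   group_size = rep(c(1L, 2L, 1L), 4))
  md <- fit_detection_function(sg$perp_distance_km, "half-normal", "none",
                               W = 0.3)
  b1 <- bootstrap_estimates(sg, eff, list(A = 1000), md, B = 59, seed = 31)
  expect_equal(b1$strata[[1]]$cv_percent, 0, tolerance = 1e-10)
  expect_equal(b1$strata[[1]]$ci_low, b1$strata[[1]]$ci_high,
               tolerance = 1e-10)

  b2 <- bootstrap_estimates(sg, eff, list(A = 1000), md, B = 59, seed = 31)
  expect_identical(b1$replicates, b2$replicates)
  expect_error(bootstrap_estimates(sg, eff[1, ], list(A = 1000), md, B = 9,
                                   seed = 1),
               "fewer than 2 transects")
})
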