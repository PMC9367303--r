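test_that("pair enumeration covers all combinations", {
  p5 <- enumerate_pairs(c("bathymetry", "slope", "sst", "chla", "ammonium"))
  expect_length(p5, 10)
  expect_false(any(duplicated(lapply(p5, sort))))
  expect_true(all(vapply(p5, function(p) p[1] != p[2], logical(1))))
  expect_length(enumerate_pairs(c("a", "b")), 1)
  expect_error(enumerate_pairs("a"), "at least 2")
})

test_that("background sampling is deterministic and validated", {
  env <- small_env(3, nx = 20, ny = 20)
  b1 <- sample_background(env, n = 50, replicates = 3, seed = 5)
  b2 <- sample_background(env, n = 50, replicates = 3, seed = 5)
  expect_identical(b1, b2)
  expect_false(identical(sort(b1[[1]]), sort(b1[[2]])))
  expect_false(identical(sort(b1[[2]]), sort(b1[[3]])))
  expect_true(all(env$sea[unlist(b1)]))
  expect_error(sample_background(env, n = 1e6, replicates = 1, seed = 1),
               "replace")
})

test_that("unpenalized MaxEnt matches a brute-force optimizer", {
  set.seed(42)
  pe <- cbind(a = rnorm(10, 1), b = rnorm(10, 0.5))
  bg <- cbind(a = rnorm(50), b = rnorm(50))
  m <- fit_maxent(pe, bg, reg_multiplier = 0, features = "l")

  # identical objective, maximized independently with optim/BFGS
  f <- rbind(pe, bg)
  fs <- cbind(f, f^2)
  ctr <- colMeans(fs); scl <- apply(fs, 2, sd)
  X <- cbind(1, sweep(sweep(fs[, 1:2], 2, ctr[1:2]), 2, scl[1:2], "/"))
  yv <- c(rep(1, 10), rep(0, 50))
  w <- c(rep(0.5 / 10, 10), rep(0.5 / 50, 50))
  nll <- function(b) -sum(w * (yv * (X %*% b) - log1p(exp(X %*% b))))
  o <- optim(c(0, 0, 0), nll, method = "BFGS",
             control = list(reltol = 1e-14))
  expect_equal(signif(unname(m$beta), 2), signif(o$par, 2))

  # second independent route: weighted logistic fit via glmnet at lambda 0
  gf <- glmnet::glmnet(X[, 2:3], yv, family = "binomial", weights = w * 60,
                       lambda = 0, standardize = FALSE, thresh = 1e-12)
  expect_equal(signif(unname(m$beta), 3),
               signif(unname(c(gf$a0, as.vector(gf$beta))), 3))

  # suitability predictions live in [0, 1] under both transforms
  pr <- predict(m, bg)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(predict(m, bg, type = "logistic") >= 0))
})

test_that("responses track the presence signal and clamp out of range", {
  set.seed(7)
  bg <- cbind(x1 = runif(300), x2 = runif(300))
  pe <- cbind(x1 = runif(30, 0.7, 1), x2 = runif(30))  # high-x1 presences
  m <- fit_maxent(pe, bg, features = "l")
  grid <- cbind(x1 = seq(0.05, 0.95, length.out = 20), x2 = 0.5)
  resp <- predict(m, grid)
  expect_true(all(diff(resp) > -1e-12))
  # a cell far beyond the training max predicts like the boundary
  expect_equal(predict(m, cbind(x1 = 10, x2 = 0.5)),
               predict(m, cbind(x1 = max(c(pe[, 1], bg[, 1])), x2 = 0.5)),
               tolerance = 1e-12)
  # constant feature is dropped with a warning
  expect_warning(fit_maxent(cbind(a = pe[, 1], b = 1),
                            cbind(a = bg[, 1], b = 1)), "constant")
})

test_that("Somers' D equals 2 AUC - 1 with ties counted half", {
  expect_equal(somers_d(c(0.9, 0.4), c(0.4, 0.1)), 0.75)
  expect_equal(somers_d(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(somers_d(c(0.5, 0.5), c(0.5, 0.5)), 0)

  # brute-force pairwise counting on random scores with ties
  set.seed(9)
  p <- round(runif(23), 1); b <- round(runif(37), 1)
  conc <- 0
  for (i in seq_along(p)) for (j in seq_along(b))
    conc <- conc + (p[i] > b[j]) + 0.5 * (p[i] == b[j])
  expect_equal(somers_d(p, b), 2 * conc / (23 * 37) - 1, tolerance = 1e-12)
  expect_error(somers_d(numeric(0), b), "non-empty")
})

test_that("cross-validation splits deterministically and does not anti-overfit", {
  set.seed(15)
  pe <- cbind(a = rnorm(10, 2), b = rnorm(10))
  bg <- cbind(a = rnorm(100), b = rnorm(100))
  r1 <- cross_validate(pe, bg, splits = 4, seed = 3)
  r2 <- cross_validate(pe, bg, splits = 4, seed = 3)
  expect_equal(vapply(r1, `[[`, numeric(1), "d"),
               vapply(r2, `[[`, numeric(1), "d"))
  # 10 presences at 80/20 -> every test set has exactly 2 presences
  expect_true(all(vapply(r1, function(r) r$model$n_presence, numeric(1)) ==
                    8))

  # null data: mean test D across seeds stays near zero
  ds <- vapply(1:20, function(s) {
    set.seed(s)
    p0 <- cbind(a = rnorm(30), b = rnorm(30))
    b0 <- cbind(a = rnorm(200), b = rnorm(200))
    mean(vapply(cross_validate(p0, b0, splits = 2, seed = s), `[[`,
                numeric(1), "d"))
  }, numeric(1))
  expect_lt(abs(mean(ds)), 0.15)

  # informative data: train D >= test D on average
  gap <- vapply(1:10, function(s) {
    set.seed(100 + s)
    p1 <- cbind(a = rnorm(20, 1.2), b = rnorm(20))
    b1 <- cbind(a = rnorm(150), b = rnorm(150))
    r <- cross_validate(p1, b1, splits = 3, seed = s)
    mean(vapply(r, `[[`, numeric(1), "train_d")) -
      mean(vapply(r, `[[`, numeric(1), "d"))
  }, numeric(1))
  expect_gte(mean(gap), 0)
})
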