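## ---- presence/background MaxEnt ---------------------------------------
## Realized as the class-weighted penalized binomial (presence vs background)
## likelihood with linear + quadratic features, which maximizes the same
## Gibbs objective as presence-background maximum entropy. Presences and
## background carry equal total weight (prevalence 0.5). L1 penalty on the
## standardized features, solved by proximal gradient (FISTA).

maxent_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  f <- cbind(x, x^2)
  colnames(f) <- c(paste0(colnames(x), "_lin"), paste0(colnames(x), "_quad"))
  if (is.null(center)) {
    center <- colMeans(f)
    scale <- apply(f, 2, stats::sd)
    scale[scale < 1e-12] <- 1
  }
  list(f = sweep(sweep(f, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

## weighted logistic negative log-likelihood (weights sum to 1)
wlogit_nll <- function(beta, X, yv, w) {
  eta <- drop(X %*% beta)
  -sum(w * (yv * eta - log1p(exp(eta))))
}

fista_logistic <- function(X, yv, w, lambda, penalize,
                           max_iter = 3000, tol = 1e-9) {
  p <- ncol(X)
  M <- crossprod(X * sqrt(w))
  L <- 0.25 * max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  L <- max(L, 1e-8)
  beta <- numeric(p)
  zeta <- beta; tk <- 1
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% zeta)
    pr <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, w * (pr - yv)))
    bnew <- zeta - grad / L
    thr <- lambda / L
    sel <- penalize
    bnew[sel] <- sign(bnew[sel]) * pmax(abs(bnew[sel]) - thr, 0)
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zeta <- bnew + ((tk - 1) / tk1) * (bnew - beta)
    beta <- bnew; tk <- tk1
    if (it %% 25 == 0) {
      obj <- wlogit_nll(beta, X, yv, w) + lambda * sum(abs(beta[penalize]))
      if (abs(obj_old - obj) < tol * (abs(obj_old) + 1)) break
      obj_old <- obj
    }
  }
  list(beta = beta, iter = it, converged = it < max_iter)
}

#' Fit a bivariate MaxEnt (presence/background) model
#'
#' Penalized presence-versus-background model with linear + quadratic
#' features of the two predictors, equal total class weights (prevalence
#' 0.5) and an L1 penalty on standardized features (so the penalty scales
#' with each feature's spread). Suitability output uses the complementary
#' log-log transform with maxnet-style entropy normalization over the
#' background; a logistic output is available.
#'
#' @param presence_env Matrix/data frame of predictor values at presence
#'   sites (>= 5 rows, 1+ columns; the ESM uses 2).
#' @param background_env Predictor values at background sites (>= 2x the
#'   presences).
#' @param reg_multiplier Multiplier on the default penalty
#'   `1/sqrt(n_presence)` (default 1; 0 disables regularization).
#' @param features `"lq"` (linear + quadratic, default) or `"l"`.
#' @return Object of class `maxent_model` with `beta`, feature scaling,
#'   training ranges (for clamping), background entropy constants and
#'   `converged`.
#' @export
fit_maxent <- function(presence_env, background_env, reg_multiplier = 1,
                       features = c("lq", "l")) {
  features <- match.arg(features)
  presence_env <- as.matrix(presence_env)
  background_env <- as.matrix(background_env)
  if (is.null(colnames(presence_env)))
    colnames(presence_env) <- paste0("v", seq_len(ncol(presence_env)))
  colnames(background_env) <- colnames(presence_env)
  np <- nrow(presence_env); nb <- nrow(background_env)
  if (np < 5) stop("need at least 5 presences")
  if (nb < 2 * np) stop("need background at least twice the presences")
  keep <- apply(rbind(presence_env, background_env), 2,
                function(v) stats::sd(v) > 1e-12)
  if (!all(keep)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(presence_env)[!keep], collapse = ", "))
    presence_env <- presence_env[, keep, drop = FALSE]
    background_env <- background_env[, keep, drop = FALSE]
  }
  if (ncol(presence_env) == 0) stop("all predictors constant")
  ft <- maxent_features(rbind(presence_env, background_env))
  if (features == "l") {
    lin <- seq_len(ncol(presence_env))
    ft$f <- ft$f[, lin, drop = FALSE]
    ft$center <- ft$center[lin]; ft$scale <- ft$scale[lin]
  }
  X <- cbind(`(Intercept)` = 1, ft$f)
  yv <- c(rep(1, np), rep(0, nb))
  w <- c(rep(0.5 / np, np), rep(0.5 / nb, nb))
  # mild default shrinkage comparable to MaxEnt's small-sample defaults:
  # the likelihood term here is on the mean (weights sum to 1) scale
  lambda <- reg_multiplier * 0.05 / sqrt(np)
  penalize <- c(FALSE, rep(TRUE, ncol(ft$f)))
  fit <- fista_logistic(X, yv, w, lambda, penalize)
  if (!fit$converged)
    stop("MaxEnt optimization did not converge within the iteration cap")
  beta <- stats::setNames(fit$beta, colnames(X))
  # entropy normalization over background for the cloglog output
  eta_bg <- drop(X[yv == 0, -1, drop = FALSE] %*% beta[-1])
  a_norm <- -log(sum(exp(eta_bg - max(eta_bg)))) - max(eta_bg)
  p_bg <- exp(eta_bg + a_norm)
  H <- -sum(p_bg * log(pmax(p_bg, 1e-300)))
  structure(
    list(beta = beta, center = ft$center, scale = ft$scale,
         features = features, vars = colnames(presence_env),
         ranges = apply(rbind(presence_env, background_env), 2, range),
         a_norm = a_norm, entropy = H, converged = fit$converged,
         lambda = lambda, n_presence = np, n_background = nb),
    class = "maxent_model"
  )
}

#' Predict habitat suitability from a fitted MaxEnt model
#'
#' @param object A `maxent_model`.
#' @param newdata Matrix/data frame with the model's predictors (columns
#'   matched by name when present).
#' @param type `"cloglog"` (default), `"logistic"` or `"link"`.
#' @param clamp Clamp predictors to the training range before evaluation
#'   (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predictions (suitability in \[0, 1\] for
#'   `"cloglog"`/`"logistic"`).
#' @export
predict.maxent_model <- function(object, newdata, type = c("cloglog",
                                 "logistic", "link"), clamp = TRUE, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && all(object$vars %in% colnames(newdata)))
    newdata <- newdata[, object$vars, drop = FALSE]
  if (clamp)
    for (j in seq_len(ncol(newdata)))
      newdata[, j] <- pmin(pmax(newdata[, j], object$ranges[1, j]),
                           object$ranges[2, j])
  colnames(newdata) <- object$vars
  ft <- maxent_features(newdata, object$center, object$scale)
  f <- ft$f
  if (object$features == "l")
    f <- f[, seq_along(object$vars), drop = FALSE]
  eta <- drop(f %*% object$beta[-1])
  switch(type,
    link = object$beta[[1]] + eta,
    logistic = stats::plogis(object$beta[[1]] + eta),
    cloglog = 1 - exp(-exp(eta + object$a_norm + object$entropy)))
}

#' Somers' D rank discrimination index
#'
#' `D = 2 * AUC - 1`, where the AUC compares presence scores against
#' background scores with ties counted as 1/2 (Mann-Whitney form).
#'
#' @param presence_scores,background_scores Numeric score vectors
#'   (non-empty).
#' @return D in \[-1, 1\].
#' @export
somers_d <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
  2 * auc - 1
}

#' Cross-validate one bivariate model on one background replicate
#'
#' Repeated random 80/20 splits: each run trains a MaxEnt model on 80% of
#' the presences (background split alike) and scores the held-out 20%
#' presences against the held-out background with Somers' D.
#'
#' @param presence_env Predictor values at presences (>= 5 rows).
#' @param background_env Predictor values at background points.
#' @param splits Number of runs (default 10).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed; split membership is deterministic given it.
#' @param reg_multiplier Passed to [fit_maxent()].
#' @return List of runs; each has `model`, `d` (test Somers' D), `train_d`,
#'   and `test_idx`. Runs whose test split has < 2 presences are skipped
#'   with a warning.
#' @export
cross_validate <- function(presence_env, background_env, splits = 10,
                           train_frac = 0.8, seed = 1L, reg_multiplier = 1) {
  presence_env <- as.matrix(presence_env)
  background_env <- as.matrix(background_env)
  np <- nrow(presence_env)
  if (np < 5) stop("need at least 5 presences")
  set.seed(seed)
  runs <- vector("list", splits)
  for (k in seq_len(splits)) {
    tr_p <- sample.int(np, max(1, round(train_frac * np)))
    te_p <- setdiff(seq_len(np), tr_p)
    nb <- nrow(background_env)
    tr_b <- sample.int(nb, max(1, round(train_frac * nb)))
    te_b <- setdiff(seq_len(nb), tr_b)
    if (length(te_p) < 2) {
      warning("run ", k, " skipped: fewer than 2 test presences")
      next
    }
    m <- try(fit_maxent(presence_env[tr_p, , drop = FALSE],
                        background_env[tr_b, , drop = FALSE],
                        reg_multiplier = reg_multiplier), silent = TRUE)
    if (inherits(m, "try-error")) next
    d_test <- somers_d(predict(m, presence_env[te_p, , drop = FALSE]),
                       predict(m, background_env[te_b, , drop = FALSE]))
    d_train <- somers_d(predict(m, presence_env[tr_p, , drop = FALSE]),
                        predict(m, background_env[tr_b, , drop = FALSE]))
    runs[[k]] <- list(model = m, d = d_test, train_d = d_train,
                      cv_run = k)
  }
  runs[!vapply(runs, is.null, logical(1))]
}
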