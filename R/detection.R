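#' Convert a clinometer declination angle to perpendicular distance
#'
#' Aerial observers record the declination angle when a group is abeam; the
#' perpendicular distance follows from the flight altitude:
#' `distance = altitude / tan(declination)`.
#'
#' @param declination_deg Declination angle in degrees, in (0, 90].
#' @param altitude_m Flight altitude in metres (> 0).
#' @return Perpendicular distance in metres.
#' @export
distance_from_declination <- function(declination_deg, altitude_m) {
  if (any(altitude_m <= 0)) stop("altitude must be positive")
  if (any(declination_deg <= 0))
    stop("declination must be positive: a 0 degree (horizon) sighting has ",
         "undefined distance")
  if (any(declination_deg > 90)) stop("declination cannot exceed 90 degrees")
  altitude_m / tan(declination_deg * pi / 180)
}

## ---- detection function internals -------------------------------------
## A model is described by a key ("uniform", "half-normal", "hazard-rate"),
## an adjustment family ("none", "cosine", "hermite", "poly") and the series
## orders in use. Parameters are packed as
##   half-normal: log(sigma); hazard-rate: log(sigma), log(shape)
## followed by one coefficient per adjustment order.

key_n_par <- function(key) switch(key, uniform = 0L, `half-normal` = 1L,
                                  `hazard-rate` = 2L)

key_fn <- function(y, key, kpar) {
  switch(key,
    uniform = rep(1, length(y)),
    `half-normal` = exp(-y^2 / (2 * exp(2 * kpar[1]))),
    `hazard-rate` = {
      sigma <- exp(kpar[1]); b <- exp(kpar[2])
      p <- 1 - exp(-(y / sigma)^(-b))
      p[y == 0] <- 1
      p
    })
}

## scaled adjustment basis h_j(y); hermite uses probabilists' polynomials
adj_basis <- function(y, family, orders, W, sigma = NULL) {
  if (family == "none" || length(orders) == 0)
    return(matrix(0, length(y), 0))
  sapply(orders, function(j) {
    switch(family,
      cosine = cos(j * pi * y / W),
      hermite = {
        z <- y / sigma
        if (j == 4) z^4 - 6 * z^2 + 3
        else if (j == 6) z^6 - 15 * z^4 + 45 * z^2 - 15
        else stop("unsupported Hermite order ", j)
      },
      poly = (y / W)^j)
  }, simplify = "array") |> matrix(nrow = length(y))
}

## unnormalized detection function (not yet scaled to g(0) = 1)
g_unnorm <- function(y, key, kpar, family, orders, apar, W) {
  k <- key_fn(y, key, kpar)
  if (length(orders) == 0) return(k)
  sigma <- if (key == "uniform") NULL else exp(kpar[1])
  h <- adj_basis(y, family, orders, W, sigma)
  k * (1 + as.vector(h %*% apar))
}

## g scaled so g(0) = 1
g_eval <- function(y, key, kpar, family, orders, apar, W) {
  g0 <- g_unnorm(0, key, kpar, family, orders, apar, W)
  g_unnorm(y, key, kpar, family, orders, apar, W) / g0
}

#' Evaluate a fitted detection function
#'
#' @param model A `detection_model` from [fit_detection_function()].
#' @param y Perpendicular distances (km).
#' @return `g(y)`, with `g(0) = 1`.
#' @export
detection_prob <- function(model, y) {
  g_eval(y, model$key, model$key_par, model$adjustment, model$orders,
         model$adj_par, model$W)
}

## conditional log likelihood sum log(g(y_i)/mu); returns -Inf surrogate when
## the series goes negative on [0, W]
detfn_negloglik <- function(par, y, key, family, orders, W, check_grid) {
  nk <- key_n_par(key)
  kpar <- par[seq_len(nk)]
  apar <- par[-seq_len(nk)]
  if (nk == 0) apar <- par
  gg <- g_eval(check_grid, key, kpar, family, orders, apar, W)
  if (any(!is.finite(gg))) return(1e10)
  pen <- 0
  if (any(gg < 0)) pen <- 1e6 * sum(pmin(gg, 0)^2) + 1e4
  gy <- g_eval(y, key, kpar, family, orders, apar, W)
  mu <- detfn_esw(key, kpar, family, orders, apar, W)
  if (!is.finite(mu) || mu <= 0 || any(gy <= 0)) return(1e10 + pen)
  -(sum(log(gy)) - length(y) * log(mu)) + pen
}

detfn_esw <- function(key, kpar, family, orders, apar, W) {
  out <- try(stats::integrate(function(y)
    g_eval(y, key, kpar, family, orders, apar, W),
    0, W, rel.tol = 1e-9, subdivisions = 400L)$value, silent = TRUE)
  if (inherits(out, "try-error")) NA_real_ else out
}

fit_one_structure <- function(y, key, family, orders, W) {
  nk <- key_n_par(key)
  na <- length(orders)
  check_grid <- seq(0, W, length.out = 101)
  start <- c(
    switch(key,
      uniform = numeric(0),
      `half-normal` = log(max(stats::sd(y), 1e-4)),
      `hazard-rate` = c(log(max(stats::median(y), 1e-4)), log(2))),
    rep(0, na)
  )
  npar <- length(start)
  if (npar == 0) {
    ll <- -length(y) * log(W)
    return(list(par = numeric(0), loglik = ll, convergence = 0L,
                degenerate = FALSE))
  }
  obj <- function(p) detfn_negloglik(p, y, key, family, orders, W, check_grid)
  if (npar == 1) {
    opt <- stats::optim(start, obj, method = "Brent",
                        lower = start - 12, upper = start + 6)
  } else {
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
  }
  degenerate <- FALSE
  if (nk >= 1 && key != "uniform" &&
      (exp(opt$par[1]) <= 2e-4 || opt$par[1] <= start[1] - 11))
    degenerate <- TRUE
  list(par = opt$par, loglik = -opt$value, convergence = opt$convergence,
       degenerate = degenerate)
}

default_orders <- function(key, family) {
  if (family == "none") return(integer(0))
  switch(paste(key, family),
    "uniform cosine" = c(1L, 2L, 3L),
    "half-normal cosine" = c(2L, 3L),
    "half-normal hermite" = c(4L, 6L),
    "hazard-rate poly" = c(4L, 6L),
    stop("unsupported key/adjustment combination: ", key, " + ", family))
}

#' Fit a line-transect detection function by maximum likelihood
#'
#' Maximizes the conditional likelihood `prod g(y_i) / mu`, where
#' `mu = integral of g over [0, W]` is the effective strip width (ESW), for a
#' key function with optional series adjustments. Adjustment terms are added
#' greedily in their conventional order (cosine orders 1,2,3 for the uniform
#' key, 2,3 for half-normal; Hermite 4,6; simple polynomial 4,6 for
#' hazard-rate) while AIC improves, up to `max_adjust_terms`. The fitted
#' function is normalized to `g(0) = 1`; negativity of the adjusted series on
#' `[0, W]` is penalized during optimization, and a fit that still dips below
#' zero is refitted with fewer terms and flagged.
#'
#' @param distances Perpendicular distances (km), inside `(0, W]` after
#'   truncation; at least 2 required.
#' @param key `"uniform"`, `"half-normal"` or `"hazard-rate"`.
#' @param adjustment `"none"`, `"cosine"`, `"hermite"` or `"poly"`.
#' @param W Truncation distance (km); default = max observed distance.
#' @param max_adjust_terms Maximum number of adjustment terms (default 3).
#' @param orders Force exactly these adjustment orders (skips greedy
#'   selection); `NULL` for the default greedy path.
#' @return An object of class `detection_model` with elements `key`,
#'   `adjustment`, `orders`, `key_par`, `adj_par`, `loglik`, `n_params`,
#'   `aic`, `W`, `esw`, `n`, `monotone`, `degenerate`, `truncated_negative`.
#' @export
fit_detection_function <- function(distances, key = "half-normal",
                                   adjustment = "none", W = NULL,
                                   max_adjust_terms = 3, orders = NULL) {
  key <- match.arg(key, c("uniform", "half-normal", "hazard-rate"))
  adjustment <- match.arg(adjustment, c("none", "cosine", "hermite", "poly"))
  distances <- distances[!is.na(distances)]
  if (is.null(W)) W <- max(distances)
  if (W <= 0) stop("truncation distance W must be positive")
  distances <- distances[distances <= W]
  if (length(distances) < 2) stop("need at least 2 distances within (0, W]")

  pool <- if (is.null(orders)) default_orders(key, adjustment) else integer(0)
  use <- if (is.null(orders)) integer(0) else as.integer(orders)

  fit <- fit_one_structure(distances, key, adjustment, use, W)
  best <- list(orders = use, fit = fit,
               aic = 2 * (key_n_par(key) + length(use)) - 2 * fit$loglik)
  if (is.null(orders)) {
    for (j in pool) {
      if (length(best$orders) >= max_adjust_terms) break
      cand_orders <- c(best$orders, j)
      cand <- fit_one_structure(distances, key, adjustment, cand_orders, W)
      aic <- 2 * (key_n_par(key) + length(cand_orders)) - 2 * cand$loglik
      if (is.finite(aic) && aic < best$aic - 1e-9) {
        best <- list(orders = cand_orders, fit = cand, aic = aic)
      } else break
    }
  }

  nk <- key_n_par(key)
  kpar <- best$fit$par[seq_len(nk)]
  apar <- if (nk == 0) best$fit$par else best$fit$par[-seq_len(nk)]
  grid <- seq(0, W, length.out = 201)
  gg <- g_eval(grid, key, kpar, adjustment, best$orders, apar, W)
  truncated_negative <- FALSE
  if (any(gg < -1e-8)) {
    # drop terms until non-negative
    while (length(best$orders) > 0 && any(gg < -1e-8)) {
      best$orders <- best$orders[-length(best$orders)]
      best$fit <- fit_one_structure(distances, key, adjustment, best$orders, W)
      best$aic <- 2 * (nk + length(best$orders)) - 2 * best$fit$loglik
      kpar <- best$fit$par[seq_len(nk)]
      apar <- if (nk == 0) best$fit$par else best$fit$par[-seq_len(nk)]
      gg <- g_eval(grid, key, kpar, adjustment, best$orders, apar, W)
    }
    truncated_negative <- TRUE
  }
  esw <- detfn_esw(key, kpar, adjustment, best$orders, apar, W)
  n_params <- nk + length(best$orders)
  structure(
    list(key = key, adjustment = adjustment, orders = best$orders,
         key_par = kpar, adj_par = apar, loglik = best$fit$loglik,
         n_params = n_params, aic = 2 * n_params - 2 * best$fit$loglik,
         W = W, esw = esw, n = length(distances),
         monotone = all(diff(gg) <= 1e-8),
         degenerate = isTRUE(best$fit$degenerate),
         truncated_negative = truncated_negative,
         convergence = best$fit$convergence),
    class = "detection_model"
  )
}

#' @export
print.detection_model <- function(x, ...) {
  adj <- if (length(x$orders)) sprintf(" + %s(%s)", x$adjustment,
                                       paste(x$orders, collapse = ","))
         else ""
  cat(sprintf("Detection function: %s key%s\n", x$key, adj))
  cat(sprintf("  n = %d, W = %.4g km, ESW = %.5g km\n", x$n, x$W, x$esw))
  cat(sprintf("  logLik = %.3f, k = %d, AIC = %.2f\n",
              x$loglik, x$n_params, x$aic))
  if (!x$monotone) cat("  note: fitted g(y) is non-monotone\n")
  if (x$degenerate) cat("  note: scale at optimization bound (degenerate)\n")
  invisible(x)
}

#' Select the best detection model by AIC
#'
#' Minimum AIC wins; exact ties are broken by fewer parameters, then by key
#' order uniform < half-normal < hazard-rate.
#'
#' @param models List of `detection_model` objects.
#' @return The selected `detection_model`.
#' @export
select_model <- function(models) {
  if (length(models) == 0) stop("no candidate models supplied")
  key_rank <- c(uniform = 1, `half-normal` = 2, `hazard-rate` = 3)
  aics <- vapply(models, `[[`, numeric(1), "aic")
  ks <- vapply(models, `[[`, numeric(1), "n_params")
  kr <- key_rank[vapply(models, `[[`, character(1), "key")]
  ord <- order(round(aics, 8), ks, kr)
  models[[ord[1]]]
}

#' Effective strip width of a fitted detection function
#'
#' `mu = integral of g(y) dy over [0, W]`, by adaptive quadrature.
#'
#' @param model A `detection_model`.
#' @return ESW in km, in `(0, W]`.
#' @export
effective_strip_width <- function(model) {
  detfn_esw(model$key, model$key_par, model$adjustment, model$orders,
            model$adj_par, model$W)
}

#' Fit the four conventional key/adjustment combinations and pick one
#'
#' Candidates: uniform + cosine, half-normal + cosine, half-normal + Hermite,
#' hazard-rate + simple polynomial — the standard recommended set for
#' line-transect data — selected by AIC via [select_model()].
#'
#' @inheritParams fit_detection_function
#' @return List with `model` (the AIC-best `detection_model`) and
#'   `candidates` (all four fits).
#' @export
fit_candidate_models <- function(distances, W = NULL, max_adjust_terms = 3) {
  specs <- list(
    list(key = "uniform", adjustment = "cosine"),
    list(key = "half-normal", adjustment = "cosine"),
    list(key = "half-normal", adjustment = "hermite"),
    list(key = "hazard-rate", adjustment = "poly")
  )
  candidates <- lapply(specs, function(s)
    try(fit_detection_function(distances, s$key, s$adjustment, W = W,
                               max_adjust_terms = max_adjust_terms),
        silent = TRUE))
  ok <- !vapply(candidates, inherits, logical(1), "try-error")
  if (!any(ok)) stop("no detection model converged")
  candidates <- candidates[ok]
  list(model = select_model(candidates), candidates = candidates)
}
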