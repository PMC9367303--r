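#' All unordered pairs of predictor names
#'
#' The ensemble-of-small-models strategy fits every bivariate model, i.e.
#' one model per unordered pair of eco-geographical variables.
#'
#' @param egv_names Character vector of >= 2 names.
#' @return List of length-2 character vectors, `C(k, 2)` of them, in stable
#'   (combination) order.
#' @export
enumerate_pairs <- function(egv_names) {
  if (length(egv_names) < 2) stop("need at least 2 EGVs")
  utils::combn(egv_names, 2, simplify = FALSE)
}

#' Sample background points from the sea cells of a stack
#'
#' @param env An `env_truth` or any list with `sea` (logical matrix) and
#'   `grid`.
#' @param n Points per replicate (default 10000).
#' @param replicates Number of independent background datasets (default 10).
#' @param seed Integer seed.
#' @param replace Sample with replacement (required if `n` exceeds the
#'   number of sea cells).
#' @return List of `replicates` integer vectors of cell indices (into the
#'   layer matrices), each with attribute `replicate`.
#' @export
sample_background <- function(env, n = 10000, replicates = 10, seed = 1L,
                              replace = FALSE) {
  sea_idx <- which(as.vector(env$sea))
  if (length(sea_idx) == 0) stop("empty sea mask")
  if (!replace && n > length(sea_idx))
    stop("n exceeds the number of sea cells; set replace = TRUE")
  set.seed(seed)
  lapply(seq_len(replicates), function(r) {
    out <- sample(sea_idx, n, replace = replace)
    attr(out, "replicate") <- r
    out
  })
}

## predictor values of a stack at cell indices, as a named matrix
stack_values_at <- function(layers, idx) {
  vapply(layers, function(m) as.vector(m)[idx], numeric(length(idx)))
}

#' Build a Somers'-D-weighted ensemble from bivariate runs
#'
#' Runs with `D < d_threshold` are discarded; the rest are weighted
#' proportionally to their D (`w_i = D_i / sum(D_j)`), and the ensemble
#' prediction is the weighted average of member predictions.
#'
#' @param runs List of runs as returned by [cross_validate()] (each with
#'   `model`, `d`, and optionally `pair`/`replicate` metadata).
#' @param d_threshold Somers'-D retention threshold (default 0.5, kept when
#'   `D >= d_threshold`).
#' @return Object of class `ensemble_model`: `runs` (retained), `weights`
#'   (sum to 1), `d_threshold`, `n_candidates`.
#' @export
build_ensemble <- function(runs, d_threshold = 0.5) {
  if (length(runs) == 0) stop("no runs supplied")
  ds <- vapply(runs, `[[`, numeric(1), "d")
  keep <- ds >= d_threshold
  if (!any(keep))
    stop("no skillful models: every run has Somers' D below ", d_threshold)
  kept <- runs[keep]
  w <- ds[keep] / sum(ds[keep])
  structure(
    list(runs = kept, weights = w, d_threshold = d_threshold,
         n_candidates = length(runs)),
    class = "ensemble_model"
  )
}

#' Predict the ensemble habitat-suitability index over a stack
#'
#' Weighted average of the member model predictions, cell by cell. Each
#' member clamps predictor values to its training range. Cells that are
#' nodata in any required layer are nodata in the output.
#'
#' @param ensemble An `ensemble_model`.
#' @param layers Named list of layer matrices containing every predictor
#'   used by the retained runs.
#' @return Matrix of HSI values in \[0, 1\] (`NA` where inputs are `NA`).
#' @export
predict_map <- function(ensemble, layers) {
  need <- unique(unlist(lapply(ensemble$runs, function(r) r$model$vars)))
  missing <- setdiff(need, names(layers))
  if (length(missing) > 0)
    stop("missing layer(s): ", paste(missing, collapse = ", "))
  dims <- dim(layers[[need[1]]])
  vals <- vapply(layers[need], as.vector, numeric(prod(dims)))
  ok <- stats::complete.cases(vals)
  out <- rep(NA_real_, prod(dims))
  acc <- numeric(sum(ok))
  for (i in seq_along(ensemble$runs)) {
    m <- ensemble$runs[[i]]$model
    acc <- acc + ensemble$weights[i] *
      predict(m, vals[ok, m$vars, drop = FALSE])
  }
  out[ok] <- acc
  matrix(out, dims[1], dims[2])
}

#' Continuous Boyce Index
#'
#' Calibration measure for presence-only predictions: the Spearman rank
#' correlation between the predicted-to-expected presence ratio (P/E) and
#' the suitability class, computed in a moving window swept across the HSI
#' range.
#'
#' @param hsi Suitability map (matrix) or vector of map values; `NA`
#'   ignored.
#' @param presence_hsi HSI values at evaluation presences (>= 5).
#' @param n_classes Number of window midpoints (default 101).
#' @param window_frac Window width as a fraction of the HSI range
#'   (default 0.1).
#' @return CBI in \[-1, 1\]; 0 (with attribute `degenerate = TRUE`) for a
#'   constant map.
#' @export
boyce_index <- function(hsi, presence_hsi, n_classes = 101,
                        window_frac = 0.1) {
  bg <- as.vector(hsi)
  bg <- bg[!is.na(bg)]
  presence_hsi <- presence_hsi[!is.na(presence_hsi)]
  if (length(presence_hsi) < 5) stop("need at least 5 evaluation presences")
  rng <- range(bg)
  if (diff(rng) < 1e-12) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  w <- window_frac * diff(rng)
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_classes)
  pe <- vapply(mids, function(m) {
    lo <- m - w / 2; hi <- m + w / 2
    p <- mean(presence_hsi >= lo & presence_hsi <= hi)
    e <- mean(bg >= lo & bg <= hi)
    if (e == 0) NA_real_ else p / e
  }, numeric(1))
  ok <- !is.na(pe)
  pe <- pe[ok]; mids <- mids[ok]
  # drop consecutive duplicate P/E values produced by overlapping windows
  keep <- c(TRUE, diff(pe) != 0)
  pe <- pe[keep]; mids <- mids[keep]
  if (length(pe) < 3) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  suppressWarnings(stats::cor(pe, mids, method = "spearman"))
}

#' Per-variable contribution percentages of an ensemble
#'
#' A variable's score is the mean Somers' D over all bivariate runs whose
#' pair contains it (the full run pool, not only the runs retained for
#' prediction); contributions are the scores normalized to sum to 100.
#' Negative mean scores are clamped to 0 before normalizing.
#'
#' @param runs A list of runs (each with `d` and `pair` or a fitted
#'   `model`), or an `ensemble_model` (its retained runs are used).
#' @param egv_names Variables to report (default: all appearing in runs).
#' @return Named numeric vector of percentages summing to 100 (variables in
#'   no run get 0).
#' @export
variable_contribution <- function(runs, egv_names = NULL) {
  if (inherits(runs, "ensemble_model")) runs <- runs$runs
  if (length(runs) == 0) stop("no runs supplied")
  pairs <- lapply(runs, function(r)
    if (!is.null(r$pair)) r$pair else r$model$vars)
  ds <- vapply(runs, `[[`, numeric(1), "d")
  if (is.null(egv_names)) egv_names <- sort(unique(unlist(pairs)))
  score <- vapply(egv_names, function(v) {
    has <- vapply(pairs, function(p) v %in% p, logical(1))
    if (!any(has)) 0 else max(0, mean(ds[has]))
  }, numeric(1))
  if (sum(score) == 0) return(stats::setNames(rep(0, length(score)),
                                              egv_names))
  100 * score / sum(score)
}

#' Cell-wise mean and coefficient of variation of annual HSI maps
#'
#' @param maps List of >= 2 HSI matrices on one grid.
#' @return List with `mean` and `cv` matrices; CV = sample SD / mean, `NA`
#'   where the mean is 0 or inputs are `NA`.
#' @export
annual_mean_and_cv <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 annual maps")
  dims <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), dims), logical(1))))
    stop("annual maps are on mismatched grids")
  arr <- simplify2array(maps)
  mn <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  cv <- sdv / mn
  cv[!is.na(mn) & mn == 0] <- NA_real_
  list(mean = mn, cv = cv)
}

#' Run the full ensemble-of-small-models analysis for one presence set
#'
#' Enumerates every bivariate predictor pair, fits each pair on each
#' background replicate with repeated 80/20 cross-validation, retains runs
#' with Somers' D >= `d_threshold`, and returns the D-weighted ensemble, its
#' HSI map, variable contributions and the run ledger.
#'
#' @param presence_xy Two-column matrix of presence coordinates (km), on sea
#'   cells of `env`.
#' @param env An `env_truth` (or list with `grid`, `layers`, `sea`).
#' @param egv_names Predictors to use (default: all layers).
#' @param n_background Background points per replicate.
#' @param replicates Background replicates.
#' @param splits Cross-validation runs per pair x replicate.
#' @param d_threshold Somers'-D retention threshold.
#' @param reg_multiplier MaxEnt regularization multiplier.
#' @param seed Integer seed (whole stage deterministic given it).
#' @return List of class `esm_fit`: `ensemble`, `hsi` (matrix),
#'   `contributions`, `runs_ledger` (data frame: pair, replicate, cv_run, d,
#'   retained), `cbi` (on the training presences), `n_presence`.
#' @export
run_esm <- function(presence_xy, env, egv_names = names(env$layers),
                    n_background = 10000, replicates = 10, splits = 10,
                    d_threshold = 0.5, reg_multiplier = 1, seed = 1L) {
  presence_xy <- as.matrix(presence_xy)
  rc <- xy_to_rowcol(env$grid, presence_xy[, 1], presence_xy[, 2])
  pres_idx <- (rc[, "col"] - 1L) * env$grid$ny + rc[, "row"]
  if (anyNA(pres_idx)) stop("presences outside the grid extent")
  if (!all(as.vector(env$sea)[pres_idx]))
    stop("presences must fall on sea cells")
  layers <- env$layers[egv_names]
  pres_env <- stack_values_at(layers, pres_idx)
  colnames(pres_env) <- egv_names
  bgs <- sample_background(env, n = n_background, replicates = replicates,
                           seed = seed)
  pairs <- enumerate_pairs(egv_names)
  all_runs <- list()
  ledger <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    for (bi in seq_along(bgs)) {
      bg_env <- stack_values_at(layers[pr], bgs[[bi]])
      colnames(bg_env) <- pr
      runs <- cross_validate(pres_env[, pr, drop = FALSE], bg_env,
                             splits = splits,
                             seed = (seed + 7919L * pi + 104729L * bi) %%
                               .Machine$integer.max,
                             reg_multiplier = reg_multiplier)
      for (r in runs) {
        r$pair <- pr
        r$replicate <- bi
        all_runs[[length(all_runs) + 1L]] <- r
        ledger[[length(ledger) + 1L]] <- data.frame(
          pair = paste(pr, collapse = "+"), replicate = bi,
          cv_run = r$cv_run, d = r$d)
      }
    }
  }
  ledger <- do.call(rbind, ledger)
  ensemble <- build_ensemble(all_runs, d_threshold = d_threshold)
  ledger$retained <- ledger$d >= d_threshold
  hsi <- predict_map(ensemble, layers)
  contrib <- variable_contribution(all_runs, egv_names)
  cbi <- boyce_index(hsi, as.vector(hsi)[pres_idx])
  structure(
    list(ensemble = ensemble, hsi = hsi, contributions = contrib,
         runs_ledger = ledger, cbi = as.numeric(cbi),
         n_presence = nrow(presence_xy), seed = seed),
    class = "esm_fit"
  )
}
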