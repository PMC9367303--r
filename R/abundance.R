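#' Expected group size via size-bias regression
#'
#' Larger groups are easier to detect far from the trackline, which inflates
#' the observed mean group size. Following the conventional correction, the
#' log of group size is regressed on the fitted detection probability
#' `g(y_i)`; if the slope is significant at level `alpha` (two-sided,
#' default 0.15), the expected group size is the back-transformed prediction
#' at `g = 1`, `exp(a + b + s^2/2)` with the log-normal bias correction
#' `s^2/2`; otherwise the observed mean is used.
#'
#' @param sightings Data frame with columns `perp_distance_km` and
#'   `group_size` (>= 3 rows).
#' @param model A `detection_model` used to compute `g(y_i)`.
#' @param alpha Significance level for the slope test (default 0.15).
#' @return An object of class `group_size_estimate`: `observed_mean`,
#'   `expected_mean`, `slope`, `slope_p`, `used_expected`, `cv_percent`.
#' @export
expected_group_size <- function(sightings, model, alpha = 0.15) {
  s <- sightings$group_size
  if (length(s) < 3) stop("need at least 3 sightings")
  obs_mean <- mean(s)
  obs_cv <- if (length(s) > 1 && obs_mean > 0)
    100 * stats::sd(s) / (obs_mean * sqrt(length(s))) else 0
  out <- list(observed_mean = obs_mean, expected_mean = obs_mean,
              slope = NA_real_, slope_p = NA_real_, used_expected = FALSE,
              cv_percent = obs_cv)
  if (stats::var(s) > 0) {
    ghat <- detection_prob(model, sightings$perp_distance_km)
    if (all(is.finite(ghat)) && stats::var(ghat) > 1e-10) {
      fit <- stats::lm(log(s) ~ ghat)
      sm <- summary(fit)
      if (!"ghat" %in% rownames(sm$coefficients) ||
          anyNA(stats::coef(fit))) return(structure(out,
            class = "group_size_estimate"))
      slope <- stats::coef(fit)[["ghat"]]
      p <- sm$coefficients["ghat", "Pr(>|t|)"]
      out$slope <- slope
      out$slope_p <- p
      if (is.finite(p) && p <= alpha) {
        s2 <- sm$sigma^2
        pred <- stats::predict(fit, newdata = data.frame(ghat = 1),
                               se.fit = TRUE)
        exp_mean <- exp(pred$fit + s2 / 2)
        out$expected_mean <- max(1, unname(exp_mean))
        out$used_expected <- TRUE
        # delta-method CV on the log scale: SE of the linear predictor at g=1
        out$cv_percent <- 100 * unname(pred$se.fit)
      }
    }
  }
  class(out) <- "group_size_estimate"
  out
}

#' Stratum density and abundance under conventional distance sampling
#'
#' The CDS estimator with availability correction:
#' `D = n * E[s] / (2 * L * mu * g0)` and `N = D * A`, where `n` is the
#' number of sightings, `E[s]` the expected group size, `L` the effort,
#' `mu` the effective strip width and `g0` the trackline detection
#' probability.
#'
#' @param sightings Stratum sightings (data frame; may have 0 rows).
#' @param effort_km Total transect length surveyed in the stratum (> 0).
#' @param area_km2 Stratum area (km^2).
#' @param model Fitted `detection_model` (usually the pooled, global one).
#' @param group_size A `group_size_estimate`, or a single number taken as
#'   `E[s]` directly.
#' @param g0 Trackline detection probability in (0, 1]; 1 means no
#'   availability correction.
#' @param stratum Stratum label.
#' @return An object of class `stratum_estimate`: `stratum`, `n_sightings`,
#'   `n_individuals`, `effort_km`, `area_km2`, `esw_km`, `expected_group_size`,
#'   `g0_used`, `density`, `abundance`, plus `cv_percent`/`ci_low`/`ci_high`
#'   slots filled by [bootstrap_estimates()].
#' @export
estimate_density <- function(sightings, effort_km, area_km2, model,
                             group_size, g0 = 1, stratum = "all") {
  if (effort_km <= 0) stop("effort must be positive")
  if (g0 <= 0 || g0 > 1) stop("g0 must lie in (0, 1]")
  es <- if (inherits(group_size, "group_size_estimate"))
    group_size$expected_mean else as.numeric(group_size)
  mu <- model$esw
  n <- nrow(sightings)
  D <- if (n == 0) 0 else n * es / (2 * effort_km * mu * g0)
  structure(
    list(stratum = stratum, n_sightings = n,
         n_individuals = sum(sightings$group_size),
         effort_km = effort_km, area_km2 = area_km2, esw_km = mu,
         expected_group_size = es, g0_used = g0,
         density = D, abundance = D * area_km2,
         cv_percent = NA_real_, ci_low = NA_real_, ci_high = NA_real_),
    class = "stratum_estimate"
  )
}

#' Combine stratum estimates into an overall estimate
#'
#' Overall density is the effort-weighted mean of stratum densities,
#' `D = sum(D_i * L_i) / sum(L_i)`; overall abundance is `D * total_area`.
#'
#' @param estimates List of `stratum_estimate` objects (>= 1).
#' @param total_area Total study-area size (km^2); default = sum of stratum
#'   areas.
#' @return An object of class `combined_estimate`: `strata` (the input list),
#'   `density`, `abundance`, `total_area`, `effort_km`, `rule`.
#' @export
combine_strata <- function(estimates, total_area = NULL) {
  if (length(estimates) == 0) stop("need at least one stratum estimate")
  L <- vapply(estimates, `[[`, numeric(1), "effort_km")
  D <- vapply(estimates, `[[`, numeric(1), "density")
  if (sum(L) <= 0) stop("total effort is zero")
  if (is.null(total_area))
    total_area <- sum(vapply(estimates, `[[`, numeric(1), "area_km2"))
  Dall <- sum(D * L) / sum(L)
  structure(
    list(strata = estimates, density = Dall,
         abundance = Dall * total_area, total_area = total_area,
         effort_km = sum(L), rule = "effort-weighted",
         cv_percent = NA_real_, ci_low = NA_real_, ci_high = NA_real_),
    class = "combined_estimate"
  )
}

#' Apply (or re-apply) an availability correction g(0)
#'
#' Divides density and abundance by `g0`; the CV is unchanged because the
#' correction is a known multiplicative constant.
#'
#' @param estimate A `stratum_estimate` or `combined_estimate` computed with
#'   `g0 = 1`.
#' @param g0 Trackline detection probability in (0, 1].
#' @return The corrected estimate (same class).
#' @export
apply_g0 <- function(estimate, g0) {
  if (g0 <= 0 || g0 > 1) stop("g0 must lie in (0, 1]")
  scale_est <- function(e) {
    e$density <- e$density / g0
    e$abundance <- e$abundance / g0
    if (!is.na(e$ci_low)) e$ci_low <- e$ci_low / g0
    if (!is.na(e$ci_high)) e$ci_high <- e$ci_high / g0
    if (!is.null(e$g0_used)) e$g0_used <- e$g0_used * g0
    e
  }
  if (inherits(estimate, "combined_estimate")) {
    estimate$strata <- lapply(estimate$strata, scale_est)
    estimate <- scale_est(estimate)
  } else {
    estimate <- scale_est(estimate)
  }
  estimate
}

## Run the full CDS analysis once on a (sightings, effort, areas) survey:
## pooled detection fit (fixed structure), size-bias regression, per-stratum
## and combined estimates.
cds_once <- function(sightings, effort, areas, key, adjustment, orders, W,
                     g0, alpha = 0.15, total_area = NULL) {
  model <- fit_detection_function(sightings$perp_distance_km, key, adjustment,
                                  W = W, orders = orders)
  gs <- expected_group_size(sightings, model, alpha = alpha)
  strata <- names(areas)
  ests <- lapply(strata, function(st) {
    s_st <- sightings[sightings$stratum == st, , drop = FALSE]
    L_st <- sum(effort$length_km[effort$stratum == st])
    estimate_density(s_st, L_st, areas[[st]], model, gs, g0 = g0,
                     stratum = st)
  })
  list(model = model, group_size = gs, strata = ests,
       combined = combine_strata(ests, total_area = total_area))
}

#' Bootstrap CVs and confidence intervals for CDS estimates
#'
#' Nonparametric bootstrap using transects as the sampling unit: within each
#' stratum, transects are resampled with replacement; each replicate refits
#' the pooled detection function (same key/adjustment structure as the
#' selected model), re-runs the size-bias regression and recomputes all
#' stratum and overall estimates. A replicate with no sightings contributes
#' a density of 0 (kept, not dropped). CV = SD/mean x 100; CIs are the
#' 2.5th/97.5th percentiles.
#'
#' @param sightings Survey sightings (`transect_id`, `stratum`,
#'   `perp_distance_km`, `group_size`).
#' @param effort Effort table (`transect_id`, `stratum`, `length_km`); every
#'   stratum needs >= 2 transects.
#' @param areas Named list/vector of stratum areas (km^2).
#' @param model The selected `detection_model` (its structure is refitted in
#'   each replicate).
#' @param B Number of bootstrap replicates (default 999).
#' @param seed Integer seed (replicates are deterministic given the seed).
#' @param g0 Trackline detection probability.
#' @param alpha Size-bias regression significance level.
#' @param total_area Total area for the combined estimate.
#' @return List with `strata` (list of `stratum_estimate` with `cv_percent`,
#'   `ci_low`, `ci_high` filled in), `combined` (likewise), `replicates`
#'   (matrix of replicate densities, one column per stratum plus `overall`).
#' @export
bootstrap_estimates <- function(sightings, effort, areas, model, B = 999,
                                seed = 1L, g0 = 1, alpha = 0.15,
                                total_area = NULL) {
  strata <- names(areas)
  eff_split <- split(effort, effort$stratum)
  for (st in strata)
    if (nrow(eff_split[[st]]) < 2)
      stop("stratum ", st, " has fewer than 2 transects")
  sight_by_tr <- split(sightings, sightings$transect_id)
  set.seed(seed)
  reps <- matrix(NA_real_, B, length(strata) + 1,
                 dimnames = list(NULL, c(strata, "overall")))
  for (b in seq_len(B)) {
    rs_list <- vector("list", length(strata))
    re_list <- vector("list", length(strata))
    for (k in seq_along(strata)) {
      eff_st <- eff_split[[strata[k]]]
      pick <- sample.int(nrow(eff_st), replace = TRUE)
      ids <- eff_st$transect_id[pick]
      re <- eff_st[pick, , drop = FALSE]
      re$transect_id <- sprintf("%s.b%d", ids, seq_along(ids))
      srows <- lapply(seq_along(ids), function(i) {
        s <- sight_by_tr[[ids[i]]]
        if (is.null(s) || nrow(s) == 0) return(NULL)
        s$transect_id <- re$transect_id[i]
        s
      })
      rs_list[[k]] <- do.call(rbind, srows)
      re_list[[k]] <- re
    }
    rs <- do.call(rbind, rs_list)
    re <- do.call(rbind, re_list)
    if (is.null(rs) || nrow(rs) < 2) {
      reps[b, ] <- 0
      next
    }
    est <- try(cds_once(rs, re, areas, model$key, model$adjustment,
                        model$orders, model$W, g0, alpha, total_area),
               silent = TRUE)
    if (inherits(est, "try-error")) next
    reps[b, ] <- c(vapply(est$strata, `[[`, numeric(1), "density"),
                   est$combined$density)
  }
  ok <- stats::complete.cases(reps)
  reps_ok <- reps[ok, , drop = FALSE]
  summar <- function(v) {
    m <- mean(v)
    list(cv = if (m > 0) 100 * stats::sd(v) / m else 0,
         lo = unname(stats::quantile(v, 0.025, type = 7)),
         hi = unname(stats::quantile(v, 0.975, type = 7)))
  }
  point <- cds_once(sightings, effort, areas, model$key, model$adjustment,
                    model$orders, model$W, g0, alpha, total_area)
  for (k in seq_along(strata)) {
    s <- summar(reps_ok[, k])
    point$strata[[k]]$cv_percent <- s$cv
    point$strata[[k]]$ci_low <- s$lo
    point$strata[[k]]$ci_high <- s$hi
  }
  s <- summar(reps_ok[, "overall"])
  point$combined$cv_percent <- s$cv
  point$combined$ci_low <- s$lo
  point$combined$ci_high <- s$hi
  list(strata = point$strata, combined = point$combined,
       model = point$model, group_size = point$group_size,
       replicates = reps, n_used = sum(ok))
}

#' Format stratum estimates as a report table
#'
#' One row per stratum plus a total row: transects, effort, sightings,
#' individuals, expected group size, density (3 decimals), abundance
#' (nearest integer), CV and 95% CI.
#'
#' @param strata List of `stratum_estimate` objects.
#' @param combined Matching `combined_estimate`.
#' @param effort Effort table (to count transects per stratum).
#' @return A data frame.
#' @export
estimate_table <- function(strata, combined, effort) {
  row_of <- function(e, n_tr) data.frame(
    stratum = e$stratum, transects = n_tr,
    distance_km = round(e$effort_km, 1),
    sightings = e$n_sightings, individuals = e$n_individuals,
    expected_group_size = round(e$expected_group_size, 2),
    density = round(e$density, 3),
    density_ci = sprintf("%.3f-%.3f", e$ci_low, e$ci_high),
    abundance = round(e$abundance),
    abundance_ci = sprintf("%.0f-%.0f", e$ci_low * e$area_km2,
                           e$ci_high * e$area_km2),
    cv_percent = round(e$cv_percent, 2)
  )
  rows <- lapply(strata, function(e)
    row_of(e, sum(effort$stratum == e$stratum)))
  tot <- combined
  tot_row <- data.frame(
    stratum = "Total", transects = nrow(effort),
    distance_km = round(tot$effort_km, 1),
    sightings = sum(vapply(strata, `[[`, numeric(1), "n_sightings")),
    individuals = sum(vapply(strata, `[[`, numeric(1), "n_individuals")),
    expected_group_size = NA_real_,
    density = round(tot$density, 3),
    density_ci = sprintf("%.3f-%.3f", tot$ci_low, tot$ci_high),
    abundance = round(tot$abundance),
    abundance_ci = sprintf("%.0f-%.0f", tot$ci_low * tot$total_area,
                           tot$ci_high * tot$total_area),
    cv_percent = round(tot$cv_percent, 2)
  )
  rbind(do.call(rbind, rows), tot_row)
}
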