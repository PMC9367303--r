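#' Default configuration for the end-to-end pipeline
#'
#' A compact demonstration setup: one or more survey years on a synthetic
#' coastal grid, conventional distance sampling with bootstrap uncertainty,
#' and the ensemble-of-small-models habitat analysis. All sizes are
#' overridable; defaults are chosen so a single-year run completes quickly.
#'
#' @param nx,ny Grid size (1 km cells).
#' @param years Integer vector of survey years.
#' @param intensity_scale Expected groups per km^2 at suitability 1.
#' @param g0 Trackline detection probability used both in simulation truth
#'   and in the estimator.
#' @param sigma_km True half-normal detection scale.
#' @param W_km Truncation distance.
#' @param B Bootstrap replicates.
#' @param alpha Size-bias regression significance level.
#' @param n_background,bg_replicates,splits,d_threshold ESM options.
#' @param seed Global seed; stage seeds are derived from it by fixed
#'   offsets.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(nx = 40, ny = 240, years = 2011L,
                            intensity_scale = 2, g0 = 0.364,
                            sigma_km = 0.12, W_km = 0.3, B = 199,
                            alpha = 0.15, n_background = 1000,
                            bg_replicates = 2, splits = 5,
                            d_threshold = 0.5, seed = 1L) {
  cfg <- list(nx = nx, ny = ny, years = as.integer(years),
              intensity_scale = intensity_scale, g0 = g0,
              sigma_km = sigma_km, W_km = W_km, B = B, alpha = alpha,
              n_background = n_background, bg_replicates = bg_replicates,
              splits = splits, d_threshold = d_threshold,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$g0 <= 0 || cfg$g0 > 1) stop("config invalid: g0 must be in (0, 1]")
  if (cfg$nx < 16 || cfg$ny < 16) stop("config invalid: grid too small")
  if (cfg$sigma_km <= 0 || cfg$W_km <= 0)
    stop("config invalid: sigma and W must be positive")
  if (cfg$B < 2) stop("config invalid: need at least 2 bootstrap replicates")
  if (length(cfg$years) < 1) stop("config invalid: need at least one year")
  invisible(cfg)
}

## deterministic child seeds per stage/year
child_seed <- function(seed, stage, k = 0L) {
  (as.integer(seed) + 1000003L * stage + 97L * as.integer(k)) %%
    .Machine$integer.max
}

#' Run the full simulate -> preprocess -> estimate -> ESM pipeline
#'
#' Generates a synthetic environment and porpoise population per year,
#' simulates the aerial survey, fits the four candidate detection functions
#' and selects by AIC, computes stratified (per-year) and overall density
#' and abundance with the g(0) correction and transect bootstrap, then runs
#' the annual ensemble-of-small-models habitat analysis on the sighting
#' locations and summarizes annual HSI maps into mean and CV maps.
#' Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out Optional output directory; when given, sightings/effort CSVs,
#'   ASCII-grid HSI rasters, the estimate table (TSV) and a JSON-ready
#'   manifest are written there.
#' @return A list of class `run_report`: `estimate_table`, `aic_table`,
#'   `model`, `group_size`, `strata`, `combined`, `esm` (per year),
#'   `contributions`, `cbi`, `hsi_mean`, `hsi_cv`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out = NULL) {
  validate_config(config)
  grid <- grid_spec(config$nx, config$ny)
  truth <- suitability_truth(intensity_scale = config$intensity_scale)
  scenario <- survey_scenario(sigma_km = config$sigma_km, g0 = config$g0,
                              W_km = config$W_km)
  years <- config$years
  sightings <- list(); effort <- list(); envs <- list(); esm <- list()
  areas <- list()
  for (i in seq_along(years)) {
    yr <- years[i]
    env <- make_environment(grid, seed = child_seed(config$seed, 1L, i))
    suit <- true_suitability(env, truth)
    pop <- place_groups(suit, grid, truth$intensity_scale,
                        seed = child_seed(config$seed, 2L, i))
    tr <- make_transects(env, scenario)
    sv <- simulate_survey(pop, tr, scenario,
                          seed = child_seed(config$seed, 3L, i),
                          stratum = as.character(yr), year = yr)
    sv$sightings$transect_id <- paste0(yr, ".", sv$sightings$transect_id)
    sv$effort$transect_id <- paste0(yr, ".", sv$effort$transect_id)
    sightings[[i]] <- sv$sightings
    effort[[i]] <- sv$effort
    envs[[i]] <- env
    areas[[as.character(yr)]] <- sum(env$sea) * grid$cell_size_km^2
  }
  sightings <- do.call(rbind, sightings)
  effort <- do.call(rbind, effort)
  if (nrow(sightings) < 5)
    stop("stage fit-distance failed: too few sightings simulated")

  cand <- fit_candidate_models(sightings$perp_distance_km, W = config$W_km)
  aic_table <- data.frame(
    key = vapply(cand$candidates, `[[`, character(1), "key"),
    adjustment = vapply(cand$candidates, `[[`, character(1), "adjustment"),
    n_params = vapply(cand$candidates, `[[`, numeric(1), "n_params"),
    aic = vapply(cand$candidates, `[[`, numeric(1), "aic")
  )
  # annual strata resurvey the same region: the overall abundance uses the
  # region's area, not the sum over years
  boot <- bootstrap_estimates(sightings, effort, areas, cand$model,
                              B = config$B,
                              seed = child_seed(config$seed, 4L),
                              g0 = config$g0, alpha = config$alpha,
                              total_area = areas[[1]])

  # ESM uses the detected group locations; re-simulate with the same child
  # seeds to recover coordinates (identical realization and thinning)
  esm <- list()
  for (i in seq_along(years)) {
    yr <- years[i]
    env <- envs[[i]]
    suit <- true_suitability(env, truth)
    pop <- place_groups(suit, grid, truth$intensity_scale,
                        seed = child_seed(config$seed, 2L, i))
    tr <- make_transects(env, scenario)
    # detected groups with coordinates, same thinning as simulate_survey
    set.seed(child_seed(config$seed, 3L, i))
    pres <- list()
    for (j in seq_len(nrow(tr))) {
      d <- abs(pop$y - tr$y_km[j])
      in_strip <- d <= scenario$W_km & pop$x >= tr$x_start[j] &
        pop$x <= tr$x_end[j]
      if (!any(in_strip)) next
      dd <- d[in_strip]
      p <- scenario$g0 * true_detect_prob(dd, scenario)
      seen <- stats::runif(length(dd)) < p
      if (any(seen))
        pres[[length(pres) + 1L]] <- cbind(x = pop$x[in_strip][seen],
                                           y = pop$y[in_strip][seen])
    }
    pres <- do.call(rbind, pres)
    if (is.null(pres) || nrow(pres) < 8) {
      warning("year ", yr, ": too few presences for the ESM; skipped")
      next
    }
    esm[[as.character(yr)]] <- run_esm(
      pres, env, n_background = config$n_background,
      replicates = config$bg_replicates, splits = config$splits,
      d_threshold = config$d_threshold,
      seed = child_seed(config$seed, 5L, i))
  }
  contributions <- if (length(esm))
    do.call(rbind, lapply(esm, `[[`, "contributions")) else NULL
  cbi <- if (length(esm)) vapply(esm, `[[`, numeric(1), "cbi") else NULL
  hsi_maps <- lapply(esm, `[[`, "hsi")
  hsi_summary <- if (length(hsi_maps) >= 2) annual_mean_and_cv(hsi_maps)
                 else list(mean = if (length(hsi_maps)) hsi_maps[[1]]
                           else NULL, cv = NULL)

  report <- structure(
    list(estimate_table = estimate_table(boot$strata, boot$combined, effort),
         aic_table = aic_table, model = boot$model,
         group_size = boot$group_size, strata = boot$strata,
         combined = boot$combined, esm = esm,
         contributions = contributions, cbi = cbi,
         hsi_mean = hsi_summary$mean, hsi_cv = hsi_summary$cv,
         config = config, sightings = sightings, effort = effort),
    class = "run_report"
  )
  if (!is.null(out)) write_report(report, envs, out)
  report
}

write_report <- function(report, envs, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_sightings_csv(report$sightings, file.path(out, "sightings.csv"))
  write_effort_csv(report$effort, file.path(out, "effort.csv"))
  utils::write.table(report$estimate_table,
                     file.path(out, "estimates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(report$aic_table, file.path(out, "aic_table.csv"),
                   row.names = FALSE)
  if (!is.null(report$contributions))
    utils::write.csv(report$contributions,
                     file.path(out, "contributions.csv"))
  grid <- envs[[1]]$grid
  for (yr in names(report$esm))
    write_ascii_grid(report$esm[[yr]]$hsi, grid,
                     file.path(out, sprintf("hsi_%s.asc", yr)))
  if (!is.null(report$hsi_mean))
    write_ascii_grid(report$hsi_mean, grid, file.path(out, "hsi_mean.asc"))
  if (!is.null(report$hsi_cv))
    write_ascii_grid(report$hsi_cv, grid, file.path(out, "hsi_cv.asc"))
  invisible(out)
}

#' Parameter-recovery experiment for the distance-sampling estimator
#'
#' Repeats simulate -> estimate on a flat-suitability scenario with known
#' true density and reports the mean relative bias of the density estimate,
#' empirical coverage of the bootstrap CI (when `B > 0`) and the mean
#' relative ESW error. Each replicate pools `visits` independent passes over
#' the same transect design (the multi-year pooling used for a global
#' detection function), so the pooled sample sizes match a multi-year
#' coastal survey.
#'
#' @param n_replicates Number of simulated surveys (>= 10).
#' @param config A [pipeline_config()] (grid, detection and g0 settings are
#'   used; `intensity_scale` here is the uniform group density in groups per
#'   km^2, since the recovery scenario sets suitability to 1 over the sea).
#' @param visits Independent survey passes pooled per replicate (default 5).
#' @param assumed_g0 g(0) used by the estimator (default: the true value in
#'   `config`; set 1 to study the uncorrected bias).
#' @param B Bootstrap replicates per survey for the coverage column (0
#'   disables the bootstrap and reports `NA` coverage).
#' @return A one-row data frame: `n_replicates`, `true_density`,
#'   `mean_density`, `mean_rel_bias`, `coverage`, `mean_esw_rel_error`,
#'   `mean_n_sightings`.
#' @export
recovery_experiment <- function(n_replicates = 200,
                                config = pipeline_config(
                                  ny = 740, intensity_scale = 0.07),
                                visits = 5L, assumed_g0 = config$g0, B = 0) {
  if (n_replicates < 10) stop("need at least 10 replicates")
  validate_config(config)
  grid <- grid_spec(config$nx, config$ny)
  scenario <- survey_scenario(sigma_km = config$sigma_km, g0 = config$g0,
                              W_km = config$W_km)
  env <- make_environment(grid, seed = child_seed(config$seed, 11L),
                          flat_bathymetry = TRUE)
  suit <- env$layers$bathymetry * 0 + 1   # uniform suitability over sea
  lambda <- 0.70
  es_true <- lambda / (1 - exp(-lambda))
  true_D <- config$intensity_scale * es_true   # individuals per km^2
  area <- sum(env$sea) * grid$cell_size_km^2
  tr <- make_transects(env, scenario)
  Dhat <- esw_err <- nsgt <- numeric(n_replicates)
  covered <- rep(NA, n_replicates)
  esw_true <- stats::integrate(function(y) true_detect_prob(y, scenario),
                               0, scenario$W_km)$value
  for (r in seq_len(n_replicates)) {
    svs <- lapply(seq_len(visits), function(v) {
      pop <- place_groups(suit, grid, config$intensity_scale,
                          group_size_lambda = lambda,
                          seed = child_seed(config$seed, 12L, 100L * r + v))
      sv <- simulate_survey(pop, tr, scenario,
                            seed = child_seed(config$seed, 13L,
                                              100L * r + v),
                            stratum = "all")
      sv$sightings$transect_id <- paste0("v", v, ".", sv$sightings$transect_id)
      sv$effort$transect_id <- paste0("v", v, ".", sv$effort$transect_id)
      sv
    })
    sgt <- do.call(rbind, lapply(svs, `[[`, "sightings"))
    eff <- do.call(rbind, lapply(svs, `[[`, "effort"))
    if (nrow(sgt) < 5) { Dhat[r] <- NA; next }
    m <- fit_detection_function(sgt$perp_distance_km,
                                "half-normal", "none", W = scenario$W_km)
    gs <- expected_group_size(sgt, m, alpha = config$alpha)
    L <- sum(eff$length_km)
    est <- estimate_density(sgt, L, area, m, gs, g0 = assumed_g0)
    Dhat[r] <- est$density
    esw_err[r] <- (m$esw - esw_true) / esw_true
    nsgt[r] <- nrow(sgt)
    if (B > 0) {
      bt <- bootstrap_estimates(sgt, eff, list(all = area), m, B = B,
                                seed = child_seed(config$seed, 14L, r),
                                g0 = assumed_g0, alpha = config$alpha)
      covered[r] <- bt$combined$ci_low <= true_D &
        true_D <= bt$combined$ci_high
    }
  }
  ok <- !is.na(Dhat)
  data.frame(
    n_replicates = sum(ok), true_density = true_D,
    mean_density = mean(Dhat[ok]),
    mean_rel_bias = mean(Dhat[ok] / true_D - 1),
    coverage = if (B > 0) mean(covered[ok]) else NA_real_,
    mean_esw_rel_error = mean(abs(esw_err[ok])),
    mean_n_sightings = mean(nsgt[ok])
  )
}

#' Power experiment: does the ESM recover a chlorophyll-driven truth?
#'
#' Generates independent environments whose true suitability rises markedly
#' with chlorophyll-a (with mild negative SST and depth effects), samples
#' presences from populations placed on that truth, runs the full
#' ensemble-of-small-models analysis, and reports how often chlorophyll-a
#' ranks among the top-2 variable contributions.
#'
#' @param n_runs Number of independent seeded runs (default 20).
#' @param n_presence Presences per run (default 80).
#' @param nx,ny Grid size (default 60 x 300 km).
#' @param n_background,replicates,splits ESM sizes per run.
#' @param seed Base seed; run `s` uses fixed offsets from it.
#' @return List with `top2_rate`, `ranks` (chla's contribution rank per
#'   run) and `contributions` (matrix, one row per run).
#' @export
esm_power_experiment <- function(n_runs = 20, n_presence = 80, nx = 60,
                                 ny = 300, n_background = 1000,
                                 replicates = 2, splits = 5, seed = 100L) {
  truth <- suitability_truth(intercept = 0.5, chla = 1.2, sst = -0.2,
                             depth = -0.01, slope = 0, ammonium = 0)
  ranks <- numeric(n_runs)
  contribs <- matrix(NA_real_, n_runs, 5)
  g <- grid_spec(nx, ny)
  for (s in seq_len(n_runs)) {
    env <- make_environment(g, seed = child_seed(seed, 21L, s))
    suit <- true_suitability(env, truth)
    pop <- place_groups(suit, g, 2.0, seed = child_seed(seed, 22L, s))
    set.seed(child_seed(seed, 23L, s))
    idx <- sample(nrow(pop), min(n_presence, nrow(pop)))
    fit <- run_esm(cbind(pop$x[idx], pop$y[idx]), env,
                   n_background = n_background, replicates = replicates,
                   splits = splits, seed = child_seed(seed, 24L, s))
    colnames(contribs) <- names(fit$contributions)
    contribs[s, ] <- fit$contributions
    ranks[s] <- rank(-fit$contributions)[["chla"]]
  }
  list(top2_rate = mean(ranks <= 2), ranks = ranks,
       contributions = contribs)
}
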