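#' Write / read the sightings CSV dialect
#'
#' Columns: `transect_id, stratum, year, perp_distance_m, group_size`
#' (distances stored in metres on disk, km in memory). Optional columns
#' `declination_deg, altitude_m` are converted to distances on read when
#' `perp_distance_m` is absent.
#'
#' @param sightings Data frame with `perp_distance_km`.
#' @param path File path.
#' @export
write_sightings_csv <- function(sightings, path) {
  out <- data.frame(
    transect_id = sightings$transect_id,
    stratum = sightings$stratum,
    year = sightings$year,
    perp_distance_m = sightings$perp_distance_km * 1000,
    group_size = sightings$group_size
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sightings_csv
#' @return `read_sightings_csv`: data frame with `perp_distance_km` (km).
#' @export
read_sightings_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"perp_distance_m" %in% names(d)) {
    if (!all(c("declination_deg", "altitude_m") %in% names(d)))
      stop("need perp_distance_m or declination_deg + altitude_m columns")
    d$perp_distance_m <- distance_from_declination(d$declination_deg,
                                                   d$altitude_m)
  }
  d$perp_distance_km <- d$perp_distance_m / 1000
  d$perp_distance_m <- NULL
  d
}

#' Write / read the effort CSV dialect
#'
#' Columns: `transect_id, stratum, year, length_km`.
#'
#' @param effort Data frame.
#' @param path File path.
#' @export
write_effort_csv <- function(effort, path) {
  utils::write.csv(
    effort[, intersect(c("transect_id", "stratum", "year", "length_km"),
                       names(effort))],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effort_csv
#' @export
read_effort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
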