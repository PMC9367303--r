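#' Terrain slope from a bathymetry layer (Horn's method)
#'
#' 3x3 Horn gradient on the depth layer; slope = `atan(|grad z|)` in degrees.
#' Border cells use replicated edges; `NA` (land) neighbours are replaced by
#' the centre value, and cells that are themselves `NA` stay `NA`.
#'
#' @param bathymetry `ny x nx` depth matrix in metres (`NA` = land).
#' @param cell_size_km Cell edge length in km.
#' @return Slope matrix in degrees.
#' @export
slope_from_bathymetry <- function(bathymetry, cell_size_km = 1) {
  z <- bathymetry
  if (all(is.na(z))) stop("bathymetry layer is all nodata")
  ny <- nrow(z); nx <- ncol(z)
  if (ny < 3 || nx < 3) stop("need at least a 3x3 grid")
  zp <- rbind(z[1, , drop = FALSE], z, z[ny, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nx, drop = FALSE])
  shift <- function(dr, dc) zp[(1 + dr):(ny + dr), (1 + dc):(nx + dc)]
  ctr <- shift(1, 1)
  fill <- function(m) { m[is.na(m)] <- ctr[is.na(m)]; m }
  nw <- fill(shift(0, 0)); n_ <- fill(shift(0, 1)); ne <- fill(shift(0, 2))
  w_ <- fill(shift(1, 0));                          e_ <- fill(shift(1, 2))
  sw <- fill(shift(2, 0)); s_ <- fill(shift(2, 1)); se <- fill(shift(2, 2))
  cell_m <- cell_size_km * 1000
  dzdx <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cell_m)
  dzdy <- ((sw + 2 * s_ + se) - (nw + 2 * n_ + ne)) / (8 * cell_m)
  sl <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  sl[is.na(z)] <- NA_real_
  sl
}

#' Distance to the nearest coast (land cell)
#'
#' Euclidean distance from each sea-cell centre to the nearest land-cell
#' centre; land cells get 0.
#'
#' @param bathymetry Depth matrix with `NA` marking land.
#' @param cell_size_km Cell edge length in km.
#' @return Distance matrix in km.
#' @export
distance_to_coast <- function(bathymetry, cell_size_km = 1) {
  land <- is.na(bathymetry)
  if (!any(land)) stop("no land cells in the layer")
  ny <- nrow(bathymetry); nx <- ncol(bathymetry)
  idx <- which(land)
  lr <- ((idx - 1) %% ny) + 1
  lc <- ((idx - 1) %/% ny) + 1
  out <- matrix(0, ny, nx)
  sea <- which(!land)
  sr <- ((sea - 1) %% ny) + 1
  sc <- ((sea - 1) %/% ny) + 1
  # chunked brute-force nearest-neighbour scan
  chunk <- 2000L
  for (start in seq(1, length(sea), by = chunk)) {
    ii <- start:min(start + chunk - 1L, length(sea))
    d2 <- outer(sr[ii], lr, `-`)^2 + outer(sc[ii], lc, `-`)^2
    out[sea[ii]] <- sqrt(apply(d2, 1, min)) * cell_size_km
  }
  out
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Classic IDW: each target cell takes `sum(w_i v_i)/sum(w_i)` with
#' `w_i = d_i^-power` over the `k` nearest source points; a target within
#' numerical tolerance of a source returns that source value exactly.
#'
#' @param src_xy Two-column matrix of source coordinates (km).
#' @param src_v Source values (one per row of `src_xy`).
#' @param grid Target [grid_spec()].
#' @param power IDW power (default 2).
#' @param k Number of nearest sources used (default 12; capped at the number
#'   of sources).
#' @return `ny x nx` matrix of interpolated values.
#' @export
idw_interpolate <- function(src_xy, src_v, grid, power = 2, k = 12) {
  src_xy <- as.matrix(src_xy)
  if (nrow(src_xy) < 1) stop("need at least one source point")
  stopifnot(length(src_v) == nrow(src_xy))
  k <- min(k, nrow(src_xy))
  tgt <- cell_xy(grid)
  out <- numeric(nrow(tgt))
  chunk <- 2000L
  for (start in seq(1, nrow(tgt), by = chunk)) {
    ii <- start:min(start + chunk - 1L, nrow(tgt))
    d2 <- outer(tgt[ii, 1], src_xy[, 1], `-`)^2 +
      outer(tgt[ii, 2], src_xy[, 2], `-`)^2
    out[ii] <- vapply(seq_along(ii), function(r) {
      d2r <- d2[r, ]
      near <- order(d2r)[seq_len(k)]
      dn <- sqrt(d2r[near])
      if (dn[1] < 1e-9) return(src_v[near[1]])
      w <- dn^(-power)
      sum(w * src_v[near]) / sum(w)
    }, numeric(1))
  }
  matrix(out, grid$ny, grid$nx)
}

#' Screen collinear environmental layers by pairwise Pearson correlation
#'
#' Computes pairwise Pearson correlations over sea cells
#' (pairwise-complete), across all years supplied, and iteratively drops the
#' lower-priority member of the worst-offending pair with `|r|` strictly
#' above the threshold. A variable that fails in any year is dropped
#' everywhere, so the retained set is constant across the study period.
#'
#' @param stacks A named list of layers (matrices), or a list of such lists
#'   (one per year).
#' @param threshold Correlation threshold (default 0.7, strict `>`).
#' @param keep_priority Character vector: earlier names win when a pair
#'   exceeds the threshold. Defaults to the order of the first stack.
#' @return List with `retained` (names), `dropped`, `cor` (list of per-year
#'   correlation matrices over all input layers).
#' @export
correlation_screen <- function(stacks, threshold = 0.7,
                               keep_priority = NULL) {
  if (is.matrix(stacks[[1]])) stacks <- list(stacks)
  nm <- names(stacks[[1]])
  if (length(nm) < 2) stop("need at least 2 layers to screen")
  if (is.null(keep_priority)) keep_priority <- nm
  prio <- match(nm, keep_priority)
  prio[is.na(prio)] <- length(keep_priority) + match(
    nm[is.na(prio)], nm[is.na(prio)])
  cors <- lapply(stacks, function(st) {
    m <- vapply(st, as.vector, numeric(length(st[[1]])))
    stats::cor(m, use = "pairwise.complete.obs")
  })
  retained <- nm
  repeat {
    worst <- NULL; worst_r <- threshold
    for (cm in cors) {
      sub <- cm[retained, retained, drop = FALSE]
      diag(sub) <- 0
      mx <- max(abs(sub))
      if (mx > worst_r) {
        worst_r <- mx
        ij <- which(abs(sub) == mx, arr.ind = TRUE)[1, ]
        worst <- retained[ij]
      }
    }
    if (is.null(worst)) break
    pr <- prio[match(worst, nm)]
    drop <- worst[which.max(pr)]
    retained <- setdiff(retained, drop)
    if (length(retained) == 1) break
  }
  list(retained = retained, dropped = setdiff(nm, retained), cor = cors)
}
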