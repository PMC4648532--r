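#' Lambert azimuthal equal-area projection (km)
#'
#' Projects lat/lon onto an equal-area plane centred at `center`
#' (defaults to the points' centroid). Equal-area projection is required
#' for defensible km2 areas and overlap ratios.
#'
#' @param lat,lon decimal degrees.
#' @param center `c(lat, lon)` projection centre.
#' @param R Earth radius in km (6371).
#' @return data.frame (x, y) in km, with the centre as attribute.
#' @export
project_laea <- function(lat, lon, center = c(mean(lat), mean(lon)), R = 6371) {
  phi <- lat * pi / 180; lam <- lon * pi / 180
  phi1 <- center[1] * pi / 180; lam0 <- center[2] * pi / 180
  denom <- 1 + sin(phi1) * sin(phi) + cos(phi1) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / denom)
  out <- data.frame(x = R * k * cos(phi) * sin(lam - lam0),
                    y = R * k * (cos(phi1) * sin(phi) -
                                 sin(phi1) * cos(phi) * cos(lam - lam0)))
  attr(out, "center") <- center
  out
}

#' Inverse Lambert azimuthal equal-area projection
#' @param x,y planar coordinates in km.
#' @param center `c(lat, lon)` projection centre.
#' @param R Earth radius in km.
#' @return data.frame (lat, lon).
#' @export
unproject_laea <- function(x, y, center, R = 6371) {
  phi1 <- center[1] * pi / 180; lam0 <- center[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- 2 * asin(pmin(1, rho / (2 * R)))
  lat <- ifelse(rho == 0, phi1,
                asin(cos(c_ang) * sin(phi1) + y * sin(c_ang) * cos(phi1) / rho))
  lon <- lam0 + atan2(x * sin(c_ang),
                      rho * cos(phi1) * cos(c_ang) - y * sin(phi1) * sin(c_ang))
  data.frame(lat = lat * 180 / pi, lon = ((lon * 180 / pi + 180) %% 360) - 180)
}

## closed-form least-squares cross-validation score for an isotropic
## bivariate Gaussian kernel: LSCV(h) = int fhat^2 - (2/n) sum fhat_{-i}(x_i)
lscv_score <- function(h, d2) {
  n <- attr(d2, "n")
  t1 <- (1 / (4 * pi * h^2 * n^2)) * (n + 2 * sum(exp(-d2 / (4 * h^2))))
  t2 <- (2 / (n * (n - 1))) * (1 / (2 * pi * h^2)) * 2 * sum(exp(-d2 / (2 * h^2)))
  t1 - t2
}

#' Kernel utilization distribution on a regular grid
#'
#' Projects positions to an equal-area plane, smooths with an isotropic
#' Gaussian kernel and evaluates the density on a square grid
#' (`grid_km` cell size, 50 km default). The bandwidth either minimises
#' the least-squares cross-validation (LSCV) score over 30 log-spaced
#' candidates spanning 0.1-3 times the bivariate Silverman reference
#' bandwidth, or is given numerically. A degenerate LSCV profile
#' (minimum on the candidate boundary) falls back to the reference
#' bandwidth with a warning. Cell masses are normalised to sum to 1.
#'
#' @param points data.frame with `lat`, `lon` (>= 10 rows), or `x`, `y`
#'   in km if `projected = TRUE`.
#' @param grid_km grid cell size in km (50).
#' @param bandwidth "lscv" or a numeric bandwidth in km.
#' @param center optional projection centre `c(lat, lon)`; share one
#'   centre (and `grid_origin`) across UDs that will be overlaid.
#' @param grid_origin optional `c(x0, y0)` km anchoring cell edges so
#'   that independently fitted UDs share cell geometry.
#' @param pad_km padding beyond the point extent (3 bandwidths default).
#' @param projected set TRUE if `points` are already planar km.
#' @return object of class `murrelog_ud`: cell centres `x`, `y`, matrix
#'   `z` (probability mass per cell), `cell_km`, `bandwidth_km`,
#'   `center`, `n`.
#' @export
fit_kernel_ud <- function(points, grid_km = 50, bandwidth = "lscv",
                          center = NULL, grid_origin = c(0, 0),
                          pad_km = NULL, projected = FALSE) {
  if (nrow(points) < 10)
    stop("fit_kernel_ud: need at least 10 points", call. = FALSE)
  if (projected) {
    xy <- points[, c("x", "y")]
    if (is.null(center)) center <- c(NA, NA)
  } else {
    if (is.null(center)) center <- c(mean(points$lat), mean(points$lon))
    xy <- project_laea(points$lat, points$lon, center)
  }
  n <- nrow(xy)
  d2 <- as.numeric(stats::dist(xy))^2
  attr(d2, "n") <- n
  h_ref <- sqrt((stats::var(xy$x) + stats::var(xy$y)) / 2) * n^(-1 / 6)
  if (identical(bandwidth, "lscv")) {
    cand <- exp(seq(log(0.1 * h_ref), log(3 * h_ref), length.out = 30))
    scores <- vapply(cand, lscv_score, numeric(1), d2 = d2)
    k <- which.min(scores)
    if (k == 1 || k == length(cand)) {
      warning("fit_kernel_ud: degenerate LSCV profile; falling back to reference bandwidth")
      h <- h_ref
    } else h <- cand[k]
  } else {
    h <- as.numeric(bandwidth)
    stopifnot(h > 0)
  }
  if (is.null(pad_km)) pad_km <- 3 * h + grid_km
  ## cell edges snapped to the shared origin so overlaid UDs align
  lo_x <- floor((min(xy$x) - pad_km - grid_origin[1]) / grid_km) * grid_km + grid_origin[1]
  hi_x <- ceiling((max(xy$x) + pad_km - grid_origin[1]) / grid_km) * grid_km + grid_origin[1]
  lo_y <- floor((min(xy$y) - pad_km - grid_origin[2]) / grid_km) * grid_km + grid_origin[2]
  hi_y <- ceiling((max(xy$y) + pad_km - grid_origin[2]) / grid_km) * grid_km + grid_origin[2]
  gx <- seq(lo_x + grid_km / 2, hi_x - grid_km / 2, by = grid_km)
  gy <- seq(lo_y + grid_km / 2, hi_y - grid_km / 2, by = grid_km)
  ## density on the grid: separable Gaussian products summed over points
  Ex <- outer(gx, xy$x, function(g, p) exp(-(g - p)^2 / (2 * h^2)))
  Ey <- outer(gy, xy$y, function(g, p) exp(-(g - p)^2 / (2 * h^2)))
  z <- tcrossprod(Ex, Ey) / (2 * pi * h^2 * n)  # sum over points of the product kernel
  mass <- z * grid_km^2
  mass <- mass / sum(mass)
  structure(list(x = gx, y = gy, z = mass, cell_km = grid_km,
                 bandwidth_km = h, center = center, n = n),
            class = "murrelog_ud")
}

#' Core-area contour of a utilization distribution
#'
#' The smallest set of highest-density cells whose cumulative mass
#' reaches `level` (0.5 for the core foraging area), with its area in
#' km2.
#'
#' @param ud a `murrelog_ud`.
#' @param level probability level (0.5).
#' @return object of class `core_area`: `level`, `cells` (data.frame
#'   x, y of included cell centres), `cell_km`, `area_km2`, `center`.
#' @export
core_contour <- function(ud, level = 0.5) {
  stopifnot(inherits(ud, "murrelog_ud"), level > 0, level <= 1)
  m <- as.numeric(ud$z)
  ord <- order(m, decreasing = TRUE)
  cum <- cumsum(m[ord])
  k <- which(cum >= level - 1e-12)[1]
  sel <- ord[seq_len(k)]
  idx <- arrayInd(sel, dim(ud$z))
  core_area(data.frame(x = ud$x[idx[, 1]], y = ud$y[idx[, 2]]),
            cell_km = ud$cell_km, level = level, center = ud$center)
}

#' Construct a core area from cells
#'
#' @param cells data.frame of cell centres (x, y) in km.
#' @param cell_km cell size.
#' @param level probability level the cells represent.
#' @param center projection centre `c(lat, lon)` (may be NA for purely
#'   planar constructions).
#' @return object of class `core_area`.
#' @export
core_area <- function(cells, cell_km, level = 0.5, center = c(NA, NA)) {
  structure(list(level = level, cells = cells, cell_km = cell_km,
                 area_km2 = nrow(cells) * cell_km^2, center = center),
            class = "core_area")
}

#' Directional overlap of two core areas
#'
#' `hr_fm = A(f, m) / A(f)` and `hr_mf = A(f, m) / A(m)` where
#' `A(f, m)` is the intersection area; `mean_overlap` is their mean.
#' Cores must share projection centre and cell geometry.
#'
#' @param core_f,core_m `core_area` objects (female, male).
#' @return list: `hr_fm`, `hr_mf`, `mean_overlap`, `intersection_km2`.
#' @export
overlap_hr <- function(core_f, core_m) {
  stopifnot(inherits(core_f, "core_area"), inherits(core_m, "core_area"))
  if (core_f$area_km2 == 0 || core_m$area_km2 == 0)
    stop("overlap_hr: empty core area", call. = FALSE)
  if (!isTRUE(all.equal(core_f$cell_km, core_m$cell_km)) ||
      (!all(is.na(core_f$center)) &&
       !isTRUE(all.equal(core_f$center, core_m$center))))
    stop("overlap_hr: core areas are not on the same grid/projection", call. = FALSE)
  key <- function(cells) paste(round(cells$x, 6), round(cells$y, 6))
  inter <- length(intersect(key(core_f$cells), key(core_m$cells))) * core_f$cell_km^2
  list(hr_fm = inter / core_f$area_km2,
       hr_mf = inter / core_m$area_km2,
       mean_overlap = (inter / core_f$area_km2 + inter / core_m$area_km2) / 2,
       intersection_km2 = inter)
}

#' Write a core area as GeoJSON
#'
#' Each grid cell becomes a square polygon in lon/lat (inverse
#' equal-area projection), collected in a FeatureCollection.
#'
#' @param core a `core_area` with a valid projection centre.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_core_geojson <- function(core, path) {
  stopifnot(inherits(core, "core_area"))
  if (any(is.na(core$center)))
    stop("write_core_geojson: core has no geographic projection centre", call. = FALSE)
  half <- core$cell_km / 2
  feats <- lapply(seq_len(nrow(core$cells)), function(i) {
    cx <- core$cells$x[i]; cy <- core$cells$y[i]
    corners <- unproject_laea(c(cx - half, cx + half, cx + half, cx - half, cx - half),
                              c(cy - half, cy - half, cy + half, cy + half, cy - half),
                              core$center)
    list(type = "Feature",
         properties = list(level = core$level),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(corners)), function(j)
                           c(corners$lon[j], corners$lat[j])))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
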