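#' Positions classified as resident
#'
#' Joins decoded states back onto positions and keeps those whose Viterbi
#' state is resident. Each step's state is attributed to the position at the
#' step's end day, so the first position of a track carries no state and is
#' excluded.
#'
#' @param tracks Track tibble.
#' @param decoded Decoded step tibble from [decode_states()].
#' @return Tibble of resident positions (`fish_id`, `date`, `lat`, `lon`).
#' @export
resident_points <- function(tracks, decoded) {
  require_cols(tracks, c("fish_id", "date", "lat", "lon"))
  require_cols(decoded, c("fish_id", "date", "state"))
  pts <- tracks |>
    dplyr::inner_join(
      dplyr::select(decoded, "fish_id", "date", "state"),
      by = c("fish_id", "date")) |>
    dplyr::filter(.data$state == "resident") |>
    dplyr::select("fish_id", "date", "lat", "lon")
  if (nrow(pts) == 0) abort("no positions classified as resident")
  pts
}

#' Two-dimensional kernel density of positions
#'
#' Gaussian product-kernel density on a regular longitude/latitude grid.
#' The density is expressed per square kilometre using cos-latitude cell
#' areas and normalised so that density times cell area sums to one over the
#' grid. Bandwidths default to Silverman's rule per axis (in degrees).
#'
#' @param points Tibble with `lon`, `lat`.
#' @param bandwidth Length-2 numeric (lon, lat) bandwidth in degrees, or
#'   `NULL` for Silverman's rule.
#' @param grid_res Grid resolution, degrees.
#' @param pad Margin added around the point cloud, degrees.
#' @return Object of class `residency_grid`: tibble with `lon`, `lat`,
#'   `density` (km^-2) and `cell_area_km2`; grid vectors and bandwidths are
#'   kept as attributes.
#' @export
kde2d_map <- function(points, bandwidth = NULL, grid_res = 0.5, pad = 3) {
  require_cols(points, c("lon", "lat"))
  x <- points$lon; y <- points$lat
  if (length(x) < 2) abort("need at least 2 points")
  if (is.null(bandwidth)) {
    bandwidth <- c(silverman_bw(x), silverman_bw(y))
  }
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 1e-6)) {
    abort("degenerate point cloud for this bandwidth; supply a larger bandwidth")
  }
  gx <- seq(floor(min(x) - pad), ceiling(max(x) + pad), by = grid_res)
  gy <- seq(floor(min(y) - pad), ceiling(max(y) + pad), by = grid_res)
  A <- outer(gx, x, function(g, xi) dnorm(g - xi, sd = bandwidth[1]))
  B <- outer(gy, y, function(g, yi) dnorm(g - yi, sd = bandwidth[2]))
  dens_deg <- (A %*% t(B)) / length(x) # lon x lat, per square degree
  grid <- tidyr::expand_grid(lon = gx, lat = gy)
  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  grid$cell_area_km2 <- grid_res^2 * km_per_deg^2 * cos(grid$lat * pi / 180)
  # expand_grid varies lat fastest within lon, matching column-major
  # vectorisation of the lat x lon transpose
  grid$density <- as.vector(t(dens_deg))
  grid$density <- grid$density / (km_per_deg^2 * cos(grid$lat * pi / 180))
  total <- sum(grid$density * grid$cell_area_km2)
  grid$density <- grid$density / total
  structure(grid,
            class = c("residency_grid", class(grid)),
            lon_grid = gx, lat_grid = gy, grid_res = grid_res,
            bandwidth = bandwidth, n_points = length(x))
}

silverman_bw <- function(v) {
  n <- length(v)
  s <- min(sd(v), IQR(v) / 1.34)
  if (!is.finite(s) || s == 0) s <- sd(v)
  1.06 * s * n^(-1 / 5)
}

#' Extract contiguous high-density residency regions
#'
#' Thresholds the density grid at a quantile of its positive cell densities
#' and collects the cells above the threshold into 8-neighbour connected
#' components, ranked by the probability mass they contain.
#'
#' @param grid A `residency_grid` from [kde2d_map()].
#' @param quantile Density quantile in (0, 1) defining the threshold.
#' @return Tibble with one row per region: `region` (rank label), `n_cells`,
#'   `mass` (contained probability), `area_km2`, `centroid_lon`,
#'   `centroid_lat`, and a list-column `cells` of member cells.
#' @export
extract_regions <- function(grid, quantile = 0.75) {
  stopifnot(inherits(grid, "residency_grid"))
  if (quantile <= 0 || quantile >= 1) abort("quantile must be in (0, 1)")
  gx <- attr(grid, "lon_grid"); gy <- attr(grid, "lat_grid")
  nlon <- length(gx); nlat <- length(gy)
  # rebuild the lon x lat matrix (rows lon, cols lat; lat varies fastest)
  dens <- matrix(grid$density, nrow = nlat, ncol = nlon)
  area <- matrix(grid$cell_area_km2, nrow = nlat, ncol = nlon)
  thr <- stats::quantile(grid$density[grid$density > 0], quantile)
  above <- dens > thr
  labels <- matrix(0L, nlat, nlon)
  nxt <- 0L
  for (j in seq_len(nlon)) {
    for (i in seq_len(nlat)) {
      if (above[i, j] && labels[i, j] == 0L) {
        nxt <- nxt + 1L
        labels <- flood_fill(above, labels, i, j, nxt)
      }
    }
  }
  if (nxt == 0L) return(tibble::tibble(
    region = character(), n_cells = integer(), mass = numeric(),
    area_km2 = numeric(), centroid_lon = numeric(), centroid_lat = numeric(),
    cells = list()))
  regions <- purrr::map(seq_len(nxt), function(k) {
    idx <- which(labels == k, arr.ind = TRUE)
    lon_k <- gx[idx[, 2]]; lat_k <- gy[idx[, 1]]
    d_k <- dens[idx]; a_k <- area[idx]
    m <- d_k * a_k
    tibble::tibble(
      n_cells = nrow(idx),
      mass = sum(m),
      area_km2 = sum(a_k),
      centroid_lon = sum(lon_k * m) / sum(m),
      centroid_lat = sum(lat_k * m) / sum(m),
      cells = list(tibble::tibble(lon = lon_k, lat = lat_k, density = d_k)))
  }) |> purrr::list_rbind()
  regions <- regions[order(-regions$mass), , drop = FALSE]
  regions$region <- paste0("R", seq_len(nrow(regions)))
  dplyr::select(regions, "region", dplyr::everything())
}

# iterative 8-neighbour flood fill
flood_fill <- function(above, labels, i0, j0, lab) {
  nr <- nrow(above); nc <- ncol(above)
  stack <- matrix(c(i0, j0), ncol = 2)
  labels[i0, j0] <- lab
  while (nrow(stack) > 0) {
    i <- stack[1, 1]; j <- stack[1, 2]
    stack <- stack[-1, , drop = FALSE]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          above[ii, jj] && labels[ii, jj] == 0L) {
        labels[ii, jj] <- lab
        stack <- rbind(stack, c(ii, jj))
      }
    }
  }
  labels
}
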