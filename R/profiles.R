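#' Construct a gridded temperature climatology
#'
#' A regular longitude/latitude grid with discrete depth layers, emulating a
#' pre-averaged ocean climatology. Cells may be masked (NA = land / no
#' data); masked cells are never returned as data.
#'
#' @param lon_edges,lat_edges Strictly increasing numeric vectors of cell
#'   edges (degrees). A grid with `k` edges has `k - 1` cells on that axis.
#' @param depths Strictly increasing non-negative depth layers (m).
#' @param temperature Numeric array of dim
#'   `c(length(lon_edges)-1, length(lat_edges)-1, length(depths))` (deg C);
#'   `NA` marks masked cells.
#' @return An object of class `temperature_grid`.
#' @export
temperature_grid <- function(lon_edges, lat_edges, depths, temperature) {
  stopifnot(all(diff(lon_edges) > 0), all(diff(lat_edges) > 0),
            all(diff(depths) > 0) || length(depths) == 1L, all(depths >= 0))
  dims <- c(length(lon_edges) - 1L, length(lat_edges) - 1L, length(depths))
  temperature <- array(temperature, dim = dims)
  structure(list(lon_edges = lon_edges, lat_edges = lat_edges,
                 depths = depths, temperature = temperature),
            class = "temperature_grid")
}

#' Read a long-format temperature grid from TSV
#'
#' Expects columns `lon`, `lat`, `depth`, `temp` where `lon`/`lat` are cell
#' centers on a regular grid. Cell edges are inferred as centers +/- half
#' the grid spacing. Missing (lon, lat, depth) combinations become masked
#' cells.
#'
#' @param path TSV path.
#' @return A `temperature_grid`.
#' @export
read_temperature_grid <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lon", "lat", "depth", "temp") %in% names(d)))
  lons <- sort(unique(d$lon))
  lats <- sort(unique(d$lat))
  deps <- sort(unique(d$depth))
  spacing <- function(x) {
    if (length(x) < 2L) return(1)
    dx <- unique(round(diff(x), 9))
    if (length(dx) > 1L) stop("grid centers are not regularly spaced")
    dx
  }
  dlon <- spacing(lons); dlat <- spacing(lats)
  arr <- array(NA_real_, dim = c(length(lons), length(lats), length(deps)))
  i <- match(d$lon, lons); j <- match(d$lat, lats); k <- match(d$depth, deps)
  arr[cbind(i, j, k)] <- d$temp
  temperature_grid(c(lons - dlon / 2, lons[length(lons)] + dlon / 2),
                   c(lats - dlat / 2, lats[length(lats)] + dlat / 2),
                   deps, arr)
}

#' Look up habitat temperature for occurrence coordinates
#'
#' Each record is assigned to the grid cell whose half-open interval
#' `[edge, next_edge)` contains its longitude and latitude, at the nearest
#' depth layer at or above the record depth (the shallower side; records
#' shallower than the first layer use the first layer). Masked cells return
#' `NA`.
#'
#' @param grid A `temperature_grid`.
#' @param lon,lat,depth Numeric vectors (degrees, degrees, metres),
#'   recycled to a common length.
#' @return Numeric vector of temperatures (deg C), `NA` where masked.
#' @export
lookup_temperature <- function(grid, lon, lat, depth) {
  stopifnot(inherits(grid, "temperature_grid"))
  n <- max(length(lon), length(lat), length(depth))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); depth <- rep_len(depth, n)
  if (any(lon < -180 | lon > 180)) stop("longitude out of [-180, 180]")
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  if (any(depth < 0)) stop("depth must be >= 0")
  i <- findInterval(lon, grid$lon_edges)
  j <- findInterval(lat, grid$lat_edges)
  ncell_lon <- length(grid$lon_edges) - 1L
  ncell_lat <- length(grid$lat_edges) - 1L
  out_of_grid <- i < 1L | i > ncell_lon | j < 1L | j > ncell_lat
  if (any(out_of_grid)) stop("coordinates outside the grid extent")
  # shallowest layer is the floor for near-surface records
  k <- findInterval(depth, grid$depths)
  k[k < 1L] <- 1L
  grid$temperature[cbind(i, j, k)]
}

#' Summarize one species' habitat-temperature records
#'
#' Thermal limits are the 1st (`t01`) and 99th (`t99`) percentiles of the
#' habitat-temperature records, computed by linear interpolation between
#' order statistics; `sd` uses the n-1 denominator.
#'
#' @param temps Numeric vector of habitat temperatures (deg C); `NA`s are
#'   dropped.
#' @param species_id Optional identifier carried into the result.
#' @return One-row data.frame: `species_id`, `mean_temp`, `sd_temp`, `t01`,
#'   `t99`, `n_records`.
#' @export
summarize_species <- function(temps, species_id = NA_character_) {
  temps <- temps[!is.na(temps)]
  if (!length(temps)) stop("no non-missing temperature records")
  q <- unname(stats::quantile(temps, c(0.01, 0.99), type = 7))
  data.frame(species_id = species_id,
             mean_temp = mean(temps),
             sd_temp = if (length(temps) > 1L) stats::sd(temps) else 0,
             t01 = q[1], t99 = q[2],
             n_records = length(temps),
             stringsAsFactors = FALSE)
}

#' Per-species habitat-temperature profiles
#'
#' @param records data.frame with columns `species_id` and `temperature`
#'   (deg C); rows with missing temperature are dropped per species, and
#'   species with no usable records are excluded with a warning.
#' @return data.frame of [summarize_species] rows, one per retained
#'   species, ordered by `species_id`.
#' @export
species_thermal_profiles <- function(records) {
  stopifnot(all(c("species_id", "temperature") %in% names(records)))
  ids <- sort(unique(as.character(records$species_id)))
  rows <- list()
  dropped <- character(0)
  for (id in ids) {
    temps <- records$temperature[records$species_id == id]
    temps <- temps[!is.na(temps)]
    if (!length(temps)) {
      dropped <- c(dropped, id)
      next
    }
    rows[[id]] <- summarize_species(temps, id)
  }
  if (length(dropped)) {
    warning("species excluded (all records missing): ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
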