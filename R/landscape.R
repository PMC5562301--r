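#' Read an ESRI ASCII grid
#'
#' Parses the plain-text raster dialect used by most landscape-genetics
#' simulators: a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by `nrows` whitespace-separated rows,
#' stored from the north-west corner.
#'
#' @param path Path to a `.asc` file, or a character vector of its lines.
#' @return A list with `values` (an `nrows x ncols` numeric matrix, row 1 =
#'   northernmost row, `NODATA` cells as `NA`), and the georeference fields
#'   `xllcorner`, `yllcorner`, `cellsize`, `nodata`.
#' @seealso [write_ascii_grid()] for the inverse operation.
#' @export
load_ascii_grid <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 7L)
    stop("ASCII grid: fewer than 7 non-empty lines")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop(sprintf("ASCII grid: malformed header line %d: '%s'", i, lines[i]))
    key <- tolower(parts[1])
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val))
      stop(sprintf("ASCII grid: non-numeric value on header line %d: '%s'", i, lines[i]))
    hdr[[key]] <- val
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("ASCII grid: header missing field(s): ", paste(miss, collapse = ", "))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  if (length(body) != nr)
    stop(sprintf("ASCII grid: expected %d data rows, found %d", nr, length(body)))
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != nc)
      stop(sprintf("ASCII grid: data line %d has %d values, expected %d",
                   r + 6L, length(row), nc))
    if (anyNA(row))
      stop(sprintf("ASCII grid: non-numeric value on data line %d", r + 6L))
    vals[r, ] <- row
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  list(values = vals, xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [load_ascii_grid()]; `NA` cells are written as the `nodata`
#' sentinel. Integer-valued grids round-trip bit-exactly.
#'
#' @param grid List as returned by [load_ascii_grid()].
#' @param path Output path; if `NULL`, the lines are returned invisibly.
#' @export
write_ascii_grid <- function(grid, path = NULL) {
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  fmt <- function(x) sub("\\.0+$", "", format(x, scientific = FALSE, trim = TRUE))
  hdr <- c(
    paste("ncols", ncol(grid$values)),
    paste("nrows", nrow(grid$values)),
    paste("xllcorner", fmt(grid$xllcorner)),
    paste("yllcorner", fmt(grid$yllcorner)),
    paste("cellsize", fmt(grid$cellsize)),
    paste("NODATA_value", fmt(grid$nodata))
  )
  body <- apply(v, 1L, function(r) paste(fmt(r), collapse = " "))
  out <- c(hdr, body)
  if (!is.null(path)) writeLines(out, path) else invisible(out)
}

#' Assemble a landscape grid
#'
#' Combines an elevation raster and a habitability mask into the georeferenced
#' landscape object used by the forward and backward simulators. Habitable
#' cells are split into three latitudinal carrying-capacity zones (NORTH,
#' CENTRAL, SOUTH) delimited by two boundary latitudes; a cell belongs to the
#' zone containing its centre latitude.
#'
#' @param elevation `nrows x ncols` matrix of elevation (m ASL), row 1 north;
#'   or a list from [load_ascii_grid()] (its georeference is then used).
#' @param habitable Logical matrix of the same shape (`NA` in `elevation`
#'   also masks a cell), or `NULL` to take all non-`NA` cells as habitable.
#' @param zone_lats Two latitudes (decimal degrees), the North/Central and
#'   Central/South boundaries, in any order.
#' @param georef List with `xllcorner`, `yllcorner`, `cellsize` (degrees).
#' @param cell_area Cell area in km^2 (default 1.73).
#' @return A `landscape_grid` object: matrices `elevation`, `habitable`,
#'   `zone` (factor levels NORTH/CENTRAL/SOUTH, `NA` off-habitat), vectors of
#'   per-cell centre `lat`/`lon`, and the georeference.
#' @export
build_landscape <- function(elevation, habitable = NULL, zone_lats,
                            georef = NULL, cell_area = 1.73) {
  if (is.list(elevation) && !is.null(elevation$values)) {
    if (is.null(georef))
      georef <- elevation[c("xllcorner", "yllcorner", "cellsize")]
    elevation <- elevation$values
  }
  if (is.null(georef))
    georef <- list(xllcorner = 0, yllcorner = 0, cellsize = 0.01)
  stopifnot(is.matrix(elevation), length(zone_lats) == 2L)
  if (zone_lats[1] == zone_lats[2]) stop("zone boundary latitudes must differ")
  zone_lats <- sort(as.numeric(zone_lats))
  if (is.list(habitable) && !is.null(habitable$values)) habitable <- habitable$values
  if (is.null(habitable)) habitable <- !is.na(elevation)
  if (!is.logical(habitable)) habitable <- !is.na(habitable) & habitable != 0
  habitable <- habitable & !is.na(elevation)
  nr <- nrow(elevation); nc <- ncol(elevation)
  stopifnot(nrow(habitable) == nr, ncol(habitable) == nc)
  if (any(elevation[habitable] < 0, na.rm = TRUE))
    stop("habitable cells must have non-negative elevation")

  # cell-centre coordinates; row 1 is the northern edge of the raster
  cs <- georef$cellsize
  lon_c <- georef$xllcorner + (seq_len(nc) - 0.5) * cs
  lat_c <- georef$yllcorner + (nr - seq_len(nr) + 0.5) * cs
  lat_m <- matrix(lat_c, nr, nc, byrow = FALSE)
  lon_m <- matrix(lon_c, nr, nc, byrow = TRUE)

  zone <- matrix(NA_character_, nr, nc)
  zone[habitable & lat_m > zone_lats[2]] <- "NORTH"
  zone[habitable & lat_m <= zone_lats[2] & lat_m > zone_lats[1]] <- "CENTRAL"
  zone[habitable & lat_m <= zone_lats[1]] <- "SOUTH"
  counts <- table(factor(zone, levels = c("NORTH", "CENTRAL", "SOUTH")))
  empty <- names(counts)[counts == 0]
  if (length(empty) && any(habitable))
    warning("zone(s) with no habitable cell: ", paste(empty, collapse = ", "))

  structure(
    list(n_rows = nr, n_cols = nc, cell_area = cell_area,
         elevation = elevation, habitable = habitable,
         zone = zone, zone_lats = zone_lats,
         lat = lat_m, lon = lon_m, georef = georef),
    class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("landscape_grid: %d x %d cells (%.2f km^2 each), %d habitable\n",
              x$n_rows, x$n_cols, x$cell_area, sum(x$habitable)))
  print(zone_counts(x))
  invisible(x)
}

#' Habitable-cell counts per latitudinal zone
#' @param grid A `landscape_grid`.
#' @return Named integer vector over NORTH, CENTRAL, SOUTH.
#' @export
zone_counts <- function(grid) {
  tab <- table(factor(grid$zone[grid$habitable],
                      levels = c("NORTH", "CENTRAL", "SOUTH")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Elevation-friction parameters
#'
#' Governs how terrain shapes migrant flow between adjacent demes. Suitability
#' of a destination cell declines logistically with its elevation,
#' `s(e) = 1 / (1 + exp(steepness * (e - e_thresh)))`, and an exponential
#' directional bias `exp(beta_up * (e_j - e_i) / 100)` favours moves towards
#' higher ground. With `beta_up = log(36)/2`, an allele is 36-fold less likely
#' to flow 100 m downhill than 100 m uphill.
#'
#' @param e_thresh Elevation (m ASL) above which suitability declines
#'   (default 600).
#' @param steepness Logistic scale of the decline, per metre (> 0).
#' @param beta_up Log-odds increment per +100 m elevation difference.
#' @return A `friction_params` list.
#' @export
friction_params <- function(e_thresh = 600, steepness = 0.01,
                            beta_up = log(36) / 2) {
  stopifnot(e_thresh >= 0, steepness > 0)
  structure(list(e_thresh = e_thresh, steepness = steepness,
                 beta_up = beta_up), class = "friction_params")
}

# Row/col offsets of the four cardinal neighbours, in N, E, S, W order.
.cardinal <- cbind(dr = c(-1L, 0L, 1L, 0L), dc = c(0L, 1L, 0L, -1L))

#' Migration weights towards the four cardinal neighbours
#'
#' Splits a focal deme's emigrant pool over its cardinal neighbours in
#' proportion to destination suitability times the uphill bias (see
#' [friction_params()]); non-habitable or off-grid neighbours get weight 0 and
#' the rest renormalize (reflecting boundary). If no habitable neighbour
#' exists all four weights are 0.
#'
#' @param grid A `landscape_grid`.
#' @param cell Integer `c(row, col)` of a habitable focal cell.
#' @param friction A `friction_params` object.
#' @return Numeric length-4 vector of weights in N, E, S, W order.
#' @export
migration_weights <- function(grid, cell, friction = friction_params()) {
  r <- cell[1]; c <- cell[2]
  if (!grid$habitable[r, c]) stop("focal cell is not habitable")
  e_i <- grid$elevation[r, c]
  w <- numeric(4)
  for (k in 1:4) {
    rr <- r + .cardinal[k, 1]; cc <- c + .cardinal[k, 2]
    if (rr < 1 || rr > grid$n_rows || cc < 1 || cc > grid$n_cols) next
    if (!grid$habitable[rr, cc]) next
    e_j <- grid$elevation[rr, cc]
    s <- 1 / (1 + exp(friction$steepness * (e_j - friction$e_thresh)))
    w[k] <- s * exp(friction$beta_up * (e_j - e_i) / 100)
  }
  tot <- sum(w)
  if (tot > 0) w / tot else w
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6,371 km.
#'
#' @param a,b Coordinates `c(lat, lon)` in decimal degrees.
#' @return Distance in kilometres.
#' @export
great_circle_km <- function(a, b) {
  chk <- rbind(a, b)
  if (any(abs(chk[, 1]) > 90) || any(abs(chk[, 2]) > 180))
    stop("coordinates out of range: latitude in [-90,90], longitude in [-180,180]")
  # geosphere expects (lon, lat) and returns metres
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]), r = 6371000) / 1000
}

# Vectorized haversine (km) between paired (lat, lon) matrices; internal.
.gc_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000) / 1000
}

# Linear (column-major) indices of habitable cells and a cells x 4 neighbour
# index table (NA where off-grid); internal plumbing shared by the simulators.
.neighbour_table <- function(grid) {
  nr <- grid$n_rows; nc <- grid$n_cols
  idx <- matrix(seq_len(nr * nc), nr, nc)
  nb <- matrix(NA_integer_, nr * nc, 4)
  # N, E, S, W
  nb[idx[-1, ], 1] <- idx[-nr, ]
  nb[idx[, -nc], 2] <- idx[, -1]
  nb[idx[-nr, ], 3] <- idx[-1, ]
  nb[idx[, -1], 4] <- idx[, -nc]
  hab <- as.vector(grid$habitable)
  nb[!is.na(nb) & !hab[ifelse(is.na(nb), 1L, nb)]] <- NA_integer_
  nb
}

# Per-cell 4-column migration weight matrix for all habitable cells; rows of
# non-habitable cells are zero. Vectorized version of migration_weights().
.weight_matrix <- function(grid, friction) {
  nb <- .neighbour_table(grid)
  elev <- as.vector(grid$elevation)
  hab <- as.vector(grid$habitable)
  W <- matrix(0, length(hab), 4)
  for (k in 1:4) {
    ok <- hab & !is.na(nb[, k])
    e_j <- elev[nb[ok, k]]
    s <- 1 / (1 + exp(friction$steepness * (e_j - friction$e_thresh)))
    W[ok, k] <- s * exp(friction$beta_up * (e_j - elev[ok]) / 100)
  }
  tot <- rowSums(W)
  pos <- tot > 0
  W[pos, ] <- W[pos, , drop = FALSE] / tot[pos]
  W
}
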