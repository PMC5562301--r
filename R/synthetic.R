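#' Generate a synthetic island landscape
#'
#' Procedurally builds an elongated island inside a sea border: an
#' elliptical habitable mask whose major axis runs diagonally (northwest to
#' southeast), a central mountain ridge along that axis with smooth
#' low-frequency noise, and `n_valleys` transverse low-elevation cuts. The
#' valley centre latitudes become the landscape's zone boundary latitudes,
#' so `n_valleys = 2` yields three non-empty latitudinal
#' carrying-capacity zones. Deterministic given the seed.
#'
#' @param n_rows,n_cols Grid dimensions (at least 10 x 20).
#' @param ridge_height Approximate maximum elevation in m ASL (default
#'   1,630).
#' @param n_valleys Number of transverse valleys (default 2).
#' @param seed Integer seed for the noise field.
#' @param georef Georeference; default places the island near 21.5 S,
#'   165.5 E with cells of about 1.3 km.
#' @param cell_area Cell area in km^2 (default 1.73).
#' @return A `landscape_grid` with attribute `valley_lats`.
#' @export
make_synthetic_landscape <- function(n_rows = 40, n_cols = 80,
                                     ridge_height = 1630, n_valleys = 2,
                                     seed = 1,
                                     georef = list(xllcorner = 165.0,
                                                   yllcorner = -22.0,
                                                   cellsize = 0.012),
                                     cell_area = 1.73) {
  stopifnot(n_rows >= 10, n_cols >= 20, n_valleys >= 0)
  set.seed(seed)
  rr <- matrix(seq_len(n_rows), n_rows, n_cols)
  cc <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  r0 <- (n_rows + 1) / 2; c0 <- (n_cols + 1) / 2
  # major axis from (row 1, col 1) towards (row n, col n): NW -> SE
  ax <- c(n_rows, n_cols) / sqrt(n_rows^2 + n_cols^2)
  u <- (rr - r0) * ax[1] + (cc - c0) * ax[2]        # along-axis
  v <- -(rr - r0) * ax[2] + (cc - c0) * ax[1]       # across-axis
  a <- 0.46 * sqrt(n_rows^2 + n_cols^2)
  b <- 0.34 * min(n_rows, n_cols)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  # ridge along the major axis, tapering towards the island tips
  elev <- ridge_height * exp(-(v / (0.45 * b))^2) *
    sqrt(pmax(0, 1 - (u / a)^2))
  # smooth noise: a handful of random long-wavelength sinusoids
  for (h in 1:4) {
    kx <- stats::runif(1, 0.5, 2.5) * pi / n_rows
    ky <- stats::runif(1, 0.5, 2.5) * pi / n_cols
    ph <- stats::runif(2, 0, 2 * pi)
    elev <- elev + 0.06 * ridge_height *
      sin(kx * rr + ph[1]) * sin(ky * cc + ph[2])
  }
  valley_u <- if (n_valleys > 0)
    -a + (seq_len(n_valleys)) * (2 * a / (n_valleys + 1)) else numeric(0)
  for (uk in valley_u)
    elev <- elev * (1 - 0.92 * exp(-((u - uk) / (0.05 * 2 * a))^2))
  elev <- pmax(elev, 0)
  elev[!inside] <- NA
  # valley centre latitude: where the valley cut crosses the major axis
  lat_of <- function(row) georef$yllcorner + (n_rows - row + 0.5) * georef$cellsize
  valley_rows <- r0 + valley_u * ax[1]
  valley_lats <- sort(lat_of(valley_rows))
  zone_lats <- if (length(valley_lats) >= 2)
    valley_lats[c(1, length(valley_lats))]
  else {  # degenerate: split the island's latitude span evenly
    lats <- lat_of(rr)[inside]
    stats::quantile(lats, c(1 / 3, 2 / 3), names = FALSE)
  }
  grid <- build_landscape(elev, habitable = inside, zone_lats = zone_lats,
                          georef = georef, cell_area = cell_area)
  attr(grid, "valley_lats") <- valley_lats
  grid
}

#' Default sampling design scattered along the island axis
#'
#' Places `n_sites` sites on habitable pixels spread along the island's long
#' axis (preferring mid-elevation pixels, which expansions reach first) and
#' splits `individuals_total` as evenly as possible.
#'
#' @param grid A `landscape_grid`.
#' @param n_sites Number of sampling sites (default 11).
#' @param individuals_total Total diploid individuals (default 222).
#' @param n_loci Microsatellite loci (default 10).
#' @param seed Integer seed (site jitter).
#' @return A [sample_design()].
#' @export
default_sampling_design <- function(grid, n_sites = 11,
                                    individuals_total = 222, n_loci = 10,
                                    seed = 1) {
  stopifnot(n_sites >= 1, individuals_total >= n_sites)
  set.seed(seed)
  hab <- which(grid$habitable)
  lat <- as.vector(grid$lat)[hab]
  lon <- as.vector(grid$lon)[hab]
  elev <- as.vector(grid$elevation)[hab]
  # order habitable pixels along the long axis (latitude + longitude mix)
  ax <- (lat - min(lat)) / max(1e-9, diff(range(lat))) +
    (lon - min(lon)) / max(1e-9, diff(range(lon)))
  qs <- stats::quantile(ax, probs = (seq_len(n_sites) - 0.5) / n_sites,
                        names = FALSE)
  cells <- integer(n_sites)
  emid <- stats::median(elev)
  for (s in seq_len(n_sites)) {
    cand <- order(abs(ax - qs[s]))[1:min(25, length(ax))]
    # among the nearest pixels along the axis, prefer mid-elevation ones
    pick <- cand[order(abs(elev[cand] - emid))[1:min(5, length(cand))]]
    cells[s] <- sample(pick, 1)
  }
  base <- individuals_total %/% n_sites
  n_ind <- rep(base, n_sites)
  extra <- individuals_total - base * n_sites
  if (extra > 0) n_ind[seq_len(extra)] <- n_ind[seq_len(extra)] + 1L
  sample_design(data.frame(name = sprintf("S%02d", seq_len(n_sites)),
                           lat = lat[cells], lon = lon[cells],
                           n_ind = n_ind),
                n_loci = n_loci)
}

#' Pseudo-observed microsatellite dataset with recorded truth
#'
#' Wraps [simulate_microsat_dataset()]; the returned truth record (the full
#' parameter object and the seed) regenerates the dataset bit-exactly.
#'
#' @param grid A `landscape_grid`.
#' @param params_or_prior A [spatial_params()] object, or a [prior_spec()]
#'   from which one parameter vector is drawn.
#' @param design A [sample_design()].
#' @param seed Integer seed.
#' @param base_params Base [spatial_params()], required when a prior is
#'   supplied.
#' @return List `dataset` (a `microsat_dataset`) and `truth`
#'   (`list(params, seed)`).
#' @export
make_pseudo_observed_microsat <- function(grid, params_or_prior, design,
                                          seed = 1, base_params = NULL) {
  if (inherits(params_or_prior, "prior_spec")) {
    stopifnot(!is.null(base_params))
    draw <- draw_priors(params_or_prior, grid, 1, seed = seed)
    params <- .params_from_draw(base_params, draw, grid)
  } else {
    params <- params_or_prior
  }
  ds <- simulate_microsat_dataset(grid, params, design, seed = seed)
  list(dataset = ds, truth = list(params = params, seed = seed))
}

#' Pseudo-observed SFS with recorded truth
#'
#' Wraps [simulate_sfs()] and records the generating scenario parameters
#' and seed.
#'
#' @param spec A [scenario_spec()].
#' @param params Named parameter vector (default the scenario's point
#'   values).
#' @param n_sequences Independent sequences to simulate.
#' @param seed Integer seed.
#' @param seq_length Sequence length in bp (default 300).
#' @return List `sfs` (folded `sfs2d`) and `truth` (`list(params, seed)`).
#' @export
make_pseudo_observed_sfs <- function(spec, params = NULL, n_sequences = 1000,
                                     seed = 1, seq_length = 300) {
  if (is.null(params)) params <- spec$defaults
  sfs <- simulate_sfs(spec, params, n_sequences, seq_length, seed = seed,
                      fold = TRUE)
  list(sfs = sfs, truth = list(params = params, seed = seed,
                               n_sequences = n_sequences,
                               seq_length = seq_length))
}
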