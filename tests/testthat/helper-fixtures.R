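# Shared in-code fixtures; everything is generated, nothing is stored.

# Flat rectangular landscape, fully habitable, uniform elevation.
flat_grid <- function(n_rows = 10, n_cols = 10, elev = 100,
                      cellsize = 0.01, yll = -22, xll = 165,
                      zone_lats = NULL) {
  if (is.null(zone_lats)) {
    lat_top <- yll + n_rows * cellsize
    zone_lats <- yll + c(0.34, 0.67) * (lat_top - yll)
  }
  suppressWarnings(build_landscape(
    matrix(elev, n_rows, n_cols), zone_lats = zone_lats,
    georef = list(xllcorner = xll, yllcorner = yll, cellsize = cellsize)))
}

# Hand-built demographic database: constant deme sizes, chosen emigrant
# counts (zero by default), bypassing the forward simulator so backward
# operations can be tested against closed forms.
const_db <- function(N0, t_exp, n_rows = 1, n_cols = 1,
                     anc_north = N0, anc_south = N0, t_div = t_exp + 100,
                     E = NULL) {
  ncell <- n_rows * n_cols
  structure(list(
    N = matrix(N0, t_exp + 1, ncell),
    E = if (is.null(E)) array(0, c(t_exp, ncell, 4)) else E,
    n_rows = n_rows, n_cols = n_cols,
    params = list(anc_north = anc_north, anc_south = anc_south,
                  t_exp = as.integer(t_exp), t_div = as.integer(t_div),
                  origin_north = c(1L, 1L),
                  origin_south = c(n_rows, n_cols)),
    mode = "deterministic"), class = "demographic_db")
}

# Single-site design on a given grid cell.
site_design <- function(grid, row, col, n_ind, n_loci = 1, name = "A") {
  sample_design(data.frame(name = name,
                           lat = grid$lat[row, col],
                           lon = grid$lon[row, col],
                           n_ind = n_ind),
                n_loci = n_loci)
}

# Two-leaf genealogy with divergence time t (leaves in one deme).
pair_genealogy <- function(t) {
  structure(list(parent = c(2L, 2L, -1L), time = c(0, 0, t),
                 deme = c(0L, 0L, -1L), n_leaves = 2L,
                 leaf_pop = c(1L, 1L)), class = "genealogy")
}

# Small diploid microsatellite dataset from an explicit genotype list:
# geno[[pop]][[ind]] is a matrix loci x 2 of repeat counts.
manual_dataset <- function(geno) {
  pops <- names(geno)
  n_ind <- sum(lengths(geno))
  n_loci <- nrow(geno[[1]][[1]])
  alleles <- array(NA_integer_, c(n_ind, n_loci, 2))
  pop <- character(n_ind)
  i <- 0L
  for (p in pops) for (ind in geno[[p]]) {
    i <- i + 1L
    alleles[i, , ] <- ind
    pop[i] <- p
  }
  structure(list(alleles = alleles, pop = factor(pop, levels = pops),
                 sites = NULL, valid = TRUE), class = "microsat_dataset")
}

# Small demo landscape + truth parameters used by several ABC tests.
demo_world <- function(seed = 5) {
  g <- make_synthetic_landscape(12, 24, seed = seed,
         georef = list(xllcorner = 165, yllcorner = -22, cellsize = 0.03))
  hab <- which(g$habitable, arr.ind = TRUE)
  latv <- g$lat[g$habitable]
  on <- hab[which.max(latv), ]
  os <- hab[which.min(latv), ]
  base <- spatial_params(origin_north = on, origin_south = os,
                         k_north = 120, k_central = 120, k_south = 40,
                         anc_north = 800, anc_south = 300,
                         r = 3, m = 0.15, mu = 5e-4, p_gsm = 0.3,
                         t_exp = 100, t_div = 240, grid = g)
  des <- default_sampling_design(g, n_sites = 8, individuals_total = 64,
                                 n_loci = 10, seed = 2)
  prior <- prior_spec(params = list(
    m = list(dist = "logunif", lower = 0.02, upper = 0.5),
    k_south = list(dist = "logunif", lower = 10, upper = 400),
    mu = list(dist = "logunif", lower = 1e-4, upper = 2e-3)))
  list(grid = g, base = base, design = des, prior = prior,
       origin_north = on, origin_south = os)
}
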