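#' Spatial expansion parameters
#'
#' Bundles everything the spatial simulators need: the two ancestral origin
#' cells, pre-onset ancestral sizes, zoned carrying capacities, logistic
#' growth and emigration rates, elevation friction, the microsatellite
#' mutation model and the two fixed time horizons. Population sizes are in
#' gene copies (haploid units); a diploid individual carries two.
#'
#' Defaults follow the study design this package reimplements: divergence of
#' the two ancestral populations 5,850 generations ago (23,400 y at 4
#' y/generation), expansion onset 3,200 generations ago (12,800 y), ancestral
#' sizes 10,100 (North) and 1,550 (South) gene copies, and Northern/Central
#' carrying capacities roughly 20-fold the Southern one.
#'
#' @param origin_north,origin_south `c(row, col)` of the two onset demes.
#' @param anc_north,anc_south Pre-onset ancestral sizes (gene copies).
#' @param n0_north,n0_south Sizes seeded at the origin demes at onset;
#'   default `min(anc, K_zone_of_origin)`.
#' @param k_north,k_central,k_south Carrying capacity per deme (gene copies).
#' @param r Intrinsic logistic growth rate per generation.
#' @param m Intrinsic emigration fraction per generation (0 < m < 1).
#' @param friction A [friction_params()] object.
#' @param mu Microsatellite mutation rate per locus per generation.
#' @param p_gsm Geometric step-size parameter of the generalized stepwise
#'   mutation model, in (0, 1]; 1 recovers the strict stepwise model.
#' @param t_exp Generations since expansion onset.
#' @param t_div Generations since North-South divergence (> `t_exp`).
#' @param grid Optional `landscape_grid`, used only to default `n0_*` from
#'   the origin deme's zone capacity.
#' @return A `spatial_params` list.
#' @export
spatial_params <- function(origin_north, origin_south,
                           anc_north = 10100, anc_south = 1550,
                           n0_north = NULL, n0_south = NULL,
                           k_north = 200, k_central = 200, k_south = 10,
                           r = 5, m = 0.1,
                           friction = friction_params(),
                           mu = 5e-4, p_gsm = 0.22,
                           t_exp = 3200, t_div = 5850,
                           grid = NULL) {
  stopifnot(m > 0, m < 1, r > 0, t_exp > 0, t_div > t_exp,
            anc_north > 0, anc_south > 0,
            k_north > 0, k_central > 0, k_south > 0,
            mu >= 0, p_gsm > 0, p_gsm <= 1)
  if (all(origin_north == origin_south))
    stop("the two origins must be distinct cells")
  kz <- c(NORTH = k_north, CENTRAL = k_central, SOUTH = k_south)
  k_of <- function(cell) {
    if (is.null(grid)) return(max(kz))
    z <- grid$zone[cell[1], cell[2]]
    if (is.na(z)) stop("origin cell is not habitable") else kz[[z]]
  }
  if (!is.null(grid)) {
    if (!grid$habitable[origin_north[1], origin_north[2]] ||
        !grid$habitable[origin_south[1], origin_south[2]])
      stop("origins must be habitable cells")
  }
  if (is.null(n0_north)) n0_north <- min(anc_north, k_of(origin_north))
  if (is.null(n0_south)) n0_south <- min(anc_south, k_of(origin_south))
  structure(list(origin_north = as.integer(origin_north),
                 origin_south = as.integer(origin_south),
                 anc_north = anc_north, anc_south = anc_south,
                 n0_north = n0_north, n0_south = n0_south,
                 k_north = k_north, k_central = k_central, k_south = k_south,
                 r = r, m = m, friction = friction,
                 mu = mu, p_gsm = p_gsm,
                 t_exp = as.integer(t_exp), t_div = as.integer(t_div)),
            class = "spatial_params")
}

#' One generation of discrete logistic growth
#'
#' `n' = n * (1 + r * (1 - n / k))`, floored at 0. With `n` far below `k` the
#' one-generation proportional increase is approximately `r`.
#'
#' @param n Current size (gene copies), >= 0.
#' @param r Intrinsic growth rate per generation.
#' @param k Carrying capacity (> 0).
#' @return Next-generation size (real-valued).
#' @export
logistic_growth <- function(n, r, k) {
  stopifnot(all(n >= 0), all(k > 0))
  pmax(0, n * (1 + r * (1 - n / k)))
}

# Per-cell carrying capacity vector from zoned parameters; 0 off-habitat.
.k_vector <- function(grid, params) {
  kz <- c(NORTH = params$k_north, CENTRAL = params$k_central,
          SOUTH = params$k_south)
  k <- rep(0, grid$n_rows * grid$n_cols)
  z <- as.vector(grid$zone)
  ok <- !is.na(z)
  k[ok] <- kz[z[ok]]
  k
}

#' Advance the stepping-stone demography by one generation
#'
#' Event order within a generation: logistic growth, then emigration of a
#' fraction `m` of each deme split over habitable cardinal neighbours by
#' [migration_weights()], then immigration. In `"deterministic"` mode sizes
#' are real-valued expectations; in `"stochastic"` mode the emigrant total of
#' each deme is Binomial(N, m) and its split multinomial.
#'
#' @param n Numeric vector of deme sizes (one per grid cell, column-major).
#' @param grid A `landscape_grid`.
#' @param params A `spatial_params` object.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param W Optional precomputed weight matrix (internal reuse).
#' @param kvec Optional precomputed carrying-capacity vector.
#' @param nb Optional precomputed neighbour table (internal reuse).
#' @return List with `n` (next sizes) and `emig` (cells x 4 emigrant counts
#'   in N, E, S, W order).
#' @export
step_generation <- function(n, grid, params, mode = c("deterministic", "stochastic"),
                            W = NULL, kvec = NULL, nb = NULL) {
  mode <- match.arg(mode)
  if (is.null(W)) W <- .weight_matrix(grid, params$friction)
  if (is.null(kvec)) kvec <- .k_vector(grid, params)
  if (is.null(nb)) nb <- .neighbour_table(grid)
  hab <- as.vector(grid$habitable)
  n2 <- n
  grow <- hab & n > 0
  n2[grow] <- logistic_growth(n[grow], params$r, kvec[grow])
  emig <- matrix(0, length(n), 4)
  src <- which(n2 > 0 & rowSums(W) > 0)
  if (length(src)) {
    if (mode == "deterministic") {
      etot <- params$m * n2[src]
      emig[src, ] <- W[src, , drop = FALSE] * etot
    } else {
      etot <- stats::rbinom(length(src), round(n2[src]), params$m)
      for (ii in seq_along(src)) {
        if (etot[ii] > 0)
          emig[src[ii], ] <- stats::rmultinom(1, etot[ii], W[src[ii], ])
      }
    }
  }
  n3 <- n2 - rowSums(emig)
  # deposit emigrants; within one direction every source has a distinct
  # destination, so plain indexed addition is safe
  for (k in 1:4) {
    ok <- which(emig[, k] > 0)
    if (length(ok)) {
      dest <- nb[ok, k]
      n3[dest] <- n3[dest] + emig[ok, k]
    }
  }
  list(n = n3, emig = emig)
}

#' Run the forward range expansion
#'
#' Seeds the two origin demes at onset with `n0_north` / `n0_south` gene
#' copies, iterates [step_generation()] `t_exp` times, and records the full
#' demographic history (per-generation deme sizes and emigrant counts) that
#' the backward coalescent conditions on.
#'
#' @param grid A `landscape_grid`.
#' @param params A `spatial_params`; origins must be habitable.
#' @param mode `"deterministic"` (expected sizes) or `"stochastic"`.
#' @param seed Integer seed, used only in stochastic mode.
#' @return A `demographic_db`: `N` is a `(t_exp + 1) x n_cells` matrix
#'   (row `tau + 1` = sizes at generation `tau` after onset), `E` a
#'   `t_exp x n_cells x 4` array of emigrants sent during step
#'   `tau -> tau + 1`, plus `grid` dims and the `params` used.
#' @export
run_forward <- function(grid, params, mode = c("deterministic", "stochastic"),
                        seed = NULL) {
  mode <- match.arg(mode)
  if (params$t_exp <= 0) stop("t_exp must be positive")
  if (!grid$habitable[params$origin_north[1], params$origin_north[2]] ||
      !grid$habitable[params$origin_south[1], params$origin_south[2]])
    stop("origins must be habitable cells")
  if (mode == "stochastic") {
    if (is.null(seed)) stop("stochastic mode requires a seed")
    set.seed(seed)
  }
  ncell <- grid$n_rows * grid$n_cols
  W <- .weight_matrix(grid, params$friction)
  kvec <- .k_vector(grid, params)
  nb <- .neighbour_table(grid)
  tx <- params$t_exp
  N <- matrix(0, tx + 1L, ncell)
  E <- array(0, c(tx, ncell, 4))
  cell_idx <- function(cell) (cell[2] - 1L) * grid$n_rows + cell[1]
  n <- rep(0, ncell)
  n[cell_idx(params$origin_north)] <- params$n0_north
  n[cell_idx(params$origin_south)] <- n[cell_idx(params$origin_south)] +
    params$n0_south
  N[1, ] <- n
  for (tau in seq_len(tx)) {
    st <- step_generation(n, grid, params, mode, W = W, kvec = kvec, nb = nb)
    n <- st$n
    N[tau + 1L, ] <- n
    E[tau, , ] <- st$emig
  }
  structure(list(N = N, E = E, n_rows = grid$n_rows, n_cols = grid$n_cols,
                 params = params, mode = mode),
            class = "demographic_db")
}

#' @export
print.demographic_db <- function(x, ...) {
  occ <- sum(x$N[nrow(x$N), ] > 0)
  cat(sprintf("demographic_db: %d generations, %d cells, %d occupied at present, total N = %.0f\n",
              nrow(x$N) - 1L, ncol(x$N), occ, sum(x$N[nrow(x$N), ])))
  invisible(x)
}
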