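#' Prior specification for the spatial ABC
#'
#' Scalar parameters get independent uniform or log-uniform priors; the two
#' origin locations are uniform over habitable pixels, either anywhere
#' (`origin_mode = "unconstrained"`) or with the North origin restricted to
#' the northern half of the habitable latitude range and the South origin to
#' the southern half (`origin_mode = "halves"`).
#'
#' @param params Named list; each element `list(dist = "unif"|"logunif",
#'   lower =, upper =)`. Parameters of [spatial_params()] not listed here
#'   stay at the base values supplied to [run_reference_table()].
#' @param origin_mode `"halves"` (default) or `"unconstrained"`.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(params = default_spatial_priors(),
                       origin_mode = c("halves", "unconstrained")) {
  origin_mode <- match.arg(origin_mode)
  for (nm in names(params)) {
    p <- params[[nm]]
    stopifnot(p$dist %in% c("unif", "logunif"),
              is.finite(p$lower), is.finite(p$upper), p$lower <= p$upper)
    if (p$dist == "logunif") stopifnot(p$lower > 0)
  }
  structure(list(params = params, origin_mode = origin_mode),
            class = "prior_spec")
}

#' Default priors over the spatial expansion parameters
#'
#' Emigration fraction and per-deme mutation rate are log-uniform (scale
#' parameters); the logistic growth rate spans the 0.5--10 range of
#' plausible one-generation proportional increases; carrying capacities are
#' log-uniform per deme in gene copies; the friction threshold brackets
#' mid-elevation terrain and the uphill bias spans none to strong.
#'
#' @return Named list suitable for [prior_spec()].
#' @export
default_spatial_priors <- function() {
  list(
    m = list(dist = "logunif", lower = 0.01, upper = 0.5),
    r = list(dist = "unif", lower = 0.5, upper = 10),
    k_north = list(dist = "logunif", lower = 10, upper = 1000),
    k_central = list(dist = "logunif", lower = 10, upper = 1000),
    k_south = list(dist = "logunif", lower = 10, upper = 1000),
    mu = list(dist = "logunif", lower = 5e-5, upper = 5e-3),
    p_gsm = list(dist = "unif", lower = 0.05, upper = 1),
    anc_north = list(dist = "logunif", lower = 100, upper = 30000),
    anc_south = list(dist = "logunif", lower = 100, upper = 30000))
}

# Habitable cell pools for origin draws under each mode.
.origin_pools <- function(grid, origin_mode) {
  hab <- which(grid$habitable)
  lat <- as.vector(grid$lat)[hab]
  if (origin_mode == "unconstrained") {
    list(north = hab, south = hab)
  } else {
    mid <- stats::median(lat)
    north <- hab[lat >= mid]
    south <- hab[lat < mid]
    if (!length(north) || !length(south))
      stop("origin prior: a landscape half has no habitable pixel")
    list(north = north, south = south)
  }
}

#' Draw parameter vectors from the prior
#'
#' @param prior A [prior_spec()].
#' @param grid The `landscape_grid` providing the origin support.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Data frame with one column per scalar parameter plus origin cell
#'   indices and centre coordinates (`origin_north_cell`, `origin_north_lat`,
#'   `origin_north_lon`, same for south).
#' @export
draw_priors <- function(prior, grid, n, seed = 1) {
  stopifnot(inherits(prior, "prior_spec"), n >= 1)
  set.seed(seed)
  out <- list()
  for (nm in names(prior$params)) {
    p <- prior$params[[nm]]
    out[[nm]] <- if (p$dist == "logunif")
      exp(stats::runif(n, log(p$lower), log(p$upper)))
    else stats::runif(n, p$lower, p$upper)
  }
  pools <- .origin_pools(grid, prior$origin_mode)
  lat <- as.vector(grid$lat); lon <- as.vector(grid$lon)
  repeat {
    cn <- sample(pools$north, n, replace = TRUE)
    cs <- sample(pools$south, n, replace = TRUE)
    same <- cn == cs
    if (!any(same)) break
    # identical twin origins are outside the model; redraw those rows
    cs[same] <- sample(pools$south, sum(same), replace = TRUE)
    if (!any(cn == cs)) break
  }
  out$origin_north_cell <- cn
  out$origin_north_lat <- lat[cn]
  out$origin_north_lon <- lon[cn]
  out$origin_south_cell <- cs
  out$origin_south_lat <- lat[cs]
  out$origin_south_lon <- lon[cs]
  as.data.frame(out)
}

# Build concrete spatial_params from a base object and one prior draw.
.params_from_draw <- function(base, draw, grid) {
  ov <- as.list(draw)
  if (isTRUE(ov$origin_north_cell == ov$origin_south_cell)) {
    # regression-adjusted origins can snap onto the same pixel; shift the
    # south one to the nearest other habitable cell
    hab <- setdiff(which(grid$habitable), ov$origin_north_cell)
    lat <- as.vector(grid$lat); lon <- as.vector(grid$lon)
    d <- .gc_km(lat[ov$origin_south_cell], lon[ov$origin_south_cell],
                lat[hab], lon[hab])
    ov$origin_south_cell <- hab[which.min(d)]
  }
  cell_rc <- function(cell) {
    cell <- as.integer(cell)
    c(((cell - 1L) %% grid$n_rows) + 1L, ((cell - 1L) %/% grid$n_rows) + 1L)
  }
  fr <- base$friction
  if (!is.null(ov$e_thresh) || !is.null(ov$beta_up) || !is.null(ov$steepness))
    fr <- friction_params(
      e_thresh = if (is.null(ov$e_thresh)) fr$e_thresh else ov$e_thresh,
      steepness = if (is.null(ov$steepness)) fr$steepness else ov$steepness,
      beta_up = if (is.null(ov$beta_up)) fr$beta_up else ov$beta_up)
  g <- function(nm) if (is.null(ov[[nm]])) base[[nm]] else ov[[nm]]
  spatial_params(
    origin_north = cell_rc(ov$origin_north_cell),
    origin_south = cell_rc(ov$origin_south_cell),
    anc_north = g("anc_north"), anc_south = g("anc_south"),
    k_north = g("k_north"), k_central = g("k_central"),
    k_south = g("k_south"),
    r = g("r"), m = g("m"), friction = fr,
    mu = g("mu"), p_gsm = g("p_gsm"),
    t_exp = base$t_exp, t_div = base$t_div, grid = grid)
}

#' Simulate the ABC reference table
#'
#' For each prior draw, runs the full generative chain
#' ([simulate_microsat_dataset()] then [assemble_stat_vector()]). Draws whose
#' sampled demes are uncolonized at present are flagged invalid and kept in
#' the table (they count towards, but are excluded from, the posterior).
#' With a `checkpoint` path the table is appended to disk in blocks and a
#' restarted call resumes after the last completed block.
#'
#' @param grid A `landscape_grid`.
#' @param prior A [prior_spec()].
#' @param design A [sample_design()].
#' @param n_sims Number of simulations (study protocol 600,000; desk scale
#'   a few thousand).
#' @param seed Integer seed.
#' @param base_params A [spatial_params()] supplying every parameter the
#'   prior does not vary (and the fixed `t_exp` / `t_div`).
#' @param checkpoint Optional RDS-free checkpoint path prefix (two CSVs).
#' @param progress Print a line every 500 draws.
#' @return An `abc_reference`: `params` (prior draws), `stats` (matrix,
#'   `NA` rows for invalid draws), `valid`, plus `prior`, `design`,
#'   `base_params` for downstream stages.
#' @export
run_reference_table <- function(grid, prior, design, n_sims, seed = 1,
                                base_params, checkpoint = NULL,
                                progress = FALSE) {
  draws <- draw_priors(prior, grid, n_sims, seed = seed)
  stats_list <- vector("list", n_sims)
  valid <- logical(n_sims)
  start_at <- 1L
  if (!is.null(checkpoint) && file.exists(paste0(checkpoint, ".stats.csv"))) {
    prev <- utils::read.csv(paste0(checkpoint, ".stats.csv"))
    done <- nrow(prev)
    if (done > 0) {
      for (i in seq_len(done)) {
        row <- as.numeric(prev[i, -1])
        valid[i] <- prev[i, 1] == 1
        stats_list[[i]] <- row
      }
      start_at <- done + 1L
    }
  }
  n_stats <- NULL
  for (i in seq(start_at, length.out = max(0L, n_sims - start_at + 1L))) {
    sim_seed <- (seed * 1009L + i * 2L) %% .Machine$integer.max
    par_i <- .params_from_draw(base_params, draws[i, ], grid)
    ds <- simulate_microsat_dataset(grid, par_i, design, seed = sim_seed)
    if (isTRUE(ds$valid)) {
      stats_list[[i]] <- as.numeric(assemble_stat_vector(ds))
      valid[i] <- TRUE
    }
    if (progress && i %% 500 == 0)
      message("reference table: ", i, "/", n_sims)
    if (!is.null(checkpoint) && (i %% 200 == 0 || i == n_sims)) {
      n_stats <- max(vapply(stats_list[seq_len(i)], length, integer(1)), 0L)
      blk <- t(vapply(seq_len(i), function(k) {
        s <- stats_list[[k]]
        c(as.numeric(valid[k]),
          if (is.null(s)) rep(NA_real_, n_stats) else s)
      }, numeric(n_stats + 1L)))
      utils::write.csv(blk, paste0(checkpoint, ".stats.csv"),
                       row.names = FALSE)
    }
  }
  if (mean(valid) < 0.5)
    stop(sprintf(paste0("only %.0f%% of draws produced a valid dataset; ",
                        "the prior support reaches mostly uncolonized ",
                        "sampling sites"), 100 * mean(valid)))
  # statistic names from the first valid dataset
  i1 <- which(valid)[1]
  par_i <- .params_from_draw(base_params, draws[i1, ], grid)
  nm_seed <- (seed * 1009L + i1 * 2L) %% .Machine$integer.max
  nms <- names(assemble_stat_vector(
    simulate_microsat_dataset(grid, par_i, design, seed = nm_seed)))
  S <- length(nms)
  stats <- matrix(NA_real_, n_sims, S, dimnames = list(NULL, nms))
  for (i in which(valid)) stats[i, ] <- stats_list[[i]]
  structure(list(params = draws, stats = stats, valid = valid,
                 prior = prior, design = design, base_params = base_params,
                 seed = seed),
            class = "abc_reference")
}

#' @export
print.abc_reference <- function(x, ...) {
  cat(sprintf("abc_reference: %d draws (%d valid), %d statistics\n",
              nrow(x$params), sum(x$valid), ncol(x$stats)))
  invisible(x)
}

# Columns treated as inferred parameters in the posterior; origins are the
# continuous centre coordinates.
.posterior_param_cols <- function(table) {
  c(names(table$prior$params),
    "origin_north_lat", "origin_north_lon",
    "origin_south_lat", "origin_south_lon")
}

# Logit-scale transform pair for a bounded scalar prior; identity for the
# origin coordinates (adjusted in continuous space, snapped afterwards).
.param_transform <- function(table) {
  pr <- table$prior$params
  list(
    fwd = function(nm, x) {
      p <- pr[[nm]]
      if (is.null(p)) return(x)
      lo <- p$lower; up <- p$upper
      if (p$dist == "logunif") { x <- log(x); lo <- log(lo); up <- log(up) }
      u <- pmin(pmax((x - lo) / (up - lo), 1e-6), 1 - 1e-6)
      log(u / (1 - u))
    },
    bwd = function(nm, z) {
      p <- pr[[nm]]
      if (is.null(p)) return(z)
      lo <- p$lower; up <- p$upper
      logscale <- p$dist == "logunif"
      if (logscale) { lo <- log(lo); up <- log(up) }
      x <- lo + (up - lo) / (1 + exp(-z))
      if (logscale) exp(x) else x
    })
}

#' Rejection + regression-adjusted ABC posterior
#'
#' Statistics are standardized by their median absolute deviation over valid
#' simulations (missing entries imputed by the column mean, constant columns
#' dropped with a warning), simulations ranked by Euclidean distance to the
#' observed vector, and the `tolerance` fraction closest kept with
#' Epanechnikov weights. Optional regression adjustment fits each parameter
#' on the accepted statistics -- weighted local-linear (`"linear"`) or a
#' single-hidden-layer neural network (`"nonlinear"`) -- and corrects the
#' accepted values to the observed statistic point; bounded parameters are
#' adjusted on a logit scale and origin coordinates in continuous space
#' before snapping back to the nearest habitable pixel.
#'
#' @param obs_stats Observed summary-statistic vector (same schema as the
#'   table).
#' @param table An `abc_reference`.
#' @param grid The `landscape_grid` (for origin snapping).
#' @param tolerance Fraction of valid simulations to keep (study protocol
#'   0.005).
#' @param adjust `"none"`, `"linear"` or `"nonlinear"`.
#' @param seed Integer seed (neural-network initialization).
#' @return An `abc_posterior`: `accepted` (indices into the table),
#'   `raw` and `adjusted` parameter data frames, `weights`, `tolerance`,
#'   `obs_stats`, and the carried-through `prior`/`design`/`base_params`.
#' @export
abc_posterior <- function(obs_stats, table, grid, tolerance = 0.005,
                          adjust = c("nonlinear", "linear", "none"),
                          seed = 1) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(table, "abc_reference"),
            tolerance > 0, tolerance <= 1)
  obs <- as.numeric(obs_stats)
  X <- table$stats[table$valid, , drop = FALSE]
  n_valid <- nrow(X)
  if (length(obs) != ncol(X)) stop("observed statistics do not match the table schema")
  col_mean <- colMeans(X, na.rm = TRUE)
  for (s in seq_len(ncol(X))) {
    nas <- is.na(X[, s])
    if (any(nas)) X[nas, s] <- col_mean[s]
    if (is.na(obs[s])) obs[s] <- col_mean[s]
  }
  scale <- apply(X, 2, stats::mad)
  keep <- is.finite(scale) & scale > 0
  if (!all(keep)) warning(sum(!keep), " constant statistic column(s) dropped")
  Xs <- sweep(X[, keep, drop = FALSE], 2, scale[keep], "/")
  obs_s <- obs[keep] / scale[keep]
  d <- sqrt(rowSums(sweep(Xs, 2, obs_s)^2))
  n_acc <- min(n_valid, ceiling(tolerance * n_valid))
  if (n_acc < 50) warning("fewer than 50 accepted draws (", n_acc, ")")
  ord <- order(d, seq_along(d))
  acc <- ord[seq_len(n_acc)]
  dmax <- max(d[acc])
  w <- if (dmax > 0) 1 - (d[acc] / dmax)^2 else rep(1, n_acc)
  if (sum(w) == 0) w <- rep(1, n_acc)
  w <- w / sum(w)

  valid_idx <- which(table$valid)
  pcols <- .posterior_param_cols(table)
  raw <- table$params[valid_idx[acc], pcols, drop = FALSE]
  rownames(raw) <- NULL
  adjusted <- raw
  if (adjust != "none" && n_acc >= 10) {
    tr <- .param_transform(table)
    A <- Xs[acc, , drop = FALSE]
    A_c <- sweep(A, 2, obs_s)   # regressors centred at the observed point
    # reduce the statistic space to its leading principal directions before
    # regressing; keeps the regression determined when the accepted set is
    # small relative to the statistic count
    q <- max(3L, min(15L, floor(n_acc / 5)))
    pcr <- stats::prcomp(A_c, center = FALSE)
    q <- min(q, ncol(pcr$rotation), sum(pcr$sdev > 1e-8))
    S <- pcr$x[, seq_len(q), drop = FALSE]
    set.seed(seed)
    for (nm in pcols) {
      z <- tr$fwd(nm, raw[[nm]])
      if (stats::sd(z) == 0) next
      lin_fit <- function() {
        # weighted ridge regression: shrinks the low-variance principal
        # directions, whose unpenalized coefficients dominate (and wreck)
        # the extrapolation to the observed point
        A <- cbind(1, S)
        lam <- 0.1 * mean(colSums(w * S^2))
        M <- crossprod(A, w * A) + diag(c(0, rep(lam, ncol(S))))
        beta <- drop(solve(M, crossprod(A, w * z)))
        list(fitted = drop(A %*% beta), at_obs = beta[1])
      }
      pred <- tryCatch({
        if (adjust == "linear") {
          lin_fit()
        } else {
          mz <- mean(z); sz <- stats::sd(z)
          nn <- nnet::nnet(S, (z - mz) / sz, size = 4, linout = TRUE,
                           decay = 0.05, maxit = 300,
                           weights = w * n_acc, trace = FALSE)
          p <- list(fitted = mz + sz * drop(stats::predict(nn, S)),
                    at_obs = mz + sz *
                      drop(stats::predict(nn, matrix(0, 1, q))))
          # a network extrapolating beyond the accepted span at the
          # observed point is untrustworthy; use the local-linear fallback
          if (p$at_obs < min(z) || p$at_obs > max(z)) lin_fit() else p
        }
      }, error = function(e) NULL)
      if (is.null(pred)) next
      z_adj <- pred$at_obs + (z - pred$fitted)
      adjusted[[nm]] <- tr$bwd(nm, z_adj)
    }
    # snap adjusted origins back onto habitable pixels (coordinates first
    # clamped to the habitable span so a wild regression extrapolation
    # cannot leave the island)
    hab <- which(grid$habitable)
    lat_h <- as.vector(grid$lat)[hab]
    lon_h <- as.vector(grid$lon)[hab]
    snap <- function(lat, lon) {
      lat <- pmin(pmax(lat, min(lat_h)), max(lat_h))
      lon <- pmin(pmax(lon, min(lon_h)), max(lon_h))
      vapply(seq_along(lat), function(i)
        hab[which.min(.gc_km(lat[i], lon[i], lat_h, lon_h))], integer(1))
    }
    cn <- snap(adjusted$origin_north_lat, adjusted$origin_north_lon)
    cs <- snap(adjusted$origin_south_lat, adjusted$origin_south_lon)
    lat <- as.vector(grid$lat); lon <- as.vector(grid$lon)
    adjusted$origin_north_cell <- cn
    adjusted$origin_north_lat <- lat[cn]
    adjusted$origin_north_lon <- lon[cn]
    adjusted$origin_south_cell <- cs
    adjusted$origin_south_lat <- lat[cs]
    adjusted$origin_south_lon <- lon[cs]
  } else {
    adjusted$origin_north_cell <- table$params$origin_north_cell[valid_idx[acc]]
    adjusted$origin_south_cell <- table$params$origin_south_cell[valid_idx[acc]]
  }
  structure(list(accepted = valid_idx[acc], raw = raw, adjusted = adjusted,
                 weights = w, tolerance = tolerance, adjust = adjust,
                 distances = d[acc], obs_stats = obs,
                 prior = table$prior, design = table$design,
                 base_params = table$base_params),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("abc_posterior: %d accepted draws (tolerance %.3g, adjust = %s)\n",
              length(x$accepted), x$tolerance, x$adjust))
  invisible(x)
}

# Weighted median.
.wmedian <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' Posterior median point estimates
#' @param posterior An `abc_posterior`.
#' @return Named numeric vector of weighted posterior medians over the
#'   adjusted draws.
#' @export
posterior_median <- function(posterior) {
  pc <- setdiff(names(posterior$adjusted),
                c("origin_north_cell", "origin_south_cell"))
  vapply(pc, function(nm) .wmedian(posterior$adjusted[[nm]], posterior$weights),
         numeric(1))
}

#' Posterior density map of the origin locations
#'
#' Weighted Gaussian kernel density of each origin's posterior draws,
#' evaluated at habitable pixel centres, with highest-density regions at 50%
#' and 95% posterior mass, the maximum-density pixel per origin, and the
#' great-circle distance between the two maxima.
#'
#' @param posterior An `abc_posterior` with origin draws.
#' @param grid The `landscape_grid`.
#' @return List with per-origin components (`density` over all cells,
#'   `env50`/`env95` logical vectors, `max_cell`, `max_lat`, `max_lon`) under
#'   `north` and `south`, plus `distance_km` between the maxima.
#' @export
origin_density <- function(posterior, grid) {
  hab <- which(grid$habitable)
  lat_h <- as.vector(grid$lat)[hab]
  lon_h <- as.vector(grid$lon)[hab]
  w <- posterior$weights
  one <- function(lat, lon) {
    n_eff <- 1 / sum(w^2)
    bw_lat <- max(1.06 * sqrt(sum(w * (lat - sum(w * lat))^2)) * n_eff^(-1/5),
                  grid$georef$cellsize / 2)
    bw_lon <- max(1.06 * sqrt(sum(w * (lon - sum(w * lon))^2)) * n_eff^(-1/5),
                  grid$georef$cellsize / 2)
    dens_h <- vapply(seq_along(hab), function(i) {
      sum(w * stats::dnorm(lat, lat_h[i], bw_lat) *
            stats::dnorm(lon, lon_h[i], bw_lon))
    }, numeric(1))
    dens_h <- dens_h / sum(dens_h)
    # highest-density regions: smallest pixel sets holding the target mass
    o <- order(dens_h, decreasing = TRUE)
    cum <- cumsum(dens_h[o])
    in50 <- in95 <- logical(length(hab))
    in50[o[seq_len(which(cum >= 0.5)[1])]] <- TRUE
    in95[o[seq_len(which(cum >= 0.95)[1])]] <- TRUE
    full <- function(v) { out <- rep(0, length(as.vector(grid$lat))); out[hab] <- v; out }
    fullL <- function(v) { out <- rep(FALSE, length(as.vector(grid$lat))); out[hab] <- v; out }
    mx <- hab[o[1]]
    list(density = full(dens_h), env50 = fullL(in50), env95 = fullL(in95),
         max_cell = mx, max_lat = as.vector(grid$lat)[mx],
         max_lon = as.vector(grid$lon)[mx])
  }
  north <- one(posterior$adjusted$origin_north_lat,
               posterior$adjusted$origin_north_lon)
  south <- one(posterior$adjusted$origin_south_lat,
               posterior$adjusted$origin_south_lon)
  list(north = north, south = south,
       distance_km = great_circle_km(c(north$max_lat, north$max_lon),
                                     c(south$max_lat, south$max_lon)))
}

#' Leave-one-out cross-validation of the ABC estimator
#'
#' Treats `n_cv` valid reference-table rows in turn as pseudo-observed data,
#' re-estimates their parameters from the remaining rows, and summarizes
#' accuracy as the mean-standardized root-mean-square error per scalar
#' parameter (RMSE of the posterior-median estimates divided by the mean
#' true value; prior-range denominator if that mean is 0) and the median
#' great-circle distance between true and estimated origin locations.
#'
#' @param table An `abc_reference`.
#' @param grid The `landscape_grid`.
#' @param n_cv Number of held-out rows (study protocol 100).
#' @param tolerance,adjust Passed to [abc_posterior()].
#' @param seed Integer seed (row selection).
#' @param estimator Optional replacement estimator
#'   `function(obs_stats, table) -> named vector` (used by diagnostics).
#' @return List `srmse` (named), `origin_km = c(north, south)` medians, and
#'   the per-row `details` data frame.
#' @export
cross_validate <- function(table, grid, n_cv = 100, tolerance = 0.05,
                           adjust = "nonlinear", seed = 1,
                           estimator = NULL) {
  valid_idx <- which(table$valid)
  stopifnot(n_cv >= 1, n_cv <= length(valid_idx))
  set.seed(seed)
  rows <- sample(valid_idx, n_cv)
  pcols <- .posterior_param_cols(table)
  est <- matrix(NA_real_, n_cv, length(pcols), dimnames = list(NULL, pcols))
  for (i in seq_len(n_cv)) {
    ri <- rows[i]
    sub <- table
    sub$valid[ri] <- FALSE   # hold the row out
    if (is.null(estimator)) {
      post <- abc_posterior(table$stats[ri, ], sub, grid,
                            tolerance = tolerance, adjust = adjust,
                            seed = seed + i)
      pm <- suppressWarnings(posterior_median(post))
      est[i, names(pm)] <- pm
    } else {
      pm <- estimator(table$stats[ri, ], sub)
      est[i, names(pm)] <- pm
    }
  }
  truth <- table$params[rows, pcols, drop = FALSE]
  srmse <- vapply(names(table$prior$params), function(nm) {
    rmse <- sqrt(mean((est[, nm] - truth[[nm]])^2))
    denom <- mean(truth[[nm]])
    if (abs(denom) < 1e-12) {
      p <- table$prior$params[[nm]]
      denom <- p$upper - p$lower
    }
    rmse / denom
  }, numeric(1))
  dn <- .gc_km(truth$origin_north_lat, truth$origin_north_lon,
               est[, "origin_north_lat"], est[, "origin_north_lon"])
  ds <- .gc_km(truth$origin_south_lat, truth$origin_south_lon,
               est[, "origin_south_lat"], est[, "origin_south_lon"])
  list(srmse = srmse,
       origin_km = c(north = stats::median(dn), south = stats::median(ds)),
       details = data.frame(row = rows, dist_north_km = dn,
                            dist_south_km = ds))
}

#' Posterior predictive check
#'
#' Resimulates `n_ppc` datasets at parameter vectors drawn from the
#' (weighted, adjusted) posterior and reports the fraction of observed
#' statistics lying within the range of the simulated ones, plus the
#' coordinates of the simulated cloud and the observed point in the first
#' two principal components of the statistic space.
#'
#' @param posterior An `abc_posterior` (carries the observed statistics).
#' @param grid The `landscape_grid`.
#' @param design A [sample_design()]; defaults to the one in the posterior.
#' @param n_ppc Number of resimulations (study protocol 2,850).
#' @param seed Integer seed.
#' @return List `coverage` (fraction in [0, 1]), `within` (per-statistic
#'   logical), `scores` (n_ppc x 2), `obs_score` (length 2).
#' @export
posterior_predictive_check <- function(posterior, grid, design = NULL,
                                       n_ppc = 100, seed = 1) {
  stopifnot(n_ppc >= 2)
  if (is.null(design)) design <- posterior$design
  set.seed(seed)
  picks <- sample(nrow(posterior$adjusted), n_ppc, replace = TRUE,
                  prob = posterior$weights)
  sims <- NULL
  for (b in seq_len(n_ppc)) {
    draw <- posterior$adjusted[picks[b], ]
    draw <- .clamp_to_prior(draw, posterior$prior)
    par_b <- .params_from_draw(posterior$base_params, draw, grid)
    ds <- simulate_microsat_dataset(grid, par_b, design,
                                    seed = (seed * 883L + b * 2L) %%
                                      .Machine$integer.max)
    if (!isTRUE(ds$valid)) next
    sims <- rbind(sims, as.numeric(assemble_stat_vector(ds)))
  }
  if (is.null(sims) || nrow(sims) < 2)
    stop("posterior predictive check: fewer than 2 valid resimulations")
  obs <- posterior$obs_stats
  col_mean <- colMeans(sims, na.rm = TRUE)
  for (s in seq_len(ncol(sims))) {
    nas <- is.na(sims[, s])
    if (any(nas)) sims[nas, s] <- col_mean[s]
    if (is.na(obs[s])) obs[s] <- col_mean[s]
  }
  rng_lo <- apply(sims, 2, min)
  rng_hi <- apply(sims, 2, max)
  within <- obs >= rng_lo & obs <= rng_hi
  varying <- apply(sims, 2, stats::sd) > 0
  pc <- stats::prcomp(sims[, varying, drop = FALSE], center = TRUE,
                      scale. = TRUE)
  obs_sc <- scale(matrix(obs[varying], 1), pc$center, pc$scale) %*%
    pc$rotation[, 1:2]
  list(coverage = mean(within), within = within,
       scores = pc$x[, 1:2, drop = FALSE], obs_score = drop(obs_sc),
       sims = sims)
}

# Clamp a (possibly regression-adjusted) draw back into the prior support.
.clamp_to_prior <- function(draw, prior) {
  for (nm in names(prior$params)) {
    p <- prior$params[[nm]]
    draw[[nm]] <- min(max(draw[[nm]], p$lower), p$upper)
  }
  draw
}
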