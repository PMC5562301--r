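#' Simulate a joint SFS under a demographic scenario
#'
#' Runs the continuous-time structured coalescent compiled from the scenario
#' (piecewise-constant sizes, backward migration, divergence joins) once per
#' independent sequence, drops infinite-sites mutations at `mu` per bp per
#' generation, and tabulates joint derived-allele counts over the two
#' sampled groups.
#'
#' @param spec A [scenario_spec()].
#' @param params Named numeric vector for the free parameters; default the
#'   scenario's point values.
#' @param n_sequences Number of independent non-recombining sequences.
#' @param seq_length Sequence length in bp (default 300).
#' @param seed Integer seed (optional; inherits the RNG stream if `NULL`).
#' @param fold Return the folded spectrum (default TRUE).
#' @param expected If `TRUE`, accumulate each branch's expected mutation
#'   mass instead of Poisson draws (a lower-variance estimate of the
#'   expected SFS, used by the fitting objective).
#' @return An `sfs2d` of SNP counts.
#' @export
simulate_sfs <- function(spec, params = NULL, n_sequences = 1000,
                         seq_length = 300, seed = NULL, fold = TRUE,
                         expected = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"), n_sequences >= 1)
  if (is.null(params)) params <- spec$defaults
  for (nm in names(spec$free)) {
    f <- spec$free[[nm]]
    if (is.na(params[nm]) || params[nm] < f$lower || params[nm] > f$upper)
      stop("parameter out of bounds: ", nm)
  }
  comp <- .compile_scenario(spec, params)
  if (is.null(comp)) stop("invalid event ordering for these parameter values")
  if (!is.null(seed)) set.seed(seed)
  m <- .coal_sfs_cpp(comp$leaf_deme, comp$leaf_group,
                     comp$epoch_start, comp$sizes, comp$mig, comp$joins,
                     as.integer(n_sequences), comp$mu * seq_length, expected)
  out <- sfs2d(m, folded = FALSE)
  if (fold) fold_sfs(out) else out
}

# Map free parameters to/from the unconstrained optimizer scale: logit of
# the (possibly log-transformed) position within the bounds.
.to_unconstrained <- function(x, free) {
  vapply(names(free), function(nm) {
    f <- free[[nm]]
    if (isTRUE(f$log)) {
      u <- (log(x[[nm]]) - log(f$lower)) / (log(f$upper) - log(f$lower))
    } else u <- (x[[nm]] - f$lower) / (f$upper - f$lower)
    u <- min(max(u, 1e-8), 1 - 1e-8)
    log(u / (1 - u))
  }, numeric(1))
}

.from_unconstrained <- function(z, free) {
  u <- 1 / (1 + exp(-z))
  vapply(seq_along(free), function(i) {
    f <- free[[i]]
    if (isTRUE(f$log)) exp(log(f$lower) + u[i] * (log(f$upper) - log(f$lower)))
    else f$lower + u[i] * (f$upper - f$lower)
  }, numeric(1)) |> stats::setNames(names(free))
}

# Draw one random start uniformly (or log-uniformly) within the bounds.
.draw_start <- function(free) {
  vapply(free, function(f) {
    if (isTRUE(f$log)) exp(stats::runif(1, log(f$lower), log(f$upper)))
    else stats::runif(1, f$lower, f$upper)
  }, numeric(1))
}

#' Fit a scenario to an observed SFS by maximum composite likelihood
#'
#' Simulation-based likelihood: the expected SFS at a candidate parameter
#' vector is Monte-Carlo estimated with `sims_per_eval` sequences using
#' common random numbers within each run (the same stream for every
#' evaluation, so the objective is a deterministic function of the
#' parameters), and maximized by bounded derivative-free search (Nelder-Mead
#' on a logit-transformed scale) restarted from `n_runs` random initial
#' points. Parameter vectors that violate event ordering score `-Inf`.
#'
#' @param spec A [scenario_spec()] with at least one free parameter.
#' @param obs Observed `sfs2d` (folded or unfolded; simulations match it).
#' @param n_runs Number of independent random restarts (study protocol 120;
#'   scale down for desk use).
#' @param sims_per_eval Sequences per likelihood evaluation.
#' @param seed Integer seed.
#' @param seq_length Sequence length in bp matching the observed data.
#' @param maxit Nelder-Mead iteration budget per run.
#' @param n_screen Random parameter draws screened per run; the local
#'   search starts from the best of them (helps high-dimensional
#'   scenarios).
#' @param final_sims Sequences used to rescore the winning parameter
#'   vector with a seed derived from `seed` alone, so likelihoods (and
#'   hence AICs) of different scenarios fitted with the same `seed` are
#'   computed under common random numbers.
#' @return A `fit_result`: `id`, `estimate` (named vector), `max_cl`, `k`,
#'   `aic = 2k - 2 max_cl`, per-run optima, and the call conditions.
#' @export
fit_scenario <- function(spec, obs, n_runs = 10, sims_per_eval = 500,
                         seed = 1, seq_length = 300, maxit = 120,
                         n_screen = 25, final_sims = 8 * sims_per_eval) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(obs, "sfs2d"),
            n_runs >= 1, spec$k >= 1)
  free <- spec$free
  runs <- vector("list", n_runs)
  id_salt <- sum(utf8ToInt(spec$id)) * 131L
  for (run in seq_len(n_runs)) {
    run_seed <- (seed * 97L + run * 7919L + id_salt) %% .Machine$integer.max
    objective <- function(z) {
      par <- .from_unconstrained(z, free)
      comp <- tryCatch(.compile_scenario(spec, par), error = function(e) NULL)
      if (is.null(comp)) return(1e12)
      set.seed(run_seed)  # common random numbers within the run
      m <- .coal_sfs_cpp(comp$leaf_deme, comp$leaf_group, comp$epoch_start,
                         comp$sizes, comp$mig, comp$joins,
                         as.integer(sims_per_eval), comp$mu * seq_length,
                         TRUE)
      e <- sfs2d(m, folded = FALSE)
      if (obs$folded) e <- fold_sfs(e)
      -composite_loglik(obs, e)
    }
    set.seed(run_seed + 1L)
    # screen random valid starts and begin the local search at the best
    # (candidates are all drawn first: the objective reseeds the RNG for
    # its common-random-numbers contract)
    cands <- list()
    tries <- 0L
    while (length(cands) < max(1L, n_screen) &&
             tries < 100L + 10L * n_screen) {
      tries <- tries + 1L
      cand <- .draw_start(free)
      if (!is.null(tryCatch(.compile_scenario(spec, cand),
                            error = function(e) NULL)))
        cands[[length(cands) + 1L]] <- cand
    }
    if (!length(cands)) cands <- list(.draw_start(free))
    objs <- vapply(cands, function(cand)
      objective(.to_unconstrained(cand, free)), numeric(1))
    start <- cands[[which.min(objs)]]
    res <- tryCatch({
      if (length(free) == 1L) {
        # golden-section search on the transformed scale
        opt <- stats::optimize(function(z) objective(z),
                               interval = c(-14, 14), tol = 1e-4)
        list(par = opt$minimum, value = opt$objective)
      } else {
        stats::optim(.to_unconstrained(start, free), objective,
                     method = "Nelder-Mead",
                     control = list(maxit = maxit, reltol = 1e-6))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      runs[[run]] <- list(ok = FALSE, message = conditionMessage(res))
    } else {
      runs[[run]] <- list(ok = TRUE, cl = -res$value,
                          par = .from_unconstrained(res$par, free))
    }
  }
  ok <- vapply(runs, `[[`, logical(1), "ok")
  if (!any(ok))
    stop("all optimization runs failed: ",
         paste(vapply(runs[!ok], `[[`, character(1), "message"), collapse = "; "))
  cls <- vapply(runs[ok], `[[`, numeric(1), "cl")
  best <- runs[ok][[which.max(cls)]]
  # rescore the winner at higher precision under a scenario-independent
  # stream so models fitted with the same seed are directly comparable
  e_final <- simulate_sfs(spec, best$par, final_sims, seq_length,
                          seed = (seed * 31L + 7L) %% .Machine$integer.max,
                          fold = obs$folded, expected = TRUE)
  best$cl <- composite_loglik(obs, e_final)
  structure(list(id = spec$id, estimate = best$par, max_cl = best$cl,
                 k = spec$k, aic = 2 * spec$k - 2 * best$cl,
                 run_optima = cls, n_runs = n_runs,
                 sims_per_eval = sims_per_eval, seq_length = seq_length,
                 obs_snps = sum(obs$mat)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result '%s': max CL = %.2f, k = %d, AIC = %.2f (%d runs)\n",
              x$id, x$max_cl, x$k, x$aic, x$n_runs))
  print(signif(x$estimate, 4))
  invisible(x)
}

#' Rank fitted scenarios by AIC
#'
#' @param fits List of `fit_result` objects on the same observed SFS.
#' @return Data frame sorted by ascending AIC with `delta_aic` and the
#'   evidence ratio `exp(delta_aic / 2)` of each model against the best.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2)
  df <- data.frame(
    id = vapply(fits, `[[`, character(1), "id"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    max_cl = vapply(fits, `[[`, numeric(1), "max_cl"),
    aic = vapply(fits, `[[`, numeric(1), "aic"))
  df <- df[order(df$aic), ]
  df$delta_aic <- df$aic - df$aic[1]
  df$evidence_ratio <- exp(df$delta_aic / 2)
  rownames(df) <- NULL
  df
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates `n_boot` SFSs at the fitted point estimates (same SNP yield as
#' the observed data via the same sequence count), refits each, and returns
#' per-parameter 2.5--97.5 percentile intervals.
#'
#' @param fit A `fit_result`.
#' @param spec The `scenario_spec` that produced it.
#' @param n_boot Number of bootstrap replicates (study protocol 100).
#' @param seed Integer seed.
#' @param n_sequences Sequences per bootstrap SFS.
#' @param n_runs,maxit Refit effort per replicate.
#' @return Matrix with rows `lower`/`upper` over the free parameters, with
#'   attribute `estimates` holding the refitted parameter matrix.
#' @export
parametric_bootstrap <- function(fit, spec, n_boot = 100, seed = 1,
                                 n_sequences = 2000, n_runs = 2, maxit = 60) {
  stopifnot(n_boot >= 2)
  est <- matrix(NA_real_, n_boot, spec$k,
                dimnames = list(NULL, names(spec$free)))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    bseed <- (seed * 131L + b * 8191L) %% .Machine$integer.max
    sim <- simulate_sfs(spec, fit$estimate, n_sequences,
                        fit$seq_length, seed = bseed, fold = TRUE)
    refit <- tryCatch(
      fit_scenario(spec, sim, n_runs = n_runs,
                   sims_per_eval = fit$sims_per_eval,
                   seed = bseed + 1L, seq_length = fit$seq_length,
                   maxit = maxit),
      error = function(e) NULL)
    if (is.null(refit)) failed <- failed + 1L else est[b, ] <- refit$estimate
  }
  if (failed > 0.2 * n_boot)
    stop(sprintf("parametric bootstrap: %d of %d refits failed", failed, n_boot))
  ci <- apply(est, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  rownames(ci) <- c("lower", "upper")
  attr(ci, "estimates") <- est
  ci
}

# Haploid two-level ANOVA variance components for one biallelic site with
# derived counts (i of n1, j of n2); ratio-of-sums over sites gives the
# Weir & Cockerham estimator for allele-count data.
.wc_components_counts <- function(i, j, n1, n2) {
  p1 <- i / n1; p2 <- j / n2
  n <- n1 + n2; r <- 2
  pbar <- (i + j) / n
  ssb <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  ssw <- n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)
  msb <- ssb / (r - 1)
  msw <- ssw / (n - r)
  nc <- (n - (n1^2 + n2^2) / n) / (r - 1)
  c(num = msb - msw, den = msb + (nc - 1) * msw)
}

#' Predictive check of a fitted scenario
#'
#' Simulates sequence polymorphism at the point estimates and reports the
#' statistics the model is expected to predict: Weir & Cockerham's F_ST over
#' all biallelic sites (ratio-of-sums of haploid variance components), the
#' fraction of singletons per population (sites whose within-population
#' minor allele is a private single copy, over sites segregating in that
#' population), and unbiased expected heterozygosity per population averaged
#' over its segregating sites.
#'
#' @param fit A `fit_result` (or any list with `estimate`).
#' @param spec The matching `scenario_spec`.
#' @param seed Integer seed.
#' @param n_sequences Sequences to simulate (study protocol 1e5).
#' @param seq_length Sequence length in bp (study protocol 300).
#' @return List with `wc_fst`, `singleton_fraction` (length 2, North/South
#'   order of the sampled groups), `heterozygosity` (length 2) and
#'   `n_snps`; statistics are `NA` where no site qualifies.
#' @export
predictive_check <- function(fit, spec, seed = 1, n_sequences = 1e5,
                             seq_length = 300) {
  sfs <- simulate_sfs(spec, fit$estimate, n_sequences, seq_length,
                      seed = seed, fold = FALSE)
  n1 <- sfs$n1; n2 <- sfs$n2
  m <- sfs$mat
  m[1, 1] <- 0; m[n1 + 1, n2 + 1] <- 0
  n_snps <- sum(m)
  if (n_snps == 0) {
    return(list(wc_fst = NA_real_, singleton_fraction = c(NA_real_, NA_real_),
                heterozygosity = c(NA_real_, NA_real_), n_snps = 0))
  }
  num <- 0; den <- 0
  het1 <- 0; seg1 <- 0; het2 <- 0; seg2 <- 0
  for (i in 0:n1) for (j in 0:n2) {
    w <- m[i + 1, j + 1]
    if (w == 0) next
    comp <- .wc_components_counts(i, j, n1, n2)
    num <- num + w * comp["num"]; den <- den + w * comp["den"]
    if (i > 0 && i < n1) {
      seg1 <- seg1 + w
      het1 <- het1 + w * (n1 / (n1 - 1)) * 2 * (i / n1) * (1 - i / n1)
    }
    if (j > 0 && j < n2) {
      seg2 <- seg2 + w
      het2 <- het2 + w * (n2 / (n2 - 1)) * 2 * (j / n2) * (1 - j / n2)
    }
  }
  sing1 <- m[2, 1] + m[n1, n2 + 1]      # (1, 0) and (n1 - 1, n2)
  sing2 <- m[1, 2] + m[n1 + 1, n2]      # (0, 1) and (n1, n2 - 1)
  list(wc_fst = if (den > 0) unname(num / den) else NA_real_,
       singleton_fraction = c(if (seg1 > 0) sing1 / seg1 else NA_real_,
                              if (seg2 > 0) sing2 / seg2 else NA_real_),
       heterozygosity = c(if (seg1 > 0) het1 / seg1 else NA_real_,
                          if (seg2 > 0) het2 / seg2 else NA_real_),
       n_snps = n_snps)
}
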