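test_that("prior draws respect their support and cover the origin pixels", {
  g <- flat_grid(5, 5)
  pr <- prior_spec(params = list(
    a = list(dist = "unif", lower = 2, upper = 2),
    b = list(dist = "logunif", lower = 1e-3, upper = 1e-1)),
    origin_mode = "unconstrained")
  d <- draw_priors(pr, g, 2000, seed = 1)
  expect_true(all(d$a == 2))
  expect_true(all(d$b >= 1e-3 & d$b <= 1e-1))
  expect_true(all(d$origin_north_cell != d$origin_south_cell))

  # chi-square uniformity of origin draws over the 25 pixels
  counts <- tabulate(d$origin_north_cell, 25)
  expect_true(all(counts > 0))
  chi <- sum((counts - 80)^2 / 80)
  expect_lt(chi, qchisq(0.999, df = 24))

  # halves mode separates the two origin supports by latitude
  pr2 <- prior_spec(params = list(), origin_mode = "halves")
  d2 <- draw_priors(pr2, g, 500, seed = 2)
  expect_true(all(d2$origin_north_lat >= d2$origin_south_lat))
})

test_that("the reference table is reproducible and records validity", {
  w <- demo_world()
  small <- default_sampling_design(w$grid, n_sites = 4,
                                   individuals_total = 24, n_loci = 5,
                                   seed = 3)
  t1 <- run_reference_table(w$grid, w$prior, small, n_sims = 12, seed = 9,
                            base_params = w$base)
  t2 <- run_reference_table(w$grid, w$prior, small, n_sims = 12, seed = 9,
                            base_params = w$base)
  expect_equal(nrow(t1$params), 12)
  expect_identical(t1$stats, t2$stats)
  expect_identical(t1$valid, t2$valid)
  expect_true(all(is.na(t1$stats[!t1$valid, 1])))

  # replicate draws at one parameter point vary only by simulation noise
  p0 <- w$base
  reps <- t(vapply(1:8, function(s) {
    ds <- simulate_microsat_dataset(w$grid, p0, small, seed = s)
    as.numeric(assemble_stat_vector(ds))
  }, numeric(4 * 4 + 2 * 6 + 5)))
  he_cols <- grep("^He_", names(assemble_stat_vector(
    simulate_microsat_dataset(w$grid, p0, small, seed = 1))))
  expect_gt(min(apply(reps[, he_cols], 2, sd)), 0)
})

test_that("rejection honours the tolerance and reduces to the prior when loose", {
  w <- demo_world()
  small <- default_sampling_design(w$grid, n_sites = 4,
                                   individuals_total = 24, n_loci = 5,
                                   seed = 3)
  tab <- run_reference_table(w$grid, w$prior, small, n_sims = 80, seed = 5,
                             base_params = w$base)
  obs <- tab$stats[which(tab$valid)[3], ]

  # tolerance 1 + no adjustment: the posterior is exactly the valid prior
  post <- suppressWarnings(abc_posterior(obs, tab, w$grid, tolerance = 1,
                                         adjust = "none"))
  expect_equal(length(post$accepted), sum(tab$valid))
  expect_setequal(post$accepted, which(tab$valid))
  expect_equal(sum(post$weights), 1)

  # a table member is accepted at any tolerance, with distance zero first
  post2 <- suppressWarnings(abc_posterior(obs, tab, w$grid,
                                          tolerance = 1 / sum(tab$valid),
                                          adjust = "none"))
  expect_equal(post2$accepted[1], which(tab$valid)[3])
  expect_equal(post2$distances[1], 0)

  # acceptance count honours ceil(tolerance x valid)
  post3 <- suppressWarnings(abc_posterior(obs, tab, w$grid, tolerance = 0.33,
                                          adjust = "none"))
  expect_equal(length(post3$accepted), ceiling(0.33 * sum(tab$valid)))

  # without adjustment the posterior draws are a subset of the prior draws
  expect_true(all(post3$adjusted$m %in% tab$params$m))
})

test_that("regression adjustment keeps origins on habitable pixels", {
  w <- demo_world()
  small <- default_sampling_design(w$grid, n_sites = 4,
                                   individuals_total = 24, n_loci = 5,
                                   seed = 3)
  tab <- run_reference_table(w$grid, w$prior, small, n_sims = 120, seed = 6,
                             base_params = w$base)
  obs <- tab$stats[which(tab$valid)[1], ]
  for (adj in c("linear", "nonlinear")) {
    post <- suppressWarnings(abc_posterior(obs, tab, w$grid, tolerance = 0.5,
                                           adjust = adj, seed = 2))
    cells <- c(post$adjusted$origin_north_cell,
               post$adjusted$origin_south_cell)
    expect_true(all(w$grid$habitable[cells]))
    # bounded parameters stay inside their prior bounds after adjustment
    expect_true(all(post$adjusted$m >= 0.02 & post$adjusted$m <= 0.5))
    expect_true(all(post$adjusted$k_south >= 10 &
                      post$adjusted$k_south <= 400))
  }
})

test_that("origin density maps are proper distributions with nested envelopes", {
  w <- demo_world()
  small <- default_sampling_design(w$grid, n_sites = 4,
                                   individuals_total = 24, n_loci = 5,
                                   seed = 3)
  tab <- run_reference_table(w$grid, w$prior, small, n_sims = 60, seed = 7,
                             base_params = w$base)
  obs <- tab$stats[which(tab$valid)[1], ]
  post <- suppressWarnings(abc_posterior(obs, tab, w$grid, tolerance = 0.4,
                                         adjust = "none"))
  dens <- origin_density(post, w$grid)
  for (side in c("north", "south")) {
    o <- dens[[side]]
    expect_equal(sum(o$density), 1, tolerance = 1e-9)
    expect_true(all(o$env50 <= o$env95))         # 50% region nested in 95%
    expect_true(w$grid$habitable[o$max_cell])
    expect_gte(sum(o$density[o$env95]), 0.95)
  }
  expect_gte(dens$distance_km, 0)

  # degenerate posterior: all draws at one pixel
  post1 <- post
  keep_cell <- post$adjusted$origin_north_cell[1]
  for (cc in c("origin_north_cell", "origin_south_cell"))
    post1$adjusted[[cc]] <- rep(keep_cell, nrow(post1$adjusted))
  for (cc in c("origin_north_lat", "origin_south_lat"))
    post1$adjusted[[cc]] <- rep(as.vector(w$grid$lat)[keep_cell],
                                nrow(post1$adjusted))
  for (cc in c("origin_north_lon", "origin_south_lon"))
    post1$adjusted[[cc]] <- rep(as.vector(w$grid$lon)[keep_cell],
                                nrow(post1$adjusted))
  dens1 <- origin_density(post1, w$grid)
  expect_equal(dens1$distance_km, 0)
  expect_equal(dens1$north$max_cell, keep_cell)
  expect_equal(sum(dens1$north$env50), 1)
})

test_that("cross-validation scores an oracle estimator as perfect", {
  w <- demo_world()
  small <- default_sampling_design(w$grid, n_sites = 4,
                                   individuals_total = 24, n_loci = 5,
                                   seed = 3)
  tab <- run_reference_table(w$grid, w$prior, small, n_sims = 40, seed = 8,
                             base_params = w$base)
  # oracle: look the held-out row up by its statistics and return its truth
  oracle <- function(obs_stats, table) {
    full <- tab$stats
    hit <- which(apply(full, 1, function(r) isTRUE(all.equal(r, obs_stats))))
    unlist(tab$params[hit[1], paleorange:::.posterior_param_cols(tab)])
  }
  cv <- cross_validate(tab, w$grid, n_cv = 6, tolerance = 0.5,
                       seed = 3, estimator = oracle)
  expect_equal(unname(cv$srmse), rep(0, 3))
  expect_equal(unname(cv$origin_km), c(0, 0))

  # the ABC estimator itself returns finite accuracy summaries
  cv2 <- suppressWarnings(cross_validate(tab, w$grid, n_cv = 4,
                                         tolerance = 0.5, adjust = "linear",
                                         seed = 4))
  expect_true(all(is.finite(cv2$srmse)))
  expect_true(all(is.finite(cv2$origin_km)))
})

test_that("posterior predictive checks cover an in-cloud observation", {
  w <- demo_world()
  small <- default_sampling_design(w$grid, n_sites = 4,
                                   individuals_total = 24, n_loci = 5,
                                   seed = 3)
  tab <- run_reference_table(w$grid, w$prior, small, n_sims = 50, seed = 10,
                             base_params = w$base)
  obs <- tab$stats[which(tab$valid)[2], ]
  post <- suppressWarnings(abc_posterior(obs, tab, w$grid, tolerance = 0.5,
                                         adjust = "none"))
  ppc <- posterior_predictive_check(post, w$grid, small, n_ppc = 15,
                                    seed = 6)
  expect_true(ppc$coverage >= 0 && ppc$coverage <= 1)
  expect_equal(ncol(ppc$scores), 2)

  # an observation that IS one of the resimulated vectors is fully covered
  post_self <- post
  post_self$obs_stats <- ppc$sims[1, ]
  ppc2 <- posterior_predictive_check(post_self, w$grid, small, n_ppc = 15,
                                     seed = 6)
  expect_equal(ppc2$coverage, 1)
})
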