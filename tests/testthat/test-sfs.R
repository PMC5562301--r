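test_that("folding maps cells onto minor-allele coordinates and conserves mass", {
  # all mass already on the minor side: unchanged
  m <- matrix(0, 3, 3); m[1, 2] <- 7          # cell (0,1), n1 = n2 = 2
  f <- fold_sfs(sfs2d(m))
  expect_equal(f$mat[1, 2], 7)
  expect_equal(sum(f$mat), 7)

  # mass at (2,2) folds onto (0,0); exact-half cells split evenly
  m2 <- matrix(0, 3, 3)
  m2[3, 3] <- 4       # (2,2): total 4 > 2 -> complement (0,0)
  m2[3, 1] <- 6       # (2,0): total 2 == half -> split with (0,2)
  f2 <- fold_sfs(sfs2d(m2))
  expect_equal(f2$mat[1, 1], 4)
  expect_equal(f2$mat[3, 1], 3)
  expect_equal(f2$mat[1, 3], 3)
  expect_equal(sum(f2$mat), 10)

  expect_error(fold_sfs(f2), "already folded")

  # conservation on random fixtures
  set.seed(3)
  for (k in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    m <- matrix(rpois((n1 + 1) * (n2 + 1), 3), n1 + 1, n2 + 1)
    u <- sfs2d(m, n1, n2)
    f <- fold_sfs(u)
    expect_equal(sum(f$mat), sum(m))
    idx <- which(f$mat > 0, arr.ind = TRUE)
    expect_true(all((idx[, 1] - 1) + (idx[, 2] - 1) <= (n1 + n2) / 2))
  }
})

test_that("composite log-likelihood matches hand arithmetic and handles zeros", {
  obs <- sfs2d(matrix(c(0, 10, 30, 0), 2, 2), folded = FALSE)
  ex <- sfs2d(matrix(c(0, 1, 3, 0), 2, 2), folded = FALSE)
  expect_equal(composite_loglik(obs, ex), 10 * log(0.25) + 30 * log(0.75))

  # observed mass in an empty expected cell uses the eps floor
  ex0 <- sfs2d(matrix(c(0, 0, 3, 0), 2, 2), folded = FALSE)
  cl <- composite_loglik(obs, ex0)
  expect_true(is.finite(cl))
  expect_equal(cl, 10 * log(1e-10) + 30 * log(1), tolerance = 1e-6)

  expect_error(composite_loglik(obs, sfs2d(matrix(0:8, 3, 3), folded = FALSE)),
               "shape")
})

test_that("the observed proportions maximize the composite likelihood", {
  set.seed(8)
  for (k in 1:100) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    m <- matrix(rpois((n1 + 1) * (n2 + 1), 4), n1 + 1, n2 + 1)
    m[1, 1] <- 0; m[n1 + 1, n2 + 1] <- 0
    if (sum(m) == 0) next
    obs <- sfs2d(m, n1, n2)
    best <- composite_loglik(obs, obs)
    alt <- sfs2d(matrix(rexp((n1 + 1) * (n2 + 1)), n1 + 1, n2 + 1), n1, n2)
    expect_gte(best, composite_loglik(obs, alt))
  }
})

test_that("SFS text files round-trip", {
  set.seed(1)
  s <- sfs2d(matrix(rpois(12, 5), 3, 4), folded = FALSE)
  f <- tempfile(fileext = ".sfs")
  write_sfs(s, f)
  s2 <- read_sfs(f)
  expect_equal(s2$mat, s$mat)
  expect_equal(s2$folded, FALSE)
  expect_equal(c(s2$n1, s2$n2), c(2L, 3L))
})

test_that("the coalescent SFS simulator reproduces neutral expectations", {
  # single panmictic population (second deme merges immediately)
  spec <- scenario_spec("pan", sizes = list(1000, 1000), samples = c(4L, 0L),
                        events = list(list(kind = "join", time = 5,
                                           from = 2, to = 1)),
                        mu = 1e-6)
  s <- simulate_sfs(spec, n_sequences = 2e4, seq_length = 300, seed = 2,
                    fold = FALSE)
  m <- s$mat[, 1]
  # E[count at frequency i] = theta / i (theta = 2 N mu L per sequence)
  theta_seq <- 2 * 1000 * 1e-6 * 300 * 2e4
  for (i in 1:3) {
    expect_equal(m[i + 1], theta_seq / i,
                 tolerance = 4 / sqrt(theta_seq / i))
  }
  # mu = 0 gives an empty spectrum
  spec0 <- scenario_spec("null", sizes = list(1000, 1000),
                         samples = c(4L, 0L),
                         events = list(list(kind = "join", time = 5,
                                            from = 2, to = 1)),
                         mu = 0)
  expect_equal(sum(simulate_sfs(spec0, n_sequences = 200, seed = 1)$mat), 0)
})

test_that("a fully symmetric two-population scenario yields a swap-symmetric SFS", {
  spec <- scenario_spec("sym", sizes = list(2000, 2000), samples = c(6L, 6L),
                        events = list(list(kind = "join", time = 1500,
                                           from = 2, to = 1)),
                        mu = 1e-6)
  reps <- lapply(1:20, function(k)
    simulate_sfs(spec, n_sequences = 1500, seed = 100 + k, fold = FALSE)$mat)
  avg <- Reduce(`+`, reps) / length(reps)
  sdm <- sqrt(Reduce(`+`, lapply(reps, function(m) (m - avg)^2)) /
                (length(reps) - 1))
  se <- sdm / sqrt(length(reps))
  diff <- abs(avg - t(avg))
  tol <- 3 * (se + t(se)) + 1e-9
  expect_true(all(diff[avg + t(avg) > 5] <= tol[avg + t(avg) > 5]))
})

test_that("the scenario catalogue matches the study typology", {
  cat13 <- build_scenario_catalogue()
  expect_length(cat13, 13)
  expect_true("2M" %in% names(cat13))
  for (spec in cat13) expect_equal(spec$k, length(spec$free))

  # reference model point values are the published estimates
  d <- cat13$`2M`$defaults
  expect_equal(unname(d[c("N_S_old", "N_S", "N_N_old", "N_N")]),
               c(1550, 10000, 10100, 10150))
  expect_equal(unname(d[c("t_exp", "t_div")]), c(3200, 5850))
  # the structured model carries three extra unsampled demes
  expect_equal(cat13$`5STR`$n_demes, 5)
  expect_equal(sum(cat13$`5STR`$samples > 0), 2)
})

test_that("scenario compilation rejects inverted event orderings", {
  spec <- build_scenario_catalogue()$`2M`
  bad <- spec$defaults
  bad["t_div"] <- bad["t_exp"] - 100
  expect_error(simulate_sfs(spec, bad, n_sequences = 10, seed = 1),
               "event ordering|bounds")
})

test_that("model comparison arithmetic is exact", {
  f <- function(id, cl, k) structure(list(id = id, max_cl = cl, k = k,
                                          aic = 2 * k - 2 * cl),
                                     class = "fit_result")
  tab <- compare_models(list(f("a", -100, 3), f("b", -100, 3)))
  expect_equal(tab$evidence_ratio, c(1, 1))

  tab2 <- compare_models(list(f("a", -100, 3), f("b", -100, 4)))
  expect_equal(tab2$delta_aic[2], 2)
  expect_equal(tab2$evidence_ratio[2], exp(1))

  # ranking invariant to input order
  fits <- list(f("a", -120, 2), f("b", -100, 5), f("c", -90, 9))
  expect_equal(compare_models(fits)$id, compare_models(rev(fits))$id)
})

test_that("fitting recovers a one-parameter truth and is deterministic", {
  spec <- scenario_spec("toy", sizes = list("N", 2000), samples = c(8L, 8L),
                        events = list(list(kind = "join", time = 3000,
                                           from = 2, to = 1)),
                        free = list(N = list(lower = 200, upper = 50000,
                                             log = TRUE)),
                        mu = 1e-7, defaults = c(N = 5000))
  obs <- simulate_sfs(spec, c(N = 5000), n_sequences = 2e4, seed = 21)
  fit <- fit_scenario(spec, obs, n_runs = 2, sims_per_eval = 4000, seed = 3)
  expect_lt(abs(fit$estimate[["N"]] - 5000) / 5000, 0.10)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$max_cl)

  fit2 <- fit_scenario(spec, obs, n_runs = 1, sims_per_eval = 1000, seed = 9)
  fit3 <- fit_scenario(spec, obs, n_runs = 1, sims_per_eval = 1000, seed = 9)
  expect_identical(fit2$estimate, fit3$estimate)
})

test_that("parametric bootstrap returns ordered intervals bracketing the fit", {
  spec <- scenario_spec("toy", sizes = list("N", 2000), samples = c(6L, 6L),
                        events = list(list(kind = "join", time = 3000,
                                           from = 2, to = 1)),
                        free = list(N = list(lower = 200, upper = 50000,
                                             log = TRUE)),
                        mu = 1e-7, defaults = c(N = 5000))
  obs <- simulate_sfs(spec, c(N = 5000), n_sequences = 5000, seed = 4)
  fit <- fit_scenario(spec, obs, n_runs = 1, sims_per_eval = 2000, seed = 5)
  ci <- parametric_bootstrap(fit, spec, n_boot = 8, seed = 6,
                             n_sequences = 5000)
  expect_lt(ci["lower", "N"], ci["upper", "N"])
  expect_gt(fit$estimate[["N"]], ci["lower", "N"] / 3)
  expect_lt(fit$estimate[["N"]], ci["upper", "N"] * 3)
})

test_that("predictive check reports missing statistics without polymorphism", {
  spec0 <- scenario_spec("null", sizes = list(1000, 1000),
                         samples = c(4L, 4L),
                         events = list(list(kind = "join", time = 5,
                                            from = 2, to = 1)),
                         mu = 0)
  pc <- predictive_check(list(estimate = numeric(0)), spec0, seed = 1,
                         n_sequences = 100)
  expect_true(is.na(pc$wc_fst))
  expect_equal(pc$n_snps, 0)
})

test_that("long-isolated populations approach complete fixation (F_ST -> 1)", {
  spec <- scenario_spec("iso", sizes = list(500, 500), samples = c(10L, 10L),
                        events = list(list(kind = "join", time = 5e4,
                                           from = 2, to = 1)),
                        mu = 2e-7)
  pc <- predictive_check(list(estimate = numeric(0)), spec, seed = 2,
                         n_sequences = 4000)
  expect_gt(pc$wc_fst, 0.9)
})
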