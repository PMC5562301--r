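# Independent transcription of the Weir & Cockerham (1984) variance
# components, allele by allele, used as the oracle for the package's
# matrix-based implementation.
oracle_theta <- function(dataset, pops) {
  n_loci <- dim(dataset$alleles)[2]
  num <- den <- 0
  for (l in seq_len(n_loci)) {
    per_pop <- lapply(pops, function(p) {
      idx <- which(dataset$pop == p)
      g <- dataset$alleles[idx, l, , drop = FALSE]
      ok <- !is.na(g[, 1, 1]) & !is.na(g[, 1, 2])
      g[ok, 1, , drop = FALSE]
    })
    ni <- vapply(per_pop, nrow, integer(1))
    keep <- ni > 0
    per_pop <- per_pop[keep]; ni <- ni[keep]
    r <- length(ni)
    if (r < 2) next
    alleles <- unique(unlist(lapply(per_pop, as.vector)))
    if (length(alleles) < 2) next
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    loc_num <- loc_den <- 0
    informative <- FALSE
    for (u in alleles) {
      p_i <- vapply(per_pop, function(g) mean(g == u), numeric(1))
      h_i <- vapply(per_pop, function(g)
        mean(xor(g[, 1, 1] == u, g[, 1, 2] == u)), numeric(1))
      pbar <- sum(ni * p_i) / (r * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / (r * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      loc_num <- loc_num + a
      loc_den <- loc_den + a + b + cc
      if (pbar > 0 && pbar < 1) informative <- TRUE
    }
    if (informative) { num <- num + loc_num; den <- den + loc_den }
  }
  if (den == 0) NA_real_ else num / den
}

random_dataset <- function(seed, n_pops = 2, n_ind = 8, n_loci = 3,
                           n_alleles = 4) {
  set.seed(seed)
  geno <- lapply(seq_len(n_pops), function(p) {
    freqs <- matrix(rexp(n_loci * n_alleles), n_loci)
    lapply(seq_len(n_ind), function(i) {
      t(vapply(seq_len(n_loci), function(l)
        sample(10L + seq_len(n_alleles), 2, replace = TRUE,
               prob = freqs[l, ]), integer(2)))
    })
  })
  names(geno) <- paste0("P", seq_len(n_pops))
  manual_dataset(geno)
}

test_that("within-population statistics match hand computations", {
  # monomorphic locus
  mono <- manual_dataset(list(A = list(matrix(c(15L, 15L), 1, 2),
                                       matrix(c(15L, 15L), 1, 2))))
  w <- within_pop_stats(mono, "A")
  expect_equal(w$n_alleles, 1)
  expect_equal(w$He, 0)
  expect_equal(w$range, 0)
  expect_equal(w$M_ratio, 1)

  # 8 gene copies, two equifrequent alleles: He = (8/7) (1 - 0.5)
  two <- manual_dataset(list(A = lapply(1:4, function(i)
    matrix(c(10L, 12L), 1, 2))))
  w2 <- within_pop_stats(two, "A")
  expect_equal(w2$He, (8 / 7) * 0.5, tolerance = 1e-12)
  expect_equal(w2$n_alleles, 2)
  expect_equal(w2$range, 2)
  expect_equal(w2$M_ratio, 2 / 3)

  # duplicating an individual changes neither allele count nor range
  dup <- manual_dataset(list(A = lapply(1:5, function(i)
    matrix(c(10L, 12L), 1, 2))))
  w3 <- within_pop_stats(dup, "A")
  expect_equal(w3$n_alleles, w2$n_alleles)
  expect_equal(w3$range, w2$range)
})

test_that("pairwise theta behaves at the boundaries", {
  fixed_same <- manual_dataset(list(
    A = lapply(1:5, function(i) matrix(c(20L, 20L), 1, 2)),
    B = lapply(1:5, function(i) matrix(c(20L, 20L), 1, 2))))
  expect_true(is.na(wc_fst(fixed_same, "A", "B")))

  fixed_diff <- manual_dataset(list(
    A = lapply(1:30, function(i) matrix(c(20L, 20L), 1, 2)),
    B = lapply(1:30, function(i) matrix(c(26L, 26L), 1, 2))))
  expect_gt(wc_fst(fixed_diff, "A", "B"), 0.97)
  expect_lte(wc_fst(fixed_diff, "A", "B"), 1)
})

test_that("theta agrees with the independent variance-component oracle", {
  for (s in 1:50) {
    ds <- random_dataset(s, n_ind = sample(4:10, 1),
                         n_loci = sample(1:4, 1))
    mine <- wc_fst(ds, "P1", "P2")
    ref <- oracle_theta(ds, c("P1", "P2"))
    if (is.na(ref)) expect_true(is.na(mine))
    else expect_equal(mine, ref, tolerance = 1e-10)
  }
  # multi-population overall theta against the same oracle
  for (s in 1:10) {
    ds <- random_dataset(100 + s, n_pops = 4)
    sv <- assemble_stat_vector(ds)
    expect_equal(unname(sv["overall_fst"]),
                 oracle_theta(ds, paste0("P", 1:4)), tolerance = 1e-10)
  }
})

test_that("the permutation test is calibrated and catches divergence", {
  # strongly diverged pair: the observed theta tops every permutation
  # unequal sizes so no permutation can reproduce the perfect split
  div <- manual_dataset(list(
    A = lapply(1:8, function(i) matrix(c(20L, 20L), 1, 2)),
    B = lapply(1:7, function(i) matrix(c(30L, 30L), 1, 2))))
  res <- permutation_test_fst(div, "A", "B", n_perm = 99, seed = 2)
  expect_equal(res$p_value, 1 / 100)
  res2 <- permutation_test_fst(div, "A", "B", n_perm = 99, seed = 2)
  expect_identical(res, res2)

  # panmictic null: rejection rate near the nominal 5%
  set.seed(31)
  rejections <- vapply(1:100, function(k) {
    pool <- manual_dataset(list(
      A = lapply(1:6, function(i)
        matrix(sample(c(10L, 11L, 12L), 2, TRUE), 1, 2)),
      B = lapply(1:6, function(i)
        matrix(sample(c(10L, 11L, 12L), 2, TRUE), 1, 2))))
    p <- permutation_test_fst(pool, "A", "B", n_perm = 99, seed = k)$p_value
    !is.na(p) && p <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 100) + 1e-9)
})

test_that("(delta mu)^2 matches arithmetic and is symmetric", {
  same <- manual_dataset(list(
    A = lapply(1:4, function(i) matrix(c(10L, 12L), 1, 2)),
    B = lapply(1:4, function(i) matrix(c(12L, 10L), 1, 2))))
  expect_equal(delta_mu2(same, "A", "B"), 0)

  off <- manual_dataset(list(
    A = lapply(1:4, function(i) matrix(c(10L, 10L), 1, 2)),
    B = lapply(1:4, function(i) matrix(c(13L, 13L), 1, 2))))
  expect_equal(delta_mu2(off, "A", "B"), 9)
  expect_equal(delta_mu2(off, "B", "A"), 9)
})

test_that("the statistic vector has the documented schema and invariances", {
  # default study design: 11 populations -> 159 statistics
  ds11 <- random_dataset(7, n_pops = 11, n_ind = 4, n_loci = 2)
  sv <- assemble_stat_vector(ds11)
  expect_length(sv, 159)

  ds3 <- random_dataset(8, n_pops = 3)
  sv3 <- assemble_stat_vector(ds3)
  expect_length(sv3, 3 * 4 + 3 * 2 + 5)

  # permuting individuals within populations leaves the vector unchanged
  set.seed(5)
  perm <- ds3
  for (p in levels(ds3$pop)) {
    idx <- which(ds3$pop == p)
    perm$alleles[idx, , ] <- ds3$alleles[sample(idx), , ]
  }
  expect_equal(assemble_stat_vector(perm), sv3)
})

test_that("theta declines with migration in a two-deme exchange", {
  # two demes of constant size exchanging a fixed migrant count per
  # generation, genealogies conditioned on the recorded flows
  g <- flat_grid(2, 1)
  theta_at <- function(migrants, reps, seed) {
    E <- array(0, c(400, 2, 4))
    E[, 1, 3] <- migrants
    E[, 2, 1] <- migrants
    db <- const_db(200, t_exp = 400, n_rows = 2, n_cols = 1,
                   anc_north = 200, anc_south = 200, t_div = 3000, E = E)
    des <- sample_design(data.frame(name = c("a", "b"),
                                    lat = c(g$lat[1, 1], g$lat[2, 1]),
                                    lon = c(g$lon[1, 1], g$lon[2, 1]),
                                    n_ind = c(8, 8)), n_loci = 1)
    set.seed(seed)
    mean(vapply(seq_len(reps), function(k) {
      gen <- simulate_genealogy(db, g, des, 1)[[1]]
      leaves <- apply_gsm(gen, mu = 5e-3, p_gsm = 0.5)
      al <- array(NA_integer_, c(16, 1, 2))
      al[, 1, 1] <- leaves[seq(1, 31, 2)]
      al[, 1, 2] <- leaves[seq(2, 32, 2)]
      dsx <- structure(list(alleles = al,
                            pop = factor(rep(c("a", "b"), each = 8)),
                            sites = NULL, valid = TRUE),
                       class = "microsat_dataset")
      th <- wc_fst(dsx, "a", "b")
      if (is.na(th)) 0 else th
    }, numeric(1)))
  }
  th <- c(theta_at(1, 100, 1), theta_at(5, 100, 2), theta_at(25, 100, 3))
  expect_true(all(diff(th) < 0))
})
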