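# Allele matrix (copies x loci) for the individuals of selected populations.
.allele_rows <- function(dataset, pops = NULL) {
  idx <- if (is.null(pops)) seq_along(dataset$pop)
         else which(dataset$pop %in% pops)
  a <- dataset$alleles[idx, , , drop = FALSE]
  n_loci <- dim(a)[2]
  out <- matrix(NA_integer_, 2 * length(idx), n_loci)
  if (length(idx)) {
    out[seq(1, by = 2, length.out = length(idx)), ] <- a[, , 1]
    out[seq(2, by = 2, length.out = length(idx)), ] <- a[, , 2]
  }
  out
}

#' Within-population diversity statistics
#'
#' Per-locus statistics averaged over loci (loci with no genotyped copy in
#' the population are skipped): number of distinct alleles, unbiased
#' expected heterozygosity `(n/(n-1)) (1 - sum p^2)`, allelic size range
#' (max - min repeat count), and the M-ratio `n_alleles / (range + 1)`.
#'
#' @param dataset A `microsat_dataset`.
#' @param population Population label (a level of `dataset$pop`).
#' @return Named list `n_alleles`, `He`, `range`, `M_ratio`.
#' @export
within_pop_stats <- function(dataset, population) {
  al <- .allele_rows(dataset, population)
  if (!nrow(al)) stop("no genotyped individual in population ", population)
  per_locus <- apply(al, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA, NA, NA, NA))
    tab <- table(x)
    n <- length(x)
    p <- tab / n
    he <- if (n > 1) (n / (n - 1)) * (1 - sum(p^2)) else 0
    rng <- max(x) - min(x)
    c(length(tab), he, rng, length(tab) / (rng + 1))
  })
  means <- rowMeans(per_locus, na.rm = TRUE)
  list(n_alleles = means[1], He = means[2], range = means[3],
       M_ratio = means[4])
}

# Per-locus allele-count and heterozygote-count tables for every population,
# computed once per dataset and shared by all theta / distance calls.
.wc_prep <- function(dataset) {
  pops <- levels(dataset$pop)
  n_loci <- dim(dataset$alleles)[2]
  lapply(seq_len(n_loci), function(l) {
    a1 <- dataset$alleles[, l, 1]; a2 <- dataset$alleles[, l, 2]
    ok <- !is.na(a1) & !is.na(a2)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    A <- length(alleles)
    ni <- integer(length(pops))
    cnt <- matrix(0, length(pops), max(A, 1))
    het <- matrix(0, length(pops), max(A, 1))
    for (k in seq_along(pops)) {
      idx <- ok & dataset$pop == pops[k]
      ni[k] <- sum(idx)
      if (!ni[k] || !A) next
      c1 <- match(a1[idx], alleles); c2 <- match(a2[idx], alleles)
      cnt[k, ] <- tabulate(c1, A) + tabulate(c2, A)
      hp <- which(c1 != c2)
      if (length(hp)) het[k, ] <- tabulate(c(c1[hp], c2[hp]), A)
    }
    list(ni = ni, cnt = cnt, het = het, alleles = alleles, n_all = A)
  })
}

# Weir & Cockerham (1984) variance-component theta over the populations at
# integer indices `use_pops`, multi-allelic diploid data, alleles and loci
# combined ratio-of-sums. NA when no variance component is defined.
.wc_theta_prep <- function(prep, use_pops) {
  sum_a <- 0; sum_abc <- 0; any_def <- FALSE
  for (lp in prep) {
    if (lp$n_all < 2) next
    ni <- lp$ni[use_pops]
    use <- use_pops[ni > 0]
    ni <- ni[ni > 0]
    ru <- length(use)
    if (ru < 2) next
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (ru * nbar - sum(ni^2) / (ru * nbar)) / (ru - 1)
    if (nc <= 0) next
    p_iu <- lp$cnt[use, , drop = FALSE] / (2 * ni)
    h_iu <- lp$het[use, , drop = FALSE] / ni
    pbar <- colSums(ni * p_iu) / (ru * nbar)
    s2 <- colSums(ni * (p_iu - rep(pbar, each = ru))^2) / ((ru - 1) * nbar)
    hbar <- colSums(ni * h_iu) / (ru * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (ru - 1) / ru * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (ru - 1) / ru * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (any(p_iu > 0 & p_iu < 1) || any(pbar > 0 & pbar < 1)) {
      sum_a <- sum_a + sum(a)
      sum_abc <- sum_abc + sum(a + b + cc)
      any_def <- TRUE
    }
  }
  if (!any_def || sum_abc == 0) return(NA_real_)
  sum_a / sum_abc
}

.wc_theta <- function(dataset, pops) {
  .wc_theta_prep(.wc_prep(dataset), match(pops, levels(dataset$pop)))
}

#' Weir & Cockerham pairwise F_ST
#'
#' Multi-allelic theta for diploid genotypes, with variance components
#' combined ratio-of-sums over alleles and loci. Returns `NA` when the pair
#' carries no polymorphism.
#'
#' @param dataset A `microsat_dataset`.
#' @param pop_a,pop_b Population labels.
#' @return Estimated theta (a scalar, at most 1), or `NA`.
#' @export
wc_fst <- function(dataset, pop_a, pop_b) {
  stopifnot(sum(dataset$pop == pop_a) >= 2, sum(dataset$pop == pop_b) >= 2)
  .wc_theta(dataset, c(pop_a, pop_b))
}

#' Permutation test for pairwise F_ST
#'
#' Permutes individuals between the two populations and reports
#' `p = (1 + #permuted theta >= observed) / (n_perm + 1)`.
#'
#' @param dataset A `microsat_dataset`.
#' @param pop_a,pop_b Population labels.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List `theta` (observed) and `p_value`.
#' @export
permutation_test_fst <- function(dataset, pop_a, pop_b, n_perm = 999,
                                 seed = 1) {
  stopifnot(n_perm >= 99)
  obs <- wc_fst(dataset, pop_a, pop_b)
  if (is.na(obs)) return(list(theta = NA_real_, p_value = NA_real_))
  idx <- which(dataset$pop %in% c(pop_a, pop_b))
  sub <- list(alleles = dataset$alleles[idx, , , drop = FALSE],
              pop = factor(dataset$pop[idx]))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pd <- sub
    pd$pop <- sub$pop[sample(length(idx))]
    th <- .wc_theta(pd, c(pop_a, pop_b))
    if (!is.na(th) && th >= obs) hits <- hits + 1L
  }
  list(theta = obs, p_value = (1 + hits) / (n_perm + 1))
}

#' Goldstein's (delta mu)^2 distance
#'
#' Squared difference of mean repeat counts between two populations,
#' averaged over loci with data in both.
#'
#' @param dataset A `microsat_dataset`.
#' @param pop_a,pop_b Population labels.
#' @return The distance, or `NA` if no locus has data in both populations.
#' @export
delta_mu2 <- function(dataset, pop_a, pop_b) {
  a <- .allele_rows(dataset, pop_a)
  b <- .allele_rows(dataset, pop_b)
  per_locus <- vapply(seq_len(ncol(a)), function(l) {
    xa <- a[, l]; xb <- b[, l]
    if (all(is.na(xa)) || all(is.na(xb))) return(NA_real_)
    (mean(xa, na.rm = TRUE) - mean(xb, na.rm = TRUE))^2
  }, numeric(1))
  if (all(is.na(per_locus))) NA_real_ else mean(per_locus, na.rm = TRUE)
}

#' Assemble the ABC summary-statistic vector
#'
#' Deterministically ordered, named vector: a within-population block (4
#' statistics per population: allele number, expected heterozygosity,
#' allelic size range, M-ratio), a pairwise block (Weir & Cockerham F_ST and
#' (delta mu)^2 for every unordered pair), and a global block (total
#' distinct alleles summed over loci, overall multi-population F_ST, mean
#' He, mean allelic range, total private-allele count). For the default 11
#' populations this yields 4*11 + 2*55 + 5 = 159 statistics. Undefined
#' statistics are encoded as `NA` (the ABC layer imputes them).
#'
#' @param dataset A valid `microsat_dataset`.
#' @return Named numeric `summary_stat_vector`.
#' @export
assemble_stat_vector <- function(dataset) {
  stopifnot(isTRUE(dataset$valid))
  pops <- levels(dataset$pop)
  P <- length(pops)
  out <- numeric(0)
  for (p in pops) {
    w <- within_pop_stats(dataset, p)
    v <- c(w$n_alleles, w$He, w$range, w$M_ratio)
    names(v) <- paste0(c("nall_", "He_", "range_", "M_"), p)
    out <- c(out, v)
  }
  prep <- .wc_prep(dataset)
  if (P >= 2) {
    # mean repeat count per population per locus, for (delta mu)^2
    mrep <- vapply(prep, function(lp) {
      tot <- rowSums(lp$cnt)
      ifelse(tot > 0, as.vector(lp$cnt %*% lp$alleles) / tot, NA_real_)
    }, numeric(P))
    if (is.null(dim(mrep))) mrep <- matrix(mrep, nrow = 1)
    for (i in seq_len(P - 1)) for (j in (i + 1):P) {
      dm <- mean((mrep[i, ] - mrep[j, ])^2, na.rm = TRUE)
      v <- c(.wc_theta_prep(prep, c(i, j)), if (is.nan(dm)) NA_real_ else dm)
      names(v) <- paste0(c("fst_", "dmu2_"), pops[i], ".", pops[j])
      out <- c(out, v)
    }
  }
  total_alleles <- sum(vapply(prep, `[[`, integer(1), "n_all"))
  private <- sum(vapply(prep, function(lp) {
    if (!lp$n_all) return(0L)
    sum(colSums(lp$cnt > 0) == 1L)
  }, integer(1)))
  he_idx <- grep("^He_", names(out))
  rng_idx <- grep("^range_", names(out))
  glob <- c(total_alleles = total_alleles,
            overall_fst = if (P >= 2) .wc_theta(dataset, pops) else NA_real_,
            mean_He = mean(out[he_idx], na.rm = TRUE),
            mean_range = mean(out[rng_idx], na.rm = TRUE),
            private_alleles = private)
  structure(c(out, glob), class = "summary_stat_vector")
}
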