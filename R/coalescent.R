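#' Sampling design for the spatial coalescent
#'
#' @param sites Data frame with columns `name`, `lat`, `lon`, `n_ind`
#'   (diploid individuals per site).
#' @param n_loci Number of independent microsatellite loci (default 10).
#' @return A `sample_design` object.
#' @export
sample_design <- function(sites, n_loci = 10) {
  stopifnot(all(c("name", "lat", "lon", "n_ind") %in% names(sites)),
            n_loci >= 1, all(sites$n_ind >= 0))
  structure(list(sites = as.data.frame(sites), n_loci = as.integer(n_loci)),
            class = "sample_design")
}

# Nearest habitable cell (linear index) for each (lat, lon) site.
.site_cells <- function(grid, sites) {
  hab <- which(grid$habitable)
  vapply(seq_len(nrow(sites)), function(i) {
    d <- .gc_km(sites$lat[i], sites$lon[i],
                as.vector(grid$lat)[hab], as.vector(grid$lon)[hab])
    hab[which.min(d)]
  }, integer(1))
}

# Pool assignment (0 = North, 1 = South) for every cell by great-circle
# distance to the two origins; ties go North.
.pool_of_cell <- function(grid, params) {
  oc <- function(cell) c(grid$lat[cell[1], cell[2]], grid$lon[cell[1], cell[2]])
  on <- oc(params$origin_north); os <- oc(params$origin_south)
  lat <- as.vector(grid$lat); lon <- as.vector(grid$lon)
  dn <- .gc_km(lat, lon, on[1], on[2])
  ds <- .gc_km(lat, lon, os[1], os[2])
  as.integer(ds < dn)
}

#' Backward migration distribution for one deme and generation
#'
#' Inverts the recorded forward migrant counts: a lineage found in deme `j`
#' at generation `tau` immigrated from cardinal neighbour `i` during the step
#' `tau - 1 -> tau` with probability `E[i -> j] / N_j(tau)`; the remaining
#' mass stays in `j`. Probabilities exceeding 1 in total (possible in
#' deterministic mode with extreme growth) are clipped with a warning.
#'
#' @param db A `demographic_db` from [run_forward()].
#' @param cell Integer `c(row, col)` of the focal deme.
#' @param tau Generation index in `1..t_exp` (the arrival generation).
#' @return Named numeric length-5 vector `(N, E, S, W, stay)` summing to 1.
#' @export
backward_migration <- function(db, cell, tau) {
  t_exp <- nrow(db$N) - 1L
  stopifnot(tau >= 1, tau <= t_exp)
  j <- (cell[2] - 1L) * db$n_rows + cell[1]
  Nj <- db$N[tau + 1L, j]
  if (Nj <= 0) stop("deme has zero size at this generation")
  grid_dims <- list(n_rows = db$n_rows, n_cols = db$n_cols,
                    habitable = matrix(TRUE, db$n_rows, db$n_cols))
  nb <- .neighbour_table(grid_dims)
  p <- numeric(4)
  for (d in 1:4) {
    src <- nb[j, d]
    if (!is.na(src)) p[d] <- db$E[tau, src, ((d + 1L) %% 4L) + 1L] / Nj
  }
  if (sum(p) > 1) {
    warning("immigrant counts exceed deme size; probabilities clipped")
    p <- p / sum(p)
  }
  stats::setNames(c(p, 1 - sum(p)), c("N", "E", "S", "W", "stay"))
}

#' Simulate genealogies conditional on a demographic history
#'
#' Tracks the sampled gene copies backward through the recorded expansion:
#' per generation, co-located pairs coalesce with probability `1/N_d(tau)`
#' and surviving lineages relocate by [backward_migration()]. At the
#' expansion onset remaining lineages collapse into the ancestral pool of
#' the origin nearest their deme; pools are panmictic (sizes `anc_north`,
#' `anc_south`) until `t_div`, when they merge into a single ancestor of
#' summed size.
#'
#' @param db A `demographic_db` from [run_forward()].
#' @param grid The `landscape_grid` the database was simulated on.
#' @param design A [sample_design()]; every site must map to a colonized deme.
#' @param locus_count Number of independent genealogies to draw.
#' @param seed Integer seed.
#' @return A list of `genealogy` objects (fields `parent`, `time`, `deme`,
#'   `n_leaves`, `leaf_pop`); leaves are numbered site by site, two gene
#'   copies per individual.
#' @export
simulate_genealogy <- function(db, grid, design, locus_count = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- db$params
  cells <- .site_cells(grid, design$sites)
  present <- db$N[nrow(db$N), ]
  bad <- present[cells] <= 0
  if (any(bad))
    stop("sampled site(s) map to uncolonized demes: ",
         paste(design$sites$name[bad], collapse = ", "))
  copies <- 2L * design$sites$n_ind
  if (any(present[cells] < copies))
    stop("sample larger than the deme supports at present")
  leaf_cell <- rep(cells, copies) - 1L
  leaf_pop <- rep(seq_len(nrow(design$sites)), copies)
  pool <- .pool_of_cell(grid, p)
  nbt <- .neighbour_table(grid)
  nbt[is.na(nbt)] <- 0L
  nbt <- nbt - 1L  # 0-based, -1 = none
  lapply(seq_len(locus_count), function(l) {
    g <- .spatial_coal_cpp(db$N, as.numeric(db$E), nbt, leaf_cell, pool,
                           p$anc_north, p$anc_south, p$t_exp, p$t_div)
    structure(list(parent = g$parent, time = g$time, deme = g$deme,
                   n_leaves = length(leaf_cell), leaf_pop = leaf_pop,
                   n_clipped = g$n_clipped),
              class = "genealogy")
  })
}

#' Drop generalized stepwise mutations on a genealogy
#'
#' Mutation counts on a branch of length `t` are Poisson(`mu * t`); each
#' mutation shifts the repeat count by `+S` or `-S` with equal probability,
#' `S ~ Geometric(p_gsm)` on 1, 2, ... (`p_gsm = 1` is the strict stepwise
#' model). Repeat counts are floored at 1.
#'
#' @param genealogy A `genealogy` object.
#' @param mu Mutation rate per locus per generation.
#' @param p_gsm Geometric step parameter in (0, 1].
#' @param ancestral_repeat Repeat count at the root (default 20).
#' @param seed Optional integer seed.
#' @return Integer vector of leaf repeat counts.
#' @export
apply_gsm <- function(genealogy, mu, p_gsm, ancestral_repeat = 20, seed = NULL) {
  stopifnot(mu >= 0, p_gsm > 0, p_gsm <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_nodes <- length(genealogy$parent)
  val <- integer(n_nodes)
  root <- which(genealogy$parent == -1L)
  val[root] <- ancestral_repeat
  ord <- order(genealogy$time, decreasing = TRUE)
  for (i in ord) {
    if (genealogy$parent[i] == -1L) next
    par <- genealogy$parent[i] + 1L
    len <- genealogy$time[par] - genealogy$time[i]
    nm <- stats::rpois(1, mu * len)
    step <- 0L
    if (nm > 0) {
      sizes <- stats::rgeom(nm, p_gsm) + 1L
      signs <- sample(c(-1L, 1L), nm, replace = TRUE)
      step <- sum(sizes * signs)
    }
    val[i] <- max(1L, val[par] + step)
  }
  as.integer(val[seq_len(genealogy$n_leaves)])
}

#' Simulate one microsatellite dataset under the spatial model
#'
#' Full generative chain for one parameter draw: forward expansion
#' ([run_forward()]), then per locus a conditioned genealogy
#' ([simulate_genealogy()]) with generalized stepwise mutations
#' ([apply_gsm()]); the two gene copies of each diploid individual are paired
#' into genotypes. If a sampled deme is uncolonized at present the call
#' returns an invalid marker object instead of failing (the ABC layer counts
#' it as a rejected draw).
#'
#' @param grid A `landscape_grid`.
#' @param params A [spatial_params()] object.
#' @param design A [sample_design()].
#' @param seed Integer seed (drives forward and backward stages).
#' @param mode Forward mode, `"deterministic"` (default) or `"stochastic"`.
#' @param db Optional precomputed `demographic_db` to reuse.
#' @return A `microsat_dataset`: integer array `alleles` of dim
#'   `(individuals, loci, 2)`, factor `pop`, the `sites` table and
#'   `valid = TRUE`; or `valid = FALSE` with a `reason` when sampling failed.
#' @export
simulate_microsat_dataset <- function(grid, params, design, seed,
                                      mode = "deterministic", db = NULL) {
  set.seed(seed)
  if (is.null(db))
    db <- run_forward(grid, params, mode = mode,
                      seed = if (mode == "stochastic") seed else NULL)
  set.seed(seed + 1L)
  n_ind <- sum(design$sites$n_ind)
  if (n_ind == 0) {
    return(structure(list(alleles = array(integer(0), c(0, design$n_loci, 2)),
                          pop = factor(character(0)),
                          sites = design$sites, valid = TRUE),
                     class = "microsat_dataset"))
  }
  gens <- tryCatch(
    simulate_genealogy(db, grid, design, locus_count = design$n_loci),
    error = function(e) e)
  if (inherits(gens, "error")) {
    return(structure(list(alleles = NULL, pop = NULL, sites = design$sites,
                          valid = FALSE, reason = conditionMessage(gens)),
                     class = "microsat_dataset"))
  }
  alleles <- array(NA_integer_, c(n_ind, design$n_loci, 2))
  for (l in seq_len(design$n_loci)) {
    leaves <- apply_gsm(gens[[l]], params$mu, params$p_gsm)
    alleles[, l, 1] <- leaves[seq(1, 2 * n_ind, by = 2)]
    alleles[, l, 2] <- leaves[seq(2, 2 * n_ind, by = 2)]
  }
  pop <- factor(rep(design$sites$name, design$sites$n_ind),
                levels = design$sites$name)
  structure(list(alleles = alleles, pop = pop, sites = design$sites,
                 valid = TRUE),
            class = "microsat_dataset")
}

#' @export
print.microsat_dataset <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat("microsat_dataset: INVALID (", x$reason, ")\n")
  } else {
    cat(sprintf("microsat_dataset: %d individuals, %d populations, %d loci\n",
                dim(x$alleles)[1], nlevels(x$pop), dim(x$alleles)[2]))
  }
  invisible(x)
}

#' Write a microsatellite dataset in GenePop format
#'
#' Diploid two-allele genotypes with 3-digit allele codes; populations are
#' separated by `Pop` lines. Site coordinates go to a sidecar TSV
#' (`<path>.coords.tsv`) since GenePop itself carries none.
#'
#' @param dataset A valid `microsat_dataset`.
#' @param path Output file path.
#' @export
write_genepop <- function(dataset, path) {
  stopifnot(isTRUE(dataset$valid))
  n_loci <- dim(dataset$alleles)[2]
  out <- c("paleorange microsatellite dataset",
           paste0("locus", seq_len(n_loci)))
  for (p in levels(dataset$pop)) {
    out <- c(out, "Pop")
    idx <- which(dataset$pop == p)
    for (i in idx) {
      g <- vapply(seq_len(n_loci), function(l) {
        a <- dataset$alleles[i, l, ]
        if (anyNA(a)) "000000" else sprintf("%03d%03d", a[1], a[2])
      }, character(1))
      out <- c(out, paste0(p, " ,  ", paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  utils::write.table(dataset$sites, paste0(path, ".coords.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GenePop microsatellite file
#'
#' @param path Path to a GenePop file written by [write_genepop()] (or any
#'   3-digit diploid GenePop file with one locus name per line); if a sidecar
#'   `<path>.coords.tsv` exists it supplies site coordinates.
#' @return A `microsat_dataset`.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pop_rows <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_rows)) stop("GenePop: no 'Pop' separator found")
  n_loci <- pop_rows[1] - 2L
  if (n_loci < 1) stop("GenePop: no locus names before first 'Pop'")
  pop_of <- findInterval(seq_along(lines), pop_rows)
  geno_rows <- setdiff(which(pop_of >= 1), pop_rows)
  n_ind <- length(geno_rows)
  alleles <- array(NA_integer_, c(n_ind, n_loci, 2))
  pop_names <- character(n_ind)
  for (ii in seq_along(geno_rows)) {
    ln <- lines[geno_rows[ii]]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("GenePop: malformed genotype line: ", ln)
    pop_names[ii] <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(codes) != n_loci)
      stop("GenePop: expected ", n_loci, " genotypes, found ", length(codes))
    for (l in seq_len(n_loci)) {
      a1 <- as.integer(substr(codes[l], 1, 3))
      a2 <- as.integer(substr(codes[l], 4, 6))
      if (!is.na(a1) && a1 > 0) alleles[ii, l, 1] <- a1
      if (!is.na(a2) && a2 > 0) alleles[ii, l, 2] <- a2
    }
  }
  pop_id <- pop_of[geno_rows]
  lab <- vapply(split(pop_names, pop_id), function(x) x[1], character(1))
  pop <- factor(lab[as.character(pop_id)], levels = unique(lab))
  sites <- NULL
  side <- paste0(path, ".coords.tsv")
  if (file.exists(side))
    sites <- utils::read.table(side, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  structure(list(alleles = alleles, pop = pop, sites = sites, valid = TRUE),
            class = "microsat_dataset")
}
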