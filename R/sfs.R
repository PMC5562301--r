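#' Joint two-dimensional site frequency spectrum
#'
#' An `(n1 + 1) x (n2 + 1)` matrix of SNP counts indexed by allele count in
#' each of two population groups (0-based); `folded = TRUE` means indices are
#' minor-allele counts, with mass only where the combined count is at most
#' `(n1 + n2) / 2`.
#'
#' @param mat Non-negative numeric matrix.
#' @param n1,n2 Sample sizes in gene copies; default from `dim(mat) - 1`.
#' @param folded Logical flag.
#' @return An `sfs2d` object.
#' @export
sfs2d <- function(mat, n1 = nrow(mat) - 1L, n2 = ncol(mat) - 1L,
                  folded = FALSE) {
  stopifnot(is.matrix(mat), all(mat >= 0),
            nrow(mat) == n1 + 1L, ncol(mat) == n2 + 1L)
  structure(list(mat = mat, n1 = as.integer(n1), n2 = as.integer(n2),
                 folded = folded), class = "sfs2d")
}

#' @export
print.sfs2d <- function(x, ...) {
  cat(sprintf("sfs2d: n1 = %d, n2 = %d, %s, %.0f SNPs\n",
              x$n1, x$n2, if (x$folded) "folded" else "unfolded",
              sum(x$mat)))
  invisible(x)
}

#' Fold a joint SFS onto minor-allele counts
#'
#' Every cell `(i, j)` with `i + j > (n1 + n2) / 2` is added into its
#' complement `(n1 - i, n2 - j)`; cells exactly at half the total are split
#' evenly between the two complements. Total SNP mass is conserved.
#'
#' @param unfolded An unfolded `sfs2d`.
#' @return A folded `sfs2d`.
#' @export
fold_sfs <- function(unfolded) {
  stopifnot(inherits(unfolded, "sfs2d"))
  if (unfolded$folded) stop("SFS is already folded")
  n1 <- unfolded$n1; n2 <- unfolded$n2
  half <- (n1 + n2) / 2
  m <- unfolded$mat
  out <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in 0:n1) for (j in 0:n2) {
    v <- m[i + 1L, j + 1L]
    if (v == 0) next
    tot <- i + j
    if (tot < half) {
      out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + v
    } else if (tot > half) {
      out[n1 - i + 1L, n2 - j + 1L] <- out[n1 - i + 1L, n2 - j + 1L] + v
    } else {
      out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + v / 2
      out[n1 - i + 1L, n2 - j + 1L] <- out[n1 - i + 1L, n2 - j + 1L] + v / 2
    }
  }
  sfs2d(out, n1, n2, folded = TRUE)
}

# Logical mask of the cells that enter the composite likelihood: everything
# except the monomorphic corner(s).
.polymorphic_mask <- function(sfs) {
  msk <- matrix(TRUE, sfs$n1 + 1L, sfs$n2 + 1L)
  msk[1, 1] <- FALSE
  if (!sfs$folded) msk[sfs$n1 + 1L, sfs$n2 + 1L] <- FALSE
  msk
}

#' Composite log-likelihood of an observed SFS
#'
#' Treats SNPs as independent multinomial draws over the polymorphic SFS
#' cells: `CL = sum over cells obs_ij * log p_ij`, with `p` the expected SFS
#' normalized to proportions over polymorphic cells (the monomorphic corner
#' is excluded) and floored at `eps` so observed mass in an empty expected
#' cell stays finite.
#'
#' @param obs,expected `sfs2d` objects of identical shape and folding.
#' @param eps Probability floor for empty expected cells (default 1e-10).
#' @return The composite log-likelihood (a scalar).
#' @export
composite_loglik <- function(obs, expected, eps = 1e-10) {
  stopifnot(inherits(obs, "sfs2d"), inherits(expected, "sfs2d"))
  if (obs$n1 != expected$n1 || obs$n2 != expected$n2 ||
      obs$folded != expected$folded)
    stop("observed and expected SFS have different shape or folding")
  msk <- .polymorphic_mask(obs)
  e <- expected$mat[msk]
  o <- obs$mat[msk]
  tot <- sum(e)
  if (tot <= 0) stop("expected SFS has no polymorphic mass")
  p <- pmax(e / tot, eps)
  sum(o * log(p))
}

#' Write an SFS as plain text
#'
#' One header line `n1 n2 folded|unfolded`, then the `(n1+1) x (n2+1)`
#' matrix, one row per line.
#'
#' @param sfs An `sfs2d`.
#' @param path Output path.
#' @export
write_sfs <- function(sfs, path) {
  hdr <- paste(sfs$n1, sfs$n2, if (sfs$folded) "folded" else "unfolded")
  body <- apply(sfs$mat, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an SFS written by [write_sfs()]
#' @param path Input path.
#' @return An `sfs2d`.
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 3) stop("SFS header must be 'n1 n2 folded|unfolded'")
  n1 <- as.integer(hdr[1]); n2 <- as.integer(hdr[2])
  folded <- identical(hdr[3], "folded")
  rows <- lapply(lines[-1][seq_len(n1 + 1L)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  mat <- do.call(rbind, rows)
  sfs2d(mat, n1, n2, folded = folded)
}
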