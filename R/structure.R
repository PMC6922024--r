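# Weir & Cockerham (1984) two-level variance components for one biallelic
# locus and r = 2 populations.  n, p, h: per-population sample size
# (non-missing diploids), allele frequency and observed het frequency.
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham FST
#'
#' Multilocus theta between two populations from the Weir & Cockerham
#' (1984) variance components: per locus, among-population (`a`),
#' between-individual (`b`) and within-individual (`c`) components are
#' computed from sample sizes, allele frequencies and observed heterozygote
#' frequencies; the multilocus estimate is the ratio of sums
#' \eqn{\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)}.  Negative per-locus
#' components are retained (not truncated).  Loci monomorphic across both
#' populations, or with fewer than two non-missing genotypes in either
#' population, are excluded.
#'
#' @param g a [genotypes] panel.
#' @param pop_a,pop_b population labels.
#' @return multilocus theta (scalar).
#' @export
pairwise_fst <- function(g, pop_a, pop_b) {
  da <- pop_dosage(g, pop_a)
  db <- pop_dosage(g, pop_b)
  na_ <- colSums(!is.na(da)); nb_ <- colSums(!is.na(db))
  pa <- colMeans(da, na.rm = TRUE) / 2
  pb <- colMeans(db, na.rm = TRUE) / 2
  ha <- colMeans(da == 1L, na.rm = TRUE)
  hb <- colMeans(db == 1L, na.rm = TRUE)
  use <- na_ >= 2 & nb_ >= 2 & !(pa %in% c(0, 1) & pb == pa)
  if (!any(use)) stop("no usable polymorphic loci between ", pop_a, " and ", pop_b)
  num <- den <- 0
  for (l in which(use)) {
    abc <- wc_components(c(na_[l], nb_[l]), c(pa[l], pb[l]), c(ha[l], hb[l]))
    if (anyNA(abc)) next
    num <- num + abc["a"]
    den <- den + sum(abc)
  }
  if (den == 0) stop("zero FST denominator between ", pop_a, " and ", pop_b)
  unname(num / den)
}

#' Pairwise FST matrix over all populations
#'
#' @param g a [genotypes] panel with at least two populations.
#' @return object of class `"fst_matrix"`: list with `populations` and
#'   `values` (symmetric matrix, zero diagonal).
#' @export
fst_matrix <- function(g) {
  pops <- populations(g)
  if (length(pops) < 2) stop("need >= 2 populations for an FST matrix")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    th <- tryCatch(pairwise_fst(g, pops[i], pops[j]),
                   error = function(e) stop("FST failed for pair (", pops[i],
                                            ", ", pops[j], "): ",
                                            conditionMessage(e), call. = FALSE))
    m[i, j] <- m[j, i] <- th
  }
  structure(list(populations = pops, values = m), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise Weir-Cockerham FST (", length(x$populations), " populations)\n",
      sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Identity-by-state distance matrix
#'
#' Per sample pair, `1 - shared alleles / (2 x loci compared)`, where a
#' locus contributes `2 - |x_i - x_j|` shared alleles and loci missing in
#' either sample are skipped.
#'
#' @param g a [genotypes] panel with >= 2 samples.
#' @return symmetric samples x samples distance matrix (zero diagonal).
#' @export
ibs_distance_matrix <- function(g) {
  x <- g$dosage
  n <- nrow(x)
  if (n < 2) stop("need >= 2 samples for IBS distances")
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0L
  xo <- x0 * obs
  # sum over shared loci of |xi - xj| = sum xi^2 + xj^2 - 2 xi xj is wrong for L1;
  # use the identity |a-b| for a,b in {0,1,2}: |a-b| = a + b - 2*min(a,b).
  # min(a,b) decomposes on indicators of >=1 and ==2:
  ge1 <- (x0 >= 1L) * obs
  eq2 <- (x0 == 2L) * obs
  sum_min <- tcrossprod(ge1) + tcrossprod(eq2)          # sum over shared loci of min
  sum_a <- xo %*% t(obs * 1) ; sum_b <- t(sum_a)
  n_loci <- tcrossprod(obs * 1)
  if (any(n_loci[upper.tri(n_loci)] == 0)) {
    bad <- which(n_loci == 0 & upper.tri(n_loci), arr.ind = TRUE)[1, ]
    stop("no comparable loci between samples ", g$samples$id[bad[1]], " and ",
         g$samples$id[bad[2]])
  }
  l1 <- sum_a + sum_b - 2 * sum_min
  d <- l1 / (2 * n_loci)
  diag(d) <- 0
  dimnames(d) <- list(g$samples$id, g$samples$id)
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-d^2/2`, eigendecomposes, and scales the top-`k`
#' eigenvectors by the square root of their eigenvalues.  Explained
#' fractions are eigenvalues over the sum of positive eigenvalues.  `k` is
#' reduced with a warning if fewer positive eigenvalues exist.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param k number of axes.
#' @return object of class `"ordination"`: `ids`, `coordinates`
#'   (n x k), `explained` (fraction per axis).
#' @export
classical_mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), all(abs(diag(d)) < 1e-12))
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(abs(e$values), 1e-300)
  npos <- sum(pos)
  if (k > npos) {
    warning("k reduced from ", k, " to ", npos, " positive eigenvalues")
    k <- npos
  }
  if (k < 1) stop("no positive eigenvalues in MDS")
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  rownames(coords) <- rownames(d)
  structure(list(ids = rownames(d), coordinates = coords,
                 explained = e$values[seq_len(k)] / sum(e$values[pos])),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination: ", nrow(x$coordinates), " samples x ",
      ncol(x$coordinates), " axes; explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Principal component analysis of genotypes
#'
#' Centers dosages by `2p` per locus (`p` estimated from non-missing
#' calls), mean-imputes missing dosages, optionally applies Patterson
#' scaling `1/sqrt(p(1-p))`, and takes the SVD of the samples x loci
#' matrix.  Monomorphic loci are excluded under Patterson scaling.
#' Explained fractions come from the squared singular values.
#'
#' @param g a QC'd [genotypes] panel.
#' @param k number of axes.
#' @param scaling `"patterson"` (default) or `"unit"` (no variance
#'   scaling).
#' @return an `"ordination"` (see [classical_mds]).
#' @export
pca_genotypes <- function(g, k = 2L, scaling = c("patterson", "unit")) {
  scaling <- match.arg(scaling)
  x <- g$dosage
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- !is.nan(p)
  if (scaling == "patterson") keep <- keep & p > 0 & p < 1
  x <- x[, keep, drop = FALSE]; p <- p[keep]
  xm <- sweep(x, 2, 2 * p, "-")
  xm[is.na(xm)] <- 0                     # mean imputation after centering
  if (scaling == "patterson") xm <- sweep(xm, 2, sqrt(p * (1 - p)), "/")
  sv <- svd(xm, nu = min(k, nrow(xm)), nv = 0)
  k <- min(k, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(coords) <- g$samples$id
  structure(list(ids = g$samples$id, coordinates = coords,
                 explained = sv$d[seq_len(k)]^2 / sum(sv$d^2)),
            class = "ordination")
}
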