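#' Map physical distance to recombination rate
#'
#' Converts a physical SNP-pair distance into a recombination rate `c` in
#' Morgans.  `"linear"` applies a constant rate (default 1 cM/Mb);
#' `"sved_feldman"` additionally applies the non-linear adjustment
#' `c = d / (1 + 2 d)` to the linear map distance `d`, damping large
#' distances.  Both are capped just below 0.5.
#'
#' @param d_bp physical distance(s) in bp, `> 0`.
#' @param mapping `"linear"` or `"sved_feldman"`.
#' @param rate_M_per_Mb local recombination rate for the linear map
#'   (Morgans per Mb; default 0.01 = 1 cM/Mb).
#' @return recombination rate(s) in Morgans, in `(0, 0.5)`.
#' @export
map_distance_to_c <- function(d_bp, mapping = c("linear", "sved_feldman"),
                              rate_M_per_Mb = 0.01) {
  mapping <- match.arg(mapping)
  stopifnot(all(d_bp > 0))
  d_lin <- (d_bp / 1e6) * rate_M_per_Mb
  c_out <- switch(mapping, linear = d_lin, sved_feldman = d_lin / (1 + 2 * d_lin))
  pmin(c_out, 0.5 - 1e-9)
}

#' Sample-size correction of mean r-squared
#'
#' Subtracts the finite-sample inflation `1/(beta * n)` from a mean squared
#' correlation: `beta = 1` for unphased dosage data (the default for array
#' genotypes), `beta = 2` for phased haplotypes.  Values that would go
#' non-positive are floored at a small epsilon with a warning.
#'
#' @param mean_r2 mean squared correlation(s).
#' @param n sample count (diploid individuals).
#' @param phased haplotype data?
#' @param eps positive floor.
#' @return corrected mean r-squared.
#' @export
correct_r2 <- function(mean_r2, n, phased = FALSE, eps = 1e-6) {
  stopifnot(n >= 2)
  beta <- if (phased) 2 else 1
  adj <- mean_r2 - 1 / (beta * n)
  if (any(adj <= 0, na.rm = TRUE)) {
    warning(sum(adj <= 0, na.rm = TRUE),
            " bin(s) floored at eps in sample-size correction")
    adj[!is.na(adj) & adj <= 0] <- eps
  }
  adj
}

#' Distance bins targeting a grid of generations ago
#'
#' Builds physical-distance bin edges whose representative distances map,
#' under the linear 1 cM/Mb map, to `t = 1/(2c)` exactly at the requested
#' generation grid (so `t = 5` and `t = 50` are representable).  Edges are
#' geometric means between adjacent representative distances.
#'
#' @param t_grid generations-ago targets, ascending.
#' @param rate_M_per_Mb linear map rate.
#' @return data.frame with `t_target`, `d_rep` (bp), `d_min`, `d_max`.
#' @export
ld_bins_for_generations <- function(t_grid = c(5, 10, 15, 20, 25, 30, 40,
                                               50, 65, 80, 100),
                                    rate_M_per_Mb = 0.01) {
  t_grid <- sort(unique(t_grid))
  d_rep <- 1 / (2 * t_grid * rate_M_per_Mb * 1e-6)     # bp; descending in t
  d_rep <- rev(d_rep)                                   # ascending distances
  inner <- sqrt(d_rep[-1] * d_rep[-length(d_rep)])
  ratio <- if (length(d_rep) > 1) sqrt(d_rep[2] / d_rep[1]) else sqrt(2)
  edges <- c(d_rep[1] / ratio, inner, d_rep[length(d_rep)] * ratio)
  data.frame(t_target = rev(t_grid), d_rep = d_rep,
             d_min = edges[-length(edges)], d_max = edges[-1])
}

#' Distance-binned pairwise linkage disequilibrium
#'
#' For every same-chromosome SNP pair within `max_dist_bp`, computes
#' r-squared as the squared Pearson correlation of dosage vectors over
#' individuals non-missing at both loci, and averages within physical
#' distance bins.  Zero-variance loci are skipped; bins with fewer than
#' `min_pairs` pairs are flagged (`usable = FALSE`).
#'
#' @param g a [genotypes] panel.
#' @param population population label.
#' @param bins data.frame from [ld_bins_for_generations] (or any frame
#'   with `d_min`, `d_max`, `d_rep` columns).
#' @param min_maf within-population MAF floor for loci entering pairs.
#' @param min_pairs minimum pair count per usable bin.
#' @return data.frame per bin: `d_min`, `d_max`, `d_rep`, `n_pairs`,
#'   `mean_r2`, `usable` (plus `t_target` when present in `bins`).
#' @export
pairwise_r2_binned <- function(g, population, bins = ld_bins_for_generations(),
                               min_maf = 0.05, min_pairs = 50L) {
  d <- pop_dosage(g, population)
  if (nrow(d) < 2) stop("need >= 2 samples in population ", population)
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.nan(p) & pmin(p, 1 - p) >= min_maf
  max_dist <- max(bins$d_max)
  nb <- nrow(bins)
  sums <- numeric(nb); cnts <- integer(nb)
  for (idx in snp_index_by_chrom(g)) {
    use <- idx[keep[idx]]
    if (length(use) < 2) next
    pos <- g$snps$pos[use]
    x <- d[, use, drop = FALSE]
    r2 <- if (anyNA(x)) {
      suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))^2
    } else suppressWarnings(stats::cor(x))^2
    dist <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dist)
    dd <- dist[ut]; rr <- r2[ut]
    ok <- dd <= max_dist & !is.na(rr)
    dd <- dd[ok]; rr <- rr[ok]
    bi <- findInterval(dd, c(bins$d_min[1], bins$d_max), left.open = TRUE,
                       rightmost.closed = FALSE)
    inb <- bi >= 1 & bi <= nb & dd > bins$d_min[1]
    bi <- bi[inb]; rr <- rr[inb]
    sums <- sums + as.numeric(tapply(rr, factor(bi, levels = seq_len(nb)), sum,
                                     default = 0))
    cnts <- cnts + as.integer(tapply(rr, factor(bi, levels = seq_len(nb)), length,
                                     default = 0L))
  }
  out <- bins
  out$n_pairs <- cnts
  out$mean_r2 <- ifelse(cnts > 0, sums / cnts, NA_real_)
  out$usable <- cnts >= min_pairs
  out
}

#' Historical Ne trajectory from binned LD
#'
#' Converts distance-binned mean r-squared into effective population size
#' estimates: after the sample-size correction ([correct_r2]) each bin's
#' representative distance is mapped to a recombination rate `c`
#' ([map_distance_to_c]) and
#' \deqn{N_e(t) = \frac{1}{4c}\left(\frac{1}{r^2_{adj}} - \alpha\right),
#'   \qquad t = \frac{1}{2c},}
#' with `alpha_mut = 2.2` accounting for mutation.  Non-positive estimates
#' and unusable bins are dropped with a warning.
#'
#' @param bins output of [pairwise_r2_binned].
#' @param n sample count used for the r-squared estimates.
#' @param alpha_mut mutation adjustment (default 2.2).
#' @param mapping,rate_M_per_Mb see [map_distance_to_c].
#' @param phased passed to [correct_r2].
#' @return object of class `"ne_trajectory"`: data.frame `points`
#'   (`t`, `c`, `mean_r2`, `mean_r2_adj`, `n_pairs`, `Ne`, sorted by `t`)
#'   plus the configuration echo as attributes.
#' @export
ne_trajectory <- function(bins, n, alpha_mut = 2.2,
                          mapping = c("linear", "sved_feldman"),
                          rate_M_per_Mb = 0.01, phased = FALSE) {
  mapping <- match.arg(mapping)
  b <- bins[bins$usable & !is.na(bins$mean_r2), , drop = FALSE]
  if (!nrow(b)) stop("no usable LD bins for Ne estimation")
  cc <- map_distance_to_c(b$d_rep, mapping, rate_M_per_Mb)
  r2a <- correct_r2(b$mean_r2, n, phased = phased)
  ne <- (1 / (4 * cc)) * (1 / r2a - alpha_mut)
  tt <- 1 / (2 * cc)
  drop <- ne <= 0
  if (any(drop)) warning(sum(drop), " non-positive Ne point(s) dropped")
  if (all(drop)) stop("all Ne points non-positive")
  pts <- data.frame(t = tt, c = cc, mean_r2 = b$mean_r2, mean_r2_adj = r2a,
                    n_pairs = b$n_pairs, Ne = ne)[!drop, , drop = FALSE]
  pts <- pts[order(pts$t), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts,
                 config = list(alpha_mut = alpha_mut, mapping = mapping,
                               rate_M_per_Mb = rate_M_per_Mb, n = n,
                               phased = phased)),
            class = "ne_trajectory")
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("LD-based Ne trajectory (", nrow(x$points), " points, alpha = ",
      x$config$alpha_mut, ", mapping = ", x$config$mapping, ")\n", sep = "")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Ne at a target number of generations ago
#'
#' Returns the trajectory point whose `t` is nearest `t_target` (ties go to
#' the smaller `t`), reporting the achieved `t`.  Warns when the nearest
#' point is farther than `tol_factor` times the target.
#'
#' @param traj an `"ne_trajectory"`.
#' @param t_target generations ago (5 and 50 are the conventional recent /
#'   historical reference points).
#' @param tol_factor warn when `max(t/t_target, t_target/t)` exceeds this.
#' @return list with `Ne`, `t_achieved`, `t_target`.
#' @export
ne_at_generation <- function(traj, t_target, tol_factor = 2) {
  pts <- traj$points
  if (!nrow(pts)) stop("empty trajectory")
  i <- which.min(abs(pts$t - t_target))
  t_ach <- pts$t[i]
  if (max(t_ach / t_target, t_target / t_ach) > tol_factor)
    warning("nearest trajectory point t = ", signif(t_ach, 3),
            " is far from target t = ", t_target)
  list(Ne = pts$Ne[i], t_achieved = t_ach, t_target = t_target)
}

#' One-call Ne estimation for a population
#'
#' Convenience wrapper: bins LD, corrects it and returns the trajectory
#' plus the conventional `Ne_5` and `Ne_50` summaries.
#'
#' @inheritParams pairwise_r2_binned
#' @inheritParams ne_trajectory
#' @param t_grid generation targets for [ld_bins_for_generations].
#' @return list with `trajectory`, `Ne5`, `Ne50`.
#' @export
estimate_ne <- function(g, population, t_grid = c(5, 10, 15, 20, 25, 30, 40,
                                                  50, 65, 80, 100),
                        alpha_mut = 2.2, mapping = "linear",
                        rate_M_per_Mb = 0.01, min_maf = 0.05,
                        min_pairs = 50L, phased = FALSE) {
  bins <- ld_bins_for_generations(t_grid, rate_M_per_Mb)
  ld <- pairwise_r2_binned(g, population, bins, min_maf = min_maf,
                           min_pairs = min_pairs)
  n <- sum(g$samples$pop == population)
  traj <- ne_trajectory(ld, n, alpha_mut = alpha_mut, mapping = mapping,
                        rate_M_per_Mb = rate_M_per_Mb, phased = phased)
  list(trajectory = traj,
       Ne5 = ne_at_generation(traj, 5),
       Ne50 = ne_at_generation(traj, 50))
}
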