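#' Observed heterozygosity
#'
#' Per-locus fraction of non-missing genotypes that are heterozygous within
#' one population, and the mean over loci with at least one non-missing
#' call.
#'
#' @param g a [genotypes] panel.
#' @param population population label (must be present in `g`).
#' @return list with `per_locus` (numeric vector, `NaN` where no calls) and
#'   `mean`.
#' @export
observed_heterozygosity <- function(g, population) {
  d <- pop_dosage(g, population)
  per_locus <- colMeans(d == 1L, na.rm = TRUE)
  list(per_locus = per_locus, mean = mean(per_locus[!is.nan(per_locus)]))
}

#' Unbiased expected heterozygosity
#'
#' Nei's small-sample estimator per locus,
#' \deqn{\hat H_{e(u)} = \frac{2n}{2n-1}\,\bigl(1 - \sum_a p_a^2\bigr),}
#' with \eqn{n} the non-missing diploid count at the locus.  Loci with
#' fewer than two non-missing genotypes are skipped (returned `NA`) and
#' counted in the result.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus`, `mean` (over usable loci) and
#'   `n_skipped`.
#' @export
unbiased_expected_heterozygosity <- function(g, population) {
  d <- pop_dosage(g, population)
  n <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  he <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
  he[n < 2] <- NA_real_
  if (any(n < 2))
    message("unbiased He: ", sum(n < 2), " locus/loci skipped (n < 2)")
  list(per_locus = he, mean = mean(he, na.rm = TRUE), n_skipped = sum(n < 2))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles per locus in a standardized
#' subsample of `g_rarefy` gene copies (hypergeometric rarefaction), meaned
#' over loci and reported per population.  For a biallelic locus the value
#' lies in `[1, 2]`.
#'
#' Per locus and population, with \eqn{2N} non-missing gene copies of which
#' \eqn{N_a} carry allele \eqn{a}:
#' \deqn{A_r = \sum_a \left[1 -
#'   \binom{2N-N_a}{g}\Big/\binom{2N}{g}\right].}
#'
#' @param g a [genotypes] panel.
#' @param pops population labels (default: all in `g`).
#' @param g_rarefy gene-copy count to rarefy to, or `"auto"` = the smallest
#'   per-population, per-locus non-missing gene count (so every locus is
#'   usable everywhere).
#' @return list with `per_population` (named mean Ar), `per_locus` (matrix
#'   loci x populations) and `g_rarefy` used.
#' @export
rarefied_allelic_richness <- function(g, pops = populations(g), g_rarefy = "auto") {
  counts <- lapply(pops, function(pp) {
    d <- pop_dosage(g, pp)
    nb <- colSums(d, na.rm = TRUE)               # allele-b copies
    n2 <- 2 * colSums(!is.na(d))                 # gene copies
    cbind(n2 = n2, nb = nb)
  })
  names(counts) <- pops
  if (identical(g_rarefy, "auto")) {
    g_rarefy <- min(vapply(counts, function(m) min(m[, "n2"]), numeric(1)))
  }
  g_rarefy <- as.integer(g_rarefy)
  if (g_rarefy < 2) stop("g_rarefy must be >= 2")
  per_locus <- sapply(pops, function(pp) {
    m <- counts[[pp]]
    n2 <- m[, "n2"]; nb <- m[, "nb"]; na_ <- n2 - nb
    if (any(n2 < g_rarefy))
      stop("g_rarefy (", g_rarefy, ") exceeds gene copies at some locus in ", pp)
    term <- function(cnt)
      ifelse(cnt > 0, 1 - exp(lchoose(n2 - cnt, g_rarefy) - lchoose(n2, g_rarefy)), 0)
    ar <- term(na_) + term(nb)
    ar[n2 == 0] <- NA_real_
    ar
  })
  per_locus <- matrix(per_locus, ncol = length(pops),
                      dimnames = list(g$snps$id, pops))
  list(per_population = colMeans(per_locus, na.rm = TRUE),
       per_locus = per_locus, g_rarefy = g_rarefy)
}

#' Within-population inbreeding coefficient Fis
#'
#' \eqn{F_{IS} = 1 - \bar H_o / \bar H_{e(u)}} on locus-mean
#' heterozygosities (ratio of means), with a seeded percentile bootstrap
#' over loci for the 95% confidence interval.
#'
#' @inheritParams observed_heterozygosity
#' @param n_boot bootstrap replicates (resampling loci with replacement).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return list with `fis`, `ci` (length-2 numeric), `n_loci`.
#' @export
inbreeding_fis <- function(g, population, n_boot = 1000L, seed = 1L,
                           conf = 0.95) {
  ho <- observed_heterozygosity(g, population)$per_locus
  he <- unbiased_expected_heterozygosity(g, population)$per_locus
  use <- !is.na(he) & !is.nan(ho)
  ho <- ho[use]; he <- he[use]
  if (sum(he > 0) < 2) stop("need >= 2 polymorphic loci for Fis")
  if (mean(he) == 0) stop("mean unbiased He is zero; Fis undefined")
  fis <- 1 - mean(ho) / mean(he)
  L <- length(ho)
  boot <- local({
    old <- .Random.seed_exists()
    on.exit(.restore_seed(old))
    set.seed(seed)
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(L, L, replace = TRUE)
      m_he <- mean(he[i])
      if (m_he == 0) return(NA_real_)
      1 - mean(ho[i]) / m_he
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  list(fis = fis, ci = ci, n_loci = L)
}

# save/restore the global RNG state so seeded internals do not perturb
# the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Per-population diversity summary table
#'
#' Convenience wrapper assembling n, rarefied allelic richness, observed and
#' unbiased expected heterozygosity and Fis (with bootstrap CI) for every
#' population — the standard within-population diversity table of a
#' SNP-array breed survey.
#'
#' @param g a [genotypes] panel.
#' @param n_boot,seed,conf passed to [inbreeding_fis].
#' @param g_rarefy passed to [rarefied_allelic_richness].
#' @return data.frame with one row per population: `pop`, `n`, `Ar`, `Ho`,
#'   `He_u`, `Fis`, `Fis_lo`, `Fis_hi`.
#' @export
diversity_summary <- function(g, n_boot = 1000L, seed = 1L, conf = 0.95,
                              g_rarefy = "auto") {
  pops <- populations(g)
  ar <- rarefied_allelic_richness(g, pops, g_rarefy)$per_population
  rows <- lapply(pops, function(pp) {
    fis <- inbreeding_fis(g, pp, n_boot = n_boot, seed = seed, conf = conf)
    data.frame(pop = pp, n = sum(g$samples$pop == pp),
               Ar = unname(ar[pp]),
               Ho = observed_heterozygosity(g, pp)$mean,
               He_u = unbiased_expected_heterozygosity(g, pp)$mean,
               Fis = fis$fis, Fis_lo = fis$ci[1], Fis_hi = fis$ci[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
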