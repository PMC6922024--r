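#' Quality-control configuration
#'
#' Thresholds for [apply_qc], defaulting to the standard SNP-array settings
#' for livestock panels: samples with more than 10% missing calls, SNPs with
#' call rate below 0.90 or MAF below 0.05, and non-autosomal SNPs are
#' discarded.
#'
#' @param snp_call_rate_min minimum per-SNP call rate (fraction in `[0,1]`).
#' @param sample_missing_max maximum per-sample missing rate.
#' @param maf_min minimum minor allele frequency, computed on retained
#'   samples from non-missing calls.
#' @param autosomes_only drop SNPs outside `1..n_autosomes`?
#' @param n_autosomes autosome count (26 for sheep).
#' @return a list of class `"qc_config"`.
#' @export
qc_config <- function(snp_call_rate_min = 0.90, sample_missing_max = 0.10,
                      maf_min = 0.05, autosomes_only = TRUE, n_autosomes = 26L) {
  stopifnot(snp_call_rate_min >= 0, snp_call_rate_min <= 1,
            sample_missing_max >= 0, sample_missing_max <= 1,
            maf_min >= 0, maf_min <= 1, n_autosomes >= 1)
  structure(list(snp_call_rate_min = snp_call_rate_min,
                 sample_missing_max = sample_missing_max,
                 maf_min = maf_min, autosomes_only = autosomes_only,
                 n_autosomes = as.integer(n_autosomes)),
            class = "qc_config")
}

#' Apply genotype quality control
#'
#' Filters a panel in a fixed, reported order: (1) samples with missing rate
#' above `sample_missing_max`; (2) non-autosomal SNPs; (3) SNPs with call
#' rate below `snp_call_rate_min`; (4) SNPs with MAF below `maf_min`,
#' computed on the samples retained at step 1 from non-missing calls only.
#'
#' @param g a [genotypes] panel.
#' @param cfg a [qc_config].
#' @param verbose log per-step counts to stderr?
#' @return a list with elements `genotypes` (the filtered panel) and
#'   `report` (data.frame of per-step removal counts plus removed ids).
#' @export
apply_qc <- function(g, cfg = qc_config(), verbose = TRUE) {
  stopifnot(inherits(g, "genotypes"))
  if (n_snps(g) == 0 || n_samples(g) == 0) stop("empty panel supplied to apply_qc")

  steps <- list()
  # 1. sample missing rate
  miss_rate <- rowMeans(is.na(g$dosage))
  drop_sam <- miss_rate > cfg$sample_missing_max
  removed_samples <- g$samples$id[drop_sam]
  g <- g[!drop_sam, ]
  steps$samples_missing <- sum(drop_sam)
  if (n_samples(g) == 0) stop("empty after QC: all samples removed (missing rate)")

  # 2. autosomes
  if (cfg$autosomes_only) {
    drop_auto <- !(g$snps$chrom %in% seq_len(cfg$n_autosomes))
  } else drop_auto <- rep(FALSE, n_snps(g))
  g <- g[, !drop_auto]
  steps$snps_non_autosomal <- sum(drop_auto)

  # 3. SNP call rate
  if (n_snps(g)) {
    call_rate <- 1 - colMeans(is.na(g$dosage))
    drop_cr <- call_rate < cfg$snp_call_rate_min
  } else drop_cr <- logical(0)
  removed_cr <- g$snps$id[drop_cr]
  g <- g[, !drop_cr]
  steps$snps_call_rate <- sum(drop_cr)

  # 4. MAF on retained samples
  if (n_snps(g)) {
    m <- maf(g)
    drop_maf <- is.nan(m) | m < cfg$maf_min
  } else drop_maf <- logical(0)
  removed_maf <- g$snps$id[drop_maf]
  g <- g[, !drop_maf]
  steps$snps_maf <- sum(drop_maf)

  if (n_snps(g) == 0) stop("empty after QC: all SNPs removed")

  report <- data.frame(
    step = c("samples_missing", "snps_non_autosomal", "snps_call_rate", "snps_maf"),
    removed = c(steps$samples_missing, steps$snps_non_autosomal,
                steps$snps_call_rate, steps$snps_maf),
    remaining_samples = n_samples(g),
    remaining_snps = n_snps(g),
    stringsAsFactors = FALSE)
  if (verbose)
    message(paste(sprintf("QC %s: removed %d", report$step, report$removed),
                  collapse = "; "),
            "; kept ", n_samples(g), " samples x ", n_snps(g), " SNPs")
  list(genotypes = g, report = report,
       removed = list(samples = removed_samples,
                      snps_call_rate = removed_cr, snps_maf = removed_maf))
}

#' Unified additive relationship (UAR) matrix
#'
#' Genomic relationship estimator of Yang et al. type.  Off-diagonal entries
#' average, over SNPs non-missing in both individuals,
#' \deqn{A_{jk} = \mathrm{mean}_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)},}
#' and diagonal entries use the same-individual form
#' \deqn{A_{jj} = 1 + \mathrm{mean}_i \frac{x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2}{2p_i(1-p_i)},}
#' with allele frequencies \eqn{p_i} estimated from all non-missing calls.
#' Missing genotypes are excluded pairwise (per-pair SNP counts in the
#' denominator).
#'
#' @param g a QC'd [genotypes] panel (no monomorphic SNPs).
#' @return a list of class `"uar"`: `sample_ids`, `values` (symmetric
#'   samples x samples matrix).
#' @export
compute_uar <- function(g) {
  p <- allele_freq(g)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("monomorphic or all-missing SNP encountered; run apply_qc first")
  x <- g$dosage
  denom <- 2 * p * (1 - p)
  z <- sweep(sweep(x, 2, 2 * p, "-"), 2, sqrt(denom), "/")
  obs <- !is.na(z)
  z0 <- z; z0[!obs] <- 0
  npair <- tcrossprod(obs * 1)               # SNPs non-missing in both
  A <- tcrossprod(z0) / npair
  # diagonal: same-individual estimator
  dterm <- x^2 - sweep(x, 2, 1 + 2 * p, "*") +
    matrix(2 * p^2, nrow(x), ncol(x), byrow = TRUE)
  dterm <- sweep(dterm, 2, denom, "/")
  diag(A) <- 1 + rowMeans(dterm, na.rm = TRUE)
  dimnames(A) <- list(g$samples$id, g$samples$id)
  structure(list(sample_ids = g$samples$id, values = A), class = "uar")
}

#' Prune close relatives
#'
#' Greedy removal of samples until no off-diagonal relationship exceeds
#' `threshold`: at each step the sample participating in the most
#' above-threshold pairs is removed (ties broken by larger mean relatedness
#' among its offending pairs, then by input order).
#'
#' @param g a [genotypes] panel.
#' @param r a `"uar"` object computed on `g` (see [compute_uar]).
#' @param threshold relationship cutoff (default 0.35).
#' @param verbose log removed ids to stderr?
#' @return a list: `genotypes` (pruned panel), `removed` (character ids,
#'   in removal order).
#' @export
prune_related <- function(g, r, threshold = 0.35, verbose = TRUE) {
  stopifnot(inherits(r, "uar"), identical(r$sample_ids, g$samples$id))
  A <- r$values
  diag(A) <- 0
  keep <- rep(TRUE, nrow(A))
  removed <- character(0)
  repeat {
    W <- A[keep, keep, drop = FALSE] > threshold
    if (!any(W)) break
    deg <- rowSums(W)
    cand <- which(deg == max(deg))
    if (length(cand) > 1) {
      mean_rel <- vapply(cand, function(i) {
        off <- A[keep, keep, drop = FALSE][i, W[i, ]]
        mean(off)
      }, numeric(1))
      cand <- cand[mean_rel == max(mean_rel)]
    }
    victim_local <- cand[1]                          # input order tie-break
    victim <- which(keep)[victim_local]
    keep[victim] <- FALSE
    removed <- c(removed, g$samples$id[victim])
  }
  if (verbose && length(removed))
    message("prune_related: removed ", length(removed), " sample(s): ",
            paste(removed, collapse = ", "))
  list(genotypes = g[keep, ], removed = removed)
}
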