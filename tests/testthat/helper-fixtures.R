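# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (brute force / literal transcription) and
# never call the implementation path they check.

# small hand-assembled panel
make_panel <- function(dosage, chrom = NULL, pos = NULL, pops = NULL) {
  dosage <- as.matrix(dosage)
  S <- ncol(dosage); n <- nrow(dosage)
  if (is.null(chrom)) chrom <- rep(1L, S)
  if (is.null(pos)) {
    sp <- min(1e6, floor(2.1e9 / (max(table(chrom)) + 1)))
    pos <- as.integer(ave(seq_len(S), chrom, FUN = seq_along) * sp)
  }
  if (is.null(pops)) pops <- rep("P1", n)
  genotypes(dosage,
            data.frame(id = sprintf("s%03d", seq_len(S)), chrom = chrom, pos = pos,
                       allele_a = "A", allele_b = "B", stringsAsFactors = FALSE),
            data.frame(id = sprintf("i%03d", seq_len(n)), pop = pops,
                       stringsAsFactors = FALSE))
}

# random panel under HWE with configurable missingness (independent loci)
random_panel <- function(n, S, maf_range = c(0.05, 0.5), miss = 0, pops = NULL,
                         n_chrom = 1L) {
  p <- runif(S, maf_range[1], maf_range[2])
  dosage <- matrix(rbinom(n * S, 2, rep(p, each = n)), n, S)
  if (miss > 0) dosage[runif(n * S) < miss] <- NA_integer_
  chrom <- sort(rep_len(seq_len(n_chrom), S))
  make_panel(dosage, chrom = chrom, pops = pops)
}

# drop loci fixed in the whole panel (compute_uar requires polymorphism)
polymorphic <- function(g) {
  p <- allele_freq(g)
  g[, !is.nan(p) & p > 0 & p < 1]
}

# ---- brute-force ROH oracle -------------------------------------------------
# Enumerates every homozygous-terminal index interval, keeps those within the
# het/missing budgets, min_snps and min_length, drops intervals contained in a
# budget-valid interval (maximality), then greedily selects non-overlapping
# runs left to right (ties toward the longer run).
roh_oracle_chrom <- function(d, pos, params) {
  S <- length(d)
  state <- ifelse(is.na(d), 2L, ifelse(d == 1L, 1L, 0L))
  cand <- NULL
  for (i in seq_len(S)) for (j in i:S) {
    if (state[i] != 0L || state[j] != 0L) next
    st <- state[i:j]
    if (sum(st == 1L) > params$max_het) next
    if (sum(st == 2L) > params$max_missing) next
    cand <- rbind(cand, c(i, j))
  }
  if (is.null(cand)) return(NULL)
  # maximality among budget-valid homozygous-terminal intervals
  keep <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    for (m in seq_len(nrow(cand))) {
      if (m != k && cand[m, 1] <= cand[k, 1] && cand[m, 2] >= cand[k, 2]) {
        keep[k] <- FALSE; break
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  # thresholds
  ok <- (cand[, 2] - cand[, 1] + 1L) >= params$min_snps &
    (pos[cand[, 2]] - pos[cand[, 1]]) >= params$min_length_bp
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(cand[, 1], -cand[, 2]), , drop = FALSE]
  sel <- NULL; last_end <- -1L
  for (k in seq_len(nrow(cand))) {
    if (cand[k, 1] > last_end) { sel <- rbind(sel, cand[k, ]); last_end <- cand[k, 2] }
  }
  sel
}

roh_oracle <- function(g, params) {
  out <- NULL
  for (ci in unique(g$snps$chrom)) {
    idx <- which(g$snps$chrom == ci)
    pos <- g$snps$pos[idx]
    for (s in seq_len(nrow(g$samples))) {
      sel <- roh_oracle_chrom(g$dosage[s, idx], pos, params)
      if (is.null(sel)) next
      out <- rbind(out, data.frame(sample_id = g$samples$id[s],
                                   chrom = as.integer(ci),
                                   start_bp = pos[sel[, 1]], end_bp = pos[sel[, 2]],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# ---- literal Weir-Cockerham (1984) transcription ---------------------------
# independent of wc_components: scalar arithmetic, two populations
wc_oracle_locus <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}
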