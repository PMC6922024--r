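#' ROH detection parameters
#'
#' Settings for the window-free consecutive-runs scan of [detect_roh].
#' Defaults follow common SNP-array practice for livestock: runs of at
#' least 1000 kb, allowing at most one heterozygous and one missing call
#' inside a run.
#'
#' @param min_length_bp minimum physical span of a run (bp).
#' @param max_het maximum heterozygous calls allowed inside a run.
#' @param max_missing maximum missing calls allowed inside a run.
#' @param min_snps minimum number of SNPs in a run (>= 2); typically set
#'   from [min_snp_threshold].
#' @return a list of class `"roh_params"`.
#' @export
roh_params <- function(min_length_bp = 1e6, max_het = 1L, max_missing = 1L,
                       min_snps = 2L) {
  stopifnot(min_length_bp > 0, max_het >= 0, max_missing >= 0, min_snps >= 2)
  structure(list(min_length_bp = min_length_bp, max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 min_snps = as.integer(min_snps)),
            class = "roh_params")
}

#' Minimum-SNP threshold for ROH calling
#'
#' Number of consecutive homozygous SNPs needed so that the expected count
#' of chance (non-autozygous) runs over the whole dataset is below
#' `alpha_fp`:
#' \deqn{l = \left\lceil \frac{\ln(\alpha / (n_s\,n_i))}{\ln(1 -
#'   \overline{het})} \right\rceil,}
#' with \eqn{n_s} genotyped SNPs per individual, \eqn{n_i} individuals and
#' \eqn{\overline{het}} the mean SNP heterozygosity.  One genome-wide
#' threshold is used for a merged dataset.
#'
#' @param n_snps genotyped SNPs per individual.
#' @param n_individuals number of individuals.
#' @param alpha_fp tolerated expected number of false-positive runs
#'   (default 0.05).
#' @param mean_het mean heterozygosity across SNPs, strictly in (0, 1).
#' @return integer `l`.
#' @export
min_snp_threshold <- function(n_snps, n_individuals, alpha_fp = 0.05, mean_het) {
  stopifnot(n_snps > 0, n_individuals > 0, alpha_fp > 0)
  if (!(mean_het > 0 && mean_het < 1))
    stop("mean_het must lie strictly between 0 and 1")
  as.integer(ceiling(log(alpha_fp / (n_snps * n_individuals)) / log(1 - mean_het)))
}

# maximal qualifying runs on one chromosome of one individual.
# state: 0 = homozygous, 1 = het, 2 = missing.  Returns index pairs of
# maximal homozygous-terminal intervals satisfying the het/missing budgets.
roh_scan_chrom <- function(state, max_het, max_missing) {
  S <- length(state)
  empty <- cbind(start = integer(0), end = integer(0))
  if (S == 0) return(empty)
  hom_idx <- which(state == 0L)
  if (!length(hom_idx)) return(empty)
  hets <- which(state == 1L)
  miss <- which(state == 2L)
  cum_h <- c(0L, cumsum(state == 1L))   # cum_h[i] = het calls before SNP i
  cum_m <- c(0L, cumsum(state == 2L))
  # J(i) = largest j such that window [i, j] stays within both budgets:
  # bounded by the (budget+1)-th violation at or after i
  bound_from <- function(vio, cum, budget) {
    r <- cum[seq_len(S)] + budget + 1L
    b <- rep.int(S, S)
    has <- r <= length(vio)
    b[has] <- vio[r[has]] - 1L
    b
  }
  J <- pmin(bound_from(hets, cum_h, max_het),
            bound_from(miss, cum_m, max_missing))
  # a window [i, J(i)] is maximal iff nonempty and not left-extendable
  is_max <- J >= seq_len(S) & c(TRUE, J[-S] < J[-1])
  wi <- which(is_max)
  if (!length(wi)) return(empty)
  wj <- J[wi]
  # shrink terminals to homozygous SNPs
  v <- rep.int(S + 1L, S); v[hom_idx] <- hom_idx
  next_hom <- rev(cummin(rev(v)))
  v <- rep.int(0L, S); v[hom_idx] <- hom_idx
  prev_hom <- cummax(v)
  a <- next_hom[wi]; b <- prev_hom[wj]
  okrun <- a <= S & b >= 1L & a <= b
  if (!any(okrun)) return(empty)
  runs <- unique(cbind(start = a[okrun], end = b[okrun]))
  # drop runs contained in another (maximality over hom-terminal intervals)
  keep <- rep(TRUE, nrow(runs))
  for (k in seq_len(nrow(runs))) {
    contained <- runs[, "start"] <= runs[k, "start"] & runs[, "end"] >= runs[k, "end"]
    contained[k] <- FALSE
    if (any(contained)) keep[k] <- FALSE
  }
  runs[keep, , drop = FALSE]
}

# greedy left-to-right selection of non-overlapping runs; at equal starts
# the longer run wins
roh_select_nonoverlap <- function(runs) {
  if (!nrow(runs)) return(runs)
  o <- order(runs[, "start"], -runs[, "end"])
  runs <- runs[o, , drop = FALSE]
  last_end <- -1L
  keep <- logical(nrow(runs))
  for (k in seq_len(nrow(runs))) {
    if (runs[k, "start"] > last_end) { keep[k] <- TRUE; last_end <- runs[k, "end"] }
  }
  runs[keep, , drop = FALSE]
}

#' Detect runs of homozygosity (consecutive-runs method)
#'
#' Window-free scan for maximal runs of consecutive SNPs per individual and
#' chromosome containing at most `max_het` heterozygous and `max_missing`
#' missing calls, at least `min_snps` SNPs, and spanning at least
#' `min_length_bp`.  Runs start and end on homozygous SNPs, never cross a
#' chromosome boundary, are maximal (not extendable in either direction
#' without violating a constraint) and non-overlapping within an individual
#' (greedy left-to-right selection; ties broken toward the longer run).
#' Run length is `end_bp - start_bp` of the terminal SNPs.
#'
#' @param g a [genotypes] panel with a sorted map.
#' @param params a [roh_params].
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `n_het`, `n_missing`, `length_bp`.
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "genotypes"), inherits(params, "roh_params"))
  out <- list()
  by_chrom <- snp_index_by_chrom(g)
  for (ci in names(by_chrom)) {
    idx <- by_chrom[[ci]]
    pos <- g$snps$pos[idx]
    for (s in seq_len(n_samples(g))) {
      d <- g$dosage[s, idx]
      state <- ifelse(is.na(d), 2L, ifelse(d == 1L, 1L, 0L))
      runs <- roh_scan_chrom(state, params$max_het, params$max_missing)
      if (!nrow(runs)) next
      span <- pos[runs[, "end"]] - pos[runs[, "start"]]
      nsnp <- runs[, "end"] - runs[, "start"] + 1L
      sel <- span >= params$min_length_bp & nsnp >= params$min_snps
      runs <- runs[sel, , drop = FALSE]
      if (!nrow(runs)) next
      runs <- roh_select_nonoverlap(runs)
      nh <- nm <- integer(nrow(runs))
      for (k in seq_len(nrow(runs))) {
        st <- state[runs[k, "start"]:runs[k, "end"]]
        nh[k] <- sum(st == 1L); nm[k] <- sum(st == 2L)
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_id = g$samples$id[s], chrom = as.integer(ci),
        start_bp = pos[runs[, "start"]], end_bp = pos[runs[, "end"]],
        n_snps = runs[, "end"] - runs[, "start"] + 1L,
        n_het = nh, n_missing = nm,
        length_bp = pos[runs[, "end"]] - pos[runs[, "start"]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = integer(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_snps = integer(0), n_het = integer(0),
                      n_missing = integer(0), length_bp = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' ROH length classes
#'
#' Bins segments into the standard length classes 1-2, 2-4, 4-8, 8-16 and
#' >16 Mb (half-open bins, lower edge inclusive: a 2.0 Mb run falls in
#' 2-4 Mb).
#'
#' @param segments a segment data.frame from [detect_roh].
#' @param pop optional named character vector mapping `sample_id` to a
#'   breed/population; when given, counts are tabulated per population.
#' @return data.frame with `class`, `count`, `percent` (and `pop` when
#'   grouped).
#' @export
classify_roh <- function(segments, pop = NULL) {
  breaks <- c(1, 2, 4, 8, 16, Inf) * 1e6
  labels <- c("1-2Mb", "2-4Mb", "4-8Mb", "8-16Mb", ">16Mb")
  if (nrow(segments) && any(segments$length_bp < 1e6))
    stop("segment shorter than 1 Mb violates the class floor")
  cls <- cut(segments$length_bp, breaks, labels = labels, right = FALSE)
  tab_one <- function(cl) {
    cnt <- as.integer(table(cl))
    data.frame(class = labels, count = cnt,
               percent = if (sum(cnt)) 100 * cnt / sum(cnt) else rep(0, 5),
               stringsAsFactors = FALSE)
  }
  if (is.null(pop)) return(tab_one(cls))
  pops <- pop[segments$sample_id]
  out <- lapply(unique(pops), function(pp) {
    cbind(pop = pp, tab_one(cls[pops == pp]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Per individual, the summed length of ROH segments at least
#' `min_length_bp` long, divided by the autosomal genome length covered by
#' the SNP panel.
#'
#' @param segments a segment data.frame from [detect_roh].
#' @param sample_ids character vector of all individuals to report
#'   (individuals without qualifying segments get 0).
#' @param min_length_bp segment length floor (1, 5 or 10 Mb conventionally;
#'   any positive value accepted).
#' @param genome_length_bp autosomal SNP coverage denominator; the default
#'   2.44e9 bp is the sheep autosomal coverage of a 50K array panel.
#' @return named numeric vector of F_ROH per individual.
#' @export
froh <- function(segments, sample_ids, min_length_bp = 1e6,
                 genome_length_bp = 2.44e9) {
  stopifnot(genome_length_bp > 0)
  keep <- segments$length_bp >= min_length_bp
  sums <- tapply(segments$length_bp[keep], segments$sample_id[keep], sum)
  out <- stats::setNames(numeric(length(sample_ids)), sample_ids)
  out[names(sums)] <- sums
  out / genome_length_bp
}

#' Per-breed ROH and F_ROH summary
#'
#' The standard breed-level summary of an ROH survey: segment counts, mean
#' per-individual summed ROH length, and mean/min/max F_ROH at 1, 5 and
#' 10 Mb length floors.
#'
#' @param segments a segment data.frame from [detect_roh].
#' @param samples data.frame with `id` and `pop` columns (all genotyped
#'   individuals, so zero-ROH animals enter the means).
#' @param genome_length_bp denominator for F_ROH (see [froh]).
#' @return data.frame, one row per population.
#' @export
roh_summary <- function(segments, samples, genome_length_bp = 2.44e9) {
  rows <- lapply(unique(samples$pop), function(pp) {
    ids <- samples$id[samples$pop == pp]
    seg <- segments[segments$sample_id %in% ids, , drop = FALSE]
    sums <- froh(seg, ids, 1e6, 1)              # raw summed bp per individual
    f1 <- froh(seg, ids, 1e6, genome_length_bp)
    f5 <- froh(seg, ids, 5e6, genome_length_bp)
    f10 <- froh(seg, ids, 1e7, genome_length_bp)
    data.frame(pop = pp, n = length(ids),
               roh_count = nrow(seg),
               mean_sum_roh_mb = mean(sums) / 1e6,
               froh1_mean = mean(f1), froh1_min = min(f1), froh1_max = max(f1),
               froh5_mean = mean(f5), froh5_min = min(f5), froh5_max = max(f5),
               froh10_mean = mean(f10), froh10_min = min(f10), froh10_max = max(f10),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
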