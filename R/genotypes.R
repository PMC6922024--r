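#' Genotype panel container
#'
#' An S3 container for a diploid biallelic SNP panel: a samples x SNPs
#' dosage matrix (counts of `allele_b`, coded 0/1/2, `NA` = missing call),
#' a SNP map and per-sample population labels.  Every downstream statistic
#' in flockdiv operates on this object.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; values
#'   in `{0, 1, 2, NA}`.  Row names are ignored (taken from `samples`).
#' @param snps data.frame with columns `id` (unique character), `chrom`
#'   (integer chromosome label, autosomes `1..n`), `pos` (1-based physical
#'   position in bp), `allele_a`, `allele_b` (nucleotide or A/B codes).
#'   Within each chromosome SNPs must be sorted by position.
#' @param samples data.frame with columns `id` (unique character) and
#'   `pop` (population label).
#'
#' @return An object of class `"genotypes"`: a list with elements
#'   `dosage`, `snps`, `samples`.
#' @export
#' @examples
#' g <- genotypes(matrix(c(0L, 1L, 2L, 1L, 0L, NA), nrow = 2, byrow = TRUE),
#'                snps = data.frame(id = c("s1", "s2", "s3"), chrom = 1L,
#'                                  pos = c(100L, 200L, 300L),
#'                                  allele_a = "A", allele_b = "B"),
#'                samples = data.frame(id = c("i1", "i2"), pop = "P1"))
#' g
genotypes <- function(dosage, snps, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  obj <- structure(list(dosage = dosage, snps = snps, samples = samples),
                   class = "genotypes")
  validate_genotypes(obj)
  obj
}

validate_genotypes <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  d <- g$dosage
  if (nrow(d) != nrow(g$samples))
    stop("dosage has ", nrow(d), " rows but ", nrow(g$samples), " samples")
  if (ncol(d) != nrow(g$snps))
    stop("dosage has ", ncol(d), " columns but ", nrow(g$snps), " SNPs")
  need_snp <- c("id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need_snp %in% names(g$snps)))
    stop("snps must have columns: ", paste(need_snp, collapse = ", "))
  if (!all(c("id", "pop") %in% names(g$samples)))
    stop("samples must have columns: id, pop")
  if (anyDuplicated(g$snps$id))
    stop("duplicate SNP ids: ", paste(unique(g$snps$id[duplicated(g$snps$id)])[1:3], collapse = ", "))
  if (anyDuplicated(g$samples$id))
    stop("duplicate sample ids: ",
         paste(unique(g$samples$id[duplicated(g$samples$id)])[1:3], collapse = ", "))
  if (any(g$snps$pos < 1)) stop("SNP positions must be >= 1 (1-based)")
  bad <- d[!is.na(d) & !(d %in% 0:2)]
  if (length(bad)) stop("dosage values must be 0, 1, 2 or NA")
  # map sortedness within each chromosome (chromosome block order is free)
  sorted <- tapply(g$snps$pos, g$snps$chrom, function(x) !is.unsorted(x))
  if (!all(unlist(sorted)))
    stop("SNP map must be sorted by position within each chromosome")
  if (any(is.na(g$samples$pop)))
    stop("every sample needs a population label")
  invisible(g)
}

#' @export
print.genotypes <- function(x, ...) {
  cat("genotypes panel: ", n_samples(x), " samples x ", n_snps(x), " SNPs\n", sep = "")
  tab <- table(x$samples$pop)
  cat("populations: ",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "), "\n", sep = "")
  cat("chromosomes: ", length(unique(x$snps$chrom)),
      "; missing calls: ", sprintf("%.3f%%", 100 * mean(is.na(x$dosage))), "\n", sep = "")
  invisible(x)
}

#' @rdname genotypes
#' @param g,x a `genotypes` object.
#' @export
n_samples <- function(g) nrow(g$samples)

#' @rdname genotypes
#' @export
n_snps <- function(g) nrow(g$snps)

#' Subset a genotype panel
#'
#' @param x a `genotypes` object.
#' @param i sample index (logical, integer or sample-id character vector).
#' @param j SNP index (logical, integer or SNP-id character vector).
#' @param ... unused.
#' @return the subset `genotypes` object.
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_snps(x))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, x$snps$id)
  if (anyNA(i)) stop("unknown sample id in subset")
  if (anyNA(j)) stop("unknown SNP id in subset")
  genotypes(x$dosage[i, j, drop = FALSE],
            x$snps[j, , drop = FALSE],
            x$samples[i, , drop = FALSE])
}

#' Per-SNP allele-b frequency
#'
#' Frequency of `allele_b` among non-missing calls, optionally within one
#' population.
#'
#' @param g a `genotypes` object.
#' @param population optional population label; default uses all samples.
#' @return numeric vector, one frequency per SNP (`NaN` where no calls).
#' @export
allele_freq <- function(g, population = NULL) {
  d <- pop_dosage(g, population)
  colMeans(d, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#' @inheritParams allele_freq
#' @return numeric vector of MAF per SNP.
#' @export
maf <- function(g, population = NULL) {
  p <- allele_freq(g, population)
  pmin(p, 1 - p)
}

# dosage submatrix for one population (or all samples); errors on unknown label
pop_dosage <- function(g, population = NULL) {
  if (is.null(population)) return(g$dosage)
  keep <- g$samples$pop == population
  if (!any(keep)) stop("population label not present: ", population)
  g$dosage[keep, , drop = FALSE]
}

#' Population labels present in a panel
#' @param g a `genotypes` object.
#' @return character vector of unique labels, in order of first appearance.
#' @export
populations <- function(g) unique(g$samples$pop)

# split SNP indices by chromosome, preserving map order
snp_index_by_chrom <- function(g) split(seq_len(n_snps(g)), g$snps$chrom)
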