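#' Read a PLINK panel
#'
#' Reads PED/MAP text or BED/BIM/FAM binary (variant-major, magic bytes
#' `0x6c 0x1b 0x01`) into a [genotypes] panel.  Dosage counts copies of
#' `allele_b` (the second/A2 allele in BIM order); missing genotypes become
#' `NA`.  The population label is taken from the family-ID column of the
#' FAM/PED file.
#'
#' For PED input (which carries no allele declaration) alleles at each SNP
#' are assigned deterministically: the lexicographically smaller observed
#' allele becomes `allele_a`.  A locus with more than two observed alleles,
#' or a half-missing genotype, is a parse error naming the locus.
#'
#' @param prefix file-path stem; `<prefix>.ped`/`.map` or
#'   `<prefix>.bed`/`.bim`/`.fam` must exist.
#' @param format `"bed"`, `"ped"`, or `"auto"` (default: prefer BED if
#'   present).
#' @return a [genotypes] object.
#' @export
read_plink <- function(prefix, format = c("auto", "bed", "ped")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (file.exists(paste0(prefix, ".bed"))) "bed" else "ped"
  if (format == "bed") read_plink_bed(prefix) else read_plink_ped(prefix)
}

read_map_file <- function(path) {
  map <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"))
  data.frame(id = as.character(map$id), chrom = as.integer(map$chrom),
             pos = as.integer(map$pos), stringsAsFactors = FALSE)
}

read_plink_ped <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path) || !file.exists(map_path))
    stop("missing .ped/.map files for prefix ", prefix)
  map <- read_map_file(map_path)
  n_snp <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n_field <- lengths(toks)
  if (any(n_field != 6 + 2 * n_snp))
    stop("PED/MAP dimension mismatch: expected ", 6 + 2 * n_snp,
         " fields per line, found ", paste(unique(n_field), collapse = "/"))
  tok <- do.call(rbind, toks)
  samples <- data.frame(id = tok[, 2], pop = tok[, 1], stringsAsFactors = FALSE)
  a1 <- tok[, 6 + 2 * seq_len(n_snp) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(n_snp), drop = FALSE]
  dosage <- matrix(NA_integer_, nrow(tok), n_snp)
  allele_a <- allele_b <- character(n_snp)
  for (s in seq_len(n_snp)) {
    x1 <- a1[, s]; x2 <- a2[, s]
    half <- xor(x1 == "0", x2 == "0")
    if (any(half))
      stop("half-missing genotype at locus ", map$id[s])
    obs <- setdiff(sort(unique(c(x1, x2))), "0")
    if (length(obs) > 2)
      stop("more than two alleles at locus ", map$id[s], ": ",
           paste(obs, collapse = "/"))
    aa <- if (length(obs) >= 1) obs[1] else "0"
    ab <- if (length(obs) == 2) obs[2] else "0"
    allele_a[s] <- aa; allele_b[s] <- ab
    miss <- x1 == "0"
    dosage[, s] <- ifelse(miss, NA_integer_, (x1 == ab) + (x2 == ab))
  }
  snps <- cbind(map, data.frame(allele_a = allele_a, allele_b = allele_b,
                                stringsAsFactors = FALSE))
  genotypes(dosage, snps[, c("id", "chrom", "pos", "allele_a", "allele_b")], samples)
}

read_plink_bed <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  if (!all(file.exists(c(bed_path, bim_path, fam_path))))
    stop("missing .bed/.bim/.fam files for prefix ", prefix)
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  n_snp <- nrow(bim)
  n_sam <- nrow(fam)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("sample-major BED not supported: ", bed_path)
  bpv <- ceiling(n_sam / 4)  # bytes per variant
  if (length(raw) - 3L != bpv * n_snp)
    stop("BED size inconsistent with BIM/FAM dimensions: ", bed_path)
  body <- as.integer(raw[-(1:3)])
  # unpack 2-bit codes, sample-fastest within each variant block
  codes <- matrix(0L, nrow = 4L * bpv, ncol = n_snp)
  for (k in 0:3) {
    codes[seq.int(k + 1L, by = 4L, length.out = bpv), ] <-
      matrix(body %/% 4L^k %% 4L, nrow = bpv)
  }
  codes <- codes[seq_len(n_sam), , drop = FALSE]
  # 00 -> hom a1 (0 copies of a2), 01 -> missing, 10 -> het, 11 -> hom a2
  dosage <- matrix(c(0L, NA_integer_, 1L, 2L)[codes + 1L], n_sam, n_snp)
  snps <- data.frame(id = as.character(bim$id), chrom = as.integer(bim$chrom),
                     pos = as.integer(bim$pos),
                     allele_a = as.character(bim$a1),
                     allele_b = as.character(bim$a2), stringsAsFactors = FALSE)
  samples <- data.frame(id = as.character(fam[[2]]), pop = as.character(fam[[1]]),
                        stringsAsFactors = FALSE)
  genotypes(dosage, snps, samples)
}

#' Write a PLINK panel
#'
#' Writes PED/MAP or BED/BIM/FAM files for a [genotypes] panel.  The FAM/PED
#' family-ID column carries the population label.  Hets in PED are written
#' `allele_a allele_b`; missing calls as `0 0`.
#'
#' @param g a [genotypes] object.
#' @param prefix output path stem.
#' @param format `"bed"` (default) or `"ped"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  if (format == "ped") write_plink_ped(g, prefix) else write_plink_bed(g, prefix)
  invisible(prefix)
}

write_plink_ped <- function(g, prefix) {
  map <- g$snps
  utils::write.table(
    data.frame(map$chrom, map$id, 0, map$pos),
    paste0(prefix, ".map"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n_snp <- n_snps(g)
  a1 <- a2 <- matrix("0", n_samples(g), n_snp)
  for (s in seq_len(n_snp)) {
    d <- g$dosage[, s]
    aa <- map$allele_a[s]; ab <- map$allele_b[s]
    a1[, s] <- c(aa, aa, ab)[d + 1L]
    a2[, s] <- c(aa, ab, ab)[d + 1L]
    a1[is.na(d), s] <- "0"; a2[is.na(d), s] <- "0"
  }
  geno <- matrix("", n_samples(g), 2 * n_snp)
  geno[, 2 * seq_len(n_snp) - 1] <- a1
  geno[, 2 * seq_len(n_snp)] <- a2
  ped <- cbind(g$samples$pop, g$samples$id, "0", "0", "0", "-9", geno)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

write_plink_bed <- function(g, prefix) {
  map <- g$snps
  utils::write.table(
    data.frame(map$chrom, map$id, 0, map$pos, map$allele_a, map$allele_b),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(g$samples$pop, g$samples$id, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n_sam <- n_samples(g)
  bpv <- ceiling(n_sam / 4)
  # dosage -> 2-bit codes: 0->00, 1->10, 2->11, NA->01
  code <- matrix(c(0L, 2L, 3L)[g$dosage + 1L], n_sam, n_snps(g))
  code[is.na(code)] <- 1L
  pad <- matrix(0L, 4L * bpv, n_snps(g))
  pad[seq_len(n_sam), ] <- code
  bytes <- pad[seq.int(1L, by = 4L, length.out = bpv), , drop = FALSE] +
    4L * pad[seq.int(2L, by = 4L, length.out = bpv), , drop = FALSE] +
    16L * pad[seq.int(3L, by = 4L, length.out = bpv), , drop = FALSE] +
    64L * pad[seq.int(4L, by = 4L, length.out = bpv), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
}

#' Merge two array panels by SNP intersection
#'
#' Keeps exactly the SNPs present in both panels (matched by id) and
#' concatenates samples.  Alleles are harmonized so dosage counts the same
#' allele in both panels: an A/B swap in the second panel flips its dosage
#' `0 <-> 2`.  SNPs whose allele pairs cannot be reconciled (including
#' strand-ambiguous mismatches) are dropped and logged to stderr, never
#' guessed.
#'
#' @param a,b [genotypes] panels sharing a SNP-id namespace.
#' @return the merged [genotypes] panel, with SNP map (order, positions,
#'   alleles) taken from `a`.
#' @export
intersect_panels <- function(a, b) {
  if (length(intersect(a$samples$id, b$samples$id)))
    stop("duplicate sample ids across panels: ",
         paste(utils::head(intersect(a$samples$id, b$samples$id), 3), collapse = ", "))
  shared <- intersect(a$snps$id, b$snps$id)
  if (!length(shared)) stop("zero overlapping SNPs between panels")
  ia <- match(shared, a$snps$id)
  ia <- ia[order(ia)]                       # keep panel-a map order
  shared <- a$snps$id[ia]
  ib <- match(shared, b$snps$id)
  aa <- a$snps$allele_a[ia]; ab <- a$snps$allele_b[ia]
  ba <- b$snps$allele_a[ib]; bb <- b$snps$allele_b[ib]
  same <- aa == ba & ab == bb
  flip <- aa == bb & ab == ba & !same
  keep <- same | flip
  if (any(!keep)) {
    message(sum(!keep), " SNP(s) dropped in intersect_panels (allele conflict): ",
            paste(utils::head(shared[!keep], 5), collapse = ", "))
  }
  ia <- ia[keep]; ib <- ib[keep]; flip <- flip[keep]
  if (!length(ia)) stop("zero overlapping SNPs after allele harmonization")
  db <- b$dosage[, ib, drop = FALSE]
  if (any(flip)) db[, flip] <- 2L - db[, flip, drop = FALSE]
  genotypes(rbind(a$dosage[, ia, drop = FALSE], db),
            a$snps[ia, , drop = FALSE],
            rbind(a$samples, b$samples))
}
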