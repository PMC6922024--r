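# sanitize population labels for whitespace-sensitive formats; writes a
# mapping file alongside when anything changed
sanitize_labels <- function(labels, path_map = NULL) {
  clean <- gsub("[[:space:]]+", "_", labels)
  if (!identical(clean, labels) && !is.null(path_map)) {
    utils::write.table(data.frame(original = labels, sanitized = clean),
                       path_map, sep = "\t", quote = FALSE, row.names = FALSE)
    message("labels sanitized; mapping written to ", path_map)
  }
  clean
}

#' Export an FST matrix in PHYLIP square format
#'
#' @param fst an `"fst_matrix"` (see [fst_matrix]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_phylip <- function(fst, path) {
  labs <- sanitize_labels(fst$populations, paste0(path, ".labels.tsv"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(labs)), con)
  for (i in seq_along(labs)) {
    writeLines(paste(c(formatC(labs[i], width = -10),
                       sprintf("%.8f", fst$values[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#' @param path PHYLIP file written by [export_phylip].
#' @return an `"fst_matrix"`-shaped list (`populations`, `values`).
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  toks <- strsplit(trimws(lines[1 + seq_len(n)]), "[ \t]+")
  labs <- vapply(toks, `[[`, character(1), 1)
  vals <- t(vapply(toks, function(tk) as.numeric(tk[-1]), numeric(n)))
  dimnames(vals) <- list(labs, labs)
  structure(list(populations = labs, values = vals), class = "fst_matrix")
}

#' Export an FST matrix as a NEXUS distances block
#'
#' Produces a minimal NEXUS file (taxa + distances, lower-triangular with
#' diagonal) readable by SplitsTree for Neighbor-Net construction.
#'
#' @inheritParams export_phylip
#' @return `path`, invisibly.
#' @export
export_nexus <- function(fst, path) {
  labs <- sanitize_labels(fst$populations, paste0(path, ".labels.tsv"))
  n <- length(labs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN Taxa;", sprintf("DIMENSIONS ntax=%d;", n),
               "TAXLABELS"), con)
  writeLines(sprintf("[%d] '%s'", seq_len(n), labs), con)
  writeLines(c(";", "END;", "", "BEGIN Distances;",
               sprintf("DIMENSIONS ntax=%d;", n),
               "FORMAT labels=left diagonal triangle=lower;", "MATRIX"), con)
  for (i in seq_len(n))
    writeLines(paste(c(sprintf("'%s'", labs[i]),
                       sprintf("%.8f", fst$values[i, seq_len(i)])),
                     collapse = " "), con)
  writeLines(c(";", "END;"), con)
  invisible(path)
}

#' Read a NEXUS distances block written by [export_nexus]
#' @param path NEXUS file.
#' @return an `"fst_matrix"`-shaped list.
#' @export
read_nexus <- function(path) {
  lines <- readLines(path)
  mstart <- grep("^MATRIX$", lines)[length(grep("^MATRIX$", lines))]
  rows <- character(0)
  for (l in lines[(mstart + 1):length(lines)]) {
    if (trimws(l) == ";") break
    rows <- c(rows, l)
  }
  labs <- sub("^'([^']*)'.*$", "\\1", rows)
  n <- length(labs)
  vals <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    v <- as.numeric(strsplit(sub("^'[^']*' *", "", rows[i]), "[ \t]+")[[1]])
    vals[i, seq_len(i)] <- v
    vals[seq_len(i), i] <- v
  }
  structure(list(populations = labs, values = vals), class = "fst_matrix")
}

#' Export per-population allele counts for TreeMix
#'
#' Writes the gzip text table TreeMix expects: a header of population
#' labels, then one line per SNP of `countA,countB` fields (counts of
#' `allele_a` and `allele_b` gene copies among non-missing calls).
#'
#' @param g a [genotypes] panel.
#' @param path output path (a `.gz` file is written).
#' @return `path`, invisibly.
#' @export
export_treemix <- function(g, path) {
  pops <- populations(g)
  labs <- sanitize_labels(pops, paste0(path, ".labels.tsv"))
  cols <- lapply(pops, function(pp) {
    d <- pop_dosage(g, pp)
    nb <- colSums(d, na.rm = TRUE)
    n2 <- 2 * colSums(!is.na(d))
    sprintf("%d,%d", n2 - nb, nb)
  })
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(paste(labs, collapse = " "), con)
  writeLines(do.call(paste, cols), con)
  invisible(path)
}

#' Export a panel in ADMIXTURE-compatible PLINK format
#'
#' ADMIXTURE consumes PLINK BED/BIM/FAM (or PED/MAP) directly; this writes
#' BED with whitespace-sanitized family (population) labels.
#'
#' @param g a [genotypes] panel.
#' @param prefix output path stem.
#' @param format `"bed"` (default) or `"ped"`.
#' @return `prefix`, invisibly.
#' @export
export_admixture <- function(g, prefix, format = c("bed", "ped")) {
  g$samples$pop <- sanitize_labels(g$samples$pop, paste0(prefix, ".labels.tsv"))
  write_plink(g, prefix, match.arg(format))
}
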