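#' Pipeline configuration
#'
#' Collects every tunable of the full workflow.  `input_prefix` points at a
#' PLINK panel; alternatively `simulate = TRUE` runs on the built-in
#' study-shaped fixture ([survey_shaped_fixture]) so the whole pipeline is
#' demonstrable without data.
#'
#' @param out_dir output directory.
#' @param input_prefix PLINK path stem (PED/MAP or BED/BIM/FAM), or `NA`.
#' @param input_format `"auto"`, `"bed"` or `"ped"`.
#' @param simulate run on the built-in simulated fixture instead of files?
#' @param seed seed for every stochastic step (simulation, bootstrap).
#' @param snp_call_rate_min,sample_missing_max,maf_min,n_autosomes QC
#'   thresholds (see [qc_config]).
#' @param relatedness_max UAR pruning threshold.
#' @param roh_min_length_bp,roh_max_het,roh_max_missing ROH scan settings.
#' @param roh_min_snps integer, or `"auto"` to compute [min_snp_threshold]
#'   from the post-QC panel with `roh_alpha_fp`.
#' @param roh_alpha_fp false-positive allowance for the auto threshold.
#' @param genome_length_bp F_ROH denominator (autosomal SNP coverage).
#' @param ne_alpha_mut,ne_mapping,ne_min_maf,ne_min_pairs Ne settings
#'   (see [estimate_ne]).
#' @param n_boot bootstrap replicates for Fis.
#' @param mds_axes,pca_axes ordination dimensions.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = "flockdiv_out",
                            input_prefix = NA_character_,
                            input_format = "auto",
                            simulate = is.na(input_prefix),
                            seed = 1L,
                            snp_call_rate_min = 0.90,
                            sample_missing_max = 0.10,
                            maf_min = 0.05,
                            n_autosomes = 26L,
                            relatedness_max = 0.35,
                            roh_min_length_bp = 1e6,
                            roh_max_het = 1L,
                            roh_max_missing = 1L,
                            roh_min_snps = "auto",
                            roh_alpha_fp = 0.05,
                            genome_length_bp = 2.44e9,
                            ne_alpha_mut = 2.2,
                            ne_mapping = "linear",
                            ne_min_maf = 0.05,
                            ne_min_pairs = 50L,
                            n_boot = 1000L,
                            mds_axes = 2L,
                            pca_axes = 2L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a key = value text file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values are
#' coerced to numeric where possible; unknown keys are an error.
#'
#' @param path config file.
#' @return a [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "[ \t]*=[ \t]*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num
    else if (v %in% c("TRUE", "FALSE", "true", "false")) as.logical(toupper(v))
    else v
  })
  known <- names(formals(pipeline_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, stats::setNames(vals, keys))
}

write_tsv_with_header <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), unlist(lapply(meta, format))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         " (partial outputs preserved)", call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes genotype I/O + QC + relatedness pruning, within-population
#' diversity, ROH and F_ROH, LD-based Ne, and between-population structure
#' in order, writing a per-population diversity/Ne table, a per-breed
#' ROH/F_ROH summary, the FST matrix (TSV/PHYLIP/NEXUS), MDS and PCA
#' coordinates, external-tool exports and a machine-readable JSON manifest
#' of all parameters and stepwise sample/SNP counts.  Deterministic for a
#' given configuration: the same seed yields byte-identical outputs.
#'
#' @param cfg a [pipeline_config] or path to a config file.
#' @return invisibly, a list (`genotypes`, `tables`, `paths`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = cfg$seed, package = "flockdiv",
               version = as.character(utils::packageVersion("flockdiv")))

  g <- run_stage("input", {
    if (isTRUE(cfg$simulate)) {
      survey_shaped_fixture(seed = cfg$seed)$genotypes
    } else read_plink(cfg$input_prefix, cfg$input_format)
  })
  n_in <- c(samples = n_samples(g), snps = n_snps(g))

  qc <- run_stage("qc", apply_qc(g, qc_config(cfg$snp_call_rate_min,
                                              cfg$sample_missing_max,
                                              cfg$maf_min, TRUE,
                                              cfg$n_autosomes), verbose = FALSE))
  write_tsv_with_header(qc$report, file.path(cfg$out_dir, "qc_report.tsv"), meta)
  g <- qc$genotypes

  pruned <- run_stage("relatedness", {
    prune_related(g, compute_uar(g), cfg$relatedness_max, verbose = FALSE)
  })
  g <- pruned$genotypes

  div <- run_stage("diversity",
                   diversity_summary(g, n_boot = cfg$n_boot, seed = cfg$seed))

  roh_p <- run_stage("roh", {
    min_snps <- if (identical(cfg$roh_min_snps, "auto")) {
      het <- mean(g$dosage == 1L, na.rm = TRUE)
      max(2L, min_snp_threshold(n_snps(g), n_samples(g), cfg$roh_alpha_fp, het))
    } else as.integer(cfg$roh_min_snps)
    params <- roh_params(cfg$roh_min_length_bp, cfg$roh_max_het,
                         cfg$roh_max_missing, min_snps)
    segs <- detect_roh(g, params)
    list(params = params, segments = segs,
         classes = classify_roh(segs, stats::setNames(g$samples$pop, g$samples$id)),
         summary = roh_summary(segs, g$samples, cfg$genome_length_bp))
  })
  write_tsv_with_header(roh_p$segments, file.path(cfg$out_dir, "roh_segments.tsv"),
                        c(meta, roh_p$params))
  write_tsv_with_header(roh_p$summary, file.path(cfg$out_dir, "roh_summary.tsv"),
                        c(meta, roh_p$params))
  write_tsv_with_header(roh_p$classes, file.path(cfg$out_dir, "roh_classes.tsv"), meta)

  ne_tab <- run_stage("ne", {
    rows <- lapply(populations(g), function(pp) {
      est <- estimate_ne(g, pp, alpha_mut = cfg$ne_alpha_mut,
                         mapping = cfg$ne_mapping, min_maf = cfg$ne_min_maf,
                         min_pairs = cfg$ne_min_pairs)
      write_tsv_with_header(est$trajectory$points,
                            file.path(cfg$out_dir, paste0("ne_trajectory_", pp, ".tsv")),
                            c(meta, est$trajectory$config))
      data.frame(pop = pp, Ne5 = est$Ne5$Ne, Ne5_t = est$Ne5$t_achieved,
                 Ne50 = est$Ne50$Ne, Ne50_t = est$Ne50$t_achieved,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  div_ne <- merge(div, ne_tab, by = "pop", sort = FALSE)
  write_tsv_with_header(div_ne, file.path(cfg$out_dir, "diversity_ne.tsv"), meta)

  struct <- run_stage("structure", {
    fst <- fst_matrix(g)
    utils::write.table(fst$values, file.path(cfg$out_dir, "fst_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    export_phylip(fst, file.path(cfg$out_dir, "fst_matrix.phy"))
    export_nexus(fst, file.path(cfg$out_dir, "fst_matrix.nex"))
    d <- ibs_distance_matrix(g)
    mds <- classical_mds(d, cfg$mds_axes)
    pca <- pca_genotypes(g, cfg$pca_axes)
    ord_df <- function(o) data.frame(id = o$ids, pop = g$samples$pop,
                                     o$coordinates,
                                     stringsAsFactors = FALSE)
    write_tsv_with_header(ord_df(mds), file.path(cfg$out_dir, "mds.tsv"),
                          c(meta, list(explained = paste(signif(mds$explained, 6),
                                                         collapse = ","))))
    write_tsv_with_header(ord_df(pca), file.path(cfg$out_dir, "pca.tsv"),
                          c(meta, list(explained = paste(signif(pca$explained, 6),
                                                         collapse = ","))))
    export_treemix(g, file.path(cfg$out_dir, "treemix_counts.gz"))
    export_admixture(g, file.path(cfg$out_dir, "admixture_input"))
    list(fst = fst, mds = mds, pca = pca)
  })

  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    counts = list(input = as.list(n_in),
                  qc = stats::setNames(as.list(qc$report$removed), qc$report$step),
                  related_removed = length(pruned$removed),
                  analyzed = list(samples = n_samples(g), snps = n_snps(g)),
                  roh_segments = nrow(roh_p$segments)),
    roh_params = unclass(roh_p$params),
    populations = as.list(table(g$samples$pop)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(genotypes = g,
                 tables = list(qc = qc$report, diversity_ne = div_ne,
                               roh_summary = roh_p$summary,
                               roh_classes = roh_p$classes,
                               roh_segments = roh_p$segments,
                               fst = struct$fst, mds = struct$mds,
                               pca = struct$pca),
                 manifest = manifest, out_dir = cfg$out_dir))
}

#' Compare a pipeline run against reference values
#'
#' The reference file is a TSV with columns `statistic`, `pop` (a label,
#' a pair `"A:B"` for FST, or empty for panel-level counts), `expected`
#' and `tolerance`.  Supported statistics: `Ho`, `He_u`, `Ar`, `Fis`,
#' `Ne5`, `Ne50`, `froh1_mean`, `froh5_mean`, `froh10_mean`, `roh_count`,
#' `fst`, `n_snps_retained`, `n_samples_retained`.
#'
#' @param bundle the result of [run_pipeline].
#' @param reference path to the reference TSV.
#' @return data.frame with per-row `computed`, `expected`, `tolerance`,
#'   `pass`.
#' @export
validate_against_reference <- function(bundle, reference) {
  ref <- utils::read.table(reference, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("statistic", "pop", "expected", "tolerance") %in% names(ref)))
  tab <- bundle$tables
  get_one <- function(stat, pop) {
    div <- tab$diversity_ne
    rohs <- tab$roh_summary
    switch(stat,
      Ho = div$Ho[div$pop == pop], He_u = div$He_u[div$pop == pop],
      Ar = div$Ar[div$pop == pop], Fis = div$Fis[div$pop == pop],
      Ne5 = div$Ne5[div$pop == pop], Ne50 = div$Ne50[div$pop == pop],
      froh1_mean = rohs$froh1_mean[rohs$pop == pop],
      froh5_mean = rohs$froh5_mean[rohs$pop == pop],
      froh10_mean = rohs$froh10_mean[rohs$pop == pop],
      roh_count = rohs$roh_count[rohs$pop == pop],
      fst = {
        pq <- strsplit(pop, ":")[[1]]
        tab$fst$values[pq[1], pq[2]]
      },
      n_snps_retained = n_snps(bundle$genotypes),
      n_samples_retained = n_samples(bundle$genotypes),
      stop("unknown statistic in reference: ", stat))
  }
  computed <- mapply(get_one, ref$statistic, ref$pop)
  data.frame(ref[, c("statistic", "pop")], computed = computed,
             expected = ref$expected, tolerance = ref$tolerance,
             pass = abs(computed - ref$expected) <= ref$tolerance,
             stringsAsFactors = FALSE)
}
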