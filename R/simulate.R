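#' Population specification for the simulator
#'
#' One population branch of a [sim_config]: its label, how many individuals
#' are sampled at present, its effective-size history and when it split
#' from the common ancestral population.
#'
#' @param label population label.
#' @param sample_size individuals sampled at generation 0.
#' @param ne effective-size trajectory along the branch: a single number
#'   (constant Ne) or a two-column matrix/data.frame `(span, Ne)` listed
#'   oldest first.  Padded (oldest end) or truncated to the branch length.
#' @param split generations ago at which the branch left the ancestral
#'   population.  With more than one population all splits must be >= 1;
#'   a single population may use `split = 0` (the ancestral population is
#'   sampled directly).
#' @return a list of class `"pop_spec"`.
#' @export
pop_spec <- function(label, sample_size, ne = 200, split = 10) {
  stopifnot(sample_size >= 1, split >= 0)
  structure(list(label = label, sample_size = as.integer(sample_size),
                 ne = ne, split = as.integer(split)), class = "pop_spec")
}

#' Simulation configuration
#'
#' Describes a Wright-Fisher gene-dropping scenario: discrete generations,
#' random mating, recombination as a Poisson crossover process on a linear
#' genetic map (default 1 cM/Mb), ancestral allele frequencies drawn from a
#' uniform MAF spectrum truncated below `maf_floor` (array SNPs are
#' ascertained toward common variants), populations branching from a
#' common ancestral population and drifting at their stated Ne, optional
#' final-generation pedigree loops creating recent inbreeding, and uniform
#' random missingness.
#'
#' @param populations list of [pop_spec] objects.
#' @param n_chromosomes autosome count (26 for sheep).
#' @param snps_per_chromosome SNPs per chromosome.
#' @param chromosome_length_bp physical chromosome length; the default
#'   9.4e7 x 26 approximates a 2.44 Gb autosomal genome.
#' @param ne_ancestral diploid size of the ancestral population.
#' @param burn_in generations the ancestral population drifts before the
#'   oldest split (builds up background LD).
#' @param pedigree_loops `NULL` or a data.frame with columns `type`
#'   (`"half_sib"`, `"full_sib"`, `"selfing"`), `count`, `pop`; loop
#'   offspring replace the last sampled individuals of that population.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @param maf_floor lower truncation of the ancestral MAF spectrum.
#' @param rate_M_per_Mb recombination rate of the linear map.
#' @param seed RNG seed; a fixed seed makes the output reproducible.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(populations,
                       n_chromosomes = 26L, snps_per_chromosome = 1480L,
                       chromosome_length_bp = 9.4e7,
                       ne_ancestral = 200L, burn_in = 50L,
                       pedigree_loops = NULL,
                       missing_rate = 0.002, maf_floor = 0.05,
                       rate_M_per_Mb = 0.01, seed = 1L) {
  stopifnot(length(populations) >= 1,
            all(vapply(populations, inherits, logical(1), "pop_spec")),
            n_chromosomes >= 1, snps_per_chromosome >= 2,
            chromosome_length_bp > 0, ne_ancestral >= 2, burn_in >= 0,
            missing_rate >= 0, missing_rate < 1,
            maf_floor >= 0, maf_floor < 0.5, rate_M_per_Mb > 0)
  labs <- vapply(populations, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate population labels")
  splits <- vapply(populations, `[[`, integer(1), "split")
  if (length(populations) > 1 && any(splits < 1))
    stop("with more than one population all split times must be >= 1")
  structure(list(populations = populations, n_chromosomes = as.integer(n_chromosomes),
                 snps_per_chromosome = as.integer(snps_per_chromosome),
                 chromosome_length_bp = chromosome_length_bp,
                 ne_ancestral = as.integer(ne_ancestral),
                 burn_in = as.integer(burn_in),
                 pedigree_loops = pedigree_loops,
                 missing_rate = missing_rate, maf_floor = maf_floor,
                 rate_M_per_Mb = rate_M_per_Mb, seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected per-branch fixation under pure drift
#'
#' Closed form `1 - (1 - 1/(2N))^t` for the fixation index accumulated by
#' `t` generations of drift at constant diploid size `N`; the test oracle
#' for simulated divergence.
#'
#' @param N diploid population size (>= 1).
#' @param t generations (>= 0).
#' @return expected fixation (scalar, in `[0, 1]`).
#' @export
expected_drift_fst <- function(N, t) {
  stopifnot(N >= 1, t >= 0)
  1 - (1 - 1 / (2 * N))^t
}

# drift fixation along an arbitrary size sequence
drift_f_along <- function(sizes) 1 - prod(1 - 1 / (2 * sizes))

# expand a pop_spec ne field to a per-generation size vector (oldest first)
expand_ne <- function(ne, t) {
  if (t == 0) return(integer(0))
  if (is.numeric(ne) && is.null(dim(ne))) return(rep(as.integer(ne), t))
  ne <- as.matrix(ne)
  v <- rep(as.integer(ne[, 2]), times = as.integer(ne[, 1]))
  if (length(v) < t) v <- c(rep(v[1], t - length(v)), v)
  if (length(v) > t) v <- v[(length(v) - t + 1):length(v)]
  v
}

# random mating pedigree for one generation: K children from Nprev parents,
# sire != dam whenever Nprev > 1
draw_mating <- function(Nprev, K) {
  sire <- sample.int(Nprev, K, replace = TRUE)
  dam <- sample.int(Nprev, K, replace = TRUE)
  if (Nprev > 1) {
    while (any(bad <- dam == sire))
      dam[bad] <- sample.int(Nprev, sum(bad), replace = TRUE)
  }
  cbind(sire, dam)
}

loop_f_values <- c(half_sib = 0.125, full_sib = 0.25, selfing = 0.5)

#' Simulate a genotype panel with known truth
#'
#' Wright-Fisher gene dropping per [sim_config]: founder haplotypes carry
#' unique ids, every meiosis recombines via a Poisson crossover process,
#' and the final generation's haplotype mosaics determine both genotypes
#' (founder alleles drawn from the truncated-uniform MAF spectrum) and the
#' true autozygous tracts (runs where both haplotypes descend from the
#' same founder haplotype).  Pedigree loops are grafted onto the final
#' generation.  Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return list with `genotypes` (a [genotypes] panel) and `truth`, a list:
#'   `pedigree_f` (named per sample), `ne_trajectories` (per population,
#'   oldest first), `split_generations`, `expected_fst` (pairwise drift
#'   expectation), `tracts` (data.frame `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`), `ancestral_size`, `seed`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_exists(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)

  pops <- cfg$populations
  npop <- length(pops)
  labs <- vapply(pops, `[[`, character(1), "label")
  splits <- vapply(pops, `[[`, integer(1), "split")
  samp_n <- vapply(pops, `[[`, integer(1), "sample_size")
  t_max <- max(splits)

  # per-branch size sequences with final-generation headroom for sampling
  branch_sizes <- vector("list", npop)
  for (k in seq_len(npop)) {
    v <- expand_ne(pops[[k]]$ne, splits[k])
    ne_final <- if (length(v)) v[length(v)] else cfg$ne_ancestral
    if (samp_n[k] > 2 * ne_final)
      stop("infeasible config: sample_size ", samp_n[k], " > 2*Ne (",
           2 * ne_final, ") in ", labs[k])
    if (length(v)) v[length(v)] <- max(v[length(v)], samp_n[k])
    else if (samp_n[k] > cfg$ne_ancestral)
      stop("infeasible config: sample_size exceeds ancestral size for ", labs[k])
    branch_sizes[[k]] <- v
  }

  # ancestral lineage: burn_in before the oldest split, then segments
  # between successive split events (youngest split may be 0 only for a
  # single population)
  t_min <- min(splits)
  T_anc <- cfg$burn_in + (t_max - t_min)
  anc_sizes <- rep(cfg$ne_ancestral, T_anc)
  fork_at <- cfg$burn_in + (t_max - splits)    # anc generation index per pop

  # --- draw all pedigrees once (shared across chromosomes) ---
  anc_ped <- vector("list", T_anc)
  Nprev <- cfg$ne_ancestral
  for (gg in seq_len(T_anc)) {
    anc_ped[[gg]] <- draw_mating(Nprev, anc_sizes[gg])
    Nprev <- anc_sizes[gg]
  }
  branch_ped <- vector("list", npop)
  for (k in seq_len(npop)) {
    sizes <- branch_sizes[[k]]
    ped <- vector("list", length(sizes))
    Nprev <- cfg$ne_ancestral
    for (gg in seq_along(sizes)) {
      ped[[gg]] <- draw_mating(Nprev, sizes[gg])
      Nprev <- sizes[gg]
    }
    branch_ped[[k]] <- ped
  }

  # --- pedigree-loop plans per population ---
  ped_f <- lapply(seq_len(npop), function(k) {
    stats::setNames(numeric(samp_n[k]),
                    sprintf("%s_%02d", labs[k], seq_len(samp_n[k])))
  })
  names(ped_f) <- labs
  loop_plan <- vector("list", npop)          # NULL or list(stageA, childAB, childSelf, slots)
  if (!is.null(cfg$pedigree_loops)) {
    pl <- cfg$pedigree_loops
    stopifnot(all(c("type", "count", "pop") %in% names(pl)),
              all(pl$type %in% names(loop_f_values)))
    for (k in seq_len(npop)) {
      rows <- pl[pl$pop == labs[k], , drop = FALSE]
      if (!nrow(rows)) next
      types <- rep(rows$type, rows$count)
      n_loops <- length(types)
      if (n_loops > samp_n[k])
        stop("more pedigree-loop offspring than sampled individuals in ", labs[k])
      N_final <- if (length(branch_sizes[[k]])) {
        branch_sizes[[k]][length(branch_sizes[[k]])]
      } else cfg$ne_ancestral
      slots <- (samp_n[k] - n_loops + 1):samp_n[k]
      pool <- sample(setdiff(seq_len(N_final), slots))
      need <- sum(c(half_sib = 3, full_sib = 2, selfing = 1)[types])
      if (need > length(pool))
        stop("not enough individuals for pedigree loops in ", labs[k])
      stageA <- NULL; childAB <- NULL; childSelf <- NULL
      child_kind <- character(0)             # "ab" or "self", in loop order
      pi_ <- 0L
      for (ty in types) {
        if (ty == "half_sib") {
          s <- pool[pi_ + 1L]; d1 <- pool[pi_ + 2L]; d2 <- pool[pi_ + 3L]; pi_ <- pi_ + 3L
          stageA <- rbind(stageA, c(s, d1), c(s, d2))
          childAB <- rbind(childAB, c(nrow(stageA) - 1L, nrow(stageA)))
          child_kind <- c(child_kind, "ab")
        } else if (ty == "full_sib") {
          p1 <- pool[pi_ + 1L]; p2 <- pool[pi_ + 2L]; pi_ <- pi_ + 2L
          stageA <- rbind(stageA, c(p1, p2), c(p1, p2))
          childAB <- rbind(childAB, c(nrow(stageA) - 1L, nrow(stageA)))
          child_kind <- c(child_kind, "ab")
        } else {                             # selfing proxy
          p1 <- pool[pi_ + 1L]; pi_ <- pi_ + 1L
          childSelf <- rbind(childSelf, c(p1, p1))
          child_kind <- c(child_kind, "self")
        }
      }
      loop_plan[[k]] <- list(stageA = stageA, childAB = childAB,
                             childSelf = childSelf, kind = child_kind,
                             slots = slots)
      ped_f[[k]][slots] <- loop_f_values[types]
    }
  }

  # --- per-chromosome gene dropping ---
  S <- cfg$snps_per_chromosome
  n_total <- sum(samp_n)
  sample_ids <- unlist(lapply(seq_len(npop),
                              function(k) sprintf("%s_%02d", labs[k], seq_len(samp_n[k]))))
  dosage <- matrix(NA_integer_, n_total, S * cfg$n_chromosomes)
  snp_list <- vector("list", cfg$n_chromosomes)
  tract_list <- list()
  L_morgans <- cfg$chromosome_length_bp * cfg$rate_M_per_Mb * 1e-6
  n0 <- 2L * cfg$ne_ancestral

  for (cc in seq_len(cfg$n_chromosomes)) {
    pos <- sort(sample.int(cfg$chromosome_length_bp, S))
    pos_M <- pos * cfg$rate_M_per_Mb * 1e-6
    m <- stats::runif(S, cfg$maf_floor, 0.5)
    p <- ifelse(stats::runif(S) < 0.5, m, 1 - m)
    founder_alleles <- matrix(stats::rbinom(S * n0, 1L, p), S, n0)
    H0 <- matrix(rep(seq_len(n0), each = S), S, n0)

    # ancestral lineage in segments, capturing each fork state
    fork_states <- vector("list", npop)
    ord <- order(fork_at)
    cur <- H0; done <- 0L
    for (k in ord) {
      seg <- fork_at[k] - done
      if (seg > 0) {
        cur <- drop_pedigree_chrom(cur, pos_M, L_morgans,
                                   anc_ped[done + seq_len(seg)])
        done <- done + seg
      }
      fork_states[[k]] <- cur
    }

    col0 <- (cc - 1L) * S
    row0 <- 0L
    for (k in seq_len(npop)) {
      Hk <- if (length(branch_ped[[k]])) {
        drop_pedigree_chrom(fork_states[[k]], pos_M, L_morgans, branch_ped[[k]])
      } else fork_states[[k]]
      lp <- loop_plan[[k]]
      if (!is.null(lp)) {
        iAB <- 0L; iSelf <- 0L
        childAB_H <- NULL
        if (!is.null(lp$stageA)) {
          HA <- drop_pedigree_chrom(Hk, pos_M, L_morgans, list(lp$stageA))
          childAB_H <- drop_pedigree_chrom(HA, pos_M, L_morgans, list(lp$childAB))
        }
        childSelf_H <- if (!is.null(lp$childSelf)) {
          drop_pedigree_chrom(Hk, pos_M, L_morgans, list(lp$childSelf))
        } else NULL
        for (j in seq_along(lp$kind)) {
          slot <- lp$slots[j]
          if (lp$kind[j] == "ab") {
            iAB <- iAB + 1L
            Hk[, 2L * slot - 1L] <- childAB_H[, 2L * iAB - 1L]
            Hk[, 2L * slot] <- childAB_H[, 2L * iAB]
          } else {
            iSelf <- iSelf + 1L
            Hk[, 2L * slot - 1L] <- childSelf_H[, 2L * iSelf - 1L]
            Hk[, 2L * slot] <- childSelf_H[, 2L * iSelf]
          }
        }
      }
      hap_cols <- as.vector(rbind(2L * seq_len(samp_n[k]) - 1L, 2L * seq_len(samp_n[k])))
      Hs <- Hk[, hap_cols, drop = FALSE]
      G <- matrix(founder_alleles[cbind(rep(seq_len(S), ncol(Hs)), as.vector(Hs))],
                  S, ncol(Hs))
      dos <- G[, seq(1L, ncol(G), 2L), drop = FALSE] +
        G[, seq(2L, ncol(G), 2L), drop = FALSE]
      dosage[row0 + seq_len(samp_n[k]), col0 + seq_len(S)] <- t(dos)
      # true autozygous tracts: identical founder-haplotype id on both copies
      for (i in seq_len(samp_n[k])) {
        eq <- Hs[, 2L * i - 1L] == Hs[, 2L * i]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        w <- which(r$values)
        if (length(w))
          tract_list[[length(tract_list) + 1L]] <- data.frame(
            sample_id = sample_ids[row0 + i], chrom = cc,
            start_bp = pos[starts[w]], end_bp = pos[ends[w]],
            stringsAsFactors = FALSE)
      }
      row0 <- row0 + samp_n[k]
    }
    snp_list[[cc]] <- data.frame(
      id = sprintf("c%d_s%04d", cc, seq_len(S)), chrom = cc, pos = pos,
      allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  }

  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(dosage)) < cfg$missing_rate
    dosage[mask] <- NA_integer_
  }

  g <- genotypes(dosage, do.call(rbind, snp_list),
                 data.frame(id = sample_ids,
                            pop = rep(labs, samp_n), stringsAsFactors = FALSE))

  # drift-expected pairwise FST: for a pair that diverged when the older
  # branch forked, each lineage accumulates F = 1 - prod(1 - 1/(2N)) along
  # its own path; the small-F expectation of theta is the mean of the two
  exp_fst <- matrix(0, npop, npop, dimnames = list(labs, labs))
  for (a in seq_len(npop)) for (b in seq_len(npop)) if (a != b) {
    t_div <- max(splits[a], splits[b])
    path_f <- function(k) {
      anc_extra <- rep(cfg$ne_ancestral, t_div - splits[k])
      drift_f_along(c(anc_extra, branch_sizes[[k]]))
    }
    exp_fst[a, b] <- (path_f(a) + path_f(b)) / 2
  }

  truth <- list(pedigree_f = unlist(unname(ped_f)),
                ne_trajectories = stats::setNames(branch_sizes, labs),
                split_generations = stats::setNames(splits, labs),
                expected_fst = exp_fst,
                tracts = if (length(tract_list)) do.call(rbind, tract_list)
                         else data.frame(sample_id = character(0), chrom = integer(0),
                                         start_bp = integer(0), end_bp = integer(0)),
                ancestral_size = cfg$ne_ancestral,
                genome_length_bp = cfg$n_chromosomes * cfg$chromosome_length_bp,
                seed = cfg$seed)
  list(genotypes = g, truth = truth)
}

#' Study-shaped integration fixture
#'
#' A five-population panel matching the statistical regime of a typical
#' SNP-array survey of local sheep breeds: sample sizes (31, 31, 30, 13,
#' 24), 26 autosomes with ~38,000 SNPs in total, pairwise FST spanning
#' roughly 0.01-0.07 (branch Ne between 120 and 600, star split 16
#' generations ago from an ancestral population of 800), and one
#' population (`P1`) carrying elevated recent inbreeding via half-sib
#' pedigree loops.  The ancestral MAF floor of 0.09 emulates array
#' ascertainment toward common variants and keeps the merged panel largely
#' intact through the 0.05 MAF filter despite drift.
#'
#' @param seed RNG seed.
#' @param snps_per_chromosome SNP density (default 1480, giving 38,480
#'   SNPs; reduce for quick tests).
#' @return as [simulate_panel].
#' @export
survey_shaped_fixture <- function(seed = 1L, snps_per_chromosome = 1480L) {
  cfg <- sim_config(
    populations = list(
      pop_spec("P1", 31, ne = 120, split = 16),
      pop_spec("P2", 31, ne = 600, split = 16),
      pop_spec("P3", 30, ne = 500, split = 16),
      pop_spec("P4", 13, ne = 150, split = 16),
      pop_spec("P5", 24, ne = 250, split = 16)),
    n_chromosomes = 26L, snps_per_chromosome = snps_per_chromosome,
    chromosome_length_bp = 9.4e7,
    ne_ancestral = 800L, burn_in = 50L,
    pedigree_loops = data.frame(type = "half_sib", count = 8, pop = "P1",
                                stringsAsFactors = FALSE),
    missing_rate = 0.002, maf_floor = 0.09, seed = seed)
  simulate_panel(cfg)
}

#' Write simulation ground truth to disk
#'
#' JSON for the scalar/field truth and a BED-like TSV for the autozygous
#' tracts.
#'
#' @param truth the `truth` element of [simulate_panel] output.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- truth[setdiff(names(truth), "tracts")]
  jsonlite::write_json(meta, file.path(dir, "sim_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(truth$tracts, file.path(dir, "sim_tracts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
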