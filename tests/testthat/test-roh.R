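test_that("minimum-SNP threshold follows the false-positive formula", {
  # ln(0.05 / (5e4 * 100)) / ln(0.6) = 36.06 -> 37
  expect_identical(min_snp_threshold(5e4, 100, 0.05, 0.4), 37L)
  expect_identical(min_snp_threshold(5e4, 100, 0.05, 0.4),
                   as.integer(ceiling(log(0.05 / (5e4 * 100)) / log(1 - 0.4))))
  # monotone decreasing in het
  l_seq <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                  function(h) min_snp_threshold(5e4, 100, 0.05, h), integer(1))
  expect_true(all(diff(l_seq) <= 0))
  expect_error(min_snp_threshold(100, 10, 0.05, 0), "between 0 and 1")
  expect_error(min_snp_threshold(100, 10, 0.05, 1), "between 0 and 1")
})

test_that("detect_roh reproduces the worked single-het example", {
  # 25 homozygous SNPs at 1 Mb spacing, one het at 13 Mb
  d <- rep(0L, 25); d[13] <- 1L
  g <- make_panel(matrix(d, nrow = 1), pos = as.integer((1:25) * 1e6))
  seg <- detect_roh(g, roh_params(min_length_bp = 1e6, max_het = 1,
                                  max_missing = 1, min_snps = 18))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start_bp, 1e6)
  expect_equal(seg$end_bp, 25e6)
  expect_equal(seg$length_bp, 24e6)
  expect_equal(seg$n_snps, 25)
  expect_equal(seg$n_het, 1)
  # with max_het = 0 the two het-free runs have only 12 SNPs each
  seg0 <- detect_roh(g, roh_params(min_length_bp = 1e6, max_het = 0,
                                   max_missing = 1, min_snps = 18))
  expect_equal(nrow(seg0), 0)
  # fully heterozygous individual: nothing
  gh <- make_panel(matrix(1L, 1, 30), pos = as.integer((1:30) * 1e6))
  expect_equal(nrow(detect_roh(gh, roh_params(min_snps = 2))), 0)
})

test_that("runs never start or end on het/missing calls and never cross
           chromosomes", {
  d <- c(1L, 0L, 0L, 0L, NA, 0L, 0L, 0L, 1L)
  g <- make_panel(matrix(c(d, d), nrow = 1),
                  chrom = rep(1:2, each = 9),
                  pos = as.integer(rep((1:9) * 2e6, 2)))
  seg <- detect_roh(g, roh_params(min_length_bp = 1e6, max_het = 1,
                                  max_missing = 1, min_snps = 3))
  expect_equal(nrow(seg), 2)                 # one per chromosome
  expect_true(all(seg$start_bp == 4e6 & seg$end_bp == 16e6))
  expect_true(all(seg$chrom == 1:2))
})

test_that("detect_roh equals the brute-force oracle on random small panels", {
  set.seed(31)
  for (rep in 1:25) {
    S <- sample(10:50, 1)
    state_p <- c(hom = 0.75, het = 0.15, mis = 0.10)
    d <- sample(c(0L, 1L, NA), S, replace = TRUE, prob = state_p)
    hom <- which(!is.na(d) & d == 0L)
    d[hom] <- sample(c(0L, 2L), length(hom), replace = TRUE)
    pos <- sort(sample.int(5e7, S))
    params <- roh_params(min_length_bp = sample(c(1e6, 5e6), 1),
                         max_het = sample(0:2, 1), max_missing = sample(0:2, 1),
                         min_snps = sample(2:6, 1))
    g <- make_panel(matrix(d, nrow = 1), pos = pos)
    got <- detect_roh(g, params)
    want <- roh_oracle(g, params)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[, c("start_bp", "end_bp")], want[, c("start_bp", "end_bp")],
                   ignore_attr = TRUE)
    }
  }
})

test_that("classification uses half-open Mb bins with documented boundaries", {
  seg <- data.frame(sample_id = "x", length_bp = c(1.5e6, 3e6, 20e6))
  cl <- classify_roh(seg)
  expect_equal(cl$count, c(1L, 1L, 0L, 0L, 1L))
  expect_equal(sum(cl$percent), 100)
  # boundary 2.0 Mb belongs to 2-4 Mb
  cl2 <- classify_roh(data.frame(sample_id = "x", length_bp = 2e6))
  expect_equal(cl2$count[cl2$class == "2-4Mb"], 1L)
  expect_error(classify_roh(data.frame(sample_id = "x", length_bp = 0.5e6)),
               "1 Mb")
  # percentages equal a brute-force histogram on random segment sets
  set.seed(32)
  lens <- 10^runif(300, 6, 7.6)
  cl3 <- classify_roh(data.frame(sample_id = "x", length_bp = lens))
  brute <- sapply(list(c(1, 2), c(2, 4), c(4, 8), c(8, 16), c(16, Inf)),
                  function(b) sum(lens >= b[1] * 1e6 & lens < b[2] * 1e6))
  expect_equal(cl3$count, as.integer(brute))
  expect_equal(cl3$percent, 100 * brute / sum(brute))
})

test_that("F_ROH is the genome fraction above a length floor, with nesting", {
  seg <- data.frame(sample_id = "a", chrom = 1, length_bp = 24.4e6)
  expect_equal(unname(froh(seg, "a", 1e6, 2.44e9)), 0.01)
  expect_equal(unname(froh(seg, c("a", "b"), 1e6, 2.44e9))[2], 0)   # no segments
  expect_equal(unname(froh(seg, "a", 30e6, 2.44e9)), 0)             # below floor
  set.seed(33)
  segs <- data.frame(sample_id = sample(letters[1:5], 60, TRUE),
                     length_bp = 10^runif(60, 6, 7.5))
  f1 <- froh(segs, letters[1:5], 1e6); f5 <- froh(segs, letters[1:5], 5e6)
  f10 <- froh(segs, letters[1:5], 1e7)
  expect_true(all(f10 <= f5 + 1e-15) && all(f5 <= f1 + 1e-15))
})

test_that("roh_summary aggregates per breed including zero-ROH animals", {
  samples <- data.frame(id = c("a", "b", "c"), pop = c("X", "X", "Y"))
  segs <- data.frame(sample_id = c("a", "a"), chrom = 1,
                     start_bp = c(1e6, 30e6), end_bp = c(11e6, 36e6),
                     length_bp = c(1e7, 6e6))
  s <- roh_summary(segs, samples, genome_length_bp = 1e9)
  expect_equal(s$roh_count[s$pop == "X"], 2)
  expect_equal(s$froh1_mean[s$pop == "X"], mean(c(1.6e7 / 1e9, 0)))
  expect_equal(s$froh10_mean[s$pop == "X"], mean(c(1e7 / 1e9, 0)))
  expect_equal(s$froh1_mean[s$pop == "Y"], 0)
  expect_equal(s$mean_sum_roh_mb[s$pop == "X"], mean(c(16, 0)))
})

test_that("recent inbreeding leaves longer runs than ancient inbreeding", {
  # same machinery as the headline analysis: a recent half-sib loop versus a
  # long-standing small-Ne population, compared on the >8 Mb ROH share
  recent <- simulate_panel(sim_config(
    list(pop_spec("R", 20, ne = 500, split = 0)),
    n_chromosomes = 6, snps_per_chromosome = 900, chromosome_length_bp = 9.4e7,
    ne_ancestral = 500, burn_in = 0,
    pedigree_loops = data.frame(type = "half_sib", count = 20, pop = "R"),
    missing_rate = 0, seed = 71))
  ancient <- simulate_panel(sim_config(
    list(pop_spec("A", 20, ne = 30, split = 60)),
    n_chromosomes = 6, snps_per_chromosome = 900, chromosome_length_bp = 9.4e7,
    ne_ancestral = 500, burn_in = 0, missing_rate = 0, seed = 72))
  params <- roh_params(min_length_bp = 1e6, min_snps = 20)
  share_long <- function(g) {
    seg <- detect_roh(g, params)
    sum(seg$length_bp[seg$length_bp > 8e6]) / sum(seg$length_bp)
  }
  expect_gt(share_long(recent$genotypes), share_long(ancient$genotypes))
})
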