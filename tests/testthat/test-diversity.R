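# The three closed-form hand examples (He_u = 0.6, Ar = 4/3, Fis = 4/9) are
# asserted at 1e-12 in test-acceptance.R; here the operations are exercised
# on broader inputs and their invariants.

test_that("observed heterozygosity counts het fractions per locus", {
  g <- make_panel(matrix(c(0L, 1L, 2L,   # locus 1: AA, AG, GG -> 1/3
                           1L, 1L, NA),  # locus 2: two hets, one missing -> 1
                         nrow = 3))
  ho <- observed_heterozygosity(g, "P1")
  expect_equal(unname(ho$per_locus), c(1 / 3, 1))
  expect_equal(ho$mean, mean(c(1 / 3, 1)))
  expect_error(observed_heterozygosity(g, "nope"), "not present")
  # all-homozygous population
  g0 <- make_panel(matrix(c(0L, 2L, 0L, 2L), 2))
  expect_equal(observed_heterozygosity(g0, "P1")$mean, 0)
})

test_that("Ho matches the HWE binomial expectation on simulated data", {
  set.seed(21)
  n <- 500; p <- 0.3
  g <- make_panel(matrix(rbinom(n, 2, p), ncol = 1))
  ho <- observed_heterozygosity(g, "P1")$mean
  se <- sqrt(2 * p * (1 - p) * (1 - 2 * p * (1 - p)) / n)
  expect_lt(abs(ho - 2 * p * (1 - p)), 3 * se)
})

test_that("unbiased He applies the 2n/(2n-1) factor and handles edge cases", {
  g <- make_panel(matrix(c(0L, 1L, 2L), nrow = 3))
  expect_equal(unbiased_expected_heterozygosity(g, "P1")$per_locus[[1]], 0.6)
  g0 <- make_panel(matrix(0L, 5, 1))
  expect_equal(unbiased_expected_heterozygosity(g0, "P1")$per_locus[[1]], 0)
  # n < 2 loci are skipped with a message
  g1 <- make_panel(matrix(c(1L, NA, NA), nrow = 3))
  expect_message(r <- unbiased_expected_heterozygosity(g1, "P1"), "skipped")
  expect_equal(r$n_skipped, 1)
  # large-n limit -> 1 - sum p^2
  set.seed(22)
  n <- 1e4; p <- 0.37
  gl <- make_panel(matrix(rbinom(n, 2, p), ncol = 1))
  he <- unbiased_expected_heterozygosity(gl, "P1")$per_locus[[1]]
  phat <- allele_freq(gl)
  expect_lt(abs(he - (1 - phat^2 - (1 - phat)^2)), 1e-3)
  # finite-sample inequality He_u >= 1 - sum p^2, any locus
  gr <- random_panel(20, 50)
  heu <- unbiased_expected_heterozygosity(gr, "P1")$per_locus
  pr <- allele_freq(gr)
  expect_true(all(heu >= (1 - pr^2 - (1 - pr)^2) - 1e-12))
})

test_that("rarefied allelic richness matches hypergeometric inclusion and a
           Monte-Carlo subsampling oracle", {
  # monomorphic locus -> Ar = 1 for any g
  g0 <- make_panel(matrix(2L, 4, 1))
  expect_equal(unname(rarefied_allelic_richness(g0, g_rarefy = 2)$per_population), 1)
  # g_rarefy = 2N -> observed allele count
  g1 <- make_panel(matrix(c(0L, 1L, 2L), nrow = 3))
  expect_equal(unname(rarefied_allelic_richness(g1, g_rarefy = 6)$per_population), 2)
  # Monte-Carlo oracle: resample 2 of the 6 gene copies without replacement
  g2 <- make_panel(matrix(c(2L, 2L, 1L), nrow = 3))   # allele counts (5, 1)
  ar <- unname(rarefied_allelic_richness(g2, g_rarefy = 2)$per_population)
  set.seed(23)
  genes <- c(rep("B", 5), "A")
  mc <- mean(replicate(20000, length(unique(sample(genes, 2)))))
  expect_lt(abs(ar - mc), 0.02)
  # monotone non-decreasing in g_rarefy
  set.seed(24)
  gr <- random_panel(12, 40)
  ars <- vapply(2:10, function(gg)
    unname(rarefied_allelic_richness(gr, g_rarefy = gg)$per_population), numeric(1))
  expect_true(all(diff(ars) >= -1e-12))
  expect_error(rarefied_allelic_richness(gr, g_rarefy = 1), ">= 2")
})

test_that("Fis recovers a generative inbreeding coefficient with covering CIs", {
  # genotypes drawn with P(het) = 2p(1-F)(1-p): Fis should estimate F
  draw_inbred <- function(n, S, f) {
    p <- runif(S, 0.1, 0.5)
    d <- vapply(p, function(pp) {
      hom_b <- pp^2 + f * pp * (1 - pp)
      het <- 2 * pp * (1 - pp) * (1 - f)
      sample(c(2L, 1L, 0L), n, replace = TRUE,
             prob = c(hom_b, het, 1 - hom_b - het))
    }, integer(n))
    make_panel(d)
  }
  set.seed(25)
  reps <- 30
  cover <- 0; ests <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- draw_inbred(150, 400, 0.1)
    fis <- inbreeding_fis(g, "P1", n_boot = 300, seed = r)
    ests[r] <- fis$fis
    cover <- cover + (fis$ci[1] <= 0.1 && 0.1 <= fis$ci[2])
  }
  expect_lt(abs(mean(ests) - 0.1), 0.02)
  # nominal 95% CIs: allow binomial slack at 30 replicates
  expect_gte(cover, 25)
})

test_that("Fis edge cases and bootstrap behaviour", {
  # Ho == He_u everywhere -> Fis ~ 0 (random mating, large n)
  set.seed(26)
  g <- random_panel(400, 300)
  expect_lt(abs(inbreeding_fis(g, "P1", n_boot = 100, seed = 1)$fis), 0.02)
  # CI width shrinks with locus count
  g_small <- random_panel(50, 100)
  g_big <- random_panel(50, 10000)
  w <- function(gg) diff(inbreeding_fis(gg, "P1", n_boot = 300, seed = 2)$ci)
  expect_lt(w(g_big), w(g_small))
  # same seed -> identical CI; RNG stream of the caller untouched
  f1 <- inbreeding_fis(g_small, "P1", n_boot = 100, seed = 3)
  f2 <- inbreeding_fis(g_small, "P1", n_boot = 100, seed = 3)
  expect_identical(f1$ci, f2$ci)
  expect_error(inbreeding_fis(make_panel(matrix(0L, 4, 3)), "P1"), "polymorphic")
})

test_that("all diversity statistics are invariant to allele-label swaps", {
  set.seed(27)
  g <- random_panel(25, 60, miss = 0.03, pops = rep(c("A", "B"), c(12, 13)))
  gs <- g
  flip <- sample(n_snps(g), 20)
  gs$dosage[, flip] <- 2L - gs$dosage[, flip]
  for (pp in c("A", "B")) {
    expect_equal(observed_heterozygosity(gs, pp)$per_locus,
                 observed_heterozygosity(g, pp)$per_locus)
    expect_equal(unbiased_expected_heterozygosity(gs, pp)$per_locus,
                 unbiased_expected_heterozygosity(g, pp)$per_locus)
  }
  expect_equal(rarefied_allelic_richness(gs)$per_population,
               rarefied_allelic_richness(g)$per_population)
})

test_that("diversity_summary assembles the per-population table", {
  set.seed(28)
  g <- random_panel(30, 150, pops = rep(c("A", "B"), 15))
  tab <- diversity_summary(g, n_boot = 50, seed = 1)
  expect_equal(tab$pop, c("A", "B"))
  expect_equal(tab$n, c(15, 15))
  expect_true(all(tab$Ho >= 0 & tab$Ho <= 1))
  expect_true(all(tab$He_u >= 0 & tab$He_u <= 1))
  expect_true(all(tab$Ar >= 1 & tab$Ar <= 2))
  expect_true(all(tab$Fis_lo <= tab$Fis & tab$Fis <= tab$Fis_hi))
})
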