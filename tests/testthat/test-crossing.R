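test_that("gametes segregate fairly and homozygotes transmit deterministically", {
  withr::local_seed(1)
  expect_identical(sample_gamete(rep("AA", 5)), rep("A", 5))
  # mixed row: homozygous loci fixed, heterozygous locus random
  g <- sample_gamete(c("AA", "AG", "GG"))
  expect_identical(g[c(1, 3)], c("A", "G"))
  expect_true(g[2] %in% c("A", "G"))
  # fair segregation at many heterozygous loci
  frac_a <- mean(sample_gamete(rep("AG", 1e4)) == "A")
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / 1e4))
  # missing propagates
  expect_true(is.na(sample_gamete(NA_character_)))
})

test_that("crossing pure pools produces the expected offspring classes", {
  pures <- make_diagnostic_pures(n_loci = 50, n = 20, seed = 1)
  # pure x same pure: all offspring homozygous for that pure's alleles
  aa <- cross(pures$pure_a, pures$pure_a, 10, seed = 2)
  expect_equal(as.matrix(aa[, locus_ids(aa)]),
               as.matrix(pures$pure_a[1:10, locus_ids(aa)]),
               ignore_attr = TRUE)
  # fully diagnostic A x B: every offspring heterozygous everywhere (F1)
  f1 <- cross(pures$pure_a, pures$pure_b, 25, seed = 3)
  m <- as.matrix(f1[, locus_ids(f1)])
  expect_true(all(substr(m, 1, 1) != substr(m, 2, 2)))
  # allele conservation: offspring alleles all occur in the parents
  par_alleles <- sort(unique(unlist(strsplit(
    c(as.matrix(pures$pure_a[, locus_ids(f1)]),
      as.matrix(pures$pure_b[, locus_ids(f1)])), ""))))
  expect_true(all(unlist(strsplit(as.vector(m), "")) %in% par_alleles))

  expect_error(cross(pures$pure_a[0, ], pures$pure_b, 5), "empty parent pool")
  # determinism
  expect_identical(cross(pures$pure_a, pures$pure_b, 5, seed = 9),
                   cross(pures$pure_a, pures$pure_b, 5, seed = 9))
})

test_that("F1 x F1 offspring show 1/4 - 1/2 - 1/4 genotype fractions", {
  pures <- make_diagnostic_pures(n_loci = 50, n = 20, seed = 4)
  f1 <- cross(pures$pure_a, pures$pure_b, 200, seed = 5, label = "F1")
  off <- cross(f1, f1, 2000, seed = 6)
  d <- diagnose_panel(dplyr::bind_rows(pures$pure_a, pures$pure_b),
                      "PUREA", "PUREB")
  sc <- score_individuals(off, d, local_pop = "PUREA")
  n_markers <- sum(sc$n_obs)
  se <- function(p) 3 * sqrt(p * (1 - p) / n_markers)
  expect_lt(abs(sum(sc$k_het) / n_markers - 0.5), se(0.5))
  expect_lt(abs(sum(sc$k_hom_local) / n_markers - 0.25), se(0.25))
  expect_lt(abs(sum(sc$k_hom_foreign) / n_markers - 0.25), se(0.25))
})

test_that("missing parental calls propagate to offspring without imputation", {
  pures <- make_diagnostic_pures(n_loci = 20, n = 30, seed = 7,
                                 missing_rate = 0.2)
  off <- cross(pures$pure_a, pures$pure_b, 100, seed = 8)
  expect_gt(sum(is.na(as.matrix(off[, locus_ids(off)]))), 0)
})

test_that("simulated backcross generations match their expected heterozygosity", {
  pures <- make_diagnostic_pures(n_loci = 50, n = 40, seed = 10)
  d <- diagnose_panel(dplyr::bind_rows(pures$pure_a, pures$pure_b),
                      "PUREA", "PUREB")
  # F1 heterozygous everywhere, exactly
  f1 <- simulate_category(pures$pure_a, pures$pure_b, "F1", 50, seed = 11)
  expect_true(all(score_individuals(f1, d)$k_het == 50))
  # FgA: heterozygous fraction ~ 2^(1-g), within 3 s.e. of the mean fraction
  for (cat in c("F2A", "F5B")) {
    g <- as.integer(substr(cat, 2, 2))
    sim <- simulate_category(pures$pure_a, pures$pure_b, cat, 400, seed = 11 + g)
    expect_identical(unique(sim$label), cat)
    kh <- score_individuals(sim, d)$k_het
    p <- 2^(1 - g)
    expect_lt(abs(mean(kh) / 50 - p), 3 * sqrt(p * (1 - p) / (400 * 50)))
  }
  expect_error(simulate_category(pures$pure_a, pures$pure_b, "F0", 5),
               "not a simulable")
  expect_error(simulate_category(pures$pure_a, pures$pure_b, "F3", 5),
               "direction")
})

test_that("Fg heterozygote counts are Binomial(n, 2^(1-g)) (goodness of fit)", {
  pures <- make_diagnostic_pures(n_loci = 20, n = 40, seed = 20)
  d <- diagnose_panel(dplyr::bind_rows(pures$pure_a, pures$pure_b),
                      "PUREA", "PUREB")
  sim <- simulate_category(pures$pure_a, pures$pure_b, "F3A", 1e4, seed = 21)
  kh <- score_individuals(sim, d)$k_het
  p <- 2^(1 - 3)
  expected <- dbinom(0:20, 20, p)
  # pool tail bins with tiny expectation for a valid chi-square
  keep <- expected * 1e4 >= 5
  obs <- tabulate(kh + 1, 21)
  obs_p <- c(obs[keep], sum(obs[!keep]))
  exp_p <- c(expected[keep], sum(expected[!keep]))
  expect_gt(suppressWarnings(chisq.test(obs_p, p = exp_p))$p.value, 0.01)
})

test_that("build_baseline assembles the labelled category layout", {
  pures <- make_diagnostic_pures(n_loci = 30, n = 95, seed = 30)
  base <- build_baseline(pures$pure_a, pures$pure_b, n_per_category = 100,
                         max_generation = 5, seed = 31)
  expect_setequal(unique(base$label),
                  c("PUREA", "PUREB", "F1", paste0("F", 2:5, "A"),
                    paste0("F", 2:5, "B")))
  expect_equal(nrow(base), 95 + 95 + 9 * 100)
  expect_false(any(duplicated(base$individual_id)))

  small <- build_baseline(pures$pure_a, pures$pure_b, n_per_category = 10,
                          max_generation = 2, seed = 32)
  expect_length(unique(small$label), 5)
  expect_error(build_baseline(pures$pure_a, pures$pure_b, max_generation = 1),
               "max_generation")

  # per-category mean heterozygosity is ordered F1 > F2 > F3 > F4 > F5
  d <- diagnose_panel(base, "PUREA", "PUREB")
  sc <- score_individuals(base, d)
  mh <- tapply(sc$k_het, sc$label, mean)
  expect_true(all(diff(mh[c("F1", paste0("F", 2:5, "A"))]) < 0))
  expect_true(all(diff(mh[c("F1", paste0("F", 2:5, "B"))]) < 0))
})

test_that("reciprocal backcross statistics mirror under mirrored profiles", {
  pures <- make_diagnostic_pures(n_loci = 40, n = 50, seed = 40)
  d <- diagnose_panel(dplyr::bind_rows(pures$pure_a, pures$pure_b),
                      "PUREA", "PUREB")
  fa <- simulate_category(pures$pure_a, pures$pure_b, "F3A", 2000, seed = 41)
  fb <- simulate_category(pures$pure_a, pures$pure_b, "F3B", 2000, seed = 41)
  ka <- score_individuals(fa, d, local_pop = "PUREA")$k_het
  kb <- score_individuals(fb, d, local_pop = "PUREB")$k_het
  p <- 2^(1 - 3)
  se3 <- 3 * sqrt(p * (1 - p) / (2000 * 40))
  expect_lt(abs(mean(ka) - mean(kb)) / 40, 2 * se3)
})

test_that("expected cross fractions come out of parental-state enumeration", {
  f2 <- cross_expected_fractions("F2xF2")
  expect_equal(setNames(f2$fraction, f2$class),
               c(hom_local = 0.5625, het = 0.375, hom_foreign = 0.0625))
  f1 <- cross_expected_fractions("F1xF1")
  expect_equal(setNames(f1$fraction, f1$class),
               c(hom_local = 0.25, het = 0.5, hom_foreign = 0.25))
  expect_equal(sum(cross_expected_fractions("F3xF5")$fraction), 1)
  expect_error(cross_expected_fractions("F2xPURE"), "unrecognised")
})
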