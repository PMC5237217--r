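test_that("per-marker heterozygosity probabilities follow the three scenarios", {
  expect_equal(het_probability(1, "diagnostic"), 1)
  expect_equal(het_probability(2:5, "diagnostic"), c(0.5, 0.25, 0.125, 0.0625))
  expect_equal(het_probability(3, "introgressing_maf", m = 0.05), 0.2375)
  # symmetry makes g = 2 exactly 1/2 whatever m is
  expect_equal(het_probability(2, "symmetric_maf", m = 0.05), 0.5)
  expect_equal(het_probability(2, "symmetric_maf", m = 0.2), 0.5)
  expect_error(het_probability(0, "diagnostic"))
})

test_that("n = 1 partitions {0, 1} between Native and F1 only", {
  tab <- classification_table(1, "diagnostic")
  expect_equal(tab$k_lo[tab$category == "F1"], 1)
  expect_equal(tab$k_hi[tab$category == "F1"], 1)
  expect_equal(tab$k_lo[tab$category == "Native"], 0)
  expect_equal(tab$k_hi[tab$category == "Native"], 0)
  expect_true(all(is.na(tab$k_lo[!tab$category %in% c("F1", "Native")])))
})

test_that("interval partition: non-empty intervals tile 0..n exactly once", {
  grid <- expand.grid(n = c(1, 5, 12, 50, 73),
                      scenario = c("diagnostic", "introgressing_maf", "symmetric_maf"),
                      m = c(0.01, 0.05, 0.2), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    tab <- classification_table(grid$n[i], grid$scenario[i], grid$m[i])
    owners <- rep(0L, grid$n[i] + 1)
    for (j in which(!is.na(tab$k_lo))) {
      ks <- tab$k_lo[j]:tab$k_hi[j]
      owners[ks + 1] <- owners[ks + 1] + 1L
    }
    expect_true(all(owners == 1L),
                label = sprintf("partition at n=%d %s m=%g", grid$n[i],
                                grid$scenario[i], grid$m[i]))
    # lower bounds strictly decrease with generation until intervals vanish
    lo <- tab$k_lo[grepl("^F", tab$category)]
    lo <- lo[!is.na(lo)]
    expect_true(all(diff(lo) < 0))
  }
})

test_that("classifier agrees with a brute-force argmax oracle for n <= 12", {
  # oracle: direct argmax over exact binomial pmfs, ties to the lower
  # generation, F1 claiming k >= ceiling(n / sqrt(2)) by convention
  oracle <- function(k, n, scenario, m, max_g = 8) {
    if (k >= ceiling(n / sqrt(2))) return("F1")
    p <- c(het_probability(seq_len(max_g), scenario, m),
           if (scenario == "symmetric_maf") 2 * m * (1 - m) else 0)
    cats <- c(paste0("F", seq_len(max_g)), "Native")
    drop_f1 <- -1          # F1 handled by the convention above
    lik <- dbinom(k, n, p)[drop_f1]
    cats <- cats[drop_f1]
    best <- which(lik == max(lik))
    # tie-break: lower generation, Native last
    cats[best[1]]
  }
  for (scenario in c("diagnostic", "introgressing_maf", "symmetric_maf")) {
    m <- if (scenario == "diagnostic") 0 else 0.05
    for (n in c(3, 8, 12)) {
      scores <- tibble::tibble(individual_id = as.character(0:n),
                               n_obs = n, k_het = 0:n)
      got <- classify_generation(scores, scenario, m)$category
      want <- vapply(0:n, oracle, "", n = n, scenario = scenario, m = m)
      expect_identical(got, want,
                       label = sprintf("oracle match n=%d %s", n, scenario))
    }
  }
})

test_that("classification of heterozygote counts matches the printed anchors", {
  scores <- tibble::tibble(individual_id = c("a", "b", "c"),
                           n_obs = 50, k_het = c(50, 0, 12))
  got <- classify_generation(scores, "diagnostic")
  expect_identical(got$category, c("F1", "Native", "F3"))
  # log-likelihoods are finite for achievable categories and ordered sanely
  ll <- got$loglik[[3]]
  expect_true(ll$loglik[ll$category == "F3"] == max(ll$loglik))
  expect_error(classify_generation(tibble::tibble(n_obs = 10, k_het = 11)),
               "invariant")
})

test_that("Monte-Carlo classification reproduces prob_correct for F2..F5", {
  pures <- make_diagnostic_pures(n_loci = 50, n = 40, seed = 50)
  d <- diagnose_panel(dplyr::bind_rows(pures$pure_a, pures$pure_b),
                      "PUREA", "PUREB")
  tab <- classification_table(50, "diagnostic")
  n_sim <- 4000
  for (g in 2:5) {
    sim <- simulate_category(pures$pure_a, pures$pure_b,
                             paste0("F", g, "A"), n_sim, seed = 50 + g)
    cls <- classify_generation(score_individuals(sim, d), "diagnostic")
    acc <- mean(cls$category == paste0("F", g))
    pc <- tab$prob_correct[tab$category == paste0("F", g)]
    expect_lt(abs(acc - pc), 3 * sqrt(pc * (1 - pc) / n_sim),
              label = paste0("prob_correct F", g))
  }
})

test_that("dual-ancestry flagging distinguishes hybrid x hybrid from backcrosses", {
  pures <- make_diagnostic_pures(n_loci = 50, n = 40, seed = 60)
  d <- diagnose_panel(dplyr::bind_rows(pures$pure_a, pures$pure_b),
                      "PUREA", "PUREB")
  f2 <- simulate_category(pures$pure_a, pures$pure_b, "F2A", 200, seed = 61)
  # pure backcrosses can never carry a foreign homozygote
  sc_bc <- dual_ancestry_test(score_individuals(f2, d))
  expect_true(all(sc_bc$k_hom_foreign == 0))
  expect_true(all(!sc_bc$dual_flag))
  expect_true(all(sc_bc$p_backcross_tail == 1))
  # F2 x F2 offspring mostly do carry foreign homozygotes
  f2b <- simulate_category(pures$pure_a, pures$pure_b, "F2A", 200, seed = 62)
  off <- cross(f2, f2b, 400, seed = 63)
  sc_off <- dual_ancestry_test(score_individuals(off, d))
  flagged <- mean(sc_off$dual_flag)
  expect_gt(flagged, 0.9)       # expected miss rate ~ (0.9375)^50 ~ 4%
  expect_true(all(sc_off$p_backcross_tail[sc_off$k_hom_foreign > 0] == 0))
})

test_that("dual-detection probabilities match exact trinomial arithmetic", {
  expect_equal(dual_detection_probability(50, 51, "F1xF1"), 0)
  expect_equal(dual_detection_probability(50, 0, "F1xF1"), 1)
  # independent oracle: dense enumeration with dmultinom
  oracle <- function(n, t, p) {
    tot <- 0
    for (ka in 0:n) for (kb in 0:(n - ka)) {
      if (ka >= t && kb >= t) {
        tot <- tot + dmultinom(c(ka, kb, n - ka - kb),
                               prob = c(p[1], p[2], p[3]))
      }
    }
    tot
  }
  got <- dual_detection_probability(50, 3, "F1xF1")
  expect_equal(got, oracle(50, 3, c(0.25, 0.25, 0.5)), tolerance = 1e-10)
  # the exact value is ~99.997%, distinct from a rounded 99.8%
  expect_gt(got, 0.999)
  got2 <- dual_detection_probability(50, 3, "F2xF2")
  expect_equal(got2, oracle(50, 3, c(0.5625, 0.0625, 0.375)), tolerance = 1e-10)
  # P(no foreign homozygote | F2 x F2, 50 markers) = 0.9375^50
  p_none <- 1 - dual_detection_probability(50, 1, "F2xF2")
  # detection here requires BOTH sides >= 1; under F2xF2 hom_local is
  # essentially always present, so the complement is P(no foreign hom)
  expect_equal(p_none, 1 - oracle(50, 1, c(0.5625, 0.0625, 0.375)),
               tolerance = 1e-10)
})
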