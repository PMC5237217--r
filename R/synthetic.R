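#' Allele-frequency profiles for two populations
#'
#' Builds the per-locus generative truth for a two-population (A, B)
#' baseline under one of three fixedness scenarios:
#'
#' * `"diagnostic"`: every locus strictly fixed for opposite alleles
#'   (allele-b frequency 0 in A, 1 in B);
#' * `"introgressing_maf"`: only population B carries the A-type allele as
#'   a minor allele (frequency of allele b in B is `1 - MAF`; A stays
#'   fixed), the situation of one species introgressing into the other's
#'   range;
#' * `"symmetric_maf"`: both populations carry the other's allele at a
#'   minor frequency.
#'
#' MAFs are either constant at `m` or drawn uniformly on (0, m] per locus.
#' Loci are placed one per scaffold with strictly decreasing scaffold
#' lengths, so the panel is unlinked by construction and "longest
#' scaffold" selection is well defined downstream.
#'
#' @param n_loci Number of loci.
#' @param scenario One of `"diagnostic"`, `"introgressing_maf"`,
#'   `"symmetric_maf"`.
#' @param m Minor allele frequency bound, in `[0, 0.5)`. Ignored for
#'   `"diagnostic"`.
#' @param maf_draw `"constant"` (every MAF locus at `m`) or `"uniform"`
#'   (uniform on (0, m]).
#' @param seed Integer seed; the profile is deterministic given it.
#' @return A tibble with columns `locus_id`, `scaffold_id`,
#'   `scaffold_length`, `position`, `allele_a`, `allele_b`, `freq_A`,
#'   `freq_B` (the allele-b frequency in each population).
#' @export
frequency_profile <- function(n_loci,
                              scenario = c("diagnostic", "introgressing_maf", "symmetric_maf"),
                              m = 0,
                              maf_draw = c("constant", "uniform"),
                              seed = NULL) {
  scenario <- match.arg(scenario)
  maf_draw <- match.arg(maf_draw)
  stopifnot(n_loci >= 1)
  if (scenario != "diagnostic" && (m < 0 || m >= 0.5)) {
    abort("m must be in [0, 0.5)")
  }
  seed_guard(seed)
  w <- max(3, nchar(as.character(n_loci)))
  pair <- t(vapply(seq_len(n_loci),
                   function(i) sort(sample(c("A", "C", "G", "T"), 2)),
                   character(2)))
  draw_maf <- function() {
    switch(maf_draw,
           constant = rep(m, n_loci),
           uniform = runif(n_loci, 0, m))
  }
  freq <- switch(scenario,
                 diagnostic = list(A = rep(0, n_loci), B = rep(1, n_loci)),
                 introgressing_maf = list(A = rep(0, n_loci), B = 1 - draw_maf()),
                 symmetric_maf = list(A = draw_maf(), B = 1 - draw_maf()))
  tibble(
    locus_id = sprintf("L%0*d", w, seq_len(n_loci)),
    scaffold_id = sprintf("S%0*d", w, seq_len(n_loci)),
    scaffold_length = as.integer(2e6 + (n_loci - seq_len(n_loci) + 1) * 1e4),
    position = as.integer(1e6),
    allele_a = pair[, 1],
    allele_b = pair[, 2],
    freq_A = freq$A,
    freq_B = freq$B
  )
}

#' Sample a population of genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual's call at each locus is drawn as Binomial(2, freq) copies
#' of allele b, loci independent (the panel is unlinked by design). Missing
#' calls are applied i.i.d. at `missing_rate`, emulating assay dropout.
#'
#' @param freqs A frequency profile from [frequency_profile()].
#' @param pop `"A"` or `"B"` (selects the `freq_A`/`freq_B` column).
#' @param n Number of individuals (> 0).
#' @param missing_rate Per-call probability of a missing genotype.
#' @param seed Integer seed.
#' @param label Label for the sampled individuals; default `"PUREA"`/`"PUREB"`.
#' @param id_prefix Prefix for individual ids.
#' @return A genotype tibble.
#' @export
sample_population <- function(freqs, pop, n, missing_rate = 0, seed = NULL,
                              label = paste0("PURE", pop),
                              id_prefix = paste0(label, "_")) {
  col <- paste0("freq_", pop)
  if (!col %in% names(freqs)) abort(paste0("population not in profile: ", pop))
  if (n <= 0) abort("n must be positive")
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  seed_guard(seed)
  L <- nrow(freqs)
  f <- freqs[[col]]
  nb <- matrix(rbinom(n * L, 2, rep(f, each = n)), nrow = n)
  calls <- matrix(NA_character_, n, L)
  for (k in seq_len(L)) {
    a <- freqs$allele_a[k]; b <- freqs$allele_b[k]
    calls[, k] <- c(paste0(a, a), paste0(a, b), paste0(b, b))[nb[, k] + 1L]
  }
  if (missing_rate > 0) {
    calls[matrix(runif(n * L) < missing_rate, n, L)] <- NA_character_
  }
  colnames(calls) <- freqs$locus_id
  new_genotypes(calls, sprintf("%s%04d", id_prefix, seq_len(n)),
                rep(label, n), loci = freqs[, 1:6])
}

#' Simulate pooled-sequencing allele counts
#'
#' Emulates pooled resequencing of equal-contribution pools: for each site
#' and pool, the pool's 2 x `individuals_per_pool` allele copies are drawn
#' from the pool population's frequency, read depth is Poisson
#' (`mean_depth`), and each read draws an allele uniformly from the pool's
#' copies. The two-stage draw inflates the allele-count variance relative
#' to a plain binomial read model, as finite pools do in practice; set
#' `two_stage = FALSE` for the one-stage binomial.
#'
#' @param freqs Per-site frequency tibble (as [frequency_profile()], used
#'   here as per-site truth; neutral sites are rows with `freq_A == freq_B`).
#' @param pools A tibble with columns `pool_id` and `pop`; default two
#'   pools per population.
#' @param individuals_per_pool Diploid individuals per pool.
#' @param mean_depth Mean reads per site per pool.
#' @param two_stage Use the finite-pool two-stage model (default).
#' @param seed Integer seed.
#' @return A tibble of per-site, per-pool counts: `scaffold_id`,
#'   `scaffold_length`, `position`, `pool_id`, `depth`, `count_allele_a`,
#'   `count_allele_b`. Zero-depth sites are recorded, not dropped.
#' @export
simulate_pooled_counts <- function(freqs, pools = NULL,
                                   individuals_per_pool = 18,
                                   mean_depth = 12,
                                   two_stage = TRUE,
                                   seed = NULL) {
  stopifnot(individuals_per_pool >= 1, mean_depth > 0)
  if (is.null(pools)) {
    pools <- tibble(pool_id = c("A1", "A2", "B1", "B2"),
                    pop = c("A", "A", "B", "B"))
  }
  seed_guard(seed)
  ncopies <- 2L * as.integer(individuals_per_pool)
  out <- vector("list", nrow(pools))
  for (j in seq_len(nrow(pools))) {
    f <- freqs[[paste0("freq_", pools$pop[j])]]
    L <- length(f)
    depth <- rpois(L, mean_depth)
    if (two_stage) {
      nb_copies <- rbinom(L, ncopies, f)
      count_b <- rbinom(L, depth, nb_copies / ncopies)
    } else {
      count_b <- rbinom(L, depth, f)
    }
    out[[j]] <- tibble(scaffold_id = freqs$scaffold_id,
                       scaffold_length = freqs$scaffold_length,
                       position = freqs$position,
                       pool_id = pools$pool_id[j],
                       depth = depth,
                       count_allele_a = depth - count_b,
                       count_allele_b = count_b)
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$scaffold_id, .data$position, .data$pool_id)
}

#' Read/write pooled allele-count tables
#'
#' Tab-separated, columns `scaffold_id scaffold_length position pool_id
#' depth count_allele_a count_allele_b`.
#'
#' @param path File path.
#' @param sites A pooled-count tibble from [simulate_pooled_counts()].
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_pooled_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    scaffold_id = "c", scaffold_length = "i", position = "i",
    pool_id = "c", depth = "i", count_allele_a = "i", count_allele_b = "i"))
}

#' @rdname read_pooled_counts
#' @export
write_pooled_counts <- function(sites, path) {
  cols <- c("scaffold_id", "scaffold_length", "position", "pool_id",
            "depth", "count_allele_a", "count_allele_b")
  readr::write_tsv(sites[, cols], path)
  invisible(path)
}
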