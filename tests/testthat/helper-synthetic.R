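# Shared fixtures, all generated in code.

# strictly fixed two-population panel and its pure samples
make_diagnostic_pures <- function(n_loci = 50, n = 95, seed = 42,
                                  missing_rate = 0) {
  freqs <- frequency_profile(n_loci, "diagnostic", seed = seed)
  list(freqs = freqs,
       pure_a = sample_population(freqs, "A", n, missing_rate, seed = seed + 1),
       pure_b = sample_population(freqs, "B", n, missing_rate, seed = seed + 2))
}

# drop locus metadata so call matrices can be compared cell-for-cell
strip_loci <- function(geno) {
  attr(geno, "loci") <- NULL
  as.data.frame(geno)
}

# small hand-built genotype table: 2 individuals x 2 loci, one missing call
tiny_geno <- function() {
  loci <- tibble::tibble(locus_id = c("L1", "L2"),
                         scaffold_id = c("S1", "S2"),
                         scaffold_length = c(1000L, 900L),
                         position = c(10L, 20L),
                         allele_a = c("A", "C"),
                         allele_b = c("G", "T"))
  new_genotypes(data.frame(L1 = c("AA", "GG"), L2 = c("CT", NA)),
                individual_id = c("ind1", "ind2"),
                label = c("POPX", "POPY"),
                loci = loci)
}

# planted diagnostic sites among same-frequency neutral background, pooled
make_sites <- function(n_diag = 10, n_neutral = 200, depth = 100, seed = 500) {
  diag <- frequency_profile(n_diag, "diagnostic", seed = seed)
  freqs <- diag
  if (n_neutral > 0) {
    neutral <- frequency_profile(n_neutral, "diagnostic", seed = seed + 1)
    withr::with_seed(seed + 2, {
      f <- runif(n_neutral, 0.2, 0.8)
      neutral$freq_A <- f
      neutral$freq_B <- f
    })
    neutral$locus_id <- paste0("N", neutral$locus_id)
    neutral$scaffold_id <- diag$scaffold_id[(seq_len(n_neutral) - 1) %% n_diag + 1]
    neutral$scaffold_length <- diag$scaffold_length[(seq_len(n_neutral) - 1) %% n_diag + 1]
    neutral$position <- as.integer(2e6 + seq_len(n_neutral))
    freqs <- dplyr::bind_rows(diag, neutral)
  }
  sites <- simulate_pooled_counts(freqs, mean_depth = depth, seed = seed + 3)
  list(freqs = freqs, diag = diag, sites = sites,
       scaffolds = tibble::tibble(scaffold_id = diag$scaffold_id,
                                  length = diag$scaffold_length))
}

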