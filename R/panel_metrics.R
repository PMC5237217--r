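#' Agresti-Coull confidence interval for a binomial proportion
#'
#' Adjusted estimate `p~ = (x + z^2/2) / (n + z^2)` with interval
#' `p~ +/- z * sqrt(p~ (1 - p~) / (n + z^2))`, clamped to `[0, 1]`. Used
#' throughout for minor-allele-frequency bounds on allele copies, where the
#' interesting case is x = 0: even when no minor allele is observed, the
#' upper bound stays well above zero at realistic sample sizes.
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level in (0, 1).
#' @return A tibble with columns `estimate` (the adjusted `p~`), `lower`,
#'   `upper`.
#' @export
agresti_coull_ci <- function(x, n, conf = 0.95) {
  if (any(conf <= 0) || any(conf >= 1)) abort("conf must be in (0, 1)")
  stopifnot(all(n >= 1), all(x >= 0), all(x <= n))
  z <- qnorm(1 - (1 - conf) / 2)
  nt <- n + z^2
  p <- (x + z^2 / 2) / nt
  half <- z * sqrt(p * (1 - p) / nt)
  tibble(estimate = p,
         lower = pmax(0, p - half),
         upper = pmin(1, p + half))
}

#' Per-locus diagnosticity of a two-population panel
#'
#' For each locus, each population's diagnostic allele is its majority
#' allele (a 50/50 tie breaks towards the alphabetically first allele,
#' deterministically). The population's minor allele frequency is the
#' observed frequency of the *other* population's diagnostic allele, with
#' an Agresti-Coull interval on allele copies (2 x called individuals). A
#' locus is *fully diagnostic* in the observed-data sense: no copy of the
#' other population's diagnostic allele was seen in either population.
#' That is a statement about the sample, not the population — the CI upper
#' bounds say how large an unseen MAF could still be.
#'
#' @param geno A genotype tibble containing both populations.
#' @param pop_a,pop_b The two population labels.
#' @param conf Confidence level for the MAF intervals.
#' @return A tibble with one row per locus: diagnostic alleles, per-pop
#'   MAF and CI, called counts, `fully_diagnostic`, and `oriented`
#'   (whether the two populations favour different alleles, i.e. the locus
#'   can be scored at all). Loci with a population entirely missing are
#'   flagged (`n_called_* == 0`, `fully_diagnostic` NA), never dropped.
#' @export
diagnose_panel <- function(geno, pop_a, pop_b, conf = 0.95) {
  for (p in c(pop_a, pop_b)) {
    if (!p %in% geno$label) abort(paste0("label not present: ", p))
  }
  ids <- locus_ids(geno)
  ma <- geno_matrix(geno[geno$label == pop_a, ])
  mb <- geno_matrix(geno[geno$label == pop_b, ])
  one <- function(calls) {   # allele letters carried by one pop at one locus
    obs <- calls[!is.na(calls)]
    list(n_called = length(obs), letters = unlist(strsplit(obs, "")))
  }
  majority <- function(letters) {  # ties break towards the alphabetically first
    tab <- sort(table(letters), decreasing = TRUE)
    cand <- names(tab)[tab == tab[1]]
    sort(cand)[1]
  }
  rows <- lapply(seq_along(ids), function(k) {
    ca <- one(ma[, k]); cb <- one(mb[, k])
    da <- if (ca$n_called > 0) majority(ca$letters) else NA_character_
    db <- if (cb$n_called > 0) majority(cb$letters) else NA_character_
    minor_a <- if (ca$n_called > 0 && !is.na(db)) sum(ca$letters == db) else NA_integer_
    minor_b <- if (cb$n_called > 0 && !is.na(da)) sum(cb$letters == da) else NA_integer_
    ci <- function(x, n) {
      if (is.na(x) || n == 0) return(tibble(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
      agresti_coull_ci(x, 2 * n, conf)
    }
    cia <- ci(minor_a, ca$n_called); cib <- ci(minor_b, cb$n_called)
    tibble(locus_id = ids[k],
           diag_allele_a = da, diag_allele_b = db,
           n_called_a = ca$n_called, n_called_b = cb$n_called,
           minor_count_a = minor_a, minor_count_b = minor_b,
           maf_a = if (ca$n_called > 0) minor_a / (2 * ca$n_called) else NA_real_,
           maf_b = if (cb$n_called > 0) minor_b / (2 * cb$n_called) else NA_real_,
           maf_lower_a = cia$lower, maf_upper_a = cia$upper,
           maf_lower_b = cib$lower, maf_upper_b = cib$upper,
           oriented = !is.na(da) && !is.na(db) && da != db,
           fully_diagnostic = if (ca$n_called == 0 || cb$n_called == 0) NA
                              else !is.na(da) && !is.na(db) && da != db &&
                                   minor_a == 0 && minor_b == 0)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pop_a") <- pop_a
  attr(out, "pop_b") <- pop_b
  attr(out, "conf") <- conf
  out
}

#' Score individuals against an oriented panel
#'
#' Counts, per individual, the markers that are heterozygous, homozygous
#' for the local population's diagnostic allele, and homozygous for the
#' foreign population's diagnostic allele. Missing calls are excluded from
#' `n_obs`; loci without a diagnostic orientation (both populations favour
#' the same allele, or a population was entirely missing) are excluded
#' with a warning. The counting identity
#' `k_het + k_hom_local + k_hom_foreign == n_obs` always holds.
#'
#' @param geno Genotype tibble of the individuals to score.
#' @param diagnosis Panel diagnosis from [diagnose_panel()].
#' @param local_pop Which population counts as local: one of the two labels
#'   the diagnosis was computed from (default its `pop_a`).
#' @return A tibble: `individual_id`, `label`, `n_obs`, `k_het`,
#'   `k_hom_local`, `k_hom_foreign`.
#' @export
score_individuals <- function(geno, diagnosis, local_pop = attr(diagnosis, "pop_a")) {
  pops <- c(attr(diagnosis, "pop_a"), attr(diagnosis, "pop_b"))
  if (!local_pop %in% pops) abort("local_pop must be one of the diagnosis populations")
  ids <- locus_ids(geno)
  if (!all(ids %in% diagnosis$locus_id)) {
    abort(paste0("diagnosis does not cover loci: ",
                 paste(setdiff(ids, diagnosis$locus_id), collapse = ", ")))
  }
  d <- diagnosis[match(ids, diagnosis$locus_id), ]
  usable <- !is.na(d$oriented) & d$oriented
  if (any(!usable)) {
    warn(paste0("excluding ", sum(!usable), " locus/loci without diagnostic orientation: ",
                paste(head(d$locus_id[!usable], 5), collapse = ", ")))
  }
  local_allele <- if (local_pop == pops[1]) d$diag_allele_a else d$diag_allele_b
  foreign_allele <- if (local_pop == pops[1]) d$diag_allele_b else d$diag_allele_a
  m <- geno_matrix(geno)[, usable, drop = FALSE]
  la <- local_allele[usable]; fa <- foreign_allele[usable]
  het <- is_het_call(m)
  hom_local <- m == matrix(paste0(la, la), nrow(m), ncol(m), byrow = TRUE)
  hom_foreign <- m == matrix(paste0(fa, fa), nrow(m), ncol(m), byrow = TRUE)
  obs <- !is.na(m)
  tibble(individual_id = geno$individual_id,
         label = geno$label,
         n_obs = rowSums(obs),
         k_het = rowSums(het & obs, na.rm = TRUE),
         k_hom_local = rowSums(hom_local & obs, na.rm = TRUE),
         k_hom_foreign = rowSums(hom_foreign & obs, na.rm = TRUE))
}
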