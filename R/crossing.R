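#' Draw gametes from genotype rows
#'
#' Mendelian segregation at unlinked loci: a homozygote transmits its
#' allele, a heterozygote transmits either allele with probability 1/2
#' independently across loci. A missing parental call yields a missing
#' transmitted allele (no imputation). Uses the current RNG state; seed at
#' the calling operation.
#'
#' @param calls Character vector (or individuals x loci matrix) of
#'   two-letter genotype calls.
#' @return Single-letter allele vector (or matrix) of the same shape.
#' @export
sample_gamete <- function(calls) {
  m <- is.matrix(calls)
  x <- if (m) calls else matrix(calls, nrow = 1)
  a1 <- substr(x, 1, 1)
  a2 <- substr(x, 2, 2)
  pick <- matrix(runif(length(x)) < 0.5, nrow(x))
  g <- ifelse(pick, a1, a2)
  g[is.na(x)] <- NA_character_
  if (m) g else as.vector(g)
}

#' Cross two parental pools
#'
#' Each offspring draws one parent uniformly at random (with replacement)
#' from each pool and receives one gamete from each. Offspring alleles all
#' exist in some parent: there is no mutation.
#'
#' @param parents_a,parents_b Genotype tibbles sharing the same locus panel.
#' @param n_offspring Number of offspring.
#' @param seed Integer seed.
#' @param label Label given to the offspring.
#' @param id_prefix Prefix for offspring ids.
#' @return A genotype tibble of offspring.
#' @export
cross <- function(parents_a, parents_b, n_offspring, seed = NULL,
                  label = "OFFSPRING", id_prefix = paste0(label, "_")) {
  if (nrow(parents_a) == 0 || nrow(parents_b) == 0) {
    abort("empty parent pool")
  }
  if (!identical(locus_ids(parents_a), locus_ids(parents_b))) {
    abort("parent pools must share the same locus panel")
  }
  stopifnot(n_offspring >= 1)
  seed_guard(seed)
  ma <- geno_matrix(parents_a)
  mb <- geno_matrix(parents_b)
  ia <- sample.int(nrow(ma), n_offspring, replace = TRUE)
  ib <- sample.int(nrow(mb), n_offspring, replace = TRUE)
  g1 <- sample_gamete(ma[ia, , drop = FALSE])
  g2 <- sample_gamete(mb[ib, , drop = FALSE])
  calls <- matrix(make_call(g1, g2), n_offspring,
                  dimnames = list(NULL, locus_ids(parents_a)))
  new_genotypes(calls, sprintf("%s%04d", id_prefix, seq_len(n_offspring)),
                rep(label, n_offspring), loci = attr(parents_a, "loci"))
}

#' Simulate a pedigree category by iterated backcrossing
#'
#' Reproduces the reciprocal backcross chain: `F1 = pure A x pure B`;
#' `FgA = F(g-1)A x pure A` (a backcross of the hybrid lineage into
#' population A), and symmetrically `FgB`. Intermediate generations are
#' regenerated internally; only the requested category is returned. The
#' expected foreign-lineage fraction of generation g is `2^(1-g)`.
#'
#' @param pure_a,pure_b Pure parental genotype tibbles (same panel).
#' @param category `"F1"`, `"FgA"` or `"FgB"` with g >= 2 (e.g. `"F3A"`).
#' @param n Offspring per generation (the returned category has `n` rows).
#' @param seed Integer seed.
#' @return A genotype tibble labelled with `category`.
#' @export
simulate_category <- function(pure_a, pure_b, category, n, seed = NULL) {
  g <- category_generation(category)
  if (is.na(g) || g < 1) abort(paste0("not a simulable category: ", category))
  if (g > 1 && !grepl("[AB]$", category)) {
    abort("backcross categories need a direction suffix, e.g. F2A")
  }
  seed_guard(seed)
  cur <- cross(pure_a, pure_b, n, label = "F1")
  if (g == 1) return(cur)
  into_a <- endsWith(category, "A")
  pure <- if (into_a) pure_a else pure_b
  for (gen in 2:g) {
    lab <- paste0("F", gen, if (into_a) "A" else "B")
    cur <- cross(cur, pure, n, label = lab)
  }
  cur
}

#' Build a labelled hybrid/backcross baseline
#'
#' Assembles the full simulated baseline: the two pure pools (relabelled
#' `PUREA`/`PUREB`), F1 hybrids, and reciprocal backcrosses `F2A..FmaxA`
#' and `F2B..FmaxB`. With `max_generation = 5` that is the 11-category
#' baseline layout used for assignment.
#'
#' @inheritParams simulate_category
#' @param n_per_category Simulated individuals per hybrid/backcross
#'   category; the pure pools keep their own sizes.
#' @param max_generation Deepest backcross generation (>= 2).
#' @param seed Integer seed.
#' @return A genotype tibble with one label per category.
#' @export
build_baseline <- function(pure_a, pure_b, n_per_category = 100,
                           max_generation = 5, seed = NULL) {
  if (max_generation < 2) abort("max_generation must be >= 2")
  seed_guard(seed)
  pa <- dplyr::mutate(pure_a, label = "PUREA")
  pb <- dplyr::mutate(pure_b, label = "PUREB")
  parts <- list(pa, pb)
  # one chain per direction so each category is the previous one's offspring,
  # so each category is the previous generation's offspring pool
  for (dir in c("A", "B")) {
    cur <- cross(pure_a, pure_b, n_per_category, label = "F1",
                 id_prefix = paste0("F1", dir, "_"))
    if (dir == "A") parts <- c(parts, list(cur))
    pure <- if (dir == "A") pure_a else pure_b
    for (gen in 2:max_generation) {
      cur <- cross(cur, pure, n_per_category, label = paste0("F", gen, dir))
      parts <- c(parts, list(cur))
    }
  }
  out <- dplyr::bind_rows(parts)
  out$individual_id <- make.unique(out$individual_id)
  attr(out, "loci") <- attr(pure_a, "loci")
  out
}

#' Expected marker-class fractions in the offspring of two hybrids
#'
#' For a fully diagnostic panel, the genotype class of each marker in the
#' offspring of two independent hybrid-lineage parents follows a trinomial
#' over (homozygous local, heterozygous, homozygous foreign). The fractions
#' are computed by enumerating the two parents' marker states (heterozygous
#' with probability `2^(1-g)`, homozygous local otherwise; a pure backcross
#' parent carries no foreign homozygote) and Mendelian transmission.
#'
#' @param cross_name `"F1xF1"`, `"F2xF2"`, or generally `"FgxFh"`.
#' @return A tibble with columns `class`
#'   (`hom_local`, `het`, `hom_foreign`) and `fraction`.
#' @export
cross_expected_fractions <- function(cross_name) {
  if (!grepl("^F\\d+xF\\d+$", cross_name)) {
    abort(paste0("unrecognised cross: ", cross_name))
  }
  gs <- as.integer(sub("^F(\\d+)xF(\\d+)$", "\\1", cross_name))
  gh <- as.integer(sub("^F(\\d+)xF(\\d+)$", "\\2", cross_name))
  p_het <- 2^(1 - c(gs, gh))     # per-marker heterozygosity of each parent
  acc <- c(hom_local = 0, het = 0, hom_foreign = 0)
  for (s1 in c("het", "hom_local")) {
    for (s2 in c("het", "hom_local")) {
      w <- (if (s1 == "het") p_het[1] else 1 - p_het[1]) *
           (if (s2 == "het") p_het[2] else 1 - p_het[2])
      t1 <- if (s1 == "het") 0.5 else 0   # P(transmit foreign allele)
      t2 <- if (s2 == "het") 0.5 else 0
      acc["hom_foreign"] <- acc["hom_foreign"] + w * t1 * t2
      acc["het"] <- acc["het"] + w * (t1 * (1 - t2) + (1 - t1) * t2)
      acc["hom_local"] <- acc["hom_local"] + w * (1 - t1) * (1 - t2)
    }
  }
  tibble(class = names(acc), fraction = unname(acc))
}
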