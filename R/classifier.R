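#' Per-marker heterozygosity probability of a backcross generation
#'
#' Under unlinked diagnostic markers, a generation-g individual of a pure
#' backcross chain carries the foreign lineage at an expected fraction
#' `f_g = 2^(1-g)` of its genome, and the number of heterozygous markers is
#' binomial with per-marker probability:
#'
#' * `diagnostic`: `p_g = 2^(1-g)` — markers strictly fixed in both
#'   populations;
#' * `introgressing_maf`: `p_g = 2^(1-g) (1 - m)` — the native population
#'   is fixed but the foreign one carries the native-type allele at MAF
#'   `m`, so a foreign-lineage marker is heterozygous only when the
#'   foreign copy really is the foreign allele;
#' * `symmetric_maf`: `p_g = f_g (1 - h) + (1 - f_g) h` with
#'   `h = 2 m (1 - m)` — both populations carry minor alleles, so even
#'   native-lineage markers are heterozygous at rate `h`.
#'
#' A native (non-hybrid) individual has `p = 0` in the first two scenarios
#' and `p = h` under `symmetric_maf`.
#'
#' @param g Generation index (>= 1); vectorised.
#' @param scenario Fixedness scenario, as in [frequency_profile()].
#' @param m Minor allele frequency.
#' @return Heterozygosity probability per marker.
#' @export
het_probability <- function(g, scenario = c("diagnostic", "introgressing_maf", "symmetric_maf"),
                            m = 0) {
  scenario <- match.arg(scenario)
  stopifnot(all(g >= 1))
  f <- 2^(1 - g)
  switch(scenario,
         diagnostic = f,
         introgressing_maf = f * (1 - m),
         symmetric_maf = {
           h <- 2 * m * (1 - m)
           f * (1 - h) + (1 - f) * h
         })
}

native_het_probability <- function(scenario, m) {
  if (scenario == "symmetric_maf") 2 * m * (1 - m) else 0
}

#' Maximum-likelihood classification intervals for hybrid generations
#'
#' Partitions the heterozygous-marker counts `0..n` among the categories
#' Native, F1, F2, ..., Fmax by pairwise binomial likelihood: the boundary
#' between adjacent generations g and g+1 is the smallest count k at which
#' `Binom(k; n, p_g) >= Binom(k; n, p_(g+1))` (a likelihood tie is awarded
#' to the more recent, lower-g generation, which favours flagging
#' introgression for follow-up). Native competes the same way below the
#' deepest generation.
#'
#' The F1/F2 boundary needs a convention: with fully diagnostic markers
#' `p_1 = 1`, so the F1 likelihood is zero for any k < n and pure maximum
#' likelihood degenerates. The F1 interval is taken to start at
#' `ceiling(n / sqrt(2))` — the geometric mean of the adjacent expected
#' counts n and n/2 — in every scenario. This is a convention, not a
#' derivation.
#'
#' `prob_correct` for a category is the probability that a true member's
#' heterozygote count falls inside its own interval. Categories that are
#' never the most likely have an empty interval (`k_lo`/`k_hi` NA).
#'
#' @param n Number of diagnostic markers (>= 1).
#' @inheritParams het_probability
#' @param max_generation Deepest generation modelled (default 8).
#' @return A `classification_table`: a tibble with columns `category`,
#'   `p_het`, `k_lo`, `k_hi`, `prob_correct`, and attributes `n`,
#'   `scenario`, `m`.
#' @export
classification_table <- function(n, scenario = c("diagnostic", "introgressing_maf", "symmetric_maf"),
                                 m = 0, max_generation = 8) {
  scenario <- match.arg(scenario)
  stopifnot(n >= 1, max_generation >= 1)
  p <- het_probability(seq_len(max_generation), scenario, m)
  p_native <- native_het_probability(scenario, m)
  probs <- c(p, p_native)                       # F1..Fmax, Native
  cats <- c(paste0("F", seq_len(max_generation)), "Native")
  k <- 0:n
  lo <- integer(length(probs))
  lo[1] <- min(ceiling(n / sqrt(2)), n)          # F1 boundary convention
  if (length(probs) >= 2) {
    for (i in 2:length(probs)) {
      if (i == length(probs)) { lo[i] <- 0L; break }
      cross_at <- which(dbinom(k, n, probs[i]) >= dbinom(k, n, probs[i + 1]))
      lo[i] <- if (length(cross_at) == 0) n + 1L else k[cross_at[1]]
    }
  }
  hi <- c(n, lo[-length(lo)] - 1L)
  empty <- lo > hi
  pc <- ifelse(empty, NA_real_,
               pbinom(hi, n, probs) - pbinom(lo - 1L, n, probs))
  out <- tibble(category = cats,
                p_het = probs,
                k_lo = ifelse(empty, NA_integer_, lo),
                k_hi = ifelse(empty, NA_integer_, hi),
                prob_correct = pc)
  structure(out, n = n, scenario = scenario, m = m,
            max_generation = max_generation,
            class = c("classification_table", class(out)))
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("Heterozygote-count classification table (n = %d markers, %s%s)\n",
              attr(x, "n"), attr(x, "scenario"),
              if (attr(x, "m") > 0) sprintf(", MAF = %g", attr(x, "m")) else ""))
  df <- as.data.frame(x)
  df$interval <- ifelse(is.na(df$k_lo), "never most likely",
                        paste0(df$k_lo, "-", df$k_hi))
  print(df[, c("category", "p_het", "interval", "prob_correct")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @method tidy classification_table
#' @export
tidy.classification_table <- function(x, ...) {
  out <- as_tibble(x)
  out$n_markers <- attr(x, "n")
  out$scenario <- attr(x, "scenario")
  out$m <- attr(x, "m")
  out
}

#' @method glance classification_table
#' @export
glance.classification_table <- function(x, ...) {
  tibble(n_markers = attr(x, "n"),
         scenario = attr(x, "scenario"),
         m = attr(x, "m"),
         max_generation = attr(x, "max_generation"),
         n_categories = nrow(x),
         n_never_likely = sum(is.na(x$k_lo)))
}

#' Classify individuals' hybrid generation from heterozygote counts
#'
#' Assigns each scored individual to the interval owner of its
#' heterozygous-marker count under [classification_table()] recomputed at
#' that individual's own `n_obs` (missing markers shrink n rather than
#' rescaling k). Per-category binomial log-likelihoods are returned in a
#' nested list-column.
#'
#' @param scores A tibble from [score_individuals()] (needs `n_obs`,
#'   `k_het`).
#' @inheritParams classification_table
#' @return The input with columns `category` (the ML class) and `loglik`
#'   (list of per-category log-likelihood tibbles) appended.
#' @export
classify_generation <- function(scores, scenario = c("diagnostic", "introgressing_maf", "symmetric_maf"),
                                m = 0, max_generation = 8) {
  scenario <- match.arg(scenario)
  stopifnot(all(scores$n_obs >= 1))
  if (any(scores$k_het > scores$n_obs)) {
    abort("k_het exceeds n_obs: counting invariant violated")
  }
  tabs <- list()
  res <- purrr::pmap(list(scores$n_obs, scores$k_het), function(n, k) {
    key <- as.character(n)
    if (is.null(tabs[[key]])) {
      tabs[[key]] <<- classification_table(n, scenario, m, max_generation)
    }
    tab <- tabs[[key]]
    own <- which(!is.na(tab$k_lo) & tab$k_lo <= k & k <= tab$k_hi)
    ll <- ifelse(tab$p_het == 0 & k > 0, -Inf, dbinom(k, n, tab$p_het, log = TRUE))
    list(category = tab$category[own][1],
         loglik = tibble(category = tab$category, loglik = ll))
  })
  scores$category <- vapply(res, `[[`, "", "category")
  scores$loglik <- lapply(res, `[[`, "loglik")
  scores
}

#' Flag mixed (hybrid x hybrid) ancestry from marker-class counts
#'
#' Under a pure backcross chain on fully diagnostic markers, an individual
#' can never be homozygous for the foreign population's allele: each
#' generation has one pure local parent contributing a local allele
#' everywhere. Homozygote markers specific to *both* ancestor populations
#' therefore reveal hybrid x hybrid parentage. `p_backcross_tail` is the
#' probability that a pure backcross would show at least the observed
#' number of foreign homozygotes — 0 for any positive count on a fully
#' diagnostic panel.
#'
#' Expected marker-class fractions for named crosses come from
#' [cross_expected_fractions()]; detection power from
#' [dual_detection_probability()].
#'
#' @param scores A tibble from [score_individuals()].
#' @return The input with `dual_flag` and `p_backcross_tail` appended.
#' @export
dual_ancestry_test <- function(scores) {
  scores$dual_flag <- scores$k_hom_local > 0 & scores$k_hom_foreign > 0 &
    scores$k_het > 0
  scores$p_backcross_tail <- ifelse(scores$k_hom_foreign > 0, 0, 1)
  scores
}

#' Probability of detecting mixed ancestry in a hybrid x hybrid offspring
#'
#' Exact trinomial probability that, over `n` fully diagnostic markers, the
#' offspring of the named cross shows at least `t` homozygote markers for
#' *each* ancestral population, computed by brute-force summation over the
#' (k_local, k_foreign) grid.
#'
#' @param n Number of markers.
#' @param t Detection threshold (markers per ancestral side).
#' @param cross_name `"F1xF1"` or `"F2xF2"` (any `"FgxFh"` accepted).
#' @return A probability.
#' @export
dual_detection_probability <- function(n, t, cross_name = "F1xF1") {
  stopifnot(n >= 1)
  if (t > n) return(0)
  if (t <= 0) return(1)
  fr <- cross_expected_fractions(cross_name)
  p <- setNames(fr$fraction, fr$class)
  total <- 0
  for (ka in t:n) {
    kb <- t:(n - ka)
    kb <- kb[kb >= t & kb <= n - ka]
    if (length(kb) == 0) next
    total <- total + sum(exp(
      lgamma(n + 1) - lgamma(ka + 1) - lgamma(kb + 1) - lgamma(n - ka - kb + 1) +
        ka * log(p[["hom_local"]]) + kb * log(p[["hom_foreign"]]) +
        (n - ka - kb) * log(p[["het"]])))
  }
  unname(total)
}
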