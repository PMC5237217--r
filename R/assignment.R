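# Internal: per-category allele counts over the baseline.
# Returns list(cats, alleles (L x 2 letters), counts_b (C x L), n_called (C x L)).
baseline_counts <- function(baseline) {
  ids <- locus_ids(baseline)
  loci <- loci_info(baseline)
  cats <- unique(baseline$label)
  m <- geno_matrix(baseline)
  nb <- matrix(NA_integer_, nrow(m), length(ids))
  for (k in seq_along(ids)) {
    nb[, k] <- allele_copies(m[, k], loci$allele_b[k])
  }
  counts_b <- matrix(0, length(cats), length(ids), dimnames = list(cats, ids))
  n_called <- counts_b
  for (i in seq_along(cats)) {
    sel <- baseline$label == cats[i]
    counts_b[i, ] <- colSums(nb[sel, , drop = FALSE], na.rm = TRUE)
    n_called[i, ] <- colSums(!is.na(nb[sel, , drop = FALSE]))
  }
  list(cats = cats, loci = loci, counts_b = counts_b, n_called = n_called)
}

# Per-locus log-probability of genotype code g (copies of allele b: 0/1/2)
# for one category, from adjusted allele counts.
cat_loglik <- function(g, counts_b, n_called, method) {
  ok <- !is.na(g)
  if (method == "empirical") {
    usable <- ok & n_called > 0
    n2 <- 2 * n_called[usable]
    p <- counts_b[usable] / n2
    floor_p <- 1 / (n2 + 1)                 # zero-frequency floor, per 2N+1
    p <- pmin(pmax(p, floor_p), 1 - floor_p)
    gg <- g[usable]
    sum(log(ifelse(gg == 2, p^2, ifelse(gg == 1, 2 * p * (1 - p), (1 - p)^2))))
  } else {                                   # rannala_mountain, prior 1/K = 1/2
    usable <- ok
    nb <- counts_b[usable]; nt <- 2 * n_called[usable]
    na_ <- nt - nb
    gg <- g[usable]
    pr <- ifelse(gg == 2, (nb + 0.5) * (nb + 1.5),
          ifelse(gg == 0, (na_ + 0.5) * (na_ + 1.5),
                 2 * (na_ + 0.5) * (nb + 0.5))) / ((nt + 1) * (nt + 2))
    sum(log(pr))
  }
}

#' Likelihood-based assignment to baseline categories
#'
#' Assigns each test individual to the baseline category (pure species,
#' hybrid or backcross class) with the highest genotype likelihood.
#'
#' Two likelihood models are available:
#'
#' * `"empirical"` — conditional maximum likelihood: the probability of the
#'   individual's genotype at each non-missing locus is its Hardy-Weinberg
#'   probability under the category's empirical allele frequencies, with
#'   zero frequencies floored at `1/(2N+1)` (N = called individuals in the
#'   category at the locus, a standard assignment-software convention).
#'   Loci where a category has no called alleles are skipped for that
#'   category with a warning.
#' * `"rannala_mountain"` — the Bayesian method of Rannala & Mountain: the
#'   individual's two allele copies are drawn sequentially from the
#'   Dirichlet-compound posterior with prior 1/K per allele (K = 2) added
#'   to the category's observed counts; an empty category falls back to
#'   the prior alone.
#'
#' With `leave_one_out = TRUE`, a test individual that is itself a member
#' of the baseline has its own allele copies removed from its category's
#' counts before its likelihood is computed (self-assignment without this
#' correction is optimistically biased).
#'
#' Scores are reported GeneClass-style: the best category's likelihood as
#' a percentage of the summed likelihoods over all candidate categories.
#'
#' @param test Genotype tibble of individuals to assign (loci must be a
#'   subset of the baseline's).
#' @param baseline Labelled genotype tibble (e.g. from [build_baseline()]).
#' @param method `"empirical"` or `"rannala_mountain"`.
#' @param leave_one_out Remove a baseline member's own alleles from its
#'   category before scoring it.
#' @return A tibble: `individual_id`, `label` (the true/test label),
#'   `best_category`, `score_percent`, and `loglik` (list-column of
#'   per-category log-likelihood tibbles).
#' @export
assign_individuals <- function(test, baseline,
                               method = c("empirical", "rannala_mountain"),
                               leave_one_out = FALSE) {
  method <- match.arg(method)
  ids <- locus_ids(test)
  if (!all(ids %in% locus_ids(baseline))) {
    abort("test loci must be a subset of baseline loci")
  }
  bc <- baseline_counts(baseline)
  kloc <- match(ids, colnames(bc$counts_b))
  counts_b <- bc$counts_b[, kloc, drop = FALSE]
  n_called <- bc$n_called[, kloc, drop = FALSE]
  loci <- bc$loci[kloc, ]
  if (method == "empirical" && any(n_called == 0)) {
    warn(paste0("categories with zero called alleles at ",
                sum(n_called == 0), " category-locus pairs: loci skipped there"))
  }
  m <- geno_matrix(test)
  gmat <- matrix(NA_integer_, nrow(m), length(ids))
  for (k in seq_along(ids)) gmat[, k] <- allele_copies(m[, k], loci$allele_b[k])

  base_key <- paste(baseline$individual_id, baseline$label)
  rows <- vector("list", nrow(test))
  for (i in seq_len(nrow(test))) {
    g <- gmat[i, ]
    if (all(is.na(g))) {
      abort(paste0("individual ", test$individual_id[i],
                   " has no called genotypes; no assignment possible"))
    }
    ll <- vapply(seq_along(bc$cats), function(ci) {
      cb <- counts_b[ci, ]; nc <- n_called[ci, ]
      if (leave_one_out &&
          paste(test$individual_id[i], bc$cats[ci]) %in% base_key) {
        own_called <- !is.na(g)
        cb <- cb - ifelse(own_called, g, 0L)
        nc <- nc - as.integer(own_called)
      }
      cat_loglik(g, cb, nc, method)
    }, numeric(1))
    lik <- exp(ll - max(ll))
    pct <- 100 * lik / sum(lik)
    best <- which.max(ll)
    rows[[i]] <- tibble(individual_id = test$individual_id[i],
                        label = test$label[i],
                        best_category = bc$cats[best],
                        score_percent = pct[best],
                        loglik = list(tibble(category = bc$cats, loglik = ll,
                                             score_percent = pct)))
  }
  dplyr::bind_rows(rows)
}

#' Confusion matrix of assignment against a labelled baseline
#'
#' Assigns every test individual with [assign_individuals()] and
#' tabulates true category (rows) against assigned category (columns),
#' correct assignments on the diagonal.
#'
#' @inheritParams assign_individuals
#' @return A `confusion_matrix`: a tibble with a `true` column and one
#'   count column per assigned category.
#' @export
confusion_matrix <- function(test, baseline,
                             method = c("empirical", "rannala_mountain"),
                             leave_one_out = FALSE) {
  asg <- assign_individuals(test, baseline, method, leave_one_out)
  cats <- intersect(category_chain(20), unique(baseline$label))
  cats <- c(cats, setdiff(unique(baseline$label), cats))
  tab <- table(factor(asg$label, levels = union(cats, unique(asg$label))),
               factor(asg$best_category, levels = cats))
  out <- as_tibble(as.data.frame.matrix(tab), rownames = "true")
  out <- out[rowSums(out[, -1]) > 0 | out$true %in% asg$label, ]
  structure(out, class = c("confusion_matrix", class(out)),
            method = method[1])
}

#' Adjacency-aware assignment accuracy summary
#'
#' Per-category percent correct plus the fraction of misassignments that
#' landed in a category adjacent along the backcross chain
#' (PUREA - F5A - ... - F2A - F1 - F2B - ... - PUREB).
#'
#' @param assignments Output of [assign_individuals()].
#' @param max_generation Depth of the chain used for adjacency.
#' @return A list with `per_category` (tibble: label, n, n_correct,
#'   pct_correct) and `pct_misassigned_adjacent`.
#' @export
assignment_summary <- function(assignments, max_generation = 5) {
  chain <- category_chain(max_generation)
  per_cat <- dplyr::summarise(
    dplyr::group_by(assignments, .data$label),
    n = dplyr::n(),
    n_correct = sum(.data$best_category == .data$label),
    pct_correct = 100 * .data$n_correct / .data$n,
    .groups = "drop")
  mis <- assignments[assignments$best_category != assignments$label, ]
  adj <- if (nrow(mis) == 0) NA_real_ else {
    d <- abs(match(mis$best_category, chain) - match(mis$label, chain))
    100 * mean(d == 1, na.rm = TRUE)
  }
  list(per_category = per_cat, pct_misassigned_adjacent = adj)
}

#' Maximum-likelihood hybrid index
#'
#' A deterministic admixture-proportion estimator: the individual's q (the
#' proportion of its ancestry drawn from population A) maximises the
#' product over called loci of Hardy-Weinberg genotype probabilities under
#' the per-allele mixture frequency `q p_A + (1 - q) p_B`. The 95% CI is
#' the profile-likelihood interval (log-likelihood drop of 1.92). This is
#' a deliberately simple, reproducible alternative to MCMC admixture
#' clustering, not a reimplementation of it.
#'
#' @param geno Genotype tibble.
#' @param freqs Frequency profile ([frequency_profile()]-shaped: per-locus
#'   `freq_A`, `freq_B` allele-b frequencies) covering the panel's loci.
#' @return A tibble: `individual_id`, `label`, `q`, `lower`, `upper`.
#' @export
estimate_hybrid_index <- function(geno, freqs) {
  ids <- locus_ids(geno)
  if (!all(ids %in% freqs$locus_id)) {
    abort("freqs must cover every locus of the genotype table")
  }
  fr <- freqs[match(ids, freqs$locus_id), ]
  m <- geno_matrix(geno)
  gmat <- matrix(NA_integer_, nrow(m), length(ids))
  for (k in seq_along(ids)) gmat[, k] <- allele_copies(m[, k], fr$allele_b[k])
  eps <- 1e-9
  rows <- lapply(seq_len(nrow(geno)), function(i) {
    g <- gmat[i, ]
    ok <- !is.na(g)
    if (!any(ok)) {
      return(tibble(individual_id = geno$individual_id[i], label = geno$label[i],
                    q = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    pa <- fr$freq_A[ok]; pb <- fr$freq_B[ok]; gg <- g[ok]
    ll <- function(q) {
      p <- pmin(pmax(q * pa + (1 - q) * pb, eps), 1 - eps)
      sum(dbinom(gg, 2, p, log = TRUE))
    }
    opt <- optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(0, opt$maximum, 1)
    vals <- vapply(cand, ll, numeric(1))
    qhat <- cand[which.max(vals)]
    llmax <- max(vals)
    cut <- function(q) ll(q) - llmax + qnorm(0.975)^2 / 2
    lower <- if (qhat > 0 && cut(0) < 0) {
      uniroot(cut, c(0, qhat), tol = 1e-7)$root
    } else 0
    upper <- if (qhat < 1 && cut(1) < 0) {
      uniroot(cut, c(qhat, 1), tol = 1e-7)$root
    } else 1
    tibble(individual_id = geno$individual_id[i], label = geno$label[i],
           q = qhat, lower = lower, upper = upper)
  })
  dplyr::bind_rows(rows)
}
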