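#' Coverage filter for pooled-sequencing sites
#'
#' Removes sites whose total depth (summed over pools) is more than
#' `bound` standard deviations from the mean total depth, both computed
#' over the input itself in a first pass. Extreme coverage flags
#' collapsed repeats or dropout, either of which corrupts pooled allele
#' frequencies.
#'
#' @param sites Pooled-count tibble (see [simulate_pooled_counts()]).
#' @param bound Number of standard deviations retained (default 2).
#' @return The filtered tibble.
#' @export
coverage_filter <- function(sites, bound = 2) {
  if (nrow(sites) == 0) {
    warn("empty site table: nothing to filter")
    return(sites)
  }
  tot <- dplyr::summarise(
    dplyr::group_by(sites, .data$scaffold_id, .data$position),
    total_depth = sum(.data$depth), .groups = "drop")
  mu <- mean(tot$total_depth)
  sdv <- sd(tot$total_depth)
  if (is.na(sdv)) sdv <- 0                     # single site
  keep <- tot[abs(tot$total_depth - mu) <= bound * sdv, c("scaffold_id", "position")]
  dplyr::inner_join(sites, keep, by = c("scaffold_id", "position"))
}

#' Surrogate information score for candidate diagnostic sites
#'
#' Scores each site by the lower bound of the 95% (Agresti-Coull, on read
#' counts) confidence interval of the absolute allele-frequency difference
#' between the two pool groups, truncated at 0. The score is a *surrogate*
#' for the expected-SNP-information-value statistic of upstream pooled-seq
#' tooling, whose formula is not restated here; it is monotone in both
#' the frequency difference and the sequencing depth, which is what the
#' selection strategy requires, and it is a plug-in point for any
#' alternative score.
#'
#' @param sites Pooled-count tibble.
#' @param group_a,group_b Pool ids of the two groups.
#' @param conf Confidence level.
#' @param min_pools_covered Minimum pools with positive depth required in
#'   each group; sites below it score 0.
#' @return One row per site: `scaffold_id`, `scaffold_length`, `position`,
#'   per-group read-level allele-b frequencies `freq_group_a`,
#'   `freq_group_b`, and `score`.
#' @export
information_score <- function(sites, group_a, group_b, conf = 0.95,
                              min_pools_covered = 1) {
  grp <- function(ids) {
    s <- sites[sites$pool_id %in% ids, ]
    dplyr::summarise(
      dplyr::group_by(s, .data$scaffold_id, .data$scaffold_length, .data$position),
      depth = sum(.data$depth),
      count_b = sum(.data$count_allele_b),
      pools_covered = sum(.data$depth > 0),
      .groups = "drop")
  }
  a <- grp(group_a); b <- grp(group_b)
  j <- dplyr::inner_join(a, b, by = c("scaffold_id", "scaffold_length", "position"),
                         suffix = c("_a", "_b"))
  z <- qnorm(1 - (1 - conf) / 2)
  ac <- function(x, n) {
    nt <- n + z^2
    p <- (x + z^2 / 2) / nt
    list(p = p, se = sqrt(p * (1 - p) / nt))
  }
  ca <- ac(j$count_b_a, j$depth_a)
  cb <- ac(j$count_b_b, j$depth_b)
  d <- abs(cb$p - ca$p)
  score <- pmax(0, d - z * sqrt(ca$se^2 + cb$se^2))
  score[j$depth_a == 0 | j$depth_b == 0 |
          j$pools_covered_a < min_pools_covered |
          j$pools_covered_b < min_pools_covered] <- 0
  tibble(scaffold_id = j$scaffold_id,
         scaffold_length = j$scaffold_length,
         position = j$position,
         freq_group_a = ifelse(j$depth_a > 0, j$count_b_a / j$depth_a, NA_real_),
         freq_group_b = ifelse(j$depth_b > 0, j$count_b_b / j$depth_b, NA_real_),
         score = score)
}

#' Select candidate diagnostic SNPs from pooled counts
#'
#' The selection strategy: restrict to the `n_scaffolds` longest scaffolds
#' of the catalogue (long scaffolds maximise genomic distance between
#' chosen loci, approximating marker independence; length ties break by
#' scaffold id), apply the coverage filter, score the surviving sites with
#' [information_score()], and keep the `per_scaffold` top-scoring sites of
#' each scaffold. Output is sorted by descending score.
#'
#' @param sites Pooled-count tibble.
#' @param scaffolds Catalogue tibble with `scaffold_id`, `length`.
#' @inheritParams information_score
#' @param n_scaffolds,per_scaffold Selection breadth (defaults 50 and 2).
#' @param coverage_sd_bound Passed to [coverage_filter()]; `NULL` skips
#'   the filter.
#' @return Candidate tibble: `locus_id`, `scaffold_id`, `position`,
#'   `score`, `freq_group_a`, `freq_group_b`.
#' @export
select_candidates <- function(sites, scaffolds, group_a, group_b,
                              n_scaffolds = 50, per_scaffold = 2,
                              coverage_sd_bound = 2, conf = 0.95,
                              min_pools_covered = 1) {
  unknown <- setdiff(unique(sites$scaffold_id), scaffolds$scaffold_id)
  if (length(unknown) > 0) {
    warn(paste0("skipping sites on ", length(unknown),
                " scaffold(s) absent from the catalogue"))
    sites <- sites[!sites$scaffold_id %in% unknown, ]
  }
  if (n_scaffolds > nrow(scaffolds)) {
    warn(sprintf("only %d scaffolds available (%d requested); using all",
                 nrow(scaffolds), n_scaffolds))
  }
  keep_sc <- scaffolds[order(-scaffolds$length, scaffolds$scaffold_id), ]
  keep_sc <- head(keep_sc$scaffold_id, n_scaffolds)
  sites <- sites[sites$scaffold_id %in% keep_sc, ]
  if (!is.null(coverage_sd_bound)) sites <- coverage_filter(sites, coverage_sd_bound)
  scored <- information_score(sites, group_a, group_b, conf, min_pools_covered)
  picked <- dplyr::slice_max(
    dplyr::group_by(scored, .data$scaffold_id),
    order_by = .data$score, n = per_scaffold, with_ties = FALSE)
  picked <- dplyr::ungroup(picked)
  picked <- dplyr::arrange(picked, dplyr::desc(.data$score),
                           .data$scaffold_id, .data$position)
  tibble(locus_id = paste0(picked$scaffold_id, "_", picked$position),
         scaffold_id = picked$scaffold_id,
         position = picked$position,
         score = picked$score,
         freq_group_a = picked$freq_group_a,
         freq_group_b = picked$freq_group_b)
}

#' Resolve same-scaffold conflicts within assay groups
#'
#' When an assay group ends up with several loci from the same scaffold,
#' only the highest-scoring locus per scaffold survives (applied
#' transitively; ties break by locus id, deterministically).
#'
#' @param candidates Candidate tibble from [select_candidates()].
#' @param assay_group Optional vector (or column name) grouping candidates
#'   into multiplex assays; default treats all candidates as one group.
#' @return The pruned candidate tibble, original order preserved.
#' @export
resolve_conflicts <- function(candidates, assay_group = NULL) {
  grp <- if (is.null(assay_group)) rep(1L, nrow(candidates))
         else if (is.character(assay_group) && length(assay_group) == 1 &&
                  assay_group %in% names(candidates)) candidates[[assay_group]]
         else assay_group
  ord <- order(-candidates$score, candidates$locus_id)
  keep <- !duplicated(paste(grp, candidates$scaffold_id)[ord])
  candidates[sort(ord[keep]), ]
}
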