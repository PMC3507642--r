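#' Filter peaks to a high-confidence cistrome
#'
#' Retains peaks whose binding score AND fold enrichment meet joint
#' cutoffs. Cutoffs are either given (`thresholds = list(score_cut,
#' fe_cut)`, defaults 500 and 20) or calibrated (`thresholds = "auto"`)
#' against a set of "negative" peaks obtained by swapping the ChIP and
#' control channels: auto cutoffs are the smallest round values strictly
#' exceeding every negative peak (scores rounded up to the next multiple
#' of 10, fold enrichments to the next integer), so no negative peak would
#' survive the filter.
#'
#' @param positive `CistromeSet` of candidate peaks.
#' @param negative `CistromeSet` of swapped-channel peaks (required for
#'   auto mode).
#' @param thresholds `"auto"` or list with `score_cut` and `fe_cut`.
#' @return the filtered `CistromeSet`, with attribute `thresholds`.
#' @export
filter_high_confidence <- function(positive, negative = NULL,
                                   thresholds = list(score_cut = 500,
                                                     fe_cut = 20)) {
  if (identical(thresholds, "auto")) {
    if (is.null(negative) || nrow(negative) == 0L)
      stopf("auto thresholds need a non-empty negative (swapped) set")
    sc <- floor(max(negative$score) / 10) * 10 + 10
    fc <- floor(max(negative$fold_enrichment)) + 1
    thresholds <- list(score_cut = sc, fe_cut = fc)
  }
  if (thresholds$score_cut < 0 || thresholds$fe_cut < 0)
    stopf("thresholds must be >= 0")
  keep <- positive$score >= thresholds$score_cut &
    positive$fold_enrichment >= thresholds$fe_cut
  out <- cistrome_set(as.data.frame(positive)[keep, , drop = FALSE],
                      label = attr(positive, "label"))
  attr(out, "thresholds") <- thresholds
  out
}

#' Percent impact of a treatment on differential binding
#'
#' The dose metric of the package. "Maximum" and "minimum" cistromes come
#' from the untreated high- and low-agonist conditions. The differential
#' sites are the maximum-cistrome peaks with no (>= 1 bp) overlap in the
#' minimum cistrome; the percent impact of a treated cistrome is the
#' percentage of those differential sites that have no overlap in it.
#' Treated = maximum gives 0; treated = minimum gives 100.
#'
#' @param max_set,min_set,treated `CistromeSet`s (high-confidence).
#' @return list with `differential_sites`, `lost_in_treated`,
#'   `percent_impact` (in `[0, 100]`) and `differential_ids`.
#' @export
percent_impact <- function(max_set, min_set, treated) {
  if (nrow(min_set)) {
    ov <- overlap_sets(min_set, max_set)
    if (ov$n_unique_a > 0)
      warnf("%d of %d minimum-cistrome sites have no overlap in the maximum cistrome",
            ov$n_unique_a, nrow(min_set))
  }
  in_min <- if (nrow(min_set))
    max_set$id %in% overlap_sets(max_set, min_set)$pairs$a_id
  else rep(FALSE, nrow(max_set))
  diff_ids <- max_set$id[!in_min]
  if (!length(diff_ids))
    stopf("no differentially occupied sites between maximum and minimum cistromes; percent impact undefined")
  diffs <- cistrome_set(as.data.frame(max_set)[!in_min, , drop = FALSE],
                        label = "differential")
  in_tr <- if (nrow(treated))
    diffs$id %in% overlap_sets(diffs, treated)$pairs$a_id
  else rep(FALSE, nrow(diffs))
  lost <- sum(!in_tr)
  list(differential_sites = length(diff_ids),
       lost_in_treated = lost,
       percent_impact = 100 * lost / length(diff_ids),
       differential_ids = diff_ids)
}

#' Compare binding-score distributions of two peak groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, e.g. for sites shared
#' with a second condition versus sites unique to the first.
#'
#' @param scores_a,scores_b numeric score vectors (both non-empty).
#' @return list with `U` statistic (number of (a, b) pairs with a > b,
#'   counting ties as 1/2), two-sided `p`, and the two group medians.
#' @export
compare_strength_groups <- function(scores_a, scores_b) {
  if (!length(scores_a) || !length(scores_b))
    stopf("both groups must be non-empty")
  if (length(unique(c(scores_a, scores_b))) == 1L) {
    return(list(U = length(scores_a) * length(scores_b) / 2, p = 1,
                median_a = median(scores_a), median_b = median(scores_b)))
  }
  wt <- suppressWarnings(wilcox.test(scores_a, scores_b,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       median_a = median(scores_a), median_b = median(scores_b))
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail probability of observing at least `shared` common elements
#' between two sets of sizes `set_a` and `set_b` drawn from a universe of
#' `universe` elements.
#'
#' @param universe,set_a,set_b,shared non-negative counts.
#' @return `P(X >= shared)` under `Hypergeometric(universe, set_a, set_b)`.
#' @export
overlap_enrichment <- function(universe, set_a, set_b, shared) {
  for (v in list(universe, set_a, set_b, shared))
    if (!is_count(v)) stopf("all arguments must be non-negative integers")
  if (set_a > universe || set_b > universe)
    stopf("set sizes cannot exceed the universe")
  if (shared > min(set_a, set_b))
    stopf("shared (%d) exceeds the smaller set (%d)",
          shared, min(set_a, set_b))
  if (shared < max(0, set_a + set_b - universe))
    stopf("shared (%d) below the forced minimum overlap", shared)
  phyper(shared - 1, set_a, universe - set_a, set_b, lower.tail = FALSE)
}

#' Sort peaks by binding strength
#'
#' Descending binding score; ties broken by descending fold enrichment;
#' remaining ties by chromosome and start coordinate (documented stable
#' total order).
#'
#' @param cistrome a `CistromeSet`.
#' @return the reordered `CistromeSet`.
#' @export
sort_by_strength <- function(cistrome) {
  o <- order(-cistrome$score, -cistrome$fold_enrichment,
             cistrome$chrom, cistrome$start)
  out <- cistrome_set(as.data.frame(cistrome)[o, , drop = FALSE],
                      label = attr(cistrome, "label"))
  rownames(out) <- NULL
  out
}
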