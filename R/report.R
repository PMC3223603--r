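# ---- score distribution reporting ----------------------------------------

#' Histogram of similarity scores in fixed-width bins
#'
#' Bin index is round-half-to-even of `score / bin_width` (the C `rint`
#' convention), so 0.615 and 0.625 both land in the 0.62 bin at the default
#' width.
#'
#' @param scores Finite numeric vector of scores.
#' @param bin_width Bin width (default 0.01).
#' @return Data frame `bin, center, count, cum_count, cum_pct`; every
#'   integer bin between the extremes is present and the final `cum_pct`
#'   is 100.
#' @export
score_histogram <- function(scores, bin_width = 0.01) {
  stopifnot(length(scores) > 0L, all(is.finite(scores)))
  bins <- round(scores / bin_width)  # round() is half-to-even
  rng <- seq(min(bins), max(bins))
  counts <- tabulate(bins - min(bins) + 1L, nbins = length(rng))
  out <- data.frame(bin = rng, center = rng * bin_width, count = counts)
  out$cum_count <- cumsum(out$count)
  out$cum_pct <- 100 * out$cum_count / length(scores)
  out
}

#' Mean-plus-k-sigma thresholds and their coverage
#'
#' `mu + k sigma` for each k, plus (when scores are supplied) the
#' percentage of scores at or below each threshold, the layout used to
#' read off how exceptional a given similarity value is against the
#' random-pair distribution.
#'
#' @param mean,sd Distribution mean and standard deviation (`sd >= 0`).
#' @param k Numeric vector of SD multiples (default `c(1, 2)`).
#' @param scores Optional score vector for empirical coverage.
#' @return Data frame `k, threshold, coverage_pct` (`NA` without scores).
#' @export
percentile_thresholds <- function(mean, sd, k = c(1, 2), scores = NULL) {
  stopifnot(sd >= 0)
  thr <- mean + k * sd
  cov <- if (is.null(scores)) rep(NA_real_, length(k))
         else vapply(thr, function(t) 100 * base::mean(scores <= t), numeric(1))
  data.frame(k = k, threshold = thr, coverage_pct = cov)
}

#' Chance probability of 3-D neighbor status
#'
#' Given the percentages of random pairs falling below the ST and CT
#' neighbor thresholds, returns the chance (in percent, assuming
#' independence of the two scores) that a random pair clears both, and
#' its "1 in N" reciprocal.  The convention is the product of the two
#' percentage tails, `(100 - a) * (100 - b)`, capped at 100, with
#' `one_in = round(100 / p)` — the reporting arithmetic conventionally
#' used with these score distributions.
#'
#' @param frac_below_st,frac_below_ct Percent of random pairs below the ST
#'   and CT thresholds (0-100).
#' @return List `probability` (percent) and `one_in` (`round(100 / p)`;
#'   `Inf` when the probability is zero).
#' @export
neighbor_probability <- function(frac_below_st, frac_below_ct) {
  stopifnot(frac_below_st >= 0, frac_below_st <= 100,
            frac_below_ct >= 0, frac_below_ct <= 100)
  p <- min((100 - frac_below_st) * (100 - frac_below_ct), 100)
  list(probability = p, one_in = if (p == 0) Inf else round(100 / p))
}

#' Standard score
#'
#' @param x Value.
#' @param mean,sd Reference mean and standard deviation (`sd > 0`).
#' @return `(x - mean) / sd`.
#' @export
zscore <- function(x, mean, sd) {
  if (sd <= 0) stop("sd must be positive")
  (x - mean) / sd
}

#' Per-compound similarity profile
#'
#' Mean and population SD of each measure over all records a compound
#' appears in (against all scored partners), the per-CID view of the
#' random-pair distribution.
#'
#' @param records Similarity table from [score_matrix()].
#' @param cids Optional CID subset; default is every CID in `records`.
#' @return Data frame `cid, n_partners`, then `<m>_mean, <m>_sd` per
#'   measure.
#' @export
per_cid_profile <- function(records, cids = NULL) {
  all_cids <- sort(unique(c(records$cid_a, records$cid_b)))
  if (is.null(cids)) cids <- all_cids
  rows <- lapply(as.integer(cids), function(cid) {
    sub <- records[records$cid_a == cid | records$cid_b == cid, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no records involving cid ", cid)
    out <- data.frame(cid = cid, n_partners = nrow(sub))
    for (m in MEASURES) {
      out[[paste0(m, "_mean")]] <- mean(sub[[m]])
      out[[paste0(m, "_sd")]] <- pop_sd(sub[[m]])
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Connected components of the similarity-threshold graph
#'
#' Builds the graph whose vertices are all CIDs in `records`, with an edge
#' wherever the chosen measure is at or above the threshold, and returns
#' its connected components: the "everything interrelated at score >= t"
#' view of a compound set.
#'
#' @param records Similarity table from [score_matrix()].
#' @param measure One of the six measure names.
#' @param threshold Edge threshold on the measure.
#' @return List `sizes` (component sizes, decreasing), `membership` (named
#'   integer vector, component id per CID), `n_components`.
#' @export
threshold_components <- function(records, measure = "combo_ctopt", threshold) {
  measure <- match.arg(measure, MEASURES)
  verts <- as.character(sort(unique(c(records$cid_a, records$cid_b))))
  edges <- records[records[[measure]] >= threshold, c("cid_a", "cid_b"),
                   drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$cid_a),
               to = as.character(edges$cid_b)),
    directed = FALSE, vertices = verts)
  comp <- igraph::components(g)
  list(sizes = sort(unname(comp$csize), decreasing = TRUE),
       membership = setNames(as.integer(comp$membership),
                             names(comp$membership)),
       n_components = comp$no)
}

# ---- end-to-end assay pipeline --------------------------------------------

#' Per-assay pipeline over a conformer + assay collection
#'
#' Runs the whole statistical chain: partitions each assay into NN/NI
#' pairs (restricted to compounds with conformers), drops assays below the
#' pair-count floors, scores the union of needed pairs once (each pair is
#' scored a single time however many assays share it), and computes
#' per-assay statistics.
#'
#' @param conformers List of [conformer()] objects.
#' @param assays List of [assay_table()] objects.
#' @param params [overlap_params()].
#' @param min_nn,min_ni Pair-count floors for [filter_eligible()].
#' @param scores Optional precomputed [score_matrix()] table; pairs missing
#'   from it are computed and appended.
#' @return List: `stats` (per-assay rows), `scores` (the score table used),
#'   `eligible` (AIDs kept), `pair_sets` (per-AID pair partitions).
#' @export
assay_study_stats <- function(conformers, assays, params = overlap_params(),
                              min_nn = 6L, min_ni = 6L, scores = NULL) {
  have <- vapply(conformers, `[[`, integer(1), "cid")
  pair_sets <- lapply(assays, enumerate_pairs, have_3d = have)
  names(pair_sets) <- vapply(assays, `[[`, integer(1), "aid")
  eligible <- filter_eligible(pair_sets, min_nn, min_ni)
  keep <- vapply(assays, function(a) a$aid %in% eligible, logical(1))
  needed <- unique(do.call(rbind, lapply(pair_sets[as.character(eligible)],
                                         function(p) rbind(p$nn, p$ni))))
  if (is.null(scores)) scores <- empty_score_table()
  if (!is.null(needed) && nrow(needed)) {
    have_key <- paste(scores$cid_a, scores$cid_b)
    todo <- needed[!paste(needed[, 1], needed[, 2]) %in% have_key, ,
                   drop = FALSE]
    if (nrow(todo))
      scores <- rbind(scores, score_matrix(conformers, todo, params))
  }
  stats <- do.call(rbind, lapply(assays[keep], function(a)
    per_aid_statistics(a, pair_sets[[as.character(a$aid)]], scores)))
  list(stats = stats, scores = scores, eligible = eligible,
       pair_sets = pair_sets)
}
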