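# ---- assay tables and pair partitioning -----------------------------------

#' Classify a raw bioassay outcome
#'
#' Anything not explicitly reported as "inactive" counts as noninactive:
#' active, inconclusive, probe and unspecified outcomes all land in the
#' noninactive ("active space") class.  Case-insensitive.
#'
#' @param raw Character vector of raw outcome strings.
#' @return Character vector of `"inactive"` / `"noninactive"`.
#' @export
classify_outcome <- function(raw) {
  if (any(!nzchar(trimws(raw)))) stop("empty outcome string")
  ifelse(tolower(trimws(raw)) == "inactive", "inactive", "noninactive")
}

#' Construct an assay table
#'
#' One bioassay (AID): its category and one raw outcome per tested CID.
#' Duplicate CIDs with conflicting outcomes resolve to noninactive (any
#' non-inactive report makes the compound noninactive) with a warning.
#'
#' @param aid Integer assay identifier.
#' @param category One of `screening, confirmatory, summary, other,
#'   unspecified`.
#' @param cids Integer vector of tested compound ids.
#' @param outcomes Character vector of raw outcome strings, parallel to
#'   `cids`.
#' @return An object of class `"assay_table"`.
#' @export
assay_table <- function(aid, category, cids, outcomes) {
  category <- match.arg(category, ASSAY_CATEGORIES)
  stopifnot(length(cids) == length(outcomes))
  cids <- as.integer(cids)
  if (anyDuplicated(cids)) {
    cls <- classify_outcome(outcomes)
    keep <- !logical(length(cids))
    for (cid in unique(cids[duplicated(cids)])) {
      idx <- which(cids == cid)
      if (length(unique(cls[idx])) > 1L)
        warning(sprintf("AID %d CID %d: conflicting outcomes, kept noninactive",
                        aid, cid))
      winner <- idx[match("noninactive", cls[idx], nomatch = 1L)]
      keep[setdiff(idx, winner)] <- FALSE
    }
    cids <- cids[keep]; outcomes <- outcomes[keep]
  }
  structure(list(aid = as.integer(aid), category = category,
                 outcomes = setNames(as.character(outcomes),
                                     as.character(cids))),
            class = "assay_table")
}

#' @export
print.assay_table <- function(x, ...) {
  cls <- classify_outcome(x$outcomes)
  cat(sprintf("<assay_table AID %d (%s): %d CIDs, %d noninactive / %d inactive>\n",
              x$aid, x$category, length(x$outcomes),
              sum(cls == "noninactive"), sum(cls == "inactive")))
  invisible(x)
}

#' Partition an assay's compounds into NN and NI pairs
#'
#' Restricts the assay to CIDs with a 3-D description, then forms the
#' noninactive-noninactive (NN) pairs, all unordered pairs of distinct
#' noninactives, and the noninactive-inactive (NI) pairs, all cross pairs.
#' Inactive-inactive pairs are never used.  With k noninactives and m
#' inactives, `n_nn = k (k - 1) / 2` and `n_ni = k m`.
#'
#' @param assay An [assay_table()].
#' @param have_3d Integer vector of CIDs for which conformers exist; assay
#'   CIDs outside this set are excluded from both pair sets.
#' @return A list of class `"pair_set"`: `nn` and `ni` (two-column matrices
#'   with `cid_a < cid_b`), `n_nn`, `n_ni`.
#' @export
enumerate_pairs <- function(assay, have_3d = NULL) {
  cids <- as.integer(names(assay$outcomes))
  if (!is.null(have_3d)) {
    keep <- cids %in% as.integer(have_3d)
    cids <- cids[keep]
  } else keep <- rep(TRUE, length(cids))
  cls <- classify_outcome(assay$outcomes[keep])
  non <- sort(cids[cls == "noninactive"])
  inact <- sort(cids[cls == "inactive"])
  nn <- if (length(non) >= 2L) t(combn(non, 2L)) else
    matrix(integer(), 0L, 2L)
  ni <- if (length(non) >= 1L && length(inact) >= 1L) {
    g <- expand.grid(a = non, b = inact)
    cbind(pmin(g$a, g$b), pmax(g$a, g$b))
  } else matrix(integer(), 0L, 2L)
  colnames(nn) <- colnames(ni) <- c("cid_a", "cid_b")
  structure(list(nn = nn, ni = ni, n_nn = nrow(nn), n_ni = nrow(ni)),
            class = "pair_set")
}

#' Filter assays by minimum pair counts
#'
#' Keeps AIDs with at least `min_nn` NN pairs and at least `min_ni` NI
#' pairs; assays below either floor yield unstable per-assay averages.
#'
#' @param pair_sets Named list of [enumerate_pairs()] results, names = AIDs.
#' @param min_nn,min_ni Inclusive pair-count floors (default 6 each).
#' @return Integer vector of eligible AIDs.
#' @export
filter_eligible <- function(pair_sets, min_nn = 6L, min_ni = 6L) {
  keep <- vapply(pair_sets, function(p) p$n_nn >= min_nn && p$n_ni >= min_ni,
                 logical(1))
  as.integer(names(pair_sets)[keep])
}

# ---- per-assay statistics -------------------------------------------------

pop_sd <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Look up score rows for a set of (cid_a < cid_b) pairs; errors name the
# first missing pair.
lookup_scores <- function(pairs, scores) {
  if (nrow(pairs) == 0L)
    return(scores[integer(), , drop = FALSE])
  key <- paste(scores$cid_a, scores$cid_b)
  idx <- match(paste(pairs[, 1], pairs[, 2]), key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop(sprintf("no similarity record for pair (%d, %d)",
                 pairs[miss, 1], pairs[miss, 2]))
  }
  scores[idx, , drop = FALSE]
}

#' Per-assay similarity statistics
#'
#' For each of the six measures: mean and standard deviation over the NN
#' pair scores and over the NI pair scores, the NN-NI mean difference
#' (`mu_diff = mu_nn - mu_ni`, identical to the mean over all
#' `n_nn * n_ni` cross differences), and its spread.  Standard deviations
#' use the population divisor `n`; `sd_diff` is `sqrt(sd_nn^2 + sd_ni^2)`,
#' the population SD of the full cross-difference set (set
#' `sd_diff = "pooled"` for the standard-error form
#' `sqrt(sd_nn^2/n_nn + sd_ni^2/n_ni)`).
#'
#' @param assay An [assay_table()].
#' @param pairs The assay's [enumerate_pairs()] result.
#' @param scores Similarity table from [score_matrix()] covering every NN
#'   and NI pair (missing pairs are an error naming the pair).
#' @param sd_diff `"cross"` (default) or `"pooled"`.
#' @return One-row data frame: `aid, category, n_nn, n_ni`, then per
#'   measure `<m>_mu_nn, <m>_sd_nn, <m>_mu_ni, <m>_sd_ni, <m>_mu_diff,
#'   <m>_sd_diff`.
#' @export
per_aid_statistics <- function(assay, pairs, scores,
                               sd_diff = c("cross", "pooled")) {
  sd_diff <- match.arg(sd_diff)
  nn <- lookup_scores(pairs$nn, scores)
  ni <- lookup_scores(pairs$ni, scores)
  out <- data.frame(aid = assay$aid, category = assay$category,
                    n_nn = pairs$n_nn, n_ni = pairs$n_ni)
  for (m in MEASURES) {
    a <- nn[[m]]; b <- ni[[m]]
    sn <- pop_sd(a); si <- pop_sd(b)
    out[[paste0(m, "_mu_nn")]] <- mean(a)
    out[[paste0(m, "_sd_nn")]] <- sn
    out[[paste0(m, "_mu_ni")]] <- mean(b)
    out[[paste0(m, "_sd_ni")]] <- si
    out[[paste0(m, "_mu_diff")]] <- mean(a) - mean(b)
    out[[paste0(m, "_sd_diff")]] <-
      if (sd_diff == "cross") sqrt(sn^2 + si^2)
      else sqrt(sn^2 / length(a) + si^2 / length(b))
  }
  out
}

#' Aggregate per-assay statistics across assays
#'
#' For every assay category present, and for `"All"`, computes the mean and
#' population SD across assays of each per-assay quantity: the NN mean, NI
#' mean and NN-NI difference, and their per-assay SDs, for all six
#' measures.  This is the bracketed-moment layer: `mu[mu(XT)]`,
#' `sigma[mu(XT)]`, `mu[sigma(XT)]`, `sigma[sigma(XT)]`.
#'
#' @param stats Data frame of [per_aid_statistics()] rows.
#' @return Long data frame with columns `grouping, n_aids, measure, set`
#'   (`nn`/`ni`/`diff`), `mu_of_mu, sigma_of_mu, mu_of_sigma,
#'   sigma_of_sigma`.
#' @export
aggregate_assay_stats <- function(stats) {
  if (nrow(stats) == 0L) stop("no per-assay statistics to aggregate")
  groups <- c(intersect(ASSAY_CATEGORIES, unique(stats$category)), "All")
  rows <- list()
  for (g in groups) {
    sub <- if (g == "All") stats else stats[stats$category == g, , drop = FALSE]
    for (m in MEASURES) {
      for (set in c("nn", "ni", "diff")) {
        mu_col <- paste0(m, "_mu_", set)
        sd_col <- paste0(m, "_sd_", set)
        rows[[length(rows) + 1L]] <- data.frame(
          grouping = g, n_aids = nrow(sub), measure = m, set = set,
          mu_of_mu = mean(sub[[mu_col]]), sigma_of_mu = pop_sd(sub[[mu_col]]),
          mu_of_sigma = mean(sub[[sd_col]]),
          sigma_of_sigma = pop_sd(sub[[sd_col]]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- outliers -------------------------------------------------------------

#' Outlier assays for one similarity measure
#'
#' Bounds are `mu +/- k sigma` of the per-assay NN-NI mean difference over
#' all supplied assays.  Upper-bound outliers separate actives from
#' inactives more strongly than typical; lower-bound outliers show the
#' reverse (e.g. activity-cliff series where most of a 3-D-similar series
#' is inactive).
#'
#' @param stats Data frame of [per_aid_statistics()] rows (>= 2 assays).
#' @param measure One of the six measure names, e.g. `"combo_stopt"`.
#' @param k Bound width in SD units (default 1).
#' @return List: `measure`, `mu`, `sigma`, `bounds` (length 2), `lower` and
#'   `upper` (integer AID vectors).  Zero variance across assays yields
#'   empty sets with a warning.
#' @export
find_outliers <- function(stats, measure = "combo_stopt", k = 1) {
  measure <- match.arg(measure, MEASURES)
  if (nrow(stats) < 2L) stop("need at least two assays")
  x <- stats[[paste0(measure, "_mu_diff")]]
  mu <- mean(x); sigma <- pop_sd(x)
  if (sigma == 0) {
    warning("zero variance across assays; no outliers")
    return(list(measure = measure, mu = mu, sigma = sigma,
                bounds = c(mu, mu), lower = integer(), upper = integer()))
  }
  bounds <- c(mu - k * sigma, mu + k * sigma)
  list(measure = measure, mu = mu, sigma = sigma, bounds = bounds,
       lower = stats$aid[x < bounds[1]], upper = stats$aid[x > bounds[2]])
}

#' Full outlier report across measures
#'
#' Runs [find_outliers()] for all six measures and assembles the
#' cross-measure structure: per-measure lower/upper sets, overlap counts
#' between the three measures within each optimization type, the
#' cross-optimization ComboT overlap, and per-category outlier counts with
#' percentages.
#'
#' @inheritParams find_outliers
#' @return List with `per_measure` (per-measure [find_outliers()] results),
#'   `measure_overlap` (per opt type and bound side, counts of AIDs shared
#'   between ST/CT/ComboT sets), `combo_opt_overlap` (ComboT ST-opt vs
#'   CT-opt shared counts per side), and `category_counts` (data frame of
#'   counts and percentages per category, measure and side).
#' @export
outlier_report <- function(stats, k = 1) {
  per <- lapply(setNames(MEASURES, MEASURES),
                function(m) find_outliers(stats, m, k))
  overlap3 <- function(opt, side) {
    sets <- lapply(paste0(c("st_", "ct_", "combo_"), opt),
                   function(m) per[[m]][[side]])
    names(sets) <- c("st", "ct", "combo")
    c(st_ct = length(intersect(sets$st, sets$ct)),
      st_combo = length(intersect(sets$st, sets$combo)),
      ct_combo = length(intersect(sets$ct, sets$combo)),
      all_three = length(Reduce(intersect, sets)))
  }
  measure_overlap <- list(
    stopt = list(lower = overlap3("stopt", "lower"),
                 upper = overlap3("stopt", "upper")),
    ctopt = list(lower = overlap3("ctopt", "lower"),
                 upper = overlap3("ctopt", "upper")))
  combo_opt_overlap <- vapply(c(lower = "lower", upper = "upper"),
    function(side) length(intersect(per$combo_stopt[[side]],
                                    per$combo_ctopt[[side]])), integer(1))
  cats <- c(intersect(ASSAY_CATEGORIES, unique(stats$category)), "All")
  rows <- list()
  for (m in MEASURES) for (side in c("lower", "upper")) for (g in cats) {
    in_g <- if (g == "All") stats$aid else stats$aid[stats$category == g]
    n_out <- length(intersect(per[[m]][[side]], in_g))
    rows[[length(rows) + 1L]] <- data.frame(
      measure = m, side = side, category = g, n_assays = length(in_g),
      n_outliers = n_out, pct = 100 * n_out / max(length(in_g), 1L))
  }
  list(per_measure = per, measure_overlap = measure_overlap,
       combo_opt_overlap = combo_opt_overlap,
       category_counts = do.call(rbind, rows))
}

#' Rank assays by average ComboT NN-NI separation
#'
#' Averages the ComboT NN-NI mean difference over the two optimization
#' types and sorts descending, the layout used to report the strongest
#' upper-bound outlier assays.
#'
#' @param stats Data frame of [per_aid_statistics()] rows (needs the
#'   `combo_stopt_mu_diff` and `combo_ctopt_mu_diff` columns).
#' @param aids Optional AID subset (e.g. the common upper-bound outliers).
#' @return Data frame `aid, category, mu_diff_stopt, mu_diff_ctopt,
#'   average`, sorted by decreasing `average`.
#' @export
rank_outliers <- function(stats, aids = NULL) {
  if (!is.null(aids)) stats <- stats[stats$aid %in% aids, , drop = FALSE]
  out <- data.frame(aid = stats$aid, category = stats$category,
                    mu_diff_stopt = stats$combo_stopt_mu_diff,
                    mu_diff_ctopt = stats$combo_ctopt_mu_diff)
  out$average <- (out$mu_diff_stopt + out$mu_diff_ctopt) / 2
  out <- out[order(-out$average, out$aid), , drop = FALSE]
  rownames(out) <- NULL
  out
}
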