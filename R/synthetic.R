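# ---- synthetic conformers and assay studies -------------------------------

#' Generator configuration
#'
#' Parameters of the synthetic population.  The defaults reproduce the
#' descriptor profile of large biologically-tested compound collections:
#' heavy-atom count 24.6 +/- 6.4 truncated to the 5-50 range, and per-type
#' pharmacophore feature rates (acceptor 2.9 +/- 1.6, donor 1.1 +/- 1.0,
#' anion 0.2 +/- 0.4, cation 0.6 +/- 0.8, hydrophobe 0.3 +/- 0.6, ring
#' 3.0 +/- 1.2, about 8 features per molecule in total).
#'
#' @param n_compounds Background population size.
#' @param atom_mean,atom_sd Heavy-atom count distribution (truncated
#'   normal, rounded).
#' @param atom_range Inclusive truncation bounds on the atom count.
#' @param feature_rates Named list of `c(mean, sd)` per feature type.
#' @param bond_length Successive chain bond length, Angstrom.
#' @param assay_plan Data frame with one row per assay: `category`,
#'   `n_noninactive`, `n_inactive`, `mode` (`"null"` or `"clustered"`),
#'   `sigma` (clustered-mode perturbation SD, Angstrom).  See
#'   [assay_plan()].
#' @param feature_keep_prob Probability a perturbed compound retains each
#'   template feature (clustered mode).
#' @param seed Optional integer seed applied by [synthesize_study()].
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_compounds = 120,
                             atom_mean = 24.6, atom_sd = 6.4,
                             atom_range = c(5L, 50L),
                             feature_rates = list(
                               acceptor = c(2.9, 1.6), donor = c(1.1, 1.0),
                               anion = c(0.2, 0.4), cation = c(0.6, 0.8),
                               hydrophobe = c(0.3, 0.6), ring = c(3.0, 1.2)),
                             bond_length = 1.54,
                             assay_plan = NULL,
                             feature_keep_prob = 1.0,
                             seed = NULL) {
  stopifnot(n_compounds >= 1, atom_sd >= 0,
            all(vapply(feature_rates, function(r) r[2] >= 0, logical(1))),
            all(names(feature_rates) %in% FEATURE_TYPES))
  structure(list(n_compounds = n_compounds, atom_mean = atom_mean,
                 atom_sd = atom_sd, atom_range = as.integer(atom_range),
                 feature_rates = feature_rates, bond_length = bond_length,
                 assay_plan = assay_plan,
                 feature_keep_prob = feature_keep_prob, seed = seed),
            class = "generator_config")
}

#' Build an assay plan
#'
#' @param n_null Number of null-mode assays (compounds sampled i.i.d. from
#'   the background population, so NN and NI scores share one
#'   distribution).
#' @param n_clustered Number of clustered-mode assays (noninactives are
#'   perturbed copies of one or two template conformers, modeling a
#'   congeneric compound series).
#' @param n_noninactive,n_inactive Compounds per assay in each outcome
#'   class.
#' @param sigma Per-coordinate perturbation SD for clustered noninactives,
#'   Angstrom.
#' @param categories Category labels recycled across assays.
#' @return Data frame usable as `assay_plan` in [generator_config()].
#' @export
assay_plan <- function(n_null = 50L, n_clustered = 0L,
                       n_noninactive = 6L, n_inactive = 8L,
                       sigma = 0.25,
                       categories = c("screening", "confirmatory")) {
  n <- n_null + n_clustered
  data.frame(category = rep_len(categories, n),
             n_noninactive = n_noninactive, n_inactive = n_inactive,
             mode = rep(c("null", "clustered"), c(n_null, n_clustered)),
             sigma = sigma)
}

# Rounded truncated-normal sample by rejection.
rtrunc_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a random synthetic conformer
#'
#' A self-avoiding 3-D chain: successive bonds of fixed length, bond
#' angles near tetrahedral (109.5 degrees with jitter), uniform dihedrals,
#' and a 2.0 Angstrom minimum distance between non-bonded atoms enforced
#' by rejection (bounded retries, then a fresh chain).  Elements are
#' carbon with a 25% chance of N/O substitution; features are placed on
#' randomly chosen atoms with per-type counts drawn from the configured
#' truncated-normal rates.  Draws from the current RNG stream, so a fixed
#' seed gives a bitwise-identical conformer.
#'
#' @param cid Compound id to assign.
#' @param n_atoms Heavy-atom count (1-50); default draws from the
#'   configured distribution.
#' @param config A [generator_config()].
#' @return A [conformer()].
#' @export
random_conformer <- function(cid, n_atoms = NULL,
                             config = generator_config()) {
  if (is.null(n_atoms))
    n_atoms <- rtrunc_int(1L, config$atom_mean, config$atom_sd,
                          config$atom_range[1], config$atom_range[2])
  stopifnot(n_atoms >= 1L, n_atoms <= 50L)
  xyz <- chain_coords(n_atoms, config$bond_length)
  elements <- c("C", "N", "O")[1L + (runif(n_atoms) < 0.25) *
                                 sample.int(2L, n_atoms, replace = TRUE)]
  counts <- vapply(FEATURE_TYPES, function(t) {
    r <- config$feature_rates[[t]]
    if (is.null(r)) return(0L)
    max(0L, as.integer(round(rnorm(1L, r[1], r[2]))))
  }, integer(1))
  counts <- pmin(counts, n_atoms)
  ftype <- rep(names(counts), counts)
  members <- lapply(seq_along(ftype),
                    function(i) sample.int(n_atoms, 1L))
  feats <- feature_points(ftype, members = members, atom_xyz = xyz)
  conformer(cid, xyz, elements, feats)
}

# Self-avoiding chain coordinates; restarts the whole chain when an atom
# cannot be placed, erroring after max_restarts.
chain_coords <- function(n_atoms, bond_length, max_restarts = 50L) {
  for (attempt in seq_len(max_restarts)) {
    xyz <- matrix(0, n_atoms, 3L)
    if (n_atoms >= 2L) xyz[2L, ] <- c(bond_length, 0, 0)
    ok <- TRUE
    i <- 3L
    while (i <= n_atoms) {
      placed <- FALSE
      for (try in 1:30) {
        ang <- (109.5 + rnorm(1L, 0, 5)) * pi / 180
        dih <- runif(1L, 0, 2 * pi)
        prev <- xyz[i - 1L, ]; prev2 <- xyz[i - 2L, ]
        b1 <- prev - prev2
        b1 <- b1 / sqrt(sum(b1^2))
        # arbitrary perpendicular frame around b1
        ref <- if (abs(b1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        u <- ref - sum(ref * b1) * b1
        u <- u / sqrt(sum(u^2))
        v <- c(b1[2] * u[3] - b1[3] * u[2],
               b1[3] * u[1] - b1[1] * u[3],
               b1[1] * u[2] - b1[2] * u[1])
        dirn <- cos(pi - ang) * b1 +
          sin(pi - ang) * (cos(dih) * u + sin(dih) * v)
        cand <- prev + bond_length * dirn
        d2 <- rowSums(sweep(xyz[seq_len(i - 2L), , drop = FALSE], 2L,
                            cand)^2)
        if (all(d2 >= 2.0^2)) {
          xyz[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
      i <- i + 1L
    }
    if (ok) return(xyz)
  }
  stop("failed to place a self-avoiding chain after ", max_restarts,
       " restarts")
}

#' Perturb a conformer
#'
#' Adds i.i.d. Gaussian noise (SD `sigma` per coordinate) to every atom,
#' moves each feature to the centroid of its (displaced) member atoms,
#' retains each feature independently with probability `keep_prob`, and
#' assigns a new cid.  Models within-series structural relatedness.
#'
#' @param conf Template [conformer()].
#' @param cid New compound id.
#' @param sigma Perturbation SD, Angstrom (>= 0).
#' @param keep_prob Per-feature retention probability.
#' @return A new [conformer()].
#' @export
perturb_conformer <- function(conf, cid, sigma = 0.25, keep_prob = 1.0) {
  stopifnot(sigma >= 0)
  xyz <- conf$xyz + matrix(rnorm(length(conf$xyz), 0, sigma),
                           nrow(conf$xyz), 3L)
  feats <- conf$features
  if (nrow(feats)) {
    keep <- runif(nrow(feats)) <= keep_prob
    feats <- feats[keep, , drop = FALSE]
    if (nrow(feats)) {
      feats <- feature_points(feats$ftype, members = feats$members,
                              atom_xyz = xyz, radius = feats$radius[1])
    } else feats <- feature_points()
  }
  conformer(cid, xyz, conf$elements, feats)
}

#' Synthesize a full study: conformer population plus assays
#'
#' Generates the background conformer population, then each planned assay:
#' null-mode assays draw both noninactives and inactives i.i.d. from the
#' population; clustered-mode assays build their noninactives by
#' perturbing one template conformer (two templates when the noninactive
#' set has at least eight members, modeling a pair of compound series) and
#' draw inactives from the background.  Ground-truth assay modes are
#' returned for recovery experiments.
#'
#' @param config A [generator_config()] whose `assay_plan` is non-NULL.
#' @return A list of class `"synthetic_study"`: `conformers`, `assays`
#'   (list of [assay_table()]), `truth` (data frame `aid, category, mode,
#'   sigma`), and the `config`.
#' @export
synthesize_study <- function(config = generator_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  plan <- config$assay_plan
  if (is.null(plan)) stop("config$assay_plan is required")
  if (any(plan$n_noninactive + plan$n_inactive > config$n_compounds))
    stop("assay larger than the population")
  conformers <- lapply(seq_len(config$n_compounds), random_conformer,
                       config = config)
  next_cid <- config$n_compounds
  assays <- vector("list", nrow(plan))
  truth <- data.frame(aid = seq_len(nrow(plan)), category = plan$category,
                      mode = plan$mode, sigma = plan$sigma)
  for (a in seq_len(nrow(plan))) {
    k <- plan$n_noninactive[a]; m <- plan$n_inactive[a]
    if (plan$mode[a] == "null") {
      picked <- sample.int(config$n_compounds, k + m)
      cids <- vapply(conformers[picked], `[[`, integer(1), "cid")
      outcomes <- rep(c("Active", "Inactive"), c(k, m))
    } else {
      n_templates <- if (k >= 8L) 2L else 1L
      tpl_idx <- sample.int(config$n_compounds, n_templates)
      templates <- conformers[tpl_idx]
      series <- lapply(seq_len(k), function(i) {
        tpl <- templates[[1L + (i - 1L) %% n_templates]]
        perturb_conformer(tpl, next_cid + i, plan$sigma[a],
                          config$feature_keep_prob)
      })
      next_cid <- next_cid + k
      conformers <- c(conformers, series)
      # inactives come from the background, never from the template series
      pool <- setdiff(seq_len(config$n_compounds), tpl_idx)
      inact <- conformers[sample(pool, m)]
      cids <- c(vapply(series, `[[`, integer(1), "cid"),
                vapply(inact, `[[`, integer(1), "cid"))
      outcomes <- rep(c("Active", "Inactive"), c(k, m))
    }
    assays[[a]] <- assay_table(a, plan$category[a], cids, outcomes)
  }
  structure(list(conformers = conformers, assays = assays, truth = truth,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study: %d conformers, %d assays (%d clustered)>\n",
              length(x$conformers), length(x$assays),
              sum(x$truth$mode == "clustered")))
  invisible(x)
}
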