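#' Monopole (steric) volume
#'
#' First-order inclusion-exclusion Gaussian volume
#' `sum_i v_i - sum_{i<j} v_ij`, where `v_i` is an isolated atom's Gaussian
#' volume (calibrated to `4/3 pi R^3`) and `v_ij` the pairwise density
#' overlap.  A descriptor of molecular size, distinct from the density
#' self-overlap used inside the Tanimoto scores.  Rigid-motion invariant.
#'
#' @param conf A [conformer()].
#' @param params [overlap_params()].
#' @return Volume, A^3.
#' @export
monopole_volume <- function(conf, params = overlap_params()) {
  if (!inherits(conf, "conformer") || nrow(conf$xyz) < 1L) stop("no atoms")
  k <- shape_kappa(conf, params)
  v1 <- params$amplitude * (pi / k)^1.5
  n <- nrow(conf$xyz)
  if (n == 1L) return(v1)
  vpair_all <- overlap_sum_cpp(conf$xyz, k, integer(n), conf$xyz, k, integer(n),
                               params$amplitude^2, params$skip_log)
  vself <- sum(params$amplitude^2 * (pi / (2 * k))^1.5)
  # all-pairs sum counts each i<j twice and includes the diagonal
  sum(v1) - (vpair_all - vself) / 2
}

#' Shape quadrupole moments
#'
#' Second central moments of the Gaussian shape density evaluated along its
#' principal axes: `Q_a = integral(rho(r) (a . (r - c))^2 dr)` with `c` the
#' density centroid, reported sorted `Qx >= Qy >= Qz` so the three values
#' read as squared length, width and height weighted by volume (A^5).
#' Rigid-motion invariant.
#'
#' @inheritParams monopole_volume
#' @return Named numeric vector `c(qx, qy, qz)`, A^5.
#' @export
shape_quadrupole <- function(conf, params = overlap_params()) {
  if (!inherits(conf, "conformer") || nrow(conf$xyz) < 1L) stop("no atoms")
  k <- shape_kappa(conf, params)
  v <- params$amplitude * (pi / k)^1.5
  ctr <- colSums(conf$xyz * v) / sum(v)
  d <- sweep(conf$xyz, 2L, ctr)
  # integral of rho_i (x - c)(x - c)^T = v_i (d_i d_i^T + I / (2 k_i))
  M <- crossprod(d * v, d) + diag(3) * sum(v / (2 * k))
  q <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
            decreasing = TRUE)
  setNames(q, c("qx", "qy", "qz"))
}

#' Count pharmacophore features by type
#'
#' @param conf A [conformer()].
#' @return Named integer vector over the six feature types plus `total`.
#' @export
feature_counts <- function(conf) {
  counts <- vapply(FEATURE_TYPES, function(t) sum(conf$features$ftype == t),
                   integer(1))
  c(counts, total = sum(counts))
}

#' Conformer eligibility rules
#'
#' A conformer enters the analysis only if it is a single covalent component
#' of organic elements (H, C, N, O, F, P, S, Cl, Br, I), has at most 50
#' heavy atoms, at most 15 effective rotors, and at most 5 undefined
#' stereocenters.  Rotor and stereocenter counts come from metadata: the
#' synthetic generator supplies them, and file ingest estimates rotors from
#' the bond block when available.
#'
#' @param conf A [conformer()].
#' @param n_components Number of covalent components.
#' @param rotor_count Effective rotor count.
#' @param undefined_stereo Number of undefined stereocenters.
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   every violated rule; empty when eligible).
#' @export
eligibility_check <- function(conf, n_components = 1L, rotor_count = 0L,
                              undefined_stereo = 0L) {
  reasons <- character()
  if (n_components > 1L) reasons <- c(reasons, "multiple covalent components")
  if (any(!conf$elements %in% ORGANIC_ELEMENTS))
    reasons <- c(reasons, "non-organic element")
  if (nrow(conf$xyz) > 50L) reasons <- c(reasons, "too many heavy atoms")
  if (rotor_count > 15L) reasons <- c(reasons, "too many effective rotors")
  if (undefined_stereo > 5L)
    reasons <- c(reasons, "too many undefined stereocenters")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Descriptor row for a conformer
#'
#' Assembles the steric and feature descriptors into a one-row data frame
#' matching the descriptor TSV layout.
#'
#' @inheritParams monopole_volume
#' @return One-row data frame: `cid, heavy_atoms, volume, qx, qy, qz`,
#'   per-type feature counts and `n_total`.
#' @export
conformer_descriptors <- function(conf, params = overlap_params()) {
  q <- shape_quadrupole(conf, params)
  fc <- feature_counts(conf)
  out <- data.frame(cid = conf$cid, heavy_atoms = nrow(conf$xyz),
                    volume = monopole_volume(conf, params),
                    qx = q[["qx"]], qy = q[["qy"]], qz = q[["qz"]])
  for (t in FEATURE_TYPES) out[[paste0("n_", t)]] <- unname(fc[[t]])
  out$n_total <- unname(fc[["total"]])
  out
}
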