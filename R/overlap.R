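# ---- shape overlap --------------------------------------------------------

# Per-atom Gaussian widths for a conformer under params.
shape_kappa <- function(conf, params) {
  kappa_from_radius(conf$radii, params$amplitude)
}

#' Shape self-overlap volume
#'
#' `V_AA`, the density self-overlap `integral(rho_A^2)`, in cubic Angstrom.
#'
#' @param conf A [conformer()].
#' @param params [overlap_params()].
#' @return Positive volume, A^3.
#' @export
self_overlap <- function(conf, params = overlap_params()) {
  if (!inherits(conf, "conformer")) stop("conf must be a conformer")
  pair_overlap(conf, conf, params = params)
}

#' Shape overlap volume of a conformer pair
#'
#' `V_AB = sum_{i in A, j in B} p^2 (pi/(k_i+k_j))^{3/2}
#'  exp(-k_i k_j / (k_i+k_j) d_ij^2)`, the analytic density-overlap
#' integral of the two Gaussian shape densities, after applying `tf` to B.
#'
#' @param confA,confB [conformer()] objects.
#' @param tf [rigid_transform()] applied to B before integration.
#' @param params [overlap_params()].
#' @return Overlap volume, A^3.
#' @export
pair_overlap <- function(confA, confB, tf = rigid_transform(),
                         params = overlap_params()) {
  bx <- apply_transform(tf, confB$xyz)
  overlap_sum_cpp(confA$xyz, shape_kappa(confA, params),
                  integer(nrow(confA$xyz)),
                  bx, shape_kappa(confB, params),
                  integer(nrow(bx)),
                  params$amplitude^2, params$skip_log)
}

#' Shape-Tanimoto score at a fixed pose
#'
#' `ST = V_AB / (V_AA + V_BB - V_AB)`, in `[0, 1]`.
#'
#' @inheritParams pair_overlap
#' @return Dimensionless score.
#' @export
shape_tanimoto <- function(confA, confB, tf = rigid_transform(),
                           params = overlap_params()) {
  vaa <- self_overlap(confA, params)
  vbb <- self_overlap(confB, params)
  vab <- pair_overlap(confA, confB, tf, params)
  denom <- vaa + vbb - vab
  stopifnot(denom > 0)
  vab / denom
}

#' Grid-quadrature overlap oracle
#'
#' Numeric quadrature of `rho_A * rho_B` on a regular grid over the padded
#' union bounding box.  A test oracle, independent of the analytic pairwise
#' path; not meant for production scoring.
#'
#' @inheritParams pair_overlap
#' @param spacing Grid spacing, Angstrom.
#' @param pad Box padding beyond the atom extents, Angstrom.
#' @param color Integrate the feature densities of one type instead of the
#'   shape densities; pass a feature type name.
#' @return Overlap volume, A^3.
#' @export
grid_overlap_oracle <- function(confA, confB, tf = rigid_transform(),
                                params = overlap_params(), spacing = 0.1,
                                pad = 4, color = NULL) {
  if (is.null(color)) {
    ax <- confA$xyz; ak <- shape_kappa(confA, params)
    b <- apply_transform(tf, confB)
    bx <- b$xyz; bk <- shape_kappa(confB, params)
    p <- params$amplitude
  } else {
    kc <- kappa_from_radius(params$color_radius, params$color_amplitude)
    sel_a <- confA$features$ftype == color
    ax <- feature_xyz(confA)[sel_a, , drop = FALSE]
    ak <- rep(kc, sum(sel_a))
    b <- apply_transform(tf, confB)
    sel_b <- b$features$ftype == color
    bx <- feature_xyz(b)[sel_b, , drop = FALSE]
    bk <- rep(kc, sum(sel_b))
    p <- params$color_amplitude
  }
  if (nrow(ax) == 0L || nrow(bx) == 0L) return(0)
  grid_overlap_cpp(ax, ak, bx, bk, p, spacing, pad)
}

# ---- color overlap --------------------------------------------------------

#' Per-type feature ("color") overlap volumes
#'
#' Gaussian overlap of same-type feature points only: the six feature types
#' are independent fictitious atom types, so cross-type overlap is zero by
#' construction.
#'
#' @inheritParams pair_overlap
#' @return A list of class `"color_overlap_terms"` with per-type vectors
#'   `v_aa`, `v_bb`, `v_ab` (named by feature type, A^3).
#' @export
color_overlap <- function(confA, confB, tf = rigid_transform(),
                          params = overlap_params()) {
  kc <- kappa_from_radius(params$color_radius, params$color_amplitude)
  p2 <- params$color_amplitude^2
  ax <- feature_xyz(confA); at <- feature_type_codes(confA)
  bt_conf <- apply_transform(tf, confB)
  bx <- feature_xyz(bt_conf); bt <- feature_type_codes(bt_conf)
  one_set <- function(x1, t1, x2, t2) {
    vapply(seq_along(FEATURE_TYPES), function(code) {
      i <- t1 == code; j <- t2 == code
      if (!any(i) || !any(j)) return(0)
      overlap_sum_cpp(x1[i, , drop = FALSE], rep(kc, sum(i)), integer(sum(i)),
                      x2[j, , drop = FALSE], rep(kc, sum(j)), integer(sum(j)),
                      p2, params$skip_log)
    }, numeric(1))
  }
  out <- list(v_aa = one_set(ax, at, ax, at),
              v_bb = one_set(bx, bt, bx, bt),
              v_ab = one_set(ax, at, bx, bt))
  out <- lapply(out, function(v) setNames(v, FEATURE_TYPES))
  structure(out, class = "color_overlap_terms")
}

#' Color-Tanimoto score from overlap terms
#'
#' Tanimoto of the type-summed feature overlaps:
#' `CT = sum_f V_AB^f / (sum_f V_AA^f + sum_f V_BB^f - sum_f V_AB^f)`.
#' When both conformers are featureless the score is 0 by convention, so a
#' pair of plain hydrocarbons scores no feature similarity.
#'
#' @param terms A `"color_overlap_terms"` object from [color_overlap()].
#' @return Dimensionless score in `[0, 1]`.
#' @export
color_tanimoto <- function(terms) {
  saa <- sum(terms$v_aa); sbb <- sum(terms$v_bb); sab <- sum(terms$v_ab)
  if (saa == 0 && sbb == 0) return(0)
  denom <- saa + sbb - sab
  stopifnot(denom > 0)
  sab / denom
}

#' Combo-Tanimoto score
#'
#' `ComboT = ST + CT`, range `[0, 2]`.  No rescaling is applied.
#'
#' @param st Shape-Tanimoto in `[0, 1]`.
#' @param ct Color-Tanimoto in `[0, 1]`.
#' @return Dimensionless score in `[0, 2]`.
#' @export
combo_tanimoto <- function(st, ct) {
  if (any(st < 0 | st > 1) || any(ct < 0 | ct > 1))
    stop("ST and CT must lie in [0, 1]")
  st + ct
}
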