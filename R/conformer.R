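#' Gaussian overlap parameters
#'
#' Parameters of the atom-centred Gaussian model used throughout the scoring
#' layer.  Each heavy atom is a spherical Gaussian `p * exp(-kappa * r^2)`
#' whose width `kappa` is calibrated so that the integral of an isolated atom
#' equals its hard-sphere volume `4/3 * pi * radius^3`.  Pharmacophore
#' features ("color atoms") use the same functional form at a smaller radius.
#'
#' @param amplitude Gaussian amplitude `p` for shape atoms (dimensionless).
#'   The default 2.7 is the conventional approximation to `2 * sqrt(2)`, the
#'   value at which two fully coincident atoms reproduce a single atom's
#'   hard-sphere volume under first-order inclusion-exclusion.
#' @param radius Uniform heavy-atom radius in Angstrom.  All heavy atoms use
#'   the carbon-like 1.70 A; hydrogens never contribute.
#' @param color_amplitude,color_radius Amplitude and radius for feature
#'   Gaussians (defaults 2.7 and 1.0 A).
#' @param skip_log Pairwise overlap terms whose exponent falls below this
#'   value are dropped (default -30, an error below 1e-13 per term).
#' @return A list of class `"overlap_params"`.
#' @export
overlap_params <- function(amplitude = 2.7, radius = 1.70,
                           color_amplitude = 2.7, color_radius = 1.0,
                           skip_log = -30) {
  stopifnot(amplitude > 0, radius > 0, color_amplitude > 0, color_radius > 0)
  structure(list(amplitude = amplitude, radius = radius,
                 color_amplitude = color_amplitude, color_radius = color_radius,
                 skip_log = skip_log),
            class = "overlap_params")
}

#' Gaussian width from a hard-sphere radius
#'
#' `kappa = pi * (3 p / (4 pi R^3))^(2/3)`, the width at which
#' `integral(p exp(-kappa r^2)) = 4/3 pi R^3`.
#'
#' @param radius Sphere radius, Angstrom.
#' @param amplitude Gaussian amplitude `p`.
#' @return Width `kappa` in 1/Angstrom^2.
#' @export
kappa_from_radius <- function(radius, amplitude = 2.7) {
  pi * (3 * amplitude / (4 * pi * radius^3))^(2 / 3)
}

#' Construct a conformer
#'
#' A conformer is the unit of all scoring: heavy atoms with 3-D coordinates
#' plus zero or more typed pharmacophore feature points.  Hydrogens are not
#' representable; drop them before construction (file ingest does this).
#'
#' @param cid Integer compound identifier, unique within a collection.
#' @param xyz Numeric n x 3 matrix of heavy-atom coordinates, Angstrom.
#' @param elements Character vector of element symbols, one per atom; must
#'   be drawn from the organic set `C, N, O, F, P, S, Cl, Br, I`.
#' @param features Feature data frame as built by [feature_points()], or
#'   `NULL` for a featureless conformer.
#' @param radius Uniform atom radius, Angstrom.
#' @return An object of class `"conformer"`.
#' @export
conformer <- function(cid, xyz, elements = rep("C", nrow(xyz)),
                      features = NULL, radius = 1.70) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("no atoms")
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  if (length(elements) != nrow(xyz))
    stop("one element symbol per atom required")
  if (any(elements == "H"))
    stop("hydrogens must be dropped before constructing a conformer")
  bad <- setdiff(unique(elements), ORGANIC_ELEMENTS)
  if (length(bad))
    stop("non-organic element(s): ", paste(bad, collapse = ", "))
  if (is.null(features)) features <- feature_points()
  if (nrow(features)) {
    idx <- unlist(features$members)
    if (length(idx) && (any(idx < 1L) | any(idx > nrow(xyz))))
      stop("feature member atom index out of range")
  }
  structure(list(cid = as.integer(cid), xyz = xyz,
                 elements = as.character(elements),
                 radii = rep(radius, nrow(xyz)),
                 features = features),
            class = "conformer")
}

#' Build a feature-point table
#'
#' @param ftype Character vector of feature types, each one of
#'   `donor, acceptor, cation, anion, hydrophobe, ring`.
#' @param xyz Numeric m x 3 matrix of feature positions, or `NULL` to place
#'   each feature at the centroid of its member atoms (requires `atom_xyz`).
#' @param members List of integer vectors of 1-based member-atom indices.
#' @param atom_xyz Atom coordinate matrix used to compute centroids when
#'   `xyz` is `NULL`.
#' @param radius Feature Gaussian radius, Angstrom.
#' @return A data frame with columns `ftype, x, y, z, radius` and a
#'   list-column `members`.
#' @export
feature_points <- function(ftype = character(), xyz = NULL, members = NULL,
                           atom_xyz = NULL, radius = 1.0) {
  n <- length(ftype)
  if (n == 0L) {
    return(data.frame(ftype = character(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric(),
                      members = I(list())))
  }
  bad <- setdiff(unique(ftype), FEATURE_TYPES)
  if (length(bad)) stop("unknown feature type(s): ", paste(bad, collapse = ", "))
  if (is.null(members)) members <- rep(list(integer()), n)
  if (length(members) != n) stop("one member set per feature required")
  if (is.null(xyz)) {
    if (is.null(atom_xyz)) stop("need xyz or atom_xyz + members")
    xyz <- t(vapply(members, function(m) colMeans(atom_xyz[m, , drop = FALSE]),
                    numeric(3)))
  }
  xyz <- as.matrix(xyz)
  data.frame(ftype = as.character(ftype), x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], radius = rep(radius, length.out = n),
             members = I(lapply(members, as.integer)))
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer cid=%d: %d heavy atoms, %d features>\n",
              x$cid, nrow(x$xyz), nrow(x$features)))
  invisible(x)
}

# Feature coordinate matrix (m x 3); empty matrix when featureless.
feature_xyz <- function(conf) {
  if (!nrow(conf$features)) return(matrix(numeric(), 0L, 3L))
  unname(as.matrix(conf$features[, c("x", "y", "z")]))
}

# Integer codes for feature types (1..6 in FEATURE_TYPES order).
feature_type_codes <- function(conf) {
  match(conf$features$ftype, FEATURE_TYPES)
}
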