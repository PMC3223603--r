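# Shared fixtures: tiny hand-built conformers and closed-form constants.

# Gaussian constants for the default parameters (p = 2.7, R = 1.70 A,
# color R = 1.0 A), frozen from the closed forms:
#   kappa   = pi (3 p / (4 pi R^3))^(2/3)
#   V1      = 4/3 pi R^3                  (isolated-atom Gaussian volume)
#   VSELF   = p^2 (pi / (2 kappa))^(3/2)  (single-atom self density overlap)
KAPPA_SHAPE <- 0.811151794258
KAPPA_COLOR <- 2.34422868541
V_ATOM <- 20.5795262761
V_SELF_ATOM <- 19.6450954877
V_SELF_COLOR <- 3.99859464434

atom_conf <- function(xyz, cid = 1L, elements = NULL, features = NULL) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  if (is.null(elements)) elements <- rep("C", nrow(xyz))
  conformer(cid, xyz, elements, features)
}

single_atom <- function(cid = 1L, at = c(0, 0, 0)) atom_conf(at, cid)

# n-atom linear chain along x at given spacing
chain_conf <- function(n, spacing = 1.54, cid = 1L) {
  atom_conf(as.vector(t(cbind((seq_len(n) - 1) * spacing, 0, 0))), cid)
}

# conformer with one feature of each requested type placed on given atoms
with_features <- function(conf, ftype, atoms) {
  conf$features <- feature_points(ftype, members = as.list(atoms),
                                  atom_xyz = conf$xyz)
  conf
}

random_rigid <- function() {
  rigid_transform(combotan:::random_rotation(), rnorm(3, 0, 5))
}

# six-measure fake score table for statistics tests: every measure column
# gets the same values unless a named list overrides specific measures
fake_scores <- function(cid_a, cid_b, values, override = list()) {
  out <- data.frame(cid_a = cid_a, cid_b = cid_b)
  for (m in combotan:::MEASURES)
    out[[m]] <- if (!is.null(override[[m]])) override[[m]] else values
  out
}

# one-row per-assay stats frame with controllable NN-NI differences;
# stopt_diff / ctopt_diff override the two ComboT columns specifically
fake_stats_row <- function(aid, category, mu_diff = 0,
                           stopt_diff = mu_diff, ctopt_diff = mu_diff) {
  out <- data.frame(aid = as.integer(aid), category = category,
                    n_nn = 10L, n_ni = 10L)
  for (m in combotan:::MEASURES) {
    d <- switch(m, combo_stopt = stopt_diff, combo_ctopt = ctopt_diff,
                mu_diff)
    out[[paste0(m, "_mu_nn")]] <- 0.5 + d
    out[[paste0(m, "_sd_nn")]] <- 0.1
    out[[paste0(m, "_mu_ni")]] <- 0.5
    out[[paste0(m, "_sd_ni")]] <- 0.1
    out[[paste0(m, "_mu_diff")]] <- d
    out[[paste0(m, "_sd_diff")]] <- 0.1 * sqrt(2)
  }
  out
}
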