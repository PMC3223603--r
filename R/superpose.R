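# ---- starting poses -------------------------------------------------------

# Density-weighted centroid and principal-axis matrix (rows = axes,
# descending variance).  Sign convention: the largest-magnitude component of
# each of the first two axes is positive; the third axis is their cross
# product, so the frame is always right-handed and deterministic.
principal_frame <- function(conf, params = overlap_params()) {
  k <- shape_kappa(conf, params)
  v <- params$amplitude * (pi / k)^1.5
  ctr <- colSums(conf$xyz * v) / sum(v)
  if (nrow(conf$xyz) == 1L)
    return(list(center = ctr, axes = diag(3)))
  d <- sweep(conf$xyz, 2L, ctr)
  M <- crossprod(d * v, d)
  ev <- eigen(M, symmetric = TRUE)
  P <- t(ev$vectors)
  for (i in 1:2) {
    j <- which.max(abs(P[i, ]))
    if (P[i, j] < 0) P[i, ] <- -P[i, ]
  }
  P[3, ] <- c(P[1, 2] * P[2, 3] - P[1, 3] * P[2, 2],
              P[1, 3] * P[2, 1] - P[1, 1] * P[2, 3],
              P[1, 1] * P[2, 2] - P[1, 2] * P[2, 1])
  list(center = ctr, axes = P)
}

#' Principal (inertial) pose of a conformer
#'
#' The rigid transform that moves the density centroid to the origin and
#' the principal axes of the shape density onto x, y, z in descending
#' variance order.  Deterministic: axis signs follow a fixed convention and
#' a single atom maps to the identity rotation.
#'
#' @param conf A [conformer()].
#' @param params [overlap_params()].
#' @return A [rigid_transform()].
#' @export
principal_pose <- function(conf, params = overlap_params()) {
  fr <- principal_frame(conf, params)
  rigid_transform(fr$axes, as.numeric(-fr$axes %*% fr$center), check = FALSE)
}

# The four proper axis-flip start rotations in the joint principal frame.
START_FLIPS <- list(diag(3),
                    diag(c(1, -1, -1)),
                    diag(c(-1, 1, -1)),
                    diag(c(-1, -1, 1)))

# Start transforms placing B onto A through their joint principal frames.
shape_starts <- function(confA, confB, params) {
  fa <- principal_frame(confA, params)
  fb <- principal_frame(confB, params)
  lapply(START_FLIPS, function(Fk) {
    R <- t(fa$axes) %*% Fk %*% fb$axes
    rigid_transform(R, as.numeric(fa$center - R %*% fb$center), check = FALSE)
  })
}

# Extra color starts: for each feature type both conformers carry, take the
# identity-flip principal rotation and retranslate so that the two type-f
# feature centroids coincide.
color_starts <- function(confA, confB, params) {
  shared <- intersect(unique(confA$features$ftype), unique(confB$features$ftype))
  if (!length(shared)) return(list())
  fa <- principal_frame(confA, params)
  fb <- principal_frame(confB, params)
  R <- t(fa$axes) %*% fb$axes
  lapply(shared, function(f) {
    ca <- colMeans(feature_xyz(confA)[confA$features$ftype == f, , drop = FALSE])
    cb <- colMeans(feature_xyz(confB)[confB$features$ftype == f, , drop = FALSE])
    rigid_transform(R, as.numeric(ca - R %*% cb), check = FALSE)
  })
}

# ---- local optimization ---------------------------------------------------

# Overlap-maximization problem: Gaussian centres, widths and type labels of
# both conformers (type 0 = shape atoms; 1..6 = feature types).
shape_problem <- function(confA, confB, params) {
  list(ax = confA$xyz, ak = shape_kappa(confA, params),
       at = integer(nrow(confA$xyz)),
       bx = confB$xyz, bk = shape_kappa(confB, params),
       bt = integer(nrow(confB$xyz)),
       p2 = params$amplitude^2, skip = params$skip_log)
}

color_problem <- function(confA, confB, params) {
  kc <- kappa_from_radius(params$color_radius, params$color_amplitude)
  ax <- feature_xyz(confA); bx <- feature_xyz(confB)
  list(ax = ax, ak = rep(kc, nrow(ax)), at = feature_type_codes(confA),
       bx = bx, bk = rep(kc, nrow(bx)), bt = feature_type_codes(confB),
       p2 = params$color_amplitude^2, skip = params$skip_log)
}

problem_eval <- function(prob, w, R0, t, want_grad = FALSE) {
  overlap_value_grad_cpp(prob$ax, prob$ak, prob$at, prob$bx, prob$bk,
                         prob$bt, w, R0, t, prob$p2, prob$skip, want_grad)
}

# BFGS maximization (analytic gradient) from one start transform; the pose
# parameter is c(w, t) with rotation exp([w]) %*% start rotation.
polish_pose <- function(prob, start, maxit = 200) {
  R0 <- start$rotation
  fit <- optim(c(0, 0, 0, start$translation),
               fn = function(p) -problem_eval(prob, p[1:3], R0, p[4:6])$value,
               gr = function(p) -problem_eval(prob, p[1:3], R0, p[4:6],
                                              TRUE)$grad,
               method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  tf <- rigid_transform(rotation_from_vector(fit$par[1:3]) %*% R0,
                        fit$par[4:6], check = FALSE)
  list(transform = tf, value = -fit$value,
       converged = fit$convergence == 0L)
}

# Run the optimizer from every start; keep the best final pose (first start
# wins ties).  Monotonicity guard: the winner must be at least as good as
# the objective at every start pose.
best_pose <- function(prob, starts, maxit = 200) {
  stopifnot(length(starts) > 0L)
  fits <- lapply(starts, polish_pose, prob = prob, maxit = maxit)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.max(vals)]]
  start_vals <- vapply(starts, function(s)
    problem_eval(prob, c(0, 0, 0), s$rotation, s$translation)$value,
    numeric(1))
  best$value <- max(best$value, max(start_vals))
  best
}

# All three scores of a pair evaluated at one fixed pose.
score_at_pose <- function(confA, confB, tf, params) {
  st <- shape_tanimoto(confA, confB, tf, params)
  ct <- color_tanimoto(color_overlap(confA, confB, tf, params))
  st <- min(max(st, 0), 1)
  ct <- min(max(ct, 0), 1)
  list(st = st, ct = ct, combo = st + ct)
}

# ---- user-facing optimizers ----------------------------------------------

#' Shape-optimized superposition
#'
#' Maximizes the shape overlap volume `V_AB` over the six rigid degrees of
#' freedom, starting from the four proper axis-flip poses in the joint
#' principal frame, with BFGS local refinement.  All three scores are
#' evaluated at the returned (ST-optimal) pose, so the CT reported here is
#' the feature similarity at the shape alignment.
#'
#' @param confA,confB [conformer()] objects.
#' @param params [overlap_params()].
#' @param extra_starts Optional list of additional [rigid_transform()]
#'   starting poses.
#' @return List with `transform`, `st`, `ct`, `combo`, `objective` (final
#'   `V_AB`, A^3) and `converged`.
#' @export
optimize_shape <- function(confA, confB, params = overlap_params(),
                           extra_starts = list()) {
  starts <- c(shape_starts(confA, confB, params), extra_starts)
  fit <- best_pose(shape_problem(confA, confB, params), starts)
  c(score_at_pose(confA, confB, fit$transform, params),
    list(transform = fit$transform, objective = fit$value,
         converged = fit$converged))
}

#' Color-optimized superposition
#'
#' Maximizes the summed same-type feature overlap over the six rigid
#' degrees of freedom, from the shape starting poses plus one
#' feature-centroid-aligned start per shared feature type.  ST is evaluated
#' at the returned (CT-optimal) pose.  If either conformer has no features
#' the color objective is identically zero, so the ST-optimized pose is
#' returned with CT = 0.
#'
#' @inheritParams optimize_shape
#' @return As [optimize_shape()]; `objective` is the final summed color
#'   overlap (A^3), or the shape objective for the featureless fallback.
#' @export
optimize_color <- function(confA, confB, params = overlap_params(),
                           extra_starts = list()) {
  if (nrow(confA$features) == 0L || nrow(confB$features) == 0L)
    return(optimize_shape(confA, confB, params, extra_starts))
  starts <- c(shape_starts(confA, confB, params),
              color_starts(confA, confB, params), extra_starts)
  fit <- best_pose(color_problem(confA, confB, params), starts)
  c(score_at_pose(confA, confB, fit$transform, params),
    list(transform = fit$transform, objective = fit$value,
         converged = fit$converged))
}

#' Score one conformer pair under both optimizations
#'
#' Runs the ST-optimized and CT-optimized superpositions and assembles the
#' six similarity measures.  Each optimum's pose is offered to the other
#' optimizer as an additional start, which enforces the defining argmax
#' property (`st_stopt >= st_ctopt`, `ct_ctopt >= ct_stopt`) even when one
#' multi-start search alone would miss the better basin.  Inputs are
#' canonicalized to `cid_a < cid_b`, so scores are order-independent.
#'
#' @param confA,confB [conformer()] objects with distinct cids.
#' @param params [overlap_params()].
#' @return A one-row data frame of class `"similarity_record"`: `cid_a`,
#'   `cid_b`, the six scores, and the two optimal poses flattened as
#'   `stopt_r11..stopt_t3` / `ctopt_r11..ctopt_t3`.
#' @export
score_pair <- function(confA, confB, params = overlap_params()) {
  if (confA$cid == confB$cid) stop("self-pair: cids must differ")
  if (confA$cid > confB$cid) { tmp <- confA; confA <- confB; confB <- tmp }
  s <- optimize_shape(confA, confB, params)
  co <- if (nrow(confA$features) == 0L || nrow(confB$features) == 0L) s
        else optimize_color(confA, confB, params,
                            extra_starts = list(s$transform))
  # cross-seed the shape search with the color optimum: a single local
  # polish from the CT-optimal pose guards the argmax property
  if (!identical(co$transform, s$transform)) {
    s2 <- polish_pose(shape_problem(confA, confB, params), co$transform)
    if (s2$value > s$objective)
      s <- c(score_at_pose(confA, confB, s2$transform, params),
             list(transform = s2$transform, objective = s2$value,
                  converged = s2$converged))
  }
  rec <- data.frame(cid_a = confA$cid, cid_b = confB$cid,
                    st_stopt = s$st, ct_stopt = s$ct, combo_stopt = s$combo,
                    st_ctopt = co$st, ct_ctopt = co$ct, combo_ctopt = co$combo)
  rec <- cbind(rec, flatten_transform(s$transform, "stopt"),
               flatten_transform(co$transform, "ctopt"))
  class(rec) <- c("similarity_record", "data.frame")
  rec
}

flatten_transform <- function(tf, prefix) {
  vals <- c(t(tf$rotation), tf$translation)
  names(vals) <- paste0(prefix, "_", c("r11", "r12", "r13", "r21", "r22",
                                       "r23", "r31", "r32", "r33",
                                       "t1", "t2", "t3"))
  as.data.frame(as.list(vals))
}

# Rebuild a rigid_transform from score-table columns.
unflatten_transform <- function(row, prefix) {
  v <- as.numeric(row[paste0(prefix, "_", c("r11", "r12", "r13", "r21", "r22",
                                            "r23", "r31", "r32", "r33",
                                            "t1", "t2", "t3"))])
  rigid_transform(matrix(v[1:9], 3L, 3L, byrow = TRUE), v[10:12], check = FALSE)
}

#' Score all (or selected) conformer pairs
#'
#' @param conformers List of [conformer()] objects with unique cids.
#' @param pairs Optional two-column matrix or data frame of cid pairs to
#'   score; `NULL` scores every unordered pair once
#'   (`n (n - 1) / 2` records).
#' @param params [overlap_params()].
#' @param transforms Keep the pose columns in the output (default `TRUE`).
#' @return Data frame of similarity records, one row per unordered pair,
#'   keyed by `cid_a < cid_b`.
#' @export
score_matrix <- function(conformers, pairs = NULL, params = overlap_params(),
                         transforms = TRUE) {
  cids <- vapply(conformers, `[[`, integer(1), "cid")
  if (anyDuplicated(cids)) stop("duplicate cids in conformer set")
  by_cid <- setNames(conformers, as.character(cids))
  if (is.null(pairs)) {
    if (length(cids) < 2L) {
      return(empty_score_table(transforms))
    }
    pairs <- t(combn(sort(cids), 2L))
  } else {
    pairs <- as.matrix(pairs[, 1:2])
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pairs <- unique(pairs)
  }
  if (nrow(pairs) == 0L) return(empty_score_table(transforms))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    score_pair(by_cid[[as.character(pairs[i, 1])]],
               by_cid[[as.character(pairs[i, 2])]], params)
  })
  out <- do.call(rbind, rows)
  if (!transforms) out <- out[, c("cid_a", "cid_b", MEASURES)]
  rownames(out) <- NULL
  out
}

empty_score_table <- function(transforms = TRUE) {
  cols <- c("cid_a", "cid_b", MEASURES)
  tf_cols <- c(paste0("r", rep(1:3, each = 3), rep(1:3, 3)), paste0("t", 1:3))
  if (transforms)
    cols <- c(cols, paste0("stopt_", tf_cols), paste0("ctopt_", tf_cols))
  out <- as.data.frame(setNames(rep(list(numeric()), length(cols)), cols))
  out
}
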