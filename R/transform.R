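#' Rigid-body transform
#'
#' `x' = R x + t` with `R` a proper rotation (orthonormal, det +1).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation vector, Angstrom.
#' @param check Validate orthonormality and handedness (tolerance 1e-6).
#' @return An object of class `"rigid_transform"`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            check = TRUE) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (check) {
    if (!all(dim(rotation) == c(3L, 3L)) ||
        max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
        abs(det(rotation) - 1) > 1e-6)
      stop("rotation must be orthonormal with det +1")
    if (length(translation) != 3L) stop("translation must have length 3")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\nrotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 6), collapse = " "), "\n")
  invisible(x)
}

#' Apply a rigid transform
#'
#' @param tf A [rigid_transform()].
#' @param x An n x 3 coordinate matrix or a [conformer()]; for a conformer
#'   both atoms and feature points are moved.
#' @return Object of the same kind as `x`.
#' @export
apply_transform <- function(tf, x) {
  if (inherits(x, "conformer")) {
    x$xyz <- apply_transform(tf, x$xyz)
    if (nrow(x$features)) {
      fx <- apply_transform(tf, unname(as.matrix(x$features[, c("x", "y", "z")])))
      x$features$x <- fx[, 1]; x$features$y <- fx[, 2]; x$features$z <- fx[, 3]
    }
    return(x)
  }
  if (nrow(x) == 0L) return(x)
  sweep(x %*% t(tf$rotation), 2L, tf$translation, "+")
}

#' Compose rigid transforms
#'
#' Returns the transform applying `b` first, then `a`.
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation,
                  check = FALSE)
}

#' Invert a rigid transform
#' @param tf A [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, as.numeric(-rt %*% tf$translation), check = FALSE)
}

#' Rotation matrix from a rotation vector
#'
#' Rodrigues' formula; the vector's direction is the axis and its norm the
#' angle in radians.  Stable for small angles via series fallback.
#'
#' @param w Length-3 rotation vector.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_from_vector <- function(w) {
  theta <- sqrt(sum(w^2))
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3L, 3L)
  if (theta < 1e-8) return(diag(3) + K + 0.5 * K %*% K)
  diag(3) + (sin(theta) / theta) * K +
    ((1 - cos(theta)) / theta^2) * (K %*% K)
}

# Random proper rotation (uniform via QR of Gaussian matrix, det fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3L, 3L))
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d + (d == 0)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}
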