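#' Rigid (similarity) transform
#'
#' A rotation + translation (+ optional uniform scale) acting on 3D points as
#' `p' = scale * R p + t`. The rotation must be orthonormal with determinant
#' +1 (proper rotation, no reflection), checked to 1e-8.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric vector (cm).
#' @param scale Positive scalar, default 1.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0), scale = 1) {
  rotation <- as.matrix(rotation)
  if (!identical(dim(rotation), c(3L, 3L))) abort("`rotation` must be 3x3.")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    abort("`rotation` is not orthonormal (tolerance 1e-8).")
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    abort("`rotation` has determinant != +1 (reflection not allowed).")
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3 || !all(is.finite(translation))) {
    abort("`translation` must be a finite 3-vector.")
  }
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) || scale <= 0) {
    abort("`scale` must be a positive scalar.")
  }
  structure(list(rotation = rotation, translation = translation, scale = scale),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(round(x$translation, 6), collapse = ", "), "\n")
  if (x$scale != 1) cat("  scale:", x$scale, "\n")
  invisible(x)
}

#' Apply a rigid transform to a point cloud
#'
#' @param cloud A tibble with `x`, `y`, `z` (extra columns carried through).
#' @param transform A [rigid_transform()].
#' @return The transformed cloud as a tibble.
#' @export
apply_transform <- function(cloud, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- as_xyz_matrix(cloud)
  out <- transform$scale * (m %*% t(transform$rotation))
  out <- sweep(out, 2, transform$translation, "+")
  xyz_tibble(out, template = cloud)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` returns the transform equivalent to applying
#' `a` first, then `b`.
#'
#' @param b,a [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(
    rotation = b$rotation %*% a$rotation,
    translation = b$scale * as.numeric(b$rotation %*% a$translation) + b$translation,
    scale = b$scale * a$scale
  )
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  rotation_inv <- t(transform$rotation)
  rigid_transform(
    rotation = rotation_inv,
    translation = -as.numeric(rotation_inv %*% transform$translation) / transform$scale,
    scale = 1 / transform$scale
  )
}

#' Rotation matrix about a coordinate axis or arbitrary axis
#'
#' Convenience constructor used by tests and the synthetic generator.
#'
#' @param axis `"x"`, `"y"`, `"z"`, or a length-3 numeric axis vector.
#' @param angle Rotation angle in radians.
#' @return A 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
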