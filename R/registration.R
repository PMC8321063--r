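# PCA pre-alignment, cloud-to-mesh distances and ICP registration.

skewness <- function(v) {
  v <- v - mean(v)
  s <- sqrt(mean(v^2))
  if (s == 0) return(0)
  mean(v^3) / s^3
}

#' PCA pre-alignment of a point cloud
#'
#' Centres the cloud at its centroid and rotates it so that the principal
#' axes map, in decreasing-variance order, onto (Y, X, Z): a standing body's
#' long axis becomes vertical. The principal axes leave their signs
#' undetermined; signs are fixed so that the rotation is proper
#' (determinant +1) and the skewness of the Y coordinate is non-positive —
#' a standing body's legs are long and thin, so surface points thin out
#' towards the feet, giving the vertical coordinate a long lower tail when
#' the head is up. The X sign is then fixed by non-negative skewness (an
#' arbitrary but deterministic convention) and Z by the determinant. Use
#' `flip_y = TRUE` for subjects the heuristic turns upside down.
#'
#' @param cloud A tibble with `x`, `y`, `z`; at least 3 non-collinear points.
#' @param flip_y Flip the vertical axis after alignment (rotating 180
#'   degrees about Z to keep the transform proper).
#' @return A list with `cloud` (the aligned tibble, centroid at the origin)
#'   and `transform` (the [rigid_transform()] that reproduces it).
#' @export
pca_align <- function(cloud, flip_y = FALSE) {
  m <- as_xyz_matrix(cloud)
  if (nrow(m) < 3) abort("PCA alignment needs at least 3 points.")
  centroid <- colMeans(m)
  centred <- sweep(m, 2, centroid)
  cov_m <- crossprod(centred) / nrow(m)
  eig <- eigen(cov_m, symmetric = TRUE)
  if (eig$values[2] <= 1e-12 * max(eig$values[1], .Machine$double.eps)) {
    abort("Degenerate cloud: points are (near-)collinear, PCA axes undefined.")
  }
  if (eig$values[3] < 0) eig$values[3] <- 0
  # rows of R: new X <- PC2, new Y <- PC1 (largest variance), new Z <- PC3
  axis_y <- eig$vectors[, 1]
  axis_x <- eig$vectors[, 2]
  axis_z <- eig$vectors[, 3]
  if (skewness(centred %*% axis_y) > 0) axis_y <- -axis_y
  if (skewness(centred %*% axis_x) < 0) axis_x <- -axis_x
  rotation <- rbind(axis_x, axis_y, axis_z)
  if (det(rotation) < 0) rotation[3, ] <- -rotation[3, ]
  dimnames(rotation) <- NULL
  if (flip_y) rotation <- rotation_matrix("z", pi) %*% rotation
  transform <- rigid_transform(rotation, -as.numeric(rotation %*% centroid))
  list(cloud = apply_transform(cloud, transform), transform = transform)
}

#' Distance from a point to a triangle
#'
#' Euclidean distance from `p` to the closest point of the closed triangle
#' (interior, edge or vertex region).
#'
#' @param p Length-3 numeric vector.
#' @param tri 3x3 matrix, one vertex per row.
#' @return A list with `distance` (cm) and `closest` (the closest point).
#' @export
point_triangle_distance <- function(p, tri) {
  p <- as.numeric(p)
  tri <- as.matrix(tri)
  if (length(p) != 3 || !identical(dim(tri), c(3L, 3L))) {
    abort("`p` must be a 3-vector and `tri` a 3x3 matrix.")
  }
  e1 <- tri[2, ] - tri[1, ]
  e2 <- tri[3, ] - tri[1, ]
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  if (sqrt(sum(nrm^2)) <= 1e-12 * max(1, sum(abs(tri)))) {
    abort("Degenerate (zero-area) triangle.")
  }
  cpp_point_triangle(p, tri)
}

#' Unsigned distances from each cloud point to the nearest mesh triangle
#'
#' The workhorse of cloud-versus-mesh quality assessment: for every point the
#' minimum Euclidean distance over all mesh triangles. The default search
#' uses an axis-aligned bounding-box tree; `method = "brute"` scans every
#' triangle and is the reference the accelerated path must match exactly.
#'
#' @param cloud A tibble with `x`, `y`, `z`.
#' @param mesh A [triangle_mesh()].
#' @param method `"bvh"` (accelerated, default) or `"brute"` (exhaustive).
#' @param return_closest Also return the closest surface points.
#' @return A numeric vector of distances (cm), or if `return_closest` a list
#'   with `distance` and `closest` (n x 3 matrix).
#' @export
cloud_mesh_distances <- function(cloud, mesh, method = c("bvh", "brute"),
                                 return_closest = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(mesh, "triangle_mesh"))
  pts <- as_xyz_matrix(cloud)
  vm <- as_xyz_matrix(mesh$vertices, "vertices")
  if (nrow(mesh$faces) < 1) abort("Mesh has no faces.")
  res <- cpp_cloud_mesh(pts, vm, mesh$faces - 1L,
                        brute = method == "brute",
                        return_closest = return_closest)
  if (return_closest) res else res$distance
}

#' Registration error statistics from a set of unsigned distances
#'
#' Summarises cloud-to-mesh distances as the root mean square error, the
#' arithmetic mean distance and the population standard deviation, the three
#' statistics conventionally reported for point-cloud/mesh comparisons. The
#' population SD makes the identity `rmse^2 = mean^2 + sd^2` exact.
#'
#' @param distances Non-empty numeric vector of non-negative distances (cm).
#' @return A one-row tibble: `rmse`, `mean_distance`, `sd`, `n_points`.
#' @examples
#' registration_metrics(c(3, 4))
#' @export
registration_metrics <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) == 0) abort("`distances` is empty.")
  if (any(!is.finite(distances)) || any(distances < 0)) {
    abort("`distances` must be finite and non-negative.")
  }
  mean_d <- mean(distances)
  rmse <- sqrt(mean(distances^2))
  tibble::tibble(
    rmse = rmse,
    mean_distance = mean_d,
    sd = sqrt(max(0, mean(distances^2) - mean_d^2)),
    n_points = length(distances)
  )
}

#' Iterative closest point registration of a cloud to a mesh
#'
#' Rigidly aligns a source point cloud to a target triangle mesh by
#' alternating (i) closest-point correspondence — each source point is paired
#' with its nearest point on the mesh surface, not with a nearest vertex —
#' and (ii) the least-squares rigid update (Kabsch/SVD). With exact
#' correspondences the per-iteration correspondence RMSE is monotone
#' non-increasing; iteration stops when the improvement drops below
#' `convergence_tol` or after `max_iter` iterations. Scale is never
#' estimated: registration is rigid, and unit scaling is an explicit,
#' separate step ([scale_to_height()]).
#'
#' The source should be pre-aligned (e.g. by [pca_align()]); the basin of
#' reliable convergence for body-shaped clouds covers rotational offsets up
#' to roughly 30 degrees.
#'
#' @param source A tibble with `x`, `y`, `z`.
#' @param target A [triangle_mesh()].
#' @param max_iter Maximum iterations (default 50).
#' @param convergence_tol Minimum RMSE improvement (cm) to continue
#'   (default 1e-6).
#' @return An `icp_registration` object: `transform` (source -> target
#'   [rigid_transform()]), `report` (one-row tibble with `rmse`,
#'   `mean_distance`, `sd`, `n_points`, `iterations_run`, `converged`,
#'   computed on the transformed source via [cloud_mesh_distances()]),
#'   `rmse_history`, and `transformed` (the registered cloud).
#' @export
icp <- function(source, target, max_iter = 50, convergence_tol = 1e-6) {
  stopifnot(inherits(target, "triangle_mesh"))
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  src <- as_xyz_matrix(source, "source")
  vm <- as_xyz_matrix(target$vertices, "vertices")
  faces0 <- target$faces - 1L

  rot <- diag(3)
  trans <- c(0, 0, 0)
  rmse_history <- numeric(0)
  converged <- FALSE
  prev_rmse <- Inf

  for (it in seq_len(max_iter)) {
    cur <- sweep(src %*% t(rot), 2, trans, "+")
    corr <- cpp_cloud_mesh(cur, vm, faces0, brute = FALSE, return_closest = TRUE)
    rmse_it <- sqrt(mean(corr$distance^2))
    if (!is.finite(rmse_it)) {
      abort(sprintf("ICP produced a non-finite error at iteration %d.", it))
    }
    rmse_history <- c(rmse_history, rmse_it)
    if (prev_rmse - rmse_it < convergence_tol) {
      converged <- TRUE
      break
    }
    prev_rmse <- rmse_it
    # Kabsch update between current positions and their closest surface points
    cp <- corr$closest
    mu_p <- colMeans(cur)
    mu_c <- colMeans(cp)
    H <- crossprod(sweep(cur, 2, mu_p), sweep(cp, 2, mu_c))
    if (!all(is.finite(H))) {
      abort(sprintf("ICP produced a non-finite update at iteration %d.", it))
    }
    sv <- svd(H)
    d <- det(sv$v %*% t(sv$u))
    rot_d <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    t_d <- mu_c - as.numeric(rot_d %*% mu_p)
    rot <- rot_d %*% rot
    trans <- as.numeric(rot_d %*% trans) + t_d
  }

  transform <- rigid_transform(rot, trans)
  registered <- apply_transform(source, transform)
  final_dist <- cloud_mesh_distances(registered, target)
  report <- registration_metrics(final_dist) |>
    dplyr::mutate(iterations_run = length(rmse_history), converged = converged)
  structure(
    list(transform = transform, report = report,
         rmse_history = rmse_history, transformed = registered),
    class = "icp_registration"
  )
}

#' @export
print.icp_registration <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "ICP registration: %d points, %d iterations (%s)\n  RMSE %.4f cm | mean distance %.4f cm | SD %.4f cm\n",
    r$n_points, r$iterations_run,
    if (r$converged) "converged" else "max_iter reached",
    r$rmse, r$mean_distance, r$sd))
  invisible(x)
}
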