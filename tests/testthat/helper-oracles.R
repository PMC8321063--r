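# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# segmentation metrics by an explicit pixel-by-pixel loop
brute_mask_metrics <- function(pred, ref) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(ncol(ref))) {
      if (ref[i, j] && pred[i, j]) tp <- tp + 1L
      else if (!ref[i, j] && pred[i, j]) fp <- fp + 1L
      else if (ref[i, j] && !pred[i, j]) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  total <- tp + fp + fn + tn
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    hamming_loss = (fp + fn) / total,
    jaccard = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_,
    f_measure = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    accuracy = (tp + tn) / total,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    fnr = if (fn + tp > 0) fn / (fn + tp) else NA_real_
  )
}

# point-to-triangle distance by dense barycentric sampling
sampled_point_triangle <- function(p, tri, k = 250) {
  g <- expand.grid(u = seq(0, 1, length.out = k), v = seq(0, 1, length.out = k))
  g <- g[g$u + g$v <= 1, ]
  pts <- cbind(
    tri[1, 1] + g$u * (tri[2, 1] - tri[1, 1]) + g$v * (tri[3, 1] - tri[1, 1]),
    tri[1, 2] + g$u * (tri[2, 2] - tri[1, 2]) + g$v * (tri[3, 2] - tri[1, 2]),
    tri[1, 3] + g$u * (tri[2, 3] - tri[1, 3]) + g$v * (tri[3, 3] - tri[1, 3])
  )
  min(sqrt(colSums((t(pts) - p)^2)))
}

# exact ellipse perimeter via the complete elliptic integral of the 2nd kind
elliptic_perimeter <- function(a, b) {
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  4 * hi * pracma::ellipke(1 - (lo / hi)^2)$e
}

# a unit cube as a 12-triangle mesh (corner at origin)
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = 1
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = 1
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6)   # x = 1
  )
  triangle_mesh(v, f)
}

random_mesh <- function(n_tri, seed, spread = 10) {
  set.seed(seed)
  v <- matrix(runif(9 * n_tri, -spread, spread), ncol = 3)
  f <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
  triangle_mesh(v, f)
}

# hand-built slice profile for tie-break and argmin/argmax contracts
fake_profile <- function(y_center, perimeter, y_range, ok = TRUE) {
  df <- tibble::tibble(
    y_center = y_center, n_points = 100L, ok = ok, reason = NA_character_,
    a = perimeter / (2 * pi), b = perimeter / (2 * pi), angle = 0,
    center_x = 0, center_z = 0, perimeter = perimeter, fit_residual = 0
  )
  structure(df,
            mid_height_y = mean(y_range), total_height = diff(y_range),
            y_range = y_range, step = 1, thickness = 1, ramanujan_variant = 1,
            class = c("slice_profile", class(df)))
}

random_mask <- function(nr, nc, p = 0.5) matrix(runif(nr * nc) < p, nr, nc)
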