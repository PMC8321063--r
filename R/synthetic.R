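# Parametric synthetic body scans with known ground truth. A body is a
# single closed tube whose horizontal cross-section at height y is an
# ellipse with semi-axes (a(y), b(y)); a(y)/b(y) follow monotone cubic
# (Fritsch-Carlson) interpolation through control points, so profile extrema
# sit exactly at control points and the true hip/waist circumferences are
# known in closed form.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed) %% 2147483647L)
  force(code)
}

#' Parametric body profile template
#'
#' Builds a torso-like cross-section profile attaining a requested hip
#' circumference (the profile maximum, placed at 0.48 of total height, just
#' below mid-height) and waist circumference (the minimum above mid-height,
#' at 0.58). All cross-sections share one aspect ratio (default 1.35,
#' side-to-side wider than front-to-back, as human trunks are), so the
#' circumference profile is proportional to the semi-axis profile and the
#' requested circumferences are attained exactly at their control points.
#' An optional seed jitters the non-anchor control points (calves, thighs,
#' chest, shoulders) by a few percent to produce distinct subjects while
#' preserving the hip/waist ground truth.
#'
#' @param height_cm Total height (cm).
#' @param hip_circ_cm Target hip circumference (cm); profile maximum below
#'   mid-height.
#' @param waist_circ_cm Target waist circumference (cm); must not exceed
#'   `hip_circ_cm` (equality gives a cylindrical mid-section).
#' @param seed Optional integer for subject-to-subject shape jitter.
#' @param aspect_ratio Ratio of the larger to smaller cross-section
#'   semi-axis (default 1.35).
#' @return A `body_profile_spec` object: total height, control-point table
#'   (`y` cm, `a`, `b` cm, `rotation` radians) and the target
#'   circumferences.
#' @export
default_body_spec <- function(height_cm = 170, hip_circ_cm = 100,
                              waist_circ_cm = 85, seed = NULL,
                              aspect_ratio = 1.35) {
  if (height_cm <= 0 || hip_circ_cm <= 0 || waist_circ_cm <= 0) {
    abort("Height and circumferences must be positive.")
  }
  if (waist_circ_cm > hip_circ_cm) {
    abort("Infeasible pair: the default template requires waist <= hip circumference.")
  }
  if (aspect_ratio < 1) abort("`aspect_ratio` must be >= 1.")
  unit_perim <- ramanujan_perimeter(aspect_ratio, 1)
  t_hip <- hip_circ_cm / unit_perim   # semi-minor axis at the hip
  u <- waist_circ_cm / hip_circ_cm    # waist as a fraction of hip

  # relative semi-axis profile (1 = hip); anchors at hip (0.48) and waist
  # (0.58) are never jittered, and every control below mid-height stays
  # strictly under 1 so the hip remains the global maximum below mid-height
  template <- tibble::tibble(
    y_frac = c(0.00, 0.12, 0.30, 0.40, 0.48, 0.52, 0.58, 0.66,
               0.78, 0.86, 0.90, 0.95, 1.00),
    rel = c(0.42, 0.50, 0.72, 0.90, 1.00,
            u + 0.85 * (1 - u),           # upper hip shoulder of the curve
            u,                            # waist minimum
            u + 0.65 * (1 - u),
            min(0.96, u + 0.80 * (1 - u) + 0.16),  # chest
            0.60, 0.35, 0.50, 0.28),
    jitter_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  if (!is.null(seed)) {
    template <- with_seed(seed, {
      jit <- ifelse(template$jitter_ok, runif(nrow(template), 0.97, 1.03), 1)
      out <- template
      out$rel <- out$rel * jit
      # keep the hip the strict maximum below mid-height and the chest above
      # the waist
      out$rel[out$jitter_ok & out$y_frac < 0.5] <-
        pmin(out$rel[out$jitter_ok & out$y_frac < 0.5], 0.97)
      out
    })
  }
  control_points <- tibble::tibble(
    y = template$y_frac * height_cm,
    b = template$rel * t_hip,
    a = template$rel * t_hip * aspect_ratio,
    rotation = 0
  )
  structure(
    list(total_height = height_cm, control_points = control_points,
         aspect_ratio = aspect_ratio,
         hip_circ_cm = hip_circ_cm, waist_circ_cm = waist_circ_cm,
         hip_y_frac = 0.48, waist_y_frac = 0.58, seed = seed),
    class = "body_profile_spec"
  )
}

#' @export
print.body_profile_spec <- function(x, ...) {
  cat(sprintf(
    "Body profile spec: height %.1f cm, hip %.1f cm @ %.2f H, waist %.1f cm @ %.2f H (%d control points)\n",
    x$total_height, x$hip_circ_cm, x$hip_y_frac,
    x$waist_circ_cm, x$waist_y_frac, nrow(x$control_points)))
  invisible(x)
}

# Monotone cubic Hermite interpolation with Fritsch-Carlson slope limiting.
# Knot slopes are zero at local extrema and clamped into the [0, 3] x [0, 3]
# monotonicity box elsewhere, so the interpolant is monotone on every knot
# interval and profile extrema sit exactly at control points (stats'
# monoH.FC can over/undershoot by ~0.1% at non-monotone junctions, which
# would blur the generator's exact ground truth).
monotone_hermite <- function(xs, vs) {
  h <- diff(xs)
  s <- diff(vs) / h
  n <- length(xs)
  m <- numeric(n)
  m[1] <- s[1]
  m[n] <- s[n - 1]
  if (n > 2) {
    for (i in 2:(n - 1)) {
      m[i] <- if (s[i - 1] * s[i] <= 0) 0 else (s[i - 1] + s[i]) / 2
    }
  }
  for (i in seq_len(n - 1)) {      # clamp into the monotone box per interval
    if (s[i] == 0) {
      m[i] <- 0; m[i + 1] <- 0
    } else {
      for (j in c(i, i + 1)) {
        al <- m[j] / s[i]
        if (al < 0) m[j] <- 0 else if (al > 3) m[j] <- 3 * s[i]
      }
    }
  }
  function(y) {
    i <- pmin(pmax(findInterval(y, xs), 1L), n - 1L)
    t <- (y - xs[i]) / h[i]
    h00 <- (1 + 2 * t) * (1 - t)^2
    h10 <- t * (1 - t)^2
    h01 <- t^2 * (3 - 2 * t)
    h11 <- t^2 * (t - 1)
    h00 * vs[i] + h10 * h[i] * m[i] + h01 * vs[i + 1] + h11 * h[i] * m[i + 1]
  }
}

#' Interpolated cross-section parameters of a body spec
#'
#' Evaluates the monotone cubic interpolant of the semi-axis profile at
#' arbitrary heights. Monotone (shape-preserving) interpolation guarantees
#' the profile never over- or undershoots between control points, so the
#' hip/waist extrema are attained exactly at their control points.
#'
#' @param spec A [default_body_spec()] object.
#' @param y Heights in cm (within `[0, total_height]`).
#' @return A tibble with `y`, `a`, `b`, `rotation`.
#' @export
profile_semi_axes <- function(spec, y) {
  stopifnot(inherits(spec, "body_profile_spec"))
  cp <- spec$control_points
  fa <- monotone_hermite(cp$y, cp$a)
  fb <- monotone_hermite(cp$y, cp$b)
  fr <- stats::approxfun(cp$y, cp$rotation, rule = 2)
  tibble::tibble(y = y, a = fa(y), b = fb(y), rotation = fr(y))
}

#' Ground-truth circumference profile and hip/waist heights of a body spec
#'
#' Evaluates the Ramanujan perimeter of the interpolated cross-section on a
#' fine grid and extracts the true hip (perimeter maximum below mid-height)
#' and waist (minimum above mid-height, within the waist search band).
#'
#' @param spec A [default_body_spec()] object.
#' @param step Grid resolution in cm (default 0.1, i.e. 1 mm).
#' @param waist_band_hi Upper waist search bound as fraction of height.
#' @return A list: `table` (tibble `y`, `perimeter` at `step` resolution),
#'   `hip_y`, `hip_perimeter`, `waist_y`, `waist_perimeter`.
#' @export
synthetic_ground_truth <- function(spec, step = 0.1, waist_band_hi = 0.65) {
  h <- spec$total_height
  y <- seq(0, h, by = step)
  ax <- profile_semi_axes(spec, y)
  per <- ramanujan_perimeter(ax$a, ax$b)
  mid <- h / 2
  below <- which(y <= mid)
  hip_i <- below[which.max(per[below])]
  above <- which(y > mid & y <= waist_band_hi * h)
  waist_i <- above[which.min(per[above])]
  list(table = tibble::tibble(y = y, perimeter = per),
       hip_y = y[hip_i], hip_perimeter = per[hip_i],
       waist_y = y[waist_i], waist_perimeter = per[waist_i])
}

#' Triangulated surface mesh of a body spec
#'
#' Builds a watertight tube of stacked elliptical rings with fan-capped
#' ends; the stand-in for a clean structured-light (LiDAR-grade) scan.
#'
#' @param spec A [default_body_spec()] object.
#' @param n_rings Number of rings along the height (>= 2, default 100).
#' @param n_around Vertices per ring (>= 3, default 64).
#' @return A [triangle_mesh()] whose vertex y-range equals the total height.
#' @export
mesh_from_spec <- function(spec, n_rings = 100, n_around = 64) {
  stopifnot(inherits(spec, "body_profile_spec"))
  if (n_rings < 2 || n_around < 3) abort("Need n_rings >= 2 and n_around >= 3.")
  h <- spec$total_height
  ys <- seq(0, h, length.out = n_rings)
  ax <- profile_semi_axes(spec, ys)
  theta <- seq(0, 2 * pi, length.out = n_around + 1)[-(n_around + 1)]
  verts <- matrix(NA_real_, n_rings * n_around + 2, 3)
  for (i in seq_len(n_rings)) {
    u <- ax$a[i] * cos(theta)
    v <- ax$b[i] * sin(theta)
    phi <- ax$rotation[i]
    rows <- (i - 1) * n_around + seq_len(n_around)
    verts[rows, 1] <- u * cos(phi) - v * sin(phi)
    verts[rows, 2] <- ys[i]
    verts[rows, 3] <- u * sin(phi) + v * cos(phi)
  }
  bottom_c <- n_rings * n_around + 1L
  top_c <- n_rings * n_around + 2L
  verts[bottom_c, ] <- c(0, 0, 0)
  verts[top_c, ] <- c(0, h, 0)

  nxt <- c(seq_len(n_around)[-1], 1L)
  side <- do.call(rbind, lapply(seq_len(n_rings - 1), function(i) {
    lo <- (i - 1) * n_around
    hi <- i * n_around
    rbind(cbind(lo + seq_len(n_around), lo + nxt, hi + nxt),
          cbind(lo + seq_len(n_around), hi + nxt, hi + seq_len(n_around)))
  }))
  bottom <- cbind(bottom_c, nxt, seq_len(n_around))
  top_off <- (n_rings - 1) * n_around
  top <- cbind(top_c, top_off + seq_len(n_around), top_off + nxt)
  triangle_mesh(verts, rbind(side, bottom, top))
}

#' Sample a surface point cloud from a body spec or mesh
#'
#' Area-weighted uniform sampling of the mesh surface, optionally perturbed
#' by isotropic Gaussian noise — the stand-in for a clean (background-
#' masked) structure-from-motion reconstruction.
#'
#' @param x A [default_body_spec()] object or a [triangle_mesh()].
#' @param n_points Number of points (default 37000, the order of magnitude
#'   of a masked close-range SfM cloud).
#' @param noise_sigma_cm Isotropic Gaussian noise SD in cm (default 0.5).
#' @param seed Integer seed; the same seed reproduces the identical cloud.
#' @param ... Passed to [mesh_from_spec()] when `x` is a spec.
#' @return A tibble with `x`, `y`, `z`.
#' @export
sample_cloud <- function(x, n_points = 37000, noise_sigma_cm = 0.5,
                         seed = NULL, ...) {
  mesh <- if (inherits(x, "body_profile_spec")) mesh_from_spec(x, ...) else x
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (n_points < 1) abort("`n_points` must be >= 1.")
  if (noise_sigma_cm < 0) abort("`noise_sigma_cm` must be >= 0.")
  vm <- as_xyz_matrix(mesh$vertices, "vertices")
  f <- mesh$faces
  e1 <- vm[f[, 2], ] - vm[f[, 1], ]
  e2 <- vm[f[, 3], ] - vm[f[, 1], ]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areas <- sqrt(rowSums(cr^2)) / 2
  with_seed(seed, {
    fi <- sample.int(nrow(f), n_points, replace = TRUE, prob = areas)
    r1 <- runif(n_points)
    r2 <- runif(n_points)
    flip <- r1 + r2 > 1
    r1[flip] <- 1 - r1[flip]
    r2[flip] <- 1 - r2[flip]
    pts <- vm[f[fi, 1], ] + r1 * e1[fi, ] + r2 * e2[fi, ]
    if (noise_sigma_cm > 0) {
      pts <- pts + matrix(rnorm(3 * n_points, sd = noise_sigma_cm), ncol = 3)
    }
    xyz_tibble(pts)
  })
}

#' Contaminate a cloud with spurious background points
#'
#' Appends uniformly distributed points in an expanded bounding box of the
#' cloud, emulating the background debris that unmasked close-range SfM
#' reconstruction produces. With `fraction` f, the output contains
#' `f / (1 - f) * n` extra points, so f is the spurious share of the output.
#' The default fraction 0.84 reproduces the observed size ratio between raw
#' and background-masked reconstructions (roughly 6x).
#'
#' The default expansion is room-shaped rather than isotropic: walls and
#' furniture sit a couple of body-widths out horizontally while the ceiling
#' is close above the head (`c(4, 1.5, 4)` along x, y, z). This reproduces
#' the characteristic failure mode of measuring an unmasked reconstruction —
#' slice ellipses pulled far outward by high-leverage background points, so
#' circumference estimates grossly exceed the truth and degrade steadily as
#' contamination grows.
#'
#' @param cloud A tibble with `x`, `y`, `z`.
#' @param fraction Spurious fraction of the output, in `[0, 1)`.
#' @param bbox_expand Bounding-box expansion factors (all >= 1): a scalar or
#'   a length-3 vector `(x, y, z)`; default `c(4, 1.5, 4)`.
#' @param seed Integer seed.
#' @return A tibble with `x`, `y`, `z` and a logical `spurious` column
#'   flagging the added points (audit metadata; real pipelines do not get
#'   this flag).
#' @export
add_spurious <- function(cloud, fraction = 0.84, bbox_expand = c(4, 1.5, 4),
                         seed = NULL) {
  if (fraction < 0 || fraction >= 1) abort("`fraction` must lie in [0, 1).")
  if (length(bbox_expand) == 1) bbox_expand <- rep(bbox_expand, 3)
  if (length(bbox_expand) != 3 || any(bbox_expand < 1)) {
    abort("`bbox_expand` must be a scalar or 3-vector, all >= 1.")
  }
  m <- as_xyz_matrix(cloud)
  out <- xyz_tibble(m)
  out$spurious <- FALSE
  n_extra <- round(fraction / (1 - fraction) * nrow(m))
  if (n_extra == 0) return(out)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  ctr <- (lo + hi) / 2
  half <- (hi - lo) / 2 * bbox_expand
  extra <- with_seed(seed, {
    matrix(runif(3 * n_extra, -1, 1), ncol = 3) %*% diag(half) +
      matrix(ctr, n_extra, 3, byrow = TRUE)
  })
  extra_tb <- xyz_tibble(extra)
  extra_tb$spurious <- TRUE
  dplyr::bind_rows(out, extra_tb)
}

# ---- mask fixtures --------------------------------------------------------

shift_mask <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) + dr
  cs <- seq_len(ncol(m)) + dc
  ok_r <- rs >= 1 & rs <= nrow(m)
  ok_c <- cs >= 1 & cs <= ncol(m)
  out[rs[ok_r], cs[ok_c]] <- m[which(ok_r), which(ok_c)]
  out
}

dilate_mask <- function(m, k = 1) {
  for (i in seq_len(k)) {
    m <- m | shift_mask(m, 1, 0) | shift_mask(m, -1, 0) |
      shift_mask(m, 0, 1) | shift_mask(m, 0, -1)
  }
  m
}

erode_mask <- function(m, k = 1) !dilate_mask(!m, k)

#' Synthetic silhouette mask fixture
#'
#' Generates a human-silhouette-like reference mask (elliptical head and
#' torso), a degraded copy (boundary dilation/erosion plus salt-and-pepper
#' speckle of parameterised severity) standing in for an imperfect automatic
#' segmentation, and an RGB frame consistent with the mask.
#'
#' @param height_px,width_px Raster dimensions (default 120 x 90).
#' @param dilate,erode Boundary perturbation in pixels applied to the
#'   degraded mask.
#' @param speckle Per-pixel flip probability for the degraded mask.
#' @param seed Integer seed (speckle noise and frame texture).
#' @return A list with `reference` and `degraded` (binary masks) and
#'   `frame` (an `H x W x 3` integer array).
#' @export
make_mask_fixture <- function(height_px = 120, width_px = 90,
                              dilate = 0, erode = 0, speckle = 0,
                              seed = NULL) {
  if (height_px < 8 || width_px < 8) abort("Raster too small.")
  rr <- matrix(seq_len(height_px), height_px, width_px)
  cc <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
  in_ellipse <- function(r0, c0, ra, ca) {
    ((rr - r0) / ra)^2 + ((cc - c0) / ca)^2 <= 1
  }
  head_m <- in_ellipse(0.15 * height_px, 0.5 * width_px,
                       0.10 * height_px, 0.12 * width_px)
  torso <- in_ellipse(0.55 * height_px, 0.5 * width_px,
                      0.38 * height_px, 0.26 * width_px)
  reference <- head_m | torso

  degraded <- reference
  if (dilate > 0) degraded <- dilate_mask(degraded, dilate)
  if (erode > 0) degraded <- erode_mask(degraded, erode)
  frame_and_speckle <- with_seed(seed, {
    if (speckle > 0) {
      flips <- matrix(runif(height_px * width_px) < speckle, height_px, width_px)
      degraded <- xor(degraded, flips)
    }
    frame <- array(0L, c(height_px, width_px, 3))
    tex <- matrix(as.integer(round(runif(height_px * width_px, 90, 150))),
                  height_px, width_px)
    frame[, , 1] <- ifelse(reference, tex, 40L)
    frame[, , 2] <- ifelse(reference, tex - 20L, 40L)
    frame[, , 3] <- ifelse(reference, tex - 40L, 110L)
    list(degraded = degraded, frame = frame)
  })
  list(reference = reference, degraded = frame_and_speckle$degraded,
       frame = frame_and_speckle$frame)
}
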