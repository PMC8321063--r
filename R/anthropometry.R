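# Slice-based hip and waist circumference from an aligned body point cloud:
# scale to the measured height, cut 1-cm horizontal slices, fit each to an
# ellipse, evaluate the Ramanujan perimeter, then search the hip (largest
# perimeter slightly below mid-height) and the waist (above mid-height).

#' Scale a cloud uniformly so its vertical extent equals a measured height
#'
#' SfM clouds have arbitrary units; the measured standing height of the
#' subject anchors the metric scale. Scaling is uniform about the centroid
#' (the coordinate mean), so every circumference scales by the same factor.
#'
#' @param cloud A tibble with `x`, `y`, `z`, Y vertical.
#' @param measured_height_cm Positive height in cm.
#' @return A list with `cloud` (rescaled tibble) and `scale_factor`.
#' @export
scale_to_height <- function(cloud, measured_height_cm) {
  if (!is.numeric(measured_height_cm) || length(measured_height_cm) != 1 ||
      !is.finite(measured_height_cm) || measured_height_cm <= 0) {
    abort("`measured_height_cm` must be a positive scalar.")
  }
  m <- as_xyz_matrix(cloud)
  span <- max(m[, 2]) - min(m[, 2])
  if (span <= 0) abort("Cloud has zero vertical extent; cannot scale to height.")
  factor <- measured_height_cm / span
  centroid <- colMeans(m)
  out <- sweep(sweep(m, 2, centroid) * factor, 2, centroid, "+")
  list(cloud = xyz_tibble(out, template = cloud), scale_factor = factor)
}

#' Extract one horizontal slice of a cloud
#'
#' Returns the (x, z) projection of all points whose height lies within the
#' closed interval `y_center +/- thickness/2`.
#'
#' @param cloud A tibble with `x`, `y`, `z`.
#' @param y_center Slice centre height (cm).
#' @param thickness Slice thickness (cm), default 1.
#' @return A tibble with columns `x`, `z` (possibly empty).
#' @export
extract_slice <- function(cloud, y_center, thickness = 1) {
  if (thickness <= 0) abort("`thickness` must be positive.")
  m <- as_xyz_matrix(cloud)
  keep <- abs(m[, 2] - y_center) <= thickness / 2
  tibble::tibble(x = m[keep, 1], z = m[keep, 3])
}

#' Slice profile: per-slice ellipse fits along the vertical axis
#'
#' Cuts the cloud into horizontal slices at uniform `step` spacing across
#' `band`, fits each slice to an ellipse ([fit_ellipse()]) and computes its
#' Ramanujan perimeter. Slices with fewer than `min_points` points or a
#' failed/implausible fit are kept as flagged gaps (with the reason), never
#' as spurious fits.
#'
#' @param cloud A tibble with `x`, `y`, `z`, aligned (Y vertical) and scaled
#'   to metric units.
#' @param band Length-2 numeric `(y_lo, y_hi)` in cm; must lie within the
#'   cloud's vertical extent. Default: the full extent.
#' @param step Spacing between slice centres (cm), default 1.
#' @param thickness Slice thickness (cm), default 1.
#' @param min_points Minimum points for a fit (default 6).
#' @param ramanujan_variant Perimeter approximation variant (1 or 2).
#' @return A `slice_profile`: a tibble with one row per slice position
#'   (`y_center`, `n_points`, `ok`, `reason`, `a`, `b`, `angle`, `center_x`,
#'   `center_z`, `perimeter`, `fit_residual`) carrying attributes
#'   `mid_height_y`, `total_height`, `y_range`, `step`, `thickness`,
#'   `ramanujan_variant`.
#' @export
slice_profile <- function(cloud, band = NULL, step = 1, thickness = 1,
                          min_points = 6, ramanujan_variant = 1) {
  if (step <= 0 || thickness <= 0) abort("`step` and `thickness` must be positive.")
  m <- as_xyz_matrix(cloud)
  y_range <- range(m[, 2])
  if (is.null(band)) band <- y_range
  band <- as.numeric(band)
  if (length(band) != 2 || band[1] >= band[2]) abort("`band` must be (y_lo, y_hi).")
  tol <- 1e-9 * max(1, abs(y_range))
  if (band[1] < y_range[1] - tol || band[2] > y_range[2] + tol) {
    abort("`band` lies outside the cloud's vertical extent.")
  }
  centers <- seq(band[1], band[2], by = step)
  rows <- purrr::map_dfr(centers, function(yc) {
    keep <- abs(m[, 2] - yc) <= thickness / 2
    pts <- m[keep, c(1, 3), drop = FALSE]
    base <- tibble::tibble(
      y_center = yc, n_points = nrow(pts), ok = FALSE, reason = NA_character_,
      a = NA_real_, b = NA_real_, angle = NA_real_,
      center_x = NA_real_, center_z = NA_real_,
      perimeter = NA_real_, fit_residual = NA_real_
    )
    if (nrow(pts) < min_points) {
      base$reason <- sprintf("insufficient points (%d < %d)", nrow(pts), min_points)
      return(base)
    }
    fit <- tryCatch(fit_ellipse(pts), error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      base$reason <- fit
      return(base)
    }
    base$ok <- TRUE
    base$a <- fit$a; base$b <- fit$b; base$angle <- fit$angle
    base$center_x <- fit$center[1]; base$center_z <- fit$center[2]
    base$perimeter <- ramanujan_perimeter(fit$a, fit$b, variant = ramanujan_variant)
    base$fit_residual <- fit$fit_residual
    base
  })
  structure(
    rows,
    mid_height_y = mean(y_range),
    total_height = diff(y_range),
    y_range = y_range,
    step = step, thickness = thickness,
    ramanujan_variant = ramanujan_variant,
    class = c("slice_profile", class(rows))
  )
}

profile_attr <- function(profile, what) {
  v <- attr(profile, what, exact = TRUE)
  if (is.null(v)) abort("`profile` must be a slice_profile object.")
  v
}

#' Locate the hip slice
#'
#' The hip is taken, following anthropometric practice, as the region of
#' largest circumference slightly below the subject's middle height: among
#' valid slices with centre height in `[y_min + hip_band_lo * H,
#' mid_height]` the slice of maximum perimeter is returned, ties broken
#' towards the higher slice.
#'
#' @param profile A [slice_profile()].
#' @param hip_band_lo Lower bound of the search band as a fraction of total
#'   height (default 0.35).
#' @return The selected slice as a one-row tibble.
#' @export
find_hip <- function(profile, hip_band_lo = 0.35) {
  mid <- profile_attr(profile, "mid_height_y")
  y_range <- profile_attr(profile, "y_range")
  h <- profile_attr(profile, "total_height")
  lo <- y_range[1] + hip_band_lo * h
  cand <- dplyr::filter(profile, .data$ok, .data$y_center >= lo, .data$y_center <= mid)
  if (nrow(cand) == 0) {
    abort(sprintf("No valid slice in the hip band [%.1f, %.1f] cm.", lo, mid))
  }
  cand <- dplyr::arrange(cand, dplyr::desc(.data$perimeter), dplyr::desc(.data$y_center))
  tibble::as_tibble(cand[1, ])
}

#' Locate the waist slice given a reference measurement
#'
#' There is no consensus anatomical definition of the waist height; the rule
#' used here searches the slices above the subject's middle height (centre
#' height in `(mid_height, y_min + waist_band_hi * H]`) for the one whose
#' fitted perimeter is closest to the anthropometrist's tape measurement.
#' Ties are broken towards the lower slice. Note that this rule consumes the
#' reference value; for a reference-free estimate use
#' [find_waist_unsupervised()].
#'
#' @param profile A [slice_profile()].
#' @param reference_waist_cm Positive reference circumference (cm).
#' @param waist_band_hi Upper bound of the search band as a fraction of
#'   total height (default 0.65).
#' @return The selected slice as a one-row tibble.
#' @export
find_waist <- function(profile, reference_waist_cm, waist_band_hi = 0.65) {
  if (!is.numeric(reference_waist_cm) || reference_waist_cm <= 0) {
    abort("`reference_waist_cm` must be positive.")
  }
  cand <- waist_candidates(profile, waist_band_hi)
  cand <- dplyr::arrange(cand, abs(.data$perimeter - reference_waist_cm), .data$y_center)
  tibble::as_tibble(cand[1, ])
}

#' Locate the waist slice without a reference
#'
#' Reference-free alternative: returns the minimum-perimeter slice in the
#' waist band (the natural waist of an hourglass profile), ties broken
#' towards the lower slice.
#'
#' @inheritParams find_waist
#' @return The selected slice as a one-row tibble.
#' @export
find_waist_unsupervised <- function(profile, waist_band_hi = 0.65) {
  cand <- waist_candidates(profile, waist_band_hi)
  cand <- dplyr::arrange(cand, .data$perimeter, .data$y_center)
  tibble::as_tibble(cand[1, ])
}

waist_candidates <- function(profile, waist_band_hi) {
  mid <- profile_attr(profile, "mid_height_y")
  y_range <- profile_attr(profile, "y_range")
  h <- profile_attr(profile, "total_height")
  hi <- y_range[1] + waist_band_hi * h
  cand <- dplyr::filter(profile, .data$ok, .data$y_center > mid, .data$y_center <= hi)
  if (nrow(cand) == 0) {
    abort(sprintf("No valid slice in the waist band (%.1f, %.1f] cm.", mid, hi))
  }
  cand
}

#' Measure hip and waist circumference of a body point cloud
#'
#' End-to-end measurement: scales the cloud so its vertical extent equals the
#' measured height ([scale_to_height()]), builds the slice/ellipse profile
#' over the hip-to-waist search region ([slice_profile()]), and locates the
#' hip ([find_hip()]) and waist ([find_waist()] when a reference value is
#' supplied, otherwise [find_waist_unsupervised()]). All intermediate slices
#' are kept in the result for audit.
#'
#' The cloud must already be aligned with Y vertical (see [pca_align()]).
#'
#' @param cloud A tibble with `x`, `y`, `z`.
#' @param measured_height_cm The subject's measured standing height (cm).
#' @param reference_waist_cm Optional anthropometrist waist measurement (cm);
#'   selects the supervised waist rule.
#' @param hip_band,waist_band Search bands as fractions of total height;
#'   defaults `c(0.35, 0.50)` and `c(0.50, 0.65)`.
#' @param slice_step,slice_thickness Slice spacing and thickness in cm
#'   (default 1 and 1).
#' @param ramanujan_variant Perimeter approximation variant (1 or 2).
#' @return A `body_measurement` object; `glance()` gives the one-row summary
#'   (`hip_perimeter`, `hip_y`, `waist_perimeter`, `waist_y`,
#'   `scale_factor`, `waist_mode`), `tidy()` the per-slice table.
#' @export
measure_body <- function(cloud, measured_height_cm, reference_waist_cm = NULL,
                         hip_band = c(0.35, 0.50), waist_band = c(0.50, 0.65),
                         slice_step = 1, slice_thickness = 1,
                         ramanujan_variant = 1) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  scaled <- stage("scale_to_height", scale_to_height(cloud, measured_height_cm))
  m <- as_xyz_matrix(scaled$cloud)
  y_range <- range(m[, 2])
  h <- diff(y_range)
  band <- c(y_range[1] + hip_band[1] * h, y_range[1] + waist_band[2] * h)
  profile <- stage("slice_profile",
                   slice_profile(scaled$cloud, band = band, step = slice_step,
                                 thickness = slice_thickness,
                                 ramanujan_variant = ramanujan_variant))
  # the profile band covers hip-to-waist only; the mid-height reference must
  # come from the whole cloud, which it does (slice_profile stores the cloud
  # extent, not the band)
  hip <- stage("find_hip", find_hip(profile, hip_band_lo = hip_band[1]))
  supervised <- !is.null(reference_waist_cm)
  waist <- stage("find_waist", if (supervised) {
    find_waist(profile, reference_waist_cm, waist_band_hi = waist_band[2])
  } else {
    find_waist_unsupervised(profile, waist_band_hi = waist_band[2])
  })
  measurements <- tibble::tibble(
    hip_perimeter = hip$perimeter, hip_y = hip$y_center,
    waist_perimeter = waist$perimeter, waist_y = waist$y_center,
    scale_factor = scaled$scale_factor,
    waist_mode = if (supervised) "reference" else "unsupervised"
  )
  structure(
    list(measurements = measurements, profile = profile,
         hip_slice = hip, waist_slice = waist,
         settings = list(measured_height_cm = measured_height_cm,
                         reference_waist_cm = reference_waist_cm,
                         hip_band = hip_band, waist_band = waist_band,
                         slice_step = slice_step,
                         slice_thickness = slice_thickness,
                         ramanujan_variant = ramanujan_variant)),
    class = "body_measurement"
  )
}

#' @export
print.body_measurement <- function(x, ...) {
  msr <- x$measurements
  cat(sprintf(
    "Body measurement (waist rule: %s)\n  hip:   %.2f cm at y = %.1f cm\n  waist: %.2f cm at y = %.1f cm\n  scale factor: %.4g\n",
    msr$waist_mode, msr$hip_perimeter, msr$hip_y,
    msr$waist_perimeter, msr$waist_y, msr$scale_factor))
  invisible(x)
}
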