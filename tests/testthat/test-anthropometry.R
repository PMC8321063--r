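test_that("ramanujan_perimeter matches the circle limit and the elliptic integral", {
  for (r in c(0.5, 1, 13, 40)) {
    expect_equal(ramanujan_perimeter(r, r), 2 * pi * r)
    expect_equal(ramanujan_perimeter(r, r, variant = 2), 2 * pi * r)
  }
  expect_equal(ramanujan_perimeter(3, 2), pi * (15 - sqrt(99)))
  expect_equal(ramanujan_perimeter(3, 2), elliptic_perimeter(3, 2),
               tolerance = 1e-4)
  # waist-scale axes: essentially exact
  expect_equal(ramanujan_perimeter(40, 30), elliptic_perimeter(40, 30),
               tolerance = 1e-6)

  # relative error <= 1e-4 across the body-slice aspect-ratio range
  for (ba in seq(0.3, 1, by = 0.05)) {
    p1 <- ramanujan_perimeter(10, 10 * ba)
    p2 <- ramanujan_perimeter(10, 10 * ba, variant = 2)
    truth <- elliptic_perimeter(10, 10 * ba)
    expect_lt(abs(p1 - truth) / truth, 1e-4)
    expect_lt(abs(p2 - truth) / truth, 1e-4)
  }
  expect_error(ramanujan_perimeter(0, 1), "positive")
  expect_error(ramanujan_perimeter(3, -2), "positive")
})

test_that("fit_ellipse recovers exact samples to 1e-6 over shapes and poses", {
  cases <- expand.grid(a = c(2, 10, 25), ba = c(0.3, 0.6, 0.95),
                       ang = c(0, pi / 6, 1.2, 2.9))
  for (i in seq_len(nrow(cases))) {
    a <- cases$a[i]; b <- a * cases$ba[i]; ang <- cases$ang[i]
    pts <- ellipse_points(200, a, b, center = c(1, -2), angle = ang)
    fit <- fit_ellipse(pts)
    expect_equal(fit$a, a, tolerance = 1e-6)
    expect_equal(fit$b, b, tolerance = 1e-6)
    expect_equal(fit$center, c(1, -2), tolerance = 1e-6)
    expect_equal(sin(2 * (fit$angle - ang)), 0, tolerance = 1e-6)
    expect_lt(fit$fit_residual, 1e-8)
  }

  # circle: a = b = r, any rotation angle accepted
  circ <- fit_ellipse(ellipse_points(100, 7, 7))
  expect_equal(circ$a, 7, tolerance = 1e-8)
  expect_equal(circ$b, 7, tolerance = 1e-8)
})

test_that("fit_ellipse under isotropic noise recovers parameters statistically", {
  set.seed(99)
  pts <- ellipse_points(400, 10, 5, center = c(1, 2), angle = pi / 6)
  noisy <- pts + matrix(rnorm(800, sd = 0.1), ncol = 2)
  fit <- fit_ellipse(noisy)
  expect_equal(fit$a, 10, tolerance = 0.1)
  expect_equal(fit$b, 5, tolerance = 0.1)
  expect_equal(fit$center, c(1, 2), tolerance = 0.1)
  expect_equal(fit$angle, pi / 6, tolerance = 0.05)

  # the constrained fit returns an ellipse even for short noisy arcs
  arc <- ellipse_points(60, 10, 5, theta = seq(0.2, 1.8, length.out = 60)) +
    matrix(rnorm(120, sd = 0.05), ncol = 2)
  expect_s3_class(fit_ellipse(arc), "ellipse_fit")

  expect_error(fit_ellipse(ellipse_points(5, 3, 2)), "at least 6")
  expect_error(fit_ellipse(cbind(1:10, 2 * (1:10) + 3)), "collinear")
})

test_that("scale_to_height rescales uniformly about the centroid", {
  cloud <- tibble::tibble(x = c(0, 0.1, -0.1), y = c(0, 0.5, 1), z = c(0, 0, 0))
  sc <- scale_to_height(cloud, 170)
  expect_equal(sc$scale_factor, 170)
  expect_equal(diff(range(sc$cloud$y)), 170)

  sc2 <- scale_to_height(sc$cloud, 170)
  expect_equal(sc2$scale_factor, 1)
  expect_equal(as.matrix(sc2$cloud), as.matrix(sc$cloud))

  flat <- tibble::tibble(x = 1:5, y = rep(2, 5), z = 1:5)
  expect_error(scale_to_height(flat, 170), "zero vertical extent")
  expect_error(scale_to_height(cloud, -1), "positive")
})

test_that("scaling a body scales every slice perimeter by the same factor", {
  spec <- default_body_spec(170, 100, 85)
  cl <- sample_cloud(spec, 20000, 0, seed = 3)
  prof1 <- slice_profile(cl, band = c(60, 110), step = 5)
  doubled <- tibble::tibble(x = cl$x * 2, y = cl$y * 2, z = cl$z * 2)
  prof2 <- slice_profile(doubled, band = c(120, 220), step = 10, thickness = 2)
  ok <- prof1$ok & prof2$ok
  expect_equal(prof2$perimeter[ok], 2 * prof1$perimeter[ok], tolerance = 1e-9)
})

test_that("extract_slice uses a closed membership interval", {
  cloud <- tibble::tibble(x = 1:3, y = c(0, 0.5, 2), z = 4:6)
  s <- extract_slice(cloud, y_center = 0, thickness = 1)
  expect_equal(s$x, c(1, 2))          # y = 0.5 sits exactly on the boundary
  expect_equal(nrow(extract_slice(cloud, 10, 1)), 0)
  expect_error(extract_slice(cloud, 0, -1), "positive")
})

test_that("slice_profile fits real slices and flags unsupported ones", {
  spec <- default_body_spec(170, 100, 85)
  truth <- synthetic_ground_truth(spec)
  cl <- sample_cloud(spec, 50000, 0, seed = 17)
  prof <- slice_profile(cl, band = c(55, 110), step = 1)

  expect_true(all(diff(prof$y_center) == 1))
  expect_true(all(prof$ok))
  per_true <- vapply(prof$y_center, function(y) {
    truth$table$perimeter[which.min(abs(truth$table$y - y))]
  }, 1)
  expect_lt(max(abs(prof$perimeter - per_true) / per_true), 0.02)

  # a vertical gap between two clusters must come back flagged, not fitted
  gap_cloud <- dplyr::bind_rows(
    dplyr::filter(cl, y < 70), dplyr::filter(cl, y > 90))
  gp <- slice_profile(gap_cloud, band = c(60, 100), step = 5)
  gap_rows <- dplyr::filter(gp, y_center > 72, y_center < 88)
  expect_true(all(!gap_rows$ok))
  expect_true(all(grepl("insufficient", gap_rows$reason)))

  expect_error(slice_profile(cl, band = c(-50, 500)), "outside")
})

test_that("find_hip takes the in-band perimeter maximum with upward tie-break", {
  prof <- fake_profile(y_center = seq(55, 110, by = 5),
                       perimeter = c(80, 85, 90, 95, 100, 96, 88, 84, 86, 90, 92, 95),
                       y_range = c(0, 170))
  hip <- find_hip(prof)           # band [59.5, 85]
  expect_equal(hip$y_center, 75)  # global max 100 inside band
  expect_equal(hip$perimeter, 100)

  # two equal maxima: the higher slice wins
  prof2 <- fake_profile(seq(60, 85, by = 5), c(90, 99, 95, 99, 90, 85), c(0, 170))
  expect_equal(find_hip(prof2)$y_center, 75)

  # strictly decreasing perimeters below mid-height: bottom band slice wins
  prof3 <- fake_profile(seq(60, 85, by = 5), c(100, 98, 96, 94, 92, 90), c(0, 170))
  expect_equal(find_hip(prof3)$y_center, 60)

  none <- fake_profile(c(60, 70), c(90, 95), c(0, 170), ok = FALSE)
  expect_error(find_hip(none), "No valid slice")
})

test_that("find_waist honours the reference and its documented tie-breaks", {
  prof <- fake_profile(seq(86, 110, by = 2),
                       c(95, 92, 88, 85, 83, 82, 84, 87, 90, 93, 96, 99, 102),
                       c(0, 170))
  # band (85, 110.5]; reference equal to one slice's perimeter -> that slice
  w <- find_waist(prof, 84)
  expect_equal(w$perimeter, 84)
  expect_equal(w$y_center, 98)

  # reference far below all perimeters -> global band minimum
  expect_equal(find_waist(prof, 10)$perimeter, 82)

  # tie (83 at y=94 matches as well as 85 at y=92 for ref 84): lower slice wins
  w2 <- find_waist(prof, 84.0)
  expect_equal(w2$y_center, 98)
  tie <- fake_profile(c(90, 100), c(84, 84), c(0, 170))
  expect_equal(find_waist(tie, 84)$y_center, 90)

  # unsupervised: minimum-perimeter slice; constant profile -> lowest slice
  expect_equal(find_waist_unsupervised(prof)$perimeter, 82)
  flatp <- fake_profile(seq(90, 106, by = 4), rep(88, 5), c(0, 170))
  expect_equal(find_waist_unsupervised(flatp)$y_center, 90)

  expect_error(find_waist(prof, -3), "positive")
})

test_that("measure_body recovers a clean synthetic subject end to end", {
  spec <- default_body_spec(172, 104, 88, seed = 6)
  truth <- synthetic_ground_truth(spec)
  cl <- sample_cloud(spec, 40000, 0.5, seed = 7)

  mb <- measure_body(cl, 172, reference_waist_cm = truth$waist_perimeter)
  g <- glance(mb)
  expect_lt(abs(g$hip_perimeter - truth$hip_perimeter) / truth$hip_perimeter, 0.02)
  expect_lt(abs(g$waist_perimeter - truth$waist_perimeter) / truth$waist_perimeter, 0.02)
  # the profile is deliberately flat around the hip, so noise can move the
  # argmax a slice or two; the noise-free cloud pins it down tightly
  expect_lt(abs(g$hip_y - truth$hip_y), 2.5)
  expect_lt(g$hip_y, g$waist_y)

  exact <- glance(measure_body(sample_cloud(spec, 40000, 0, seed = 8), 172,
                               reference_waist_cm = truth$waist_perimeter))
  expect_lt(abs(exact$hip_y - truth$hip_y), 1)
  expect_lt(abs(exact$waist_y - truth$waist_y), 1)

  unsup <- glance(measure_body(cl, 172))
  expect_equal(unsup$waist_mode, "unsupervised")
  expect_lt(abs(unsup$waist_perimeter - truth$waist_perimeter) /
              truth$waist_perimeter, 0.02)

  # audit trail: the full slice table is retained
  expect_gt(nrow(tidy(mb)), 20)
})

test_that("measure_body is invariant to pre-scaling and to rigid motion + pca_align", {
  spec <- default_body_spec(168, 101, 86, seed = 9)
  truth <- synthetic_ground_truth(spec)
  cl <- sample_cloud(spec, 25000, 0.5, seed = 10)
  base <- glance(measure_body(cl, 168, truth$waist_perimeter))

  doubled <- tibble::tibble(x = 2 * cl$x, y = 2 * cl$y, z = 2 * cl$z)
  dd <- glance(measure_body(doubled, 168, truth$waist_perimeter))
  expect_equal(dd$hip_perimeter, base$hip_perimeter, tolerance = 1e-9)
  expect_equal(dd$waist_perimeter, base$waist_perimeter, tolerance = 1e-9)

  moved <- apply_transform(cl, rigid_transform(
    rotation_matrix(c(0.3, 1, 0.7), 0.6), c(40, -10, 25)))
  realigned <- pca_align(moved)$cloud
  rr <- glance(measure_body(realigned, 168, truth$waist_perimeter))
  expect_equal(rr$hip_perimeter, base$hip_perimeter, tolerance = 0.02)
  expect_equal(rr$waist_perimeter, base$waist_perimeter, tolerance = 0.02)
})

test_that("unmasked contamination degrades measurements by an order of magnitude", {
  spec <- default_body_spec(170, 100, 85, seed = 12)
  truth <- synthetic_ground_truth(spec)
  cl <- sample_cloud(spec, 20000, 0.5, seed = 12)
  clean <- glance(measure_body(cl, 170, truth$waist_perimeter))
  err_clean <- abs(clean$hip_perimeter - truth$hip_perimeter) +
    abs(clean$waist_perimeter - truth$waist_perimeter)

  raw <- add_spurious(cl, 0.3, seed = 13)
  contaminated <- glance(measure_body(dplyr::select(raw, "x", "y", "z"),
                                      170, truth$waist_perimeter))
  err_raw <- abs(contaminated$hip_perimeter - truth$hip_perimeter) +
    abs(contaminated$waist_perimeter - truth$waist_perimeter)
  expect_gt(err_raw, 10 * err_clean)
})

test_that("stage errors carry the failing stage's name", {
  flat <- tibble::tibble(x = rnorm(10), y = rep(1, 10), z = rnorm(10))
  expect_error(measure_body(flat, 170), "\\[scale_to_height\\]")
})
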