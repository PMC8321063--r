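test_that("default_body_spec attains the requested hip and waist circumferences", {
  grid <- expand.grid(h = c(155, 170, 190), hip = c(90, 105, 120),
                      whr = c(0.7, 0.85, 0.95))
  for (i in seq_len(nrow(grid))) {
    spec <- default_body_spec(grid$h[i], grid$hip[i], grid$hip[i] * grid$whr[i])
    gt <- synthetic_ground_truth(spec)
    expect_lt(abs(gt$hip_perimeter - grid$hip[i]), 0.1)
    expect_lt(abs(gt$waist_perimeter - grid$hip[i] * grid$whr[i]), 0.1)
    expect_equal(gt$hip_y, 0.48 * grid$h[i], tolerance = 0.01)
    expect_equal(gt$waist_y, 0.58 * grid$h[i], tolerance = 0.01)
    expect_lt(gt$hip_y, grid$h[i] / 2)
    expect_gt(gt$waist_y, grid$h[i] / 2)
  }

  # jitter keeps the anchors intact
  for (s in 1:5) {
    spec <- default_body_spec(168, 100, 82, seed = s)
    gt <- synthetic_ground_truth(spec)
    expect_lt(abs(gt$hip_perimeter - 100), 0.1)
    expect_lt(abs(gt$waist_perimeter - 82), 0.1)
  }

  # hip = waist is a valid degenerate (cylindrical mid-section) spec
  cyl <- default_body_spec(170, 95, 95)
  gtc <- synthetic_ground_truth(cyl)
  expect_lt(abs(gtc$hip_perimeter - 95), 0.1)
  expect_lt(abs(gtc$waist_perimeter - 95), 0.1)

  expect_error(default_body_spec(170, 90, 100), "Infeasible")
  expect_error(default_body_spec(-170, 90, 80), "positive")

  expect_identical(default_body_spec(170, 100, 85, seed = 7),
                   default_body_spec(170, 100, 85, seed = 7))
})

test_that("ground-truth table is consistent with the Ramanujan perimeter at knots", {
  spec <- default_body_spec(170, 100, 85, seed = 2)
  cp <- spec$control_points
  gt <- synthetic_ground_truth(spec, step = 0.1)
  for (i in seq_len(nrow(cp))) {
    j <- which.min(abs(gt$table$y - cp$y[i]))
    if (abs(gt$table$y[j] - cp$y[i]) < 1e-9) {
      expect_equal(gt$table$perimeter[j],
                   ramanujan_perimeter(cp$a[i], cp$b[i]))
    }
  }
})

test_that("mesh_from_spec builds a closed watertight tube with exact rings", {
  spec <- default_body_spec(170, 100, 85)
  mesh <- mesh_from_spec(spec, n_rings = 20, n_around = 16)
  v <- as.matrix(mesh$vertices)
  f <- mesh$faces

  expect_true(all(f >= 1 & f <= nrow(v)))
  expect_equal(diff(range(v[, 2])), 170)

  # Euler characteristic of a closed surface: V - E + F = 2
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- unique(t(apply(edges, 1, sort)))
  expect_equal(nrow(v) - nrow(edges) + nrow(f), 2)
  # watertight: every edge shared by exactly two triangles
  all_edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(all_edges[, 1], all_edges[, 2]),
               pmax(all_edges[, 1], all_edges[, 2]))
  expect_true(all(table(key) == 2))

  # ring cross-sections lie exactly on the interpolated ellipse
  ys <- seq(0, 170, length.out = 20)
  ax <- profile_semi_axes(spec, ys)
  for (i in c(3, 10, 17)) {
    ring <- v[(i - 1) * 16 + 1:16, ]
    r2 <- (ring[, 1] / ax$a[i])^2 + (ring[, 3] / ax$b[i])^2
    expect_equal(r2, rep(1, 16), tolerance = 1e-6)
    expect_equal(ring[, 2], rep(ys[i], 16))
  }
  expect_error(mesh_from_spec(spec, 1, 16), "n_rings")
})

test_that("a cylindrical spec has constant ring perimeter and closed-form area", {
  cyl <- default_body_spec(100, 80, 80)
  band <- profile_semi_axes(cyl, seq(48, 58, 0.5))  # cylindrical mid-section
  expect_equal(ramanujan_perimeter(band$a, band$b), rep(80, 21), tolerance = 1e-9)

  # full closed-form check on a true cylinder built directly from control points
  r <- 10; h <- 50
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  n_rings <- 30
  verts <- do.call(rbind, lapply(seq(0, h, length.out = n_rings), function(y) {
    cbind(r * cos(theta), y, r * sin(theta))
  }))
  spec_cyl <- structure(
    list(total_height = h,
         control_points = tibble::tibble(y = c(0, h), a = c(r, r), b = c(r, r),
                                         rotation = c(0, 0)),
         aspect_ratio = 1, hip_circ_cm = 2 * pi * r, waist_circ_cm = 2 * pi * r,
         hip_y_frac = 0.48, waist_y_frac = 0.58, seed = NULL),
    class = "body_profile_spec")
  mesh <- mesh_from_spec(spec_cyl, n_rings = 60, n_around = 96)
  v <- as.matrix(mesh$vertices)
  f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  area <- sum(sqrt(rowSums(cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2)) / 2)
  expect_equal(area, 2 * pi * r * h + 2 * pi * r^2, tolerance = 0.01)
})

test_that("sample_cloud lies on the surface at sigma = 0 and is seed-deterministic", {
  spec <- default_body_spec(170, 100, 85)
  mesh <- mesh_from_spec(spec, 40, 32)
  cl <- sample_cloud(mesh, 2000, 0, seed = 5)
  expect_lt(max(cloud_mesh_distances(cl, mesh)), 1e-9)

  expect_identical(sample_cloud(mesh, 500, 0.5, seed = 9),
                   sample_cloud(mesh, 500, 0.5, seed = 9))
  expect_false(identical(sample_cloud(mesh, 500, 0.5, seed = 9),
                         sample_cloud(mesh, 500, 0.5, seed = 10)))
})

test_that("noisy sampling reproduces the half-normal mean distance on a plane", {
  big <- triangle_mesh(rbind(c(-100, 0, -100), c(100, 0, -100),
                             c(100, 0, 100), c(-100, 0, 100)),
                       rbind(c(1, 2, 3), c(1, 3, 4)))
  sigma <- 0.5
  cl <- sample_cloud(big, 50000, sigma, seed = 20)
  md <- mean(cloud_mesh_distances(cl, big))
  expect_equal(md, sigma * sqrt(2 / pi), tolerance = 0.05)
})

test_that("add_spurious appends the right count inside the expanded box", {
  spec <- default_body_spec(170, 100, 85)
  cl <- sample_cloud(spec, 1000, 0.3, seed = 6)
  expect_identical(add_spurious(cl, 0, seed = 1)[, c("x", "y", "z")], cl)

  half <- add_spurious(cl, 0.5, seed = 2)
  expect_equal(nrow(half), 2000)
  expect_equal(sum(half$spurious), 1000)

  # spurious points stay inside the expanded bounding box
  ex <- add_spurious(cl, 0.3, bbox_expand = c(4, 1.5, 4), seed = 3)
  sp <- dplyr::filter(ex, spurious)
  ctr <- (max(cl$x) + min(cl$x)) / 2
  expect_lte(max(abs(sp$x - ctr)), (max(cl$x) - min(cl$x)) / 2 * 4 + 1e-9)

  expect_identical(add_spurious(cl, 0.4, seed = 4), add_spurious(cl, 0.4, seed = 4))
  expect_error(add_spurious(cl, 1), "fraction")
  expect_error(add_spurious(cl, 0.5, bbox_expand = 0.5), "bbox_expand")
})

test_that("mask fixtures are consistent, perturbable and deterministic", {
  fx0 <- make_mask_fixture(seed = 1)
  expect_identical(fx0$reference, fx0$degraded)
  j0 <- mask_metrics(mask_confusion(fx0$degraded, fx0$reference, "full"))$jaccard
  expect_equal(j0, 1)
  expect_equal(dim(fx0$frame), c(120, 90, 3))

  # dilation grows false positives monotonically
  fps <- vapply(1:3, function(k) {
    fx <- make_mask_fixture(dilate = k, seed = 2)
    mask_confusion(fx$degraded, fx$reference, roi = "full")$fp
  }, 1)
  expect_true(all(diff(fps) > 0))

  # erosion produces false negatives only
  fe <- make_mask_fixture(erode = 2, seed = 2)
  cc <- mask_confusion(fe$degraded, fe$reference, roi = "full")
  expect_gt(cc$fn, 0)
  expect_equal(cc$fp, 0)

  f1 <- make_mask_fixture(dilate = 1, speckle = 0.05, seed = 7)
  f2 <- make_mask_fixture(dilate = 1, speckle = 0.05, seed = 7)
  expect_identical(f1, f2)
})
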