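test_that("rigid transforms validate, compose and invert correctly", {
  R1 <- rotation_matrix("z", 0.4)
  tf <- rigid_transform(R1, c(1, 2, 3))
  cloud <- tibble::tibble(x = rnorm(10), y = rnorm(10), z = rnorm(10))
  back <- apply_transform(apply_transform(cloud, tf), invert_transform(tf))
  expect_equal(as.matrix(back), as.matrix(cloud), tolerance = 1e-12)

  comp <- compose_transforms(invert_transform(tf), tf)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-12)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-12)

  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(1, 1, -1))
  expect_error(rigid_transform(refl), "determinant")
})

test_that("pca_align centres the cloud and orders variance as (Y, X, Z)", {
  set.seed(5)
  # elongated axis-aligned cloud, already centred: alignment is a fixed point
  cloud <- tibble::tibble(x = rnorm(4000, sd = 3), y = rnorm(4000, sd = 10),
                          z = rnorm(4000, sd = 1))
  al <- pca_align(cloud)
  expect_equal(colMeans(as.matrix(al$cloud[1:3])), c(x = 0, y = 0, z = 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  v <- apply(as.matrix(al$cloud[c("y", "x", "z")]), 2, var)
  expect_true(all(diff(v) < 0))          # descending variance Y > X > Z
  expect_equal(abs(al$transform$rotation), diag(3), tolerance = 0.05)

  # a known rotation is undone: covariance re-diagonalises
  rot <- rotation_matrix(c(1, 1, 0.3), 0.8)
  moved <- apply_transform(cloud, rigid_transform(rot, c(5, 5, 5)))
  al2 <- pca_align(moved)
  cv <- cov(as.matrix(al2$cloud[c("y", "x", "z")]))
  expect_equal(cv[upper.tri(cv)], rep(0, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(diff(diag(cv)) < 0))
  # transform reproduces its own output
  expect_equal(as.matrix(apply_transform(moved, al2$transform)),
               as.matrix(al2$cloud))

  line <- tibble::tibble(x = 1:50, y = 2 * (1:50), z = 3 * (1:50))
  expect_error(pca_align(line), "collinear")
})

test_that("pca_align puts the head of a body-shaped cloud up", {
  spec <- default_body_spec(170, 100, 85, seed = 1)
  cl <- sample_cloud(spec, 8000, 0.3, seed = 2)
  # head (small cross-section) is at large y in the generated cloud
  flipped <- apply_transform(cl, rigid_transform(rotation_matrix("z", pi)))
  al <- pca_align(flipped)
  # head-up restored: slices near the top are narrower than near the bottom
  top <- extract_slice(al$cloud, max(al$cloud$y) - 10, 4)
  bottom <- extract_slice(al$cloud, min(al$cloud$y) + 30, 4)
  expect_lt(max(abs(top$x)), max(abs(bottom$x)))
})

test_that("point_triangle_distance handles interior, edge and vertex regions", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  r1 <- point_triangle_distance(c(0, 0, 1), tri)
  expect_equal(r1$distance, 1)
  expect_equal(r1$closest, c(0, 0, 0))

  r2 <- point_triangle_distance(c(2, 0, 0), tri)
  expect_equal(r2$distance, 1)
  expect_equal(r2$closest, c(1, 0, 0))

  r3 <- point_triangle_distance(c(1, 1, 0), tri)
  expect_equal(r3$distance, sqrt(0.5))
  expect_equal(r3$closest, c(0.5, 0.5, 0))

  expect_error(point_triangle_distance(c(0, 0, 1),
                                       rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "Degenerate")
})

test_that("point_triangle_distance agrees with a dense-sampling oracle", {
  set.seed(31)
  for (case in 1:100) {
    tri <- matrix(runif(9, -5, 5), 3, 3)
    # reject near-degenerate triangles the oracle cannot resolve
    area2 <- sqrt(sum(pracma::cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2))
    if (area2 < 0.5) next
    p <- runif(3, -8, 8)
    d <- point_triangle_distance(p, tri)$distance
    d_oracle <- sampled_point_triangle(p, tri, k = 250)
    expect_gte(d_oracle, d - 1e-9)       # sampling can only overestimate
    expect_lt(d_oracle - d, 0.08)        # grid resolution bound
  }
})

test_that("cloud_mesh_distances: surface points, cube centre, and brute equality", {
  spec <- default_body_spec(170, 100, 85)
  mesh <- mesh_from_spec(spec, 30, 24)
  on_surface <- sample_cloud(mesh, 500, 0, seed = 8)
  expect_lt(max(cloud_mesh_distances(on_surface, mesh)), 1e-9)

  cube <- unit_cube_mesh()
  expect_equal(cloud_mesh_distances(tibble::tibble(x = 0.5, y = 0.5, z = 0.5),
                                    cube), 0.5)

  # accelerated search must equal the exhaustive scan exactly
  rm50 <- random_mesh(50, seed = 41)
  set.seed(42)
  pts <- tibble::tibble(x = runif(100, -15, 15), y = runif(100, -15, 15),
                        z = runif(100, -15, 15))
  expect_identical(cloud_mesh_distances(pts, rm50, method = "bvh"),
                   cloud_mesh_distances(pts, rm50, method = "brute"))

  # and both equal an explicit per-triangle double loop in R
  d_loop <- vapply(seq_len(nrow(pts)), function(i) {
    p <- as.numeric(pts[i, ])
    min(vapply(seq_len(nrow(rm50$faces)), function(j) {
      point_triangle_distance(p, as.matrix(rm50$vertices)[rm50$faces[j, ], ])$distance
    }, 1))
  }, 1)
  expect_equal(cloud_mesh_distances(pts, rm50), d_loop, tolerance = 1e-12)
})

test_that("registration_metrics computes RMSE, mean and population SD", {
  r <- registration_metrics(c(3, 4))
  expect_equal(r$rmse, sqrt(12.5))
  expect_equal(r$mean_distance, 3.5)
  expect_equal(r$sd, 0.5)
  expect_equal(r$n_points, 2)

  const <- registration_metrics(rep(2.5, 10))
  expect_equal(const$rmse, 2.5)
  expect_equal(const$mean_distance, 2.5)
  expect_equal(const$sd, 0)

  set.seed(6)
  for (i in 1:20) {
    d <- rexp(sample(2:200, 1))
    m <- registration_metrics(d)
    expect_equal(m$rmse^2, m$mean_distance^2 + m$sd^2, tolerance = 1e-9)
    expect_gte(m$rmse, m$mean_distance)   # Jensen
  }
  expect_error(registration_metrics(numeric(0)), "empty")
  expect_error(registration_metrics(c(1, -2)), "non-negative")
})

test_that("icp recovers a known rigid perturbation and descends monotonically", {
  spec <- default_body_spec(170, 100, 85)
  mesh <- mesh_from_spec(spec, 50, 40)
  src <- sample_cloud(mesh, 1500, 0, seed = 13)
  true_tf <- rigid_transform(rotation_matrix(c(0.5, 1, 0.2), 30 * pi / 180),
                             c(6, -4, 9))
  moved <- apply_transform(src, true_tf)

  fit <- icp(moved, mesh, max_iter = 250, convergence_tol = 1e-13)
  comp <- compose_transforms(fit$transform, true_tf)
  expect_lt(norm(comp$rotation - diag(3), "F"), 1e-3)
  expect_lt(sqrt(sum(comp$translation^2)), 1e-3)
  expect_lt(fit$report$rmse, 1e-3)
  expect_true(all(diff(fit$rmse_history) <= 1e-12))

  # a cloud already on the surface is a fixed point
  fixed <- icp(src, mesh, max_iter = 20)
  expect_equal(fixed$transform$rotation, diag(3), tolerance = 1e-6)
  expect_lt(sqrt(sum(fixed$transform$translation^2)), 1e-6)
  expect_lte(fixed$report$iterations_run, 2)
  expect_true(fixed$report$converged)

  expect_error(icp(moved, mesh, max_iter = 0), "max_iter")
})

test_that("contaminated clouds register strictly worse than clean ones", {
  spec <- default_body_spec(165, 98, 82, seed = 4)
  mesh <- mesh_from_spec(spec, 40, 32)
  clean <- sample_cloud(mesh, 2000, 0.5, seed = 14)
  clean_rep <- icp(clean, mesh, max_iter = 15)$report
  for (f in c(0.1, 0.3)) {
    raw <- add_spurious(clean, f, seed = 15)
    raw_rep <- icp(dplyr::select(raw, "x", "y", "z"), mesh, max_iter = 15)$report
    expect_gt(raw_rep$rmse, clean_rep$rmse)
    expect_gt(raw_rep$mean_distance, clean_rep$mean_distance)
    expect_gt(raw_rep$sd, clean_rep$sd)
  }
})
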