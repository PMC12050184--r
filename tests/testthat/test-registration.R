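# Normal estimation, voxel downsampling, initial alignment and
# point-to-plane ICP.

test_that("plane and sphere normals match the analytic directions", {
  set.seed(1)
  # plane z = 0: normals +/- e_z, fixed to +e_z by the orientation rule
  P <- cbind(runif(100, -1, 1), runif(100, -1, 1), 0)
  cl <- estimate_normals(point_cloud(P), k = 8)
  expect_true(all(abs(abs(cl$normals[, 3]) - 1) < 1e-9))

  # sphere: normals within 5 degrees of radial, k = 10, 500 points
  # (quasi-uniform Fibonacci sampling so every neighbourhood is regular)
  n <- 500
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  v <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  cl <- estimate_normals(point_cloud(10 * v), k = 10)
  ang <- acos(pmin(1, abs(rowSums(cl$normals * v)))) * 180 / pi
  expect_lt(max(ang), 5)
  # orientation away from the centroid (origin)
  expect_true(all(rowSums(cl$normals * v) > 0))
})

test_that("normal estimation validates k and degenerate input", {
  cl <- point_cloud(matrix(rnorm(30), 10, 3))
  expect_error(estimate_normals(cl, k = 10), "smaller than")
  expect_error(estimate_normals(cl, k = 2), "at least 3")
  same <- point_cloud(matrix(1, 10, 3))
  expect_error(estimate_normals(same, k = 4), "coincide")
})

test_that("voxel downsampling bins to centroids on the anchored grid", {
  cl <- point_cloud(rbind(c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2),
                          c(5, 5, 5), c(7, 7, 7)))
  out <- voxel_downsample(cl, 1)
  expect_equal(out$points[1, ], c(0.15, 0.15, 0.15))
  expect_equal(nrow(out$points), 3)

  # voxel below minimal spacing: cloud unchanged up to reordering
  set.seed(2)
  P <- matrix(runif(60, 0, 10), 20, 3)
  out <- voxel_downsample(point_cloud(P), 0.01)
  expect_equal(nrow(out$points), 20)
  expect_equal(out$points[order(out$points[, 1]), ],
               P[order(P[, 1]), ])

  # occupied-cell count oracle by brute-force binning
  set.seed(3)
  P <- matrix(runif(300, 0, 2), 100, 3)
  out <- voxel_downsample(point_cloud(P), 1)
  key <- apply(floor(sweep(P, 2, floor(apply(P, 2, min)))), 1, paste,
               collapse = "/")
  expect_equal(nrow(out$points), length(unique(key)))

  # every output point lies inside its voxel; count never exceeds input
  idx <- floor(sweep(out$points, 2, floor(apply(P, 2, min))))
  expect_true(all(out$points >= idx + floor(apply(P, 2, min)) - 1e-12))
  expect_lte(nrow(out$points), nrow(P))
})

test_that("initial alignment recovers rotations and reflections", {
  ref <- asymmetric_cloud(300, seed = 4)

  # identity case
  res <- initial_align(ref, ref)
  expect_false(res$transform$mirrored)
  expect_equal(res$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(res$cloud$points, ref$points, tolerance = 1e-9)

  # rotated copy: recovered alignment restores coordinates
  R <- radssm:::rotation_about_axis(c(0, 0, 1), 30)
  rot <- point_cloud(ref$points %*% t(R))
  res <- initial_align(rot, ref)
  expect_lt(max(abs(res$cloud$points - ref$points)), 1e-6)

  # mirrored copy: detected and undone when allowed
  mir <- point_cloud(ref$points %*% diag(c(-1, 1, 1)))
  res <- initial_align(mir, ref, allow_mirror = TRUE)
  expect_true(res$transform$mirrored)
  expect_lt(sqrt(sum((colMeans(res$cloud$points) -
                      colMeans(ref$points))^2)), 1e-9)
  expect_lt(max(abs(res$cloud$points - ref$points)), 1e-6)

  # isotropic cloud is rejected
  iso <- point_cloud(rbind(diag(3), -diag(3)) * 2)
  expect_error(initial_align(iso, ref), "isotropic")
})

test_that("ICP is exact on identical clouds and recovers applied motions", {
  tpl <- make_template(500, seed = 9)
  ref <- estimate_normals(tpl$cloud, 20)

  res <- icp_point_to_plane(tpl$cloud, ref)
  expect_lte(res$report$iterations, 2)
  expect_lt(res$report$final_rmse, 1e-9)
  expect_true(res$report$passed_gate)
  expect_equal(res$transform$rotation, diag(3), tolerance = 1e-6)

  # 10 degrees about z plus (1, 2, 0): composition back to identity
  R <- radssm:::rotation_about_axis(c(0, 0, 1), 10)
  tf_app <- rigid_transform(R, c(1, 2, 0))
  moved <- apply_transform(tpl$cloud, tf_app)
  res <- icp_point_to_plane(moved, ref)
  comp <- compose_affine(list(tf_app, res$transform))
  expect_lt(max(abs(comp$A - diag(3))), 1e-3)
  expect_lt(max(abs(comp$b)), 1e-3)
  expect_true(res$report$passed_gate)
})

test_that("pairs beyond the rejection distance are excluded", {
  tpl <- make_template(400, seed = 2)
  ref <- estimate_normals(tpl$cloud, 15)
  outlier <- tpl$cloud$points[which.max(tpl$cloud$points[, 3]), ] +
    c(0, 0, 3) # 3 mm beyond every target point
  src <- point_cloud(rbind(tpl$cloud$points, outlier))
  res <- icp_point_to_plane(src, ref)
  expect_gt(res$report$rejected_fraction, 0)
  expect_equal(res$report$rejected_fraction, 1 / nrow(src$points),
               tolerance = 1e-12)
})

test_that("ICP error history is non-increasing on noiseless inputs", {
  tpl <- make_template(400, seed = 5)
  ref <- estimate_normals(tpl$cloud, 15)
  for (seed in 1:3) {
    set.seed(seed)
    tf <- rigid_transform(radssm:::random_rotation(10), runif(3, -2, 2))
    res <- icp_point_to_plane(apply_transform(tpl$cloud, tf), ref)
    h <- res$report$error_history
    expect_true(all(diff(h) <= 1e-12))
  }
})

test_that("registration error is equivariant under joint rotation", {
  tpl <- make_template(400, seed = 6)
  ref <- estimate_normals(tpl$cloud, 15)
  set.seed(7)
  tf <- rigid_transform(radssm:::random_rotation(8), c(1, -1, 0.5))
  src <- apply_transform(tpl$cloud, tf)
  r1 <- icp_point_to_plane(src, ref)

  R <- radssm:::rotation_about_axis(c(1, 1, 0), 25)
  rot_tf <- rigid_transform(R)
  r2 <- icp_point_to_plane(apply_transform(src, rot_tf),
                           apply_transform(ref, rot_tf))
  expect_equal(r1$report$final_rmse, r2$report$final_rmse,
               tolerance = 1e-9)
})

test_that("grid nearest-neighbour search equals the brute-force scan", {
  set.seed(8)
  for (i in 1:20) {
    q <- matrix(rnorm(3 * sample(5:300, 1), sd = sample(1:20, 1)), ncol = 3)
    tg <- matrix(rnorm(3 * sample(5:300, 1), sd = sample(1:20, 1)), ncol = 3)
    a <- radssm:::cpp_nn1(q, tg)
    b <- radssm:::cpp_nn1_grid(q, tg)
    expect_identical(a$index, b$index)
    expect_identical(a$dist, b$dist)
  }
})
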