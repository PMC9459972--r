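test_that("scale factor matches its closed forms and is reciprocal under swap", {
  a <- matrix(c(3, 4, 0), 1)
  b <- matrix(c(6, 8, 0), 1)
  expect_equal(scale_factor(a, b, 0), 0.5, tolerance = 1e-15)
  expect_equal(scale_factor(matrix(c(1, 1, 1), 1), matrix(c(2, 0, 0), 1), 0),
               sqrt(3) / 2, tolerance = 1e-12)
  tpl <- get_template("full_478")$landmarks
  expect_equal(scale_factor(tpl, tpl, 57), 1, tolerance = 1e-15)
  expect_error(scale_factor(a, matrix(0, 1, 3), 0),
               class = "facesym_degenerate_error")
  expect_error(scale_factor(a, b, 5), class = "facesym_validation_error")

  other <- apply_scale(tpl, 1.37)
  for (i in c(0L, 100L, 477L))
    expect_equal(scale_factor(tpl, other, i) * scale_factor(other, tpl, i),
                 1, tolerance = 1e-12)
})

test_that("scale matching equalizes the chosen landmark's distance from origin", {
  expect_equal(apply_scale(matrix(c(1, 2, 3), 1), 2), matrix(c(2, 4, 6), 1),
               tolerance = 1e-15)
  tpl <- get_template("full_478")$landmarks
  expect_identical(apply_scale(tpl, 1)$points, tpl$points)
  expect_error(apply_scale(tpl, -2), class = "facesym_validation_error")

  other <- apply_scale(tpl, 0.8, origin = c(0.1, 0, 0))
  for (i in c(3L, 250L)) {
    f <- scale_factor(tpl, other, i)
    scaled <- apply_scale(other, f)
    expect_equal(sqrt(sum(scaled$points[i + 1, ]^2)),
                 sqrt(sum(tpl$points[i + 1, ]^2)), tolerance = 1e-12)
  }
})

test_that("normal estimation recovers plane and sphere normals", {
  grid <- as.matrix(expand.grid(x = 1:6, y = 1:6))
  planar <- cbind(grid, 0)
  nrm <- estimate_normals(planar, k = 8)
  expect_equal(nrm, matrix(rep(c(0, 0, 1), each = 36), ncol = 3),
               tolerance = 1e-9)

  # Fibonacci sphere: normals should be close to radial
  n <- 500
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  sph <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  nrm <- estimate_normals(sph, k = 12)
  ang <- acos(pmin(1, abs(rowSums(nrm * sph))))
  expect_lt(max(ang), 15 * pi / 180)

  expect_error(estimate_normals(planar, k = 36),
               class = "facesym_validation_error")
  expect_error(estimate_normals(planar, k = 2),
               class = "facesym_validation_error")
})

test_that("inlier RMSE follows the root-mean-square of per-index residuals", {
  tpl <- get_template("compact_68")$landmarks
  r <- inlier_rmse(tpl, tpl)
  expect_equal(r$rmse, 0)
  expect_equal(r$residuals, rep(0, 68))

  expect_equal(inlier_rmse(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1))$rmse,
               5, tolerance = 1e-15)
  S <- rbind(c(0, 0, 0), c(0, 0, 0))
  T_ <- rbind(c(3, 0, 0), c(0, 4, 0))
  expect_equal(inlier_rmse(S, T_)$rmse, sqrt(12.5), tolerance = 1e-12)
  expect_error(inlier_rmse(S, T_[1, , drop = FALSE]),
               class = "facesym_validation_error")

  # invariance under a common rigid motion of both clouds
  tf <- make_transform(rotation_xyz(0.3, 0.1, -0.2), c(0.4, -1, 2))
  src <- get_template("compact_68")$landmarks$points
  tgt <- src + matrix(rnorm(length(src), 0, 0.01), ncol = 3)
  base <- inlier_rmse(src, tgt)$rmse
  moved <- inlier_rmse(apply_transform(tf, src), apply_transform(tf, tgt))$rmse
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("centroid initialization follows the source-minus-target convention", {
  tpl <- get_template("compact_68")$landmarks
  expect_transform_equal(centroid_init_transform(tpl, tpl),
                         identity_transform(), 1e-12)
  shifted <- set_points(tpl, tpl$points + rep(c(1, 2, 3), each = 68))
  expect_equal(centroid_init_transform(tpl, shifted)$matrix[1:3, 4],
               c(-1, -2, -3), tolerance = 1e-12)
  expect_equal(centroid_init_transform(matrix(c(5, 0, 0), 1),
                                       matrix(c(2, 0, 0), 1))$matrix[1:3, 4],
               c(3, 0, 0), tolerance = 1e-15)
})

test_that("point-to-point ICP solves translations closed-form and recovers rotations", {
  tpl <- get_template("compact_68")$landmarks
  fit <- icp_point_to_point(tpl, tpl)
  expect_transform_equal(fit$transform, identity_transform(), 1e-9)
  expect_equal(fit$inlier_rmse, 0, tolerance = 1e-12)

  off <- set_points(tpl, tpl$points + rep(c(0.002, -0.001, 0.003), each = 68))
  fit <- icp_point_to_point(tpl, off)
  expect_lte(fit$iterations, 2L)
  expect_equal(fit$transform$matrix[1:3, 4], c(0.002, -0.001, 0.003),
               tolerance = 1e-9)

  R <- rotation_xyz(0, 10 * pi / 180, 0)
  rot <- set_points(tpl, tpl$points %*% t(R))
  fit <- icp_point_to_point(tpl, rot)
  expect_transform_equal(fit$transform, make_transform(R), 1e-6)
  expect_lt(fit$inlier_rmse, 1e-8)
})

test_that("point-to-plane ICP is a fixed point at the truth and flags no overlap", {
  tpl <- get_template("compact_68")$landmarks
  tf <- make_transform(rotation_xyz(0.05, 0.1, -0.04), c(0.05, 0.02, -0.03))
  moved <- set_points(tpl, apply_transform(tf, tpl$points))
  fit <- icp_point_to_plane(tpl, moved, init = tf)
  expect_transform_equal(fit$transform, tf, 1e-9)
  expect_lt(fit$inlier_rmse, 1e-10)

  far <- set_points(tpl, tpl$points + 30)
  expect_error(icp_point_to_plane(tpl, far),
               class = "facesym_no_overlap_error")
})

test_that("global registration coarsely aligns rotated clouds and rejects degenerate input", {
  tpl <- get_template("full_478")$landmarks
  tf <- make_transform(rotation_xyz(0, 20 * pi / 180, 0), c(0.1, -0.05, 0.02))
  tgt <- set_points(tpl, apply_transform(tf, tpl$points))
  cfg <- registration_config(random_seed = 0L)
  coarse <- global_registration(tpl, tgt, cfg)
  moved <- apply_transform(coarse$transform, tpl$points)
  d2 <- outer(rowSums(moved^2), rowSums(tgt$points^2), "+") -
    2 * tcrossprod(moved, tgt$points)
  mean_nn <- mean(sqrt(pmax(apply(d2, 1, min), 0)))
  diag_len <- sqrt(sum((apply(tgt$points, 2, max) -
                          apply(tgt$points, 2, min))^2))
  expect_lt(mean_nn, 0.05 * diag_len)

  ident <- global_registration(tpl, tpl, cfg)
  expect_lt(inlier_rmse(tpl, tpl, ident$transform)$rmse, 1e-6)

  # determinism under a fixed seed
  again <- global_registration(tpl, tgt, cfg)
  expect_identical(coarse$transform$matrix, again$transform$matrix)

  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(global_registration(line, line),
               class = "facesym_degenerate_error")
  expect_error(global_registration(line[1:3, ], line[1:3, ]),
               class = "facesym_degenerate_error")
})

test_that("the scale sweep recovers similarity transforms and tracks its own minimum", {
  tpl <- get_template("full_478")$landmarks
  cfg <- registration_config(init_stride = 10L)   # full sweep, strided inits

  self <- register_landmarks(tpl, tpl, cfg)
  expect_lt(self$inlier_rmse, 1e-6)
  expect_equal(self$scale_factor, 1, tolerance = 1e-12)
  expect_equal(self$inlier_rmse, min(self$sweep_trace$inlier_rmse, na.rm = TRUE))
  expect_equal(self$inlier_rmse, sqrt(mean(self$per_landmark_residuals^2)),
               tolerance = 1e-10)

  # translation-free similarity: the Eq-2 sweep is exact here
  tf0 <- make_transform(rotation_xyz(0.05, 15 * pi / 180, 0.02), c(0, 0, 0),
                        1.15)
  tgt0 <- set_points(tpl, apply_transform(tf0, tpl$points))
  fit0 <- register_landmarks(tpl, tgt0, cfg)
  expect_lt(fit0$inlier_rmse, 1e-6)
  expect_transform_equal(fit0$transform, tf0, 1e-6)

  # translated similarity: recovery to the documented 1e-3 matrix tolerance
  tf <- make_transform(rotation_xyz(0.05, 15 * pi / 180, 0.02),
                       c(0.03, -0.02, 0.04), 1.15)
  tgt <- set_points(tpl, apply_transform(tf, tpl$points))
  fit <- register_landmarks(tpl, tgt, cfg)
  expect_lt(max(abs(fit$transform$matrix - tf$matrix)), 1e-3)
  expect_lt(fit$inlier_rmse, 1e-3)
  expect_identical(fit$method_label, "proposed")

  expect_error(register_landmarks(tpl, tpl,
                                  registration_config(sweep_indices = 999L)),
               class = "facesym_validation_error")
})

test_that("the closed-form similarity oracle is exact and statistically calibrated", {
  tpl <- get_template("full_478")$landmarks
  fit <- umeyama_similarity(tpl, tpl)
  expect_transform_equal(fit$transform, identity_transform(), 1e-10)
  expect_lt(fit$inlier_rmse, 1e-12)

  tf <- make_transform(rotation_xyz(0.3, -0.2, 0.5), c(1, 2, -0.5), 0.85)
  tgt <- set_points(tpl, apply_transform(tf, tpl$points))
  fit <- umeyama_similarity(tpl, tgt)
  expect_transform_equal(fit$transform, tf, 1e-10)

  sigma <- 0.01
  for (seed in 0:4) {
    set.seed(seed)
    noisy <- set_points(tpl, tpl$points +
                          matrix(stats::rnorm(478 * 3, 0, sigma / sqrt(3)),
                                 ncol = 3))
    r <- umeyama_similarity(tpl, noisy)$inlier_rmse
    expect_gt(r, 0.8 * sigma)
    expect_lt(r, 1.2 * sigma)
  }
  expect_error(umeyama_similarity(matrix(0, 2, 3), matrix(0, 2, 3)),
               class = "facesym_degenerate_error")
})
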