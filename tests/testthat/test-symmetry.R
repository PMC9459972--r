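test_that("the midsagittal plane bisects the iris segment", {
  tpl <- get_template("compact_68")
  ls <- tpl$landmarks; topo <- tpl$topology
  li <- topo$left_iris_index + 1L; ri <- topo$right_iris_index + 1L

  ls$points[li, ] <- c(-1, 0, 0); ls$points[ri, ] <- c(1, 0, 0)
  pl <- midsagittal_plane(ls, topo)
  expect_equal(pl$point, c(0, 0, 0), tolerance = 1e-15)
  expect_equal(pl$normal, c(1, 0, 0), tolerance = 1e-15)

  ls$points[li, ] <- c(0, 0, 0); ls$points[ri, ] <- c(0, 2, 0)
  pl <- midsagittal_plane(ls, topo)
  expect_equal(pl$point, c(0, 1, 0), tolerance = 1e-15)
  expect_equal(pl$normal, c(0, 1, 0), tolerance = 1e-15)

  ls$points[ri, ] <- ls$points[li, ]
  expect_error(midsagittal_plane(ls, topo), class = "facesym_degenerate_error")
})

test_that("plane reflection is an involution fixing the plane", {
  pl <- structure(list(point = c(0.3, -1, 2),
                       normal = c(1, 2, -2) / 3), class = "midsagittal_plane")
  expect_equal(reflect_across_plane(pl$point, pl), pl$point, tolerance = 1e-15)
  x0 <- structure(list(point = c(0, 5, -7), normal = c(1, 0, 0)),
                  class = "midsagittal_plane")
  expect_equal(reflect_across_plane(c(1, 0, 0), x0), c(-1, 0, 0),
               tolerance = 1e-15)
  set.seed(1)
  P <- matrix(rnorm(60), 20, 3)
  expect_equal(reflect_across_plane(reflect_across_plane(P, pl), pl), P,
               tolerance = 1e-12)
})

test_that("distance and angle symmetry match their closed forms on edited pairs", {
  tpl <- get_template("full_478")
  ls <- tpl$landmarks; topo <- tpl$topology
  pair1 <- topo$pairs[1, ]
  # plane stays x = 0 because the irises are untouched
  ls$points[pair1[1] + 1L, ] <- c(-1, 0, 0)
  ls$points[pair1[2] + 1L, ] <- c(1.5, 0, 0)
  d <- distance_symmetry(ls, topo)
  expect_equal(d$value[1], 0.5, tolerance = 1e-12)

  a <- angle_symmetry(ls, topo)
  expect_equal(a$value[1], 1, tolerance = 1e-12)      # (2.5,0,0) along normal
  ls$points[pair1[2] + 1L, ] <- c(-1, 1, 0)           # perpendicular pair vec
  expect_equal(angle_symmetry(ls, topo)$value[1], 0, tolerance = 1e-12)
  ls$points[pair1[2] + 1L, ] <- c(0, 1, 0)            # (1,1,0) vs (1,0,0)
  expect_equal(angle_symmetry(ls, topo)$value[1], 1 / sqrt(2),
               tolerance = 1e-12)

  ls$points[pair1[2] + 1L, ] <- ls$points[pair1[1] + 1L, ]
  expect_warning(a <- angle_symmetry(ls, topo), class = "facesym_warning")
  expect_true(is.na(a$value[1]))
})

test_that("per-pair metrics agree with an independent coordinate-wise recomputation", {
  tpl <- get_template("full_478")
  cfgS <- synthetic_face_config("full_478", palsy_side = "left",
                                palsy_attenuation = 0.4,
                                asymmetry_jitter = 0.005, seed = 11L)
  face <- apply_expression(tpl$landmarks, tpl$topology, cfgS)
  topo <- tpl$topology
  pl <- midsagittal_plane(face, topo)
  d <- distance_symmetry(face, topo, pl)
  a <- angle_symmetry(face, topo, pl)

  # brute-force per-pair evaluation, scalar arithmetic only
  for (k in sample(seq_len(nrow(topo$pairs)), 40)) {
    L <- unname(face$points[topo$pairs[k, 1] + 1L, ])
    R <- unname(face$points[topo$pairs[k, 2] + 1L, ])
    refl <- L - 2 * sum((L - pl$point) * pl$normal) * pl$normal
    dk <- sqrt((R[1] - refl[1])^2 + (R[2] - refl[2])^2 + (R[3] - refl[3])^2)
    expect_equal(d$value[k], dk, tolerance = 1e-12)
    av <- R - L
    ck <- sum(pl$normal * av) /
      (sqrt(sum(pl$normal^2)) * sqrt(sum(av^2)))
    expect_equal(a$value[k], ck, tolerance = 1e-12)
  }
})

test_that("aggregation averages eligible pairs, scales and rounds", {
  topo <- get_template("full_478")$topology
  g12 <- topo$muscle_groups[[12]]$indices   # one full pair + one half pair
  full_pair <- topo$pairs[topo$pairs[, 1] %in% g12 & topo$pairs[, 2] %in% g12, ]
  vals <- data.frame(left = c(full_pair[1], topo$pairs[1, 1]),
                     right = c(full_pair[2], topo$pairs[1, 2]),
                     value = c(0.01, 0.03))
  agg <- aggregate_by_muscle(vals, topo)
  expect_equal(agg$value[12], 1, tolerance = 1e-12)   # only its own pair
  expect_identical(agg$n_pairs[12], 1L)

  vals2 <- data.frame(left = topo$pairs[1:2, 1], right = topo$pairs[1:2, 2],
                      value = c(0.01, 0.03))
  # both pairs belong to group 1 (Frontalis) in the bundled layout
  g1 <- topo$muscle_groups[[1]]$indices
  expect_true(all(unlist(vals2[, 1:2]) %in% g1))
  agg2 <- aggregate_by_muscle(vals2, topo)
  expect_equal(agg2$value[1], 2, tolerance = 1e-12)   # mean 0.02 x 100
  expect_equal(aggregate_by_muscle(
    data.frame(left = topo$pairs[1:2, 1], right = topo$pairs[1:2, 2],
               value = c(0, 0)), topo)$value[1], 0)
  expect_equal(agg$value[2], NA_real_)                # Corrugator: no pair
})

test_that("metrics are rigid-invariant; scaling acts as expected", {
  tpl <- get_template("full_478")
  cfgS <- synthetic_face_config("full_478", palsy_side = "right",
                                palsy_attenuation = 0.6, seed = 3L)
  face <- apply_expression(tpl$landmarks, tpl$topology, cfgS)
  d0 <- distance_symmetry(face, tpl$topology)$value
  a0 <- angle_symmetry(face, tpl$topology)$value
  set.seed(7)
  for (rep in 1:3) {
    tf <- make_transform(rotation_xyz(rnorm(1), rnorm(1), rnorm(1)),
                         rnorm(3, 0, 2))
    moved <- set_points(face, apply_transform(tf, face$points))
    expect_equal(distance_symmetry(moved, tpl$topology)$value, d0,
                 tolerance = 1e-9)
    expect_equal(angle_symmetry(moved, tpl$topology)$value, a0,
                 tolerance = 1e-9)
  }
  scaled <- set_points(face, 2.5 * face$points)
  expect_equal(distance_symmetry(scaled, tpl$topology)$value, 2.5 * d0,
               tolerance = 1e-9)
  expect_equal(angle_symmetry(scaled, tpl$topology)$value, a0,
               tolerance = 1e-12)
})

test_that("flattened angle aggregation is bounded by 100 and exact for single pairs", {
  # Unlike the per-pair mean, the flattened cosine mixes pair-vector
  # magnitudes: by Cauchy-Schwarz it reaches 100 only when all pair vectors
  # in the group are identical, so on the template it is exactly 100 for
  # single-pair groups and strictly below for the rest.
  tpl <- get_template("full_478")
  flat <- angle_symmetry_flattened(tpl$landmarks, tpl$topology)
  ok <- flat$n_pairs > 0
  expect_true(all(flat$value[ok] <= 100))
  single <- flat$n_pairs == 1
  expect_equal(flat$value[single], rep(100, sum(single)), tolerance = 1e-9)
  expect_true(all(flat$value[flat$n_pairs > 1] < 100))
})
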