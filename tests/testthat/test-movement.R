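test_that("movement amounts follow the per-side displacement magnitudes", {
  tpl <- get_template("compact_68")
  ls <- tpl$landmarks; topo <- tpl$topology

  m0 <- movement_amounts(ls, ls, topo)
  expect_equal(m0$m_left, rep(0, nrow(topo$pairs)))
  expect_equal(m0$m_right, rep(0, nrow(topo$pairs)))

  smile <- ls
  pair1 <- topo$pairs[1, ]
  smile$points[pair1 + 1L, 2] <- smile$points[pair1 + 1L, 2] + 0.3
  m <- movement_amounts(ls, smile, topo)
  expect_equal(m$m_left[1], 0.3, tolerance = 1e-12)
  expect_equal(m$m_right[1], 0.3, tolerance = 1e-12)

  expect_error(movement_amounts(ls, get_template("full_478")$landmarks, topo),
               class = "facesym_validation_error")
})

test_that("generator smiles match a coordinate-wise recomputation of the movement", {
  tpl <- get_template("full_478")
  cfgS <- synthetic_face_config("full_478", seed = 5L)
  smile <- apply_expression(tpl$landmarks, tpl$topology, cfgS)
  m <- movement_amounts(tpl$landmarks, smile, tpl$topology)
  for (k in sample(seq_len(nrow(tpl$topology$pairs)), 30)) {
    iL <- tpl$topology$pairs[k, 1] + 1L
    sL <- unname(smile$points[iL, ]); nL <- unname(tpl$landmarks$points[iL, ])
    expect_equal(m$m_left[k],
                 sqrt((sL[1] - nL[1])^2 + (sL[2] - nL[2])^2 +
                        (sL[3] - nL[3])^2), tolerance = 1e-12)
  }
})

test_that("movement asymmetry is the absolute left-right difference, aggregated", {
  topo <- get_template("full_478")$topology
  am <- data.frame(left = topo$pairs[, 1], right = topo$pairs[, 2],
                   m_left = 0.2, m_right = 0.2)
  rep0 <- movement_asymmetry(am, topo)
  expect_true(all(rep0$per_muscle$value[rep0$per_muscle$n_pairs > 0] == 0))

  am1 <- data.frame(left = topo$pairs[1, 1], right = topo$pairs[1, 2],
                    m_left = 2, m_right = 3)
  rep1 <- movement_asymmetry(am1, topo)
  expect_equal(rep1$per_pair$abs_diff, 1)
  expect_equal(rep1$per_pair$diff, -1)
  expect_error(movement_asymmetry(am1[, 1:3], topo),
               class = "facesym_validation_error")
})

test_that("half-attenuated palsy yields half the healthy-side movement per group", {
  tpl <- get_template("full_478")
  cfgS <- synthetic_face_config("full_478", palsy_side = "left",
                                palsy_attenuation = 0.5, seed = 9L)
  smile <- apply_expression(tpl$landmarks, tpl$topology, cfgS)
  gt <- attr(smile, "ground_truth")
  topo <- tpl$topology
  rep <- movement_asymmetry(movement_amounts(tpl$landmarks, smile, topo),
                            topo)
  g8 <- topo$muscle_groups[[8]]$indices
  both <- topo$pairs[, 1] %in% g8 & topo$pairs[, 2] %in% g8
  expected <- mean(gt$movement_right[both]) * 0.5 * 100
  got <- rep$per_muscle$value[8]
  expect_lt(abs(got - expected) / expected, 0.10)
})

test_that("symmetric motion scores zero under any known pose, and swapping frames is neutral", {
  tpl <- get_template("full_478")
  tf <- make_transform(rotation_xyz(0.1, -0.2, 0.15), c(0.4, -0.1, 0.2))
  cfgS <- synthetic_face_config("full_478", palsy_attenuation = 1,
                                transform = tf, seed = 2L)
  smile <- apply_expression(tpl$landmarks, tpl$topology, cfgS)
  # the pose-recovering registration is the known ground-truth inverse
  m <- movement_amounts(tpl$landmarks, smile, tpl$topology,
                        invert_transform(tf))
  expect_lt(max(abs(m$m_left - m$m_right)), 1e-9)
  rep <- movement_asymmetry(m, tpl$topology)
  expect_lt(max(rep$per_muscle$value, na.rm = TRUE), 1e-9)

  # rigid pose: evaluating in the neutral frame or the smile frame is the same
  m_neutral <- movement_amounts(tpl$landmarks, smile, tpl$topology,
                                invert_transform(tf))
  m_smile <- movement_amounts(smile, tpl$landmarks, tpl$topology, tf)
  expect_equal(m_smile$m_left, m_neutral$m_left, tolerance = 1e-9)
  expect_equal(m_smile$m_right, m_neutral$m_right, tolerance = 1e-9)
})

test_that("per-muscle movement grows with palsy severity on a fixed seed", {
  tpl <- get_template("full_478")
  vals <- sapply(c(1, 0.8, 0.6, 0.4, 0.2), function(alpha) {
    cfgS <- synthetic_face_config("full_478", palsy_side = "left",
                                  palsy_attenuation = alpha, seed = 4L)
    smile <- apply_expression(tpl$landmarks, tpl$topology, cfgS)
    movement_asymmetry(movement_amounts(tpl$landmarks, smile, tpl$topology),
                       tpl$topology)$per_muscle$value[8]
  })
  expect_true(all(diff(vals) > 0))
})
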