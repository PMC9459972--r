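#' Configuration for the synthetic face generator
#'
#' The generator builds mirror-symmetric neutral faces on the bundled
#' topology and derives smile expressions, one-sided palsy, structural
#' asymmetry, measurement noise and global similarity disturbances from
#' them. It emulates the capture structure of a longitudinal palsy study
#' (neutral + smile per session); it does not model photorealistic shape.
#'
#' @param mode Topology mode.
#' @param expression_amplitude Peak smile displacement `g` in model units
#'   (the template face is about 1.5 units wide; the default 0.15 is a
#'   pronounced smile of ~10% of face width).
#' @param palsy_side `"left"`, `"right"` or `"none"`.
#' @param palsy_attenuation Multiplier `alpha` in `[0, 1]` applied to the
#'   smile displacement of landmarks on the palsy side (1 = healthy).
#' @param asymmetry_jitter Standard deviation of static structural asymmetry
#'   added to the palsy-side neutral geometry (model units).
#' @param noise_sd Root-mean-square 3D measurement noise per landmark
#'   (per-coordinate standard deviation `noise_sd / sqrt(3)`).
#' @param transform Optional similarity disturbance: a list with elements
#'   `scale`, `angles` (radians, length 3) and `translation` (length 3), or
#'   a `homogeneous_transform`, applied after all deformations.
#' @param seed Integer seed controlling all generator randomness.
#' @return A `synthetic_face_config` list.
#' @export
synthetic_face_config <- function(mode = "full_478", expression_amplitude = 0.15,
                                  palsy_side = c("none", "left", "right"),
                                  palsy_attenuation = 1, asymmetry_jitter = 0,
                                  noise_sd = 0, transform = NULL, seed = 0L) {
  palsy_side <- match.arg(palsy_side)
  if (palsy_attenuation < 0 || palsy_attenuation > 1)
    fs_stop_validation("palsy_attenuation must lie in [0, 1]")
  if (expression_amplitude < 0 || asymmetry_jitter < 0 || noise_sd < 0)
    fs_stop_validation("amplitudes and standard deviations must be >= 0")
  if (!is.null(transform) && !inherits(transform, "homogeneous_transform")) {
    scale <- transform$scale %||% 1
    if (scale <= 0) fs_stop_validation("transform scale must be > 0")
    angles <- transform$angles %||% c(0, 0, 0)
    transform <- make_transform(
      rotation_xyz(angles[1], angles[2], angles[3]),
      transform$translation %||% c(0, 0, 0), scale)
  }
  structure(list(mode = match.arg(mode, c("full_478", "compact_68")),
                 expression_amplitude = expression_amplitude,
                 palsy_side = palsy_side, palsy_attenuation = palsy_attenuation,
                 asymmetry_jitter = asymmetry_jitter, noise_sd = noise_sd,
                 transform = transform, seed = as.integer(seed)),
            class = "synthetic_face_config")
}

#' Generate the mirror-symmetric neutral template
#'
#' Landmarks are placed on a procedural frontal head surface: the right half
#' is authored, the left half is its exact mirror across the `x = 0` plane
#' and midline landmarks lie on `x = 0`, so the template is exactly
#' mirror-symmetric by construction. Coordinates are centred so the cloud
#' centroid is the coordinate origin (the origin used by scale matching).
#'
#' @param mode Topology mode.
#' @param seed Unused by the deterministic template; kept so callers can
#'   treat template generation like the other generator entry points.
#' @return A list with elements `landmarks` (a neutral `landmark_set`) and
#'   `topology` (the matching `face_topology`).
#' @export
generate_template <- function(mode = c("full_478", "compact_68"), seed = 0L) {
  mode <- match.arg(mode)
  lay <- face_layout(mode)
  pts <- cbind(lay$x, lay$y, lay$z)
  # centre y/z only: x = 0 must remain the mirror plane
  pts[, 2] <- pts[, 2] - mean(pts[, 2])
  pts[, 3] <- pts[, 3] - mean(pts[, 3])
  list(landmarks = landmark_set(pts, mode, subject_id = "template",
                                session_label = "template",
                                expression = "neutral"),
       topology = topology_from_layout(lay, mode))
}

# mirror-equivariant smile displacement field: two Gaussian lobes anchored at
# the mouth corners, pulling outward/upward/slightly forward
#' @noRd
smile_field <- function(points, topo, amplitude, width = 0.22) {
  # anchor: outermost right-side mouth landmark of the Orbicularis Oris group
  oris <- topo$muscle_groups[[8]]$indices
  oris_r <- intersect(oris, topo$pairs[, 2])
  corner_r <- points[oris_r[which.max(points[oris_r + 1L, 1])] + 1L, ]
  corner_l <- corner_r * c(-1, 1, 1)
  dir_r <- c(0.6, 0.75, 0.25); dir_r <- dir_r / sqrt(sum(dir_r^2))
  dir_l <- dir_r * c(-1, 1, 1)
  w2 <- 2 * width^2
  dr2 <- rowSums((points - rep(corner_r, each = nrow(points)))^2)
  dl2 <- rowSums((points - rep(corner_l, each = nrow(points)))^2)
  amplitude * (exp(-dr2 / w2) %o% dir_r + exp(-dl2 / w2) %o% dir_l)
}

#' Apply a smile expression (and optional palsy/noise/pose) to a template
#'
#' Starting from a neutral template, applies in order: static structural
#' asymmetry jitter on the palsy side, the mirror-symmetric smile
#' displacement field attenuated by `palsy_attenuation` on the palsy side,
#' isotropic measurement noise, and finally the optional similarity
#' disturbance. With `palsy_attenuation = 1`, no jitter and no noise the
#' result is exactly mirror-symmetric.
#'
#' @param ls The neutral template `landmark_set`.
#' @param topo Matching `face_topology`.
#' @param cfg A [synthetic_face_config()].
#' @return A `landmark_set` with expression `"smile"`. The attribute
#'   `"ground_truth"` carries the applied similarity `transform`, the clean
#'   `displacement` field (n x 3, before noise/transform) and the per-side
#'   displacement magnitudes, for use as test oracles.
#' @export
apply_expression <- function(ls, topo, cfg) {
  assert_landmark_set(ls)
  if (!identical(ls$mode, cfg$mode) || !identical(topo$mode, cfg$mode))
    fs_stop_validation("landmarks, topology and config must share one mode")
  pts <- ls$points
  n <- nrow(pts)
  side <- rep("M", n)
  side[topo$pairs[, 1] + 1L] <- "L"
  side[topo$pairs[, 2] + 1L] <- "R"
  on_palsy <- side == switch(cfg$palsy_side, left = "L", right = "R", none = "")

  with_seed(cfg$seed, {
    if (cfg$asymmetry_jitter > 0 && any(on_palsy))
      pts[on_palsy, ] <- pts[on_palsy, ] +
        matrix(stats::rnorm(3 * sum(on_palsy), 0, cfg$asymmetry_jitter),
               ncol = 3)
    disp <- smile_field(ls$points, topo, cfg$expression_amplitude)
    disp[on_palsy, ] <- disp[on_palsy, ] * cfg$palsy_attenuation
    pts <- pts + disp
    if (cfg$noise_sd > 0)
      pts <- pts + matrix(stats::rnorm(3 * n, 0, cfg$noise_sd / sqrt(3)),
                          ncol = 3)
  })
  if (!is.null(cfg$transform)) pts <- apply_transform(cfg$transform, pts)

  out <- landmark_set(pts, cfg$mode, subject_id = ls$subject_id,
                      session_label = ls$session_label, expression = "smile")
  attr(out, "ground_truth") <- list(
    transform = cfg$transform %||% identity_transform(),
    displacement = disp,
    movement_left = sqrt(rowSums(disp[topo$pairs[, 1] + 1L, , drop = FALSE]^2)),
    movement_right = sqrt(rowSums(disp[topo$pairs[, 2] + 1L, , drop = FALSE]^2)))
  out
}

#' Generate a complete synthetic capture session
#'
#' Convenience wrapper producing a neutral/smile pair for one session,
#' applying the session pose disturbance to both captures (the smile
#' additionally carries the expression field).
#'
#' @param cfg A [synthetic_face_config()].
#' @param subject_id,session_label Metadata for the generated sets.
#' @return List with `neutral`, `smile` (landmark sets), `topology`, and
#'   `ground_truth` (from [apply_expression()]).
#' @export
generate_session <- function(cfg, subject_id = "synthetic",
                             session_label = "session1") {
  tpl <- generate_template(cfg$mode, cfg$seed)
  neutral <- tpl$landmarks
  neutral$subject_id <- subject_id
  neutral$session_label <- session_label
  smile <- apply_expression(neutral, tpl$topology, cfg)
  if (!is.null(cfg$transform))
    neutral <- set_points(neutral, apply_transform(cfg$transform, neutral$points))
  list(neutral = neutral, smile = smile, topology = tpl$topology,
       ground_truth = attr(smile, "ground_truth"))
}

#' Synthetic registration benchmark case
#'
#' Builds a (source, target) landmark pair with known ground truth: the
#' source is the neutral template (or a smile derived from it) and the
#' target is the source under a random similarity transform plus isotropic
#' noise. Draws are seed-deterministic: scale in `[0.8, 1.25]`, rotation
#' about a random axis with angle up to 25 degrees, translation uniform in
#' `[-0.05, 0.05]` per axis (landmark coordinates from face-cropped
#' detectors are position-normalized, so inter-capture translation is a
#' small residual).
#'
#' @param seed Case seed.
#' @param noise_sd RMS 3D noise per landmark added to the target.
#' @param mode Topology mode.
#' @param expression If `"smile"`, the source carries a smile deformation.
#' @return List with `source`, `target` (landmark sets), `topology`,
#'   `transform` (the ground-truth similarity) and `noise_sd`.
#' @export
make_benchmark_case <- function(seed, noise_sd = 0, mode = "full_478",
                                expression = c("neutral", "smile")) {
  expression <- match.arg(expression)
  tpl <- generate_template(mode, seed)
  src <- tpl$landmarks
  if (expression == "smile")
    src <- apply_expression(src, tpl$topology,
                            synthetic_face_config(mode, seed = seed))
  gt <- with_seed(seed, {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    ang <- stats::runif(1, 0, 25 * pi / 180)
    list(R = rotation_from_axis_angle(ax * ang),
         scale = stats::runif(1, 0.8, 1.25),
         t = stats::runif(3, -0.05, 0.05),
         eps = matrix(stats::rnorm(3 * n_landmarks(src), 0,
                                   noise_sd / sqrt(3)), ncol = 3))
  })
  tf <- make_transform(gt$R, gt$t, gt$scale)
  tgt <- set_points(src, apply_transform(tf, src$points) +
                      if (noise_sd > 0) gt$eps else 0)
  tgt$session_label <- "target"
  list(source = src, target = tgt, topology = tpl$topology,
       transform = tf, noise_sd = noise_sd)
}
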