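#' Per-side landmark movement between neutral and smile
#'
#' After registering the smile capture into the neutral frame, the movement
#' amount of the `i`-th pair on each side is the displacement magnitude of
#' the corresponding landmark: `m_L,i = ||s_i^L - n_i^L||` and
#' `m_R,i = ||s_i^R - n_i^R||`, where `s` is the (registered) smile and `n`
#' the neutral capture.
#'
#' @param neutral,smile `landmark_set`s of the same subject and mode.
#' @param topo Matching `face_topology`.
#' @param reg A `registration_result` mapping smile into the neutral frame
#'   (see [register_landmarks()] with `source = smile, target = neutral`),
#'   a bare `homogeneous_transform`, or `NULL` for captures already in a
#'   common frame.
#' @return Data frame with columns `left`, `right`, `m_left`, `m_right`.
#' @export
movement_amounts <- function(neutral, smile, topo, reg = NULL) {
  assert_landmark_set(neutral, "neutral"); assert_landmark_set(smile, "smile")
  assert_same_mode(neutral, smile)
  if (!identical(neutral$mode, topo$mode))
    fs_stop_validation("topology mode does not match the landmark sets")
  tf <- if (is.null(reg)) identity_transform()
  else if (inherits(reg, "homogeneous_transform")) reg
  else reg$transform
  sp <- apply_transform(tf, smile$points)
  d <- sp - neutral$points
  m <- sqrt(rowSums(d^2))
  out <- data.frame(left = topo$pairs[, 1], right = topo$pairs[, 2])
  out$m_left <- m[out$left + 1L]
  out$m_right <- m[out$right + 1L]
  out
}

#' Left-right movement asymmetry per pair and muscle group
#'
#' The `i`-th landmark movement score is the difference between the left
#' and right movement amounts; zero means perfectly symmetric motion.
#' The per-pair score is reported as an absolute value before averaging
#' (signed means would cancel opposing pairs within a muscle); the signed
#' difference is kept alongside.
#'
#' @param amounts Data frame from [movement_amounts()] (columns `left`,
#'   `right`, `m_left`, `m_right`).
#' @param topo Matching `face_topology`.
#' @param scale Reporting scale for the per-muscle table (x100 by
#'   convention).
#' @param decimals Rounding for the per-muscle table (default 3).
#' @param reg Optional `registration_result` to record in the report.
#' @return A `movement_report`: list with `per_pair` (adds `diff` and
#'   `abs_diff` columns) and `per_muscle` (mean abs difference per group,
#'   scaled and rounded), plus `registration_used`.
#' @export
movement_asymmetry <- function(amounts, topo, scale = 100, decimals = 3,
                               reg = NULL) {
  need <- c("left", "right", "m_left", "m_right")
  if (!all(need %in% names(amounts)))
    fs_stop_validation("`amounts` must have columns left, right, m_left, m_right")
  pp <- amounts
  pp$diff <- pp$m_left - pp$m_right
  pp$abs_diff <- abs(pp$diff)
  per_pair_vals <- data.frame(left = pp$left, right = pp$right,
                              value = pp$abs_diff)
  structure(list(
    per_pair = pp,
    per_muscle = aggregate_by_muscle(per_pair_vals, topo, scale, decimals),
    registration_used = reg, scale = scale, decimals = decimals),
    class = "movement_report")
}

#' @export
print.movement_report <- function(x, ...) {
  cat("<movement_report>\n")
  tab <- x$per_muscle
  names(tab) <- c("group", "name", "movement_asymmetry", "n_pairs")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Neutral/smile movement analysis in one call
#'
#' Registers the smile capture onto the neutral capture with the scale-sweep
#' pipeline, then computes the movement asymmetry report.
#'
#' @param neutral,smile `landmark_set`s.
#' @param topo Matching `face_topology`.
#' @param cfg A [registration_config()].
#' @param scale,decimals Reporting convention.
#' @return A `movement_report` (the registration is in
#'   `$registration_used`).
#' @export
movement_analysis <- function(neutral, smile, topo,
                              cfg = registration_config(), scale = 100,
                              decimals = 3) {
  reg <- register_landmarks(smile, neutral, cfg, method = "proposed")
  movement_asymmetry(movement_amounts(neutral, smile, topo, reg), topo,
                     scale, decimals, reg = reg)
}
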