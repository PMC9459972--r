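#' Session manifest records
#'
#' @param subject_id,session_label Identifiers; labels must be unique per
#'   subject.
#' @param capture_date ISO-8601 date string.
#' @param neutral_path,smile_path Landmark file paths for the two
#'   expressions.
#' @return A one-row data frame; rbind records to build a manifest.
#' @export
session_record <- function(subject_id, session_label, capture_date,
                           neutral_path, smile_path) {
  data.frame(subject_id = subject_id, session_label = session_label,
             capture_date = capture_date, neutral_path = neutral_path,
             smile_path = smile_path)
}

#' @noRd
read_manifest_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    fs_stop_io("the 'yaml' package is required to read manifests")
  obj <- yaml::read_yaml(path)
  sessions <- obj$sessions %||% obj
  do.call(rbind, lapply(sessions, function(s)
    session_record(s$subject_id %||% "unknown", s$session_label,
                   s$date %||% NA_character_, s$neutral, s$smile)))
}

#' Longitudinal symmetry and movement tracking
#'
#' Runs the full analysis across a subject's sessions: the first session is
#' the registration reference; every later session's captures are
#' registered onto the reference neutral so distance magnitudes share one
#' scale; per-session static symmetry (computed on the smile expression)
#' and neutral-to-smile movement asymmetry are aggregated per muscle group
#' into tidy long-format tables, one row per (session, muscle group).
#'
#' @param manifest Data frame of [session_record()]s (or a manifest YAML
#'   path), all rows one subject.
#' @param cfg A [registration_config()].
#' @param mode Topology mode of the landmark files.
#' @param topo Optional `face_topology` override.
#' @param decimals_distance,decimals_movement Rounding conventions for the
#'   two table families.
#' @return A `longitudinal_report`: list with `symmetry` and `movement`
#'   long-format data frames, `sessions` (processed labels), and `failures`
#'   (named character vector of skipped sessions).
#' @export
run_longitudinal <- function(manifest, cfg = registration_config(),
                             mode = "full_478", topo = NULL,
                             decimals_distance = 6, decimals_movement = 3) {
  if (is.character(manifest) && length(manifest) == 1)
    manifest <- read_manifest_yaml(manifest)
  if (is.null(manifest) || nrow(manifest) == 0)
    fs_stop("manifest must contain at least one session",
            "facesym_usage_error")
  if (anyDuplicated(manifest$session_label))
    fs_stop_validation("session labels must be unique per subject")
  topo <- topo %||% load_topology(mode)

  sym_rows <- list(); mov_rows <- list()
  failures <- character(0)
  reference <- NULL
  for (k in seq_len(nrow(manifest))) {
    rec <- manifest[k, ]
    sess <- tryCatch({
      neutral <- load_landmarks(rec$neutral_path, mode,
                                subject_id = rec$subject_id,
                                session_label = rec$session_label,
                                expression = "neutral")
      smile <- load_landmarks(rec$smile_path, mode,
                              subject_id = rec$subject_id,
                              session_label = rec$session_label,
                              expression = "smile")
      list(neutral = neutral, smile = smile)
    }, facesym_error = function(e) e)
    if (inherits(sess, "error")) {
      failures[rec$session_label] <- conditionMessage(sess)
      next
    }
    if (is.null(reference)) {
      reference <- sess$neutral
      to_ref <- NULL
    } else {
      to_ref <- tryCatch(
        register_landmarks(sess$neutral, reference, cfg, "proposed"),
        facesym_error = function(e) e)
      if (inherits(to_ref, "error")) {
        failures[rec$session_label] <- conditionMessage(to_ref)
        next
      }
    }
    smile_ref <- if (is.null(to_ref)) sess$smile else
      set_points(sess$smile, apply_transform(to_ref$transform,
                                             sess$smile$points))
    neutral_ref <- if (is.null(to_ref)) sess$neutral else
      set_points(sess$neutral, apply_transform(to_ref$transform,
                                               sess$neutral$points))
    sym <- symmetry_report(smile_ref, topo, decimals = decimals_distance)
    # movement is a longitudinal comparison: with a single session there is
    # nothing to track, so only the symmetry tables are produced
    mov <- NULL
    if (nrow(manifest) > 1) {
      within_reg <- register_landmarks(smile_ref, neutral_ref, cfg, "proposed")
      mov <- movement_asymmetry(
        movement_amounts(neutral_ref, smile_ref, topo, within_reg),
        topo, decimals = decimals_movement, reg = within_reg)
    }
    sym_tab <- merge(sym$per_muscle_distance, sym$per_muscle_angle,
                     by = c("group_id", "group_name"),
                     suffixes = c("_d", "_a"))
    sym_rows[[rec$session_label]] <- data.frame(
      session = rec$session_label, group_id = sym_tab$group_id,
      group_name = sym_tab$group_name,
      distance_symmetry = sym_tab$value_d,
      angle_symmetry = sym_tab$value_a, n_pairs = sym_tab$n_pairs_d)
    if (!is.null(mov))
      mov_rows[[rec$session_label]] <- data.frame(
        session = rec$session_label,
        group_id = mov$per_muscle$group_id,
        group_name = mov$per_muscle$group_name,
        movement_asymmetry = mov$per_muscle$value,
        n_pairs = mov$per_muscle$n_pairs)
  }
  if (!length(sym_rows))
    fs_stop("no session could be processed", "facesym_registration_error")
  sym <- do.call(rbind, sym_rows); rownames(sym) <- NULL
  mov <- if (length(mov_rows)) do.call(rbind, mov_rows) else
    data.frame(session = character(0), group_id = integer(0),
               group_name = character(0), movement_asymmetry = numeric(0),
               n_pairs = integer(0))
  sym <- sym[order(match(sym$session, manifest$session_label), sym$group_id), ]
  mov <- mov[order(match(mov$session, manifest$session_label), mov$group_id), ]
  rownames(sym) <- rownames(mov) <- NULL
  structure(list(symmetry = sym, movement = mov,
                 sessions = names(sym_rows), failures = failures),
            class = "longitudinal_report")
}

#' @export
print.longitudinal_report <- function(x, ...) {
  cat(sprintf("<longitudinal_report: %d session(s), %d skipped>\n",
              length(x$sessions), length(x$failures)))
  invisible(x)
}

#' Write longitudinal report tables as CSV
#'
#' Values are formatted with up to 12 significant digits so that repeated
#' runs with identical inputs produce byte-identical files.
#'
#' @param report A `longitudinal_report`.
#' @param symmetry_path,movement_path Output CSV paths (`NULL` to skip one).
#' @return Invisibly, the paths written.
#' @export
write_longitudinal_csv <- function(report, symmetry_path = NULL,
                                   movement_path = NULL) {
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
    df
  }
  if (!is.null(symmetry_path))
    utils::write.csv(fmt(report$symmetry), symmetry_path, row.names = FALSE,
                     quote = FALSE)
  if (!is.null(movement_path))
    utils::write.csv(fmt(report$movement), movement_path, row.names = FALSE,
                     quote = FALSE)
  invisible(c(symmetry_path, movement_path))
}
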