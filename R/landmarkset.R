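#' 3D facial landmark sets
#'
#' A `landmark_set` holds an ordered, dense (0-based indices `0..n-1`) set of
#' `n` 3D landmark coordinates in model units, together with capture metadata.
#' Two topology modes are supported: `"full_478"` (468 face-mesh landmarks
#' plus 10 eye landmarks) and `"compact_68"` (the classic sparse layout).
#'
#' @param points An `n x 3` numeric matrix of landmark coordinates.
#' @param mode Topology mode, `"full_478"` or `"compact_68"`.
#' @param subject_id,session_label Free-form capture metadata strings.
#' @param expression One of `"neutral"`, `"smile"`, `"other"`.
#' @return A validated `landmark_set` object.
#' @examples
#' tpl <- generate_template("compact_68")
#' ls <- tpl$landmarks
#' n_landmarks(ls)
#' @export
landmark_set <- function(points, mode = c("full_478", "compact_68"),
                         subject_id = "unknown", session_label = "unknown",
                         expression = c("neutral", "smile", "other")) {
  mode <- match.arg(mode)
  expression <- match.arg(expression)
  p <- as.matrix(points)
  if (!is.numeric(p) || ncol(p) != 3)
    fs_stop_validation("landmark points must be an n x 3 numeric matrix")
  if (any(!is.finite(p)))
    fs_stop_validation("landmark coordinates must all be finite")
  n_expected <- mode_size(mode)
  if (nrow(p) != n_expected)
    fs_stop_validation(sprintf(
      "mode '%s' requires %d landmarks, got %d", mode, n_expected, nrow(p)))
  dimnames(p) <- list(NULL, c("x", "y", "z"))
  structure(
    list(points = p, n_landmarks = nrow(p), mode = mode,
         subject_id = as.character(subject_id),
         session_label = as.character(session_label),
         expression = expression),
    class = "landmark_set")
}

#' @rdname landmark_set
#' @param ls A `landmark_set`.
#' @export
n_landmarks <- function(ls) ls$n_landmarks

#' @noRd
mode_size <- function(mode) c(full_478 = 478L, compact_68 = 68L)[[mode]]

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "<landmark_set: %d landmarks (%s), subject '%s', session '%s', %s>\n",
    x$n_landmarks, x$mode, x$subject_id, x$session_label, x$expression))
  invisible(x)
}

#' @noRd
assert_landmark_set <- function(ls, arg = "ls") {
  if (!inherits(ls, "landmark_set"))
    fs_stop_validation(paste0("`", arg, "` must be a landmark_set"))
  invisible(ls)
}

#' @noRd
assert_same_mode <- function(a, b) {
  if (!identical(a$mode, b$mode))
    fs_stop_validation(sprintf("topology modes differ: '%s' vs '%s'", a$mode, b$mode))
  invisible(NULL)
}

# replace the coordinates of a landmark_set, keeping metadata
#' @noRd
set_points <- function(ls, points) {
  ls$points <- as.matrix(points)
  dimnames(ls$points) <- list(NULL, c("x", "y", "z"))
  ls
}

#' Read a landmark set from CSV or JSON
#'
#' The CSV dialect has a header `index,x,y,z` with 0-based landmark indices;
#' rows may appear in any order and are re-sorted to dense ascending order.
#' The JSON dialect is an object
#' `{subject_id, session_label, expression, mode, points: [[x,y,z], ...]}`.
#' The format is chosen by file extension (`.csv` / `.json`).
#'
#' @param path Input file path.
#' @param mode Topology mode the file must match; for JSON files the default
#'   `NULL` takes the mode stored in the file.
#' @param subject_id,session_label,expression Metadata overrides for CSV input
#'   (CSV carries no metadata).
#' @return A validated `landmark_set`.
#' @export
load_landmarks <- function(path, mode = NULL, subject_id = "unknown",
                           session_label = "unknown", expression = "neutral") {
  if (!file.exists(path)) fs_stop_io(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (f in c("mode", "points"))
      if (is.null(obj[[f]])) fs_stop_format(paste0("landmark JSON lacks field '", f, "'"))
    if (!is.null(mode) && !identical(obj$mode, mode))
      fs_stop_validation(sprintf("file mode '%s' does not match requested '%s'",
                                 obj$mode, mode))
    pts <- obj$points
    if (is.list(pts)) pts <- do.call(rbind, lapply(pts, as.numeric))
    return(landmark_set(pts, obj$mode,
                        subject_id = obj$subject_id %||% subject_id,
                        session_label = obj$session_label %||% session_label,
                        expression = obj$expression %||% expression))
  }
  if (ext != "csv") fs_stop_format(paste0("unsupported landmark format: .", ext))
  df <- tryCatch(utils::read.csv(path), error = function(e)
    fs_stop_format(paste0("cannot parse CSV: ", conditionMessage(e))))
  need <- c("index", "x", "y", "z")
  if (!all(need %in% names(df)))
    fs_stop_format("landmark CSV must have header `index,x,y,z`")
  idx <- df$index
  if (anyDuplicated(idx)) fs_stop_format("duplicate landmark index in CSV")
  if (is.null(mode)) fs_stop_validation("`mode` is required for CSV input")
  n <- mode_size(mode)
  if (!setequal(idx, 0:(n - 1)))
    if (nrow(df) != n)
      fs_stop_validation(sprintf("mode '%s' requires %d rows, got %d", mode, n, nrow(df)))
    else
      fs_stop_format("landmark indices must be dense 0..n-1")
  ord <- order(idx)
  landmark_set(as.matrix(df[ord, c("x", "y", "z")]), mode,
               subject_id = subject_id, session_label = session_label,
               expression = expression)
}

#' Write a landmark set to CSV or JSON
#'
#' Coordinates are written with 17 significant digits so that a save/load
#' round trip reproduces them bit-for-bit. The format is chosen by extension.
#'
#' @param ls A `landmark_set`.
#' @param path Output file path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
save_landmarks <- function(ls, path) {
  assert_landmark_set(ls)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- list(subject_id = ls$subject_id, session_label = ls$session_label,
                expression = ls$expression, mode = ls$mode,
                points = unname(apply(ls$points, 1, function(r) r, simplify = FALSE)))
    ok <- tryCatch({
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(path)) fs_stop_io(paste0("cannot write: ", path))
    return(invisible(path))
  }
  if (ext != "csv") fs_stop_format(paste0("unsupported landmark format: .", ext))
  lines <- c("index,x,y,z", sprintf("%d,%.17g,%.17g,%.17g",
                                    0:(ls$n_landmarks - 1),
                                    ls$points[, 1], ls$points[, 2], ls$points[, 3]))
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path)) fs_stop_io(paste0("cannot write: ", path))
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
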