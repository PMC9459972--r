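#' Midsagittal plane of a face
#'
#' The 3D symmetry plane is the perpendicular bisector of the segment
#' joining the two iris landmarks: it passes through their midpoint and its
#' unit normal points from the left iris toward the right iris.
#'
#' @param ls A `landmark_set`.
#' @param topo Matching `face_topology` (supplies the iris indices).
#' @return A `midsagittal_plane`: list with `point` and unit `normal`.
#' @export
midsagittal_plane <- function(ls, topo) {
  assert_landmark_set(ls)
  l <- unname(ls$points[topo$left_iris_index + 1L, ])
  r <- unname(ls$points[topo$right_iris_index + 1L, ])
  d <- r - l
  nrm <- sqrt(sum(d^2))
  if (nrm == 0)
    fs_stop_degenerate("iris landmarks coincide; midsagittal plane undefined")
  structure(list(point = (l + r) / 2, normal = d / nrm),
            class = "midsagittal_plane")
}

#' @export
print.midsagittal_plane <- function(x, ...) {
  cat(sprintf("<midsagittal_plane: point (%.4g, %.4g, %.4g), normal (%.4g, %.4g, %.4g)>\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Reflect points across a plane
#'
#' `p - 2 * ((p - point) . normal) * normal`; an involution.
#'
#' @param p Length-3 point or n x 3 matrix.
#' @param plane A `midsagittal_plane`.
#' @return Reflected point(s), same shape as `p`.
#' @export
reflect_across_plane <- function(p, plane) {
  v <- is.null(dim(p))
  P <- if (v) matrix(p, 1, 3) else as.matrix(p)
  a <- (sweep(P, 2, plane$point) %*% plane$normal)[, 1]
  out <- P - 2 * a %o% plane$normal
  if (v) drop(out) else out
}

#' @noRd
pair_frame <- function(ls, topo) {
  data.frame(left = topo$pairs[, 1], right = topo$pairs[, 2])
}

#' Per-pair distance symmetry
#'
#' For every (left, right) landmark pair, the left landmark is reflected
#' across the midsagittal plane and the Euclidean distance to its right
#' partner is reported: `d_i = ||p_i^R - reflect(p_i^L)||`. Zero means
#' perfect mirror symmetry. Midline landmarks are excluded by construction.
#'
#' @param ls A `landmark_set`.
#' @param topo Matching `face_topology`.
#' @param plane Optional precomputed [midsagittal_plane()].
#' @return Data frame with columns `left`, `right` (0-based indices) and
#'   `value` (model units).
#' @export
distance_symmetry <- function(ls, topo, plane = midsagittal_plane(ls, topo)) {
  out <- pair_frame(ls, topo)
  pl <- ls$points[out$left + 1L, , drop = FALSE]
  pr <- ls$points[out$right + 1L, , drop = FALSE]
  out$value <- sqrt(rowSums((pr - reflect_across_plane(pl, plane))^2))
  out
}

#' Per-pair angle symmetry (cosine similarity)
#'
#' For every pair, the pair vector `a = p^R - p^L` is compared with the
#' midsagittal plane normal by cosine similarity
#' `cos(theta) = (n . a) / (||n|| ||a||)`; 1 means the pair vector is
#' perfectly aligned with the symmetry normal (perfect symmetry), 0 means
#' perpendicular. A zero-length pair vector is flagged (`NA`) with a
#' warning and excluded from downstream means.
#'
#' @inheritParams distance_symmetry
#' @return Data frame with columns `left`, `right`, `value` (cosines in
#'   `[-1, 1]`, `NA` for degenerate pairs).
#' @export
angle_symmetry <- function(ls, topo, plane = midsagittal_plane(ls, topo)) {
  out <- pair_frame(ls, topo)
  a <- ls$points[out$right + 1L, , drop = FALSE] -
    ls$points[out$left + 1L, , drop = FALSE]
  an <- sqrt(rowSums(a^2))
  bad <- an == 0
  an[bad] <- 1
  out$value <- as.numeric(a %*% plane$normal) / an
  if (any(bad)) {
    out$value[bad] <- NA_real_
    fs_warn(sprintf("%d zero-length pair vector(s) excluded from angle symmetry",
                    sum(bad)))
  }
  out
}

#' Aggregate per-pair values over muscle groups
#'
#' For each of the 17 muscle groups, averages the values of pairs whose
#' BOTH members belong to the group, multiplies by the reporting scale
#' (x100 by convention) and rounds. Pairs straddling two groups contribute
#' to neither (their count is returned as an attribute); groups with no
#' eligible pair report `NA` with `n_pairs = 0`.
#'
#' @param values Per-pair data frame (`left`, `right`, `value`) from
#'   [distance_symmetry()], [angle_symmetry()] or [movement_asymmetry()].
#' @param topo Matching `face_topology`.
#' @param scale Reporting scale (default 100).
#' @param decimals Rounding for display (default 6).
#' @return Data frame `group_id`, `group_name`, `value`, `n_pairs`, with
#'   attribute `n_cross_pairs`.
#' @export
aggregate_by_muscle <- function(values, topo, scale = 100, decimals = 6) {
  stopifnot(all(c("left", "right", "value") %in% names(values)))
  nm <- muscle_group_names()
  res <- data.frame(group_id = 1:17, group_name = nm, value = NA_real_,
                    n_pairs = 0L)
  cross <- 0L
  for (k in 1:17) {
    idx <- topo$muscle_groups[[k]]$indices
    both <- values$left %in% idx & values$right %in% idx
    one <- xor(values$left %in% idx, values$right %in% idx)
    cross <- cross + sum(one)
    v <- values$value[both]
    v <- v[!is.na(v)]
    res$n_pairs[k] <- length(v)
    if (length(v)) res$value[k] <- round(mean(v) * scale, decimals)
  }
  attr(res, "n_cross_pairs") <- cross
  res
}

#' Flattened per-muscle angle symmetry
#'
#' Alternative aggregation that concatenates all pair vectors of a group
#' into one long vector (with the plane normal repeated alongside) and
#' takes a single cosine per group, instead of averaging per-pair cosines.
#'
#' @inheritParams distance_symmetry
#' @param scale,decimals Reporting scale and rounding.
#' @return Data frame `group_id`, `group_name`, `value`, `n_pairs`.
#' @export
angle_symmetry_flattened <- function(ls, topo,
                                     plane = midsagittal_plane(ls, topo),
                                     scale = 100, decimals = 6) {
  pf <- pair_frame(ls, topo)
  a <- ls$points[pf$right + 1L, , drop = FALSE] -
    ls$points[pf$left + 1L, , drop = FALSE]
  nm <- muscle_group_names()
  res <- data.frame(group_id = 1:17, group_name = nm, value = NA_real_,
                    n_pairs = 0L)
  for (k in 1:17) {
    idx <- topo$muscle_groups[[k]]$indices
    both <- pf$left %in% idx & pf$right %in% idx
    if (!any(both)) next
    ak <- a[both, , drop = FALSE]
    nk <- matrix(plane$normal, nrow(ak), 3, byrow = TRUE)
    res$n_pairs[k] <- nrow(ak)
    res$value[k] <- round(sum(nk * ak) /
                            (sqrt(sum(nk^2)) * sqrt(sum(ak^2))) * scale,
                          decimals)
  }
  res
}

#' Full static-symmetry report for one capture
#'
#' Computes the midsagittal plane, per-pair distance and angle symmetry,
#' and their per-muscle aggregates (x100, rounded) in one call.
#'
#' @inheritParams distance_symmetry
#' @param scale,decimals Reporting convention for the per-muscle tables.
#' @return A `symmetry_report`: list with `plane`, `per_pair_distance`,
#'   `per_pair_cosine`, `per_muscle_distance`, `per_muscle_angle`.
#' @export
symmetry_report <- function(ls, topo, plane = midsagittal_plane(ls, topo),
                            scale = 100, decimals = 6) {
  d <- distance_symmetry(ls, topo, plane)
  a <- angle_symmetry(ls, topo, plane)
  structure(list(
    plane = plane,
    per_pair_distance = d, per_pair_cosine = a,
    per_muscle_distance = aggregate_by_muscle(d, topo, scale, decimals),
    per_muscle_angle = aggregate_by_muscle(a, topo, scale, decimals),
    scale = scale, decimals = decimals), class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat("<symmetry_report>\n")
  tab <- merge(x$per_muscle_distance, x$per_muscle_angle,
               by = c("group_id", "group_name"), suffixes = c("_dist", "_angle"))
  tab <- tab[order(tab$group_id), c("group_id", "group_name", "value_dist",
                                    "value_angle", "n_pairs_dist")]
  names(tab) <- c("group", "name", "distance_symmetry", "angle_symmetry",
                  "n_pairs")
  print(tab, row.names = FALSE)
  invisible(x)
}
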