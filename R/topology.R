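#' Muscle-group names used for aggregation
#'
#' Seventeen facial regions: sixteen mimetic/masticatory muscles plus the
#' nose tip, which is not a muscle but bends under palsy of its neighbours
#' and is therefore a useful analysis region.
#'
#' @return Character vector of length 17, in group-id order.
#' @export
muscle_group_names <- function() c(
  "Frontalis", "Corrugator", "Procerus", "Orbicularis Oculi",
  "Levator Labii Superioris", "Nasalis", "Nose Tip", "Orbicularis Oris",
  "Mentalis", "Depressor Anguli Oris", "Zygomaticus Minor",
  "Zygomaticus Major", "Buccinator", "Risorius", "Platysma", "Masseter",
  "Temporalis")

# published per-group landmark counts the bundled resources must reproduce
#' @noRd
muscle_group_cardinalities <- function(mode) {
  if (mode == "full_478")
    c(6L, 1L, 1L, 59L, 10L, 6L, 32L, 44L, 6L, 8L, 6L, 3L, 4L, 3L, 5L, 9L, 16L)
  else
    c(0L, 0L, 2L, 6L, 0L, 2L, 3L, 12L, 0L, 2L, 0L, 0L, 0L, 0L, 2L, 4L, 1L)
}

# ---------------------------------------------------------------------------
# Procedural canonical layout.
#
# The layout is the single source of truth for (a) the bundled topology
# resources and (b) the synthetic template geometry. The right half (x > 0)
# is authored; the left half is its exact mirror across the x = 0 plane;
# midline landmarks sit on x = 0. A small deterministic position jitter keeps
# landmarks in dense regions from coinciding exactly.
# ---------------------------------------------------------------------------

# frontal head surface height field; even in x so mirroring is exact
#' @noRd
face_surface_z <- function(x, y) {
  base <- 0.75 * sqrt(pmax(0, 1 - (x / 0.95)^2 - (y / 1.10)^2))
  nose <- 0.22 * exp(-(x^2 + (y + 0.05)^2) / 0.018)
  brow <- 0.04 * exp(-((y - 0.40)^2) / 0.02)
  socket <- -0.05 * exp(-((abs(x) - 0.38)^2 + (y - 0.28)^2) / 0.012)
  lips <- 0.05 * exp(-((x / 1.6)^2 + (y + 0.42)^2) / 0.02)
  base + nose + brow + socket + lips
}

#' @noRd
face_layout <- function(mode) {
  units <- list()
  ucount <- 0L
  jit <- function(a, p) 0.004 * sin(3.7 * ucount + a + p)
  pair <- function(x, y, g = 0L, gl = g, gr = g, iris = FALSE) {
    ucount <<- ucount + 1L
    units[[length(units) + 1L]] <<- list(
      type = "pair", x = x + jit(1, 0), y = y + jit(2, 0.5),
      gl = as.integer(gl), gr = as.integer(gr), iris = iris)
  }
  pairs <- function(xs, ys, g = 0L) for (k in seq_along(xs)) pair(xs[k], ys[k], g)
  mid <- function(y, g = 0L) {
    ucount <<- ucount + 1L
    units[[length(units) + 1L]] <<- list(type = "mid", y = y + jit(2, 0.5),
                                         g = as.integer(g))
  }
  ring <- function(cx, cy, rx, ry, n, g = 0L, span = c(0, 2 * pi)) {
    t <- seq(span[1], span[2], length.out = n + 1)[seq_len(n)]
    pairs(cx + rx * cos(t), cy + ry * sin(t), g)
  }
  # right half of an open arc (used for lip rings): angles strictly off x = 0
  half_ring <- function(cy, rx, ry, n, deg_max, g = 0L) {
    t <- seq(-deg_max, deg_max, length.out = n) * pi / 180
    pairs(rx * cos(t), cy + ry * sin(t), g)
  }
  hw <- function(y) 0.76 * sqrt(pmax(0.02, 1 - ((y + 0.05) / 0.82)^2))

  if (mode == "full_478") {
    ey <- c(0.38, 0.28)                               # right eye centre
    # -- grouped landmarks (published per-group cardinalities) --
    pairs(c(0.18, 0.33, 0.47), c(0.62, 0.59, 0.54), 1)        # Frontalis 3x2
    pair(0.10, 0.44, gl = 2L, gr = 0L)                        # Corrugator half
    mid(0.40, 3)                                              # Procerus
    ring(ey[1], ey[2], 0.13, 0.08, 12, 4)                     # Orb. Oculi rings
    ring(ey[1], ey[2], 0.17, 0.12, 10, 4)
    ring(ey[1], ey[2], 0.21, 0.16, 7, 4)
    pair(0.13, 0.38, gl = 0L, gr = 4L)                        # Orb. Oculi half
    pairs(c(0.10, 0.16, 0.22, 0.28, 0.33),
          c(-0.20, -0.18, -0.18, -0.20, -0.24), 5)            # Lev. Labii 5x2
    pairs(c(0.08, 0.10, 0.12), c(0.02, -0.04, -0.10), 6)      # Nasalis 3x2
    pairs(c(0.03, 0.05, 0.07, 0.09, 0.05, 0.03, 0.06, 0.04, 0.08, 0.10,
            0.02, 0.02, 0.07, 0.09, 0.11),
          c(-0.02, -0.05, -0.08, -0.11, -0.12, -0.08, 0.00, -0.14, -0.14,
            -0.13, -0.05, -0.11, -0.03, -0.05, -0.09), 7)     # Nose tip 15x2
    mid(-0.02, 7); mid(-0.12, 7)                              # nose tip midline
    half_ring(-0.42, 0.22, 0.100, 11, 80, 8)                  # Orb. Oris outer
    half_ring(-0.42, 0.17, 0.065, 10, 75, 8)                  # Orb. Oris middle
    mid(-0.32, 8); mid(-0.52, 8)                              # lip midline
    pairs(c(0.05, 0.09), c(-0.62, -0.66), 9)                  # Mentalis 2x2
    mid(-0.60, 9); mid(-0.66, 9)
    pairs(c(0.24, 0.28, 0.22, 0.30), c(-0.50, -0.54, -0.56, -0.48), 10)
    pairs(c(0.28, 0.33, 0.38), c(-0.08, -0.12, -0.16), 11)    # Zyg. Minor
    pair(0.44, -0.20, 12)                                     # Zyg. Major
    pair(0.48, -0.26, gl = 0L, gr = 12L)
    pairs(c(0.42, 0.47), c(-0.34, -0.38), 13)                 # Buccinator
    pair(0.36, -0.42, 14)                                     # Risorius
    pair(0.40, -0.46, gl = 14L, gr = 0L)
    pairs(c(0.26, 0.34), c(-0.78, -0.72), 15)                 # Platysma
    pair(0.18, -0.83, gl = 0L, gr = 15L)
    pairs(c(0.54, 0.58, 0.50, 0.56), c(-0.42, -0.34, -0.50, -0.26), 16)
    pair(0.60, -0.44, gl = 16L, gr = 0L)                      # Masseter half
    for (tx in c(0.58, 0.66)) for (ty in c(0.28, 0.38, 0.48, 0.58))
      pair(tx, ty, 17)                                        # Temporalis 8x2

    # -- ungrouped landmarks --
    pair(ey[1], ey[2], iris = TRUE)                           # iris centre
    pairs(ey[1] + c(-0.035, 0.035, 0, 0), ey[2] + c(0, 0, -0.035, 0.035))
    ring(ey[1], ey[2], 0.065, 0.035, 8)                       # eye contour
    pairs(c(0.30, 0.38, 0.46, 0.54), c(0.14, 0.12, 0.14, 0.18))  # under-eye
    pairs(c(0.15, 0.25, 0.35, 0.44, 0.52),
          c(0.50, 0.52, 0.50, 0.46, 0.40))                    # brow line
    for (by in c(0.30, 0.22, 0.14, 0.06)) mid(by)             # nose bridge
    pairs(c(0.05, 0.06, 0.04, 0.13), c(0.12, 0.06, 0.20, -0.14)) # nose side
    t <- seq(70, -86, length.out = 16) * pi / 180             # face outline
    pairs(0.76 * cos(t), -0.05 + 0.82 * sin(t))
    mid(-0.89)                                                # chin bottom
    for (fy in c(0.68, 0.76, 0.84, 0.92)) {
      h <- 0.95 * sqrt(pmax(0.02, 1 - (fy / 1.10)^2))
      for (f in c(0.15, 0.35, 0.55, 0.75, 0.90)) pair(f * h, fy)
      mid(fy)
    }                                                         # forehead
    for (cy in c(-0.02, -0.14, -0.26, -0.40, -0.54))
      for (f in c(0.18, 0.34, 0.50, 0.66, 0.80, 0.92)) pair(f * hw(cy), cy)
    half_ring(-0.42, 0.13, 0.045, 8, 70)                      # inner lips
    mid(-0.375); mid(-0.465)
    pairs(c(0.04, 0.08, 0.12), c(-0.28, -0.29, -0.30))        # philtrum
    mid(-0.27)
    pairs(c(0.05, 0.10, 0.15), c(-0.56, -0.57, -0.58))        # below lip
    mid(-0.565)
    for (sy in c(0.15, 0.02, -0.12, -0.25, -0.38, -0.50)) pair(0.97 * hw(sy), sy)
    for (tx in c(0.66, 0.74)) for (ty in c(0.46, 0.56, 0.66)) pair(tx, ty)
    mid(0.98); mid(0.47); mid(-0.93); mid(-0.97)
  } else {
    # classic sparse 68-point layout
    t <- seq(65, -80, length.out = 8) * pi / 180
    jx <- 0.72 * cos(t); jy <- -0.05 + 0.85 * sin(t)
    jg <- list(c(0L, 17L), c(0L, 0L), c(0L, 0L), c(0L, 0L),
               c(16L, 16L), c(16L, 16L), c(10L, 10L), c(15L, 15L))
    for (k in 1:8) pair(jx[k], jy[k], gl = jg[[k]][1], gr = jg[[k]][2])
    mid(-0.90)                                                # chin
    pair(0.12, 0.46, 3)                                       # inner brow
    pairs(c(0.22, 0.32, 0.42, 0.50), c(0.50, 0.50, 0.47, 0.42))
    for (by in c(0.35, 0.25, 0.15, 0.05)) mid(by)             # nose bridge
    pair(0.05, -0.10, 6); pair(0.10, -0.08, 7); mid(-0.11, 7) # nose bottom
    pair(0.52, 0.28, iris = TRUE)                             # outer eye corner
    pair(0.25, 0.28, 4); pair(0.43, 0.32, 4); pair(0.43, 0.24, 4)
    pair(0.34, 0.32); pair(0.34, 0.24)
    pair(0.30, -0.42, 8); pair(0.18, -0.35, 8); pair(0.08, -0.33, 8)
    mid(-0.32)
    pair(0.08, -0.50, 8); pair(0.18, -0.48, 8)
    mid(-0.52)                                                # outer lip
    pair(0.22, -0.42, 8); pair(0.10, -0.39); pair(0.10, -0.455)
    mid(-0.385); mid(-0.46)                                   # inner lip
  }

  # materialize indices: for a pair the left landmark precedes the right
  rows <- vector("list", 2 * length(units))
  nr <- 0L; idx <- 0L
  for (u in units) {
    if (u$type == "mid") {
      nr <- nr + 1L
      rows[[nr]] <- data.frame(index = idx, x = 0, y = u$y, side = "M",
                               partner = NA_integer_, group = u$g, iris = FALSE)
      idx <- idx + 1L
    } else {
      nr <- nr + 1L
      rows[[nr]] <- data.frame(index = idx, x = -u$x, y = u$y, side = "L",
                               partner = idx + 1L, group = u$gl, iris = u$iris)
      nr <- nr + 1L
      rows[[nr]] <- data.frame(index = idx + 1L, x = u$x, y = u$y, side = "R",
                               partner = idx, group = u$gr, iris = u$iris)
      idx <- idx + 2L
    }
  }
  lay <- do.call(rbind, rows[seq_len(nr)])
  lay$z <- face_surface_z(lay$x, lay$y)
  stopifnot(nrow(lay) == mode_size(mode))
  lay
}

# ---------------------------------------------------------------------------
# FaceTopology
# ---------------------------------------------------------------------------

#' Face topology: left/right pairing, midline and muscle groups
#'
#' A `face_topology` describes the structure shared by all landmark sets of a
#' given mode: the left/right landmark pairing, the indices on the sagittal
#' midline, the iris landmark pair used to construct the midsagittal plane,
#' and the 17 muscle-group index lists over which metrics are aggregated.
#' All landmark indices are 0-based, matching the landmark file formats.
#'
#' @param mode Topology mode.
#' @param pairs Integer matrix (`n_pairs x 2`) of `(left, right)` 0-based
#'   index pairs.
#' @param midline Integer vector of 0-based midline indices.
#' @param iris Length-2 named list or vector with elements `left`, `right`.
#' @param muscle_groups List of 17 lists `{id, name, indices}`.
#' @return A validated `face_topology`.
#' @seealso [load_topology()] for the bundled resources.
#' @export
face_topology <- function(mode, pairs, midline, iris, muscle_groups) {
  mode <- match.arg(mode, c("full_478", "compact_68"))
  pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2)
  midline <- as.integer(midline)
  topo <- structure(
    list(mode = mode, pairs = pairs, midline = midline,
         left_iris_index = as.integer(iris[["left"]]),
         right_iris_index = as.integer(iris[["right"]]),
         muscle_groups = muscle_groups),
    class = "face_topology")
  validate_topology(topo)
  topo
}

#' @export
print.face_topology <- function(x, ...) {
  cat(sprintf("<face_topology: %s, %d pairs, %d midline, 17 muscle groups>\n",
              x$mode, nrow(x$pairs), length(x$midline)))
  invisible(x)
}

#' Validate a face topology against its structural invariants
#'
#' Checks that the pairing is an involution with disjoint left/right sides,
#' that pairs and midline together cover exactly the index range of the mode,
#' that the iris indices form a left/right pair, and that the 17 muscle-group
#' cardinalities equal the published per-mode counts.
#'
#' @param topo A `face_topology`.
#' @return `topo`, invisibly; signals a validation error otherwise.
#' @export
validate_topology <- function(topo) {
  n <- mode_size(topo$mode)
  p <- topo$pairs
  left <- p[, 1]; right <- p[, 2]
  if (length(intersect(left, right)) > 0 || anyDuplicated(c(left, right)) > 0)
    fs_stop_validation("left/right pairing must be a disjoint involution")
  covered <- sort(c(left, right, topo$midline))
  if (!identical(covered, 0:(n - 1)))
    fs_stop_validation("pairs and midline must cover exactly the index range 0..n-1")
  mg <- topo$muscle_groups
  if (length(mg) != 17)
    fs_stop_validation("a face topology must define exactly 17 muscle groups")
  card <- muscle_group_cardinalities(topo$mode)
  for (k in seq_len(17)) {
    g <- mg[[k]]
    if (!identical(as.integer(g$id), k))
      fs_stop_validation("muscle groups must be ordered by id 1..17")
    if (length(g$indices) != card[k])
      fs_stop_validation(sprintf(
        "group %d (%s) has %d landmarks, expected %d for mode %s",
        k, g$name, length(g$indices), card[k], topo$mode))
    if (length(g$indices) && (min(g$indices) < 0 || max(g$indices) >= n))
      fs_stop_validation(sprintf("group %d contains out-of-range indices", k))
  }
  ir <- c(topo$left_iris_index, topo$right_iris_index)
  hit <- which(left == ir[1] & right == ir[2])
  if (length(hit) != 1)
    fs_stop_validation("iris indices must form a (left, right) landmark pair")
  invisible(topo)
}

#' @noRd
topology_from_layout <- function(lay, mode) {
  lidx <- lay$index[lay$side == "L"]
  pr <- cbind(lidx, lay$partner[lay$side == "L"])
  iris <- list(left = lay$index[lay$side == "L" & lay$iris],
               right = lay$index[lay$side == "R" & lay$iris])
  nm <- muscle_group_names()
  mg <- lapply(seq_len(17), function(k)
    list(id = k, name = nm[k], indices = sort(lay$index[lay$group == k])))
  face_topology(mode, pr, lay$index[lay$side == "M"], iris, mg)
}

#' Load a bundled (or user-supplied) face topology resource
#'
#' The package bundles one topology JSON per mode under `extdata/`; pass
#' `path` to override with a compatible resource (for example to designate a
#' different iris landmark). The resource is validated on load; any
#' cardinality or pairing defect is a validation error.
#'
#' @param mode Topology mode.
#' @param path Optional path to a topology JSON overriding the bundled one.
#' @return A validated `face_topology`.
#' @export
load_topology <- function(mode = c("full_478", "compact_68"), path = NULL) {
  mode <- match.arg(mode)
  if (is.null(path)) {
    path <- system.file("extdata", paste0("topology_", mode, ".json"),
                        package = "facesym")
    if (!nzchar(path)) fs_stop_io("bundled topology resource not found")
  }
  if (!file.exists(path)) fs_stop_io(paste0("no such file: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$mode, mode))
    fs_stop_validation(sprintf("resource mode '%s' does not match '%s'",
                               obj$mode, mode))
  mg <- lapply(seq_len(nrow(obj$muscle_groups)), function(k) list(
    id = obj$muscle_groups$id[k], name = obj$muscle_groups$name[k],
    indices = as.integer(obj$muscle_groups$indices[[k]])))
  face_topology(mode, obj$pairs, obj$midline, obj$iris, mg)
}

#' Serialize a face topology to JSON
#'
#' @param topo A `face_topology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_topology <- function(topo, path) {
  obj <- list(
    mode = topo$mode,
    pairs = unname(lapply(seq_len(nrow(topo$pairs)),
                          function(k) topo$pairs[k, ])),
    midline = topo$midline,
    iris = list(left = topo$left_iris_index, right = topo$right_iris_index),
    muscle_groups = lapply(topo$muscle_groups, function(g)
      list(id = g$id, name = g$name, indices = as.integer(g$indices))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Map landmark indices to their mirror partners
#'
#' Returns the permutation sending every left index to its paired right
#' index and vice versa; midline indices map to themselves.
#'
#' @param topo A `face_topology`.
#' @return Integer vector `perm` (0-based values) such that `perm[i + 1]` is
#'   the mirror partner of 0-based index `i`.
#' @export
mirror_permutation <- function(topo) {
  n <- mode_size(topo$mode)
  perm <- 0:(n - 1)
  perm[topo$pairs[, 1] + 1L] <- topo$pairs[, 2]
  perm[topo$pairs[, 2] + 1L] <- topo$pairs[, 1]
  perm
}
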