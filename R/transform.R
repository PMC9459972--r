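#' Homogeneous 4x4 transforms
#'
#' A `homogeneous_transform` wraps a 4x4 matrix acting on 3D points in
#' homogeneous coordinates. Two kinds are supported: `"rigid"` (proper
#' rotation + translation) and `"similarity"` (positive isotropic scale times
#' a proper rotation, + translation). The bottom row is always `(0, 0, 0, 1)`.
#'
#' @param matrix A numeric 4x4 matrix.
#' @param kind `"rigid"` or `"similarity"`.
#' @param tol Orthonormality tolerance for validation.
#' @return A `homogeneous_transform` object.
#' @examples
#' homogeneous_transform(diag(4))
#' @export
homogeneous_transform <- function(matrix, kind = c("rigid", "similarity"),
                                  tol = 1e-8) {
  kind <- match.arg(kind)
  m <- as.matrix(matrix)
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)) || any(!is.finite(m)))
    fs_stop_validation("a homogeneous transform must be a finite 4x4 numeric matrix")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > tol)
    fs_stop_validation("bottom row of a homogeneous transform must be (0, 0, 0, 1)")
  m[4, ] <- c(0, 0, 0, 1)
  A <- m[1:3, 1:3]
  d <- det(A)
  if (d <= 0) fs_stop_validation("linear part must be orientation-preserving (det > 0)")
  s <- d^(1 / 3)
  R <- A / s
  if (max(abs(crossprod(R) - diag(3))) > max(tol, 1e-7))
    fs_stop_validation("linear part must be a (scaled) proper rotation")
  if (kind == "rigid" && abs(s - 1) > max(tol, 1e-7))
    fs_stop_validation("rigid transform cannot carry a scale factor != 1")
  structure(list(matrix = m, kind = kind), class = "homogeneous_transform")
}

#' @export
print.homogeneous_transform <- function(x, ...) {
  cat(sprintf("<homogeneous_transform: %s, scale %.6g>\n", x$kind, transform_scale(x)))
  print(x$matrix)
  invisible(x)
}

#' @rdname homogeneous_transform
#' @export
identity_transform <- function() homogeneous_transform(diag(4), "rigid")

#' Build a transform from rotation, translation and scale
#'
#' The action on a point `p` is `scale * R %*% p + t`.
#'
#' @param R 3x3 proper rotation matrix.
#' @param t Length-3 translation.
#' @param scale Positive isotropic scale factor.
#' @return A `homogeneous_transform`.
#' @export
make_transform <- function(R = diag(3), t = c(0, 0, 0), scale = 1) {
  m <- diag(4)
  m[1:3, 1:3] <- scale * R
  m[1:3, 4] <- t
  homogeneous_transform(m, if (isTRUE(all.equal(scale, 1, tolerance = 1e-12)))
    "rigid" else "similarity")
}

#' Isotropic scaling about a fixed origin as a homogeneous transform
#'
#' @param factor Positive scale factor.
#' @param origin Length-3 fixed point of the scaling.
#' @return A `homogeneous_transform` of kind `"similarity"`.
#' @export
scaling_transform <- function(factor, origin = c(0, 0, 0)) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) || factor <= 0)
    fs_stop_validation("scale factor must be a single positive finite number")
  make_transform(diag(3), origin - factor * origin, factor)
}

#' Apply a homogeneous transform to 3D points
#'
#' @param transform A `homogeneous_transform`.
#' @param points An n x 3 numeric matrix (or length-3 vector).
#' @return Transformed points with the same shape.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "homogeneous_transform"))
  v <- is.null(dim(points))
  p <- if (v) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(transform$matrix[1:3, 1:3]) +
    rep(transform$matrix[1:3, 4], each = nrow(p))
  if (v) drop(out) else out
}

#' Compose two homogeneous transforms
#'
#' `compose_transforms(a, b)` returns the transform that applies `b` first,
#' then `a` (matrix product `a %*% b`).
#'
#' @param a,b `homogeneous_transform` objects.
#' @return A `homogeneous_transform`.
#' @export
compose_transforms <- function(a, b) {
  kind <- if (a$kind == "rigid" && b$kind == "rigid") "rigid" else "similarity"
  homogeneous_transform(a$matrix %*% b$matrix, kind)
}

#' Invert a homogeneous transform
#'
#' @param transform A `homogeneous_transform`.
#' @return The inverse `homogeneous_transform`.
#' @export
invert_transform <- function(transform) {
  A <- transform$matrix[1:3, 1:3]
  t <- transform$matrix[1:3, 4]
  Ai <- solve(A)
  m <- diag(4)
  m[1:3, 1:3] <- Ai
  m[1:3, 4] <- -Ai %*% t
  homogeneous_transform(m, transform$kind)
}

#' Isotropic scale factor carried by a transform
#'
#' @param transform A `homogeneous_transform`.
#' @return The (positive) isotropic scale of the linear part.
#' @export
transform_scale <- function(transform) det(transform$matrix[1:3, 1:3])^(1 / 3)

#' Rotation matrix from extrinsic x-y-z Euler angles
#'
#' @param rx,ry,rz Rotation angles in radians about the x, y and z axes,
#'   applied in that order.
#' @return A 3x3 proper rotation matrix.
#' @export
rotation_xyz <- function(rx = 0, ry = 0, rz = 0) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Rodrigues rotation from an axis-angle vector; exact for any angle
#' @noRd
rotation_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-300) return(diag(3))
  k <- w / th
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Project a near-rotation onto SO(3) via SVD
#' @noRd
orthonormalize_rotation <- function(A) {
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  R
}

#' Write / read a registration transform as JSON
#'
#' The JSON layout carries the 4x4 matrix row-wise plus the scale-sweep
#' metadata (`scale_factor`, `chosen_scale_index`, `inlier_rmse`, `method`).
#'
#' @param result A `registration_result` (or bare `homogeneous_transform`).
#' @param path Output file path.
#' @return `save_transform_json`: `path`, invisibly. `load_transform_json`:
#'   a list with a `transform` element and any stored metadata.
#' @export
save_transform_json <- function(result, path) {
  if (inherits(result, "homogeneous_transform"))
    result <- list(transform = result, method_label = "unspecified")
  obj <- list(
    matrix = unname(apply(result$transform$matrix, 1, function(r) r, simplify = FALSE)),
    kind = result$transform$kind,
    scale_factor = result$scale_factor,
    chosen_scale_index = result$chosen_scale_index,
    inlier_rmse = result$inlier_rmse,
    method = result$method_label
  )
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_transform_json
#' @export
load_transform_json <- function(path) {
  if (!file.exists(path)) fs_stop_io(paste0("no such file: ", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$matrix
  if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
  m <- matrix(as.numeric(m), 4, 4)
  kind <- if (is.null(obj$kind)) "similarity" else obj$kind
  out <- list(transform = homogeneous_transform(m, kind))
  for (f in c("scale_factor", "chosen_scale_index", "inlier_rmse", "method"))
    out[[f]] <- obj[[f]]
  out
}
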