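# Stack -> model frame transform and the anatomical reference planes.
#
# The model frame is the stack frame translated to the center of mass of the
# binarized head and scaled by a single factor alpha (default 4/512, i.e. a
# 512-voxel extent maps to 4 model units). The three anatomical planes are
# defined from landmark triples: the midsagittal plane from Yintang, TOP and
# GV17; the coronal plane from the two TE20 points and TOP; a transverse
# plane at any level is perpendicular to the axis common to both.

#' Center of mass of a binary volume
#'
#' Mean voxel index triple over the foreground, in stack-frame voxel units
#' (1-based indices times spacing).
#'
#' @param bin a non-empty `binary_volume`.
#' @return Numeric xyz 3-vector.
#' @export
center_of_mass <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  if (!any(bin$mask)) stop("center of mass of an empty mask", call. = FALSE)
  d <- dim(bin$mask)
  idx <- which(bin$mask) - 1L
  i <- idx %% d[1] + 1
  j <- (idx %/% d[1]) %% d[2] + 1
  k <- idx %/% (d[1] * d[2]) + 1
  sp <- bin$spacing_mm %||% c(1, 1, 1)
  c(mean(i) * sp[1], mean(j) * sp[2], mean(k) * sp[3])
}

#' Model reference frame
#'
#' @param center_of_mass stack-frame xyz of the head's center of mass.
#' @param alpha positive scale factor; default 4/512.
#' @return An object of class `model_frame`.
#' @export
model_frame <- function(center_of_mass, alpha = 4 / 512) {
  center_of_mass <- as_point3(center_of_mass, "center_of_mass")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  structure(list(center_of_mass = center_of_mass, alpha = alpha),
            class = "model_frame")
}

#' Map points between the stack and the model frame
#'
#' `to_model_frame` applies `p' = alpha * (p - CM)` componentwise;
#' `from_model_frame` is its exact inverse.
#'
#' @param points numeric 3-vector or n x 3 matrix.
#' @param frame a [model_frame()].
#' @return Points in the other frame, same shape as the input.
#' @export
to_model_frame <- function(points, frame) {
  stopifnot(inherits(frame, "model_frame"))
  single <- is.null(dim(points))
  p <- as_points_matrix(points)
  out <- sweep(p, 2, frame$center_of_mass, "-") * frame$alpha
  if (single) as.numeric(out) else out
}

#' @rdname to_model_frame
#' @export
from_model_frame <- function(points, frame) {
  stopifnot(inherits(frame, "model_frame"))
  single <- is.null(dim(points))
  p <- as_points_matrix(points)
  out <- sweep(p / frame$alpha, 2, frame$center_of_mass, "+")
  if (single) as.numeric(out) else out
}

#' Transform a landmark set or mesh to the model frame
#'
#' @param x a `landmark_set` or `surface_mesh` in the stack frame.
#' @param frame a [model_frame()].
#' @return The same object with model-frame coordinates and `frame` tag.
#' @export
apply_model_frame <- function(x, frame) {
  if (inherits(x, "landmark_set")) {
    pts <- to_model_frame(lm_matrix(x), frame)
    x$x <- pts[, 1]; x$y <- pts[, 2]; x$z <- pts[, 3]
    x$frame <- "model"
    x
  } else if (inherits(x, "surface_mesh")) {
    x$vertices <- to_model_frame(x$vertices, frame)
    x$frame <- "model"
    x
  } else stop("unsupported object for frame transform", call. = FALSE)
}

acu_plane <- function(anchor, normal, kind) {
  anchor <- as_point3(anchor, "anchor")
  normal <- unitize(as_point3(normal, "normal"), "plane normal")
  structure(list(anchor = anchor, normal = normal, kind = kind),
            class = "acu_plane")
}

#' @export
print.acu_plane <- function(x, ...) {
  cat("<acu_plane> ", x$kind, ": normal (", paste(signif(x$normal, 4), collapse = ", "),
      "), anchor (", paste(signif(x$anchor, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Signed distance of points from a plane
#'
#' @param plane an `acu_plane`.
#' @param points 3-vector or n x 3 matrix.
#' @return Numeric vector of signed distances (positive on the normal side).
#' @export
plane_distance <- function(plane, points) {
  stopifnot(inherits(plane, "acu_plane"))
  p <- as_points_matrix(points)
  as.numeric(sweep(p, 2, plane$anchor, "-") %*% plane$normal)
}

check_noncollinear <- function(a, b, c, what) {
  n <- cross3(b - a, c - a)
  scale <- max(vnorm(b - a), vnorm(c - a))
  if (scale == 0 || vnorm(n) < 1e-12 * scale^2)
    stop("collinear or coincident points: cannot define the ", what, " plane",
         call. = FALSE)
  n
}

#' Midsagittal plane from Yintang, TOP and GV17
#'
#' Normal proportional to `(GV17 - Yintang) x (TOP - Yintang)`, anchored at
#' Yintang; the three defining points satisfy the plane equation exactly.
#'
#' @param yintang,top,gv17 xyz 3-vectors (any single frame).
#' @return An `acu_plane` of kind `"sagittal"`.
#' @export
sagittal_plane <- function(yintang, top, gv17) {
  yintang <- as_point3(yintang); top <- as_point3(top); gv17 <- as_point3(gv17)
  n <- check_noncollinear(yintang, gv17, top, "sagittal")
  acu_plane(yintang, n, "sagittal")
}

#' Coronal plane from the two TE20 points and TOP
#'
#' Normal proportional to `(TE20_left - TOP) x (TE20_right - TOP)`, anchored
#' at TOP.
#'
#' @param te20_left,te20_right,top xyz 3-vectors.
#' @return An `acu_plane` of kind `"coronal"`.
#' @export
coronal_plane <- function(te20_left, te20_right, top) {
  te20_left <- as_point3(te20_left); te20_right <- as_point3(te20_right)
  top <- as_point3(top)
  n <- cross3(te20_left - top, te20_right - top)
  scale <- max(vnorm(te20_left - top), vnorm(te20_right - top))
  if (scale == 0 || vnorm(n) < 1e-12 * scale^2)
    stop("collinear or coincident points: cannot define the coronal plane",
         call. = FALSE)
  acu_plane(top, n, "coronal")
}

#' Transverse plane at a given level
#'
#' Perpendicular to the axis common to the sagittal and the coronal planes
#' (the cross product of their normals), passing through `level_point`.
#'
#' @param sagittal,coronal `acu_plane` objects with non-parallel normals.
#' @param level_point xyz 3-vector the plane must contain.
#' @return An `acu_plane` of kind `"transverse"`.
#' @export
transverse_plane <- function(sagittal, coronal, level_point) {
  stopifnot(inherits(sagittal, "acu_plane"), inherits(coronal, "acu_plane"))
  axis <- cross3(sagittal$normal, coronal$normal)
  if (vnorm(axis) < 1e-12)
    stop("sagittal and coronal planes are parallel; no common axis", call. = FALSE)
  acu_plane(as_point3(level_point, "level_point"), axis, "transverse")
}
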