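#' Voxel volume container
#'
#' An 8-bit intensity grid with per-axis voxel spacing. Axis convention used
#' throughout the package: index `i`/axis x runs left-right across the
#' subject (subject's left at low `i`, i.e. negative model-frame x), index
#' `j`/axis y runs posterior-to-anterior (anterior at high `j`), and index
#' `k`/axis z runs inferior-to-superior (one axial slice per `k`).
#'
#' @param intensities 3D numeric/integer array with values in `[0, 255]`.
#' @param spacing_mm numeric 3-vector of per-axis voxel size in mm.
#' @return An object of class `voxel_volume` with fields `intensities`,
#'   `spacing_mm` and `dims`.
#' @export
voxel_volume <- function(intensities, spacing_mm = c(1, 1, 1)) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be three strictly positive values", call. = FALSE)
  if (any(dim(intensities) <= 0))
    stop("dims must be strictly positive", call. = FALSE)
  rng <- range(intensities)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  structure(list(intensities = intensities,
                 spacing_mm = spacing_mm,
                 dims = dim(intensities)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(x$spacing_mm, collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

binary_volume <- function(mask, threshold_used = NA_real_, label = NA_character_,
                          spacing_mm = c(1, 1, 1)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  structure(list(mask = mask, threshold_used = threshold_used, label = label,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  cat("<binary_volume> ", paste(dim(x$mask), collapse = " x "),
      ", ", sum(x$mask), " true voxels",
      if (!is.na(x$threshold_used)) paste0(", threshold ", x$threshold_used),
      if (!is.na(x$label)) paste0(" (", x$label, ")"), "\n", sep = "")
  invisible(x)
}

#' Threshold a volume into a binary mask
#'
#' A voxel is foreground iff its intensity is greater than or equal to the
#' threshold (inclusive comparison, so the conventional skin/skull thresholds
#' 10 and 110 are meaningful as minima).
#'
#' @param vol a [voxel_volume()].
#' @param threshold intensity in `[0, 255]`.
#' @param label optional tissue tag (`"skin"`, `"skull"`).
#' @return A `binary_volume`.
#' @export
binarize <- function(vol, threshold, label = NA_character_) {
  stopifnot(inherits(vol, "voxel_volume"))
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || threshold < 0 || threshold > 255)
    stop("threshold must be a single value in [0, 255]", call. = FALSE)
  mask <- vol$intensities >= threshold
  dim(mask) <- vol$dims
  binary_volume(mask, threshold_used = threshold, label = label,
                spacing_mm = vol$spacing_mm)
}

# Shift a 3D logical array by (di, dj, dk); vacated cells become `fill`.
shift3 <- function(a, di, dj, dk, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- function(n, s) {  # source/target ranges for one axis
    if (s >= 0) list(from = seq_len(n - s), to = seq_len(n - s) + s)
    else list(from = seq_len(n + s) - s, to = seq_len(n + s))
  }
  sx <- src(d[1], di); sy <- src(d[2], dj); sz <- src(d[3], dk)
  if (!length(sx$from) || !length(sy$from) || !length(sz$from)) return(out)
  out[sx$to, sy$to, sz$to] <- a[sx$from, sy$from, sz$from]
  out
}

# 6-neighbour (face-connected) binary dilation, `iterations` passes.
dilate6 <- function(mask, iterations = 1L) {
  for (it in seq_len(iterations)) {
    mask <- mask |
      shift3(mask,  1, 0, 0) | shift3(mask, -1, 0, 0) |
      shift3(mask, 0,  1, 0) | shift3(mask, 0, -1, 0) |
      shift3(mask, 0, 0,  1) | shift3(mask, 0, 0, -1)
  }
  mask
}

# Erosion dual to dilate6; voxels outside the array count as background.
erode6 <- function(mask, iterations = 1L) {
  !dilate6(!mask, iterations)
}

# Voxels of the background (!mask) reachable from the array border under
# 26-connectivity. Directional sweeps with an 8-neighbour look-back are
# repeated to a fixed point; enclosed cavities are exactly the unreached
# background voxels.
background_reach <- function(mask) {
  d <- dim(mask)
  free <- !mask
  reach <- array(FALSE, dim = d)
  # seed: free voxels on any face of the grid
  reach[c(1, d[1]), , ] <- free[c(1, d[1]), , ]
  reach[, c(1, d[2]), ] <- reach[, c(1, d[2]), ] | free[, c(1, d[2]), ]
  reach[, , c(1, d[3])] <- reach[, , c(1, d[3])] | free[, , c(1, d[3])]

  box2d <- function(m) {  # 8-neighbourhood + centre on a 2D slice
    n1 <- nrow(m); n2 <- ncol(m)
    m <- m | rbind(FALSE, m[-n1, , drop = FALSE]) | rbind(m[-1, , drop = FALSE], FALSE)
    m | cbind(FALSE, m[, -n2, drop = FALSE]) | cbind(m[, -1, drop = FALSE], FALSE)
  }

  repeat {
    before <- sum(reach)
    if (d[3] > 1) {
      for (k in 2:d[3])            # +k sweep
        reach[, , k] <- reach[, , k] | (free[, , k] & box2d(reach[, , k - 1] | reach[, , k]))
      for (k in (d[3] - 1):1)      # -k sweep
        reach[, , k] <- reach[, , k] | (free[, , k] & box2d(reach[, , k + 1] | reach[, , k]))
    }
    if (d[2] > 1) {
      for (j in 2:d[2])            # +j sweep
        reach[, j, ] <- reach[, j, ] | (free[, j, ] & box2d(reach[, j - 1, ] | reach[, j, ]))
      for (j in (d[2] - 1):1)      # -j sweep
        reach[, j, ] <- reach[, j, ] | (free[, j, ] & box2d(reach[, j + 1, ] | reach[, j, ]))
    }
    if (sum(reach) == before) break
  }
  reach
}

#' Fill enclosed holes in a binary volume
#'
#' Applies a morphological closing (6-neighbour dilation then erosion,
#' `iterations` passes each) to seal small surface perforations, then fills
#' interior cavities: background components not 26-connected to the grid
#' border become foreground. The output mask is always a superset of the
#' input and the operation is idempotent once converged.
#'
#' @param bin a `binary_volume`.
#' @param iterations non-negative closing iteration count (0 skips closing
#'   and only fills enclosed cavities).
#' @return A `binary_volume`.
#' @export
fill_holes <- function(bin, iterations = 1L) {
  stopifnot(inherits(bin, "binary_volume"))
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L)
    stop("iterations must be >= 0", call. = FALSE)
  mask <- bin$mask
  if (iterations > 0L) {
    closed <- erode6(dilate6(mask, iterations), iterations)
    mask <- mask | closed
  }
  mask <- mask | (!mask & !background_reach(mask))
  binary_volume(mask, threshold_used = bin$threshold_used, label = bin$label,
                spacing_mm = bin$spacing_mm)
}

#' Extract the one-voxel boundary of a binary volume
#'
#' A mask voxel belongs to the boundary iff at least one of its six
#' face-neighbours lies outside the mask (voxels beyond the grid count as
#' outside).
#'
#' @param bin a non-empty `binary_volume`.
#' @return A `binary_volume` holding only boundary voxels.
#' @export
extract_boundary <- function(bin) {
  stopifnot(inherits(bin, "binary_volume"))
  mask <- bin$mask
  if (!any(mask)) stop("cannot extract boundary of an empty mask", call. = FALSE)
  interior <- mask &
    shift3(mask,  1, 0, 0) & shift3(mask, -1, 0, 0) &
    shift3(mask, 0,  1, 0) & shift3(mask, 0, -1, 0) &
    shift3(mask, 0, 0,  1) & shift3(mask, 0, 0, -1)
  binary_volume(mask & !interior, threshold_used = bin$threshold_used,
                label = bin$label, spacing_mm = bin$spacing_mm)
}
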