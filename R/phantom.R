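# Synthetic two-shell head phantoms.
#
# The phantom stands in for a head CT stack: an outer "skin" ellipsoid of
# soft-tissue intensity enclosing a "skull" ellipsoidal shell of bone
# intensity, voxelized on the stack grid. Landmarks are placed at fixed
# parametric (longitude, latitude) positions on the skin surface, so every
# ground-truth position is analytically known. Intensity classes follow the
# conventional thresholds: background < 10, soft tissue in [10, 110), bone
# >= 110.

PHANTOM_BACKGROUND <- 0
PHANTOM_SOFT <- 40
PHANTOM_BONE <- 200

# Parametric landmark chart: direction on the unit sphere for each named
# landmark. Longitude `lon` is measured in degrees from the anterior (+y)
# direction, positive toward the subject's LEFT (negative x); latitude `lat`
# is elevation from the equatorial plane toward the vertex (+z). Midline
# points have lon 0 (anterior) or 180 (posterior); bilateral points are
# instantiated at +/- lon. TE20 left/right are placed exactly antipodal
# (+/-90, 0) so that their midpoint TE20CP coincides with the phantom centre,
# matching the spherical-head idealization used by the angle solver.
phantom_landmark_chart <- function() {
  rows <- list(
    # name,  lon, lat, bilateral
    c("GV15", 180, -30, FALSE),
    c("GV16", 180, -20, FALSE),
    c("GV17", 180,  10, FALSE),
    c("GV25",   0, -15, FALSE),
    c("GV26",   0, -25, FALSE),
    c("GV27",   0, -30, FALSE),
    c("GB1",   25,   5, TRUE),
    c("GB2",   72, -18, TRUE),
    c("GB3",   50,   0, TRUE),
    c("GB7",   82,  18, TRUE),
    c("GB8",   88,  25, TRUE),
    c("GB9",   97,  20, TRUE),
    c("GB12",  95, -30, TRUE),
    c("GB20", 160, -20, TRUE),
    c("ST1",   12,   0, TRUE),
    c("ST2",   13,  -5, TRUE),
    c("ST3",   14, -15, TRUE),
    c("ST4",   12, -28, TRUE),
    c("ST5",   55, -40, TRUE),
    c("ST6",   65, -45, TRUE),
    c("ST7",   60, -15, TRUE),
    c("TE17",  85, -25, TRUE),
    c("TE20",  90,   0, TRUE),
    c("TE21",  76, -10, TRUE),
    c("TE22",  78,  -5, TRUE),
    c("TE23",  27,  15, TRUE),
    c("BL1",   10,   5, TRUE),
    c("BL2",   12,  15, TRUE),
    c("CV23",   0, -55, FALSE),
    c("CV24",   0, -40, FALSE),
    c("LI19",   8, -25, TRUE),
    c("LI20",  10, -20, TRUE),
    c("SI17",  70, -40, TRUE),
    c("SI18",  30, -15, TRUE),
    c("Pupil", 12,   8, TRUE),
    c("Yintang", 0, 20, FALSE),
    c("TOP",    0,  90, FALSE)
  )
  data.frame(name = vapply(rows, `[`, "", 1),
             lon = as.numeric(vapply(rows, `[`, "", 2)),
             lat = as.numeric(vapply(rows, `[`, "", 3)),
             bilateral = vapply(rows, `[`, "", 4) == "TRUE",
             stringsAsFactors = FALSE)
}

# Unit direction for (lon, lat) in degrees on a given side
# ("left" | "right" | "midline"). Subject's left is negative x.
chart_direction <- function(lon, lat, side) {
  lon <- lon * pi / 180
  lat <- lat * pi / 180
  sgn <- switch(side, left = 1, right = -1, midline = 1)
  c(-sgn * sin(lon) * cos(lat), cos(lon) * cos(lat), sin(lat))
}

#' Specification of a synthetic head phantom
#'
#' @param skin_semiaxes_mm outer (skin) ellipsoid semiaxes along (x, y, z).
#'   The default is the spherical-head idealization, radius 60 mm.
#' @param skull_semiaxes_mm outer surface of the skull shell; must be
#'   componentwise smaller than `skin_semiaxes_mm`.
#' @param skull_thickness_mm thickness of the bone shell.
#' @param center_voxel stack-frame voxel index of the phantom centre.
#' @param dims volume dimensions (voxels).
#' @param asymmetry 3-vector of linear radial-gain gradients along (x, y, z);
#'   0 keeps the phantom bilaterally symmetric.
#' @param feature_bumps list of protuberance-like features, each a list with
#'   `name`, `direction` (3-vector) and `amplitude` (relative radial gain);
#'   gaussians of 15 degrees angular width.
#' @param noise_sd additive Gaussian intensity noise (clipped to `[0, 255]`);
#'   0 by default so that the intensity classes are exact.
#' @param seed integer seed for the noise generator.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(skin_semiaxes_mm = c(60, 60, 60),
                         skull_semiaxes_mm = c(52, 52, 52),
                         skull_thickness_mm = 6,
                         center_voxel = c(64, 64, 64),
                         dims = c(128L, 128L, 128L),
                         asymmetry = c(0, 0, 0),
                         feature_bumps = list(),
                         noise_sd = 0,
                         seed = 1L) {
  skin_semiaxes_mm <- as.numeric(skin_semiaxes_mm)
  skull_semiaxes_mm <- as.numeric(skull_semiaxes_mm)
  ax <- c("x", "y", "z")
  for (i in 1:3) {
    if (!is.finite(skin_semiaxes_mm[i]) || skin_semiaxes_mm[i] <= 0)
      stop("degenerate skin semiaxis along ", ax[i], call. = FALSE)
    if (!is.finite(skull_semiaxes_mm[i]) || skull_semiaxes_mm[i] <= 0)
      stop("degenerate skull semiaxis along ", ax[i], call. = FALSE)
    if (skull_semiaxes_mm[i] >= skin_semiaxes_mm[i])
      stop("skull semiaxis must be smaller than skin semiaxis along ", ax[i],
           call. = FALSE)
  }
  if (skull_thickness_mm <= 0 || skull_thickness_mm >= min(skull_semiaxes_mm))
    stop("skull_thickness_mm must be positive and smaller than the skull semiaxes",
         call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(skin_semiaxes_mm = skin_semiaxes_mm,
                 skull_semiaxes_mm = skull_semiaxes_mm,
                 skull_thickness_mm = skull_thickness_mm,
                 center_voxel = as.numeric(center_voxel),
                 dims = as.integer(dims),
                 asymmetry = as.numeric(asymmetry),
                 feature_bumps = feature_bumps,
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Relative radial gain (1 + deformation) for unit directions `d` (n x 3).
phantom_gain <- function(spec, d) {
  g <- rep(1, nrow(d))
  a <- spec$asymmetry
  if (any(a != 0)) g <- g + d %*% a
  sig <- 15 * pi / 180
  for (b in spec$feature_bumps) {
    u <- unitize(as_point3(b$direction, "bump direction"))
    ang <- acos(pmax(-1, pmin(1, d %*% u)))
    g <- g + b$amplitude * exp(-ang^2 / (2 * sig^2))
  }
  as.numeric(g)
}

# Radius (mm) of the deformed ellipsoid along unit directions `d` (n x 3)
# for semiaxes `semi`; the skin surface additionally carries the gain field.
ellipsoid_radius <- function(d, semi, gain = NULL) {
  r <- 1 / sqrt((d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 + (d[, 3] / semi[3])^2)
  if (!is.null(gain)) r <- r * gain
  r
}

#' Generate a synthetic two-shell head phantom
#'
#' Voxelizes the phantom described by `spec` and returns the volume together
#' with its ground-truth landmark annotation (all 34 anatomical acupoints
#' plus Pupil, Yintang and TOP) in stack-frame coordinates.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [voxel_volume()]) and
#'   `landmarks` (a `landmark_set` in the stack frame).
#' @export
generate_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  ctr <- spec$center_voxel

  # displacement of every voxel centre from the phantom centre
  xi <- seq_len(d[1]) - ctr[1]
  yj <- seq_len(d[2]) - ctr[2]
  zk <- seq_len(d[3]) - ctr[3]
  X <- array(rep(xi, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(yj, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zk, each = d[1] * d[2]), dim = d)
  rr <- sqrt(X^2 + Y^2 + Z^2)
  rr[rr == 0] <- 1e-9
  dirs <- cbind(as.vector(X / rr), as.vector(Y / rr), as.vector(Z / rr))

  # quadratic forms are exact at lattice points (no sqrt round-off at the
  # shell boundaries); the skin gain field only matters off unity
  qform <- function(semi) as.vector((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2)
  gain <- phantom_gain(spec, dirs)
  q_skin <- qform(spec$skin_semiaxes_mm)
  q_out <- qform(spec$skull_semiaxes_mm)
  q_in <- qform(spec$skull_semiaxes_mm - spec$skull_thickness_mm)

  intens <- rep(PHANTOM_BACKGROUND, length(q_skin))
  intens[q_skin <= gain^2] <- PHANTOM_SOFT
  intens[q_out <= 1 & q_in > 1] <- PHANTOM_BONE
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    intens <- round(intens + stats::rnorm(length(intens), sd = spec$noise_sd))
    intens <- pmax(0, pmin(255, intens))
  }
  vol <- voxel_volume(array(intens, dim = d), spacing_mm = c(1, 1, 1))

  chart <- phantom_landmark_chart()
  rows <- list()
  for (i in seq_len(nrow(chart))) {
    sides <- if (chart$bilateral[i]) c("left", "right") else "midline"
    for (s in sides) {
      u <- chart_direction(chart$lon[i], chart$lat[i], s)
      um <- matrix(u, ncol = 3)
      r <- ellipsoid_radius(um, spec$skin_semiaxes_mm, phantom_gain(spec, um))
      p <- ctr + r * u
      rows[[length(rows) + 1L]] <- data.frame(
        name = chart$name[i], side = s, x = p[1], y = p[2], z = p[3],
        stringsAsFactors = FALSE)
    }
  }
  lm <- do.call(rbind, rows)
  lm$frame <- "stack"
  lm$provenance <- "ground_truth"
  list(volume = vol, landmarks = landmark_set(lm))
}
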