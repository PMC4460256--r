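# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

# Full-size spherical phantom (radius 60 mm, 128^3), reconstructed and
# transformed to the model frame, with its ground-truth landmarks and the
# computed proportional points. Built lazily; ~30 s once.
sphere128 <- function() {
  if (!is.null(.fixtures$s128)) return(.fixtures$s128)
  ph <- generate_head_phantom(phantom_spec())
  skin <- fill_holes(binarize(ph$volume, 10, "skin"))
  frame <- model_frame(center_of_mass(skin))
  mesh <- apply_model_frame(marching_cubes(skin), frame)
  lms <- apply_model_frame(ph$landmarks, frame)
  prop <- compute_all_proportional(mesh, lms)
  .fixtures$s128 <- list(phantom = ph, skin = skin, frame = frame,
                         mesh = mesh, lms = lms, prop = prop,
                         pitch = 4 / 512, radius_mm = 60)
  .fixtures$s128
}

# Smaller, cheaper phantom (radius 28 mm, 64^3) for structural tests.
sphere64_spec <- function() {
  phantom_spec(skin_semiaxes_mm = c(28, 28, 28),
               skull_semiaxes_mm = c(22, 22, 22), skull_thickness_mm = 4,
               center_voxel = c(32, 32, 32), dims = c(64L, 64L, 64L))
}

sphere64 <- function() {
  if (!is.null(.fixtures$s64)) return(.fixtures$s64)
  ph <- generate_head_phantom(sphere64_spec())
  skin <- fill_holes(binarize(ph$volume, 10, "skin"))
  frame <- model_frame(center_of_mass(skin))
  mesh <- apply_model_frame(marching_cubes(skin), frame)
  lms <- apply_model_frame(ph$landmarks, frame)
  .fixtures$s64 <- list(phantom = ph, skin = skin, frame = frame,
                        mesh = mesh, lms = lms, pitch = 4 / 512,
                        radius_mm = 28)
  .fixtures$s64
}

the_catalog <- function() {
  if (is.null(.fixtures$cat)) .fixtures$cat <- load_catalog()
  .fixtures$cat
}

# Analytic UV-sphere triangulation (smooth reference mesh, radius r).
uv_sphere_mesh <- function(r = 1, n_theta = 24, n_phi = 48) {
  th <- seq(0, pi, length.out = n_theta)[-c(1, n_theta)]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  grid <- expand.grid(ph = ph, th = th)
  v <- cbind(r * sin(grid$th) * cos(grid$ph),
             r * sin(grid$th) * sin(grid$ph),
             r * cos(grid$th))
  np <- nrow(v)
  v <- rbind(v, c(0, 0, r), c(0, 0, -r))
  top <- np + 1L; bot <- np + 2L
  idx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- list()
  nb <- n_theta - 2L
  for (j in seq_len(n_phi)) {
    faces[[length(faces) + 1L]] <- c(top, idx(1, j), idx(1, j + 1))
    faces[[length(faces) + 1L]] <- c(bot, idx(nb, j + 1), idx(nb, j))
  }
  for (i in seq_len(nb - 1L)) for (j in seq_len(n_phi)) {
    a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j); d <- idx(i + 1, j + 1)
    faces[[length(faces) + 1L]] <- c(a, b, d)
    faces[[length(faces) + 1L]] <- c(a, d, cc)
  }
  f <- do.call(rbind, faces)
  # orient all faces outward (normal along the face centroid direction)
  p1 <- v[f[, 1], ]; p2 <- v[f[, 2], ]; p3 <- v[f[, 3], ]
  nrm <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
                 (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
               (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) -
                 (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
               (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                 (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
  flip <- rowSums(nrm * (p1 + p2 + p3)) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  acuhead:::surface_mesh(v, f, frame = "model")
}

# Great-circle (slerp) oracle: the point at angle fraction `ratio * theta0`
# from the GV17 ray toward the Yintang ray, at radius `r` from te20cp.
slerp_oracle <- function(aframe, ratio, r) {
  u1 <- (aframe$gv17 - aframe$te20cp); u1 <- u1 / sqrt(sum(u1^2))
  w <- aframe$yintang - aframe$te20cp
  u2 <- w - sum(w * u1) * u1; u2 <- u2 / sqrt(sum(u2^2))
  th <- ratio * aframe$theta0
  aframe$te20cp + r * (cos(th) * u1 + sin(th) * u2)
}

# Transverse-circle oracle: point on the sphere of radius `r` about te20cp,
# in the plane z = gv24_z, making the 3D angle `ratio * theta0` with the
# GV24 ray, on the requested side (left = negative x).
transverse_oracle <- function(aframe, gv24, ratio, r, side) {
  z <- gv24[3] - aframe$te20cp[3]
  rho <- sqrt(r^2 - z^2)
  th <- ratio * aframe$theta0
  cphi <- (r^2 * cos(th) - z^2) / rho^2
  stopifnot(abs(cphi) <= 1)
  phi <- acos(cphi)
  sx <- if (side == "left") -1 else 1
  aframe$te20cp + c(sx * rho * sin(phi), rho * cos(phi), z)
}

# 6-connected component count of a logical 3D array (flood-fill oracle,
# plain BFS; small volumes only).
component_count_oracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nxt <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      c0 <- arrayInd(cur, d)
      for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
        nb <- c0 + s
        if (any(nb < 1) || any(nb > d)) next
        li <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
        if (mask[li] && lab[li] == 0L) { lab[li] <- nxt; queue <- c(queue, li) }
      }
    }
  }
  nxt
}

# Random rigid transform (rotation + translation), seeded.
random_rigid <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3))
}

apply_rigid <- function(rig, pts) {
  if (is.null(dim(pts))) as.numeric(rig$R %*% pts + rig$t)
  else t(rig$R %*% t(pts) + rig$t)
}
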