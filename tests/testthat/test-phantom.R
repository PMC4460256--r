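# Voxel preprocessing and the synthetic phantom generator.

test_that("binarize thresholds inclusively and is monotone in the threshold", {
  z <- voxel_volume(array(0, c(4, 4, 4)))
  expect_false(any(binarize(z, 10)$mask))

  u <- voxel_volume(array(10, c(3, 3, 3)))
  expect_true(all(binarize(u, 10)$mask))   # >= convention at the boundary

  set.seed(11)
  vol <- voxel_volume(array(sample(0:255, 6^3, replace = TRUE), c(6, 6, 6)))
  for (thr in c(0, 10, 110, 200)) {
    lo <- binarize(vol, thr)$mask
    hi <- binarize(vol, thr + 30)$mask
    expect_true(all(lo[hi]))               # raising threshold never adds voxels
    expect_identical(lo, vol$intensities >= thr)
  }
  expect_error(binarize(vol, 300), "threshold")
})

test_that("fill_holes seals cavities, never removes voxels, and is idempotent", {
  # solid cube: no holes, unchanged
  solid <- array(FALSE, c(12, 12, 12)); solid[3:9, 3:9, 3:9] <- TRUE
  bs <- acuhead:::binary_volume(solid)
  expect_identical(fill_holes(bs, 0)$mask, solid)

  # hollow cube shell: single enclosed cavity becomes solid
  hollow <- solid
  hollow[4:8, 4:8, 4:8] <- FALSE
  filled <- fill_holes(acuhead:::binary_volume(hollow), 0)
  expect_identical(filled$mask, solid)

  # two disjoint shells: both filled, component count preserved (oracle)
  two <- array(FALSE, c(26, 12, 12))
  two[3:9, 3:9, 3:9] <- TRUE; two[4:8, 4:8, 4:8] <- FALSE
  two[15:21, 3:9, 3:9] <- TRUE; two[16:20, 4:8, 4:8] <- FALSE
  f2 <- fill_holes(acuhead:::binary_volume(two), 0)
  expect_true(all(f2$mask[two]))                      # superset of input
  expect_identical(component_count_oracle(two), 2L)
  expect_identical(component_count_oracle(f2$mask), 2L)
  expect_equal(sum(f2$mask), 2 * 7^3)

  # idempotence once converged, with and without closing passes
  for (it in c(0L, 1L)) {
    once <- fill_holes(acuhead:::binary_volume(two), it)
    twice <- fill_holes(once, it)
    expect_identical(once$mask, twice$mask)
  }
  expect_error(fill_holes(bs, -1), "iterations")
})

test_that("extract_boundary returns exactly the 6-neighbour surface voxels", {
  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  b <- extract_boundary(acuhead:::binary_volume(cube))
  expect_equal(sum(b$mask), 5^3 - 3^3)   # 98

  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_identical(extract_boundary(acuhead:::binary_volume(single))$mask, single)

  # brute-force neighbour-scan oracle on a random blob
  set.seed(3)
  blob <- array(runif(10^3) > 0.6, c(10, 10, 10))
  got <- extract_boundary(acuhead:::binary_volume(blob))$mask
  oracle <- array(FALSE, dim(blob))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    if (!blob[i, j, k]) next
    nb <- rbind(c(i + 1, j, k), c(i - 1, j, k), c(i, j + 1, k),
                c(i, j - 1, k), c(i, j, k + 1), c(i, j, k - 1))
    outside <- apply(nb, 1, function(p)
      any(p < 1) || any(p > 10) || !blob[p[1], p[2], p[3]])
    oracle[i, j, k] <- any(outside)
  }
  expect_identical(got, oracle)

  # solid sphere radius 20: boundary count within 10% of the analytic
  # monolayer estimate. The 6-neighbour boundary of a digitized convex body
  # is one voxel per surface patch column along its dominant axis, i.e.
  # density max|n| per unit area; integrate over the sphere by quadrature.
  d <- c(48, 48, 48); ctr <- c(24, 24, 24)
  co <- expand.grid(1:48, 1:48, 1:48)
  ball <- array(sqrt((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
                       (co[, 3] - ctr[3])^2) <= 20, dim = d)
  nb <- sum(extract_boundary(acuhead:::binary_volume(ball))$mask)
  th <- seq(0, pi, length.out = 201); phi <- seq(0, 2 * pi, length.out = 401)
  dth <- diff(th)[1]; dph <- diff(phi)[1]
  gr <- expand.grid(th = th[-1] - dth / 2, phi = phi[-1] - dph / 2)
  n <- cbind(sin(gr$th) * cos(gr$phi), sin(gr$th) * sin(gr$phi), cos(gr$th))
  est <- 20^2 * sum(apply(abs(n), 1, max) * sin(gr$th)) * dth * dph
  expect_lt(abs(nb - est) / est, 0.10)

  # a one-voxel boundary is (near) its own fixed point: re-extraction only
  # ever removes voxels
  bb <- extract_boundary(acuhead:::binary_volume(ball))
  bb2 <- extract_boundary(bb)
  expect_true(all(bb$mask[bb2$mask]))
  expect_error(extract_boundary(acuhead:::binary_volume(array(FALSE, c(2, 2, 2)))),
               "empty")
})

test_that("phantom generator produces the stated intensity classes and landmarks", {
  s <- sphere64()
  vol <- s$phantom$volume
  ctr <- sphere64_spec()$center_voxel
  d <- vol$dims
  co <- expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  rr <- sqrt((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2)
  inside_skin <- rr <= 28
  in_skull <- rr <= 22 & rr > 18
  expect_true(all(vol$intensities[!inside_skin] < 10))
  expect_true(all(vol$intensities[in_skull] >= 110))
  expect_true(all(vol$intensities[inside_skin & !in_skull] >= 10 &
                    vol$intensities[inside_skin & !in_skull] < 110))
  # skull-shell mask from the generator equals binarize at 110
  expect_identical(binarize(vol, 110)$mask, array(in_skull, dim = d))

  # TOP is the highest skin-shell point
  gt <- s$phantom$landmarks
  top <- lm_point(gt, "TOP", "midline")
  expect_equal(top[3], max(gt$z))
  expect_equal(top[1:2], ctr[1:2], tolerance = 1e-12)

  # the three frame landmarks define a plane containing them exactly
  pl <- sagittal_plane(lm_point(gt, "Yintang", "midline"), top,
                       lm_point(gt, "GV17", "midline"))
  for (nm in c("Yintang", "TOP", "GV17"))
    expect_lt(abs(plane_distance(pl, lm_point(gt, nm, "midline"))), 1e-9)
})

test_that("phantom generation is seed-deterministic and validates its spec", {
  sp <- phantom_spec(skin_semiaxes_mm = c(16, 15, 14),
                     skull_semiaxes_mm = c(12, 11, 10), skull_thickness_mm = 3,
                     center_voxel = c(20, 20, 20), dims = c(40L, 40L, 40L),
                     noise_sd = 3, seed = 7L)
  a <- generate_head_phantom(sp)
  b <- generate_head_phantom(sp)
  expect_identical(a$volume$intensities, b$volume$intensities)
  expect_identical(as.data.frame(a$landmarks), as.data.frame(b$landmarks))

  expect_error(phantom_spec(skin_semiaxes_mm = c(0, 60, 60)), "skin semiaxis along x")
  expect_error(phantom_spec(skull_semiaxes_mm = c(52, 52, 70)), "along z")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")

  # ground-truth landmarks are within one voxel of the reconstructed skin
  s <- sphere64()
  d <- apply(acuhead:::lm_matrix(s$lms), 1, function(p)
    sqrt(min(rowSums(sweep(s$mesh$vertices, 2, p, "-")^2))))
  expect_lt(max(d) / s$pitch, 1)
})
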