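# Model frame transform and anatomical planes.

test_that("center_of_mass is the mean foreground voxel index", {
  one <- array(FALSE, c(8, 8, 8)); one[3, 4, 5] <- TRUE
  expect_equal(center_of_mass(acuhead:::binary_volume(one)), c(3, 4, 5))

  cube <- array(FALSE, c(20, 20, 20)); cube[6:14, 6:14, 6:14] <- TRUE
  expect_equal(center_of_mass(acuhead:::binary_volume(cube)), c(10, 10, 10))

  # explicit-sum oracle on a random 100-voxel mask
  set.seed(3)
  d <- c(15, 15, 15)
  pick <- sample(prod(d), 100)
  m <- array(FALSE, d); m[pick] <- TRUE
  ind <- arrayInd(which(m), d)
  expect_equal(center_of_mass(acuhead:::binary_volume(m)), colMeans(ind))
  expect_error(center_of_mass(acuhead:::binary_volume(array(FALSE, c(2, 2, 2)))),
               "empty")
})

test_that("model frame transform is the scaled centering map and inverts exactly", {
  fr <- model_frame(c(100, 120, 90), alpha = 4 / 512)
  expect_equal(to_model_frame(c(100, 120, 90), fr), c(0, 0, 0))
  expect_equal(to_model_frame(c(100 + 512, 120, 90), fr), c(4, 0, 0))

  set.seed(5)
  pts <- matrix(runif(30, 0, 512), ncol = 3)
  expect_equal(from_model_frame(to_model_frame(pts, fr), fr), pts,
               tolerance = 1e-12)
  expect_error(model_frame(c(0, 0, 0), alpha = 0), "alpha")
})

test_that("sagittal and coronal planes honor their defining landmark triples", {
  pl <- sagittal_plane(c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  expect_equal(abs(pl$normal), c(1, 0, 0))        # plane x = 0
  for (p in list(c(0, 1, 0), c(0, 0, 1), c(0, -1, 0)))
    expect_equal(plane_distance(pl, p), 0)

  # normal orthogonal to both spanning vectors (random non-collinear triple)
  set.seed(5)
  for (rep in 1:10) {
    yin <- rnorm(3); top <- rnorm(3); gv <- rnorm(3)
    pl2 <- sagittal_plane(yin, top, gv)
    expect_lt(abs(sum(pl2$normal * (gv - yin))), 1e-12 * max(abs(gv - yin)) * 10)
    expect_lt(abs(sum(pl2$normal * (top - yin))), 1e-12 * max(abs(top - yin)) * 10)
  }
  expect_error(sagittal_plane(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), "collinear")

  co <- coronal_plane(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 1))
  expect_equal(abs(co$normal), c(0, 1, 0))        # plane y = 0
  expect_equal(plane_distance(co, c(0.3, 0, -2)), 0)
  co_sw <- coronal_plane(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1))
  expect_equal(co_sw$normal, -co$normal)          # swap sides flips the normal
  expect_equal(co_sw$anchor, co$anchor)
})

test_that("transverse plane is orthogonal to both defining planes", {
  sag <- sagittal_plane(c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))   # x = 0
  cor <- coronal_plane(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 1))    # y = 0
  tr <- transverse_plane(sag, cor, c(0, 0, 2))
  expect_equal(abs(tr$normal), c(0, 0, 1))
  expect_equal(plane_distance(tr, c(5, -3, 2)), 0)              # z = 2
  expect_lt(abs(sum(tr$normal * sag$normal)), 1e-12)
  expect_lt(abs(sum(tr$normal * cor$normal)), 1e-12)

  set.seed(11)
  for (rep in 1:5) {
    s2 <- sagittal_plane(rnorm(3), rnorm(3), rnorm(3))
    c2 <- coronal_plane(rnorm(3), rnorm(3), rnorm(3))
    lv <- rnorm(3)
    t2 <- transverse_plane(s2, c2, lv)
    expect_equal(plane_distance(t2, lv), 0)
    expect_lt(abs(sum(t2$normal * s2$normal)), 1e-9)
    expect_lt(abs(sum(t2$normal * c2$normal)), 1e-9)
  }
  expect_error(transverse_plane(sag, sag, c(0, 0, 0)), "parallel")
})

test_that("plane membership is frame-covariant", {
  s <- sphere64()
  yin_s <- lm_point(s$phantom$landmarks, "Yintang", "midline")
  top_s <- lm_point(s$phantom$landmarks, "TOP", "midline")
  gv_s <- lm_point(s$phantom$landmarks, "GV17", "midline")
  pl_stack <- sagittal_plane(yin_s, top_s, gv_s)
  pl_model <- sagittal_plane(lm_point(s$lms, "Yintang", "midline"),
                             lm_point(s$lms, "TOP", "midline"),
                             lm_point(s$lms, "GV17", "midline"))
  set.seed(2)
  pts_stack <- matrix(runif(60, 10, 54), ncol = 3)
  pts_model <- to_model_frame(pts_stack, s$frame)
  side_stack <- sign(plane_distance(pl_stack, pts_stack))
  side_model <- sign(plane_distance(pl_model, pts_model))
  # orientation of the normal may flip with the frame; classification may not
  expect_true(all(side_stack == side_model) || all(side_stack == -side_model))
})

test_that("computed sagittal plane coincides with the phantom mirror plane", {
  s <- sphere64()
  pl <- sagittal_plane(lm_point(s$lms, "Yintang", "midline"),
                       lm_point(s$lms, "TOP", "midline"),
                       lm_point(s$lms, "GV17", "midline"))
  # construction mirror plane is x = 0 in the model frame
  expect_equal(abs(pl$normal), c(1, 0, 0), tolerance = 1e-9)
  expect_lt(abs(plane_distance(pl, c(0, 0, 0))), s$pitch)
  # every midline ground-truth landmark lies on it
  mids <- s$lms[s$lms$side == "midline", ]
  expect_lt(max(abs(plane_distance(pl, acuhead:::lm_matrix(mids)))), s$pitch)
})
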