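# Angle machinery about TE20CP and the proportional-rule solvers.

test_that("build_angle_frame midpoints TE20 and measures theta0", {
  # direct arithmetic on the printed standard TE20 coordinates
  lms <- landmark_set(data.frame(
    name = c("TE20", "TE20", "Yintang", "GV17"),
    side = c("left", "right", "midline", "midline"),
    x = c(-0.628, 0.623, 0, 0), y = c(-0.004, -0.004, 1, -1),
    z = c(-0.459, -0.459, 0.2, 0.2), frame = "model"))
  af <- build_angle_frame(lms)
  expect_equal(af$te20cp, c(-0.0025, -0.004, -0.459))

  # antipodal rays about te20cp -> theta0 = pi
  mk <- function(yin, gv) landmark_set(data.frame(
    name = c("TE20", "TE20", "Yintang", "GV17"),
    side = c("left", "right", "midline", "midline"),
    x = c(-1, 1, yin[1], gv[1]), y = c(0, 0, yin[2], gv[2]),
    z = c(0, 0, yin[3], gv[3]), frame = "model"))
  expect_equal(build_angle_frame(mk(c(0, 1, 0), c(0, -1, 0)))$theta0, pi)

  # orthogonal unit rays -> theta0 = pi/2
  af2 <- build_angle_frame(mk(c(0, 1, 0), c(0, 0, 1)))
  expect_equal(af2$theta0, pi / 2)
  expect_error(build_angle_frame(mk(c(0, 0, 0), c(0, 0, 1))), "TE20CP")
})

test_that("theta1/theta2 match an independent dot-product oracle", {
  s <- sphere128()
  af <- build_angle_frame(s$lms)
  expect_equal(theta1(af$gv17, af), 0)
  expect_equal(theta1(af$yintang, af), af$theta0)

  set.seed(2)
  for (rep in 1:10) {
    p <- rnorm(3)
    a <- af$te20cp; g <- af$gv17
    oracle <- acos(sum((p - a) * (g - a)) /
                     (sqrt(sum((p - a)^2)) * sqrt(sum((g - a)^2))))
    expect_equal(theta1(p, af), oracle, tolerance = 1e-12)
  }

  gv24 <- lm_point(s$prop, "GV24", "midline")
  expect_lt(theta2(gv24, af, gv24 = gv24), 1e-6)   # acos noise floor ~sqrt(eps)
  set.seed(4)
  for (rep in 1:10) {
    p <- rnorm(3)
    a <- af$te20cp
    oracle <- acos(sum((p - a) * (gv24 - a)) /
                     (sqrt(sum((p - a)^2)) * sqrt(sum((gv24 - a)^2))))
    expect_equal(theta2(p, af, gv24 = gv24), oracle, tolerance = 1e-12)
  }
  # orthogonal ray
  a <- af$te20cp
  u <- gv24 - a
  vperp <- c(-u[2], u[1], 0)
  expect_equal(theta2(a + vperp, af, gv24 = gv24), pi / 2, tolerance = 1e-12)

  expect_error(theta2(c(1, 1, 1), af), "GV24")
  expect_error(theta1(af$te20cp, af), "zero-length")
})

test_that("sagittal-ratio points match the great-circle rotation oracle", {
  s <- sphere128()
  af <- build_angle_frame(s$lms)
  r_model <- s$radius_mm * s$pitch
  ratios <- c(GV18 = 1.5, GV19 = 3.0, GV20 = 4.5, GV21 = 6.0, GV22 = 7.5,
              GV23 = 8.5, GV24 = 9.0)
  for (nm in names(ratios)) {
    oracle <- slerp_oracle(af, ratios[[nm]] / 12.5, r_model)
    got <- lm_point(s$prop, nm, "midline")
    expect_lt(acuhead:::vnorm(got - oracle), s$pitch)
  }
})

test_that("transverse-ratio points match the rotation oracle per side", {
  s <- sphere128()
  af <- build_angle_frame(s$lms)
  gv24 <- lm_point(s$prop, "GV24", "midline")
  r_model <- s$radius_mm * s$pitch
  for (nm in c("ST8", "GB13", "BL3", "BL4")) {
    ratio <- c(ST8 = 2.25, GB13 = 1.5, BL3 = 0.25, BL4 = 0.5)[[nm]]
    for (side in c("left", "right")) {
      oracle <- transverse_oracle(af, gv24, ratio / 12.5, r_model, side)
      got <- lm_point(s$prop, nm, side)
      expect_lt(acuhead:::vnorm(got - oracle), 2 * s$pitch)
    }
  }
})

test_that("ratio zero reproduces the GV17 anchor vertex", {
  s <- sphere128()
  af <- build_angle_frame(s$lms)
  sag <- sagittal_plane(af$yintang, lm_point(s$lms, "TOP", "midline"), af$gv17)
  rule <- list(target = "GV17x", kind = "sagittal_ratio",
               ratio_numerator = 0, ratio_denominator = 12.5)
  got <- solve_ratio_point(s$mesh, af, rule, sag)
  near_gv17 <- s$mesh$vertices[acuhead:::nearest_vertex(s$mesh, af$gv17), ]
  expect_lt(acuhead:::vnorm(got - near_gv17), 1.5 * s$pitch)
})

test_that("coordinate rules satisfy their constraints on the surface", {
  s <- sphere128()
  prop <- s$prop
  # GB15: x = Pupil_x, z = GV24_z (same-side pupil)
  gv24 <- lm_point(prop, "GV24", "midline")
  for (side in c("left", "right")) {
    gb15 <- lm_point(prop, side = side, name = "GB15")
    pupil <- lm_point(s$lms, "Pupil", side)
    expect_lt(abs(gb15[1] - pupil[1]), 2 * s$pitch)
    expect_lt(abs(gb15[3] - gv24[3]), 2 * s$pitch)
    expect_gt(gb15[2], 0)                 # anterior
  }
  # BL10: x = (GV16_x + GB20_x)/2, z = GV15_z, posterior
  gv16 <- lm_point(s$lms, "GV16", "midline")
  gv15 <- lm_point(s$lms, "GV15", "midline")
  for (side in c("left", "right")) {
    bl10 <- lm_point(prop, "BL10", side)
    gb20 <- lm_point(s$lms, "GB20", side)
    expect_lt(abs(bl10[1] - (gv16[1] + gb20[1]) / 2), 2 * s$pitch)
    expect_lt(abs(bl10[3] - gv15[3]), 2 * s$pitch)
    expect_lt(bl10[2], 0)
  }
  # SI19 is the mesh vertex nearest the TE21/GB2 midpoint
  for (side in c("left", "right")) {
    mid <- (lm_point(s$lms, "TE21", side) + lm_point(s$lms, "GB2", side)) / 2
    expect_equal(lm_point(prop, "SI19", side),
                 s$mesh$vertices[acuhead:::nearest_vertex(s$mesh, mid), ])
  }
})

test_that("compute_all_proportional returns 24 on-surface points in order", {
  s <- sphere128()
  prop <- s$prop
  expect_identical(length(unique(prop$name)), 24L)
  expect_identical(nrow(prop), 41L)  # 7 midline + 17 bilateral
  expect_setequal(unique(prop$side[prop$name %in% paste0("GV", 18:24)]), "midline")

  # strictly increasing theta1 along the GV chain (ratios increase)
  af <- build_angle_frame(s$lms)
  th <- vapply(paste0("GV", 18:24), function(nm)
    theta1(lm_point(prop, nm, "midline"), af), 0)
  expect_true(all(diff(th) > 0))

  # every output point is a mesh vertex
  vkeys <- paste(s$mesh$vertices[, 1], s$mesh$vertices[, 2], s$mesh$vertices[, 3])
  pkeys <- paste(prop$x, prop$y, prop$z)
  expect_true(all(pkeys %in% vkeys))

  # AUX helper is attached but not part of the 24
  aux <- attr(prop, "aux_points")
  expect_identical(aux$name, "AUX")
  expect_false("AUX" %in% prop$name)
})

test_that("bilateral proportional points mirror through the sagittal plane", {
  s <- sphere128()
  bil <- unique(s$prop$name[s$prop$side %in% c("left", "right")])
  expect_identical(length(bil), 17L)
  for (nm in bil) {
    l <- lm_point(s$prop, nm, "left")
    r <- lm_point(s$prop, nm, "right")
    expect_lt(acuhead:::vnorm(l - c(-r[1], r[2], r[3])), 2 * s$pitch)
  }
})
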