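# Distance-functional solver for morphological points.

test_that("distance functional is zero at exact correspondence, positive off it", {
  cat_obj <- the_catalog()
  rule <- cat_obj$morph_rules[[1]]            # GB4/GB5/GB6 from ST8, GB7
  st8 <- rule$standard$ST8$left; gb7 <- rule$standard$GB7$left
  gb4 <- rule$standard$GB4$left; gb5 <- rule$standard$GB5$left

  expect_equal(distance_functional(gb4, st8, gb7, st8, gb7, gb4), 0)
  expect_gt(distance_functional(gb5, st8, gb7, st8, gb7, gb4), 0)

  # hand-computed value: L(x = GB5 | R = GB4) from plain arithmetic
  d <- function(a, b) sqrt(sum((a - b)^2))
  hand <- (d(gb5, st8) - d(gb4, st8))^2 + (d(gb5, gb7) - d(gb4, gb7))^2
  expect_equal(distance_functional(gb5, st8, gb7, st8, gb7, gb4), hand,
               tolerance = 1e-14)
})

test_that("self-consistency recovers every printed standard coordinate exactly", {
  cat_obj <- the_catalog()
  for (rule in cat_obj$morph_rules) for (side in c("left", "right")) {
    sc <- morph_self_consistency(rule, side)
    for (sol in sc$solutions) {
      expect_identical(sol$position, as.numeric(rule$standard[[sol$name]][[side]]))
      expect_identical(sol$L_value, 0)
    }
  }
})

test_that("solutions are rigidly invariant", {
  cat_obj <- the_catalog()
  rule <- cat_obj$morph_rules[[1]]
  base <- morph_self_consistency(rule, "left")
  rig <- random_rigid(97)
  curve_t <- acuhead:::curve_path(apply_rigid(rig, base$curve$points))
  controls_t <- list(apply_rigid(rig, rule$standard$ST8$left),
                     apply_rigid(rig, rule$standard$GB7$left))
  names(controls_t) <- c("ST8", "GB7")
  sols_t <- solve_morph_rule(rule, target_controls = controls_t,
                             side = "left", curve = curve_t)
  for (i in seq_along(sols_t)) {
    expect_equal(sols_t[[i]]$position,
                 apply_rigid(rig, base$solutions[[i]]$position),
                 tolerance = 1e-9)
    expect_identical(sols_t[[i]]$curve_index, base$solutions[[i]]$curve_index)
  }
})

test_that("solver agrees with a brute-force oracle on a scaled target", {
  cat_obj <- the_catalog()
  rule <- cat_obj$morph_rules[[1]]
  base <- morph_self_consistency(rule, "left")
  scale <- 1.5
  curve_s <- acuhead:::curve_path(base$curve$points * scale)
  controls_s <- list(rule$standard$ST8$left * scale,
                     rule$standard$GB7$left * scale)
  names(controls_s) <- c("ST8", "GB7")
  sols <- solve_morph_rule(rule, target_controls = controls_s, side = "left",
                           curve = curve_s)
  # independent brute force with plain arithmetic
  d <- function(a, b) sqrt(sum((a - b)^2))
  for (sol in sols) {
    r <- rule$standard[[sol$name]]$left
    p <- rule$standard$ST8$left; q <- rule$standard$GB7$left
    Ls <- apply(curve_s$points, 1, function(x)
      (d(x, p * scale) - d(r, p))^2 + (d(x, q * scale) - d(r, q))^2)
    expect_identical(sol$curve_index, which.min(Ls))
    expect_equal(sol$L_value, min(Ls), tolerance = 1e-12)
  }
})

test_that("candidate curves are planar arcs joining the controls", {
  s <- sphere64()
  pa <- lm_point(s$lms, "ST7", "left")   # two well-separated surface points
  pb <- lm_point(s$lms, "GB9", "left")
  center <- colMeans(s$mesh$vertices)
  cv <- candidate_curve(s$mesh, pa, pb, center)
  # endpoints are the nearest mesh vertices to the controls
  expect_identical(cv$vertex_index[1], acuhead:::nearest_vertex(s$mesh, pa))
  expect_identical(cv$vertex_index[length(cv$vertex_index)],
                   acuhead:::nearest_vertex(s$mesh, pb))
  # planarity within the (widened) band tolerance
  n <- acuhead:::cross3(pa - center, pb - center)
  pl <- acuhead:::acu_plane(center, n, "section")
  expect_lt(max(abs(plane_distance(pl, cv$points))), 16 * 4 / 512)
  # arc length at least the chord, strictly increasing
  expect_gte(max(cv$arc), acuhead:::vnorm(pa - pb) - 2 * s$pitch)
  expect_true(all(diff(cv$arc) > 0))
  expect_error(candidate_curve(s$mesh, pa, pa, center), "coincide")
  expect_error(candidate_curve(s$mesh, pa, 2 * pa, center), "degenerate")
})

test_that("compute_all_morphological yields 7 names on both sides, on-curve", {
  s <- sphere128()
  combined <- landmark_set(rbind(as.data.frame(s$lms), as.data.frame(s$prop)))
  morph <- compute_all_morphological(s$mesh, combined)
  expect_identical(length(unique(morph$points$name)), 7L)
  expect_identical(nrow(morph$points), 14L)
  expect_setequal(unique(morph$points$side), c("left", "right"))

  # each solution lies on its candidate curve; residual no worse than the
  # curve endpoints
  cat_obj <- the_catalog()
  for (rule in cat_obj$morph_rules) for (side in c("left", "right")) {
    cv <- morph$curves[[paste(rule$control_a, rule$control_b, side, sep = "_")]]
    pa <- lm_point(combined, rule$control_a, side)
    pb <- lm_point(combined, rule$control_b, side)
    for (tn in rule$targets) {
      sol <- Filter(function(x) x$name == tn && x$side == side,
                    morph$solutions)[[1]]
      expect_true(any(rowSums(abs(sweep(cv$points, 2, sol$position, "-"))) < 1e-12))
      ends <- distance_functional(cv$points[c(1, nrow(cv$points)), ], pa, pb,
                                  rule$standard[[rule$control_a]][[side]],
                                  rule$standard[[rule$control_b]][[side]],
                                  rule$standard[[tn]][[side]])
      expect_lte(sol$L_value, min(ends) + 1e-12)
    }
  }

  # GB4, GB5, GB6 keep their order along the curve from ST8 toward GB7
  arcs <- vapply(c("GB4", "GB5", "GB6"), function(nm)
    Filter(function(x) x$name == nm && x$side == "left", morph$solutions)[[1]]$arc, 0)
  expect_true(all(diff(arcs) > 0))

  expect_error(compute_all_morphological(s$mesh, s$lms),
               "missing control point ST8")
})
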