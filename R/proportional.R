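# Proportional acupoints: the angle machinery about TE20CP and the rule
# table of the catalog applied to skin-surface vertices.
#
# All angle ratios share the denominator 12.5: the full angle theta0 from
# the GV17 ray to the Yintang ray (vertex TE20CP) corresponds to 12.5
# proportional units, so a rule "theta1/theta0 = r/12.5" picks the skin
# vertices whose ray from TE20CP makes the fractional angle r/12.5 * theta0
# with the GV17 ray. Vertices within a small angular interval are averaged
# and the average is snapped to the nearest mesh vertex so every output lies
# on the surface.

#' Angle reference frame about TE20CP
#'
#' `te20cp` is the midpoint of the left and the right TE20; `theta0` the
#' angle between the rays from TE20CP to Yintang and to GV17.
#'
#' @param landmarks a `landmark_set` containing TE20 (left and right),
#'   Yintang and GV17 (single frame).
#' @return Object of class `angle_frame` with fields `te20cp`, `theta0`,
#'   `yintang`, `gv17`.
#' @export
build_angle_frame <- function(landmarks) {
  te20l <- lm_point(landmarks, "TE20", "left")
  te20r <- lm_point(landmarks, "TE20", "right")
  yintang <- lm_point(landmarks, "Yintang", "midline")
  gv17 <- lm_point(landmarks, "GV17", "midline")
  te20cp <- (te20l + te20r) / 2
  if (vnorm(yintang - te20cp) < 1e-12 || vnorm(gv17 - te20cp) < 1e-12)
    stop("Yintang or GV17 coincides with TE20CP; angle rays undefined",
         call. = FALSE)
  theta0 <- vec_angle(yintang - te20cp, gv17 - te20cp)
  if (theta0 <= 0)
    stop("degenerate theta0 (coincident rays)", call. = FALSE)
  structure(list(te20cp = te20cp, theta0 = theta0,
                 yintang = yintang, gv17 = gv17),
            class = "angle_frame")
}

#' @export
print.angle_frame <- function(x, ...) {
  cat("<angle_frame> te20cp (", paste(signif(x$te20cp, 4), collapse = ", "),
      "), theta0 = ", signif(x$theta0 * 180 / pi, 5), " deg\n", sep = "")
  invisible(x)
}

#' Angles at the TE20CP vertex
#'
#' `theta1` is the angle between the rays from TE20CP to `p` and to GV17;
#' `theta2` the angle between the rays to `p` and to GV24 (which is itself a
#' proportional point and must already be available).
#'
#' @param p point (3-vector) or n x 3 matrix of points.
#' @param frame an [build_angle_frame()] result.
#' @param gv17 GV17 position; defaults to the one stored in `frame`.
#' @param gv24 GV24 position (required; computed upstream).
#' @return Angle(s) in radians, in `[0, pi]`.
#' @export
theta1 <- function(p, frame, gv17 = frame$gv17) {
  stopifnot(inherits(frame, "angle_frame"))
  ray_angles(p, frame$te20cp, gv17)
}

#' @rdname theta1
#' @export
theta2 <- function(p, frame, gv24) {
  stopifnot(inherits(frame, "angle_frame"))
  if (missing(gv24) || is.null(gv24))
    stop("theta2 requires GV24; compute the sagittal ratio points first",
         call. = FALSE)
  ray_angles(p, frame$te20cp, as_point3(gv24, "GV24"))
}

ray_angles <- function(p, vertex, ref) {
  P <- as_points_matrix(p)
  u <- sweep(P, 2, vertex, "-")
  lu <- sqrt(rowSums(u^2))
  if (any(lu < 1e-12)) stop("zero-length ray from TE20CP", call. = FALSE)
  v <- ref - vertex
  lv <- vnorm(v)
  if (lv < 1e-12) stop("zero-length reference ray from TE20CP", call. = FALSE)
  ang <- acos(pmax(-1, pmin(1, (u %*% v) / (lu * lv))))
  if (is.null(dim(p))) as.numeric(ang) else as.numeric(ang)
}

#' Solver tolerances for proportional points
#'
#' @param angle_tol half-width of the angular selection interval, radians
#'   (default 0.25 degrees).
#' @param plane_tol half-width of the plane band, model-frame units
#'   (default half the model-frame voxel pitch, `alpha * spacing / 2`).
#' @param coord_tol half-width for coordinate constraints, model-frame units
#'   (default equal to `plane_tol`).
#' @param widen_factor,widen_steps geometric widening schedule applied when a
#'   selection comes up empty.
#' @param alpha,spacing_mm used only for the derived defaults.
#' @return List of solver parameters.
#' @export
proportional_params <- function(angle_tol = 0.25 * pi / 180,
                                plane_tol = NULL, coord_tol = NULL,
                                widen_factor = 2, widen_steps = 4,
                                alpha = 4 / 512, spacing_mm = 1) {
  pitch <- alpha * spacing_mm
  plane_tol <- plane_tol %||% (pitch / 2)
  coord_tol <- coord_tol %||% plane_tol
  stopifnot(angle_tol > 0, plane_tol > 0, coord_tol > 0, widen_steps >= 0)
  list(angle_tol = angle_tol, plane_tol = plane_tol, coord_tol = coord_tol,
       widen_factor = widen_factor, widen_steps = widen_steps, pitch = pitch)
}

# Select with an interval that widens geometrically until non-empty.
widening_select <- function(residual, base_tol, params, label) {
  for (s in 0:params$widen_steps) {
    tol <- base_tol * params$widen_factor^s
    sel <- which(residual <= tol)
    if (length(sel)) return(sel)
  }
  stop("empty selection after maximum widening for ", label, call. = FALSE)
}

snap_to_vertex <- function(mesh, p) {
  i <- nearest_vertex(mesh, p)
  list(index = i, point = as.numeric(mesh$vertices[i, ]))
}

#' Solve one angle-ratio rule on the skin surface
#'
#' For a sagittal-ratio rule, candidate vertices lie in the midsagittal
#' plane band on the cranial arc (GV17 over TOP to Yintang); for a
#' transverse-ratio rule they lie in the transverse band through GV24 on the
#' requested side of the sagittal plane. Vertices whose fractional angle
#' matches the rule ratio within the angular interval are averaged and the
#' average is snapped to the nearest mesh vertex.
#'
#' @param mesh model-frame skin `surface_mesh`.
#' @param frame an `angle_frame`.
#' @param rule a proportional rule record (`sagittal_ratio` or
#'   `transverse_ratio`).
#' @param plane the selection plane: the midsagittal plane for sagittal
#'   rules, the transverse plane at the GV24 level for transverse rules.
#' @param params [proportional_params()].
#' @param gv24 GV24 position (transverse rules only).
#' @param side `"left"`, `"right"` or `"midline"`; side selection is taken
#'   relative to `sagittal` for transverse rules.
#' @param sagittal the midsagittal plane (needed for side selection of
#'   transverse rules).
#' @param side_ref a landmark on the subject's left (e.g. TE20 left) fixing
#'   the sign convention of the sagittal normal.
#' @return xyz 3-vector (a mesh vertex).
#' @export
solve_ratio_point <- function(mesh, frame, rule, plane,
                              params = proportional_params(),
                              gv24 = NULL, side = "midline",
                              sagittal = NULL, side_ref = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(frame, "angle_frame"))
  r <- rule$ratio_numerator / rule$ratio_denominator
  V <- mesh$vertices
  band <- abs(plane_distance(plane, V))
  target <- r * frame$theta0

  if (rule$kind == "sagittal_ratio") {
    # cranial-arc restriction: positive component along the in-plane
    # direction orthogonal to the GV17 ray, pointing toward Yintang
    u1 <- unitize(frame$gv17 - frame$te20cp)
    w <- frame$yintang - frame$te20cp
    u2 <- unitize(w - sum(w * u1) * u1)
    rel <- sweep(V, 2, frame$te20cp, "-")
    cranial <- as.numeric(rel %*% u2) >= 0
    cand <- which(band <= params$plane_tol & cranial)
    if (!length(cand))
      cand <- which(band <= params$plane_tol * params$widen_factor^params$widen_steps & cranial)
    if (!length(cand)) stop("no skin vertices in the sagittal band for ",
                            rule$target, call. = FALSE)
    ang <- theta1(V[cand, , drop = FALSE], frame)
  } else if (rule$kind == "transverse_ratio") {
    if (is.null(gv24)) stop("transverse rule before GV24 is available", call. = FALSE)
    if (is.null(sagittal) || is.null(side_ref))
      stop("transverse rules need the sagittal plane and a side reference",
           call. = FALSE)
    left_sign <- sign(plane_distance(sagittal, as_point3(side_ref)))
    sd <- plane_distance(sagittal, V)
    on_side <- if (side == "left") sd * left_sign >= 0 else sd * left_sign <= 0
    cand <- which(band <= params$plane_tol & on_side)
    if (!length(cand))
      cand <- which(band <= params$plane_tol * params$widen_factor^params$widen_steps & on_side)
    if (!length(cand)) stop("no skin vertices in the transverse band for ",
                            rule$target, call. = FALSE)
    ang <- theta2(V[cand, , drop = FALSE], frame, gv24)
  } else stop("not a ratio rule: ", rule$kind, call. = FALSE)

  sel <- widening_select(abs(ang - target), params$angle_tol, params,
                         paste0(rule$target, " (", side, ")"))
  avg <- colMeans(V[cand[sel], , drop = FALSE])
  snap_to_vertex(mesh, avg)$point
}

#' Solve one coordinate-constraint rule
#'
#' Selects skin vertices satisfying every axis constraint within the
#' coordinate tolerance, restricted to the rule's disambiguation half-space
#' (anterior y > 0, posterior y < 0, superior z > 0 in the model frame),
#' averages them and snaps to the nearest mesh vertex. Midpoint rules
#' project the constructed point directly to the nearest vertex.
#'
#' @param mesh model-frame skin `surface_mesh`.
#' @param rule a `coordinate` or `midpoint` rule record.
#' @param env named list mapping referenced point names to xyz positions
#'   (same-side instances for bilateral references).
#' @param params [proportional_params()].
#' @param side label used in error messages.
#' @return xyz 3-vector (a mesh vertex).
#' @export
solve_coordinate_point <- function(mesh, rule, env,
                                   params = proportional_params(),
                                   side = "midline") {
  stopifnot(inherits(mesh, "surface_mesh"))
  getp <- function(ref) {
    p <- env[[ref]]
    if (is.null(p)) stop("rule ", rule$target, " references unavailable point ",
                         ref, call. = FALSE)
    p
  }
  if (rule$kind == "midpoint") {
    terms <- rule$constraints[[1]]$terms
    p <- Reduce(`+`, lapply(terms, function(t) t$coef * getp(t$ref)))
    return(snap_to_vertex(mesh, p)$point)
  }
  if (rule$kind != "coordinate") stop("not a coordinate rule: ", rule$kind,
                                      call. = FALSE)
  V <- mesh$vertices
  resid <- rep(0, nrow(V))
  axis_col <- c(x = 1L, y = 2L, z = 3L)
  for (cst in rule$constraints) {
    val <- sum(vapply(cst$terms, function(t) t$coef * getp(t$ref)[axis_col[[cst$axis]]],
                      0))
    resid <- pmax(resid, abs(V[, axis_col[[cst$axis]]] - val))
  }
  hemi_ok <- switch(rule$hemi,
                    anterior = V[, 2] > 0,
                    posterior = V[, 2] < 0,
                    superior = V[, 3] > 0,
                    rep(TRUE, nrow(V)))
  resid[!hemi_ok] <- Inf
  sel <- widening_select(resid, params$coord_tol, params,
                         paste0(rule$target, " (", side, ")"))
  avg <- colMeans(V[sel, , drop = FALSE])
  snap_to_vertex(mesh, avg)$point
}

# Resolve the model-frame position of a referenced point for a given
# instance side, preferring already-computed points.
resolve_ref <- function(ref, side, landmarks, computed, catalog) {
  lat <- catalog$points$laterality[catalog$points$name == ref]
  if (!length(lat)) lat <- "midline"  # AUX helper
  use_side <- if (lat == "bilateral") side else "midline"
  if (!is.null(computed[[paste(ref, use_side)]])) return(computed[[paste(ref, use_side)]])
  if (lm_has(landmarks, ref, use_side)) return(lm_point(landmarks, ref, use_side))
  NULL
}

#' Compute all 24 proportional acupoints
#'
#' Runs the full proportional-rule table in dependency order: the
#' midsagittal angle-ratio chain (GV18..GV24 and the AUX helper) first, then
#' the transverse-ratio rules per side (which need GV24), then the
#' coordinate rules (which reference computed points). Bilateral points are
#' produced on both sides.
#'
#' @param mesh model-frame skin `surface_mesh`.
#' @param landmarks model-frame `landmark_set` holding the complete manual
#'   annotation (34 anatomical + Pupil/Yintang/TOP).
#' @param catalog an `acu_catalog`.
#' @param params [proportional_params()].
#' @return A `landmark_set` of 41 rows (7 midline + 17 bilateral names),
#'   provenance `"computed"`; the AUX helper point is attached as
#'   `attr(, "aux_points")`.
#' @export
compute_all_proportional <- function(mesh, landmarks, catalog = load_catalog(),
                                     params = proportional_params()) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(landmarks, "landmark_set"))
  if (!all(landmarks$frame == "model") || mesh$frame != "model")
    stop("proportional solver expects model-frame mesh and landmarks",
         call. = FALSE)
  yintang <- lm_point(landmarks, "Yintang", "midline")
  top <- lm_point(landmarks, "TOP", "midline")
  gv17 <- lm_point(landmarks, "GV17", "midline")
  te20l <- lm_point(landmarks, "TE20", "left")
  te20r <- lm_point(landmarks, "TE20", "right")
  sag <- sagittal_plane(yintang, top, gv17)
  cor <- coronal_plane(te20l, te20r, top)
  aframe <- build_angle_frame(landmarks)

  computed <- list()
  lat_of <- function(nm) {
    lt <- catalog$points$laterality[catalog$points$name == nm]
    if (length(lt)) lt else "midline"
  }

  for (rule in catalog$proportional_rules) {
    sides <- if (lat_of(rule$target) == "bilateral") c("left", "right") else "midline"
    for (s in sides) {
      if (rule$kind == "sagittal_ratio") {
        p <- solve_ratio_point(mesh, aframe, rule, sag, params)
      } else if (rule$kind == "transverse_ratio") {
        gv24 <- computed[["GV24 midline"]]
        if (is.null(gv24)) stop("dependency failure: GV24 must precede ",
                                rule$target, call. = FALSE)
        trans <- transverse_plane(sag, cor, gv24)
        p <- solve_ratio_point(mesh, aframe, rule, trans, params, gv24 = gv24,
                               side = s, sagittal = sag, side_ref = te20l)
      } else {
        env <- list()
        for (cst in rule$constraints)
          for (t in cst$terms) {
            pos <- resolve_ref(t$ref, s, landmarks, computed, catalog)
            if (is.null(pos)) stop("dependency failure for ", rule$target,
                                   ": missing input ", t$ref, " (", s, ")",
                                   call. = FALSE)
            env[[t$ref]] <- pos
          }
        p <- solve_coordinate_point(mesh, rule, env, params, side = s)
      }
      computed[[paste(rule$target, s)]] <- p
    }
  }

  keys <- names(computed)
  parts <- strsplit(keys, " ", fixed = TRUE)
  df <- data.frame(name = vapply(parts, `[`, "", 1),
                   side = vapply(parts, `[`, "", 2),
                   x = vapply(computed, `[`, 0, 1),
                   y = vapply(computed, `[`, 0, 2),
                   z = vapply(computed, `[`, 0, 3),
                   frame = "model", provenance = "computed",
                   stringsAsFactors = FALSE)
  aux <- df[df$name == "AUX", ]
  out <- landmark_set(df[df$name != "AUX", ])
  attr(out, "aux_points") <- aux
  out
}
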