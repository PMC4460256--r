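# Morphological acupoints: targets that only have descriptive definitions
# are transferred from a "standard" source model onto a target head by
# minimizing a distance functional along the surface curve joining the two
# control points. For an unknown position X on the target curve with target
# controls P', Q' and source triple (P, Q, R):
#
#   L(X) = (|X - P'| - |R - P|)^2 + (|X - Q'| - |R - Q|)^2
#
# L is zero exactly when the target distances reproduce the source
# distances, so running the solver with source = target recovers the source
# points exactly.

curve_path <- function(points, vertex_index = NULL) {
  points <- as_points_matrix(points)
  if (nrow(points) < 2L) stop("curve needs at least two vertices", call. = FALSE)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (any(seg <= 0)) stop("curve arc length must be strictly increasing",
                          call. = FALSE)
  structure(list(points = points, arc = s, vertex_index = vertex_index),
            class = "curve_path")
}

#' @export
print.curve_path <- function(x, ...) {
  cat("<curve_path> ", nrow(x$points), " vertices, length ",
      signif(max(x$arc), 5), "\n", sep = "")
  invisible(x)
}

#' Candidate surface curve between two control points
#'
#' Vertices of the mesh lying within tolerance of the plane through the two
#' control points and `center` are chained along mesh edges by the shortest
#' surface path between the vertices nearest the controls (the shorter of
#' the two arcs the plane section cuts on a closed head).
#'
#' @param mesh a `surface_mesh`.
#' @param p_prime,q_prime control-point positions on the target head.
#' @param center third point fixing the section plane (typically the head
#'   centroid).
#' @param tol band half-width; defaults to one model-frame voxel pitch and
#'   widens geometrically (factor 2, 4 steps) if no connected arc is found.
#' @return A `curve_path`; `vertex_index` holds mesh vertex indices.
#' @export
candidate_curve <- function(mesh, p_prime, q_prime, center, tol = 4 / 512) {
  stopifnot(inherits(mesh, "surface_mesh"))
  p_prime <- as_point3(p_prime, "p_prime")
  q_prime <- as_point3(q_prime, "q_prime")
  center <- as_point3(center, "center")
  if (vnorm(p_prime - q_prime) < 1e-12)
    stop("control points coincide; curve undefined", call. = FALSE)
  n <- cross3(p_prime - center, q_prime - center)
  if (vnorm(n) < 1e-12 * max(vnorm(p_prime - center), vnorm(q_prime - center))^2)
    stop("degenerate section plane (controls collinear with center)", call. = FALSE)
  pl <- acu_plane(center, n, "section")

  a <- nearest_vertex(mesh, p_prime)
  b <- nearest_vertex(mesh, q_prime)
  if (a == b) stop("control points map to the same mesh vertex", call. = FALSE)
  dist <- abs(plane_distance(pl, mesh$vertices))
  ed <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])

  for (s in 0:4) {
    band <- dist <= tol * 2^s
    band[c(a, b)] <- TRUE  # controls always admissible
    keep <- band[ed[, 1]] & band[ed[, 2]]
    if (!any(keep)) next
    sub <- ed[keep, , drop = FALSE]
    w <- sqrt(rowSums((mesh$vertices[sub[, 1], , drop = FALSE] -
                         mesh$vertices[sub[, 2], , drop = FALSE])^2))
    g <- igraph::graph_from_edgelist(sub, directed = FALSE)
    igraph::E(g)$weight <- w
    if (max(sub) < max(a, b)) g <- igraph::add_vertices(g, max(a, b) - max(sub))
    sp <- suppressWarnings(igraph::shortest_paths(g, from = a, to = b,
                                                  weights = igraph::E(g)$weight))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) >= 2L) {
      return(curve_path(mesh$vertices[path, , drop = FALSE], vertex_index = path))
    }
  }
  stop("no connected surface arc between the control points", call. = FALSE)
}

#' Distance functional of the morphological solver
#'
#' @param x candidate position(s) on the target curve (3-vector or n x 3).
#' @param p_prime,q_prime target control points.
#' @param p,q,r source control points and source target position.
#' @return Non-negative residual(s); zero iff the candidate reproduces both
#'   source control distances.
#' @export
distance_functional <- function(x, p_prime, q_prime, p, q, r) {
  X <- as_points_matrix(x)
  p_prime <- as_point3(p_prime); q_prime <- as_point3(q_prime)
  p <- as_point3(p); q <- as_point3(q); r <- as_point3(r)
  dp <- vnorm(r - p); dq <- vnorm(r - q)
  ap <- sqrt(rowSums(sweep(X, 2, p_prime, "-")^2))
  aq <- sqrt(rowSums(sweep(X, 2, q_prime, "-")^2))
  out <- (ap - dp)^2 + (aq - dq)^2
  if (is.null(dim(x))) out[1] else out
}

morph_solution <- function(name, position, L_value, side, curve_index, arc) {
  structure(list(name = name, position = as.numeric(position),
                 L_value = L_value, side = side,
                 curve_index = curve_index, arc = arc),
            class = "morph_solution")
}

#' Solve one morphological rule along a curve
#'
#' Exhaustively evaluates the distance functional at every curve vertex for
#' each target of the rule and returns the minimizer (ties broken toward
#' the smaller arc-length coordinate, i.e. toward `control_a`).
#'
#' @param rule a morphological rule record from the catalog.
#' @param mesh target `surface_mesh`; may be `NULL` when `curve` is given.
#' @param target_controls a `landmark_set` holding the rule's control points
#'   on the target head (side-specific instances), or a named list of
#'   positions.
#' @param side `"left"` or `"right"` (selects the standard-source
#'   coordinates).
#' @param curve optional precomputed `curve_path`; if missing it is built
#'   with [candidate_curve()] through `center`.
#' @param center section-plane anchor used when building the curve.
#' @return List of `morph_solution` objects, one per rule target.
#' @export
solve_morph_rule <- function(rule, mesh = NULL, target_controls, side,
                             curve = NULL, center = NULL) {
  getp <- function(nm) {
    if (inherits(target_controls, "landmark_set")) {
      if (!lm_has(target_controls, nm, side))
        stop("missing control point ", nm, " (", side, ")", call. = FALSE)
      lm_point(target_controls, nm, side)
    } else {
      p <- target_controls[[nm]]
      if (is.null(p)) stop("missing control point ", nm, " (", side, ")",
                           call. = FALSE)
      as_point3(p, nm)
    }
  }
  pa <- getp(rule$control_a)
  pb <- getp(rule$control_b)
  if (is.null(curve)) {
    if (is.null(mesh)) stop("either a mesh or a curve is required", call. = FALSE)
    if (is.null(center)) center <- colMeans(mesh$vertices)
    curve <- candidate_curve(mesh, pa, pb, center)
  }
  if (!inherits(curve, "curve_path")) stop("curve must be a curve_path", call. = FALSE)
  if (nrow(curve$points) == 0L) stop("empty curve", call. = FALSE)

  lapply(rule$targets, function(tn) {
    std <- rule$standard[[tn]][[side]]
    sp_a <- rule$standard[[rule$control_a]][[side]]
    sp_b <- rule$standard[[rule$control_b]][[side]]
    if (is.null(std) || is.null(sp_a) || is.null(sp_b))
      stop("rule lacks standard coordinates for ", tn, " (", side, ")",
           call. = FALSE)
    L <- distance_functional(curve$points, pa, pb, sp_a, sp_b, std)
    i <- which.min(L)  # first minimum = smaller arc-length coordinate
    morph_solution(tn, curve$points[i, ], L[i], side,
                   curve_index = i, arc = curve$arc[i])
  })
}

#' Compute all 7 morphological acupoints (both sides)
#'
#' Applies every catalog morphological rule per side, building the candidate
#' curve between the rule's control points on the target mesh. Control
#' points come from the supplied landmark set (anatomical annotation plus
#' computed proportional points; ST8 is a proportional control).
#'
#' @param mesh model-frame skin `surface_mesh`.
#' @param landmarks `landmark_set` containing all control points.
#' @param catalog an `acu_catalog`.
#' @return A list with `points` (a `landmark_set` of 14 rows, provenance
#'   `"computed"`), `solutions` (all `morph_solution`s) and `curves` (named
#'   list of `curve_path`s per rule and side).
#' @export
compute_all_morphological <- function(mesh, landmarks, catalog = load_catalog()) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(landmarks, "landmark_set"))
  center <- colMeans(mesh$vertices)
  rows <- list(); sols <- list(); curves <- list()
  for (rule in catalog$morph_rules) {
    for (s in c("left", "right")) {
      for (nm in c(rule$control_a, rule$control_b))
        if (!lm_has(landmarks, nm, s))
          stop("missing control point ", nm, " (", s, ")", call. = FALSE)
      pa <- lm_point(landmarks, rule$control_a, s)
      pb <- lm_point(landmarks, rule$control_b, s)
      curve <- candidate_curve(mesh, pa, pb, center)
      res <- solve_morph_rule(rule, mesh, landmarks, s, curve = curve)
      curves[[paste(rule$control_a, rule$control_b, s, sep = "_")]] <- curve
      for (sol in res) {
        sols[[length(sols) + 1L]] <- sol
        rows[[length(rows) + 1L]] <- data.frame(
          name = sol$name, side = s, x = sol$position[1], y = sol$position[2],
          z = sol$position[3], frame = mesh$frame, provenance = "computed",
          stringsAsFactors = FALSE)
      }
    }
  }
  list(points = landmark_set(do.call(rbind, rows)), solutions = sols,
       curves = curves)
}

#' Self-consistency curves and recovery from the standard source
#'
#' Rebuilds, for one rule and side, the synthetic curve through the printed
#' standard positions (controls and targets interpolated with `n_sub`
#' subdivisions per segment) and runs the solver with source = target. On
#' this input every recovered point must equal its standard coordinate
#' exactly.
#'
#' @param rule a morphological rule record.
#' @param side `"left"` or `"right"`.
#' @param n_sub subdivisions per polyline segment.
#' @return List with `curve` and `solutions`.
#' @export
morph_self_consistency <- function(rule, side = "left", n_sub = 20L) {
  ordered <- c(rule$control_a, rule$targets, rule$control_b)
  pts <- t(vapply(ordered, function(nm) rule$standard[[nm]][[side]], numeric(3)))
  verts <- list(pts[1, ])
  for (i in seq_len(nrow(pts) - 1L)) {
    for (t in seq_len(n_sub) / n_sub)
      verts[[length(verts) + 1L]] <- (1 - t) * pts[i, ] + t * pts[i + 1L, ]
  }
  curve <- curve_path(do.call(rbind, verts))
  controls <- list(pts[1, ], pts[nrow(pts), ])
  names(controls) <- c(rule$control_a, rule$control_b)
  sols <- solve_morph_rule(rule, mesh = NULL, target_controls = controls,
                           side = side, curve = curve)
  list(curve = curve, solutions = sols)
}
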