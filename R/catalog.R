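#' Load the bundled head acupoint catalog
#'
#' Reads the versioned JSON registry bundled with the package: 68 point
#' records (34 anatomical, 24 proportional, 7 morphological standard points
#' plus the Pupil/Yintang/TOP landmarks), the proportional-rule table and
#' the morphological-rule table with standard-source coordinates. The file
#' checksum and all registry invariants are verified on load.
#'
#' @param path catalog file; defaults to the bundled copy.
#' @return An object of class `acu_catalog` with elements `points`
#'   (data.frame), `aux_points`, `proportional_rules`, `morph_rules`,
#'   `version`.
#' @export
load_catalog <- function(path = system.file("extdata", "catalog.json",
                                            package = "acuhead")) {
  if (!nzchar(path) || !file.exists(path))
    stop("catalog file not found", call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  data <- raw[c("catalog_version", "points", "aux_points",
                "proportional_rules", "morph_rules")]
  # coerce JSON lists back to plain shapes
  data$proportional_rules <- lapply(data$proportional_rules, function(r) {
    r$ratio_numerator <- if (is.null(r$ratio_numerator)) NA_real_ else as.numeric(r$ratio_numerator)
    r$ratio_denominator <- if (is.null(r$ratio_denominator)) NA_real_ else as.numeric(r$ratio_denominator)
    r$constraints <- lapply(r$constraints, function(cst) {
      cst$terms <- lapply(cst$terms, function(t) {
        t$coef <- as.numeric(t$coef); t
      })
      cst
    })
    r
  })
  data$morph_rules <- lapply(data$morph_rules, function(r) {
    r$targets <- as.character(unlist(r$targets))
    r$standard <- lapply(r$standard, function(s)
      list(left = as.numeric(unlist(s$left)), right = as.numeric(unlist(s$right))))
    r
  })
  if (!identical(acu_checksum(catalog_canonical(data)),
                 as.character(raw$checksum)))
    stop("bundled catalog checksum mismatch; file corrupted or edited",
         call. = FALSE)

  pts <- do.call(rbind, lapply(data$points, function(p)
    data.frame(name = p$name, meridian = p$meridian, category = p$category,
               laterality = p$laterality, surface_model = p$surface_model,
               description = p$description, stringsAsFactors = FALSE)))
  cat_obj <- structure(list(points = pts,
                            aux_points = data$aux_points,
                            proportional_rules = data$proportional_rules,
                            morph_rules = data$morph_rules,
                            version = data$catalog_version),
                       class = "acu_catalog")
  validate_catalog(cat_obj)
  cat_obj
}

#' @export
print.acu_catalog <- function(x, ...) {
  tab <- table(x$points$category)
  cat("<acu_catalog> v", x$version, ": ", nrow(x$points), " records (",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

validate_catalog <- function(cat_obj) {
  pts <- cat_obj$points
  counts <- table(factor(pts$category, levels = c("anatomical", "proportional",
                                                  "morphological", "auxiliary")))
  expected <- c(anatomical = 34L, proportional = 24L, morphological = 7L,
                auxiliary = 3L)
  if (!identical(as.integer(counts[names(expected)]), unname(expected)))
    stop("catalog category counts are not 34/24/7/3", call. = FALSE)
  if (nrow(pts) != 68L) stop("catalog must hold 68 records", call. = FALSE)
  known <- c(pts$name, vapply(cat_obj$aux_points, `[[`, "", "name"))
  # every rule target and reference resolves
  prop_targets <- vapply(cat_obj$proportional_rules, `[[`, "", "target")
  refs <- unlist(lapply(cat_obj$proportional_rules, function(r)
    unlist(lapply(r$constraints, function(cst)
      vapply(cst$terms, `[[`, "", "ref")))))
  bad <- setdiff(unique(c(prop_targets, refs)), known)
  if (length(bad)) stop("unresolved names in proportional rules: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  prop_names <- pts$name[pts$category == "proportional"]
  missing_rule <- setdiff(prop_names, prop_targets)
  if (length(missing_rule)) stop("proportional points without a rule: ",
                                 paste(missing_rule, collapse = ", "), call. = FALSE)
  morph_names <- pts$name[pts$category == "morphological"]
  covered <- character()
  for (r in cat_obj$morph_rules) {
    if (length(c(r$control_a, r$control_b)) != 2L)
      stop("morph rule must have exactly 2 control points", call. = FALSE)
    need <- c(r$targets, r$control_a, r$control_b)
    bad <- setdiff(need, known)
    if (length(bad)) stop("unresolved names in morph rules: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in need) {
      s <- r$standard[[nm]]
      if (is.null(s) || length(s$left) != 3L || length(s$right) != 3L)
        stop("morph rule lacks standard coordinates for ", nm, call. = FALSE)
      # left/right standard positions are approximately mirror-symmetric in x
      if (abs(s$left[1] + s$right[1]) > 0.05)
        stop("standard coordinates of ", nm, " violate mirror symmetry tolerance",
             call. = FALSE)
      if (s$left[1] >= 0 || s$right[1] <= 0)
        stop("standard coordinates of ", nm, " have the wrong x sign pattern",
             call. = FALSE)
    }
    covered <- c(covered, r$targets)
  }
  missing_morph <- setdiff(morph_names, covered)
  if (length(missing_morph)) stop("morphological points without a rule: ",
                                  paste(missing_morph, collapse = ", "), call. = FALSE)
  invisible(cat_obj)
}

#' Required (name, side) instances for a full manual annotation
#'
#' The 34 anatomical acupoints plus the Pupil, Yintang and TOP landmarks,
#' bilateral names expanded to left and right.
#'
#' @param catalog an `acu_catalog`.
#' @return data.frame with columns `name`, `side`.
#' @export
required_annotations <- function(catalog = load_catalog()) {
  pts <- catalog$points[catalog$points$category %in% c("anatomical", "auxiliary"), ]
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    sides <- if (pts$laterality[i] == "bilateral") c("left", "right") else "midline"
    data.frame(name = pts$name[i], side = sides, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Load and validate a manual annotation file
#'
#' Reads a landmark file (JSON or CSV, see [read_landmarks()]) and checks it
#' against the catalog: every anatomical acupoint and the three auxiliary
#' landmarks must be present (bilateral points on both sides), names must be
#' known, and no (name, side) pair may repeat.
#'
#' @param path annotation file.
#' @param catalog an `acu_catalog`.
#' @return A `landmark_set`.
#' @export
load_annotations <- function(path, catalog = load_catalog()) {
  lms <- read_landmarks(path)
  known <- c(catalog$points$name, vapply(catalog$aux_points, `[[`, "", "name"))
  unknown <- setdiff(unique(lms$name), known)
  if (length(unknown))
    stop("unknown point name(s) in annotation: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  req <- required_annotations(catalog)
  have <- paste(lms$name, lms$side)
  missing <- req[!paste(req$name, req$side) %in% have, ]
  if (nrow(missing))
    stop("annotation is missing required landmark(s): ",
         paste(sprintf("(%s, %s)", missing$name, missing$side), collapse = ", "),
         call. = FALSE)
  lms
}
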