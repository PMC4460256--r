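# In-code definition of the head acupoint registry: taxonomy and per-point
# anatomical descriptions, the proportional-rule table (angle ratios over
# the common denominator 12.5 plus coordinate-constraint, midpoint and
# composite rules) and the morphological-rule table with the standard-source
# coordinates of the normal-man model. `tools/make_catalog.R` serializes
# this into inst/extdata/catalog.json, which is what `load_catalog()` reads;
# this builder is kept in the package so the bundled file can be regenerated
# and so the checksum has a single canonical form.

build_catalog_data <- function() {
  pt <- function(name, meridian, category, laterality, surface_model = "skin",
                 description = "") {
    list(name = name, meridian = meridian, category = category,
         laterality = laterality, surface_model = surface_model,
         description = description)
  }

  anatomical <- list(
    pt("GV15", "GV", "anatomical", "midline", "bone",
       "In the depression superior to the spinous process of C2 on the posterior median line"),
    pt("GV16", "GV", "anatomical", "midline", "bone",
       "Directly inferior to the external occipital protuberance"),
    pt("GV17", "GV", "anatomical", "midline", "bone",
       "External occipital protuberance"),
    pt("GV25", "GV", "anatomical", "midline", "skin", "Tip of the nose"),
    pt("GV26", "GV", "anatomical", "midline", "skin",
       "Midpoint of the philtrum midline"),
    pt("GV27", "GV", "anatomical", "midline", "skin",
       "Midpoint of the tubercle of the upper lip"),
    pt("GB1", "GB", "anatomical", "bilateral", "skin_and_bone",
       "Outer canthus of the eye"),
    pt("GB2", "GB", "anatomical", "bilateral", "bone",
       "Depression between the intertragic notch and the condylar process of the mandible"),
    pt("GB3", "GB", "anatomical", "bilateral", "bone",
       "Depression superior to the midpoint of the zygomatic arch"),
    pt("GB7", "GB", "anatomical", "bilateral", "skin",
       "Junction of the vertical line of the posterior border of the temple hairline and the horizontal line of the auricular apex"),
    pt("GB8", "GB", "anatomical", "bilateral", "skin",
       "Directly superior to the auricular apex"),
    pt("GB9", "GB", "anatomical", "bilateral", "skin",
       "Directly superior to the posterior border of the auricular root"),
    pt("GB12", "GB", "anatomical", "bilateral", "bone",
       "Depression posteroinferior to the mastoid process"),
    pt("GB20", "GB", "anatomical", "bilateral", "bone",
       "Inferior to the occipital bone, between the origins of the sternocleidomastoid and the trapezius"),
    pt("ST1", "ST", "anatomical", "bilateral", "skin_and_bone",
       "Between the eyeball and the infraorbital margin, directly inferior to the pupil"),
    pt("ST2", "ST", "anatomical", "bilateral", "bone", "In the infraorbital foramen"),
    pt("ST3", "ST", "anatomical", "bilateral", "skin",
       "Directly inferior to the pupil, level with the inferior border of the ala of the nose"),
    pt("ST4", "ST", "anatomical", "bilateral", "skin", "Angle of the mouth"),
    pt("ST5", "ST", "anatomical", "bilateral", "bone",
       "Anterior to the angle of the mandible, depression anterior to the masseter attachment"),
    pt("ST6", "ST", "anatomical", "bilateral", "bone", "Angle of the mandible"),
    pt("ST7", "ST", "anatomical", "bilateral", "bone",
       "Depression between the midpoint of the inferior border of the zygomatic arch and the mandibular notch"),
    pt("TE17", "TE", "anatomical", "bilateral", "skin",
       "Posterior to the ear lobe, depression anterior to the inferior end of the mastoid process"),
    pt("TE20", "TE", "anatomical", "bilateral", "skin", "Auricular apex"),
    pt("TE21", "TE", "anatomical", "bilateral", "skin_and_bone",
       "Depression between the supratragic notch and the condylar process of the mandible"),
    pt("TE22", "TE", "anatomical", "bilateral", "skin",
       "Anterior to the auricular root, posterior to the superficial temporal artery"),
    pt("TE23", "TE", "anatomical", "bilateral", "skin",
       "Depression at the lateral end of the eyebrow"),
    pt("BL1", "BL", "anatomical", "bilateral", "skin_and_bone",
       "Depression between the superomedial inner canthus and the medial orbital wall"),
    pt("BL2", "BL", "anatomical", "bilateral", "skin",
       "Depression at the medial end of the eyebrow"),
    pt("CV23", "CV", "anatomical", "midline", "bone",
       "Anterior neck, superior to the thyroid cartilage, depression superior to the hyoid bone"),
    pt("CV24", "CV", "anatomical", "midline", "skin",
       "Depression in the center of the mentolabial sulcus"),
    pt("LI19", "LI", "anatomical", "bilateral", "skin",
       "Level with the midpoint of the philtrum"),
    pt("LI20", "LI", "anatomical", "bilateral", "skin",
       "In the nasolabial sulcus, level with the midpoint of the lateral border of the ala of the nose"),
    pt("SI17", "SI", "anatomical", "bilateral", "bone",
       "Posterior to the angle of the mandible, depression anterior to the sternocleidomastoid"),
    pt("SI18", "SI", "anatomical", "bilateral", "skin_and_bone",
       "Inferior to the zygomatic bone, directly inferior to the outer canthus")
  )

  proportional <- c(
    lapply(paste0("GV", 18:24), pt, meridian = "GV", category = "proportional",
           laterality = "midline"),
    lapply(paste0("GB", 13:19), pt, meridian = "GB", category = "proportional",
           laterality = "bilateral"),
    list(pt("ST8", "ST", "proportional", "bilateral")),
    lapply(paste0("BL", 3:10), pt, meridian = "BL", category = "proportional",
           laterality = "bilateral"),
    list(pt("SI19", "SI", "proportional", "bilateral"))
  )

  morphological <- list(
    pt("GB4", "GB", "morphological", "bilateral"),
    pt("GB5", "GB", "morphological", "bilateral"),
    pt("GB6", "GB", "morphological", "bilateral"),
    pt("GB10", "GB", "morphological", "bilateral"),
    pt("GB11", "GB", "morphological", "bilateral"),
    pt("TE18", "TE", "morphological", "bilateral"),
    pt("TE19", "TE", "morphological", "bilateral")
  )

  auxiliary <- list(
    pt("Pupil", "AUXILIARY", "auxiliary", "bilateral", "skin",
       "Center line of the pupil"),
    pt("Yintang", "AUXILIARY", "auxiliary", "midline", "skin",
       "Midpoint between the eyebrows"),
    pt("TOP", "AUXILIARY", "auxiliary", "midline", "skin", "Top of the head")
  )

  # AUX: angle-ratio helper on the midsagittal arc (ratio 11.0/12.5), used
  # only as an input to the GB14 coordinate rule. Not a standard point and
  # not one of the three auxiliary landmarks; carried separately.
  aux_points <- list(pt("AUX", "AUXILIARY", "auxiliary_computed", "midline"))

  ratio_rule <- function(target, kind, num) {
    list(target = target, kind = kind, ratio_numerator = num,
         ratio_denominator = 12.5, constraints = list(), hemi = "")
  }
  coord_rule <- function(target, constraints, hemi) {
    list(target = target, kind = "coordinate", ratio_numerator = NA,
         ratio_denominator = NA, constraints = constraints, hemi = hemi)
  }
  cons <- function(axis, ...) {
    terms <- list(...)
    list(axis = axis,
         terms = lapply(terms, function(t) list(ref = t[[1]], coef = as.numeric(t[[2]]))))
  }

  proportional_rules <- list(
    # midsagittal angle-ratio chain (theta1 against the GV17 ray)
    ratio_rule("GV18", "sagittal_ratio", 1.5),
    ratio_rule("GV19", "sagittal_ratio", 3.0),
    ratio_rule("GV20", "sagittal_ratio", 4.5),
    ratio_rule("GV21", "sagittal_ratio", 6.0),
    ratio_rule("GV22", "sagittal_ratio", 7.5),
    ratio_rule("GV23", "sagittal_ratio", 8.5),
    ratio_rule("GV24", "sagittal_ratio", 9.0),
    ratio_rule("AUX", "sagittal_ratio", 11.0),
    # hairline band (theta2 against the GV24 ray, per side)
    ratio_rule("ST8", "transverse_ratio", 2.25),
    ratio_rule("GB13", "transverse_ratio", 1.5),
    ratio_rule("BL3", "transverse_ratio", 0.25),
    ratio_rule("BL4", "transverse_ratio", 0.5),
    # coordinate-constraint rules (evaluated after the ratio rules)
    coord_rule("GB14", list(cons("x", list("Pupil", 1)), cons("z", list("AUX", 1))),
               hemi = "anterior"),
    coord_rule("GB15", list(cons("x", list("Pupil", 1)), cons("z", list("GV24", 1))),
               hemi = "anterior"),
    coord_rule("GB16", list(cons("x", list("Pupil", 1)), cons("z", list("GV23", 1))),
               hemi = "anterior"),
    coord_rule("GB17", list(cons("x", list("Pupil", 1)),
                            cons("z", list("GV22", 0.5), list("GV23", 0.5))),
               hemi = "anterior"),
    coord_rule("BL5", list(cons("x", list("BL4", 1)), cons("z", list("GV23", 1))),
               hemi = "anterior"),
    coord_rule("BL6", list(cons("x", list("BL4", 1)),
                           cons("y", list("GV21", 1 / 3), list("GV22", 2 / 3))),
               hemi = "superior"),
    coord_rule("BL7", list(cons("x", list("BL4", 1)),
                           cons("y", list("GV20", 1 / 3), list("GV21", 2 / 3))),
               hemi = "superior"),
    coord_rule("BL8", list(cons("x", list("BL4", 1)),
                           cons("y", list("GV19", 1 / 3), list("GV20", 2 / 3))),
               hemi = "superior"),
    # composite rule; coefficient grouping 1.3/1.5 is deliberately isolated
    # here so it can be corrected without code changes
    coord_rule("BL9", list(cons("x", list("GV17", 1), list("BL4", -1.3 / 1.5),
                                list("GV24", 1.3 / 1.5)),
                           cons("z", list("GV17", 1))),
               hemi = "posterior"),
    coord_rule("GB18", list(cons("x", list("GB17", 1)), cons("z", list("BL7", 1))),
               hemi = "posterior"),
    coord_rule("GB19", list(cons("x", list("GB20", 1)), cons("z", list("GV17", 1))),
               hemi = "posterior"),
    coord_rule("BL10", list(cons("x", list("GV16", 0.5), list("GB20", 0.5)),
                            cons("z", list("GV15", 1))),
               hemi = "posterior"),
    # 3D midpoint projected to the skin surface
    list(target = "SI19", kind = "midpoint", ratio_numerator = NA,
         ratio_denominator = NA,
         constraints = list(cons("xyz", list("TE21", 0.5), list("GB2", 0.5))),
         hemi = "")
  )

  std <- function(lx, ly, lz, rx, ry, rz) list(left = c(lx, ly, lz), right = c(rx, ry, rz))
  morph_rules <- list(
    list(targets = c("GB4", "GB5", "GB6"), control_a = "ST8", control_b = "GB7",
         standard = list(
           GB4 = std(-0.539, 0.274, -0.912, 0.560, 0.274, -0.912),
           GB5 = std(-0.610, 0.272, -0.759, 0.628, 0.272, -0.759),
           GB6 = std(-0.639, 0.239, -0.594, 0.655, 0.239, -0.594),
           ST8 = std(-0.447, 0.278, -1.026, 0.457, 0.278, -1.026),
           GB7 = std(-0.641, 0.155, -0.474, 0.651, 0.155, -0.474))),
    list(targets = c("GB10", "GB11"), control_a = "GB9", control_b = "GB12",
         standard = list(
           GB10 = std(-0.584, -0.266, -0.467, 0.541, -0.266, -0.467),
           GB11 = std(-0.556, -0.266, -0.220, 0.541, -0.266, -0.220),
           GB9 = std(-0.641, -0.089, -0.714, 0.613, -0.089, -0.714),
           GB12 = std(-0.529, -0.138, 0.027, 0.529, -0.138, 0.027))),
    list(targets = c("TE18", "TE19"), control_a = "TE17", control_b = "TE20",
         standard = list(
           TE18 = std(-0.555, -0.159, -0.128, 0.555, -0.134, -0.128),
           TE19 = std(-0.604, -0.159, -0.284, 0.585, -0.159, -0.284),
           TE17 = std(-0.546, -0.004, 0.027, 0.566, -0.004, 0.027),
           TE20 = std(-0.628, -0.004, -0.459, 0.623, -0.004, -0.459)))
  )

  list(catalog_version = "1.0",
       points = c(anatomical, proportional, morphological, auxiliary),
       aux_points = aux_points,
       proportional_rules = proportional_rules,
       morph_rules = morph_rules)
}

# Canonical serialization used for the bundled-file checksum; must be stable
# across write (tools/make_catalog.R) and read (load_catalog).
catalog_canonical <- function(data) {
  fmt <- function(x) {
    if (is.numeric(x)) paste(trimws(formatC(x, format = "g", digits = 15)), collapse = ",")
    else paste(as.character(x), collapse = ",")
  }
  pts <- vapply(c(data$points, data$aux_points), function(p)
    paste(p$name, p$meridian, p$category, p$laterality, p$surface_model,
          p$description, sep = "|"), "")
  rules <- vapply(data$proportional_rules, function(r) {
    con <- vapply(r$constraints, function(cst)
      paste(cst$axis, paste(vapply(cst$terms, function(t)
        paste0(t$ref, "*", fmt(t$coef)), ""), collapse = "+"), sep = ":"), "")
    paste(r$target, r$kind, fmt(r$ratio_numerator), fmt(r$ratio_denominator),
          paste(con, collapse = ";"), r$hemi, sep = "|")
  }, "")
  morph <- vapply(data$morph_rules, function(r) {
    stds <- vapply(names(r$standard), function(nm)
      paste(nm, fmt(r$standard[[nm]]$left), fmt(r$standard[[nm]]$right), sep = "@"), "")
    paste(paste(r$targets, collapse = ","), r$control_a, r$control_b,
          paste(stds, collapse = ";"), sep = "|")
  }, "")
  paste(c(data$catalog_version, pts, rules, morph), collapse = "\n")
}
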