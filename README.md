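# acuhead

Localization of the 65 standardized head acupuncture points on 3D surface
models reconstructed from axial image stacks (head CT-like data), for
researchers who need reproducible, quantitative point positions instead of
manual cun-based measurement.

Every head acupoint falls in one of three classes, and each class has its
own solver:

- **Anatomical (34)** — defined by skin/skull structure; supplied as a
  manual annotation (or by the built-in phantom as ground truth).
- **Proportional (24)** — computed from angle ratios about TE20CP, the
  midpoint of the two TE20 points. With θ₀ the angle
  ∠(Yintang, TE20CP, GV17) worth 12.5 units, a rule θ₁/θ₀ = r/12.5 selects
  skin vertices at the fractional angle from the GV17 ray in the
  midsagittal band (θ₂ rules likewise in the transverse band at the GV24
  level, per side), averages them and snaps to the surface. Coordinate
  rules (e.g. GB15: `P_x = Pupil_x`, `P_z = GV24_z`) constrain coordinates
  instead of angles.
- **Morphological (7)** — only descriptively defined; transferred from a
  standard source model by minimizing, along the surface curve between the
  two control points,
  `L(X) = (|X−P′| − |R−P|)² + (|X−Q′| − |R−Q|)²`
  where (P, Q, R) are the source controls/target and (P′, Q′) the target
  controls.

All computation happens in a centered, scaled model frame
`p′ = α (p − CM)`, α = 4/512, with anatomical planes fixed by landmark
triples (midsagittal: Yintang/TOP/GV17; coronal: TE20 left/right/TOP).

A synthetic two-shell head phantom (skin intensity ≥ 10, skull ≥ 110,
analytically known landmarks) provides end-to-end validation against
closed-form spherical oracles. See `vignettes/acuhead-methods.Rmd` for the
full model description and design rationale.

## Worked example

```r
library(acuhead)

## phantom head -> BMP stack -> mesh -> all 65 points
root <- tempfile("acuhead")
cfg <- run_config(
  phantom = phantom_spec(),                       # 128^3, r = 60 mm sphere
  paths = list(stack_dir  = file.path(root, "stack"),
               mesh       = file.path(root, "skin.ply"),
               annotation = file.path(root, "stack", "landmarks.json"),
               points_csv = file.path(root, "points.csv")))
cmd_phantom(cfg)        # stack + ground-truth annotation
cmd_reconstruct(cfg)    # binarize >= 10, fill, triangulate, model frame
pts <- cmd_position(cfg)

table(read.csv(cfg$paths$points_csv, comment.char = "#")$category)
#>    anatomical morphological  proportional
#>            60            14            41      (115 instances, 65 names)
```

On the spherical phantom the solver recovers the stated proportional units
(printed by the acceptance tests): GV20 at 4.49/12.5 against its defining
4.5, ST8 at 2.25/12.5, and every GV-chain point within one voxel of the
closed-form great-circle position.

Morphological self-consistency (the solver run with source = target on the
bundled standard-source curves) returns the standard coordinates exactly:

```r
cat <- load_catalog()
sc <- morph_self_consistency(cat$morph_rules[[1]], side = "left")
sc$solutions[[1]][c("name", "position", "L_value")]
#> $name     [1] "GB4"
#> $position [1] -0.539  0.274 -0.912
#> $L_value  [1] 0
```

## Command line

`inst/cli/acuhead.R` wraps the same four commands
(`phantom`, `reconstruct`, `frames`, `position`) with `--config cfg.json`
(YAML accepted when the `yaml` package is installed); `position` accepts
`--dump-curves curves.json` for plotting the control-point curves.
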