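# grainstereo

Automatic measurement of rice/grain **thickness** from a two-camera stereo
pair, using the **shape of the grain edge** instead of surface texture.

## Why this exists

Length and width of a grain are easy 2-D image measurements; thickness
needs depth. Stereo reconstruction would give depth, but a grain's crown is
smooth and textureless — there is nothing for a conventional matcher to
match at exactly the points that define thickness. `grainstereo` works
around this with two ideas:

1. **Half-thickness hypothesis.** A grain of thickness *H* resting on a
   board shows its silhouette rim at height *h* with one side up and
   *H − h* with the other. With fair random flips the expected rim height is

   ```
   ½·h + ½·(H − h) = ½·H
   ```

   so the **thickness is twice the mean rim height** over a population of
   randomly dropped grains. The measurement target moves from the
   unmatchable crown to the matchable silhouette edge.

2. **Polar-distance edge matching.** Each segmented grain boundary becomes
   a 360-element profile `h(θ)` — centroid-to-edge distance resampled at 1°
   by linear interpolation. Corresponding edge points across the stereo
   pair are found as the circular shift `k` maximising the Pearson
   correlation between the two profiles; left angle `i` then corresponds to
   right angle `(i + k) mod 360`.

The pipeline: undistort → segment (gray → median → Otsu → area filter) →
orient each camera by **space resection** on a circle-grid board → match
grains, then edge points → triangulate each pair by **space intersection**
(collinearity equations, 4 equations / 3 unknowns) → per-grain mean rim
height → thickness = 2 × mean over grains.

A fully ground-truthed **synthetic stereo-scene generator** ships with the
package, so every stage — and the end-to-end error — can be exercised and
scored without any real imagery.

## Worked example

```r
library(grainstereo)

# a synthetic scene at the study geometry: 20 grains of true thickness
# 1.8 mm (rim asymmetry 0.15 mm), cameras 350 mm up, 80 mm baseline,
# ~0.1 mm/px, gray noise sigma = 2 levels
scene <- sample_scene(n_grains = 20, H = 1.8, delta = 0.15, seed = 7)
imgs  <- render_stereo(scene)

# orient both cameras from the board's circle grid (space resection)
ori <- orient_stereo(imgs$left, imgs$right, scene$board,
                     camera_model(scene$left_cam$io,
                                  width = scene$left_cam$width,
                                  height = scene$left_cam$height),
                     camera_model(scene$right_cam$io,
                                  width = scene$right_cam$width,
                                  height = scene$right_cam$height),
                     px_per_mm = 10)

report <- measure_thickness(imgs$left, imgs$right, ori$left, ori$right,
                            board = scene$board,
                            exclude_masks = ori$circle_masks)
print(report)
```

```
Grain thickness report
  grains measured : 20
  mean edge height: 0.8864 mm
  thickness       : 1.7728 mm  (2 x mean edge height)
  mean reprojection residual: 0.065 px
```

The true thickness is 1.8 mm; the 0.027 mm shortfall here is almost
entirely the flip average of this particular scene (12 of 20 grains landed
low-side-up), not the imaging chain — resection RMS was 0.005 px and the
mean reprojection residual 0.065 px. `report$per_grain` lists each grain's
rim height (here ≈ 0.73 mm or ≈ 1.04 mm depending on flip), matched region
ids and residuals; `write_thickness_csv()` exports the table.

A command-line front end (`inst/cli/grainstereo`) wraps the same steps as
`orient` / `measure` / `simulate` / `evaluate` subcommands for shell use.

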