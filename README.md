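# stereotrap

Stereo camera-trap depth estimation and distance sampling, at desk scale.

Camera traps are the workhorse of automated wildlife monitoring, but almost
all of them are monocular: they cannot measure how far an animal is from the
camera. That distance is exactly what abundance-estimation methods such as
camera-trap distance sampling (CTDS) need, because the effective area a
camera surveys must be inferred statistically from the distances of observed
animals. A stereo camera trap closes this gap: two horizontally displaced
cameras yield a disparity for every pixel, and disparity converts to metric
depth through the rig geometry. `stereotrap` implements the full analysis
chain downstream of the hardware as a tested R package:

1. **Stereo matching** (`build_cost_volume`, `disparity_from_cost_volume`) —
   a sum-squared-difference cost volume over rectified pairs,
   `V(i,j,d) = Σ_{Δj=-c..c} (a(i, j+Δj) - b(i-d, j+Δj))²`,
   read out by winner-take-all with optional sub-pixel refinement.
2. **Depth** (`disparity_to_depth`) — `z = b·f/d` with baseline `b` (m) and
   focal length `f` (px); zero/invalid disparities map to `NaN`, never `Inf`.
3. **Quality metrics** (`pointwise_errors`, `disparity_error_summary`,
   `temporal_quality`, `fallback_flow`) — RMSE and endpoint error against
   rangefinder ground truth, compared in disparity space, and the
   flow-compensated temporal instability
   `E_t = (1/((N_T-1)·N_P)) Σ_n Σ_{x,y} |D(x,y,n) - D(x-m_x, y-m_y, n-1)|`.
4. **Frame sampling** (`sample_video_adaptive`, `fixed_rate_sample`) — fixed
   temporal rate, or motion-adaptive selection that accumulates the
   foreground ratio from Gaussian-mixture background subtraction until a
   threshold (default 10%) is reached.
5. **Distance fusion** (`animal_distance_mask`, `animal_distance_bbox`,
   `build_observation_table`) — applies instance masks (median) or bounding
   boxes (lower quartile) from an external detector to the depth maps,
   producing per-animal observation distances.
6. **Distance sampling** (`fit_detection_function`) — bins distances into
   equal intervals between left/right truncations (default 7 bins, 3–11 m)
   and fits a detection function `g(r)` — uniform key with cosine
   adjustment(s), or half-normal — by binned multinomial maximum likelihood
   under point-transect geometry (`p_k ∝ ∫_bin r·g(r) dr`), reporting the
   average detection probability `P̄ = ∫ g(r)·2r dr / (w_r² - w_l²)`.
7. **Synthetic scenes** (`scene_spec`, `render_stereo_pair`,
   `render_motion_video`, `degrade_night`) — seeded generators with exact
   ground truth, used throughout the test suite.

Detections themselves (MegaDetector-style JSON boxes or per-instance mask
images) and the rectification maps are consumed as inputs; no detector or
calibration is trained or computed here.

## Conventions

* Images are matrices `[row, column]`, intensities in `[0, 1]`. In all
  files and CLI options, pixel coordinates are 0-based with `x` = column;
  boxes are half-open.
* The right image is searched leftward: a point at left column `i` with
  disparity `d` sits at right column `i - d`.
* Invalid pixels are `NaN` (also inside PFM files).
* Float maps are little-endian Middlebury PFM; grayscale frames and masks
  are Netpbm PGM (this environment ships no PNG/TIFF reader for R).

## Worked example

Render a synthetic scene (an "animal" disk at 5 m in front of a 20 m
background, rig: baseline 0.5 m, focal length 320 px), match it, fuse the
mask with depth, then fit a detection function to distances simulated from a
known model:

```r
library(stereotrap)
rig  <- stereo_rig(baseline_m = 0.5, focal_px = 320)
spec <- scene_spec(width = 96, height = 72, rig = rig, background_depth_m = 20,
                   blobs = list(list(center = c(70, 36), radius = 11, depth_m = 5)),
                   seed = 7)
sc    <- render_stereo_pair(spec)
vol   <- build_cost_volume(sc$pair, max_disparity = 56, patch_half_height = 1)
disp  <- disparity_from_cost_volume(vol)
depth <- disparity_to_depth(disp, rig)
disp[37, 71]                               # 32  (px: 0.5 * 320 / 5)
animal_distance_mask(sc$masks[[1]], depth) # 5   (m)

true <- detection_function("uniform", 1L, coefficients = 0.5)
d    <- simulate_distances(true, 2000, seed = 7)
ds   <- distance_dataset(d, left_trunc = 3, right_trunc = 11, n_bins = 7)
fit  <- fit_detection_function(bin_distances(ds), ds)
fit
#> <detection_fit> uniform key, cosine order(s) 1, a = 0.5086
#>   logLik -3880.5189, AIC 7763.0379, average detection probability 0.5848
#>   chi-square GOF 6.0709 on 5 df (p = 0.2994)
```

The recovered cosine coefficient (0.5086) matches the generating value 0.5
within sampling error; the average detection probability says that an animal
present uniformly over the 3–11 m annulus is detected with probability
about 0.58 under this model, the quantity that scales observed counts
toward abundance.

## Command line

A wrapper script is installed at
`system.file("cli", "stereotrap", package = "stereotrap")`:

```sh
stereotrap match --left L.pgm --right R.pgm --max-disparity 56 \
    --patch-half-height 1 -o disp.pfm
stereotrap depth --disparity disp.pfm --calib calib.yaml -o depth.pfm
stereotrap eval --pred disp.pfm --calib calib.yaml --gt points.csv
stereotrap eval-temporal --frames 'disp_*.pfm' --fallback-flow --block 16 --range 8
stereotrap sample --mode adaptive --ratios ratios.csv --threshold 0.10 --burn-in 50
stereotrap distances --detections md.json --depth 'out/*_depth.pfm' \
    --calib calib.yaml -o obs.csv
stereotrap ctds --distances obs.csv --left-trunc 3 --right-trunc 11 --bins 7
stereotrap run --config pipeline.yaml
```

`calib.yaml` is flat YAML: `baseline_m`, `focal_px`, optional
`image_width`/`image_height` and `rectify_{left,right}_{x,y}` PFM remap-grid
paths.

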