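# scleraflow

Blood-flow velocimetry for unstable grayscale video of scleral and
conjunctival microvessels.

Video of the eye's surface vessels carries diagnostic information — linear
and volumetric blood speed, and the topology of the vascular net — but the
raw footage is unusable as-is: the eye cannot be fixed, so the view
translates between frames (sometimes jumping far away), sharpness and
illumination drift, and only part of each frame holds analyzable contrast.
`scleraflow` implements the full measurement cascade for such video and a
synthetic vascular phantom generator that provides ground truth (mask,
centerline, camera offsets, per-segment speeds) for validating every stage.

The cascade:

1. **Informative regions** — gradient magnitude as the maximum of the two
   3×3 Sobel responses; Michelson-type contrast on the gradient image,
   C = (I_max − I_min)/(I_max + I_min), with frames below C = 0.3
   discarded; binarization at the knee (maximum bend) of the cumulative
   gradient histogram; debris removal and dilation; ROI bounding box.
2. **Fragmentation** — the weighted centroid of informative pixels is
   tracked; a fragment ends when the centroid drifts more than 100 px;
   frames are cropped to a common contrast box.
3. **Stabilization** — zero-normalized cross-correlation against a
   reference patch (50% of the first frame's ROI), or Shi–Tomasi corners
   tracked by pyramidal Lucas–Kanade flow with the per-frame offset as the
   median keypoint displacement. Matching quality is scored as
   Mr = 200·M/(Kp1 + Kp2).
4. **Vessel masking** — multi-scale Hessian (Frangi-type) tubularness
   enhancement (probability polarity: 0 = vessel), plus the
   accuracy / RMS-deviation evaluation statistics; an optional
   phantom-trained sliding-window patch classifier.
5. **Flow and topology** — constant background fill from the halo mean,
   iterative brightness equalization to mean γ = 0.5, Farnebäck dense
   optical flow, velocity profiles along the skeleton midline, vessel width
   from the distance transform, volumetric speed Q = v·S with
   S = π(w/2)², and net metrics (length, branchiness, compactness,
   tortuosity).

## Worked example

Generate a jittered, drifting phantom whose main tube advects texture at
2 px/frame, run the full cascade, and read the per-segment report:

```r
library(scleraflow)

scene  <- make_vessel_tree(3, seed = 2, layout = "straight")
motion <- phantom_motion(jitter_sd = 2, blur_sd_range = c(0, 0.4),
                         illumination_drift_amplitude = 0.03, seed = 8)
rv <- render_video(scene, motion, speeds = c(2, 0.6, 0.6), n_frames = 12)
rv$video
#> vessel_video: 12 frames of 160x160 (uncalibrated)

report <- run_pipeline(pipeline_config(seed = 1), video = rv$video)
report
#> pipeline_report: status 'ok', 1 fragment(s)
#>   frames 1-12: 3 segment(s), ok

segs <- report$fragments[[1]]$segments
main <- segs[[which.max(vapply(segs, function(s) s$length, 0))]]
sprintf("length %.1f px, width %.2f px, v = %.3f px/frame, Q = %.1f px^3/frame",
        main$length, main$width, main$v_rel, main$Q)
#> "length 108.6 px, width 7.21 px, v = 1.868 px/frame, Q = 76.2 px^3/frame"
```

The measured centerline speed of 1.868 px/frame recovers the true advection
speed of 2 px/frame to within 6.6% after ROI detection, fragmentation,
stabilization, masking and dense optical flow. `Q` is the volumetric speed
under the circular cross-section model; with `um_per_px` and `fps` supplied,
`calibrate()` converts relative speeds to m/s. The fragment's topology block
reports total skeleton length, branch-node count, branchiness, compactness
and per-segment tortuosity.

A shell wrapper is included at `inst/scripts/scleraflow.R`
(`run` / `simulate` / `eval-seg` subcommands) for running the cascade on a
frame directory or TIFF without writing R code.

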