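Package: scleraflow
Title: Blood-Flow Velocimetry in Scleral and Conjunctival Vessel Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures blood-flow characteristics in unstable grayscale video of
    scleral/conjunctival microvessels. The cascade locates informative regions
    by gradient contrast and a cumulative-histogram knee threshold, splits the
    video into trackable fragments by centroid drift, stabilizes each fragment
    with normalized cross-correlation or Shi-Tomasi keypoints tracked by
    pyramidal Lucas-Kanade flow, masks vessels with a multi-scale Hessian
    tubularness enhancer, and derives linear and volumetric flow speed along
    skeleton midlines from Farneback dense optical flow, together with
    vascular-net topology metrics (length, branchiness, compactness,
    tortuosity). A synthetic vascular phantom generator provides full ground
    truth (mask, centerline, camera offsets, per-segment speeds) for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    utils
Suggests:
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
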