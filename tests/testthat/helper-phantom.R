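# Shared phantom fixtures, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx_cache[[name]])) assign(name, build(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# motion spec with every acquisition defect disabled
quiet_motion <- function(seed = 2L) {
  phantom_motion(jitter_sd = 0, blur_sd_range = c(0, 0),
                 illumination_drift_amplitude = 0, seed = seed)
}

# single random tube, static, defect-free
fx_single_static <- function() fx("single_static", function() {
  scene <- make_vessel_tree(1, seed = 3)
  rv <- render_video(scene, quiet_motion(), speeds = 0, n_frames = 2)
  c(rv, list(scene = scene))
})

# single straight tube advected at 2 px/frame, static camera
fx_straight_v2 <- function() fx("straight_v2", function() {
  scene <- make_vessel_tree(1, seed = 3, layout = "straight")
  rv <- render_video(scene, quiet_motion(), speeds = 2, n_frames = 6)
  c(rv, list(scene = scene))
})

# Y bifurcation with conserved flow, static camera
fx_y_conserved <- function() fx("y_conserved", function() {
  scene <- make_vessel_tree(3, seed = 5, layout = "y", canvas = c(192L, 192L))
  speeds <- assign_speeds(scene, 2, conserve_flow = TRUE)
  rv <- render_video(scene, quiet_motion(), speeds = speeds, n_frames = 8)
  c(rv, list(scene = scene, speeds = speeds))
})

# jittered branching scene for stabilization tests (no advection, so the
# ground-truth camera offsets are the only motion)
fx_jittered <- function() fx("jittered", function() {
  scene <- make_vessel_tree(3, seed = 7)
  rv <- render_video(scene, phantom_motion(jitter_sd = 3, seed = 11),
                     speeds = 0, n_frames = 30)
  c(rv, list(scene = scene))
})

# normalize + equalize + dense flow over all consecutive pairs
phantom_flows <- function(rv, mask = rv$truth$mask, fill_margin = 2) {
  fm <- if (fill_margin > 0) scleraflow:::dilate_disc(mask, fill_margin) else mask
  norm <- lapply(rv$video$frames, function(f)
    equalize_brightness(normalize_background(f, fm)))
  lapply(seq_len(length(norm) - 1L), function(t)
    dense_flow(norm[[t]], norm[[t + 1L]]))
}

# semicircular arc mask of given radius/thickness, built analytically
arc_mask <- function(radius = 50, thick = 3, dim = c(140L, 160L)) {
  ctr <- c(dim[1] / 2 + radius / 2, dim[2] / 2)
  m <- matrix(FALSE, dim[1], dim[2])
  for (t in seq(0, pi, length.out = 4 * radius)) {
    r <- ctr[1] - radius * sin(t); c <- ctr[2] + radius * cos(t)
    rr <- round(r) + (-thick):thick; cc <- round(c) + (-thick):thick
    g <- expand.grid(rr, cc)
    g <- g[(g[, 1] - r)^2 + (g[, 2] - c)^2 <= (thick + 0.5)^2, ]
    g <- g[g[, 1] >= 1 & g[, 1] <= dim[1] & g[, 2] >= 1 & g[, 2] <= dim[2], ]
    m[as.matrix(g)] <- TRUE
  }
  m
}
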