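# shared shortcuts for the test suite: small, fast simulation configs

quick_cfg <- function(task, seed = 1, ...) {
  simulation_config(task, seed = seed, ...)
}

# low-resolution depth rendering for tests that need a depth stream
depth_cfg <- function(task, seed = 1, duration_s = NULL, ...) {
  simulation_config(task, seed = seed, duration_s = duration_s,
                    render_depth = TRUE, depth_width = 96,
                    depth_height = 80, depth_fps = 3, ...)
}

# a tiny hand-built skeleton-only recording: pelvis follows z(t), all other
# landmarks rigidly attached; no noise
toy_recording <- function(t, z, task = "SIP", x = 0, y = 0) {
  n <- length(t)
  tmpl <- mocapqc:::body_template()
  xyz <- array(rep(t(tmpl), n), dim = c(3, 25, n))
  xyz <- aperm(xyz, c(3, 2, 1))
  dimnames(xyz) <- list(NULL, landmark_names(), c("x", "y", "z"))
  xyz[, , 1] <- xyz[, , 1] + x
  xyz[, , 2] <- xyz[, , 2] - 0.8 + y
  xyz[, , 3] <- xyz[, , 3] + z
  conf <- matrix(0.95, n, 25)
  new_recording(
    recording_metadata("toy", "toy-subject", task),
    skeleton = list(t = t, xyz = xyz, conf = conf))
}
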