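# Camera model shared by the simulator's depth renderer and the
# disturbance detector's silhouette reprojection.
#
# Fixed pinhole model: focal length 365.6 px at 512 px image width (scaled
# proportionally for other resolutions), principal point at the image
# center. The camera sits cam_height_m above the floor, optical axis
# horizontal. Skeleton coordinates are camera-frame: x lateral, y up with
# origin at the optical center (so the floor lies at y = -cam_height_m),
# z = distance from the camera.

camera_intrinsics <- function(width, height) {
  f <- 365.6 * width / 512
  list(fx = f, fy = f, cx = width / 2, cy = height / 2,
       width = as.integer(width), height = as.integer(height))
}

# bone graph: 24 capsules over the 25 canonical landmarks, with per-bone
# surface radii (meters) approximating an adult body
body_bones <- function() {
  e <- function(a, b, r) c(LM[[a]], LM[[b]], r)
  m <- rbind(
    e("SpineBase", "SpineMid", 0.13),
    e("SpineMid", "SpineShoulder", 0.13),
    e("SpineShoulder", "Neck", 0.06),
    e("Neck", "Head", 0.10),
    e("SpineShoulder", "ShoulderLeft", 0.05),
    e("ShoulderLeft", "ElbowLeft", 0.045),
    e("ElbowLeft", "WristLeft", 0.04),
    e("WristLeft", "HandLeft", 0.035),
    e("HandLeft", "HandTipLeft", 0.03),
    e("WristLeft", "ThumbLeft", 0.025),
    e("SpineShoulder", "ShoulderRight", 0.05),
    e("ShoulderRight", "ElbowRight", 0.045),
    e("ElbowRight", "WristRight", 0.04),
    e("WristRight", "HandRight", 0.035),
    e("HandRight", "HandTipRight", 0.03),
    e("WristRight", "ThumbRight", 0.025),
    e("SpineBase", "HipLeft", 0.10),
    e("HipLeft", "KneeLeft", 0.08),
    e("KneeLeft", "AnkleLeft", 0.06),
    e("AnkleLeft", "FootLeft", 0.05),
    e("SpineBase", "HipRight", 0.10),
    e("HipRight", "KneeRight", 0.08),
    e("KneeRight", "AnkleRight", 0.06),
    e("AnkleRight", "FootRight", 0.05))
  list(bones = matrix(as.integer(m[, 1:2]), ncol = 2),
       radii = m[, 3])
}

# rasterize a 25 x 3 camera-frame joint matrix into an integer depth
# matrix (mm); background 0
raster_body <- function(joints, intr, radius_scale = 1) {
  bb <- body_bones()
  .raster_capsules(joints, bb$bones, bb$radii * radius_scale,
                   intr$width, intr$height, intr$fx, intr$fy,
                   intr$cx, intr$cy)
}

# depth (mm) of the floor plane y_world = 0 for every image row; 0 where
# the floor is not visible or out of range
floor_depth_rows <- function(intr, cam_height_m, z_min = 0.8, z_max = 6) {
  v <- seq_len(intr$height)
  dv <- v - intr$cy
  z <- ifelse(dv > 0.5, intr$fy * cam_height_m / dv, Inf)
  mm <- ifelse(z >= z_min & z <= z_max, round(z * 1000), 0)
  as.integer(mm)
}

compose_floor <- function(body, floor_rows) {
  fl <- matrix(floor_rows, nrow = nrow(body), ncol = ncol(body))
  out <- ifelse(body > 0L, pmin(body, ifelse(fl > 0L, fl, body)), fl)
  storage.mode(out) <- "integer"
  out
}
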