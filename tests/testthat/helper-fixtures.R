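# Shared fixtures and independent oracles used across the suite.

# Two-camera toy rig, 60 degrees apart, looking at the origin from 500 mm.
toy_rig <- function(n = 2, angles_deg = seq(0, by = 60, length.out = n),
                    dist = 500) {
  cams <- lapply(seq_len(n), function(i) {
    th <- angles_deg[i] * pi / 180
    # camera at dist along the rotated -z axis, optical axis toward origin
    Rz <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
    pos <- Rz %*% c(0, 0, -dist)
    z <- -pos / sqrt(sum(pos^2))
    up <- c(0, 1, 0)
    x <- c(up[2] * z[3] - up[3] * z[2], up[3] * z[1] - up[1] * z[3],
           up[1] * z[2] - up[2] * z[1])
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    R <- rbind(x, y, as.numeric(z)); dimnames(R) <- NULL
    camera_model(paste0("cam", i), c(1280, 720), c(1000, 1000), c(640, 360),
                 rotation = R, translation = as.numeric(-R %*% pos))
  })
  camera_rig(cams)
}

# Independent triangulation oracle: coarse-to-fine 3D grid search minimizing
# the summed squared reprojection error (never calls the DLT path).
grid_search_point <- function(observations, center, half_width = 30) {
  best <- center
  width <- half_width
  for (level in 1:4) {
    g <- seq(-width, width, length.out = 13)
    grid <- as.matrix(expand.grid(best[1] + g, best[2] + g, best[3] + g))
    cost <- numeric(nrow(grid))
    for (ob in observations) {
      px <- handmocap:::project_points(grid, ob$cam)
      cost <- cost + (px[, 1] - ob$px[1])^2 + (px[, 2] - ob$px[2])^2
    }
    best <- grid[which.min(cost), ]
    width <- width / 5
  }
  as.numeric(best)
}

# A fully visible track with identical coordinates in every channel.
constant_track <- function(value, TT = 120, fs = 30) {
  track3d(array(value, c(TT, 21, 3)), fs = fs)
}

# Track whose every channel carries the scalar signal x.
signal_track <- function(x, fs = 30) {
  track3d(array(rep(x, 21 * 3), c(length(x), 21, 3)), fs = fs)
}
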