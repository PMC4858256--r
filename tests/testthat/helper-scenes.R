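# Shared fixture builders: everything is generated in code at test time.

# Small vascular scene used across modules; defaults give a mid-density
# disc at desk scale in a few hundred ms.
small_scene <- function(n_vessels = 8, delta = 0.6, noise_sd = 0.05,
                        seed = 11, nx = 64, ny = 64, nz = 64,
                        radius_px = 2, ...) {
  scene_spec(nx = nx, ny = ny, nz = nz,
             z_ilm = round(0.25 * nz), z_alc = round(0.6 * nz),
             vessels = make_vessel_tree(n_vessels, nx = nx, ny = ny,
                                        radius_px = radius_px, delta = delta),
             noise_sd = noise_sd, seed = seed, ...)
}

# Independent brute-force oracle for the flow signal (triple loop).
flow_loop_oracle <- function(dat) {
  d <- dim(dat)
  out <- array(0, dim = d[1:3])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    acc <- 0
    for (i in seq_len(d[4] - 1)) {
      acc <- acc + Mod(dat[x, y, z, i + 1] - dat[x, y, z, i])
    }
    out[x, y, z] <- acc / (d[4] - 1)
  }
  out
}

# Independent MIP oracle.
mip_loop_oracle <- function(flow, mask) {
  d <- dim(flow)
  out <- matrix(0, d[1], d[2])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    best <- -Inf
    for (z in seq_len(d[3])) {
      if (mask[x, y, z] && flow[x, y, z] > best) best <- flow[x, y, z]
    }
    out[x, y] <- if (is.finite(best)) best else 0
  }
  out
}

# Independent point-in-polygon oracle: winding by angle summation.
polygon_area_oracle <- function(poly, nx, ny) {
  px <- poly[[1]]; py <- poly[[2]]
  inside <- function(x0, y0) {
    ang <- 0
    n <- length(px)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      a1 <- atan2(py[i] - y0, px[i] - x0)
      a2 <- atan2(py[j] - y0, px[j] - x0)
      da <- a2 - a1
      if (da > pi) da <- da - 2 * pi
      if (da < -pi) da <- da + 2 * pi
      ang <- ang + da
    }
    abs(ang) > pi
  }
  cnt <- 0L
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    if (inside(x, y)) cnt <- cnt + 1L
  }
  cnt
}

# Exhaustive-search Otsu oracle over candidate thresholds.
otsu_oracle <- function(x) {
  u <- sort(unique(x))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; thr <- NA
  for (t in cand) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    bc <- length(lo) * length(hi) / length(x)^2 * (mean(hi) - mean(lo))^2
    if (bc > best) { best <- bc; thr <- t }
  }
  thr
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
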