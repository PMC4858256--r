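#' Render a synthetic repeated-B-scan complex OCT volume
#'
#' Simulates the signal model underlying OMAG angiography: static tissue
#' returns an identical complex signal in every repeated B-scan, while
#' voxels inside vessels decorrelate between repeats. Each vessel voxel
#' with decorrelation magnitude `delta` gets, per repeat, a phase offset
#' drawn uniformly from `[0, 2*pi*delta]` and a multiplicative amplitude
#' jitter uniform on `1 +/- 0.3*delta`; complex Gaussian read noise is
#' added independently per repeat. All randomness is governed by
#' `spec$seed`, and the number and order of random draws do not depend on
#' the `delta` values, so two scenes differing only in `delta` share the
#' same noise realization.
#'
#' @param spec A scene description from [scene_spec()].
#' @return A list with components:
#'   \describe{
#'     \item{volume}{`onh_volume`: complex array `[nx, ny, nz, R]` plus
#'       acquisition metadata.}
#'     \item{truth}{`onh_ground_truth`: 3-D vessel mask, per-voxel
#'       decorrelation magnitude, true surfaces, en-face disc mask and the
#'       true vessel-pixel fraction inside the disc.}
#'   }
#' @export
#' @examples
#' sim <- generate_volume(scene_spec(nx = 32, ny = 32, nz = 48, seed = 7))
#' dim(sim$volume$data)
#' sim$truth$vessel_fraction
generate_volume <- function(spec) {
  if (!inherits(spec, "onh_scene_spec")) {
    abort("spec must be created with scene_spec()")
  }
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz; R <- spec$n_repeats
  n_vox <- nx * ny * nz

  # rasterized (integer) surfaces: a boundary sample belongs to the deeper
  # side, so tissue occupies z in [ceiling(z_ilm), ceiling(z_alc) - 1]
  ziu <- ceiling(spec$z_ilm)
  zau <- ceiling(spec$z_alc)

  zidx <- array(rep(seq_len(nz), each = nx * ny), dim = c(nx, ny, nz))
  ilm3 <- array(ziu, dim = c(nx, ny, nz))
  alc3 <- array(zau, dim = c(nx, ny, nz))

  disc <- disc_mask_enface(spec)
  disc3 <- array(disc, dim = c(nx, ny, nz))

  amp <- array(spec$vitreous_level, dim = c(nx, ny, nz))
  amp[zidx >= ilm3 & zidx < alc3] <- spec$tissue_reflectivity
  below <- zidx >= alc3
  amp[below & disc3] <- spec$lamina_level
  band <- below & !disc3 & zidx < alc3 + spec$band_thickness_px
  deep <- below & !disc3 & !band
  amp[band] <- spec$band_level
  amp[deep] <- 0.4 * spec$tissue_reflectivity

  ves <- rasterize_vessels(spec, ziu, zau)
  vidx <- which(ves$mask)
  dvox <- ves$delta[vidx]

  set.seed(spec$seed)
  phi0 <- array(runif(n_vox, 0, 2 * pi), dim = c(nx, ny, nz))
  nv <- length(vidx)
  u_phase <- if (nv) matrix(runif(nv * R), nv, R) else matrix(0, 0, R)
  u_amp <- if (nv) matrix(runif(nv * R, -0.3, 0.3), nv, R) else matrix(0, 0, R)
  noise <- if (spec$noise_sd > 0) {
    rnorm(2 * n_vox * R, sd = spec$noise_sd)
  } else numeric(0)

  dat <- array(0i, dim = c(nx, ny, nz, R))
  base_re <- amp * cos(phi0)
  base_im <- amp * sin(phi0)
  for (k in seq_len(R)) {
    re <- base_re; im <- base_im
    if (nv) {
      a <- amp[vidx] * (1 + dvox * u_amp[, k])
      ph <- phi0[vidx] + 2 * pi * dvox * u_phase[, k]
      re[vidx] <- a * cos(ph)
      im[vidx] <- a * sin(ph)
    }
    if (spec$noise_sd > 0) {
      off <- (k - 1L) * 2L * n_vox
      re <- re + noise[(off + 1L):(off + n_vox)]
      im <- im + noise[(off + n_vox + 1L):(off + 2L * n_vox)]
    }
    dat[, , , k] <- complex(real = re, imaginary = im)
  }

  vol <- structure(list(
    data = dat, n_repeats = R, extent_mm = spec$extent_mm,
    ascan_rate_hz = spec$ascan_rate_hz, seed = spec$seed
  ), class = "onh_volume")

  proj <- ves$mask
  dim(proj) <- c(nx * ny, nz)
  proj <- matrix(rowSums(proj) > 0, nx, ny)

  truth <- structure(list(
    vessel_mask = ves$mask,
    decorrelation = ves$delta,
    z_ilm = spec$z_ilm,
    z_alc = spec$z_alc,
    disc_mask = disc,
    vessel_enface = proj,
    vessel_fraction = if (sum(disc)) sum(proj & disc) / sum(disc) else 0
  ), class = "onh_ground_truth")

  list(volume = vol, truth = truth)
}

# En-face disc mask implied by the scene: circle of disc_radius_mm centred
# in the scan (an ellipse in pixel units if the grid is anisotropic).
disc_mask_enface <- function(spec) {
  rx <- spec$disc_radius_mm / spec$extent_mm * spec$nx
  ry <- spec$disc_radius_mm / spec$extent_mm * spec$ny
  cx <- (spec$nx + 1) / 2; cy <- (spec$ny + 1) / 2
  xg <- matrix(seq_len(spec$nx), spec$nx, spec$ny)
  yg <- matrix(seq_len(spec$ny), spec$nx, spec$ny, byrow = TRUE)
  ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
}

# Rasterize the vessel tree into a 3-D mask plus per-voxel decorrelation.
# Tubes run along x at mid-slab depth, clipped to the tissue slab.
rasterize_vessels <- function(spec, ziu, zau) {
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  mask <- array(FALSE, dim = c(nx, ny, nz))
  delta <- array(0, dim = c(nx, ny, nz))
  for (v in spec$vessels) {
    r <- v$radius_px
    for (x in seq_len(nx)) {
      yc <- v$y0 + v$wobble_px *
        sin(2 * pi * v$periods * (x - 1) / (nx - 1) + v$phase)
      yj <- max(1L, min(ny, as.integer(round(yc))))
      zc <- (ziu[x, yj] + zau[x, yj] - 1) / 2
      ylo <- max(1L, as.integer(ceiling(yc - r)))
      yhi <- min(ny, as.integer(floor(yc + r)))
      if (yhi < ylo) next
      for (y in ylo:yhi) {
        dz <- sqrt(max(0, r^2 - (y - yc)^2))
        zlo <- max(ziu[x, y], as.integer(ceiling(zc - dz)))
        zhi <- min(zau[x, y] - 1L, as.integer(floor(zc + dz)))
        if (zhi >= zlo) {
          mask[x, y, zlo:zhi] <- TRUE
          delta[x, y, zlo:zhi] <- pmax(delta[x, y, zlo:zhi], v$delta)
        }
      }
    }
  }
  list(mask = mask, delta = delta)
}

#' Structural (amplitude) volume from repeated B-scans
#'
#' Repeat-averaged signal magnitude, the structural image the layer
#' segmentation operates on.
#'
#' @param vol An `onh_volume` or a complex array `[nx, ny, nz, R]`.
#' @return Numeric array `[nx, ny, nz]`.
#' @export
structural_volume <- function(vol) {
  dat <- volume_data(vol)
  d <- dim(dat)
  s <- Mod(dat[, , , 1])
  for (k in seq_len(d[4])[-1]) s <- s + Mod(dat[, , , k])
  s / d[4]
}

volume_data <- function(vol) {
  dat <- if (inherits(vol, "onh_volume")) vol$data else vol
  if (!is.array(dat) || length(dim(dat)) != 4L) {
    abort("expected an onh_volume or a 4-D complex array [nx, ny, nz, R]")
  }
  dat
}

#' @export
print.onh_scene_spec <- function(x, ...) {
  cat(sprintf(
    "<onh_scene_spec> %d x %d x %d, R = %d, %.1f mm, %d vessel(s), noise sd %.3g\n",
    x$nx, x$ny, x$nz, x$n_repeats, x$extent_mm, length(x$vessels), x$noise_sd))
  invisible(x)
}

#' @export
print.onh_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<onh_volume> %d x %d x %d, R = %d repeats, %.1f mm extent\n",
              d[1], d[2], d[3], d[4], x$extent_mm))
  invisible(x)
}
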