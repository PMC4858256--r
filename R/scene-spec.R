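#' Specify a synthetic ONH scan scene
#'
#' Builds the description of a synthetic optic-nerve-head (ONH) OCT
#' acquisition from which [generate_volume()] renders a repeated-B-scan
#' complex volume with known ground truth. The default geometry is a
#' desk-scale 128 x 128 x 256 grid standing in for the device's
#' 2.4 x 2.4 mm scan of 245 transversal locations with R = 4 repeated
#' B-scans per location; the full-size geometry is available by setting
#' `nx`, `ny` and `nz` accordingly.
#'
#' The scene stacks, from shallow to deep: dark vitreous, the inner
#' limiting membrane (ILM) at `z_ilm`, reflective pre-laminar tissue, and
#' at `z_alc` either the bright retinal pigment epithelium / Bruch's
#' membrane band (outside the disc) or the moderately reflective anterior
#' lamina cribrosa (inside the disc). Bruch's membrane terminates at the
#' disc margin, a circle of radius `disc_radius_mm` centred in the scan.
#' Vessels are tubes threaded through the pre-laminar slab whose complex
#' signal decorrelates between repeats with per-vessel magnitude
#' `delta` in `[0, 1]`.
#'
#' @param nx,ny,nz Grid dimensions: A-scans per B-scan, slow-axis
#'   locations, and depth samples.
#' @param n_repeats Number of repeated B-scans per location (R >= 2;
#'   device value 4).
#' @param extent_mm Physical scan extent (square), in mm.
#' @param z_ilm,z_alc ILM and anterior-LC/RPE surfaces in depth samples:
#'   a scalar (flat surface) or an `nx` x `ny` matrix. Must satisfy
#'   `0 < z_ilm < z_alc <= nz` everywhere.
#' @param disc_radius_mm Disc (Bruch's membrane opening) radius in mm;
#'   must be less than half the scan extent.
#' @param vessels Vessel tree: a list of vessel descriptions as produced
#'   by [make_vessel_tree()], possibly empty.
#' @param tissue_reflectivity,vitreous_level,lamina_level,band_level
#'   Amplitudes of the structural signal in the pre-laminar tissue, the
#'   vitreous, the lamina cribrosa, and the RPE/Bruch's band.
#' @param band_thickness_px Thickness of the RPE/Bruch's band in depth
#'   samples.
#' @param noise_sd Standard deviation of the additive complex Gaussian
#'   noise applied independently per repeat (per real/imaginary channel).
#' @param ascan_rate_hz A-scan acquisition rate, metadata only.
#' @param seed Random seed consumed by [generate_volume()].
#'
#' @return An object of class `onh_scene_spec`.
#' @seealso [generate_volume()], [make_vessel_tree()]
#' @export
#' @examples
#' spec <- scene_spec(nx = 48, ny = 48, nz = 64,
#'                    vessels = make_vessel_tree(3, nx = 48, ny = 48))
#' spec$disc_radius_mm
scene_spec <- function(nx = 128L, ny = 128L, nz = 256L, n_repeats = 4L,
                       extent_mm = 2.4,
                       z_ilm = round(0.2 * nz),
                       z_alc = round(0.55 * nz),
                       disc_radius_mm = 0.75,
                       vessels = list(),
                       tissue_reflectivity = 1,
                       vitreous_level = 0.05,
                       lamina_level = 1.4,
                       band_level = 2.2,
                       band_thickness_px = 4L,
                       noise_sd = 0.05,
                       ascan_rate_hz = 68000,
                       seed = 1L) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  n_repeats <- as.integer(n_repeats)
  if (any(c(nx, ny, nz) < 8L)) abort("grid dimensions must each be >= 8")
  if (n_repeats < 2L) abort("n_repeats must be >= 2")
  as_surface <- function(s, name) {
    if (length(s) == 1L) s <- matrix(as.numeric(s), nx, ny)
    if (!is.matrix(s) || !all(dim(s) == c(nx, ny))) {
      abort(paste0(name, " must be a scalar or an nx-by-ny matrix"))
    }
    s
  }
  z_ilm <- as_surface(z_ilm, "z_ilm")
  z_alc <- as_surface(z_alc, "z_alc")
  if (any(z_ilm < 1) || any(z_ilm >= z_alc) || any(z_alc > nz)) {
    abort("surfaces must satisfy 1 <= z_ilm < z_alc <= nz everywhere")
  }
  if (disc_radius_mm <= 0 || disc_radius_mm >= extent_mm / 2) {
    abort("disc_radius_mm must lie in (0, extent_mm / 2)")
  }
  for (v in vessels) {
    if (v$delta < 0 || v$delta > 1) abort("vessel delta must lie in [0, 1]")
    if (v$radius_px < 1) abort("vessel radius_px must be >= 1")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  structure(list(
    nx = nx, ny = ny, nz = nz, n_repeats = n_repeats,
    extent_mm = extent_mm, z_ilm = z_ilm, z_alc = z_alc,
    disc_radius_mm = disc_radius_mm, vessels = vessels,
    tissue_reflectivity = tissue_reflectivity,
    vitreous_level = vitreous_level, lamina_level = lamina_level,
    band_level = band_level, band_thickness_px = as.integer(band_thickness_px),
    noise_sd = noise_sd, ascan_rate_hz = ascan_rate_hz,
    seed = as.integer(seed)
  ), class = "onh_scene_spec")
}

#' Build a simple synthetic vessel tree
#'
#' Lays `n_vessels` roughly parallel vessels across the scan along the fast
#' (x) axis, evenly spaced over the vertical span of the disc, each with a
#' gentle sinusoidal wobble. Radii of 2-4 px at the default sampling
#' (~10 um/px) correspond to capillaries up to mid-sized disc vessels.
#'
#' @param n_vessels Number of vessels.
#' @param nx,ny Scene grid dimensions the tree is built for.
#' @param radius_px Tube radius in pixels (scalar or per-vessel vector).
#' @param delta Decorrelation magnitude in `[0, 1]` (scalar or per-vessel).
#' @param span_frac Fraction of `ny` over which the vessels are spread,
#'   centred on the scan centre.
#' @param wobble_px Amplitude of the sinusoidal centerline wobble.
#' @return A list of vessel descriptions for [scene_spec()].
#' @export
make_vessel_tree <- function(n_vessels, nx = 128L, ny = 128L,
                             radius_px = 2, delta = 0.6,
                             span_frac = 0.62, wobble_px = 2.5) {
  if (n_vessels < 1L) return(list())
  radius_px <- rep_len(radius_px, n_vessels)
  delta <- rep_len(delta, n_vessels)
  span <- span_frac * ny
  y0 <- (ny + 1) / 2 + seq(-span / 2, span / 2, length.out = n_vessels)
  lapply(seq_len(n_vessels), function(i) {
    list(
      y0 = y0[i],
      wobble_px = wobble_px,
      periods = 1.25,
      phase = (i - 1) * 2.39996,  # golden-angle stagger, decorrelates wobble
      radius_px = radius_px[i],
      delta = delta[i]
    )
  })
}
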