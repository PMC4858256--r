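#' OMAG flow signal from repeated complex B-scans
#'
#' Computes the optical microangiography blood-flow signal: at every voxel,
#' the mean magnitude of the complex difference between consecutive
#' repeated B-scans,
#' \deqn{I_{Flow}(x,y,z) = \frac{1}{R-1} \sum_{i=1}^{R-1}
#'       \lvert C_{i+1}(x,y,z) - C_i(x,y,z) \rvert ,}
#' which cancels static tissue (identical complex signal across repeats)
#' and retains moving-scatterer decorrelation. The result is in raw
#' `|dC|` units; map it onto the 0-255 dynamic range with
#' [scale_to_dynamic_range()] before projection and metrics.
#'
#' @param vol An `onh_volume` from [generate_volume()] / [read_volume()],
#'   or a complex array `[nx, ny, nz, R]` with `R >= 2`.
#' @return An `onh_flow` object: `flow` (numeric array `[nx, ny, nz]`),
#'   `scaled` (FALSE), `scale_factor` (NA until scaling).
#' @export
#' @examples
#' reps <- array(complex(real = c(1, -1, 1, -1)), dim = c(1, 1, 1, 4))
#' compute_flow(reps)$flow  # mean(|{-2, 2, -2}|) = 2
compute_flow <- function(vol) {
  dat <- volume_data(vol)
  R <- dim(dat)[4]
  if (R < 2L) abort("at least R = 2 repeated B-scans are required")
  if (anyNA(dat)) abort("complex volume contains NA/NaN values")
  d <- dim(dat)
  rep_slice <- function(i) array(dat[, , , i], dim = d[1:3])
  flow <- Mod(rep_slice(2) - rep_slice(1))
  if (R > 2L) {
    for (i in 2:(R - 1L)) flow <- flow + Mod(rep_slice(i + 1) - rep_slice(i))
  }
  structure(list(
    flow = flow / (R - 1),
    scaled = FALSE,
    scale_factor = NA_real_,
    mode = NULL,
    all_zero = all(flow == 0)
  ), class = "onh_flow")
}

#' Map a raw flow volume onto the 0-255 dynamic range
#'
#' The perfusion metrics normalize the flow signal by its full dynamic
#' range of 255, so the raw `|dC|` flow must first be placed on that
#' scale. Mode `"percentile"` (default) divides by the 99.5th percentile
#' and clips, which is robust to isolated hot voxels; mode `"max"`
#' divides by the volume maximum.
#'
#' @param flow An `onh_flow` object with raw (unscaled) values.
#' @param mode `"percentile"` or `"max"`.
#' @param probs Clipping quantile for `"percentile"` mode.
#' @param ref Optional explicit divisor (raw flow value mapped to 255),
#'   overriding `mode`. Use a common `ref` when volumes acquired under
#'   different conditions must share one dynamic range, as a real device
#'   with a fixed display mapping would.
#' @return An `onh_flow` with values in `[0, 255]`, `scaled = TRUE` and
#'   the divisor recorded in `scale_factor`. An all-zero volume is
#'   returned as all zeros with `all_zero = TRUE`.
#' @export
scale_to_dynamic_range <- function(flow, mode = c("percentile", "max"),
                                   probs = 0.995, ref = NULL) {
  mode <- match.arg(mode)
  if (!inherits(flow, "onh_flow")) abort("flow must be an onh_flow object")
  if (isTRUE(flow$scaled)) abort("flow volume is already scaled")
  f <- flow$flow
  if (!is.null(ref)) {
    mode <- "fixed"
  } else {
    ref <- if (mode == "max") max(f) else quantile(f, probs, names = FALSE)
  }
  if (ref <= 0) {
    # degenerate: nothing to scale (either all-zero, or the chosen
    # percentile is zero on a nearly-empty volume) -> fall back to max
    ref <- max(f)
    if (ref <= 0) {
      flow$scaled <- TRUE
      flow$scale_factor <- 0
      flow$mode <- mode
      flow$all_zero <- TRUE
      return(flow)
    }
  }
  flow$flow <- pmin(f / ref, 1) * 255
  flow$scaled <- TRUE
  flow$scale_factor <- ref
  flow$mode <- mode
  flow$all_zero <- FALSE
  flow
}

#' Inter-B-scan time difference
#'
#' Time between two successive B-scans at one transversal location: the
#' number of A-scans per B-scan divided by the A-scan rate. For the
#' device geometry (245 A-scans at 68 kHz) this is approximately 3.6 ms.
#'
#' @param n_ascans A-scans per B-scan.
#' @param ascan_rate_hz A-scan rate in Hz.
#' @return Period in milliseconds.
#' @export
#' @examples
#' interscan_period_ms(245, 68000)
interscan_period_ms <- function(n_ascans = 245, ascan_rate_hz = 68000) {
  if (n_ascans <= 0 || ascan_rate_hz <= 0) abort("arguments must be positive")
  n_ascans / ascan_rate_hz * 1000
}

#' @export
print.onh_flow <- function(x, ...) {
  d <- dim(x$flow)
  cat(sprintf("<onh_flow> %d x %d x %d, %s, range [%.3g, %.3g]\n",
              d[1], d[2], d[3],
              if (isTRUE(x$scaled)) sprintf("scaled 0-255 (%s)", x$mode)
              else "raw |dC|",
              min(x$flow), max(x$flow)))
  invisible(x)
}
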