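#' Segment the ILM and anterior-LC/RPE surfaces
#'
#' Gradient-based layer segmentation of the structural volume. Per
#' A-scan, the depth profile is Gaussian-smoothed (sigma depth samples),
#' the axial gradient is taken by central differences, and an adaptive
#' threshold (mean + `k_thresh` SD of that A-scan's gradient) selects
#' boundary candidates. The inner limiting membrane (ILM) is the first
#' threshold crossing, refined to the nearest local gradient maximum
#' (ties resolved to the deeper sample, so a step edge is assigned to its
#' first bright sample). The anterior lamina cribrosa / RPE surface is
#' the strongest positive gradient deeper than the ILM; within the disc
#' this continuous surface is the anterior lamina, outside it the RPE.
#' Both surfaces are regularized with a 3x3 median filter and the
#' ordering `z_ilm <= z_alc` is enforced.
#'
#' Manual overrides replace the corresponding automatic surface verbatim
#' (the semi-automatic mode): supply full matrices, or sparse control
#' points which are interpolated by [surface_from_points()].
#'
#' @param structural Numeric array `[nx, ny, nz]` of non-negative
#'   intensities (see [structural_volume()]).
#' @param sigma Depth-smoothing Gaussian SD, in samples.
#' @param k_thresh Adaptive threshold multiplier (mean + k SD).
#' @param margin Samples below the ILM excluded from the ALC search.
#' @param max_fail Maximum tolerated fraction of A-scans without a
#'   gradient above threshold before the segmentation aborts.
#' @param override Optional list with elements `z_ilm` and/or `z_alc`:
#'   either `nx x ny` matrices or data frames of `(x, y, z)` control
#'   points.
#' @return An `onh_layer_model` with surfaces `z_ilm`, `z_alc` (depth
#'   samples, `nx x ny`), no disc mask yet (see
#'   [delineate_disc_margin()]), and a `failed` matrix marking A-scans
#'   where detection fell back to neighbourhood smoothing.
#' @export
segment_layers <- function(structural, sigma = 2, k_thresh = 2,
                           margin = ceiling(3 * sigma), max_fail = 0.05,
                           override = NULL) {
  if (!is.array(structural) || length(dim(structural)) != 3L) {
    abort("structural must be a 3-D array [nx, ny, nz]")
  }
  if (any(!is.finite(structural)) || any(structural < 0)) {
    abort("structural volume must be finite and non-negative")
  }
  d <- dim(structural); nx <- d[1]; ny <- d[2]; nz <- d[3]

  ov <- normalize_override(override, nx, ny)
  need_auto <- is.null(ov$z_ilm) || is.null(ov$z_alc)

  if (need_auto) {
    # profiles as columns: [nz, nx*ny]
    P <- matrix(aperm(structural, c(3, 1, 2)), nz, nx * ny)
    K <- depth_smoother(nz, sigma)
    Ps <- K %*% P
    g <- rbind(0, (Ps[-(1:2), , drop = FALSE] -
                     Ps[1:(nz - 2), , drop = FALSE]) / 2, 0)
    mu <- colMeans(g)
    s2 <- colMeans(g * g) - mu^2
    # floor keeps numerically-flat profiles (no real boundary) undetected
    thr <- pmax(mu + k_thresh * sqrt(pmax(s2, 0)), 1e-6 * max(abs(structural)))

    n_col <- nx * ny
    ilm <- rep(NA_real_, n_col)
    alc <- rep(NA_real_, n_col)
    for (j in seq_len(n_col)) {
      gj <- g[, j]
      above <- gj > thr[j]
      if (!any(above)) next
      f <- which.max(above)
      w <- f:min(f + 6L, nz)
      gv <- gj[w]
      ilm[j] <- w[max(which(gv == max(gv)))]  # tie -> deeper sample
      lo <- min(nz, ilm[j] + margin)
      if (lo < nz) {
        seg <- gj[lo:nz]
        alc[j] <- lo - 1L + which.max(seg)
      }
    }
    fail <- is.na(ilm) | is.na(alc)
    if (mean(fail) > max_fail) {
      bad <- which(matrix(fail, nx, ny), arr.ind = TRUE)
      abort(c(
        sprintf("layer segmentation failed on %.1f%% of A-scans (max %.1f%%)",
                100 * mean(fail), 100 * max_fail),
        "i" = sprintf("first failing A-scan at (x = %d, y = %d)",
                      bad[1, 1], bad[1, 2])
      ))
    }
    ilm_m <- matrix(ilm, nx, ny)
    alc_m <- matrix(alc, nx, ny)
    ilm_m <- median_filter_3x3(ilm_m)
    alc_m <- median_filter_3x3(alc_m)
    # fill any residual failures from the median-filtered neighbourhood
    ilm_m[is.na(ilm_m)] <- median(ilm_m, na.rm = TRUE)
    alc_m[is.na(alc_m)] <- median(alc_m, na.rm = TRUE)
    fail_m <- matrix(fail, nx, ny)
  } else {
    ilm_m <- alc_m <- NULL
    fail_m <- matrix(FALSE, nx, ny)
  }

  z_ilm <- if (!is.null(ov$z_ilm)) ov$z_ilm else ilm_m
  z_alc <- if (!is.null(ov$z_alc)) ov$z_alc else alc_m
  if (is.null(ov$z_alc)) z_alc <- pmax(z_alc, z_ilm)  # ordering invariant

  structure(list(
    z_ilm = z_ilm, z_alc = z_alc,
    disc_mask = NULL, disc_contour = NULL,
    area_onh_px = NA_integer_, area_onh_mm2 = NA_real_,
    nz = nz, failed = fail_m,
    override = list(z_ilm = !is.null(ov$z_ilm), z_alc = !is.null(ov$z_alc))
  ), class = "onh_layer_model")
}

# Banded Gaussian smoothing operator along depth with edge renormalization.
depth_smoother <- function(nz, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, nz, nz)
  for (i in seq_len(nz)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1L & idx <= nz
    K[i, idx[ok]] <- k[ok] / sum(k[ok])
  }
  K
}

normalize_override <- function(override, nx, ny) {
  out <- list(z_ilm = NULL, z_alc = NULL)
  if (is.null(override)) return(out)
  for (nm in c("z_ilm", "z_alc")) {
    o <- override[[nm]]
    if (is.null(o)) next
    if (is.matrix(o)) {
      if (!all(dim(o) == c(nx, ny))) abort(paste0(nm, " override has wrong dims"))
      out[[nm]] <- o
    } else if (is.data.frame(o)) {
      out[[nm]] <- surface_from_points(o, nx, ny)
    } else {
      abort(paste0(nm, " override must be a matrix or a data frame of points"))
    }
  }
  out
}

#' Interpolate a surface from sparse control points
#'
#' Turns operator-supplied `(x, y, z)` control points (e.g. read from a
#' CSV) into a full depth surface by a thin-plate regression smooth
#' (three or fewer points fall back to a plane fit). This is the
#' reproducible stand-in for interactive manual guidance.
#'
#' @param points Data frame with columns `x`, `y`, `z`.
#' @param nx,ny Output surface dimensions.
#' @return `nx x ny` numeric matrix of depths.
#' @export
surface_from_points <- function(points, nx, ny) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  pts <- as.data.frame(points)[c("x", "y", "z")]
  grid <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  if (nrow(pts) <= 4L) {
    fit <- lm(z ~ x + y, data = pts)
    z <- predict(fit, newdata = grid)
  } else {
    k <- min(nrow(pts) - 1L, 30L)
    fit <- mgcv::gam(z ~ s(x, y, bs = "tp", k = k), data = pts)
    z <- predict(fit, newdata = grid)
  }
  matrix(as.numeric(z), nx, ny)
}

#' Delineate the disc margin at the termination of Bruch's membrane
#'
#' The optic disc margin is where the bright retinal pigment epithelium /
#' Bruch's membrane complex ends. For every B-scan (fixed y), the
#' presence of the band below the ILM is traced from each lateral edge
#' toward the centre; the first sustained disappearance of the band marks
#' a terminus. An ellipse is fit to all collected termini by direct least
#' squares and its interior, rasterized, becomes the disc mask. At least
#' six termini are required, otherwise the fit is underdetermined and an
#' error is raised. Alternatively a manual closed contour (data frame of
#' `x`, `y` vertices) is rasterized directly.
#'
#' @param structural Numeric array `[nx, ny, nz]`.
#' @param layers An `onh_layer_model` from [segment_layers()].
#' @param extent_mm Physical scan extent, for the mm^2 disc area.
#' @param contour Optional manual polygon (data frame with `x`, `y`).
#' @param min_gap Minimum run (px) of absent band accepted as a
#'   termination.
#' @return The layer model completed with `disc_mask`, `disc_contour`
#'   (fitted ellipse parameters or the manual polygon), `area_onh_px`
#'   and `area_onh_mm2`.
#' @export
delineate_disc_margin <- function(structural, layers, extent_mm = 2.4,
                                  contour = NULL, min_gap = 4L) {
  if (!inherits(layers, "onh_layer_model")) {
    abort("layers must be an onh_layer_model")
  }
  d <- dim(structural); nx <- d[1]; ny <- d[2]; nz <- d[3]

  if (!is.null(contour)) {
    mask <- rasterize_polygon(contour, nx, ny)
    layers$disc_mask <- mask
    layers$disc_contour <- contour
  } else {
    # band-presence map: is there a bright reflector well below the ILM?
    zi <- ceiling(layers$z_ilm)
    P <- matrix(aperm(structural, c(3, 1, 2)), nz, nx * ny)
    lo <- pmin(nz, as.vector(zi) + 4L)
    peak <- vapply(seq_len(nx * ny),
                   function(j) max(P[lo[j]:nz, j]), numeric(1))
    thr <- otsu_threshold(peak)
    if (is.na(thr)) abort("no Bruch's membrane contrast found")
    pres <- matrix(peak > thr, nx, ny)
    term <- trace_band_termini(pres, min_gap)
    if (nrow(term) < 6L) {
      abort(c("disc margin not found: fewer than 6 Bruch's membrane termini",
              "i" = "supply a manual contour via `contour=`"))
    }
    e <- fit_ellipse(term$x, term$y)
    if (is.null(e)) abort("ellipse fit to Bruch's membrane termini failed")
    layers$disc_mask <- rasterize_ellipse(e, nx, ny)
    layers$disc_contour <- e
    layers$termini <- term
  }
  if (!any(layers$disc_mask)) abort("disc mask is empty")
  layers$area_onh_px <- sum(layers$disc_mask)
  layers$area_onh_mm2 <- layers$area_onh_px * (extent_mm / nx) * (extent_mm / ny)
  layers
}

# March inward from both lateral edges of each B-scan row; a terminus is the
# last x where the band is present before a sustained gap.
trace_band_termini <- function(pres, min_gap) {
  nx <- nrow(pres); ny <- ncol(pres)
  xs <- integer(0); ys <- integer(0)
  for (y in seq_len(ny)) {
    p <- pres[, y]
    if (!p[1] || !p[nx]) next  # band must be detectable at both edges
    gaps <- rle(p)
    if (length(gaps$lengths) < 3L) next
    ends <- cumsum(gaps$lengths)
    starts <- ends - gaps$lengths + 1L
    gap_idx <- which(!gaps$values & gaps$lengths >= min_gap)
    if (!length(gap_idx)) next
    # leftmost qualifying gap entered from the left edge, rightmost from right
    gl <- gap_idx[1]; gr <- gap_idx[length(gap_idx)]
    xs <- c(xs, starts[gl] - 1L, ends[gr] + 1L)
    ys <- c(ys, y, y)
  }
  tibble(x = xs, y = ys)
}

#' Pre-laminar tissue voxel mask
#'
#' Marks the voxels analysed by the perfusion pipeline: `(x, y, z)` is
#' inside the pre-laminar slab iff the disc mask is true at `(x, y)` and
#' `z_ilm <= z < z_alc` (half-open in depth, so the per-pixel voxel count
#' is exactly `z_alc - z_ilm` for integer surfaces).
#'
#' @param layers An `onh_layer_model` with a disc mask.
#' @param nz Number of depth samples (defaults to the value recorded at
#'   segmentation).
#' @return Logical array `[nx, ny, nz]`.
#' @export
prelc_mask <- function(layers, nz = layers$nz) {
  if (!inherits(layers, "onh_layer_model")) {
    abort("layers must be an onh_layer_model")
  }
  if (is.null(layers$disc_mask)) abort("layer model has no disc mask yet")
  nx <- nrow(layers$z_ilm); ny <- ncol(layers$z_ilm)
  zi <- ceiling(layers$z_ilm); za <- ceiling(layers$z_alc)
  zidx <- array(rep(seq_len(nz), each = nx * ny), dim = c(nx, ny, nz))
  array(layers$disc_mask, dim = c(nx, ny, nz)) &
    zidx >= array(zi, dim = c(nx, ny, nz)) &
    zidx < array(za, dim = c(nx, ny, nz))
}

#' @export
print.onh_layer_model <- function(x, ...) {
  cat(sprintf("<onh_layer_model> %d x %d surfaces, ILM depth %.1f-%.1f",
              nrow(x$z_ilm), ncol(x$z_ilm), min(x$z_ilm), max(x$z_ilm)))
  if (!is.null(x$disc_mask)) {
    cat(sprintf(", disc %d px (%.3f mm^2)", x$area_onh_px, x$area_onh_mm2))
  }
  cat("\n")
  invisible(x)
}
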