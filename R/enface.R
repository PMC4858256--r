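#' Maximum intensity projection of the flow volume over the pre-laminar slab
#'
#' For each en-face pixel `(x, y)`, takes the maximum scaled flow value
#' over the depth samples selected by the pre-laminar mask — the brightest
#' flow signal along each A-scan. Pixels whose slab is empty are set to 0
#' and flagged.
#'
#' @param flow An `onh_flow` scaled to the 0-255 range.
#' @param mask Logical array `[nx, ny, nz]` from [prelc_mask()].
#' @return An `onh_enface` object holding the MIP image `mip`
#'   (`nx x ny`, values in `[0, 255]`) and the `empty_slab` flag matrix;
#'   the vesselness and vessel-mask slots are filled by [vesselness()]
#'   and [binarize_vessels()].
#' @export
mip_enface <- function(flow, mask) {
  if (!inherits(flow, "onh_flow")) abort("flow must be an onh_flow object")
  if (!isTRUE(flow$scaled)) abort("scale flow with scale_to_dynamic_range() first")
  f <- flow$flow
  if (!is.array(mask) || !identical(dim(mask), dim(f))) {
    abort("mask dimensions must match the flow volume")
  }
  d <- dim(f); nx <- d[1]; ny <- d[2]; nz <- d[3]
  f[!mask] <- -Inf
  dim(f) <- c(nx * ny, nz)
  m <- f[, 1]
  for (z in seq_len(nz)[-1]) m <- pmax(m, f[, z])
  empty <- !is.finite(m)
  m[empty] <- 0
  structure(list(
    mip = matrix(m, nx, ny),
    empty_slab = matrix(empty, nx, ny),
    vesselness = NULL, vessel_mask = NULL,
    scales = NULL, threshold = NULL, method = NULL
  ), class = "onh_enface")
}

#' Multiscale Hessian (Frangi-type) vesselness
#'
#' Probability-like bright-ridge response of the en-face angiogram. At
#' each scale `sigma` the image is Gaussian-smoothed and the
#' scale-normalized Hessian (second derivatives multiplied by `sigma^2`)
#' is formed; with eigenvalues ordered `|l1| <= |l2|`, the response is 0
#' where `l2 > 0` (dark ridge / blob) and otherwise
#' `exp(-Rb^2 / 2 beta^2) * (1 - exp(-S^2 / 2 c^2))` with blobness
#' `Rb = |l1| / |l2|` and second-order structure `S = sqrt(l1^2 + l2^2)`.
#' The final map is the maximum over scales. `c` defaults to half the
#' maximum Frobenius norm of the scale-normalized Hessian over the image,
#' taken across all scales (one `c` for the whole filter, so weak
#' large-scale responses are not renormalized upward).
#'
#' @param x An `onh_enface` object or a numeric matrix.
#' @param scales Gaussian scales in pixels (vessel radii probed).
#' @param beta Blobness sensitivity.
#' @param c Structureness sensitivity; `NULL` for the per-scale default.
#' @return For an `onh_enface` input, the object with `vesselness`
#'   (values in `[0, 1]`) and `scales` filled in; for a matrix input, the
#'   vesselness matrix itself.
#' @export
vesselness <- function(x, scales = c(1, 2, 3, 4), beta = 0.5, c = NULL) {
  img <- if (inherits(x, "onh_enface")) x$mip else x
  if (!is.matrix(img) || any(!is.finite(img))) {
    abort("input image must be a finite numeric matrix")
  }
  if (!length(scales)) abort("at least one scale is required")
  if (any(scales < 1)) abort("scales must be >= 1 pixel")
  eigs <- lapply(scales, function(s) {
    H <- hessian_2d(gaussian_blur(img, s))
    hxx <- s^2 * H$xx; hyy <- s^2 * H$yy; hxy <- s^2 * H$xy
    tmp <- sqrt((hxx - hyy)^2 + 4 * hxy^2)
    e1 <- (hxx + hyy + tmp) / 2
    e2 <- (hxx + hyy - tmp) / 2
    swap <- abs(e1) > abs(e2)          # enforce |l1| <= |l2|
    list(l1 = ifelse(swap, e2, e1), l2 = ifelse(swap, e1, e2))
  })
  s2max <- max(vapply(eigs, function(e) max(e$l1^2 + e$l2^2), numeric(1)))
  cc <- if (is.null(c)) 0.5 * sqrt(s2max) else c
  V <- matrix(0, nrow(img), ncol(img))
  for (e in eigs) {
    S2 <- e$l1^2 + e$l2^2
    resp <- matrix(0, nrow(img), ncol(img))
    ok <- e$l2 < 0 & S2 > 0
    if (any(ok) && cc > 0) {
      rb2 <- (e$l1[ok] / e$l2[ok])^2
      resp[ok] <- exp(-rb2 / (2 * beta^2)) *
        (1 - exp(-S2[ok] / (2 * cc^2)))
    }
    V <- pmax(V, resp)
  }
  if (inherits(x, "onh_enface")) {
    x$vesselness <- V
    x$scales <- scales
    x
  } else {
    V
  }
}

#' Binarize a vesselness map
#'
#' Thresholds the vesselness probability map into a vessel mask. The
#' default method `"hysteresis"` seeds vessels where `V` exceeds the Otsu
#' threshold of the values restricted to `roi` (normally the disc mask,
#' where the perfusion metrics live) and grows the seeds by 4-connected
#' propagation into the contiguous region above half that level — the
#' canonical strong/weak = 2:1 hysteresis convention. This recovers the
#' vessel edges that a single class-midpoint threshold erodes, while
#' isolated speckle response (not contiguous to any seed) stays
#' excluded. Method `"otsu"` uses the strong threshold alone; `"fixed"`
#' applies the strict threshold `t` (default 0.5). A degenerate
#' (constant) map under the adaptive methods falls back to the fixed
#' threshold with a warning.
#'
#' @param x An `onh_enface` with a vesselness map, or a numeric matrix
#'   of vesselness values.
#' @param method `"hysteresis"`, `"otsu"` or `"fixed"`.
#' @param t Fixed threshold (strict: mask is `V > t`).
#' @param roi Optional logical matrix restricting the Otsu statistics.
#' @return For `onh_enface` input, the object with `vessel_mask`,
#'   `threshold` and `method` filled; for a matrix, the logical mask with
#'   the threshold as attribute `"threshold"`.
#' @export
binarize_vessels <- function(x, method = c("hysteresis", "otsu", "fixed"),
                             t = 0.5, roi = NULL) {
  method <- match.arg(method)
  V <- if (inherits(x, "onh_enface")) x$vesselness else x
  if (is.null(V)) abort("compute vesselness() first")
  if (any(V < 0 | V > 1)) abort("vesselness values must lie in [0, 1]")
  thr <- t
  if (method %in% c("otsu", "hysteresis")) {
    vals <- if (is.null(roi)) V else V[roi]
    ot <- otsu_threshold(vals)
    if (is.na(ot)) {
      warn("vesselness map is degenerate; falling back to the fixed threshold")
      method <- "fixed"
    } else {
      thr <- ot
    }
  }
  mask <- if (method == "hysteresis") {
    hysteresis_grow(V > thr, V > thr / 2)
  } else {
    V > thr
  }
  if (inherits(x, "onh_enface")) {
    x$vessel_mask <- mask
    x$threshold <- thr
    x$method <- method
    x
  } else {
    attr(mask, "threshold") <- thr
    mask
  }
}

# 4-connected binary propagation of seeds constrained to the weak region.
hysteresis_grow <- function(seed, weak) {
  m <- seed & weak | seed
  n1 <- nrow(m); n2 <- ncol(m)
  repeat {
    p <- pad_replicate(m, 1L)
    grown <- (p[1:n1, 2:(n2 + 1)] | p[3:(n1 + 2), 2:(n2 + 1)] |
                p[2:(n1 + 1), 1:n2] | p[2:(n1 + 1), 3:(n2 + 2)] | m) & weak
    grown <- grown | seed
    if (identical(grown, m)) return(m)
    m <- grown
  }
}

#' @export
print.onh_enface <- function(x, ...) {
  cat(sprintf("<onh_enface> %d x %d MIP, range [%.1f, %.1f]",
              nrow(x$mip), ncol(x$mip), min(x$mip), max(x$mip)))
  if (!is.null(x$vesselness)) cat(", vesselness computed")
  if (!is.null(x$vessel_mask)) {
    cat(sprintf(", %d vessel px (thr %.3g)", sum(x$vessel_mask), x$threshold))
  }
  cat("\n")
  invisible(x)
}
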