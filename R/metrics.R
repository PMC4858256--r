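#' ONH perfusion metrics
#'
#' The three perfusion metrics are ratios without units, computed on the
#' en-face maximum-intensity projection within the optic disc mask:
#'
#' * **flux** — mean of the flow signal normalized by its full dynamic
#'   range 255, over all disc pixels: the mean number of moving
#'   scatterers crossing per unit area.
#' * **vessel area density** — fraction of the disc area occupied by
#'   detected vessels.
#' * **normalized flux** — mean normalized flow over vessel pixels only,
#'   i.e. the flux normalized by the vessel area, insulating the measure
#'   from tissue loss.
#'
#' They satisfy the exact decomposition
#' `flux = density * normalized_flux + (1 - density) * mean_background`,
#' where `mean_background` is the mean normalized flow over non-vessel
#' disc pixels.
#'
#' @param enface Numeric `nx x ny` MIP image in `[0, 255]`, or an
#'   `onh_enface` object.
#' @param disc_mask Logical matrix: the disc (ONH) region.
#' @param vessel_mask Logical matrix: detected vessel pixels.
#' @return `compute_flux()` and `compute_vessel_area_density()` return a
#'   single number in `[0, 1]`; `compute_normalized_flux()` returns a
#'   number in `[0, 1]` or `NA` (flagged with a warning) when no vessel
#'   pixel falls inside the disc.
#' @name perfusion_metrics
NULL

enface_image <- function(enface) {
  img <- if (inherits(enface, "onh_enface")) enface$mip else enface
  if (!is.matrix(img)) abort("enface must be a matrix or onh_enface")
  if (any(img < 0 | img > 255)) abort("en-face values must lie in [0, 255]")
  img
}

#' @rdname perfusion_metrics
#' @export
compute_flux <- function(enface, disc_mask) {
  img <- enface_image(enface)
  if (!any(disc_mask)) abort("disc mask is empty")
  mean(img[disc_mask]) / 255
}

#' @rdname perfusion_metrics
#' @export
compute_vessel_area_density <- function(vessel_mask, disc_mask) {
  if (!identical(dim(vessel_mask), dim(disc_mask))) {
    abort("vessel and disc masks must have identical dimensions")
  }
  if (!any(disc_mask)) abort("disc mask is empty")
  sum(vessel_mask & disc_mask) / sum(disc_mask)
}

#' @rdname perfusion_metrics
#' @export
compute_normalized_flux <- function(enface, vessel_mask, disc_mask) {
  img <- enface_image(enface)
  sel <- vessel_mask & disc_mask
  if (!any(sel)) {
    warn("no vessel pixels inside the disc; normalized flux is undefined")
    return(NA_real_)
  }
  mean(img[sel]) / 255
}

#' All perfusion metrics for one eye as a tibble row
#'
#' Convenience wrapper running the three metric computations on a
#' processed en-face result and returning one tidy record.
#'
#' @param enface An `onh_enface` with vessel mask, or a numeric MIP
#'   matrix (then `vessel_mask` is required).
#' @param disc_mask Logical disc mask.
#' @param vessel_mask Logical vessel mask (taken from `enface` when
#'   omitted).
#' @param eye_id Identifier recorded in the output.
#' @param signal_strength,motion Scan-quality metadata carried through to
#'   [qc_filter()].
#' @return One-row tibble with columns `eye_id`, `flux`,
#'   `vessel_area_density`, `normalized_flux`, `area_onh_px`,
#'   `vessel_area_px`, `signal_strength`, `motion`.
#' @export
compute_perfusion_metrics <- function(enface, disc_mask, vessel_mask = NULL,
                                      eye_id = "eye1",
                                      signal_strength = NA_real_,
                                      motion = FALSE) {
  if (is.null(vessel_mask)) {
    if (!inherits(enface, "onh_enface") || is.null(enface$vessel_mask)) {
      abort("vessel_mask is required when enface carries none")
    }
    vessel_mask <- enface$vessel_mask
  }
  tibble(
    eye_id = eye_id,
    flux = compute_flux(enface, disc_mask),
    vessel_area_density = compute_vessel_area_density(vessel_mask, disc_mask),
    normalized_flux = compute_normalized_flux(enface, vessel_mask, disc_mask),
    area_onh_px = sum(disc_mask),
    vessel_area_px = sum(vessel_mask & disc_mask),
    signal_strength = signal_strength,
    motion = motion
  )
}

#' Scan-level quality-control filter
#'
#' Applies the study's exclusion rule: a scan is excluded when its
#' device-reported signal strength falls below the cutoff (`< 6` on the
#' 0-10 scale) or when noticeable eye movement was flagged. Records with
#' missing signal strength are excluded with a warning.
#'
#' @param records Data frame with columns `signal_strength` and `motion`
#'   (logical), optionally `group`.
#' @param cutoff Minimum acceptable signal strength (inclusive).
#' @return The input as a tibble with a logical `qc_pass` column.
#' @seealso [qc_summary()]
#' @export
#' @examples
#' qc_filter(tibble::tibble(signal_strength = c(5, 6, 9),
#'                          motion = c(FALSE, FALSE, TRUE)))
qc_filter <- function(records, cutoff = 6) {
  records <- as_tibble(records)
  if (!all(c("signal_strength", "motion") %in% names(records))) {
    abort("records need `signal_strength` and `motion` columns")
  }
  ss <- records$signal_strength
  if (any(is.na(ss))) {
    warn("records with missing signal strength are treated as excluded")
  }
  if (any(ss < 0 | ss > 10, na.rm = TRUE)) {
    abort("signal strength must lie in [0, 10]")
  }
  records$qc_pass <- !is.na(ss) & ss >= cutoff & !isTRUE_vec(records$motion)
  records
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Per-group QC accounting
#'
#' @param records Output of [qc_filter()] with a `group` column.
#' @return Tibble with per-group `enrolled`, `excluded` and `included`
#'   counts.
#' @export
qc_summary <- function(records) {
  if (!"qc_pass" %in% names(records)) records <- qc_filter(records)
  records |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      enrolled = dplyr::n(),
      excluded = sum(!.data$qc_pass),
      included = sum(.data$qc_pass),
      .groups = "drop"
    )
}
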