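# Quantitative autoradiography: phosphor-plate calibration against known
# activity standards, intensity-to-activity conversion, significance
# thresholding against healthy tissue, and per-region uptake.

#' Fit a phosphor-plate calibration line
#'
#' Ordinary least squares of plate intensity on standard activity. The
#' intercept is left free to absorb plate background; r-squared is reported
#' so the user can audit linearity. Standards and tissue sections are
#' assumed to share the same exposure duration and isotope, so decay during
#' exposure cancels in the linear map.
#'
#' @param standards data frame with columns `activity_bq` and `intensity`.
#' @param exposure_h exposure duration in hours (metadata, default 23).
#' @return object of class `calibration_curve`: `slope` (intensity per Bq),
#'   `intercept`, `exposure_h`, `r_squared`.
#' @export
fit_calibration <- function(standards, exposure_h = 23) {
  a <- standards$activity_bq
  i <- standards$intensity
  if (length(unique(a)) < 2) stop("need at least 2 standards with distinct activities")
  if (any(a <= 0)) stop("standard activities must be positive")
  fit <- stats::lm(i ~ a)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) stop("calibration slope must be positive")
  # r-squared and parameter covariance computed directly (an exact fit is a
  # legitimate input here and must not warn)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((i - mean(i))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  vc <- if (length(a) > 2) {
    X <- cbind(1, a)
    (rss / (length(a) - 2)) * solve(crossprod(X))
  } else matrix(0, 2, 2)
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 exposure_h = exposure_h, r_squared = r2, vcov = vc),
            class = "calibration_curve")
}

#' Convert plate intensities to activity
#'
#' Inverts the calibration line pixel-wise, `(intensity - intercept)/slope`,
#' clipping negative results at zero.
#'
#' @param intensity numeric matrix (or vector) of plate intensities.
#' @param curve a `calibration_curve`.
#' @return activity in Bq per pixel, same shape as `intensity`.
#' @export
intensity_to_activity <- function(intensity, curve) {
  pmax((intensity - curve$intercept) / curve$slope, 0)
}

#' Significance threshold against healthy tissue
#'
#' Mean of the healthy-tissue values plus 1.96 sample standard deviations
#' (n-1 denominator), the two-sided 5% criterion used to mark pixels whose
#' uptake exceeds healthy background.
#'
#' @param healthy_values numeric vector of healthy-tissue activities
#'   (length >= 2).
#' @return the threshold on the same scale as the input.
#' @export
significance_threshold <- function(healthy_values) {
  if (length(healthy_values) < 2) stop("need at least 2 healthy values")
  mean(healthy_values) + 1.96 * stats::sd(healthy_values)
}

#' Per-region uptake from an activity map
#'
#' Sums pixel activities under an integer mask label. When the section mass
#' is supplied, a per-gram concentration is derived by attributing the
#' section mass to regions in proportion to their pixel area (uniform
#' section thickness), with the section taken as all labelled (mask > 0)
#' pixels.
#'
#' @param activity activity matrix in Bq per pixel.
#' @param mask integer label matrix of the same shape (0 background,
#'   1 healthy, 2+ lesions).
#' @param label region label to quantify.
#' @param section_mass_g optional whole-section mass in grams.
#' @param time_h optional time post-injection carried into the result.
#' @return object of class `region_uptake`: `label`, `total_bq`,
#'   `per_gram_bq`, `n_pixels`, `time_h`.
#' @export
roi_uptake <- function(activity, mask, label, section_mass_g = NULL,
                       time_h = NA_real_) {
  if (!all(dim(activity) == dim(mask))) stop("activity and mask shapes differ")
  sel <- mask == label
  if (!any(sel)) stop(sprintf("label %s not present in mask", label))
  total <- sum(activity[sel])
  per_gram <- NA_real_
  if (!is.null(section_mass_g)) {
    if (section_mass_g <= 0) stop("section_mass_g must be positive")
    n_section <- sum(mask > 0)
    region_mass <- section_mass_g * sum(sel) / n_section
    per_gram <- total / region_mass
  }
  structure(list(label = label, total_bq = total, per_gram_bq = per_gram,
                 n_pixels = sum(sel), time_h = time_h),
            class = "region_uptake")
}

#' Ratio of cumulated activities (lesion vs healthy)
#'
#' @param bm cumulated activity in the lesion (a `cumulated_activity`
#'   object or a number in dis/g).
#' @param healthy cumulated activity in healthy tissue (> 0).
#' @return the dimensionless ratio.
#' @export
accumulated_ratio <- function(bm, healthy) {
  v1 <- if (inherits(bm, "cumulated_activity")) bm$value else as.numeric(bm)
  v2 <- if (inherits(healthy, "cumulated_activity")) healthy$value else as.numeric(healthy)
  if (v2 <= 0) stop("healthy cumulated activity must be positive")
  v1 / v2
}

#' Nearest-neighbour mask resampling
#'
#' Resamples an integer label mask onto a grid with a different pixel size,
#' for masks drawn on an imaging grid that does not match the autoradiograph.
#' Pixel centres of the target grid are mapped to source coordinates and the
#' nearest source label is taken; no interpolation of labels occurs.
#'
#' @param mask integer label matrix.
#' @param from_px source pixel size (mm).
#' @param to_px target pixel size (mm).
#' @return resampled integer matrix.
#' @export
resample_mask_nn <- function(mask, from_px, to_px) {
  nr <- max(1L, round(nrow(mask) * from_px / to_px))
  nc <- max(1L, round(ncol(mask) * from_px / to_px))
  ri <- pmin(nrow(mask), pmax(1L, round((seq_len(nr) - 0.5) * to_px / from_px + 0.5)))
  ci <- pmin(ncol(mask), pmax(1L, round((seq_len(nc) - 0.5) * to_px / from_px + 0.5)))
  mask[ri, ci, drop = FALSE]
}

#' Read / write 16-bit autoradiograph images
#'
#' Thin wrappers over the tiff package storing integer plate units in
#' 16-bit grayscale TIFF ([0, 65535]).
#'
#' @param img numeric matrix of plate units.
#' @param path file path.
#' @return `read_autorad_tiff` returns an integer-valued matrix.
#' @export
write_autorad_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
  tiff::writeTIFF(pmin(pmax(img, 0), 65535) / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_autorad_tiff
#' @export
read_autorad_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
  round(tiff::readTIFF(path) * 65535)
}
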