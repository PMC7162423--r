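# Diffusion MRI microstructure metrics: log-linear tensor estimation,
# eigenvalue summaries (FA/MD/AD/RD) and the non-Gaussian kurtosis signal
# model over a multi-b-value ladder.

#' Default 6-direction gradient scheme
#'
#' Six non-collinear unit vectors (icosahedral pairs), the minimal set for
#' tensor estimation.
#'
#' @return 6 x 3 matrix of unit vectors.
#' @export
dwi_directions6 <- function() {
  g <- rbind(c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1),
             c(0, 1, -1), c(1, 1, 0), c(-1, 1, 0)) / sqrt(2)
  g
}

#' Fit a diffusion tensor by log-linear least squares
#'
#' Solves `log(S/S0) = -b g' D g` for the six unique tensor elements, then
#' eigendecomposes. Eigenvalues are returned sorted descending; negative
#' eigenvalues (noise-driven) are clipped to zero and flagged.
#'
#' @param signals measured signals, one per (direction, b) row.
#' @param b_values b-value per measurement in s/mm^2.
#' @param directions matrix of unit gradient directions, one row per
#'   measurement.
#' @param s0 reference signal at b ~ 0.
#' @return object of class `tensor_eigenvalues`: `lambda` (sorted
#'   descending, mm^2/s), `tensor` (3 x 3), `clipped` flag.
#' @export
fit_tensor <- function(signals, b_values, directions, s0) {
  directions <- as.matrix(directions)
  if (any(signals <= 0) || s0 <= 0) stop("signals must be positive")
  if (nrow(directions) != length(signals) || length(b_values) != length(signals)) {
    stop("signals, b_values and directions must align")
  }
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) directions <- directions / nrm
  X <- cbind(directions[, 1]^2, directions[, 2]^2, directions[, 3]^2,
             2 * directions[, 1] * directions[, 2],
             2 * directions[, 1] * directions[, 3],
             2 * directions[, 2] * directions[, 3]) * (-b_values)
  if (qr(X)$rank < 6) {
    stop("direction set is rank-deficient: need >= 6 non-collinear directions")
  }
  y <- log(signals / s0)
  d <- stats::lm.fit(X, y)$coefficients
  D <- matrix(c(d[1], d[4], d[5],
                d[4], d[2], d[6],
                d[5], d[6], d[3]), 3, 3)
  ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  clipped <- any(ev < 0)
  structure(list(lambda = pmax(ev, 0), tensor = D, clipped = clipped),
            class = "tensor_eigenvalues")
}

#' Tensor eigenvalue summaries (FA, MD, AD, RD)
#'
#' Mean diffusivity `MD = (l1 + l2 + l3)/3`, axial `AD = l1`, radial
#' `RD = (l2 + l3)/2`, and fractional anisotropy
#' `FA = sqrt(3/2) * sqrt(sum((l - MD)^2) / sum(l^2))`, defined as 0 for
#' the zero tensor.
#'
#' @param eigs a `tensor_eigenvalues` object or a length-3 vector of
#'   eigenvalues (any order).
#' @return list with `fa`, `md`, `ad`, `rd` (diffusivities in mm^2/s).
#' @export
dti_metrics <- function(eigs) {
  l <- if (inherits(eigs, "tensor_eigenvalues")) eigs$lambda else sort(eigs, decreasing = TRUE)
  if (length(l) != 3) stop("need exactly 3 eigenvalues")
  md <- mean(l)
  ss <- sum(l^2)
  fa <- if (ss == 0) 0 else sqrt(1.5) * sqrt(sum((l - md)^2) / ss)
  list(fa = min(max(fa, 0), 1), md = md, ad = l[1], rd = (l[2] + l[3]) / 2)
}

# log-signal of the kurtosis model: S(b) = S0 exp(-b ADC + (b ADC)^2 K / 6)
dki_log_signal <- function(b, log_s0, adc, k) {
  log_s0 - b * adc + (b * adc)^2 * k / 6
}

#' Fit the diffusion-kurtosis signal model
#'
#' Nonlinear least squares on the log signal,
#' `log S(b) = log S0 - b*ADC + (b*ADC)^2 K/6`, with bounds `ADC > 0` and
#' `K` in `[0, 10]`. K = 0 recovers mono-exponential (Gaussian) decay; K
#' grows with tissue heterogeneity. Signals below `min_signal` are excluded
#' (the model assumes signal well above the noise floor).
#'
#' @param b_values b-values in s/mm^2 (>= 4 distinct values, one near 0).
#' @param signals positive signals, same length.
#' @param min_signal exclusion floor for low-signal points (default 0).
#' @return list with `s0`, `adc` (mm^2/s), `k`, `residual_norm` (on log
#'   signal), `n_points`.
#' @export
fit_kurtosis <- function(b_values, signals, min_signal = 0) {
  if (any(signals <= 0)) stop("signals must be positive")
  keep <- signals >= min_signal
  b <- b_values[keep]; s <- signals[keep]
  if (length(unique(b)) < 4) stop("need >= 4 distinct b-values")
  if (min(b) > 100) stop("need a reference measurement near b = 0")
  y <- log(s)
  # starts: mono-exponential slope for ADC
  sl <- stats::lm.fit(cbind(1, b), y)$coefficients
  p0 <- c(log_s0 = unname(sl[1]), adc = max(-unname(sl[2]), 1e-6), k = 0.5)
  fit <- minpack.lm::nls.lm(
    par = p0,
    fn = function(p) dki_log_signal(b, p[1], p[2], p[3]) - y,
    lower = c(-Inf, 1e-12, 0), upper = c(Inf, Inf, 10),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  list(s0 = exp(unname(p[1])), adc = unname(p[2]), k = unname(p[3]),
       residual_norm = sqrt(sum((dki_log_signal(b, p[1], p[2], p[3]) - y)^2)),
       n_points = length(b))
}

#' Mono-exponential ADC fit
#'
#' The kurtosis model with K frozen at zero: a straight-line fit of log
#' signal against b. Reported separately because the apparent diffusion
#' coefficient is conventionally quoted from the mono-exponential model.
#'
#' @param b_values b-values in s/mm^2 (>= 2 distinct).
#' @param signals positive signals.
#' @return list with `s0`, `adc`, `residual_norm`.
#' @export
fit_adc <- function(b_values, signals) {
  if (any(signals <= 0)) stop("signals must be positive")
  if (length(unique(b_values)) < 2) stop("need >= 2 distinct b-values")
  y <- log(signals)
  co <- stats::lm.fit(cbind(1, b_values), y)$coefficients
  adc <- max(-unname(co[2]), 0)
  list(s0 = exp(unname(co[1])), adc = adc,
       residual_norm = sqrt(sum((unname(co[1]) - b_values * adc - y)^2)))
}
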