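# Clonogenic survival analysis: surviving fractions from colony counts,
# linear-quadratic / exponential dose-response fits, SF2, D50 and
# surviving-fraction effect ratios between radiation qualities.

#' Surviving fraction from colony counts
#'
#' `SF = colonies / (cells_plated * plating_efficiency)`, the standard
#' clonogenic definition. The plating efficiency is the colony yield of
#' unirradiated controls per cell plated.
#'
#' @param colonies colony count(s).
#' @param cells_plated cells seeded per well (> 0).
#' @param plating_efficiency fraction in (0, 1].
#' @return surviving fraction(s).
#' @export
surviving_fraction <- function(colonies, cells_plated, plating_efficiency) {
  if (any(cells_plated <= 0)) stop("cells_plated must be positive")
  if (any(plating_efficiency <= 0) || any(plating_efficiency > 1)) {
    stop("plating_efficiency must be in (0, 1]")
  }
  colonies / (cells_plated * plating_efficiency)
}

#' Fit a clonogenic survival curve
#'
#' Weighted least squares on the log surviving fraction. The
#' linear-quadratic model is `ln SF = -(alpha*D + beta*D^2)`; the
#' exponential model fixes `beta = 0` (the classical log-linear response of
#' high-LET radiation). Per-dose log-SF means are weighted by the total
#' colony count at the dose, the inverse-variance weight under Poisson
#' counting statistics (Var[ln N] ~ 1/N). Parameters are constrained
#' non-negative. A grossly non-monotone response (mean SF rising by more
#' than 20% between consecutive doses) is flagged with a warning rather
#' than silently fitted.
#'
#' @param data data frame with columns `dose`, `colonies`, `cells_plated`
#'   (one row per well). Dose 0 wells define the plating efficiency unless
#'   `plating_efficiency` is supplied.
#' @param model `"lq"` or `"exponential"`.
#' @param plating_efficiency optional override of the control-derived value.
#' @param gy_per_kbq optional factor converting activity-denominated dose
#'   levels (kBq) to Gy before fitting; without it doses are used as given.
#' @return object of class `survival_fit`: `model`, `alpha` (1/Gy), `beta`
#'   (1/Gy^2), `sf2`, `d50`, `covariance`, `plating_efficiency`,
#'   `non_monotone` flag, and the per-dose summary table.
#' @export
fit_survival <- function(data, model = c("lq", "exponential"),
                         plating_efficiency = NULL, gy_per_kbq = NULL) {
  model <- match.arg(model)
  d <- data
  if (!all(c("dose", "colonies", "cells_plated") %in% names(d))) {
    stop("data must have columns dose, colonies, cells_plated")
  }
  if (any(d$colonies < 0)) stop("colony counts must be non-negative")
  if (!is.null(gy_per_kbq)) d$dose <- d$dose * gy_per_kbq
  if (is.null(plating_efficiency)) {
    ctrl <- d[d$dose == 0, , drop = FALSE]
    if (nrow(ctrl) == 0) stop("dose-0 control wells (or plating_efficiency) required")
    plating_efficiency <- sum(ctrl$colonies) / sum(ctrl$cells_plated)
  }
  d$sf <- surviving_fraction(d$colonies, d$cells_plated, plating_efficiency)

  pos <- d[d$dose > 0, , drop = FALSE]
  n_levels <- length(unique(pos$dose))
  need <- if (model == "lq") 3 else 2
  if (n_levels < need) {
    stop(sprintf("%s fit needs >= %d nonzero dose levels, got %d",
                 model, need, n_levels))
  }
  # per-dose aggregation on all levels (including 0 for monotonicity check)
  agg <- do.call(rbind, lapply(split(d, d$dose), function(g) {
    data.frame(dose = g$dose[1], mean_sf = mean(g$sf),
               total_colonies = sum(g$colonies), n_wells = nrow(g))
  }))
  agg <- agg[order(agg$dose), ]
  non_monotone <- any(diff(agg$mean_sf) / pmax(agg$mean_sf[-nrow(agg)], 1e-12) > 0.2)
  if (non_monotone) {
    warning("surviving fraction is grossly non-monotone in dose; fit flagged")
  }

  fitdat <- agg[agg$dose > 0 & agg$mean_sf > 0, , drop = FALSE]
  y <- -log(fitdat$mean_sf)                 # alpha*D + beta*D^2 >= 0
  w <- fitdat$total_colonies
  X <- if (model == "lq") cbind(fitdat$dose, fitdat$dose^2) else cbind(fitdat$dose)

  # weighted least squares with non-negativity via bounded Levenberg-Marquardt
  p0 <- pmax(stats::lm.fit(X * sqrt(w), y * sqrt(w))$coefficients, 1e-6)
  fit <- minpack.lm::nls.lm(
    par = p0,
    fn = function(p) sqrt(w) * (as.vector(X %*% p) - y),
    lower = rep(0, ncol(X)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  alpha <- p[1]
  beta <- if (model == "lq") p[2] else 0

  dof <- max(nrow(fitdat) - ncol(X), 1)
  sigma2 <- sum((sqrt(w) * (as.vector(X %*% p) - y))^2) / dof
  xtwx <- crossprod(X * sqrt(w))
  covm <- tryCatch(solve(xtwx) * sigma2, error = function(e) matrix(NA_real_, ncol(X), ncol(X)))

  out <- structure(
    list(model = model, alpha = unname(alpha), beta = unname(beta),
         covariance = covm, plating_efficiency = plating_efficiency,
         non_monotone = non_monotone, per_dose = agg),
    class = "survival_fit")
  out$sf2 <- sf_at_dose(out, 2)
  out$d50 <- d_at_sf(out, 0.5)
  out
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Clonogenic survival fit (%s)\n", x$model))
  cat(sprintf("  alpha = %.4g /Gy, beta = %.4g /Gy^2\n", x$alpha, x$beta))
  cat(sprintf("  SF2 = %.4g, D50 = %.4g Gy, PE = %.3g\n",
              x$sf2, x$d50, x$plating_efficiency))
  invisible(x)
}

#' Surviving fraction at a dose
#'
#' `SF(D) = exp(-alpha*D - beta*D^2)`.
#'
#' @param fit a `survival_fit` (or list with `alpha`, `beta`).
#' @param dose dose in Gy (>= 0).
#' @return surviving fraction.
#' @export
sf_at_dose <- function(fit, dose) {
  if (any(dose < 0)) stop("dose must be non-negative")
  exp(-fit$alpha * dose - fit$beta * dose^2)
}

#' Dose at a surviving fraction
#'
#' Inverts `SF(D) = exp(-alpha*D - beta*D^2)` for `sf` in (0, 1]; the
#' positive root of the quadratic is taken:
#' `D = (-alpha + sqrt(alpha^2 - 4*beta*ln(sf))) / (2*beta)`.
#'
#' @param fit a `survival_fit`.
#' @param sf surviving fraction in (0, 1].
#' @return dose in Gy.
#' @export
d_at_sf <- function(fit, sf) {
  if (any(sf <= 0) || any(sf > 1)) stop("sf must be in (0, 1]")
  lnsf <- log(sf)
  if (fit$beta > 0) {
    (-fit$alpha + sqrt(fit$alpha^2 - 4 * fit$beta * lnsf)) / (2 * fit$beta)
  } else {
    if (fit$alpha <= 0) stop("degenerate fit: alpha and beta both zero")
    -lnsf / fit$alpha
  }
}

#' Surviving-fraction effect ratio at matched dose
#'
#' The ratio of surviving fractions of the reference radiation quality to
#' the test quality at the same absorbed dose. Note this is an
#' effect-at-fixed-dose ratio, not the classical iso-effect dose-ratio RBE;
#' see the methods vignette.
#'
#' @param sf_reference surviving fraction under the reference modality
#'   (e.g. X-rays).
#' @param sf_test surviving fraction under the test modality (> 0).
#' @return dimensionless ratio.
#' @export
rbe_sf_ratio <- function(sf_reference, sf_test) {
  if (any(sf_test <= 0)) stop("sf_test must be positive")
  sf_reference / sf_test
}
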