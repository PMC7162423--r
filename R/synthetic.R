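# Seeded generators reproducing the statistical structure of each data
# stage: organ time-activity curves, autoradiograph phantoms, diffusion
# signals, clonogenic colony counts and two-arm survival times. Every
# generator records the ground truth alongside its output so downstream
# fits can be validated against it.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Generate synthetic time-activity samples
#'
#' Draws activities on the rise-and-decay curve
#' `A(t) = A0 (1 - exp(-lr t)) exp(-ld t)` with multiplicative lognormal
#' noise of a given coefficient of variation (mean-one noise, so the
#' expected sample equals the model value). Defaults mirror a typical
#' biodistribution design: sampling at 2, 4, 8 and 24 h with 4 animals per
#' time point.
#'
#' @param A0 activity scale in Bq/g.
#' @param lambda_r rise constant (1/h).
#' @param lambda_d decay constant (1/h).
#' @param times_h sampling times in hours.
#' @param n_per_time animals per time point.
#' @param cv multiplicative noise coefficient of variation (>= 0).
#' @param region region label.
#' @param seed RNG seed.
#' @return an `activity_samples` data frame with a `truth` attribute
#'   (list of the generating parameters).
#' @export
gen_tac <- function(A0 = 100, lambda_r = 1, lambda_d = 0.0654,
                    times_h = c(2, 4, 8, 24), n_per_time = 4,
                    cv = 0.05, region = "organ", seed = NULL) {
  if (cv < 0) stop("cv must be non-negative")
  with_seed(seed, {
    t <- rep(times_h, each = n_per_time)
    mu <- tac_model(t, A0, lambda_r, lambda_d)
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      noise <- stats::rlnorm(length(t), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      noise <- rep(1, length(t))
    }
    out <- activity_samples(region = region, time_h = t,
                            activity_bq_per_g = mu * noise)
    attr(out, "truth") <- list(A0 = A0, lambda_r = lambda_r,
                               lambda_d = lambda_d, cv = cv)
    out
  })
}

#' Generate an autoradiograph phantom with calibration standards
#'
#' Builds a section-shaped healthy region containing square uptake spots,
#' maps per-pixel activity through a linear plate response
#' `intensity = slope * activity + intercept`, and Poisson-samples the
#' plate intensities. Calibration standards (default 1, 2, 4 and 10 Bq) are
#' passed through the same response. The mask labels healthy tissue 1 and
#' spots 2, 3, ...; pixels outside the section are 0.
#'
#' @param dim image dimensions (rows, cols).
#' @param spots list of spots, each `list(row =, col =, size =,
#'   activity_bq =)` giving the top-left corner, square side and per-pixel
#'   activity in Bq.
#' @param healthy_activity_bq per-pixel activity of healthy tissue.
#' @param slope,intercept plate response (intensity units per Bq;
#'   background offset).
#' @param standard_activities_bq activities of the calibration standards.
#' @param seed RNG seed.
#' @return list with `intensity` (matrix), `mask` (integer matrix),
#'   `standards` (data frame `activity_bq`, `intensity`) and `truth`.
#' @export
gen_autorad_phantom <- function(dim = c(64, 64),
                                spots = list(list(row = 10, col = 10, size = 3,
                                                  activity_bq = 0.2)),
                                healthy_activity_bq = 0.01,
                                slope = 5000, intercept = 100,
                                standard_activities_bq = c(1, 2, 4, 10),
                                seed = NULL) {
  with_seed(seed, {
    mask <- matrix(1L, dim[1], dim[2])
    act <- matrix(healthy_activity_bq, dim[1], dim[2])
    lab <- 2L
    for (sp in spots) {
      ri <- sp$row:(sp$row + sp$size - 1)
      ci <- sp$col:(sp$col + sp$size - 1)
      if (max(ri) > dim[1] || max(ci) > dim[2]) stop("spot outside the grid")
      if (any(mask[ri, ci] != 1L)) warning("overlapping spots")
      mask[ri, ci] <- lab
      act[ri, ci] <- sp$activity_bq
      lab <- lab + 1L
    }
    mu <- slope * act + intercept
    intensity <- matrix(stats::rpois(length(mu), mu), dim[1], dim[2])
    standards <- data.frame(
      activity_bq = standard_activities_bq,
      intensity = stats::rpois(length(standard_activities_bq),
                               slope * standard_activities_bq + intercept))
    list(intensity = intensity, mask = mask, standards = standards,
         truth = list(activity = act, slope = slope, intercept = intercept,
                      spots = spots, healthy_activity_bq = healthy_activity_bq))
  })
}

#' Generate synthetic diffusion-weighted signals
#'
#' Forward-simulates either a diffusion-tensor acquisition (6 directions x
#' b ladder) or an isotropic kurtosis-model decay over the ladder, with
#' optional Rician or Gaussian noise at a given SNR (defined as
#' `s0 / noise sigma`). `snr = Inf` gives noiseless signals, which the
#' corresponding fits recover exactly.
#'
#' @param model `"dti"` or `"kurtosis"`.
#' @param eigenvalues tensor eigenvalues in mm^2/s (dti model).
#' @param adc,k apparent diffusion coefficient and kurtosis (kurtosis
#'   model).
#' @param b_values diffusion weightings in s/mm^2 (a b = 0 reference is
#'   added automatically for the dti model).
#' @param directions gradient scheme for the dti model.
#' @param s0 signal at b = 0.
#' @param snr signal-to-noise ratio at b = 0; `Inf` for noiseless.
#' @param noise `"rician"` or `"gaussian"`.
#' @param seed RNG seed.
#' @return list with `b_values`, `directions` (dti only), `signals`, `s0`
#'   and `truth`.
#' @export
gen_dwi <- function(model = c("dti", "kurtosis"),
                    eigenvalues = c(1.7e-3, 0.3e-3, 0.3e-3),
                    adc = 0.8e-3, k = 1.2,
                    b_values = c(200, 500, 750, 1000, 1500, 2000),
                    directions = dwi_directions6(),
                    s0 = 1000, snr = Inf,
                    noise = c("rician", "gaussian"), seed = NULL) {
  model <- match.arg(model)
  noise <- match.arg(noise)
  with_seed(seed, {
    if (model == "dti") {
      D <- diag(eigenvalues)
      g <- as.matrix(directions)
      bb <- rep(b_values, each = nrow(g))
      gg <- g[rep(seq_len(nrow(g)), times = length(b_values)), , drop = FALSE]
      mu <- s0 * exp(-bb * rowSums((gg %*% D) * gg))
      out <- list(b_values = bb, directions = gg, s0 = s0,
                  truth = list(eigenvalues = eigenvalues, s0 = s0, snr = snr,
                               noise = noise))
    } else {
      bb <- b_values
      mu <- s0 * exp(-bb * adc + (bb * adc)^2 * k / 6)
      out <- list(b_values = bb, s0 = s0,
                  truth = list(adc = adc, k = k, s0 = s0, snr = snr,
                               noise = noise))
    }
    if (is.finite(snr)) {
      sigma <- s0 / snr
      if (noise == "rician") {
        mu <- sqrt((mu + stats::rnorm(length(mu), 0, sigma))^2 +
                     stats::rnorm(length(mu), 0, sigma)^2)
      } else {
        mu <- pmax(mu + stats::rnorm(length(mu), 0, sigma), 1e-9)
      }
    }
    out$signals <- mu
    out
  })
}

#' Generate a synthetic clonogenic experiment
#'
#' Colony counts are Poisson with mean
#' `cells_plated * PE * SF(D)`, `SF(D) = exp(-alpha D - beta D^2)`.
#' Defaults mirror the common assay design: 750 cells per well, 3 wells per
#' dose, 4 biological repeats, X-ray doses 0-8 Gy.
#'
#' @param alpha,beta linear-quadratic parameters (1/Gy, 1/Gy^2).
#' @param plating_efficiency control colony yield per cell plated.
#' @param cells_plated cells seeded per well.
#' @param doses dose levels in Gy (must include 0).
#' @param wells_per_dose technical replicate wells per dose.
#' @param repeats biological repeats.
#' @param seed RNG seed.
#' @return data frame with columns `repeat_id`, `dose`, `well`, `colonies`,
#'   `cells_plated` and a `truth` attribute.
#' @export
gen_clonogenic <- function(alpha = 0.2, beta = 0.06, plating_efficiency = 0.4,
                           cells_plated = 750, doses = c(0, 2, 4, 6, 8),
                           wells_per_dose = 3, repeats = 4, seed = NULL) {
  if (!0 %in% doses) stop("doses must include the 0 Gy control")
  with_seed(seed, {
    grid <- expand.grid(repeat_id = seq_len(repeats), dose = doses,
                        well = seq_len(wells_per_dose))
    sf <- exp(-alpha * grid$dose - beta * grid$dose^2)
    grid$colonies <- stats::rpois(nrow(grid), cells_plated * plating_efficiency * sf)
    grid$cells_plated <- cells_plated
    out <- grid[order(grid$repeat_id, grid$dose, grid$well), ]
    rownames(out) <- NULL
    attr(out, "truth") <- list(alpha = alpha, beta = beta,
                               plating_efficiency = plating_efficiency)
    out
  })
}

#' Generate two-arm (or multi-arm) survival records
#'
#' Times are drawn per group from a normal distribution truncated at zero,
#' then administratively censored at the study endpoint (times at or past
#' the endpoint are recorded as censored at the endpoint). Default arms
#' mirror a five-group preclinical efficacy design: untreated and inactive
#' controls around 24 days, external-beam radiotherapy near 27.6 days and
#' the targeted arm near 35.6 days, with a 40-day endpoint.
#'
#' @param groups named list; each element `list(mean =, sd =, n =)` in
#'   days.
#' @param endpoint_day administrative censoring time (days); `Inf`
#'   disables censoring.
#' @param seed RNG seed.
#' @return data frame with columns `subject`, `group`, `time_days`,
#'   `event`, plus a `truth` attribute.
#' @export
gen_survival <- function(groups = list(
                           untreated = list(mean = 23.8, sd = 1.3, n = 5),
                           cold_conjugate = list(mean = 23.3, sd = 1.3, n = 3),
                           igg_conjugate = list(mean = 24.0, sd = 1.0, n = 3),
                           wbrt = list(mean = 27.6, sd = 2.4, n = 5),
                           tat = list(mean = 35.6, sd = 2.1, n = 5)),
                         endpoint_day = 40, seed = NULL) {
  with_seed(seed, {
    rows <- lapply(names(groups), function(g) {
      p <- groups[[g]]
      t <- numeric(0)
      while (length(t) < p$n) {   # truncate the normal at zero by rejection
        draw <- stats::rnorm(p$n, p$mean, p$sd)
        t <- c(t, draw[draw > 0])[seq_len(min(p$n, length(t) + sum(draw > 0)))]
      }
      event <- as.integer(t < endpoint_day)
      t <- pmin(t, endpoint_day)
      data.frame(subject = paste0(g, "_", seq_len(p$n)), group = g,
                 time_days = t, event = event, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(groups = groups, endpoint_day = endpoint_day)
    out
  })
}
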