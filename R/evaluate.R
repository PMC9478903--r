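#' Sample an intensity profile along a line segment
#'
#' Bilinear interpolation at unit-pixel spacing from `start` to `end`
#' (inclusive of both endpoints, the last step possibly shorter). Points are
#' `(row, col)` in pixel-center coordinates (1-based, as in the matrix).
#'
#' @param image Numeric matrix.
#' @param start,end Numeric `c(row, col)` endpoints inside the image.
#' @return Numeric vector of interpolated intensities; step length in pixels
#'   is carried in `attr(, "step")` (always 1 except for the final point).
#' @export
line_profile <- function(image, start, end) {
  stopifnot(length(start) == 2, length(end) == 2)
  M <- nrow(image); N <- ncol(image)
  if (any(c(start, end) < 1) || start[1] > M || end[1] > M ||
      start[2] > N || end[2] > N) {
    stop("profile endpoints must lie inside the image")
  }
  len <- sqrt(sum((end - start)^2))
  if (len == 0) stop("zero-length profile segment")
  t <- unique(c(seq(0, len, by = 1), len)) / len
  r <- start[1] + t * (end[1] - start[1])
  c_ <- start[2] + t * (end[2] - start[2])
  r0 <- pmin(pmax(floor(r), 1), M - 1); c0 <- pmin(pmax(floor(c_), 1), N - 1)
  fr <- r - r0; fc <- c_ - c0
  val <- (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
         fr * (1 - fc) * image[cbind(r0 + 1, c0)] +
         (1 - fr) * fc * image[cbind(r0, c0 + 1)] +
         fr * fc * image[cbind(r0 + 1, c0 + 1)]
  structure(val, step = 1)
}

#' Gaussian fit of a line profile and its FWHM
#'
#' Least-squares fit of `amplitude * exp(-(t - center)^2 / (2 sigma^2)) +
#' baseline` to a sampled profile, reported with
#' `FWHM = 2 sqrt(2 ln 2) * sigma * pitch` in mm — the standard estimate of
#' spatial resolution from the image of a thin absorbing wire. A dip or a
#' peak is detected automatically: the polarity with the larger excursion
#' from the profile median is fitted (a wire in a transmission image dips,
#' so the negated profile is fitted and the amplitude reported negative).
#' Initialization: baseline = median, amplitude = extremum - baseline,
#' center = extremum location, sigma = half the width at half excursion.
#'
#' @param profile Numeric vector (length >= 5) sampled at unit-pixel
#'   spacing, e.g. from [line_profile()].
#' @param pitch Pixel pitch in mm (converts sigma to physical units).
#' @return A `ProfileFit` list: `amplitude`, `center` (pixels), `sigma`
#'   (pixels), `baseline`, `fwhm_mm`, `residual_rms` and the fitted values.
#' @examples
#' t <- 1:41
#' prof <- 2 * exp(-(t - 21)^2 / (2 * 3^2)) + 1
#' fit_gaussian_fwhm(prof, pitch = 0.52)$fwhm_mm  # 2.3548 * 3 * 0.52
#' @export
fit_gaussian_fwhm <- function(profile, pitch = 0.52) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 5) stop("profile must have at least 5 samples")
  base0 <- median(profile)
  i_max <- which.max(profile); i_min <- which.min(profile)
  dip <- abs(profile[i_min] - base0) > abs(profile[i_max] - base0)
  sgn <- if (dip) -1 else 1
  work <- sgn * profile
  base_w <- median(work)
  i_ext <- which.max(work)
  amp0 <- work[i_ext] - base_w
  if (amp0 <= 0 || !is.finite(amp0)) {
    stop("profile has no peak or dip to fit")
  }
  above <- (work - base_w) >= amp0 / 2
  left <- i_ext; while (left > 1 && above[left - 1]) left <- left - 1
  right <- i_ext; while (right < n && above[right + 1]) right <- right + 1
  sigma0 <- max((right - left + 1) / 2, 0.5)
  t <- seq_len(n)
  df <- data.frame(t = t, y = work)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(t - mu)^2 / (2 * s^2)) + b,
                      data = df,
                      start = list(A = amp0, mu = i_ext, s = sigma0, b = base_w),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop(sprintf(paste0("Gaussian fit did not converge (start: A=%.4g, mu=%.4g, ",
                          "s=%.4g, b=%.4g; initial residual RMS=%.4g): %s"),
                   amp0, i_ext, sigma0, base_w,
                   sqrt(mean((work - (amp0 * exp(-(t - i_ext)^2 / (2 * sigma0^2)) + base_w))^2)),
                   conditionMessage(e)))
    })
  p <- coef(fit)
  sigma <- abs(p[["s"]])
  if (sigma <= 0 || !is.finite(sigma)) stop("degenerate Gaussian fit (sigma <= 0)")
  fitted_y <- sgn * predict(fit)
  structure(list(amplitude = sgn * p[["A"]],
                 center = p[["mu"]],
                 sigma = sigma,
                 baseline = sgn * p[["b"]],
                 fwhm_mm = 2 * sqrt(2 * log(2)) * sigma * pitch,
                 residual_rms = sqrt(mean((profile - fitted_y)^2)),
                 fitted = fitted_y,
                 dip = dip),
            class = "fsi_profile_fit")
}

#' @export
print.fsi_profile_fit <- function(x, ...) {
  cat(sprintf("<profile fit> %s: FWHM %.3f mm (sigma %.3f px, center %.2f px), residual RMS %.3g\n",
              if (x$dip) "dip" else "peak", x$fwhm_mm, x$sigma, x$center,
              x$residual_rms))
  invisible(x)
}

#' Mean intensity over a square region of interest
#'
#' Arithmetic mean over a `window x window` pixel block centered at
#' `center` (row, col), the averaging used when reading out per-sample
#' intensities from a reconstruction.
#'
#' @param image Numeric matrix.
#' @param center Integer `c(row, col)` block center.
#' @param window Odd block side length in pixels (default 5).
#' @return Mean intensity (scalar).
#' @export
roi_mean <- function(image, center, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  h <- (window - 1) / 2
  r <- round(center[1]); cc <- round(center[2])
  if (r - h < 1 || r + h > nrow(image) || cc - h < 1 || cc + h > ncol(image)) {
    stop("ROI window clipped by the image border")
  }
  mean(image[(r - h):(r + h), (cc - h):(cc + h)])
}

#' Linear calibration of ROI intensity against concentration
#'
#' Ordinary least squares of mean intensity on concentration, with
#' `R^2 = 1 - SS_res / SS_tot` — the sensitivity calibration performed on a
#' serial-dilution series. The caller selects which points enter the fit
#' (typically the detectable subset).
#'
#' @param concentrations Numeric vector (>= 3 values, not all equal),
#'   nmol/ml.
#' @param intensities ROI mean intensities, same length.
#' @return A `CalibrationFit` list: `slope` (intensity per nmol/ml),
#'   `intercept`, `r_squared`, `roi_means`, `concentrations` and the `lm`
#'   fit object.
#' @export
fit_calibration <- function(concentrations, intensities) {
  stopifnot(length(concentrations) == length(intensities))
  if (length(concentrations) < 3) stop("calibration needs at least 3 points")
  if (diff(range(concentrations)) == 0) {
    stop("calibration concentrations are all equal")
  }
  fit <- lm(y ~ x, data = data.frame(x = concentrations, y = intensities))
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((intensities - mean(intensities))^2)
  # flat response: SS_res = SS_tot = 0, conventionally no variance explained
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 concentrations = concentrations,
                 roi_means = intensities,
                 fit = fit),
            class = "fsi_calibration_fit")
}

#' @export
print.fsi_calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration fit> slope %.4g / (nmol/ml), intercept %.4g, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Detection limit from a dilution series
#'
#' Operationalizes "minimum detectable concentration" as the lowest
#' concentration whose ROI mean exceeds the blank mean by more than three
#' blank-level standard deviations (the usual 3-sigma limit of blank rule).
#'
#' @param concentrations Concentrations of the non-blank wells, nmol/ml.
#' @param intensities Their ROI means.
#' @param blank_mean,blank_sd Mean and standard deviation of the blank
#'   (pure-water) signal.
#' @return The lowest detectable concentration, or `Inf` when none passes.
#' @export
sensitivity_limit <- function(concentrations, intensities, blank_mean, blank_sd) {
  stopifnot(length(concentrations) == length(intensities))
  det <- intensities > blank_mean + 3 * blank_sd
  if (!any(det)) return(Inf)
  min(concentrations[det])
}

#' Depth detectability by contrast-to-noise ratio
#'
#' Computes `CNR = (mean_tube - mean_background) / sd_background` between
#' two disjoint pixel masks of a reconstruction and flags the tube as
#' detectable when CNR meets the threshold (default 5, the Rose criterion
#' for reliable visual detection). The statistic is invariant to affine
#' intensity changes `a * I + b` of the image.
#'
#' @param image Reconstruction matrix.
#' @param tube_mask,background_mask Logical matrices (disjoint, non-empty).
#' @param threshold Detectability threshold on CNR (default 5).
#' @return List with `contrast` (the CNR), `detectable`, `mean_tube`,
#'   `mean_background`, `sd_background`, `threshold`.
#' @export
depth_detectability <- function(image, tube_mask, background_mask, threshold = 5) {
  stopifnot(all(dim(tube_mask) == dim(image)),
            all(dim(background_mask) == dim(image)))
  if (!any(tube_mask) || !any(background_mask)) stop("empty mask")
  if (any(tube_mask & background_mask)) stop("tube and background masks overlap")
  m_t <- mean(image[tube_mask])
  m_b <- mean(image[background_mask])
  s_b <- sd(image[background_mask])
  cnr <- if (s_b == 0) {
    if (m_t == m_b) 0 else Inf * sign(m_t - m_b)
  } else {
    (m_t - m_b) / s_b
  }
  list(contrast = cnr, detectable = is.finite(threshold) && cnr >= threshold,
       mean_tube = m_t, mean_background = m_b, sd_background = s_b,
       threshold = threshold)
}
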