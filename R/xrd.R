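#' Locate expected diffraction peaks in an XRD pattern
#'
#' For each expected 2-theta position, searches for a local intensity maximum
#' within `+/- window` degrees. A position whose window contains no interior
#' local maximum is reported as absent.
#'
#' @param pattern an [xrd_pattern].
#' @param expected_positions expected 2-theta positions, degrees.
#' @param window half-width of the search window, degrees.
#' @return data frame with `expected`, `found` (logical), `position`,
#'   `height`.
#' @export
locate_peaks <- function(pattern, expected_positions, window = 1.0) {
  stopifnot(inherits(pattern, "xrd_pattern"))
  tth <- pattern$two_theta; y <- pattern$intensity
  if (!length(tth)) stop("empty pattern")
  if (any(expected_positions < min(tth) | expected_positions > max(tth)))
    stop("expected positions fall outside the pattern grid")
  out <- data.frame(expected = expected_positions, found = FALSE,
                    position = NA_real_, height = NA_real_)
  # interior local maxima of the full pattern
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  for (i in seq_along(expected_positions)) {
    w <- which(abs(tth - expected_positions[i]) <= window & is_max)
    if (length(w)) {
      j <- w[which.max(y[w])]
      out$found[i] <- TRUE
      out$position[i] <- tth[j]
      out$height[i] <- y[j]
    }
  }
  out
}

#' Segal crystallinity index
#'
#' `CrI = (I_max - I_am) / I_max * 100`, where `I_max` is the intensity of the
#' main crystalline reflection and `I_am` the intensity at the amorphous
#' angle. Intensities are read off the pattern at the nearest grid points.
#'
#' @param pattern an [xrd_pattern].
#' @param crystalline_peak_2theta 2-theta of the main crystalline peak,
#'   degrees (intensity taken as the local maximum within `window`).
#' @param amorphous_2theta 2-theta of the amorphous minimum, degrees
#'   (18.0 for cellulose I; cellulose III has no standard value, 16.0 is a
#'   configurable default).
#' @param window search half-width for the crystalline peak, degrees.
#' @return crystallinity index, percent (0-100).
#' @examples
#' # I_max = 100 and I_am = 7.5 give CrI = 92.5
#' @export
segal_cri <- function(pattern, crystalline_peak_2theta = 23.0,
                      amorphous_2theta = 18.0, window = 1.0) {
  stopifnot(inherits(pattern, "xrd_pattern"))
  tth <- pattern$two_theta; y <- pattern$intensity
  if (crystalline_peak_2theta < min(tth) || crystalline_peak_2theta > max(tth) ||
      amorphous_2theta < min(tth) || amorphous_2theta > max(tth))
    stop("angles must lie on the pattern grid")
  in_win <- abs(tth - crystalline_peak_2theta) <= window
  i_max <- max(y[in_win])
  i_am <- y[which.min(abs(tth - amorphous_2theta))]
  if (i_am > i_max)
    stop("amorphous intensity exceeds crystalline peak intensity (non-physical)")
  (i_max - i_am) / i_max * 100
}

#' Scherrer crystallite size
#'
#' `size = K * lambda / (beta * cos(theta))` with `beta` the peak full width
#' at half maximum in radians and `theta` half the Bragg angle.
#'
#' @param two_theta Bragg angle 2-theta, degrees (0 < 2theta < 180).
#' @param fwhm full width at half maximum, degrees (> 0).
#' @param wavelength X-ray wavelength, nm (Cu K-alpha 0.15418).
#' @param K shape factor (0.9).
#' @return crystallite size, nm.
#' @examples
#' scherrer_size(23.0, 0.90) # about 9.0 nm
#' @export
scherrer_size <- function(two_theta, fwhm, wavelength = 0.15418, K = 0.9) {
  if (fwhm <= 0) stop("fwhm must be positive (zero width implies infinite size)")
  if (two_theta <= 0 || two_theta >= 180) stop("two_theta must lie in (0, 180)")
  beta <- fwhm * pi / 180
  theta <- two_theta / 2 * pi / 180
  K * wavelength / (beta * cos(theta))
}

#' Measure a peak's FWHM by local Gaussian fit
#'
#' Fits `h * exp(-(x - mu)^2 / (2 s^2)) + c` to the pattern within
#' `+/- window` of the peak and returns the implied full width at half
#' maximum (`2 sqrt(2 log 2) s`), which is more noise-robust than raw
#' half-height crossings.
#'
#' @param pattern an [xrd_pattern].
#' @param peak_2theta approximate peak position, degrees.
#' @param window fit half-width, degrees.
#' @return list with `fwhm` (degrees), `position`, `height`.
#' @export
peak_fwhm <- function(pattern, peak_2theta, window = 2.0) {
  stopifnot(inherits(pattern, "xrd_pattern"))
  keep <- abs(pattern$two_theta - peak_2theta) <= window
  if (sum(keep) < 6) stop("too few grid points around the peak")
  x <- pattern$two_theta[keep]; y <- pattern$intensity[keep]
  fit <- minpack.lm::nlsLM(
    y ~ h * exp(-(x - mu)^2 / (2 * s^2)) + c0,
    start = list(h = max(y) - min(y), mu = x[which.max(y)],
                 s = window / 4, c0 = min(y)),
    lower = c(1e-9, min(x), 1e-4, -Inf),
    upper = c(Inf, max(x), window, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  list(fwhm = 2 * sqrt(2 * log(2)) * unname(cf["s"]),
       position = unname(cf["mu"]),
       height = unname(cf["h"]))
}
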