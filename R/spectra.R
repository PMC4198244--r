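#' Default wavelength grid
#'
#' The working wavelength grid for all spectra and sensitivity curves:
#' 300--700 nm at 1 nm. The lower bound extends into the ultraviolet because
#' avian single cones (and the UV camera channel) respond below 400 nm.
#'
#' @param from,to,by grid limits and step in nanometres.
#' @return Numeric vector of wavelengths (nm), strictly increasing.
#' @export
wavelength_grid <- function(from = 300, to = 700, by = 1) {
  stopifnot(from < to, by > 0)
  seq(from, to, by = by)
}

#' Construct a reflectance spectrum
#'
#' @param reflectance numeric vector of unitless reflectance values in [0, 1].
#' @param wavelength_nm wavelength grid, same length, strictly increasing.
#' @return An object of class `refl_spectrum`.
#' @export
reflectance_spectrum <- function(reflectance, wavelength_nm = wavelength_grid()) {
  if (length(reflectance) != length(wavelength_nm))
    stop("reflectance and wavelength grids differ in length", call. = FALSE)
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(reflectance)) || any(reflectance < 0) || any(reflectance > 1))
    stop("reflectance values must be finite and within [0, 1]", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, reflectance = reflectance),
            class = "refl_spectrum")
}

#' Flat (spectrally neutral) reflectance spectrum
#'
#' @param level reflectance in [0, 1].
#' @inheritParams reflectance_spectrum
#' @export
flat_spectrum <- function(level, wavelength_nm = wavelength_grid()) {
  reflectance_spectrum(rep(level, length(wavelength_nm)), wavelength_nm)
}

#' @export
print.refl_spectrum <- function(x, ...) {
  cat(sprintf("<refl_spectrum> %d--%d nm (%d samples), mean reflectance %.3f\n",
              min(x$wavelength_nm), max(x$wavelength_nm),
              length(x$wavelength_nm), mean(x$reflectance)))
  invisible(x)
}

#' Construct a sensitivity curve
#'
#' A nonnegative spectral weighting function (photoreceptor sensitivity,
#' camera channel sensitivity, or illuminant spectral radiance) on the
#' working grid. Curves need not be normalised: quantum-catch integrals
#' normalise against the perfect reflector.
#'
#' @param value nonnegative numeric vector.
#' @inheritParams reflectance_spectrum
#' @param label optional channel name.
#' @export
sensitivity_curve <- function(value, wavelength_nm = wavelength_grid(), label = "") {
  if (length(value) != length(wavelength_nm))
    stop("value and wavelength grids differ in length", call. = FALSE)
  if (any(!is.finite(value)) || any(value < 0))
    stop("sensitivity values must be finite and nonnegative", call. = FALSE)
  if (sum(value) <= 0)
    stop("sensitivity curve must integrate to a positive value", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, value = value, label = label),
            class = "sensitivity_curve")
}

# CIE standard illuminant D65 relative spectral power, 300-700 nm at 5 nm
# (standard published table; interpolated to the working grid on demand).
d65_wl_5nm <- seq(300, 700, by = 5)
d65_power_5nm <- c(
  0.0341, 1.6643, 3.2945, 11.7652, 20.2360, 28.6447, 37.0535, 38.5011,
  39.9488, 42.4302, 44.9117, 45.7750, 46.6383, 49.3637, 52.0891, 51.0323,
  49.9755, 52.3118, 54.6482, 68.7015, 82.7549, 87.1204, 91.4860, 92.4589,
  93.4318, 90.0570, 86.6823, 95.7736, 104.8650, 110.9360, 117.0080,
  117.4100, 117.8120, 116.3360, 114.8610, 115.3920, 115.9230, 112.3670,
  108.8110, 109.0820, 109.3540, 108.5780, 107.8020, 106.2960, 104.7900,
  106.2390, 107.6890, 106.0470, 104.4050, 104.2250, 104.0460, 102.0230,
  100.0000, 98.1671, 96.3342, 96.0611, 95.7880, 92.2368, 88.6856,
  89.3459, 90.0062, 89.8026, 89.5991, 88.6489, 87.6987, 85.4936,
  83.2886, 83.4939, 83.6992, 81.8630, 80.0268, 80.1207, 80.2146,
  81.2462, 82.2778, 80.2810, 78.2842, 74.0027, 69.7213, 70.6652, 71.6091)

#' CIE D65 daylight illuminant on the working grid
#'
#' Relative spectral power of standard illuminant D65, linearly interpolated
#' from the published 5 nm table. Used as the single reference illuminant for
#' scene synthesis and quantum-catch integrals; equalization against the
#' in-frame grey standard cancels illuminant intensity downstream, so only
#' the spectral shape matters.
#'
#' @inheritParams reflectance_spectrum
#' @return A `sensitivity_curve`.
#' @export
illuminant_d65 <- function(wavelength_nm = wavelength_grid()) {
  v <- stats::approx(d65_wl_5nm, d65_power_5nm, xout = wavelength_nm,
                     rule = 2)$y
  sensitivity_curve(v, wavelength_nm, label = "D65")
}

#' Visual pigment absorbance template
#'
#' Standard A1 rhodopsin absorbance template (alpha band plus beta band)
#' parameterised by the wavelength of maximum absorbance. Used to generate
#' photoreceptor sensitivity curves when measured curves are not supplied.
#'
#' @param lambda_max wavelength of peak absorbance (nm).
#' @inheritParams reflectance_spectrum
#' @param beta include the short-wavelength beta band.
#' @return A `sensitivity_curve` with peak value 1.
#' @export
pigment_template <- function(lambda_max, wavelength_nm = wavelength_grid(),
                             beta = TRUE) {
  stopifnot(lambda_max > 0)
  x <- lambda_max / wavelength_nm
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  s <- alpha
  if (beta) {
    lmb <- 189 + 0.315 * lambda_max
    b <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((wavelength_nm - lmb) / b)^2)
  }
  s <- pmin(s, 1)
  sensitivity_curve(s, wavelength_nm)
}

#' Smooth random reflectance spectra library
#'
#' Generates `n` smooth reflectance spectra as sums of positive Gaussian
#' bumps clipped to [0, 1], plus flat spectra at each grey-standard
#' reflectance. Natural reflectance spectra are smooth at the scale of tens
#' of nanometres, so bump widths default to 30--80 nm. The library is the
#' training set for the camera-to-cone polynomial mapping.
#'
#' @param n number of random spectra (>= 1).
#' @param seed integer seed; generation is bit-reproducible.
#' @param smoothness mean Gaussian bump width (nm); widths are drawn
#'   uniformly in `smoothness * c(0.55, 1.45)`.
#' @param standards numeric vector of flat reflectances appended to the
#'   library (default the eight-standard ladder).
#' @inheritParams reflectance_spectrum
#' @return List of `refl_spectrum` of length `n + length(standards)`;
#'   flat standards come last.
#' @export
make_spectral_library <- function(n, seed = 1, smoothness = 55,
                                  standards = grey_standard_set()$reflectances,
                                  wavelength_nm = wavelength_grid()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a count >= 1", call. = FALSE)
  n <- as.integer(n)
  out <- vector("list", n)
  set.seed(as.integer(seed))
  for (i in seq_len(n)) {
    nb <- sample(2:6, 1)
    centre <- stats::runif(nb, min(wavelength_nm) - 40, max(wavelength_nm) + 40)
    width <- stats::runif(nb, smoothness * 0.55, smoothness * 1.45)
    amp <- stats::runif(nb, 0.05, 0.55)
    base <- stats::runif(1, 0.02, 0.25)
    r <- rep(base, length(wavelength_nm))
    for (b in seq_len(nb))
      r <- r + amp[b] * exp(-((wavelength_nm - centre[b]) / width[b])^2)
    out[[i]] <- reflectance_spectrum(pmin(pmax(r, 0), 1), wavelength_nm)
  }
  c(out, lapply(standards, flat_spectrum, wavelength_nm = wavelength_nm))
}

#' Colour-change trajectory
#'
#' A programmed per-wavelength exponential approach from a start spectrum to
#' a target spectrum. The default rate of 1.61 per minute closes 80% of the
#' gap within the first minute, emulating colour change that is mostly
#' complete after one minute.
#'
#' @param start_spectrum,target_spectrum `refl_spectrum` on the same grid.
#' @param rate_per_min positive exponential rate (1/min).
#' @export
colour_change_trajectory <- function(start_spectrum, target_spectrum,
                                     rate_per_min = 1.61) {
  stopifnot(inherits(start_spectrum, "refl_spectrum"),
            inherits(target_spectrum, "refl_spectrum"))
  if (!identical(start_spectrum$wavelength_nm, target_spectrum$wavelength_nm))
    stop("start and target spectra are on different grids", call. = FALSE)
  if (!is.numeric(rate_per_min) || rate_per_min <= 0)
    stop("rate_per_min must be positive", call. = FALSE)
  structure(list(start_spectrum = start_spectrum,
                 target_spectrum = target_spectrum,
                 rate_per_min = rate_per_min),
            class = "colour_change_trajectory")
}

#' Fish reflectance at a given time along a trajectory
#'
#' Per wavelength: `start + (target - start) * (1 - exp(-rate * t))`.
#'
#' @param traj a `colour_change_trajectory`.
#' @param t_min elapsed time in minutes, >= 0.
#' @return A `refl_spectrum`.
#' @export
fish_spectrum_at <- function(traj, t_min) {
  stopifnot(inherits(traj, "colour_change_trajectory"))
  if (!is.numeric(t_min) || length(t_min) != 1 || t_min < 0)
    stop("t_min must be a nonnegative scalar", call. = FALSE)
  f <- 1 - exp(-traj$rate_per_min * t_min)
  r <- traj$start_spectrum$reflectance +
    (traj$target_spectrum$reflectance - traj$start_spectrum$reflectance) * f
  reflectance_spectrum(pmin(pmax(r, 0), 1), traj$start_spectrum$wavelength_nm)
}
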