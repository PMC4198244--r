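#' Fit per-channel linearization curves from grey-standard responses
#'
#' Characterises the camera's response nonlinearity from its mean responses
#' to a ladder of flat grey reflectance standards, fitting per channel
#' `response = a * R^b + c` by least squares. The inverse of the fitted
#' curve maps camera response back to linear intensity. The form subsumes
#' the identity camera (a = 1, b = 1, c = 0) and any pure power-law
#' (gamma) response.
#'
#' @param responses matrix of mean responses, one row per standard, columns
#'   named lw, mw, sw, uv (as from [photograph_standards()]).
#' @param standards a `grey_standard_set` giving the row reflectances.
#' @param r2_warn warn (and record) if any channel R-squared falls below
#'   this value.
#' @return A `linearization_curve`: per channel the coefficients (a, b, c),
#'   R-squared, and the fitted response range.
#' @export
fit_linearization <- function(responses, standards, r2_warn = 0.99) {
  stopifnot(inherits(standards, "grey_standard_set"))
  R <- standards$reflectances
  if (length(R) < 3) stop("need at least 3 standards", call. = FALSE)
  if (nrow(responses) != length(R))
    stop("responses rows must match the standards", call. = FALSE)
  chans <- colnames(responses)
  fits <- lapply(chans, function(ch) {
    r <- responses[, ch]
    if (any(diff(r) <= 0))
      stop(sprintf(
        "calibration failure: responses not increasing with reflectance in channel %s",
        ch), call. = FALSE)
    # log-log slope of the response seeds b
    b0 <- stats::coef(stats::lm(log(r) ~ log(R)))[[2]]
    b0 <- min(max(b0, 0.15), 3)
    resid_fn <- function(p) p[["a"]] * R^p[["b"]] + p[["c"]] - r
    fit <- minpack.lm::nls.lm(
      par = list(a = max(r), b = b0, c = 0), fn = resid_fn,
      lower = c(a = 1e-8, b = 0.05, c = -0.5),
      upper = c(a = 10, b = 5, c = 0.5),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- fit$par
    pred <- cf[["a"]] * R^cf[["b"]] + cf[["c"]]
    r2 <- 1 - sum((r - pred)^2) / sum((r - mean(r))^2)
    list(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]], r2 = r2,
         response_range = range(r), reflectance_range = range(R))
  })
  names(fits) <- chans
  low <- vapply(fits, function(f) f$r2, numeric(1)) < r2_warn
  if (any(low))
    warning(sprintf("linearization R^2 below %.2f in channel(s): %s",
                    r2_warn, paste(chans[low], collapse = ", ")),
            call. = FALSE)
  structure(list(channels = fits, quality_flag = any(low)),
            class = "linearization_curve")
}

invert_linearization <- function(r, f) {
  # inverse of response = a*R^b + c on the fitted range
  x <- (r - f$c) / f$a
  x <- pmax(x, 0)
  x^(1 / f$b)
}

#' Apply linearization to a raw stack
#'
#' Maps every pixel through the inverse of its channel's fitted response
#' curve, yielding linear-intensity images. Responses outside the fitted
#' range are clamped to it (geometry must be preserved, so nothing is
#' dropped) and the clamped pixels are counted per channel.
#'
#' @param stack a `raw_image_stack`.
#' @param curve a `linearization_curve` fitted for all four channels.
#' @return A `linear_image_stack` with `channels`, the carried-over regions,
#'   and `clamp_report` (named counts of clamped pixels).
#' @export
apply_linearization <- function(stack, curve) {
  stopifnot(inherits(stack, "raw_image_stack"),
            inherits(curve, "linearization_curve"))
  chans <- names(stack$channels)
  if (!all(chans %in% names(curve$channels)))
    stop("curve not fitted for all channels", call. = FALSE)
  clamp <- integer(length(chans)); names(clamp) <- chans
  out <- lapply(chans, function(ch) {
    f <- curve$channels[[ch]]
    img <- stack$channels[[ch]]
    lo <- f$response_range[1]; hi <- f$response_range[2]
    clamp[ch] <<- sum(img < lo | img > hi)
    invert_linearization(pmin(pmax(img, lo), hi), f)
  })
  names(out) <- chans
  structure(list(channels = out, fish_region = stack$fish_region,
                 standard_region = stack$standard_region,
                 background_region = stack$background_region,
                 standard_reflectance = stack$standard_reflectance,
                 clamp_report = clamp, metadata = stack$metadata),
            class = "linear_image_stack")
}

#' Equalize a linear stack to its in-frame grey standard
#'
#' Rescales each channel so the mean over the standard region equals the
#' standard's known reflectance, putting all channels on a common
#' reflectance scale (1.0 = 100% reflectance) and cancelling illuminant
#' intensity. Idempotent, and invariant to any positive global scaling of
#' the input.
#'
#' @param linear_stack a `linear_image_stack` (or any stack of linear
#'   channels with a `standard_region`).
#' @param standard_region optional `region_mask` overriding the stack's own.
#' @param standard_reflectance target reflectance of the standard
#'   (default taken from the stack, normally 0.40).
#' @return A `calibrated_image_stack` with reflectance-scale channels and an
#'   `equalization` provenance record (per-channel scale factors).
#' @export
equalize_to_standard <- function(linear_stack, standard_region = NULL,
                                 standard_reflectance = NULL) {
  std <- if (is.null(standard_region)) linear_stack$standard_region
         else standard_region
  target <- if (is.null(standard_reflectance))
    linear_stack$standard_reflectance else standard_reflectance
  stopifnot(inherits(std, "region_mask"))
  scales <- vapply(linear_stack$channels, function(img) {
    m <- mean(img[std$mask])
    if (!is.finite(m) || m <= 0)
      stop("calibration failure: zero mean over standard region",
           call. = FALSE)
    target / m
  }, numeric(1))
  out <- Map(function(img, s) img * s, linear_stack$channels, scales)
  structure(list(channels = out, fish_region = linear_stack$fish_region,
                 standard_region = std,
                 background_region = linear_stack$background_region,
                 standard_reflectance = target,
                 equalization = scales,
                 clamp_report = linear_stack$clamp_report,
                 metadata = linear_stack$metadata),
            class = "calibrated_image_stack")
}

#' Calibrate a raw stack end to end
#'
#' Convenience wrapper: linearize then equalize.
#'
#' @inheritParams apply_linearization
#' @export
calibrate_stack <- function(stack, curve) {
  equalize_to_standard(apply_linearization(stack, curve))
}

#' Ratio-scale midpoint of two reflectances
#'
#' The mid grey between a dark and a light substrate on a ratio scale: the
#' geometric mean, the unique value whose ratio to the low end equals the
#' high end's ratio to it.
#'
#' @param low_reflectance,high_reflectance reflectances with
#'   0 < low < high <= 1.
#' @return `sqrt(low * high)`.
#' @export
ratio_scale_midpoint <- function(low_reflectance, high_reflectance) {
  if (!is.numeric(low_reflectance) || !is.numeric(high_reflectance) ||
      low_reflectance <= 0 || high_reflectance > 1 ||
      low_reflectance >= high_reflectance)
    stop("need 0 < low < high <= 1", call. = FALSE)
  sqrt(low_reflectance * high_reflectance)
}

#' Match the camera brightness of one spectrum to another
#'
#' Scales spectrum B so that its mean catch over the visible camera
#' channels (LW, MW, SW; UV deliberately excluded) equals spectrum A's,
#' for building colour pairs of equal average brightness.
#'
#' @param spectrum_a reference `refl_spectrum`.
#' @param spectrum_b spectrum to rescale.
#' @param camera a `camera_model`.
#' @param illuminant illuminant curve.
#' @return The rescaled spectrum B, with attribute `scale` giving the
#'   factor applied.
#' @export
match_brightness <- function(spectrum_a, spectrum_b, camera,
                             illuminant = illuminant_d65()) {
  vis <- c("lw", "mw", "sw")
  qa <- mean(camera_catches(spectrum_a, camera, illuminant)[vis])
  qb <- mean(camera_catches(spectrum_b, camera, illuminant)[vis])
  if (qb <= 0) stop("spectrum_b has zero visible catch", call. = FALSE)
  s <- qa / qb
  if (max(spectrum_b$reflectance) * s > 1 + 1e-12)
    stop(sprintf(
      "infeasible match: scale %.3f pushes reflectance above 1", s),
      call. = FALSE)
  out <- reflectance_spectrum(pmin(spectrum_b$reflectance * s, 1),
                              spectrum_b$wavelength_nm)
  attr(out, "scale") <- s
  out
}
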