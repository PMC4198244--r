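#' Avian receiver model
#'
#' The visual model of the assumed predator: five photoreceptor
#' sensitivities (four single cones uv, sw, mw, lw and the double cone that
#' drives achromatic vision), the relative cone proportions in the retina,
#' the Weber fraction of the most abundant cone type, and the illuminant.
#'
#' The default sensitivities are generated from A1 pigment templates with
#' peak wavelengths typical of a violet-sensitive bird (peafowl-like:
#' 432, 477, 537, 605 nm single cones; 565 nm effective double-cone peak),
#' and are swappable for measured curves via `sensitivities` or
#' [read_receiver_csv()]. Default cone proportions are lw 0.95, mw 1.00,
#' sw 0.86, uv 0.45 with Weber fraction 0.05 for the most abundant (mw)
#' cone.
#'
#' @param sensitivities named list of five `sensitivity_curve` (uv, sw, mw,
#'   lw, dbl); by default built from pigment templates.
#' @param cone_proportions named positive numeric (lw, mw, sw, uv).
#' @param weber_fraction Weber fraction of the most abundant cone, in (0,1).
#' @param illuminant a `sensitivity_curve`.
#' @param lambda_max_nm template peaks used when `sensitivities` is NULL.
#' @inheritParams reflectance_spectrum
#' @return An object of class `receiver_model`.
#' @export
receiver_model <- function(sensitivities = NULL,
                           cone_proportions = c(lw = 0.95, mw = 1.00,
                                                sw = 0.86, uv = 0.45),
                           weber_fraction = 0.05,
                           illuminant = illuminant_d65(wavelength_nm),
                           lambda_max_nm = c(uv = 432, sw = 477, mw = 537,
                                             lw = 605, dbl = 565),
                           wavelength_nm = wavelength_grid()) {
  if (any(cone_proportions <= 0))
    stop("cone proportions must be positive", call. = FALSE)
  if (weber_fraction <= 0 || weber_fraction >= 1)
    stop("weber_fraction must lie in (0, 1)", call. = FALSE)
  if (sum(cone_proportions == max(cone_proportions)) != 1)
    stop("exactly one cone type must be the most abundant", call. = FALSE)
  if (is.null(sensitivities)) {
    sensitivities <- lapply(lambda_max_nm, pigment_template,
                            wavelength_nm = wavelength_nm)
    names(sensitivities) <- names(lambda_max_nm)
  }
  stopifnot(all(c("uv", "sw", "mw", "lw", "dbl") %in% names(sensitivities)))
  structure(list(sensitivities = sensitivities,
                 cone_proportions = cone_proportions,
                 weber_fraction = weber_fraction,
                 illuminant = illuminant),
            class = "receiver_model")
}

#' Read / write a receiver sensitivity table
#'
#' CSV with a wavelength column plus five sensitivity columns (uv, sw, mw,
#' lw, dbl), so measured curves can replace the packaged templates.
#'
#' @param path CSV path.
#' @param ... passed to [receiver_model()].
#' @export
read_receiver_csv <- function(path, ...) {
  tab <- utils::read.csv(path)
  wl <- tab$wavelength_nm
  sens <- lapply(c("uv", "sw", "mw", "lw", "dbl"), function(ch)
    sensitivity_curve(tab[[ch]], wl, label = ch))
  names(sens) <- c("uv", "sw", "mw", "lw", "dbl")
  receiver_model(sensitivities = sens, wavelength_nm = wl, ...)
}

#' @rdname read_receiver_csv
#' @param receiver a `receiver_model`.
#' @export
write_receiver_csv <- function(receiver, path) {
  wl <- receiver$sensitivities$uv$wavelength_nm
  tab <- data.frame(wavelength_nm = wl)
  for (ch in c("uv", "sw", "mw", "lw", "dbl"))
    tab[[ch]] <- receiver$sensitivities[[ch]]$value
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Quantum catch of a photoreceptor
#'
#' The photon catch of a receptor viewing a reflecting surface:
#' `q = sum(R * I * S) / sum(I * S)` over the shared wavelength grid,
#' normalised so a perfect (100%) reflector yields 1. Linear in the
#' reflectance spectrum and invariant to rescaling the illuminant.
#'
#' @param spectrum a `refl_spectrum`.
#' @param sensitivity receptor `sensitivity_curve`.
#' @param illuminant illuminant `sensitivity_curve`.
#' @return Nonnegative scalar catch.
#' @export
quantum_catch <- function(spectrum, sensitivity, illuminant) {
  if (!identical(spectrum$wavelength_nm, sensitivity$wavelength_nm) ||
      !identical(spectrum$wavelength_nm, illuminant$wavelength_nm))
    stop("spectrum, sensitivity and illuminant grids differ", call. = FALSE)
  w <- illuminant$value * sensitivity$value
  sum(spectrum$reflectance * w) / sum(w)
}

#' Receiver quantum catches of a spectrum
#'
#' @param spectrum a `refl_spectrum`.
#' @param receiver a `receiver_model`.
#' @return A `quantum_catch_set`: named numeric (uv, sw, mw, lw, dbl).
#' @export
receiver_catches <- function(spectrum, receiver) {
  q <- vapply(receiver$sensitivities, function(s)
    quantum_catch(spectrum, s, receiver$illuminant), numeric(1))
  structure(q, class = "quantum_catch_set")
}

poly_term_exponents <- function(n_vars, degree) {
  # all monomial exponent vectors with total degree <= degree (incl. intercept)
  grid <- as.matrix(expand.grid(rep(list(0:degree), n_vars)))
  grid <- grid[rowSums(grid) <= degree, , drop = FALSE]
  grid[order(rowSums(grid), apply(grid, 1, paste, collapse = "")), ,
       drop = FALSE]
}

poly_design <- function(X, exponents) {
  # X: n x 4 camera catches; returns n x n_terms monomial design matrix
  n <- nrow(X)
  D <- matrix(1, n, nrow(exponents))
  for (j in seq_len(nrow(exponents)))
    for (v in seq_len(ncol(exponents)))
      if (exponents[j, v] > 0) D[, j] <- D[, j] * X[, v]^exponents[j, v]
  D
}

#' Fit the camera-to-cone polynomial mapping
#'
#' Least-squares fit, per cone class, of receiver quantum catches on all
#' monomials of the four camera-channel catches up to the given degree
#' (intercept and interactions included). Trained on a spectral library:
#' each spectrum contributes its camera catches (predictors) and its
#' receiver catches (responses). Training R-squared is recorded per cone
#' and a warning raised if any falls below `r2_warn`.
#'
#' @param library list of `refl_spectrum`.
#' @param camera a `camera_model`.
#' @param receiver a `receiver_model`.
#' @param degree polynomial degree (default 2).
#' @param r2_warn warning threshold on training R-squared.
#' @return A `cone_map`: per-cone coefficients, the exponent table, camera
#'   channel order, and per-cone R-squared.
#' @export
fit_cone_map <- function(library, camera, receiver, degree = 2,
                         r2_warn = 0.99) {
  exponents <- poly_term_exponents(4, degree)
  if (length(library) < 10 * nrow(exponents))
    stop(sprintf("fit failure: library of %d spectra < 10 x %d terms",
                 length(library), nrow(exponents)), call. = FALSE)
  chans <- c("lw", "mw", "sw", "uv")
  X <- t(vapply(library, function(s)
    camera_catches(s, camera, receiver$illuminant)[chans], numeric(4)))
  Y <- t(vapply(library, function(s)
    unclass(receiver_catches(s, receiver)), numeric(5)))
  D <- poly_design(X, exponents)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("fit failure: rank-deficient polynomial design", call. = FALSE)
  coefs <- qr.coef(qrD, Y)
  pred <- D %*% coefs
  r2 <- vapply(seq_len(ncol(Y)), function(j)
    1 - sum((Y[, j] - pred[, j])^2) / sum((Y[, j] - mean(Y[, j]))^2),
    numeric(1))
  names(r2) <- colnames(Y)
  low <- r2 < r2_warn
  if (any(low))
    warning(sprintf("cone-map training R^2 below %.2f for cone(s): %s",
                    r2_warn, paste(names(r2)[low], collapse = ", ")),
            call. = FALSE)
  structure(list(coefficients = coefs, exponents = exponents,
                 camera_channels = chans, degree = degree, r2 = r2),
            class = "cone_map")
}

#' Predict receiver catches from camera catches
#'
#' @param map a `cone_map`.
#' @param camera_q matrix (n x 4) or named vector of camera catches
#'   (lw, mw, sw, uv).
#' @return Matrix (n x 5) of predicted cone catches, negatives clamped to 0
#'   (clamp count in attribute `n_clamped`).
#' @export
predict_cone_map <- function(map, camera_q) {
  if (is.null(dim(camera_q)))
    camera_q <- matrix(camera_q[map$camera_channels], nrow = 1,
                       dimnames = list(NULL, map$camera_channels))
  D <- poly_design(camera_q[, map$camera_channels, drop = FALSE],
                   map$exponents)
  pred <- D %*% map$coefficients
  n_clamped <- sum(pred < 0)
  pred[pred < 0] <- 0
  attr(pred, "n_clamped") <- n_clamped
  pred
}

#' Apply a cone map to a calibrated image stack
#'
#' Per-pixel polynomial evaluation producing a five-plane cone-catch image
#' (uv, sw, mw, lw, dbl). Negative predictions are clamped to 0 and counted.
#'
#' @param stack a `calibrated_image_stack`.
#' @param map a fitted `cone_map`.
#' @return A `cone_image`: list of five matrices plus carried-over regions
#'   and `n_clamped`.
#' @export
apply_cone_map <- function(stack, map) {
  dims <- dim(stack$channels[[1]])
  if (!all(vapply(stack$channels, function(m)
    identical(dim(m), dims), logical(1))))
    stop("channel shape mismatch", call. = FALSE)
  X <- vapply(map$camera_channels, function(ch) as.vector(stack$channels[[ch]]),
              numeric(prod(dims)))
  pred <- predict_cone_map(map, X)
  planes <- lapply(seq_len(ncol(pred)), function(j)
    matrix(pred[, j], dims[1], dims[2]))
  names(planes) <- colnames(pred)
  structure(list(planes = planes, fish_region = stack$fish_region,
                 standard_region = stack$standard_region,
                 background_region = stack$background_region,
                 n_clamped = attr(pred, "n_clamped"),
                 metadata = stack$metadata),
            class = "cone_image")
}

#' Mean cone catches over a region of interest
#'
#' Arithmetic mean of each cone plane over the mask pixels — one quantum
#' catch set per fish (or background) per image, matching whole-body
#' averaging.
#'
#' @param cone_image a `cone_image`.
#' @param mask a `region_mask`.
#' @return A `quantum_catch_set` (uv, sw, mw, lw, dbl).
#' @export
roi_mean_catch <- function(cone_image, mask) {
  stopifnot(inherits(mask, "region_mask"))
  if (!identical(dim(cone_image$planes[[1]]), dim(mask$mask)))
    stop("mask shape mismatch", call. = FALSE)
  if (!any(mask$mask)) stop("empty mask", call. = FALSE)
  q <- vapply(cone_image$planes, function(p) mean(p[mask$mask]), numeric(1))
  structure(q, class = "quantum_catch_set")
}
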