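#' Simulated multispectral camera
#'
#' Four-channel (LW, MW, SW, UV) camera with Gaussian channel sensitivities,
#' a power-law response nonlinearity, a gain, and additive Gaussian noise
#' applied after the nonlinearity. The default gamma of 2.2 makes the
#' linearization stage non-trivial, as with consumer camera responses.
#'
#' @param peaks_nm named peak wavelengths for channels lw, mw, sw, uv.
#' @param width_nm Gaussian sigma of each channel (nm).
#' @param response_gamma power-law exponent: response = gain * catch^(1/gamma).
#' @param gain positive multiplicative gain on the response scale.
#' @param noise_sd standard deviation of additive post-nonlinearity noise
#'   (response units on a 0--1 scale).
#' @inheritParams reflectance_spectrum
#' @return An object of class `camera_model` with a `channel_sensitivities`
#'   list named lw, mw, sw, uv.
#' @export
camera_model <- function(peaks_nm = c(lw = 600, mw = 530, sw = 460, uv = 370),
                         width_nm = 55, response_gamma = 2.2, gain = 1,
                         noise_sd = 0, wavelength_nm = wavelength_grid()) {
  stopifnot(response_gamma > 0, gain > 0, noise_sd >= 0)
  ch <- c("lw", "mw", "sw", "uv")
  stopifnot(all(ch %in% names(peaks_nm)))
  sens <- lapply(ch, function(nm) {
    sensitivity_curve(exp(-((wavelength_nm - peaks_nm[[nm]]) / width_nm)^2),
                      wavelength_nm, label = nm)
  })
  names(sens) <- ch
  structure(list(channel_sensitivities = sens, response_gamma = response_gamma,
                 gain = gain, noise_sd = noise_sd,
                 wavelength_nm = wavelength_nm),
            class = "camera_model")
}

#' Grey reflectance standard ladder
#'
#' The set of flat-spectrum reflectance standards used to characterise the
#' camera response curve, spanning 2--99% reflectance. The 40% standard must
#' be present: every scene carries one in frame for equalization.
#'
#' @param reflectances strictly increasing values in (0, 1], length >= 2,
#'   containing 0.40.
#' @export
grey_standard_set <- function(reflectances = c(0.02, 0.05, 0.10, 0.20,
                                               0.40, 0.60, 0.80, 0.99)) {
  if (length(reflectances) < 2 || any(diff(reflectances) <= 0))
    stop("need >= 2 strictly increasing standard reflectances", call. = FALSE)
  if (any(reflectances <= 0) || any(reflectances > 1))
    stop("standard reflectances must lie in (0, 1]", call. = FALSE)
  if (!any(abs(reflectances - 0.40) < 1e-12))
    stop("the 40% equalization standard must be included", call. = FALSE)
  structure(list(reflectances = reflectances), class = "grey_standard_set")
}

#' Experimental scene plan
#'
#' The design of one background-matching experiment: two backgrounds, a
#' number of fish per background, and the photography time points.
#'
#' @param experiment_id 1 (black/white brightness experiment) or
#'   2 (red/blue colour experiment).
#' @param backgrounds named list of two `refl_spectrum` (names are the
#'   background labels; list order defines the first sample in
#'   rank-sum tests).
#' @param n_fish_per_background fish per background (default 20).
#' @param timepoints_min photography times in minutes, starting at 0,
#'   strictly increasing (default 0, 1, 10, 60).
#' @param seed integer seed for scene synthesis.
#' @export
scene_plan <- function(experiment_id, backgrounds, n_fish_per_background = 20,
                       timepoints_min = c(0, 1, 10, 60), seed = 1) {
  stopifnot(experiment_id %in% c(1, 2))
  if (length(backgrounds) != 2 || is.null(names(backgrounds)) ||
      any(!vapply(backgrounds, inherits, TRUE, "refl_spectrum")))
    stop("backgrounds must be two named refl_spectrum", call. = FALSE)
  if (timepoints_min[1] != 0 || any(diff(timepoints_min) <= 0))
    stop("timepoints must start at 0 and be strictly increasing", call. = FALSE)
  stopifnot(n_fish_per_background >= 1)
  structure(list(experiment_id = experiment_id, backgrounds = backgrounds,
                 n_fish_per_background = as.integer(n_fish_per_background),
                 timepoints_min = timepoints_min, seed = as.integer(seed)),
            class = "scene_plan")
}

#' Camera quantum catches of a spectrum
#'
#' The four camera-channel catches of a reflectance spectrum under an
#' illuminant, each normalised to the perfect reflector.
#'
#' @param spectrum a `refl_spectrum`.
#' @param camera a `camera_model`.
#' @param illuminant a `sensitivity_curve`.
#' @return Named numeric vector (lw, mw, sw, uv) in [0, 1].
#' @export
camera_catches <- function(spectrum, camera, illuminant = illuminant_d65()) {
  vapply(camera$channel_sensitivities, function(s)
    quantum_catch(spectrum, s, illuminant), numeric(1))
}

camera_response <- function(catch, camera) {
  camera$gain * catch^(1 / camera$response_gamma)
}

new_region_mask <- function(mask, label) {
  if (!any(mask)) stop("region mask has no pixels", call. = FALSE)
  structure(list(mask = mask, label = label), class = "region_mask")
}

#' Elliptical, rectangular and complement region masks
#'
#' Helpers building the flat scene geometry: a fish ellipse in the image
#' centre, a standard square in a corner, and the background as everything
#' else.
#'
#' @param nrow,ncol image dimensions in pixels.
#' @param label mask label.
#' @return A `region_mask` (logical matrix plus label).
#' @export
ellipse_mask <- function(nrow, ncol, label = "fish") {
  r <- row(matrix(0, nrow, ncol)); c <- col(matrix(0, nrow, ncol))
  cy <- (nrow + 1) / 2; cx <- (ncol + 1) / 2
  m <- ((r - cy) / (nrow * 0.22))^2 + ((c - cx) / (ncol * 0.32))^2 <= 1
  new_region_mask(m, label)
}

#' @rdname ellipse_mask
#' @param side side length of the standard square (pixels).
#' @export
corner_square_mask <- function(nrow, ncol, side = max(4L, nrow %/% 6L),
                               label = "standard") {
  m <- matrix(FALSE, nrow, ncol)
  m[seq_len(side), seq_len(side)] <- TRUE
  new_region_mask(m, label)
}

#' Render one raw image stack
#'
#' Renders a flat scene (background field, fish ellipse, 40% grey standard
#' square) through the simulated camera: per channel, response =
#' `gain * catch^(1/gamma)` plus additive Gaussian pixel noise.
#'
#' @param fish_spectrum,background_spectrum,standard_spectrum reflectance
#'   spectra of the three regions.
#' @param camera a `camera_model`.
#' @param illuminant illuminant `sensitivity_curve`.
#' @param nrow,ncol image size (pixels).
#' @param standard_reflectance nominal reflectance of the in-frame standard.
#' @param metadata list carried through to the stack.
#' @return A `raw_image_stack`: `channels` (named list of matrices, lw, mw,
#'   sw, uv), `fish_region`, `standard_region`, `background_region`,
#'   `standard_reflectance`, `metadata`.
#' @export
render_stack <- function(fish_spectrum, background_spectrum,
                         standard_spectrum = flat_spectrum(0.40,
                           fish_spectrum$wavelength_nm),
                         camera, illuminant = illuminant_d65(),
                         nrow = 48, ncol = 48,
                         standard_reflectance = 0.40, metadata = list()) {
  fish <- ellipse_mask(nrow, ncol)
  std <- corner_square_mask(nrow, ncol)
  bg <- new_region_mask(!(fish$mask | std$mask), "background")
  q <- list(fish = camera_catches(fish_spectrum, camera, illuminant),
            std = camera_catches(standard_spectrum, camera, illuminant),
            bg = camera_catches(background_spectrum, camera, illuminant))
  channels <- lapply(names(camera$channel_sensitivities), function(ch) {
    img <- matrix(camera_response(q$bg[[ch]], camera), nrow, ncol)
    img[fish$mask] <- camera_response(q$fish[[ch]], camera)
    img[std$mask] <- camera_response(q$std[[ch]], camera)
    if (camera$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nrow * ncol, 0, camera$noise_sd),
                          nrow, ncol)
    pmin(pmax(img, 0), 1.5)  # responses are bounded; generous headroom
  })
  names(channels) <- names(camera$channel_sensitivities)
  structure(list(channels = channels, fish_region = fish,
                 standard_region = std, background_region = bg,
                 standard_reflectance = standard_reflectance,
                 metadata = metadata),
            class = "raw_image_stack")
}

#' Render a full experimental scene series
#'
#' One raw stack per fish x time point, with per-fish colour-change
#' trajectories, plus a ground-truth table of the true spectra. Fully
#' seeded: the same plan renders bit-identical stacks.
#'
#' @param plan a `scene_plan`.
#' @param trajectories named list (one element per background label) of
#'   lists of `colour_change_trajectory`, one per fish.
#' @param camera a `camera_model`.
#' @param illuminant illuminant curve.
#' @param nrow,ncol image size.
#' @return List with `stacks` (list of `raw_image_stack`) and
#'   `ground_truth` (data.frame: stack index, fish_id, background,
#'   time_min, plus true fish/background spectra stored as a list column).
#' @export
render_scene <- function(plan, trajectories, camera,
                         illuminant = illuminant_d65(),
                         nrow = 48, ncol = 48) {
  stopifnot(inherits(plan, "scene_plan"))
  set.seed(plan$seed)
  stacks <- list()
  rows <- list()
  k <- 0L
  for (bg_name in names(plan$backgrounds)) {
    bg_spec <- plan$backgrounds[[bg_name]]
    for (f in seq_len(plan$n_fish_per_background)) {
      traj <- trajectories[[bg_name]][[f]]
      for (t in plan$timepoints_min) {
        k <- k + 1L
        fs <- fish_spectrum_at(traj, t)
        stacks[[k]] <- render_stack(
          fish_spectrum = fs, background_spectrum = bg_spec,
          camera = camera, illuminant = illuminant,
          nrow = nrow, ncol = ncol,
          metadata = list(fish_id = sprintf("%s_%02d", bg_name, f),
                          background = bg_name, time_min = t,
                          experiment = plan$experiment_id))
        rows[[k]] <- data.frame(
          stack = k, fish_id = sprintf("%s_%02d", bg_name, f),
          background = bg_name, time_min = t,
          experiment = plan$experiment_id)
        rows[[k]]$fish_spectrum <- I(list(fs))
        rows[[k]]$background_spectrum <- I(list(bg_spec))
      }
    }
  }
  list(stacks = stacks, ground_truth = do.call(rbind, rows))
}

#' Measured grey-standard responses for linearization
#'
#' Photographs the grey-standard ladder through the camera (mean response
#' over a uniform patch per standard) to provide the input to
#' [fit_linearization()]. With `n_pixels` > 1 and camera noise the means
#' carry sampling error, as patch means from real calibration images do.
#'
#' @param standards a `grey_standard_set`.
#' @param camera a `camera_model`.
#' @param illuminant illuminant curve.
#' @param n_pixels pixels averaged per patch.
#' @return Matrix (length(standards) x 4) of mean responses, columns
#'   lw, mw, sw, uv.
#' @export
photograph_standards <- function(standards, camera,
                                 illuminant = illuminant_d65(),
                                 n_pixels = 100) {
  resp <- sapply(names(camera$channel_sensitivities), function(ch) {
    vapply(standards$reflectances, function(R) {
      q <- quantum_catch(flat_spectrum(R, camera$wavelength_nm),
                         camera$channel_sensitivities[[ch]], illuminant)
      r <- camera_response(q, camera)
      if (camera$noise_sd > 0)
        r <- mean(r + stats::rnorm(n_pixels, 0, camera$noise_sd))
      r
    }, numeric(1))
  })
  rownames(resp) <- sprintf("R%.2f", standards$reflectances)
  resp
}

# ---- scene serialisation -------------------------------------------------

#' Write and read raw image stacks
#'
#' Stacks are written as multi-page 16-bit TIFF (page order uv, sw, mw, lw),
#' ROI masks as single-channel PNG (nonzero = inside), the plan as YAML and
#' the ground truth as CSV. Responses are stored on a 0--1 scale; values are
#' clipped to [0, 1] at export.
#'
#' @param stack a `raw_image_stack`.
#' @param path file path (TIFF).
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(c("uv", "sw", "mw", "lw"),
                  function(ch) pmin(pmax(stack$channels[[ch]], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param standard_mask_path,fish_mask_path PNG mask paths written alongside.
#' @export
write_stack_masks <- function(stack, standard_mask_path, fish_mask_path) {
  png::writePNG(stack$standard_region$mask * 1, standard_mask_path)
  png::writePNG(stack$fish_region$mask * 1, fish_mask_path)
  invisible(NULL)
}

#' @rdname write_stack_tiff
#' @param standard_reflectance nominal standard reflectance for the re-read
#'   stack.
#' @export
read_stack_tiff <- function(path, standard_mask_path, fish_mask_path,
                            standard_reflectance = 0.40) {
  pages <- tiff::readTIFF(path, all = TRUE)
  names(pages) <- c("uv", "sw", "mw", "lw")
  std <- png::readPNG(standard_mask_path) > 0
  fish <- png::readPNG(fish_mask_path) > 0
  channels <- pages[c("lw", "mw", "sw", "uv")]
  structure(list(channels = channels,
                 fish_region = new_region_mask(fish, "fish"),
                 standard_region = new_region_mask(std, "standard"),
                 background_region = new_region_mask(!(fish | std),
                                                     "background"),
                 standard_reflectance = standard_reflectance,
                 metadata = list(path = path)),
            class = "raw_image_stack")
}

#' @rdname write_stack_tiff
#' @param plan a `scene_plan`.
#' @export
write_plan_yaml <- function(plan, path) {
  yaml::write_yaml(list(
    experiment_id = plan$experiment_id,
    backgrounds = names(plan$backgrounds),
    n_fish_per_background = plan$n_fish_per_background,
    timepoints_min = plan$timepoints_min,
    seed = plan$seed), path)
  invisible(path)
}
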