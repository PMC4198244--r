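#' Default study conditions for the synthetic experiments
#'
#' The programmed conditions of the two background-matching experiments:
#' 20 fish per background photographed at 0, 1, 10 and 60 minutes, with a
#' single-exponential colour-change trajectory whose default rate
#' (1.61/min) completes 80% of the change within the first minute.
#'
#' Experiment 1 uses achromatic black and white backgrounds; fish start
#' near the ratio-scale mid grey of the two and diverge in luminance
#' (lighter on white, darker on black) by a modest amount, on the order of
#' a 0.05--0.09 difference in 0--1 photon-catch units between groups.
#' Experiment 2 uses red and blue backgrounds of equal average camera
#' brightness; fish shift hue towards their background with no programmed
#' luminance change (the spectral tilt is orthogonalised against the
#' double-cone catch).
#'
#' @param experiment_id 1 or 2.
#' @return Named list of condition parameters.
#' @export
experiment_conditions <- function(experiment_id) {
  base <- list(
    n_fish_per_background = 20L,
    timepoints_min = c(0, 1, 10, 60),
    rate_per_min = 1.61,
    start_jitter_sd = 0.020,   # between-fish flat offset around the start grey
    target_jitter_sd = 0.015,  # between-fish variation in achieved target
    camera_noise_sd = 0.004,   # pixel noise, response units
    image_side = 48L)
  if (experiment_id == 1) {
    c(base, list(
      black_reflectance = 0.04,
      white_reflectance = 0.90,
      delta_white = 0.055,     # programmed lightening on white
      delta_black = 0.035))    # programmed darkening on black
  } else {
    c(base, list(
      tilt_amp_red = 0.22,     # programmed red shift on red background
      tilt_amp_blue = -0.14))  # programmed blue shift on blue background
  }
}

#' Background spectra for the two experiments
#'
#' Experiment 1: flat black and white papers. Experiment 2: a long-pass
#' red and a Gaussian blue, with the blue rescaled by [match_brightness()]
#' so the two have equal mean camera catch over the visible (LW, MW, SW)
#' channels.
#'
#' @param experiment_id 1 or 2.
#' @param camera a `camera_model` (needed for brightness matching).
#' @param conditions study conditions list.
#' @inheritParams reflectance_spectrum
#' @return Named list of two `refl_spectrum`.
#' @export
experiment_backgrounds <- function(experiment_id, camera,
                                   conditions = experiment_conditions(experiment_id),
                                   wavelength_nm = wavelength_grid()) {
  if (experiment_id == 1) {
    list(black = flat_spectrum(conditions$black_reflectance, wavelength_nm),
         white = flat_spectrum(conditions$white_reflectance, wavelength_nm))
  } else {
    red <- reflectance_spectrum(
      0.08 + 0.55 / (1 + exp(-(wavelength_nm - 590) / 25)), wavelength_nm)
    blue <- reflectance_spectrum(
      0.08 + 0.45 * exp(-((wavelength_nm - 460) / 55)^2), wavelength_nm)
    blue <- match_brightness(red, blue, camera)
    list(red = red, blue = blue)
  }
}

# spectral tilt with zero double-cone catch: a red--blue ramp orthogonalised
# against the receiver's double-cone channel so programmed hue change leaves
# luminance untouched
luminance_neutral_tilt <- function(receiver, wavelength_nm = wavelength_grid()) {
  ramp <- (wavelength_nm - 500) / 400
  w <- receiver$illuminant$value * receiver$sensitivities$dbl$value
  ramp - sum(ramp * w) / sum(w)
}

#' Programmed colour-change trajectories for an experiment
#'
#' One trajectory per fish: a flat starting grey near the ratio-scale mid
#' grey of black and white, with seeded between-fish jitter, approaching a
#' fish-specific target (luminance shift in experiment 1, luminance-neutral
#' hue tilt in experiment 2).
#'
#' @param plan a `scene_plan`.
#' @param receiver a `receiver_model` (for the luminance-neutral tilt).
#' @param conditions study conditions list.
#' @return Named list (one per background) of lists of trajectories.
#' @export
default_trajectories <- function(plan, receiver,
                                 conditions = experiment_conditions(plan$experiment_id)) {
  wl <- plan$backgrounds[[1]]$wavelength_nm
  start_grey <- ratio_scale_midpoint(0.04, 0.90)
  set.seed(plan$seed + 7L)
  tilt <- luminance_neutral_tilt(receiver, wl)
  out <- lapply(names(plan$backgrounds), function(bg) {
    lapply(seq_len(plan$n_fish_per_background), function(f) {
      s0 <- start_grey + stats::rnorm(1, 0, conditions$start_jitter_sd)
      start <- reflectance_spectrum(
        pmin(pmax(rep(s0, length(wl)), 0.01), 1), wl)
      jit <- stats::rnorm(1, 0, conditions$target_jitter_sd)
      target_r <- if (plan$experiment_id == 1) {
        shift <- if (bg == "white") conditions$delta_white
                 else -conditions$delta_black
        start$reflectance + shift + jit
      } else {
        amp <- if (bg == "red") conditions$tilt_amp_red
               else conditions$tilt_amp_blue
        start$reflectance + (amp + jit) * tilt
      }
      target <- reflectance_spectrum(pmin(pmax(target_r, 0.01), 1), wl)
      colour_change_trajectory(start, target, conditions$rate_per_min)
    })
  })
  names(out) <- names(plan$backgrounds)
  out
}

#' Extract per-fish metric records from calibrated scenes
#'
#' For each stack: apply the cone map, average the cone planes over the
#' fish and background ROIs, and compute saturation, the experiment's hue
#' ratio, double-cone luminance, and the chromatic/achromatic JNDs of the
#' fish against its own background.
#'
#' @param stacks list of `raw_image_stack` (from [render_scene()]).
#' @param curve fitted `linearization_curve`.
#' @param map fitted `cone_map`.
#' @param receiver a `receiver_model`.
#' @param hue_fun hue function: [hue_longshort] (experiment 1) or
#'   [hue_redblue] (experiment 2).
#' @return data.frame of metric records, one row per fish x time point.
#' @export
extract_metric_records <- function(stacks, curve, map, receiver,
                                   hue_fun = hue_longshort) {
  noise <- channel_noise(receiver)
  rows <- lapply(stacks, function(stack) {
    cal <- calibrate_stack(stack, curve)
    cone <- apply_cone_map(cal, map)
    q_fish <- roi_mean_catch(cone, cone$fish_region)
    q_bg <- roi_mean_catch(cone, cone$background_region)
    md <- stack$metadata
    data.frame(
      fish_id = md$fish_id, experiment = md$experiment,
      background = md$background, time_min = md$time_min,
      saturation = saturation(q_fish), hue = hue_fun(q_fish),
      luminance = luminance(q_fish),
      chromatic_jnd = chromatic_jnd(q_fish, q_bg, noise),
      achromatic_jnd = achromatic_jnd(unclass(q_fish)[["dbl"]],
                                      unclass(q_bg)[["dbl"]],
                                      receiver$weber_fraction))
  })
  do.call(rbind, rows)
}

#' Run a full synthetic background-matching experiment
#'
#' End-to-end orchestration: render the scene series through the simulated
#' camera, photograph the grey-standard ladder and fit the linearization,
#' fit the camera-to-cone polynomial map on a seeded spectral library,
#' calibrate every stack, extract per-fish metrics and JNDs, and run the
#' statistical battery (planned between-background comparisons per time
#' point with sequential Bonferroni, plus Kruskal--Wallis camouflage trends
#' per background). Fully seeded: the same plan yields an identical report.
#'
#' @param experiment_id 1 (black/white) or 2 (red/blue).
#' @param seed integer seed.
#' @param camera a `camera_model`; default gamma-2.2 camera with the
#'   conditions' pixel noise.
#' @param receiver a `receiver_model`.
#' @param conditions study conditions (see [experiment_conditions()]).
#' @param map_library_n,map_degree cone-map training library size and
#'   polynomial degree.
#' @return List: `records` (metric table), `comparisons` (planned
#'   comparisons for saturation, hue, luminance), `trends` (Kruskal--Wallis
#'   JND trends per background and kind), `plan`, `cone_map_r2`,
#'   `linearization`.
#' @export
run_experiment <- function(experiment_id, seed = 1,
                           camera = NULL, receiver = receiver_model(),
                           conditions = experiment_conditions(experiment_id),
                           map_library_n = 200, map_degree = 2) {
  if (is.null(camera))
    camera <- camera_model(noise_sd = conditions$camera_noise_sd)
  backgrounds <- experiment_backgrounds(experiment_id, camera, conditions)
  plan <- scene_plan(experiment_id, backgrounds,
                     n_fish_per_background = conditions$n_fish_per_background,
                     timepoints_min = conditions$timepoints_min,
                     seed = seed)
  trajectories <- default_trajectories(plan, receiver, conditions)
  scene <- render_scene(plan, trajectories, camera,
                        illuminant = receiver$illuminant,
                        nrow = conditions$image_side,
                        ncol = conditions$image_side)
  set.seed(seed + 11L)
  responses <- photograph_standards(grey_standard_set(), camera,
                                    receiver$illuminant)
  curve <- fit_linearization(responses, grey_standard_set())
  lib <- make_spectral_library(map_library_n, seed = seed + 23L)
  map <- fit_cone_map(lib, camera, receiver, degree = map_degree)
  hue_fun <- if (experiment_id == 1) hue_longshort else hue_redblue
  records <- extract_metric_records(scene$stacks, curve, map, receiver,
                                    hue_fun)
  comparisons <- do.call(rbind, lapply(
    c("saturation", "hue", "luminance"),
    function(mm) planned_comparisons(records, mm,
                                     first_background = names(backgrounds)[1])))
  trends <- do.call(rbind, unlist(lapply(names(backgrounds), function(bg)
    lapply(c("chromatic", "achromatic"),
           function(kind) camouflage_trend(records, bg, kind))),
    recursive = FALSE))
  list(records = records, comparisons = comparisons, trends = trends,
       plan = plan, cone_map_r2 = map$r2,
       linearization = vapply(curve$channels, function(f) f$r2, numeric(1)))
}

#' Simulate null metric records (no programmed change)
#'
#' Draws per-fish metric records for two backgrounds and four time points
#' from identical distributions — no background effect at any time — for
#' Monte-Carlo checks of the familywise type-I error of the planned
#' comparisons.
#'
#' @param n_fish fish per background.
#' @param timepoints_min time points.
#' @param seed integer seed.
#' @return data.frame with background, time_min and metric columns.
#' @export
simulate_null_records <- function(n_fish = 20, timepoints_min = c(0, 1, 10, 60),
                                  seed = 1) {
  set.seed(seed)
  grid <- expand.grid(fish = seq_len(n_fish), background = c("A", "B"),
                      time_min = timepoints_min,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  data.frame(
    fish_id = sprintf("%s_%02d", grid$background, grid$fish),
    background = grid$background, time_min = grid$time_min,
    saturation = abs(stats::rnorm(n, 0.05, 0.02)),
    hue = stats::rnorm(n, 0, 0.05),
    luminance = stats::rnorm(n, 0.2, 0.03),
    chromatic_jnd = abs(stats::rnorm(n, 2, 0.8)),
    achromatic_jnd = abs(stats::rnorm(n, 10, 3)))
}
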