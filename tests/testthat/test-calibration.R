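test_that("identity camera yields an identity linearization with R^2 = 1", {
  cam <- camera_model(response_gamma = 1, gain = 1, noise_sd = 0)
  curve <- fitted_curve_for(cam)
  stds <- grey_standard_set()$reflectances
  for (ch in c("lw", "mw", "sw", "uv")) {
    f <- curve$channels[[ch]]
    expect_equal(f$r2, 1, tolerance = 1e-9)
    lin <- f$a * stds^f$b + f$c
    expect_equal(lin, stds, tolerance = 1e-7)
  }
})

test_that("a gamma-2.2 response curve is inverted to the true reflectances", {
  cam <- camera_model(response_gamma = 2.2, noise_sd = 0)
  std <- grey_standard_set()
  resp <- photograph_standards(std, cam)
  curve <- fit_linearization(resp, std)
  for (ch in colnames(resp)) {
    f <- curve$channels[[ch]]
    recovered <- ((resp[, ch] - f$c) / f$a)^(1 / f$b)
    expect_lt(max(abs(recovered - std$reflectances) / std$reflectances),
              0.005)
  }
})

test_that("degenerate or non-monotone standard responses fail loudly", {
  std <- grey_standard_set()
  resp <- photograph_standards(std, camera_model(noise_sd = 0))
  resp[, "mw"] <- 0.5
  expect_error(fit_linearization(resp, std), "mw")
  resp2 <- photograph_standards(std, camera_model(noise_sd = 0))
  resp2[3, "uv"] <- resp2[5, "uv"]  # break monotonicity
  expect_error(fit_linearization(resp2, std), "uv")
})

test_that("linearized gamma stacks have patch means linear in reflectance", {
  cam <- camera_model(response_gamma = 2.2, noise_sd = 0)
  curve <- fitted_curve_for(cam)
  levels <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  means <- vapply(levels, function(R) {
    stk <- render_stack(flat_spectrum(R), flat_spectrum(0.2), camera = cam,
                        nrow = 16, ncol = 16)
    lin <- apply_linearization(stk, curve)
    mean(lin$channels$lw[lin$fish_region$mask])
  }, numeric(1))
  for (i in seq_along(levels)) for (j in seq_along(levels))
    expect_equal(means[i] / means[j], levels[i] / levels[j], tolerance = 0.01)
})

test_that("out-of-range responses are clamped and counted, not dropped", {
  cam <- camera_model(response_gamma = 1, noise_sd = 0)
  curve <- fitted_curve_for(cam)
  stk <- render_stack(flat_spectrum(0.3), flat_spectrum(0.2), camera = cam,
                      nrow = 20, ncol = 20)
  n_sat <- 20  # push a block of background pixels above the fitted range
  stk$channels$lw[1, ncol(stk$channels$lw) - seq_len(n_sat) + 1] <- 1.2
  lin <- apply_linearization(stk, curve)
  expect_equal(unname(lin$clamp_report["lw"]), n_sat)
  expect_equal(sum(lin$clamp_report[c("mw", "sw", "uv")]), 0)
  expect_identical(dim(lin$channels$lw), dim(stk$channels$lw))
})

test_that("equalization pins the standard to 0.40, idempotently and scale-free", {
  cam <- camera_model(response_gamma = 2.2, noise_sd = 0)
  curve <- fitted_curve_for(cam)
  stk <- render_stack(flat_spectrum(0.35), flat_spectrum(0.12), camera = cam)
  lin <- apply_linearization(stk, curve)
  cal <- equalize_to_standard(lin)
  for (ch in names(cal$channels))
    expect_equal(mean(cal$channels[[ch]][cal$standard_region$mask]), 0.40,
                 tolerance = 1e-6)
  # idempotence
  cal2 <- equalize_to_standard(cal)
  for (ch in names(cal$channels))
    expect_equal(cal2$channels[[ch]], cal$channels[[ch]], tolerance = 1e-9)
  # invariance to a global illuminant scale
  lin_bright <- lin
  lin_bright$channels <- lapply(lin$channels, function(m) m * 2.37)
  cal3 <- equalize_to_standard(lin_bright)
  for (ch in names(cal$channels))
    expect_equal(cal3$channels[[ch]], cal$channels[[ch]], tolerance = 1e-9)
  # closed form: standard mean at 0.2 doubles every pixel
  lin_half <- lin
  lin_half$channels <- lapply(cal$channels, function(m) m * 0.5)
  cal4 <- equalize_to_standard(lin_half)
  for (ch in names(cal$channels))
    expect_equal(cal4$channels[[ch]], 2 * lin_half$channels[[ch]],
                 tolerance = 1e-9)
})

test_that("calibration round trip recovers true reflectance within 1%", {
  cam <- camera_model(response_gamma = 2.2, noise_sd = 0)
  curve <- fitted_curve_for(cam)
  for (R in c(0.05, 0.19, 0.40, 0.75)) {
    stk <- render_stack(flat_spectrum(R), flat_spectrum(0.1897),
                        camera = cam, nrow = 16, ncol = 16)
    cal <- calibrate_stack(stk, curve)
    for (ch in names(cal$channels)) {
      got <- mean(cal$channels[[ch]][cal$fish_region$mask])
      expect_lt(abs(got - R) / R, 0.01)
    }
  }
})

test_that("ratio-scale midpoint is the geometric mean and sits between", {
  expect_equal(ratio_scale_midpoint(0.25, 1), 0.5)
  expect_equal(ratio_scale_midpoint(0.04, 0.90), sqrt(0.036))
  m <- ratio_scale_midpoint(0.04, 0.90)
  expect_equal(m / 0.04, 0.90 / m)
  expect_true(m > 0.04 && m < 0.90)
  expect_error(ratio_scale_midpoint(0.04, 0.04), "low < high")
  expect_error(ratio_scale_midpoint(0.5, 0.3), "low < high")
})

test_that("brightness matching equalises mean visible camera catches", {
  cam <- camera_model(noise_sd = 0)
  a <- flat_spectrum(0.3)
  expect_equal(attr(match_brightness(a, a, cam), "scale"), 1, tolerance = 1e-12)
  b <- flat_spectrum(0.15)  # half the catch, feasible doubling
  m <- match_brightness(a, b, cam)
  expect_equal(attr(m, "scale"), 2, tolerance = 1e-9)
  wl <- wavelength_grid()
  red <- reflectance_spectrum(0.08 + 0.55 / (1 + exp(-(wl - 590) / 25)), wl)
  blue <- reflectance_spectrum(0.08 + 0.45 * exp(-((wl - 460) / 55)^2), wl)
  mb <- match_brightness(red, blue, cam)
  vis <- c("lw", "mw", "sw")
  expect_lt(abs(mean(camera_catches(red, cam)[vis]) -
                  mean(camera_catches(mb, cam)[vis])), 1e-9)
  # a UV-peaked spectrum has almost no visible catch: the required scale
  # would push its peak past full reflectance
  uv_peak <- reflectance_spectrum(0.01 + 0.5 * exp(-((wl - 345) / 12)^2), wl)
  expect_error(match_brightness(flat_spectrum(0.6), uv_peak, cam),
               "infeasible")
})
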