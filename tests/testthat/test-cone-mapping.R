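test_that("quantum catch normalises, vanishes, and factors flat spectra", {
  ill <- illuminant_d65()
  s <- receiver_model()$sensitivities$mw
  expect_equal(quantum_catch(flat_spectrum(1), s, ill), 1)
  expect_equal(quantum_catch(flat_spectrum(0), s, ill), 0)
  for (sens in receiver_model()$sensitivities)
    expect_equal(quantum_catch(flat_spectrum(0.4), sens, ill), 0.4)
  short_grid <- wavelength_grid(400, 700)
  expect_error(
    quantum_catch(flat_spectrum(0.4, short_grid), s, ill), "grids differ")
})

test_that("quantum catch is linear in reflectance and illuminant-scale free", {
  ill <- illuminant_d65()
  ill2 <- sensitivity_curve(ill$value * 3.7, ill$wavelength_nm)
  s <- receiver_model()$sensitivities$lw
  set.seed(42)
  for (i in 1:5) {
    r1 <- stats::runif(401, 0, 0.5); r2 <- stats::runif(401, 0, 0.5)
    a <- reflectance_spectrum(r1); b <- reflectance_spectrum(r2)
    ab <- reflectance_spectrum(0.3 * r1 + 0.7 * r2)
    expect_equal(quantum_catch(ab, s, ill),
                 0.3 * quantum_catch(a, s, ill) + 0.7 * quantum_catch(b, s, ill))
    expect_equal(quantum_catch(a, s, ill), quantum_catch(a, s, ill2))
  }
})

test_that("a receiver sharing the camera's sensitivities maps to identity", {
  cam <- camera_model(noise_sd = 0)
  sens <- cam$channel_sensitivities
  rec <- receiver_model(sensitivities = list(
    uv = sens$uv, sw = sens$sw, mw = sens$mw, lw = sens$lw, dbl = sens$mw))
  lib <- make_spectral_library(60, seed = 4)
  map <- fit_cone_map(lib, cam, rec, degree = 1)
  q <- camera_catches(lib[[1]], cam)
  pred <- predict_cone_map(map, q)
  expect_equal(unname(pred[1, "uv"]), unname(q["uv"]), tolerance = 1e-6)
  expect_equal(unname(pred[1, "lw"]), unname(q["lw"]), tolerance = 1e-6)
  expect_equal(unname(pred[1, "dbl"]), unname(q["mw"]), tolerance = 1e-6)
})

test_that("degree-2 cone map generalises to a disjoint library (R^2 >= 0.99)", {
  cam <- camera_model(noise_sd = 0)
  rec <- receiver_model()
  map <- fit_cone_map(make_spectral_library(200, seed = 1), cam, rec)
  expect_true(all(map$r2 >= 0.99))
  holdout <- make_spectral_library(200, seed = 2)
  X <- t(vapply(holdout, function(s) camera_catches(s, cam)[map$camera_channels],
                numeric(4)))
  Y <- t(vapply(holdout, function(s) unclass(receiver_catches(s, rec)),
                numeric(5)))
  P <- predict_cone_map(map, X)
  r2 <- vapply(1:5, function(j)
    1 - sum((Y[, j] - P[, j])^2) / sum((Y[, j] - mean(Y[, j]))^2), numeric(1))
  expect_true(all(r2 >= 0.99))
})

test_that("an underdetermined library fails the cone-map fit", {
  cam <- camera_model(noise_sd = 0)
  rec <- receiver_model()
  lib <- make_spectral_library(3, seed = 1, standards = numeric(0))
  expect_error(fit_cone_map(lib, cam, rec, degree = 2), "fit failure")
})

test_that("cone-map image application matches direct polynomial evaluation", {
  cam <- camera_model(response_gamma = 2.2, noise_sd = 0)
  rec <- receiver_model()
  map <- fit_cone_map(make_spectral_library(200, seed = 1), cam, rec)
  curve <- fitted_curve_for(cam)
  stk <- render_stack(flat_spectrum(0.3), flat_spectrum(0.15), camera = cam,
                      nrow = 12, ncol = 12)
  cal <- calibrate_stack(stk, curve)
  cone <- apply_cone_map(cal, map)
  # uniform standard patch: constant prediction across its pixels
  for (pl in cone$planes) {
    v <- pl[cone$standard_region$mask]
    expect_lt(diff(range(v)), 1e-9)
  }
  # brute-force monomial evaluation at random pixels, independent of
  # poly_design: expand the degree-2 terms explicitly
  set.seed(9)
  idx <- sample(length(cal$channels$lw), 10)
  for (i in idx) {
    x <- vapply(map$camera_channels, function(ch) cal$channels[[ch]][i],
                numeric(1))
    terms <- apply(map$exponents, 1, function(ex) prod(x^ex))
    manual <- drop(terms %*% map$coefficients)
    manual[manual < 0] <- 0
    for (cn in colnames(map$coefficients))
      expect_equal(cone$planes[[cn]][i], manual[[cn]], tolerance = 1e-12)
  }
})

test_that("ROI means average the cone planes over the mask", {
  planes <- list(uv = matrix(0.3, 4, 4), sw = matrix(0.3, 4, 4),
                 mw = matrix(0.3, 4, 4), lw = matrix(0.3, 4, 4),
                 dbl = matrix(0.3, 4, 4))
  img <- structure(list(planes = planes), class = "cone_image")
  m <- matrix(FALSE, 4, 4); m[1, 1:2] <- TRUE
  mask <- structure(list(mask = m, label = "roi"), class = "region_mask")
  expect_equal(unclass(roi_mean_catch(img, mask))[["mw"]], 0.3)
  img$planes$mw[1, 1] <- 0.2; img$planes$mw[1, 2] <- 0.4
  expect_equal(unclass(roi_mean_catch(img, mask))[["mw"]], 0.3)
  # checkerboard against direct sum/count
  chk <- matrix(rep(c(0.1, 0.7), 8), 4, 4)
  img$planes$lw <- chk
  big <- matrix(TRUE, 4, 4)
  maskb <- structure(list(mask = big, label = "all"), class = "region_mask")
  expect_equal(unclass(roi_mean_catch(img, maskb))[["lw"]],
               sum(chk) / length(chk), tolerance = 1e-12)
  empty <- structure(list(mask = matrix(FALSE, 4, 4), label = "none"),
                     class = "region_mask")
  expect_error(roi_mean_catch(img, empty), "empty mask")
})

test_that("zero-noise end-to-end pipeline recovers true cone catches within 2%", {
  cam <- camera_model(response_gamma = 2.2, noise_sd = 0)
  rec <- receiver_model()
  curve <- fitted_curve_for(cam)
  map <- fit_cone_map(make_spectral_library(200, seed = 1), cam, rec)
  wl <- wavelength_grid()
  specs <- list(flat_spectrum(0.3),
                reflectance_spectrum(0.1 + 0.4 / (1 + exp(-(wl - 560) / 30))),
                reflectance_spectrum(0.1 + 0.3 * exp(-((wl - 470) / 60)^2)))
  for (sp in specs) {
    stk <- render_stack(sp, flat_spectrum(0.1897), camera = cam,
                        nrow = 16, ncol = 16)
    cone <- apply_cone_map(calibrate_stack(stk, curve), map)
    got <- roi_mean_catch(cone, cone$fish_region)
    truth <- receiver_catches(sp, rec)
    expect_equal(unclass(got), unclass(truth), tolerance = 0.02)
  }
})

test_that("receiver sensitivity tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  rec <- receiver_model()
  path <- file.path(dir, "receiver.csv")
  write_receiver_csv(rec, path)
  back <- read_receiver_csv(path)
  expect_equal(back$sensitivities$lw$value, rec$sensitivities$lw$value,
               tolerance = 1e-12)
  expect_equal(back$cone_proportions, rec$cone_proportions)
})
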