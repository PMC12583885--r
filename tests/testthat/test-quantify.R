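test_that("the attenuation factor obeys its closed form and limits", {
  # full relaxation: E -> 1
  expect_equal(attenuation_factor(100, 0.3, 62), 1, tolerance = 1e-12)
  # 90 degrees: E = 1 - exp(-TR/T1)
  expect_equal(attenuation_factor(0.23, 0.297, 90),
               1 - exp(-0.23 / 0.297), tolerance = 1e-12)
  # lactate at the CSI settings (direct evaluation of the closed form)
  expect_equal(attenuation_factor(0.230, 0.297, 62), 0.68788,
               tolerance = 1e-4)
  # monotonicity below 90 degrees: increasing in TR, decreasing in T1
  tr <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(attenuation_factor(tr, 0.3, 62)) > 0))
  t1 <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(attenuation_factor(0.23, t1, 62)) < 0))
  expect_error(attenuation_factor(-1, 0.3, 62))
})

test_that("natural-abundance HDO concentration scales with water content", {
  expect_equal(natural_abundance_hdo_concentration(1), 17.2848,
               tolerance = 1e-6)           # 2 x 1.56e-4 x 55.4 M in mM
  expect_equal(natural_abundance_hdo_concentration(0.84),
               17.2848 * 0.84, tolerance = 1e-6)
  expect_equal(natural_abundance_hdo_concentration(0), 0)
})

test_that("effective HDO T1 is the water-weighted fast-exchange average", {
  expect_equal(effective_hdo_t1(c(csf = 0, gm = 1, wm = 0)), 0.320)
  # two compartments with equal water: harmonic mean of the rates
  cfg <- quant_config()
  cfg$water_fraction <- c(csf = 0.99, gm = 0.8, wm = 0.8)
  expect_equal(effective_hdo_t1(c(csf = 0, gm = 0.5, wm = 0.5), cfg),
               2 / (1 / 0.32 + 1 / 0.29), tolerance = 1e-12)
  # adding CSF (longest T1) raises the effective T1
  t1s <- vapply(seq(0, 0.5, by = 0.1), function(fc) {
    effective_hdo_t1(c(csf = fc, gm = (1 - fc) / 2, wm = (1 - fc) / 2))
  }, numeric(1))
  expect_true(all(diff(t1s) > 0))
})

test_that("kappa calibration inverts exactly and scales linearly", {
  ph <- make_phantom(c(6, 6, 4))
  qc <- quant_config("d7")
  roi <- roi_composition(ph, ph$brain_mask, qc)
  k1 <- calibrate_kappa(10, roi, qc)
  expect_equal(calibrate_kappa(20, roi, qc), 2 * k1)
  # round trip: converting the calibration amplitude back gives C_NA
  c_na <- natural_abundance_hdo_concentration(roi$water_fraction, qc)
  expect_equal(concentration_from_amplitude(10, "hdo", k1, roi, qc), c_na,
               tolerance = 1e-12)
  expect_error(calibrate_kappa(0, roi, qc))
})

test_that("kappa agrees across single-tissue ROIs on a noiseless simulation", {
  ph <- make_phantom()
  qc <- quant_config("d7")
  csi <- synthesize_csi(ph, list(), qc, noise_sd = 0)
  m <- build_prior_model("d7")
  kappa_for <- function(mask) {
    v <- which(mask, arr.ind = TRUE)[1, ]
    fit <- fit_fid(csi$data[, v[1], v[2], v[3]], m, dwell = csi$dwell_s)
    sub <- mask & FALSE; sub[v[1], v[2], v[3]] <- TRUE
    calibrate_kappa(fit$amplitudes[["hdo"]], roi_composition(ph, sub, qc),
                    qc)
  }
  k_wm <- kappa_for(ph$wm > 0.999)
  k_gm <- kappa_for(ph$gm > 0.999)
  expect_equal(k_wm, k_gm, tolerance = 1e-6)
  expect_equal(k_wm, 1, tolerance = 1e-6)  # generator kappa
})

test_that("kappa is recovered within 3% from a noisy GM-only ROI", {
  ph <- uniform_phantom(c(3, 3, 2))        # pure grey matter
  qc <- quant_config("d7")
  csi <- synthesize_csi(ph, list(), qc, noise_sd = "auto", seed = 29)
  fits <- fit_csi(csi, build_prior_model("d7"))
  amp <- roi_average_complex(fits$amplitude[, , , "hdo"],
                             fits$phase[, , , "hdo"], ph$brain_mask)
  roi <- roi_composition(ph, ph$brain_mask, qc)
  expect_equal(calibrate_kappa(amp, roi, qc), 1, tolerance = 0.03)
})

test_that("concentrations invert the signal equation", {
  ph <- make_phantom(c(6, 6, 4))
  qc2 <- quant_config("d2")
  qc7 <- quant_config("d7")
  roi <- roi_composition(ph, ph$brain_mask, qc7)
  kappa <- 1
  # definitional inversion
  e_glx <- attenuation_factor(qc7$tr_s, qc7$t1_s[["glx"]], qc7$flip_deg)
  a <- kappa * e_glx * qc7$n_labels[["glx"]] * 1
  expect_equal(concentration_from_amplitude(a, "glx", kappa, roi, qc7), 1,
               tolerance = 1e-12)
  # same amplitude read as d7 vs d2 glucose: concentration ratio 2/7
  c7 <- concentration_from_amplitude(5, "glc", kappa, roi, qc7)
  c2 <- concentration_from_amplitude(5, "glc", kappa, roi, qc2)
  expect_equal(c7 / c2, 2 / 7, tolerance = 1e-12)
  expect_error(concentration_from_amplitude(5, "pyruvate", kappa, roi, qc7))
})

test_that("the noiseless loop recovers glucose concentration to 1e-3", {
  # uniform-composition phantom: quantification assumptions hold exactly
  ph <- uniform_phantom(c(2, 2, 2))
  qc <- quant_config("d7")
  na <- synthesize_csi(ph, list(), qc, noise_sd = 0)
  post <- synthesize_csi(ph, list(glc = 1.5), qc, noise_sd = 0)
  m <- build_prior_model("d7")
  fna <- fit_csi(na, m)
  fpost <- fit_csi(post, m)
  roi <- roi_composition(ph, ph$brain_mask, qc)
  kappa <- calibrate_kappa(
    roi_average_complex(fna$amplitude[, , , "hdo"], fna$phase[, , , "hdo"],
                        ph$brain_mask), roi, qc)
  a_glc <- roi_average_complex(fpost$amplitude[, , , "glc"],
                               fpost$phase[, , , "glc"], ph$brain_mask)
  expect_equal(
    concentration_from_amplitude(a_glc, "glc", kappa, roi, qc), 1.5,
    tolerance = 1e-3)
})

test_that("complex ROI averaging cancels incoherent phases", {
  u <- array(2, c(2, 2, 1))
  ph0 <- array(0.7, c(2, 2, 1))
  mask <- array(TRUE, c(2, 2, 1))
  expect_equal(roi_average_complex(u, ph0, mask), 2, tolerance = 1e-12)

  amp2 <- array(c(1, 1), c(2, 1, 1))
  phase2 <- array(c(0, pi), c(2, 1, 1))
  expect_equal(roi_average_complex(amp2, phase2, array(TRUE, c(2, 1, 1))),
               0, tolerance = 1e-12)

  # random phases: complex mean magnitude below the mean single magnitude
  set.seed(41)
  n <- c(6, 6, 4)
  amp <- array(abs(rnorm(prod(n), 1, 0.1)), n)
  phs <- array(runif(prod(n), -pi, pi), n)
  expect_lt(roi_average_complex(amp, phs, array(TRUE, n)), mean(amp))

  expect_error(roi_average_complex(u, ph0, array(FALSE, c(2, 2, 1))),
               "empty")
})

test_that("trilinear interpolation to a finer grid preserves constants", {
  u <- array(3, c(2, 2, 2))
  ph0 <- array(0.5, c(2, 2, 2))
  mask <- array(TRUE, c(4, 4, 4))
  expect_equal(roi_average_complex(u, ph0, mask, target_dim = c(4, 4, 4)),
               3, tolerance = 1e-12)
})

test_that("end-to-end concentrations are nearly unbiased", {
  ph <- make_phantom(c(8, 8, 6))
  qc <- quant_config("d7")
  truth <- list(glc = 1.5, glx = 0.8, lac = 0.2)
  m <- build_prior_model("d7")
  roi <- roi_composition(ph, ph$brain_mask, qc)

  run_once <- function(noise_sd, seed) {
    na <- synthesize_csi(ph, list(), qc, noise_sd = noise_sd, seed = seed)
    post <- synthesize_csi(ph, truth, qc, noise_sd = noise_sd,
                           seed = seed + 1)
    fna <- fit_csi(na, m, mask = ph$brain_mask)
    fpost <- fit_csi(post, m, mask = ph$brain_mask)
    kappa <- calibrate_kappa(
      roi_average_complex(fna$amplitude[, , , "hdo"],
                          fna$phase[, , , "hdo"], ph$brain_mask), roi, qc)
    vapply(c(glc = "glc", hdo = "hdo"), function(met) {
      a <- roi_average_complex(fpost$amplitude[, , , met],
                               fpost$phase[, , , met], ph$brain_mask)
      concentration_from_amplitude(a, met, kappa, roi, qc)
    }, numeric(1))
  }
  # voxel tissue content varies, so the ROI truth is the tissue-weighted mean
  tissue <- ph$csf + ph$gm + ph$wm
  glc_true <- truth$glc * mean(tissue[ph$brain_mask])
  water <- ph$csf * qc$water_fraction[["csf"]] +
    ph$gm * qc$water_fraction[["gm"]] + ph$wm * qc$water_fraction[["wm"]]
  hdo_true <- natural_abundance_hdo_concentration(1, qc) *
    mean(water[ph$brain_mask])

  noiseless <- run_once(0, 1)
  expect_lt(abs(noiseless[["glc"]] - glc_true) / glc_true, 0.03)
  expect_lt(abs(noiseless[["hdo"]] - hdo_true) / hdo_true, 0.03)

  # bias at the calibrated SNR: average over independent noise realizations
  # so the single-realization spread does not mask the bias being tested
  sd_auto <- synthesize_csi(ph, list(), qc, noise_sd = "auto")$noise_sd
  noisy <- rowMeans(vapply(c(57, 157, 257, 357), function(s) {
    run_once(sd_auto, s)
  }, numeric(2)))
  expect_lt(abs(noisy[["glc"]] - glc_true) / glc_true, 0.05)
  expect_lt(abs(noisy[["hdo"]] - hdo_true) / hdo_true, 0.05)
})
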