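test_that("a noiseless single Lorentzian is recovered to high precision", {
  m <- build_prior_model("d2")
  t <- csi_time_axis()
  p <- single_resonance_params(m, "hdo", amplitude = 1, phase = 0.3,
                               linewidth = 10)
  fit <- fit_fid(evaluate_fid(m, p, t), m, dwell = 1 / 1200)
  expect_true(fit$converged)
  expect_equal(fit$amplitudes[["hdo"]], 1, tolerance = 1e-6)
  expect_equal(fit$params$phases[["hdo"]], 0.3, tolerance = 1e-6)
  expect_equal(fit$params$linewidths[["hdo"]], 10, tolerance = 1e-5)
  expect_equal(fit$params$f0_hz, 0, tolerance = 1e-5)
  expect_equal(fit$amplitudes[c("glc", "glx", "lac")],
               c(glc = 0, glx = 0, lac = 0), tolerance = 1e-6)
})

test_that("equal-concentration d7 and d2 spectra give the expected ratios", {
  t <- csi_time_axis()
  sims <- equal_concentration_fids(t)
  f2 <- fit_fid(sims$d2$fid, sims$d2$model, dwell = 1 / 1200)
  f7 <- fit_fid(sims$d7$fid, sims$d7$model, dwell = 1 / 1200)
  # the anomer-resolved prior reports 7/2 the amplitude for d7
  expect_equal(coef(f7)[["glc"]] / coef(f2)[["glc"]], 3.5,
               tolerance = 0.005)
  # label-number scaling of the products: 0.9/0.6 and 1.28/0.85
  expect_equal(coef(f7)[["glx"]] / coef(f2)[["glx"]], 1.5, tolerance = 0.01)
  expect_equal(coef(f7)[["lac"]] / coef(f2)[["lac"]], 1.28 / 0.85,
               tolerance = 0.01)
})

test_that("fitted amplitudes are linear in concentration", {
  m <- build_prior_model("d7")
  t <- csi_time_axis()
  p <- spectral_params(m, amplitudes = c(glc_alpha = 0.2, glc_beta = 0.3,
                                         hdo = 2, glx = 0.4, lac = 0.1),
                       linewidths = 14)
  p2 <- p; p2$amplitudes <- 2 * p$amplitudes
  f1 <- fit_fid(evaluate_fid(m, p, t), m, dwell = 1 / 1200)
  f2 <- fit_fid(evaluate_fid(m, p2, t), m, dwell = 1 / 1200)
  expect_equal(coef(f2), 2 * coef(f1), tolerance = 1e-5)
})

test_that("an all-zero FID yields zero amplitudes with a converged flag", {
  m <- build_prior_model("d2")
  fit <- fit_fid(complex(real = rep(0, 256)), m, dwell = 1 / 1200)
  expect_true(fit$converged)
  expect_true(all(fit$amplitudes == 0))
  expect_error(fit_fid(complex(real = rep(0, 32)), m, dwell = 1 / 1200),
               "64")
})

test_that("the fit matches a grid-search + linear-LS oracle on one resonance", {
  # independent oracle: dense grid over (linewidth, frequency), complex
  # amplitude by exact linear least squares at each node; fitted with a
  # one-resonance prior so both sides solve the same problem
  m <- one_resonance_model()
  t <- csi_time_axis()
  truth <- list(a = 1.7, phi = -0.4, lw = 11.3, f = 2.2)
  fid <- truth$a * exp(1i * (2 * pi * (0 + truth$f) * t + truth$phi)) *
    exp(-pi * truth$lw * t)
  set.seed(8)
  fid <- fid + complex(real = rnorm(256, 0, 0.01),
                       imaginary = rnorm(256, 0, 0.01))

  grid_search <- function(lws, fs, best = list(rss = Inf)) {
    for (lw in lws) {
      for (f in fs) {
        basis <- exp(1i * 2 * pi * f * t) * exp(-pi * lw * t)
        z <- sum(Conj(basis) * fid) / sum(Mod(basis)^2)
        rss <- sum(Mod(fid - z * basis)^2)
        if (rss < best$rss) {
          best <- list(rss = rss, a = Mod(z), lw = lw, f = f)
        }
      }
    }
    best
  }
  best <- grid_search(seq(10.0, 12.5, by = 0.025), seq(1.5, 3.0, by = 0.01))
  # refine around the coarse optimum
  best <- grid_search(seq(best$lw - 0.03, best$lw + 0.03, by = 0.002),
                      seq(best$f - 0.012, best$f + 0.012, by = 0.001), best)
  fit <- fit_fid(fid, m, dwell = 1 / 1200)
  expect_equal(fit$amplitudes[["hdo"]], best$a, tolerance = 1e-3)
  expect_equal(fit$params$linewidths[["hdo"]], best$lw, tolerance = 0.05)
  expect_equal(fit$params$f0_hz, best$f, tolerance = 0.02)
})

test_that("amplitude estimates at SNR 14 are unbiased with near-CRLB spread", {
  m <- build_prior_model("d2")
  t <- csi_time_axis()
  a <- 1; lw <- 14
  p <- single_resonance_params(m, "hdo", amplitude = a, linewidth = lw)
  clean <- evaluate_fid(m, p, t)
  peak <- max(Mod(fft(clean)))
  sigma <- peak / (14 * sqrt(256))

  # asymptotic prediction from the analytic Jacobian of the
  # single-resonance model (parameters a, phi, lw, f)
  mt <- exp(-pi * lw * t)             # model at phi = 0, f = 0
  cols <- cbind(mt, 1i * a * mt, -pi * t * a * mt, 2i * pi * t * a * mt)
  jr <- rbind(Re(cols), Im(cols))
  pred_sd <- sigma * sqrt(solve(t(jr) %*% jr)[1, 1])

  set.seed(17)
  amps <- replicate(200, {
    fid <- clean + complex(real = rnorm(256, 0, sigma),
                           imaginary = rnorm(256, 0, sigma))
    fit_fid(fid, m, dwell = 1 / 1200)$amplitudes[["hdo"]]
  })
  expect_lt(abs(mean(amps) - a) / a, 0.02)
  expect_lt(abs(sd(amps) - pred_sd) / pred_sd, 0.30)
})

test_that("CSI fits are spatially constant on a uniform noiseless phantom", {
  ph <- uniform_phantom(c(2, 2, 2))
  qc <- quant_config("d7")
  csi <- synthesize_csi(ph, list(glc = 1.2, glx = 0.5, lac = 0.15),
                        qc, noise_sd = 0)
  fits <- fit_csi(csi, build_prior_model("d7"))
  for (i in 1:4) {
    vals <- fits$amplitude[, , , i]
    expect_lt(sd(vals) / mean(vals), 1e-6)
  }
  expect_true(all(fits$converged))
})

test_that("absent species fit to zero and low-SNR voxels are flagged", {
  ph <- uniform_phantom(c(2, 2, 1))
  qc <- quant_config("d7")
  clean <- synthesize_csi(ph, list(), qc, noise_sd = 0)
  fits0 <- fit_csi(clean, build_prior_model("d7"))
  expect_lt(max(fits0$amplitude[, , , "glx"]), 1e-6 * mean(fits0$amplitude[, , , "hdo"]))

  noisy <- synthesize_csi(ph, list(), qc, noise_sd = "auto", seed = 21)
  fits <- fit_csi(noisy, build_prior_model("d7"), snr_floor = 100)
  expect_true(all(fits$low_snr))           # floor above the actual SNR
  glx <- fits$amplitude[, , , "glx"]
  expect_lt(mean(glx), 3 * (sd(glx) + 0.05 * mean(fits$amplitude[, , , "hdo"])))
})

test_that("fitted HDO linewidth on the calibrated simulation is near 14 Hz", {
  ph <- make_phantom()
  csi <- synthesize_csi(ph, list(), quant_config("d7"), noise_sd = "auto",
                        seed = 13)
  m <- build_prior_model("d7")
  vox <- which(ph$brain_mask, arr.ind = TRUE)
  set.seed(1)
  vox <- vox[sample(nrow(vox), 20), , drop = FALSE]
  lws <- apply(vox, 1, function(v) {
    fit_fid(csi$data[, v[1], v[2], v[3]], m,
            dwell = csi$dwell_s)$params$linewidths[["hdo"]]
  })
  expect_equal(mean(lws), 14, tolerance = 2)
})

test_that("group constraints survive the fit: one amplitude per anomer", {
  t <- csi_time_axis()
  sims <- equal_concentration_fids(t)
  fit <- fit_fid(sims$d7$fid, sims$d7$model, dwell = 1 / 1200)
  # the parameter vector holds exactly two glucose amplitudes and one
  # glucose linewidth; reported glucose amplitude is their number-weighted sum
  expect_length(fit$params$amplitudes[c("glc_alpha", "glc_beta")], 2)
  expect_equal(
    fit$amplitudes[["glc"]],
    7 * sum(fit$params$amplitudes[c("glc_alpha", "glc_beta")]))
  expect_length(fit$params$linewidths[["glc"]], 1)
})

test_that("spectral SNR behaves like a peak-over-noise ratio", {
  m <- build_prior_model("d2")
  t <- csi_time_axis()
  p <- single_resonance_params(m, "hdo", amplitude = 1, linewidth = 14)
  clean <- evaluate_fid(m, p, t)
  # noiseless input: effectively unbounded SNR (only the far Lorentzian
  # tails reach the noise window)
  expect_gt(estimate_snr(clean, 1 / 1200), 1000)

  set.seed(31)
  noise <- complex(real = rnorm(256, 0, 0.02),
                   imaginary = rnorm(256, 0, 0.02))
  s1 <- estimate_snr(clean + noise, 1 / 1200)
  s2 <- estimate_snr(2 * clean + noise, 1 / 1200)
  expect_equal(s2 / s1, 2, tolerance = 0.02)

  expect_error(estimate_snr(clean, 1 / 1200, peak_hz = c(-40, 200),
                            noise_hz = c(150, Inf)), "disjoint")

  # pure noise: distribution centred near a Monte-Carlo oracle built from
  # raw draws (max magnitude in the peak window over noise-window SD)
  oracle <- replicate(400, {
    sp <- fft(complex(real = rnorm(256), imaginary = rnorm(256)))
    k <- 0:255
    freq <- ifelse(k < 128, k, k - 256) / (256 / 1200)
    max(Mod(sp[freq >= -40 & freq <= 40])) / sd(Re(sp[freq >= 150]))
  })
  measured <- replicate(400, {
    estimate_snr(complex(real = rnorm(256), imaginary = rnorm(256)), 1 / 1200)
  })
  expect_equal(mean(measured), mean(oracle), tolerance = 0.1 * mean(oracle))
})
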