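# Shared fixtures: small acquisition geometries, uniform phantoms and
# convenience constructors used across the test files.

csi_time_axis <- function(n = 256, bw = 1200) (seq_len(n) - 1L) / bw

# params with a single active resonance (all other amplitudes zero)
single_resonance_params <- function(model, group, amplitude = 1, phase = 0,
                                    linewidth = 10, f0 = 0) {
  amps <- stats::setNames(rep(0, length(model$amp_groups)),
                          model$amp_groups)
  amps[group] <- amplitude
  spectral_params(model, amplitudes = amps, phases = phase,
                  linewidths = linewidth, f0_hz = f0)
}

# equal-concentration composite FIDs for both isotopologues (kappa = E = 1)
equal_concentration_fids <- function(t, conc_glc = 1, anomer_alpha = 0.36,
                                     hdo = 3, glx_d2 = 0.4, lac_d2 = 0.1) {
  lapply(c(d2 = "d2", d7 = "d7"), function(iso) {
    m <- build_prior_model(iso)
    n_ratio <- if (iso == "d7") 1.5 else 1           # Glx label scaling
    n_ratio_lac <- if (iso == "d7") 1.28 / 0.85 else 1
    p <- spectral_params(
      m,
      amplitudes = c(glc_alpha = anomer_alpha * conc_glc,
                     glc_beta = (1 - anomer_alpha) * conc_glc,
                     hdo = hdo, glx = glx_d2 * n_ratio,
                     lac = lac_d2 * n_ratio_lac),
      linewidths = 14)
    list(model = m, fid = evaluate_fid(m, p, t))
  })
}

# a minimal one-resonance prior (water only) for oracle comparisons
one_resonance_model <- function(shift_ppm = 4.8) {
  structure(list(
    resonances = data.frame(
      name = "hdo", shift_ppm = shift_ppm, amp_group = "hdo", weight = 1,
      phase_group = "hdo", lw_group = "hdo", metabolite = "hdo",
      stringsAsFactors = FALSE),
    isotopologue = "d2", n_positions = 0,
    reference_shift_ppm = 4.8, spectrometer_freq_mhz = 45.8,
    amp_groups = "hdo", phase_groups = "hdo", lw_groups = "hdo"
  ), class = "dmi_prior")
}

# a phantom with spatially uniform composition (for constancy checks)
uniform_phantom <- function(grid = c(6, 6, 4), gm = 1, wm = 0, csf = 0) {
  z <- array(0, grid)
  structure(list(
    csf = z + csf, gm = z + gm, wm = z + wm,
    brain_mask = array(TRUE, grid),
    occipital_mask = array(FALSE, grid),
    frontal_mask = array(FALSE, grid),
    grid_shape = grid, voxel_mm = 15
  ), class = "dmi_phantom")
}

# magnitude spectrum with fftshifted frequency axis
mag_spectrum <- function(fid, dwell) {
  n <- length(fid)
  k <- seq_len(n) - 1L
  freq <- ifelse(k < n / 2, k, k - n) / (n * dwell)
  ord <- order(freq)
  list(freq = freq[ord], mag = Mod(stats::fft(fid))[ord],
       re = Re(stats::fft(fid))[ord])
}

# a small synthetic time-course data frame on a shared time grid
toy_timecourse <- function(times = seq(10, 130, by = 20),
                           participants = c("p1", "p2"),
                           glx = 0.84, lac = 0.16, glc = 1, hdo = 5,
                           roi = "brain", cohort = "d7") {
  rows <- expand.grid(participant = participants, time_min = times,
                      metabolite = c("glc", "glx", "lac", "hdo"),
                      stringsAsFactors = FALSE)
  base <- c(glc = glc, glx = glx, lac = lac, hdo = hdo)
  rows$conc_mm <- base[rows$metabolite]
  rows$amplitude <- rows$conc_mm
  rows$roi <- roi
  rows$cohort <- cohort
  rows
}
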