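# Synthetic-data generation: gamma-variate metabolite kinetics, a digital
# brain phantom with tissue partial volumes and ROI masks, voxel-domain CSI
# synthesis from the spectral forward model, and two-cohort study emulation.

#' Gamma-variate metabolite kinetic curve
#'
#' `C(t) = A + B (k t)^2 exp(-k t)`: baseline `A`, scale `B` and rate `k`.
#' The curve peaks at `t = 2/k` with maximum `A + 4 B exp(-2)`.
#'
#' @param t time after ingestion in minutes (>= 0).
#' @param params list or named vector with `A` (mM), `B` (mM), `k` (1/min,
#'   > 0).
#' @return Concentration in mM at each `t`.
#' @export
#' @examples
#' kinetic_curve(80, c(A = 0, B = 1, k = 0.025)) # the maximum, 4 exp(-2)
kinetic_curve <- function(t, params) {
  p <- as.list(params)
  stopifnot(p$k > 0, all(t >= 0))
  p$A + p$B * (p$k * t)^2 * exp(-p$k * t)
}

#' Default cohort kinetic parameters
#'
#' Ground-truth concentration kinetics used by the cohort generator.
#' Glucose peaks at 80 min (k = 0.025/min) with a maximum near 1.6 mM;
#' Glx and lactate rise monotonically over the scan window (k = 0.012/min,
#' peak at 167 min) in the fixed concentration proportion 0.84:0.16; the
#' HDO excess above natural abundance rises monotonically (k = 0.008/min)
#' and is scaled between the isotopologues by the label-accounting ratio
#' `(4 + dN7) : dN2`, so that for glucose-d7 the total HDO amplitude
#' exceeds three times the natural-abundance level at 100 min while the
#' d7/d2 HDO ratio is about 2.3-2.4. Glucose, Glx and lactate
#' concentration kinetics are identical for the two cohorts: their signal
#' differences arise from the label numbers alone.
#'
#' @param isotopologue `"d2"` or `"d7"`.
#' @return Named list of `A`/`B`/`k` vectors for `glc`, `glx`, `lac` and
#'   `hdo_delta` (HDO excess above natural abundance, in mM).
#' @export
default_cohort_kinetics <- function(isotopologue = c("d2", "d7")) {
  isotopologue <- match.arg(isotopologue)
  acc <- label_accounting()
  hdo_scale <- if (isotopologue == "d7") 1 else
    acc$dn2 / (4 + acc$dn7)
  list(
    glc = c(A = 0, B = 2.96, k = 0.025),
    glx = c(A = 0, B = 0.84 * 2.47, k = 0.012),
    lac = c(A = 0, B = 0.16 * 2.47, k = 0.012),
    hdo_delta = c(A = 0, B = 126 * hdo_scale, k = 0.008)
  )
}

#' Digital brain phantom with tissue partial volumes and ROI masks
#'
#' An ellipsoidal "brain" on the CSI voxel grid: a grey-matter shell, a
#' white-matter core and CSF-filled central ventricles, with smooth partial
#' volumes at the boundaries. ROI masks: whole brain, and disjoint
#' occipital (posterior) and frontal (anterior) cortical regions excluding
#' the ventricles.
#'
#' @param grid_shape integer(3) voxel grid (default `c(12, 12, 8)`).
#' @param voxel_mm isotropic voxel size in mm (default 15).
#' @param seed unused placeholder for API stability; the phantom is
#'   deterministic.
#' @return An object of class `dmi_phantom`: arrays `csf`, `gm`, `wm`
#'   (partial volumes in [0, 1], summing to <= 1), logical masks
#'   `brain_mask`, `occipital_mask`, `frontal_mask`, plus `grid_shape` and
#'   `voxel_mm`.
#' @export
make_phantom <- function(grid_shape = c(12, 12, 8), voxel_mm = 15,
                         seed = NULL) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4))
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.46 * nx; ay <- 0.46 * ny; az <- 0.46 * nz

  idx <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  r <- sqrt(((idx$i - cx) / ax)^2 + ((idx$j - cy) / ay)^2 +
              ((idx$k - cz) / az)^2)
  r <- array(r, grid_shape)
  # ventricles: small central ellipsoid
  rv <- sqrt(((array(idx$i, grid_shape) - cx) / (0.22 * nx))^2 +
               ((array(idx$j, grid_shape) - cy) / (0.22 * ny))^2 +
               ((array(idx$k, grid_shape) - cz) / (0.20 * nz))^2)

  ramp <- function(x) pmin(pmax(x, 0), 1)
  brain_pv <- ramp((1 - r) / 0.12)          # 1 well inside, 0 outside
  vent_pv <- ramp((1 - rv) / 0.30) * brain_pv
  shell <- ramp((r - 0.68) / 0.12)          # 1 in the outer shell
  gm <- brain_pv * shell * (1 - vent_pv)
  wm <- brain_pv * (1 - shell) * (1 - vent_pv)
  csf <- vent_pv

  brain_mask <- (csf + gm + wm) > 0.9
  jj <- array(rep(seq_len(ny), each = nx), grid_shape)
  cortex <- brain_mask & (vent_pv < 0.05)
  occipital <- cortex & (jj <= floor(ny / 3))
  frontal <- cortex & (jj >= ceiling(2 * ny / 3) + 1)

  structure(list(
    csf = csf, gm = gm, wm = wm,
    brain_mask = brain_mask,
    occipital_mask = occipital,
    frontal_mask = frontal,
    grid_shape = grid_shape,
    voxel_mm = voxel_mm
  ), class = "dmi_phantom")
}

#' @export
print.dmi_phantom <- function(x, ...) {
  cat("Brain phantom ", paste(x$grid_shape, collapse = "x"), " voxels (",
      x$voxel_mm, " mm); brain ", sum(x$brain_mask), ", occipital ",
      sum(x$occipital_mask), ", frontal ", sum(x$frontal_mask),
      " voxels\n", sep = "")
  invisible(x)
}

# per-voxel HDO attenuation factor under fast exchange (vectorised)
.voxel_hdo_e <- function(phantom, config) {
  w_csf <- phantom$csf * config$water_fraction[["csf"]]
  w_gm <- phantom$gm * config$water_fraction[["gm"]]
  w_wm <- phantom$wm * config$water_fraction[["wm"]]
  wtot <- w_csf + w_gm + w_wm
  rate <- (w_csf / config$t1_hdo_s[["csf"]] +
             w_gm / config$t1_hdo_s[["gm"]] +
             w_wm / config$t1_hdo_s[["wm"]])
  t1 <- ifelse(wtot > 0, wtot / rate, config$t1_hdo_s[["gm"]])
  e <- attenuation_factor(config$tr_s, pmax(t1, 1e-6), config$flip_deg)
  e[wtot == 0] <- 0
  e
}

#' Synthesize a CSI dataset from the forward model
#'
#' Builds the per-voxel complex FID implied by the phantom's tissue
#' composition and the supplied metabolite concentrations, using the
#' spectral prior model, steady-state attenuation per metabolite (HDO with
#' a per-voxel fast-exchange T1), the isotopologue's label numbers and a
#' signal scale `kappa`, then adds circular white Gaussian noise in the
#' time domain.
#'
#' Per-voxel amplitudes follow `A_m = C_m * kappa * E_m * N_m`, with the
#' glucose amplitude split over the two anomers and over the labelled
#' positions. The HDO concentration is the natural-abundance level implied
#' by the local water fraction plus `conc$hdo_delta` (scaled by local water
#' relative to pure water).
#'
#' @param phantom a [make_phantom()] object.
#' @param conc named list of concentrations in mM: `glc`, `glx`, `lac`
#'   (scalars, per unit total-tissue fraction) and `hdo_delta` (HDO excess
#'   above natural abundance, per unit water fraction relative to pure
#'   water).
#' @param config a [quant_config()] object (fixes the isotopologue).
#' @param noise_sd time-domain noise standard deviation per real/imaginary
#'   component, `"auto"` to calibrate so the mean natural-abundance HDO
#'   spectral SNR over brain voxels equals `snr_target`, or a number
#'   (0 for noiseless).
#' @param seed RNG seed for the noise (optional).
#' @param kappa signal scale in signal units per mM per label (default 1).
#' @param linewidth_hz Lorentzian linewidth for all resonances (default 14).
#' @param f0_hz water-frequency offset in Hz (default 0).
#' @param anomer_alpha fraction of glucose in the alpha anomer (default
#'   0.36, the aqueous anomeric equilibrium).
#' @param n_samples FID samples (default 256).
#' @param bandwidth_hz spectral width in Hz (default 1200).
#' @param snr_target target natural-abundance HDO SNR for
#'   `noise_sd = "auto"` (default 14).
#' @param time_min acquisition time after ingestion, min (metadata).
#' @return An object of class `dmi_csi`: complex array `data` of dimension
#'   `c(n_samples, grid_shape)` plus acquisition metadata (`dwell_s`,
#'   `tr_s`, `flip_deg`, `freq_mhz`, `begin_time_s`, `voxel_mm`,
#'   `time_min`, `isotopologue`, `noise_sd`).
#' @export
synthesize_csi <- function(phantom, conc, config = quant_config("d7"),
                           noise_sd = "auto", seed = NULL, kappa = 1,
                           linewidth_hz = 14, f0_hz = 0,
                           anomer_alpha = 0.36,
                           n_samples = 256, bandwidth_hz = 1200,
                           snr_target = 14, time_min = NA_real_) {
  stopifnot(inherits(phantom, "dmi_phantom"))
  model <- build_prior_model(config$isotopologue)
  grid <- phantom$grid_shape
  nvox <- prod(grid)
  dwell <- 1 / bandwidth_hz
  t <- (seq_len(n_samples) - 1L) * dwell

  tissue <- phantom$csf + phantom$gm + phantom$wm
  water <- phantom$csf * config$water_fraction[["csf"]] +
    phantom$gm * config$water_fraction[["gm"]] +
    phantom$wm * config$water_fraction[["wm"]]

  e_glc <- attenuation_factor(config$tr_s, config$t1_s[["glc"]],
                              config$flip_deg)
  e_glx <- attenuation_factor(config$tr_s, config$t1_s[["glx"]],
                              config$flip_deg)
  e_lac <- attenuation_factor(config$tr_s, config$t1_s[["lac"]],
                              config$flip_deg)
  e_hdo <- .voxel_hdo_e(phantom, config)

  conc0 <- list(glc = 0, glx = 0, lac = 0, hdo_delta = 0)
  conc <- utils::modifyList(conc0, as.list(conc))

  c_glc <- conc$glc * tissue
  c_glx <- conc$glx * tissue
  c_lac <- conc$lac * tissue
  c_hdo <- natural_abundance_hdo_concentration(1, config) * water +
    conc$hdo_delta * water

  # per-voxel amplitude for each amplitude group (per resonance for glucose)
  amp <- rbind(
    glc_alpha = kappa * e_glc * anomer_alpha * as.vector(c_glc),
    glc_beta = kappa * e_glc * (1 - anomer_alpha) * as.vector(c_glc),
    hdo = kappa * as.vector(e_hdo) * config$n_labels[["hdo"]] *
      as.vector(c_hdo),
    glx = kappa * e_glx * config$n_labels[["glx"]] * as.vector(c_glx),
    lac = kappa * e_lac * config$n_labels[["lac"]] * as.vector(c_lac)
  )

  params0 <- spectral_params(
    model, amplitudes = stats::setNames(rep(1, length(model$amp_groups)),
                                        model$amp_groups),
    phases = 0, linewidths = linewidth_hz, f0_hz = f0_hz, begin_time = 0)
  basis <- .fid_basis(model, params0, t)        # n_samples x n_resonances
  # collapse resonances to amplitude groups
  g <- model$resonances$amp_group
  gbasis <- vapply(model$amp_groups, function(gg) {
    rowSums(basis[, g == gg, drop = FALSE])
  }, complex(n_samples))                        # n_samples x n_groups

  clean <- gbasis %*% amp[model$amp_groups, , drop = FALSE]

  if (identical(noise_sd, "auto")) {
    # NA-only reference: HDO amplitude at natural abundance, no metabolites
    na_amp <- kappa * as.vector(e_hdo) *
      natural_abundance_hdo_concentration(1, config) * as.vector(water)
    na_clean <- outer(drop(gbasis[, "hdo"]), na_amp)
    peaks <- apply(Mod(stats::mvfft(na_clean[, phantom$brain_mask,
                                             drop = FALSE])), 2, max)
    noise_sd <- mean(peaks) / (snr_target * sqrt(n_samples))
  }

  if (!is.null(seed)) set.seed(seed)
  if (noise_sd > 0) {
    noise <- complex(real = stats::rnorm(n_samples * nvox, 0, noise_sd),
                     imaginary = stats::rnorm(n_samples * nvox, 0, noise_sd))
    clean <- clean + matrix(noise, n_samples, nvox)
  }

  structure(list(
    data = array(clean, c(n_samples, grid)),
    dwell_s = dwell, tr_s = config$tr_s, flip_deg = config$flip_deg,
    freq_mhz = 45.8, begin_time_s = 0, voxel_mm = phantom$voxel_mm,
    time_min = time_min, isotopologue = config$isotopologue,
    noise_sd = noise_sd, denoised = FALSE
  ), class = "dmi_csi")
}

#' @export
print.dmi_csi <- function(x, ...) {
  d <- dim(x$data)
  cat("CSI dataset: ", d[1], " samples x ", paste(d[2:4], collapse = "x"),
      " voxels, ", 1 / x$dwell_s, " Hz bandwidth, TR ", x$tr_s * 1000,
      " ms, FA ", x$flip_deg, " deg (", x$isotopologue, ")\n", sep = "")
  if (!is.na(x$time_min)) cat("acquired ", x$time_min,
                              " min after ingestion\n", sep = "")
  invisible(x)
}

#' Cohort specification
#'
#' @param n_d2,n_d7 participants per cohort (default 8 and 7).
#' @param start_range_min range of scan-start times after ingestion, min
#'   (default `c(2, 31)`).
#' @param repeats number of serial post-ingestion CSI acquisitions per
#'   participant, or a range sampled per participant (default `c(5, 6)`).
#' @param repeat_spacing_min time between serial acquisitions (default
#'   11.2 min, the CSI scan duration).
#' @param amp_scale_sd log-normal sigma of the per-participant amplitude
#'   scale (default 0.1).
#' @param freq_drift_hz half-width of the uniform per-participant water
#'   frequency offset (default 5 Hz).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_d2 = 8, n_d7 = 7, start_range_min = c(2, 31),
                        repeats = c(5, 6), repeat_spacing_min = 11.2,
                        amp_scale_sd = 0.1, freq_drift_hz = 5) {
  stopifnot(n_d2 >= 0, n_d7 >= 0, n_d2 + n_d7 >= 1,
            all(start_range_min >= 0), all(start_range_min <= 60))
  structure(list(n_d2 = n_d2, n_d7 = n_d7,
                 start_range_min = start_range_min, repeats = repeats,
                 repeat_spacing_min = repeat_spacing_min,
                 amp_scale_sd = amp_scale_sd,
                 freq_drift_hz = freq_drift_hz), class = "cohort_spec")
}

#' Generate a synthetic two-cohort study
#'
#' Emulates the study design: each participant gets one natural-abundance
#' CSI acquisition before ingestion and a series of timed post-ingestion
#' CSI acquisitions whose start time is staggered across participants.
#' Metabolite concentrations follow [default_cohort_kinetics()] (or
#' user-supplied kinetics), modulated by per-participant random effects
#' (log-normal amplitude scale, uniform water-frequency drift).
#'
#' @param spec a [cohort_spec()].
#' @param phantom a [make_phantom()] object shared by all participants.
#' @param seed RNG seed; the full cohort is reproducible given the seed.
#' @param kinetics optional function `(isotopologue) -> kinetic params`
#'   (default [default_cohort_kinetics()]).
#' @param noise_sd noise level passed to [synthesize_csi()]; the default
#'   `"auto"` is calibrated once on the phantom and reused for every scan.
#' @param ... further arguments passed to [synthesize_csi()].
#' @return A list of class `dmi_cohort` of participants, each a list with
#'   `id`, `isotopologue`, `start_min`, `times_min`, `amp_scale`,
#'   `freq_drift_hz`, `na_scan` (a `dmi_csi`) and `scans` (list of
#'   `dmi_csi`).
#' @export
generate_cohort <- function(spec = cohort_spec(), phantom = make_phantom(),
                            seed = 1, kinetics = default_cohort_kinetics,
                            noise_sd = "auto", ...) {
  set.seed(seed)
  if (identical(noise_sd, "auto")) {
    cfg0 <- quant_config("d7")
    probe <- synthesize_csi(phantom, list(), cfg0, noise_sd = "auto",
                            seed = NULL, ...)
    noise_sd <- probe$noise_sd
  }
  cohorts <- c(rep("d2", spec$n_d2), rep("d7", spec$n_d7))
  participants <- vector("list", length(cohorts))
  for (p in seq_along(cohorts)) {
    iso <- cohorts[p]
    cfg <- quant_config(iso)
    kin <- kinetics(iso)
    start <- stats::runif(1, spec$start_range_min[1], spec$start_range_min[2])
    nrep <- if (length(spec$repeats) > 1) {
      sample(seq(min(spec$repeats), max(spec$repeats)), 1)
    } else spec$repeats
    times <- start + (seq_len(nrep) - 1L) * spec$repeat_spacing_min
    amp_scale <- stats::rlnorm(1, 0, spec$amp_scale_sd)
    drift <- stats::runif(1, -spec$freq_drift_hz, spec$freq_drift_hz)

    na_scan <- synthesize_csi(
      phantom, list(), cfg, noise_sd = noise_sd,
      kappa = amp_scale, f0_hz = drift, time_min = 0, ...)
    scans <- lapply(times, function(tm) {
      synthesize_csi(
        phantom,
        list(glc = kinetic_curve(tm, kin$glc),
             glx = kinetic_curve(tm, kin$glx),
             lac = kinetic_curve(tm, kin$lac),
             hdo_delta = kinetic_curve(tm, kin$hdo_delta)),
        cfg, noise_sd = noise_sd, kappa = amp_scale, f0_hz = drift,
        time_min = tm, ...)
    })
    participants[[p]] <- list(
      id = sprintf("%s_%02d", iso, p), isotopologue = iso,
      start_min = start, times_min = times, amp_scale = amp_scale,
      freq_drift_hz = drift, na_scan = na_scan, scans = scans)
  }
  structure(participants, class = "dmi_cohort",
            phantom = phantom, noise_sd = noise_sd, seed = seed)
}

#' @export
print.dmi_cohort <- function(x, ...) {
  iso <- vapply(x, `[[`, "", "isotopologue")
  cat("Synthetic DMI cohort: ", sum(iso == "d2"), " glucose-d2 + ",
      sum(iso == "d7"), " glucose-d7 participants\n", sep = "")
  invisible(x)
}
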