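# End-to-end orchestration: simulate -> denoise -> fit -> quantify ->
# dynamics, with a JSON-serialisable summary. All stages are deterministic
# given the seed in the configuration.

#' Default pipeline configuration
#'
#' Single source of truth for the pipeline's tunable settings. The
#' quantification constants live in [quant_config()]; everything here is
#' study design and analysis windows.
#'
#' @param seed RNG seed for the whole run.
#' @param grid_shape CSI voxel grid (default `c(12, 12, 8)`).
#' @param n_d2,n_d7 cohort sizes (defaults 8 and 7).
#' @param repeats serial CSI repeats per participant (default `c(5, 6)`).
#' @param denoise logical: apply Tucker denoising (default TRUE).
#' @param core_shape Tucker core, `NULL` for the proportional default.
#' @param ratio_window summary window for isotopologue ratios, min
#'   (default `c(100, 120)`).
#' @param ttest_window window for the region t-test (default `c(80, 100)`).
#' @param plateau_window window for plateau concentration ratios (default
#'   `c(50, 140)`).
#' @param n_reps_snr_sim repetitions for the SNR-gain simulation; 0 skips
#'   the experiments stage (default 0 -- run it explicitly via
#'   [glucose_snr_gain_simulation()]).
#' @return A list of class `dmi_config`.
#' @export
dmi_default_config <- function(seed = 1, grid_shape = c(12, 12, 8),
                               n_d2 = 8, n_d7 = 7, repeats = c(5, 6),
                               denoise = TRUE, core_shape = NULL,
                               ratio_window = c(100, 120),
                               ttest_window = c(80, 100),
                               plateau_window = c(50, 140),
                               n_reps_snr_sim = 0) {
  structure(list(
    seed = seed, grid_shape = grid_shape,
    cohort = cohort_spec(n_d2 = n_d2, n_d7 = n_d7, repeats = repeats),
    denoise = denoise, core_shape = core_shape,
    ratio_window = ratio_window, ttest_window = ttest_window,
    plateau_window = plateau_window,
    n_reps_snr_sim = n_reps_snr_sim
  ), class = "dmi_config")
}

.phantom_rois <- function(phantom) {
  list(brain = phantom$brain_mask,
       occipital = phantom$occipital_mask,
       frontal = phantom$frontal_mask)
}

# ROI-level metabolite amplitudes (complex mean and its magnitude) from a
# fitted CSI volume
.roi_amplitudes <- function(fit, rois) {
  out <- list()
  for (roi in names(rois)) {
    for (met in fit$metabolites) {
      i <- match(met, fit$metabolites)
      z <- .roi_complex_mean(
        fit$amplitude[, , , i], fit$phase[, , , i], rois[[roi]])
      out[[paste(roi, met)]] <- data.frame(
        roi = roi, metabolite = met,
        amplitude = Mod(z), amp_re = Re(z), amp_im = Im(z),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Process one participant's scans into a time course
#'
#' Denoises each acquisition, fits every brain voxel, averages the complex
#' amplitude maps over the ROIs, calibrates kappa per ROI from the
#' pre-ingestion natural-abundance HDO amplitude, and converts amplitudes
#' to concentrations.
#'
#' @param participant one element of a [generate_cohort()] result.
#' @param phantom the phantom the cohort was generated on.
#' @param config a [dmi_default_config()] list.
#' @return A list with `timecourse` (data frame rows for this participant)
#'   and `na_hdo` (per-ROI natural-abundance HDO amplitudes).
#' @export
process_participant <- function(participant, phantom,
                                config = dmi_default_config()) {
  qc <- quant_config(participant$isotopologue)
  model <- build_prior_model(participant$isotopologue)
  rois <- .phantom_rois(phantom)
  roi_comp <- lapply(rois, function(m) roi_composition(phantom, m, qc))

  prep <- function(scan) {
    if (config$denoise) scan <- tucker_denoise(scan, config$core_shape)
    fit_csi(scan, model, mask = phantom$brain_mask)
  }

  na_fit <- prep(participant$na_scan)
  na_amp <- .roi_amplitudes(na_fit, rois)
  na_hdo <- stats::setNames(
    na_amp$amplitude[na_amp$metabolite == "hdo"],
    na_amp$roi[na_amp$metabolite == "hdo"])
  kappa <- vapply(names(rois), function(r) {
    calibrate_kappa(na_hdo[[r]], roi_comp[[r]], qc)
  }, numeric(1))

  rows <- list()
  add_rows <- function(amp_tab, time_min) {
    amp_tab$participant <- participant$id
    amp_tab$cohort <- participant$isotopologue
    amp_tab$time_min <- time_min
    # concentration magnitude plus the complex concentration components,
    # so serial acquisitions can be combined coherently downstream
    scale <- mapply(function(a, roi, met) {
      concentration_from_amplitude(1, met, kappa[[roi]], roi_comp[[roi]], qc)
    }, amp_tab$amplitude, amp_tab$roi, amp_tab$metabolite)
    amp_tab$conc_mm <- amp_tab$amplitude * scale
    amp_tab$conc_re <- amp_tab$amp_re * scale
    amp_tab$conc_im <- amp_tab$amp_im * scale
    amp_tab
  }
  rows[["na"]] <- add_rows(na_amp, 0)
  for (s in seq_along(participant$scans)) {
    fit <- prep(participant$scans[[s]])
    rows[[as.character(s)]] <- add_rows(.roi_amplitudes(fit, rois),
                                        participant$times_min[s])
  }
  tc <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tc <- tc[, c("participant", "cohort", "roi", "metabolite", "time_min",
               "amplitude", "conc_mm", "conc_re", "conc_im")]
  list(timecourse = tc, na_hdo = na_hdo)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort, processes every participant
#' ([process_participant()]), assembles the normalised cohort time course,
#' and computes the headline dynamic summaries: plateau concentration
#' ratios, metabolite fractions, glucose kinetics, segmented
#' lactate-vs-Glx gradients, the occipital-vs-frontal comparison, the
#' isotopologue ratio curves (when both cohorts are present) and the label
#' accounting predictions.
#'
#' @param config a [dmi_default_config()] list.
#' @param phantom optional phantom (default built from
#'   `config$grid_shape`).
#' @param cohort optional pre-generated cohort (default: generated from the
#'   config).
#' @return A list of class `dmi_pipeline` with `timecourse` (data frame),
#'   `summary` (named list of scalar results), `kinetic_fits`,
#'   `config`.
#' @export
run_pipeline <- function(config = dmi_default_config(), phantom = NULL,
                         cohort = NULL) {
  if (is.null(phantom)) phantom <- make_phantom(config$grid_shape)
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$cohort, phantom, seed = config$seed)
  }

  res <- lapply(cohort, process_participant, phantom = phantom,
                config = config)
  tc <- do.call(rbind, c(lapply(res, `[[`, "timecourse"),
                         list(make.row.names = FALSE)))
  na_hdo_brain <- vapply(res, function(r) r$na_hdo[["brain"]], numeric(1))
  names(na_hdo_brain) <- vapply(cohort, `[[`, "", "id")
  tc <- normalize_to_na_hdo(tc, na_hdo_brain)

  summary <- list()
  kinetic_fits <- list()
  win <- config$plateau_window

  # participant-level plateau concentration: in-window serial records are
  # averaged as complex values before taking the magnitude, so that noise
  # on weak resonances (lactate) is not rectified upward
  plateau_conc <- function(sub_met) {
    per_part <- tapply(
      complex(real = sub_met$conc_re, imaginary = sub_met$conc_im),
      sub_met$participant, function(z) Mod(mean(z)))
    mean(per_part)
  }

  for (iso in unique(tc$cohort)) {
    sub <- tc[tc$cohort == iso & tc$roi == "brain" & tc$time_min > 0, ]
    in_win <- sub$time_min >= win[1] & sub$time_min <= win[2]
    glx <- sub[sub$metabolite == "glx" & in_win, ]
    lac <- sub[sub$metabolite == "lac" & in_win, ]
    if (nrow(glx) && nrow(lac)) {
      glx_c <- plateau_conc(glx)
      lac_c <- plateau_conc(lac)
      summary[[paste0("lac_over_glx_plateau_", iso)]] <- lac_c / glx_c
      summary[[paste0("glx_fraction_plateau_", iso)]] <-
        glx_c / (glx_c + lac_c)
    }
    glc <- sub[sub$metabolite == "glc", ]
    if (nrow(glc) >= 4) {
      kf <- fit_kinetic_curve(glc$time_min, glc$conc_mm)
      kinetic_fits[[paste0("glc_", iso)]] <- kf
      summary[[paste0("glc_tmax_min_", iso)]] <- kf$t_max_min
      summary[[paste0("glc_cmax_mm_", iso)]] <- kf$c_max
    }
    hdo <- sub[sub$metabolite == "hdo", ]
    if (nrow(hdo)) {
      n_part <- length(unique(sub$participant))
      if (nrow(hdo) >= n_part) {
        curve <- moving_average_timecourse(hdo$time_min, hdo$norm_amplitude,
                                           n_part)
        i100 <- which.min(abs(curve$time_min - 100))
        summary[[paste0("hdo_norm_at_100min_", iso)]] <- curve$mean[i100]
      }
    }
  }

  if (all(c("d2", "d7") %in% tc$cohort)) {
    for (met in c("glc", "glx", "lac", "hdo")) {
      curves <- lapply(c(d7 = "d7", d2 = "d2"), function(iso) {
        sub <- tc[tc$cohort == iso & tc$roi == "brain" &
                    tc$metabolite == met & tc$time_min > 0, ]
        n_part <- length(unique(sub$participant))
        moving_average_timecourse(sub$time_min, sub$norm_amplitude, n_part)
      })
      rat <- tryCatch(
        isotopologue_ratio(curves$d7, curves$d2, config$ratio_window),
        error = function(e) NULL)
      if (!is.null(rat) && is.finite(rat$window_mean)) {
        summary[[paste0("ratio_d7_d2_", met)]] <- rat$window_mean
      }
    }
  }

  seg <- tryCatch(
    segmented_lac_glx_regression(tc[tc$time_min > 0, ]),
    error = function(e) NULL)

  ttest <- tryCatch({
    iso_main <- if ("d7" %in% tc$cohort) "d7" else "d2"
    region_ttest(tc[tc$cohort == iso_main & tc$time_min > 0, ],
                 "occipital", "frontal", "glx", config$ttest_window)
  }, error = function(e) NULL)
  if (!is.null(ttest)) summary$glx_occipital_vs_frontal_p <- ttest$p.value

  acc <- label_accounting()
  summary$delta_n_d2 <- acc$dn2
  summary$delta_n_d7 <- acc$dn7
  summary$delta_hdo_upper_ratio <- delta_hdo_upper_ratio(acc)

  experiments <- NULL
  if (config$n_reps_snr_sim > 0) {
    experiments <- glucose_snr_gain_simulation(
      snr_sim_config(n_reps = config$n_reps_snr_sim), seed = config$seed)
    summary$glc_snr_gain_d7_d2 <- experiments$ratio
  }

  structure(list(
    timecourse = tc, summary = summary, kinetic_fits = kinetic_fits,
    segmented_regression = seg, region_ttest = ttest,
    experiments = experiments, config = config
  ), class = "dmi_pipeline")
}

#' @export
print.dmi_pipeline <- function(x, ...) {
  cat("DMI analysis pipeline result:",
      length(unique(x$timecourse$participant)), "participants,",
      nrow(x$timecourse), "time-course records\n")
  for (k in names(x$summary)) {
    cat(sprintf("  %-28s %s\n", k, signif(x$summary[[k]], 4)))
  }
  invisible(x)
}

#' Write a pipeline summary to JSON
#'
#' @param result a [run_pipeline()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_summary <- function(result, path) {
  jsonlite::write_json(result$summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
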