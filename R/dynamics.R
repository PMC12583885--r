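# Cohort-level time-course analysis: normalisation to natural-abundance
# HDO, moving-average curves, isotopologue ratios, metabolite fractions,
# segmented lactate-vs-Glx regression, gamma-variate kinetic fits and the
# region-comparison t-test.

# A time course is a data frame with columns: participant, cohort, roi,
# metabolite, time_min, amplitude and (optionally) norm_amplitude, conc_mm.
.check_timecourse <- function(tc) {
  need <- c("participant", "cohort", "roi", "metabolite", "time_min",
            "amplitude")
  miss <- setdiff(need, names(tc))
  if (length(miss)) stop("time course lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tc$time_min < 0)) stop("times must be >= 0")
  invisible(tc)
}

#' Normalise a time course to natural-abundance HDO
#'
#' Divides each participant's amplitudes by that participant's
#' natural-abundance HDO amplitude (measured at t = 0, before ingestion),
#' making amplitudes comparable across participants and cohorts.
#'
#' @param tc time-course data frame.
#' @param na_hdo named numeric: natural-abundance HDO amplitude per
#'   participant (per ROI: a data frame with `participant`, `roi`,
#'   `na_hdo` is also accepted).
#' @return The time course with a `norm_amplitude` column.
#' @export
normalize_to_na_hdo <- function(tc, na_hdo) {
  .check_timecourse(tc)
  if (is.data.frame(na_hdo)) {
    key <- paste(tc$participant, tc$roi)
    ref <- stats::setNames(na_hdo$na_hdo, paste(na_hdo$participant,
                                                na_hdo$roi))
    denom <- ref[key]
  } else {
    denom <- na_hdo[tc$participant]
  }
  if (any(is.na(denom))) {
    stop("missing natural-abundance HDO record for participant(s): ",
         paste(unique(tc$participant[is.na(denom)]), collapse = ", "))
  }
  if (any(denom <= 0)) stop("natural-abundance HDO amplitudes must be > 0")
  tc$norm_amplitude <- tc$amplitude / unname(denom)
  tc
}

#' Moving-average curve over a pooled time course
#'
#' Orders the pooled records in time and slides a window of `window_size`
#' records with stride one; reports the mean and standard deviation of the
#' value in each window at the mean acquisition time of the window. The
#' window size defaults to the number of participants, so each window
#' holds roughly one record per participant.
#'
#' @param times record times in minutes.
#' @param values record values.
#' @param window_size records per window.
#' @return Data frame with `time_min`, `mean`, `sd`, `n`.
#' @export
moving_average_timecourse <- function(times, values, window_size) {
  stopifnot(length(times) == length(values), window_size >= 1)
  if (length(times) < window_size) {
    stop("window larger than the number of records")
  }
  ord <- order(times)
  t <- times[ord]; v <- values[ord]
  n_out <- length(t) - window_size + 1L
  out <- data.frame(time_min = numeric(n_out), mean = numeric(n_out),
                    sd = numeric(n_out), n = window_size)
  for (i in seq_len(n_out)) {
    w <- i:(i + window_size - 1L)
    out$time_min[i] <- mean(t[w])
    out$mean[i] <- mean(v[w])
    out$sd[i] <- stats::sd(v[w])
  }
  out
}

#' Ratio of d7 to d2 metabolite curves
#'
#' Interpolates the glucose-d2 curve linearly onto the glucose-d7 time
#' points, forms the pointwise ratio, and summarises it as mean and SD over
#' a reporting window (default 100-120 min).
#'
#' @param curve_d7,curve_d2 data frames with `time_min` and `mean` (as from
#'   [moving_average_timecourse()]).
#' @param window summary window in minutes (default `c(100, 120)`).
#' @return A list with `time_min`, `ratio` (at the d7 time points falling
#'   inside the d2 range), `window`, `window_mean`, `window_sd`.
#' @export
isotopologue_ratio <- function(curve_d7, curve_d2, window = c(100, 120)) {
  rng <- range(curve_d2$time_min)
  keep <- curve_d7$time_min >= rng[1] & curve_d7$time_min <= rng[2]
  if (!any(keep)) stop("the curves have no overlapping time range")
  t7 <- curve_d7$time_min[keep]
  d2_interp <- stats::approx(curve_d2$time_min, curve_d2$mean, xout = t7)$y
  ratio <- curve_d7$mean[keep] / d2_interp
  in_win <- t7 >= window[1] & t7 <= window[2]
  list(time_min = t7, ratio = ratio, window = window,
       window_mean = if (any(in_win)) mean(ratio[in_win]) else NA_real_,
       window_sd = if (sum(in_win) > 1) stats::sd(ratio[in_win]) else
         NA_real_)
}

#' Metabolite fraction curves
#'
#' Computes `X / (Glx + Lac)` curves: for glucose, Glx and lactate the
#' ratio of concentrations; for the HDO increase above natural abundance
#' the ratio of T1-corrected amplitudes (amplitude divided by the
#' steady-state attenuation factor). Points where the denominator falls
#' below `flag_sd_mult` times its propagated standard error are kept but
#' flagged.
#'
#' @param tc time-course data frame for one cohort and ROI with `conc_mm`,
#'   `amplitude` and `norm_amplitude` columns; must contain glc, glx, lac
#'   and hdo records on a common time grid per participant.
#' @param roi a [roi_composition()] for the ROI (for the HDO attenuation
#'   factor).
#' @param config a [quant_config()].
#' @param na_hdo_amplitude named per-participant natural-abundance HDO
#'   amplitude (baseline subtracted to form the HDO increase).
#' @param flag_sd_mult denominator SE multiple below which a point is
#'   flagged (default 3).
#' @return Data frame with `participant`, `time_min`, `glx_fraction`,
#'   `lac_fraction`, `glc_over_glxlac`, `dhdo_over_glxlac`, `flagged`.
#' @export
metabolite_fractions <- function(tc, roi, config, na_hdo_amplitude,
                                 flag_sd_mult = 3) {
  .check_timecourse(tc)
  wide <- function(metab, col) {
    sub <- tc[tc$metabolite == metab, c("participant", "time_min", col)]
    names(sub)[3] <- metab
    sub
  }
  m <- Reduce(function(a, b) merge(a, b, by = c("participant", "time_min")),
              list(wide("glx", "conc_mm"), wide("lac", "conc_mm"),
                   wide("glc", "conc_mm")))
  hdo <- wide("hdo", "amplitude")
  m <- merge(m, hdo, by = c("participant", "time_min"))

  e_hdo <- attenuation_factor(config$tr_s, roi$t1_hdo_s, config$flip_deg)
  e_glx <- attenuation_factor(config$tr_s, config$t1_s[["glx"]],
                              config$flip_deg)
  e_lac <- attenuation_factor(config$tr_s, config$t1_s[["lac"]],
                              config$flip_deg)

  denom_conc <- m$glx + m$lac
  glx_amp_t1 <- NULL # amplitudes reconstructed below for the dHDO ratio
  # T1-corrected amplitude ratio for the HDO increase: both numerator and
  # denominator as amplitude / E
  na_amp <- na_hdo_amplitude[m$participant]
  dhdo_t1 <- (m$hdo - na_amp) / e_hdo
  # Glx+Lac T1-corrected amplitudes from concentrations: A/E = C kappa N;
  # kappa cancels in the ratio only if shared, so recover amplitudes
  glxlac_t1 <- NA_real_
  amp_glx <- tc[tc$metabolite == "glx", c("participant", "time_min",
                                          "amplitude")]
  names(amp_glx)[3] <- "glx_amp"
  amp_lac <- tc[tc$metabolite == "lac", c("participant", "time_min",
                                          "amplitude")]
  names(amp_lac)[3] <- "lac_amp"
  m <- merge(merge(m, amp_glx, by = c("participant", "time_min")),
             amp_lac, by = c("participant", "time_min"))
  glxlac_t1 <- m$glx_amp / e_glx + m$lac_amp / e_lac

  se_floor <- flag_sd_mult * stats::sd(denom_conc) / sqrt(length(denom_conc))
  data.frame(
    participant = m$participant,
    time_min = m$time_min,
    glx_fraction = m$glx / denom_conc,
    lac_fraction = m$lac / denom_conc,
    glc_over_glxlac = m$glc / denom_conc,
    dhdo_over_glxlac = dhdo_t1 / glxlac_t1,
    flagged = denom_conc < se_floor,
    stringsAsFactors = FALSE
  )
}

#' Segmented lactate-versus-Glx regression
#'
#' Ordinary least squares of lactate concentration on Glx concentration,
#' fitted separately for records before and after a breakpoint (default
#' 50 min), per ROI. The early gradient indexes the glycolytic label
#' fraction before the concentration ratio settles.
#'
#' @param tc time-course data frame with `conc_mm` for glx and lac.
#' @param breakpoint_min segment boundary (default 50).
#' @param end_min last time considered (default 140).
#' @return Data frame with one row per ROI and segment: `roi`, `segment`,
#'   `gradient`, `se`, `ci_low`, `ci_high`, `n`.
#' @export
segmented_lac_glx_regression <- function(tc, breakpoint_min = 50,
                                         end_min = 140) {
  .check_timecourse(tc)
  glx <- tc[tc$metabolite == "glx", c("participant", "roi", "time_min",
                                      "conc_mm")]
  lac <- tc[tc$metabolite == "lac", c("participant", "roi", "time_min",
                                      "conc_mm")]
  names(glx)[4] <- "glx"; names(lac)[4] <- "lac"
  m <- merge(glx, lac, by = c("participant", "roi", "time_min"))
  m <- m[m$time_min <= end_min, ]
  out <- list()
  for (roi in unique(m$roi)) {
    for (seg in c("early", "late")) {
      sub <- if (seg == "early") {
        m[m$roi == roi & m$time_min <= breakpoint_min, ]
      } else {
        m[m$roi == roi & m$time_min > breakpoint_min, ]
      }
      if (nrow(sub) < 3) next
      if (stats::sd(sub$glx) == 0) {
        stop("degenerate segment: Glx is constant in ", roi, "/", seg)
      }
      fit <- stats::lm(lac ~ glx, data = sub)
      ci <- stats::confint(fit)["glx", ]
      out[[paste(roi, seg)]] <- data.frame(
        roi = roi, segment = seg,
        gradient = unname(stats::coef(fit)["glx"]),
        se = summary(fit)$coefficients["glx", "Std. Error"],
        ci_low = ci[1], ci_high = ci[2], n = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fit a gamma-variate kinetic curve
#'
#' Nonlinear least squares of `C(t) = A + B (k t)^2 exp(-k t)` to a
#' metabolite time course, reporting the fitted parameters together with
#' the derived maximum (`C_max = A + 4 B exp(-2)`, at `T_max = 2/k`) and
#' the goodness of fit.
#'
#' @param times time in minutes.
#' @param concentrations concentrations (mM) or normalised amplitudes.
#' @param start optional starting values `c(A, B, k)`.
#' @return An object of class `dmi_kinfit`: coefficients `A`, `B`, `k`,
#'   derived `t_max_min`, `c_max`, `r_squared`, `converged`, and the data.
#'   Supports `print`, `coef`, `predict`, `fitted`, `residuals`.
#' @export
fit_kinetic_curve <- function(times, concentrations, start = NULL) {
  stopifnot(length(times) == length(concentrations), length(times) >= 4)
  if (is.null(start)) {
    a0 <- max(min(concentrations), 0)
    k0 <- 2 / max(times[which.max(concentrations)], 1)
    b0 <- max((max(concentrations) - a0) / (4 * exp(-2)), 1e-6)
    start <- c(A = a0, B = b0, k = k0)
  }
  fn <- function(par) {
    kinetic_curve(times, c(A = par[1], B = par[2], k = par[3])) -
      concentrations
  }
  fit <- minpack.lm::nls.lm(
    par = unname(start), fn = fn,
    lower = c(0, 0, 1e-5), upper = c(Inf, Inf, 1),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  par <- stats::setNames(fit$par, c("A", "B", "k"))
  pred <- kinetic_curve(times, par)
  ss_res <- sum((concentrations - pred)^2)
  ss_tot <- sum((concentrations - mean(concentrations))^2)
  structure(list(
    coefficients = par,
    t_max_min = 2 / par[["k"]],
    c_max = par[["A"]] + 4 * par[["B"]] * exp(-2),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    converged = fit$info %in% c(1L, 2L, 3L, 4L),
    times = times, concentrations = concentrations
  ), class = "dmi_kinfit")
}

#' @export
print.dmi_kinfit <- function(x, ...) {
  cat("Gamma-variate kinetic fit: C(t) = A + B (k t)^2 exp(-k t)\n")
  print(signif(x$coefficients, 5))
  cat("T_max =", signif(x$t_max_min, 4), "min, C_max =",
      signif(x$c_max, 4), ", r^2 =", signif(x$r_squared, 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
coef.dmi_kinfit <- function(object, ...) object$coefficients

#' @export
fitted.dmi_kinfit <- function(object, ...) {
  kinetic_curve(object$times, object$coefficients)
}

#' @export
residuals.dmi_kinfit <- function(object, ...) {
  object$concentrations - fitted(object)
}

#' @export
predict.dmi_kinfit <- function(object, times = object$times, ...) {
  kinetic_curve(times, object$coefficients)
}

#' @export
plot.dmi_kinfit <- function(x, ...) {
  graphics::plot(x$times, x$concentrations, xlab = "time (min)",
                 ylab = "concentration", ...)
  tt <- seq(min(x$times), max(x$times), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red3")
  invisible(x)
}

#' Two-sample comparison of regional concentrations
#'
#' Two-sample, two-tailed t-test on participant-level mean concentrations
#' of one metabolite in two ROIs over a time window.
#'
#' @param tc time-course data frame with `conc_mm`.
#' @param roi_a,roi_b ROI labels to compare.
#' @param metabolite metabolite to test.
#' @param window time window in minutes (default `c(80, 100)`).
#' @return The `htest` object from [stats::t.test()].
#' @export
region_ttest <- function(tc, roi_a, roi_b, metabolite,
                         window = c(80, 100)) {
  .check_timecourse(tc)
  sel <- tc$metabolite == metabolite & tc$time_min >= window[1] &
    tc$time_min <= window[2]
  per_part <- function(roi) {
    sub <- tc[sel & tc$roi == roi, ]
    if (nrow(sub) == 0) stop("no records for ROI ", roi, " in the window")
    tapply(sub$conc_mm, sub$participant, mean)
  }
  a <- per_part(roi_a)
  b <- per_part(roi_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("need at least two participants per group")
  }
  stats::t.test(a, b, var.equal = FALSE)
}

#' Glucose-load proxy curve
#'
#' Proxy for the total glucose that has entered the tissue: the observed
#' glucose concentration plus half the summed Glx and lactate
#' concentrations (each glucose yields two labelled product molecules).
#'
#' @param glc,glx,lac concentration vectors on a common time grid.
#' @return `glc + (glx + lac) / 2`.
#' @export
glucose_load_proxy <- function(glc, glx, lac) {
  glc + (glx + lac) / 2
}
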