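#' Default deuterium chemical shift table
#'
#' Chemical shifts (ppm) of the carbon-bound deuterons of both glucose
#' anomers, plus the HDO, Glx and lactate singlets. Deuterium shifts match
#' the corresponding 1H shifts, so the table carries literature 1H values.
#' All fitting is done with shifts expressed relative to the water
#' resonance, so only differences to `hdo` matter.
#'
#' @return A data frame with columns `species` (`"glc_alpha"`, `"glc_beta"`,
#'   `"hdo"`, `"glx"`, `"lac"`), `position` (`"C1"`..`"C6b"` for glucose,
#'   `NA` otherwise) and `shift_ppm`.
#' @export
#' @examples
#' dmi_shift_table()
dmi_shift_table <- function() {
  rbind(
    data.frame(
      species = "glc_alpha",
      position = c("C1", "C2", "C3", "C4", "C5", "C6", "C6b"),
      shift_ppm = c(5.22, 3.52, 3.70, 3.40, 3.82, 3.83, 3.75),
      stringsAsFactors = FALSE
    ),
    data.frame(
      species = "glc_beta",
      position = c("C1", "C2", "C3", "C4", "C5", "C6", "C6b"),
      shift_ppm = c(4.63, 3.23, 3.47, 3.39, 3.45, 3.88, 3.71),
      stringsAsFactors = FALSE
    ),
    data.frame(
      species = c("hdo", "glx", "lac"),
      position = NA_character_,
      shift_ppm = c(4.80, 2.40, 1.30),
      stringsAsFactors = FALSE
    )
  )
}

#' Convert a chemical shift to a frequency offset
#'
#' @param shift_ppm chemical shift in ppm.
#' @param reference_shift_ppm shift of the reference (water) resonance, ppm.
#' @param spectrometer_freq_mhz spectrometer frequency for the observed
#'   nucleus, MHz (2H at 7 T is 45.8 MHz).
#' @return Frequency offset in Hz relative to the reference.
#' @export
#' @examples
#' ppm_to_hz(1.3, 4.8, 45.8) # lactate, about -160 Hz from water
ppm_to_hz <- function(shift_ppm, reference_shift_ppm, spectrometer_freq_mhz) {
  (shift_ppm - reference_shift_ppm) * spectrometer_freq_mhz
}

#' Build a constrained prior-knowledge spectral model
#'
#' Constructs the resonance list and parameter-sharing groups used by the
#' time-domain fit for one glucose isotopologue. For glucose-d7 all seven
#' deuterated positions of both anomers are modelled (14 resonances); for
#' glucose-d2 only the two C6 deuterons of each anomer (4 resonances). The
#' HDO, Glx and lactate+lipid singlets are always included.
#'
#' Constraint structure: each glucose anomer shares a single amplitude
#' across its positions (anomers may differ); all glucose resonances share
#' one linewidth; all glucose resonances share one phase except the C1
#' pair, which gets its own phase group (d7 only -- d2 has no C1 label).
#' The three singlets have independent amplitude, phase and linewidth.
#'
#' @param isotopologue `"d2"` or `"d7"`.
#' @param shifts shift table as returned by [dmi_shift_table()].
#' @param reference_shift_ppm shift assigned to water (default 4.8 ppm).
#' @param spectrometer_freq_mhz 2H frequency in MHz (default 45.8, i.e. 7 T).
#' @return An object of class `dmi_prior`: a list with elements
#'   `resonances` (data frame: name, shift_ppm, amp_group, weight,
#'   phase_group, lw_group, metabolite), `isotopologue`,
#'   `reference_shift_ppm`, `spectrometer_freq_mhz`, and the group level
#'   sets `amp_groups`, `phase_groups`, `lw_groups`.
#' @export
#' @examples
#' m7 <- build_prior_model("d7")
#' nrow(m7$resonances) # 17 = 14 glucose + HDO + Glx + Lac
build_prior_model <- function(isotopologue = c("d2", "d7"),
                              shifts = dmi_shift_table(),
                              reference_shift_ppm = 4.8,
                              spectrometer_freq_mhz = 45.8) {
  isotopologue <- match.arg(isotopologue)
  positions <- if (isotopologue == "d7") {
    c("C1", "C2", "C3", "C4", "C5", "C6", "C6b")
  } else {
    c("C6", "C6b")
  }

  glc <- shifts[shifts$species %in% c("glc_alpha", "glc_beta") &
                  shifts$position %in% positions, ]
  if (nrow(glc) != 2L * length(positions)) {
    stop("shift table is missing glucose entries for positions: ",
         paste(setdiff(positions, glc$position), collapse = ", "))
  }
  singlets <- shifts[shifts$species %in% c("hdo", "glx", "lac"), ]
  if (nrow(singlets) != 3L) {
    stop("shift table must contain hdo, glx and lac entries")
  }

  anomer <- ifelse(glc$species == "glc_alpha", "glc_alpha", "glc_beta")
  phase_group <- rep("glc", nrow(glc))
  if (isotopologue == "d7") {
    phase_group[glc$position == "C1"] <- "glc_c1"
  }
  res <- data.frame(
    name = paste0(anomer, "_", glc$position),
    shift_ppm = glc$shift_ppm,
    amp_group = anomer,
    weight = 1,
    phase_group = phase_group,
    lw_group = "glc",
    metabolite = "glc",
    stringsAsFactors = FALSE
  )
  res <- rbind(res, data.frame(
    name = singlets$species,
    shift_ppm = singlets$shift_ppm,
    amp_group = singlets$species,
    weight = 1,
    phase_group = singlets$species,
    lw_group = singlets$species,
    metabolite = singlets$species,
    stringsAsFactors = FALSE
  ))

  structure(list(
    resonances = res,
    isotopologue = isotopologue,
    n_positions = length(positions),
    reference_shift_ppm = reference_shift_ppm,
    spectrometer_freq_mhz = spectrometer_freq_mhz,
    amp_groups = unique(res$amp_group),
    phase_groups = unique(res$phase_group),
    lw_groups = unique(res$lw_group)
  ), class = "dmi_prior")
}

#' @export
print.dmi_prior <- function(x, ...) {
  cat("Deuterium spectral prior model (", x$isotopologue, ")\n", sep = "")
  cat("  ", nrow(x$resonances), " resonances; ",
      length(x$amp_groups), " amplitude groups, ",
      length(x$phase_groups), " phase groups, ",
      length(x$lw_groups), " linewidth groups\n", sep = "")
  cat("  reference ", x$reference_shift_ppm, " ppm at ",
      x$spectrometer_freq_mhz, " MHz\n", sep = "")
  invisible(x)
}

#' Spectral parameter set for a prior model
#'
#' Bundles per-group amplitudes, phases and linewidths together with the
#' global water-frequency shift and the acquisition dead time into the
#' parameter object consumed by [evaluate_fid()].
#'
#' @param model a [build_prior_model()] object.
#' @param amplitudes named numeric, one entry per amplitude group
#'   (unnamed scalars are recycled to all groups). Signal units, >= 0.
#' @param phases named numeric per phase group, radians in (-pi, pi]
#'   (scalar recycled). Default 0.
#' @param linewidths named numeric per linewidth group, Lorentzian FWHM in
#'   Hz, > 0 (scalar recycled). Default 14.
#' @param f0_hz global water-frequency offset in Hz (absorbs B0 error).
#' @param begin_time acquisition dead time (echo time) in seconds.
#' @return A list of class `dmi_params`.
#' @export
spectral_params <- function(model, amplitudes, phases = 0, linewidths = 14,
                            f0_hz = 0, begin_time = 0) {
  expand <- function(x, groups, what) {
    if (is.null(names(x))) {
      if (length(x) == 1L) x <- rep(x, length(groups))
      if (length(x) != length(groups)) {
        stop("need one ", what, " per group (", length(groups), ")")
      }
      names(x) <- groups
      return(x)
    }
    miss <- setdiff(groups, names(x))
    if (length(miss)) stop("missing ", what, " for group(s): ",
                           paste(miss, collapse = ", "))
    x[groups]
  }
  a <- expand(amplitudes, model$amp_groups, "amplitude")
  p <- expand(phases, model$phase_groups, "phase")
  l <- expand(linewidths, model$lw_groups, "linewidth")
  if (any(a < 0)) stop("amplitudes must be >= 0")
  if (any(l <= 0)) stop("linewidths must be > 0")
  structure(list(amplitudes = a, phases = p, linewidths = l,
                 f0_hz = f0_hz, begin_time = begin_time),
            class = "dmi_params")
}

# Per-resonance complex basis at unit amplitude: column k is
# w_k exp(i(2 pi f_k t + phi_k)) exp(-pi lw_k t). Shared by the forward
# model and the fit Jacobian.
.fid_basis <- function(model, params, t) {
  res <- model$resonances
  f <- ppm_to_hz(res$shift_ppm, model$reference_shift_ppm,
                 model$spectrometer_freq_mhz) + params$f0_hz
  ph <- params$phases[res$phase_group]
  lw <- params$linewidths[res$lw_group]
  arg <- outer(t, 2 * pi * f) +
    matrix(ph, length(t), nrow(res), byrow = TRUE)
  damp <- exp(-pi * outer(t, lw))
  (exp(1i * arg) * damp) *
    matrix(res$weight, length(t), nrow(res), byrow = TRUE)
}

#' Evaluate the complex free induction decay of a prior model
#'
#' Sum of exponentially damped complex sinusoids (Lorentzian lineshape):
#' `FID(t) = sum_k a_k w_k exp(i(2 pi f_k t + phi_k)) exp(-pi lw_k t)`,
#' linear in the amplitudes.
#'
#' @param model a [build_prior_model()] object.
#' @param params a [spectral_params()] object.
#' @param t time axis in seconds, uniformly spaced, starting at
#'   `params$begin_time`.
#' @return Complex vector of length `length(t)`.
#' @export
#' @examples
#' m <- build_prior_model("d2")
#' p <- spectral_params(m, amplitudes = c(glc_alpha = 1, glc_beta = 1,
#'                                        hdo = 3, glx = 0, lac = 0))
#' fid <- evaluate_fid(m, p, seq(0, 0.213, by = 1/1200))
evaluate_fid <- function(model, params, t) {
  if (any(params$linewidths <= 0)) stop("linewidths must be > 0")
  a <- params$amplitudes[model$resonances$amp_group]
  drop(.fid_basis(model, params, t) %*% a)
}

#' Metabolite-level amplitudes from per-group amplitudes
#'
#' Collapses the fitted amplitude groups to one amplitude per metabolite.
#' The glucose amplitude is the total signal over all fitted glucose
#' resonances (sum of the two anomer amplitudes times the number of
#' labelled positions), so that at equal concentration one glucose-d7
#' molecule reports 7/2 the amplitude of one glucose-d2 molecule.
#'
#' @param model a [build_prior_model()] object.
#' @param amplitudes named per-group amplitudes.
#' @return Named numeric, one entry per metabolite in the model (for the
#'   standard priors: `glc`, `hdo`, `glx`, `lac`).
#' @export
metabolite_amplitudes <- function(model, amplitudes) {
  res <- model$resonances
  contrib <- unname(amplitudes[res$amp_group]) * res$weight
  mets <- unique(res$metabolite)
  vapply(mets, function(mm) sum(contrib[res$metabolite == mm]), numeric(1))
}

#' Serialize a prior model to JSON
#'
#' @param model a `dmi_prior` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
prior_to_json <- function(model, path = NULL) {
  obj <- unclass(model)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
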