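# Conversion of fitted signal amplitudes to concentrations: steady-state
# attenuation factors, natural-abundance water referencing (kappa), tissue
# water/T1 bookkeeping and ROI aggregation of complex amplitude maps.

#' Quantification constants
#'
#' All constants entering the amplitude-to-concentration conversion:
#' acquisition timing, metabolite T1 values, per-tissue HDO T1 and water
#' content, effective deuterium label numbers per molecule (corrected for
#' label loss into water), the natural isotopic abundance of deuterium and
#' the molar concentration of pure water.
#'
#' Label numbers: after glucose-d2 ingestion HDO/glucose/Glx/lactate carry
#' 1, 2, 0.6 and 0.85 effective labels per molecule; after glucose-d7,
#' 1, 7, 0.9 and 1.28 (the Glx/lactate values are the d2 values scaled by
#' 3/2 because three of the seven labels reach the pyruvate pool).
#'
#' @param isotopologue `"d2"` or `"d7"`.
#' @param tr_s repetition time, s.
#' @param flip_deg excitation flip angle, degrees.
#' @return A list of class `quant_config` with elements `tr_s`, `flip_deg`,
#'   `t1_s` (glc/glx/lac, seconds), `t1_hdo_s` (csf/gm/wm), `n_labels`
#'   (hdo/glc/glx/lac), `abundance`, `water_molar`, `water_fraction`
#'   (csf/gm/wm), `isotopologue`.
#' @export
quant_config <- function(isotopologue = c("d2", "d7"), tr_s = 0.230,
                         flip_deg = 62) {
  isotopologue <- match.arg(isotopologue)
  n_labels <- if (isotopologue == "d2") {
    c(hdo = 1, glc = 2, glx = 0.6, lac = 0.85)
  } else {
    c(hdo = 1, glc = 7, glx = 0.9, lac = 1.28)
  }
  structure(list(
    isotopologue = isotopologue,
    tr_s = tr_s,
    flip_deg = flip_deg,
    t1_s = c(glc = 0.067, glx = 0.139, lac = 0.297),
    t1_hdo_s = c(csf = 0.510, gm = 0.320, wm = 0.290),
    n_labels = n_labels,
    abundance = 1.56e-4,
    water_molar = 55.4,
    water_fraction = c(csf = 0.99, gm = 0.84, wm = 0.69)
  ), class = "quant_config")
}

#' Steady-state attenuation factor
#'
#' Fractional steady-state longitudinal magnetisation sampled by a spoiled
#' acquisition with repetition time `TR` and flip angle `theta`:
#' `E = (1 - exp(-TR/T1)) / (1 - exp(-TR/T1) cos(theta))`.
#'
#' @param tr_s repetition time, s (> 0).
#' @param t1_s longitudinal relaxation time, s (> 0).
#' @param theta_deg flip angle in degrees, in (0, 180).
#' @return E in (0, 1].
#' @export
#' @examples
#' attenuation_factor(0.230, 0.297, 62) # lactate at the CSI settings
attenuation_factor <- function(tr_s, t1_s, theta_deg) {
  stopifnot(all(tr_s > 0), all(t1_s > 0),
            all(theta_deg > 0), all(theta_deg < 180))
  e1 <- exp(-tr_s / t1_s)
  (1 - e1) / (1 - e1 * cos(theta_deg * pi / 180))
}

#' Natural-abundance HDO deuteron concentration
#'
#' Concentration of deuterium in semi-heavy water at natural abundance:
#' two hydrogen sites per water molecule, each deuterated with probability
#' equal to the natural abundance, scaled by the tissue water fraction.
#'
#' @param water_fraction volumetric water fraction of the tissue/ROI,
#'   in (0, 1].
#' @param config a [quant_config()] object.
#' @return Concentration in mM (about 17.3 mM in pure water).
#' @export
natural_abundance_hdo_concentration <- function(water_fraction,
                                                config = quant_config()) {
  stopifnot(all(water_fraction >= 0), all(water_fraction <= 1))
  2 * config$abundance * config$water_molar * 1000 * water_fraction
}

#' Tissue composition of a region of interest
#'
#' Summarises the CSF/GM/WM make-up of an ROI: mean tissue fractions over
#' the masked voxels (normalised to sum to one), the net water fraction,
#' and the effective HDO T1 under fast exchange.
#'
#' @param phantom a [make_phantom()] object (or any list with `csf`, `gm`,
#'   `wm` partial-volume arrays).
#' @param mask logical array on the phantom grid.
#' @param config a [quant_config()] object.
#' @return A list of class `roi_composition`: `fractions` (csf/gm/wm),
#'   `water_fraction`, `t1_hdo_s`.
#' @export
roi_composition <- function(phantom, mask, config = quant_config()) {
  stopifnot(any(mask))
  f <- c(csf = mean(phantom$csf[mask]),
         gm = mean(phantom$gm[mask]),
         wm = mean(phantom$wm[mask]))
  f <- f / sum(f)
  structure(list(
    fractions = f,
    water_fraction = sum(f * config$water_fraction),
    t1_hdo_s = effective_hdo_t1(f, config)
  ), class = "roi_composition")
}

#' Effective HDO T1 of a tissue mixture
#'
#' Fast-exchange average over compartments: the relaxation rates are
#' averaged with weights proportional to each compartment's water content,
#' `1/T1_eff = sum_i w_i / T1_i`, `w_i = f_i * water_i / sum_j f_j water_j`.
#'
#' @param fractions named tissue fractions (csf/gm/wm), summing to ~1.
#' @param config a [quant_config()] object.
#' @return Effective T1 in seconds.
#' @export
#' @examples
#' effective_hdo_t1(c(csf = 0, gm = 1, wm = 0)) # pure grey matter: 0.32 s
effective_hdo_t1 <- function(fractions, config = quant_config()) {
  tis <- c("csf", "gm", "wm")
  f <- fractions[tis]
  w <- f * config$water_fraction[tis]
  w <- w / sum(w)
  1 / sum(w / config$t1_hdo_s[tis])
}

#' Calibrate the signal-to-concentration constant kappa
#'
#' The scaling constant linking fitted amplitude to deuteron concentration
#' is obtained from the natural-abundance HDO amplitude measured in the ROI
#' before glucose ingestion: `kappa = A_NA / (E_HDO * N_HDO * C_NA)` with
#' `N_HDO = 1`, `E_HDO` computed from the ROI-effective HDO T1 and `C_NA`
#' from the ROI water fraction.
#'
#' @param na_hdo_amplitude natural-abundance HDO amplitude in the ROI (> 0).
#' @param roi a [roi_composition()] object.
#' @param config a [quant_config()] object.
#' @return kappa, in signal units per mM per label.
#' @export
calibrate_kappa <- function(na_hdo_amplitude, roi, config = quant_config()) {
  if (na_hdo_amplitude <= 0) stop("natural-abundance amplitude must be > 0")
  e_hdo <- attenuation_factor(config$tr_s, roi$t1_hdo_s, config$flip_deg)
  c_na <- natural_abundance_hdo_concentration(roi$water_fraction, config)
  na_hdo_amplitude / (e_hdo * config$n_labels[["hdo"]] * c_na)
}

#' Convert a fitted amplitude to a concentration
#'
#' Inverts the signal equation `A_m = C_m * kappa * E_m * N_m`:
#' `C_m = A_m / (kappa * E_m * N_m)`. HDO uses the ROI-effective T1; the
#' other metabolites use their tabulated T1. Values reported for `"lac"`
#' quantify the 1.3 ppm lactate+lipid resonance as lactate and may contain
#' lipid contamination.
#'
#' @param amplitude fitted metabolite amplitude (signal units).
#' @param metabolite one of `"hdo"`, `"glc"`, `"glx"`, `"lac"`.
#' @param kappa calibration constant from [calibrate_kappa()].
#' @param roi a [roi_composition()] object (needed for HDO).
#' @param config a [quant_config()] object (fixes the isotopologue's label
#'   numbers).
#' @return Concentration in mM.
#' @export
concentration_from_amplitude <- function(amplitude, metabolite, kappa, roi,
                                         config = quant_config()) {
  metabolite <- match.arg(metabolite, c("hdo", "glc", "glx", "lac"))
  t1 <- if (metabolite == "hdo") roi$t1_hdo_s else config$t1_s[[metabolite]]
  e <- attenuation_factor(config$tr_s, t1, config$flip_deg)
  amplitude / (kappa * e * config$n_labels[[metabolite]])
}

# trilinear interpolation of a 3D array onto a finer/coarser grid, voxel
# centres aligned (source index of target centre u: (i-0.5)*n_src/n_tgt+0.5)
.interp3 <- function(arr, target_dim) {
  d <- dim(arr)
  if (all(d == target_dim)) return(arr)
  coords <- lapply(1:3, function(ax) {
    u <- (seq_len(target_dim[ax]) - 0.5) * d[ax] / target_dim[ax] + 0.5
    pmin(pmax(u, 1), d[ax])
  })
  out <- array(0, target_dim)
  x <- coords[[1]]; y <- coords[[2]]; z <- coords[[3]]
  x0 <- pmin(floor(x), d[1] - 1L); x0 <- pmax(x0, 1L)
  y0 <- pmin(floor(y), d[2] - 1L); y0 <- pmax(y0, 1L)
  z0 <- pmin(floor(z), d[3] - 1L); z0 <- pmax(z0, 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  for (k in seq_len(target_dim[3])) {
    zk0 <- z0[k]; zk1 <- zk0 + 1L; fzk <- fz[k]
    sl0 <- arr[, , zk0]; sl1 <- arr[, , zk1]
    # bilinear in-plane, for both z slabs
    bil <- function(sl) {
      a00 <- sl[x0, y0, drop = FALSE]
      a10 <- sl[x0 + 1L, y0, drop = FALSE]
      a01 <- sl[x0, y0 + 1L, drop = FALSE]
      a11 <- sl[x0 + 1L, y0 + 1L, drop = FALSE]
      wx <- matrix(fx, length(x), length(y))
      wy <- matrix(fy, length(x), length(y), byrow = TRUE)
      a00 * (1 - wx) * (1 - wy) + a10 * wx * (1 - wy) +
        a01 * (1 - wx) * wy + a11 * wx * wy
    }
    out[, , k] <- bil(sl0) * (1 - fzk) + bil(sl1) * fzk
  }
  out
}

#' ROI average of a complex amplitude map
#'
#' Combines amplitude and phase maps into complex values `A exp(i phi)`,
#' optionally interpolates them (trilinearly, on the complex values) to a
#' finer target grid, averages over the masked voxels and returns the
#' magnitude of the mean. Averaging complex values lets incoherent noise
#' phases cancel rather than rectify.
#'
#' @param amplitude 3D amplitude map.
#' @param phase 3D phase map, radians.
#' @param mask logical array on the target grid.
#' @param target_dim grid to interpolate to (default: the mask's grid).
#' @return Magnitude of the complex ROI mean.
#' @export
roi_average_complex <- function(amplitude, phase, mask,
                                target_dim = dim(mask)) {
  Mod(.roi_complex_mean(amplitude, phase, mask, target_dim))
}

# the complex ROI mean itself; kept for window-level averaging across
# serial acquisitions, where taking the magnitude per acquisition would
# rectify noise upward on weak resonances
.roi_complex_mean <- function(amplitude, phase, mask,
                              target_dim = dim(mask)) {
  if (!any(mask)) stop("empty ROI mask")
  if (!all(dim(mask) == target_dim)) stop("mask must live on the target grid")
  z <- amplitude * exp(1i * phase)
  zi <- .interp3(Re(z), target_dim) + 1i * .interp3(Im(z), target_dim)
  mean(zi[mask])
}
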