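---
title: "Models and methods for quantitative deuterium metabolic imaging"
author: "dmiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantitative deuterium metabolic imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmiquant)
```

# Scope

`dmiquant` analyses dynamic deuterium (²H) chemical shift imaging (CSI) of
the human brain after ingestion of deuterated glucose, for the two
isotopologues in practical use: glucose-d₂ (two labels on C6) and
glucose-d₇ (labels on every carbon-bound position). The package covers the
spectral forward model and prior-knowledge fitting, tensor denoising,
water-referenced quantification, cohort-level dynamics, isotope label
accounting, and the in-silico design analyses (flip-angle optimisation and
the Monte-Carlo glucose SNR-gain estimate). Because no public DMI data
exist for this design, a synthetic-data generator is a first-class module:
it encodes the study conditions and provides the ground truth against
which every downstream stage is tested.

# The spectral model

An FID is modelled as a sum of exponentially damped complex sinusoids
(Lorentzian lines),

$$s(t) = \sum_k a_k\, w_k\, e^{i(2\pi f_k t + \phi_k)}\, e^{-\pi\,\mathrm{lw}_k t},$$

with per-resonance frequency $f_k$ fixed by the chemical shift relative to
water plus a single global water-frequency offset that absorbs B₀ error.
Deuterium shifts equal the corresponding ¹H shifts, so the default shift
table (`dmi_shift_table()`) carries literature ¹H values for both glucose
anomers; the exact values are configuration, not science — only
differences to the 4.8 ppm water reference matter, scaled by the 45.8 MHz
²H frequency at 7 T.

The prior-knowledge constraints mirror standard AMARES practice for this
experiment:

* glucose-d₇: 14 resonances (7 positions × 2 anomers); glucose-d₂: 4
  (C6/C6′ × 2 anomers);
* one amplitude per anomer (positions within an anomer share it with unit
  weights), so the reported glucose amplitude — the anomer sum times the
  number of labelled positions — is 7/2 larger for d₇ than for d₂ at equal
  concentration;
* one linewidth shared by all glucose resonances;
* one phase shared by all glucose resonances except the C1 pair (d₇
  only), which is far enough downfield to earn its own phase group;
* HDO, Glx and lactate+lipid are independent singlets.

Lineshapes are purely Lorentzian; J-coupling, quadrupolar structure and
macromolecule baselines are not modelled (unresolvable at ~14 Hz
linewidths). First-order phase is fixed by the acquisition dead time
(`begin_time`), not fitted; only zero-order phases per group are free.

# Fitting

`fit_fid()` performs bounded Levenberg–Marquardt least squares on the
stacked real/imaginary residuals with analytic Jacobians. Default bounds
(user-overridable): linewidths 2–40 Hz, water-frequency offset ±30 Hz,
amplitudes ≥ 0, phases in (−π, π]. Starting values: the water frequency
from the dominant magnitude peak within the offset bounds; amplitudes and
phases from a complex linear least-squares solve at the initial 14 Hz
linewidth (a variable-projection-style initialisation — the model is
linear in the complex amplitudes once frequencies and linewidths are
fixed). A fit that exhausts its iterations is restarted once from
perturbed values (linewidth +10 %, phases zero) and flagged if still
unconverged; an all-zero input short-circuits to a converged zero result.
On single-resonance problems the fit agrees with a dense grid-search plus
linear least-squares oracle to better than 0.1 % in amplitude (tested),
and at the calibrated SNR of 14 the amplitude estimates are unbiased
within 2 % with spread close to the asymptotic prediction from the
Jacobian at truth.

The 1.3 ppm component is always labelled lactate+lipid: the fit cannot
distinguish lactate from lipid contamination, and quantifying it with
lactate's T₁ and label number is a documented caveat, not a claim.

# Denoising

`tucker_denoise()` computes a multilinear low-rank (Tucker) approximation
of the complex 4D tensor: truncated HOSVD initialisation, then HOOI
refinement (tolerance 1e-6 on the explained norm, at most 50 sweeps),
complex SVDs throughout. The default core [64, 6, 6, 4] corresponds to a
[256, 12, 12, 8] acquisition and is scaled proportionally (rounded,
minimum 1) for other grids. Full-rank cores reproduce the input to
machine precision and exactly low-rank tensors are recovered; on the
calibrated natural-abundance simulation, denoising raises the HDO
spectral SNR of every brain voxel (both tested). Rank selection beyond
the fixed default (MDL/SURE) is out of scope. Denoising is applied
directly to the stored voxel-domain tensor; no apodization is applied
anywhere in the pipeline.

# Quantification

Concentrations invert the steady-state signal equation
$C_m = A_m / (\kappa E_m N_m)$ with
$E_m = (1 - e^{-TR/T_{1m}}) / (1 - e^{-TR/T_{1m}}\cos\theta)$.
Constants (all in `quant_config()`, the single source of truth): TR 230 ms,
flip angle 62°; T₁ of glucose/Glx/lactate 67/139/297 ms; HDO T₁ of
CSF/GM/WM 510/320/290 ms combined under fast exchange with
water-content-weighted rate averaging; tissue water fractions
0.99/0.84/0.69; deuterium natural abundance 0.0156 %; pure water 55.4 M.
Effective label numbers per molecule: d₂ — HDO 1, Glc 2, Glx 0.6,
Lac 0.85; d₇ — HDO 1, Glc 7, Glx 0.9, Lac 1.28 (the product values are
the d₂ ones scaled by 3/2 because three of seven labels reach the
pyruvate pool). These are taken as constants; their derivation from raw
label-loss data is out of scope.

κ is calibrated per ROI from the pre-ingestion natural-abundance HDO
amplitude: $\kappa = A_{\mathrm{NA}} / (E_{\mathrm{HDO}} \cdot 1 \cdot
C_{\mathrm{NA}})$, where $C_{\mathrm{NA}} = 2 \times 1.56\times10^{-4}
\times 55.4\,\mathrm{M} \times$ water fraction (two hydrogen sites per
water molecule; HDO is reported as deuteron concentration in singly
deuterated water — the doubly deuterated species is negligible). A
per-voxel κ would be possible but is not the default: the per-voxel
natural-abundance SNR is too low for a stable calibration.

ROI aggregation averages *complex* amplitudes $A e^{i\phi}$ (trilinear
interpolation when the mask lives on a finer grid) and returns the
magnitude of the mean: incoherent noise phases then cancel instead of
rectifying, which is also the only reading under which averaging before
magnitude makes sense. ROI tissue composition comes from the phantom's
partial-volume maps (in real use: user-supplied segmentations).

# The synthetic-data generator

The generator is the package's statement of the study conditions:

* **Geometry and acquisition**: 12×12×8 voxels of 15 mm, 256 FID samples
  at 1200 Hz bandwidth, TR 230 ms, flip angle 62°, 45.8 MHz. The phantom
  is an ellipsoidal brain with a GM shell, WM core and CSF ventricles,
  smooth partial volumes, and whole-brain/occipital/frontal masks.
* **Cohorts**: 8 glucose-d₂ + 7 glucose-d₇ participants; per participant
  one pre-ingestion scan plus 5–6 serial scans at 11.2 min spacing
  starting uniformly 2–31 min after ingestion; log-normal amplitude scale
  (σ = 0.1) and ±5 Hz water-frequency drift as participant random
  effects.
* **Kinetics**: every metabolite follows the gamma-variate
  $C(t) = A + B(kt)^2 e^{-kt}$ (maximum $A + 4Be^{-2}$ at $t = 2/k$).
  Glucose peaks at 80 min ($k = 0.025$/min, $C_\mathrm{max} \approx
  1.6$ mM). Glx and lactate share $k = 0.012$/min in the fixed proportion
  0.84 : 0.16, so the plateau concentration ratio Lac/Glx is 0.16/0.84 ≈
  0.19 at all times. The HDO excess above natural abundance rises
  monotonically ($k = 0.008$/min) with scale B = 126 mM per unit water
  for d₇ — chosen so the normalised HDO signal crosses three times the
  natural-abundance level just before 100 min — and is scaled for d₂ by
  the label-accounting ratio ΔN₂/(4 + ΔN₇) ≈ 0.142, which makes the
  implied d₇/d₂ HDO signal ratio ≈ 2.3–2.4 near 100 min. Glucose, Glx
  and lactate concentration kinetics are identical across cohorts: their
  signal differences arise from label numbers alone. The gamma-variate
  family for HDO/Glx/Lac (with small rates, hence monotone over the
  session) is a modelling choice; only "rising throughout the session" is
  constrained by observation.
* **Noise**: white circular Gaussian in the time domain, one variance for
  all voxels, calibrated (`noise_sd = "auto"`) so the mean
  natural-abundance HDO spectral SNR over brain voxels is 14 (the
  measured value in this kind of acquisition), with ~14 Hz linewidths.
* **Not emulated**: k-space encoding and acquisition-weighted averaging
  (the analysis operates after reconstruction), physiological plasma
  kinetics, B₁ inhomogeneity, slice profiles, chemical-shift
  displacement, inter-session motion. Lipid contamination of edge voxels
  exists in vivo but is off by default. Passing tests therefore
  demonstrate correctness of the analysis given the forward model, not
  robustness to every in vivo artefact.

# Dynamics and cohort analyses

Time courses are normalised per participant to the pre-ingestion
natural-abundance HDO amplitude. Pooled cohort curves use a moving
average over time-ordered records with a window equal to the cohort size,
advancing one record at a time (maximal overlap; the stride is a design
choice), plotted at the mean window time. Isotopologue ratio curves
interpolate the d₂ curve linearly onto the d₇ time points and summarise
over 100–120 min; the region comparison uses a Welch two-sample t-test on
participant-level means over 80–100 min; plateau concentration ratios are
ratios of window means over 50–140 min (a ratio of means is stabler than
a mean of ratios when the denominator is noisy). Within the plateau
window each participant's serial acquisitions are combined as *complex*
values before the magnitude is taken — at per-voxel lactate SNR well
below one, taking magnitudes per acquisition would rectify noise upward
(a Rician-type bias of several percent), whereas coherent combination of
repeats, the standard way of pooling serial CSI acquisitions, keeps the
weak-resonance estimates nearly unbiased. The HDO-increase
fraction ΔHDO/(Glx+Lac) uses T₁-corrected amplitudes (each amplitude
divided by its attenuation factor) with the participant's own
natural-abundance level as baseline; early low-SNR points are flagged,
not dropped. Gamma-variate fits report {A, B, k} with the derived
$T_\mathrm{max} = 2/k$ and $C_\mathrm{max} = A + 4Be^{-2}$. Positivity
bounds on per-voxel amplitudes leave a residual few-percent inflation of
the weakest amplitudes at low SNR; the complex ROI averaging and the
coherent window combination keep its effect on the reported ratios at the
percent level.

# Label accounting and design analyses

With plateau fractions $f_\mathrm{Glx} = 0.84$, $f_\mathrm{Lac} = 0.16$
and $P$ labels entering the pyruvate pool per glucose (2 for d₂, 3 for
d₇), the mean deuterons lost to water per glucose is
$\Delta N = f_\mathrm{Glx}(P - 2N_\mathrm{Glx}) + f_\mathrm{Lac}(P -
2N_\mathrm{Lac})$ — 0.72 for d₂ and 1.078 for d₇ at the default
constants. The upper bound on the d₇/d₂ ratio of HDO increases is
$(4 + \Delta N_7)/\Delta N_2 \approx 7.1$ (the 4 counts the C2–C5 labels
released during glycolysis), and including the natural-abundance
background the predicted total-HDO ratio at metabolised glucose $G$ is
$(C_\mathrm{NA} + (4+\Delta N_7)G)/(C_\mathrm{NA} + \Delta N_2 G)$.
TCA-cycle and extra-cerebral HDO influx are excluded, consistent with the
upper-bound framing. The plateau fractions are arguments, not constants.

The flip-angle analysis is closed-form: the Ernst angle
$\arccos(e^{-TR/T_1})$ is 62.6° for lactate at TR = 230 ms — so the 62°
acquisition is lactate-optimal and within a percent for HDO in GM/WM —
while glucose (T₁ = 67 ms) would gain a factor ≈ 1.1 at its own optimum.
The corresponding closed form for Glx gives ≈ 1.05, which is what this
package reports. Deuterium SNR scales as $B_0^{1.65}$, so a gain $g$
over 7 T requires $7g^{1/1.65}$ T: ≈ 10 T for 1.8 and ≈ 12.5 T for 2.6.

The Monte-Carlo SNR-gain experiment simulates composite FIDs with equal
glucose concentrations as d₂ or d₇ over a fixed background of
HDO : Glc : Glx : Lac+Lip = 3 : 1 : 0.4 : 0.1 (in d₂ label-equivalents,
approximating a spectrum ~100 min after ingestion; explicit configuration,
since only "appropriately weighted" is observationally constrained), adds
noise matched to raw HDO spectral SNR 14 at 14 Hz linewidths, fits 1000
noise realizations per isotopologue (the same realization added to both
spectra in each repetition — common random numbers, which stabilises the
ratio without changing its expectation), and reports the ratio of
amplitude SNRs (mean/SD), d₇ over d₂, with a paired bootstrap interval.
Under the default background the ratio comes out near 2.4: well below
the 3.5 amplitude gain, because several d₇ glucose resonances overlap
the dominant HDO peak and inherit its uncertainty; removing the HDO
background pushes the ratio back towards 3.5 (tested). The exact value
moves by a few tenths with the assumed background weighting, which is
why that weighting is explicit configuration.

# Problem sizes, determinism and numerics

All randomness flows through explicit seeds; a seeded pipeline run is
byte-identical on repetition. The packaged analyses use full-size
spectra (256 points) everywhere; the cohort-level recovery analyses run
on an 8×8×6 voxel grid (≈ 112 brain voxels, ~5,000 voxel fits for a
7-participant cohort) — the package's chosen balance between statistical
stability of the recovered ratios and the cost of ~50,000 fits on the
full 12×12×8 grid, which changes no conclusion since voxels are fitted
independently. Degenerate inputs are defined: all-zero FIDs return
converged zero fits; empty ROI masks, non-overlapping ratio curves,
constant-Glx regression segments and missing normalisation records raise
errors naming the problem. Amplitude positivity is enforced by bounds,
which slightly inflates near-zero amplitudes at low SNR (visible in the
lactate plateau ratio at the few-percent level); complex ROI averaging
before ratio formation keeps this bias small.

# Known limitations

* The lactate+lipid resonance is quantified as lactate by declaration;
  lipid contamination is not separable at this linewidth.
* κ assumes uniform transmit/receive fields; no B₁ mapping.
* No partial-volume deconvolution of CSI voxels; ROI composition is the
  mask-averaged partial volume.
* The kinetic forms for HDO/Glx/Lac beyond monotone growth, and the
  background weighting of the SNR experiment, are modelling choices
  documented above.
* Supplementary fitting bounds of the original acquisition protocol are
  not public; the defaults here (linewidth 2–40 Hz, ±30 Hz water offset,
  14 Hz initial linewidth) are explicit stand-ins and user-overridable.
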