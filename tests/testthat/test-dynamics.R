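test_that("normalisation to natural-abundance HDO is per participant", {
  tc <- toy_timecourse()
  na <- c(p1 = 2, p2 = 4)
  out <- normalize_to_na_hdo(tc, na)
  expect_equal(out$norm_amplitude, out$amplitude / na[out$participant],
               ignore_attr = TRUE)
  # the NA HDO record itself normalises to 1
  tc1 <- tc[1, ]; tc1$metabolite <- "hdo"; tc1$amplitude <- 2
  expect_equal(normalize_to_na_hdo(tc1, na)$norm_amplitude, 1)
  # per-participant rescaling leaves normalised values unchanged
  tc_scaled <- tc
  scale <- c(p1 = 3, p2 = 0.5)
  tc_scaled$amplitude <- tc$amplitude * scale[tc$participant]
  out2 <- normalize_to_na_hdo(tc_scaled, na * scale)
  expect_equal(out2$norm_amplitude, out$norm_amplitude)
  expect_error(normalize_to_na_hdo(tc, c(p1 = 2)), "missing")
})

test_that("the moving average slides one record at a time", {
  # hand-computed example
  out <- moving_average_timecourse(1:5, 1:5, 3)
  expect_equal(out$time_min, c(2, 3, 4))
  expect_equal(out$mean, c(2, 3, 4))
  # window equal to the record count: one global point
  out1 <- moving_average_timecourse(1:5, c(2, 4, 6, 8, 10), 5)
  expect_equal(nrow(out1), 1L)
  expect_equal(out1$mean, 6)
  expect_equal(out1$time_min, 3)
  # constant records: zero SD
  outc <- moving_average_timecourse(1:6, rep(7, 6), 3)
  expect_true(all(outc$mean == 7))
  expect_true(all(outc$sd == 0))
  # invariant to the ordering of equal-time records
  set.seed(2)
  times <- c(1, 1, 2, 2, 3, 3)
  vals <- c(1, 2, 3, 4, 5, 6)
  perm <- c(2, 1, 4, 3, 6, 5)
  a <- moving_average_timecourse(times, vals, 4)
  b <- moving_average_timecourse(times[perm], vals[perm], 4)
  expect_equal(a$mean, b$mean)
  expect_equal(a$time_min, b$time_min)
  expect_error(moving_average_timecourse(1:3, 1:3, 4), "window")
})

test_that("isotopologue ratio interpolates d2 onto d7 time points", {
  c7 <- data.frame(time_min = seq(10, 130, by = 10), mean = 2)
  c2 <- data.frame(time_min = seq(5, 135, by = 13), mean = 2)
  r <- isotopologue_ratio(c7, c2)
  expect_true(all(abs(r$ratio - 1) < 1e-12))
  expect_equal(r$window_mean, 1)
  # a curve against itself is exactly 1 at every interior point
  r2 <- isotopologue_ratio(c7, c7)
  expect_true(all(r2$ratio == 1))
  # scaling the d7 curve scales the ratio
  c7b <- c7; c7b$mean <- 3.5 * c7$mean
  expect_equal(isotopologue_ratio(c7b, c2)$window_mean, 3.5)
  expect_error(
    isotopologue_ratio(data.frame(time_min = 1:3, mean = 1),
                       data.frame(time_min = 10:12, mean = 1)), "overlap")
})

test_that("metabolite fractions sum to one and hit the plateau values", {
  tc <- toy_timecourse(glx = 0.84, lac = 0.16)
  qc <- quant_config("d7")
  ph <- make_phantom(c(6, 6, 4))
  roi <- roi_composition(ph, ph$brain_mask, qc)
  na <- c(p1 = 1, p2 = 1)
  fr <- metabolite_fractions(tc, roi, qc, na)
  expect_equal(fr$glx_fraction + fr$lac_fraction, rep(1, nrow(fr)))
  expect_true(all(abs(fr$glx_fraction - 0.84) < 1e-12))
  # equal Glx and Lac: both fractions one half
  tc2 <- toy_timecourse(glx = 0.5, lac = 0.5)
  fr2 <- metabolite_fractions(tc2, roi, qc, na)
  expect_true(all(fr2$glx_fraction == 0.5 & fr2$lac_fraction == 0.5))
})

test_that("segmented regression recovers gradients per segment", {
  # exactly collinear points with slope 0.2
  glx <- seq(0.1, 1.2, length.out = 12)
  times <- seq(10, 120, by = 10)
  tc <- rbind(
    data.frame(participant = "p1", cohort = "d7", roi = "brain",
               metabolite = "glx", time_min = times, amplitude = glx,
               conc_mm = glx),
    data.frame(participant = "p1", cohort = "d7", roi = "brain",
               metabolite = "lac", time_min = times, amplitude = 0.2 * glx,
               conc_mm = 0.2 * glx))
  # exact collinearity triggers lm's perfect-fit notice; that is the point
  seg <- suppressWarnings(segmented_lac_glx_regression(tc))
  expect_equal(seg$gradient, rep(0.2, 2), tolerance = 1e-12)
  expect_setequal(seg$segment, c("early", "late"))
  # permuting record order leaves the gradients unchanged
  perm <- sample(nrow(tc))
  seg2 <- suppressWarnings(segmented_lac_glx_regression(tc[perm, ]))
  expect_equal(sort(seg2$gradient), sort(seg$gradient))
  # a raised early lactate fraction yields a steeper early gradient
  lac_frac <- ifelse(times <= 50, 0.25, 0.19)
  tc$conc_mm[tc$metabolite == "lac"] <- lac_frac * glx
  seg3 <- suppressWarnings(segmented_lac_glx_regression(tc))
  expect_gt(seg3$gradient[seg3$segment == "early"],
            seg3$gradient[seg3$segment == "late"])
})

test_that("kinetic curve fitting recovers parameters and identities", {
  tt <- seq(5, 135, by = 5)
  truth <- c(A = 0.2, B = 1.0, k = 0.025)
  fit <- fit_kinetic_curve(tt, kinetic_curve(tt, truth))
  expect_true(fit$converged)
  expect_equal(coef(fit), truth, tolerance = 1e-4)
  # definitional identities of the derived quantities
  expect_equal(fit$t_max_min, 2 / coef(fit)[["k"]])
  expect_equal(fit$c_max,
               coef(fit)[["A"]] + 4 * coef(fit)[["B"]] * exp(-2))
  expect_gt(fit$r_squared, 0.999999)

  # recovery under 5% noise: median relative error in k below 10%
  set.seed(19)
  errs <- replicate(100, {
    y <- kinetic_curve(tt, truth)
    y <- y + rnorm(length(y), 0, 0.05 * max(y))
    abs(coef(fit_kinetic_curve(tt, y))[["k"]] - truth[["k"]]) / truth[["k"]]
  })
  expect_lt(median(errs), 0.10)
})

test_that("the region t-test is calibrated, powered and label-symmetric", {
  make_tc <- function(off_b = 0, seed = 1) {
    set.seed(seed)
    rows <- expand.grid(participant = paste0("p", 1:6),
                        roi = c("occipital", "frontal"),
                        time_min = c(85, 95), stringsAsFactors = FALSE)
    rows$cohort <- "d7"
    rows$metabolite <- "glx"
    rows$conc_mm <- rnorm(nrow(rows), 1, 0.1) +
      ifelse(rows$roi == "frontal", off_b, 0)
    rows$amplitude <- rows$conc_mm
    rows
  }
  # null calibration: p-values roughly uniform across seeds
  ps <- vapply(1:400, function(s) {
    region_ttest(make_tc(0, s), "occipital", "frontal", "glx")$p.value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # power sanity: a 10-SD offset is detected
  expect_lt(region_ttest(make_tc(1.0, 3), "occipital", "frontal",
                         "glx")$p.value, 0.001)
  # swapping the group labels leaves p unchanged
  t1 <- region_ttest(make_tc(0.3, 5), "occipital", "frontal", "glx")
  t2 <- region_ttest(make_tc(0.3, 5), "frontal", "occipital", "glx")
  expect_equal(t1$p.value, t2$p.value)
})

test_that("the glucose-load proxy combines the three pools", {
  expect_equal(glucose_load_proxy(1, 0.8, 0.2), 1.5)
  expect_equal(glucose_load_proxy(c(1, 2), 0, 0), c(1, 2))
  # the proxy decays more slowly after the peak than glucose alone:
  # products accumulate while free glucose clears
  kin <- default_cohort_kinetics("d7")
  tt <- seq(80, 140, by = 5)
  glc <- kinetic_curve(tt, kin$glc)
  proxy <- glucose_load_proxy(glc, kinetic_curve(tt, kin$glx),
                              kinetic_curve(tt, kin$lac))
  rel_drop <- function(x) (x[1] - x[length(x)]) / x[1]
  expect_lt(rel_drop(proxy), rel_drop(glc))
})
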