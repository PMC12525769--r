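test_that("time axis channels and the IRF kernel are well-formed", {
  ax <- time_axis()
  expect_equal(ax$n_channels, 4096L)
  expect_equal(round(ax$dt_ns * 1000), 3)  # ~3 ps channels
  expect_equal(ax$centers_ns[1], ax$dt_ns / 2)

  k <- irf_kernel(irf_model(100, 0.25), ax)
  expect_true(all(k >= 0))
  expect_equal(sum(k), 1, tolerance = 1e-12)
  # peak at the kernel centre
  expect_equal(ax$edges_ns[which.max(k)], 0.25, tolerance = 2 * ax$dt_ns)
  expect_error(irf_kernel(irf_model(100, 50), ax), "mass")
})

test_that("propagate matches closed forms and an adaptive ODE oracle", {
  ax <- small_axis(64, 5)
  one <- eet_cascade(lifetimes_ns = c(X = 1), transfer_frac = numeric(0))
  c1 <- propagate(one, ax)
  expect_equal(as.numeric(c1), exp(-ax$centers_ns), tolerance = 1e-10)

  # equal total rates: defective matrix handled by the integrator fallback,
  # checked against the analytic sequential-decay solution k^2 t exp(-kt)
  m2 <- eet_cascade(lifetimes_ns = c(A = 1, B = 1), transfer_frac = 0.9)
  tt <- c(0.5, 1, 2)
  c2 <- propagate(m2, times_ns = tt)
  expect_equal(c2[, 2], 0.9 * tt * exp(-tt), tolerance = 1e-8)

  set.seed(42)
  for (i in 1:8) {
    n <- sample(2:5, 1)
    K <- matrix(runif(n * n, 0, 3), n); diag(K) <- 0
    diag(K) <- -(colSums(K) + runif(n, 0.2, 2))
    m <- eet_cascade(rate_matrix = K, initial = runif(n))
    tt <- seq(0.01, 5, length.out = 40)
    a <- propagate(m, times_ns = tt)
    f <- function(t, y, p) list(as.vector(K %*% y))
    b <- deSolve::lsoda(m$initial, c(0, tt), f, rtol = 1e-12, atol = 1e-14)[-1, -1]
    expect_lt(max(abs(a - unname(b))), 1e-8)
  }

  # everything decays to ground
  late <- propagate(eet_cascade(), times_ns = 200)
  expect_true(all(late < 1e-12))
})

test_that("ideal TRES surfaces have the expected algebraic structure", {
  ax <- small_axis(256, 10)
  sp <- emission_spectra(peaks_nm = c(X = 640), fwhm_nm = 30, brightness = 2,
                         wavelengths_nm = seq(600, 700, 5))
  cc <- propagate(eet_cascade(lifetimes_ns = c(X = 1)), ax)
  sig <- tres_ideal(cc, sp)
  expect_equal(qr(sig)$rank, 1)  # outer product
  sp0 <- emission_spectra(peaks_nm = c(X = 640), fwhm_nm = 30, brightness = 0,
                          wavelengths_nm = seq(600, 700, 5))
  expect_true(all(tres_ideal(cc, sp0) == 0))

  # wavelength-integrated default cascade = 3 exponentials at the total rates
  cc3 <- propagate(eet_cascade(), ax)
  s3 <- rowSums(tres_ideal(cc3, small_spectra()))
  tau <- c(0.070, 0.165, 1.9)
  X <- exp(-outer(ax$centers_ns, 1 / tau))
  resid <- lm.fit(X, s3)$residuals
  expect_lt(max(abs(resid)) / max(s3), 1e-10)
})

test_that("IRF convolution is causal, intensity-preserving and matches the EMG closed form", {
  ax <- small_axis(2048, 12.5)
  irf <- irf_model(100, 0.25)
  # fast-decaying signal fully inside the window: integral preserved
  x <- exp(-ax$centers_ns / 0.4)
  y <- convolve_irf(x, irf, ax)
  expect_equal(sum(y), sum(x), tolerance = 1e-9)
  # constant signal unchanged beyond the kernel support
  cst <- rep(1, ax$n_channels)
  yc <- convolve_irf(cst, irf, ax)
  beyond <- ax$centers_ns > 0.25 + 8 * irf$sigma_ns
  expect_equal(yc[beyond], cst[beyond], tolerance = 1e-9)
  # near-delta kernel acts as identity up to a sub-channel shift
  irf0 <- irf_model(1e-4, 0)
  expect_equal(convolve_irf(x, irf0, ax), x, tolerance = 1e-4)

  emg <- function(tt, tau, s, t0)
    0.5 * exp(s^2 / (2 * tau^2) - (tt - t0) / tau) *
      pracma::erfc(s / (tau * sqrt(2)) - (tt - t0) / (s * sqrt(2)))
  # fine axis: discretisation error below 1e-6
  axf <- time_axis(65536, 12.5)
  Bf <- reconvolution_basis(1, irf, axf)
  ref <- emg(axf$centers_ns, 1, irf$sigma_ns, 0.25)
  expect_lt(max(abs(Bf[, 1] - ref)) / max(ref), 1e-6)
  # default 3-ps channels: bounded by the quadrature error
  axd <- time_axis()
  Bd <- reconvolution_basis(1, irf, axd)
  refd <- emg(axd$centers_ns, 1, irf$sigma_ns, 0.25)
  expect_lt(max(abs(Bd[, 1] - refd)) / max(refd), 1e-4)
})

test_that("Poisson noise is reproducible and unbiased", {
  ax <- small_axis(128, 5)
  sp <- emission_spectra(peaks_nm = c(X = 640), fwhm_nm = 30,
                         wavelengths_nm = seq(620, 660, 10))
  sig <- tres_ideal(propagate(eet_cascade(lifetimes_ns = c(X = 1)), ax), sp)
  d1 <- add_poisson(sig, ax, sp$wavelengths_nm, 500, seed = 7)
  d2 <- add_poisson(sig, ax, sp$wavelengths_nm, 500, seed = 7)
  expect_identical(d1$counts, d2$counts)
  d3 <- add_poisson(sig, ax, sp$wavelengths_nm, 500, seed = 8)
  expect_false(identical(d1$counts, d3$counts))

  z <- add_poisson(sig * 0, ax, sp$wavelengths_nm, 500, seed = 1)
  expect_true(all(z$counts == 0))

  # bright-pixel mean over replicates within 3 sigma of the scaled signal
  mu <- max(sig) * 500 / max(sig)  # = 500 at the brightest pixel
  reps <- vapply(1:200, function(s)
    max(add_poisson(sig, ax, sp$wavelengths_nm, 500, seed = s)$counts[
      which.max(sig)]), 0)
  expect_lt(abs(mean(reps) - mu), 3 * sqrt(mu / 200))
  expect_error(add_poisson(sig - 1e5, ax, sp$wavelengths_nm, 500), "nonnegative")
})

test_that("steady-state spectra reproduce the quenching-induced peak shift", {
  unq <- steady_state_spectrum(eet_cascade())
  expect_equal(round(unq$peak_nm), 663)
  # strong quench of the terminal emitter moves the maximum to the PC band
  q <- steady_state_spectrum(eet_cascade(lifetimes_ns = c(PE = 0.070, PC = 0.165,
                                                          AP = 0.019)))
  expect_equal(round(q$peak_nm), 646)
  # single compartment: peak equals that band's maximum
  one <- steady_state_spectrum(
    eet_cascade(lifetimes_ns = c(X = 1), transfer_frac = numeric(0)),
    emission_spectra(peaks_nm = c(X = 646), fwhm_nm = 24))
  expect_equal(one$peak_nm, 646, tolerance = 1e-6)
  # analytic time-integrals of the cascade
  expect_equal(unname(unq$integrals_ns),
               c(0.070, 0.9 * 0.165, 0.81 * 1.9), tolerance = 1e-12)
})

test_that("NPQ induction traces follow the saturating-exponential model", {
  flat <- simulate_npq_timecourse(0.05, 0, duration_s = 10)
  expect_true(all(flat$F == 1))
  tr <- simulate_npq_timecourse(0.05, 0.8, duration_s = 400, n_points = 400)
  expect_equal(tr$F[1], 1)
  expect_equal(tail(tr$F, 1), 1 - 0.8, tolerance = 1e-6)
  # half-quenching time by inversion: F = 0.5 at t = -ln(0.375)/k
  t_half <- -log(1 - 0.5 / 0.8) / 0.05
  expect_equal(approx(tr$t_s, tr$F, t_half)$y, 0.5, tolerance = 1e-3)
  n1 <- simulate_npq_timecourse(0.05, 0.8, noise_sd = 0.02, seed = 3)
  n2 <- simulate_npq_timecourse(0.05, 0.8, noise_sd = 0.02, seed = 3)
  expect_identical(n1, n2)
})

test_that("photocycle series follow Arrhenius kinetics", {
  flat <- simulate_photocycle_series(0, lnA = log(0.02), temps_C = c(5, 15, 25))
  expect_equal(length(unique(vapply(flat, `[[`, 0, "k_true_s"))), 1)

  s1 <- simulate_photocycle_series(60, lnA = 20, temps_C = c(5, 25))
  s2 <- simulate_photocycle_series(60, lnA = 40, temps_C = c(5, 25))
  expect_equal(log(vapply(s2, `[[`, 0, "k_true_s")) -
               log(vapply(s1, `[[`, 0, "k_true_s")), c(20, 20))

  # hand-evaluated Arrhenius ratio between 25 C and 5 C at Ea = 60 kJ/mol
  lnA <- log(0.01) + 60000 / (8.314 * 298.15)
  s <- simulate_photocycle_series(60, lnA, temps_C = c(25, 5))
  expect_equal(s[[1]]$k_true_s, 0.01, tolerance = 1e-12)
  expect_equal(s[[2]]$k_true_s,
               0.01 * exp(-60000 / 8.314 * (1 / 278.15 - 1 / 298.15)),
               tolerance = 1e-12)
  # noiseless traces decay monotonically
  expect_true(all(diff(s[[1]]$trace$A550) < 0))
  expect_error(simulate_photocycle_series(-5, 20), "nonnegative")
})
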