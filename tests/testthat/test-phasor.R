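omega_for <- function(period) 2 * pi / period

test_that("binned monoexponential phasors match the analytic semicircle point", {
  # omega*tau = 1 puts the phasor at (1/2, 1/2)
  tau <- 1; period <- 2 * pi * tau
  d <- expected_decay(tau, total = 1, n_bins = 1024, period = period)
  p <- phasor_transform(d)
  expect_equal(p$g, 0.5, tolerance = 1e-3)
  expect_equal(p$s, 0.5, tolerance = 1e-3)
})

test_that("delta and uniform decays sit at the semicircle extremes", {
  counts <- c(1000, rep(0, 1023))
  p <- phasor_transform(decay_histogram(counts, 25))
  expect_equal(p$g, 1, tolerance = 1e-4)
  expect_equal(p$s, 0, tolerance = 5e-3)
  pu <- phasor_transform(decay_histogram(rep(7, 1024), 25))
  expect_lt(abs(pu$g), 1e-12)
  expect_lt(abs(pu$s), 1e-12)
  expect_error(phasor_transform(decay_histogram(rep(0, 16), 25)),
               "zero total")
})

test_that("reference phasors lie exactly on the universal semicircle", {
  expect_equal(reference_phasor(1, 1)$g, 0.5)
  expect_equal(reference_phasor(1, 1)$s, 0.5)
  p0 <- reference_phasor(1e-12, 1)
  expect_equal(c(p0$g, p0$s), c(1, 0), tolerance = 1e-9)
  om <- 2 * pi / 25  # 40 MHz
  p <- reference_phasor(5.9, om)
  wt <- om * 5.9
  expect_equal(p$g, 1 / (1 + wt^2), tolerance = 1e-12)
  expect_equal(p$s, wt / (1 + wt^2), tolerance = 1e-12)
  expect_equal((p$g - 0.5)^2 + p$s^2, 0.25, tolerance = 1e-12)
  expect_error(reference_phasor(-1, 1), "tau")
})

test_that("simulated monoexponentials fall on the semicircle at shot-noise level", {
  for (tau in c(0.5, 1.4, 3, 5.5, 5.9)) {
    d <- simulate_decay(tau, 2e5, 256, 25, seed = round(tau * 10))
    p <- phasor_transform(d)
    expect_lt(abs((p$g - 0.5)^2 + p$s^2 - 0.25), 5e-3)
  }
})

test_that("phase and modulation lifetimes behave as the phasor geometry dictates", {
  lt <- phasor_lifetime(new_phasor <- reference_phasor(2, 0.5))
  expect_equal(lt$tau_phase, 2, tolerance = 1e-12)
  expect_equal(lt$tau_mod, 2, tolerance = 1e-12)
  # 50/50 mixture falls inside the semicircle: tau_phase < tau_mod
  mix <- expected_decay(data.frame(tau = c(1.4, 5.9), fraction = c(.5, .5)),
                        n_bins = 1024, period = 25)
  lm <- phasor_lifetime(phasor_transform(mix))
  expect_lt(lm$tau_phase, lm$tau_mod)
  # tau -> 0 limit
  expect_equal(phasor_lifetime(reference_phasor(1e-12, 1))$tau_phase, 0,
               tolerance = 1e-9)
  bad <- reference_phasor(1, 1); bad$g <- 0
  expect_error(phasor_lifetime(bad), "phase lifetime")
})

test_that("the phasor of an intensity mixture is the convex combination of phasors", {
  om <- omega_for(25)
  pa <- phasor_transform(expected_decay(1.4, n_bins = 512, period = 25))
  pb <- phasor_transform(expected_decay(5.9, n_bins = 512, period = 25))
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    mix <- expected_decay(data.frame(tau = c(1.4, 5.9), fraction = c(f, 1 - f)),
                          n_bins = 512, period = 25)
    pm <- phasor_transform(mix)
    expect_equal(pm$g, f * pa$g + (1 - f) * pb$g, tolerance = 1e-9)
    expect_equal(pm$s, f * pa$s + (1 - f) * pb$s, tolerance = 1e-9)
  }
})

test_that("three-component unmixing solves the barycentric system", {
  om <- omega_for(25)
  refs <- lapply(c(5.9, 5.5, 1.4), reference_phasor, omega = om)
  for (j in 1:3) {
    u <- unmix_three(refs[[j]], refs)
    f <- c(0, 0, 0); f[j] <- 1
    expect_equal(u$fractions, f, tolerance = 1e-10)
  }
  centroid <- new_phasor(mean(sapply(refs, `[[`, "g")),
                         mean(sapply(refs, `[[`, "s")), om)
  expect_equal(unmix_three(centroid, refs)$fractions, rep(1 / 3, 3),
               tolerance = 1e-10)
  # random interior points vs an independent least-squares solve
  set.seed(20)
  for (i in 1:20) {
    w <- stats::runif(3); w <- w / sum(w)
    p <- new_phasor(sum(w * sapply(refs, `[[`, "g")),
                    sum(w * sapply(refs, `[[`, "s")), om)
    u <- unmix_three(p, refs)
    expect_equal(u$fractions, bf_unmix(p$g, p$s, refs), tolerance = 1e-10)
    expect_equal(u$residual, 0)
  }
  collinear <- lapply(c(0.1, 0.2, 0.3), function(g) new_phasor(g, 2 * g, om))
  expect_error(unmix_three(refs[[1]], collinear), "collinear")
})

test_that("out-of-triangle phasors are projected with a recorded residual", {
  om <- omega_for(25)
  refs <- lapply(c(5.9, 5.5, 1.4), reference_phasor, omega = om)
  outside <- new_phasor(0.95, 0.02, om)
  u <- unmix_three(outside, refs)
  expect_gt(u$residual, 0)
  expect_true(all(u$fractions >= 0))
  expect_equal(sum(u$fractions), 1, tolerance = 1e-9)
})

test_that("noiseless unmixing recovers generating fractions to 1e-6", {
  om <- omega_for(25)
  taus <- c(5.9, 5.5, 1.4)
  refs <- lapply(taus, function(tau) {
    phasor_transform(expected_decay(tau, n_bins = 256, period = 25))
  })
  set.seed(21)
  for (i in 1:10) {
    w <- stats::runif(3); w <- w / sum(w)
    mix <- expected_decay(data.frame(tau = taus, fraction = w),
                          n_bins = 256, period = 25)
    u <- unmix_three(phasor_transform(mix), refs)
    expect_equal(u$fractions, w, tolerance = 1e-6)
  }
})

test_that("unmixing under Poisson noise at 1e4 photons keeps MAE below 0.05", {
  om <- omega_for(25)
  taus <- c(1.4, 3.0, 5.9)  # well-separated species
  refs <- lapply(taus, reference_phasor, omega = om)
  set.seed(22)
  errs <- replicate(40, {
    w <- stats::runif(3); w <- w / sum(w)
    d <- simulate_decay(data.frame(tau = taus, fraction = w), 1e4,
                        n_bins = 256, period = 25)
    mean(abs(unmix_three(phasor_transform(d), refs)$fractions - w))
  })
  expect_lt(mean(errs), 0.05)
})

test_that("for near-degenerate references the summed fraction stays accurate", {
  # 5.9 and 5.5 ns phasors are only ~0.03 apart: the split between them is
  # ill-conditioned, but their combined fraction against 1.4 ns is not
  om <- omega_for(25)
  taus <- c(5.9, 5.5, 1.4)
  refs <- lapply(taus, reference_phasor, omega = om)
  set.seed(23)
  errs <- replicate(40, {
    w <- stats::runif(3); w <- w / sum(w)
    d <- simulate_decay(data.frame(tau = taus, fraction = w), 1e4,
                        n_bins = 256, period = 25)
    f <- unmix_three(phasor_transform(d), refs)$fractions
    abs((f[1] + f[2]) - (w[1] + w[2]))
  })
  expect_lt(mean(errs), 0.02)
})

test_that("two-component unmixing projects onto the reference segment", {
  om <- omega_for(25)
  refs <- lapply(c(5.9, 1.4), reference_phasor, omega = om)
  mid <- new_phasor((refs[[1]]$g + refs[[2]]$g) / 2,
                    (refs[[1]]$s + refs[[2]]$s) / 2, om)
  u <- unmix_two(mid, refs)
  expect_equal(u$fractions, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unmix_two(refs[[1]], refs)$fractions, c(1, 0))
})

test_that("maximum-likelihood fit is exact on noiseless input and calibrated under noise", {
  fe <- fit_monoexponential(expected_decay(2, total = 1e6))
  expect_equal(fe$tau, 2, tolerance = 1e-6)
  d <- simulate_decay(1.8, 1e6, 256, 25, seed = 30)
  f <- fit_monoexponential(d)
  expect_lt(abs(f$tau - 1.8), 3 * f$se)
  expect_true(f$se > 0 && f$se < 0.01)
  expect_error(fit_monoexponential(decay_histogram(rep(0, 256), 25)),
               "1000")
})

test_that("MLE and phasor phase lifetime agree on high-count monoexponentials", {
  for (tau in c(1.4, 3.0, 5.9)) {
    d <- simulate_decay(tau, 5e5, 256, 25, seed = round(100 * tau))
    tp <- phasor_lifetime(phasor_transform(d))$tau_phase
    tm <- fit_monoexponential(d)$tau
    expect_lt(abs(tp - tm) / tm, 0.02)
  }
})

test_that("reference calibration undoes a Gaussian instrument response", {
  # both sample and reference measured through the same IRF
  samp <- simulate_decay(4.2, 5e5, 512, 25, irf_sigma = 0.4, seed = 31)
  refm <- simulate_decay(1.0, 5e5, 512, 25, irf_sigma = 0.4, seed = 32)
  raw <- phasor_lifetime(phasor_transform(samp))$tau_phase
  cal <- phasor_calibrate(phasor_transform(samp), phasor_transform(refm),
                          reference_tau = 1.0)
  calt <- phasor_lifetime(cal)$tau_phase
  expect_gt(abs(raw - 4.2), abs(calt - 4.2))  # calibration strictly helps
  expect_equal(calt, 4.2, tolerance = 0.05)
})

test_that("decay histogram constructor validates its invariants", {
  expect_error(decay_histogram(c(-1, 2), 25), "non-negative")
  expect_error(decay_histogram(1:10, 25, bin_edges = seq(0, 30, length.out = 11)),
               "one period")
  expect_error(decay_histogram(1:10, 25, bin_edges = c(0, 1, 3, 6, 7:13)),
               "uniform")
})
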