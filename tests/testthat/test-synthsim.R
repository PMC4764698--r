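test_that("ERP kernel peaks at its amplitude and integrates analytically", {
  t_ms <- seq(-100, 500, by = 1 / 1024 * 1000)
  p <- component_param("MMN", "ignore", -2.81, 159, 30, "anterior")
  k <- erp_kernel(p, t_ms)
  expect_equal(min(k), -2.81, tolerance = 1e-4)
  expect_equal(t_ms[which.min(k)], 159, tolerance = 1)
  # decays to ~0 beyond 3 widths
  expect_lt(max(abs(k[abs(t_ms - 159) > 3 * 30])), abs(-2.81) * 0.012)
  # quadrature vs closed form: integral = amplitude * width * sqrt(2*pi)
  dt <- diff(t_ms)[1]
  expect_equal(sum(k) * dt, -2.81 * 30 * sqrt(2 * pi), tolerance = 0.01)

  p0 <- component_param("P3a", "ignore", 0, 297, 60, "anterior")
  expect_true(all(erp_kernel(p0, t_ms) == 0))
  expect_error(erp_kernel(p, seq(300, 500)), "latency")
})

test_that("component parameter invariants are enforced", {
  expect_error(component_param("MMN", "ignore", 1, 159, 30, "anterior"),
               "MMN")
  expect_error(component_param("P3b", "attend", -1, 506, 80, "posterior"),
               "P3")
  expect_error(component_param("P3a", "ignore", 1, 297, 0, "anterior"),
               "width")
  expect_error(subject_profile("x", list(), p_hit = 1.2), "probabilities")
})

test_that("background noise has 1/f spectral slope before filtering", {
  set.seed(11)
  n <- 2^15
  fs <- 1024
  # averaged periodogram over several realizations
  psd <- 0
  for (r in 1:6) {
    x <- pink_noise(n, fs, rms = 10)
    psd <- psd + Mod(fft(x))^2 / n
  }
  f <- (0:(n - 1)) * fs / n
  sel <- f >= 1 & f <= 100
  # bin-average in log-f to equalize leverage
  bins <- cut(log10(f[sel]), 24)
  lp <- tapply(log10(psd[sel]), bins, mean)
  lf <- tapply(log10(f[sel]), bins, mean)
  slope <- coef(lm(lp ~ lf))[2]
  expect_lt(abs(slope - (-1)), 0.2)
  # scaled to the requested RMS
  expect_equal(sd(pink_noise(n, fs, rms = 10)), 10, tolerance = 1e-6)
})

test_that("simulation is deterministic and respects the montage", {
  prof <- control_profile()
  sched <- make_control_schedule(3)
  r1 <- simulate_recording(prof, sched, "control", seed = 5)
  r2 <- simulate_recording(prof, sched, "control", seed = 5)
  expect_identical(r1$signal, r2$signal)
  expect_equal(nrow(r1$markers), 3)
  expect_true(all(r1$markers$sample <= nrow(r1$signal)))
  expect_error(simulate_recording(prof, sched, "control", seed = 1,
                                  channels = character(0)), "montage")
})

test_that("noiseless epoch averages reproduce the kernel sum exactly", {
  prof <- control_profile(noise_rms = 0, blink_rate = 0)
  # a 125-ms IOI makes every sequence onset land exactly on a sample at
  # 1024 Hz, so the comparison is exact rather than sub-sample-shifted
  sched <- make_ignore_schedule(n_blocks = 1, n_per_block = 40,
                                p_deviant = 0.05, seed = 4,
                                spec = pattern_spec(ioi = 125))
  rec <- simulate_recording(prof, sched, "ignore", seed = 4,
                            calibrate = FALSE)
  ep <- extract_epochs(rec, -100, 500)
  ep$rejected <- reject_artifacts(ep)
  expect_equal(sum(ep$rejected), 0)
  ep <- baseline_correct(ep)
  d <- difference_wave(average_condition(ep, "deviant"),
                       average_condition(ep, "standard"))
  ant <- roi_average(d, roi_spec()$anterior)
  comps <- Filter(function(cp) cp$task == "ignore", prof$components)
  expected <- Reduce(`+`, lapply(comps, erp_kernel, time_ms = ant$time_ms))
  # ROI-normalized topography: anterior ROI mean equals the kernel sum;
  # the kernels have negligible baseline content, so baseline correction
  # leaves them intact
  expect_equal(ant$values, expected, tolerance = 1e-5)
  # at FCz the kernel is scaled by the (normalized) FCz weight
  fcz <- d$data["FCz", ]
  w_fcz <- 1.00 / mean(c(0.90, 0.97, 1.00, 0.93))
  expect_equal(unname(fcz), expected * w_fcz, tolerance = 1e-5)
})

test_that("amplitude calibration closes the loop through the full pipeline", {
  # noiseless subject, but with the standard 0.5-25 Hz filter in the chain:
  # quantified mean amplitudes should come back at the profile values
  prof <- control_profile(noise_rms = 0, blink_rate = 0)
  sched <- make_ignore_schedule(n_blocks = 1, n_per_block = 60,
                                p_deviant = 0.05, seed = 8)
  rec <- bandpass(simulate_recording(prof, sched, "ignore", seed = 8))
  ep <- baseline_correct(extract_epochs(rec, -100, 500))
  d <- difference_wave(average_condition(ep, "deviant"),
                       average_condition(ep, "standard"))
  for (cmp in c("MMN", "P3a")) {
    truth <- Filter(function(cp) cp$task == "ignore" && cp$name == cmp,
                    prof$components)[[1]]
    wins <- component_windows("ignore")
    m <- quantify_component(d, cmp, task = "ignore",
                            governing_peak = "individual",
                            windows = wins, ci_method = "baseline")
    expect_equal(m$mean_amplitude, truth$amplitude, tolerance = 0.05)
    expect_equal(m$peak_latency, truth$latency, tolerance = 5)
  }
})

test_that("keypress simulation matches its Bernoulli rates", {
  set.seed(99)
  sched <- make_attend_schedule(n_trials = 2000, p_deviant_trial = 0.5,
                                seed = 3)
  prof <- control_profile()  # p_hit 0.83, p_fa 0.14
  resp <- simulate_behavior(prof, sched, seed = 12)
  sc <- score_responses(sched, resp)
  expect_lt(abs(sc$hits - 0.83), 3 * sqrt(0.83 * 0.17 / 1000) + 0.005)
  expect_lt(abs(sc$false_alarms - 0.14),
            3 * sqrt(0.14 * 0.86 / 1000) + 0.005)

  # degenerate probabilities
  p1 <- control_profile(p_hit = 1, p_fa = 0)
  sc1 <- score_responses(sched, simulate_behavior(p1, sched, seed = 2))
  expect_equal(sc1$hits, 1)
  expect_equal(sc1$false_alarms, 0)

  # conservative case profile: expected hit count ~ n * p_hit
  pj <- case_j_profile()  # p_hit 0.36
  hits <- replicate(60, {
    s <- make_attend_schedule(n_trials = 120, p_deviant_trial = 0.5,
                              seed = sample.int(1e6, 1))
    sum(score_responses(s, simulate_behavior(pj, s,
                                             seed = sample.int(1e6, 1))
    )$correct[s$trials$deviant])
  })
  expect_equal(mean(hits), 60 * 0.36, tolerance = 0.1)
})
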