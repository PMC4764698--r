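test_that("difference waves are pointwise and linear", {
  set.seed(2)
  a <- make_wave(matrix(rnorm(200), 2))
  b <- make_wave(matrix(rnorm(200), 2))
  cst <- make_wave(matrix(1, 2, 100))

  expect_true(all(difference_wave(a, a)$data == 0))
  ab <- difference_wave(a, b)
  expect_equal(ab$data, a$data - b$data)
  # shift-invariance: diff(a + c, b + c) = diff(a, b)
  ac <- a; ac$data <- a$data + cst$data
  bc <- b; bc$data <- b$data + cst$data
  expect_equal(difference_wave(ac, bc)$data, ab$data, tolerance = 1e-12)

  short <- make_wave(matrix(rnorm(100), 2, 50))
  expect_error(difference_wave(a, short), "alignment")
})

test_that("ROI averaging is an unweighted, order-invariant electrode mean", {
  chans <- c("AFz", "Fz", "FCz", "Cz")
  w <- make_wave(matrix(rep(c(0, 0, 0, 4), 10), 4, 10, byrow = FALSE),
                 channels = chans)
  expect_true(all(roi_average(w, chans)$values == 1))

  same <- make_wave(matrix(rep(3.3, 40), 4, 10), channels = chans)
  expect_true(all(roi_average(same, chans)$values == 3.3))

  set.seed(4)
  r <- make_wave(matrix(rnorm(40), 4, 10), channels = chans)
  expect_equal(roi_average(r, chans)$values,
               roi_average(r, rev(chans))$values)
  expect_error(roi_average(r, c("AFz", "Pz")), "montage")
})

test_that("peak finding honors polarity, windows, and early tie-breaks", {
  t_ms <- seq(-100, 500, length.out = 616)
  p <- component_param("MMN", "ignore", -2.81, 159, 30, "anterior")
  s <- make_series(erp_kernel(p, t_ms), t_ms)
  expect_equal(find_peak(s, "negative", c(100, 250)), 159, tolerance = 1)

  ramp <- make_series(seq_along(t_ms) * 0.01, t_ms)
  expect_equal(find_peak(ramp, "positive", c(100, 250)),
               max(t_ms[t_ms <= 250]))
  expect_equal(find_peak(ramp, "negative", c(100, 250)),
               min(t_ms[t_ms >= 100]))

  # two equal minima: the earlier latency wins
  v <- rep(0, length(t_ms))
  v[c(300, 400)] <- -5
  tie <- make_series(v, t_ms)
  expect_equal(find_peak(tie, "negative", c(-100, 500)), t_ms[300])

  expect_error(find_peak(s, "negative", c(600, 700)), "empty")
})

test_that("window means match the closed-form Gaussian oracle", {
  fs <- 1024
  t_ms <- seq(-100, 500, by = 1000 / fs)
  cst <- make_series(rep(-2.81, length(t_ms)), t_ms)
  expect_equal(window_mean(cst, 159, 40), -2.81)

  p <- component_param("P3a", "ignore", 1.10, 297, 60, "anterior")
  s <- make_series(erp_kernel(p, t_ms), t_ms)
  expect_equal(window_mean(s, 297, 40),
               gauss_window_mean(1.10, 297, 60, 277, 317),
               tolerance = 5e-3)
  # off-center windows too
  expect_equal(window_mean(s, 350, 40),
               gauss_window_mean(1.10, 297, 60, 330, 370),
               tolerance = 5e-3)

  # translation equivariance: shifting series and center together by a
  # whole number of samples leaves the value unchanged exactly
  shift <- 50 * 1000 / fs
  s2 <- make_series(erp_kernel(p, t_ms - shift), t_ms)
  expect_equal(window_mean(s2, 297 + shift, 40), window_mean(s, 297, 40),
               tolerance = 1e-9)

  # width 0 degenerates to the nearest sample
  expect_equal(window_mean(s, 297, 0),
               s$values[which.min(abs(t_ms - 297))])
  expect_error(window_mean(s, 495, 40), "epoch edge")
})

test_that("baseline-noise CI matches the closed form on white noise", {
  fs <- 1024
  t_ms <- seq(-100, 500, by = 1000 / fs)
  nb <- sum(t_ms >= -100 & t_ms <= 0)

  quiet <- make_series(c(rep(0, nb), rnorm(length(t_ms) - nb)), t_ms)
  expect_equal(baseline_noise_ci(quiet), 0)

  set.seed(31)
  sigma <- 2
  cis <- replicate(400, baseline_noise_ci(
    make_series(rnorm(length(t_ms), sd = sigma), t_ms)))
  expect_equal(mean(cis), qt(0.975, nb - 1) * sigma / sqrt(nb),
               tolerance = 0.05)
  few <- make_series(1:2, c(-50, 0))
  expect_error(baseline_noise_ci(few), "estimation")
})

test_that("component quantification recovers noiseless kernels analytically", {
  fs <- 1024
  t_ms <- seq(-100, 500, by = 1000 / fs)
  rois <- roi_spec()
  p <- component_param("MMN", "ignore", -2.81, 159, 30, "anterior")
  mat <- matrix(rep(erp_kernel(p, t_ms), each = 8), 8,
                dimnames = list(c(rois$anterior, rois$posterior), NULL))
  w <- make_wave(mat, channels = rownames(mat))

  m <- quantify_component(w, "MMN", task = "ignore",
                          governing_peak = "individual",
                          ci_method = "baseline")
  expect_equal(m$peak_latency, 159, tolerance = 1)
  expect_equal(m$mean_amplitude,
               gauss_window_mean(-2.81, 159, 30,
                                 m$win_lo, m$win_hi),
               tolerance = 2e-3)
  expect_equal(m$win_hi - m$win_lo, 40)
  expect_true(m$reliable)   # zero baseline noise, nonzero amplitude

  # group mode centers the window on the supplied grand-average latency
  g <- quantify_component(w, "MMN", task = "ignore",
                          governing_peak = "group", group_latency = 154,
                          ci_method = "baseline")
  expect_equal(c(g$win_lo, g$win_hi), c(134, 174))
  expect_equal(g$mean_amplitude,
               gauss_window_mean(-2.81, 159, 30, 134, 174),
               tolerance = 2e-3)
})

test_that("reliability verdict compares the window mean with the noise CI", {
  # an amplitude of -0.09 uV against a +-0.20 uV noise CI is not reliable
  fs <- 1024
  t_ms <- seq(-100, 900, by = 1000 / fs)
  nb <- sum(t_ms <= 0)
  set.seed(5)
  base <- rnorm(nb)
  base <- (base - mean(base)) / sd(base)
  sigma <- 0.20 / (qt(0.975, nb - 1) / sqrt(nb))  # calibrated to ci = 0.20
  vals <- c(base * sigma, rep(0, length(t_ms) - nb))
  vals[t_ms >= 480 & t_ms <= 540] <- -0.09
  mat <- matrix(rep(vals, each = 8), 8,
                dimnames = list(unlist(roi_spec()), NULL))
  w <- make_wave(mat, channels = rownames(mat))
  m <- quantify_component(w, "P3b", task = "attend",
                          governing_peak = "group", group_latency = 506,
                          ci_method = "baseline")
  expect_equal(m$ci_baseline, 0.20, tolerance = 1e-6)
  expect_equal(m$mean_amplitude, -0.09, tolerance = 1e-6)
  expect_false(m$reliable)
})

test_that("epoch-level CI behaves like a trial-sampling standard error", {
  # epochs of pure white noise: the Welch CI of the deviant-standard window
  # mean should scale like 1.96 * sigma * sqrt(1/n_d + 1/n_s) / sqrt(nw)
  fs <- 1024
  nt <- 1025
  nd <- 40; ns <- 80
  set.seed(8)
  dat <- array(rnorm((nd + ns) * 1 * nt, sd = 3), c(nd + ns, 1, nt))
  ep <- make_epochs(dat, fs, condition = factor(
    rep(c("deviant", "standard"), c(nd, ns)),
    levels = c("standard", "deviant")))
  ep$channels <- "anterior"
  dimnames(ep$data)[[2]] <- "anterior"
  ci <- oddbeat:::epoch_window_ci(ep, "anterior", center = 500, width = 40)
  nw <- sum(ep$time_ms >= 480 & ep$time_ms <= 520)
  expected <- 1.96 * 3 * sqrt(1 / nd + 1 / ns) / sqrt(nw)
  expect_equal(ci, expected, tolerance = 0.25)
})

test_that("grand averages are unweighted subject means", {
  set.seed(6)
  ws <- lapply(1:5, function(i) make_wave(matrix(rnorm(40), 4, 10),
                                          channels = c("a", "b", "c", "d")))
  g <- grand_average(ws)
  expect_equal(g$data, Reduce(`+`, lapply(ws, `[[`, "data")) / 5)
})
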