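test_that("bandpass attenuates DC and stopband, passes the band", {
  fs <- 1024
  n <- 16 * fs
  t <- (0:(n - 1)) / fs
  mid <- (6 * fs):(10 * fs)  # avoid edge transients when measuring

  dc <- bandpass(make_rec(matrix(5, n, 1), fs))
  expect_lt(max(abs(dc$signal[mid, 1])) / 5, 0.01)      # > 40 dB down

  s10 <- bandpass(make_rec(matrix(sin(2 * pi * 10 * t), n, 1), fs))
  amp10 <- max(abs(s10$signal[mid, 1]))
  expect_lt(abs(amp10 - 1), 0.05)                       # within 5% of unity

  s50 <- bandpass(make_rec(matrix(sin(2 * pi * 50 * t), n, 1), fs))
  expect_lt(max(abs(s50$signal[mid, 1])), 0.1)          # > 20 dB down

  expect_equal(nrow(s10$signal), n)                     # length preserved
  # zero phase: 10 Hz component keeps its phase (no latency shift)
  ref <- sin(2 * pi * 10 * t[mid])
  lagfit <- ccf(s10$signal[mid, 1], ref, lag.max = 20, plot = FALSE)
  expect_equal(lagfit$lag[which.max(lagfit$acf)], 0)

  expect_error(bandpass(make_rec(matrix(0, 100, 1), fs), 0.5, 600),
               "Nyquist")
})

test_that("epoch extraction counts and boundary handling are exact", {
  fs <- 1024
  n <- 10 * fs
  mk <- data.frame(sample = c(1L, seq(2 * fs, 9 * fs, by = fs)),
                   onset_ms = NA, code = 2L, label = "deviant")
  mk$onset_ms <- (mk$sample - 1) / fs * 1000
  rec <- make_rec(matrix(0, n, 2), fs, mk)
  ep <- extract_epochs(rec, -100, 500)
  # ignore-task epoch: 600 ms span at 1024 Hz, inclusive endpoints
  expect_equal(length(ep$time_ms), 615)
  expect_equal(range(ep$time_ms), c(-102, 512) / 1024 * 1000,
               tolerance = 1e-10)
  # the marker at sample 1 cannot host a -100 ms baseline: dropped, logged
  expect_equal(ep$n_dropped, 1L)
  expect_equal(dim(ep$data)[1], nrow(mk) - 1L)
  expect_error(extract_epochs(make_rec(matrix(0, n, 1), fs), -100, 500),
               "empty-epochs")
  expect_error(extract_epochs(rec, 100, 500), "tmin")
})

test_that("one epoch is produced per target marker of a real schedule", {
  sched <- make_ignore_schedule(n_blocks = 1, n_per_block = 80,
                                p_deviant = 0.05, seed = 13)
  rec <- simulate_recording(control_profile(noise_rms = 1, blink_rate = 0),
                            sched, "ignore", seed = 13)
  ep <- extract_epochs(rec, -100, 500)
  n_dev <- sum(sched$labels == "deviant")
  expect_equal(sum(ep$condition == "deviant"), n_dev)
  expect_equal(dim(ep$data)[1] + ep$n_dropped, 80)
})

test_that("artifact rejection uses a strict sliding peak-to-peak criterion", {
  fs <- 1024
  nt <- 615
  dat <- array(0, c(4, 2, nt))
  # epoch 2: a 100 uV blink-like excursion -> rejected
  dat[2, 1, 300:350] <- 100
  # epoch 3: exactly 75 uV peak-to-peak -> retained (strict >)
  dat[3, 2, 100:200] <- 75
  # epoch 4: 75 uV swing but split across channels (50 + 40) -> retained
  dat[4, 1, 100:200] <- 50
  dat[4, 2, 100:200] <- -40
  ep <- make_epochs(dat, fs)
  rej <- reject_artifacts(ep, threshold = 75, window_ms = 500)
  expect_equal(rej, c(FALSE, TRUE, FALSE, FALSE))

  # slightly over threshold on one channel -> rejected
  dat[3, 2, 100:200] <- 75.2
  expect_equal(reject_artifacts(make_epochs(dat, fs), 75, 500)[3], TRUE)

  # a slow drift exceeding 75 uV overall but < 75 within any 500 ms window
  drift <- array(0, c(1, 1, nt))
  drift[1, 1, ] <- seq(0, 95, length.out = nt)  # 79.1 uV per 500 ms window
  expect_equal(reject_artifacts(make_epochs(drift, fs), 75, 500), TRUE)
  drift[1, 1, ] <- seq(0, 85, length.out = nt)  # 70.8 uV per 500 ms window
  expect_equal(reject_artifacts(make_epochs(drift, fs), 75, 500), FALSE)

  expect_error(reject_artifacts(ep, threshold = 0), "threshold")
  expect_error(reject_artifacts(ep, window_ms = 700), "window")
})

test_that("rejection mask is invariant to channel order", {
  set.seed(21)
  dat <- array(rnorm(6 * 3 * 615, sd = 30), c(6, 3, 615))
  ep <- make_epochs(dat, 1024)
  ep_perm <- make_epochs(dat[, c(3, 1, 2), , drop = FALSE], 1024)
  expect_equal(reject_artifacts(ep), reject_artifacts(ep_perm))
})

test_that("baseline correction zeroes the baseline and is idempotent", {
  set.seed(7)
  dat <- array(rnorm(5 * 2 * 615, mean = 3), c(5, 2, 615))
  ep <- make_epochs(dat, 1024)
  bc <- baseline_correct(ep)
  ib <- bc$time_ms >= -100 & bc$time_ms <= 0
  for (i in 1:5) for (j in 1:2)
    expect_equal(mean(bc$data[i, j, ib]), 0, tolerance = 1e-12)
  # constant epochs vanish entirely
  cst <- make_epochs(array(5, c(2, 1, 615)), 1024)
  expect_true(all(abs(baseline_correct(cst)$data) < 1e-12))
  # idempotent
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)
})

test_that("condition averaging respects rejection and correctness flags", {
  dat <- array(0, c(6, 1, 615))
  for (i in 1:6) dat[i, 1, ] <- i
  cond <- factor(rep(c("standard", "deviant"), each = 3),
                 levels = c("standard", "deviant"))
  ep <- make_epochs(dat, 1024, condition = cond)

  # identical epochs average to themselves
  same <- make_epochs(array(2, c(3, 1, 615)), 1024)
  avg <- average_condition(same, "deviant")
  expect_true(all(avg$data == 2))
  expect_equal(avg$n_epochs, 3)

  # rejection removes epochs from the average
  ep$rejected <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(unname(average_condition(ep, "standard")$data[1, 1]),
               mean(c(1, 3)))

  # correctness gating: retained AND correct
  correct <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  a <- average_condition(ep, "deviant", correct_only = TRUE,
                         correct = correct)
  expect_equal(a$n_epochs, 2)
  expect_equal(unname(a$data[1, 1]), mean(c(4, 6)))

  ep$rejected <- rep(TRUE, 6)
  expect_error(average_condition(ep, "deviant"), "empty-average")
})

test_that("averaging commutes with ROI pooling (linearity)", {
  set.seed(3)
  chans <- c("AFz", "Fz", "FCz", "Cz")
  dat <- array(rnorm(8 * 4 * 100), c(8, 4, 100))
  ep <- make_epochs(dat, 1024, channels = chans)
  avg <- average_condition(ep, "deviant")
  pooled_after <- roi_average(avg, chans)$values
  # pool first, then average epochs
  pooled_first <- colMeans(apply(dat, c(1, 3), mean))
  expect_equal(pooled_after, pooled_first, tolerance = 1e-12)
})

test_that("nose re-referencing subtracts the reference channel when present", {
  sig <- cbind(a = rnorm(100), Nose = rnorm(100))
  rec <- rereference(make_rec(sig, 1024), "Nose")
  expect_equal(rec$signal[, "a"], sig[, "a"] - sig[, "Nose"])
  expect_true(all(rec$signal[, "Nose"] == 0))
  # no-op without the channel
  rec2 <- rereference(make_rec(sig[, 1, drop = FALSE], 1024), "Nose")
  expect_equal(rec2$signal[, 1], sig[, 1])
})
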