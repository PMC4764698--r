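# shared fixtures, built in code

# a desk-scale configuration for fast end-to-end checks
tiny_config <- function(n_controls = 3L, cases = c("case_m", "case_j"), ...) {
  study_config(n_controls = n_controls, cases = cases,
               ignore = list(n_blocks = 1L, n_per_block = 60L,
                             p_deviant = 0.05, min_gap = 3L,
                             epoch = c(-100, 500)),
               attend = list(n_trials = 20L, p_deviant_trial = 0.5,
                             epoch = c(-100, 900)),
               ...)
}

# the full-design cohort is expensive; compute it once per test run
.cohort_cache <- new.env(parent = emptyenv())
full_cohort <- function(seed = 42L) {
  key <- paste0("seed", seed)
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- run_study(study_config(), seed = seed)
  .cohort_cache[[key]]
}

# minimal recording / epochs constructors for arithmetic-level tests
make_rec <- function(signal, fs = 1024, markers = NULL) {
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1)
  if (is.null(colnames(signal)))
    colnames(signal) <- paste0("ch", seq_len(ncol(signal)))
  if (is.null(markers))
    markers <- data.frame(sample = integer(), onset_ms = numeric(),
                          code = integer(), label = character())
  structure(list(signal = signal, fs = fs, channels = colnames(signal),
                 markers = markers,
                 duration_ms = nrow(signal) / fs * 1000),
            class = "eeg_recording")
}

make_epochs <- function(dat, fs = 1024, tmin = -100,
                        condition = NULL, channels = NULL) {
  ne <- dim(dat)[1]; nc <- dim(dat)[2]; nt <- dim(dat)[3]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  dimnames(dat) <- list(NULL, channels, NULL)
  if (is.null(condition))
    condition <- factor(rep("deviant", ne), levels = c("standard", "deviant"))
  o0 <- round(tmin / 1000 * fs)
  structure(list(data = dat, time_ms = (o0:(o0 + nt - 1)) / fs * 1000,
                 channels = channels, condition = condition,
                 onset_ms = seq_len(ne) * 1000,
                 fs = fs, rejected = rep(FALSE, ne), n_dropped = 0L),
            class = "erp_epochs")
}

make_wave <- function(mat, fs = 1024, tmin = -100, channels = NULL) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(mat)))
  rownames(mat) <- channels
  o0 <- round(tmin / 1000 * fs)
  structure(list(data = mat,
                 time_ms = (o0:(o0 + ncol(mat) - 1)) / fs * 1000,
                 channels = channels, condition = "difference",
                 n_epochs = 1L),
            class = "erp_waveform")
}

make_series <- function(values, time_ms) {
  structure(list(values = values, time_ms = time_ms, electrodes = "x"),
            class = "roi_wave")
}

# analytic mean of a gaussian bump of peak A, sd w over [lo, hi] (ms)
gauss_window_mean <- function(A, latency, w, lo, hi) {
  A * w * sqrt(2 * pi) / (hi - lo) *
    (pnorm((hi - latency) / w) - pnorm((lo - latency) / w))
}

min_deviant_gap <- function(sched) {
  idx <- which(sched$labels == "deviant")
  if (length(idx) < 2) Inf else min(diff(idx)) - 1L
}
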