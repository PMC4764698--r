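#' Study configuration
#'
#' Bundles every tunable parameter of the end-to-end study: cohort makeup,
#' design parameters for both tasks, preprocessing, quantification and
#' statistics settings. Defaults reproduce the reference design: 10 controls
#' plus the two case profiles; a passive stream of 10 blocks x 300 sequences
#' with 5% deviants and a minimum gap of 3 standards; 120 active-detection
#' trials, half deviant; 0.5-25 Hz band; 75 uV / 500 ms peak-to-peak
#' rejection; -100..500 ms (ignore) and -100..900 ms (attend) epochs; 40-ms
#' quantification windows; one-tailed Crawford tests in the direction of
#' poorer case performance.
#'
#' @param n_controls Number of control subjects.
#' @param cases Character vector of built-in case profile names
#'   (`"case_m"`, `"case_j"`), or an empty vector.
#' @param fs Sampling rate, Hz.
#' @param channels Montage.
#' @param ignore,attend,reject,quant Nested parameter lists; see defaults.
#' @param band Bandpass edges, Hz.
#' @param response_window Seconds.
#' @param tails Named list of Crawford tail directions per measure family.
#' @param alpha Significance level.
#' @param profile_args Extra arguments passed to every profile constructor
#'   (e.g. `noise_rms`).
#' @return List of class `study_config`.
#' @export
study_config <- function(n_controls = 10L,
                         cases = c("case_m", "case_j"),
                         fs = 1024,
                         channels = default_montage(),
                         ignore = list(n_blocks = 10L, n_per_block = 300L,
                                       p_deviant = 0.05, min_gap = 3L,
                                       epoch = c(-100, 500)),
                         attend = list(n_trials = 120L,
                                       p_deviant_trial = 0.5,
                                       epoch = c(-100, 900)),
                         band = c(0.5, 25),
                         reject = list(threshold = 75, window_ms = 500),
                         response_window = 6,
                         quant = list(width = 40, ci_method = "epochs"),
                         tails = list(hits = "lower", false_alarms = "upper",
                                      A = "lower", b = "upper",
                                      MMN_amplitude = "upper",
                                      P3a_amplitude = "lower",
                                      P3b_amplitude = "lower",
                                      latency = "two"),
                         alpha = 0.05,
                         profile_args = list()) {
  structure(list(n_controls = as.integer(n_controls), cases = cases,
                 fs = fs, channels = channels, ignore = ignore,
                 attend = attend, band = band, reject = reject,
                 response_window = response_window, quant = quant,
                 tails = tails, alpha = alpha, profile_args = profile_args),
            class = "study_config")
}

#' Validate a study configuration
#'
#' Checks every module precondition and returns a character vector of
#' violations (empty when the configuration is runnable). Never raises.
#'
#' @param config A [study_config()].
#' @return Character vector of violation messages.
#' @export
validate_config <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  ig <- config$ignore
  at <- config$attend
  if (config$n_controls < 2) add("n_controls: need >= 2 controls")
  if (ig$p_deviant < 0 || ig$p_deviant > 1)
    add("ignore$p_deviant: probability outside [0, 1]")
  nd <- ig$p_deviant * ig$n_per_block
  if (abs(nd - round(nd)) > 1e-9)
    add("ignore$p_deviant: p_deviant * n_per_block not an integer")
  else if (round(nd) > 0 &&
           (round(nd) - 1) * (ig$min_gap + 1) + 1 > ig$n_per_block)
    add(sprintf(
      "ignore$min_gap: infeasible, %d deviants need %d slots but a block has %d",
      as.integer(round(nd)),
      as.integer((round(nd) - 1) * (ig$min_gap + 1) + 1), ig$n_per_block))
  ndt <- at$n_trials * at$p_deviant_trial
  if (at$p_deviant_trial < 0 || at$p_deviant_trial > 1)
    add("attend$p_deviant_trial: probability outside [0, 1]")
  if (abs(ndt - round(ndt)) > 1e-9)
    add("attend$p_deviant_trial: n_trials * p_deviant_trial not an integer")
  if (!(config$band[1] > 0 && config$band[1] < config$band[2] &&
        config$band[2] < config$fs / 2))
    add("band: need 0 < low < high < Nyquist")
  if (config$reject$threshold <= 0)
    add("reject$threshold: must be positive")
  for (tk in c("ignore", "attend")) {
    ep <- config[[tk]]$epoch
    if (!(ep[1] < 0 && ep[2] > 0)) add(sprintf("%s$epoch: need tmin < 0 < tmax", tk))
    if (config$reject$window_ms > diff(ep))
      add(sprintf("reject$window_ms: exceeds the %s epoch length", tk))
  }
  if (config$alpha <= 0 || config$alpha >= 1) add("alpha: outside (0, 1)")
  pa <- config$profile_args
  if (!is.null(pa$noise_rms) && pa$noise_rms < 0)
    add("noise_rms: must be >= 0")
  if (!is.null(pa$p_hit) && (pa$p_hit < 0 || pa$p_hit > 1))
    add("p_hit: probability outside [0, 1]")
  if (!all(roi_spec()$anterior %in% config$channels) ||
      !all(roi_spec()$posterior %in% config$channels))
    add("channels: montage must include both ROIs' electrodes")
  v
}

#' Write / read a study configuration as YAML
#'
#' @param config A [study_config()].
#' @param path File path.
#' @export
write_study_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(study_config, x[setdiff(names(x), character(0))])
}

## deterministic per-(subject, task, purpose) seed derivation from the master
## seed; keeps every stream independent yet reproducible, and below 2^31
derive_seed <- function(seed, subject, task, purpose = 1L) {
  task_id <- match(task, c("ignore", "attend", "control"))
  (as.double(seed) %% 100000) * 20011 + subject * 1000 +
    task_id * 100 + purpose
}

## collapse full-montage epochs to one virtual channel per ROI
collapse_roi_epochs <- function(ep, rois = roi_spec()) {
  nE <- dim(ep$data)[1]; nT <- dim(ep$data)[3]
  arr <- array(NA_real_, c(nE, length(rois), nT),
               dimnames = list(NULL, names(rois), NULL))
  for (r in seq_along(rois)) {
    idx <- match(rois[[r]], ep$channels)
    arr[, r, ] <- colMeans(aperm(ep$data[, idx, , drop = FALSE],
                                 c(2, 1, 3)))
  }
  out <- ep
  out$data <- arr
  out$channels <- names(rois)
  out
}

collapse_roi_wave <- function(wave, rois = roi_spec()) {
  mat <- t(vapply(rois, function(el)
    colMeans(wave$data[el, , drop = FALSE]), numeric(ncol(wave$data))))
  rownames(mat) <- names(rois)
  out <- wave
  out$data <- mat
  out$channels <- names(rois)
  out
}

## run one subject through one task: simulate, filter, epoch, reject,
## baseline-correct, average; returns ROI-collapsed epochs and waveforms
process_task <- function(profile, config, task, seed) {
  if (task == "ignore") {
    sched <- make_ignore_schedule(config$ignore$n_blocks,
                                  config$ignore$n_per_block,
                                  config$ignore$p_deviant,
                                  config$ignore$min_gap,
                                  seed = derive_seed(seed, 0, task, 2))
    behavior <- NULL
  } else {
    sched <- make_attend_schedule(config$attend$n_trials,
                                  config$attend$p_deviant_trial,
                                  seed = derive_seed(seed, 0, task, 2))
    behavior <- simulate_behavior(profile, sched,
                                  seed = derive_seed(seed, 0, task, 3))
  }
  rec <- simulate_recording(profile, sched, task,
                            seed = derive_seed(seed, 0, task, 4),
                            fs = config$fs, channels = config$channels,
                            band = config$band)
  rec <- rereference(rec)
  rec <- bandpass(rec, config$band[1], config$band[2])
  ep <- extract_epochs(rec, config[[task]]$epoch[1], config[[task]]$epoch[2])
  rm(rec)
  ep$rejected <- reject_artifacts(ep, config$reject$threshold,
                                  config$reject$window_ms)
  ep <- baseline_correct(ep)

  correct_ep <- NULL
  score <- NULL
  if (task == "attend") {
    score <- score_responses(sched, behavior, config$response_window)
    trial_dur <- 5 * sched$sequence_duration_ms
    ep_trial <- floor(ep$onset_ms / trial_dur) + 1L
    correct_ep <- score$correct[ep_trial]
  }
  std <- average_condition(ep, "standard", correct_only = task == "attend",
                           correct = correct_ep)
  dev <- average_condition(ep, "deviant", correct_only = task == "attend",
                           correct = correct_ep)
  log <- data.frame(task = task,
                    n_markers = length(ep$rejected) + ep$n_dropped,
                    extracted = length(ep$rejected),
                    truncated = ep$n_dropped,
                    rejected = sum(ep$rejected),
                    retained = sum(!ep$rejected),
                    std_averaged = std$n_epochs,
                    dev_averaged = dev$n_epochs)
  ep_roi <- collapse_roi_epochs(ep)
  rm(ep)
  list(epochs = ep_roi, correct = correct_ep,
       std = collapse_roi_wave(std), dev = collapse_roi_wave(dev),
       diff = difference_wave(collapse_roi_wave(dev),
                              collapse_roi_wave(std)),
       score = score, log = log)
}

## virtual-ROI lookup passed to quantify_component for collapsed data
.roi_virtual <- list(anterior = "anterior", posterior = "posterior")

quantify_subject <- function(res, task, mode, group_lat, config) {
  wins <- component_windows(task)
  if (task == "ignore") {
    ## keep the P3a search inside the short passive epoch
    hi <- max(res$diff$time_ms) - config$quant$width / 2
    wins$P3a$search[2] <- min(wins$P3a$search[2], floor(hi))
  }
  rows <- lapply(names(wins), function(cmp)
    quantify_component(res$diff, cmp, task = task,
                       governing_peak = mode,
                       group_latency = group_lat[[cmp]],
                       rois = .roi_virtual, windows = wins,
                       width = config$quant$width,
                       ci_method = config$quant$ci_method,
                       epochs = res$epochs, correct = res$correct,
                       alpha = config$alpha))
  do.call(rbind, rows)
}

#' Run the full beat-omission oddball study
#'
#' Simulates the whole cohort (controls plus cases), runs both tasks through
#' the preprocessing and quantification pipeline, scores the behavioral
#' responses, and computes the full inferential layer: the chance-level test
#' on detection performance, deviant-vs-standard repeated-measures ANOVAs for
#' each component in the control group, Crawford modified t comparisons of
#' every case against the controls for every behavioral and ERP measure,
#' leave-one-out control analyses, and behavior-ERP correlations. The ignore
#' task is processed before the attend task, mirroring the protocol order.
#' Control subjects are quantified in group mode (windows centered on the
#' control grand-average peak latencies); cases in individual mode (their own
#' peaks), to avoid underestimating their amplitudes.
#'
#' Deterministic given `seed`: running twice with the same seed and
#' configuration yields identical results.
#'
#' @param config A [study_config()].
#' @param seed Master seed; split into independent per-subject, per-task
#'   substreams.
#' @return An object of class `beat_study`; see [print.beat_study()] /
#'   [summary.beat_study()], and [export_reports()] for file output.
#' @export
run_study <- function(config = study_config(), seed = 1L) {
  viol <- validate_config(config)
  if (length(viol))
    stop("configuration error:\n  ", paste(viol, collapse = "\n  "))

  builders <- c(list(control = control_profile),
                stats::setNames(
                  lapply(config$cases, function(nm)
                    switch(nm, case_m = case_m_profile,
                           case_j = case_j_profile,
                           stop("configuration error: unknown case ", nm))),
                  config$cases))
  ids <- c(sprintf("ctrl%02d", seq_len(config$n_controls)), config$cases)
  is_control <- c(rep(TRUE, config$n_controls),
                  rep(FALSE, length(config$cases)))

  subjects <- list()
  for (k in seq_along(ids)) {
    bld <- if (is_control[k]) builders$control else builders[[ids[k]]]
    profile <- do.call(bld, c(list(id = ids[k]), config$profile_args))
    sseed <- seed + k * 37L
    res <- list(profile = profile)
    for (task in c("ignore", "attend"))
      res[[task]] <- process_task(profile, config, task,
                                  derive_seed(sseed, k, task, 1))
    res$behavior <- data.frame(
      id = ids[k],
      hits = res$attend$score$hits,
      false_alarms = res$attend$score$false_alarms,
      A = sensitivity_A(res$attend$score$hits,
                        res$attend$score$false_alarms),
      b = bias_b(res$attend$score$hits, res$attend$score$false_alarms),
      stringsAsFactors = FALSE)
    subjects[[ids[k]]] <- res
  }

  ## control grand-average difference waves and group peak latencies
  ctrl <- subjects[is_control]
  grand <- list(ignore = grand_average(lapply(ctrl, function(s) s$ignore$diff)),
                attend = grand_average(lapply(ctrl, function(s) s$attend$diff)))
  group_lat <- list(ignore = list(), attend = list())
  for (task in c("ignore", "attend")) {
    wins <- component_windows(task)
    if (task == "ignore")
      wins$P3a$search[2] <- min(wins$P3a$search[2],
                                floor(max(grand[[task]]$time_ms) -
                                        config$quant$width / 2))
    for (cmp in names(wins))
      group_lat[[task]][[cmp]] <- find_peak(
        roi_average(grand[[task]], .roi_virtual[[wins[[cmp]]$roi]]),
        wins[[cmp]]$polarity, wins[[cmp]]$search)
  }

  ## per-subject component measures (controls: group mode; cases: individual)
  measures <- list()
  for (k in seq_along(ids)) {
    mode <- if (is_control[k]) "group" else "individual"
    rows <- lapply(c("ignore", "attend"), function(task) {
      m <- quantify_subject(subjects[[ids[k]]][[task]], task, mode,
                            group_lat[[task]], config)
      m$task <- task
      m
    })
    m <- do.call(rbind, rows)
    m$id <- ids[k]
    measures[[ids[k]]] <- m
  }
  measures <- do.call(rbind, measures)
  rownames(measures) <- NULL

  behavior <- do.call(rbind, lapply(subjects, function(s) s$behavior))
  rownames(behavior) <- NULL

  ## drop the bulky epoch stores before assembling the result
  for (k in seq_along(subjects)) {
    subjects[[k]]$ignore$epochs <- NULL
    subjects[[k]]$attend$epochs <- NULL
    subjects[[k]]$ignore$correct <- NULL
    subjects[[k]]$attend$correct <- NULL
  }

  res <- structure(list(config = config, seed = seed, ids = ids,
                        is_control = is_control,
                        behavior = behavior, measures = measures,
                        grand = grand, group_latency = group_lat,
                        subjects = subjects),
                   class = "beat_study")
  res$stats <- study_stats(res)
  res$tables <- study_tables(res)
  res$epoch_log <- do.call(rbind, lapply(ids, function(id) {
    lg <- rbind(subjects[[id]]$ignore$log, subjects[[id]]$attend$log)
    lg$id <- id
    lg
  }))
  res
}

measure_of <- function(measures, id, task, cmp, what = "mean_amplitude")
  measures[[what]][measures$id == id & measures$task == task &
                     measures$component == cmp]

study_stats <- function(study) {
  cfg <- study$config
  ctrl_ids <- study$ids[study$is_control]
  case_ids <- study$ids[!study$is_control]
  beh <- study$behavior
  ctrl_beh <- beh[beh$id %in% ctrl_ids, ]

  ## chance-level test on overall proportion correct (one-tailed, > 0.5)
  pc <- (ctrl_beh$hits + (1 - ctrl_beh$false_alarms)) / 2
  chance <- one_sample_t(pc, mu = 0.5, alternative = "greater")

  ## repeated-measures ANOVAs: controls' deviant vs standard window means at
  ## the group windows
  anovas <- list()
  for (task in c("ignore", "attend")) {
    for (cmp in names(component_windows(task))) {
      lat <- study$group_latency[[task]][[cmp]]
      roi <- component_windows(task)[[cmp]]$roi
      vals <- vapply(ctrl_ids, function(id) {
        s <- study$subjects[[id]][[task]]
        c(window_mean(roi_average(s$dev, roi), lat, cfg$quant$width),
          window_mean(roi_average(s$std, roi), lat, cfg$quant$width))
      }, numeric(2))
      anovas[[paste(task, cmp, sep = ".")]] <-
        rm_anova_2level(vals[1, ], vals[2, ])
    }
  }

  ## Crawford case comparisons, behavioral and ERP
  tail_of <- function(meas, cmp = NULL) {
    tl <- cfg$tails
    switch(meas,
           hits = tl$hits, false_alarms = tl$false_alarms,
           A = tl$A, b = tl$b,
           amplitude = tl[[paste0(cmp, "_amplitude")]],
           latency = tl$latency)
  }
  craw <- list()
  for (cid in case_ids) {
    rows <- list()
    for (meas in c("hits", "false_alarms", "A", "b"))
      rows[[meas]] <- crawford_t(beh[[meas]][beh$id == cid],
                                 ctrl_beh[[meas]], tail = tail_of(meas),
                                 measure = meas)
    for (task in c("ignore", "attend")) {
      for (cmp in names(component_windows(task))) {
        for (what in c("mean_amplitude", "peak_latency")) {
          nm <- paste(task, cmp,
                      if (what == "mean_amplitude") "amplitude" else
                        "latency", sep = ".")
          rows[[nm]] <- crawford_t(
            measure_of(study$measures, cid, task, cmp, what),
            vapply(ctrl_ids, function(id)
              measure_of(study$measures, id, task, cmp, what), numeric(1)),
            tail = tail_of(if (what == "mean_amplitude") "amplitude"
                           else "latency", cmp),
            measure = nm)
        }
      }
    }
    tab <- do.call(rbind, rows)
    tab$case <- cid
    craw[[cid]] <- tab
  }
  crawford <- do.call(rbind, craw)
  rownames(crawford) <- NULL

  ## leave-one-out control analyses (the three reference analyses)
  loo_specs <- list(
    ignore.P3a.amplitude = c("ignore", "P3a", "mean_amplitude"),
    attend.P3a.latency   = c("attend", "P3a", "peak_latency"),
    attend.P3b.amplitude = c("attend", "P3b", "mean_amplitude"))
  loo <- lapply(loo_specs, function(sp) {
    vals <- vapply(ctrl_ids, function(id)
      measure_of(study$measures, id, sp[1], sp[2], sp[3]), numeric(1))
    out <- loo_control_analysis(vals, tail = "two", alpha = cfg$alpha,
                                measure = paste(sp, collapse = "."))
    out$subject <- ctrl_ids
    out
  })

  ## behavior-ERP correlations over the control group (attend P3 measures)
  erp <- data.frame(
    P3a_amplitude = vapply(ctrl_ids, function(id)
      measure_of(study$measures, id, "attend", "P3a"), numeric(1)),
    P3a_latency = vapply(ctrl_ids, function(id)
      measure_of(study$measures, id, "attend", "P3a", "peak_latency"),
      numeric(1)),
    P3b_amplitude = vapply(ctrl_ids, function(id)
      measure_of(study$measures, id, "attend", "P3b"), numeric(1)),
    P3b_latency = vapply(ctrl_ids, function(id)
      measure_of(study$measures, id, "attend", "P3b", "peak_latency"),
      numeric(1)))
  correlations <- correlate_behavior_erp(
    ctrl_beh[, c("hits", "false_alarms", "A", "b")], erp)

  list(chance = chance, anova = anovas, crawford = crawford, loo = loo,
       correlations = correlations)
}

study_tables <- function(study) {
  ctrl_ids <- study$ids[study$is_control]
  case_ids <- study$ids[!study$is_control]
  beh <- study$behavior
  craw <- study$stats$crawford

  mk <- function(rows, ctrl_vals) {
    tab <- data.frame(measure = rows, controls_mean = ctrl_vals)
    for (cid in case_ids) {
      cc <- craw[craw$case == cid, ]
      m <- match(rows, cc$measure)
      tab[[cid]] <- cc$case_value[m]
      tab[[paste0(cid, "_t")]] <- cc$t[m]
    }
    tab
  }
  t1 <- mk(c("hits", "false_alarms", "A", "b"),
           vapply(c("hits", "false_alarms", "A", "b"), function(m)
             mean(beh[[m]][beh$id %in% ctrl_ids]), numeric(1)))
  erp_rows <- function(task) {
    cmps <- names(component_windows(task))
    rows <- c(paste(task, cmps, "amplitude", sep = "."),
              paste(task, cmps, "latency", sep = "."))
    ctrl_vals <- c(
      vapply(cmps, function(cmp) mean(vapply(ctrl_ids, function(id)
        measure_of(study$measures, id, task, cmp), numeric(1))), numeric(1)),
      vapply(cmps, function(cmp) mean(vapply(ctrl_ids, function(id)
        measure_of(study$measures, id, task, cmp, "peak_latency"),
        numeric(1))), numeric(1)))
    mk(rows, ctrl_vals)
  }
  list(behavior = t1, ignore = erp_rows("ignore"),
       attend = erp_rows("attend"))
}

#' @export
print.beat_study <- function(x, digits = 3, ...) {
  cat(sprintf("Beat-omission oddball study: %d controls + %d case(s), seed %s\n\n",
              sum(x$is_control), sum(!x$is_control), format(x$seed)))
  cat("Behavioral accuracy (attend task):\n")
  print(format_table(x$tables$behavior, digits))
  cat(sprintf("\nChance-level test (proportion correct > 0.5): t(%d) = %.2f, p = %.2g\n",
              x$stats$chance$df, x$stats$chance$t, x$stats$chance$p))
  cat("\nIgnore task (deviant - standard), anterior ROI:\n")
  print(format_table(x$tables$ignore, digits))
  cat("\nAttend task (deviant - standard):\n")
  print(format_table(x$tables$attend, digits))
  cat("\nRepeated-measures ANOVAs (controls, deviant vs standard):\n")
  for (nm in names(x$stats$anova)) {
    a <- x$stats$anova[[nm]]
    cat(sprintf("  %-12s F(%d, %d) = %.2f, p = %.2g\n",
                nm, a$df1, a$df2, a$F, a$p))
  }
  rel <- x$measures[!x$measures$reliable, c("id", "task", "component")]
  if (nrow(rel)) {
    cat("\nComponents not distinguishable from noise:\n")
    for (i in seq_len(nrow(rel)))
      cat(sprintf("  %s: %s %s\n", rel$id[i], rel$task[i], rel$component[i]))
  } else cat("\nAll components reliable (exceed their 95% noise CIs).\n")
  invisible(x)
}

format_table <- function(tab, digits) {
  out <- tab
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], digits)
  out
}

#' @export
summary.beat_study <- function(object, ...) {
  print(object)
  cat("\nEpoch accounting:\n")
  print(object$epoch_log)
  cat("\nLeave-one-out control analyses (flagged controls):\n")
  for (nm in names(object$stats$loo)) {
    fl <- object$stats$loo[[nm]]
    fl <- fl$subject[fl$flagged]
    cat(sprintf("  %-22s %s\n", nm,
                if (length(fl)) paste(fl, collapse = ", ") else "none"))
  }
  cat("\nBehavior-ERP correlations (controls):\n")
  print(format_table(object$stats$correlations, 3))
  invisible(object)
}

#' Plot grand-average and case difference waves
#'
#' Base-graphics view of the deviant-minus-standard ROI difference waves: the
#' control grand average with each case overlaid, and the quantification
#' windows shaded. Negative is plotted upward, as is conventional for ERP
#' figures.
#'
#' @param x A `beat_study`.
#' @param task "ignore" or "attend".
#' @param roi "anterior" or "posterior".
#' @param ... Passed to `matplot`.
#' @export
plot.beat_study <- function(x, task = c("ignore", "attend"),
                            roi = c("anterior", "posterior"), ...) {
  task <- match.arg(task)
  roi <- match.arg(roi)
  g <- roi_average(x$grand[[task]], roi)
  case_ids <- x$ids[!x$is_control]
  mat <- cbind(grand = g$values,
               vapply(case_ids, function(id)
                 roi_average(x$subjects[[id]][[task]]$diff, roi)$values,
                 numeric(length(g$values))))
  graphics::matplot(g$time_ms, mat, type = "l", lty = 1,
                    col = c("black", "firebrick", "steelblue")[
                      seq_len(ncol(mat))],
                    xlab = "time (ms)", ylab = "amplitude (µV)",
                    ylim = rev(range(mat)),  # negative up
                    main = sprintf("%s task, %s ROI (deviant - standard)",
                                   task, roi), ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c("black", "firebrick", "steelblue")[
                     seq_len(ncol(mat))],
                   legend = c("controls (grand avg)", case_ids))
  invisible(x)
}

#' Export study reports as tab-separated files
#'
#' Writes the three report tables (behavior, ignore-task and attend-task
#' component comparisons), the per-subject component measures with
#' reliability verdicts, the epoch-accounting log, leave-one-out analyses,
#' the correlation table, and a human-readable summary.
#'
#' @param study A `beat_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_reports <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, nm) {
    p <- file.path(dir, nm)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(
    wt(study$tables$behavior, "table_behavior.tsv"),
    wt(study$tables$ignore, "table_ignore.tsv"),
    wt(study$tables$attend, "table_attend.tsv"),
    wt(study$measures, "component_measures.tsv"),
    wt(study$epoch_log, "epoch_log.tsv"),
    wt(do.call(rbind, study$stats$loo), "loo_analyses.tsv"),
    wt(study$stats$correlations, "correlations.tsv"),
    wt(study$stats$crawford, "crawford_tests.tsv"))
  sm <- file.path(dir, "summary.txt")
  utils::capture.output(summary(study), file = sm)
  invisible(c(files, sm))
}
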