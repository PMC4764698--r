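#' Drum-pattern specification
#'
#' Describes the repeating two-measure rock drum pattern used as the standard
#' stimulus: `n_positions` isochronous positions separated by `ioi`
#' milliseconds, with one or more timbre layers each occupying a subset of
#' positions. The default layout places the hi-hat on all eight positions, the
#' bass drum on positions 1 and 5, and the snare on positions 3 and 7, an
#' approximation of the canonical rock accompaniment; it is fully
#' configurable. Sound durations are fixed by timbre (hi-hat 50 ms, bass
#' 100 ms, snare 150 ms) and acoustic intensity is ranked bass > snare >
#' hi-hat (rank 1 = loudest).
#'
#' @param n_positions Number of isochronous positions per sequence.
#' @param ioi Onset-to-onset interval between positions, ms.
#' @param layers List of layers, each a list with elements `timbre`,
#'   `positions` (integer vector within `1:n_positions`), `duration` (ms, one
#'   of 50/100/150) and `intensity` (rank, 1 = loudest).
#' @return An object of class `pattern_spec`.
#' @examples
#' spec <- pattern_spec()
#' build_pattern(spec, "standard")
#' @export
pattern_spec <- function(n_positions = 8L, ioi = 150,
                         layers = list(
                           list(timbre = "bass",   positions = c(1L, 5L),
                                duration = 100, intensity = 1L),
                           list(timbre = "snare",  positions = c(3L, 7L),
                                duration = 150, intensity = 2L),
                           list(timbre = "hihat",  positions = 1:8,
                                duration = 50,  intensity = 3L))) {
  if (length(n_positions) != 1L || n_positions < 1L)
    stop("configuration error: n_positions must be a positive count")
  if (length(ioi) != 1L || ioi <= 0)
    stop("configuration error: ioi must be positive")
  for (lay in layers) {
    stopifnot(is.character(lay$timbre), length(lay$timbre) == 1L)
    if (length(lay$positions) &&
        (any(lay$positions < 1L) || any(lay$positions > n_positions)))
      stop("configuration error: layer position outside 1..n_positions")
    if (!lay$duration %in% c(50, 100, 150))
      stop("configuration error: sound duration must be 50, 100 or 150 ms")
  }
  structure(list(n_positions = as.integer(n_positions), ioi = ioi,
                 layers = layers),
            class = "pattern_spec")
}

#' Build one sequence variant from a pattern specification
#'
#' The standard variant contains an event at every occupied position of every
#' layer; the deviant variant omits the bass-drum and hi-hat events at
#' position 1 (the metrically strongest position), producing a salient
#' syncopation. Standard and deviant are identical everywhere else. Event
#' onsets are `(position - 1) * ioi` ms within the sequence.
#'
#' @param spec A [pattern_spec()].
#' @param kind `"standard"` or `"deviant"`.
#' @return An object of class `sequence_variant`: a list with `kind`,
#'   `events` (data.frame with `onset_ms`, `position`, `timbre`,
#'   `duration_ms`, `intensity`), and `duration_ms` of the whole sequence.
#' @export
build_pattern <- function(spec, kind = c("standard", "deviant")) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "pattern_spec"))
  rows <- lapply(spec$layers, function(lay) {
    pos <- lay$positions
    if (kind == "deviant" && lay$timbre %in% c("bass", "hihat"))
      pos <- pos[pos != 1L]
    if (!length(pos)) return(NULL)
    data.frame(onset_ms = (pos - 1) * spec$ioi, position = pos,
               timbre = lay$timbre, duration_ms = lay$duration,
               intensity = lay$intensity)
  })
  events <- do.call(rbind, rows)
  if (is.null(events))
    events <- data.frame(onset_ms = numeric(), position = integer(),
                         timbre = character(), duration_ms = numeric(),
                         intensity = integer())
  events <- events[order(events$onset_ms, events$intensity), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(kind = kind, events = events,
                 duration_ms = spec$n_positions * spec$ioi),
            class = "sequence_variant")
}

## marker codes: 1 = standard target (position-1 onset of a standard
## sequence), 2 = deviant target, 9 = trial start (attend task only)
MARKER_STANDARD <- 1L
MARKER_DEVIANT <- 2L
MARKER_TRIAL <- 9L

new_schedule <- function(labels, spec, kind, extra = list()) {
  seq_dur <- spec$n_positions * spec$ioi
  onset <- (seq_along(labels) - 1) * seq_dur
  events <- data.frame(
    onset_ms = onset,
    code = ifelse(labels == "deviant", MARKER_DEVIANT, MARKER_STANDARD),
    label = labels, stringsAsFactors = FALSE)
  structure(c(list(kind = kind, labels = labels, events = events,
                   n_sequences = length(labels),
                   sequence_duration_ms = seq_dur,
                   duration_ms = length(labels) * seq_dur, spec = spec),
              extra),
            class = "beat_schedule")
}

#' Pseudo-randomized oddball schedule for the passive (ignore) task
#'
#' Generates `n_blocks` blocks of `n_per_block` sequences each, with an exact
#' proportion `p_deviant` of deviant sequences per block and at least
#' `min_gap` standard sequences between any two deviants (enforced within and
#' across block boundaries, since presentation is continuous). Orderings are
#' rejection-sampled, so the schedule is reproducible given `seed`. Sequences
#' abut without gaps; every sequence's position-1 onset carries a target
#' marker (code 1 standard, 2 deviant).
#'
#' @param n_blocks,n_per_block Block structure (defaults 10 x 300).
#' @param p_deviant Deviant probability per block; `p_deviant * n_per_block`
#'   must be an integer.
#' @param min_gap Minimum number of standards between consecutive deviants.
#' @param seed Integer seed.
#' @param spec A [pattern_spec()].
#' @return A `beat_schedule` whose `events` data.frame holds one target
#'   marker per sequence (`onset_ms`, `code`, `label`).
#' @export
make_ignore_schedule <- function(n_blocks = 10L, n_per_block = 300L,
                                 p_deviant = 0.05, min_gap = 3L,
                                 seed = 1L, spec = pattern_spec()) {
  n_dev <- p_deviant * n_per_block
  if (abs(n_dev - round(n_dev)) > 1e-9)
    stop("design error: p_deviant * n_per_block must be an integer")
  n_dev <- as.integer(round(n_dev))
  if (n_dev > 0 && (n_dev - 1L) * (min_gap + 1L) + 1L > n_per_block)
    stop("design error: min_gap constraint infeasible for this deviant count")
  set.seed(seed)
  labels <- character(0)
  last_dev <- -Inf  # index (global) of most recent deviant
  for (b in seq_len(n_blocks)) {
    repeat {
      pos <- sort(sample.int(n_per_block, n_dev))
      ok <- (n_dev < 2L || all(diff(pos) > min_gap)) &&
        (n_dev == 0L || (length(labels) + pos[1L]) - last_dev > min_gap)
      if (ok) break
    }
    block <- rep("standard", n_per_block)
    block[pos] <- "deviant"
    if (n_dev > 0L) last_dev <- length(labels) + pos[n_dev]
    labels <- c(labels, block)
  }
  new_schedule(labels, spec, kind = "ignore")
}

#' Deviant-only control schedule
#'
#' `n` repetitions of the deviant sequence with no standards, used to verify
#' that omission responses depend on the rarity of the omission rather than
#' its acoustics.
#'
#' @param n Number of deviant sequences (>= 1).
#' @param spec A [pattern_spec()].
#' @export
make_control_schedule <- function(n = 300L, spec = pattern_spec()) {
  if (length(n) != 1L || n < 1L) stop("design error: n must be >= 1")
  new_schedule(rep("deviant", n), spec, kind = "control")
}

#' Trial schedule for the active detection (attend) task
#'
#' `n_trials` trials of five sequences each. An exact proportion
#' `p_deviant_trial` of trials contains a single deviant sequence, inserted in
#' slot 4 or 5 (uniformly at random); the first three sequences of every trial
#' are standard to induce a sense of meter. Target markers are attached to the
#' position-1 onset of the deviant sequence in deviant trials and of the
#' slot-4 and slot-5 sequences in all-standard trials (the contextually
#' identical positions); each trial start carries marker code 9.
#'
#' @param n_trials Number of trials (default 120).
#' @param p_deviant_trial Proportion of deviant trials;
#'   `n_trials * p_deviant_trial` must be an integer.
#' @param seed Integer seed.
#' @param spec A [pattern_spec()].
#' @return A `beat_schedule` of kind `"attend"` with extra elements `trials`
#'   (data.frame: `trial`, `deviant` flag, `slot` 4/5 or NA, `onset_ms`).
#' @export
make_attend_schedule <- function(n_trials = 120L, p_deviant_trial = 0.5,
                                 seed = 1L, spec = pattern_spec()) {
  n_dev <- n_trials * p_deviant_trial
  if (abs(n_dev - round(n_dev)) > 1e-9)
    stop("design error: n_trials * p_deviant_trial must be an integer")
  n_dev <- as.integer(round(n_dev))
  set.seed(seed)
  dev_trials <- sort(sample.int(n_trials, n_dev))
  slots <- sample(c(4L, 5L), n_dev, replace = TRUE)
  seq_dur <- spec$n_positions * spec$ioi
  trial_dur <- 5 * seq_dur
  labels <- character(0)
  slot_of <- rep(NA_integer_, n_trials)
  slot_of[dev_trials] <- slots
  for (tr in seq_len(n_trials)) {
    trial <- rep("standard", 5L)
    if (!is.na(slot_of[tr])) trial[slot_of[tr]] <- "deviant"
    labels <- c(labels, trial)
  }
  sched <- new_schedule(labels, spec, kind = "attend",
                        extra = list(trials = data.frame(
                          trial = seq_len(n_trials),
                          deviant = !is.na(slot_of),
                          slot = slot_of,
                          onset_ms = (seq_len(n_trials) - 1) * trial_dur)))
  ## restrict target markers to slots 4/5 of standard trials and to the
  ## deviant slot of deviant trials; prepend trial-start markers
  ev <- sched$events
  ev$trial <- rep(seq_len(n_trials), each = 5L)
  ev$slot <- rep(1:5, n_trials)
  keep <- (ev$label == "deviant") |
    (!sched$trials$deviant[ev$trial] & ev$slot >= 4L)
  targets <- ev[keep, c("onset_ms", "code", "label")]
  starts <- data.frame(onset_ms = sched$trials$onset_ms,
                       code = MARKER_TRIAL, label = "trial")
  ev <- rbind(targets, starts)
  ev <- ev[order(ev$onset_ms, ev$code), ]
  rownames(ev) <- NULL
  sched$events <- ev
  sched
}

#' Export schedule event markers as a tab-separated file
#'
#' Writes `onset_ms`, `code`, `label` columns, one row per marker.
#'
#' @param schedule A `beat_schedule`.
#' @param path Output file path.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "beat_schedule"))
  utils::write.table(schedule$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.beat_schedule <- function(x, ...) {
  n_dev <- sum(x$labels == "deviant")
  cat(sprintf("<beat_schedule: %s> %d sequences (%d deviant), %.1f s\n",
              x$kind, x$n_sequences, n_dev, x$duration_ms / 1000))
  invisible(x)
}
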