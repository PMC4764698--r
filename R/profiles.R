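#' ERP component parameter
#'
#' Ground-truth generative parameters for one event-related deflection in the
#' deviant-minus-standard difference: a Gaussian bump of the given signed
#' peak `amplitude` (microvolts) at `latency` ms after the target onset, with
#' kernel SD `width` ms, projected onto the scalp through the named
#' `topography` ("anterior" for MMN/P3a, "posterior" for P3b).
#'
#' MMN amplitudes must be non-positive; P3a/P3b amplitudes non-negative
#' (zero models an absent component).
#'
#' @param name One of "MMN", "P3a", "P3b".
#' @param task Task the component belongs to: "ignore" or "attend".
#' @param amplitude Peak amplitude, microvolts, deviant minus standard.
#' @param latency Peak latency, ms post-target.
#' @param width Gaussian kernel SD, ms.
#' @param topography "anterior" or "posterior".
#' @export
component_param <- function(name = c("MMN", "P3a", "P3b"),
                            task = c("ignore", "attend"),
                            amplitude, latency, width,
                            topography = c("anterior", "posterior")) {
  name <- match.arg(name)
  task <- match.arg(task)
  topography <- match.arg(topography)
  if (name == "MMN" && amplitude > 0)
    stop("configuration error: MMN amplitude must be <= 0")
  if (name != "MMN" && amplitude < 0)
    stop("configuration error: P3 amplitude must be >= 0")
  if (width <= 0) stop("configuration error: width must be positive")
  structure(list(name = name, task = task, amplitude = amplitude,
                 latency = latency, width = width, topography = topography),
            class = "component_param")
}

#' Subject generative profile
#'
#' Bundles the per-subject ground truth used by the simulator: the component
#' set, background-noise RMS, blink statistics, and the Bernoulli keypress
#' probabilities with the reaction-time distribution for the attend task.
#'
#' @param id Subject identifier.
#' @param components List of [component_param()]s.
#' @param noise_rms Broadband 1/f background noise RMS per channel,
#'   microvolts (> 0).
#' @param blink_rate Blink events per minute.
#' @param blink_amplitude Blink peak amplitude on the vertical EOG,
#'   microvolts.
#' @param p_hit Probability of a "deviant" response on a deviant trial.
#' @param p_fa Probability of a "deviant" response on a standard trial.
#' @param rt_mean,rt_sd Reaction-time distribution (Gaussian, truncated at
#'   zero), seconds.
#' @export
subject_profile <- function(id, components, noise_rms = 10,
                            blink_rate = 3, blink_amplitude = 150,
                            p_hit = 0.83, p_fa = 0.14,
                            rt_mean = 1.5, rt_sd = 0.5) {
  if (noise_rms < 0) stop("configuration error: noise_rms must be >= 0")
  if (p_hit < 0 || p_hit > 1 || p_fa < 0 || p_fa > 1)
    stop("configuration error: probabilities must lie in [0, 1]")
  structure(list(id = id, components = components, noise_rms = noise_rms,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 p_hit = p_hit, p_fa = p_fa,
                 rt_mean = rt_mean, rt_sd = rt_sd),
            class = "subject_profile")
}

## default kernel SDs by component (ms): the MMN is a sharp deflection, the
## P3 family is broad
.default_width <- c(MMN = 30, P3a = 60, P3b = 80)

#' Built-in cohort profiles
#'
#' `control_profile()` carries the control-group mean component parameters
#' (ignore task: MMN -2.81 uV at 159 ms, P3a +1.10 uV at 297 ms; attend task:
#' P3a +3.24 uV at 496 ms anterior, P3b +2.90 uV at 506 ms posterior, plus
#' the same MMN) and control-mean keypress probabilities (hits 0.83, false
#' alarms 0.14). `case_m_profile()` models a beat-deaf case with an absent
#' attend-task P3b (amplitude 0) and reduced detection (hits 0.57, FA 0.16);
#' `case_j_profile()` a case with enlarged P3a/P3b responses (ignore P3a
#' +3.11 uV, attend P3b +6.74 uV) and a strong conservative response bias
#' (hits 0.36, FA 0.03).
#'
#' @param id Subject identifier.
#' @param ... Passed on to [subject_profile()] (e.g. `noise_rms`).
#' @name cohort_profiles
NULL

comp <- function(name, task, amplitude, latency,
                 topography = if (name == "P3b") "posterior" else "anterior")
  component_param(name, task, amplitude, latency,
                  width = .default_width[[name]], topography = topography)

profile_with_defaults <- function(defaults, overrides) {
  do.call(subject_profile, utils::modifyList(defaults, overrides))
}

#' @rdname cohort_profiles
#' @export
control_profile <- function(id = "control", ...) {
  profile_with_defaults(list(id = id, components = list(
    comp("MMN", "ignore", -2.81, 159),
    comp("P3a", "ignore",  1.10, 297),
    comp("MMN", "attend", -2.81, 159),
    comp("P3a", "attend",  3.24, 496),
    comp("P3b", "attend",  2.90, 506)),
    p_hit = 0.83, p_fa = 0.14), list(...))
}

#' @rdname cohort_profiles
#' @export
case_m_profile <- function(id = "case_m", ...) {
  profile_with_defaults(list(id = id, components = list(
    comp("MMN", "ignore", -5.13, 188),
    comp("P3a", "ignore",  0.10, 297),
    comp("MMN", "attend", -5.13, 188),
    comp("P3a", "attend",  1.64, 486),
    comp("P3b", "attend",  0.00, 506)),   # absent P3b
    p_hit = 0.57, p_fa = 0.16), list(...))
}

#' @rdname cohort_profiles
#' @export
case_j_profile <- function(id = "case_j", ...) {
  profile_with_defaults(list(id = id, components = list(
    comp("MMN", "ignore", -3.10, 137),
    comp("P3a", "ignore",  3.11, 266),
    comp("MMN", "attend", -3.10, 137),
    comp("P3a", "attend",  1.20, 300),
    comp("P3b", "attend",  6.74, 480)),
    p_hit = 0.36, p_fa = 0.03), list(...))
}
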