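#' Score attend-task responses
#'
#' Computes hit and false-alarm rates from a one-response-per-trial table. A
#' hit is a "deviant" response within `response_window` seconds of trial
#' onset on a deviant trial; a false alarm is a timely "deviant" response on
#' a standard trial. Rates are normalized per trial type. Responses slower
#' than the window are not counted as correct: the per-trial `correct` flag
#' (used to exclude trials from ERP averages) requires both the matching
#' response and a timely keypress. When several keypresses per trial are
#' recorded, the last one wins (configurable upstream by pre-filtering).
#'
#' @param trials An attend `beat_schedule` (uses its `trials` table).
#' @param responses data.frame with `trial`, `response`, `rt` (seconds), as
#'   from [simulate_behavior()].
#' @param response_window Seconds; default 6.
#' @return List with `hits`, `false_alarms`, `correct` (logical per trial),
#'   `n_deviant`, `n_standard`.
#' @export
score_responses <- function(trials, responses, response_window = 6) {
  stopifnot(inherits(trials, "beat_schedule"), !is.null(trials$trials))
  tab <- trials$trials
  if (!all(responses$trial %in% tab$trial))
    stop("data error: response for unknown trial")
  ## last response per trial wins
  responses <- responses[!duplicated(responses$trial, fromLast = TRUE), ]
  m <- match(tab$trial, responses$trial)
  resp <- responses$response[m]
  rt <- responses$rt[m]
  timely <- !is.na(rt) & rt <= response_window
  said_dev <- !is.na(resp) & resp == "deviant" & timely
  hits <- mean(said_dev[tab$deviant])
  fas <- mean(said_dev[!tab$deviant])
  correct <- ifelse(tab$deviant, said_dev,
                    !is.na(resp) & resp == "standard" & timely)
  list(hits = hits, false_alarms = fas, correct = correct,
       n_deviant = sum(tab$deviant), n_standard = sum(!tab$deviant))
}

check_hf <- function(H, F) {
  if (length(H) != 1 || length(F) != 1 || is.na(H) || is.na(F) ||
      H < 0 || H > 1 || F < 0 || F > 1)
    stop("domain error: H and F must be single values in [0, 1]")
}

#' Zhang-Mueller nonparametric sensitivity A
#'
#' Distribution-free sensitivity computed by averaging the minimum and
#' maximum proper ROC curves consistent with one (hit, false-alarm) pair.
#' `A` ranges over \[0, 1\], equals 0.5 at chance (`H = F`), and for `H >= F`
#' follows the piecewise form:
#' \deqn{A = 3/4 + (H-F)/4 - F(1-H)           \quad F \le 0.5 \le H}
#' \deqn{A = 3/4 + (H-F)/4 - F/(4H)           \quad F \le H < 0.5}
#' \deqn{A = 3/4 + (H-F)/4 - (1-H)/(4(1-F))   \quad 0.5 < F \le H}
#' Below-chance pairs (`H < F`) are handled by symmetry,
#' `A(H, F) = 1 - A(F, H)`.
#'
#' @param H Hit rate.
#' @param F False-alarm rate.
#' @return Sensitivity A in \[0, 1\].
#' @examples
#' sensitivity_A(0.57, 0.16)  # 0.78 at 2 dp
#' @export
sensitivity_A <- function(H, F) {
  check_hf(H, F)
  if (H == F) return(0.5)
  if (H < F) return(1 - sensitivity_A(F, H))
  if (F <= 0.5 && H >= 0.5) 3 / 4 + (H - F) / 4 - F * (1 - H)
  else if (H < 0.5)          3 / 4 + (H - F) / 4 - F / (4 * H)
  else                       3 / 4 + (H - F) / 4 - (1 - H) / (4 * (1 - F))
}

#' Zhang-Mueller nonparametric bias b
#'
#' Response bias defined as the slope of the A ROC curve at the observed
#' operating point; `b > 1` indicates a conservative ("say standard") bias.
#' For `H >= F`:
#' \deqn{b = (5 - 4H) / (1 + 4F)                        \quad F \le 0.5 \le H}
#' \deqn{b = (H^2 + H) / (H^2 + F)                       \quad F \le H < 0.5}
#' \deqn{b = ((1-F)^2 + (1-H)) / ((1-F)^2 + (1-F))       \quad 0.5 < F \le H}
#' At the chance diagonal `H = F` the slope is 1, which is also the defined
#' limit at the degenerate corners (`H = F = 0` or `1`). Below-chance pairs
#' use the reciprocal symmetry `b(H, F) = 1 / b(F, H)`.
#'
#' @inheritParams sensitivity_A
#' @return Bias b (> 0).
#' @examples
#' bias_b(0.57, 0.16)  # 1.66 at 2 dp
#' @export
bias_b <- function(H, F) {
  check_hf(H, F)
  if (H == F) return(1)
  if (H < F) return(1 / bias_b(F, H))
  if (F <= 0.5 && H >= 0.5) (5 - 4 * H) / (1 + 4 * F)
  else if (H < 0.5)          (H^2 + H) / (H^2 + F)
  else ((1 - F)^2 + (1 - H)) / ((1 - F)^2 + (1 - F))
}

#' Correlate behavioral measures with ERP measures across subjects
#'
#' Pearson product-moment correlation and two-sided p-value for every pair of
#' one behavioral column and one ERP column. Pairs in which either variable
#' has zero variance are flagged undefined (`r = NA`).
#'
#' @param behavior data.frame of per-subject behavioral measures (numeric
#'   columns).
#' @param erp data.frame of per-subject ERP measures (numeric columns), same
#'   row order.
#' @return data.frame: `behavioral`, `erp`, `r`, `p`, `undefined`.
#' @export
correlate_behavior_erp <- function(behavior, erp) {
  if (nrow(behavior) != nrow(erp) || nrow(behavior) < 3)
    stop("configuration error: need >= 3 paired observations")
  out <- expand.grid(behavioral = names(behavior), erp = names(erp),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_
  out$p <- NA_real_
  out$undefined <- FALSE
  for (i in seq_len(nrow(out))) {
    x <- behavior[[out$behavioral[i]]]
    y <- erp[[out$erp[i]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      out$undefined[i] <- TRUE
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    out$r[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}
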