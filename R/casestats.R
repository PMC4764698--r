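#' Crawford modified t-test for a single case against a control sample
#'
#' Compares one individual's score with a small normative sample using the
#' Crawford-Howell statistic
#' \deqn{t = (x - \bar{c}) / (s_c \sqrt{(n+1)/n}),}
#' referred to Student's t with `n - 1` degrees of freedom; the inflation
#' factor accounts for the uncertainty of the control mean in small samples.
#' The sign of t always follows `case - control mean`. One-tailed by
#' default direction `"lower"` (case hypothesized below controls).
#'
#' @param case_value The case's score.
#' @param control_values Numeric vector of control scores (n >= 2, SD > 0).
#' @param tail "lower", "upper" or "two".
#' @param measure Optional measure label carried into the result.
#' @return A one-row data.frame of class `case_comparison`: `measure`,
#'   `case_value`, `control_mean`, `control_sd`, `n`, `t`, `df`, `p`,
#'   `tail`.
#' @export
crawford_t <- function(case_value, control_values,
                       tail = c("lower", "upper", "two"),
                       measure = NA_character_) {
  tail <- match.arg(tail)
  n <- length(control_values)
  if (n < 2) stop("degenerate-sample error: need >= 2 controls")
  s <- stats::sd(control_values)
  if (s == 0) stop("degenerate-sample error: zero control SD")
  m <- mean(control_values)
  t <- (case_value - m) / (s * sqrt((n + 1) / n))
  df <- n - 1
  p <- switch(tail,
              lower = stats::pt(t, df),
              upper = stats::pt(t, df, lower.tail = FALSE),
              two = 2 * stats::pt(-abs(t), df))
  structure(data.frame(measure = measure, case_value = case_value,
                       control_mean = m, control_sd = s, n = n,
                       t = t, df = df, p = p, tail = tail,
                       stringsAsFactors = FALSE),
            class = c("case_comparison", "data.frame"))
}

#' Leave-one-out control analysis
#'
#' Each control's value is compared, via [crawford_t()], with the remaining
#' `n - 1` controls; a comparison is flagged significant at `alpha`
#' (two-tailed by default, so an outlier in either direction is caught).
#' With `n` controls the per-comparison df is `n - 2`.
#'
#' @param values Numeric vector of control values (n >= 3).
#' @param tail Tail passed to [crawford_t()].
#' @param alpha Significance level for flagging.
#' @param measure Optional measure label.
#' @return data.frame of class `loo_analysis`, one row per control:
#'   the [crawford_t()] columns plus `subject` and `flagged`.
#' @export
loo_control_analysis <- function(values, tail = "two", alpha = 0.05,
                                 measure = NA_character_) {
  n <- length(values)
  if (n < 3) stop("degenerate-sample error: need >= 3 controls")
  rows <- lapply(seq_len(n), function(i)
    crawford_t(values[i], values[-i], tail = tail, measure = measure))
  out <- do.call(rbind, rows)
  out$subject <- seq_len(n)
  out$flagged <- out$p < alpha
  structure(out, class = c("loo_analysis", "data.frame"))
}

#' Two-level repeated-measures ANOVA
#'
#' One-way repeated-measures ANOVA with two within-subject levels
#' (deviant vs standard condition means per subject), fitted with
#' `stats::aov` with a subject error stratum; df are `(1, n - 1)`. For two
#' levels the F statistic equals the square of the paired t statistic.
#'
#' @param deviant,standard Paired numeric vectors, one value per subject.
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2level <- function(deviant, standard) {
  if (length(deviant) != length(standard))
    stop("pairing error: condition vectors differ in length")
  n <- length(deviant)
  if (n < 2) stop("pairing error: need >= 2 subjects")
  if (all(deviant == standard))   # no effect at all: F is exactly 0
    return(list(F = 0, df1 = 1L, df2 = n - 1L, p = 1))
  d <- data.frame(value = c(deviant, standard),
                  condition = factor(rep(c("deviant", "standard"),
                                         each = n)),
                  subject = factor(rep(seq_len(n), 2)))
  fit <- stats::aov(value ~ condition + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  list(F = tab["condition", "F value"],
       df1 = tab["condition", "Df"],
       df2 = tab["Residuals", "Df"],
       p = tab["condition", "Pr(>F)"])
}

#' One-sample t-test against a fixed level
#'
#' Standard one-sample Student t-test (wrapper around `stats::t.test`),
#' e.g. for testing detection performance against the 50% chance level.
#'
#' @param values Numeric vector (n >= 2, nonzero variance).
#' @param mu Null value.
#' @param alternative Passed to `stats::t.test`.
#' @return List: `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(values) < 2) stop("degenerate error: need >= 2 values")
  if (stats::sd(values) == 0) stop("degenerate error: zero variance")
  tt <- stats::t.test(values, mu = mu, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
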