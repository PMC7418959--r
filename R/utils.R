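# internal numerical helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# logistic P(a beats b) at inverse temperature beta
sigmoid2 <- function(beta, a, b) 1 / (1 + exp(-beta * (a - b)))

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chance-level selection rate for an n-option trial
#'
#' Base rate (in percent) of selecting, or resampling, any one option of an
#' n-option trial under pure chance: 33, 25 and 20\% for 3-, 4- and
#' 5-option sequences.
#'
#' @param n_options integer number of options (>= 1).
#' @return chance level in percent.
#' @export
#' @examples
#' chance_level(3)  # 33.3
chance_level <- function(n_options) {
  if (any(n_options < 1)) stop_invalid("n_options must be >= 1")
  100 / n_options
}

#' Minimal sample size for a one-sample t-test
#'
#' Smallest n achieving the requested power for a two-tailed one-sample
#' t-test against zero, given an effect mean and standard deviation
#' (e.g. a group-level test on a fitted bonus parameter).
#'
#' @param mean effect mean.
#' @param sd effect standard deviation across subjects.
#' @param power target power (default 0.9).
#' @param sig_level two-tailed alpha (default 0.05).
#' @return integer minimal sample size.
#' @export
#' @examples
#' power_min_n(0.59, 0.089 * sqrt(29))
power_min_n <- function(mean, sd, power = 0.9, sig_level = 0.05) {
  pw <- stats::power.t.test(delta = mean, sd = sd, power = power,
                            sig.level = sig_level, type = "one.sample",
                            alternative = "two.sided")
  as.integer(ceiling(pw$n))
}
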