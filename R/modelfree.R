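# Shared machinery: within each subject, ordinary least squares of an
# outcome on a serial-position regressor, separately per trial length,
# averaged (equal weight per length) to one coefficient per subject, then
# a two-tailed one-sample t-test on the coefficients at the group level.
# OLS is used even for the binary chosen-best outcome, mirroring the scale
# of the reported linear-regression coefficients. Length strata with fewer
# than 3 distinct regressor values are skipped (with a warning when the
# regressor is constant).
regression_summary <- function(per_subject_xy, min_distinct = 3L) {
  slopes <- vapply(per_subject_xy, function(d) {
    if (is.null(d) || !nrow(d)) return(NA_real_)
    by_len <- split(d, d$length)
    sl <- vapply(by_len, function(g) {
      k <- length(unique(g$x))
      if (k < 2L) {
        warning("constant regressor in a length stratum; stratum skipped")
        return(NA_real_)
      }
      if (k < min_distinct) return(NA_real_)
      ols_slope(g$x, g$y)
    }, 0)
    if (all(is.na(sl))) NA_real_ else mean(sl, na.rm = TRUE)
  }, 0)
  ok <- slopes[!is.na(slopes)]
  if (length(ok) < 2L)
    stop_invalid("fewer than 2 subjects with estimable slopes")
  tt <- stats::t.test(ok, mu = 0)
  structure(list(slopes = slopes, b = mean(ok),
                 sem = sd(ok) / sqrt(length(ok)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, n = length(ok)),
            class = "cc_regsum")
}

#' @export
print.cc_regsum <- function(x, ...) {
  cat(sprintf("b = %.4g +/- %.4g, t(%d) = %.3g, p = %.3g (n = %d)\n",
              x$b, x$sem, x$df, x$t, x$p, x$n))
  invisible(x)
}

analyzed_choices <- function(sub) {
  ch <- sub$choices
  ch[!ch$is_catch, , drop = FALSE]
}

#' Regression of choosing the best option on its serial position
#'
#' Within each subject and trial length, OLS of the 0/1 chosen-best
#' indicator on the best option's serial position; coefficients averaged
#' over lengths to one value per subject, then a group-level two-tailed
#' t-test against zero. A negative group slope is the model-free signature
#' of covert pairwise comparison: the best option is chosen less often
#' when it arrives later in the sequence.
#'
#' @param subjects list of subjects (\code{items}, \code{session},
#'   \code{choices}).
#' @return object of class \code{cc_regsum}: per-subject slopes, group
#'   mean \code{b}, \code{sem}, \code{t}, \code{df}, two-tailed \code{p}.
#' @export
slope_pbest_vs_position <- function(subjects) {
  regression_summary(lapply(subjects, function(sub) {
    ch <- analyzed_choices(sub)
    data.frame(length = ch$length, x = ch$best_pos,
               y = as.numeric(ch$chose_best))
  }))
}

#' Regression of choosing the best option on its relative position
#'
#' As \code{\link{slope_pbest_vs_position}}, with the regressor replaced
#' by the serial position of the best option minus that of the second-best
#' (positive when the best comes later).
#'
#' @inheritParams slope_pbest_vs_position
#' @return a \code{cc_regsum}.
#' @export
slope_vs_relative_position <- function(subjects) {
  regression_summary(lapply(subjects, function(sub) {
    ch <- analyzed_choices(sub)
    bp <- best_positions(sub$session, sub$items)
    rel <- ch$best_pos - bp$second_pos[ch$trial_id]
    data.frame(length = ch$length, x = rel, y = as.numeric(ch$chose_best))
  }))
}

#' Regression of confidence on the best option's serial position
#'
#' Restricted to trials where the best option was chosen; confidence is the
#' model-defined selection probability of the chosen option (or an
#' empirical confidence column if the dataset carries one). Per-length OLS
#' within subject, averaged, then group t-test, as in
#' \code{\link{slope_pbest_vs_position}}.
#'
#' @inheritParams slope_pbest_vs_position
#' @return a \code{cc_regsum}; subjects with no qualifying trials drop out.
#' @export
slope_confidence_vs_position <- function(subjects) {
  regression_summary(lapply(subjects, function(sub) {
    ch <- analyzed_choices(sub)
    ch <- ch[ch$chose_best, , drop = FALSE]
    if (!nrow(ch)) return(NULL)
    data.frame(length = ch$length, x = ch$best_pos, y = ch$confidence)
  }))
}

#' Model-free analysis report
#'
#' Runs the three serial-position regressions on a group and returns one
#' summary table.
#'
#' @inheritParams slope_pbest_vs_position
#' @return data.frame with one row per analysis: group \code{b},
#'   \code{sem}, \code{t}, \code{df}, \code{p}.
#' @export
modelfree_report <- function(subjects) {
  res <- list(
    pbest_vs_position = slope_pbest_vs_position(subjects),
    pbest_vs_relative_position = slope_vs_relative_position(subjects),
    confidence_vs_position = slope_confidence_vs_position(subjects))
  do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    data.frame(analysis = nm, b = r$b, sem = r$sem, t = r$t, df = r$df,
               p = r$p)
  }))
}
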