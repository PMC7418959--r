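# fast per-trial best/second-best lookup (no data.frame construction);
# returns a list of integer/numeric vectors over trials
best_positions <- function(session, items) {
  rk <- item_ranks(items)
  n <- length(session$sequences)
  best_pos <- second_pos <- integer(n)
  best <- second <- integer(n)
  for (t in seq_len(n)) {
    s <- session$sequences[[t]]
    r <- rk[match(s, items$item_id)]
    o <- order(r)
    best_pos[t] <- o[1L]; best[t] <- s[o[1L]]
    if (length(s) > 1L) { second_pos[t] <- o[2L]; second[t] <- s[o[2L]] }
    else { second_pos[t] <- NA_integer_; second[t] <- NA_integer_ }
  }
  list(best = best, best_pos = best_pos, second = second,
       second_pos = second_pos, length = lengths(session$sequences))
}

#' Simulate the choices of one subject
#'
#' Samples one choice per trial from the model's selection probabilities,
#' recording as confidence the selection probability of the chosen option.
#' Sampling order equals the designed sequence (resampling is not
#' simulated). For carry-over modes in which values depend on earlier
#' overt choices (two-level, overt-only), trials are simulated
#' sequentially so each choice feeds back into the carried values.
#'
#' @inheritParams session_probs
#' @param seed optional RNG seed.
#' @return a choice dataset: data.frame with one row per trial
#'   (\code{trial_id}, \code{length}, \code{is_catch}, \code{chosen},
#'   \code{chosen_pos}, \code{confidence}, \code{best}, \code{best_pos},
#'   \code{chose_best}, \code{p_best}), of class \code{cc_choices}.
#'   \code{p_best} is the model probability of the best-rated option.
#' @export
simulate_subject <- function(spec, params, items, session, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_tr <- length(session$sequences)
  bp <- best_positions(session, items)
  sequential <- spec$carry_mode %in% c("two_level", "overt_only")
  chosen_pos <- integer(n_tr)
  confidence <- p_best <- numeric(n_tr)
  if (!sequential) {
    pm <- session_probs(spec, params, items, session)
    for (t in seq_len(n_tr)) {
      p <- pm[t, seq_len(bp$length[t])]
      chosen_pos[t] <- sample.int(bp$length[t], 1L, prob = p)
      confidence[t] <- p[chosen_pos[t]]
      p_best[t] <- p[bp$best_pos[t]]
    }
  } else {
    state <- init_value_state(items)
    for (t in seq_len(n_tr)) {
      tp <- trial_probabilities(spec, params,
                                list(sequence = session$sequences[[t]]), state)
      state <- tp$state
      p <- as.numeric(tp$probs)
      chosen_pos[t] <- sample.int(bp$length[t], 1L, prob = p)
      confidence[t] <- p[chosen_pos[t]]
      p_best[t] <- p[bp$best_pos[t]]
      state <- apply_overt_choice(spec, params, state,
                                  session$sequences[[t]][chosen_pos[t]])
    }
  }
  chosen <- vapply(seq_len(n_tr),
                   function(t) session$sequences[[t]][chosen_pos[t]], 0L)
  out <- data.frame(trial_id = seq_len(n_tr), length = bp$length,
                    is_catch = session$is_catch, chosen = chosen,
                    chosen_pos = chosen_pos, confidence = confidence,
                    best = bp$best, best_pos = bp$best_pos,
                    chose_best = chosen == bp$best, p_best = p_best)
  class(out) <- c("cc_choices", "data.frame")
  out
}

#' Simulate a group of subjects
#'
#' Each subject gets freshly generated ratings and a freshly built session
#' design, then choices are simulated under the given model.
#'
#' @inheritParams simulate_subject
#' @param n_subjects group size (default 30).
#' @param profile task variant.
#' @param seed RNG seed for the whole group.
#' @param skew rating skew passed to \code{\link{generate_ratings}}.
#' @param n_sessions category sessions per subject, see
#'   \code{\link{generate_subject}}.
#' @return list of subjects, each a list with \code{items}, \code{session},
#'   \code{choices}.
#' @export
simulate_group <- function(spec, params, n_subjects = 30L,
                           profile = "exp1", seed = NULL, skew = 0.3,
                           n_sessions = 1L) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    sub <- generate_subject(profile, skew = skew, n_sessions = n_sessions)
    sub$choices <- simulate_subject(spec, params, sub$items, sub$session)
    sub
  })
}

# per-length OLS slope of y on x; NA if degenerate
ols_slope <- function(x, y) {
  if (length(x) < 2L || length(unique(x)) < 2L) return(NA_real_)
  stats::cov(x, y) / stats::var(x)
}

#' P(best) by serial position of the best option
#'
#' Tabulates, over analyzed trials, the probability of choosing the
#' best-rated option as a function of its serial position, separately per
#' trial length, with across-subject means and SEMs, plus the per-subject
#' per-length linear slopes of that relationship.
#'
#' @param subjects list of subjects as returned by
#'   \code{\link{simulate_group}} (each with \code{items}, \code{session},
#'   \code{choices}).
#' @param measure \code{"choice"} uses the 0/1 chosen-best indicator;
#'   \code{"probability"} uses the model's selection probability of the
#'   best option (the quantity averaged in the simulation figures).
#' @return list with \code{cells} (data.frame \code{length},
#'   \code{position}, \code{mean}, \code{sem}, \code{n_subjects}; cells
#'   with no observations are NA, not zero) and \code{slopes} (data.frame
#'   \code{subject}, \code{length}, \code{slope}).
#' @export
pbest_by_position <- function(subjects, measure = c("choice", "probability")) {
  measure <- match.arg(measure)
  per_sub <- lapply(seq_along(subjects), function(i) {
    ch <- subjects[[i]]$choices
    ch <- ch[!ch$is_catch, ]
    y <- if (measure == "choice") as.numeric(ch$chose_best) else ch$p_best
    data.frame(subject = i, length = ch$length, position = ch$best_pos, y = y)
  })
  d <- do.call(rbind, per_sub)
  lens <- sort(unique(d$length))
  cells <- do.call(rbind, lapply(lens, function(L) {
    do.call(rbind, lapply(seq_len(L), function(p) {
      sub_means <- vapply(unique(d$subject), function(s) {
        v <- d$y[d$subject == s & d$length == L & d$position == p]
        if (length(v)) mean(v) else NA_real_
      }, 0)
      sub_means <- sub_means[!is.na(sub_means)]
      n <- length(sub_means)
      data.frame(length = L, position = p,
                 mean = if (n) mean(sub_means) else NA_real_,
                 sem = if (n > 1L) sd(sub_means) / sqrt(n) else NA_real_,
                 n_subjects = n)
    }))
  }))
  slopes <- do.call(rbind, lapply(split(d, list(d$subject, d$length)),
    function(g) data.frame(subject = g$subject[1L], length = g$length[1L],
                           slope = ols_slope(g$position, g$y))))
  rownames(slopes) <- NULL
  list(cells = cells, slopes = slopes)
}

#' Serial-position signatures of the model family
#'
#' Simulates many datasets under each of several models on shared designs
#' and returns the average per-length slope of P(best) against the best
#' option's serial position -- the qualitative signature separating the
#' model family: flat under the null model, negative under primacy and
#' bonus models, positive under pruning and recency.
#'
#' For every (dataset, subject) one set of ratings and one session design
#' are generated and evaluated under all models, so model curves differ
#' only through the model, not the designs.
#'
#' @param models named list; each element a list with elements \code{spec}
#'   (a \code{\link{model_spec}}) and \code{params}
#'   (a \code{\link{model_params}}).
#' @param n_datasets number of simulated datasets (default 200).
#' @param n_subjects subjects per dataset (default 30).
#' @param profile task variant.
#' @param seed RNG seed.
#' @param skew rating skew.
#' @param measure see \code{\link{pbest_by_position}}; the default
#'   "probability" averages selection probabilities.
#' @return data.frame with \code{model}, \code{length}, \code{slope} (mean
#'   over datasets of the group-mean per-length slope) and \code{sem}
#'   (across datasets).
#' @export
signature_slopes <- function(models, n_datasets = 200L, n_subjects = 30L,
                             profile = "exp1", seed = 1L, skew = 0.3,
                             measure = c("probability", "choice")) {
  measure <- match.arg(measure)
  set.seed(seed)
  lens <- if (profile == "exp1") 3:6 else 3:5
  acc <- array(0, dim = c(length(models), length(lens), n_datasets),
               dimnames = list(names(models), lens, NULL))
  for (d in seq_len(n_datasets)) {
    sl <- matrix(0, length(models), length(lens))
    for (s in seq_len(n_subjects)) {
      sub <- generate_subject(profile, skew = skew)
      bp <- best_positions(sub$session, sub$items)
      an <- which(!sub$session$is_catch)
      for (m in seq_along(models)) {
        pm <- session_probs(models[[m]]$spec, models[[m]]$params,
                            sub$items, sub$session)
        y <- pm[cbind(an, bp$best_pos[an])]
        if (measure == "choice") {
          ch <- vapply(an, function(t)
            sample.int(bp$length[t], 1L,
                       prob = pm[t, seq_len(bp$length[t])]), 0L)
          y <- as.numeric(ch == bp$best_pos[an])
        }
        for (li in seq_along(lens)) {
          k <- bp$length[an] == lens[li]
          sl[m, li] <- sl[m, li] + ols_slope(bp$best_pos[an][k], y[k])
        }
      }
    }
    acc[, , d] <- sl / n_subjects
  }
  out <- expand.grid(model = names(models), length = lens,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$slope <- mapply(function(m, L) mean(acc[m, as.character(L), ]),
                      out$model, out$length)
  out$sem <- mapply(function(m, L) sd(acc[m, as.character(L), ]) /
                      sqrt(n_datasets), out$model, out$length)
  out
}
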