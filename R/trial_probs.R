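#' Initialize the value state of a subject
#'
#' The value state holds the initial likeability ratings V_i(t0) and the
#' cross-trial store of carried values, which equals the ratings at every
#' trial start under local carry-over and accumulates updates under the
#' global / two-level / overt-only modes.
#'
#' @param items an item set from \code{\link{generate_ratings}} (or any
#'   data.frame with \code{item_id} and \code{rating}).
#' @return an object of class \code{cc_state}.
#' @export
init_value_state <- function(items) {
  structure(list(item_id = items$item_id,
                 ratings = items$rating,
                 carried = items$rating,
                 current_best = NA_integer_),
            class = "cc_state")
}

#' Per-trial choice probabilities under any model
#'
#' Dispatches a trial to the model's value-updating rule and returns the
#' probability of each option being chosen, together with the updated value
#' state. The sampling sequence may contain revisits (repeated item ids):
#' under the bonus models a re-revealed option that is not the current best
#' triggers a fresh comparison, while re-revealing the current best
#' triggers none; serial positions for the primacy models are the
#' first-appearance positions.
#'
#' Overt-choice bonuses (two-level and hybrid carry-over) are applied
#' separately with \code{\link{apply_overt_choice}} once the choice is
#' known.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param params a \code{\link{model_params}} vector.
#' @param trial list with \code{sequence} (item ids in sampling order,
#'   possibly with revisits).
#' @param state a \code{cc_state} from \code{\link{init_value_state}}.
#' @return list with \code{probs} (named by item id, over unique options in
#'   first-appearance order) and \code{state} (updated).
#' @export
trial_probabilities <- function(spec, params, trial, state) {
  stopifnot(inherits(spec, "cc_model_spec"))
  seq_ids <- trial$sequence
  ids <- unique(seq_ids)
  idx <- match(ids, state$item_id)
  if (anyNA(idx)) stop_invalid("trial contains item ids absent from the item set")
  v0 <- state$carried[idx]
  r0 <- state$ratings[idx]
  p <- params
  probs <- NULL
  v <- v0
  switch(spec$update,
    "none" = { v <- v0 },
    "H1"   = { v <- update_primacy(v0, p[["lam"]], variant = "H1") },
    "H1a"  = { v <- update_primacy(v0, p[["lam"]], variant = "H1a") },
    "H1b"  = { v <- update_primacy(v0, p[["lam"]], variant = "H1b") },
    "H1.1" = { v <- update_primacy(v0, p[["lam"]], p[["lam1"]], variant = "H1.1") },
    "saliency" = { v <- apply_saliency(v0, p[["gamma"]]) },
    "bonus" = {
      up <- update_bonus(v0, p[["delta"]], first_bonus = spec$first_bonus,
                         winner_rule = spec$winner_rule, initial = r0,
                         order = match(seq_ids, ids))
      v <- up$values
      if (spec$carry_mode == "global") state$carried[idx] <- v
    },
    "pruning" = { probs <- choice_probs_pruning(v0, p[["beta"]]) },
    "prob_bonus" = {
      probs <- as.numeric(choice_probs_probabilistic_bonus(
        v0, p[["beta"]], p[["beta_c"]], p[["delta"]],
        first_bonus = spec$first_bonus))
    },
    stop_invalid("unknown update rule '%s'", spec$update)
  )
  if (is.null(probs)) probs <- softmax_choice(v, p[["beta"]])
  list(probs = setNames(probs, ids), state = state)
}

#' Persist the overt-choice bonus after a trial
#'
#' Under the two-level and overt-only (hybrid) carry-over modes the overtly
#' chosen option gains \code{delta_overt}, persisted to all subsequent
#' trials; nothing is subtracted from the unchosen options. Other carry
#' modes leave the state untouched.
#'
#' @inheritParams trial_probabilities
#' @param chosen_item item id of the overtly chosen option.
#' @return the updated \code{cc_state}.
#' @export
apply_overt_choice <- function(spec, params, state, chosen_item) {
  if (spec$carry_mode %in% c("two_level", "overt_only")) {
    i <- match(chosen_item, state$item_id)
    if (is.na(i)) stop_invalid("chosen item %s not in item set", chosen_item)
    state$carried[i] <- state$carried[i] + params[["delta_overt"]]
  }
  state
}

# ---- session-level engine ----------------------------------------------

# Pack a session into index matrices for the compiled engine.
# Items are addressed by row in `items`; sequences are stored 1-based with
# 0 padding.
session_matrix <- function(session, items) {
  n_tr <- length(session$sequences)
  maxlen <- max(lengths(session$sequences))
  m <- matrix(0L, n_tr, maxlen)
  for (t in seq_len(n_tr)) {
    s <- match(session$sequences[[t]], items$item_id)
    m[t, seq_along(s)] <- s
  }
  list(seqm = m, len = lengths(session$sequences))
}

.model_code <- c(none = 0L, H1 = 1L, H1a = 2L, H1b = 3L, "H1.1" = 4L,
                 bonus = 5L, pruning = 6L, saliency = 7L, prob_bonus = 8L)
.carry_code <- c(local = 0L, global = 1L, two_level = 2L, overt_only = 3L)

#' Choice probabilities for every trial of a session
#'
#' Computes the model's probability vector for each trial of a session in
#' chronological order, propagating carried values across trials where the
#' carry-over mode requires it. The compiled engine is used by default; the
#' pure-R engine (\code{\link{trial_probabilities}}) gives identical
#' results and is used automatically when sequences contain revisits.
#'
#' @inheritParams trial_probabilities
#' @param items item set (data.frame with \code{item_id}, \code{rating}).
#' @param session a \code{\link{build_session}} design.
#' @param choices optional choice dataset (required for the two-level and
#'   overt-only carry modes, whose value updates depend on the actual
#'   choices).
#' @param engine \code{"cpp"} (default) or \code{"R"}.
#' @return numeric matrix (n_trials x max sequence length) of choice
#'   probabilities in sequence-slot order, NA-padded.
#' @export
session_probs <- function(spec, params, items, session, choices = NULL,
                          engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  needs_choices <- spec$carry_mode %in% c("two_level", "overt_only")
  if (needs_choices && is.null(choices))
    stop_invalid("carry mode '%s' needs the choice dataset", spec$carry_mode)
  chosen <- if (is.null(choices)) rep(0L, length(session$sequences))
            else as.integer(match(choices$chosen[match(seq_along(session$sequences),
                                                       choices$trial_id)],
                                  items$item_id))
  chosen[is.na(chosen)] <- 0L
  has_revisits <- any(vapply(session$sequences, anyDuplicated, 0L) > 0L)
  if (engine == "cpp" && !has_revisits) {
    sm <- session_matrix(session, items)
    pm <- cc_engine(.model_code[[spec$update]], .carry_code[[spec$carry_mode]],
                    items$rating, sm$seqm, sm$len, chosen,
                    as.numeric(params), spec$first_bonus,
                    spec$winner_rule == "initial")
    pm[sm$seqm == 0L] <- NA_real_
    return(pm)
  }
  state <- init_value_state(items)
  maxlen <- max(lengths(session$sequences))
  pm <- matrix(NA_real_, length(session$sequences), maxlen)
  for (t in seq_along(session$sequences)) {
    tp <- trial_probabilities(spec, params,
                              list(sequence = session$sequences[[t]]), state)
    state <- tp$state
    pm[t, seq_along(tp$probs)] <- tp$probs
    if (chosen[t] > 0L)
      state <- apply_overt_choice(spec, params, state,
                                  items$item_id[chosen[t]])
  }
  pm
}

#' Log-likelihood of a choice dataset
#'
#' Sum over analyzed (non-catch) trials of the log probability of the
#' chosen option under the model. A zero-probability choice yields
#' \code{-Inf}, with the offending trials flagged in attribute
#' \code{"zero_prob_trials"}.
#'
#' @inheritParams session_probs
#' @param choices a choice dataset (data.frame with \code{trial_id},
#'   \code{chosen}).
#' @return scalar log-likelihood (<= 0).
#' @export
loglik <- function(spec, params, choices, session, items,
                   engine = c("cpp", "R")) {
  pm <- session_probs(spec, params, items, session, choices = choices,
                      engine = match.arg(engine))
  analyzed <- which(!session$is_catch & seq_along(session$sequences) %in% choices$trial_id)
  ll <- 0
  zero <- integer()
  for (t in analyzed) {
    seq_ids <- session$sequences[[t]]
    ch <- choices$chosen[match(t, choices$trial_id)]
    pos <- match(ch, seq_ids)
    if (is.na(pos)) stop_invalid("trial %d: chosen item %s not in sequence", t, ch)
    p <- pm[t, pos]
    if (p <= 0) zero <- c(zero, t)
    ll <- ll + log(p)
  }
  if (length(zero)) attr(ll, "zero_prob_trials") <- zero
  ll
}
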