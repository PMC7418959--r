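#' Softmax choice probabilities
#'
#' Noisy value comparison at the moment of overt choice: option i is chosen
#' with probability proportional to exp(beta * V_i). beta is the inverse
#' temperature weighting values against noise; beta = 0 gives the uniform
#' distribution. Computed with max-subtraction for numerical stability, so
#' the result is invariant to adding a constant to all values.
#'
#' @param values numeric vector of option values (at least one).
#' @param beta inverse temperature, >= 0.
#' @return probability vector of the same length, summing to 1.
#' @export
#' @examples
#' softmax_choice(c(80, 60), 0.081)
softmax_choice <- function(values, beta) {
  if (length(values) < 1L) stop_invalid("`values` must contain at least one value")
  if (!is.finite(beta) || beta < 0) stop_invalid("`beta` must be finite and >= 0")
  z <- beta * values
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Serial-position (primacy/recency) value updates
#'
#' Adds a position-dependent bias to the value of each option in the
#' sampling sequence. Variants:
#' \describe{
#'   \item{H1}{additive inverse bias, V + lam / s_i;}
#'   \item{H1a}{additive power bias, V + lam^(s_i);}
#'   \item{H1b}{multiplicative bias, V * (1 + lam / s_i);}
#'   \item{H1.1}{H1 plus an extra first-item bonus lam1 at s_i = 1.}
#' }
#' Positive \code{lam} produces a primacy bias, negative \code{lam} a
#' recency bias. Serial positions s_i are 1-based.
#'
#' @param ratings_in_order option values in sampling order.
#' @param lam bias magnitude.
#' @param lam1 extra first-item bonus (H1.1 only).
#' @param variant one of "H1", "H1a", "H1b", "H1.1".
#' @return updated values, same order.
#' @export
#' @examples
#' update_primacy(c(40, 40, 40), lam = 6, variant = "H1")  # 46 43 42
update_primacy <- function(ratings_in_order, lam, lam1 = 0,
                           variant = c("H1", "H1a", "H1b", "H1.1")) {
  variant <- match.arg(variant)
  s <- seq_along(ratings_in_order)
  switch(variant,
    "H1"   = ratings_in_order + lam / s,
    "H1a"  = ratings_in_order + lam^s,
    "H1b"  = ratings_in_order * (1 + lam / s),
    "H1.1" = ratings_in_order + lam / s + ifelse(s == 1L, lam1, 0)
  )
}

#' Covert pairwise comparison (bonus) value updates
#'
#' Iterates through the sampling sequence keeping track of the current best
#' option. Each newly revealed option is compared with the current best;
#' the winner gains \code{+delta}, the loser \code{-delta}, and the winner
#' becomes the current best. With \code{first_bonus = TRUE} the first option
#' additionally gains \code{+delta} before any comparison, as if winning
#' against a fictive null option. Each pairwise update conserves the sum of
#' the two compared values, so the trial total is conserved without the
#' first bonus and shifted by exactly \code{+delta} with it.
#'
#' @param values option values in sampling order (current values; equal to
#'   initial ratings unless updates are carried over from earlier trials).
#' @param delta bonus size (may be negative).
#' @param first_bonus logical; add \code{delta} to the first option.
#' @param winner_rule \code{"initial"} (default) decides each comparison on
#'   the initial ratings, prior to any bonus; \code{"current"} decides on
#'   the values as updated so far. Both readings appear in descriptions of
#'   the process; the initial-ratings rule keeps the likelihood smooth in
#'   \code{delta} (the comparison trace does not depend on it).
#' @param initial initial ratings in the same order, used under
#'   \code{winner_rule = "initial"}.
#' @param order optional sampling order as indices into \code{values},
#'   possibly with revisits. A re-revealed option that is not the current
#'   best triggers a fresh comparison; re-revealing the current best
#'   triggers none. Default: each option once, in order.
#' @return list with \code{values} (updated, original order) and
#'   \code{trace}, a data.frame of the comparisons performed
#'   (step, incumbent, challenger, winner as indices).
#' @export
#' @examples
#' update_bonus(c(50, 20, 80, 60), delta = 0.5, first_bonus = TRUE)$values
update_bonus <- function(values, delta, first_bonus = FALSE,
                         winner_rule = c("initial", "current"),
                         initial = values, order = seq_along(values)) {
  winner_rule <- match.arg(winner_rule)
  if (length(values) < 1L) stop_invalid("`values` must contain at least one option")
  v <- values
  trace <- list()
  best <- order[1L]
  if (first_bonus) v[best] <- v[best] + delta
  if (length(order) > 1L) {
    for (k in 2:length(order)) {
      new <- order[k]
      if (new == best) next  # re-revealing the current best: no comparison
      cmpv <- if (winner_rule == "current") v else initial
      # ties: the incumbent current best wins
      if (cmpv[new] > cmpv[best]) {
        v[new] <- v[new] + delta
        v[best] <- v[best] - delta
        winner <- new
      } else {
        v[best] <- v[best] + delta
        v[new] <- v[new] - delta
        winner <- best
      }
      trace[[length(trace) + 1L]] <- c(step = k, incumbent = best,
                                       challenger = new, winner = winner)
      best <- winner
    }
  }
  trace <- if (length(trace)) as.data.frame(do.call(rbind, trace))
           else data.frame(step = integer(), incumbent = integer(),
                           challenger = integer(), winner = integer())
  list(values = v, trace = trace, current_best = best)
}

#' Pruning-model choice probabilities
#'
#' Instead of updating values, each covert comparison eliminates one of the
#' two options: the newly revealed option displaces the current survivor
#' with softmax probability on their initial ratings. The chosen option is
#' the one surviving all comparisons. The exact survivor distribution is
#' computed by a forward recursion over the sequence (equivalent to
#' multiplying conditional probabilities along every branch of the
#' probability tree).
#'
#' @param ratings_in_order initial ratings in sampling order (never updated).
#' @param beta inverse temperature of the covert comparisons, >= 0.
#' @return probability vector over options, in sequence order.
#' @export
#' @examples
#' choice_probs_pruning(c(80, 60, 40), beta = 0.1)
choice_probs_pruning <- function(ratings_in_order, beta) {
  n <- length(ratings_in_order)
  if (n < 1L) stop_invalid("`ratings_in_order` must contain at least one option")
  if (!is.finite(beta) || beta < 0) stop_invalid("`beta` must be finite and >= 0")
  surv <- numeric(n)
  surv[1L] <- 1
  if (n > 1L) {
    for (k in 2:n) {
      q <- sigmoid2(beta, ratings_in_order[k], ratings_in_order[seq_len(k - 1L)])
      surv[k] <- sum(surv[seq_len(k - 1L)] * q)
      surv[seq_len(k - 1L)] <- surv[seq_len(k - 1L)] * (1 - q)
    }
  }
  surv
}

#' Probabilistic bonus-model choice probabilities
#'
#' Variant of the covert pairwise comparison model in which the outcome of
#' each covert comparison is probabilistic, governed by a second softmax
#' with inverse temperature \code{beta_c}. All 2^(n-1) covert-outcome paths
#' are enumerated; along each path values receive the same +/-delta updates
#' as the deterministic model, the path probability is the product of the
#' per-comparison softmax probabilities evaluated on the current values
#' along that path, and the overall choice probabilities are the
#' path-probability-weighted average of the overt softmax (inverse
#' temperature \code{beta}) applied to each path's final values.
#'
#' @param ratings_in_order initial ratings in sampling order.
#' @param beta overt-choice inverse temperature, >= 0.
#' @param beta_c covert-comparison inverse temperature, >= 0.
#' @param delta bonus size.
#' @param first_bonus logical; deterministic +delta to the first option
#'   before enumeration (the first-option bonus is not a comparison).
#' @param max_n enumeration cap on the number of options (default 8).
#' @return probability vector over options in sequence order, with the
#'   vector of path probabilities attached as attribute
#'   \code{"path_probs"}.
#' @export
choice_probs_probabilistic_bonus <- function(ratings_in_order, beta, beta_c,
                                             delta, first_bonus = TRUE,
                                             max_n = 8L) {
  n <- length(ratings_in_order)
  if (n < 2L) stop_invalid("need at least 2 options")
  if (n > max_n)
    stop_invalid("trial has %d options, above the enumeration cap of %d", n, max_n)
  n_paths <- 2L^(n - 1L)
  probs <- numeric(n)
  path_probs <- numeric(n_paths)
  for (m in seq_len(n_paths) - 1L) {
    v <- ratings_in_order
    best <- 1L
    if (first_bonus) v[1L] <- v[1L] + delta
    pp <- 1
    for (k in 2:n) {
      p_new <- sigmoid2(beta_c, v[k], v[best])
      new_wins <- bitwAnd(m, bitwShiftL(1L, k - 2L)) != 0L
      pp <- pp * if (new_wins) p_new else 1 - p_new
      if (new_wins) {
        v[k] <- v[k] + delta; v[best] <- v[best] - delta; best <- k
      } else {
        v[best] <- v[best] + delta; v[k] <- v[k] - delta
      }
    }
    path_probs[m + 1L] <- pp
    probs <- probs + pp * softmax_choice(v, beta)
  }
  structure(probs, path_probs = path_probs)
}

#' Saliency bonus
#'
#' Multiplies the value of the best option (highest current value, ties
#' broken by lowest serial position) by \code{1 + gamma}, leaving all other
#' values unchanged. The bonus is independent of the best option's serial
#' position.
#'
#' @param ratings option values.
#' @param gamma saliency bonus (proportional).
#' @return updated values.
#' @export
#' @examples
#' apply_saliency(c(50, 80, 20), gamma = 0.1)  # 50 88 20
apply_saliency <- function(ratings, gamma) {
  if (length(ratings) < 1L) stop_invalid("`ratings` must contain at least one option")
  best <- which.max(ratings)  # first max: ties broken by lowest position
  ratings[best] <- ratings[best] * (1 + gamma)
  ratings
}
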