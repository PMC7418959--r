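# Small in-code fixtures and independent oracles used across tests.

# hand-built item set / session (bypasses the design generators)
make_items <- function(ratings) {
  out <- data.frame(item_id = seq_along(ratings), rating = ratings,
                    category = "test")
  class(out) <- c("cc_items", "data.frame")
  out
}

make_session <- function(sequences, is_catch = rep(FALSE, length(sequences)),
                         profile = "custom") {
  structure(list(sequences = sequences, is_catch = is_catch,
                 trial_id = seq_along(sequences), profile = profile,
                 repetitions = NA_integer_),
            class = "cc_session")
}

make_choices <- function(trial_id, chosen, confidence = NA_real_) {
  data.frame(trial_id = trial_id, chosen = chosen,
             confidence = rep_len(confidence, length(trial_id)))
}

# independent oracle for the pruning model: explicit enumeration of all
# 2^(n-1) covert-outcome paths of the probability tree
prune_enumerate <- function(ratings, beta) {
  n <- length(ratings)
  probs <- numeric(n)
  recurse <- function(survivor, k, p) {
    if (k > n) {
      probs[survivor] <<- probs[survivor] + p
      return(invisible())
    }
    q <- 1 / (1 + exp(-beta * (ratings[k] - ratings[survivor])))
    recurse(k, k + 1L, p * q)          # new option displaces the survivor
    recurse(survivor, k + 1L, p * (1 - q))
  }
  recurse(1L, 2L, 1)
  probs
}

# simulated subjects shared by several slow tests (built once per run)
h0_group <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_group(model_spec("H0"), model_params(beta = 0.081),
                               n_subjects = 20L, profile = "exp1", seed = 42L)
    cache
  }
})
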