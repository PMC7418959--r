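#' Generate likeability ratings for a synthetic item set
#'
#' Ratings emulate the empirical distribution of likeability reports on a
#' 0-100 visual analog scale: uniform over the scale, optionally slightly
#' left-skewed towards 0. The skewed family is a scaled Beta(1/(1+skew), 1):
#' \code{skew = 0} gives the uniform, \code{skew > 0} pulls mass (and the
#' population mean) below 50.
#'
#' @param n_items number of items (>= 1).
#' @param skew skew parameter (>= 0); default 0.3, a slight left skew.
#' @param seed optional RNG seed.
#' @param category category label recycled over items.
#' @return an item set: data.frame with \code{item_id}, \code{rating},
#'   \code{category}, of class \code{cc_items}. Tied ratings are permitted
#'   but flagged in attribute \code{"ties"}.
#' @export
#' @examples
#' items <- generate_ratings(60, skew = 0.3, seed = 1)
generate_ratings <- function(n_items, skew = 0.3, seed = NULL,
                             category = "synthetic") {
  if (n_items < 1) stop_invalid("`n_items` must be >= 1")
  if (!is.finite(skew) || skew < 0) stop_invalid("`skew` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  rating <- 100 * rbeta(n_items, shape1 = 1 / (1 + skew), shape2 = 1)
  out <- data.frame(item_id = seq_len(n_items), rating = rating,
                    category = rep_len(category, n_items))
  class(out) <- c("cc_items", "data.frame")
  attr(out, "ties") <- anyDuplicated(rating) > 0L
  out
}

# value ranks: 1 = highest rating; ties broken by item index (the task
# used rating response times for tie-breaks, unavailable synthetically)
item_ranks <- function(items) {
  ord <- order(-items$rating, items$item_id)
  rk <- integer(nrow(items))
  rk[ord] <- seq_len(nrow(items))
  setNames(rk, items$item_id)
}

new_session <- function(sequences, is_catch, profile, repetitions) {
  structure(list(sequences = sequences, is_catch = is_catch,
                 trial_id = seq_along(sequences), profile = profile,
                 repetitions = repetitions),
            class = "cc_session")
}

#' @export
print.cc_session <- function(x, ...) {
  cat(sprintf("<session %s> %d trials (%d analyzed), lengths %s\n",
              x$profile, length(x$sequences), sum(!x$is_catch),
              paste(sort(unique(lengths(x$sequences))), collapse = "/")))
  invisible(x)
}

# best (highest initial rating) and second-best item per trial, with their
# serial positions
trial_best <- function(session, items) {
  rk <- item_ranks(items)
  do.call(rbind, lapply(seq_along(session$sequences), function(t) {
    s <- session$sequences[[t]]
    r <- rk[as.character(s)]
    o <- order(r)
    data.frame(trial_id = t, length = length(s), is_catch = session$is_catch[t],
               best = s[o[1L]], best_pos = o[1L],
               second = if (length(s) > 1L) s[o[2L]] else NA_integer_,
               second_pos = if (length(s) > 1L) o[2L] else NA_integer_,
               best_rank = r[o[1L]], second_rank = if (length(s) > 1L) r[o[2L]] else NA_integer_)
  }))
}

# sample `n` distinct items weighted by remaining repetition counts;
# returns NULL if infeasible
draw_items <- function(counts, n, exclude = integer()) {
  avail <- setdiff(which(counts > 0L), exclude)
  if (length(avail) < n) return(NULL)
  if (length(avail) == n) return(avail)
  sample(avail, n, prob = counts[avail])
}

# order a trial's items: best at `pos` (round-robin balanced by caller),
# others shuffled; for sequences of >= 4 options the second-best is kept
# out of the slots adjacent to the best. `rk` is the full rank vector
# named by item id.
order_trial <- function(trial_items, rk, pos, avoid_adjacent) {
  n <- length(trial_items)
  o <- order(rk[as.character(trial_items)])
  best <- trial_items[o[1L]]
  rest <- trial_items[-o[1L]]
  slots <- setdiff(seq_len(n), pos)
  out <- integer(n)
  out[pos] <- best
  if (avoid_adjacent && n >= 4L) {
    second <- trial_items[o[2L]]
    ok <- setdiff(slots, c(pos - 1L, pos + 1L))
    sec_slot <- if (length(ok) == 1L) ok else sample(ok, 1L)
    fill <- setdiff(rest, second)
    rest_slots <- setdiff(slots, sec_slot)
    out[sec_slot] <- second
    out[rest_slots] <- if (length(fill) > 1L) sample(fill) else fill
  } else {
    out[slots] <- if (length(rest) > 1L) sample(rest) else rest
  }
  out
}

# round-robin assignment of the best option's serial position within each
# trial-length stratum; guarantees per-position counts differ by <= 1
balance_positions <- function(lens) {
  pos <- integer(length(lens))
  for (L in unique(lens)) {
    i <- which(lens == L)
    pos[i] <- rep_len(seq_len(L), length(i))
  }
  pos
}

build_exp1_attempt <- function(items, length_counts) {
  lens <- sample(rep(as.integer(names(length_counts)), length_counts))
  counts <- rep(4L, nrow(items))
  sets <- vector("list", length(lens))
  for (t in order(-lens)) {  # longer trials first: fewer dead ends
    picked <- draw_items(counts, lens[t])
    if (is.null(picked)) return(NULL)
    counts[picked] <- counts[picked] - 1L
    sets[[t]] <- items$item_id[picked]
  }
  pos <- balance_positions(lens)
  rk <- item_ranks(items)
  seqs <- lapply(seq_along(sets), function(t)
    order_trial(sets[[t]], rk, pos[t], avoid_adjacent = FALSE))
  new_session(seqs, rep(FALSE, length(seqs)), "exp1", 4L)
}

# exp2/exp3: 48 middle-ranked items grouped into 72 trials (24 each of
# lengths 3/4/5) such that best and second-best are within 3 value ranks,
# plus 12 six-option catch trials made of the 6 highest- and 6
# lowest-rated items
build_exp23_attempt <- function(items, profile, max_rank_dist = 3L) {
  rk <- item_ranks(items)
  ord <- order(rk)                       # item row index by rank
  extreme <- c(ord[1:6], ord[(length(ord) - 5):length(ord)])
  middle <- ord[7:(length(ord) - 6)]     # row indices, rank order 1..48
  n_mid <- length(middle)

  # (best, second) pairs: top-down greedy, each item used at most its
  # remaining repetition count, second within max_rank_dist ranks of best
  counts <- rep(6L, n_mid)
  pairs <- matrix(0L, 72L, 2L)
  for (p in seq_len(72L)) {
    b <- NA_integer_
    for (r in which(counts > 0L)) {
      s_cand <- (r + 1L):min(r + max_rank_dist, n_mid)
      s_cand <- s_cand[s_cand > r & counts[s_cand] > 0L]
      if (length(s_cand)) { b <- r; break }
    }
    if (is.na(b)) return(NULL)
    s_cand <- (b + 1L):min(b + max_rank_dist, n_mid)
    s_cand <- s_cand[counts[s_cand] > 0L]
    s <- if (length(s_cand) == 1L) s_cand
         else sample(s_cand, 1L, prob = counts[s_cand])
    counts[b] <- counts[b] - 1L
    counts[s] <- counts[s] - 1L
    pairs[p, ] <- c(b, s)
  }

  # fillers: strictly lower-ranked than the trial's second-best; most
  # restrictive trials (lowest-rated second-best) served first
  lens <- sample(rep(3:5, each = 24L))
  pair_for_trial <- sample(72L)
  sets <- vector("list", 72L)
  need <- lens - 2L
  trial_order <- order(-pairs[pair_for_trial, 2L])
  for (t in trial_order) {
    bs <- pairs[pair_for_trial[t], ]
    lower <- which(counts > 0L)
    lower <- lower[lower > bs[2L]]
    if (length(lower) < need[t]) return(NULL)
    fill <- if (length(lower) == need[t]) lower
            else sample(lower, need[t], prob = counts[lower])
    counts[fill] <- counts[fill] - 1L
    sets[[t]] <- items$item_id[middle[c(bs, fill)]]
  }

  pos <- balance_positions(lens)
  seqs <- lapply(seq_len(72L), function(t)
    order_trial(sets[[t]], rk, pos[t], avoid_adjacent = TRUE))

  # catch trials: 12 extreme items, 6 per trial, each item in 6 of the 12
  catch <- lapply(0:11, function(j)
    sample(items$item_id[extreme[(j + 0:5) %% 12L + 1L]]))

  all_seqs <- c(seqs, catch)
  is_catch <- c(rep(FALSE, 72L), rep(TRUE, 12L))
  shuffle <- sample(84L)
  new_session(all_seqs[shuffle], is_catch[shuffle], profile, 6L)
}

#' Build a choice-session design
#'
#' Groups a rated item set into choice trials reproducing the design
#' constraints of the three task variants:
#' \describe{
#'   \item{exp1}{86 items, 72 analyzed trials of 3-6 options (default
#'     12/16/20/24 trials per length), every item appearing exactly 4
#'     times;}
#'   \item{exp2, exp3}{60 items, 84 trials of which 72 analyzed (24 each
#'     of lengths 3/4/5 built from the 48 middle-ranked items) and 12
#'     six-option catch trials built from the 6 highest- and 6
#'     lowest-rated items, every item appearing exactly 6 times. In
#'     analyzed trials the best and second-best options are within 3 value
#'     ranks, and in trials of 4+ options they are never displayed in
#'     consecutive serial positions.}
#' }
#' Within each trial-length stratum the serial position of the best option
#' is balanced by round-robin assignment. Trial composition is randomized
#' under the constraints; construction is retried with fresh draws when a
#' greedy assignment dead-ends, and fails with a diagnostic if no valid
#' session is found.
#'
#' @param items item set from \code{\link{generate_ratings}}; must have 86
#'   items for exp1 and 60 for exp2/exp3.
#' @param profile one of "exp1", "exp2", "exp3".
#' @param seed optional RNG seed.
#' @param length_counts named integer vector of trials per length (exp1
#'   only); must satisfy sum(length * count) = 4 * n_items.
#' @param max_tries construction attempts before giving up.
#' @return a session design of class \code{cc_session}.
#' @export
#' @examples
#' items <- generate_ratings(60, seed = 7)
#' build_session(items, "exp2", seed = 7)
build_session <- function(items, profile = c("exp1", "exp2", "exp3"),
                          seed = NULL,
                          length_counts = c("3" = 12L, "4" = 16L,
                                            "5" = 20L, "6" = 24L),
                          max_tries = 200L) {
  profile <- match.arg(profile)
  if (!is.null(seed)) set.seed(seed)
  n_items <- nrow(items)
  if (profile == "exp1") {
    if (n_items != 86L)
      stop_invalid("exp1 requires 86 items, got %d", n_items)
    slots <- sum(as.integer(names(length_counts)) * length_counts)
    if (slots != 4L * n_items)
      stop_invalid("length_counts fill %d slots; need 4 x %d = %d",
                   slots, n_items, 4L * n_items)
  } else if (n_items != 60L) {
    stop_invalid("%s requires 60 items, got %d", profile, n_items)
  }
  for (i in seq_len(max_tries)) {
    s <- if (profile == "exp1") build_exp1_attempt(items, length_counts)
         else build_exp23_attempt(items, profile)
    if (!is.null(s)) return(s)
  }
  stop_invalid(paste0("could not build a valid %s session in %d attempts; ",
                      "the rating configuration may make the pairing ",
                      "constraints infeasible"), profile, max_tries)
}

#' Check and enforce the pairing constraints of exp2/exp3 designs
#'
#' Verifies that in every analyzed trial the best and second-best options
#' are within \code{max_rank_dist} value ranks (a set property of the
#' trial: violations are an error), and that in trials of 4+ options they
#' do not occupy consecutive serial positions (an ordering property:
#' violating trials are reordered in place, keeping the best option's
#' serial position untouched).
#'
#' @param session a session design (profile exp2 or exp3).
#' @param items the item set the session was built from.
#' @param max_rank_dist maximal allowed value-rank distance (default 3).
#' @return the (possibly reordered) session.
#' @export
apply_pairing_constraints <- function(session, items, max_rank_dist = 3L) {
  if (!session$profile %in% c("exp2", "exp3"))
    stop_invalid("pairing constraints apply to exp2/exp3 profiles only")
  tb <- trial_best(session, items)
  an <- tb[!tb$is_catch, ]
  bad <- an$trial_id[an$second_rank - an$best_rank > max_rank_dist]
  if (length(bad))
    stop_invalid("rank-distance constraint violated in trial(s) %s",
                 paste(bad, collapse = ", "))
  for (t in an$trial_id) {
    row <- an[an$trial_id == t, ]
    n <- row$length
    if (n < 4L || abs(row$best_pos - row$second_pos) != 1L) next
    s <- session$sequences[[t]]
    ok <- setdiff(seq_len(n), c(row$best_pos - 1L, row$best_pos,
                                row$best_pos + 1L))
    swap <- ok[1L]
    s[c(row$second_pos, swap)] <- s[c(swap, row$second_pos)]
    session$sequences[[t]] <- s
  }
  session
}

#' Generate a complete synthetic subject (ratings + session design)
#'
#' A subject comprises one or more category sessions, each with its own
#' item set and trial design (the first task variant used five sessions of
#' 86 items, one per stimulus category; the others three sessions of 60
#' items). Sessions use disjoint items, so they are returned merged: item
#' ids are offset per session and the trial lists concatenated in session
#' order.
#'
#' @param profile task variant, see \code{\link{build_session}}.
#' @param seed optional RNG seed.
#' @param skew rating skew, see \code{\link{generate_ratings}}.
#' @param n_sessions number of category sessions (default 1).
#' @param ... passed on to \code{\link{build_session}}.
#' @return list with \code{items} and \code{session}.
#' @export
generate_subject <- function(profile = c("exp1", "exp2", "exp3"),
                             seed = NULL, skew = 0.3, n_sessions = 1L, ...) {
  profile <- match.arg(profile)
  if (!is.null(seed)) set.seed(seed)
  n_items <- if (profile == "exp1") 86L else 60L
  blocks <- lapply(seq_len(n_sessions), function(b) {
    items <- generate_ratings(n_items, skew = skew,
                              category = sprintf("category%d", b))
    list(items = items, session = build_session(items, profile, ...))
  })
  if (n_sessions == 1L) return(blocks[[1L]])
  items <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    it <- blocks[[b]]$items
    it$item_id <- it$item_id + (b - 1L) * n_items
    it
  }))
  class(items) <- c("cc_items", "data.frame")
  attr(items, "ties") <- anyDuplicated(items$rating) > 0L
  seqs <- do.call(c, lapply(seq_along(blocks), function(b)
    lapply(blocks[[b]]$session$sequences, function(s)
      s + (b - 1L) * n_items)))
  is_catch <- do.call(c, lapply(blocks, function(b) b$session$is_catch))
  list(items = items,
       session = new_session(seqs, is_catch, profile,
                             blocks[[1L]]$session$repetitions))
}
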