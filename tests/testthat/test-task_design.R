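test_that("rating generator matches the target distribution family", {
  it <- generate_ratings(10000, skew = 0, seed = 1)
  expect_true(all(it$rating >= 0 & it$rating <= 100))
  expect_lt(abs(mean(it$rating) - 50), 1)          # uniform case
  it2 <- generate_ratings(10000, skew = 0.3, seed = 1)
  expect_lt(mean(it2$rating), 50)                  # mass pulled towards 0
  expect_true(all(it2$rating >= 0 & it2$rating <= 100))
  one <- generate_ratings(1, skew = 2, seed = 5)
  expect_equal(nrow(one), 1L)
  expect_true(one$rating >= 0 && one$rating <= 100)
  expect_false(anyDuplicated(it$item_id) > 0)
  expect_error(generate_ratings(0), "n_items")
  expect_error(generate_ratings(10, skew = -1), "skew")
})

test_that("exp2 sessions reproduce the published trial structure", {
  items <- generate_ratings(60, seed = 7)
  s <- build_session(items, "exp2", seed = 7)
  expect_equal(length(s$sequences), 84L)           # 84 trials per session
  expect_equal(sum(!s$is_catch), 72L)              # 72 in data analysis
  an_len <- lengths(s$sequences)[!s$is_catch]
  expect_equal(as.vector(table(an_len)), c(24L, 24L, 24L))
  # catch trials are exactly the 6-option trials
  expect_true(all(lengths(s$sequences)[s$is_catch] == 6L))
  # every item appears exactly 6 times
  expect_true(all(table(unlist(s$sequences)) == 6L))
  # catch trials use only the 6 highest- and 6 lowest-rated items
  rk <- covertchoice:::item_ranks(items)
  catch_items <- unique(unlist(s$sequences[s$is_catch]))
  expect_setequal(rk[match(catch_items, items$item_id)],
                  c(1:6, 55:60))
  expect_error(build_session(generate_ratings(50, seed = 1), "exp2"),
               "60 items")
})

test_that("exp1 sessions give every item four appearances", {
  items <- generate_ratings(86, seed = 7)
  s <- build_session(items, "exp1", seed = 7)
  expect_equal(length(s$sequences), 72L)
  expect_true(all(!s$is_catch))
  expect_true(all(table(unlist(s$sequences)) == 4L))
  expect_equal(as.vector(table(lengths(s$sequences))),
               c(12L, 16L, 20L, 24L))
  expect_false(any(vapply(s$sequences, anyDuplicated, 0L) > 0L))
  expect_error(build_session(items, "exp1",
                             length_counts = c("3" = 10L, "4" = 10L,
                                               "5" = 10L, "6" = 10L)),
               "slots")
  expect_error(build_session(generate_ratings(60, seed = 1), "exp1"),
               "86 items")
})

test_that("pairing constraints hold in exp2/exp3 designs", {
  for (seed in c(3, 11)) {
    items <- generate_ratings(60, seed = seed)
    s <- build_session(items, "exp3", seed = seed)
    tb <- covertchoice:::trial_best(s, items)
    an <- tb[!tb$is_catch, ]
    # best and second-best within three value ranks
    expect_lte(max(an$second_rank - an$best_rank), 3L)
    # no consecutive best/second-best in 4+ option trials
    long <- an[an$length >= 4L, ]
    expect_false(any(abs(long$best_pos - long$second_pos) == 1L))
    # 3-option trials carry no adjacency constraint (adjacency can occur)
    expect_identical(s, apply_pairing_constraints(s, items))
  }
  # the checker reorders a violating 4-option trial without moving the best
  items <- make_items(c(80, 75, 40, 30, 20, 10, 5, 90, 85, 70,
                        rep(50, 50)))
  expect_error(apply_pairing_constraints(
    make_session(list(c(1L, 2L))), items), "exp2/exp3")
})

test_that("best-option serial position is balanced within lengths", {
  items <- generate_ratings(86, seed = 2)
  s <- build_session(items, "exp1", seed = 2)
  tb <- covertchoice:::trial_best(s, items)
  for (L in 3:6) {
    counts <- table(factor(tb$best_pos[tb$length == L], levels = 1:L))
    expect_lte(diff(range(counts)), 1L, label = sprintf("length %d", L))
  }
  items2 <- generate_ratings(60, seed = 2)
  s2 <- build_session(items2, "exp2", seed = 2)
  tb2 <- covertchoice:::trial_best(s2, items2)
  an <- tb2[!tb2$is_catch, ]
  for (L in 3:5) {
    counts <- table(factor(an$best_pos[an$length == L], levels = 1:L))
    expect_lte(diff(range(counts)), 1L, label = sprintf("length %d", L))
  }
})

test_that("identical seeds reproduce identical sessions", {
  items <- generate_ratings(60, seed = 9)
  expect_identical(build_session(items, "exp2", seed = 123),
                   build_session(items, "exp2", seed = 123))
  items1 <- generate_ratings(86, seed = 9)
  expect_identical(build_session(items1, "exp1", seed = 123),
                   build_session(items1, "exp1", seed = 123))
  expect_identical(generate_subject("exp1", seed = 4, n_sessions = 2),
                   generate_subject("exp1", seed = 4, n_sessions = 2))
})

test_that("multi-session subjects use disjoint item blocks", {
  sub <- generate_subject("exp1", seed = 8, n_sessions = 5)
  expect_equal(nrow(sub$items), 5L * 86L)
  expect_equal(length(sub$session$sequences), 5L * 72L)
  expect_true(all(table(unlist(sub$session$sequences)) == 4L))
  # trials 1-72 use items 1-86, trials 73-144 items 87-172, ...
  for (b in 1:5) {
    blk <- unlist(sub$session$sequences[(b - 1) * 72 + 1:72])
    expect_true(all(blk > (b - 1) * 86 & blk <= b * 86))
  }
})
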