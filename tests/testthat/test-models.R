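test_that("softmax choice probabilities behave as a softmax should", {
  expect_equal(softmax_choice(c(50, 50, 50), 0.3), rep(1 / 3, 3))
  expect_equal(softmax_choice(c(80, 60), 0), c(0.5, 0.5))
  expect_equal(softmax_choice(c(80, 60), 0.081)[1],
               1 / (1 + exp(-0.081 * 20)), tolerance = 1e-12)
  # shift invariance and normalization over random cases
  set.seed(1)
  for (i in 1:20) {
    v <- runif(sample(2:6, 1), 0, 100)
    b <- runif(1, 0, 0.5)
    p <- softmax_choice(v, b)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    expect_equal(p, softmax_choice(v + 17.3, b), tolerance = 1e-12)
  }
  expect_error(softmax_choice(numeric(0), 1), "at least one")
  expect_error(softmax_choice(c(1, 2), -0.1), "beta")
})

test_that("serial-position updates implement the four variants", {
  expect_equal(update_primacy(c(40, 40, 40), lam = 6), c(46, 43, 42))
  r <- c(55, 10, 70)
  expect_equal(update_primacy(r, 0, variant = "H1"), r)
  expect_equal(update_primacy(r, 0, variant = "H1b"), r)
  expect_equal(update_primacy(r, 0, 0, variant = "H1.1"), r)
  expect_equal(update_primacy(r, 0.5, variant = "H1a"), r + 0.5^(1:3))
  expect_equal(update_primacy(r, 6, variant = "H1b"), r * (1 + 6 / (1:3)))
  # the "2 lam" variant: first item receives twice the bias in total
  expect_equal(update_primacy(r, 6, lam1 = 6, variant = "H1.1")[1], r[1] + 12)
  # negative lam produces a recency gradient (later positions lose less)
  up <- update_primacy(c(50, 50, 50), -6)
  expect_true(all(diff(up) > 0))
  expect_error(update_primacy(r, 1, variant = "H9"))
})

test_that("bonus updating follows the covert comparison trace", {
  expect_equal(update_bonus(c(50, 20, 80, 60), 0.5, first_bonus = TRUE)$values,
               c(50.5, 19.5, 81.0, 59.5))
  up <- update_bonus(c(50, 20, 80, 60), 0.5, first_bonus = FALSE)
  expect_equal(up$values, c(50.0, 19.5, 81.0, 59.5))
  expect_equal(sum(up$values), 210)  # symmetric +/- delta conserves the sum
  expect_equal(update_bonus(c(50, 20, 80), 0)$values, c(50, 20, 80))
  # pairwise conservation on random traces; H2.1 shifts the total by +delta
  set.seed(2)
  for (i in 1:20) {
    v <- runif(sample(3:6, 1), 0, 100)
    d <- runif(1, -2, 2)
    expect_equal(sum(update_bonus(v, d)$values), sum(v), tolerance = 1e-10)
    expect_equal(sum(update_bonus(v, d, first_bonus = TRUE)$values),
                 sum(v) + d, tolerance = 1e-10)
  }
  # ties: the incumbent wins and keeps the bonus
  tie <- update_bonus(c(50, 50), 1)
  expect_equal(tie$values, c(51, 49))
  expect_equal(tie$current_best, 1L)
  # revisits: re-revealing the current best triggers no comparison
  rv <- update_bonus(c(80, 60), 1, order = c(1L, 2L, 1L, 2L))
  expect_equal(rv$values, c(82, 58))  # option 2 challenged (and lost) twice
})

test_that("winner rule switch decides comparisons on initial ratings", {
  # with a large negative delta the updated leader can fall behind; under
  # the initial-ratings rule the trace ignores the updates
  v <- c(60, 55, 58)
  cur <- update_bonus(v, -10, winner_rule = "current")
  ini <- update_bonus(v, -10, winner_rule = "initial")
  expect_equal(ini$values, c(60 - 20, 55 + 10, 58 + 10))
  expect_false(isTRUE(all.equal(cur$values, ini$values)))
})

test_that("pruning forward recursion equals exhaustive path enumeration", {
  expect_equal(choice_probs_pruning(c(80, 60, 40), 0.1)[1],
               (1 / (1 + exp(-2))) * (1 / (1 + exp(-4))), tolerance = 1e-10)
  expect_equal(choice_probs_pruning(c(10, 90), 0.2),
               softmax_choice(c(10, 90), 0.2), tolerance = 1e-8)
  # beta = 0: every comparison is a coin flip, so an option survives with
  # probability (1/2)^(number of comparisons it faces) -- late options are
  # favored, the defining feature of sequential elimination
  expect_equal(choice_probs_pruning(c(30, 70, 50, 20), 0),
               c(1 / 8, 1 / 8, 1 / 4, 1 / 2), tolerance = 1e-12)
  expect_equal(choice_probs_pruning(c(30, 70, 50, 20), 0),
               prune_enumerate(c(30, 70, 50, 20), 0), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    v <- runif(n, 0, 100)
    b <- runif(1, 0, 0.3)
    p <- choice_probs_pruning(v, b)
    expect_equal(p, prune_enumerate(v, b), tolerance = 1e-10)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("probabilistic bonus model enumerates paths and recovers limits", {
  for (n in 4:6) {
    p <- choice_probs_probabilistic_bonus(runif(n, 0, 100), 0.081, 0.24, 0.59)
    expect_length(attr(p, "path_probs"), 2^(n - 1))
    expect_equal(sum(attr(p, "path_probs")), 1, tolerance = 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  set.seed(4)
  for (i in 1:10) {
    v <- runif(sample(3:6, 1), 0, 100)
    # beta_c -> infinity: every comparison goes to the currently better
    # option, recovering the deterministic model under the current-values
    # winner rule (path comparisons use current values by definition)
    det <- update_bonus(v, 0.59, first_bonus = TRUE,
                        winner_rule = "current")$values
    expect_equal(
      as.numeric(choice_probs_probabilistic_bonus(v, 0.081, 1e6, 0.59)),
      softmax_choice(det, 0.081), tolerance = 1e-6)
    # delta = 0: paths differ only through delta, so the null model returns
    expect_equal(
      as.numeric(choice_probs_probabilistic_bonus(v, 0.081, 0.24, 0)),
      softmax_choice(v, 0.081), tolerance = 1e-12)
  }
  expect_error(choice_probs_probabilistic_bonus(runif(9, 0, 100),
                                                0.1, 0.2, 0.5),
               "enumeration cap")
})

test_that("saliency bonus is position independent and multiplicative", {
  expect_equal(apply_saliency(c(50, 80, 20), 0.1), c(50, 88, 20))
  v <- c(50, 80, 20)
  expect_equal(apply_saliency(v, 0), v)
  perm <- c(3, 2, 1)
  expect_equal(apply_saliency(v[perm], 0.1), apply_saliency(v, 0.1)[perm])
  # ties broken by lowest serial position
  expect_equal(apply_saliency(c(80, 80), 0.1), c(88, 80))
})

test_that("every model collapses to the null model at zero bias/bonus", {
  items <- make_items(c(72, 35, 88, 51, 14, 60))
  session <- make_session(list(1:4, c(5L, 2L, 6L), c(3L, 1L, 5L, 6L, 2L)))
  h0 <- session_probs(model_spec("H0"), model_params(beta = 0.081),
                      items, session)
  zero <- model_params(beta = 0.081, lam = 0, lam1 = 0, delta = 0,
                       delta_overt = 0, gamma = 0, beta_c = 0.24)
  choices <- make_choices(1:3, c(3L, 6L, 3L))
  for (m in setdiff(model_names(), "H3")) {  # H3 has no bias parameter
    pm <- session_probs(model_spec(m), zero, items, session,
                        choices = choices)
    expect_equal(pm, h0, tolerance = 1e-12, label = m)
  }
  # H0 probabilities are independent of presentation order
  session2 <- make_session(list(c(4L, 2L, 3L, 1L), c(6L, 5L, 2L),
                                c(2L, 6L, 5L, 1L, 3L)))
  h0b <- session_probs(model_spec("H0"), model_params(beta = 0.081),
                       items, session2)
  expect_equal(h0b[1, 1:4], h0[1, c(4, 2, 3, 1)], tolerance = 1e-12)
})

test_that("compiled and R engines agree for every model", {
  set.seed(6)
  items <- generate_ratings(86)
  session <- build_session(items, "exp1")
  for (m in model_names()) {
    spec <- model_spec(m)
    params <- covertchoice:::default_generating_params(m)
    choices <- if (spec$carry_mode %in% c("two_level", "overt_only"))
      simulate_subject(spec, params, items, session, seed = 9) else NULL
    a <- session_probs(spec, params, items, session, choices = choices,
                       engine = "cpp")
    b <- session_probs(spec, params, items, session, choices = choices,
                       engine = "R")
    expect_equal(a, b, tolerance = 1e-12, label = m)
    expect_equal(rowSums(a, na.rm = TRUE),
                 rep(1, nrow(a)), tolerance = 1e-12, label = m)
  }
})

test_that("probabilities are equivariant to relabeling the items", {
  set.seed(7)
  ratings <- runif(6, 0, 100)
  items <- make_items(ratings)
  session <- make_session(list(c(2L, 5L, 1L, 6L), c(4L, 3L, 2L)))
  perm <- sample(6)  # old id i becomes new id perm[i]
  items2 <- make_items(ratings[match(1:6, perm)])
  session2 <- make_session(lapply(session$sequences, function(s) perm[s]))
  for (m in c("H0", "H1", "H2", "H2.1", "H2.1prob", "H3", "SAL")) {
    spec <- model_spec(m)
    params <- covertchoice:::default_generating_params(m)
    expect_equal(session_probs(spec, params, items, session),
                 session_probs(spec, params, items2, session2),
                 tolerance = 1e-12, label = m)
  }
})

test_that("carry-over modes propagate updates as specified", {
  items <- make_items(c(80, 60, 40, 20))
  # two one-comparison trials sharing item 1
  session <- make_session(list(c(1L, 2L), c(1L, 3L)))
  params <- model_params(beta = 0.1, delta = 0.59)
  # local: both trials start from initial ratings
  loc <- session_probs(model_spec("H2.1"), params, items, session)
  expect_equal(loc[2, 1:2],
               softmax_choice(update_bonus(c(80, 40), 0.59,
                                           first_bonus = TRUE)$values, 0.1))
  # global: item 1 enters trial 2 with rating + 2 delta (first bonus + win)
  glo <- session_probs(model_spec("H2.1global"), params, items, session)
  expect_equal(glo[1, 1:2], loc[1, 1:2], tolerance = 1e-12)
  v2 <- update_bonus(c(80 + 2 * 0.59, 40), 0.59, first_bonus = TRUE)$values
  expect_equal(glo[2, 1:2], softmax_choice(v2, 0.1), tolerance = 1e-12)
  # two-level with delta = 0 is identical to the overt-only hybrid
  choices <- make_choices(1:2, c(1L, 3L))
  p2l <- session_probs(model_spec("H2.1twolevel"),
                       model_params(beta = 0.1, delta = 0, delta_overt = 10),
                       items, session, choices = choices)
  phy <- session_probs(model_spec("HYBRID"),
                       model_params(beta = 0.1, delta_overt = 10),
                       items, session, choices = choices)
  expect_equal(p2l, phy, tolerance = 1e-12)
  # and the overtly chosen item carries its bonus into the next trial
  expect_equal(phy[2, 1:2], softmax_choice(c(80 + 10, 40), 0.1),
               tolerance = 1e-12)
  expect_error(model_spec("H0", carry_mode = "sideways"), "carry_mode")
})
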