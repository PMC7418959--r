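test_that("log-likelihood matches direct evaluation", {
  items <- make_items(c(80, 60, 40))
  # single 2-option trial with equal values
  eq_items <- make_items(c(50, 50))
  ll <- loglik(model_spec("H0"), model_params(beta = 0.3),
               make_choices(1L, 1L), make_session(list(1:2)), eq_items)
  expect_equal(as.numeric(ll), log(0.5), tolerance = 1e-12)
  # beta = 0 over T trials of n options: -sum log n
  session <- make_session(list(1:3, c(2L, 3L), c(3L, 1L, 2L)))
  ll0 <- loglik(model_spec("H0"), model_params(beta = 0),
                make_choices(1:3, c(1L, 2L, 2L)), session, items)
  expect_equal(as.numeric(ll0), -(log(3) + log(2) + log(3)),
               tolerance = 1e-12)
  # hand-built 3-trial dataset, direct softmax arithmetic
  b <- 0.1
  p1 <- exp(b * 80) / sum(exp(b * c(80, 60, 40)))   # trial 1, chose item 1
  p2 <- exp(b * 40) / sum(exp(b * c(60, 40)))       # trial 2, chose item 3
  p3 <- exp(b * 60) / sum(exp(b * c(40, 80, 60)))   # trial 3, chose item 2
  llh <- loglik(model_spec("H0"), model_params(beta = b),
                make_choices(1:3, c(1L, 3L, 2L)), session, items)
  expect_equal(as.numeric(llh), log(p1) + log(p2) + log(p3),
               tolerance = 1e-12)
  # catch trials are excluded from the sum
  s_catch <- make_session(list(1:3, c(2L, 3L)), is_catch = c(FALSE, TRUE))
  llc <- loglik(model_spec("H0"), model_params(beta = b),
                make_choices(1:2, c(1L, 2L)), s_catch, items)
  expect_equal(as.numeric(llc), log(p1), tolerance = 1e-12)
  expect_error(loglik(model_spec("H0"), model_params(),
                      make_choices(1L, 3L), make_session(list(1:2)), items),
               "not in sequence")
})

test_that("Laplace free energy equals the closed-form Gaussian evidence", {
  y <- c(1.2, 0.4, 0.9); s2 <- 0.5; m0 <- 0.3; t2 <- 2
  lj <- function(th) sum(stats::dnorm(y, th, sqrt(s2), log = TRUE)) +
    stats::dnorm(th, m0, sqrt(t2), log = TRUE)
  fit <- laplace_fit(lj, start = 0, seed = 1)
  # conjugate Gaussian: evidence available in closed form (Laplace exact)
  n <- length(y)
  prec <- n / s2 + 1 / t2
  exact <- -n / 2 * log(2 * pi * s2) - 0.5 * log(2 * pi * t2) +
    0.5 * log(2 * pi / prec) - sum(y^2) / (2 * s2) - m0^2 / (2 * t2) +
    (sum(y) / s2 + m0 / t2)^2 / (2 * prec)
  expect_equal(fit$free_energy, exact, tolerance = 1e-6)
  expect_true(fit$converged)
  # posterior mode at the conjugate posterior mean
  expect_equal(fit$mode, (sum(y) / s2 + m0 / t2) / prec, tolerance = 1e-6)
})

test_that("no data leaves the fit at the prior with zero free energy", {
  items <- generate_ratings(86, seed = 1)
  session <- build_session(items, "exp1", seed = 1)
  empty <- make_choices(integer(), integer())
  f <- fit_map(model_spec("H2.1"), empty, session, items, seed = 1)
  expect_equal(f$free_energy, 0, tolerance = 1e-5)
  pri <- default_priors(model_spec("H2.1"))
  expect_equal(unname(f$posterior_mean["beta"]),
               exp(pri$mean[pri$param == "beta"]), tolerance = 1e-4)
  expect_equal(unname(f$posterior_mean["delta"]), 0, tolerance = 1e-4)
  expect_equal(f$n_trials, 0L)
})

test_that("an irrelevant extra parameter lowers the evidence on average", {
  subs <- h0_group()  # 20 subjects generated under the null model
  f_h0 <- vapply(subs, function(su)
    fit_map(model_spec("H0"), su$choices, su$session, su$items,
            n_starts = 2L, seed = 1)$free_energy, 0)
  f_h21 <- vapply(subs, function(su)
    fit_map(model_spec("H2.1"), su$choices, su$session, su$items,
            n_starts = 2L, seed = 1)$free_energy, 0)
  expect_gt(mean(f_h0), mean(f_h21))  # complexity penalty
})

test_that("parameter transforms round-trip across models", {
  for (m in model_names()) {
    spec <- model_spec(m)
    pri <- default_priors(spec)
    gen <- covertchoice:::default_generating_params(m)
    native <- gen[spec$free_params]
    if ("lam" %in% spec$free_params && native[["lam"]] == 0)
      native[["lam"]] <- spec$lam_sign * 2
    th <- covertchoice:::from_native(as.list(native), pri)
    back <- covertchoice:::to_native(th, pri)
    expect_equal(unname(back), unname(unlist(native)), tolerance = 1e-12,
                 label = m)
  }
})

test_that("random-effects BMS matches its analytic oracles", {
  # symmetry: equal evidence for K models gives Ef = Ep = 1/K
  ev <- matrix(0, 20, 4, dimnames = list(NULL, paste0("M", 1:4)))
  b <- bms(ev, n_samples = 2e5, seed = 1)
  expect_equal(b$ef, rep(0.25, 4), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(b$ep, rep(0.25, 4), tolerance = 0.01, ignore_attr = TRUE)
  # a +10 log-unit model dominates
  ev2 <- matrix(0, 20, 3); ev2[, 2] <- 10
  colnames(ev2) <- paste0("M", 1:3)
  b2 <- bms(ev2, n_samples = 2e5, seed = 1)
  expect_gt(b2$ep[2], 0.99)
  # K = 2: exceedance probability is a Beta tail probability
  set.seed(3)
  ev3 <- cbind(A = rnorm(12, 1), B = rnorm(12))
  b3 <- bms(ev3, n_samples = 1e6, seed = 2)
  expect_equal(b3$ep[1], pbeta(0.5, b3$alpha[2], b3$alpha[1]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(sum(b3$ep), 1, tolerance = 1e-12)
  # invariance to per-subject constants
  shift <- sweep(ev3, 1, rnorm(12, 0, 10), "+")
  b4 <- bms(shift, n_samples = 1e5, seed = 2)
  expect_equal(b4$alpha, b3$alpha, tolerance = 1e-8, ignore_attr = TRUE)
  # non-finite rows are dropped with a warning
  ev5 <- ev3; ev5[3, 1] <- -Inf
  expect_warning(b5 <- bms(ev5, n_samples = 1e5, seed = 2), "non-finite")
  expect_equal(b5$n_subjects, 11L)
  expect_error(bms(matrix(0, 5, 1)), "2 models")
})
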