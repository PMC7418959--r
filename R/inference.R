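# ---- parameter transforms ----------------------------------------------
#
# MAP estimation runs in an unconstrained transformed space with Gaussian
# priors. Inverse temperatures are log-transformed; the serial-position
# bias lam is log-transformed with the sign fixed by the model variant
# (positive for primacy, negative for recency); the additive bonuses and
# the saliency bonus are unconstrained (identity).

to_native <- function(theta, priors) {
  v <- numeric(length(theta))
  for (i in seq_along(theta)) {
    v[i] <- switch(priors$transform[i],
      log = exp(theta[i]),
      logpos = exp(theta[i]),
      logneg = -exp(theta[i]),
      identity = theta[i])
  }
  setNames(v, priors$param)
}

from_native <- function(native, priors) {
  th <- numeric(nrow(priors))
  for (i in seq_len(nrow(priors))) {
    x <- native[[priors$param[i]]]
    th[i] <- switch(priors$transform[i],
      log = log(x), logpos = log(x), logneg = log(-x), identity = x)
  }
  th
}

#' Default priors for a model's free parameters
#'
#' Gaussian priors on the transformed scale, centered on the scale of the
#' task. Inverse temperatures (\code{beta}, \code{beta_c}) use
#' N(log 0.1, 1) on the log scale -- values live on a 0-100 rating scale,
#' so inverse temperatures of order 0.1 give reasonable choice noise,
#' whereas a log prior centered at 0 (beta near 1) would bias fits toward
#' near-deterministic choice and, through the beta-delta trade-off, shrink
#' the comparison bonus toward zero. The sign-constrained bias \code{lam}
#' uses a standard normal on the log scale; the additive comparison bonus
#' \code{delta} and first-item bonus \code{lam1} use the weakly informative
#' N(0, 5) in rating units; the overt-choice bonus \code{delta_overt}, an
#' order of magnitude larger, uses N(0, 25); the proportional saliency
#' bonus \code{gamma} uses N(0, 1). All entries can be edited before
#' passing the data.frame to \code{\link{fit_map}}.
#'
#' @param spec a \code{\link{model_spec}}.
#' @return data.frame with columns \code{param}, \code{transform},
#'   \code{mean}, \code{sd} (transformed scale).
#' @export
default_priors <- function(spec) {
  par <- spec$free_params
  transform <- vapply(par, function(p) {
    if (p %in% c("beta", "beta_c")) "log"
    else if (p == "lam") {
      if (spec$lam_sign >= 0) "logpos" else "logneg"
    } else "identity"
  }, "")
  sd <- vapply(par, function(p)
    switch(p, delta = 5, lam1 = 5, delta_overt = 25, 1), 0)
  mean <- vapply(par, function(p)
    if (p %in% c("beta", "beta_c")) log(0.1) else 0, 0)
  data.frame(param = par, transform = unname(transform),
             mean = unname(mean), sd = unname(sd), row.names = NULL)
}

# ---- generic multi-start MAP + Laplace evidence ------------------------

# Central-difference Hessian. The step is deliberately wide (5% of the
# parameter scale): the deterministic comparison models are only piecewise
# smooth, their MAP mode typically sits at a derivative kink, and a small
# step would measure the kink (curvature -> infinity with 1/h) instead of
# the curvature of the surrounding likelihood. A wide step averages over
# the kink; for smooth (e.g. quadratic) log-joints the formula stays
# accurate to O(h^2) and exact in the Gaussian case.
num_hessian <- function(fn, x, h = 0.05) {
  d <- length(x)
  H <- matrix(0, d, d)
  hi <- h * (1 + abs(x))
  f0 <- fn(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- hi[i]
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / hi[i]^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- numeric(d); ej[j] <- hi[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) +
           fn(x - ei - ej)) / (4 * hi[i] * hi[j])
    }
  }
  H
}

#' Multi-start MAP with Laplace-approximate log evidence
#'
#' Maximizes an arbitrary log-joint (log-likelihood plus log-prior) over an
#' unconstrained parameter vector from several starting points, then
#' applies the Laplace approximation to the evidence:
#' F = logjoint(mode) + d/2 log(2 pi) - 1/2 log det(H), with H the negative
#' Hessian of the log-joint at the mode (computed by central finite
#' differences; the diagonal is jittered if H is not positive definite).
#'
#' Because some likelihoods in the family are only piecewise smooth (the
#' deterministic comparison winners flip at critical parameter values),
#' starting points are chosen by screening a pool of candidate points drawn
#' around \code{start} and keeping the best \code{n_starts} for full
#' quasi-Newton runs.
#'
#' @param logjoint function of the parameter vector returning a scalar.
#' @param start numeric starting vector (always among the candidates;
#'   further candidates are Gaussian perturbations with standard deviation
#'   \code{start_sd}).
#' @param n_starts number of optimizer starts (default 5).
#' @param start_sd perturbation scale for the candidate pool.
#' @param n_candidates size of the screened candidate pool.
#' @param seed optional RNG seed for the perturbations.
#' @return list with \code{mode}, \code{logjoint} (at the mode),
#'   \code{free_energy}, \code{hessian}, \code{cov} (inverse Hessian),
#'   \code{converged}.
#' @export
laplace_fit <- function(logjoint, start, n_starts = 5L, start_sd = 1,
                        n_candidates = max(30L, 6L * n_starts),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(start)
  neg <- function(x) {
    v <- logjoint(x)
    if (!is.finite(v)) 1e10 else -v
  }
  cand <- rbind(start,
                t(start + matrix(rnorm(d * (n_candidates - 1L)), d) *
                    start_sd))
  ord <- order(apply(cand, 1L, neg))
  best <- NULL
  for (s in seq_len(min(n_starts, nrow(cand)))) {
    x0 <- cand[ord[s], ]
    o <- tryCatch(
      stats::optim(x0, neg, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish with a simplex pass, which tolerates derivative kinks
  if (!is.null(best) && d > 1L) {
    o2 <- tryCatch(stats::optim(best$par, neg, method = "Nelder-Mead",
                                control = list(maxit = 300)),
                   error = function(e) NULL)
    if (!is.null(o2) && o2$value < best$value)
      best <- list(par = o2$par, value = o2$value,
                   convergence = best$convergence)
  }
  if (is.null(best))
    return(list(mode = start, logjoint = -Inf, free_energy = -Inf,
                hessian = diag(d), cov = diag(d), converged = FALSE))
  H <- num_hessian(neg, best$par)
  jitter <- 0
  repeat {
    ch <- tryCatch(chol(H + diag(jitter, d)), error = function(e) NULL)
    if (!is.null(ch)) break
    jitter <- if (jitter == 0) 1e-6 else jitter * 10
    if (jitter > 1e6) { ch <- NULL; break }
  }
  if (is.null(ch)) {
    logdet <- NA_real_
    covm <- diag(NA_real_, d)
    converged <- FALSE
  } else {
    logdet <- 2 * sum(log(diag(ch)))
    covm <- chol2inv(ch)
    converged <- best$convergence == 0
  }
  list(mode = unname(best$par), logjoint = -best$value,
       free_energy = -best$value + d / 2 * log(2 * pi) - logdet / 2,
       hessian = H, cov = covm, converged = converged)
}

# precompiled likelihood closure over the transformed parameters: builds
# the index matrices once and evaluates the compiled engine per call
make_loglik_fn <- function(spec, choices, session, items) {
  an <- which(!session$is_catch & session$trial_id %in% choices$trial_id)
  chosen_pos <- vapply(an, function(t) {
    ch <- choices$chosen[match(t, choices$trial_id)]
    p <- match(ch, session$sequences[[t]])
    if (is.na(p)) stop_invalid("trial %d: chosen item not in sequence", t)
    p
  }, 0L)
  base <- as.numeric(model_params())
  free_idx <- match(spec$free_params,
                    c("beta", "lam", "lam1", "delta", "delta_overt",
                      "gamma", "beta_c"))
  has_revisits <- any(vapply(session$sequences, anyDuplicated, 0L) > 0L)
  needs_choices <- spec$carry_mode %in% c("global", "two_level", "overt_only")
  if (!has_revisits) {
    sm <- session_matrix(session, items)
    chosen <- rep(0L, length(session$sequences))
    chosen[choices$trial_id] <- match(choices$chosen, items$item_id)
    mcode <- .model_code[[spec$update]]
    ccode <- .carry_code[[spec$carry_mode]]
    winit <- spec$winner_rule == "initial"
    fb <- spec$first_bonus
    function(native) {
      par <- base
      par[free_idx] <- native
      pm <- cc_engine(mcode, ccode, items$rating, sm$seqm, sm$len,
                      chosen, par, fb, winit)
      sum(log(pm[cbind(an, chosen_pos)]))
    }
  } else {
    function(native) {
      par <- base
      par[free_idx] <- native
      params <- structure(setNames(par, names(model_params())),
                          class = "cc_params")
      as.numeric(loglik(spec, params, choices, session, items, engine = "R"))
    }
  }
}

#' MAP fit of one model to one subject's choices
#'
#' Maximizes the posterior of the model's free parameters (Gaussian priors
#' on the transformed scale, see \code{\link{default_priors}}) over the
#' analyzed trials of a session, and returns the Laplace-approximate log
#' model evidence (free energy), which trades off goodness of fit against
#' model complexity.
#'
#' @inheritParams loglik
#' @param priors prior specification, see \code{\link{default_priors}}.
#' @param n_starts optimizer restarts (default 5).
#' @param seed optional RNG seed (restart perturbations).
#' @param subject_id identifier carried into the result.
#' @return object of class \code{cc_fit}: \code{posterior_mean} (free
#'   parameters, native scale), \code{posterior_cov} (transformed scale),
#'   \code{free_energy}, \code{loglik} at the mode, \code{n_trials},
#'   \code{converged}.
#' @export
fit_map <- function(spec, choices, session, items,
                    priors = default_priors(spec), n_starts = 5L,
                    seed = NULL, subject_id = NA) {
  llfn <- make_loglik_fn(spec, choices, session, items)
  lj <- function(theta) {
    native <- to_native(theta, priors)
    llfn(native) + sum(stats::dnorm(theta, priors$mean, priors$sd, log = TRUE))
  }
  fit <- laplace_fit(lj, start = priors$mean, n_starts = n_starts,
                     start_sd = priors$sd, seed = seed)
  native <- to_native(fit$mode, priors)
  full <- model_params()
  full[match(priors$param, names(full))] <- native
  structure(list(subject_id = subject_id, model = spec$name, spec = spec,
                 posterior_mean = native, params = full,
                 posterior_cov = fit$cov, free_energy = fit$free_energy,
                 loglik = llfn(native),
                 n_trials = sum(!session$is_catch &
                                  session$trial_id %in% choices$trial_id),
                 converged = fit$converged),
            class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("<fit %s> F = %.2f, logLik = %.2f, %d trials%s\n  ",
              x$model, x$free_energy, x$loglik, x$n_trials,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$posterior_mean, 4))
  invisible(x)
}

#' Fit several models to every subject of a group
#'
#' @param subjects list of subjects (\code{items}, \code{session},
#'   \code{choices}), as from \code{\link{simulate_group}}.
#' @param models character vector of model names (see
#'   \code{\link{model_names}}) or list of \code{\link{model_spec}}s.
#' @param n_starts,seed passed to \code{\link{fit_map}}.
#' @return list with \code{evidence} (subjects x models matrix of free
#'   energies) and \code{fits} (list of lists of \code{cc_fit}).
#' @export
fit_group <- function(subjects, models, n_starts = 5L, seed = NULL) {
  if (is.character(models)) models <- lapply(models, model_spec)
  mnames <- vapply(models, function(m) m$name, "")
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(seq_along(subjects), function(i) {
    sub <- subjects[[i]]
    lapply(models, function(spec)
      fit_map(spec, sub$choices, sub$session, sub$items,
              n_starts = n_starts, subject_id = i))
  })
  ev <- do.call(rbind, lapply(fits, function(f)
    vapply(f, function(x) x$free_energy, 0)))
  colnames(ev) <- mnames
  list(evidence = ev, fits = fits)
}
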