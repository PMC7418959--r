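#' Random-effects Bayesian model selection
#'
#' Group-level random-effects comparison of models from per-subject log
#' model evidences. Model frequencies in the population get a Dirichlet
#' prior (count \code{prior_count} per model); the posterior Dirichlet is
#' obtained by variational updates in which each subject's model-assignment
#' responsibilities are proportional to exp(log-evidence + digamma terms),
#' iterated to convergence. Reported are the Dirichlet counts
#' \code{alpha}, the expected model frequencies \code{ef} = alpha /
#' sum(alpha), and the exceedance probabilities \code{ep} -- the
#' probability that each model is the most frequent in the population --
#' estimated by Monte-Carlo sampling from the posterior Dirichlet.
#'
#' Subjects with any non-finite evidence are excluded with a warning. The
#' result is invariant to adding a constant to a subject's evidence row.
#'
#' @param log_evidence subjects x models matrix of log model evidences
#'   (e.g. free energies from \code{\link{fit_group}}).
#' @param prior_count Dirichlet prior count per model (default 1, uniform).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities
#'   (default 1e6).
#' @param seed optional RNG seed for the Monte-Carlo step.
#' @param tol,max_iter convergence controls of the variational iteration.
#' @return object of class \code{cc_bms}: list with \code{alpha},
#'   \code{ef}, \code{ep}, \code{models}, \code{n_subjects}.
#' @export
bms <- function(log_evidence, prior_count = 1, n_samples = 1e6,
                seed = NULL, tol = 1e-8, max_iter = 500L) {
  if (is.null(dim(log_evidence)) || ncol(log_evidence) < 2L)
    stop_invalid("need a subjects x models matrix with >= 2 models")
  keep <- apply(is.finite(log_evidence), 1L, all)
  if (!all(keep)) {
    warning(sprintf("excluding %d subject(s) with non-finite evidence",
                    sum(!keep)))
    log_evidence <- log_evidence[keep, , drop = FALSE]
  }
  n <- nrow(log_evidence); K <- ncol(log_evidence)
  if (n < 1L) stop_invalid("no subjects with finite evidence")
  alpha0 <- rep(prior_count, K)
  alpha <- alpha0 + n / K
  for (it in seq_len(max_iter)) {
    w <- sweep(log_evidence, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1L, max)
    z <- exp(w)
    z <- z / rowSums(z)
    alpha_new <- alpha0 + colSums(z)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  ef <- alpha / sum(alpha)
  ep <- dirichlet_exceedance(alpha, n_samples = n_samples, seed = seed)
  structure(list(alpha = alpha, ef = ef, ep = ep,
                 models = colnames(log_evidence), n_subjects = n,
                 prior_count = prior_count, n_samples = n_samples),
            class = "cc_bms")
}

# Monte-Carlo exceedance probabilities of a Dirichlet(alpha), chunked to
# bound memory
dirichlet_exceedance <- function(alpha, n_samples = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(alpha)
  wins <- numeric(K)
  left <- n_samples
  while (left > 0) {
    m <- min(left, 1e5)
    g <- matrix(rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    idx <- max.col(g, ties.method = "first")
    wins <- wins + tabulate(idx, K)
    left <- left - m
  }
  wins / n_samples
}

#' @export
print.cc_bms <- function(x, ...) {
  m <- rbind(alpha = x$alpha, Ef = x$ef, Ep = x$ep)
  colnames(m) <- x$models
  cat(sprintf("<bms> %d subjects, %d models\n", x$n_subjects, length(x$alpha)))
  print(round(m, 4))
  invisible(x)
}

#' Model recovery analysis
#'
#' Simulates groups of subjects under each generating model, fits every
#' model of the comparison space to every subject, runs random-effects
#' Bayesian model selection per group, and tabulates how often each model
#' wins (exceedance probability above \code{ep_threshold}) when each model
#' generated the data. Groups without a winner above threshold are left
#' out of the count, so column sums may be below 1.
#'
#' @param models comparison space: character vector of model names.
#' @param generate_from models to simulate from (default: all of
#'   \code{models}).
#' @param gen_params named list of \code{\link{model_params}} per
#'   generating model; defaults to the package's generating values
#'   (inverse temperature 0.081 with fitted-scale bonus/bias values).
#' @param n_groups simulated groups per generating model.
#' @param n_subjects subjects per group (default 30).
#' @param profile task variant (default "exp1").
#' @param seed RNG seed.
#' @param ep_threshold winning criterion on the exceedance probability
#'   (default 0.95).
#' @param n_starts optimizer restarts per fit.
#' @param skew rating skew of the simulated subjects.
#' @return object of class \code{cc_recovery}: \code{confusion} (rows =
#'   winning model plus "none", columns = simulated model, win rates over
#'   groups), \code{details} per group, \code{n_groups},
#'   \code{ep_threshold}.
#' @export
model_recovery <- function(models = c("H0", "H1", "H2", "H2.1", "H3"),
                           generate_from = models, gen_params = NULL,
                           n_groups = 10L, n_subjects = 30L,
                           profile = "exp1", seed = 1L,
                           ep_threshold = 0.95, n_starts = 5L, skew = 0.3) {
  set.seed(seed)
  specs <- lapply(models, model_spec)
  confusion <- matrix(0, length(models) + 1L, length(generate_from),
                      dimnames = list(c(models, "none"), generate_from))
  details <- list()
  for (gen in generate_from) {
    pars <- gen_params[[gen]] %||% default_generating_params(gen)
    for (g in seq_len(n_groups)) {
      subjects <- simulate_group(model_spec(gen), pars, n_subjects,
                                 profile = profile, skew = skew)
      fg <- fit_group(subjects, specs, n_starts = n_starts)
      b <- bms(fg$evidence, n_samples = 1e5)
      win <- if (max(b$ep) > ep_threshold) models[which.max(b$ep)] else "none"
      confusion[win, gen] <- confusion[win, gen] + 1 / n_groups
      details[[length(details) + 1L]] <-
        data.frame(generated = gen, group = g, winner = win,
                   max_ep = max(b$ep))
    }
  }
  structure(list(confusion = confusion, details = do.call(rbind, details),
                 n_groups = n_groups, ep_threshold = ep_threshold),
            class = "cc_recovery")
}

#' @export
print.cc_recovery <- function(x, ...) {
  cat(sprintf("<model recovery> %d groups per model, Ep > %.2f\n",
              x$n_groups, x$ep_threshold))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Parameter recovery for one model
#'
#' Simulates a group under known parameters, refits the same model to each
#' subject, and returns the per-subject posterior means next to the
#' generating values.
#'
#' @inheritParams model_recovery
#' @param spec a \code{\link{model_spec}}.
#' @param params generating \code{\link{model_params}}.
#' @param n_sessions category sessions per subject (the full first task
#'   variant comprised five).
#' @return data.frame: one row per subject, fitted free parameters on the
#'   native scale; generating values in attribute \code{"generating"}.
#' @export
parameter_recovery <- function(spec, params, n_subjects = 30L,
                               profile = "exp1", seed = 1L, n_starts = 5L,
                               skew = 0.3, n_sessions = 1L) {
  set.seed(seed)
  subjects <- simulate_group(spec, params, n_subjects, profile = profile,
                             skew = skew, n_sessions = n_sessions)
  fits <- lapply(seq_along(subjects), function(i)
    fit_map(spec, subjects[[i]]$choices, subjects[[i]]$session,
            subjects[[i]]$items, n_starts = n_starts, subject_id = i))
  out <- as.data.frame(do.call(rbind, lapply(fits, function(f)
    f$posterior_mean)))
  out$converged <- vapply(fits, function(f) f$converged, TRUE)
  attr(out, "generating") <- params[spec$free_params]
  out
}
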