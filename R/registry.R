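# Model registry: every model in the family, addressable by name.
#
# name          update rule                         carry-over   free parameters
# H0            none (initial ratings)              local        beta
# H1            + lam / s_i (lam > 0, primacy)      local        beta, lam
# H1a           + lam ^ s_i                         local        beta, lam
# H1b           * (1 + lam / s_i)                   local        beta, lam
# H1.1          H1 + first-item bonus lam1          local        beta, lam, lam1
# H1rec         + lam / s_i (lam < 0, recency)      local        beta, lam
# H2            pairwise bonus +/- delta            local        beta, delta
# H2.1          H2 + first-option bonus             local        beta, delta
# H2.1prob      probabilistic covert comparisons    local        beta, beta_c, delta
# H3            pruning (elimination)               local        beta
# SAL           best-option saliency bonus gamma    local        beta, gamma
# H2.1global    H2.1, covert updates persist        global       beta, delta
# H2.1twolevel  H2.1 local + overt bonus persists   two_level    beta, delta, delta_overt
# HYBRID        overt bonus only                    overt_only   beta, delta_overt

.model_table <- list(
  "H0"           = list(carry = "local",      free = "beta",
                        update = "none", first_bonus = FALSE, lam_sign = 0),
  "H1"           = list(carry = "local",      free = c("beta", "lam"),
                        update = "H1", first_bonus = FALSE, lam_sign = 1),
  "H1a"          = list(carry = "local",      free = c("beta", "lam"),
                        update = "H1a", first_bonus = FALSE, lam_sign = 1),
  "H1b"          = list(carry = "local",      free = c("beta", "lam"),
                        update = "H1b", first_bonus = FALSE, lam_sign = 1),
  "H1.1"         = list(carry = "local",      free = c("beta", "lam", "lam1"),
                        update = "H1.1", first_bonus = FALSE, lam_sign = 1),
  "H1rec"        = list(carry = "local",      free = c("beta", "lam"),
                        update = "H1", first_bonus = FALSE, lam_sign = -1),
  "H2"           = list(carry = "local",      free = c("beta", "delta"),
                        update = "bonus", first_bonus = FALSE, lam_sign = 0),
  "H2.1"         = list(carry = "local",      free = c("beta", "delta"),
                        update = "bonus", first_bonus = TRUE, lam_sign = 0),
  "H2.1prob"     = list(carry = "local",      free = c("beta", "beta_c", "delta"),
                        update = "prob_bonus", first_bonus = TRUE, lam_sign = 0),
  "H3"           = list(carry = "local",      free = "beta",
                        update = "pruning", first_bonus = FALSE, lam_sign = 0),
  "SAL"          = list(carry = "local",      free = c("beta", "gamma"),
                        update = "saliency", first_bonus = FALSE, lam_sign = 0),
  "H2.1global"   = list(carry = "global",     free = c("beta", "delta"),
                        update = "bonus", first_bonus = TRUE, lam_sign = 0),
  "H2.1twolevel" = list(carry = "two_level",  free = c("beta", "delta", "delta_overt"),
                        update = "bonus", first_bonus = TRUE, lam_sign = 0),
  "HYBRID"       = list(carry = "overt_only", free = c("beta", "delta_overt"),
                        update = "none", first_bonus = FALSE, lam_sign = 0)
)

#' Model names available in the registry
#' @return character vector of model names.
#' @export
model_names <- function() names(.model_table)

#' Model specification
#'
#' Looks a model up in the registry and returns its specification: update
#' rule, carry-over mode and free parameters. The carry-over mode controls
#' what persists across trials: \code{local} resets all values to initial
#' ratings at every trial start; \code{global} persists the covert
#' comparison updates; \code{two_level} keeps covert updates local but
#' persists a separate overt-choice bonus \code{delta_overt}; and
#' \code{overt_only} persists only the overt-choice bonus.
#'
#' @param name model name, one of \code{model_names()}.
#' @param carry_mode optional override of the registry carry-over mode.
#' @param winner_rule how deterministic covert comparisons are decided: on
#'   the \code{"initial"} ratings (default; keeps the likelihood smooth in
#'   the bonus) or on the \code{"current"} (updated) values.
#' @return an object of class \code{cc_model_spec}.
#' @export
#' @examples
#' model_spec("H2.1")
model_spec <- function(name, carry_mode = NULL,
                       winner_rule = c("initial", "current")) {
  if (!name %in% names(.model_table))
    stop_invalid("unknown model '%s'; see model_names()", name)
  entry <- .model_table[[name]]
  carry_mode <- carry_mode %||% entry$carry
  if (!carry_mode %in% c("local", "global", "two_level", "overt_only"))
    stop_invalid("unknown carry_mode '%s'", carry_mode)
  structure(list(name = name, update = entry$update, carry_mode = carry_mode,
                 free_params = entry$free, first_bonus = entry$first_bonus,
                 lam_sign = entry$lam_sign,
                 winner_rule = match.arg(winner_rule)),
            class = "cc_model_spec")
}

#' @export
print.cc_model_spec <- function(x, ...) {
  cat(sprintf("<model %s>  update: %s, carry: %s, free: %s\n", x$name,
              x$update, x$carry_mode, paste(x$free_params, collapse = ", ")))
  invisible(x)
}

#' Model parameters
#'
#' Full parameter set of the model family; each model uses the subset named
#' in its \code{free_params}. Units: values live on the 0-100 likeability
#' scale, so \code{lam}, \code{lam1}, \code{delta} and \code{delta_overt}
#' are in rating units, \code{gamma} is a proportional bonus, and
#' \code{beta}, \code{beta_c} are inverse temperatures in 1/rating units.
#'
#' @param beta overt-choice inverse temperature (>= 0).
#' @param lam serial-position bias magnitude.
#' @param lam1 extra first-item bonus.
#' @param delta covert-comparison bonus.
#' @param delta_overt overt-choice bonus (two-level / hybrid models).
#' @param gamma saliency bonus.
#' @param beta_c covert-comparison inverse temperature (>= 0).
#' @return an object of class \code{cc_params} (named numeric vector).
#' @export
model_params <- function(beta = 0.081, lam = 0, lam1 = 0, delta = 0,
                         delta_overt = 0, gamma = 0, beta_c = 0.24) {
  if (beta < 0 || beta_c < 0) stop_invalid("beta and beta_c must be >= 0")
  structure(c(beta = beta, lam = lam, lam1 = lam1, delta = delta,
              delta_overt = delta_overt, gamma = gamma, beta_c = beta_c),
            class = "cc_params")
}

# generating parameters used by default in simulations and recovery:
# beta from the winning-model fit reported for the first task variant;
# delta likewise (0.59); delta/beta_c for the probabilistic variant (0.57,
# 0.24); delta_overt ~ 25 (overt bonus scale); lam/lam1/gamma chosen to
# give serial-position effects of comparable size to the bonus models.
default_generating_params <- function(name) {
  base <- list(beta = 0.081, lam = 0, lam1 = 0, delta = 0, delta_overt = 0,
               gamma = 0, beta_c = 0.24)
  extra <- switch(name,
    "H1" = , "H1b" = list(lam = 6),
    "H1a" = list(lam = 0.9),
    "H1.1" = list(lam = 6, lam1 = 6),
    "H1rec" = list(lam = -6),
    "H2" = , "H2.1" = , "H2.1global" = list(delta = 0.59),
    "H2.1prob" = list(delta = 0.57, beta_c = 0.24),
    "SAL" = list(gamma = 0.1),
    "H2.1twolevel" = list(delta = 0.48, delta_overt = 24.73),
    "HYBRID" = list(delta_overt = 24.73),
    list())
  do.call(model_params, modifyList(base, extra))
}
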