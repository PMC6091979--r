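#' Trial-by-trial updating rules for starting point and rate
#'
#' Six factor levels describe how stimulus history modulates the evidence
#' accumulator, applied separately to the response-defining feature (RDF)
#' and the target-defining dimension (TDD):
#'
#' * `no_update` -- no modulation.
#' * `s0_full_memory` -- the starting point is the log prior odds of the
#'   trial's correct response class, with the prior learned by Bayesian
#'   updating of a Beta hyperprior over the Bernoulli rate (one free
#'   parameter, the initial symmetric shape `beta0`).
#' * `s0_decay` -- as above plus Dynamic-Belief-Model forgetting: before
#'   each trial the hyperprior is mixed with the initial distribution with
#'   weight `1 - alpha` (parameters `alpha`, `beta0`).
#' * `rate_binary` -- the accumulation rate is scaled by `kappa0 < 1` on
#'   trials where the update variable switched from the immediately
#'   preceding trial, and by 1 on repeats (parameter `kappa0`).
#' * `rate_decay` -- a scaling factor `kappa` (start 1) is increased by
#'   `delta` after each repetition and decreased by `delta` after each
#'   switch, with exponential forgetting toward 1 (parameters `alpha`,
#'   `delta`).
#' * `rate_weighted` -- one scaling factor per update-variable value, with
#'   the pair summing to 2 (a shared weight resource); after each trial
#'   `delta` is moved toward the value that occurred, with the same
#'   forgetting rule (parameters `alpha`, `delta`).
#'
#' The hyperprior is represented on a uniform grid of 401 midpoints on
#' (0, 1); with `alpha = 1` the grid updates agree with the conjugate
#' Beta closed forms to well below 1e-3.
#'
#' @name updating-rules
NULL

.n_grid_default <- 401L

#' Log prior odds
#'
#' The starting-point offset implied by a prior probability `p_hat` of the
#' trial's correct response class: `log(p_hat / (1 - p_hat))`.
#'
#' @param p_hat prior probability, strictly inside (0, 1).
#' @return log prior odds in evidence units.
#' @export
log_prior_odds <- function(p_hat) {
  if (any(p_hat <= 0 | p_hat >= 1)) stop("p_hat must lie strictly in (0, 1)")
  log(p_hat / (1 - p_hat))
}

#' Discretized hyperprior over a Bernoulli rate
#'
#' State for the starting-point updating levels: a grid of probabilities
#' with weights initialized from a symmetric Beta(`beta0`, `beta0`), with
#' forgetting persistence `alpha` (1 = full memory).
#'
#' @param beta0 initial symmetric Beta shape, > 0.
#' @param alpha memory persistence between 0 (instant forgetting) and 1 (full memory).
#' @param n_grid number of grid midpoints.
#' @return object of class `belief_state` with elements `p`, `w`, `w0`,
#'   `alpha`, `beta0`.
#' @export
belief_state <- function(beta0, alpha = 1, n_grid = .n_grid_default) {
  stopifnot(beta0 > 0, alpha >= 0, alpha <= 1)
  p <- (seq_len(n_grid) - 0.5) / n_grid
  w0 <- dbeta(p, beta0, beta0)
  w0 <- w0 / sum(w0)
  structure(list(p = p, w = w0, w0 = w0, alpha = alpha, beta0 = beta0),
            class = "belief_state")
}

#' @describeIn belief_state expected value of the hyperprior (the current
#'   point estimate of the Bernoulli rate).
#' @param state a `belief_state`.
#' @export
belief_p_hat <- function(state) sum(state$p * state$w)

#' @describeIn belief_state forgetting step: mix the current weights with
#'   the initial distribution, weight `1 - alpha` (applied before each
#'   trial's starting point is read).
#' @export
belief_predict <- function(state) {
  state$w <- state$alpha * state$w + (1 - state$alpha) * state$w0
  state
}

#' @describeIn belief_state Bayes step with a Bernoulli likelihood:
#'   reweight by `p` for outcome `"u1"` or `1 - p` for `"u2"`, then
#'   renormalize.
#' @param outcome `"u1"` or `"u2"`.
#' @export
belief_observe <- function(state, outcome) {
  stopifnot(outcome %in% c("u1", "u2"))
  lik <- if (outcome == "u1") state$p else 1 - state$p
  w <- state$w * lik
  state$w <- w / sum(w)
  state
}

.eps_kappa <- 1e-3

#' Rate-updating state
#'
#' State for the rate-scaling levels. `mode = "binary"` tracks only the
#' previous update-variable value; `"decay"` carries a single scaling
#' factor; `"weighted"` carries one factor per value with the pair
#' constrained to sum to 2.
#'
#' @param mode `"binary"`, `"decay"` or `"weighted"`.
#' @param kappa0 switch scaling in (0, 1) (binary mode).
#' @param alpha memory persistence between 0 (instant forgetting) and 1 (full memory) (decay/weighted).
#' @param delta per-trial increment, >= 0 (decay/weighted).
#' @return object of class `rate_state`.
#' @export
rate_state <- function(mode = c("binary", "decay", "weighted"),
                       kappa0 = 0.8, alpha = 1, delta = 0.1) {
  mode <- match.arg(mode)
  if (mode == "binary") stopifnot(kappa0 > 0, kappa0 < 1)
  stopifnot(alpha >= 0, alpha <= 1, delta >= 0)
  structure(list(mode = mode, kappa0 = kappa0, alpha = alpha, delta = delta,
                 kappa = 1, kappa_pair = c(1, 1), last_uv = "none"),
            class = "rate_state")
}

#' One step of the binary rate rule
#'
#' Scaling is `kappa0` when the update variable switched relative to the
#' immediately preceding applicable trial and 1 otherwise (including the
#' first trial, which has no predecessor).
#'
#' @param state a `rate_state` with `mode = "binary"`.
#' @param uv `"u1"` or `"u2"`, the trial's update-variable value.
#' @param uv_applies whether the rule applies on this trial (for
#'   dimension-based updating: target-present trials only). On
#'   non-applicable trials the scaling is 1 and the predecessor memory is
#'   cleared (the binary rule requires an *immediately* preceding
#'   applicable trial).
#' @return list with `scaling` and the updated `state`.
#' @export
rate_step_binary <- function(state, uv, uv_applies = TRUE) {
  stopifnot(state$mode == "binary")
  if (!uv_applies) {
    state$last_uv <- "none"
    return(list(scaling = 1, state = state))
  }
  scaling <- if (state$last_uv != "none" && uv != state$last_uv) state$kappa0 else 1
  state$last_uv <- uv
  list(scaling = scaling, state = state)
}

#' One step of the decaying rate rule
#'
#' The current factor `kappa` scales this trial's rate; afterwards it is
#' incremented by `delta` on a repetition of the update variable (or
#' decremented on a switch) and pulled toward 1 by the forgetting rule
#' `kappa <- alpha * kappa + (1 - alpha)`. On non-applicable trials (e.g.
#' target-absent trials under dimension-based updating) no `delta` step
#' and no scaling occur, but the forgetting step still runs; the
#' repetition comparison is with the most recent applicable trial.
#'
#' @inheritParams rate_step_binary
#' @export
rate_step_decay <- function(state, uv, uv_applies = TRUE) {
  stopifnot(state$mode == "decay")
  scaling <- if (uv_applies) max(state$kappa, .eps_kappa) else 1
  ku <- state$kappa
  if (uv_applies && state$last_uv != "none") {
    ku <- ku + if (uv == state$last_uv) state$delta else -state$delta
  }
  state$kappa <- state$alpha * ku + (1 - state$alpha)
  if (uv_applies) state$last_uv <- uv
  list(scaling = scaling, state = state)
}

#' One step of the weighted (shared-resource) rate rule
#'
#' Each update-variable value has its own scaling factor and the two sum
#' to 2 at every step. The factor for the value that occurred is
#' incremented by `delta` and the other decremented, followed by the same
#' forgetting rule as the decaying level. On non-applicable trials only
#' the forgetting step runs and no scaling is applied.
#'
#' @inheritParams rate_step_binary
#' @return list with `scaling` (the factor for this trial's value, or 1
#'   when not applicable), `kappa_pair`, and the updated `state`.
#' @export
rate_step_weighted <- function(state, uv, uv_applies = TRUE) {
  stopifnot(state$mode == "weighted")
  i <- if (uv == "u1") 1L else 2L
  scaling <- if (uv_applies) max(state$kappa_pair[i], .eps_kappa) else 1
  ku <- state$kappa_pair
  if (uv_applies) ku <- ku + c(1, -1) * (if (i == 1L) 1 else -1) * state$delta
  state$kappa_pair <- state$alpha * ku + (1 - state$alpha)
  list(scaling = scaling, kappa_pair = state$kappa_pair, state = state)
}

.rule_levels <- c("no_update", "s0_full_memory", "s0_decay",
                  "rate_binary", "rate_decay", "rate_weighted")

#' Parameters required by each updating level
#'
#' @param level one of the six level names.
#' @return character vector of parameter names (empty for `no_update`).
#' @export
rule_params <- function(level) {
  switch(match.arg(level, .rule_levels),
         no_update = character(0),
         s0_full_memory = "beta0",
         s0_decay = c("alpha", "beta0"),
         rate_binary = "kappa0",
         rate_decay = c("alpha", "delta"),
         rate_weighted = c("alpha", "delta"))
}

#' Updating-rule specification for one scope
#'
#' @param level one of `"no_update"`, `"s0_full_memory"`, `"s0_decay"`,
#'   `"rate_binary"`, `"rate_decay"`, `"rate_weighted"`.
#' @param params named list/vector of the level's parameters (see
#'   [rule_params()]); may be empty for `no_update`.
#' @return object of class `update_rule_spec`.
#' @export
update_rule <- function(level, params = list()) {
  level <- match.arg(level, .rule_levels)
  need <- rule_params(level)
  params <- as.list(params)
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("level ", level, " needs parameter(s): ", paste(missing, collapse = ", "))
  }
  structure(list(level = level, params = params[need]), class = "update_rule_spec")
}

rule_level_code <- function(level) match(level, .rule_levels) - 1L

rule_par_vector <- function(rule) {
  as.numeric(unlist(rule$params[rule_params(rule$level)], use.names = FALSE))
}

#' Per-trial accumulator modulations from the two updating rules
#'
#' Runs the RDF-scope and TDD-scope updating rules over a participant's
#' full trial sequence (in presentation order, across block and section
#' boundaries) and returns, for every trial, the starting-point offset
#' `s0` (summed over active starting-point rules, expressed toward the
#' trial's correct response boundary) and the rate scaling `kappa`
#' (product of the active rate rules). Updating consumes the stimulus
#' truth only -- never responses -- and sees every trial, including error
#' and outlier trials.
#'
#' The per-trial order is: forgetting (predictive prior) for belief
#' states, then the modulations for the current trial are read, then the
#' Bayes / rate-step updates are applied with the trial's true stimulus
#' values.
#'
#' @param rdf_rule,tdd_rule `update_rule` objects for the response-defining
#'   feature and target-defining dimension scopes.
#' @param trials trial (or schedule) table for one participant; must carry
#'   `experiment`/`target_present`/`target_dimension` columns (the RDF
#'   value is derived via [rdf_value()]).
#' @param n_grid hyperprior grid size.
#' @return list with numeric vectors `s0` and `kappa` (one per trial) and
#'   state-trajectory matrices `rdf_traj`, `tdd_traj` (hyperprior means
#'   for starting-point levels, scaling factors for rate levels).
#' @export
apply_rules <- function(rdf_rule, tdd_rule, trials, n_grid = .n_grid_default) {
  stopifnot(inherits(rdf_rule, "update_rule_spec"),
            inherits(tdd_rule, "update_rule_spec"))
  uv <- ifelse(rdf_value(trials) == "u1", 1L, 2L)
  dim_code <- match(trials$target_dimension, c("color", "orientation"))
  dim_code[is.na(dim_code)] <- 0L
  apply_rules_cpp(uv, as.integer(dim_code), trials$target_present,
                  rule_level_code(rdf_rule$level), rule_par_vector(rdf_rule),
                  rule_level_code(tdd_rule$level), rule_par_vector(tdd_rule),
                  as.integer(n_grid))
}
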