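# Shared small synthetic data set: one participant, no-update LATER+nd,
# short Exp-3 session (6 blocks, 390 trials).
local_trials <- local({
  spec <- model_spec("LATER", "with")
  cfg <- generator_config("exp3_detection_mixed", spec, n_participants = 1,
                          n_blocks = 6, seed = 77)
  list(spec = spec, cfg = cfg,
       trials = simulate_participant(cfg, 1234, "p01"))
})

test_that("negative log-likelihood is additive over included trials", {
  spec <- local_trials$spec
  trials <- local_trials$trials
  pars <- default_true_params(spec, "exp3_detection_mixed")
  inc <- modeling_outlier_mask(trials)

  base <- negloglik(spec, pars, trials, include = inc)
  # masking one trial removes exactly that trial's term
  i <- which(inc)[10]
  inc2 <- inc; inc2[i] <- FALSE
  drop1 <- negloglik(spec, pars, trials, include = inc2)
  p <- later_params(1, 6.5, 1.3, 0.3)
  expect_equal(base - drop1, -later_logpdf(trials$rt[i], p), tolerance = 1e-10)

  # doubling the data doubles the likelihood at fixed parameters
  tr2 <- rbind(trials, trials)
  tr2$block <- c(trials$block, trials$block + max(trials$block) + 1L)
  expect_equal(negloglik(spec, pars, tr2, include = rep(inc, 2)),
               2 * base, tolerance = 1e-8)

  # an included trial faster than t_er drives the likelihood to +Inf
  tr3 <- trials; tr3$rt[which(inc)[1]] <- 0.25
  expect_identical(negloglik(spec, pars, tr3, include = inc), Inf)
})

test_that("the likelihood prefers the generating parameters (dominance oracle)", {
  spec <- local_trials$spec
  trials <- local_trials$trials
  pars <- default_true_params(spec, "exp3_detection_mixed")
  inc <- modeling_outlier_mask(trials)
  base <- negloglik(spec, pars, trials, include = inc)

  set.seed(55)
  worse <- 0
  for (i in 1:100) {
    pert <- pars
    j <- sample(length(pars), 1)
    pert[j] <- pars[j] * runif(1, 0.8, 1.2)
    if (negloglik(spec, pert, trials, include = inc) >= base - 1e-9) {
      worse <- worse + 1
    }
  }
  expect_gte(worse, 95)
})

test_that("fitting recovers no-update parameters and is a likelihood fixed point", {
  spec <- local_trials$spec
  trials <- local_trials$trials
  fit <- fit_model(spec, trials, options = fit_options(n_restarts = 1))
  expect_s3_class(fit, "intertrial_fit")
  expect_true(fit$converged)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  expect_equal(fit$n_params, 10)  # 9 inner + t_er

  # rate ratio D/mu sets the RT scale; recover it within 10% per class
  for (cl in c("absent", "color", "orientation")) {
    ratio <- fit$params[paste0(cl, ".D")] / fit$params[paste0(cl, ".mu")]
    expect_equal(unname(ratio), 1 / 6.5, tolerance = 0.1)
  }
  expect_gt(fit$params["t_er"], 0.2)
  expect_lt(fit$params["t_er"], 0.4)

  # idempotence: the fitted likelihood equals negloglik at the fitted params
  nll <- negloglik(spec, fit$params, trials)
  expect_equal(-nll, fit$loglik, tolerance = 1e-6)

  # reproducibility under fixed options
  fit2 <- fit_model(spec, trials, options = fit_options(n_restarts = 1))
  expect_equal(fit2$params, fit$params, tolerance = 1e-10)
})

test_that("nesting: s0_decay at alpha = 0 never beats no_update's likelihood", {
  spec0 <- local_trials$spec
  trials <- local_trials$trials
  fit0 <- fit_model(spec0, trials, options = fit_options(n_restarts = 1))
  lay <- param_layout(model_spec("LATER", "with", "s0_decay"),
                      "exp3_detection_mixed")
  pinned <- c(fit0$params[1:9], fit0$params["t_er"],
              rdf_alpha = 0, rdf_beta0 = 2)
  names(pinned)[1:10] <- c(lay$inner, "t_er")
  nll_pinned <- negloglik(model_spec("LATER", "with", "s0_decay"),
                          pinned, trials)
  expect_equal(-nll_pinned, fit0$loglik, tolerance = 1e-6)
})

test_that("comparison table centers on the overall winner", {
  mk_fit <- function(pid, label, aic) {
    structure(list(spec = structure(list(accumulator = "LATER",
                                         nd_time = "with",
                                         rdf_level = label,
                                         tdd_level = "no_update"),
                                    class = "model_spec"),
                   participant_id = pid, aic = aic),
              class = "intertrial_fit")
  }
  fits <- list(mk_fit("p1", "no_update", 100), mk_fit("p1", "s0_decay", 110),
               mk_fit("p2", "no_update", 90), mk_fit("p2", "s0_decay", 120))
  cmp <- compare_models(fits)
  expect_identical(cmp$winner, "LATER+nd/rdf=no_update/tdd=no_update")
  expect_equal(cmp$table$mean_relative_aic, c(0, 20))

  # a missing (participant, spec) cell is an error
  expect_error(compare_models(fits[1:3]), "missing fit")
})

test_that("predicted cell means track observed means for the generating model", {
  trials <- local_trials$trials
  fit <- fit_model(local_trials$spec, trials,
                   options = fit_options(n_restarts = 1))
  cells <- predict_cell_means(fit, trials, n_draws = 60, seed = 2)
  expect_true(all(cells$predicted > fit$params["t_er"]))
  # a history-blind model and its data: predictions correlate with observation
  # across cells and sit within a few tens of ms on average
  expect_lt(mean(abs(cells$predicted - cells$observed)), 0.05)

  # no-update predictions do not differ systematically by inter-trial label
  agg <- tapply(cells$predicted, cells[c("condition", "intertrial")], mean)
  expect_lt(max(abs(agg[, "repeat"] - agg[, "switch"]), na.rm = TRUE), 0.02)
})
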