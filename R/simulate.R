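#' Generative simulator for complete synthetic experiments
#'
#' Produces participants x trials tables with RTs (and occasional errors)
#' from any model in the factorial space: the stimulus schedule comes
#' from the corresponding design generator, per-trial modulations from
#' the updating rules (driven by stimulus truth, exactly as in fitting),
#' and RTs from the model's accumulator. Errors arise from a lapse
#' process (response flipped, RT uniform on a lapse range) -- the
#' single-boundary LATER model cannot produce errors itself -- and, for
#' the DDM, additionally from natural absorption at the wrong boundary.
#' Updating proceeds across error trials unchanged.
#'
#' @name synthetic-data
NULL

#' Generator configuration
#'
#' Defaults emulate the observed error rates of the three experiments
#' (1.5-3.3%) via a 2% lapse rate, and the default accumulator
#' parameters put the median correct RT near 0.45 s.
#'
#' @param experiment experiment label (selects the design generator).
#' @param spec generating `model_spec`.
#' @param true_params named parameter vector/list covering
#'   [param_layout()] of `spec` (see [default_true_params()]).
#' @param n_participants number of simulated participants.
#' @param lapse_rate probability of a lapse per trial, between 0 and 0.1.
#' @param lapse_rt_range range (s) of uniform lapse RTs.
#' @param seed master integer seed.
#' @param section_order ratio permutation for Exps 1-2.
#' @param n_blocks Exp-3 block count.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(experiment, spec, true_params = NULL,
                             n_participants = 12, lapse_rate = 0.02,
                             lapse_rt_range = c(0.15, 2.0), seed = 1L,
                             section_order = c(0.75, 0.50, 0.25),
                             n_blocks = 20L) {
  stopifnot(experiment %in% .experiments,
            lapse_rate >= 0, lapse_rate <= 0.1,
            length(lapse_rt_range) == 2, diff(lapse_rt_range) > 0)
  if (is.null(true_params)) true_params <- default_true_params(spec, experiment)
  structure(list(experiment = experiment, spec = spec,
                 true_params = true_params, n_participants = n_participants,
                 lapse_rate = lapse_rate, lapse_rt_range = lapse_rt_range,
                 seed = as.integer(seed), section_order = section_order,
                 n_blocks = as.integer(n_blocks)),
            class = "generator_config")
}

#' Default generating parameters for a model specification
#'
#' LATER classes get `D = 1`, `mu = 6.5` (s^-1), `sigma = 1.3`; DDM
#' classes `a = 2`, `v = 6.5`, `s = 1.5`; `t_er = 0.3` s when the spec
#' has a non-decision time. Updating-rule defaults: `alpha = 0.8`,
#' `beta0 = 2`, `delta = 0.1`, `kappa0 = 0.8` (dimension-scope `alpha`
#' defaults to 0.9, matching the slower decay of dimension weighting).
#'
#' @param spec a `model_spec`.
#' @param experiment experiment label.
#' @return named parameter vector covering the spec's layout.
#' @export
default_true_params <- function(spec, experiment) {
  layout <- param_layout(spec, experiment)
  inner_def <- if (spec$accumulator == "LATER") {
    c(D = 1, mu = 6.5, sigma = 1.3)
  } else {
    c(a = 2, v = 6.5, s = 1.5)
  }
  vals <- setNames(rep(inner_def, length(layout$classes)), layout$inner)
  outer_def <- c(t_er = 0.3, rdf_alpha = 0.8, rdf_beta0 = 2, rdf_delta = 0.1,
                 rdf_kappa0 = 0.8, tdd_alpha = 0.9, tdd_beta0 = 2,
                 tdd_delta = 0.1, tdd_kappa0 = 0.8)
  c(vals, outer_def[layout$outer])
}

experiment_schedule <- function(cfg, seed) {
  switch(cfg$experiment,
         exp1_detection_blocked = generate_exp1_schedule(seed, cfg$section_order),
         exp2_dimension_discrimination = generate_exp2_schedule(seed, cfg$section_order),
         exp3_detection_mixed = generate_exp3_schedule(seed, cfg$n_blocks))
}

correct_response <- function(experiment, present, dimension) {
  if (experiment == "exp2_dimension_discrimination") dimension
  else ifelse(present, "present", "absent")
}

wrong_response <- function(experiment, truth) {
  if (experiment == "exp2_dimension_discrimination") {
    ifelse(truth == "color", "orientation", "color")
  } else {
    ifelse(truth == "present", "absent", "present")
  }
}

#' Simulate one participant
#'
#' @param cfg a [generator_config()].
#' @param participant_seed integer seed for this participant (schedule,
#'   RTs and lapses).
#' @param participant_id identifier stored in the output.
#' @return validated trial table (one participant).
#' @export
simulate_participant <- function(cfg, participant_seed,
                                 participant_id = "p01") {
  spec <- cfg$spec
  layout <- param_layout(spec, cfg$experiment)
  up <- unpack_params(layout, pack_params(layout, cfg$true_params,
                                          t_er_max = Inf))
  t_er <- if (spec$nd_time == "with") unname(up$outer["t_er"]) else 0

  sched <- experiment_schedule(cfg, participant_seed)
  sched$experiment <- cfg$experiment
  mod <- spec_modulations(spec, up$outer, sched, .n_grid_default)
  cls <- trial_class(sched)
  n <- nrow(sched)

  with_seed(participant_seed + 1L, {
    rt <- numeric(n)
    natural_error <- logical(n)
    for (cl in layout$classes) {
      idx <- which(cls == cl)
      if (length(idx) == 0) next
      p3 <- up$inner[cl, ]
      if (spec$accumulator == "LATER") {
        p <- later_params(p3[1], p3[2], p3[3], t_er)
        rt[idx] <- later_sample(length(idx), p, mod$s0[idx], mod$kappa[idx])
      } else {
        p <- ddm_params(p3[1], p3[2], p3[3], t_er)
        sm <- ddm_sample(length(idx), p, mod$s0[idx], mod$kappa[idx])
        cens <- sm$boundary == 0
        if (any(cens)) {   # censored paths: resample at the time cap
          sm$rt[cens] <- 10 + t_er
          sm$boundary[cens] <- 1
        }
        rt[idx] <- sm$rt
        natural_error[idx] <- sm$boundary == -1
      }
    }
    lapse <- runif(n) < cfg$lapse_rate
    rt[lapse] <- runif(sum(lapse), cfg$lapse_rt_range[1], cfg$lapse_rt_range[2])

    truth <- correct_response(cfg$experiment, sched$target_present,
                              sched$target_dimension)
    error <- xor(natural_error, lapse)
    response <- ifelse(error, wrong_response(cfg$experiment, truth), truth)

    trials <- data.frame(participant_id = participant_id,
                         experiment = cfg$experiment,
                         section = sched$section, block = sched$block,
                         trial = sched$trial,
                         target_present = sched$target_present,
                         target_dimension = sched$target_dimension,
                         target_feature = sched$target_feature,
                         response = response, correct = !error, rt = rt,
                         stringsAsFactors = FALSE)
    validate_trials(trials)
    trials
  })
}

#' Simulate a complete experiment
#'
#' Participants are simulated independently with seeds derived from the
#' master seed.
#'
#' @param cfg a [generator_config()].
#' @return validated trial table with `cfg$n_participants` participants
#'   (`p01`, `p02`, ...).
#' @export
simulate_experiment <- function(cfg) {
  out <- lapply(seq_len(cfg$n_participants), function(i) {
    simulate_participant(cfg, cfg$seed * 131L + i * 7L,
                         sprintf("p%02d", i))
  })
  do.call(rbind, out)
}

#' Parameter- and model-recovery experiment
#'
#' Simulates data from a generating specification, refits, and
#' tabulates. With `candidate_specs = NULL` the generating spec alone is
#' refitted to each participant and per-parameter recovery (bias, RMSE)
#' is reported. With a candidate list, every candidate is fitted to
#' every participant in each replicate and the winning specification
#' (lowest mean relative AIC) is recorded per replicate.
#'
#' @param cfg a [generator_config()].
#' @param options fitting options.
#' @param n_replicates replicate count (model recovery) -- each
#'   replicate simulates a fresh experiment.
#' @param candidate_specs optional list of `model_spec` candidates.
#' @return for parameter recovery: list with `fits`, `estimates`
#'   (participants x parameters), `truth`, `bias`, `rmse`; for model
#'   recovery: list with `winners` (per replicate), `n_correct`, and the
#'   per-replicate comparison tables.
#' @export
recovery_experiment <- function(cfg, options = fit_options(),
                                n_replicates = 1, candidate_specs = NULL) {
  if (is.null(candidate_specs)) {
    trials <- simulate_experiment(cfg)
    pids <- unique(trials$participant_id)
    fits <- lapply(pids, function(pid) {
      tr <- trials[trials$participant_id == pid, ]
      fit_model(cfg$spec, tr, options = options)
    })
    est <- do.call(rbind, lapply(fits, function(f) f$params))
    rownames(est) <- pids
    layout <- param_layout(cfg$spec, cfg$experiment)
    truth <- pack_params(layout, cfg$true_params, t_er_max = Inf)
    bias <- colMeans(est) - truth
    rmse <- sqrt(colMeans(sweep(est, 2, truth)^2))
    list(fits = fits, estimates = est, truth = truth, bias = bias,
         rmse = rmse)
  } else {
    winners <- character(n_replicates)
    tables <- vector("list", n_replicates)
    gen_label <- spec_label(cfg$spec)
    for (rep_i in seq_len(n_replicates)) {
      cfg_i <- cfg
      cfg_i$seed <- cfg$seed + 1009L * rep_i
      trials <- simulate_experiment(cfg_i)
      pids <- unique(trials$participant_id)
      fits <- list()
      for (pid in pids) {
        tr <- trials[trials$participant_id == pid, ]
        inc <- modeling_outlier_mask(tr)
        for (cand in candidate_specs) {
          fits[[length(fits) + 1L]] <- fit_model(cand, tr, include = inc,
                                                 options = options)
        }
      }
      cmp <- compare_models(fits)
      winners[rep_i] <- cmp$winner
      tables[[rep_i]] <- cmp$table
    }
    list(winners = winners, n_correct = sum(winners == gen_label),
         generating = gen_label, tables = tables)
  }
}

#' Read a generator configuration from a YAML file
#'
#' The file carries the design parameters (experiment, ratios/section
#' order, block count), the generating model (accumulator, nd_time,
#' rdf/tdd levels), its true parameters, and the simulation settings
#' (participants, lapse rate/range, seed). Three ready-made
#' configurations, one per experiment design, ship under
#' `system.file("extdata", package = "intertrial")`.
#'
#' @param path YAML file path.
#' @return a [generator_config()].
#' @export
read_generator_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  spec <- model_spec(y$model$accumulator, y$model$nd_time,
                     y$model$rdf_level, y$model$tdd_level)
  generator_config(
    experiment = y$experiment, spec = spec,
    true_params = unlist(y$true_params),
    n_participants = y$n_participants %||% 12,
    lapse_rate = y$lapse_rate %||% 0.02,
    lapse_rt_range = unlist(y$lapse_rt_range %||% c(0.15, 2.0)),
    seed = y$seed %||% 1L,
    section_order = unlist(y$section_order %||% c(0.75, 0.50, 0.25)),
    n_blocks = y$n_blocks %||% 20L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
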