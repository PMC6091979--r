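#' Nested maximum-likelihood fitting and AIC comparison
#'
#' One model is fitted to one participant's trial sequence by maximum
#' likelihood with a nested search: the outer loop optimizes the
#' non-decision time and updating-rule parameters; for each outer
#' candidate the inner loop optimizes the accumulator parameters of each
#' stimulus class separately (the likelihood factorizes over classes once
#' the per-trial modulations are fixed). Both loops are bounded local
#' searches ([stats::nlminb]); the outer search is multi-started from
#' seeded random points. Error trials and outliers are excluded from the
#' likelihood but still drive the updating rules.
#'
#' @name fitting
NULL

#' Fitting options
#'
#' @param n_restarts outer multi-starts (first start is deterministic,
#'   the rest random within bounds).
#' @param inner_tol,outer_tol relative convergence tolerances of the
#'   inner resp. outer [stats::nlminb] searches.
#' @param outer_iter_max iteration cap of the outer search.
#' @param n_grid hyperprior grid size.
#' @param seed integer seed controlling the random restarts.
#' @return list of options for [fit_model()].
#' @export
fit_options <- function(n_restarts = 5, inner_tol = 1e-6, outer_tol = 1e-4,
                        outer_iter_max = 100, n_grid = .n_grid_default,
                        seed = 1L) {
  list(n_restarts = n_restarts, inner_tol = inner_tol, outer_tol = outer_tol,
       outer_iter_max = outer_iter_max, n_grid = n_grid, seed = seed)
}

# Modulations for a spec at given outer parameters.
spec_modulations <- function(spec, outer, trials, n_grid) {
  rules <- spec_rules(spec, outer)
  apply_rules(rules$rdf, rules$tdd, trials, n_grid = n_grid)
}

class_nll <- function(accumulator, rt, par3, t_er, s0, kappa) {
  if (accumulator == "LATER") {
    later_nll_cpp(rt, par3[1], par3[2], par3[3], t_er, s0, kappa)
  } else {
    ddm_nll_cpp(rt, par3[1], par3[2], par3[3], t_er, s0, kappa, .wiener_eps)
  }
}

#' Negative log-likelihood of a model at fixed parameters
#'
#' Runs the updating rules over *all* trials to obtain the per-trial
#' modulations, then sums the negative log-density over the
#' likelihood-included trials only, each evaluated with its stimulus
#' class's accumulator parameters. Any included trial with
#' `rt <= t_er` yields `+Inf`.
#'
#' @param spec a `model_spec`.
#' @param params named vector/list covering the [param_layout()] of
#'   `spec` for the data's experiment.
#' @param trials one participant's trial table.
#' @param include logical likelihood mask (default
#'   [modeling_outlier_mask()]).
#' @param n_grid hyperprior grid size.
#' @return scalar negative log-likelihood.
#' @export
negloglik <- function(spec, params, trials, include = NULL,
                      n_grid = .n_grid_default) {
  layout <- param_layout(spec, trials$experiment[1])
  up <- unpack_params(layout, pack_params(layout, params, t_er_max = Inf))
  if (is.null(include)) include <- modeling_outlier_mask(trials)
  t_er <- if (spec$nd_time == "with") unname(up$outer["t_er"]) else 0
  mod <- spec_modulations(spec, up$outer, trials, n_grid)
  cls <- trial_class(trials)
  total <- 0
  for (cl in layout$classes) {
    idx <- include & cls == cl
    if (!any(idx)) next
    total <- total + class_nll(spec$accumulator, trials$rt[idx],
                               up$inner[cl, ], t_er,
                               mod$s0[idx], mod$kappa[idx])
  }
  total
}

# Moment-heuristic inner start for one class: D (or a) = 1, rate from the
# mean reciprocal decision time, spread from its SD.
inner_start <- function(accumulator, rt, t_er) {
  dec <- pmax(rt - t_er, 1e-2)
  r <- 1 / dec
  if (accumulator == "LATER") {
    c(1, mean(r), max(sd(r), 0.2))
  } else {
    # a = 2 puts the start one evidence unit from each boundary
    c(2, mean(r), max(sd(r) / 2, 0.2))
  }
}

inner_bounds <- function(accumulator) {
  nm <- .inner_names[[accumulator]]
  list(lower = vapply(nm, function(n) .param_bounds[[n]][1], 0),
       upper = vapply(nm, function(n) .param_bounds[[n]][2], 0))
}

#' Fit one model to one participant by nested maximum likelihood
#'
#' @param spec a `model_spec`.
#' @param trials one participant's trial table, in presentation order.
#' @param include logical likelihood mask; defaults to
#'   [modeling_outlier_mask()].
#' @param options see [fit_options()].
#' @return object of class `intertrial_fit`: a list with the fitted
#'   named parameter vector `params`, `loglik` over included trials,
#'   `n_params`, `aic = 2 * n_params - 2 * loglik`, `n_included`,
#'   `converged`, and bookkeeping (`spec`, `layout`, `seed`).
#' @export
fit_model <- function(spec, trials, include = NULL, options = fit_options()) {
  stopifnot(inherits(spec, "model_spec"))
  experiment <- trials$experiment[1]
  layout <- param_layout(spec, experiment)
  if (is.null(include)) include <- modeling_outlier_mask(trials)
  if (!any(include)) stop("no trials included in the likelihood")
  cls <- trial_class(trials)
  rt_min <- min(trials$rt[include])
  t_er_max <- 0.95 * rt_min
  b <- layout_bounds(layout, t_er_max)

  outer_names <- layout$outer
  k_out <- length(outer_names)
  out_lower <- b[outer_names, "lower"]
  out_upper <- b[outer_names, "upper"]
  ib <- inner_bounds(spec$accumulator)

  # warm-start cache for the per-class inner solutions
  inner_warm <- new.env(parent = emptyenv())

  inner_fit_all <- function(outer) {
    t_er <- if (spec$nd_time == "with") unname(outer["t_er"]) else 0
    mod <- spec_modulations(spec, outer, trials, options$n_grid)
    total <- 0
    pars <- list()
    for (cl in layout$classes) {
      idx <- which(include & cls == cl)
      if (length(idx) == 0) {
        pars[[cl]] <- setNames(rep(NA_real_, 3), layout$acc_par)
        next
      }
      rt <- trials$rt[idx]
      s0 <- mod$s0[idx]
      kap <- mod$kappa[idx]
      obj <- function(p) class_nll(spec$accumulator, rt, p, t_er, s0, kap)
      start <- if (!is.null(inner_warm[[cl]])) inner_warm[[cl]] else
        pmin(pmax(inner_start(spec$accumulator, rt, t_er), ib$lower), ib$upper)
      res <- suppressWarnings(
        nlminb(start, obj, lower = ib$lower, upper = ib$upper,
               control = list(rel.tol = options$inner_tol)))
      # fall back to the cold start if the warm one went astray
      if (!is.null(inner_warm[[cl]]) && !is.finite(res$objective)) {
        res <- suppressWarnings(
          nlminb(pmin(pmax(inner_start(spec$accumulator, rt, t_er),
                           ib$lower), ib$upper),
                 obj, lower = ib$lower, upper = ib$upper,
                 control = list(rel.tol = options$inner_tol)))
      }
      inner_warm[[cl]] <- res$par
      pars[[cl]] <- setNames(res$par, layout$acc_par)
      total <- total + res$objective
    }
    list(nll = total, pars = pars)
  }

  outer_obj <- function(outer) {
    names(outer) <- outer_names
    inner_fit_all(outer)$nll
  }

  default_start <- vapply(outer_names, function(nm) {
    switch(base_param(nm),
           t_er = 0.5 * t_er_max, alpha = 0.7, beta0 = 2,
           delta = 0.1, kappa0 = 0.8)
  }, 0)

  starts <- list(default_start)
  if (options$n_restarts > 1 && k_out > 0) {
    extra <- with_seed(options$seed, {
      lapply(seq_len(options$n_restarts - 1), function(i) {
        lo <- out_lower
        hi <- pmin(out_upper, c(t_er = t_er_max, alpha = 1, beta0 = 20,
                                delta = 0.3, kappa0 = 1)[base_param(outer_names)],
                   na.rm = TRUE)
        setNames(runif(k_out, lo, hi), outer_names)
      })
    })
    starts <- c(starts, extra)
  }

  best <- NULL
  converged <- FALSE
  if (k_out == 0) {
    sol <- inner_fit_all(numeric(0))
    best <- list(outer = numeric(0), nll = sol$nll, pars = sol$pars,
                 convergence = 0L)
    converged <- is.finite(sol$nll)
  } else {
    for (st in starts) {
      res <- suppressWarnings(
        nlminb(st, outer_obj, lower = out_lower, upper = out_upper,
               control = list(rel.tol = options$outer_tol,
                              iter.max = options$outer_iter_max)))
      if (is.null(best) || res$objective < best$nll) {
        sol <- inner_fit_all(setNames(res$par, outer_names))
        best <- list(outer = setNames(res$par, outer_names), nll = sol$nll,
                     pars = sol$pars, convergence = res$convergence)
        converged <- converged || res$convergence == 0
      }
    }
  }

  flat <- c(unlist(lapply(layout$classes, function(cl) {
    setNames(best$pars[[cl]], paste(cl, layout$acc_par, sep = "."))
  })), best$outer)
  flat <- flat[c(layout$inner, layout$outer)]

  structure(list(spec = spec, experiment = experiment,
                 participant_id = trials$participant_id[1],
                 params = flat, loglik = -best$nll,
                 n_params = layout$n_params,
                 aic = 2 * layout$n_params + 2 * best$nll,
                 n_included = sum(include), converged = converged,
                 seed = options$seed, layout = layout),
            class = "intertrial_fit")
}

#' @export
print.intertrial_fit <- function(x, ...) {
  cat("<intertrial_fit>", spec_label(x$spec), "\n",
      " participant:", x$participant_id,
      " loglik:", format(x$loglik, digits = 6),
      " AIC:", format(x$aic, digits = 6),
      " k:", x$n_params,
      " n:", x$n_included,
      if (x$converged) "" else " (not converged)", "\n")
  invisible(x)
}

#' Factorial comparison table of fitted models
#'
#' Given fits of the same specification set for every participant, the
#' overall winner is the specification with the lowest mean AIC across
#' participants; for each participant, that winner's AIC is subtracted
#' from every specification's AIC, and the relative AICs are averaged
#' across participants. The winner's mean relative AIC is therefore 0.
#'
#' @param fits list of `intertrial_fit` objects (all participants x all
#'   specs).
#' @return list with `table` (data.frame: `spec`, `mean_relative_aic`,
#'   `sd`, `n_participants`, ascending), `winner` (spec label), and
#'   `cells` (the participant x spec AIC matrix).
#' @export
compare_models <- function(fits) {
  labels <- vapply(fits, function(f) spec_label(f$spec), "")
  pids <- vapply(fits, function(f) f$participant_id, "")
  aics <- vapply(fits, function(f) f$aic, 0)
  specs <- sort(unique(labels))
  parts <- sort(unique(pids))
  cells <- matrix(NA_real_, length(parts), length(specs),
                  dimnames = list(parts, specs))
  cells[cbind(match(pids, parts), match(labels, specs))] <- aics
  if (anyNA(cells)) {
    miss <- which(is.na(cells), arr.ind = TRUE)[1, ]
    stop("missing fit: participant ", parts[miss[1]], ", spec ", specs[miss[2]])
  }
  winner <- specs[which.min(colMeans(cells))]
  rel <- cells - cells[, winner]
  tab <- data.frame(spec = specs,
                    mean_relative_aic = colMeans(rel),
                    sd = apply(rel, 2, sd),
                    n_participants = nrow(cells),
                    row.names = NULL, stringsAsFactors = FALSE)
  tab <- tab[order(tab$mean_relative_aic), ]
  rownames(tab) <- NULL
  list(table = tab, winner = winner, cells = cells)
}

#' Predicted vs. observed mean RT per design cell
#'
#' Simulates the fitted model over the participant's actual stimulus
#' sequence (`n_draws` RT draws per trial from the fitted accumulator
#' under that trial's modulation) and averages within cells defined by
#' the frequency condition (section ratio of the trial's target
#' condition), the target condition, and the inter-trial condition
#' (repeat/switch of the target condition; first trial of each block
#' unlabeled). Observed means use correct, descriptive-included trials;
#' predictions average over the same trials.
#'
#' @param fit a converged `intertrial_fit`.
#' @param trials the participant's trial table the fit was obtained from.
#' @param n_draws Monte-Carlo draws per trial.
#' @param include_descriptives logical mask (default
#'   [descriptive_outlier_mask()]).
#' @param seed integer seed for the draws.
#' @return data.frame with cell labels, `n`, `observed` and `predicted`
#'   mean RT (seconds).
#' @export
predict_cell_means <- function(fit, trials, n_draws = 100,
                               include_descriptives = NULL, seed = 1L) {
  layout <- fit$layout
  up <- unpack_params(layout, fit$params)
  t_er <- if (fit$spec$nd_time == "with") unname(up$outer["t_er"]) else 0
  mod <- spec_modulations(fit$spec, up$outer, trials, .n_grid_default)
  cls <- trial_class(trials)
  if (is.null(include_descriptives)) {
    include_descriptives <- descriptive_outlier_mask(trials)
  }

  pred <- with_seed(seed, {
    out <- numeric(nrow(trials))
    for (cl in layout$classes) {
      idx <- which(cls == cl)
      if (length(idx) == 0) next
      p3 <- up$inner[cl, ]
      for (i in idx) {
        if (fit$spec$accumulator == "LATER") {
          p <- later_params(p3[1], p3[2], p3[3], t_er)
          out[i] <- mean(later_sample(n_draws, p, mod$s0[i], mod$kappa[i]))
        } else {
          p <- ddm_params(p3[1], p3[2], p3[3], t_er)
          sm <- ddm_sample(n_draws, p, mod$s0[i], mod$kappa[i])
          ok <- sm$boundary == 1
          out[i] <- if (any(ok)) mean(sm$rt[ok]) else NA_real_
        }
      }
    }
    out
  })

  condition <- cls
  same_block <- c(FALSE, diff(trials$block) == 0 &
                    trials$participant_id[-1] == trials$participant_id[-nrow(trials)])
  intertrial <- rep(NA_character_, nrow(trials))
  intertrial[same_block] <- ifelse(
    condition[same_block] == condition[which(same_block) - 1L],
    "repeat", "switch")
  ratio <- section_ratio(trials)
  freq <- ifelse(condition == "absent", 1 - ratio, ratio)
  if (trials$experiment[1] == "exp2_dimension_discrimination") {
    freq <- ifelse(condition == "color", ratio, 1 - ratio)
  }

  keep <- include_descriptives & !is.na(intertrial) & !is.na(pred)
  df <- data.frame(frequency = freq, condition = condition,
                   intertrial = intertrial, observed = trials$rt,
                   predicted = pred)[keep, ]
  agg <- aggregate(cbind(observed, predicted) ~ frequency + condition + intertrial,
                   data = df, FUN = mean)
  n <- aggregate(observed ~ frequency + condition + intertrial, data = df,
                 FUN = length)
  agg$n <- n$observed
  agg
}
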