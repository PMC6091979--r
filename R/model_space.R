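#' The factorial model space
#'
#' Four factors define a model: non-decision time (without/with), the
#' accumulator (DDM/LATER), the RDF-based updating level and the
#' TDD-based updating level (six levels each), giving 2 x 2 x 6 x 6 = 144
#' cells. The full-memory starting-point level for the dimension scope is
#' constructible but excluded from the default comparison space (its fits
#' are prone to parameter degeneration); a flag restores it.
#'
#' @name model-space
NULL

#' Construct a model specification
#'
#' @param accumulator `"LATER"` or `"DDM"`.
#' @param nd_time `"with"` or `"without"` a free non-decision time.
#' @param rdf_level,tdd_level updating level names (see
#'   [`updating-rules`][updating-rules]).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(accumulator = c("LATER", "DDM"),
                       nd_time = c("with", "without"),
                       rdf_level = "no_update", tdd_level = "no_update") {
  spec <- structure(
    list(accumulator = match.arg(accumulator),
         nd_time = match.arg(nd_time),
         rdf_level = match.arg(rdf_level, .rule_levels),
         tdd_level = match.arg(tdd_level, .rule_levels)),
    class = "model_spec")
  spec
}

#' Short string form of a model specification
#'
#' e.g. `"LATER+nd/rdf=s0_decay/tdd=rate_weighted"`; `-nd` marks the
#' variant without non-decision time.
#'
#' @param spec a `model_spec`.
#' @return character scalar.
#' @export
spec_label <- function(spec) {
  paste0(spec$accumulator, if (spec$nd_time == "with") "+nd" else "-nd",
         "/rdf=", spec$rdf_level, "/tdd=", spec$tdd_level)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", spec_label(x), "\n")
  invisible(x)
}

#' Enumerate the factorial model space
#'
#' @param include_tdd_full_memory keep the `s0_full_memory` level in the
#'   TDD factor (FALSE reproduces the comparison space actually used,
#'   120 models; TRUE gives the full 144).
#' @return list of `model_spec` objects covering the Cartesian product.
#' @export
enumerate_models <- function(include_tdd_full_memory = FALSE) {
  tdd_levels <- .rule_levels
  if (!include_tdd_full_memory) {
    tdd_levels <- setdiff(tdd_levels, "s0_full_memory")
  }
  grid <- expand.grid(nd_time = c("without", "with"),
                      accumulator = c("DDM", "LATER"),
                      rdf_level = .rule_levels, tdd_level = tdd_levels,
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    model_spec(grid$accumulator[i], grid$nd_time[i],
               grid$rdf_level[i], grid$tdd_level[i])
  })
}

stimulus_classes <- function(experiment) {
  if (experiment == "exp2_dimension_discrimination") {
    c("color", "orientation")
  } else {
    c("absent", "color", "orientation")
  }
}

trial_class <- function(trials) {
  ifelse(trials$target_present, trials$target_dimension, "absent")
}

.inner_names <- list(LATER = c("D", "mu", "sigma"), DDM = c("a", "v", "s"))

# Box bounds for every fit parameter; t_er's upper bound is data-dependent
# and supplied by the fitting routine.
.param_bounds <- list(
  D = c(0.1, 10), a = c(0.1, 10),
  mu = c(0.1, 60), v = c(0.1, 60),
  sigma = c(0.01, 30), s = c(0.01, 30),
  t_er = c(0, Inf),
  alpha = c(0, 1), beta0 = c(0.05, 100), delta = c(0, 0.5),
  kappa0 = c(1e-3, 1 - 1e-3))

base_param <- function(name) sub("^(rdf|tdd)_", "", name)

#' Parameter layout of a model specification
#'
#' Inner parameters are the accumulator's own, one triplet per stimulus
#' class (absent/color/orientation for the detection experiments, 9
#' parameters; color/orientation for the discrimination experiment, 6).
#' Outer parameters are the non-decision time (when present) plus the
#' updating-rule parameters of the two scopes (0 to 5 in total), prefixed
#' `rdf_`/`tdd_`.
#'
#' @param spec a `model_spec`.
#' @param experiment experiment label (determines the stimulus classes).
#' @return list with `classes`, `inner` (matrix-layout names:
#'   class-qualified accumulator parameters), `outer` (named character
#'   vector), and counts `n_inner`, `n_outer`, `n_params`.
#' @export
param_layout <- function(spec, experiment) {
  classes <- stimulus_classes(experiment)
  acc_par <- .inner_names[[spec$accumulator]]
  inner <- as.vector(outer(acc_par, classes, function(p, cl) paste(cl, p, sep = ".")))
  outer_names <- character(0)
  if (spec$nd_time == "with") outer_names <- "t_er"
  rdf <- rule_params(spec$rdf_level)
  tdd <- rule_params(spec$tdd_level)
  if (length(rdf)) outer_names <- c(outer_names, paste0("rdf_", rdf))
  if (length(tdd)) outer_names <- c(outer_names, paste0("tdd_", tdd))
  list(spec = spec, experiment = experiment, classes = classes,
       acc_par = acc_par, inner = inner, outer = outer_names,
       n_inner = length(inner), n_outer = length(outer_names),
       n_params = length(inner) + length(outer_names))
}

layout_bounds <- function(layout, t_er_max = 1) {
  nm <- c(layout$inner, layout$outer)
  base <- vapply(nm, function(n) base_param(sub("^[a-z]+\\.", "", n)), "")
  lower <- vapply(base, function(b) .param_bounds[[b]][1], 0)
  upper <- vapply(base, function(b) .param_bounds[[b]][2], 0)
  upper[base == "t_er"] <- t_er_max
  data.frame(param = nm, base = base, lower = lower, upper = upper,
             row.names = nm, stringsAsFactors = FALSE)
}

#' Pack named parameters into a flat bounded vector
#'
#' @param layout a [param_layout()].
#' @param params named list or vector covering every layout parameter.
#' @param t_er_max data-dependent upper bound for the non-decision time.
#' @return named numeric vector in layout order; out-of-bounds values
#'   raise an error naming the parameter.
#' @export
pack_params <- function(layout, params, t_er_max = 1) {
  nm <- c(layout$inner, layout$outer)
  params <- unlist(params)
  missing <- setdiff(nm, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  x <- params[nm]
  b <- layout_bounds(layout, t_er_max)
  bad <- x < b$lower | x > b$upper
  if (any(bad)) {
    stop("parameter out of bounds: ", nm[which(bad)[1]], " = ",
         signif(x[which(bad)[1]], 4))
  }
  x
}

#' Unpack a flat vector into named parameters
#'
#' Inverse of [pack_params()]: returns a named list with the accumulator
#' parameters arranged per stimulus class plus the outer parameters.
#'
#' @param layout a [param_layout()].
#' @param x numeric vector in layout order.
#' @return named list (`inner` matrix classes x accumulator parameters,
#'   `outer` named vector, `flat` the named flat vector).
#' @export
unpack_params <- function(layout, x) {
  nm <- c(layout$inner, layout$outer)
  stopifnot(length(x) == length(nm))
  names(x) <- nm
  inner <- matrix(x[layout$inner], nrow = length(layout$classes),
                  byrow = TRUE,
                  dimnames = list(layout$classes, layout$acc_par))
  outer <- x[layout$outer]
  list(inner = inner, outer = outer, flat = x)
}

spec_rules <- function(spec, outer) {
  mk <- function(scope, level) {
    need <- rule_params(level)
    if (length(need) == 0) return(update_rule(level))
    update_rule(level, setNames(as.list(outer[paste0(scope, "_", need)]), need))
  }
  list(rdf = mk("rdf", spec$rdf_level), tdd = mk("tdd", spec$tdd_level))
}
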