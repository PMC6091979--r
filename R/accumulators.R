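#' Evidence-accumulation likelihoods and samplers
#'
#' Two accumulator models map a trial's stimulus class and history
#' modulation to an RT density:
#'
#' * **LATER**: evidence rises linearly from the starting point to a
#'   single boundary at distance `D` with a rate that is constant within a
#'   trial but varies across trials as Normal(`mu`, `sigma`), truncated to
#'   positive rates and renormalized. The RT is
#'   `t_er + D_eff / R` (a "recinormal" distribution).
#' * **DDM**: a Wiener diffusion with boundary separation `a`, diffusion
#'   scale `s` and drift `v`; the likelihood of a correct response at time
#'   `t` is the defective first-passage density at the correct (upper)
#'   boundary, computed by the standard small-time/large-time series with
#'   automatic regime selection (truncation tolerance 1e-7).
#'
#' History modulations enter identically in both models: the
#' starting-point offset `s0` (log prior odds toward the correct
#' boundary) reduces the LATER separation (`D_eff = D - s0`, floored at
#' 1e-3) resp. shifts the DDM start from `a/2` toward the upper boundary
#' (clamped 1e-3 from either boundary), and the rate scaling `kappa`
#' multiplies the mean rate `mu` resp. the drift `v`.
#'
#' @name accumulators
NULL

.wiener_eps <- 1e-7

#' LATER parameter set
#'
#' @param D start-to-boundary separation at neutral prior, > 0 (evidence
#'   units).
#' @param mu mean accumulation rate (evidence units / s).
#' @param sigma across-trial SD of the rate, > 0.
#' @param t_er non-decision time in seconds (0 when the model variant has
#'   no non-decision component).
#' @return list of class `later_params`.
#' @export
later_params <- function(D, mu, sigma, t_er = 0) {
  stopifnot(D > 0, sigma > 0, t_er >= 0)
  structure(list(D = D, mu = mu, sigma = sigma, t_er = t_er),
            class = "later_params")
}

#' DDM parameter set
#'
#' @param a boundary separation, > 0 (evidence units).
#' @param v drift rate (evidence units / s).
#' @param s diffusion scale, > 0 (evidence units / sqrt(s)); free because
#'   the starting-point updating makes the evidence scale non-arbitrary.
#' @param t_er non-decision time in seconds.
#' @return list of class `ddm_params`.
#' @export
ddm_params <- function(a, v, s, t_er = 0) {
  stopifnot(a > 0, s > 0, t_er >= 0)
  structure(list(a = a, v = v, s = s, t_er = t_er), class = "ddm_params")
}

#' LATER log-density
#'
#' Log of the density of `T = t_er + D_eff / R` with
#' `R ~ Normal(kappa * mu, sigma)` truncated to `R > 0`:
#' `f(t) = D_eff / (t - t_er)^2 * phi((D_eff/(t - t_er) - kappa*mu)/sigma) /
#' sigma / Phi(kappa*mu/sigma)`. Returns `-Inf` for `rt <= t_er`
#' (impossible datum).
#'
#' @param rt reaction times in seconds (vectorized).
#' @param p `later_params`.
#' @param s0 starting-point offset(s), subtracted from `D` (scalar or one
#'   per rt).
#' @param kappa rate scaling(s), multiplying `mu`.
#' @return log-density vector.
#' @export
later_logpdf <- function(rt, p, s0 = 0, kappa = 1) {
  D_eff <- pmax(p$D - s0, 1e-3)
  mu_eff <- kappa * p$mu
  dt <- rt - p$t_er
  out <- rep(-Inf, length(rt))
  ok <- dt > 0
  if (any(ok)) {
    dts <- dt[ok]
    D_ok <- if (length(D_eff) > 1) D_eff[ok] else D_eff
    mu_ok <- if (length(mu_eff) > 1) mu_eff[ok] else mu_eff
    out[ok] <- log(D_ok) - 2 * log(dts) +
      dnorm((D_ok / dts - mu_ok) / p$sigma, log = TRUE) - log(p$sigma) -
      pnorm(mu_ok / p$sigma, log.p = TRUE)
  }
  out
}

#' Sample reaction times from the LATER model
#'
#' Draws rates from the truncated normal by rejection and returns
#' `t_er + D_eff / R`.
#'
#' @inheritParams later_logpdf
#' @param n number of samples.
#' @param seed optional integer seed for reproducibility.
#' @return vector of `n` RTs (seconds), all `> t_er`.
#' @export
later_sample <- function(n, p, s0 = 0, kappa = 1, seed = NULL) {
  draw <- function() {
    D_eff <- pmax(p$D - s0, 1e-3)
    mu_eff <- kappa * p$mu
    r <- rnorm(n, mu_eff, p$sigma)
    bad <- r <= 0
    while (any(bad)) {
      r[bad] <- rnorm(sum(bad), if (length(mu_eff) > 1) mu_eff[bad] else mu_eff,
                      p$sigma)
      bad <- r <= 0
    }
    p$t_er + D_eff / r
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' DDM log-density of a correct response
#'
#' Log of the defective first-passage density at the correct (upper)
#' boundary of the Wiener process, evaluated at decision time
#' `rt - t_er`. Returns `-Inf` for `rt <= t_er`.
#'
#' @param rt reaction times in seconds (vectorized).
#' @param p `ddm_params`.
#' @param s0 starting-point offset(s) from `a/2` toward the correct
#'   boundary.
#' @param kappa drift scaling(s).
#' @return log-density vector.
#' @export
ddm_logpdf_correct <- function(rt, p, s0 = 0, kappa = 1) {
  ddm_logpdf_cpp(rt, p$a, p$v, p$s, p$t_er, s0, kappa, .wiener_eps)
}

#' Probability of absorption at the correct (upper) boundary
#'
#' Closed form `(1 - exp(-2 v z / s^2)) / (1 - exp(-2 v a / s^2))` with
#' `z = a/2 + s0` (clamped), reducing to `z / a` at zero drift.
#'
#' @inheritParams ddm_logpdf_correct
#' @return scalar probability.
#' @export
ddm_prob_correct <- function(p, s0 = 0, kappa = 1) {
  z <- min(max(p$a / 2 + s0, 1e-3), p$a - 1e-3)
  ddm_prob_upper_cpp(p$a, z, kappa * p$v, p$s)
}

#' Simulate DDM trials by Euler-Maruyama path integration
#'
#' @inheritParams ddm_logpdf_correct
#' @param n number of trials.
#' @param dt integration step in seconds (1e-3 or finer recommended).
#' @param t_max decision-time cap; paths still unabsorbed at `t_max` are
#'   returned as censored (`boundary = 0`, `rt = NA`).
#' @param seed optional integer seed.
#' @return data.frame with `boundary` (1 = correct/upper, -1 =
#'   incorrect/lower, 0 = censored) and `rt` (seconds, including `t_er`).
#' @export
ddm_sample <- function(n, p, s0 = 0, kappa = 1, dt = 1e-3, t_max = 10,
                       seed = NULL) {
  draw <- function() {
    out <- ddm_sample_cpp(n, p$a, p$v, p$s, p$t_er, s0, kappa, dt, t_max)
    data.frame(boundary = out$boundary, rt = out$rt)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
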