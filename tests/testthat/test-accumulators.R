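test_that("LATER density normalizes and matches the closed-form median", {
  p <- later_params(D = 1, mu = 5, sigma = 1, t_er = 0.3)
  f <- function(t) exp(later_logpdf(t, p))
  expect_equal(integrate(f, 0.3, Inf)$value, 1, tolerance = 1e-4)

  # median of D_eff / R is D_eff / median(R) (monotone transform; at
  # mu/sigma = 5 the positive-rate truncation is negligible)
  med <- uniroot(function(q) integrate(f, 0.3, q)$value - 0.5,
                 c(0.31, 3))$root
  expect_equal(med, 0.3 + 1 / 5, tolerance = 1e-3)

  # impossible data
  expect_identical(later_logpdf(c(0.1, 0.3), p), c(-Inf, -Inf))
})

test_that("LATER density normalizes across random parameter sets (property)", {
  set.seed(31)
  for (i in 1:20) {
    p <- later_params(D = runif(1, 0.3, 3), mu = runif(1, 2, 12),
                      sigma = runif(1, 0.3, 3), t_er = runif(1, 0, 0.4))
    s0 <- runif(1, -0.5, 0.5)
    kappa <- runif(1, 0.6, 1.4)
    val <- integrate(function(t) exp(later_logpdf(t, p, s0, kappa)),
                     p$t_er, Inf, rel.tol = 1e-8)$value
    expect_equal(val, 1, tolerance = 1e-4)
  }
})

test_that("LATER sampler agrees with the density (Monte-Carlo oracle)", {
  p <- later_params(D = 1, mu = 5, sigma = 1, t_er = 0.3)
  x <- later_sample(2e5, p, seed = 99)
  expect_true(all(x > p$t_er))

  # KS distance between empirical and analytic CDF
  f <- function(t) exp(later_logpdf(t, p))
  grid <- quantile(x, seq(0.01, 0.99, by = 0.02))
  theo <- vapply(grid, function(q) integrate(f, p$t_er, q)$value, 0)
  emp <- ecdf(x)(grid)
  expect_lt(max(abs(emp - theo)), 0.01)

  expect_equal(median(x), 0.3 + 1 / 5, tolerance = 2e-3)
  expect_identical(later_sample(100, p, seed = 5),
                   later_sample(100, p, seed = 5))
})

test_that("Wiener defective densities integrate to the absorption probabilities", {
  # symmetric, driftless: each boundary takes half the mass
  d0 <- ddm_params(a = 1, v = 0, s = 0.5, t_er = 0.3)
  expect_equal(integrate(function(t) exp(ddm_logpdf_correct(t, d0)),
                         0.3, Inf)$value, 0.5, tolerance = 1e-3)

  # drifted, biased start: integral equals the classical absorption formula
  d <- ddm_params(a = 1, v = 0.8, s = 0.5, t_er = 0)
  s0 <- 0.1   # z = 0.6
  p_closed <- (1 - exp(-2 * 0.8 * 0.6 / 0.25)) / (1 - exp(-2 * 0.8 * 1 / 0.25))
  expect_equal(ddm_prob_correct(d, s0 = s0), p_closed, tolerance = 1e-10)
  p_num <- integrate(function(t) exp(ddm_logpdf_correct(t, d, s0 = s0)),
                     0, Inf)$value
  expect_equal(p_num, p_closed, tolerance = 1e-3)

  # upper + lower defective integrals sum to 1 (lower via mirrored process)
  p_low <- integrate(function(t) {
    exp(ddm_logpdf_correct(t, ddm_params(1, -0.8, 0.5, 0), s0 = -s0))
  }, 0, Inf)$value
  expect_equal(p_num + p_low, 1, tolerance = 1e-3)

  expect_identical(ddm_logpdf_correct(c(0.1, 0.3), d0), c(-Inf, -Inf))
})

test_that("Euler-Maruyama simulation matches density and absorption closed form", {
  d <- ddm_params(a = 1, v = 0.8, s = 0.5, t_er = 0)
  sm <- ddm_sample(2e4, d, s0 = 0.1, dt = 1e-4, seed = 17)
  expect_equal(mean(sm$boundary == 1), ddm_prob_correct(d, s0 = 0.1),
               tolerance = 0.01)

  # driftless symmetric case: hit fraction 1/2
  d0 <- ddm_params(a = 1, v = 0, s = 0.5, t_er = 0)
  sm0 <- ddm_sample(1e4, d0, dt = 1e-4, seed = 23)
  expect_equal(mean(sm0$boundary == 1), 0.5, tolerance = 0.02)

  # KS distance between simulated correct RTs and the conditional density
  rt <- sm$rt[sm$boundary == 1]
  pc <- ddm_prob_correct(d, s0 = 0.1)
  Fc <- function(q) integrate(function(t) exp(ddm_logpdf_correct(t, d, s0 = 0.1)),
                              0, q, rel.tol = 1e-8)$value / pc
  grid <- quantile(rt, seq(0.02, 0.98, by = 0.04))
  theo <- vapply(grid, Fc, 0)
  expect_lt(max(abs(ecdf(rt)(grid) - theo)), 0.02)

  expect_identical(ddm_sample(50, d, seed = 3), ddm_sample(50, d, seed = 3))
})

test_that("starting-point shifts speed responses; neutral modulations change nothing", {
  p <- later_params(D = 1, mu = 5, sigma = 1, t_er = 0.2)
  d <- ddm_params(a = 1, v = 3, s = 1, t_er = 0.2)
  for (s0 in c(0.1, 0.3)) {
    m_later <- integrate(function(t) t * exp(later_logpdf(t, p, s0 = s0)),
                         p$t_er, Inf)$value
    m0_later <- integrate(function(t) t * exp(later_logpdf(t, p)),
                          p$t_er, Inf)$value
    expect_lt(m_later, m0_later)

    pc <- ddm_prob_correct(d, s0 = s0)
    m_ddm <- integrate(function(t) t * exp(ddm_logpdf_correct(t, d, s0 = s0)),
                       d$t_er, Inf)$value / pc
    m0_ddm <- integrate(function(t) t * exp(ddm_logpdf_correct(t, d)),
                        d$t_er, Inf)$value / ddm_prob_correct(d)
    expect_lt(m_ddm, m0_ddm)
  }

  # kappa = 1, s0 = 0 reproduce the unmodulated densities exactly
  tt <- seq(0.25, 1.5, by = 0.05)
  expect_identical(later_logpdf(tt, p, s0 = 0, kappa = 1), later_logpdf(tt, p))
  expect_identical(ddm_logpdf_correct(tt, d, s0 = 0, kappa = 1),
                   ddm_logpdf_correct(tt, d))
})
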