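test_that("log prior odds has the closed form and antisymmetry", {
  expect_identical(log_prior_odds(0.5), 0)
  expect_equal(log_prior_odds(0.75), log(3))
  for (p in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(log_prior_odds(1 - p), -log_prior_odds(p))
  }
  expect_error(log_prior_odds(1), "strictly")
  expect_error(log_prior_odds(0), "strictly")
})

test_that("grid belief updating matches conjugate Beta closed forms", {
  # single success from a flat prior: Beta(2, 1) mean
  s <- belief_observe(belief_state(1), "u1")
  expect_equal(belief_p_hat(s), 2 / 3, tolerance = 1e-3)

  # one success then one failure from a symmetric start: back to 1/2
  s2 <- belief_observe(s, "u2")
  expect_equal(belief_p_hat(s2), 0.5, tolerance = 1e-3)

  # Laplace rule: k successes in n trials with beta0 = 1 -> (k+1)/(n+2)
  set.seed(12)
  outs <- sample(c("u1", "u2"), 200, replace = TRUE)
  s <- belief_state(1)
  for (o in outs) s <- belief_observe(belief_predict(s), o)
  k <- sum(outs == "u1")
  expect_equal(belief_p_hat(s), (k + 1) / (200 + 2), tolerance = 1e-3)

  # general conjugate oracle over random sequences and shapes
  for (beta0 in c(0.5, 2, 8)) {
    outs <- sample(c("u1", "u2"), 120, replace = TRUE)
    s <- belief_state(beta0)
    for (o in outs) s <- belief_observe(s, o)
    k <- sum(outs == "u1")
    expect_equal(belief_p_hat(s), (k + beta0) / (120 + 2 * beta0),
                 tolerance = 1e-3)
  }
})

test_that("forgetting mixes toward the initial prior", {
  # alpha = 1: predict is the identity
  s <- belief_observe(belief_state(2, alpha = 1), "u1")
  expect_identical(belief_predict(s)$w, s$w)

  # alpha = 0: full reset, p_hat back to 1/2
  s0 <- belief_observe(belief_state(2, alpha = 0), "u1")
  expect_equal(belief_p_hat(belief_predict(s0)), 0.5, tolerance = 1e-12)

  # alpha = 0.5 with a Beta(3, 1)-shaped posterior: mixture of expectations
  s <- belief_state(1, alpha = 0.5)
  s$w <- dbeta(s$p, 3, 1); s$w <- s$w / sum(s$w)
  expect_equal(belief_p_hat(belief_predict(s)), 0.5 * 0.75 + 0.5 * 0.5,
               tolerance = 1e-3)
})

test_that("binary rate rule scales only immediate switches", {
  st <- rate_state("binary", kappa0 = 0.8)
  r1 <- rate_step_binary(st, "u1")          # first trial: no predecessor
  expect_identical(r1$scaling, 1)
  r2 <- rate_step_binary(r1$state, "u1")    # repeat
  expect_identical(r2$scaling, 1)
  r3 <- rate_step_binary(r2$state, "u2")    # switch
  expect_identical(r3$scaling, 0.8)
  # non-applicable trial clears the predecessor: next switch scales by 1
  r4 <- rate_step_binary(r3$state, "u2", uv_applies = FALSE)
  expect_identical(r4$scaling, 1)
  r5 <- rate_step_binary(r4$state, "u1")
  expect_identical(r5$scaling, 1)
})

test_that("decaying rate rule follows the hand iteration and its limits", {
  # alpha = 1, delta = 0.1, all repeats: scalings 1, 1, 1.1, 1.2
  st <- rate_state("decay", alpha = 1, delta = 0.1)
  sc <- numeric(4)
  for (i in 1:4) { r <- rate_step_decay(st, "u1"); sc[i] <- r$scaling; st <- r$state }
  expect_equal(sc, c(1, 1, 1.1, 1.2))

  # alpha = 0 collapses to baseline on every trial
  st <- rate_state("decay", alpha = 0, delta = 0.2)
  set.seed(4)
  for (uv in sample(c("u1", "u2"), 50, TRUE)) {
    r <- rate_step_decay(st, uv)
    expect_identical(r$scaling, 1)
    st <- r$state
  }

  # target-absent trial (dimension scope): forgetting only, no delta step
  st <- rate_state("decay", alpha = 0.5, delta = 0.1)
  st$kappa <- 1.4; st$last_uv <- "u1"
  r <- rate_step_decay(st, "u1", uv_applies = FALSE)
  expect_identical(r$scaling, 1)
  expect_equal(r$state$kappa, 0.5 * 1.4 + 0.5)
  expect_identical(r$state$last_uv, "u1")   # memory persists across absent trials
})

test_that("weighted rate rule conserves the shared resource", {
  # delta = 0.1, alpha = 1, one u1 trial -> pair (1.1, 0.9)
  st <- rate_state("weighted", alpha = 1, delta = 0.1)
  r <- rate_step_weighted(st, "u1")
  expect_equal(r$kappa_pair, c(1.1, 0.9))

  # kappa1 + kappa2 = 2 after any 500-step random sequence, machine precision
  st <- rate_state("weighted", alpha = 0.9, delta = 0.1)
  set.seed(8)
  for (i in 1:500) {
    r <- rate_step_weighted(st, sample(c("u1", "u2"), 1),
                            uv_applies = runif(1) > 0.3)
    st <- r$state
    expect_equal(sum(st$kappa_pair), 2, tolerance = 1e-12)
  }

  # alpha = 0: pair pinned at (1, 1)
  st <- rate_state("weighted", alpha = 0, delta = 0.3)
  for (uv in c("u1", "u2", "u2")) {
    r <- rate_step_weighted(st, uv)
    expect_identical(r$scaling, 1)
    expect_equal(r$state$kappa_pair, c(1, 1))
    st <- r$state
  }
})

test_that("apply_rules composes scopes and honors the TDD gating", {
  # both scopes off: neutral modulations everywhere
  sched <- generate_exp3_block(2)
  tr <- schedule_as_trials(sched, "exp3_detection_mixed")
  m <- apply_rules(update_rule("no_update"), update_rule("no_update"), tr)
  expect_true(all(m$s0 == 0))
  expect_true(all(m$kappa == 1))

  # RDF s0 learning on an all-present run: s0 strictly increases early on
  tr_run <- make_detection_trials(rep(TRUE, 8),
                                  experiment = "exp1_detection_blocked")
  m <- apply_rules(update_rule("s0_decay", list(alpha = 0.9, beta0 = 2)),
                   update_rule("no_update"), tr_run)
  expect_true(all(diff(m$s0[1:5]) > 0))
  expect_equal(m$s0[1], 0)   # symmetric prior at start

  # TDD binary: kappa0 only when the immediately preceding trial was a
  # present trial in the other dimension
  tr3 <- make_detection_trials(c(TRUE, TRUE, TRUE, FALSE, TRUE),
                               dimension = c("color", "orientation",
                                             "orientation", "none", "color"))
  m <- apply_rules(update_rule("no_update"),
                   update_rule("rate_binary", list(kappa0 = 0.8)), tr3)
  expect_equal(m$kappa, c(1, 0.8, 1, 1, 1))

  # per-dimension beliefs drive s0 only on present trials
  m <- apply_rules(update_rule("no_update"),
                   update_rule("s0_decay", list(alpha = 0.8, beta0 = 2)), tr3)
  expect_identical(m$s0[4], 0)
})

test_that("equivalence limits: alpha 0 is no updating, alpha 1 is full memory", {
  set.seed(21)
  sched <- generate_exp3_schedule(6, n_blocks = 4)
  tr <- schedule_as_trials(sched, "exp3_detection_mixed")
  none <- apply_rules(update_rule("no_update"), update_rule("no_update"), tr)

  for (level in c("s0_decay", "rate_decay", "rate_weighted")) {
    params <- if (level == "s0_decay") list(alpha = 0, beta0 = 2)
              else list(alpha = 0, delta = 0.2)
    m_rdf <- apply_rules(update_rule(level, params), update_rule("no_update"), tr)
    expect_equal(m_rdf$s0, none$s0, tolerance = 1e-12)
    expect_equal(m_rdf$kappa, none$kappa, tolerance = 1e-12)
    if (level != "s0_decay") {
      m_tdd <- apply_rules(update_rule("no_update"), update_rule(level, params), tr)
      expect_equal(m_tdd$kappa, none$kappa, tolerance = 1e-12)
    }
  }

  # s0_decay with alpha = 1 traces s0_full_memory exactly, for both scopes
  full <- apply_rules(update_rule("s0_full_memory", list(beta0 = 3)),
                      update_rule("s0_full_memory", list(beta0 = 1.5)), tr)
  decay1 <- apply_rules(update_rule("s0_decay", list(alpha = 1, beta0 = 3)),
                        update_rule("s0_decay", list(alpha = 1, beta0 = 1.5)), tr)
  expect_equal(decay1$s0, full$s0, tolerance = 1e-12)
})

test_that("updating consumes stimulus truth, never responses", {
  set.seed(14)
  sched <- generate_exp1_schedule(9)
  tr <- schedule_as_trials(sched, "exp1_detection_blocked")
  rule <- update_rule("s0_decay", list(alpha = 0.8, beta0 = 2))
  m1 <- apply_rules(rule, update_rule("rate_decay", list(alpha = 0.9, delta = 0.1)), tr)
  # corrupt a sprinkling of responses: trajectories must not move
  tr2 <- tr
  flip <- sample(nrow(tr2), 40)
  tr2$response[flip] <- ifelse(tr2$target_present[flip], "absent", "present")
  tr2$correct[flip] <- FALSE
  m2 <- apply_rules(rule, update_rule("rate_decay", list(alpha = 0.9, delta = 0.1)), tr2)
  expect_identical(m1$s0, m2$s0)
  expect_identical(m1$kappa, m2$kappa)
})
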