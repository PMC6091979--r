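test_that("CSV round-trip is lossless and validates", {
  set.seed(1)
  sched <- generate_exp1_schedule(3)
  trials <- schedule_as_trials(sched, "exp1_detection_blocked",
                               rt = runif(nrow(sched), 0.3, 1.2))
  trials$correct[5] <- FALSE
  trials$response[5] <- "absent"

  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back[names(trials)], trials, tolerance = 1e-12)

  # header carries the documented 1-based interchange columns
  hdr <- names(read.csv(path, nrows = 1))
  expect_true(all(c("participant_id", "block", "trial", "rt_s") %in% hdr))
  expect_equal(min(read.csv(path)$trial), 1)
})

test_that("invariant violations are rejected with the offending row", {
  trials <- make_detection_trials(c(TRUE, FALSE, TRUE))
  bad <- trials
  bad$target_dimension[1] <- "none"   # present but no dimension
  expect_error(validate_trials(bad), "row 1")

  bad <- trials
  bad$target_feature[3] <- "tilt_left" # color dimension, orientation feature
  expect_error(validate_trials(bad), "inconsistent")

  bad <- trials
  bad$correct[2] <- FALSE              # response matches truth but flagged wrong
  expect_error(validate_trials(bad), "correct flag")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,experiment\np,exp", path)
  expect_error(read_trials(path), "missing column")
})

test_that("rdf value follows the task mapping of each experiment", {
  det <- make_detection_trials(c(TRUE, FALSE),
                               experiment = "exp1_detection_blocked")
  expect_equal(rdf_value(det), c("u1", "u2"))
  det3 <- make_detection_trials(c(FALSE, TRUE))
  expect_equal(rdf_value(det3), c("u2", "u1"))

  disc <- make_detection_trials(c(TRUE, TRUE),
                                dimension = c("color", "orientation"),
                                experiment = "exp2_dimension_discrimination",
                                response = c("color", "orientation"))
  expect_equal(rdf_value(disc), c("u1", "u2"))
})

test_that("modeling outlier rule excludes errors, slow and fast-tail trials", {
  # > 2 s excluded even when correct
  tr <- make_detection_trials(rep(TRUE, 6),
                              rt = c(0.4, 0.45, 0.5, 0.55, 2.5, 0.6))
  inc <- modeling_outlier_mask(tr)
  expect_false(inc[5])
  expect_true(all(inc[-5]))

  # tight sample: no exclusions
  tr <- make_detection_trials(rep(TRUE, 4), rt = c(0.40, 0.41, 0.42, 0.43))
  expect_true(all(modeling_outlier_mask(tr)))

  # hand computation: twenty 0.5 s trials and one 0.05 s trial;
  # mean ~ 0.479, IQR = 0 on 0.5-only quartiles is 0; use a spread sample
  rt <- c(seq(0.45, 0.55, length.out = 20), 0.05)
  tr <- make_detection_trials(rep(TRUE, 21), rt = rt)
  m <- mean(rt); iqr <- IQR(rt)
  expect_true(0.05 < m - 1.5 * iqr)   # oracle for the rule itself
  inc <- modeling_outlier_mask(tr)
  expect_false(inc[21])
  expect_true(all(inc[-21]))

  # error trials always excluded; statistics computed over correct trials only
  tr <- make_detection_trials(rep(TRUE, 6), rt = rep(0.5, 6),
                              response = c("present", "absent",
                                           rep("present", 4)))
  inc <- modeling_outlier_mask(tr)
  expect_false(inc[2])
  expect_true(all(inc[-2]))

  expect_error(modeling_outlier_mask(tr[0, ]), "empty")
})

test_that("descriptive outlier rule uses the 3-SD inverse-RT criterion", {
  # all equal RTs: SD = 0, nothing excluded
  tr <- make_detection_trials(rep(TRUE, 5), rt = rep(0.5, 5))
  expect_true(all(descriptive_outlier_mask(tr)))

  # one extreme inverse RT among thirty
  set.seed(7)
  rt <- c(rnorm(30, 0.5, 0.02), 0.05)
  tr <- make_detection_trials(rep(TRUE, 31), rt = rt)
  inv <- 1 / rt
  expect_true(abs(inv[31] - mean(inv)) > 3 * sd(inv))  # sample is an outlier
  inc <- descriptive_outlier_mask(tr)
  expect_false(inc[31])

  # error trials excluded regardless of rt
  tr <- make_detection_trials(rep(TRUE, 5), rt = rep(0.5, 5),
                              response = c("absent", rep("present", 4)))
  expect_false(descriptive_outlier_mask(tr)[1])
})

test_that("masks are idempotent and do not touch the trial sequence", {
  set.seed(42)
  sched <- generate_exp3_block(11)
  trials <- schedule_as_trials(sched, "exp3_detection_mixed",
                               rt = runif(65, 0.3, 0.9))
  trials$rt[10] <- 2.6
  inc <- modeling_outlier_mask(trials)
  expect_false(inc[10])
  # idempotence: re-masking the included subset excludes nothing further
  expect_true(all(modeling_outlier_mask(trials[inc, ])))
  dinc <- descriptive_outlier_mask(trials)
  expect_true(all(descriptive_outlier_mask(trials[dinc, ])))
  # masking must not change updating trajectories: apply_rules ignores masks
  rule <- update_rule("s0_decay", list(alpha = 0.8, beta0 = 2))
  m1 <- apply_rules(rule, update_rule("no_update"), trials)
  trials2 <- trials; trials2$correct[3] <- FALSE
  trials2$response[3] <- ifelse(trials2$target_present[3], "absent", "present")
  m2 <- apply_rules(rule, update_rule("no_update"), trials2)
  expect_identical(m1$s0, m2$s0)
  expect_identical(m1$kappa, m2$kappa)
})
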