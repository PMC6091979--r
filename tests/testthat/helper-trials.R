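# Small hand-built trial tables used across tests.

# A detection-experiment trial table from explicit vectors; response defaults
# to the correct one, rt to 0.5 s.
make_detection_trials <- function(present,
                                  dimension = ifelse(present, "color", "none"),
                                  feature = NULL,
                                  rt = rep(0.5, length(present)),
                                  response = NULL,
                                  participant_id = "p01",
                                  experiment = "exp3_detection_mixed",
                                  block = rep(0L, length(present))) {
  if (is.null(feature)) {
    feature <- c(color = "green", orientation = "tilt_left",
                 none = "none")[dimension]
  }
  truth <- ifelse(present, "present", "absent")
  if (is.null(response)) response <- truth
  data.frame(participant_id = participant_id, experiment = experiment,
             section = 0L, block = block,
             trial = as.integer(seq_along(present) - 1L),
             target_present = present, target_dimension = dimension,
             target_feature = unname(feature), response = response,
             correct = response == truth, rt = rt,
             stringsAsFactors = FALSE)
}

# Schedule -> minimal trial table (correct responses, constant rt), for
# feeding schedules into apply_rules / summaries.
schedule_as_trials <- function(sched, experiment, rt = 0.5,
                               participant_id = "p01") {
  truth <- if (experiment == "exp2_dimension_discrimination") {
    sched$target_dimension
  } else {
    ifelse(sched$target_present, "present", "absent")
  }
  data.frame(participant_id = participant_id, experiment = experiment,
             section = sched$section, block = sched$block, trial = sched$trial,
             target_present = sched$target_present,
             target_dimension = sched$target_dimension,
             target_feature = sched$target_feature,
             response = truth, correct = TRUE, rt = rt,
             stringsAsFactors = FALSE)
}

# Ordered-pair census of an Experiment-3 block over the 8 De Bruijn labels
# (target features 1:4, absent placeholders collapse onto their original
# labels is impossible post hoc, so the census works on the emitted stimuli:
# 4 features + absent). Returns the 5x5 transition count matrix.
stimulus_pair_census <- function(block) {
  lab <- ifelse(block$target_present, block$target_feature, "absent")
  lev <- c("green", "purple", "tilt_left", "tilt_right", "absent")
  table(factor(lab[-length(lab)], lev), factor(lab[-1], lev))
}
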