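#' Trial-level data model for pop-out search experiments
#'
#' A trial table is a plain `data.frame` with one row per search trial, in
#' presentation order within participant, carrying the stimulus truth
#' (target presence, defining dimension, feature), the recorded response,
#' its correctness, and the reaction time in seconds. All indices are
#' 0-based internally; the CSV interchange format carries 1-based
#' `section`/`block`/`trial` columns and an `rt_s` column (see
#' [read_trials()]).
#'
#' @name trial-data
#' @keywords internal
NULL

.experiments <- c("exp1_detection_blocked", "exp2_dimension_discrimination",
                  "exp3_detection_mixed")
.dimensions  <- c("color", "orientation", "none")
.features    <- c("green", "purple", "tilt_left", "tilt_right", "none")
.responses   <- c("present", "absent", "color", "orientation")

.trial_cols <- c("participant_id", "experiment", "section", "block", "trial",
                 "target_present", "target_dimension", "target_feature",
                 "response", "correct", "rt")

feature_dimension <- function(feature) {
  c(green = "color", purple = "color", tilt_left = "orientation",
    tilt_right = "orientation", none = "none")[feature]
}

#' Validate a trial table against the data-model invariants
#'
#' Checks column presence and types, the coupling between target presence,
#' dimension and feature, the detection/discrimination response alphabet,
#' and the consistency of the `correct` flag with the stimulus truth.
#'
#' @param trials data.frame of trials (see [read_trials()] for columns).
#' @return `trials`, invisibly, if valid; otherwise an error naming the
#'   first offending row.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(.trial_cols, names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_row <- function(cond, what) {
    if (any(cond)) {
      stop("invalid trial data (row ", which(cond)[1], "): ", what)
    }
  }
  bad_row(!trials$experiment %in% .experiments, "unknown experiment label")
  bad_row(!trials$target_dimension %in% .dimensions, "unknown target_dimension")
  bad_row(!trials$target_feature %in% .features, "unknown target_feature")
  bad_row(!trials$response %in% .responses, "unknown response")
  bad_row(!is.finite(trials$rt) | trials$rt <= 0, "rt must be a positive number of seconds")

  pres <- trials$target_present
  bad_row(pres != (trials$target_dimension != "none"),
          "target_present = FALSE <=> target_dimension = none violated")
  bad_row(pres != (trials$target_feature != "none"),
          "target_present = FALSE <=> target_feature = none violated")
  bad_row(trials$target_dimension != unname(feature_dimension(trials$target_feature)),
          "target_feature inconsistent with target_dimension")
  bad_row(trials$experiment == "exp2_dimension_discrimination" & !pres,
          "experiment 2 requires a target on every trial")

  is_exp2 <- trials$experiment == "exp2_dimension_discrimination"
  bad_row(!is_exp2 & !trials$response %in% c("present", "absent"),
          "detection experiments take present/absent responses")
  bad_row(is_exp2 & !trials$response %in% c("color", "orientation"),
          "discrimination experiment takes color/orientation responses")

  truth <- ifelse(is_exp2, trials$target_dimension,
                  ifelse(pres, "present", "absent"))
  bad_row(trials$correct != (trials$response == truth),
          "correct flag inconsistent with response and stimulus truth")
  invisible(trials)
}

#' Read a trial table from CSV
#'
#' The interchange format is comma-separated UTF-8 with a header row and
#' columns `participant_id`, `experiment`, `section`, `block`, `trial`
#' (1-based), `target_present` (0/1), `target_dimension`, `target_feature`,
#' `response`, `correct` (0/1) and `rt_s` (decimal seconds). Non-default
#' column names can be mapped via `schema`.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical column
#'   names (names) to the file's column names (values).
#' @return data.frame of validated trials with 0-based `section`, `block`
#'   and `trial` indices, ordered by participant, section, block, trial.
#' @export
read_trials <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  file_cols <- c(.trial_cols[1:10], "rt_s")
  names(file_cols) <- c(.trial_cols[1:10], "rt")
  if (!is.null(schema)) file_cols[names(schema)] <- schema
  missing <- setdiff(unname(file_cols), names(raw))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  trials <- setNames(raw[, unname(file_cols)], names(file_cols))
  trials$target_present <- as.logical(trials$target_present)
  trials$correct <- as.logical(trials$correct)
  for (col in c("section", "block", "trial")) {
    trials[[col]] <- as.integer(trials[[col]]) - 1L   # to 0-based
  }
  trials <- trials[order(trials$participant_id, trials$section,
                         trials$block, trials$trial), , drop = FALSE]
  rownames(trials) <- NULL
  validate_trials(trials)
  trials
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trials()]: indices are converted back to 1-based and
#' `rt` is written as `rt_s`; logicals are written as 0/1.
#'
#' @param trials validated trial table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  out <- trials[, .trial_cols]
  for (col in c("section", "block", "trial")) out[[col]] <- out[[col]] + 1L
  out$target_present <- as.integer(out$target_present)
  out$correct <- as.integer(out$correct)
  names(out)[names(out) == "rt"] <- "rt_s"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Response-defining feature (RDF) value of each trial
#'
#' The RDF is the stimulus attribute mapped to the response: target
#' presence/absence in the detection experiments (1 and 3) and the target
#' dimension (color vs. orientation) in the discrimination experiment (2).
#' Its two values are coded `"u1"`/`"u2"`: present/color are `u1`,
#' absent/orientation are `u2`.
#'
#' @param trials trial table.
#' @return character vector of `"u1"`/`"u2"`, one per trial.
#' @export
rdf_value <- function(trials) {
  is_exp2 <- trials$experiment == "exp2_dimension_discrimination"
  ifelse(is_exp2,
         ifelse(trials$target_dimension == "color", "u1", "u2"),
         ifelse(trials$target_present, "u1", "u2"))
}

per_participant <- function(trials, f) {
  out <- logical(nrow(trials))
  for (pid in unique(trials$participant_id)) {
    idx <- which(trials$participant_id == pid)
    out[idx] <- f(trials[idx, , drop = FALSE])
  }
  out
}

#' Likelihood-inclusion mask for model fitting
#'
#' Flags the trials that enter the likelihood: error trials are excluded,
#' as are correct trials with RT above 2 s or more than 1.5 interquartile
#' ranges below the mean RT. Mean and IQR are computed per participant
#' over that participant's correct trials within the 2-s cap; if the IQR
#' is zero no lower-tail exclusion is applied. The mask only gates
#' likelihood sums -- every
#' trial, including errors and outliers, is still presented to the
#' updating rules.
#'
#' @param trials trial table (at least 4 trials per participant).
#' @return logical vector `include_in_likelihood`, one element per trial.
#' @export
modeling_outlier_mask <- function(trials) {
  if (nrow(trials) == 0) stop("empty trial table")
  per_participant(trials, function(tr) {
    if (nrow(tr) < 4) {
      stop("participant ", tr$participant_id[1],
           " has fewer than 4 trials; IQR-based outlier rule undefined")
    }
    # location statistics over correct trials within the 2-s cap, so a
    # single very slow trial cannot inflate the mean and sweep the fast
    # tail out with it
    ok <- tr$correct & tr$rt <= 2
    m <- mean(tr$rt[ok])
    iqr <- unname(stats::IQR(tr$rt[ok]))
    lower <- if (iqr > 0) m - 1.5 * iqr else -Inf
    tr$correct & tr$rt <= 2 & tr$rt >= lower
  })
}

#' Descriptive-inclusion mask for mean-RT analyses
#'
#' Flags the trials that enter descriptive RT summaries: error trials are
#' excluded, as are trials whose inverse RT (1/RT) lies more than three
#' standard deviations from the participant's mean inverse RT (mean and SD
#' over correct trials; no exclusion when the SD is zero).
#'
#' @param trials trial table (at least 2 trials per participant).
#' @return logical vector `include_in_descriptives`, one element per trial.
#' @export
descriptive_outlier_mask <- function(trials) {
  if (nrow(trials) == 0) stop("empty trial table")
  per_participant(trials, function(tr) {
    if (nrow(tr) < 2) stop("participant ", tr$participant_id[1],
                           " has fewer than 2 trials")
    inv <- 1 / tr$rt
    m <- mean(inv[tr$correct])
    s <- sd(inv[tr$correct])
    if (!is.finite(s) || s == 0) return(tr$correct)
    tr$correct & abs(inv - m) <= 3 * s
  })
}
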