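#' Descriptive inter-trial summaries
#'
#' Per-participant cell summaries of mean correct RT, its standard
#' error, trial counts and error rates, split by repetition vs. switch
#' of the target condition, the target dimension, or the target feature
#' relative to the preceding trial. Pairs are formed within blocks only:
#' the first trial of each block carries no inter-trial label (blocks
#' are separated by feedback screens). RT statistics use trials passing
#' the descriptive mask; error rates are computed over all trials of the
#' cell.
#'
#' @name reporting
NULL

# previous-trial index within the same participant and block (NA otherwise)
prev_in_block <- function(trials, lag = 1L) {
  n <- nrow(trials)
  prev <- seq_len(n) - lag
  prev[prev < 1] <- NA
  ok <- !is.na(prev) &
    trials$participant_id[pmax(prev, 1)] == trials$participant_id &
    trials$block[pmax(prev, 1)] == trials$block &
    trials$section[pmax(prev, 1)] == trials$section
  prev[!ok] <- NA
  prev
}

cell_summarize <- function(trials, keep_rt, groups) {
  df <- cbind(data.frame(participant_id = trials$participant_id,
                         stringsAsFactors = FALSE), groups)
  df$rt <- ifelse(keep_rt, trials$rt, NA_real_)
  df$err <- !trials$correct
  in_cell <- stats::complete.cases(groups)
  df <- df[in_cell, , drop = FALSE]
  if (nrow(df) == 0) {
    return(data.frame(participant_id = character(0)))
  }
  key <- c("participant_id", names(groups))
  agg <- aggregate(df$rt, by = df[key], FUN = function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), sem = sd(x) / sqrt(length(x)), n = length(x))
  })
  stats_mat <- agg$x
  agg$x <- NULL
  agg$mean_rt <- stats_mat[, "mean"]
  agg$sem <- stats_mat[, "sem"]
  agg$n <- stats_mat[, "n"]
  er <- aggregate(df$err, by = df[key], FUN = mean)
  agg$error_rate <- er$x[match(do.call(paste, agg[key]),
                               do.call(paste, er[key]))]
  agg[order(do.call(paste, agg[key])), , drop = FALSE]
}

#' Repeat/switch summary of the target condition
#'
#' Labels every within-block trial pair as a repetition or switch of the
#' target condition (absent / color / orientation; for the
#' discrimination experiment, color / orientation) and summarizes RTs
#' per participant, frequency condition and target condition. Target
#' frequency is the section frequency of the trial's own target
#' condition.
#'
#' @param trials trial table (all participants).
#' @param mask descriptive inclusion mask (default
#'   [descriptive_outlier_mask()]).
#' @param section_order ratio permutation used at generation time.
#' @return data.frame with columns `participant_id`, `frequency`,
#'   `condition`, `intertrial`, `mean_rt`, `sem`, `n`, `error_rate`.
#' @export
intertrial_summary <- function(trials, mask = NULL,
                               section_order = c(0.75, 0.50, 0.25)) {
  if (is.null(mask)) mask <- descriptive_outlier_mask(trials)
  cond <- trial_class(trials)
  prev <- prev_in_block(trials)
  intertrial <- ifelse(is.na(prev), NA_character_,
                       ifelse(cond == cond[pmax(prev, 1)], "repeat", "switch"))
  ratio <- section_ratio(trials, section_order)
  freq <- if (trials$experiment[1] == "exp2_dimension_discrimination") {
    ifelse(cond == "color", ratio, 1 - ratio)
  } else {
    ifelse(cond == "absent", 1 - ratio, ratio)
  }
  cell_summarize(trials, mask & trials$correct,
                 data.frame(frequency = freq, condition = cond,
                            intertrial = intertrial, stringsAsFactors = FALSE))
}

#' Dimension repetition/switch summary
#'
#' Restricts to target-present trials whose immediately preceding trial
#' (within the block) was also target-present, and classifies them by
#' repetition vs. switch of the target-defining dimension. The
#' `lag2` component reports the analogous contrast from trial n-2 to
#' trial n, restricted to present pairs whose intervening trial does not
#' itself repeat the dimension of trial n (isolating the two-back
#' effect).
#'
#' @inheritParams intertrial_summary
#' @return list with data.frames `lag1` and `lag2` (columns as in
#'   [intertrial_summary()] with `condition` = target dimension).
#' @export
dimension_repetition_summary <- function(trials, mask = NULL) {
  if (is.null(mask)) mask <- descriptive_outlier_mask(trials)
  dims <- trials$target_dimension
  pres <- trials$target_present

  prev1 <- prev_in_block(trials)
  pair1 <- pres & !is.na(prev1) & pres[pmax(prev1, 1)]
  lab1 <- rep(NA_character_, nrow(trials))
  lab1[pair1] <- ifelse(dims[pair1] == dims[prev1[pair1]], "repeat", "switch")
  lag1 <- cell_summarize(trials, mask & trials$correct,
                         data.frame(condition = ifelse(pair1, dims, NA),
                                    intertrial = lab1,
                                    stringsAsFactors = FALSE))

  prev2 <- prev_in_block(trials, lag = 2L)
  pair2 <- pres & !is.na(prev2) & pres[pmax(prev2, 1)]
  # exclude cases where trial n-1 already shares trial n's dimension
  mid_same <- !is.na(prev1) & pres[pmax(prev1, 1)] &
    dims == dims[pmax(prev1, 1)]
  pair2 <- pair2 & !mid_same
  lab2 <- rep(NA_character_, nrow(trials))
  lab2[pair2] <- ifelse(dims[pair2] == dims[prev2[pair2]], "repeat", "switch")
  lag2 <- cell_summarize(trials, mask & trials$correct,
                         data.frame(condition = ifelse(pair2, dims, NA),
                                    intertrial = lab2,
                                    stringsAsFactors = FALSE))
  list(lag1 = lag1, lag2 = lag2)
}

#' Feature repetition/switch summary
#'
#' Among within-block consecutive target-present pairs in which the
#' target dimension stayed the same, classifies trials by repetition vs.
#' switch of the target feature, per dimension.
#'
#' @inheritParams intertrial_summary
#' @return data.frame as in [intertrial_summary()] with `condition` =
#'   target dimension.
#' @export
feature_repetition_summary <- function(trials, mask = NULL) {
  if (is.null(mask)) mask <- descriptive_outlier_mask(trials)
  dims <- trials$target_dimension
  feats <- trials$target_feature
  pres <- trials$target_present
  prev <- prev_in_block(trials)
  pair <- pres & !is.na(prev) & pres[pmax(prev, 1)] &
    dims == dims[pmax(prev, 1)]
  lab <- rep(NA_character_, nrow(trials))
  lab[pair] <- ifelse(feats[pair] == feats[prev[pair]], "repeat", "switch")
  cell_summarize(trials, mask & trials$correct,
                 data.frame(condition = ifelse(pair, dims, NA),
                            intertrial = lab, stringsAsFactors = FALSE))
}
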