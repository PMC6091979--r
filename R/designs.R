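#' Trial-sequence generators for the three experimental designs
#'
#' These functions produce stimulus schedules only (no RTs): data.frames
#' with 0-based `section`, `block` (within experiment) and `trial` (within
#' block) indices plus the stimulus truth columns `target_present`,
#' `target_dimension` and `target_feature`.
#'
#' Experiments 1 and 2 run 3 sections x 10 blocks x 40 trials with
#' target-present (Exp 1) resp. color-target (Exp 2) proportions of
#' 75/50/25% across sections. Counts are exact per block
#' (shuffled fixed multisets rather than i.i.d. draws), so the stated
#' block proportions hold exactly. Experiment 3 runs 65-trial blocks built
#' from a De Bruijn sequence (see [generate_exp3_block()]).
#'
#' @name designs
NULL

.exp12_ratios <- c(0.75, 0.50, 0.25)

draw_features <- function(dimension, n) {
  feats <- switch(dimension,
                  color = c("green", "purple"),
                  orientation = c("tilt_left", "tilt_right"))
  sample(feats, n, replace = TRUE)
}

schedule_row_template <- function(n) {
  data.frame(section = integer(n), block = integer(n), trial = integer(n),
             target_present = logical(n), target_dimension = character(n),
             target_feature = character(n), stringsAsFactors = FALSE)
}

#' Generate an Experiment-1 schedule (blocked detection)
#'
#' Three sections of ten 40-trial blocks; within each block the number of
#' target-present trials is exactly `ratio * 40`. Blocks alternate between
#' color-only and orientation-only targets (starting with color), and the
#' target feature on present trials is drawn uniformly within the block's
#' dimension.
#'
#' @param seed integer seed; the same seed reproduces the same schedule.
#' @param section_order permutation of the target-present ratios, one per
#'   section (default 0.75, 0.50, 0.25).
#' @return schedule data.frame of 1200 trials.
#' @export
generate_exp1_schedule <- function(seed, section_order = .exp12_ratios) {
  stopifnot(length(section_order) == 3, all(section_order %in% .exp12_ratios))
  with_seed(seed, {
    sections <- lapply(seq_along(section_order), function(s) {
      blocks <- lapply(0:9, function(b) {
        global_block <- (s - 1L) * 10L + b
        dimension <- if (global_block %% 2L == 0L) "color" else "orientation"
        n_present <- as.integer(round(section_order[s] * 40))
        present <- sample(rep(c(TRUE, FALSE), c(n_present, 40L - n_present)))
        out <- schedule_row_template(40L)
        out$section <- s - 1L
        out$block <- global_block
        out$trial <- 0:39
        out$target_present <- present
        out$target_dimension <- ifelse(present, dimension, "none")
        out$target_feature <- "none"
        out$target_feature[present] <- draw_features(dimension, n_present)
        out
      })
      do.call(rbind, blocks)
    })
    do.call(rbind, sections)
  })
}

#' Generate an Experiment-2 schedule (dimension discrimination)
#'
#' As Experiment 1 but a target is present on every trial; within each
#' block exactly `ratio * 40` trials carry a color target (the rest
#' orientation), with both dimensions interleaved within the block.
#'
#' @inheritParams generate_exp1_schedule
#' @param section_order permutation of the color-target ratios.
#' @return schedule data.frame of 1200 trials.
#' @export
generate_exp2_schedule <- function(seed, section_order = .exp12_ratios) {
  stopifnot(length(section_order) == 3, all(section_order %in% .exp12_ratios))
  with_seed(seed, {
    sections <- lapply(seq_along(section_order), function(s) {
      blocks <- lapply(0:9, function(b) {
        n_color <- as.integer(round(section_order[s] * 40))
        dims <- sample(rep(c("color", "orientation"), c(n_color, 40L - n_color)))
        out <- schedule_row_template(40L)
        out$section <- s - 1L
        out$block <- (s - 1L) * 10L + b
        out$trial <- 0:39
        out$target_present <- TRUE
        out$target_dimension <- dims
        out$target_feature[dims == "color"] <- draw_features("color", n_color)
        out$target_feature[dims == "orientation"] <- draw_features("orientation", 40L - n_color)
        out
      })
      do.call(rbind, blocks)
    })
    do.call(rbind, sections)
  })
}

# Random Eulerian circuit on the complete digraph (with self-loops) over
# `n_labels` vertices, by Hierholzer's algorithm with randomized edge order.
# Returns a vertex sequence of length n_labels^2 + 1 whose consecutive pairs
# enumerate every ordered pair of labels exactly once.
random_eulerian_sequence <- function(n_labels) {
  nbrs <- lapply(seq_len(n_labels), function(v) sample(seq_len(n_labels)))
  next_edge <- rep(1L, n_labels)
  start <- sample(n_labels, 1)
  stack <- c(start)
  circuit <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    if (next_edge[v] <= n_labels) {
      u <- nbrs[[v]][next_edge[v]]
      next_edge[v] <- next_edge[v] + 1L
      stack <- c(stack, u)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  rev(circuit)
}

.exp3_labels <- data.frame(
  label = 1:8,
  target_present = c(rep(TRUE, 4), rep(FALSE, 4)),
  target_dimension = c("color", "color", "orientation", "orientation",
                       rep("none", 4)),
  target_feature = c("green", "purple", "tilt_left", "tilt_right",
                     rep("none", 4)),
  stringsAsFactors = FALSE)

#' Generate one Experiment-3 block (De Bruijn-balanced mixed detection)
#'
#' Builds a linear (non-cyclic) order-2 De Bruijn sequence over eight trial
#' labels -- the four target types (green, purple, left-tilted,
#' right-tilted) plus four placeholder labels that all realize the
#' target-absent display -- by drawing a random Eulerian circuit on the
#' complete 8-vertex digraph. Every ordered pair of labels occurs exactly
#' once among consecutive trials, so each target type is followed exactly
#' once by each of the 8 labels; collapsing the placeholders, each target
#' type is followed equally often (4 times) by a target-present as by a
#' target-absent trial, and equally often by every target type including
#' itself. The construction needs 8^2 + 1 = 65 trials.
#'
#' @param seed integer seed selecting a member of the De Bruijn family.
#' @return schedule data.frame of 65 trials (`section`/`block` set to 0).
#' @export
generate_exp3_block <- function(seed) {
  labels <- with_seed(seed, random_eulerian_sequence(8L))
  out <- .exp3_labels[labels, -1]
  out <- cbind(schedule_row_template(length(labels))[1:3], out)
  out$trial <- seq_along(labels) - 1L
  rownames(out) <- NULL
  out
}

#' Generate a full Experiment-3 schedule
#'
#' Concatenates independent De Bruijn-balanced 65-trial blocks
#' (one section; target presence and the two dimensions each balanced
#' 50/50 up to the odd trial).
#'
#' @param seed integer seed.
#' @param n_blocks number of 65-trial blocks (default 20, giving a session
#'   length comparable to the 1200 trials of Experiments 1-2).
#' @return schedule data.frame of `65 * n_blocks` trials.
#' @export
generate_exp3_schedule <- function(seed, n_blocks = 20L) {
  blocks <- lapply(seq_len(n_blocks), function(b) {
    out <- generate_exp3_block((abs(seed) %% 1000000L) * 1000L + b)
    out$block <- b - 1L
    out
  })
  do.call(rbind, blocks)
}

#' Section ratio of each trial in a schedule
#'
#' For Experiments 1-2, maps each trial to its section's design ratio
#' (target-present proportion for Exp 1, color-target proportion for
#' Exp 2); 0.5 everywhere for Experiment 3.
#'
#' @param schedule schedule or trial data.frame.
#' @param section_order ratio permutation used at generation time.
#' @return numeric vector of per-trial section ratios.
#' @export
section_ratio <- function(schedule, section_order = .exp12_ratios) {
  if (all(schedule$section == 0L)) return(rep(0.5, nrow(schedule)))
  section_order[schedule$section + 1L]
}
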