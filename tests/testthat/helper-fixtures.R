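# Shared fixtures built in code.

exp1_grid <- function() grid_spec(22, 16)
exp2_grid <- function() grid_spec(32, 24, screen_px = c(1280, 1024))

# A hand-built classified fixation report: `labels` is a list of per-trial
# label vectors for fixations 2..(length+1); fixation 1 is always
# "unclassified" (the forced central fixation).
toy_classified <- function(labels, participant = 1, condition = "split_half",
                           target_present = FALSE, correct = TRUE) {
  rows <- lapply(seq_along(labels), function(t) {
    lab <- c("unclassified", labels[[t]])
    data.frame(participant = participant, trial = t, phase = "search",
               condition = condition, configuration = "hard_up",
               target_present = target_present,
               target_col = NA_integer_, target_row = NA_integer_,
               response = if (target_present) "present" else "absent",
               correct = correct, rt_ms = 1000 * length(lab),
               fix_index = seq_along(lab),
               x_px = 512, y_px = 384, dur_ms = 250,
               stim_id = t, label = lab,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Tiny accuracy table for exclusion-rule tests: one participant, given
# TA accuracy and (optionally) hard-condition TP accuracy.
toy_by_condition <- function(participant, ta_accuracy, hard_accuracy = NA) {
  out <- data.frame(participant = participant, condition = "split_half",
                    target = "absent", n_trials = 80,
                    accuracy = ta_accuracy, median_rt_ms = 5000,
                    stringsAsFactors = FALSE)
  if (!is.na(hard_accuracy)) {
    out <- rbind(out, data.frame(participant = participant, condition = "hard",
                                 target = "present", n_trials = 12,
                                 accuracy = hard_accuracy, median_rt_ms = 6000,
                                 stringsAsFactors = FALSE))
  }
  out
}

# Orientation membership modulo pi: is `ori` within the closed interval of
# half-width `range/2` around `centre`, on the circle of circumference pi?
ori_in_range <- function(ori, centre, range) {
  d <- (ori - centre) %% pi
  d <- pmin(d, pi - d)
  d <= range / 2 + 1e-9
}
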