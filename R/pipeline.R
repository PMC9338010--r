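# Preprocessing, fixation classification, exclusion filters and the
# search-strategy (efficiency) statistic.

report_required_cols <- c("participant", "trial", "phase", "condition",
                          "configuration", "target_present", "target_col",
                          "target_row", "response", "correct", "rt_ms",
                          "fix_index", "x_px", "y_px", "dur_ms")

#' Read a fixation report
#'
#' Parses the tab-separated fixation table produced by
#' [write_fixation_report()] (or an equivalent export from an eye-tracking
#' preprocessing chain). Missing columns and non-numeric coordinates are
#' rejected with informative errors naming the column and the offending rows.
#'
#' @param path path to the report file.
#' @return A fixation-report data frame.
#' @export
read_fixation_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  report <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(report_required_cols, names(report))
  if (length(missing)) {
    stop(sprintf("fixation report is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("x_px", "y_px", "dur_ms", "rt_ms", "fix_index")) {
    v <- report[[col]]
    if (!is.numeric(v) && !is.logical(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric values in column '%s' at row(s) %s",
                     col, paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      }
      report[[col]] <- num
    }
  }
  report
}

fixation_labels <- c("heterogeneous", "homogeneous", "unclassified", "out_of_bounds")

#' Flag fixations landing outside the search array
#'
#' Uses the half-open pixel convention: a fixation is inside iff
#' `origin <= p < origin + extent` on both axes, so a fixation at exactly the
#' right or bottom edge is out of bounds.
#'
#' @param x_px,y_px fixation coordinates (vectors).
#' @param grid a [grid_spec()] giving the array origin and extent.
#' @return Logical vector, `TRUE` where out of bounds.
#' @export
mark_out_of_bounds <- function(x_px, y_px, grid) {
  o <- grid$origin_px; e <- grid_extent_px(grid)
  x_px < o[1] | x_px >= o[1] + e[1] | y_px < o[2] | y_px >= o[2] + e[2]
}

#' Classify fixations on a split-half array
#'
#' Labels each fixation by the side of the midline it falls on, mapped to
#' heterogeneous/homogeneous via the configuration (`"hard_up"`,
#' `"hard_down"`, `"hard_left"`, `"hard_right"`). Fixations within the
#' central strip of total width `strip_px` (half on each side of the midline,
#' oriented along the split axis) are left unclassified; a fixation exactly
#' at `strip_px / 2` from the midline counts as classified.
#'
#' @inheritParams mark_out_of_bounds
#' @param configuration configuration string (scalar or vector).
#' @param strip_px total width (px) of the unclassified central strip.
#' @return Character vector of labels (`"heterogeneous"`, `"homogeneous"`, or
#'   `"unclassified"`); out-of-bounds filtering is the caller's job.
#' @export
classify_split_half <- function(x_px, y_px, configuration, grid, strip_px = 30) {
  n <- length(x_px)
  configuration <- rep_len(configuration, n)
  ok <- configuration %in% c("hard_up", "hard_down", "hard_left", "hard_right")
  if (any(!ok)) {
    stop(sprintf("unknown split-half configuration: %s",
                 paste(unique(configuration[!ok]), collapse = ", ")), call. = FALSE)
  }
  o <- grid$origin_px; e <- grid_extent_px(grid)
  horiz <- configuration %in% c("hard_up", "hard_down")   # up/down halves
  delta <- ifelse(horiz, y_px - (o[2] + e[2] / 2), x_px - (o[1] + e[1] / 2))
  first_side <- delta < 0                                  # up, or left
  hard_first <- configuration %in% c("hard_up", "hard_left")
  label <- ifelse(first_side == hard_first, "heterogeneous", "homogeneous")
  label[abs(delta) < strip_px / 2] <- "unclassified"
  label
}

#' Classify fixations on a jumbled array
#'
#' A fixation is heterogeneous iff the difficulty of the fixated cell exceeds
#' `threshold` (strictly; a cell at exactly the threshold is homogeneous).
#'
#' @inheritParams mark_out_of_bounds
#' @param stim the trial's `stimulus_array` (provides cell difficulties).
#' @param threshold difficulty cut point (default 0.5).
#' @return Character vector of labels.
#' @export
classify_jumbled <- function(x_px, y_px, stim, threshold = 0.5) {
  cells <- px_to_cell(stim$grid, x_px, y_px)
  if (anyNA(cells)) {
    stop("out-of-bounds fixations must be filtered before classify_jumbled()",
         call. = FALSE)
  }
  d <- stim$cell_difficulty[cbind(cells[, "row"] + 1L, cells[, "col"] + 1L)]
  ifelse(d > threshold, "heterogeneous", "homogeneous")
}

#' Classify every fixation of a report
#'
#' Applies, in order: the out-of-bounds rule ([mark_out_of_bounds()]), the
#' split-half midline rule with the unclassified central strip
#' ([classify_split_half()]) for split-half trials, and the cell-difficulty
#' threshold rule ([classify_jumbled()]) for jumbled trials. Uniformly easy /
#' hard arrays are homogeneous / heterogeneous everywhere. The four labels
#' partition the fixations.
#'
#' @param report a fixation-report data frame.
#' @param grid a [grid_spec()]; default from `experiment`.
#' @param stimuli stimulus list indexed by the report's `stim_id` column
#'   (attached automatically by the simulator); required when the report
#'   contains jumbled trials.
#' @param experiment `"exp1"` or `"exp2"`, used only for the default grid.
#' @param strip_px,threshold classification parameters.
#' @return The report with an added `label` column.
#' @export
classify_fixations <- function(report, grid = NULL, stimuli = NULL,
                               experiment = c("exp1", "exp2"),
                               strip_px = 30, threshold = 0.5) {
  experiment <- match.arg(experiment)
  grid <- grid %||% experiment_grid(experiment)
  stimuli <- stimuli %||% attr(report, "stimuli")
  label <- rep(NA_character_, nrow(report))

  oob <- mark_out_of_bounds(report$x_px, report$y_px, grid)
  label[oob] <- "out_of_bounds"

  sh <- !oob & report$condition == "split_half"
  if (any(sh)) {
    label[sh] <- classify_split_half(report$x_px[sh], report$y_px[sh],
                                     report$configuration[sh], grid, strip_px)
  }
  ez <- !oob & report$condition == "easy"
  label[ez] <- "homogeneous"
  hd <- !oob & report$condition == "hard"
  label[hd] <- "heterogeneous"

  jm <- !oob & report$condition == "jumbled"
  if (any(jm)) {
    if (is.null(stimuli)) {
      stop("jumbled trials need `stimuli` (per-cell difficulties) to classify",
           call. = FALSE)
    }
    for (sid in unique(report$stim_id[jm])) {
      sel <- jm & report$stim_id == sid
      label[sel] <- classify_jumbled(report$x_px[sel], report$y_px[sel],
                                     stimuli[[sid]], threshold)
    }
  }
  report$label <- label
  report
}

#' Search-efficiency (strategy) score
#'
#' Pools classified fixations with index in `fix_range` (default 2--6; the
#' first fixation is the forced central one) over *correct target-absent
#' search trials*, and scores each participant's strategy as
#' `n_het / (n_het + n_homo)` -- the proportion of classified fixations on
#' heterogeneous regions, 1 being optimal. Unclassified and out-of-bounds
#' fixations enter neither numerator nor denominator. With an empty
#' denominator the score is flagged undefined (`NA`), not 0.
#'
#' @param classified a report with a `label` column (see
#'   [classify_fixations()]).
#' @param fix_range fixation indices to pool (default `2:6`).
#' @param conditions conditions to score (those with a heterogeneity
#'   structure); scored separately per condition.
#' @return A data frame with one row per participant x condition present in
#'   the data: `participant`, `condition`, `n_het`, `n_homo`, `efficiency`,
#'   `undefined`.
#' @export
efficiency_score <- function(classified, fix_range = 2:6,
                             conditions = c("split_half", "jumbled")) {
  stopifnot("label" %in% names(classified))
  keep <- classified$phase == "search" &
    !classified$target_present &
    classified$correct %in% TRUE &
    classified$fix_index %in% fix_range &
    classified$condition %in% conditions
  base <- unique(classified[classified$condition %in% conditions &
                              classified$phase == "search",
                            c("participant", "condition")])
  sub <- classified[keep & classified$label %in% c("heterogeneous", "homogeneous"), ]
  agg <- function(lab) {
    s <- sub[sub$label == lab, ]
    if (nrow(s) == 0L) {
      return(data.frame(participant = character(0), condition = character(0),
                        n = integer(0)))
    }
    stats::aggregate(list(n = s$label), by = list(participant = s$participant,
                                                  condition = s$condition),
                     FUN = length)
  }
  out <- base[order(base$participant, base$condition), , drop = FALSE]
  rownames(out) <- NULL
  key <- paste(out$participant, out$condition)
  out$n_het <- 0L; out$n_homo <- 0L
  if (nrow(sub)) {
    for (lab in c("heterogeneous", "homogeneous")) {
      a <- agg(lab)
      if (nrow(a)) {
        idx <- match(paste(a$participant, a$condition), key)
        out[[if (lab == "heterogeneous") "n_het" else "n_homo"]][idx] <- a$n
      }
    }
  }
  denom <- out$n_het + out$n_homo
  out$efficiency <- ifelse(denom > 0, out$n_het / denom, NA_real_)
  out$undefined <- denom == 0
  out
}

#' Per-participant, per-condition accuracy and median reaction time
#'
#' Accuracy is the fraction of correct responses; reaction time is summarised
#' by the median over *correct* trials (robust to the long right tail).
#' Target-present and target-absent trials are summarised separately. For
#' jumbled (and split-half) target-present trials a second table bins
#' accuracy by the difficulty of the target's cell (bins of width 0.1) when
#' `stimuli` are available.
#'
#' @param report a fixation report (classification not required).
#' @param stimuli optional stimulus list (for target-cell difficulties).
#' @return A list with `by_condition` (columns `participant`, `condition`,
#'   `target`, `n_trials`, `accuracy`, `median_rt_ms`) and `by_difficulty`
#'   (columns `condition`, `bin`, `n_trials`, `accuracy`; `NULL` without
#'   stimuli).
#' @export
accuracy_rt_tables <- function(report, stimuli = NULL) {
  stimuli <- stimuli %||% attr(report, "stimuli")
  trials <- unique(report[report$phase == "search",
                          c("participant", "trial", "condition", "configuration",
                            "target_present", "target_col", "target_row",
                            "response", "correct", "rt_ms", "stim_id")])
  trials$target <- ifelse(trials$target_present, "present", "absent")
  grp <- interaction(trials$participant, trials$condition, trials$target, drop = TRUE)
  by_condition <- do.call(rbind, lapply(split(trials, grp), function(d) {
    data.frame(participant = d$participant[1], condition = d$condition[1],
               target = d$target[1], n_trials = nrow(d),
               accuracy = mean(d$correct %in% TRUE),
               median_rt_ms = stats::median(d$rt_ms[d$correct %in% TRUE]),
               stringsAsFactors = FALSE)
  }))
  rownames(by_condition) <- NULL

  by_difficulty <- NULL
  if (!is.null(stimuli) && "stim_id" %in% names(trials)) {
    tp <- trials[trials$target_present &
                   trials$condition %in% c("jumbled", "split_half"), ]
    if (nrow(tp)) {
      d <- vapply(seq_len(nrow(tp)), function(i) {
        s <- stimuli[[tp$stim_id[i]]]
        s$cell_difficulty[tp$target_row[i] + 1L, tp$target_col[i] + 1L]
      }, numeric(1))
      bin <- pmin(floor(d * 10), 9) / 10
      tp$bin <- bin
      g <- interaction(tp$condition, tp$bin, drop = TRUE)
      by_difficulty <- do.call(rbind, lapply(split(tp, g), function(x) {
        data.frame(condition = x$condition[1], bin = x$bin[1],
                   n_trials = nrow(x), accuracy = mean(x$correct %in% TRUE),
                   stringsAsFactors = FALSE)
      }))
      rownames(by_difficulty) <- NULL
    }
  }
  list(by_condition = by_condition, by_difficulty = by_difficulty)
}

#' Apply participant exclusion rules
#'
#' Participants are excluded for target-absent accuracy strictly below 0.75
#' (both experiments: failure to understand the task) and, under the `exp2`
#' rules, additionally for accuracy strictly below 0.25 on hard-condition
#' target-present trials (a strategy of not even trying). Accuracy exactly at
#' a threshold is retained. Flagged participants stay in the table.
#'
#' @param by_condition the `by_condition` table from [accuracy_rt_tables()].
#' @param experiment `"exp1"` or `"exp2"`.
#' @param ta_min,hard_min exclusion thresholds.
#' @return A data frame `participant`, `ta_accuracy`, `hard_accuracy`,
#'   `excluded`, `reason`.
#' @export
apply_exclusions <- function(by_condition, experiment = c("exp1", "exp2"),
                             ta_min = 0.75, hard_min = 0.25) {
  experiment <- match.arg(experiment)
  parts <- unique(by_condition$participant)
  res <- lapply(parts, function(p) {
    d <- by_condition[by_condition$participant == p, ]
    ta <- d[d$target == "absent", ]
    ta_acc <- if (nrow(ta)) sum(ta$accuracy * ta$n_trials) / sum(ta$n_trials) else NA_real_
    hd <- d[d$target == "present" & d$condition == "hard", ]
    hard_acc <- if (nrow(hd)) sum(hd$accuracy * hd$n_trials) / sum(hd$n_trials) else NA_real_
    reasons <- character(0)
    if (!is.na(ta_acc) && ta_acc < ta_min) reasons <- c(reasons, "low_ta_accuracy")
    if (experiment == "exp2" && !is.na(hard_acc) && hard_acc < hard_min) {
      reasons <- c(reasons, "low_hard_accuracy")
    }
    data.frame(participant = p, ta_accuracy = ta_acc, hard_accuracy = hard_acc,
               excluded = length(reasons) > 0,
               reason = if (length(reasons)) paste(reasons, collapse = "+") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-participant strategy summary
#'
#' Convenience wrapper joining the efficiency score, accuracy / reaction-time
#' tables and exclusion flags into one table per participant and condition.
#'
#' @param classified a classified fixation report.
#' @param stimuli optional stimulus list.
#' @param experiment `"exp1"` or `"exp2"` (sets the exclusion rules).
#' @param fix_range fixation indices pooled by the efficiency score.
#' @return A data frame with one row per participant x scored condition.
#' @export
strategy_summary <- function(classified, stimuli = NULL,
                             experiment = c("exp1", "exp2"), fix_range = 2:6) {
  experiment <- match.arg(experiment)
  eff <- efficiency_score(classified, fix_range = fix_range)
  tabs <- accuracy_rt_tables(classified, stimuli)
  excl <- apply_exclusions(tabs$by_condition, experiment)
  out <- merge(eff, excl, by = "participant", all.x = TRUE, sort = TRUE)
  ta_rt <- tabs$by_condition[tabs$by_condition$target == "absent",
                             c("participant", "condition", "median_rt_ms")]
  names(ta_rt)[3] <- "median_rt_ta_ms"
  out <- merge(out, ta_rt, by = c("participant", "condition"), all.x = TRUE)
  out[order(out$participant, out$condition), , drop = FALSE]
}
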