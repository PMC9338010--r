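# Synthetic observers: parametric scanpath simulation, experiment designs,
# responses and reaction times.

#' Parameters of a simulated observer
#'
#' A simulated observer chooses each post-initial fixation in two stages:
#' first the class of the next cell -- heterogeneous (cell difficulty > 0.5)
#' with probability governed by `w_het`, homogeneous otherwise -- then a cell
#' within that class, preferring upper-half cells by a factor `upper_bias`
#' and nearby cells via an exponential saccade-amplitude penalty
#' `exp(-distance / amp_scale)`. `w_het` is therefore exactly the long-run
#' proportion of post-initial fixations directed at heterogeneous regions
#' whenever `upper_bias = 1` or the two classes are balanced across the upper
#' and lower halves (e.g. any left/right split).
#'
#' Peripheral target detection is distance based: a target whose cell lies
#' within `detect_radius_easy + d * (detect_radius_hard - detect_radius_easy)`
#' cells of the current fixation is detected, where `d` is the target cell's
#' difficulty. A radius of `detect_radius_easy` at least the grid diagonal
#' puts detection of targets on homogeneous backgrounds at ceiling;
#' `detect_radius_hard` near 0 puts purely peripheral detection on
#' heterogeneous backgrounds at chance, so such targets must be approached.
#'
#' @param w_het probability in \[0, 1\] that a post-initial fixation targets a
#'   heterogeneous cell (difficulty > 0.5) during search.
#' @param upper_bias multiplicative preference (>= 0) for upper-half cells.
#' @param amp_scale saccade-amplitude penalty scale, in cells (`Inf` disables
#'   the distance penalty).
#' @param detect_radius_easy,detect_radius_hard peripheral detection radii, in
#'   cells, at target-cell difficulty 0 and 1; `detect_radius_easy >=
#'   detect_radius_hard >= 0`.
#' @param fix_dur_median_ms,fix_dur_sigma median (ms) and log-scale sd of the
#'   log-normal fixation-duration distribution.
#' @param giveup_fix number of fixations after which the observer responds
#'   "absent" if no target was detected.
#' @param w_het_passive,upper_bias_passive the corresponding preferences used
#'   during passive viewing (the two tasks may engage different biases).
#' @param id optional participant identifier.
#' @param seed optional integer recorded with the parameters.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(w_het = 0.5, upper_bias = 1, amp_scale = 6,
                            detect_radius_easy = 40, detect_radius_hard = 4,
                            fix_dur_median_ms = 250, fix_dur_sigma = 0.3,
                            giveup_fix = 24,
                            w_het_passive = w_het,
                            upper_bias_passive = upper_bias,
                            id = NULL, seed = NULL) {
  stop_if_not_scalar(w_het, "w_het", 0, 1)
  stop_if_not_scalar(w_het_passive, "w_het_passive", 0, 1)
  stopifnot(upper_bias >= 0, upper_bias_passive >= 0,
            amp_scale > 0, giveup_fix >= 1,
            detect_radius_easy >= detect_radius_hard, detect_radius_hard >= 0,
            fix_dur_median_ms > 0, fix_dur_sigma >= 0)
  structure(list(w_het = w_het, upper_bias = upper_bias, amp_scale = amp_scale,
                 detect_radius_easy = detect_radius_easy,
                 detect_radius_hard = detect_radius_hard,
                 fix_dur_median_ms = fix_dur_median_ms,
                 fix_dur_sigma = fix_dur_sigma,
                 giveup_fix = as.integer(giveup_fix),
                 w_het_passive = w_het_passive,
                 upper_bias_passive = upper_bias_passive,
                 id = id, seed = seed),
            class = "observer_params")
}

#' Population distributions over observer parameters
#'
#' Each entry is either a single number (all observers share that value) or,
#' for `w_het` and `w_het_passive`, a length-2 vector of Beta shape
#' parameters, and for `upper_bias` and `upper_bias_passive`, a length-2
#' vector `c(meanlog, sdlog)` of a log-normal. Defaults give a cohort
#' spanning counter-optimal to near-optimal searchers (`w_het ~ Beta(2, 2)`),
#' a heterogeneity preference during passive viewing (`Beta(4, 2)`), and an
#' upper-half preference in passive viewing only.
#'
#' @param w_het,w_het_passive Beta shapes or a fixed value in \[0, 1\].
#' @param upper_bias,upper_bias_passive log-normal `c(meanlog, sdlog)` or a
#'   fixed value.
#' @param ... fixed values forwarded to [observer_params()] for the remaining
#'   fields (detection radii, durations, give-up budget, ...).
#' @return An object of class `population_hyperparams`.
#' @export
population_hyperparams <- function(w_het = c(2, 2), w_het_passive = c(4, 2),
                                   upper_bias = 1, upper_bias_passive = 2,
                                   ...) {
  structure(list(w_het = w_het, w_het_passive = w_het_passive,
                 upper_bias = upper_bias, upper_bias_passive = upper_bias_passive,
                 fixed = list(...)),
            class = "population_hyperparams")
}

draw_beta_or_fixed <- function(n, spec, name) {
  if (length(spec) == 1L) return(rep(spec, n))
  if (length(spec) == 2L && all(spec > 0)) return(stats::rbeta(n, spec[1], spec[2]))
  stop(sprintf("invalid hyperparameters for `%s`", name), call. = FALSE)
}

draw_lnorm_or_fixed <- function(n, spec, name) {
  if (length(spec) == 1L) return(rep(spec, n))
  if (length(spec) == 2L && spec[2] >= 0) return(stats::rlnorm(n, spec[1], spec[2]))
  stop(sprintf("invalid hyperparameters for `%s`", name), call. = FALSE)
}

#' Draw a cohort of simulated observers
#'
#' @param n number of observers (>= 1).
#' @param hyper a [population_hyperparams()].
#' @param seed optional integer seed; a fixed seed reproduces the cohort.
#' @return A list of [observer_params()], with ids `1:n`.
#' @export
sample_population <- function(n, hyper = population_hyperparams(), seed = NULL) {
  stopifnot(n >= 1, inherits(hyper, "population_hyperparams"))
  with_seed_opt(seed, {
    w <- draw_beta_or_fixed(n, hyper$w_het, "w_het")
    wp <- draw_beta_or_fixed(n, hyper$w_het_passive, "w_het_passive")
    ub <- draw_lnorm_or_fixed(n, hyper$upper_bias, "upper_bias")
    ubp <- draw_lnorm_or_fixed(n, hyper$upper_bias_passive, "upper_bias_passive")
    lapply(seq_len(n), function(i) {
      do.call(observer_params,
              c(list(w_het = w[i], w_het_passive = wp[i],
                     upper_bias = ub[i], upper_bias_passive = ubp[i], id = i),
                hyper$fixed))
    })
  })
}

#' Experiment trial designs
#'
#' Builds the randomized trial list for one participant.
#'
#' * `exp1` (horizontal split): 10 passive-viewing trials, then 5 practice
#'   trials, then 160 search trials -- 40 with the target on the easy half,
#'   40 on the hard half and 80 target-absent -- randomly intermixed in four
#'   blocks of 40, with the hard side assigned to the upper or lower half at
#'   random on every trial.
#' * `exp2` (four conditions, left/right split): 100 search trials in four
#'   blocks of 25, 25 trials per condition (easy, hard, split-half, jumbled)
#'   mixed and randomised within block; 12 of each condition's trials are
#'   target-present and 13 target-absent.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param seed optional integer seed.
#' @return A data frame (class `design_spec`) with columns `trial`, `phase`,
#'   `block`, `condition`, `configuration`, `target_present`, `target_half`,
#'   and attribute `experiment`.
#' @export
make_design <- function(experiment = c("exp1", "exp2"), seed = NULL) {
  experiment <- match.arg(experiment)
  with_seed_opt(seed, {
    if (experiment == "exp1") {
      passive <- data.frame(phase = "passive", block = 0L,
                            condition = "split_half",
                            target_present = FALSE, target_half = "absent",
                            stringsAsFactors = FALSE)[rep(1, 10), ]
      practice <- data.frame(phase = "practice", block = 0L,
                             condition = "split_half",
                             target_present = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                             target_half = c("easy", "hard", "absent", "absent", "absent"),
                             stringsAsFactors = FALSE)
      search <- data.frame(phase = "search", block = 0L,
                           condition = "split_half",
                           target_present = rep(c(TRUE, TRUE, FALSE), c(40, 40, 80)),
                           target_half = rep(c("easy", "hard", "absent"), c(40, 40, 80)),
                           stringsAsFactors = FALSE)
      search <- search[sample.int(nrow(search)), ]
      search$block <- rep(1:4, each = 40L)
      design <- rbind(passive, practice, search)
      design$configuration <- sample(c("hard_up", "hard_down"), nrow(design),
                                     replace = TRUE)
    } else {
      conds <- c("easy", "hard", "split_half", "jumbled")
      per_cond <- do.call(rbind, lapply(conds, function(cn) {
        data.frame(phase = "search", block = 0L, condition = cn,
                   target_present = rep(c(TRUE, FALSE), c(12, 13)),
                   stringsAsFactors = FALSE)
      }))
      per_cond <- per_cond[sample.int(nrow(per_cond)), ]
      per_cond$block <- rep(1:4, each = 25L)
      design <- per_cond
      design$configuration <- ifelse(
        design$condition == "split_half",
        sample(c("hard_left", "hard_right"), nrow(design), replace = TRUE),
        "none")
      design$target_half <- ifelse(
        !design$target_present, "absent",
        ifelse(design$condition == "split_half",
               sample(c("easy", "hard"), nrow(design), replace = TRUE),
               "any"))
    }
    design$trial <- seq_len(nrow(design))
    rownames(design) <- NULL
    design <- design[, c("trial", "phase", "block", "condition", "configuration",
                         "target_present", "target_half")]
    attr(design, "experiment") <- experiment
    class(design) <- c("design_spec", "data.frame")
    design
  })
}

#' Default grid geometry for each experiment
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @return A [grid_spec()]: 22 x 16 cells centred on a 1024 x 768 screen for
#'   `exp1`; 32 x 24 cells (1024 x 768 px array) centred on a 1280 x 1024
#'   screen for `exp2`.
#' @export
experiment_grid <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") grid_spec(22, 16)
  else grid_spec(32, 24, screen_px = c(1280, 1024))
}

#' Generate the stimulus for every trial of a design
#'
#' @param design a [make_design()] data frame.
#' @param grid a [grid_spec()]; default from the design's experiment.
#' @param mapping an [orientation_range_mapping()].
#' @param theta target orientation (radians).
#' @param seed optional integer seed.
#' @return A list of `stimulus_array` objects, one per design row; its index
#'   is the `stim_id` used in fixation reports.
#' @export
build_stimuli <- function(design, grid = NULL,
                          mapping = orientation_range_mapping(),
                          theta = pi / 4, seed = NULL) {
  grid <- grid %||% experiment_grid(attr(design, "experiment") %||% "exp1")
  with_seed_opt(seed, {
    seeds <- child_seeds(nrow(design))
    lapply(seq_len(nrow(design)), function(i) {
      row <- design[i, ]
      if (row$condition == "split_half") {
        axis <- if (row$configuration %in% c("hard_up", "hard_down"))
          "horizontal" else "vertical"
        side <- sub("^hard_", "", row$configuration)
        th <- row$target_half
        if (th == "any") th <- sample(c("easy", "hard"), 1L)
        make_split_half(grid, axis = axis, hard_side = side, target_half = th,
                        mapping = mapping, theta = theta, seed = seeds[i])
      } else if (row$condition == "jumbled") {
        make_jumbled(grid, mapping = mapping,
                     target_present = row$target_present,
                     theta = theta, seed = seeds[i])
      } else {
        make_uniform_array(grid, condition = row$condition,
                           target_present = row$target_present,
                           mapping = mapping, theta = theta, seed = seeds[i])
      }
    })
  })
}

# --- scanpath machinery -----------------------------------------------------

# Per-stimulus quantities reused across fixations of a trial.
prep_sim <- function(stim) {
  nc <- stim$grid$n_cols; nr <- stim$grid$n_rows
  col <- rep(0:(nc - 1), each = nr)
  row <- rep(0:(nr - 1), times = nc)
  het <- as.vector(stim$cell_difficulty) > 0.5        # column-major: (row, col)
  list(nc = nc, nr = nr, col = col, row = row,
       cx = col + 0.5, cy = row + 0.5,
       het = het,
       het_idx = which(het), homo_idx = which(!het),
       upper = (row + 0.5) < nr / 2)
}

# Sample the index (column-major over cells) of the next fixated cell.
# Two stages: class (heterogeneous vs homogeneous, by w_het weighted with the
# class's mean upper-half weight), then a cell within the class.
sample_next_cell <- function(prep, ubw, cur_idx, w_het, amp_scale) {
  het_idx <- prep$het_idx; homo_idx <- prep$homo_idx
  if (!is.na(cur_idx)) {
    if (prep$het[cur_idx]) het_idx <- het_idx[het_idx != cur_idx]
    else homo_idx <- homo_idx[homo_idx != cur_idx]
  }
  u_het <- if (length(het_idx)) mean(ubw[het_idx]) else 0
  u_homo <- if (length(homo_idx)) mean(ubw[homo_idx]) else 0
  ph <- w_het * u_het
  pm <- (1 - w_het) * u_homo
  if (ph + pm <= 0) {                       # degenerate: requested class empty
    ph <- as.numeric(length(het_idx) > 0); pm <- as.numeric(length(homo_idx) > 0)
  }
  cand <- if (stats::runif(1) < ph / (ph + pm)) het_idx else homo_idx
  w <- ubw[cand]
  if (is.finite(amp_scale) && !is.na(cur_idx)) {
    w <- w * exp(-sqrt((prep$cx[cand] - prep$cx[cur_idx])^2 +
                         (prep$cy[cand] - prep$cy[cur_idx])^2) / amp_scale)
  }
  cand[sample.int(length(cand), 1L, prob = w)]
}

#' Sample the next fixation location
#'
#' Applies the observer's two-stage cell choice (see [observer_params()]) given
#' the current fixation and returns the centre of the chosen cell with a small
#' uniform jitter (within the cell). The current cell is excluded.
#'
#' @param state the current fixation: a list with element `cell`, the 0-based
#'   `c(col, row)` currently fixated (or such a vector directly).
#' @param stim a `stimulus_array`.
#' @param params an [observer_params()].
#' @param phase `"search"` or `"passive"` (selects which `w_het`/`upper_bias`
#'   pair is used).
#' @return A list with `cell` (0-based `c(col, row)`) and `xy` (pixel
#'   coordinates `c(x, y)`).
#' @export
next_fixation <- function(state, stim, params, phase = c("search", "passive")) {
  phase <- match.arg(phase)
  cell <- if (is.list(state)) state$cell else state
  prep <- prep_sim(stim)
  ub <- if (phase == "passive") params$upper_bias_passive else params$upper_bias
  w <- if (phase == "passive") params$w_het_passive else params$w_het
  ubw <- ub^prep$upper
  cur_idx <- cell[1] * prep$nr + cell[2] + 1L
  idx <- sample_next_cell(prep, ubw, cur_idx, w, params$amp_scale)
  new_cell <- c(prep$col[idx], prep$row[idx])
  ctr <- cell_center_px(stim$grid, new_cell[1], new_cell[2])
  jit <- stats::runif(2, -stim$grid$cell_px / 4, stim$grid$cell_px / 4)
  list(cell = new_cell, xy = c(ctr[1, "x"] + jit[1], ctr[1, "y"] + jit[2]))
}

#' Peripheral target detection
#'
#' The target is detected from the current fixation iff the distance (in
#' cells) between the fixated cell and the target cell does not exceed the
#' difficulty-interpolated radius
#' `detect_radius_easy + d * (detect_radius_hard - detect_radius_easy)`,
#' where `d` is the target cell's difficulty.
#'
#' @param fix_cell 0-based `c(col, row)` of the fixated cell.
#' @param stim a `stimulus_array` with a present target.
#' @param params an [observer_params()].
#' @return Logical flag.
#' @export
peripheral_detect <- function(fix_cell, stim, params) {
  if (!stim$target$present) stop("peripheral_detect() requires a present target",
                                 call. = FALSE)
  tc <- stim$target$cell
  d <- stim$cell_difficulty[tc[2] + 1L, tc[1] + 1L]
  radius <- params$detect_radius_easy +
    d * (params$detect_radius_hard - params$detect_radius_easy)
  dist <- sqrt(sum((fix_cell - tc)^2))
  dist <= radius
}

#' Simulate one trial
#'
#' The first fixation is at the array centre (the trial-initiation fixation).
#' On search trials the observer fixates until the target is detected
#' peripherally (response "present"), the give-up budget of `giveup_fix`
#' fixations is exhausted (response "absent"), or the cumulative fixation time
#' reaches `timeout_ms` (response "timeout", counted incorrect). Passive
#' trials fixate for `passive_dur_ms` with no response. Reaction time is the
#' sum of fixation durations up to the response.
#'
#' @param design_row one row of a [make_design()] data frame (or a list with
#'   the same fields).
#' @param stim the trial's `stimulus_array`.
#' @param params an [observer_params()].
#' @param timeout_ms response deadline in ms (60 000 by default).
#' @param passive_dur_ms stimulus duration of passive-viewing trials, ms.
#' @return A list with the trial's `response`, `correct`, `rt_ms` and a
#'   `fixations` data frame (`fix_index`, `x_px`, `y_px`, `dur_ms`).
#' @export
simulate_trial <- function(design_row, stim, params,
                           timeout_ms = 60000, passive_dur_ms = 5000) {
  prep <- prep_sim(stim)
  passive <- identical(design_row$phase, "passive")
  ub <- if (passive) params$upper_bias_passive else params$upper_bias
  w <- if (passive) params$w_het_passive else params$w_het
  ubw <- ub^prep$upper
  grid <- stim$grid
  centre <- grid$origin_px + grid_extent_px(grid) / 2

  max_fix <- if (passive) 1000L else params$giveup_fix
  xs <- numeric(0); ys <- numeric(0); durs <- numeric(0)
  response <- NA_character_; rt <- NA_real_
  cum <- 0
  cur_idx <- NA_integer_; cur_cell <- c(NA_real_, NA_real_)
  i <- 0L
  repeat {
    i <- i + 1L
    if (i == 1L) {
      jit <- stats::runif(2, -grid$cell_px / 4, grid$cell_px / 4)
      xy <- centre + jit
      cell <- px_to_cell(grid, xy[1], xy[2])
      cur_cell <- c(cell[1, "col"], cell[1, "row"])
    } else {
      idx <- sample_next_cell(prep, ubw, cur_idx, w, params$amp_scale)
      cur_cell <- c(prep$col[idx], prep$row[idx])
      ctr <- cell_center_px(grid, cur_cell[1], cur_cell[2])
      jit <- stats::runif(2, -grid$cell_px / 4, grid$cell_px / 4)
      xy <- c(ctr[1, "x"] + jit[1], ctr[1, "y"] + jit[2])
    }
    cur_idx <- as.integer(cur_cell[1] * prep$nr + cur_cell[2] + 1L)
    dur <- stats::rlnorm(1, log(params$fix_dur_median_ms), params$fix_dur_sigma)
    cum <- cum + dur

    if (passive) {
      if (cum >= passive_dur_ms) {
        dur <- dur - (cum - passive_dur_ms)
        xs <- c(xs, xy[1]); ys <- c(ys, xy[2]); durs <- c(durs, dur)
        break
      }
      xs <- c(xs, xy[1]); ys <- c(ys, xy[2]); durs <- c(durs, dur)
      next
    }

    if (cum > timeout_ms) {                # deadline reached mid-fixation
      dur <- max(dur - (cum - timeout_ms), 1)
      xs <- c(xs, xy[1]); ys <- c(ys, xy[2]); durs <- c(durs, dur)
      response <- "timeout"; rt <- timeout_ms
      break
    }
    xs <- c(xs, xy[1]); ys <- c(ys, xy[2]); durs <- c(durs, dur)
    if (stim$target$present && peripheral_detect(cur_cell, stim, params)) {
      response <- "present"; rt <- cum
      break
    }
    if (i >= max_fix) {
      response <- "absent"; rt <- cum
      break
    }
  }
  correct <- if (passive) NA else
    identical(response, if (isTRUE(design_row$target_present)) "present" else "absent")
  list(response = response, correct = correct, rt_ms = rt,
       fixations = data.frame(fix_index = seq_along(xs),
                              x_px = xs, y_px = ys, dur_ms = durs))
}

#' Simulate a full session for one participant
#'
#' Runs [simulate_trial()] over every row of a design, producing a long
#' fixation report (one row per fixation; trial-level fields repeated).
#'
#' @param design a [make_design()] data frame.
#' @param params an [observer_params()].
#' @param stimuli list of stimuli parallel to the design rows (from
#'   [build_stimuli()]); generated on the fly when `NULL`.
#' @param participant participant identifier stored in the report.
#' @param timeout_ms,passive_dur_ms forwarded to [simulate_trial()].
#' @param seed optional integer seed (covers stimulus generation too when
#'   `stimuli` is `NULL`).
#' @return A fixation-report data frame; see [write_fixation_report()] for the
#'   columns. The stimulus list is attached as attribute `"stimuli"`.
#' @export
simulate_session <- function(design, params, stimuli = NULL, participant = 1L,
                             timeout_ms = 60000, passive_dur_ms = 5000,
                             seed = NULL) {
  with_seed_opt(seed, {
    if (is.null(stimuli)) stimuli <- build_stimuli(design)
    stopifnot(length(stimuli) == nrow(design))
    out <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      row <- design[i, ]
      stim <- stimuli[[i]]
      tr <- simulate_trial(row, stim, params,
                           timeout_ms = timeout_ms,
                           passive_dur_ms = passive_dur_ms)
      nf <- nrow(tr$fixations)
      tgt <- stim$target
      out[[i]] <- data.frame(
        participant = params$id %||% participant,
        trial = row$trial, phase = row$phase,
        condition = row$condition, configuration = row$configuration,
        target_present = row$target_present,
        target_col = if (tgt$present) tgt$cell[1] else NA_integer_,
        target_row = if (tgt$present) tgt$cell[2] else NA_integer_,
        response = tr$response, correct = tr$correct, rt_ms = tr$rt_ms,
        fix_index = tr$fixations$fix_index,
        x_px = tr$fixations$x_px, y_px = tr$fixations$y_px,
        dur_ms = tr$fixations$dur_ms,
        stim_id = i,
        stringsAsFactors = FALSE)
    }
    report <- do.call(rbind, out)
    rownames(report) <- NULL
    attr(report, "stimuli") <- stimuli
    report
  })
}

#' Simulate a cohort of participants on a shared design
#'
#' Every participant runs the same trial list and stimulus set (a fixed item
#' bank), with independent scanpaths.
#'
#' @param design a [make_design()] data frame.
#' @param cohort list of [observer_params()] (e.g. from
#'   [sample_population()]).
#' @param stimuli optional shared stimulus list; generated once when `NULL`.
#' @param seed optional integer seed.
#' @param ... forwarded to [simulate_session()].
#' @return A combined fixation report with attribute `"stimuli"`.
#' @export
simulate_cohort <- function(design, cohort, stimuli = NULL, seed = NULL, ...) {
  with_seed_opt(seed, {
    if (is.null(stimuli)) stimuli <- build_stimuli(design)
    reports <- lapply(seq_along(cohort), function(i) {
      p <- cohort[[i]]
      if (is.null(p$id)) p$id <- i
      simulate_session(design, p, stimuli = stimuli, participant = p$id, ...)
    })
    report <- do.call(rbind, reports)
    rownames(report) <- NULL
    attr(report, "stimuli") <- stimuli
    report
  })
}

#' Write / read a fixation report
#'
#' The report is a flat tab-separated table with one row per fixation and
#' columns `participant, trial, phase, condition, configuration,
#' target_present, target_col, target_row, response, correct, rt_ms,
#' fix_index, x_px, y_px, dur_ms, stim_id` (the final column links each trial
#' to its stimulus so jumbled trials can be classified; extra columns are
#' preserved). Writing then reading restores the data frame exactly.
#'
#' @param report a fixation-report data frame.
#' @param path file path.
#' @return `write_fixation_report()` returns `path` invisibly.
#' @export
write_fixation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
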