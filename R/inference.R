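# Group-level summaries: per-index strategy curves, hierarchical proportion
# estimates with 95% intervals, reaction-time correlations, and the
# parameter-recovery / calibration harnesses.

#' Strategy curve by fixation index
#'
#' For each fixation index in `fix_range` (default 2--6), the proportion of
#' correct target-absent search trials whose index-i fixation landed on a
#' heterogeneous region, among trials where that fixation is classified
#' (per-index denominators: a trial whose fixation 4 is unclassified drops
#' out of index 4 only).
#'
#' @param classified a classified fixation report ([classify_fixations()]).
#' @param fix_range fixation indices.
#' @param tasks phases to include (search and/or passive; passive trials are
#'   all "target absent").
#' @return A list with `by_participant` (columns `participant`, `task`,
#'   `condition`, `configuration`, `fix_index`, `n_trials`, `prop_het`) and
#'   `group` (mean over participants per task x condition x configuration x
#'   index).
#' @export
strategy_by_index <- function(classified, fix_range = 2:6,
                              tasks = c("search", "passive")) {
  stopifnot("label" %in% names(classified))
  keep <- classified$phase %in% tasks &
    !classified$target_present &
    (classified$phase == "passive" | classified$correct %in% TRUE) &
    classified$fix_index %in% fix_range &
    classified$label %in% c("heterogeneous", "homogeneous")
  sub <- classified[keep, ]
  if (!nrow(sub)) {
    empty <- data.frame(participant = integer(0), task = character(0),
                        condition = character(0), configuration = character(0),
                        fix_index = integer(0), n_trials = integer(0),
                        prop_het = numeric(0))
    return(list(by_participant = empty, group = empty[-1]))
  }
  g <- interaction(sub$participant, sub$phase, sub$condition, sub$configuration,
                   sub$fix_index, drop = TRUE)
  by_participant <- do.call(rbind, lapply(split(sub, g), function(d) {
    data.frame(participant = d$participant[1], task = d$phase[1],
               condition = d$condition[1], configuration = d$configuration[1],
               fix_index = d$fix_index[1], n_trials = nrow(d),
               prop_het = mean(d$label == "heterogeneous"),
               stringsAsFactors = FALSE)
  }))
  rownames(by_participant) <- NULL
  g2 <- interaction(by_participant$task, by_participant$condition,
                    by_participant$configuration, by_participant$fix_index,
                    drop = TRUE)
  group <- do.call(rbind, lapply(split(by_participant, g2), function(d) {
    data.frame(task = d$task[1], condition = d$condition[1],
               configuration = d$configuration[1], fix_index = d$fix_index[1],
               n_participants = nrow(d), prop_het = mean(d$prop_het),
               stringsAsFactors = FALSE)
  }))
  rownames(group) <- NULL
  list(by_participant = by_participant,
       group = group[order(group$task, group$condition, group$configuration,
                           group$fix_index), ])
}

# Build the per-participant x cell binomial table used by both backends.
proportion_cells <- function(data, factors) {
  stopifnot(all(c("participant", "y", factors) %in% names(data)))
  cell <- if (length(factors)) {
    interaction(data[factors], drop = TRUE, sep = ":")
  } else factor(rep("all", nrow(data)))
  agg <- stats::aggregate(list(k = as.numeric(data$y)),
                          by = list(participant = data$participant, cell = cell),
                          FUN = sum)
  n <- stats::aggregate(list(n = rep(1, nrow(data))),
                        by = list(participant = data$participant, cell = cell),
                        FUN = sum)
  agg$n <- n$n[match(paste(agg$participant, agg$cell),
                     paste(n$participant, n$cell))]
  agg$p <- agg$k / agg$n
  agg
}

pairwise_diffs <- function(cells) {
  if (length(cells) < 2) return(NULL)
  utils::combn(as.character(cells), 2, simplify = FALSE)
}

#' Hierarchical estimate of the probability of fixating heterogeneous regions
#'
#' Estimates, for each cell of a factorial layout (e.g. task x
#' configuration), the group-level probability that a classified fixation
#' lands on a heterogeneous region, with 95% intervals, plus intervals for
#' all pairwise cell differences. Two backends:
#'
#' * `"bootstrap"` (default, dependency-light): the group estimate per cell
#'   is the unweighted mean of per-participant proportions (the "average
#'   participant"); intervals are percentile intervals over resamples of
#'   participants. With a single participant, fixations are resampled
#'   instead, which approaches the binomial Wald interval.
#' * `"glmer"`: a logistic mixed model with fixed effects for the factors and
#'   their interaction and per-participant random effects (maximal slope
#'   structure, falling back to a random intercept if the maximal fit
#'   fails). Cell probabilities and differences are summarised by parametric
#'   simulation from the approximate posterior of the fixed effects.
#'
#' @param data a data frame with columns `participant`, logical `y`
#'   (fixation on a heterogeneous region) and the factor columns named in
#'   `factors`. See [proportion_data()] for building it from a classified
#'   report.
#' @param factors character vector of factor column names (may be empty for
#'   a single overall proportion).
#' @param backend `"bootstrap"` or `"glmer"`.
#' @param n_boot bootstrap resamples (or posterior draws for `"glmer"`).
#' @param conf confidence level.
#' @param seed optional integer seed.
#' @param type bootstrap interval type: `"boot_t"` (default; point estimate
#'   +/- a Student-t quantile times the bootstrap standard error, clipped to
#'   the parameter range -- better calibrated at the typical 13-participant
#'   scale) or `"percentile"`.
#' @return An object of class `interval_estimates`: list with `estimates`
#'   (cell, estimate, lower, upper), `differences` (cell_a, cell_b, estimate,
#'   lower, upper), `backend`.
#' @export
hierarchical_proportion <- function(data, factors = c("task", "configuration"),
                                    backend = c("bootstrap", "glmer"),
                                    n_boot = 2000, conf = 0.95, seed = NULL,
                                    type = c("boot_t", "percentile")) {
  backend <- match.arg(backend)
  type <- match.arg(type)
  factors <- intersect(factors, names(data))
  if (length(unique(data$participant)) < 2 && backend == "glmer") {
    stop("the glmer backend needs at least 2 participants", call. = FALSE)
  }
  if (length(unique(data$y)) < 2) {
    warning("degenerate data: a single outcome label; intervals sit at the boundary")
  }
  with_seed_opt(seed, {
    if (backend == "bootstrap") {
      boot_proportion(data, factors, n_boot, conf, type)
    } else {
      glmer_proportion(data, factors, n_boot, conf)
    }
  })
}

#' @rdname hierarchical_proportion
#' @param classified a classified fixation report.
#' @param conditions conditions whose fixations enter the data.
#' @param fix_range fixation indices used.
#' @details `proportion_data()` converts a classified report into the
#'   `(participant, task, configuration, y)` layout: correct target-absent
#'   search trials (all passive trials), fixations 2--6, classified labels
#'   only.
#' @export
proportion_data <- function(classified, conditions = "split_half",
                            fix_range = 2:6) {
  keep <- classified$condition %in% conditions &
    !classified$target_present &
    (classified$phase == "passive" | classified$correct %in% TRUE) &
    classified$phase %in% c("search", "passive") &
    classified$fix_index %in% fix_range &
    classified$label %in% c("heterogeneous", "homogeneous")
  d <- classified[keep, ]
  data.frame(participant = d$participant, task = d$phase,
             configuration = d$configuration,
             y = d$label == "heterogeneous", stringsAsFactors = FALSE)
}

boot_proportion <- function(data, factors, n_boot, conf, type = "boot_t") {
  cells <- proportion_cells(data, factors)
  lev <- levels(cells$cell)
  parts <- unique(cells$participant)
  alpha <- (1 - conf) / 2

  cell_mean <- function(tab) {
    vapply(lev, function(cl) {
      p <- tab$p[tab$cell == cl]
      if (length(p)) mean(p) else NA_real_
    }, numeric(1))
  }
  point <- cell_mean(cells)

  if (length(parts) > 1) {
    split_by_part <- split(cells, cells$participant)
    draws <- matrix(NA_real_, n_boot, length(lev))
    for (b in seq_len(n_boot)) {
      take <- sample(names(split_by_part), length(parts), replace = TRUE)
      tab <- do.call(rbind, split_by_part[take])
      draws[b, ] <- cell_mean(tab)
    }
    df <- length(parts) - 1
  } else {
    # single participant: resample fixations within each cell
    cellf <- if (length(factors)) interaction(data[factors], drop = TRUE, sep = ":")
             else factor(rep("all", nrow(data)))
    draws <- matrix(NA_real_, n_boot, length(lev))
    for (b in seq_len(n_boot)) {
      draws[b, ] <- vapply(lev, function(cl) {
        y <- data$y[cellf == cl]
        mean(sample(y, length(y), replace = TRUE))
      }, numeric(1))
    }
    df <- max(nrow(data) - 1, 1)
  }
  interval <- function(pt, dr, lo_bound, hi_bound) {
    if (type == "percentile") {
      q <- stats::quantile(dr, probs = c(alpha, 1 - alpha), na.rm = TRUE)
      c(q[1], q[2])
    } else {                 # t interval with bootstrap SE (small-n default)
      se <- stats::sd(dr, na.rm = TRUE)
      tq <- stats::qt(1 - alpha, df)
      c(max(lo_bound, pt - tq * se), min(hi_bound, pt + tq * se))
    }
  }
  est <- t(vapply(seq_along(lev), function(i) {
    interval(point[i], draws[, i], 0, 1)
  }, numeric(2)))
  estimates <- data.frame(cell = lev, estimate = unname(point),
                          lower = est[, 1], upper = est[, 2],
                          stringsAsFactors = FALSE, row.names = NULL)
  differences <- NULL
  prs <- pairwise_diffs(lev)
  if (!is.null(prs)) {
    differences <- do.call(rbind, lapply(prs, function(pr) {
      i <- match(pr, lev)
      ci <- interval(point[i[1]] - point[i[2]], draws[, i[1]] - draws[, i[2]],
                     -1, 1)
      data.frame(cell_a = pr[1], cell_b = pr[2],
                 estimate = point[i[1]] - point[i[2]],
                 lower = ci[1], upper = ci[2],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  structure(list(estimates = estimates, differences = differences,
                 backend = "bootstrap", type = type, conf = conf),
            class = "interval_estimates")
}

glmer_proportion <- function(data, factors, n_draws, conf) {
  cells <- proportion_cells(data, factors)
  lev <- levels(cells$cell)
  alpha <- (1 - conf) / 2
  if (length(factors)) {
    fx <- paste(factors, collapse = " * ")
  } else {
    cells$cell <- factor("all"); fx <- "1"
  }
  tab <- cells
  if (length(factors)) {
    sp <- do.call(rbind, strsplit(as.character(tab$cell), ":", fixed = TRUE))
    for (j in seq_along(factors)) tab[[factors[j]]] <- sp[, j]
  }
  form_max <- stats::as.formula(
    sprintf("cbind(k, n - k) ~ %s + (%s | participant)", fx, fx))
  form_int <- stats::as.formula(
    sprintf("cbind(k, n - k) ~ %s + (1 | participant)", fx))
  fit <- tryCatch(
    suppressWarnings(lme4::glmer(form_max, data = tab, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- suppressWarnings(lme4::glmer(form_int, data = tab,
                                        family = stats::binomial()))
  }
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  newdata <- unique(tab[, c("cell", factors), drop = FALSE])
  newdata <- newdata[match(lev, as.character(newdata$cell)), , drop = FALSE]
  X <- stats::model.matrix(stats::as.formula(paste("~", fx)), newdata)
  B <- MASS::mvrnorm(n_draws, beta, V)
  draws <- stats::plogis(B %*% t(X))        # n_draws x n_cells
  point <- stats::plogis(as.vector(X %*% beta))
  qs <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  estimates <- data.frame(cell = lev, estimate = point,
                          lower = qs[1, ], upper = qs[2, ],
                          stringsAsFactors = FALSE, row.names = NULL)
  differences <- NULL
  prs <- pairwise_diffs(lev)
  if (!is.null(prs)) {
    differences <- do.call(rbind, lapply(prs, function(pr) {
      i <- match(pr, lev)
      dd <- draws[, i[1]] - draws[, i[2]]
      q <- stats::quantile(dd, probs = c(alpha, 1 - alpha))
      data.frame(cell_a = pr[1], cell_b = pr[2],
                 estimate = point[i[1]] - point[i[2]],
                 lower = q[1], upper = q[2],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  structure(list(estimates = estimates, differences = differences,
                 backend = "glmer", conf = conf, fit = fit),
            class = "interval_estimates")
}

#' @export
print.interval_estimates <- function(x, ...) {
  cat(sprintf("<interval_estimates> backend '%s', %.0f%% intervals\n",
              x$backend, 100 * x$conf))
  print(x$estimates, row.names = FALSE, digits = 3)
  if (!is.null(x$differences)) {
    cat("differences:\n")
    print(x$differences, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Reaction-time and strategy correlations across conditions
#'
#' Pearson correlation matrices of per-participant log2 median reaction times
#' across conditions, computed separately for target-absent and
#' target-present trials, plus the correlation between split-half and
#' jumbled strategy (efficiency) scores with a Fisher-z 95% confidence
#' interval.
#'
#' @param by_condition the `by_condition` table from [accuracy_rt_tables()].
#' @param efficiency optional [efficiency_score()] table; enables the
#'   strategy correlation when it holds both split-half and jumbled scores.
#' @param conf confidence level for the strategy correlation.
#' @return An object of class `correlation_report`: list with `ta` and `tp`
#'   correlation matrices (conditions x conditions) and `strategy`
#'   (`r`, `lower`, `upper`, `n`), or `NULL` when unavailable.
#' @export
rt_correlations <- function(by_condition, efficiency = NULL, conf = 0.95) {
  if (length(unique(by_condition$participant)) < 3) {
    stop("rt_correlations() needs at least 3 participants", call. = FALSE)
  }
  mat_for <- function(target) {
    d <- by_condition[by_condition$target == target, ]
    conds <- sort(unique(d$condition))
    parts <- sort(unique(d$participant))
    m <- matrix(NA_real_, length(parts), length(conds),
                dimnames = list(parts, conds))
    m[cbind(match(d$participant, parts), match(d$condition, conds))] <-
      log2(d$median_rt_ms)
    stats::cor(m, use = "pairwise.complete.obs")
  }
  strategy <- NULL
  if (!is.null(efficiency) &&
      all(c("split_half", "jumbled") %in% efficiency$condition)) {
    sh <- efficiency[efficiency$condition == "split_half", ]
    jm <- efficiency[efficiency$condition == "jumbled", ]
    common <- intersect(sh$participant, jm$participant)
    x <- sh$efficiency[match(common, sh$participant)]
    y <- jm$efficiency[match(common, jm$participant)]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(x[ok], y[ok], conf.level = conf)  # Fisher z CI
      strategy <- list(r = unname(ct$estimate), lower = ct$conf.int[1],
                       upper = ct$conf.int[2], n = sum(ok))
    }
  }
  structure(list(ta = mat_for("absent"), tp = mat_for("present"),
                 strategy = strategy),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> log2 median RT correlations\n target absent:\n")
  print(round(x$ta, 2))
  cat(" target present:\n")
  print(round(x$tp, 2))
  if (!is.null(x$strategy)) {
    cat(sprintf(" strategy (split-half vs jumbled): r = %.3f, 95%% CI [%.3f, %.3f], n = %d\n",
                x$strategy$r, x$strategy$lower, x$strategy$upper, x$strategy$n))
  }
  invisible(x)
}

# Minimal target-absent search design used by the recovery harnesses.
ta_only_design <- function(n_trials, condition, experiment) {
  configs <- if (experiment == "exp1") c("hard_up", "hard_down")
             else c("hard_left", "hard_right")
  design <- data.frame(
    trial = seq_len(n_trials), phase = "search",
    block = rep(seq_len(4), length.out = n_trials),
    condition = condition,
    configuration = if (condition == "split_half")
      rep_len(configs, n_trials) else "none",
    target_present = FALSE, target_half = "absent",
    stringsAsFactors = FALSE)
  attr(design, "experiment") <- experiment
  class(design) <- c("design_spec", "data.frame")
  design
}

#' Parameter-recovery experiment
#'
#' End-to-end validation of the simulator + pipeline: for each value of the
#' heterogeneity weight `w_het`, a cohort of observers is simulated on
#' target-absent search trials, the fixation reports are classified, and each
#' observer's efficiency score is compared with the generating `w_het`.
#' Reports per-`w_het` bias of the cohort mean, RMSE of individual scores,
#' and a bootstrap interval for the cohort mean with a coverage flag.
#'
#' @param w_het_grid generating heterogeneity weights.
#' @param n_observers observers per cohort.
#' @param n_trials target-absent trials per observer.
#' @param condition `"split_half"` or `"jumbled"`.
#' @param experiment experiment geometry to use (`"exp1"` for the 22 x 16
#'   split-half arrays, `"exp2"` for the 32 x 24 dense arrays).
#' @param hyper population hyperparameters for all non-`w_het` fields.
#' @param seed optional integer seed.
#' @param n_boot bootstrap resamples for the cohort-mean interval.
#' @return A data frame of class `recovery_report` with one row per `w_het`:
#'   `w_het`, `mean_efficiency`, `bias`, `rmse`, `lower`, `upper`, `covered`,
#'   `n_observers`, `n_trials`; attribute `max_abs_bias`.
#' @export
recovery_experiment <- function(w_het_grid = seq(0.1, 0.9, by = 0.1),
                                n_observers = 20, n_trials = 80,
                                condition = c("split_half", "jumbled"),
                                experiment = NULL,
                                hyper = population_hyperparams(),
                                seed = NULL, n_boot = 1000) {
  condition <- match.arg(condition)
  experiment <- experiment %||% if (condition == "split_half") "exp1" else "exp2"
  with_seed_opt(seed, {
    design <- ta_only_design(n_trials, condition, experiment)
    stimuli <- build_stimuli(design, grid = experiment_grid(experiment))
    rows <- lapply(w_het_grid, function(w) {
      hy <- hyper
      hy$w_het <- w                      # point mass at the generating value
      cohort <- sample_population(n_observers, hy)
      report <- simulate_cohort(design, cohort, stimuli = stimuli)
      classified <- classify_fixations(report, grid = experiment_grid(experiment),
                                       stimuli = stimuli, experiment = experiment)
      eff <- efficiency_score(classified, conditions = condition)
      e <- eff$efficiency[!eff$undefined]
      bm <- replicate(n_boot, mean(sample(e, length(e), replace = TRUE)))
      ci <- stats::quantile(bm, c(0.025, 0.975))
      data.frame(w_het = w, mean_efficiency = mean(e), bias = mean(e) - w,
                 rmse = sqrt(mean((e - w)^2)),
                 lower = ci[1], upper = ci[2],
                 covered = ci[1] <= w && w <= ci[2],
                 n_observers = length(e), n_trials = n_trials,
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    out <- do.call(rbind, rows)
    attr(out, "max_abs_bias") <- max(abs(out$bias))
    attr(out, "condition") <- condition
    class(out) <- c("recovery_report", "data.frame")
    out
  })
}

#' Interval-calibration experiment
#'
#' Repeatedly simulates cohorts whose true probability of fixating the
#' heterogeneous side is `true_p` (a point-mass `w_het`), runs the full
#' classification pipeline, fits [hierarchical_proportion()] with no factors
#' (one overall cell), and records whether the 95% interval covers `true_p`.
#'
#' @param n_reps number of replicate cohorts.
#' @param n_participants participants per cohort.
#' @param true_p generating probability.
#' @param n_trials target-absent trials per participant.
#' @param backend interval backend.
#' @param n_boot resamples per fit.
#' @param seed optional integer seed.
#' @return A list: `coverage` (fraction of replicates covering `true_p`),
#'   `n_reps`, `widths` (interval widths per replicate).
#' @export
coverage_experiment <- function(n_reps = 100, n_participants = 13,
                                true_p = 0.5, n_trials = 80,
                                backend = "bootstrap", n_boot = 1000,
                                seed = NULL) {
  with_seed_opt(seed, {
    design <- ta_only_design(n_trials, "split_half", "exp1")
    stimuli <- build_stimuli(design, grid = experiment_grid("exp1"))
    hy <- population_hyperparams(w_het = true_p)
    covered <- logical(n_reps); widths <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      cohort <- sample_population(n_participants, hy)
      report <- simulate_cohort(design, cohort, stimuli = stimuli)
      classified <- classify_fixations(report, grid = experiment_grid("exp1"),
                                       stimuli = stimuli)
      pd <- proportion_data(classified)
      est <- hierarchical_proportion(pd, factors = character(0),
                                     backend = backend, n_boot = n_boot)
      covered[r] <- est$estimates$lower[1] <= true_p &&
        true_p <= est$estimates$upper[1]
      widths[r] <- est$estimates$upper[1] - est$estimates$lower[1]
    }
    list(coverage = mean(covered), n_reps = n_reps, widths = widths)
  })
}
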