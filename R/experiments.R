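#' Run repeated trials of one schedule
#'
#' Runs `n_trials` independent trials of a fixed schedule with seeds
#' `base_seed + 0:(n_trials - 1)` and stacks their tidy results.
#'
#' @param schedule A schedule tibble.
#' @param params An [engram_params()] object.
#' @param n_trials Number of trials.
#' @param base_seed First seed; trial `k` uses `base_seed + k - 1`.
#' @param record Trace recording mode passed to [run_trial()].
#' @return A tibble: one row per recall per trial (see [tidy.engram_trial()]),
#'   plus `trial` and `n_tagged_first` columns.
#' @export
run_trials <- function(schedule, params, n_trials = 10, base_seed = 1,
                       record = "recall") {
  purrr::map_dfr(seq_len(n_trials), function(k) {
    tr <- run_trial(schedule, params, seed = base_seed + k - 1L,
                    record = record)
    out <- tidy(tr)
    out$trial <- k
    out$n_tagged_first <- glance(tr)$n_tagged_first
    out
  })
}

experiment_conditions <- function(name, delays, variant, shock_levels,
                                  reduced_levels) {
  switch(name,
    single_context = tibble::tibble(condition = c("full_cue", "partial_cue"),
                                    partial_cue = c(0L, 4L)),
    two_context = tibble::tibble(condition = paste0(delays, "h"),
                                 delay_h = delays),
    fear_linking = tibble::tibble(
      condition = ifelse(shock_levels, "shock", "no_shock"),
      shock = shock_levels),
    allocation = tibble::tibble(
      condition = c("eps_plus", "control"),
      eps_plus = c(TRUE, FALSE)),
    allocation_overlap = tibble::tibble(condition = paste0(delays, "h"),
                                        delay_h = delays),
    competition = tidyr::expand_grid(delay_h = delays,
                                     reduced_i1 = reduced_levels) |>
      dplyr::mutate(condition = paste0(.data$delay_h, "h",
                                       ifelse(.data$reduced_i1,
                                              "_reduced_inhibition", ""))) |>
      dplyr::relocate("condition"))
}

#' Run a named multi-trial experiment
#'
#' Expands an experiment into its conditions (delays, shock vs control,
#' manipulation vs control, ...), runs `n_trials` seeded trials per
#' condition (the same seed set across conditions, so comparisons are
#' paired), and collects per-trial read-outs and per-condition aggregates.
#' Excluded trials (any rate reaching 100 Hz) are kept in the per-trial
#' table but never enter aggregates, and are not replaced.
#'
#' @param name Experiment name; see [experiment_schedule()].
#' @param params An [engram_params()] object.
#' @param n_trials Trials per condition.
#' @param seed Base seed; trial `k` uses `seed + k - 1`.
#' @param delays Training-session delays (hours) for the delay-based
#'   experiments.
#' @param variant `two_context` variant, see [experiment_schedule()].
#' @param shock_levels For `fear_linking`: which shock conditions to run.
#' @param reduced_levels For `competition`: which inhibition settings to run.
#' @return An object of class `engram_experiment` with fields `name`,
#'   `params`, `conditions`, `trials` (per-recall per-trial tibble) and the
#'   seed policy; see [tidy.engram_experiment()] and
#'   [glance.engram_experiment()].
#' @examples
#' \donttest{
#' ex <- run_experiment("two_context", engram_params(), n_trials = 3)
#' glance(ex)
#' }
#' @export
run_experiment <- function(name, params = engram_params(), n_trials = 10,
                           seed = 1, delays = c(6, 24),
                           variant = "control",
                           shock_levels = c(TRUE, FALSE),
                           reduced_levels = c(FALSE, TRUE)) {
  conds <- experiment_conditions(name, delays, variant, shock_levels,
                                 reduced_levels)
  trials <- purrr::map_dfr(seq_len(nrow(conds)), function(ci) {
    cond <- conds[ci, ]
    args <- as.list(cond[setdiff(names(cond), "condition")])
    sch <- do.call(experiment_schedule,
                   c(list(name = name, params = params, variant = variant),
                     args))
    purrr::map_dfr(seq_len(n_trials), function(k) {
      tr <- run_trial(sch, params, seed = seed + k - 1L, record = "recall")
      out <- tidy(tr)
      if (!nrow(out))
        out <- tibble::tibble(label = NA_character_, context = NA_integer_,
                              onset = NA_real_, size = NA_integer_,
                              strength = NA_real_, overlap = NA_real_,
                              seed = tr$seed, excluded = tr$excluded,
                              failed = tr$failed)
      out$condition <- cond$condition
      out$trial <- k
      out$n_tagged_first <- glance(tr)$n_tagged_first
      out
    })
  })
  structure(list(name = name, params = params, conditions = conds,
                 trials = trials, n_trials = n_trials, base_seed = seed),
            class = "engram_experiment")
}

#' @export
print.engram_experiment <- function(x, ...) {
  cat("<engram_experiment>", x$name, "| preset", x$params$preset,
      "|", x$n_trials, "trials/condition | base seed", x$base_seed, "\n")
  print(as.data.frame(glance(x)), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-trial results of an experiment
#' @param x An `engram_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per recall per trial: `condition`, `trial`,
#'   `seed`, recall `label`/`context`, engram `size`, `strength`, `overlap`
#'   with the first recall, `n_tagged_first`, and the `excluded`/`failed`
#'   flags.
#' @export
tidy.engram_experiment <- function(x, ...) x$trials

#' Per-condition aggregates of an experiment
#'
#' Aggregates are computed over included trials only (no replacement of
#' excluded trials); `n_requested = n_included + n_excluded + n_failed` per
#' condition.
#'
#' @param x An `engram_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per condition and recall label: trial
#'   accounting and mean / standard error of the engram size, memory
#'   strength and overlap.
#' @export
glance.engram_experiment <- function(x, ...) {
  sem <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  }
  x$trials |>
    dplyr::group_by(.data$condition, .data$label) |>
    dplyr::summarise(
      n_requested = dplyr::n(),
      n_excluded = sum(.data$excluded),
      n_failed = sum(.data$failed & !.data$excluded),
      n_included = sum(!.data$excluded & !.data$failed),
      mean_size = mean(.data$size[!.data$excluded & !.data$failed]),
      mean_strength = mean(.data$strength[!.data$excluded & !.data$failed]),
      sem_strength = sem(.data$strength[!.data$excluded & !.data$failed]),
      mean_overlap = mean(.data$overlap[!.data$excluded & !.data$failed]),
      sem_overlap = sem(.data$overlap[!.data$excluded & !.data$failed]),
      .groups = "drop")
}

#' Compare two conditions of an experiment
#'
#' Descriptive two-sample (Welch) comparison of a per-trial metric between
#' two conditions, over included trials.
#'
#' @param x An `engram_experiment`.
#' @param a,b Condition labels to compare.
#' @param metric One of `"overlap"`, `"strength"`, `"size"`.
#' @param label Recall label to compare at; defaults to the last recall
#'   (where overlap and the second memory's strength are read out).
#' @return A one-row tibble: per-condition means and ns, the mean
#'   difference `a - b`, its pooled standard error, and the Welch statistic
#'   and p value.
#' @export
compare_conditions <- function(x, a, b, metric = c("overlap", "strength",
                                                   "size"),
                               label = NULL) {
  metric <- match.arg(metric)
  tr <- x$trials |> dplyr::filter(!.data$excluded, !.data$failed)
  if (is.null(label)) label <- utils::tail(stats::na.omit(unique(tr$label)), 1)
  va <- tr |> dplyr::filter(.data$condition == a, .data$label == !!label) |>
    dplyr::pull(metric)
  vb <- tr |> dplyr::filter(.data$condition == b, .data$label == !!label) |>
    dplyr::pull(metric)
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) < 2 || length(vb) < 2)
    stop("need at least two included trials per condition", call. = FALSE)
  tt <- stats::t.test(va, vb)
  tibble::tibble(
    metric = metric, label = label, condition_a = a, condition_b = b,
    n_a = length(va), n_b = length(vb),
    mean_a = mean(va), mean_b = mean(vb),
    difference = mean(va) - mean(vb),
    se = sqrt(stats::var(va) / length(va) + stats::var(vb) / length(vb)),
    statistic = unname(tt$statistic), p_value = tt$p.value)
}
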