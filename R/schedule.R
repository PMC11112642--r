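ms_min <- 60e3
ms_hour <- 3600e3
ms_day <- 24 * ms_hour

new_session <- function(label, kind, context, start, n_presentations,
                        us = FALSE, eps_plus = FALSE, i_plus = FALSE,
                        reduced_i1 = FALSE, noise = FALSE, tagging = kind == "training",
                        partial_cue = 0L) {
  tibble::tibble(
    label = label, kind = kind, context = as.integer(context), start = start,
    n_presentations = as.integer(n_presentations),
    us = us, eps_plus = eps_plus, i_plus = i_plus,
    reduced_i1 = reduced_i1, noise = noise, tagging = tagging,
    partial_cue = as.integer(partial_cue)
  )
}

#' Build a training session
#'
#' A training session presents one context `n_stim` times for
#' `stim_duration` ms with an `isi` gap; the context's 10 input neurons fire
#' at `r_cs` during each presentation and are silent in between. When `us`
#' is set, the unconditioned stimulus is paired synchronously with every
#' presentation, multiplying the learning rule by `1 + us_plus`. Tagging
#' (threshold crossing marks a neuron for a later excitability jump) is
#' active during training sessions.
#'
#' @param context Context index (1-3).
#' @param start Session start time, ms.
#' @param params An [engram_params()] object.
#' @param us Pair the unconditioned stimulus with each presentation?
#' @param eps_plus Add `eps_increase` to the first `n_eps_plus` neurons for
#'   the duration of this session?
#' @param i_plus Subtract `i_inhib` from the first `n_inhib` neurons for the
#'   duration of this session?
#' @param reduced_i1 Use the reduced inhibition gain `i1_reduced` during this
#'   session?
#' @param noise Add per-step uniform drive noise during this session?
#' @param label Session label (defaults to `"train_ctx<k>"`).
#' @return A one-row schedule tibble.
#' @export
training_session <- function(context, start, params, us = TRUE,
                             eps_plus = FALSE, i_plus = FALSE,
                             reduced_i1 = FALSE, noise = FALSE,
                             label = paste0("train_ctx", context)) {
  if (!context %in% 1:3) stop("context must be 1, 2 or 3", call. = FALSE)
  new_session(label, "training", context, start, params$n_stim,
              us = us, eps_plus = eps_plus, i_plus = i_plus,
              reduced_i1 = reduced_i1, noise = noise)
}

#' Build a recall probe
#'
#' A recall session presents one context once for `stim_duration` ms.
#' Engram membership and the memory-strength read-out are evaluated from the
#' rates recorded around this probe. With `partial_cue = k > 0` the input
#' layer stays silent and the first `k` neurons tagged during the first
#' training session instead receive a direct external current equal to the
#' full feed-forward drive of a cued receptive-field neuron.
#'
#' @inheritParams training_session
#' @param partial_cue Number of tagged neurons to stimulate directly
#'   (0 = ordinary full cue through the input layer).
#' @param tagging Tag threshold-crossing neurons during this recall (used by
#'   the recall-tagging experiment variant)?
#' @return A one-row schedule tibble.
#' @export
recall_session <- function(context, start, params, i_plus = FALSE,
                           noise = FALSE, partial_cue = 0L, tagging = FALSE,
                           label = paste0("recall_ctx", context)) {
  if (!context %in% 1:3) stop("context must be 1, 2 or 3", call. = FALSE)
  new_session(label, "recall", context, start, 1L,
              us = FALSE, i_plus = i_plus, noise = noise,
              tagging = tagging, partial_cue = partial_cue)
}

#' Active span of a session, ms
#' @keywords internal
session_span <- function(session, params) {
  if (session$kind == "training")
    session$n_presentations * params$stim_duration +
      (session$n_presentations - 1L) * params$isi
  else if (session$partial_cue > 0L)
    max(params$stim_duration, params$readout_window)
  else params$stim_duration
}

#' Trailing fine-resolution window of a session, ms
#' @keywords internal
session_post <- function(session, params) {
  if (session$kind == "training") params$post_session_fine
  else if (isTRUE(session$tagging)) max(params$post_recall_fine, 600)
  else params$post_recall_fine
}

#' Named experiment schedules
#'
#' Builds the stimulation timeline of one of the study's named experiments.
#'
#' \describe{
#'   \item{`single_context`}{one training session (context 1, shock paired),
#'     then recall of the same context `recall_delay_h` hours later (default
#'     1 h, while assembly excitability is still elevated). `partial_cue = 4`
#'     replaces the recall cue by direct stimulation of 4 tagged assembly
#'     neurons; pattern completion through the strengthened recurrent weights
#'     then reactivates the rest of the assembly.}
#'   \item{`two_context`}{training of context 1 at 0 h and context 2 after
#'     `delay_h` hours (both shock-paired); 24 h after the second session both
#'     contexts are recalled, 25 min apart (context 1 first). `variant` selects
#'     the control protocol or one of the model-analysis variants:
#'     `"tag_on_recall"` (excitability is also raised 300 ms after recall
#'     onset for neurons active during recall), `"heterogeneous_theta"`
#'     (per-neuron training thresholds drawn from a half-normal around the
#'     nominal threshold, recall threshold fixed), `"fixed_excitability"`
#'     (excitability never leaves baseline), `"noise"` (uniform drive noise at
#'     every integration step).}
#'   \item{`fear_linking`}{three contexts at 0, +7 d and +7 d 5 h (no shock);
#'     context 3 is presented again 2 d later paired with the shock when
#'     `shock = TRUE`; all three contexts are recalled 2 d after that,
#'     25 min apart. Use the `"fear"` parameter preset.}
#'   \item{`allocation`}{context-1 training with the excitability manipulation
#'     (`eps_plus`, toggled by the argument) on the first 8 neurons; recall
#'     24 h later while the first 6 of those neurons are inhibited.}
#'   \item{`allocation_overlap`}{`eps_plus` during context-1 training; context
#'     2 trained after `delay_h`; both contexts recalled 24 h later with the
#'     enhanced subset inhibited during the context-2 recall.}
#'   \item{`competition`}{`eps_plus` during context-1 training; the subset is
#'     inhibited during context-2 *training* (after `delay_h`), optionally with
#'     the reduced global inhibition gain; both contexts recalled 24 h later.}
#' }
#'
#' @param name Experiment name (see Details).
#' @param params An [engram_params()] object.
#' @param delay_h Delay between the two training sessions, hours.
#' @param recall_delay_h For `single_context`: delay from training to the
#'   recall probe, hours.
#' @param variant `two_context` variant (see above).
#' @param partial_cue For `single_context`: number of tagged neurons to cue
#'   directly at recall (0 = full cue).
#' @param shock For `fear_linking`: pair the second context-3 session with the
#'   unconditioned stimulus?
#' @param eps_plus For `allocation`: apply the excitability manipulation?
#' @param reduced_i1 For `competition`: reduce the global inhibition gain
#'   during context-2 training?
#' @param i_plus_recall For `competition`: additionally inhibit the subset
#'   during the context-2 recall?
#' @return A schedule tibble (one row per session, time-ordered), with variant
#'   flags stored in the `"engram_variants"` attribute.
#' @examples
#' experiment_schedule("two_context", engram_params(), delay_h = 6)
#' @export
experiment_schedule <- function(name = c("single_context", "two_context",
                                         "fear_linking", "allocation",
                                         "allocation_overlap", "competition"),
                                params, delay_h = 6,
                                variant = c("control", "tag_on_recall",
                                            "heterogeneous_theta",
                                            "fixed_excitability", "noise"),
                                partial_cue = 0L, shock = TRUE,
                                eps_plus = TRUE, reduced_i1 = FALSE,
                                i_plus_recall = FALSE, recall_delay_h = 1) {
  name <- match.arg(name)
  variant <- match.arg(variant)
  delay <- delay_h * ms_hour
  noise <- name == "two_context" && variant == "noise"
  tag_recall <- name == "two_context" && variant == "tag_on_recall"

  sch <- switch(name,
    single_context = {
      s1 <- training_session(1, 0, params)
      dplyr::bind_rows(
        s1,
        recall_session(1, recall_delay_h * ms_hour, params,
                       partial_cue = partial_cue))
    },
    two_context = {
      s1 <- training_session(1, 0, params, noise = noise)
      s2 <- training_session(2, delay, params, noise = noise)
      r1 <- recall_session(1, delay + ms_day, params, noise = noise,
                           tagging = tag_recall)
      r2 <- recall_session(2, delay + ms_day + 25 * ms_min, params,
                           noise = noise, tagging = tag_recall)
      dplyr::bind_rows(s1, s2, r1, r2)
    },
    fear_linking = {
      t3b_start <- 7 * ms_day + 5 * ms_hour + 2 * ms_day
      rec_start <- t3b_start + 2 * ms_day
      rows <- list(
        training_session(1, 0, params, us = FALSE),
        training_session(2, 7 * ms_day, params, us = FALSE),
        training_session(3, 7 * ms_day + 5 * ms_hour, params, us = FALSE))
      # the conditioning session IS the shock application; the control
      # timeline omits it (three neutral exposures, then recall)
      if (shock)
        rows <- c(rows, list(training_session(3, t3b_start, params, us = TRUE,
                                              label = "train_ctx3_shock")))
      rows <- c(rows, list(
        recall_session(1, rec_start, params),
        recall_session(2, rec_start + 25 * ms_min, params),
        recall_session(3, rec_start + 50 * ms_min, params)))
      dplyr::bind_rows(rows)
    },
    allocation = {
      dplyr::bind_rows(
        training_session(1, 0, params, eps_plus = eps_plus),
        recall_session(1, ms_day, params, i_plus = TRUE))
    },
    allocation_overlap = {
      dplyr::bind_rows(
        training_session(1, 0, params, eps_plus = TRUE),
        training_session(2, delay, params),
        recall_session(1, delay + ms_day, params),
        recall_session(2, delay + ms_day + 25 * ms_min, params,
                       i_plus = TRUE))
    },
    competition = {
      dplyr::bind_rows(
        training_session(1, 0, params, eps_plus = TRUE),
        training_session(2, delay, params, i_plus = TRUE,
                         reduced_i1 = reduced_i1),
        recall_session(1, delay + ms_day, params),
        recall_session(2, delay + ms_day + 25 * ms_min, params,
                       i_plus = i_plus_recall))
    })

  validate_schedule(sch, params)
  attr(sch, "engram_variants") <- list(
    heterogeneous_theta = name == "two_context" && variant == "heterogeneous_theta",
    fixed_excitability = name == "two_context" && variant == "fixed_excitability")
  attr(sch, "experiment") <- name
  sch
}

#' Check a schedule for structural validity
#'
#' Sessions must be time-ordered and non-overlapping (including their
#' trailing fine windows), recalls have exactly one presentation, and the
#' unconditioned stimulus can only be paired with training sessions.
#'
#' @param schedule A schedule tibble.
#' @param params An [engram_params()] object.
#' @return The schedule, invisibly; errors on violation.
#' @export
validate_schedule <- function(schedule, params) {
  if (nrow(schedule) == 0) return(invisible(schedule))
  if (is.unsorted(schedule$start, strictly = TRUE) && nrow(schedule) > 1)
    stop("sessions must be strictly time-ordered", call. = FALSE)
  ends <- schedule$start + vapply(seq_len(nrow(schedule)), function(i) {
    s <- schedule[i, ]
    session_span(s, params) + session_post(s, params)
  }, 0)
  if (nrow(schedule) > 1 && any(ends[-nrow(schedule)] > schedule$start[-1]))
    stop("sessions (with trailing fine windows) overlap", call. = FALSE)
  if (any(schedule$kind == "recall" & schedule$n_presentations != 1L))
    stop("recall sessions have exactly one presentation", call. = FALSE)
  if (any(schedule$us & schedule$kind != "training"))
    stop("the unconditioned stimulus can only be paired with training",
         call. = FALSE)
  invisible(schedule)
}

#' Integration phase plan for a schedule
#'
#' Lists the alternating integration phases covering the timeline: a
#' fine-resolution phase (`dt_fine`) for every session plus its trailing
#' window, and coarse decay phases (`dt_coarse`; weights frozen) for the
#' gaps in between. The phases tile the timeline exactly.
#'
#' @param schedule A schedule tibble.
#' @param params An [engram_params()] object.
#' @return A tibble with columns `phase` (`"fine"`/`"coarse"`), `start`,
#'   `end`, `dt` and `session` (label, `NA` for gaps).
#' @export
phase_plan <- function(schedule, params) {
  validate_schedule(schedule, params)
  out <- list()
  t <- 0
  for (i in seq_len(nrow(schedule))) {
    s <- schedule[i, ]
    if (s$start > t)
      out[[length(out) + 1L]] <- tibble::tibble(
        phase = "coarse", start = t, end = s$start, dt = params$dt_coarse,
        session = NA_character_)
    fin <- s$start + session_span(s, params) + session_post(s, params)
    out[[length(out) + 1L]] <- tibble::tibble(
      phase = "fine", start = s$start, end = fin, dt = params$dt_fine,
      session = s$label)
    t <- fin
  }
  dplyr::bind_rows(out)
}
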