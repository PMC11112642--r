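#' Run one trial of a stimulation schedule
#'
#' Integrates the network through the full timeline of `schedule` with the
#' multi-resolution scheme: explicit Euler at `dt_fine` during every session
#' and its trailing window (3 s after training, 300 ms after recall), and
#' coarse decay phases (`dt_coarse`; recurrent weights frozen, excitability
#' relaxing exactly) in between. Baseline excitability is drawn once per
#' trial from the half-normal distribution; the seed fixes that draw and any
#' noise, so the same seed reproduces the trial bit-for-bit.
#'
#' After the last session the trial is scored: engram membership and the
#' memory-strength observer for every recall probe, pairwise overlap with
#' the first recall's engram, and the exclusion flag (any rate reaching the
#' 100 Hz threshold at any recorded time point).
#'
#' @param schedule A schedule tibble from [experiment_schedule()] or built
#'   from [training_session()] / [recall_session()] rows.
#' @param params An [engram_params()] object.
#' @param seed Integer seed for this trial.
#' @param record Which rate traces to keep: `"recall"` (default; every fine
#'   step around recall probes), `"all"` (also training sessions, decimated
#'   to 10 ms), or `"none"`.
#' @return An object of class `engram_trial`; see [tidy.engram_trial()].
#' @examples
#' \donttest{
#' p <- engram_params()
#' tr <- run_trial(experiment_schedule("single_context", p), p, seed = 1)
#' tidy(tr)
#' }
#' @export
run_trial <- function(schedule, params, seed,
                      record = c("recall", "all", "none")) {
  record <- match.arg(record)
  validate_schedule(schedule, params)
  variants <- attr(schedule, "engram_variants") %||%
    list(heterogeneous_theta = FALSE, fixed_excitability = FALSE)

  n <- params$n_neurons
  set.seed(seed)
  eps0 <- sample_excitability(n, params$eps0_sigma)
  theta_train <- if (isTRUE(variants$heterogeneous_theta))
    abs(stats::rnorm(n, params$theta_active, 1)) else rep(params$theta_active, n)
  apply_jumps <- !isTRUE(variants$fixed_excitability)

  w_ff <- feedforward_matrix(params)
  tau_eps <- tau_eps_ms(params)
  noise_any <- any(schedule$noise)

  state <- list(t = 0, r = numeric(n), W = matrix(0, n, n), eps = eps0,
                pending = rep(-1, n))
  max_rate <- 0
  tagged <- list()
  weights <- list()
  excit <- list()
  traces <- list()
  recalls <- list()
  first_train_tags <- integer()
  failed <- FALSE

  for (i in seq_len(nrow(schedule))) {
    s <- schedule[i, ]

    if (s$start > state$t) {
      gap <- .sim_coarse_gap(state$r, state$W, state$eps, eps0,
                             s$start - state$t, params$dt_coarse,
                             params$tau_r, tau_eps, params$i0, params$i1,
                             params$rate_floor, state$pending,
                             params$eps_jump, state$t,
                             noise_any, params$noise_amplitude)
      state$r <- as.vector(gap$r)
      state$eps <- as.vector(gap$eps)
      state$pending <- as.vector(gap$pending_jump_time)
      state$t <- gap$t_end
      max_rate <- max(max_rate, gap$max_rate)
    }

    span <- session_span(s, params)
    post <- session_post(s, params)
    n_steps <- as.integer(round((span + post) / params$dt_fine))
    on_ms <- if (s$kind == "recall" && s$partial_cue > 0L)
      max(params$stim_duration, params$readout_window) else params$stim_duration
    on_steps <- as.integer(round(on_ms / params$dt_fine))
    gap_steps <- as.integer(round(params$isi / params$dt_fine))
    stim_on <- integer(n_steps)
    for (k in seq_len(s$n_presentations)) {
      a <- (k - 1L) * (on_steps + gap_steps)
      stim_on[(a + 1L):(a + on_steps)] <- 1L
    }
    us_on <- if (isTRUE(s$us)) stim_on else integer(n_steps)

    ext_always <- numeric(n)
    if (isTRUE(s$eps_plus))
      ext_always[seq_len(params$n_eps_plus)] <-
        ext_always[seq_len(params$n_eps_plus)] + params$eps_increase
    if (isTRUE(s$i_plus))
      ext_always[seq_len(params$n_inhib)] <-
        ext_always[seq_len(params$n_inhib)] - params$i_inhib

    ext_stim <- numeric(n)
    if (s$partial_cue > 0L) {
      if (!length(first_train_tags))
        stop("partial-cue recall requires a preceding training session",
             call. = FALSE)
      cue <- utils::head(first_train_tags, s$partial_cue)
      ext_stim[cue] <- params$partial_cue_drive
      ff_on <- numeric(n)                       # input layer silent
    } else {
      ff_on <- as.vector(w_ff %*% context_input(s$context, params))
    }

    i1 <- if (isTRUE(s$reduced_i1)) params$i1_reduced else params$i1
    fixed_jump <- if (s$kind == "recall" && isTRUE(s$tagging))
      s$start + 300 else -1
    # recall phases are always recorded at full resolution: the engram and
    # strength read-outs are computed from them; `record` governs retention
    rec_every <- if (s$kind == "recall") 1L
      else if (record == "all") 20L else 0L

    out <- tryCatch(
      .sim_fine_phase(state$r, state$W, state$eps, eps0, ff_on,
                      stim_on, us_on, params$us_plus, ext_stim, ext_always,
                      params$dt_fine, params$tau_r, params$tau_w, tau_eps,
                      params$i0, i1, theta_train,
                      params$eps_jump, params$tag_delay,
                      isTRUE(s$tagging), apply_jumps, fixed_jump,
                      s$start, params$delta_avg, params$rate_floor,
                      params$w_min, params$w_max, TRUE,
                      identical(params$hebbian, "pre_gates_post"),
                      isTRUE(s$noise), params$noise_amplitude, rec_every),
      error = function(e) e)
    if (inherits(out, "error")) {
      failed <- TRUE
      break
    }

    state$r <- as.vector(out$r)
    state$W <- out$W
    state$eps <- as.vector(out$eps)
    state$pending <- as.vector(out$pending_jump_time)
    state$t <- out$t_end
    max_rate <- max(max_rate, out$max_rate)

    tags <- which(as.logical(out$tagged))
    tagged[[s$label]] <- tags
    if (s$kind == "training" && !length(first_train_tags))
      first_train_tags <- tags
    weights[[s$label]] <- out$W
    excit[[s$label]] <- as.vector(out$eps)

    if (rec_every > 0L && record != "none")
      traces[[s$label]] <- list(times = as.vector(out$trace_times),
                                rates = out$trace)

    if (s$kind == "recall") {
      members <- engram_members(out$trace, as.vector(out$trace_times),
                                s$start, params$stim_duration,
                                params$theta_active)
      strength <- memory_strength(out$trace, as.vector(out$trace_times),
                                  members, s$start, params$readout_window)
      n_members <- length(members)
      recalls[[length(recalls) + 1L]] <- tibble::tibble(
        label = s$label, context = s$context, onset = s$start,
        members = list(members), size = n_members, strength = strength)
    }
  }

  recalls <- if (length(recalls)) dplyr::bind_rows(recalls) else
    tibble::tibble(label = character(), context = integer(), onset = numeric(),
                   members = list(), size = integer(), strength = numeric())

  overlaps <- if (nrow(recalls) >= 2) {
    ref_members <- recalls$members[[1]]
    ov <- vapply(recalls$members[-1], function(m)
      if (length(ref_members)) engram_overlap(ref_members, m) else NA_real_, 0)
    tibble::tibble(ref = recalls$label[1], other = recalls$label[-1],
                   overlap = ov)
  } else tibble::tibble(ref = character(), other = character(),
                        overlap = numeric())

  structure(list(
    recalls = recalls,
    overlaps = overlaps,
    tagged = tagged,
    weights = weights,
    excitability = excit,
    eps0 = eps0,
    traces = traces,
    max_rate = max_rate,
    excluded = is.finite(max_rate) && max_rate >= params$exclusion_rate,
    failed = failed,
    seed = seed,
    params = params,
    schedule = schedule,
    final_state = state
  ), class = "engram_trial")
}

#' @export
print.engram_trial <- function(x, ...) {
  cat("<engram_trial> seed", x$seed, "| preset", x$params$preset, "\n")
  cat("  sessions:", nrow(x$schedule),
      "| excluded:", x$excluded, "| failed:", x$failed,
      "| max rate:", signif(x$max_rate, 4), "Hz\n")
  if (nrow(x$recalls)) {
    df <- dplyr::select(x$recalls, "label", "size", "strength")
    print(as.data.frame(df), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy a simulated trial
#'
#' @param x An `engram_trial`.
#' @param ... Unused.
#' @return One row per recall probe: `label`, `context`, `onset` (ms),
#'   `size` (engram size), `strength` (memory-strength observer, Hz s),
#'   `overlap` (fraction of the first recall's engram reactivated; `NA` for
#'   the first recall itself), plus the trial-level `seed`, `excluded` and
#'   `failed` flags.
#' @export
tidy.engram_trial <- function(x, ...) {
  out <- dplyr::select(x$recalls, "label", "context", "onset", "size",
                       "strength")
  ov <- c(NA_real_, x$overlaps$overlap)[seq_len(nrow(out))]
  out$overlap <- if (nrow(out)) ov else numeric()
  out$seed <- x$seed
  out$excluded <- x$excluded
  out$failed <- x$failed
  out
}

#' One-line summary of a trial
#' @param x An `engram_trial`.
#' @param ... Unused.
#' @return A one-row tibble: seed, number of sessions and recalls, size of
#'   the first training engram, maximum rate, exclusion and failure flags.
#' @export
glance.engram_trial <- function(x, ...) {
  first_tags <- if (length(x$tagged)) length(x$tagged[[1]]) else NA_integer_
  tibble::tibble(
    seed = x$seed,
    n_sessions = nrow(x$schedule),
    n_recalls = nrow(x$recalls),
    n_tagged_first = first_tags,
    max_rate = x$max_rate,
    excluded = x$excluded,
    failed = x$failed)
}
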