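#' Model parameters for the engram network
#'
#' Builds the full parameter set of the rate-network model: network sizes,
#' time constants, inhibition, plasticity and excitability constants, the
#' stimulation-protocol geometry, and integration settings. Four presets are
#' provided; `"default"`, `"overlap"` and `"competition"` share one column of
#' values (they differ only in which experiments consult the reduced
#' inhibition gain), while `"fear"` is a second calibration used for the
#' fear-conditioning / memory-linking protocol, matched to hippocampal dCA1
#' overlap kinetics (faster excitability decay, lower active threshold,
#' fewer and faster-learned presentations, weaker shock gain).
#'
#' All times are stored in milliseconds internally; the constructor accepts
#' the conventional mixed units noted below.
#'
#' @param preset One of `"default"`, `"overlap"`, `"competition"`, `"fear"`.
#' @param ... Named overrides of individual fields, e.g. `theta_active = 4`.
#'
#' @return An object of class `engram_params`: a named list with fields
#' \describe{
#'   \item{n_neurons, n_inputs}{network and input-layer sizes (60, 30).}
#'   \item{tau_r}{rate relaxation time constant, ms (15).}
#'   \item{tau_w}{Hebbian learning time constant, ms (750; 500 for `"fear"`).}
#'   \item{tau_eps_h}{excitability decay time constant, hours (24; 12 for `"fear"`).}
#'   \item{eps_jump}{elevated excitability value E set after tagging (3.5; 4 for `"fear"`).}
#'   \item{theta_active}{active threshold, Hz (6; 4 for `"fear"`).}
#'   \item{i0, i1, i1_reduced}{global inhibition: baseline, gain on summed
#'     rates, and the reduced gain used when a session requests lowered
#'     inhibition (6, 0.9, 0.88).}
#'   \item{stim_duration, n_stim, isi}{presentation length (ms), number of
#'     presentations per training session, inter-stimulus gap (ms)
#'     (40, 20, 150; 15 presentations for `"fear"`).}
#'   \item{w_ff_rf, w_ff_nonrf}{feed-forward weights inside / outside a
#'     receptive-field block (0.3, 0.2).}
#'   \item{w_min, w_max}{caps on the plastic recurrent weights (0, 1).}
#'   \item{us_plus}{unconditioned-stimulus gain on the learning rule while the
#'     shock is paired with a presentation (1; 0.5 for `"fear"`).}
#'   \item{r_cs}{firing rate of activated input neurons, Hz (4).}
#'   \item{delta_avg}{window of the running mean rate used by the learning
#'     rule, ms (15000).}
#'   \item{n_eps_plus, eps_increase}{size of the subset receiving the
#'     excitability manipulation, and the added drive (8, 5).}
#'   \item{n_inhib, i_inhib}{size of the optogenetic-style inhibited subset
#'     (drawn from the enhanced subset) and the subtracted current (6, 0.5).}
#'   \item{readout_window}{integration window of the memory-strength observer,
#'     ms (100).}
#'   \item{tag_delay}{delay from threshold crossing to the excitability jump,
#'     ms (2900).}
#'   \item{eps0_sigma}{scale of the half-normal baseline excitability (0.5).}
#'   \item{rate_floor}{rates below this are set to exactly 0 (1e-5).}
#'   \item{exclusion_rate}{trial-exclusion threshold, Hz (100).}
#'   \item{dt_fine, dt_coarse}{integration steps, ms (0.5, 20000).}
#'   \item{post_session_fine, post_recall_fine}{trailing fine-resolution
#'     windows after training and recall sessions, ms (3000, 300).}
#'   \item{noise_amplitude}{full width of the per-step uniform drive noise,
#'     used only by noise experiments (4).}
#'   \item{partial_cue_drive}{direct depolarizing current delivered to each
#'     cued neuron during a partial-cue recall (16; drives cued assembly
#'     neurons to training-like rates so that completion through the
#'     strengthened recurrent weights can recruit the rest).}
#'   \item{hebbian}{orientation of the learning rule:
#'     `"pre_gates_post"` (presynaptic rate times postsynaptic deviation,
#'     the default) or `"post_gates_pre"` (the transpose), kept switchable
#'     for sensitivity checks.}
#' }
#' @examples
#' p <- engram_params()
#' p$theta_active
#' engram_params("fear")$n_stim
#' @export
engram_params <- function(preset = c("default", "overlap", "competition", "fear"),
                          ...) {
  preset <- match.arg(preset)
  p <- list(
    preset = preset,
    n_neurons = 60L,
    n_inputs = 30L,
    tau_r = 15,
    tau_w = 750,
    tau_eps_h = 24,
    eps_jump = 3.5,
    theta_active = 6,
    i0 = 6,
    i1 = 0.9,
    i1_reduced = 0.88,
    stim_duration = 40,
    n_stim = 20L,
    isi = 150,
    w_ff_rf = 0.3,
    w_ff_nonrf = 0.2,
    w_min = 0,
    w_max = 1,
    us_plus = 1,
    r_cs = 4,
    delta_avg = 15000,
    n_eps_plus = 8L,
    eps_increase = 5,
    n_inhib = 6L,
    i_inhib = 0.5,
    readout_window = 100,
    tag_delay = 2900,
    eps0_sigma = 0.5,
    rate_floor = 1e-5,
    exclusion_rate = 100,
    dt_fine = 0.5,
    dt_coarse = 20000,
    post_session_fine = 3000,
    post_recall_fine = 300,
    noise_amplitude = 4,
    partial_cue_drive = 16,
    hebbian = "pre_gates_post"
  )
  if (preset == "fear") {
    p$tau_eps_h <- 12
    p$eps_jump <- 4
    p$theta_active <- 4
    p$n_stim <- 15L
    p$tau_w <- 500
    p$us_plus <- 0.5
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    p[names(dots)] <- dots
  }
  class(p) <- "engram_params"
  rep_ok <- validate_engram_params(p)
  if (nrow(rep_ok))
    stop("invalid parameters:\n  ",
         paste(rep_ok$invariant, collapse = "\n  "), call. = FALSE)
  p
}

#' Excitability decay time constant in milliseconds
#' @param params An `engram_params` object.
#' @return The decay time constant, ms.
#' @keywords internal
tau_eps_ms <- function(params) params$tau_eps_h * 3600 * 1000

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set and reports the
#' violations. An empty report means the set is valid; nothing is thrown.
#'
#' @param params An `engram_params` object (or a bare named list with the
#'   same fields).
#' @return A tibble with columns `invariant` (the violated rule, as text) and
#'   `value` (a short rendering of the offending values); zero rows when the
#'   set is valid.
#' @examples
#' nrow(validate_engram_params(engram_params()))  # 0
#' @export
validate_engram_params <- function(params) {
  bad <- list()
  note <- function(rule, val) bad[[length(bad) + 1L]] <<-
      tibble::tibble(invariant = rule, value = val)

  pos <- c("n_neurons", "n_inputs", "tau_r", "tau_w", "tau_eps_h", "theta_active",
           "stim_duration", "n_stim", "isi", "r_cs", "delta_avg", "readout_window",
           "exclusion_rate", "dt_fine", "dt_coarse", "eps0_sigma", "rate_floor")
  for (f in pos) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      note(paste0(f, " > 0"), format(v))
  }
  if (params$w_min > params$w_max)
    note("w_min <= w_max", paste(params$w_min, ">", params$w_max))
  if (params$theta_active >= params$exclusion_rate)
    note("theta_active < exclusion_rate",
         paste(params$theta_active, ">=", params$exclusion_rate))
  if (params$n_eps_plus > params$n_neurons)
    note("n_eps_plus <= n_neurons",
         paste(params$n_eps_plus, ">", params$n_neurons))
  if (params$n_inhib > params$n_eps_plus)
    note("n_inhib <= n_eps_plus",
         paste(params$n_inhib, ">", params$n_eps_plus))
  if (!params$hebbian %in% c("pre_gates_post", "post_gates_pre"))
    note("hebbian orientation known", params$hebbian)
  # the fine step must tile presentations, gaps and the tag delay exactly
  for (f in c("stim_duration", "isi", "tag_delay", "post_session_fine",
              "post_recall_fine")) {
    v <- params[[f]]
    if (is.numeric(v) && abs(v / params$dt_fine - round(v / params$dt_fine)) > 1e-9)
      note(paste0("dt_fine divides ", f), paste(params$dt_fine, "vs", v))
  }
  if (length(bad)) dplyr::bind_rows(bad)
  else tibble::tibble(invariant = character(), value = character())
}

#' @export
print.engram_params <- function(x, ...) {
  cat("<engram_params> preset:", x$preset, "\n")
  flat <- x[setdiff(names(x), "preset")]
  cat(sprintf("  %-18s %s\n", names(flat),
              vapply(flat, function(v) paste(format(v), collapse = " "), "")),
      sep = "")
  invisible(x)
}

#' Write / read a parameter set as a flat YAML config
#'
#' The file holds one key per field in the conventional units used by
#' [engram_params()]. A round trip (`write` then `read`) reproduces the
#' parameter set exactly.
#'
#' @param params An `engram_params` object.
#' @param path File path.
#' @return `write_engram_params()` returns `path` invisibly;
#'   `read_engram_params()` returns an `engram_params` object.
#' @export
write_engram_params <- function(params, path) {
  stopifnot(inherits(params, "engram_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_engram_params
#' @export
read_engram_params <- function(path) {
  raw <- yaml::read_yaml(path)
  preset <- raw$preset %||% "default"
  raw$preset <- NULL
  int_fields <- c("n_neurons", "n_inputs", "n_stim", "n_eps_plus", "n_inhib")
  raw[int_fields] <- lapply(raw[int_fields], as.integer)
  do.call(engram_params, c(list(preset = preset), raw))
}
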