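#' Feed-forward weight matrix with block receptive fields
#'
#' The input layer is divided into three groups of 10 neurons, one per
#' context. Each group projects with strong weights (`w_ff_rf`) onto its
#' 15-neuron receptive-field block in the main network (inputs 1-10 drive
#' neurons 1-15, 11-20 drive 16-30, 21-30 drive 31-45); every other entry,
#' including all rows of the 15 neurons without a receptive field, carries
#' the weak background weight `w_ff_nonrf`. These weights are static.
#'
#' @param params An [engram_params()] object.
#' @return A dense `n_neurons` x `n_inputs` numeric matrix.
#' @examples
#' W <- feedforward_matrix(engram_params())
#' W[1, 1]; W[1, 15]
#' @export
feedforward_matrix <- function(params) {
  n <- params$n_neurons
  nin <- params$n_inputs
  W <- matrix(params$w_ff_nonrf, n, nin)
  blk_out <- 15L
  blk_in <- 10L
  for (b in 1:3) {
    rows <- ((b - 1L) * blk_out + 1L):(b * blk_out)
    cols <- ((b - 1L) * blk_in + 1L):(b * blk_in)
    W[rows, cols] <- params$w_ff_rf
  }
  W
}

#' Input-layer rate vector for a context presentation
#'
#' While a context is presented, its 10 input neurons fire at `r_cs` and all
#' other inputs are silent.
#'
#' @param context Context index, 1, 2 or 3.
#' @param params An [engram_params()] object.
#' @return Numeric vector of length `n_inputs`.
#' @export
context_input <- function(context, params) {
  if (!context %in% 1:3) stop("context must be 1, 2 or 3", call. = FALSE)
  r_in <- numeric(params$n_inputs)
  blk_in <- 10L
  r_in[((context - 1L) * blk_in + 1L):(context * blk_in)] <- params$r_cs
  r_in
}

#' Sample baseline excitability
#'
#' Baseline excitabilities are drawn from a half-normal distribution: the
#' absolute value of a zero-mean normal with scale `sigma`.
#'
#' @param n Number of neurons.
#' @param sigma Scale of the underlying normal.
#' @return Numeric vector of length `n`, all entries non-negative.
#' @examples
#' set.seed(1)
#' e0 <- sample_excitability(60, 0.5)
#' @export
sample_excitability <- function(n, sigma = 0.5) {
  stopifnot(sigma > 0)
  abs(stats::rnorm(n, 0, sigma))
}

#' Pre-activation drive of the network (reference implementation)
#'
#' Computes the argument of the rectifier for every neuron: recurrent input
#' plus feed-forward input minus global inhibition `I0 + I1 * sum(r)` plus
#' excitability and any external current. Rectification is applied by the
#' integration step, not here.
#'
#' @param r Current rate vector (length `n_neurons`).
#' @param w_rec Recurrent weight matrix.
#' @param w_ff Feed-forward matrix.
#' @param r_in Input-layer rate vector.
#' @param eps Excitability vector.
#' @param params An [engram_params()] object.
#' @param ext Optional external per-neuron drive (default 0).
#' @param i1 Inhibition gain; defaults to `params$i1`.
#' @return Numeric vector of pre-activations (may be negative).
#' @export
total_drive <- function(r, w_rec, w_ff, r_in, eps, params, ext = 0,
                        i1 = params$i1) {
  if (length(r) != nrow(w_rec) || ncol(w_ff) != length(r_in))
    stop("dimension mismatch in total_drive()", call. = FALSE)
  as.vector(w_rec %*% r) + as.vector(w_ff %*% r_in) -
    (params$i0 + i1 * sum(r)) + eps + ext
}

#' One explicit Euler step of the rate dynamics (reference implementation)
#'
#' `r <- r + (dt / tau_r) * (ReLU(drive) - r)`, then rates below the floor
#' are set to exactly zero. This mirrors the compiled integration core and is
#' used as its independent check.
#'
#' @param r Rate vector.
#' @param drive Pre-activation vector (see [total_drive()]).
#' @param dt Step, ms.
#' @param params An [engram_params()] object.
#' @return Updated rate vector.
#' @export
rate_step <- function(r, drive, dt, params) {
  r <- r + (dt / params$tau_r) * (pmax(drive, 0) - r)
  r[r < params$rate_floor] <- 0
  r
}

#' Windowed mean firing rate (reference implementation)
#'
#' Mean of a rate trace over the trailing window `delta` ending at `t_end`,
#' zero-padded before the start of the trace: the integral is always divided
#' by the full window length.
#'
#' @param times Sample times (ms), equally spaced by the fine step.
#' @param rates Rate samples at `times` (one neuron).
#' @param t_end Right edge of the window, ms.
#' @param delta Window length, ms.
#' @return The windowed mean rate, Hz.
#' @export
windowed_mean <- function(times, rates, t_end, delta) {
  dt <- if (length(times) > 1) times[2] - times[1] else delta
  # half-open window (t_end - delta, t_end]: exactly delta / dt samples
  keep <- times > t_end - delta + 1e-9 & times <= t_end + 1e-9
  sum(rates[keep]) * dt / delta
}

#' One Hebbian plasticity step (reference implementation)
#'
#' For every connection the weight moves by
#' `(dt / tau_w) * (1 + US) * tanh(r_pre * (r_post - r0_post))` under the
#' default orientation (`"pre_gates_post"`): the presynaptic rate gates the
#' postsynaptic deviation from its recent mean `r0`. The transpose
#' orientation swaps the roles. Weights are then clipped to
#' `[w_min, w_max]`. Autapses (diagonal entries) are plastic like any other
#' connection.
#'
#' @param w_rec Recurrent weight matrix (entry `[i, j]` is the weight from
#'   neuron `j` onto neuron `i`).
#' @param r Current rate vector.
#' @param r0 Windowed mean rate vector.
#' @param us_active Whether the unconditioned stimulus is paired right now.
#' @param dt Step, ms.
#' @param params An [engram_params()] object.
#' @return Updated weight matrix.
#' @export
plasticity_step <- function(w_rec, r, r0, us_active, dt, params) {
  us <- if (isTRUE(us_active)) params$us_plus else 0
  gain <- (dt / params$tau_w) * (1 + us)
  dw <- if (identical(params$hebbian, "post_gates_pre"))
    tanh(outer(r, r - r0)) else tanh(outer(r - r0, r))
  w <- w_rec + gain * dw
  w[w < params$w_min] <- params$w_min
  w[w > params$w_max] <- params$w_max
  w
}

#' Exact excitability relaxation
#'
#' Closed-form solution of the first-order decay toward baseline:
#' `eps0 + (eps - eps0) * exp(-elapsed / tau)`. Exact for any elapsed time,
#' so composing successive calls over split intervals equals one call over
#' the total interval.
#'
#' @param eps Current excitability vector.
#' @param eps0 Baseline excitability vector.
#' @param elapsed Elapsed time, ms (non-negative).
#' @param tau_eps Decay time constant, ms.
#' @return Updated excitability vector.
#' @examples
#' excitability_decay(3.5, 0, 24 * 3600e3, 24 * 3600e3)  # 3.5 / e
#' @export
excitability_decay <- function(eps, eps0, elapsed, tau_eps) {
  stopifnot(elapsed >= 0)
  eps0 + (eps - eps0) * exp(-elapsed / tau_eps)
}
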