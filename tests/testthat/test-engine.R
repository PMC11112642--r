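# The compiled fine-phase integrator is checked against an independent pure-R
# re-implementation built from the exported reference operations, and against
# closed-form solutions of the rate and excitability dynamics.

fine_phase <- function(...) engramsim:::.sim_fine_phase(...)
coarse_gap <- function(...) engramsim:::.sim_coarse_gap(...)

run_engine <- function(p, n_steps, stim_on, us_on = integer(n_steps),
                       W = matrix(0, p$n_neurons, p$n_neurons),
                       eps = rep(0, p$n_neurons), eps0 = eps,
                       ff_on = rep(0, p$n_neurons),
                       ext_always = rep(0, p$n_neurons),
                       theta = rep(p$theta_active, p$n_neurons),
                       tagging = FALSE, plastic = TRUE, i0 = p$i0,
                       i1 = p$i1, record = 1L) {
  fine_phase(rep(0, p$n_neurons), W, eps, eps0, ff_on, stim_on, us_on,
             p$us_plus, rep(0, p$n_neurons), ext_always,
             p$dt_fine, p$tau_r, p$tau_w, p$tau_eps_h * 3600e3,
             i0, i1, theta, p$eps_jump, p$tag_delay,
             tagging, TRUE, -1, 0, p$delta_avg, p$rate_floor,
             p$w_min, p$w_max, plastic, TRUE, FALSE, p$noise_amplitude,
             record)
}

test_that("compiled stepper matches the pure-R reference step for step", {
  p <- engram_params()
  n <- p$n_neurons
  Wff <- feedforward_matrix(p)
  ff_on <- as.vector(Wff %*% context_input(1, p))
  n_steps <- 400L
  stim_on <- rep(c(1L, 0L), c(300L, 100L))
  set.seed(7)
  eps0 <- sample_excitability(n, 0.5)

  out <- fine_phase(rep(0, n), matrix(0, n, n), eps0, eps0, ff_on,
                    stim_on, stim_on, p$us_plus, rep(0, n), rep(0, n),
                    p$dt_fine, p$tau_r, p$tau_w, p$tau_eps_h * 3600e3,
                    p$i0, p$i1, rep(p$theta_active, n),
                    p$eps_jump, p$tag_delay, TRUE, TRUE, -1, 0,
                    p$delta_avg, p$rate_floor, p$w_min, p$w_max,
                    TRUE, TRUE, FALSE, 4, 0L)

  # independent replica from the exported reference operations
  r <- rep(0, n); W <- matrix(0, n, n); eps <- eps0
  win_sum <- rep(0, n)
  dec <- exp(-p$dt_fine / (p$tau_eps_h * 3600e3))
  for (s in seq_len(n_steps)) {
    rin <- if (stim_on[s] == 1L) context_input(1, p) else numeric(p$n_inputs)
    u <- total_drive(r, W, Wff, rin, eps, p)
    r <- rate_step(r, u, p$dt_fine, p)
    win_sum <- win_sum + r
    r0 <- win_sum * p$dt_fine / p$delta_avg
    if (max(r) > 0)
      W <- plasticity_step(W, r, r0, stim_on[s] == 1L, p$dt_fine, p)
    eps <- eps0 + (eps - eps0) * dec
  }
  expect_equal(as.vector(out$r), r, tolerance = 1e-12)
  expect_equal(out$W, W, tolerance = 1e-12)
  expect_equal(as.vector(out$eps), eps, tolerance = 1e-12)
})

test_that("rate integration converges to the exponential at first order", {
  # frozen positive drive u0: r(t) = u0 * (1 - exp(-t / tau_r))
  p <- engram_params()
  u0 <- 5
  horizon <- 60   # ms
  dev <- sapply(c(0.5, 0.25), function(dt) {
    ns <- as.integer(horizon / dt)
    out <- fine_phase(rep(0, 60), matrix(0, 60, 60), rep(0, 60), rep(0, 60),
                      rep(u0, 60), rep(1L, ns), integer(ns), 0,
                      rep(0, 60), rep(0, 60), dt, p$tau_r, p$tau_w,
                      p$tau_eps_h * 3600e3, 0, 0, rep(99, 60), 0, 0,
                      FALSE, TRUE, -1, 0, p$delta_avg, p$rate_floor, 0, 1,
                      FALSE, TRUE, FALSE, 4, 1L)
    exact <- u0 * (1 - exp(-out$trace_times / p$tau_r))
    max(abs(out$trace[, 1] - exact))
  })
  expect_lt(dev[1], 0.05)
  expect_gt(dev[1] / dev[2], 1.6)   # halving dt roughly halves the error
  expect_lt(dev[1] / dev[2], 2.4)
})

test_that("a quiescent network with sub-threshold excitability stays silent", {
  p <- engram_params()
  set.seed(3)
  eps0 <- sample_excitability(60, 0.5)     # far below i0 = 6
  out <- run_engine(p, 2000L, integer(2000L), eps = eps0, eps0 = eps0,
                    tagging = TRUE)
  expect_equal(max(out$max_rate), 0)
  expect_equal(sum(out$tagged), 0L)
  expect_equal(out$W, matrix(0, 60, 60))
})

test_that("silent neurons never change their incident weights", {
  p <- engram_params()
  ext <- rep(0, 60); ext[1:3] <- 13    # drive only neurons 1-3
  out <- run_engine(p, 2000L, integer(2000L), ext_always = ext)
  active <- 1:3
  expect_gt(min(out$W[active, active][upper.tri(diag(3))]), 0)
  expect_equal(out$W[-active, ], matrix(0, 57, 60))
  expect_equal(out$W[, -active], matrix(0, 60, 57))
})

test_that("weights respect their caps through a full training session", {
  p <- engram_params()
  one <- rep(c(1L, 0L), c(80L, 300L))
  stim <- c(rep(one, 19), rep(1L, 80L), rep(0L, 6000L))
  set.seed(5)
  eps0 <- sample_excitability(60, 0.5)
  out <- run_engine(p, length(stim), stim, us_on = stim, eps = eps0,
                    eps0 = eps0,
                    ff_on = as.vector(feedforward_matrix(p) %*%
                                        context_input(1, p)),
                    tagging = TRUE)
  expect_gte(min(out$W), 0)
  expect_lte(max(out$W), 1)
  expect_gt(max(out$W), 0.99)        # assembly weights saturate
})

test_that("threshold crossing tags once and sets excitability after the delay", {
  p <- engram_params()
  ext <- rep(0, 60); ext[1] <- 18   # fixed point 12/1.9 = 6.3 Hz, over theta
  ns <- 8000L                                # 4 s at 0.5 ms
  out <- run_engine(p, ns, integer(ns), ext_always = ext, tagging = TRUE,
                    plastic = FALSE)
  expect_true(as.logical(out$tagged[1]))
  expect_equal(sum(as.logical(out$tagged)), 1L)
  # jump happened in-phase: eps was SET to E, then decayed for < 4 s
  expect_gt(out$eps[1], 3.49)
  expect_lte(out$eps[1], 3.5)
  expect_equal(as.vector(out$pending_jump_time), rep(-1, 60))
  tagt <- out$tag_time[1]
  expect_lt(tagt, 100)                        # crossed within ~0.1 s

  # with jumps disabled the tag is recorded but excitability never moves
  outf <- fine_phase(rep(0, 60), matrix(0, 60, 60), rep(0, 60), rep(0, 60),
                     rep(0, 60), integer(ns), integer(ns), 0, rep(0, 60),
                     ext, p$dt_fine, p$tau_r, p$tau_w, p$tau_eps_h * 3600e3,
                     p$i0, p$i1, rep(6, 60), p$eps_jump, p$tag_delay,
                     TRUE, FALSE, -1, 0, p$delta_avg, p$rate_floor, 0, 1,
                     FALSE, TRUE, FALSE, 4, 0L)
  expect_true(as.logical(outf$tagged[1]))
  expect_equal(as.vector(outf$eps), rep(0, 60))
})

test_that("coarse stepping applies pending jumps and relaxes excitability exactly", {
  p <- engram_params()
  tau <- p$tau_eps_h * 3600e3
  eps0 <- rep(0.2, 60)
  pend <- rep(-1, 60); pend[4] <- 3600e3     # jump one hour in
  out <- coarse_gap(rep(0, 60), matrix(0, 60, 60), eps0, eps0,
                    6 * 3600e3, p$dt_coarse, p$tau_r, tau, p$i0, p$i1,
                    p$rate_floor, pend, p$eps_jump, 0, FALSE, 4)
  # neuron 4: at baseline for 1 h, set to E, then decays for 5 h
  expect_equal(out$eps[4],
               excitability_decay(p$eps_jump, 0.2, 5 * 3600e3, tau),
               tolerance = 1e-9)
  expect_equal(out$eps[1], 0.2)
  expect_equal(out$max_rate, 0)
})
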