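test_that("feed-forward matrix has the block receptive-field structure", {
  p <- engram_params()
  W <- feedforward_matrix(p)
  expect_equal(dim(W), c(60L, 30L))
  expect_equal(W[1, 1], 0.3)      # inside the first RF block
  expect_equal(W[1, 15], 0.2)     # outside it
  expect_equal(W[20, 15], 0.3)    # second block
  expect_true(all(W[46:60, ] == 0.2))   # neurons without an RF
  # every RF row: 10 strong + 20 weak inputs
  expect_equal(unname(rowSums(W)[1:45]), rep(10 * 0.3 + 20 * 0.2, 45))
})

test_that("pre-activation combines feed-forward drive and global inhibition", {
  p <- engram_params()
  Wff <- feedforward_matrix(p)
  W0 <- matrix(0, 60, 60)
  zero <- numeric(60)

  # context 1 at r_cs, everything else silent: RF neuron gets 12 - 6 = 6
  d <- total_drive(zero, W0, Wff, context_input(1, p), zero, p)
  expect_equal(d[1], 6)
  expect_equal(d[50], 10 * 0.2 * 4 - 6)   # non-RF neuron

  # fully silent network: baseline inhibition only
  expect_equal(total_drive(zero, W0, Wff, numeric(30), zero, p),
               rep(-6, 60))

  # population rate term: 60 neurons at 1 Hz -> I = 6 + 0.9 * 60
  d2 <- total_drive(rep(1, 60), W0, Wff, numeric(30), zero, p)
  expect_equal(d2, rep(-(6 + 0.9 * 60), 60))

  expect_error(total_drive(rep(1, 10), W0, Wff, numeric(30), zero, p),
               "dimension")
})

test_that("Euler rate step relaxes to the rectified drive and floors tiny rates", {
  p <- engram_params()
  # one explicit step from 8 Hz with drive forced to zero
  expect_equal(rate_step(8, 0, 0.5, p), 8 * (1 - 0.5 / 15))
  # negative drive rectifies to zero target
  expect_equal(rate_step(0, -6, 0.5, p), 0)
  # fixed point: holding u constant converges to u
  r <- 0
  for (i in 1:2000) r <- rate_step(r, 9.3, 0.5, p)
  expect_equal(r, 9.3, tolerance = 1e-6)
  # rates under the floor snap to exactly zero
  expect_identical(rate_step(1e-6, 0, 0.5, p), 0)
})

test_that("windowed mean is a zero-padded trailing average", {
  delta <- 15000
  times <- seq(0.5, 30000, by = 0.5)
  expect_equal(windowed_mean(times, rep(3, length(times)), 30000, delta), 3)
  expect_equal(windowed_mean(times, rep(0, length(times)), 30000, delta), 0)
  # active for the first half-window only, queried at the window edge
  rates <- ifelse(times <= delta / 2, 4, 0)
  expect_equal(windowed_mean(times, rates, delta, delta), 2)
})

test_that("Hebbian step gates the postsynaptic deviation by the presynaptic rate", {
  p <- engram_params()
  n <- 3
  r0 <- rep(0, n)
  # silent network: no change anywhere
  expect_equal(plasticity_step(matrix(0.5, n, n), rep(0, n), r0, FALSE, 0.5, p),
               matrix(0.5, n, n))
  # pre 4 Hz, post 6 Hz, mean 0: dW = (dt / tau_w) * tanh(24)
  r <- c(6, 4, 0)
  W1 <- plasticity_step(matrix(0, n, n), r, r0, FALSE, 0.5, p)
  expect_equal(W1[1, 2], (0.5 / 750) * tanh(4 * 6))
  # the unconditioned stimulus doubles the update
  W2 <- plasticity_step(matrix(0, n, n), r, r0, TRUE, 0.5, p)
  expect_equal(W2[1, 2], 2 * W1[1, 2])
  # depression cannot push weights below the lower cap
  W3 <- plasticity_step(matrix(0, n, n), c(1, 4, 0), c(5, 0, 0), FALSE, 0.5, p)
  expect_true(all(W3 >= p$w_min))
  expect_equal(W3[1, 2], 0)   # tanh(4 * (1 - 5)) < 0, clipped at 0
})

test_that("excitability decay is the exact exponential and composes", {
  tau <- 24 * 3600e3
  expect_equal(excitability_decay(3.5, 0, tau, tau), 3.5 / exp(1))
  expect_equal(excitability_decay(c(1, 2), c(1, 2), 5e6, tau), c(1, 2))
  expect_equal(excitability_decay(3.5, 0.2, 0, tau), 3.5)
  # splitting an interval arbitrarily gives the same answer
  set.seed(42)
  for (i in 1:20) {
    total <- runif(1, 1e3, 1e8)
    cut <- runif(1, 0, total)
    one <- excitability_decay(3.5, 0.4, total, tau)
    two <- excitability_decay(excitability_decay(3.5, 0.4, cut, tau),
                              0.4, total - cut, tau)
    expect_equal(two, one)
  }
  # closed-form values at the protocol delays (baseline 0)
  expect_equal(excitability_decay(3.5, 0, 6 * 3600e3, tau),
               3.5 * exp(-0.25))
  expect_equal(excitability_decay(3.5, 0, 24 * 3600e3, tau), 3.5 / exp(1))
})

test_that("baseline excitability is half-normal and seed-reproducible", {
  set.seed(11)
  e <- sample_excitability(1e5, 0.5)
  expect_true(all(e >= 0))
  # half-normal mean = sigma * sqrt(2 / pi); 3 standard errors of the mean
  se <- sqrt(0.5^2 * (1 - 2 / pi)) / sqrt(1e5)
  expect_lt(abs(mean(e) - 0.5 * sqrt(2 / pi)), 3 * se)
  set.seed(99); a <- sample_excitability(60, 0.5)
  set.seed(99); b <- sample_excitability(60, 0.5)
  expect_identical(a, b)
})
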