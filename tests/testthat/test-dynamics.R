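test_that("one step applies the decayed coupling map exactly", {
  cfg <- sim_config()
  expect_equal(step_dyad(c(0.3, -0.2), context_matrix(0, 0, 0, 0), cfg),
               c(-0.03, 0.02))
  expect_equal(step_dyad(c(1, 1), context_matrix(1, 0, 0, 1), cfg),
               c(0.9, 0.9))
  expect_equal(step_dyad(c(1, 1), context_matrix(1, 1, 1, 1), cfg),
               c(1.9, 1.9))
  # noise enters additively
  expect_equal(step_dyad(c(0, 0), context_matrix(1, 1, 1, 1), cfg,
                         noise = c(0.2, -0.1)),
               c(0.2, -0.1))
  expect_error(step_dyad(c(Inf, 0), context_matrix(0, 0, 0, 0), cfg),
               "invalid state")
})

test_that("spectral radius diagnoses divergent contexts", {
  expect_equal(spectral_radius(context_matrix(0, 0, 0, 0)), 0.1)
  expect_equal(spectral_radius(context_matrix(1, 1, 1, 1)), 1.9)
  expect_equal(spectral_radius(context_matrix(-1, -1, -1, -1)), 2.1)
})

test_that("simulation records n_turns points and is bit-reproducible", {
  cfg <- sim_config(seed = 11)
  tr <- simulate_dyad(context_matrix(1, 0, 1, -1), cfg)
  expect_length(tr$b1, 500L)
  expect_length(tr$b2, 500L)
  expect_true(all(is.finite(tr$b1)) && all(is.finite(tr$b2)))
  tr2 <- simulate_dyad(context_matrix(1, 0, 1, -1), cfg)
  expect_identical(tr$b1, tr2$b1)
  expect_identical(tr$b2, tr2$b2)
})

test_that("noise-free identity coupling decays geometrically", {
  n <- 40L
  cfg <- sim_config(n_turns = n)
  tr <- simulate_dyad(context_matrix(1, 0, 0, 1), cfg,
                      noise = matrix(0, n - 1, 2), init = c(1, 1))
  expect_equal(tr$b1, 0.9^(0:(n - 1)))
  expect_equal(tr$b2, 0.9^(0:(n - 1)))
})

test_that("noise-free trajectories equal the matrix-power closed form on all 81 contexts", {
  ctx <- enumerate_contexts()
  n <- 21L
  cfg <- sim_config(n_turns = n)
  init <- c(0.3, -0.4)
  for (i in seq_len(nrow(ctx))) {
    cm <- as_context_matrix(ctx[i, ])
    m <- coupling_matrix(cm, cfg)
    tr <- simulate_dyad(cm, cfg, noise = matrix(0, n - 1, 2), init = init)
    state <- init
    for (t in 2:n) {
      state <- as.vector(m %*% state)
      expect_equal(c(tr$b1[t], tr$b2[t]), state, tolerance = 1e-12)
    }
  }
})

test_that("with zero coupling and no decay the series is iid uniform noise", {
  cfg <- sim_config(alpha = 0, seed = 5)
  tr <- simulate_dyad(context_matrix(0, 0, 0, 0), cfg)
  # sample mean of ~U(-0.5, 0.5): 3 SD bound = 3 * (1/sqrt(12)) / sqrt(500)
  expect_lt(abs(mean(tr$b1)), 0.07)
  expect_lt(abs(mean(tr$b2)), 0.07)
  expect_gt(stats::var(tr$b1[-1]), 0.05)  # close to 1/12
  expect_lt(stats::var(tr$b1[-1]), 0.12)
})

test_that("swapping agent labels swaps the channels exactly", {
  cfgs <- list(sim_config(n_turns = 60),
               sim_config(n_turns = 60, update_mode = "alternating",
                          start_agent = "agent1"))
  set.seed(99)
  picks <- enumerate_contexts()[sample.int(81, 6), ]
  for (cfg in cfgs) {
    swapped_cfg <- cfg
    if (cfg$update_mode == "alternating") swapped_cfg$start_agent <- "agent2"
    for (i in seq_len(nrow(picks))) {
      p <- picks[i, ]
      noise <- matrix(stats::runif(118, -0.5, 0.5), ncol = 2)
      init <- stats::runif(2, -0.5, 0.5)
      a <- simulate_dyad(context_matrix(p$s1, p$o1, p$o2, p$s2), cfg,
                         noise = noise, init = init)
      b <- simulate_dyad(context_matrix(p$s2, p$o2, p$o1, p$s1), swapped_cfg,
                         noise = noise[, 2:1], init = init[2:1])
      expect_equal(b$b1, a$b2, tolerance = 1e-12)
      expect_equal(b$b2, a$b1, tolerance = 1e-12)
    }
  }
})

test_that("stable contexts stay within the accumulated operator-norm bound", {
  # For spectral radius < 1 the series sum_k ||M^k|| converges; every state
  # satisfies ||b(t)|| <= ||M^t|| ||b(0)|| + sum_{k<t} ||M^k|| ||e||. (The
  # eigenvalue-only geometric bound fails for non-normal M, whose transients
  # overshoot the spectral radius.)
  ctx <- enumerate_contexts()
  cfg <- sim_config(seed = 3)
  opnorm <- function(m) svd(m, nu = 0, nv = 0)$d[1]
  for (i in seq_len(nrow(ctx))) {
    cm <- as_context_matrix(ctx[i, ])
    if (spectral_radius(cm, cfg) >= 0.99) next
    m <- coupling_matrix(cm, cfg)
    norms <- numeric(cfg$n_turns)
    p <- diag(2)
    for (k in seq_len(cfg$n_turns)) { norms[k] <- opnorm(p); p <- m %*% p }
    tr <- simulate_dyad(cm, cfg)
    init_norm <- sqrt(tr$b1[1]^2 + tr$b2[1]^2)
    bound <- max(norms) * init_norm +
      sum(norms) * cfg$noise_high * sqrt(2)
    expect_lt(max(sqrt(tr$b1^2 + tr$b2^2)), bound + 1e-9)
  }
})

test_that("start policies and alternating updates behave as documented", {
  cfg1 <- sim_config(n_turns = 30, start_agent = "agent1", seed = 2)
  tr1 <- simulate_dyad(context_matrix(0, 0, 0, 0), cfg1)
  expect_identical(tr1$b2[1], 0)
  expect_false(tr1$b1[1] == 0)
  cfg2 <- sim_config(n_turns = 30, start_agent = "agent2", seed = 2)
  tr2 <- simulate_dyad(context_matrix(0, 0, 0, 0), cfg2)
  expect_identical(tr2$b1[1], 0)

  alt <- simulate_dyad(context_matrix(1, 1, 1, 1),
                       sim_config(n_turns = 30, seed = 4,
                                  update_mode = "alternating"))
  ch1 <- diff(alt$b1) != 0
  ch2 <- diff(alt$b2) != 0
  expect_false(any(ch1 & ch2))     # never both in one step
  expect_true(ch1[1])              # agent 1 moves first by default
  expect_true(all(xor(ch1, ch2)))  # exactly one moves per step
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_turns = 1), "n_turns")
  expect_error(sim_config(alpha = 1.5), "alpha")
  expect_error(sim_config(noise_low = 0.5, noise_high = -0.5), "noise")
  expect_error(sim_config(seed = -1), "seed")
  expect_error(sim_config(update_mode = "jacobi"), "update_mode|arg")
})
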