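test_that("global inhibition follows its quadratic form", {
  p <- network_params()
  expect_equal(global_inhibition(rep(0, 50), p), 12)
  r <- rep(0, 50); r[1] <- 1
  expect_equal(global_inhibition(r, p), 12 + 0.5 + 0.05)
  set.seed(1)
  for (i in 1:20) {
    r <- runif(50, 0, 10)
    expect_gte(global_inhibition(r, p), p$I0)
  }
})

test_that("rate step decays geometrically with no input and finds the ReLU fixed point", {
  p <- network_params(N = 3)
  W <- matrix(0, 3, 3)
  r <- c(10, 10, 10)
  for (k in 1:5) r <- rate_step(r, 0, rep(0, 3), W, 12, p)
  expect_equal(r, rep(10 * (1 - 1 / 20)^5, 3))

  # stationary rate with eps = 20, I = I0 = 12: r* = ReLU(20 - 12) = 8
  r <- rep(0, 3)
  for (k in 1:2000) r <- rate_step(r, 0, rep(20, 3), W, 12, p)
  expect_equal(r, rep(8, 3), tolerance = 1e-10)

  expect_error(rate_step(c(NaN, 1, 1), 0, rep(0, 3), W, 12, p), "non-finite")
})

test_that("slope mode multiplies the activation instead of shifting it", {
  p <- network_params(N = 2, excitability_mode = "slope")
  W <- matrix(0, 2, 2)
  r <- c(0, 0)
  # input = drive - I = 3; f = eps * 3
  for (k in 1:2000) r <- rate_step(r, 15, c(0.5, 2), W, 12, p)
  expect_equal(r, c(1.5, 6), tolerance = 1e-10)
})

test_that("hebbian step decays, clips at the cap and respects the mask", {
  p <- network_params(N = 4)
  W <- matrix(0.5, 4, 4)
  mask <- matrix(1, 4, 4)
  W1 <- hebbian_weight_step(rep(0, 4), W, mask, p)
  expect_equal(W1, W * (1 - 1 / 1000))

  W2 <- hebbian_weight_step(rep(100, 4), W, mask, p) # unclipped step >> c
  expect_true(all(W2 == p$c))

  mask[1, 2] <- 0
  W <- matrix(0, 4, 4)
  for (k in 1:1000) W <- hebbian_weight_step(rep(50, 4), W, mask, p)
  expect_equal(W[1, 2], 0)
  expect_equal(W[2, 1], p$c)
  expect_error(hebbian_weight_step(rep(0, 3), W, mask, p), "N x N")
})

test_that("active neurons use a strict threshold", {
  expect_equal(active_neurons(c(0, 6, 5), 5), 2L)
  expect_equal(active_neurons(rep(0, 10), 5), integer(0))
  expect_error(active_neurons(c(1, 2), -1), "theta")
})

test_that("a schedule with zero drive leaves the naive network silent", {
  net <- tiny_network(E = 0)
  proto <- tiny_protocol()
  set.seed(1)
  sch <- build_schedule(proto, net)
  sch$drive[] <- 0
  rec <- simulate_network(sch, net)
  expect_lt(max(rec$rates), 1e-12)
  expect_lt(max(abs(rec$final_W)), 1e-12)
})

test_that("vectorized simulator matches the scalar-loop oracle to machine precision", {
  net <- network_params(N = 5)
  proto <- protocol_params(n_days = 2, Nrep = 2, T_rep = 60, IR = 40, ID = 50,
                           boost_blocks = list(1:2, 3:4))
  set.seed(7)
  sch <- build_schedule(proto, net)
  expect_equal(sch$n_steps, 500)
  rec <- simulate_network(sch, net)
  ora <- oracle_simulate(sch, net)
  expect_lt(max(abs(rec$rates - ora$rates)), 1e-10)
  expect_lt(max(abs(rec$final_W - ora$W)), 1e-10)
})

test_that("trajectories respect the weight bounds, non-negative rates and symmetry", {
  net <- tiny_network()
  proto <- tiny_protocol()
  set.seed(3)
  sch <- build_schedule(proto, net)
  rec <- simulate_network(sch, net)
  expect_true(all(rec$rates >= 0))
  for (d in seq_along(rec$W_snapshots)) {
    W <- rec$W_snapshots[[d]]
    expect_true(all(W >= 0 & W <= net$c))
    expect_equal(W, t(W))  # dense symmetric update keeps W symmetric
  }
})

test_that("fixed seed and config give bit-identical records", {
  net <- tiny_network(sparsity = 0.3)
  proto <- tiny_protocol()
  a <- run_simulation(proto, net, seed = 11, with_baseline = TRUE)
  b <- run_simulation(proto, net, seed = 11, with_baseline = TRUE)
  expect_identical(a$rates, b$rates)
  expect_identical(a$patterns, b$patterns)
  expect_identical(a$mask, b$mask)
  expect_identical(a$baseline$patterns, b$baseline$patterns)
})

test_that("the sparsity mask zeroes the prescribed fraction and pins synapses", {
  net <- tiny_network(sparsity = 0.5)
  set.seed(5)
  m <- sample_mask(net)
  expect_true(abs(mean(m) - 0.5) < 0.15)
  proto <- tiny_protocol()
  rec <- run_simulation(proto, net, seed = 2)
  expect_true(all(rec$final_W[rec$mask == 0] == 0))
})
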