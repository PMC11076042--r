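test_that("the default schedule lays out the published 4-day timing", {
  net <- network_params()
  proto <- protocol_params()
  set.seed(1)
  sch <- build_schedule(proto, net)
  expect_equal(sch$n_steps, 12000)
  # drive is exactly delta or 0
  expect_setequal(unique(sch$drive), c(0, net$delta))
  # day-1 drive confined to steps 1000-3000 (0-based), in repetition windows
  driven <- which(sch$drive > 0 & sch$day_of_step == 1) - 1L
  expect_gte(min(driven), 1000)
  expect_lt(max(driven), 3000)
  # 10 repetitions x 100 steps per day
  expect_equal(length(driven), 1000)
  # repetition windows spaced by T + IR
  expect_equal(min(driven), 1000)
  expect_equal(sort(unique(driven %/% 200)), 5:14)
  # pattern step = final step of the last repetition
  expect_equal(sch$pattern_steps[, 1], c(2900, 5900, 8900, 11900))
  # days partition the run
  expect_equal(sch$day_windows[, "start"], c(0, 3000, 6000, 9000))
})

test_that("Nrep = 1 gives a single drive window per day", {
  net <- tiny_network()
  proto <- protocol_params(n_days = 2, Nrep = 1, T_rep = 30, IR = 10,
                           ID = 20, boost_blocks = list(1:3, 4:6))
  set.seed(1)
  sch <- build_schedule(proto, net)
  d1 <- which(sch$drive > 0 & sch$day_of_step == 1)
  expect_equal(length(d1), 30)
  expect_true(all(diff(d1) == 1))
})

test_that("excitability is boosted on the day's block and resampled daily", {
  net <- network_params()
  proto <- protocol_params()
  set.seed(42)
  boosted <- replicate(20, {
    e <- sample_excitability(1, proto, net)
    mean(e$epsilon[11:20]) - mean(e$epsilon[-(11:20)])
  })
  # block mean exceeds the rest by about E on average
  expect_equal(mean(boosted), net$E, tolerance = 0.35)
  set.seed(42)
  e <- sample_excitability(1, proto, net)
  expect_equal(e$epsilon[11:20], e$baseline[11:20] + net$E)
  expect_equal(e$epsilon[-(11:20)], e$baseline[-(11:20)])
  expect_true(all(e$baseline >= 0))

  set.seed(9)
  sch <- build_schedule(proto, net)
  # per-day draws differ
  expect_gt(max(abs(sch$epsilon_by_day[1, ] - sch$epsilon_by_day[2, ])), 0.1)
})

test_that("E = 0 removes any block structure from excitability", {
  net <- network_params(E = 0)
  proto <- protocol_params()
  set.seed(2)
  e <- sample_excitability(1, proto, net)
  expect_equal(e$epsilon, e$baseline)
})

test_that("slope-variant excitability is centred near its published mean", {
  vp <- variant_params("slope")
  set.seed(3)
  draws <- replicate(30, sample_excitability(1, vp$protocol, vp$network)$baseline)
  expect_true(all(draws > 0))
  expect_equal(mean(draws), 0.4, tolerance = 0.05)
})

test_that("baseline replay removes exactly the boost and is idempotent", {
  net <- network_params()
  proto <- protocol_params()
  set.seed(4)
  sch <- build_schedule(proto, net)
  rep0 <- baseline_replay(sch)
  for (d in 1:4) {
    blk <- proto$boost_blocks[[d]]
    drop <- mean(sch$epsilon_by_day[d, blk]) - mean(rep0$epsilon_by_day[d, blk])
    expect_equal(drop, net$E)
    # untouched outside the block
    expect_equal(sch$epsilon_by_day[d, -blk], rep0$epsilon_by_day[d, -blk])
  }
  expect_identical(baseline_replay(rep0), rep0)

  netE0 <- network_params(E = 0)
  set.seed(4)
  schE0 <- build_schedule(proto, netE0)
  expect_equal(baseline_replay(schE0)$epsilon_by_day, schE0$epsilon_by_day)
})

test_that("two-context schedules partition neurons and interleave blocks", {
  vp <- variant_params("two_context")
  set.seed(5)
  sch <- build_two_context_schedule(vp$protocol, vp$network)
  expect_equal(sort(unique(sch$context)), c(1L, 2L))
  expect_equal(sum(sch$context == 1), 25)
  expect_equal(sch$n_steps, 24000)
  # day-1 windows: A at 1000-3000, B at 4000-6000 (0-based)
  a1 <- which(sch$drive > 0 & sch$target == 1 & sch$day_of_step == 1) - 1L
  b1 <- which(sch$drive > 0 & sch$target == 2 & sch$day_of_step == 1) - 1L
  expect_gte(min(a1), 1000); expect_lt(max(a1), 3000)
  expect_gte(min(b1), 4000); expect_lt(max(b1), 6000)
  expect_equal(unname(sch$pattern_steps[1, ]), c(2900L, 5900L))
  # supervision currents only during day-1 blocks
  expect_equal(range(which(sch$beta[, 1] > 0)) - 1L, c(1000L, 2999L))
  expect_equal(range(which(sch$beta[, 2] > 0)) - 1L, c(4000L, 5999L))
  expect_true(all(sch$beta[sch$day_of_step > 1, ] == 0))

  expect_error(build_two_context_schedule(vp$protocol, network_params(N = 49)),
               "even N")
})

test_that("two-context drive never reaches the other context's neurons", {
  vp <- variant_params("two_context")
  vp$protocol <- protocol_params(n_days = 2, Nrep = 1, T_rep = 40, IR = 10,
                                 ID = 50, two_context = TRUE,
                                 boost_blocks = list(1:5, 6:10))
  net <- network_params(N = 20, tau_decay = 4000, I0 = 8, I1 = 0.8,
                        delta = 12)
  set.seed(6)
  sch <- build_two_context_schedule(vp$protocol, net)
  rec <- simulate_network(sch, net)
  half_b <- which(sch$context == 2)
  # during the very first A repetition, B neurons receive no drive and the
  # naive network gives them no recurrent input either
  first_a <- which(sch$drive > 0 & sch$target == 1)[1:10]
  expect_lt(max(rec$rates[first_a, half_b]), 1e-8)
})

test_that("schedules round-trip through JSON serialization", {
  net <- tiny_network()
  proto <- tiny_protocol()
  set.seed(8)
  sch <- build_schedule(proto, net)
  path <- tempfile(fileext = ".json")
  write_schedule(sch, path)
  back <- read_schedule(path)
  for (f in c("n_steps", "drive", "target", "day_of_step", "day_windows",
              "pattern_steps", "epsilon_by_day", "epsilon_baseline",
              "delta", "two_context"))
    expect_equal(back[[f]], sch[[f]], label = f)

  set.seed(8)
  tc <- build_two_context_schedule(protocol_params(two_context = TRUE),
                                   variant_params("two_context")$network)
  write_schedule(tc, path)
  back <- read_schedule(path)
  expect_equal(back$context, tc$context)
  expect_equal(back$beta, tc$beta)
  expect_equal(back$pattern_steps, tc$pattern_steps)
})
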