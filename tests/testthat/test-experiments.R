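small_net <- function(...) tiny_network(...)
small_proto <- function(...) tiny_protocol(...)

test_that("the drift experiment returns one correlation row per later day", {
  res <- run_experiment("drift", seeds = 0, network = small_net(),
                        protocol = small_proto())
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$tables$correlation_by_day), 3)
  expect_equal(res$tables$correlation_by_day$day, 2:4)
  expect_equal(nrow(res$tables$drift_summary), 1)
  expect_true(all(c("drift_rate", "within_block_w", "out_block_w") %in%
                    names(res$tables$drift_summary)))
})

test_that("experiments are bit-reproducible from their seeds", {
  a <- run_experiment("drift", seeds = 0:1, network = small_net(),
                      protocol = small_proto())
  b <- run_experiment("drift", seeds = 0:1, network = small_net(),
                      protocol = small_proto())
  expect_identical(a$tables, b$tables)
})

test_that("summaries report mean and s.e.m. per group", {
  res <- run_experiment("drift", seeds = 0:2, network = small_net(),
                        protocol = small_proto())
  s <- summarize_experiment(res)
  cb <- s$correlation_by_day
  expect_equal(nrow(cb), 3)
  expect_equal(cb$n, rep(3, 3))
  d2 <- res$tables$correlation_by_day
  expect_equal(cb$corr_day1_mean[cb$day == 2],
               mean(d2$corr_day1[d2$day == 2]))
  expect_equal(cb$corr_day1_sem[cb$day == 2],
               sd(d2$corr_day1[d2$day == 2]) / sqrt(3))

  res1 <- run_experiment("drift", seeds = 0, network = small_net(),
                         protocol = small_proto())
  expect_warning(s1 <- summarize_experiment(res1), "s.e.m. undefined")
  expect_true(is.na(s1$correlation_by_day$corr_day1_sem[1]))
})

test_that("the day-decoder experiment produces real and shuffled tables", {
  res <- run_experiment("day_decoder", seeds = 0, n_shuffle = 3,
                        network = small_net(), protocol = small_proto())
  expect_equal(nrow(res$tables$decoding), 4)
  expect_equal(nrow(res$tables$shuffled), 3)
  expect_true(all(abs(res$tables$decoding$error) <= 3))
})

test_that("the ordinal sweep covers the requested amplitude grid", {
  res <- run_experiment("ordinal_sweep", seeds = 0:1, E_grid = c(0, 1.5),
                        network = small_net(), protocol = small_proto())
  tab <- res$tables$ordinal
  expect_equal(nrow(tab), 4)
  expect_setequal(unique(tab$E), c(0, 1.5))
  expect_true(all(is.finite(tab$t_real)))
})

test_that("the size sweep varies block width with wrap-around", {
  res <- run_experiment("size_sweep", seeds = 0, widths = c(2, 4),
                        network = small_net(), protocol = small_proto())
  tab <- res$tables$size_sweep
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$drift_rate)))
})

test_that("the read-out experiment reports Q and per-day centers of mass", {
  res <- run_experiment("readout", seeds = 0, network = small_net(),
                        protocol = small_proto())
  expect_equal(nrow(res$tables$readout_by_day), 4)
  expect_equal(nrow(res$tables$readout_summary), 1)
  expect_true(is.finite(res$tables$readout_summary$Q))
})

test_that("experiment output directories carry tables and a manifest", {
  out <- file.path(tempdir(), "driftnet-exp-test")
  on.exit(unlink(out, recursive = TRUE))
  res <- run_experiment("drift", seeds = 0, network = small_net(),
                        protocol = small_proto(), out_dir = out)
  expect_true(file.exists(file.path(out, "correlation_by_day.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$experiment, "drift")
  expect_equal(man$seeds, 0)
  expect_match(man$config_md5, "^[0-9a-f]{32}$")
})

test_that("records round-trip through the plain-text container", {
  net <- small_net()
  proto <- small_proto()
  rec <- run_simulation(proto, net, seed = 3, with_baseline = TRUE)
  dir <- file.path(tempdir(), "driftnet-rec-test")
  on.exit(unlink(dir, recursive = TRUE))
  write_record(rec, dir)
  back <- read_record(dir)
  expect_equal(back$patterns, rec$patterns)
  expect_equal(back$baseline_patterns, rec$baseline$patterns)
  expect_equal(back$epsilon, rec$epsilon)
  expect_equal(back$W_snapshots[[2]], rec$W_snapshots[[2]])
  expect_equal(back$rates, rec$rates)
  expect_equal(back$meta$seed, 3)
})
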