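#' Run a named simulation experiment
#'
#' Orchestrates the multi-seed experiments that regenerate the study's
#' figure-level results from configuration plus seeds:
#'
#' * `"drift"` — single-ensemble runs; per-day correlation with the day-1
#'   pattern, drift rate, day-1 assembly composition and weight-block
#'   statistics.
#' * `"day_decoder"` — boosted runs plus baseline replays; day-decoder
#'   errors on real and label-shuffled patterns.
#' * `"ordinal_sweep"` — ordinal time decoder t-statistics (real vs
#'   label-shuffled) across excitability amplitudes.
#' * `"sparse"`, `"slope"` — the structural robustness variants, running
#'   drift, day-decoder and ordinal analyses under that parameter set.
#' * `"size_sweep"` — drift rate as a function of boost-block width.
#' * `"readout"` — read-out neuron runs; output vs shuffled-weight control,
#'   quality index Q, weight center of mass per day.
#' * `"quality_sweep"` — Q against drift rate across excitability
#'   amplitudes.
#' * `"two_context"` — two interleaved ensembles with two supervised
#'   read-out neurons; per-context drift and own/other-context responses.
#'
#' Every result is a tidy table; re-running with the same seeds reproduces
#' all tables exactly. If `out_dir` is given, tables are written as CSV
#' together with a JSON manifest (config, seeds, MD5 of the config).
#'
#' @param name Experiment name (see above).
#' @param n_seeds Number of seeds (default 10; seeds are `0:(n_seeds-1)`
#'   unless `seeds` is given).
#' @param seeds Integer vector of seeds.
#' @param E_grid Excitability amplitudes for the sweep experiments.
#' @param widths Boost-block widths for `"size_sweep"`.
#' @param n_shuffle Label shuffles per seed for decoder nulls.
#' @param network,protocol Optional parameter overrides; defaults are the
#'   variant's published set.
#' @param out_dir Optional output directory for CSV tables + manifest.
#' @return An `experiment_result`: list with `name`, `seeds`, `tables`
#'   (named data.frames) and `config`.
#' @seealso [summarize_experiment()]
#' @export
run_experiment <- function(name = c("drift", "day_decoder", "ordinal_sweep",
                                    "sparse", "slope", "size_sweep",
                                    "readout", "quality_sweep",
                                    "two_context"),
                           n_seeds = 10, seeds = NULL,
                           E_grid = NULL, widths = c(5, 10, 20),
                           n_shuffle = 10,
                           network = NULL, protocol = NULL,
                           out_dir = NULL) {
  name <- match.arg(name)
  if (is.null(seeds)) seeds <- seq_len(n_seeds) - 1L
  tables <- switch(name,
    drift = exp_drift(seeds, network, protocol),
    day_decoder = exp_day_decoder(seeds, network, protocol, n_shuffle),
    ordinal_sweep = exp_ordinal_sweep(seeds, network, protocol,
                                      E_grid %||% c(0, 0.5, 1, 1.5, 2, 3)),
    sparse = exp_variant("sparse", seeds, n_shuffle),
    slope = exp_variant("slope", seeds, n_shuffle),
    size_sweep = exp_size_sweep(seeds, widths, network, protocol),
    readout = exp_readout(seeds, network, protocol),
    quality_sweep = exp_quality_sweep(seeds, network, protocol,
                                      E_grid %||% c(0.5, 1.5, 3)),
    two_context = exp_two_context(seeds)
  )
  res <- structure(list(name = name, seeds = seeds, tables = tables,
                        config = list(E_grid = E_grid, widths = widths,
                                      n_shuffle = n_shuffle)),
                   class = "experiment_result")
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s, %d seeds\n", x$name, length(x$seeds)))
  for (nm in names(x$tables))
    cat(sprintf("  $%s: %d x %d\n", nm, nrow(x$tables[[nm]]),
                ncol(x$tables[[nm]])))
  invisible(x)
}

default_pair <- function(network, protocol, variant = "default") {
  vp <- variant_params(variant)
  list(network = network %||% vp$network, protocol = protocol %||% vp$protocol)
}

# per-seed single-ensemble run: correlation curve, drift, assembly stats
drift_seed_metrics <- function(seed, network, protocol,
                               with_baseline = FALSE) {
  rec <- run_simulation(protocol, network, seed, with_baseline = with_baseline,
                        record_rates = FALSE)
  V <- rec$patterns
  n_days <- nrow(V)
  corrs <- vapply(2:n_days, function(d)
    pattern_correlation(V[1, ], V[d, ]), numeric(1))
  blk <- protocol$boost_blocks[[1]]
  W1 <- rec$W_snapshots[[1]]
  out <- setdiff(seq_len(network$N), blk)
  list(rec = rec,
       corr = data.frame(seed = seed, day = 2:n_days, corr_day1 = corrs),
       summary = data.frame(
         seed = seed,
         drift_rate = drift_rate(V),
         n_active_day1 = length(rec$active[[1]]),
         block_all_active = all(blk %in% rec$active[[1]]),
         within_block_w = mean(W1[blk, blk]),
         out_block_w = mean(W1[out, out])))
}

exp_drift <- function(seeds, network, protocol) {
  p <- default_pair(network, protocol)
  res <- lapply(seeds, drift_seed_metrics, network = p$network,
                protocol = p$protocol)
  list(correlation_by_day = do.call(rbind, lapply(res, `[[`, "corr")),
       drift_summary = do.call(rbind, lapply(res, `[[`, "summary")))
}

day_decoder_seed <- function(seed, network, protocol, n_shuffle) {
  rec <- run_simulation(protocol, network, seed, with_baseline = TRUE,
                        record_rates = FALSE)
  ps <- get_patterns(rec)
  dd <- day_decode(ps)
  shuf_err <- vapply(seq_len(n_shuffle), function(i) {
    Vs <- shuffle_day_labels(ps$V)
    mean(abs(day_decode(Vs, V0 = ps$V0)$error))
  }, numeric(1))
  list(real = cbind(seed = seed, dd),
       shuffled = data.frame(seed = seed, shuffle = seq_len(n_shuffle),
                             mean_abs_error = shuf_err))
}

exp_day_decoder <- function(seeds, network, protocol, n_shuffle) {
  p <- default_pair(network, protocol)
  res <- lapply(seeds, day_decoder_seed, network = p$network,
                protocol = p$protocol, n_shuffle = n_shuffle)
  list(decoding = do.call(rbind, lapply(res, `[[`, "real")),
       shuffled = do.call(rbind, lapply(res, `[[`, "shuffled")))
}

ordinal_seed <- function(seed, network, protocol) {
  rec <- run_simulation(protocol, network, seed, record_rates = FALSE)
  od <- ordinal_decode(rec$patterns)
  ods <- ordinal_decode(shuffle_day_labels(rec$patterns))
  data.frame(seed = seed, E = network$E, t_real = od$t_value,
             t_shuffled = ods$t_value, S_real = od$S_real,
             real_is_max = od$real_is_max)
}

exp_ordinal_sweep <- function(seeds, network, protocol, E_grid) {
  p <- default_pair(network, protocol)
  rows <- list()
  for (E in E_grid) {
    net <- p$network; net$E <- E
    rows <- c(rows, lapply(seeds, ordinal_seed, network = net,
                           protocol = p$protocol))
  }
  list(ordinal = do.call(rbind, rows))
}

exp_variant <- function(variant, seeds, n_shuffle) {
  vp <- variant_params(variant)
  drift <- exp_drift(seeds, vp$network, vp$protocol)
  dd <- exp_day_decoder(seeds, vp$network, vp$protocol, n_shuffle)
  ord <- exp_ordinal_sweep(seeds, vp$network, vp$protocol,
                           E_grid = unique(c(0, vp$network$E, 3)))
  c(drift, dd, ord)
}

exp_size_sweep <- function(seeds, widths, network, protocol) {
  p <- default_pair(network, protocol)
  rows <- list()
  for (w in widths) {
    proto <- p$protocol
    proto$boost_blocks <- default_boost_blocks(proto$n_days, width = w,
                                               N = p$network$N)
    for (s in seeds) {
      rec <- run_simulation(proto, p$network, s, record_rates = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        seed = s, width = w, drift_rate = drift_rate(rec$patterns))
    }
  }
  list(size_sweep = do.call(rbind, rows))
}

readout_seed <- function(seed, network, protocol, ro_params) {
  rec <- run_simulation(protocol, network, seed, readout = ro_params,
                        record_rates = FALSE)
  n_days <- nrow(rec$epsilon)
  y_d <- rec$readout$y_at_patterns[, 1, 1]
  y_sh <- rec$readout$y_shuffle[, 1, , 1]           # n_days x n_shuffle
  com <- vapply(seq_len(n_days), function(d) {
    w <- rec$readout$W_out_snapshots[d, 1, , 1]
    if (sum(w) > 0) weight_center_of_mass(w) else NA_real_
  }, numeric(1))
  Q <- readout_quality(y_d, t(y_sh))
  list(by_day = data.frame(seed = seed, day = seq_len(n_days), y = y_d,
                           y_shuffle_mean = rowMeans(y_sh), com = com),
       summary = data.frame(seed = seed, Q = Q,
                            com_increasing = all(diff(com) > 0)))
}

exp_readout <- function(seeds, network, protocol) {
  p <- default_pair(network, protocol)
  ro <- readout_params()
  res <- lapply(seeds, readout_seed, network = p$network,
                protocol = p$protocol, ro_params = ro)
  list(readout_by_day = do.call(rbind, lapply(res, `[[`, "by_day")),
       readout_summary = do.call(rbind, lapply(res, `[[`, "summary")))
}

exp_quality_sweep <- function(seeds, network, protocol, E_grid) {
  p <- default_pair(network, protocol)
  ro <- readout_params()
  rows <- list()
  for (E in E_grid) {
    net <- p$network; net$E <- E
    for (s in seeds) {
      rec <- run_simulation(p$protocol, net, s, readout = ro,
                            record_rates = FALSE)
      y_d <- rec$readout$y_at_patterns[, 1, 1]
      y_sh <- t(rec$readout$y_shuffle[, 1, , 1])
      Q <- tryCatch(readout_quality(y_d, y_sh), error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        seed = s, E = E, drift_rate = drift_rate(rec$patterns), Q = Q)
    }
  }
  list(quality_sweep = do.call(rbind, rows))
}

two_context_seed <- function(seed, vp, ro) {
  rec <- run_simulation(vp$protocol, vp$network, seed, readout = ro,
                        with_baseline = TRUE, record_rates = FALSE)
  n_days <- nrow(rec$epsilon)
  rows_corr <- list(); rows_resp <- list()
  for (ctx in c("A", "B")) {
    k <- if (ctx == "A") 1 else 2
    ps <- get_patterns(rec, context = ctx)
    corrs <- vapply(2:n_days, function(d)
      pattern_correlation(ps$V[1, ], ps$V[d, ]), numeric(1))
    rows_corr[[ctx]] <- data.frame(seed = seed, context = ctx,
                                   day = 2:n_days, corr_day1 = corrs,
                                   drift_rate = drift_rate(ps))
    # output k responds at the end of each context's stimulation blocks
    rows_resp[[ctx]] <- data.frame(
      seed = seed, output = k, day = seq_len(n_days),
      y_own = rec$readout$y_at_patterns[, k, k],
      y_other = rec$readout$y_at_patterns[, if (k == 1) 2 else 1, k])
  }
  list(corr = do.call(rbind, rows_corr), resp = do.call(rbind, rows_resp))
}

exp_two_context <- function(seeds) {
  vp <- variant_params("two_context")
  ro <- readout_params(n_outputs = 2)
  res <- lapply(seeds, two_context_seed, vp = vp, ro = ro)
  list(context_drift = do.call(rbind, lapply(res, `[[`, "corr")),
       output_responses = do.call(rbind, lapply(res, `[[`, "resp")))
}

#' Summarize an experiment over seeds
#'
#' Per-metric mean and standard error of the mean across seeds, grouped by
#' the table's non-seed key columns (day, E, width, context, output as
#' present). With a single seed the s.e.m. is reported as `NA` and flagged
#' with a warning.
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @return Named list of summary data.frames (columns: keys, `mean`,
#'   `sem`, `n`).
#' @export
summarize_experiment <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  if (length(result$seeds) < 2)
    warning("single seed: s.e.m. undefined, reported as NA")
  lapply(result$tables, summarize_table)
}

summarize_table <- function(tab) {
  keys <- intersect(c("day", "E", "width", "context", "output", "shuffle"),
                    names(tab))
  keys <- setdiff(keys, "shuffle")
  vals <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                  c(keys, "seed", "shuffle"))
  if (length(keys) == 0) {
    out <- do.call(rbind, lapply(vals, function(v) data.frame(
      metric = v, mean = mean(tab[[v]]), sem = sem(tab[[v]]),
      n = sum(!is.na(tab[[v]])))))
    return(out)
  }
  grp <- interaction(tab[keys], drop = TRUE)
  out <- do.call(rbind, lapply(split(tab, grp), function(g) {
    row <- g[1, keys, drop = FALSE]
    for (v in vals) {
      row[[paste0(v, "_mean")]] <- mean(g[[v]])
      row[[paste0(v, "_sem")]] <- sem(g[[v]])
    }
    row$n <- nrow(g)
    row
  }))
  rownames(out) <- NULL
  out
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$tables)) {
    utils::write.csv(result$tables[[nm]],
                     file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(result$config, cfg_path, auto_unbox = TRUE,
                       null = "null")
  manifest <- list(experiment = result$name, seeds = result$seeds,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   tables = names(result$tables))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
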