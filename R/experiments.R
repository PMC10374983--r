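## Experiment presets. Each preset declares what varies across conditions
## (the "axis"), the condition levels, the metrics scored, and the fixed
## simulation overrides. The default setting everywhere else is: LCMV,
## FIXPC3, SNR 3.5 dB, BSR 0 dB, 2 interactions, delay 50-200 ms, one
## active source per region.
.experiment_presets <- function() {
  list(
    "1A" = list(axis = "metric",
                levels = c("coh", "icoh", "mic", "mim", "gc", "trgc")),
    "1B" = list(axis = "scheme",
                levels = c(paste0("fixpc", 1:6), "varpc90", "varpc99",
                           "meanfc", "central", "fcmean", "truevox"),
                metrics = c("mim", "trgc")),
    "1C" = list(axis = "surrogate", levels = "fixpc3", metrics = "mim",
                sim = list(n_interactions = 1)),
    "2A" = list(axis = "inverse",
                levels = c("eloreta", "lcmv", "dics", "champagne"),
                metrics = c("mim", "trgc")),
    "2B" = list(axis = "inverse", levels = c("eloreta", "lcmv"),
                metrics = c("mim", "trgc"),
                sim = list(n_interactions = 1)),
    "2C" = list(axis = "inverse", levels = c("eloreta", "lcmv"),
                metrics = c("mim", "trgc"), correlated = TRUE),
    "3A" = list(axis = "theta_snr",
                levels = db_to_theta(c(-7.4, 3.5, 19.1)),
                level_names = c("-7.4dB", "3.5dB", "19.1dB"),
                metrics = c("mim", "trgc")),
    "3B" = list(axis = "theta_bsr", levels = c(0.001, 0.25, 0.5, 0.75, 0.999),
                level_names = c("0%", "25%", "50%", "75%", "100%"),
                metrics = c("mim", "trgc")),
    "4" = list(axis = "n_interactions", levels = 1:5,
               metrics = c("mim", "trgc")),
    "5" = list(axis = "delay_ms", levels = c(2, 4, 6, 8, 10),
               metrics = c("mim", "trgc")),
    "6" = list(axis = "scheme", levels = paste0("fixpc", 1:6),
               metrics = c("mim", "trgc"), two_sources = TRUE))
}

#' Specify a benchmark experiment
#'
#' Builds an experiment specification from a preset id, optionally
#' restricting the condition levels or overriding the iteration count and
#' master seed. Presets: 1A FC metrics; 1B aggregation schemes; 1C
#' surrogate statistics; 2A/2B inverse solutions; 2C correlated source
#' pairs; 3A SNR levels; 3B brain/sensor-noise ratio; 4 number of
#' interactions; 5 short delays; 6 two active sources per region.
#'
#' @param id experiment id.
#' @param n_iterations Monte-Carlo iterations (default 100).
#' @param seed master seed.
#' @param levels optional subset (or override) of the preset's levels.
#' @param metrics optional override of the scored metrics.
#' @param sim_overrides named list merged into [sim_config()] arguments.
#' @return `fc_experiment_spec`.
#' @export
experiment_spec <- function(id, n_iterations = 100, seed = 0,
                            levels = NULL, metrics = NULL,
                            sim_overrides = list()) {
  presets <- .experiment_presets()
  id <- as.character(id)
  if (!id %in% names(presets)) {
    stop("unknown experiment id: ", id,
         " (available: ", paste(names(presets), collapse = ", "), ")")
  }
  p <- presets[[id]]
  if (!is.null(levels)) {
    if (is.null(p$level_names)) {
      stopifnot(all(levels %in% p$levels))
    }
    p$levels <- levels
    p$level_names <- NULL
  }
  if (!is.null(metrics)) p$metrics <- metrics
  if (is.null(p$metrics)) p$metrics <- p$levels  # 1A: levels are metrics
  structure(list(id = id, axis = p$axis, levels = p$levels,
                 level_names = p$level_names %||% as.character(p$levels),
                 metrics = p$metrics,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 sim = p$sim %||% list(),
                 correlated = isTRUE(p$correlated),
                 two_sources = isTRUE(p$two_sources),
                 sim_overrides = sim_overrides),
            class = "fc_experiment_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.simulate_for <- function(cfg_args, spec, model) {
  cfg <- do.call(sim_config, cfg_args)
  if (spec$correlated) {
    simulate_correlated_pairs(cfg, model)
  } else if (spec$two_sources) {
    simulate_two_sources_per_region(cfg, model)
  } else {
    simulate_recording(cfg, model)
  }
}

.score_rows <- function(scores, truth, iteration, condition) {
  rows <- list()
  for (m in names(scores)) {
    sc <- scores[[m]]
    if (sc$directed) {
      det <- pr_matrix(sc$band_matrix, truth, directed = TRUE,
                       task = "detection")$pr
      dirn <- pr_matrix(sc$band_matrix, truth, directed = TRUE,
                        task = "direction")$pr
      rows <- c(rows, list(
        data.frame(iteration = iteration, condition = condition,
                   metric = m, task = "detection", pr = det),
        data.frame(iteration = iteration, condition = condition,
                   metric = m, task = "direction", pr = dirn)))
    } else {
      rows <- c(rows, list(
        data.frame(iteration = iteration, condition = condition,
                   metric = m, task = "detection",
                   pr = pr_matrix(sc$band_matrix, truth)$pr)))
    }
  }
  rows
}

#' Run a benchmark experiment
#'
#' Per iteration: simulate a recording, project to source space, aggregate
#' regions, score connectivity, and evaluate the percentile rank against
#' the ground truth -- once per condition level. Within an iteration all
#' condition levels share the same master seed, so levels that only differ
#' in the tested condition reuse identical signal/noise realizations.
#'
#' @param spec an `fc_experiment_spec`.
#' @param model the `fc_leadfield` head model.
#' @param cv_n_candidates cross-validation grid size for regularized
#'   inverse solutions.
#' @param n_shuffles surrogate count (experiment 1C only).
#' @param verbose print per-iteration progress.
#' @return `fc_result_table`: `rows` (iteration, condition, metric, task,
#'   pr) plus the spec.
#' @export
run_experiment <- function(spec, model, cv_n_candidates = 15,
                           n_shuffles = 1000, verbose = FALSE) {
  stopifnot(inherits(spec, "fc_experiment_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_iterations)

  all_rows <- list()
  for (it in seq_len(spec$n_iterations)) {
    base_args <- c(list(seed = iter_seeds[it]), spec$sim,
                   spec$sim_overrides)
    rows <- switch(spec$axis,
      metric = {  # one simulation + one pipeline run scoring all metrics
        rec <- .simulate_for(base_args, spec, model)
        scores <- run_pipeline(rec, model, inverse = "lcmv",
                               scheme = "fixpc3", metrics = spec$levels)
        .score_rows(scores, rec$ground_truth$truth_regions, it, "default")
      },
      scheme = {
        rec <- .simulate_for(base_args, spec, model)
        unlist(lapply(seq_along(spec$levels), function(li) {
          scores <- run_pipeline(rec, model, inverse = "lcmv",
                                 scheme = spec$levels[li],
                                 metrics = intersect(spec$metrics,
                                   if (spec$levels[li] == "fcmean")
                                     c("mim", "mic") else .metric_names))
          .score_rows(scores, rec$ground_truth$truth_regions, it,
                      spec$level_names[li])
        }), recursive = FALSE)
      },
      inverse = {
        rec <- .simulate_for(base_args, spec, model)
        unlist(lapply(seq_along(spec$levels), function(li) {
          scores <- run_pipeline(rec, model, inverse = spec$levels[li],
                                 scheme = "fixpc3",
                                 metrics = spec$metrics,
                                 cv_n_candidates = cv_n_candidates)
          .score_rows(scores, rec$ground_truth$truth_regions, it,
                      spec$level_names[li])
        }), recursive = FALSE)
      },
      surrogate = {
        rec <- .simulate_for(base_args, spec, model)
        .surrogate_rows(rec, model, it, n_shuffles)
      },
      {  # simulation-level axis (theta_snr, theta_bsr, n_interactions,
         # delay_ms): same substreams, only the tested parameter varies
        unlist(lapply(seq_along(spec$levels), function(li) {
          args <- base_args
          args[[spec$axis]] <- spec$levels[li]
          rec <- .simulate_for(args, spec, model)
          scores <- run_pipeline(rec, model, inverse = "lcmv",
                                 scheme = "fixpc3", metrics = spec$metrics)
          .score_rows(scores, rec$ground_truth$truth_regions, it,
                      spec$level_names[li])
        }), recursive = FALSE)
      })
    all_rows <- c(all_rows, rows)
    if (verbose) {
      message(sprintf("experiment %s iteration %d/%d done", spec$id, it,
                      spec$n_iterations))
    }
  }
  structure(list(rows = do.call(rbind, all_rows), spec = spec),
            class = "fc_result_table")
}

## Experiment 1C: MIM scores plus surrogate significance of the
## ground-truth pair (PR of the truth pair and its surrogate p-value).
.surrogate_rows <- function(rec, model, it, n_shuffles) {
  scores <- run_pipeline(rec, model, inverse = "lcmv", scheme = "fixpc3",
                         metrics = "mim")
  truth <- rec$ground_truth$truth_regions
  pr <- pr_matrix(scores$mim$band_matrix, truth)$pr
  ## surrogate test on the ground-truth region pair
  Q <- rec$continuous / sqrt(mean(rec$continuous^2))
  filt <- fit_lcmv(sensor_covariance(Q), model)
  est <- structure(list(time_courses = crossprod(filt$weights, Q)),
                   class = "fc_source_estimate")
  comps <- reduce_regions(est, model$space, "fixpc3")
  xr <- comps$components[[truth$seed_region[1]]]
  yr <- comps$components[[truth$target_region[1]]]
  xe <- epoch_data(t(xr), rec$config$epoch_len)
  ye <- epoch_data(t(yr), rec$config$epoch_len)
  p <- surrogate_mim_test(xe, ye, n_shuffles = n_shuffles,
                          fs = rec$config$fs)$p
  list(data.frame(iteration = it, condition = "fixpc3", metric = "mim",
                  task = "detection", pr = pr),
       data.frame(iteration = it, condition = "fixpc3", metric = "mim",
                  task = "surrogate_p", pr = p))
}

#' Summarize an experiment result table
#'
#' Mean, median and 2.5th/97.5th percentiles of the PR per condition,
#' metric and task.
#'
#' @param table an `fc_result_table` (or its `rows` data.frame).
#' @return data.frame of summary records.
#' @export
summarize_results <- function(table) {
  rows <- if (inherits(table, "fc_result_table")) table$rows else table
  stopifnot(nrow(rows) > 0)
  key <- interaction(rows$condition, rows$metric, rows$task, drop = TRUE)
  out <- do.call(rbind, lapply(split(rows, key), function(d) {
    data.frame(condition = d$condition[1], metric = d$metric[1],
               task = d$task[1], n = nrow(d), mean = mean(d$pr),
               median = median(d$pr),
               p2.5 = unname(quantile(d$pr, 0.025)),
               p97.5 = unname(quantile(d$pr, 0.975)))
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$task, out$condition), ]
}

#' @export
print.fc_result_table <- function(x, ...) {
  cat("<fc_result_table> experiment ", x$spec$id, ", ",
      x$spec$n_iterations, " iteration(s)\n", sep = "")
  s <- summarize_results(x)
  s$mean <- round(s$mean, 2); s$median <- round(s$median, 2)
  s$p2.5 <- round(s$p2.5, 2); s$p97.5 <- round(s$p97.5, 2)
  print(s, row.names = FALSE)
  invisible(x)
}
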