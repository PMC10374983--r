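#' Run the scaled-down benchmark reproduction suite
#'
#' Executes the package's reference reproduction runs on a 500-source /
#' 68-region spherical head model with 30 Monte-Carlo iterations per
#' experiment: the chance-level calibration of the percentile rank on
#' random scores, the FC-metric comparison (LCMV + FIXPC3), the
#' inverse-solution comparisons (eLORETA with spatial cross-validation,
#' DICS), the five-interaction condition, the short-delay conditions (2 ms
#' and 10 ms) and the two-sources-per-region condition. All randomness
#' derives from the single `seed`.
#'
#' @param seed master seed for the whole suite.
#' @param n_iterations Monte-Carlo iterations per experiment.
#' @param n_sources,n_regions,n_sensors head-model size.
#' @param cv_n_candidates spatial-CV grid size for eLORETA.
#' @param n_null_draws random score vectors for the chance calibration.
#' @param exp6_schemes aggregation schemes run in the two-sources
#'   condition.
#' @param include subset of run names to execute (default: all).
#' @param verbose print progress.
#' @return list with `values` (named scalar summaries) and `tables`
#'   (the underlying `fc_result_table` objects).
#' @export
benchmark_targets <- function(seed = 0, n_iterations = 30,
                              n_sources = 500, n_regions = 68,
                              n_sensors = 97, cv_n_candidates = 5,
                              n_null_draws = 10000,
                              exp6_schemes = c("fixpc1", "fixpc3", "fixpc4"),
                              include = c("pr_null", "1A", "2A_eloreta",
                                          "2A_dics", "4", "5_2ms", "5_10ms",
                                          "6"),
                              verbose = FALSE) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  seeds <- sample.int(2^31 - 2, 16)
  say <- function(...) if (verbose) message(...)

  values <- list(); tables <- list()
  model <- NULL
  get_model <- function() {
    if (is.null(model)) {
      say("building head model (", n_sources, " sources, ", n_regions,
          " regions)")
      model <<- build_head_model(n_sources, n_regions, seed = seeds[1],
                                 n_sensors = n_sensors)
    }
    model
  }
  mean_pr <- function(tab, metric, task = "detection") {
    rows <- tab$rows
    mean(rows$pr[rows$metric == metric & rows$task == task])
  }

  if ("pr_null" %in% include) {
    say("chance-level PR calibration")
    set.seed(seeds[2])
    F_ <- n_regions * (n_regions - 1) / 2
    acc <- 0
    for (d in seq_len(n_null_draws)) {
      sc <- runif(F_)
      for (ni in 1:5) {
        acc <- acc + percentile_rank(sc, sample.int(F_, ni))$pr
      }
    }
    values$random_pr_mean <- acc / (n_null_draws * 5)
  }

  if ("1A" %in% include) {
    say("experiment 1A (FC metrics)")
    spec <- experiment_spec("1A", n_iterations, seed = seeds[3])
    tables$exp1a <- run_experiment(spec, get_model())
    values$exp1a_coh <- mean_pr(tables$exp1a, "coh")
    values$exp1a_icoh <- mean_pr(tables$exp1a, "icoh")
    values$exp1a_mim <- mean_pr(tables$exp1a, "mim")
    values$exp1a_mic <- mean_pr(tables$exp1a, "mic")
    values$exp1a_gc_detection <- mean_pr(tables$exp1a, "gc")
    values$exp1a_trgc_detection <- mean_pr(tables$exp1a, "trgc")
    values$exp1a_gc_direction <- mean_pr(tables$exp1a, "gc", "direction")
    values$exp1a_trgc_direction <- mean_pr(tables$exp1a, "trgc", "direction")
  }

  if ("2A_eloreta" %in% include) {
    say("experiment 2A (eLORETA)")
    spec <- experiment_spec("2A", n_iterations, seed = seeds[4],
                            levels = "eloreta", metrics = "mim")
    tables$exp2a_eloreta <- run_experiment(spec, get_model(),
                                           cv_n_candidates = cv_n_candidates)
    values$exp2a_eloreta_mim <- mean_pr(tables$exp2a_eloreta, "mim")
  }

  if ("2A_dics" %in% include) {
    say("experiment 2A (DICS)")
    spec <- experiment_spec("2A", n_iterations, seed = seeds[5],
                            levels = "dics", metrics = "trgc")
    tables$exp2a_dics <- run_experiment(spec, get_model())
    values$exp2a_dics_trgc_direction <-
      mean_pr(tables$exp2a_dics, "trgc", "direction")
  }

  if ("4" %in% include) {
    say("experiment 4 (five interactions)")
    spec <- experiment_spec("4", n_iterations, seed = seeds[6], levels = 5,
                            metrics = "mim")
    tables$exp4 <- run_experiment(spec, get_model())
    values$exp4_ni5_mim <- mean_pr(tables$exp4, "mim")
  }

  if ("5_2ms" %in% include) {
    say("experiment 5 (2 ms delay)")
    spec <- experiment_spec("5", n_iterations, seed = seeds[7], levels = 2,
                            metrics = "mim")
    tables$exp5_2ms <- run_experiment(spec, get_model())
    values$exp5_2ms_mim <- mean_pr(tables$exp5_2ms, "mim")
  }

  if ("5_10ms" %in% include) {
    say("experiment 5 (10 ms delay)")
    spec <- experiment_spec("5", n_iterations, seed = seeds[8], levels = 10,
                            metrics = "trgc")
    tables$exp5_10ms <- run_experiment(spec, get_model())
    values$exp5_10ms_trgc_direction <-
      mean_pr(tables$exp5_10ms, "trgc", "direction")
  }

  if ("6" %in% include) {
    say("experiment 6 (two sources per region)")
    spec <- experiment_spec("6", n_iterations, seed = seeds[9],
                            levels = exp6_schemes, metrics = "mim")
    tables$exp6 <- run_experiment(spec, get_model())
    for (sch in exp6_schemes) {
      rows <- tables$exp6$rows
      values[[paste0("exp6_", sch, "_mim")]] <-
        mean(rows$pr[rows$condition == sch & rows$metric == "mim"])
    }
  }

  list(values = values, tables = tables, n_iterations = n_iterations,
       seed = seed)
}
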