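#' Configuration for end-to-end experiments
#'
#' Collects the module, teaching, schedule and stimulus parameters for a
#' train-then-test experiment. Defaults are the desk-scale study
#' configuration (`N = 600`, `S = 200`, `C = 300` with separators on); the
#' full-size configuration of the original study is `N = 1200`, `S = 300`,
#' `C = 2200` with 60 repeats per condition.
#'
#' @param N,S,p,tau,g,k,alpha,O shared module hyperparameters; see
#'   [model_params()].
#' @param C number of training epochs (chunks plus random separators).
#' @param C_test number of held-out evaluation epochs, generated from the
#'   same schedule distribution with fresh draws (default `C / 4`).
#' @param use_separators alternate chunk epochs with random sequences.
#' @param teaching [teaching_params()].
#' @param stim [stim_params()].
#' @param threshold no-response threshold for evaluation.
#' @param warmup_ms training warm-up (no weight updates) while the
#'   normalization window fills.
#' @return An object of class `rc_experiment_config`.
#' @export
experiment_config <- function(N = 600, S = 200, p = 0.5, tau = 5, g = 1.0,
                              k = 0.2, alpha = 100, O = 3, C = 300,
                              C_test = NULL, use_separators = TRUE,
                              teaching = teaching_params(),
                              stim = stim_params(), threshold = 0.3,
                              warmup_ms = teaching$T_ms) {
  if (is.null(C_test)) C_test <- max(4L, C %/% 4L)
  structure(list(
    params1 = model_params(N = N, S = S, p = p, tau = tau, g = g, k = k,
                           alpha = alpha, I = length(stim$alphabet), O = O,
                           dt = stim$dt),
    params2 = model_params(N = N, S = S, p = p, tau = tau, g = g, k = k,
                           alpha = alpha, I = 3L * stim$sections, O = O,
                           dt = stim$dt),
    C = as.integer(C), C_test = as.integer(C_test),
    use_separators = isTRUE(use_separators),
    teaching = teaching, stim = stim, threshold = threshold,
    warmup_ms = warmup_ms
  ), class = "rc_experiment_config")
}

cfg_schedule <- function(config, C, m = 0, d = 0, delayed_modality = 2) {
  schedule_params(C = C, use_separators = config$use_separators, m = m,
                  d = d, delayed_modality = delayed_modality)
}

#' Train-then-test learning experiment
#'
#' Generates a training track, trains a model of the requested architecture,
#' generates a held-out track from the same schedule distribution, runs
#' forward inference and scores it. All randomness flows from `seed`.
#'
#' @param config [experiment_config()].
#' @param seed integer seed determining every random draw of the experiment.
#' @param variant architecture, see [build_model()].
#' @param m_train,d_train manipulations applied to the training track.
#' @param m_test,d_test manipulations applied to the evaluation track.
#' @param record_reservoir record reservoir rate histories during the
#'   evaluation run (needed for trajectory analysis).
#' @return List of class `rc_experiment`: `eval` (an `rc_eval`), `model`,
#'   `run`, `test_track`, `seed`, `variant`.
#' @export
run_learning_experiment <- function(config = experiment_config(), seed = 1,
                                    variant = "original",
                                    m_train = 0, d_train = 0,
                                    m_test = 0, d_test = 0,
                                    record_reservoir = FALSE) {
  stopifnot(inherits(config, "rc_experiment_config"))
  set.seed(seed)
  chunks <- default_chunks(config$stim)
  train_track <- generate_track(
    cfg_schedule(config, config$C, m = m_train, d = d_train),
    chunks, config$stim)
  model <- build_model(variant, config$params1, config$params2,
                       config$teaching)
  model <- train(model, train_track, warmup_ms = config$warmup_ms)
  test_track <- generate_track(
    cfg_schedule(config, config$C_test, m = m_test, d = d_test),
    chunks, config$stim)
  run <- run_inference(model, test_track,
                       record_reservoir = record_reservoir)
  ev <- evaluate_run(run, threshold = config$threshold)
  structure(list(eval = ev, model = model, run = run,
                 test_track = test_track, seed = seed, variant = variant),
            class = "rc_experiment")
}

#' @export
print.rc_experiment <- function(x, ...) {
  cat("<rc_experiment> variant =", x$variant, " seed =", x$seed, "\n")
  print(x$eval)
  invisible(x)
}

sweep_rows <- function(...) data.frame(..., stringsAsFactors = FALSE)

#' Accuracy versus pair-replacement probability m
#'
#' Two protocols: `"train"` trains on a track manipulated at probability
#' `m` and evaluates on a clean track; `"test"` trains once per seed on a
#' clean track and evaluates on tracks manipulated at each `m`.
#'
#' @param config [experiment_config()].
#' @param m_grid replacement probabilities to test.
#' @param seeds one experiment per seed and grid cell.
#' @param protocols subset of `c("train", "test")`.
#' @return Data frame with one row per (protocol, m, seed): columns
#'   `protocol`, `m`, `seed`, `accuracy`, `accuracy_rc1`, `accuracy_rc2`.
#' @export
run_cooccurrence_sweep <- function(config = experiment_config(),
                                   m_grid = seq(0, 1, by = 0.1),
                                   seeds = 1:5,
                                   protocols = c("train", "test")) {
  stopifnot(all(m_grid >= 0 & m_grid <= 1))
  out <- list()
  if ("train" %in% protocols) {
    for (m in m_grid) for (s in seeds) {
      ex <- run_learning_experiment(config, seed = s, m_train = m)
      out[[length(out) + 1]] <- sweep_rows(
        protocol = "train", m = m, seed = s, accuracy = ex$eval$accuracy,
        accuracy_rc1 = ex$eval$accuracy_rc1,
        accuracy_rc2 = ex$eval$accuracy_rc2)
    }
  }
  if ("test" %in% protocols) {
    for (s in seeds) {
      set.seed(s)
      chunks <- default_chunks(config$stim)
      track <- generate_track(cfg_schedule(config, config$C), chunks,
                              config$stim)
      model <- build_model("original", config$params1, config$params2,
                           config$teaching)
      model <- train(model, track, warmup_ms = config$warmup_ms)
      for (m in m_grid) {
        test_track <- generate_track(
          cfg_schedule(config, config$C_test, m = m), chunks, config$stim)
        ev <- evaluate_run(run_inference(model, test_track),
                           threshold = config$threshold)
        out[[length(out) + 1]] <- sweep_rows(
          protocol = "test", m = m, seed = s, accuracy = ev$accuracy,
          accuracy_rc1 = ev$accuracy_rc1, accuracy_rc2 = ev$accuracy_rc2)
      }
    }
  }
  do.call(rbind, out)
}

#' Accuracy versus inter-modal delay d
#'
#' As [run_cooccurrence_sweep()], but the manipulation is a delay of `d` ms
#' applied to one modality's stream.
#'
#' @param config [experiment_config()].
#' @param d_grid delays in ms.
#' @param seeds one experiment per seed and grid cell.
#' @param protocols subset of `c("train", "test")`.
#' @param delayed_modality which channel is delayed (default 2, image).
#' @return Data frame with one row per (protocol, d, seed).
#' @export
run_delay_sweep <- function(config = experiment_config(),
                            d_grid = seq(0, 250, by = 25), seeds = 1:5,
                            protocols = c("train", "test"),
                            delayed_modality = 2) {
  stopifnot(all(d_grid >= 0))
  out <- list()
  if ("train" %in% protocols) {
    for (d in d_grid) for (s in seeds) {
      ex <- run_learning_experiment(config, seed = s, d_train = d)
      out[[length(out) + 1]] <- sweep_rows(
        protocol = "train", d = d, seed = s, accuracy = ex$eval$accuracy,
        accuracy_rc1 = ex$eval$accuracy_rc1,
        accuracy_rc2 = ex$eval$accuracy_rc2)
    }
  }
  if ("test" %in% protocols) {
    for (s in seeds) {
      set.seed(s)
      chunks <- default_chunks(config$stim)
      track <- generate_track(cfg_schedule(config, config$C), chunks,
                              config$stim)
      model <- build_model("original", config$params1, config$params2,
                           config$teaching)
      model <- train(model, track, warmup_ms = config$warmup_ms)
      for (d in d_grid) {
        test_track <- generate_track(
          cfg_schedule(config, config$C_test, d = d,
                       delayed_modality = delayed_modality),
          chunks, config$stim)
        ev <- evaluate_run(run_inference(model, test_track),
                           threshold = config$threshold)
        out[[length(out) + 1]] <- sweep_rows(
          protocol = "test", d = d, seed = s, accuracy = ev$accuracy,
          accuracy_rc1 = ev$accuracy_rc1, accuracy_rc2 = ev$accuracy_rc2)
      }
    }
  }
  do.call(rbind, out)
}

#' Compare the original and alternative interaction architectures
#'
#' Runs the train-then-test experiment for every requested architecture and
#' seed. Association-level accuracy uses the integrated output for the
#' original model and the Hebbian association layer for a1-a3;
#' module-level accuracies score each module's own readouts.
#'
#' @param config [experiment_config()].
#' @param variants architectures to compare.
#' @param seeds one experiment per seed and architecture.
#' @return Data frame with one row per (variant, seed).
#' @export
run_variant_comparison <- function(config = experiment_config(),
                                   variants = c("original", "a1", "a2",
                                                "a3"),
                                   seeds = 1:10) {
  out <- list()
  for (v in variants) for (s in seeds) {
    ex <- run_learning_experiment(config, seed = s, variant = v)
    out[[length(out) + 1]] <- sweep_rows(
      variant = v, seed = s, accuracy = ex$eval$accuracy,
      accuracy_rc1 = ex$eval$accuracy_rc1,
      accuracy_rc2 = ex$eval$accuracy_rc2)
  }
  do.call(rbind, out)
}

#' Accuracy over a grid of model hyperparameters
#'
#' Runs the learning experiment for every row of `grid`, overriding the
#' matching fields of `config` (recognized columns: `tau`, `g`, `N`, `S`,
#' `p`, `k`, `C`).
#'
#' @param config [experiment_config()] providing the baseline values.
#' @param grid data frame of parameter combinations.
#' @param seeds one experiment per seed and grid row.
#' @return Data frame: the grid row, `seed` and accuracies per experiment.
#' @export
run_parameter_sweep <- function(config = experiment_config(), grid,
                                seeds = 1:3) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  known <- c("tau", "g", "N", "S", "p", "k", "C")
  bad <- setdiff(names(grid), known)
  if (length(bad) > 0)
    stop("unrecognized sweep parameters: ", paste(bad, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    args <- list(C = config$C, use_separators = config$use_separators,
                 teaching = config$teaching, stim = config$stim,
                 threshold = config$threshold,
                 warmup_ms = config$warmup_ms)
    for (f in c("N", "S", "p", "tau", "g", "k", "alpha", "O"))
      args[[f]] <- config$params1[[f]]
    for (f in intersect(names(grid), known)) args[[f]] <- grid[[f]][i]
    cfg <- do.call(experiment_config, args)
    for (s in seeds) {
      ex <- run_learning_experiment(cfg, seed = s)
      out[[length(out) + 1]] <- cbind(
        grid[i, , drop = FALSE],
        sweep_rows(seed = s, accuracy = ex$eval$accuracy,
                   accuracy_rc1 = ex$eval$accuracy_rc1,
                   accuracy_rc2 = ex$eval$accuracy_rc2))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
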