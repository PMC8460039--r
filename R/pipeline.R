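# End-to-end orchestration: configuration, seeded runs, report bundle.

#' Default pipeline configuration
#'
#' Central defaults for a seeded end-to-end run: filterbank geometry,
#' canonical bands, classifier grid, onset window and the statistical
#' thresholds (alpha = 0.05, q = 0.05, Rayleigh Z display threshold = 5,
#' 20000 permutations, 5000 channel-adding repetitions).  Values scaled
#' for a desk-top run can be overridden per call.
#'
#' @param seed master seed; every stochastic stage derives a child seed
#'   from it.
#' @param ... overrides of any default field.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, ...) {
  cfg <- list(seed = seed,
              n_bouts = 30,
              n_channels = 16,
              fs = 1000,
              n_bands = 100, f_range = c(2, 200),
              bands = canonical_bands()[1:5, ],
              bin_ms = 100, offset_ms = 10,
              folds = 5,
              onset_window_ms = 100,
              alpha = 0.05, q = 0.05, z_threshold = 5,
              n_perm = 20000, channel_reps = 5000,
              itpc_channels = 1)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$q <= 0 || cfg$q >= 1) stop("q must be in (0, 1)")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> preprocess -> phase locking -> decode -> onset
#' prediction, on the default synthetic dataset; returns a report bundle
#' whose numeric tables name their statistics, n, p and q columns.
#' Deterministic stages are bitwise reproducible for a fixed config.
#'
#' @param config a [run_config()].
#' @param stages character subset of
#'   `c("simulate", "preprocess", "phaselock", "decode", "onset")`.
#' @return named list of stage outputs (a `report bundle`).
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "preprocess", "phaselock",
                                    "decode", "onset")) {
  out <- list(config = config)
  grammar <- song_grammar()
  classes <- c(grammar$motif, grammar$connector_label, grammar$intro_label)
  if ("simulate" %in% stages) {
    out$annotations <- sample_behavior(grammar, config$n_bouts,
                                       config$seed, config$fs)
    model <- lfp_model(classes, channel_count = config$n_channels,
                       fs = config$fs, seed = config$seed)
    out$model <- model
    out$recording <- synthesize_lfp(out$annotations, model)
  }
  if ("preprocess" %in% stages) {
    if (is.null(out$recording)) stop("run the simulate stage first")
    out$referenced <- common_average_reference(out$recording)
  }
  if ("phaselock" %in% stages) {
    if (is.null(out$referenced)) stop("run the preprocess stage first")
    ev <- vocal_events(out$annotations)
    bouts <- ev[!is.na(ev$first_motif) & ev$first_motif &
                  ev$first_in_motif, ]
    res <- itpc_events(out$referenced, bouts$onset,
                       window = c(0.2, 0.1),
                       channel = config$itpc_channels[1])
    out$itpc <- res
    out$sustained_z <- sustained_z(res$Z, res$bands, config$fs,
                                   onset_col = which.min(abs(res$time)))
  }
  if ("decode" %in% stages) {
    if (is.null(out$referenced)) stop("run the preprocess stage first")
    ann <- contextualize(out$annotations, grammar$motif)
    sets <- select_and_balance(ann, c(grammar$motif, "silence"),
                               seed = config$seed)
    out$decode <- ablate(out$referenced, sets,
                         band = unlist(config$bands[5, c("low", "high")]),
                         bin_ms = config$bin_ms,
                         offset_ms = config$offset_ms,
                         folds = config$folds, seed = config$seed)
  }
  if ("onset" %in% stages) {
    if (is.null(out$referenced)) stop("run the preprocess stage first")
    ann <- contextualize(out$annotations, grammar$motif)
    sets <- select_and_balance(ann, grammar$motif[-1], seed = config$seed)
    sigs <- lapply(seq_len(nrow(config$bands)), function(i)
      feature_signals(out$referenced,
                      unlist(config$bands[i, c("low", "high")]), "raw"))
    tab <- list()
    for (syl in grammar$motif[-1]) {
      es <- sets[[syl]]
      cv <- onset_prediction_cv(sigs, es$times, es$anchors,
                                config$bin_ms, config$offset_ms,
                                config$fs, config$folds, config$seed,
                                config$onset_window_ms)
      pt <- prediction_tests(cv$neural_err, cv$baseline_err)
      tab[[syl]] <- data.frame(syllable = syl, n = pt$n,
                               median_neural_ms = pt$median_neural,
                               median_baseline_ms = pt$median_baseline,
                               p_different = pt$p_different,
                               p_closer = pt$p_closer)
    }
    out$onset <- evaluate_predictions(do.call(rbind, tab), config$q)
  }
  out
}
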