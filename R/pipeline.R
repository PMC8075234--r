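#' Segment, label and featurize one recording
#'
#' Convenience composition of [detect_foot_strikes()],
#' [detect_turn_intervals()], [label_steps()] and [build_feature_sets()].
#'
#' @param recording an [imu_recording()].
#' @param seg_params a [segmentation_params()].
#' @param steps optional precomputed [step_sequence()] (e.g. ground truth
#'   or manually corrected); when given, strike detection is skipped.
#' @return list with `steps` (labeled), `turns`, and `features` (the
#'   [build_feature_sets()] output).
#' @export
process_recording <- function(recording, seg_params = segmentation_params(),
                              steps = NULL) {
  if (is.null(steps)) steps <- detect_foot_strikes(recording, seg_params)
  turns <- detect_turn_intervals(recording, seg_params)
  steps <- label_steps(steps, turns)
  feats <- build_feature_sets(recording, steps)
  list(steps = steps, turns = turns, features = feats)
}

#' Build the four cohort feature tables from a synthetic cohort
#'
#' Streams through a [cohort_plan()]: each participant is simulated,
#' segmented (or taken from ground truth), featurized and discarded, so
#' memory stays flat.  Participants for whom a feature set is unavailable
#' (no turn steps) are dropped from that set's table.
#'
#' @inheritParams cohort_plan
#' @param seg_params a [segmentation_params()].
#' @param use_ground_truth use the generator's ground-truth strikes and
#'   turn labels instead of running the detector (default `FALSE`).
#' @return named list of `feature_table`s: `AS`, `S`, `T`, `S&T`.
#' @export
build_cohort_tables <- function(n = 89, n_fall_risk = 32,
                                params = gait_model_params(),
                                effects = class_effects(), seed = 1,
                                seg_params = segmentation_params(),
                                use_ground_truth = FALSE) {
  plan <- cohort_plan(n, n_fall_risk, params, effects, seed)
  vecs <- list(AS = list(), S = list(), T = list(), `S&T` = list())
  for (i in seq_len(n)) {
    sim <- simulate_participant(plan$params[[i]], plan$effects,
                                label = plan$labels[[i]],
                                seed = plan$seeds[[i]],
                                participant_id = plan$ids[[i]])
    steps <- NULL
    if (use_ground_truth)
      steps <- step_sequence(sim$truth$strikes,
                             participant_id = plan$ids[[i]])
    out <- process_recording(sim$recording, seg_params, steps = steps)
    f <- out$features
    id <- plan$ids[[i]]
    if (!is.null(f$AS)) vecs$AS[[id]] <- f$AS
    if (!is.null(f$S)) vecs$S[[id]] <- f$S
    if (!is.null(f$T)) vecs$T[[id]] <- f$T
    if (!is.null(f$ST)) vecs$`S&T`[[id]] <- f$ST
  }
  tabs <- lapply(names(vecs), function(set_id)
    feature_table(vecs[[set_id]], plan$labels, set_id = set_id))
  names(tabs) <- names(vecs)
  tabs
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate (or load) -> segment -> extract -> select ->
#' evaluate, writing feature tables, ranked configurations, the top-5
#' tree sweeps and seed-robustness summaries, plus a run manifest, to
#' `out_dir`.  The pipeline is a pure function of (inputs, config, seed).
#'
#' @param config list (or path to a JSON/YAML-free JSON file) with
#'   optional blocks `cohort` (`n`, `n_fall_risk`, `effect_scale`,
#'   `use_ground_truth`), `recordings` (character paths plus a `labels`
#'   CSV with `participant_id,fall_risk`), `modeling` (`n_trees`, `ks`,
#'   `tree_counts`, `robustness_seeds`), and `seed`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `tables`, `grid`, `top`, `sweeps`,
#'   `robustness`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("gaitfall_run")) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$recordings)) {
    if (is.null(config$labels))
      stop("stage io: config$labels (participant_id,fall_risk CSV) required")
    lab_df <- read.csv(config$labels)
    labels <- stats::setNames(as.logical(lab_df$fall_risk),
                              as.character(lab_df$participant_id))
    vecs <- list(AS = list(), S = list(), T = list(), `S&T` = list())
    for (path in unlist(config$recordings)) {
      rec <- read_recording(path)
      out <- tryCatch(process_recording(rec),
                      error = function(e) stop("stage segment/extract, participant ",
                                               rec$participant_id, ": ",
                                               conditionMessage(e)))
      id <- rec$participant_id
      f <- out$features
      if (!is.null(f$AS)) vecs$AS[[id]] <- f$AS
      if (!is.null(f$S)) vecs$S[[id]] <- f$S
      if (!is.null(f$T)) vecs$T[[id]] <- f$T
      if (!is.null(f$ST)) vecs$`S&T`[[id]] <- f$ST
    }
    tables <- lapply(names(vecs), function(s)
      feature_table(vecs[[s]], labels, set_id = s))
    names(tables) <- names(vecs)
  } else {
    ch <- config$cohort
    effects <- class_effects(effect_scale =
                               if (is.null(ch$effect_scale)) 1 else ch$effect_scale)
    tables <- build_cohort_tables(
      n = if (is.null(ch$n)) 89 else ch$n,
      n_fall_risk = if (is.null(ch$n_fall_risk)) 32 else ch$n_fall_risk,
      effects = effects, seed = seed,
      use_ground_truth = isTRUE(ch$use_ground_truth))
  }
  for (s in names(tables))
    write_feature_table(tables[[s]],
                        file.path(out_dir, paste0("features_",
                                                  gsub("&", "and", s), ".csv")))

  md <- config$modeling
  n_trees <- if (is.null(md$n_trees)) 100 else md$n_trees
  ks <- if (is.null(md$ks)) c(30, 20, 10, 5) else unlist(md$ks)
  tree_counts <- if (is.null(md$tree_counts))
    c(5, 10, 25, 50, 75, 100, 150, 200, 250, 300, 400, 500, 1000) else
      unlist(md$tree_counts)
  rob_seeds <- if (is.null(md$robustness_seeds)) seq_len(10) else
    unlist(md$robustness_seeds)

  grid <- evaluate_grid(tables, ks = ks, n_trees = n_trees, seed = seed)
  top <- summed_rank_selection(grid, top_n = 5)
  subsets <- attr(grid, "subsets")
  sweeps <- list(); robustness <- list()
  for (i in seq_len(nrow(top))) {
    cfg <- top$config[i]
    sub <- subsets[[cfg]]
    tab <- tables[[top$set_id[i]]]
    sw <- tree_sweep(tab, if (sub$selector == "none") NULL else sub,
                     tree_counts = tree_counts, seed = seed)
    rb <- seed_robustness(tab, if (sub$selector == "none") NULL else sub,
                          n_trees = sw$best_n_trees, seeds = rob_seeds)
    sweeps[[cfg]] <- sw
    robustness[[cfg]] <- rb
  }
  report <- list(
    grid = as.data.frame(grid),
    ranked = as.data.frame(attr(top, "full")),
    top5 = as.data.frame(top),
    subsets = lapply(subsets, unclass),
    sweeps = lapply(sweeps, function(s)
      list(best_n_trees = s$best_n_trees, per_count = s$per_count)),
    robustness = lapply(robustness, function(r)
      list(summary = r$summary, per_seed = r$per_seed)))
  write_model_report(report, file.path(out_dir, "model_report.json"))
  manifest <- list(seed = seed, config = config,
                   package_version = as.character(utils::packageVersion("gaitfall")),
                   r_version = R.version.string,
                   n_trees = n_trees, ks = ks, tree_counts = tree_counts,
                   robustness_seeds = rob_seeds,
                   rf_defaults = list(mtry = "floor(sqrt(p))",
                                      sampling = "bootstrap, with replacement",
                                      nodesize = 1))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tables = tables, grid = grid, top = top, sweeps = sweeps,
                 robustness = robustness, out_dir = out_dir))
}
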