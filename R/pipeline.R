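#' Run configuration for the end-to-end pipeline
#'
#' Assembles every knob of a run — synthetic-data settings (or input
#' paths), DTW parameters, analysis parameters and seeds — into one
#' round-trippable object. All randomness in a run flows from the seeds
#' recorded here, so the saved configuration reproduces the run exactly.
#'
#' @param synth A [synth_config()] (synthetic run), or `NULL` with `input_dir`
#'   pointing at on-disk data in the layout of [write_synth_dataset()].
#' @param input_dir Optional directory of ingested data.
#' @param dtw A [dtw_params()].
#' @param alpha Significance level for the co-structuring grids.
#' @param seed Analysis seed (subsampling, splits, fits).
#' @param sets Performer sets; `NULL` = all + each performer.
#' @param regression_targets,regression_feature_sets Scope of the
#'   regression stage; `NULL` skips it.
#' @param regression_grid Hyperparameter grid for the regression stage
#'   (default [regression_grid()], the canonical 48 configurations).
#' @param embed_feature Distance column for the 2D embedding export;
#'   `NULL` skips it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), input_dir = NULL,
                       dtw = dtw_params(), alpha = 1e-4, seed = 1L,
                       sets = NULL,
                       regression_targets = sonic_feature_names(),
                       regression_feature_sets = c("hand", "head", "all", "randomized"),
                       regression_grid = costruct::regression_grid(),
                       embed_feature = "f0") {
  if (is.null(synth) && is.null(input_dir))
    stopf("run_config: provide either a synth config or an input_dir")
  structure(list(synth = synth, input_dir = input_dir, dtw = dtw,
                 alpha = alpha, seed = as.integer(seed), sets = sets,
                 regression_targets = regression_targets,
                 regression_feature_sets = regression_feature_sets,
                 regression_grid = regression_grid,
                 embed_feature = embed_feature),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [run_config()] (with `synth` and `dtw` as nested maps).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- if (!is.null(y$synth)) do.call(synth_config, y$synth)
           else if (is.null(y$input_dir)) synth_config() else NULL
  dtw <- if (!is.null(y$dtw)) do.call(dtw_params, y$dtw) else dtw_params()
  run_config(synth = synth, input_dir = y$input_dir, dtw = dtw,
             alpha = y$alpha %||% 1e-4, seed = y$seed %||% 1L,
             sets = y$sets,
             regression_targets = y$regression_targets %||% sonic_feature_names(),
             regression_feature_sets = y$regression_feature_sets %||%
               c("hand", "head", "all", "randomized"),
             regression_grid = if (!is.null(y$regression_grid))
               do.call(regression_grid, y$regression_grid) else regression_grid(),
             embed_feature = if (is.null(y$embed_feature)) "f0" else
               if (identical(y$embed_feature, "none")) NULL else y$embed_feature)
}

load_ingested_dataset <- function(dir, sonic_rate = 100, kinematic_rate = 60) {
  if (!file.exists(file.path(dir, "motifs.csv")))
    stopf("no motif table at %s", file.path(dir, "motifs.csv"))
  mt <- read_motif_table(file.path(dir, "motifs.csv"))
  for (perf in unique(mt$performance_id)) {
    kp <- file.path(dir, sprintf("kinematics_%s.csv", perf))
    if (!file.exists(kp)) stopf("missing kinematics file %s", kp)
  }
  sonic <- list(); kinem <- list()
  for (i in seq_len(nrow(mt))) {
    id <- mt$motif_id[i]
    ser <- lapply(sonic_feature_names(), function(f)
      read_feature_series(file.path(dir, "sonic", sprintf("%s_%s.csv", id, f))))
    rate <- ser[[1L]]$rate; if (is.na(rate)) rate <- sonic_rate
    sonic[[id]] <- sonic_features(f0 = ser[[1]]$series, delta_f0 = ser[[2]]$series,
                                  loudness = pmin(0, ser[[3]]$series),
                                  centroid = ser[[4]]$series, rate = rate)
  }
  for (perf in unique(mt$performance_id)) {
    frames <- read_kinematics(file.path(dir, sprintf("kinematics_%s.csv", perf)),
                              rate = kinematic_rate)
    for (i in which(mt$performance_id == perf)) {
      rec <- mt[i, ]
      segs <- lapply(split(frames, frames$segment), function(sf) {
        keep <- sf$t >= rec$start_s - 1e-9 & sf$t < rec$end_s - 1e-9
        as.matrix(sf[keep, c("px", "py", "pz")])
      })
      kinem[[mt$motif_id[i]]] <- extract_kinematic_features(
        segs[KINEMATIC_SEGMENTS], rate = kinematic_rate)
    }
  }
  list(motif_table = mt, sonic = sonic, kinematic = kinem)
}

#' Run the full pipeline into a run directory
#'
#' Stages: dataset (synthetic generation or ingest), distance table,
#' co-structuring profiles, regression suite, 2D embedding export, and a
#' JSON manifest with the configuration snapshot, seeds and per-stage row
#' counts. Any stage failure aborts with the stage named. A rerun with the
#' same configuration produces byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; files overwritten).
#' @return `out_dir` invisibly, with components accessible from the written
#'   CSV/JSON artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stopf("pipeline stage '%s' failed: %s",
                                       name, conditionMessage(e)))
  }
  manifest <- list(created = "run manifest", seed = config$seed,
                   alpha = config$alpha,
                   dtw = unclass(config$dtw), stages = list())

  dataset <- stage("dataset", {
    if (!is.null(config$synth)) generate_dataset(config$synth)
    else load_ingested_dataset(config$input_dir)
  })
  if (!is.null(config$synth)) manifest$synth <- unclass(config$synth)
  write_motif_table(dataset$motif_table, file.path(out_dir, "motifs.csv"))
  manifest$stages$dataset <- list(n_motifs = nrow(dataset$motif_table))

  table <- stage("dtw", build_distance_table(dataset, config$dtw))
  write_distance_table(table, file.path(out_dir, "distance_table.csv"))
  manifest$stages$dtw <- list(n_pairs = nrow(table))

  profiles <- stage("costructure",
                    costructure(table, sets = config$sets,
                                alpha = config$alpha, seed = config$seed))
  write.csv(profile_summary(profiles), file.path(out_dir, "costructure.csv"),
            row.names = FALSE)
  manifest$stages$costructure <- list(
    n_sets = length(profiles), n_tests = attr(profiles, "n_tests"),
    n_significant = sum(vapply(profiles, function(p) sum(p$significant), 1L)))

  if (!is.null(config$regression_targets)) {
    suite <- stage("regression",
                   run_suite(table, targets = config$regression_targets,
                             feature_sets = config$regression_feature_sets,
                             grid = config$regression_grid,
                             seed = config$seed))
    write.csv(as.data.frame(suite), file.path(out_dir, "regression.csv"),
              row.names = FALSE)
    manifest$stages$regression <- list(n_reports = nrow(suite))
  }

  if (!is.null(config$embed_feature)) {
    emb <- stage("embed", export_embedding(table, config$embed_feature,
                                           seed = config$seed))
    write.csv(emb, file.path(out_dir, "embedding.csv"), row.names = FALSE)
    manifest$stages$embed <- list(n_points = nrow(emb))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' 2D embedding of motifs from one distance column
#'
#' Classical multidimensional scaling of the motif-by-motif distance
#' matrix implied by one feature column — a plain coordinate export for
#' external plotting. The projection is for visual inspection only; no
#' statistics are computed on dimensionality-reduced coordinates.
#'
#' @param table A `distance_table`.
#' @param feature One of [distance_feature_names()].
#' @param seed Accepted for interface uniformity; classical MDS is
#'   deterministic.
#' @return Data.frame with `motif_id`, `dim1`, `dim2`.
#' @export
export_embedding <- function(table, feature, seed = 1L) {
  feature <- match.arg(feature, distance_feature_names())
  if (any(!is.finite(table[[feature]])))
    stopf("export_embedding: incomplete distance column '%s'", feature)
  ids <- sort(unique(c(table$motif_i, table$motif_j)))
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[cbind(match(table$motif_i, ids), match(table$motif_j, ids))] <- table[[feature]]
  D <- D + t(D)
  xy <- cmdscale(as.dist(D), k = 2)
  data.frame(motif_id = ids, dim1 = xy[, 1L], dim2 = xy[, 2L], row.names = NULL)
}
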