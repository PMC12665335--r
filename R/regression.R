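#' Hyperparameter grid for the gradient-boosted regression
#'
#' The canonical 48-point grid: `n_estimators` in {50, 100, 150, 200},
#' `learning_rate` in {0.001, 0.01, 0.1}, `max_depth` in {2, 4, 8, 10}.
#'
#' @param n_estimators,learning_rate,max_depth Candidate values.
#' @return Data.frame with one row per configuration.
#' @export
regression_grid <- function(n_estimators = c(50L, 100L, 150L, 200L),
                            learning_rate = c(0.001, 0.01, 0.1),
                            max_depth = c(2L, 4L, 8L, 10L)) {
  expand.grid(n_estimators = n_estimators, learning_rate = learning_rate,
              max_depth = max_depth, KEEP.OUT.ATTRS = FALSE)
}

#' Build the design for one sonic-from-kinematic regression
#'
#' Predictors are the kinematic distance columns of the chosen set:
#' `"hand"` = hand position/velocity/acceleration, `"head"` = the head
#' triple, `"all"` = all six, `"randomized"` = all six with each column
#' independently permuted across rows (marginals preserved, joint rows
#' decoupled — the chance baseline). The target is one sonic distance
#' column. Strata label each row by its unordered performer-pair category,
#' the only categorical structure among motif pairs, and drive stratified
#' splitting downstream.
#'
#' @param table A `distance_table`.
#' @param target One of [sonic_feature_names()].
#' @param feature_set `"hand"`, `"head"`, `"all"` or `"randomized"`.
#' @param performer_set `"all"` (every row) or a performer id (rows where
#'   both motifs belong to that performer).
#' @param seed Seed for the randomized permutation.
#' @return List with `x` (matrix), `y`, `strata` (factor), `target`,
#'   `feature_set`.
#' @export
make_design <- function(table, target, feature_set = "all",
                        performer_set = "all", seed = 1L) {
  target <- match.arg(target, sonic_feature_names())
  feature_set <- match.arg(feature_set, c("hand", "head", "all", "randomized"))
  if (!identical(performer_set, "all"))
    table <- table[table$performer_i == performer_set &
                     table$performer_j == performer_set, , drop = FALSE]
  cols <- switch(feature_set,
                 hand = c("hand_pos", "hand_vel", "hand_acc"),
                 head = c("head_pos", "head_vel", "head_acc"),
                 all = kinematic_feature_names(),
                 randomized = kinematic_feature_names())
  x <- as.matrix(table[cols])
  if (feature_set == "randomized")
    x <- with_rng(seed, apply(x, 2L, function(col) col[sample.int(length(col))]))
  strata <- factor(paste(pmin(table$performer_i, table$performer_j),
                         pmax(table$performer_i, table$performer_j), sep = "|"))
  list(x = x, y = table[[target]], strata = strata,
       target = target, feature_set = feature_set,
       performer_set = performer_set)
}

# Stratified index split: for each stratum, assign ~frac of rows to the
# second part. Returns logical vector (TRUE = held out).
stratified_holdout <- function(strata, frac, seed) {
  with_rng(seed, {
    hold <- logical(length(strata))
    for (s in levels(strata)) {
      idx <- which(strata == s)
      k <- max(1L, round(frac * length(idx)))
      hold[sample(idx, k)] <- TRUE
    }
    hold
  })
}

# Stratified k-fold assignment.
stratified_folds <- function(strata, k, seed) {
  with_rng(seed, {
    fold <- integer(length(strata))
    for (s in levels(strata)) {
      idx <- which(strata == s)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

fit_gbr <- function(x, y, cfg, seed) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = cfg$learning_rate,
                  max_depth = cfg$max_depth, nthread = 1, seed = seed,
                  verbosity = 0),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = cfg$n_estimators, verbose = 0)
}

#' Fit and score one gradient-boosted regression under the full protocol
#'
#' Protocol: a stratified 20% holdout is split off; the 48-point grid is
#' searched by repeated stratified 3-fold cross-validation with 5
#' repetitions on the remaining 80%, scored by mean R-squared over the 15
#' fold fits (ties resolved to fewest trees, then shallowest depth); the
#' winning configuration is refit on the full training split and the
#' holdout R-squared reported. Holdout rows never influence selection or
#' the final fit.
#'
#' @param design Output of [make_design()].
#' @param grid Hyperparameter grid (default [regression_grid()], 48 rows).
#' @param holdout_frac Holdout fraction (default 0.2).
#' @param cv_folds,cv_reps Cross-validation folds and repetitions (3, 5).
#' @param seed Integer seed controlling the split, folds and fits.
#' @return A `kinreg_report`: list with `r2_holdout`, `best_params`,
#'   `cv_r2` (mean CV score of the winner), `target`, `feature_set`,
#'   `performer_set`, `n_train`, `n_holdout`.
#' @export
fit_and_score <- function(design, grid = regression_grid(),
                          holdout_frac = 0.2, cv_folds = 3L, cv_reps = 5L,
                          seed = 1L) {
  x <- design$x; y <- design$y; strata <- design$strata
  if (length(y) < 50L) stopf("fit_and_score: need >= 50 rows, got %d", length(y))
  if (var(y) == 0) stopf("fit_and_score: degenerate target (zero variance)")
  hold <- stratified_holdout(strata, holdout_frac, seed)
  xtr <- x[!hold, , drop = FALSE]; ytr <- y[!hold]
  str_tr <- droplevels(strata[!hold])
  folds <- lapply(seq_len(cv_reps), function(r)
    stratified_folds(str_tr, cv_folds, seed + 1000L * r))
  # One boosting run per (learning_rate, max_depth) and fold scores every
  # candidate n_estimators: the first k trees of a longer run are exactly
  # the k-round model, so truncated prediction reproduces each grid point.
  pairs <- unique(grid[c("learning_rate", "max_depth")])
  cv_score <- numeric(nrow(grid))
  for (p in seq_len(nrow(pairs))) {
    rows <- which(grid$learning_rate == pairs$learning_rate[p] &
                    grid$max_depth == pairs$max_depth[p])
    sizes <- grid$n_estimators[rows]
    cfg_max <- data.frame(n_estimators = max(sizes),
                          learning_rate = pairs$learning_rate[p],
                          max_depth = pairs$max_depth[p])
    scores <- matrix(0, nrow = length(rows), ncol = cv_reps * cv_folds)
    col <- 0L
    for (r in seq_len(cv_reps)) for (f in seq_len(cv_folds)) {
      col <- col + 1L
      te <- folds[[r]] == f
      fit <- fit_gbr(xtr[!te, , drop = FALSE], ytr[!te], cfg_max, seed)
      dte <- xgboost::xgb.DMatrix(xtr[te, , drop = FALSE], nthread = 1)
      for (s in seq_along(sizes)) {
        pred <- predict(fit, dte, iterationrange = c(1L, sizes[s]))
        scores[s, col] <- r_squared(ytr[te], pred)
      }
    }
    cv_score[rows] <- rowMeans(scores)
  }
  ord <- order(-cv_score, grid$n_estimators, grid$max_depth)
  best <- ord[1L]
  fit <- fit_gbr(xtr, ytr, grid[best, ], seed)
  pred <- predict(fit, xgboost::xgb.DMatrix(x[hold, , drop = FALSE], nthread = 1))
  structure(list(r2_holdout = r_squared(y[hold], pred),
                 best_params = as.list(grid[best, ]),
                 cv_r2 = cv_score[best],
                 target = design$target, feature_set = design$feature_set,
                 performer_set = design$performer_set,
                 n_train = sum(!hold), n_holdout = sum(hold), seed = seed),
            class = "kinreg_report")
}

#' @export
print.kinreg_report <- function(x, ...) {
  cat(sprintf("Gradient-boosted regression: %s ~ %s kinematics [%s]\n",
              x$target, x$feature_set, x$performer_set))
  cat(sprintf("  holdout R^2 = %.3f (n = %d), CV R^2 = %.3f, best: %d trees, lr %g, depth %d\n",
              x$r2_holdout, x$n_holdout, x$cv_r2, x$best_params$n_estimators,
              x$best_params$learning_rate, x$best_params$max_depth))
  invisible(x)
}

#' Run the regression suite over targets, feature sets and performer sets
#'
#' One report per (performer set, sonic target, feature set); the full
#' canonical design (all + 3 performers, 4 targets, 4 feature sets) yields
#' 64 reports.
#'
#' @param table A `distance_table`.
#' @param performer_sets Performer sets (default `"all"`).
#' @param targets Sonic targets (default all four).
#' @param feature_sets Kinematic feature sets (default all four variants).
#' @inheritParams fit_and_score
#' @return A data.frame (class `kinreg_suite`) with one row per report and
#'   a `reports` attribute holding the full objects.
#' @export
run_suite <- function(table, performer_sets = "all",
                      targets = sonic_feature_names(),
                      feature_sets = c("hand", "head", "all", "randomized"),
                      grid = regression_grid(), holdout_frac = 0.2,
                      cv_folds = 3L, cv_reps = 5L, seed = 1L) {
  combos <- expand.grid(performer_set = performer_sets, target = targets,
                        feature_set = feature_sets, stringsAsFactors = FALSE)
  reports <- lapply(seq_len(nrow(combos)), function(i) {
    d <- make_design(table, combos$target[i], combos$feature_set[i],
                     combos$performer_set[i], seed = seed)
    fit_and_score(d, grid = grid, holdout_frac = holdout_frac,
                  cv_folds = cv_folds, cv_reps = cv_reps, seed = seed)
  })
  out <- cbind(combos, data.frame(
    r2_holdout = vapply(reports, `[[`, 0, "r2_holdout"),
    cv_r2 = vapply(reports, `[[`, 0, "cv_r2"),
    n_estimators = vapply(reports, function(r) r$best_params$n_estimators, 0),
    learning_rate = vapply(reports, function(r) r$best_params$learning_rate, 0),
    max_depth = vapply(reports, function(r) r$best_params$max_depth, 0)))
  attr(out, "reports") <- reports
  class(out) <- c("kinreg_suite", "data.frame")
  out
}
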