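#' DTW parameters
#'
#' Bundle of parameters for the dependent banded open-endpoint DTW used to
#' compare motif feature trajectories. The defaults reproduce the reference
#' configuration: both the Sakoe-Chiba window and the open-endpoint margin
#' are a fraction 0.1 of L, the length of the longer series in the pair.
#'
#' @param band_frac Sakoe-Chiba band half-width as a fraction of L, in (0, 1].
#' @param open_frac Open-endpoint margin as a fraction of L, in [0, 0.5). The
#'   warping path may begin within `ceil(open_frac * L)` frames of the start
#'   of each series, and end within the mirrored margin of each end;
#'   `open_frac = 0` gives textbook fixed endpoints.
#' @param normalize_by_path Divide the accumulated cost by the length of the
#'   optimal path. Motif durations vary severalfold; without normalisation
#'   distance ranks are dominated by length. Default `TRUE`.
#' @param local_metric Local frame cost; only `"euclidean"` is defined (the
#'   joint Euclidean norm across dimensions — dependent DTW).
#' @return An object of class `dtw_params`.
#' @export
dtw_params <- function(band_frac = 0.1, open_frac = 0.1,
                       normalize_by_path = TRUE, local_metric = "euclidean") {
  if (!is.numeric(band_frac) || band_frac <= 0 || band_frac > 1)
    stopf("band_frac must be in (0, 1], got %s", format(band_frac))
  if (!is.numeric(open_frac) || open_frac < 0 || open_frac >= 0.5)
    stopf("open_frac must be in [0, 0.5), got %s", format(open_frac))
  local_metric <- match.arg(local_metric, "euclidean")
  structure(list(band_frac = band_frac, open_frac = open_frac,
                 normalize_by_path = isTRUE(normalize_by_path),
                 local_metric = local_metric),
            class = "dtw_params")
}

#' @export
print.dtw_params <- function(x, ...) {
  cat(sprintf("DTW parameters: band 0..%gL, open endpoints %gL, %s local cost, %spath-normalised\n",
              x$band_frac, x$open_frac, x$local_metric,
              if (x$normalize_by_path) "" else "not "))
  invisible(x)
}

as_series_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1) else x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Dependent DTW distance between two trajectories
#'
#' Minimum-cost monotone alignment between two uni- or multi-dimensional
#' time series, where the local cost is the Euclidean norm of the frame
#' difference summed jointly over dimensions (one shared warping path — the
#' "dependent" multidimensional formulation). Admissible alignments are
#' restricted to a slope-corrected Sakoe-Chiba band of half-width
#' `ceil(band_frac * L)` around the diagonal, and the path may start and end
#' within `ceil(open_frac * L)` frames of each series' extremes, absorbing
#' small segmentation offsets between otherwise similar motifs.
#'
#' The band test for cell (i, j) is `|i * len_b/len_a - j| <= ceil(band_frac * L)`,
#' which is not symmetric in the operands when lengths differ; to guarantee
#' `dtw_distance(a, b) == dtw_distance(b, a)` exactly, the pair is evaluated
#' internally with the longer series first.
#'
#' @param a,b Numeric vectors (univariate) or matrices with time in rows and
#'   dimensions in columns; both must share the same dimensionality.
#' @param params A [dtw_params()] object.
#' @return Nonnegative scalar distance. With `normalize_by_path = TRUE` the
#'   minimum accumulated cost is divided by the step count of the optimal
#'   path.
#' @examples
#' x <- sin(seq(0, 2 * pi, length.out = 50))
#' dtw_distance(x, x)                       # 0: identical series
#' dtw_distance(x, x[seq(1, 50, by = 2)])   # small: same shape, warped
#' @export
dtw_distance <- function(a, b, params = dtw_params()) {
  stopifnot(inherits(params, "dtw_params"))
  a <- as_series_matrix(a); b <- as_series_matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stopf("dtw_distance: empty series")
  if (ncol(a) != ncol(b))
    stopf("dtw_distance: dimensionality differs (%d vs %d)", ncol(a), ncol(b))
  if (anyNA(a) || anyNA(b)) stopf("dtw_distance: series contain missing values")
  if (nrow(b) > nrow(a)) { tmp <- a; a <- b; b <- tmp }  # symmetry canonicalisation
  res <- .dtw_cost_cpp(a, b, params$band_frac, params$open_frac)
  if (!is.finite(res[["cost"]]))
    stopf("no admissible warping path for lengths %d and %d with band_frac = %g, open_frac = %g",
          nrow(a), nrow(b), params$band_frac, params$open_frac)
  if (params$normalize_by_path) res[["cost"]] / res[["steps"]] else res[["cost"]]
}

#' All unordered motif pairs
#'
#' Skeleton of the pairwise distance table: one row per unordered pair
#' (i < j) of motif identifiers, in lexicographic order of indices, with
#' performer metadata. With n motifs the table has `n * (n - 1) / 2` rows —
#' e.g. 595 motifs yield 176,715 rows.
#'
#' @param motif_ids Character vector of motif identifiers (unique).
#' @param performer_ids Performer label per motif (same length).
#' @return A data.frame with columns `motif_i`, `motif_j`, `performer_i`,
#'   `performer_j`, `same_performer`.
#' @export
pair_grid <- function(motif_ids, performer_ids = NULL) {
  motif_ids <- as.character(motif_ids)
  if (anyDuplicated(motif_ids)) stopf("pair_grid: duplicated motif ids")
  n <- length(motif_ids)
  if (n < 2L) stopf("pair_grid: need at least 2 motifs, got %d", n)
  if (is.null(performer_ids)) performer_ids <- rep(NA_character_, n)
  performer_ids <- as.character(performer_ids)
  idx_i <- rep.int(1L:(n - 1L), times = (n - 1L):1L)
  idx_j <- unlist(lapply(1L:(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
  data.frame(motif_i = motif_ids[idx_i], motif_j = motif_ids[idx_j],
             performer_i = performer_ids[idx_i], performer_j = performer_ids[idx_j],
             same_performer = performer_ids[idx_i] == performer_ids[idx_j],
             stringsAsFactors = FALSE)
}

#' Build the all-pairs 10-feature DTW distance table
#'
#' For every unordered pair of motifs, computes the dependent DTW distance
#' between each of their 10 feature trajectories: the four sonic series
#' (univariate) and the six kinematic series (3-dimensional, one shared
#' warping path per feature). Motifs whose pitch track still contains an
#' unbridgeable gap (`ok = FALSE` from gap interpolation) are excluded
#' before pairing, with a warning naming them.
#'
#' @param dataset A [synth_dataset] or any list with elements `motif_table`
#'   (data.frame with `motif_id`, `performer_id`), `sonic` (named list of
#'   [sonic_features] per motif) and `kinematic` (named list of
#'   [kinematic_features] per motif).
#' @param params A [dtw_params()] object.
#' @param progress Print progress every `progress` pairs; 0 disables.
#' @return A `distance_table`: data.frame with pair metadata columns (see
#'   [pair_grid()]) and the 10 distance columns of
#'   [distance_feature_names()]. Row count is `choose(n, 2)` over included
#'   motifs.
#' @export
build_distance_table <- function(dataset, params = dtw_params(), progress = 0) {
  mt <- dataset$motif_table
  stopifnot(is.data.frame(mt), !is.null(dataset$sonic), !is.null(dataset$kinematic))
  ids <- as.character(mt$motif_id)
  ok <- vapply(dataset$sonic[ids], function(s) isTRUE(s$ok %||% TRUE), logical(1))
  if (any(!ok)) {
    warnf("excluding %d motif(s) with unbridged pitch gaps: %s",
          sum(!ok), paste(ids[!ok], collapse = ", "))
    ids <- ids[ok]
  }
  if (length(ids) < 2L) stopf("build_distance_table: fewer than 2 usable motifs")
  performers <- as.character(mt$performer_id)[match(ids, as.character(mt$motif_id))]
  grid <- pair_grid(ids, performers)

  sonic_names <- sonic_feature_names()
  kin_names <- kinematic_feature_names()
  # pre-extract matrices once
  sonic_mats <- lapply(dataset$sonic[ids], function(s)
    lapply(sonic_names, function(f) as_series_matrix(s[[f]])))
  kin_mats <- lapply(dataset$kinematic[ids], function(k)
    lapply(kin_names, function(f) as_series_matrix(k[[f]])))

  npair <- nrow(grid)
  dist_cols <- matrix(NA_real_, nrow = npair, ncol = 10,
                      dimnames = list(NULL, distance_feature_names()))
  ii <- match(grid$motif_i, ids); jj <- match(grid$motif_j, ids)
  for (r in seq_len(npair)) {
    si <- sonic_mats[[ii[r]]]; sj <- sonic_mats[[jj[r]]]
    ki <- kin_mats[[ii[r]]]; kj <- kin_mats[[jj[r]]]
    for (f in 1:4)
      dist_cols[r, f] <- dtw_distance(si[[f]], sj[[f]], params)
    for (f in 1:6)
      dist_cols[r, 4 + f] <- dtw_distance(ki[[f]], kj[[f]], params)
    if (progress > 0 && r %% progress == 0)
      message(sprintf("  %d / %d pairs", r, npair))
  }
  out <- cbind(grid, as.data.frame(dist_cols))
  class(out) <- c("distance_table", "data.frame")
  attr(out, "dtw_params") <- params
  out
}
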