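#' Equal per-performer subsampling of motifs
#'
#' For pooled (all-performer) analyses, motifs are subsampled without
#' replacement so that every performer contributes exactly as many motifs
#' as the least-represented performer, removing representation imbalance
#' from the pooled correlation.
#'
#' @param motif_ids Character vector of motif ids.
#' @param performer_ids Performer label per motif.
#' @param seed Integer seed for the subsample.
#' @return Character vector of retained motif ids (original order).
#' @export
equal_subsample <- function(motif_ids, performer_ids, seed = 1L) {
  motif_ids <- as.character(motif_ids)
  performer_ids <- as.character(performer_ids)
  stopifnot(length(motif_ids) == length(performer_ids))
  counts <- table(performer_ids)
  if (any(counts == 0L) || length(counts) < 2L)
    stopf("equal_subsample: need >= 2 performers, each with >= 1 motif")
  k <- min(counts)
  keep <- with_rng(seed, unlist(lapply(split(motif_ids, performer_ids),
                                       function(ids) sample(ids, k)),
                                use.names = FALSE))
  motif_ids[motif_ids %in% keep]
}

spearman_cell <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

# Mantel-style permutation p: permute motif labels of the kinematic column's
# distance structure and recompute Spearman rho; two-sided.
mantel_p <- function(sub, sonic_col, kin_col, n_perm, seed) {
  ids <- sort(unique(c(sub$motif_i, sub$motif_j)))
  n <- length(ids)
  ii <- match(sub$motif_i, ids); jj <- match(sub$motif_j, ids)
  key <- function(a, b) ifelse(a < b, (a - 1) * n + b, (b - 1) * n + a)
  row_of <- integer(n * n)
  row_of[key(ii, jj)] <- seq_len(nrow(sub))
  x <- rank(sub[[sonic_col]]); y <- sub[[kin_col]]
  obs <- stats::cor(x, rank(y))
  with_rng(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      yp <- y[row_of[key(perm[ii], perm[jj])]]
      if (abs(stats::cor(x, rank(yp))) >= abs(obs) - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}

#' Spearman co-structuring grid for one performer set
#'
#' For every combination of the four sonic and six kinematic distance
#' columns, the Spearman rank correlation between the two columns over the
#' motif pairs of the given performer set: `"all"` uses pairs among an
#' equal per-performer subsample of motifs (including cross-performer
#' pairs); an individual performer uses the pairs in which both motifs are
#' that performer's. A high cell means: motif pairs similar in that sonic
#' feature tend to be similar in that kinematic feature — second-order
#' co-structuring, not time-locked coupling.
#'
#' @param table A `distance_table`.
#' @param performer_set `"all"` or a performer id present in the table.
#' @param alpha Family significance level before correction (default 1e-4).
#' @param n_tests Bonferroni divisor; defaults to 24 (one grid). When
#'   several sets are analysed together use [costructure()], which sets the
#'   family-wide count (96 for the canonical all + 3 performers design).
#' @param subsample_seed Seed for the equal per-performer subsample.
#' @param mantel Use a label-permutation (Mantel-style) p-value instead of
#'   the asymptotic one. The asymptotic p treats motif pairs as independent
#'   although each motif occurs in n - 1 pairs — matching the reference
#'   analysis — while the permutation p respects that dependence; it is
#'   off by default and bounded below by `1 / (n_perm + 1)`.
#' @param n_perm Permutations for `mantel = TRUE`.
#' @return A `costructure_profile`: list with `rho`, `pval`, `significant`
#'   (4 x 6 matrices, sonic rows x kinematic columns), `performer_set`,
#'   `n_pairs`, `alpha`, `n_tests`.
#' @export
spearman_grid <- function(table, performer_set = "all", alpha = 1e-4,
                          n_tests = 24L, subsample_seed = 1L,
                          mantel = FALSE, n_perm = 199L) {
  stopifnot(is.data.frame(table))
  if (identical(performer_set, "all")) {
    ids <- unique(c(table$motif_i, table$motif_j))
    perf <- c(table$performer_i, table$performer_j)[match(ids, c(table$motif_i, table$motif_j))]
    keep <- if (length(unique(perf)) > 1L)
      equal_subsample(ids, perf, seed = subsample_seed) else ids
    sub <- table[table$motif_i %in% keep & table$motif_j %in% keep, , drop = FALSE]
  } else {
    sub <- table[table$performer_i == performer_set &
                   table$performer_j == performer_set, , drop = FALSE]
  }
  if (nrow(sub) < 3L)
    stopf("spearman_grid: fewer than 3 pairs for set '%s'", performer_set)
  sn <- sonic_feature_names(); kn <- kinematic_feature_names()
  rho <- matrix(NA_real_, 4, 6, dimnames = list(sn, kn))
  pval <- rho
  for (s in sn) for (k in kn) {
    cell <- spearman_cell(sub[[s]], sub[[k]])
    rho[s, k] <- cell["rho"]
    pval[s, k] <- if (mantel) mantel_p(sub, s, k, n_perm, subsample_seed)
                  else cell["p"]
  }
  structure(list(performer_set = performer_set, rho = rho, pval = pval,
                 n_pairs = nrow(sub), alpha = alpha, n_tests = as.integer(n_tests),
                 significant = pval < alpha / n_tests),
            class = "costructure_profile")
}

#' @export
print.costructure_profile <- function(x, digits = 3, ...) {
  cat(sprintf("Co-structuring profile: set '%s', %d pairs, %d significant of 24 cells at %g/%d\n",
              x$performer_set, x$n_pairs, sum(x$significant), x$alpha, x$n_tests))
  print(round(x$rho, digits))
  invisible(x)
}

#' Apply a Bonferroni family correction across profiles
#'
#' Re-flags significance in each profile using the family-wide test count
#' (24 cells per performer set: the canonical all + 3 performers design
#' gives 96 tests and threshold `alpha / 96`).
#'
#' @param profiles List of `costructure_profile`s.
#' @param alpha Significance level before division (default 1e-4).
#' @return The profiles with `n_tests` and `significant` updated.
#' @export
bonferroni <- function(profiles, alpha = 1e-4) {
  if (inherits(profiles, "costructure_profile")) profiles <- list(profiles)
  n_tests <- sum(vapply(profiles, function(p) length(p$pval), 1L))
  lapply(profiles, function(p) {
    p$alpha <- alpha
    p$n_tests <- as.integer(n_tests)
    p$significant <- p$pval < alpha / n_tests
    p
  })
}

#' Shuffle-null randomization of a distance table
#'
#' Destroys pair-level sonic-kinematic coupling while preserving all
#' marginals: each of the 10 distance columns is independently permuted
#' within each performer-set stratum (the unordered performer pair of the
#' row), so every value remains attributed to the same performers and each
#' column's within-stratum multiset is unchanged. Grids computed on the
#' shuffled table estimate the no-co-structuring null.
#'
#' @param table A `distance_table`.
#' @param seed Integer seed.
#' @return A `distance_table` with shuffled distance columns.
#' @export
shuffle_null <- function(table, seed = 1L) {
  stopifnot(is.data.frame(table))
  strata <- paste(pmin(table$performer_i, table$performer_j),
                  pmax(table$performer_i, table$performer_j), sep = "|")
  out <- table
  with_rng(seed, {
    for (col in distance_feature_names()) {
      for (s in unique(strata)) {
        idx <- which(strata == s)
        out[[col]][idx] <- table[[col]][idx][sample.int(length(idx))]
      }
    }
  })
  out
}

#' Co-structuring analysis over performer sets
#'
#' Runs [spearman_grid()] for the pooled set and each performer, then
#' applies the family-wide Bonferroni correction (4 sets x 24 cells = 96
#' tests in the canonical design).
#'
#' @param table A `distance_table`.
#' @param sets Performer sets; default `"all"` plus every performer in the
#'   table.
#' @inheritParams spearman_grid
#' @param seed Seed for the equal subsample (and permutations).
#' @return An object of class `costructure`: named list of profiles with
#'   attributes `alpha` and `n_tests`.
#' @export
costructure <- function(table, sets = NULL, alpha = 1e-4, seed = 1L,
                        mantel = FALSE, n_perm = 199L) {
  if (is.null(sets))
    sets <- c("all", sort(unique(c(table$performer_i, table$performer_j))))
  profiles <- lapply(sets, function(s)
    spearman_grid(table, s, alpha = alpha, subsample_seed = seed,
                  mantel = mantel, n_perm = n_perm))
  profiles <- bonferroni(profiles, alpha = alpha)
  names(profiles) <- sets
  structure(profiles, class = "costructure",
            alpha = alpha, n_tests = profiles[[1L]]$n_tests)
}

#' @export
print.costructure <- function(x, ...) {
  cat(sprintf("Co-structuring analysis: %d performer set(s), %d tests, threshold %g\n",
              length(x), attr(x, "n_tests"), attr(x, "alpha") / attr(x, "n_tests")))
  for (p in x)
    cat(sprintf("  %-10s %2d / 24 significant, max |rho| = %.3f (n = %d pairs)\n",
                p$performer_set, sum(p$significant), max(abs(p$rho)), p$n_pairs))
  invisible(x)
}

#' @export
summary.costructure <- function(object, ...) profile_summary(object)

#' Long-format report of co-structuring profiles
#'
#' One row per (performer set, sonic feature, kinematic feature) cell with
#' rho, p and the Bonferroni significance flag — 96 rows for the canonical
#' four-set design. The heatmap-ready masked matrix for a set (insignificant
#' cells as `NA`) is available via [masked_rho()].
#'
#' @param profiles A `costructure` object or list of profiles.
#' @return A data.frame.
#' @export
profile_summary <- function(profiles) {
  if (inherits(profiles, "costructure_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(unclass(profiles), function(p) {
    grid <- expand.grid(sonic = sonic_feature_names(),
                        kinematic = kinematic_feature_names(),
                        stringsAsFactors = FALSE)
    data.frame(performer_set = p$performer_set, grid,
               rho = p$rho[cbind(grid$sonic, grid$kinematic)],
               p = p$pval[cbind(grid$sonic, grid$kinematic)],
               significant = p$significant[cbind(grid$sonic, grid$kinematic)],
               row.names = NULL)
  }))
}

#' @rdname profile_summary
#' @param profile A single `costructure_profile`.
#' @return `masked_rho`: the 4 x 6 rho matrix with insignificant cells `NA`.
#' @export
masked_rho <- function(profile) {
  stopifnot(inherits(profile, "costructure_profile"))
  out <- profile$rho
  out[!profile$significant] <- NA_real_
  out
}

#' Heatmap of a co-structuring analysis
#'
#' One panel per performer set: cells coloured by Spearman rho, with
#' insignificant cells (at the family Bonferroni threshold) greyed out.
#'
#' @param x A `costructure` object.
#' @param mask_insignificant Grey out insignificant cells (default TRUE).
#' @param ... Unused.
#' @export
plot.costructure <- function(x, mask_insignificant = TRUE, ...) {
  sets <- names(x)
  old <- graphics::par(mfrow = c(1, length(sets)), mar = c(7, 7, 2, 1))
  on.exit(graphics::par(old))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  for (s in sets) {
    m <- if (mask_insignificant) masked_rho(x[[s]]) else x[[s]]$rho
    graphics::image(1:6, 1:4, t(m[4:1, , drop = FALSE]), zlim = c(-1, 1),
                    col = pal, axes = FALSE, xlab = "", ylab = "", main = s)
    graphics::axis(1, at = 1:6, labels = colnames(m), las = 2, cex.axis = 0.8)
    graphics::axis(2, at = 1:4, labels = rev(rownames(m)), las = 1, cex.axis = 0.8)
    graphics::box()
  }
  invisible(x)
}
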