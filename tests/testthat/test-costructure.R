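test_that("the grid has 4 x 6 cells with valid correlations and p-values", {
  g <- spearman_grid(small_distance_table(), "all", subsample_seed = 1)
  expect_equal(dim(g$rho), c(4, 6))
  expect_equal(rownames(g$rho), sonic_feature_names())
  expect_equal(colnames(g$rho), kinematic_feature_names())
  expect_true(all(abs(g$rho) <= 1))
  expect_true(all(g$pval >= 0 & g$pval <= 1))
  expect_identical(g$significant, g$pval < g$alpha / g$n_tests)
})

test_that("monotone transforms of a column leave Spearman cells invariant", {
  tab <- small_distance_table()
  g0 <- spearman_grid(tab, "P1")
  tab2 <- tab
  tab2$f0 <- exp(tab2$f0 / max(tab2$f0) * 3)          # strictly increasing map
  tab2$hand_vel <- rank(tab2$hand_vel)^1.5
  g1 <- spearman_grid(tab2, "P1")
  expect_equal(g1$rho["f0", ], g0$rho["f0", ], tolerance = 1e-12)
  expect_equal(g1$rho[, "hand_vel"], g0$rho[, "hand_vel"], tolerance = 1e-12)
  # a strictly decreasing function gives rho = -1 against itself
  tab3 <- tab
  tab3$hand_pos <- -tab3$f0
  g3 <- spearman_grid(tab3, "P1")
  expect_equal(unname(g3$rho["f0", "hand_pos"]), -1)
  tab3$hand_pos <- tab3$f0^3 + 1                       # increasing: rho = 1
  expect_equal(unname(spearman_grid(tab3, "P1")$rho["f0", "hand_pos"]), 1)
})

test_that("equal subsampling balances performers deterministically", {
  ids <- sprintf("m%02d", 1:24)
  perf <- rep(c("A", "B", "C"), times = c(10, 7, 7))
  keep <- equal_subsample(ids, perf, seed = 3)
  expect_equal(length(keep), 21)
  expect_true(all(table(perf[ids %in% keep]) == 7))
  expect_identical(keep, equal_subsample(ids, perf, seed = 3))
  expect_false(identical(keep, equal_subsample(ids, perf, seed = 4)))
  # already equal counts: everything retained
  expect_equal(length(equal_subsample(ids[1:14], rep(c("A", "B"), 7), seed = 1)), 14)
  expect_error(equal_subsample(ids[1:3], rep("A", 3), seed = 1), "2 performers")
})

test_that("per-performer sets use only that performer's pairs", {
  tab <- small_distance_table()
  g <- spearman_grid(tab, "P2")
  expect_equal(g$n_pairs, sum(tab$performer_i == "P2" & tab$performer_j == "P2"))
  expect_error(spearman_grid(tab, "nobody"), "fewer than 3")
})

test_that("shuffling preserves marginals and strata while breaking coupling", {
  tab <- small_distance_table()
  sh <- shuffle_null(tab, seed = 5)
  strata <- paste(tab$performer_i, tab$performer_j)
  for (col in distance_feature_names()) {
    for (s in unique(strata)) {
      idx <- strata == s
      expect_equal(sort(sh[[col]][idx]), sort(tab[[col]][idx]))
    }
  }
  expect_identical(sh$motif_i, tab$motif_i)
  expect_identical(shuffle_null(tab, seed = 5), sh)    # seeded determinism
  expect_false(identical(sh$f0, tab$f0))
})

test_that("Bonferroni correction uses the family-wide cell count", {
  tab <- small_distance_table()
  cs <- costructure(tab, seed = 1)
  expect_equal(attr(cs, "n_tests"), 96)                # all + 3 performers
  expect_equal(names(cs), c("all", "P1", "P2", "P3"))
  for (p in cs) {
    expect_equal(p$n_tests, 96)
    expect_identical(p$significant, p$pval < 1e-4 / 96)
  }
  # worked thresholds
  one <- cs[[1]]
  expect_true(1e-8 < one$alpha / one$n_tests)
  expect_false(0.001 < one$alpha / one$n_tests)
  # two sets -> 48 tests
  cs2 <- costructure(tab, sets = c("P1", "P2"), seed = 1)
  expect_equal(attr(cs2, "n_tests"), 48)
})

test_that("profile summaries are long-format, 96 rows, and round-trip", {
  cs <- costructure(small_distance_table(), seed = 1)
  rep <- profile_summary(cs)
  expect_equal(nrow(rep), 96)
  expect_setequal(unique(rep$performer_set), c("all", "P1", "P2", "P3"))
  p <- tempfile(fileext = ".csv")
  write.csv(rep, p, row.names = FALSE)
  back <- read.csv(p)
  expect_equal(back$rho, rep$rho, tolerance = 1e-12)
  expect_equal(back$significant, rep$significant)
  # masked matrix hides exactly the insignificant cells
  m <- masked_rho(cs$all)
  expect_identical(is.na(m), !cs$all$significant)
})

test_that("permutation p-values agree with asymptotic ones on strong signal", {
  tab <- small_distance_table()
  g_asy <- spearman_grid(tab, "P1")
  g_man <- spearman_grid(tab, "P1", mantel = TRUE, n_perm = 99, subsample_seed = 1)
  expect_identical(g_man$rho, g_asy$rho)               # same estimates
  # cells that are overwhelmingly significant asymptotically hit the
  # permutation floor of 1 / (n_perm + 1)
  strong <- g_asy$pval < 1e-10
  if (any(strong)) expect_true(all(g_man$pval[strong] == 1 / 100))
})

test_that("label-permutation p-values are calibrated when labels are exchangeable", {
  # lambda = 0 with fixed durations: kinematics are iid across motifs, so the
  # null of no sonic-kinematic association holds exactly under relabelling.
  # (With variable durations a motif's length is a genuine common cause of
  # its sonic and kinematic distances, and a weak true association remains.)
  fr <- sapply(1:4, function(s) {
    ds <- generate_dataset(synth_config(motifs_per_performer = 12, coupling = 0,
                                        duration_range_s = c(2, 2), seed = 100 + s))
    tab <- build_distance_table(ds)
    g <- spearman_grid(tab, "all", mantel = TRUE, n_perm = 99, subsample_seed = s)
    mean(g$pval <= 0.05)
  })
  expect_lt(mean(fr), 0.15)                            # ~0.05 nominal
})

test_that("plot and print methods run quietly on a small analysis", {
  cs <- costructure(small_distance_table(), seed = 1)
  expect_output(print(cs), "96 tests")
  expect_output(print(cs$all), "pairs")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(cs))
  expect_equal(nrow(summary(cs)), 96)
})
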