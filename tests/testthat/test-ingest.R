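make_motif_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

good_motifs <- data.frame(
  motif_id = c("m1", "m2", "m3"),
  performance_id = c("perf1", "perf1", "perf2"),
  performer_id = c("P1", "P1", "P2"),
  start_s = c(0, 5, 0), end_s = c(2, 7.5, 3.2))

test_that("a well-formed motif table round-trips through CSV", {
  p <- make_motif_csv(good_motifs)
  mt <- read_motif_table(p)
  expect_equal(nrow(mt), 3)
  expect_equal(mt$motif_id, good_motifs$motif_id)
  p2 <- tempfile(fileext = ".csv")
  write_motif_table(mt, p2)
  expect_equal(read_motif_table(p2), mt)
})

test_that("malformed motif tables are rejected with the row named", {
  bad <- good_motifs; bad$end_s[2] <- 4.9   # end <= start
  expect_error(read_motif_table(make_motif_csv(bad)), "row 2")
  short <- good_motifs; short$end_s[3] <- 1.2
  expect_error(read_motif_table(make_motif_csv(short)), "row 3")
  expect_error(read_motif_table(make_motif_csv(good_motifs[-2])),
               "performance_id")
  overlap <- good_motifs; overlap$start_s[2] <- 1.5
  expect_error(read_motif_table(make_motif_csv(overlap)), "overlap")
  dup <- good_motifs; dup$motif_id[3] <- "m1"
  expect_error(read_motif_table(make_motif_csv(dup)), "duplicate")
})

make_frames <- function(n = 60, segments = c("head", "pelvis")) {
  do.call(rbind, lapply(segments, function(s)
    data.frame(t = (0:(n - 1)) / 60, segment = s,
               px = rnorm(n), py = rnorm(n), pz = rnorm(n),
               vx = 0, vy = 0, vz = 0, ax = 0, ay = 0, az = 0)))
}

test_that("kinematic frames are read, sorted, and validated", {
  set.seed(5)
  fr <- make_frames(600)
  p <- tempfile(fileext = ".csv")
  write_kinematics(fr, p)
  got <- read_kinematics(p)
  expect_equal(nrow(got), 1200)                       # 10 s x 60 Hz x 2 segments
  expect_equal(sum(got$segment == "head"), 600)
  # shuffled rows come back sorted by time
  write_kinematics(fr[sample(nrow(fr)), ], p)
  got2 <- read_kinematics(p)
  for (s in c("head", "pelvis"))
    expect_equal(got2$t[got2$segment == s], sort(fr$t[fr$segment == s]))
  expect_equal(nrow(attr(got2, "gaps")), 0)
})

test_that("unknown segments, duplicate stamps and gaps are caught", {
  set.seed(6)
  fr <- make_frames(30)
  bad <- fr; bad$segment[1] <- "foot"
  p <- tempfile(fileext = ".csv")
  write_kinematics(bad, p)
  expect_error(read_kinematics(p), "hand_L")          # error lists allowed labels
  dup <- rbind(fr, fr[1, ])
  write_kinematics(dup, p)
  expect_error(read_kinematics(p), "duplicated")
  gap <- fr[fr$t < 0.2 | fr$t > 0.3, ]
  write_kinematics(gap, p)
  expect_warning(got <- read_kinematics(p), "gap")
  expect_gt(nrow(attr(got, "gaps")), 0)
})

test_that("motif slicing is half-open at the native rate", {
  x <- matrix(seq_len(600 * 3), ncol = 3)             # 10 s at 60 Hz
  rec <- list(start_s = 2, end_s = 4)
  sl <- slice_motif(x, 60, rec)
  expect_equal(nrow(sl), 120)                         # [2, 4) -> 120 frames
  expect_equal(sl[1, 1], x[121, 1])                   # first frame at t = 2.0
  # adjacent motifs are disjoint
  sl2 <- slice_motif(x, 60, list(start_s = 4, end_s = 6))
  expect_equal(sl2[1, 1], x[241, 1])
  # identity slice
  expect_equal(slice_motif(x, 60, list(start_s = 0, end_s = 10)), unname(x))
  expect_error(slice_motif(x, 60, list(start_s = 9, end_s = 11)), "extent")
  v <- sin(1:100)
  expect_equal(slice_motif(v, 10, list(start_s = 1, end_s = 2)), v[11:20])
})

test_that("distance tables round-trip losslessly and are validated on read", {
  tab <- small_distance_table()
  p <- tempfile(fileext = ".csv")
  write_distance_table(tab, p)
  back <- read_distance_table(p)
  ref <- as.data.frame(tab)
  attr(ref, "dtw_params") <- NULL
  expect_equal(as.data.frame(back), ref, tolerance = 1e-12)
  expect_s3_class(back, "distance_table")
  # missing distance column rejected
  df <- read.csv(p)
  write.csv(df[setdiff(names(df), "head_acc")], p, row.names = FALSE)
  expect_error(read_distance_table(p), "head_acc")
})

test_that("feature series round-trip with rate inference", {
  v <- sin((1:200) / 10)
  p <- tempfile(fileext = ".csv")
  write_feature_series(v, 100, p)
  got <- read_feature_series(p)
  expect_equal(got$series, v)
  expect_equal(got$rate, 100)
  m <- matrix(rnorm(90), ncol = 3)
  write_feature_series(m, 60, p)
  got2 <- read_feature_series(p)
  expect_equal(unname(as.matrix(got2$series)), m)
  expect_equal(got2$rate, 60)
})

test_that("WAV I/O round-trips mono 16-bit audio", {
  x <- sin(2 * pi * 440 * (0:7999) / 8000) * 0.7
  p <- tempfile(fileext = ".wav")
  write_wav(x, 8000, p)
  got <- read_wav(p)
  expect_equal(got$rate, 8000)
  expect_equal(length(got$samples), 8000)
  expect_lt(max(abs(got$samples - x)), 1 / 32767 * 2) # quantisation only
})

test_that("a generated dataset survives the full disk round trip", {
  cfg <- synth_config(n_performers = 2, motifs_per_performer = 3, seed = 17)
  ds <- generate_dataset(cfg, keep_raw = TRUE)
  dir <- tempfile()
  write_synth_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "motifs.csv")))
  mt <- read_motif_table(file.path(dir, "motifs.csv"))
  expect_equal(mt$motif_id, ds$motif_table$motif_id)
  # inter-motif spacing shows up as (expected) frame-grid gap reports
  warns <- capture_warnings(loaded <- costruct:::load_ingested_dataset(dir))
  expect_true(all(grepl("frame-grid gap", warns)))
  expect_equal(names(loaded$sonic), names(ds$sonic))
  # sonic series survive numerically
  expect_equal(loaded$sonic[[1]]$f0, ds$sonic[[1]]$f0, tolerance = 1e-9)
  # kinematic conditioning of written frames reproduces the same dominant side
  expect_equal(vapply(loaded$kinematic, `[[`, "", "dominant_side"),
               vapply(ds$kinematic, `[[`, "", "dominant_side"))
})
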