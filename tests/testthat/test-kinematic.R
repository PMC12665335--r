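test_that("Savitzky-Golay reproduces polynomials up to its order exactly", {
  t <- seq_len(60)
  quad <- 2 - 0.5 * t + 0.01 * t^2
  expect_equal(smooth_savgol(quad, rate = 60), quad, tolerance = 1e-9)
  expect_equal(smooth_savgol(rep(4.2, 30), rate = 60), rep(4.2, 30))
  # matrix input smooths each axis
  m <- cbind(quad, 1 + t, rep(2, 60))
  expect_equal(smooth_savgol(m, rate = 60), unname(m), tolerance = 1e-9)
})

test_that("Savitzky-Golay reduces noise around a smooth signal", {
  set.seed(21)
  t <- seq(0, 2, length.out = 120)
  clean <- sin(2 * pi * t)
  noisy <- clean + rnorm(120, 0, 0.2)
  sm <- smooth_savgol(noisy, rate = 60)
  expect_lt(var(sm - clean), var(noisy - clean))
})

test_that("window shorter than the series is required", {
  expect_error(smooth_savgol(1:5, rate = 60), "shorter than window")
})

test_that("body-frame transform aligns shoulders with x and centres the pelvis", {
  set.seed(31)
  segs <- reference_posture()
  # already aligned: identity up to noise in the constructed posture
  bf0 <- to_body_frame(segs)
  expect_equal(bf0$rotation, diag(3), tolerance = 1e-6)
  # random rigid pose is recovered
  world <- pose_world(segs, yaw = 2.1, offset = c(1.5, -0.7, 0))
  bf <- to_body_frame(world)
  sh <- colMeans(bf$positions$shoulder_R) - colMeans(bf$positions$shoulder_L)
  expect_lt(abs(sh[2]), 1e-9)                    # no front-back component
  expect_gt(sh[1], 0)                            # right shoulder on +x
  expect_equal(colMeans(bf$positions$pelvis), c(0, 0, 0), tolerance = 1e-9)
  # idempotence: applying the transform to an aligned posture changes nothing
  bf2 <- to_body_frame(bf$positions)
  for (s in names(bf$positions))
    expect_equal(bf2$positions[[s]], bf$positions[[s]], tolerance = 1e-9)
})

test_that("90-degree yaw is recovered and velocities rotate without translation", {
  segs <- reference_posture()
  vel <- list(hand_L = matrix(1, nrow(segs$hand_L), 3))
  world <- pose_world(segs, yaw = pi / 2, offset = c(0, 0, 0))
  bf <- to_body_frame(world, velocities = lapply(vel, function(m) m %*%
    t(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3))))
  # the back-rotation restores the original constant velocity exactly
  expect_equal(bf$velocities$hand_L,
               matrix(1, nrow(vel$hand_L), 3), tolerance = 1e-9)
})

test_that("degenerate shoulder geometry is rejected", {
  segs <- reference_posture()
  segs$shoulder_R <- segs$shoulder_L
  expect_error(to_body_frame(segs), "degenerate")
})

test_that("dominant hand selection matches brute-force kinetic energy", {
  # constant speeds 2 vs 1: left wins with ratio 4
  lv <- matrix(c(2, 0, 0), 50, 3, byrow = TRUE)
  rv <- matrix(c(0, 1, 0), 50, 3, byrow = TRUE)
  sel <- select_dominant_hand(lv, rv)
  expect_equal(sel$side, "left")
  expect_equal(sel$energy_ratio, 4)
  # exact tie goes left with a warning
  expect_warning(tie <- select_dominant_hand(lv, lv), "tie")
  expect_equal(tie$side, "left")
  expect_equal(tie$energy_ratio, 1)
  # random series agree with the loop-based oracle
  set.seed(41)
  for (rep in 1:5) {
    a <- matrix(rnorm(60), 20, 3); b <- matrix(rnorm(60), 20, 3)
    sel <- select_dominant_hand(a, b)
    keA <- ke_bruteforce(a); keB <- ke_bruteforce(b)
    expect_equal(sel$side, if (keA >= keB) "left" else "right")
    expect_equal(sel$energy_ratio, max(keA, keB) / min(keA, keB))
  }
})

test_that("mirroring negates x for right-dominant motifs and is an involution", {
  set.seed(51)
  mk <- function(side) {
    m <- function() matrix(rnorm(30), 10, 3)
    kinematic_features(m(), m(), m(), m(), m(), m(), rate = 60,
                       dominant_side = side, mirrored = side == "right",
                       energy_ratio = 2)
  }
  left <- mk("left")
  expect_identical(mirror_x(left), left)               # left: identity
  right <- mk("right")                                  # flagged mirrored
  twice <- mirror_x(mirror_x(right))
  for (f in kinematic_feature_names())
    expect_equal(twice[[f]], right[[f]])
  once <- mirror_x(right)
  for (f in kinematic_feature_names()) {
    expect_equal(once[[f]][, 1], -right[[f]][, 1])
    expect_equal(once[[f]][, 2:3], right[[f]][, 2:3])
  }
})

test_that("speed and acceleration norms are invariant under frame + mirror", {
  set.seed(61)
  segs <- reference_posture()
  world <- pose_world(segs, yaw = -1.2, offset = c(0.3, 0.4, 0))
  feats <- extract_kinematic_features(world, rate = 60)
  segs_al <- to_body_frame(world)$positions
  feats_al <- extract_kinematic_features(segs_al, rate = 60)
  expect_equal(sqrt(rowSums(feats$hand_vel^2)),
               sqrt(rowSums(feats_al$hand_vel^2)), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(feats$head_acc^2)),
               sqrt(rowSums(feats_al$head_acc^2)), tolerance = 1e-9)
})

test_that("finite differences recover linear and quadratic motion", {
  rate <- 60
  t <- (0:99) / rate
  lin <- cbind(2 * t, -1 * t, 0.5 * t)
  dk <- derive_kinematics(lin, rate)
  expect_equal(dk$velocity[5:95, ], lin[5:95, ] / t[5:95], tolerance = 1e-9)
  expect_true(all(abs(dk$acceleration[3:97, ]) < 1e-8))
  quad <- cbind(0.5 * 3 * t^2, numeric(100), numeric(100))
  dk2 <- derive_kinematics(quad, rate)
  expect_equal(dk2$acceleration[3:97, 1], rep(3, 95), tolerance = 1e-6)
  # sampled sinusoid derivative matches the analytic cosine to O(dt^2)
  s <- cbind(sin(2 * pi * t), numeric(100), numeric(100))
  dk3 <- derive_kinematics(s, rate)
  expect_lt(max(abs(dk3$velocity[2:99, 1] - 2 * pi * cos(2 * pi * t[2:99]))),
            (2 * pi)^3 / 6 * (1 / rate)^2 * 1.1)
  expect_error(derive_kinematics(lin[1:2, ], rate), "at least 3")
})

test_that("the conditioning chain is deterministic and idempotent in effect", {
  set.seed(71)
  world <- pose_world(reference_posture(60), yaw = 0.8, offset = c(2, 1, 0))
  f1 <- extract_kinematic_features(world, rate = 60)
  f2 <- extract_kinematic_features(world, rate = 60)
  expect_identical(f1, f2)
  expect_s3_class(f1, "kinematic_features")
  expect_gte(f1$energy_ratio, 1)
})
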