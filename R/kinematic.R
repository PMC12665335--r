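#' Kinematic feature bundle for one motif
#'
#' The six conditioned per-motif kinematic series in the body-centric
#' frame: 3D position, velocity and acceleration of the dominant hand and
#' of the head, all on one uniform time base.
#'
#' @param hand_pos,head_pos,hand_vel,head_vel,hand_acc,head_acc n x 3
#'   numeric matrices (columns x, y, z).
#' @param rate Frame rate in Hz (60 for the tracker used here).
#' @param dominant_side `"left"` or `"right"`: the hand with the larger
#'   kinetic energy over the motif.
#' @param mirrored `TRUE` iff the mediolateral (x) axis was negated to map a
#'   right-dominant motif into the common left-hand space.
#' @param energy_ratio Dominant / nondominant hand kinetic energy, >= 1.
#' @return An object of class `kinematic_features`.
#' @export
kinematic_features <- function(hand_pos, head_pos, hand_vel, head_vel,
                               hand_acc, head_acc, rate = 60,
                               dominant_side = "left", mirrored = FALSE,
                               energy_ratio = 1) {
  series <- list(hand_pos = hand_pos, head_pos = head_pos,
                 hand_vel = hand_vel, head_vel = head_vel,
                 hand_acc = hand_acc, head_acc = head_acc)
  series <- lapply(series, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3L) stopf("kinematic series must have 3 columns (x, y, z)")
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y", "z")
    m
  })
  n <- nrow(series[[1L]])
  if (!all(vapply(series, nrow, 1L) == n))
    stopf("all six kinematic series must share one time base")
  dominant_side <- match.arg(dominant_side, c("left", "right"))
  if (dominant_side == "right" && !isTRUE(mirrored))
    stopf("right-dominant motifs must be mirrored into left-hand space")
  if (energy_ratio < 1) stopf("energy_ratio must be >= 1, got %g", energy_ratio)
  structure(c(series, list(rate = rate, dominant_side = dominant_side,
                           mirrored = isTRUE(mirrored),
                           energy_ratio = energy_ratio)),
            class = "kinematic_features")
}

#' @export
print.kinematic_features <- function(x, ...) {
  cat(sprintf("<kinematic_features> %d frames @ %g Hz, %s-dominant (KE ratio %.2f)%s\n",
              nrow(x$hand_pos), x$rate, x$dominant_side, x$energy_ratio,
              if (x$mirrored) ", mirrored" else ""))
  invisible(x)
}

#' Savitzky-Golay smoothing of a (multi-channel) series
#'
#' Second-order Savitzky-Golay filtering applied per column: each sample is
#' replaced by the value of a local least-squares polynomial fit, which
#' suppresses tracker jitter while leaving movements at gestural time
#' scales intact. The window is `window_s` seconds converted to the nearest
#' odd sample count (125 ms at 60 Hz gives 7 samples). Polynomials of
#' degree <= `order` are reproduced exactly.
#'
#' @param x Numeric vector or matrix (time in rows).
#' @param rate Sampling rate (Hz).
#' @param window_s Window length in seconds (default 0.125).
#' @param order Polynomial order (default 2).
#' @return Smoothed series, same shape.
#' @export
smooth_savgol <- function(x, rate, window_s = 0.125, order = 2) {
  m <- as_series_matrix(x)
  wl <- 2L * round((window_s * rate - 1) / 2) + 1L
  wl <- max(wl, order + 1L + (order %% 2L == 0L))  # need wl > order, odd
  if (nrow(m) < wl)
    stopf("smooth_savgol: series length %d shorter than window %d", nrow(m), wl)
  out <- unname(apply(m, 2L, function(col) signal::sgolayfilt(col, p = order, n = wl)))
  if (is.null(dim(x))) as.numeric(out) else out
}

#' Rigid transform into the body-centric frame
#'
#' Computes, from the time-averaged shoulder and pelvis positions over the
#' motif, the yaw rotation (about the vertical z axis) that makes the
#' left-to-right shoulder line parallel to the x axis — the performer faces
#' the front of the stage — and the translation that puts the pelvis
#' centroid at the origin. One static transform per motif is used: a
#' per-frame rotation would distort velocity and acceleration dynamics.
#' Positions get rotation + translation; velocities and accelerations get
#' the rotation only.
#'
#' @param segments Named list of n x 3 position matrices; must include
#'   `shoulder_L`, `shoulder_R`, `pelvis`, and typically `head`, `hand_L`,
#'   `hand_R`.
#' @param velocities,accelerations Optional named lists of n x 3 matrices
#'   to rotate with the same transform.
#' @return List with `positions`, `velocities`, `accelerations` (transformed,
#'   same names as input), `rotation` (3 x 3) and `origin` (length-3).
#' @export
to_body_frame <- function(segments, velocities = NULL, accelerations = NULL) {
  need <- c("shoulder_L", "shoulder_R", "pelvis")
  if (!all(need %in% names(segments)))
    stopf("to_body_frame: segments must include %s", paste(need, collapse = ", "))
  segs <- lapply(segments, as_series_matrix)
  sL <- colMeans(segs$shoulder_L); sR <- colMeans(segs$shoulder_R)
  v <- sR - sL
  if (sqrt(v[1]^2 + v[2]^2) < 1e-9)
    stopf("to_body_frame: degenerate shoulder-to-shoulder vector")
  theta <- atan2(v[2], v[1])               # current yaw of the shoulder line
  ct <- cos(-theta); st <- sin(-theta)
  R <- matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), nrow = 3)  # yaw by -theta
  origin <- colMeans(segs$pelvis)
  tf_pos <- function(m) sweep(as_series_matrix(m), 2L, origin) %*% t(R)
  tf_rot <- function(m) as_series_matrix(m) %*% t(R)
  out <- list(positions = lapply(segs, tf_pos),
              rotation = R, origin = origin)
  if (!is.null(velocities)) out$velocities <- lapply(velocities, tf_rot)
  if (!is.null(accelerations)) out$accelerations <- lapply(accelerations, tf_rot)
  out
}

#' Kinetic-energy dominant hand selection
#'
#' The dominant hand of a motif is the one with the larger kinetic energy
#' `KE = sum_t 1/2 * m * |v_t|^2` over the motif, with the segment mass `m`
#' assumed equal for both sides (so it cancels; `m = 1` is used). Exact
#' ties resolve to the left hand — the common space is left-hand space —
#' with a warning.
#'
#' @param left_vel,right_vel n x 3 velocity matrices (m/s).
#' @return List with `side` (`"left"`/`"right"`), `energy_ratio`
#'   (max KE / min KE, >= 1) and the two energies.
#' @export
select_dominant_hand <- function(left_vel, right_vel) {
  lv <- as_series_matrix(left_vel); rv <- as_series_matrix(right_vel)
  if (nrow(lv) == 0L || nrow(rv) == 0L) stopf("select_dominant_hand: empty series")
  ke <- function(v) 0.5 * sum(v^2)
  keL <- ke(lv); keR <- ke(rv)
  if (keL == keR) {
    warnf("select_dominant_hand: exact kinetic-energy tie; defaulting to left")
    side <- "left"
  } else side <- if (keL > keR) "left" else "right"
  lo <- min(keL, keR)
  ratio <- if (lo > 0) max(keL, keR) / lo else if (max(keL, keR) == 0) 1 else Inf
  list(side = side, energy_ratio = ratio, ke_left = keL, ke_right = keR)
}

#' Mirror a motif into left-hand space
#'
#' Negates the mediolateral (x) components of all six series iff the motif
#' is right-hand dominant, so recurrent-but-mirrored gestures become
#' directly comparable. An involution: mirroring twice restores the input.
#'
#' @param features A [kinematic_features] object (body frame).
#' @return The features, mirrored when `dominant_side == "right"`.
#' @export
mirror_x <- function(features) {
  stopifnot(inherits(features, "kinematic_features"))
  if (features$dominant_side != "right") return(features)
  for (nm in kinematic_feature_names()) features[[nm]][, 1L] <- -features[[nm]][, 1L]
  features$mirrored <- !features$mirrored
  features
}

#' Velocity and acceleration from position by finite differences
#'
#' Central differences at interior samples, one-sided at the ends;
#' acceleration is the same operator applied to the derived velocity. Used
#' for synthetic data and as a fallback when the tracker's native
#' derivative channels are absent.
#'
#' @param pos n x 3 position matrix (n >= 3).
#' @param rate Sampling rate (Hz).
#' @return List with `velocity` and `acceleration` (n x 3).
#' @export
derive_kinematics <- function(pos, rate) {
  p <- as_series_matrix(pos)
  n <- nrow(p)
  if (n < 3L) stopf("derive_kinematics: need at least 3 frames, got %d", n)
  diff_op <- function(m) {
    d <- m
    d[2:(n - 1L), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2L), , drop = FALSE]) * (rate / 2)
    d[1L, ] <- (m[2L, ] - m[1L, ]) * rate
    d[n, ] <- (m[n, ] - m[n - 1L, ]) * rate
    d
  }
  vel <- diff_op(p)
  list(velocity = vel, acceleration = diff_op(vel))
}

#' Full kinematic conditioning chain for one motif
#'
#' Fixed deterministic order: per-series Savitzky-Golay smoothing, rigid
#' body-frame transform (yaw + translation from time-averaged shoulders
#' and pelvis), kinetic-energy dominant-hand selection, and x-mirroring of
#' right-dominant motifs. Velocities/accelerations are taken from the
#' tracker when supplied, otherwise derived from smoothed positions by
#' central differences.
#'
#' @param segments Named list of raw n x 3 position matrices over the motif:
#'   `head`, `hand_L`, `hand_R`, `shoulder_L`, `shoulder_R`, `pelvis`.
#' @param rate Frame rate (Hz), default 60.
#' @param velocities,accelerations Optional named lists (same names) of
#'   tracker-native derivative channels.
#' @param window_s,order Savitzky-Golay settings (see [smooth_savgol()]).
#' @return A [kinematic_features] object.
#' @export
extract_kinematic_features <- function(segments, rate = 60,
                                       velocities = NULL, accelerations = NULL,
                                       window_s = 0.125, order = 2) {
  need <- c("head", "hand_L", "hand_R", "shoulder_L", "shoulder_R", "pelvis")
  if (!all(need %in% names(segments)))
    stopf("extract_kinematic_features: missing segment(s): %s",
          paste(setdiff(need, names(segments)), collapse = ", "))
  sm <- lapply(segments[need], smooth_savgol, rate = rate,
               window_s = window_s, order = order)
  if (is.null(velocities)) {
    der <- lapply(sm[c("head", "hand_L", "hand_R")], derive_kinematics, rate = rate)
    velocities <- lapply(der, `[[`, "velocity")
    accelerations <- lapply(der, `[[`, "acceleration")
  } else {
    velocities <- lapply(velocities, smooth_savgol, rate = rate,
                         window_s = window_s, order = order)
    accelerations <- lapply(accelerations, smooth_savgol, rate = rate,
                            window_s = window_s, order = order)
  }
  bf <- to_body_frame(sm, velocities, accelerations)
  dom <- select_dominant_hand(bf$velocities$hand_L, bf$velocities$hand_R)
  hand <- if (dom$side == "left") "hand_L" else "hand_R"
  feats <- kinematic_features(
    hand_pos = bf$positions[[hand]], head_pos = bf$positions$head,
    hand_vel = bf$velocities[[hand]], head_vel = bf$velocities$head,
    hand_acc = bf$accelerations[[hand]], head_acc = bf$accelerations$head,
    rate = rate, dominant_side = dom$side,
    mirrored = dom$side == "right", energy_ratio = dom$energy_ratio)
  if (dom$side == "right") {
    # constructor requires mirrored = TRUE for right dominance; apply the
    # actual sign flip now (constructor flag + involution bookkeeping)
    feats$mirrored <- FALSE
    feats <- mirror_x(feats)
  }
  feats
}
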