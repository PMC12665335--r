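#' Configuration for the synthetic multimodal motif generator
#'
#' Describes a synthetic population of vocal motifs with known latent
#' melodic classes and a tunable coupling `coupling` (lambda) between the
#' sonic trajectories and the co-occurring gesture trajectories. At
#' `coupling = 1` (and vanishing noise/warp) a performer's gestures are a
#' deterministic map of the melodic class; at `coupling = 0` they are
#' statistically independent smooth movements.
#'
#' @param n_performers Number of pseudo-performers (one performance each).
#' @param motifs_per_performer Motifs per performer.
#' @param n_classes Number of latent melodic classes.
#' @param coupling Gesture-vocal coupling strength lambda in [0, 1].
#' @param sonic_noise_sd Additive noise SD on the standardised latent scale
#'   for sonic trajectories.
#' @param kinematic_noise_sd Additive positional noise SD (metres).
#' @param warp_strength Strength (>= 0) of the per-instance monotone time
#'   warp; 0 disables warping.
#' @param duration_range_s Motif duration range (s), minimum >= 1.5.
#' @param sonic_rate_hz Sonic frame rate (default 100).
#' @param kinematic_rate_hz Motion frame rate (default 60).
#' @param hand_dominance_ratio Dominant : nondominant hand kinetic-energy
#'   ratio (> 1).
#' @param p_left Probability a performer is left-dominant (default 0.89,
#'   the proportion observed in concert recordings of this style).
#' @param seed Integer seed; the full dataset is reproducible from it, and
#'   `coupling` enters only in the final deterministic mixing step, so runs
#'   that differ only in `coupling` share every random draw.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_performers = 3, motifs_per_performer = 40,
                         n_classes = 5, coupling = 0.8,
                         sonic_noise_sd = 0.05, kinematic_noise_sd = 0.005,
                         warp_strength = 0.3, duration_range_s = c(1.5, 3),
                         sonic_rate_hz = 100, kinematic_rate_hz = 60,
                         hand_dominance_ratio = 4, p_left = 0.89,
                         seed = 1L) {
  if (!is.numeric(coupling) || length(coupling) != 1L || coupling < 0 || coupling > 1)
    stopf("coupling must be a scalar in [0, 1], got %s", format(coupling))
  if (length(duration_range_s) != 2L || duration_range_s[1] < 1.5 ||
      diff(duration_range_s) < 0)
    stopf("duration_range_s must be (min, max) with min >= 1.5 s")
  if (sonic_rate_hz <= 0 || kinematic_rate_hz <= 0) stopf("rates must be > 0")
  if (sonic_noise_sd < 0 || kinematic_noise_sd < 0) stopf("noise SDs must be >= 0")
  if (warp_strength < 0) stopf("warp_strength must be >= 0")
  if (hand_dominance_ratio <= 1) stopf("hand_dominance_ratio must be > 1")
  stopifnot(n_performers >= 1, motifs_per_performer >= 1, n_classes >= 1)
  structure(list(n_performers = as.integer(n_performers),
                 motifs_per_performer = as.integer(motifs_per_performer),
                 n_classes = as.integer(n_classes), coupling = coupling,
                 sonic_noise_sd = sonic_noise_sd,
                 kinematic_noise_sd = kinematic_noise_sd,
                 warp_strength = warp_strength,
                 duration_range_s = as.numeric(duration_range_s),
                 sonic_rate_hz = sonic_rate_hz,
                 kinematic_rate_hz = kinematic_rate_hz,
                 hand_dominance_ratio = hand_dominance_ratio,
                 p_left = p_left, seed = as.integer(seed)),
            class = "synth_config")
}

# Smoothed standardised Gaussian random walk on a length-n grid; sigma in
# samples sets the smoothness (0.5-2 Hz movement at gestural time scales).
smooth_walk <- function(n, sigma) {
  z <- smooth_gaussian(cumsum(rnorm(n)), sigma)
  s <- sd(z)
  if (s < 1e-12) return(numeric(n))
  (z - mean(z)) / s
}

# Monotone random diffeomorphism of [0, 1] with bounded derivative:
# normalised cumulative integral of exp(strength * smooth noise).
random_warp <- function(n_grid, strength) {
  g <- exp(pmax(pmin(strength * smooth_walk(n_grid, sigma = n_grid / 10), 3), -3))
  w <- cumsum(g)
  (w - w[1L]) / (w[n_grid] - w[1L])
}

# Sample a latent curve (defined on grid u in [0,1]) at warped positions.
sample_latent <- function(curve, u_grid, u_query) {
  approx(u_grid, curve, xout = u_query, rule = 2)$y
}

#' Generate a synthetic multimodal motif dataset
#'
#' Each latent melodic class carries a smooth latent curve `z(u)` (a
#' smoothed Gaussian random walk) with derivative curves `z'` and `z''`.
#' A motif of class c realises, on its own warped time base:
#' \itemize{
#'   \item sonic trajectories as fixed affine maps of `(z, z')` — f0 in Hz,
#'     loudness in dB re the motif maximum, spectral centroid in Hz — plus
#'     latent-scale noise, Gaussian-smoothed, with delta-f0 derived by the
#'     package's own estimated-derivative operator;
#'   \item gesture trajectories as the mix
#'     `lambda * B_pf [z; z'; z''] + (1 - lambda) * independent smooth 3D curve`,
#'     where `B_pf` is a fixed random linear map per (performer, limb), so
#'     performers couple through different dimensions; velocity and
#'     acceleration follow by central differences;
#'   \item a nondominant hand carrying `1 / hand_dominance_ratio` of the
#'     dominant hand's kinetic energy, and near-static shoulders/pelvis;
#'     the whole skeleton is posed with a random per-performance yaw and
#'     offset, which the body-frame transform later removes.
#' }
#' The raw skeleton tracks are passed through the package's full kinematic
#' conditioning chain, so generated features exercise the same code path as
#' ingested recordings.
#'
#' @param config A [synth_config()].
#' @param keep_raw Keep the raw world-frame skeleton tracks per motif
#'   (needed to write tracker-layout CSVs); default `FALSE`.
#' @return An object of class `synth_dataset`: list with `motif_table`,
#'   `sonic` (named list of [sonic_features]), `kinematic` (named list of
#'   [kinematic_features]), `class_labels` (named integer vector) and
#'   `config`.
#' @export
generate_dataset <- function(config = synth_config(), keep_raw = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  with_rng(config$seed, generate_dataset_impl(config, keep_raw))
}

generate_dataset_impl <- function(cfg, keep_raw) {
  n_grid <- 240L
  u_grid <- seq(0, 1, length.out = n_grid)
  lambda <- cfg$coupling

  # latent class curves and their derivative curves (standardised)
  classes <- lapply(seq_len(cfg$n_classes), function(c) {
    z <- smooth_walk(n_grid, sigma = 18)
    z1 <- delta_f0(z); z1 <- if (sd(z1) > 1e-12) (z1 - mean(z1)) / sd(z1) else z1
    z2 <- delta_f0(z1); z2 <- if (sd(z2) > 1e-12) (z2 - mean(z2)) / sd(z2) else z2
    list(z = z, z1 = z1, z2 = z2)
  })

  # per (performer, limb) coupling maps; hand loads the latent level, head
  # its derivatives, so the two limbs carry partly distinct information
  maps <- lapply(seq_len(cfg$n_performers), function(p) {
    mk <- function(w) {
      B <- matrix(rnorm(9), 3, 3)
      B <- sweep(B, 2L, sqrt(colSums(B^2)), "/")
      sweep(B, 2L, w, "*") * 0.15                     # ~0.15 m amplitude
    }
    list(hand = mk(c(1, 0.4, 0.15)), head = mk(c(0.45, 1, 0.3)))
  })
  sides <- ifelse(runif(cfg$n_performers) < cfg$p_left, "left", "right")
  yaws <- runif(cfg$n_performers, -pi, pi)
  offsets <- cbind(runif(cfg$n_performers, -1, 1),
                   runif(cfg$n_performers, -1, 1), 0)

  n_motif <- cfg$n_performers * cfg$motifs_per_performer
  motif_id <- sprintf("m%03d", seq_len(n_motif))
  performer <- rep(sprintf("P%d", seq_len(cfg$n_performers)),
                   each = cfg$motifs_per_performer)
  cls <- sample(seq_len(cfg$n_classes), n_motif, replace = TRUE)
  dur <- runif(n_motif, cfg$duration_range_s[1], cfg$duration_range_s[2])

  sonic <- vector("list", n_motif); names(sonic) <- motif_id
  kinem <- vector("list", n_motif); names(kinem) <- motif_id
  raw <- if (keep_raw) vector("list", n_motif) else NULL
  if (keep_raw) names(raw) <- motif_id
  start_s <- numeric(n_motif); end_s <- numeric(n_motif)
  t_cursor <- stats::setNames(rep(0.5, cfg$n_performers),
                              sprintf("P%d", seq_len(cfg$n_performers)))

  for (i in seq_len(n_motif)) {
    p <- match(performer[i], sprintf("P%d", seq_len(cfg$n_performers)))
    cl <- classes[[cls[i]]]
    ns <- max(4L, round(dur[i] * cfg$sonic_rate_hz))
    nk <- max(4L, round(dur[i] * cfg$kinematic_rate_hz))
    warp <- random_warp(n_grid, cfg$warp_strength)
    us <- sample_latent(warp, u_grid, seq(0, 1, length.out = ns))
    uk <- sample_latent(warp, u_grid, seq(0, 1, length.out = nk))

    # ---- sonic: affine maps of the warped latent + noise, then smoothing
    zs <- sample_latent(cl$z, u_grid, us)
    z1s <- sample_latent(cl$z1, u_grid, us)
    nz <- function() rnorm(ns, 0, cfg$sonic_noise_sd)
    f0_raw <- 220 + 60 * (zs + nz())
    loud_raw <- 6 * (0.7 * zs + 0.3 * z1s + nz())
    cen_raw <- 1500 + 300 * (0.5 * zs + 0.5 * z1s + nz())
    f0 <- smooth_gaussian(pmax(f0_raw, 60), 2.5)
    loud <- smooth_gaussian(loud_raw, 2.5); loud <- loud - max(loud)
    cen <- pmax(smooth_gaussian(cen_raw, 2.5), 0)
    sonic[[i]] <- sonic_features(f0 = f0, delta_f0 = delta_f0(f0),
                                 loudness = loud, centroid = cen,
                                 rate = cfg$sonic_rate_hz, ok = TRUE)

    # ---- kinematics: coupled + independent mixture, posed in world frame
    Zk <- cbind(sample_latent(cl$z, u_grid, uk),
                sample_latent(cl$z1, u_grid, uk),
                sample_latent(cl$z2, u_grid, uk))
    indep <- function() 0.15 * cbind(smooth_walk(nk, 12), smooth_walk(nk, 12),
                                     smooth_walk(nk, 12))
    pos_noise <- function() matrix(rnorm(3L * nk, 0, cfg$kinematic_noise_sd), nk, 3L)
    hand_traj <- lambda * (Zk %*% t(maps[[p]]$hand)) + (1 - lambda) * indep() + pos_noise()
    head_traj <- lambda * (Zk %*% t(maps[[p]]$head)) + (1 - lambda) * indep() + pos_noise()

    dom_center <- c(if (sides[p] == "left") -0.35 else 0.35, 0.25, 0.45)
    nd_center <- c(-dom_center[1], 0.25, 0.45)
    scale_nd <- 1 / sqrt(cfg$hand_dominance_ratio)
    dom_hand <- sweep(hand_traj, 2L, dom_center, "+")
    nd_hand <- sweep(scale_nd * hand_traj, 2L, nd_center, "+")
    head_seg <- sweep(head_traj, 2L, c(0, 0.1, 0.75), "+")
    static <- function(center) sweep(pos_noise(), 2L, center, "+")
    segs_body <- list(head = head_seg,
                      hand_L = if (sides[p] == "left") dom_hand else nd_hand,
                      hand_R = if (sides[p] == "right") dom_hand else nd_hand,
                      shoulder_L = static(c(-0.18, 0, 0.55)),
                      shoulder_R = static(c(0.18, 0, 0.55)),
                      pelvis = static(c(0, 0, 0)))
    # pose into the world frame: yaw + horizontal offset per performance
    cy <- cos(yaws[p]); sy <- sin(yaws[p])
    Rw <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3)
    segs_world <- lapply(segs_body, function(m)
      sweep(m %*% t(Rw), 2L, offsets[p, ], "+"))
    kinem[[i]] <- extract_kinematic_features(segs_world,
                                             rate = cfg$kinematic_rate_hz)
    if (keep_raw) raw[[i]] <- segs_world

    start_s[i] <- t_cursor[performer[i]]
    end_s[i] <- start_s[i] + nk / cfg$kinematic_rate_hz
    t_cursor[performer[i]] <- end_s[i] + 0.5
  }

  motif_table <- data.frame(motif_id = motif_id,
                            performance_id = performer,
                            performer_id = performer,
                            raga_id = NA_character_,
                            start_s = start_s, end_s = end_s,
                            stringsAsFactors = FALSE)
  structure(list(motif_table = motif_table, sonic = sonic, kinematic = kinem,
                 class_labels = stats::setNames(cls, motif_id),
                 dominant_sides = stats::setNames(sides,
                   sprintf("P%d", seq_len(cfg$n_performers))),
                 raw = raw, config = cfg),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<synth_dataset> %d motifs (%d performers x %d), ",
                     "%d latent classes, coupling lambda = %g, seed %d\n"),
              nrow(x$motif_table), cfg$n_performers, cfg$motifs_per_performer,
              cfg$n_classes, cfg$coupling, cfg$seed))
  invisible(x)
}

#' Synthesize a harmonic vocal-like tone from an f0 contour
#'
#' Renders a phase-continuous harmonic complex (five harmonics with
#' geometrically decaying amplitudes) following the given f0 contour, with
#' the given amplitude envelope; unvoiced frames (`NA` or non-positive f0)
#' are rendered as silence. Intended as ground truth for testing the sonic
#' feature extractors.
#'
#' @param f0_contour Frame-rate f0 series in Hz (`NA`/0 = unvoiced).
#' @param amp_envelope Frame-rate amplitude envelope in [0, 1]; recycled if
#'   scalar.
#' @param sample_rate Output audio rate (Hz).
#' @param frame_rate Rate of the contour/envelope series (Hz), default 100.
#' @param n_harmonics,rolloff Number of harmonics and per-harmonic amplitude
#'   decay factor.
#' @return Numeric waveform in [-1, 1].
#' @export
synthesize_audio <- function(f0_contour, amp_envelope = 1, sample_rate = 48000,
                             frame_rate = 100, n_harmonics = 5, rolloff = 0.6) {
  f0 <- as.numeric(f0_contour)
  if (length(f0) == 0L) stopf("synthesize_audio: empty f0 contour")
  env <- rep_len(as.numeric(amp_envelope), length(f0))
  if (any(env < 0 | env > 1, na.rm = TRUE))
    stopf("synthesize_audio: envelope must lie in [0, 1]")
  n <- round(length(f0) * sample_rate / frame_rate)
  tf <- (seq_len(length(f0)) - 1) / frame_rate
  ts <- (seq_len(n) - 1) / sample_rate
  voiced_f <- !is.na(f0) & f0 > 0
  f0_fill <- f0; f0_fill[!voiced_f] <- 0
  f_s <- approx(tf, f0_fill, xout = ts, rule = 2)$y
  env_s <- approx(tf, env, xout = ts, rule = 2)$y
  v_s <- approx(tf, as.numeric(voiced_f), xout = ts, method = "constant",
                rule = 2)$y >= 1
  phase <- 2 * pi * cumsum(f_s) / sample_rate
  x <- numeric(n)
  for (h in seq_len(n_harmonics)) x <- x + rolloff^(h - 1) * sin(h * phase)
  x <- x * env_s * as.numeric(v_s)
  peak <- max(abs(x))
  if (peak > 0) x / peak * max(env_s) else x
}
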