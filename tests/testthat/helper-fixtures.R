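# Small shared fixtures, built in code at test time.

# A compact coupled dataset reused across statistical tests (cached per
# session; generation is deterministic in the seed).
small_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_dataset(synth_config(
        n_performers = 3, motifs_per_performer = 12, seed = seed, ...))
    cache[[key]]
  }
})

small_distance_table <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42, ...) {
    key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- build_distance_table(small_dataset(seed, ...))
    cache[[key]]
  }
})

# An aligned reference posture: shoulders parallel to x, pelvis at origin.
reference_posture <- function(n = 30) {
  list(head = cbind(rnorm(n, 0, 0.01), rnorm(n, 0.1, 0.01), rnorm(n, 0.75, 0.01)),
       hand_L = cbind(sin(seq_len(n) / 5) * 0.2 - 0.3, cos(seq_len(n) / 5) * 0.1 + 0.2,
                      rep(0.4, n)),
       hand_R = cbind(rnorm(n, 0.3, 0.02), rnorm(n, 0.2, 0.02), rnorm(n, 0.4, 0.02)),
       shoulder_L = matrix(rep(c(-0.18, 0, 0.55), each = n), ncol = 3),
       shoulder_R = matrix(rep(c(0.18, 0, 0.55), each = n), ncol = 3),
       pelvis = matrix(rep(c(0, 0, 0), each = n), ncol = 3))
}

# Apply a rigid yaw + translation to every segment of a posture.
pose_world <- function(segs, yaw, offset) {
  R <- matrix(c(cos(yaw), sin(yaw), 0, -sin(yaw), cos(yaw), 0, 0, 0, 1), 3)
  lapply(segs, function(m) sweep(m %*% t(R), 2, offset, "+"))
}
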