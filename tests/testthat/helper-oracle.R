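# Brute-force oracles, independent of the package's dynamic-programming DTW.

# Enumerate every admissible warping path by depth-first search and return
# the minimum accumulated cost (and its step count). Shares the geometry
# contract with the implementation (band, margins, steps) but searches the
# path space exhaustively instead of by recurrence. Only viable for short
# series (lengths <= ~8).
dtw_bruteforce <- function(a, b, band_frac = 0.1, open_frac = 0.1,
                           normalize = FALSE) {
  a <- if (is.null(dim(a))) matrix(a, ncol = 1) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, ncol = 1) else as.matrix(b)
  if (nrow(b) > nrow(a)) { tmp <- a; a <- b; b <- tmp }  # same canonicalisation
  n <- nrow(a); m <- nrow(b); L <- max(n, m)
  w <- ceiling(band_frac * L); mo <- ceiling(open_frac * L)
  in_band <- function(i, j) abs(i * m / n - j) <= w
  local_cost <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  is_end <- function(i, j) i >= n - mo && j >= m - mo

  best <- list(cost = Inf, steps = 0L)
  recurse <- function(i, j, acc, steps) {
    acc <- acc + local_cost(i, j)
    steps <- steps + 1L
    if (is_end(i, j) && acc < best$cost)
      best <<- list(cost = acc, steps = steps)
    for (step in list(c(1L, 1L), c(1L, 0L), c(0L, 1L))) {
      i2 <- i + step[1L]; j2 <- j + step[2L]
      if (i2 <= n && j2 <= m && in_band(i2, j2)) recurse(i2, j2, acc, steps)
    }
  }
  for (i0 in 1:min(mo + 1L, n)) for (j0 in 1:min(mo + 1L, m))
    if (in_band(i0, j0)) recurse(i0, j0, 0, 0L)
  if (!is.finite(best$cost)) return(NA_real_)
  if (normalize) best$cost / best$steps else best$cost
}

# Textbook full-endpoint DTW (no band, no open ends) as a second independent
# reference, written as the classic O(nm) recurrence over a full matrix.
dtw_textbook <- function(a, b) {
  a <- if (is.null(dim(a))) matrix(a, ncol = 1) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, ncol = 1) else as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in 1:n) for (j in 1:m) {
    cost <- sqrt(sum((a[i, ] - b[j, ])^2))
    D[i + 1, j + 1] <- cost + min(D[i, j], D[i, j + 1], D[i + 1, j])
  }
  D[n + 1, m + 1]
}

# Loop-based kinetic energy, the independent check for dominant-hand selection.
ke_bruteforce <- function(vel) {
  total <- 0
  for (t in seq_len(nrow(vel))) total <- total + 0.5 * sum(vel[t, ]^2)
  total
}
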