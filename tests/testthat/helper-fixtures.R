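# Shared fixtures, all generated in code.

# Bright disk on a dark background; the standard edge/frequency fixture.
disk_image <- function(size = 128, radius = 30, fg = 200, bg = 40) {
  ctr <- (size + 1) / 2
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
  m <- matrix(bg, size, size)
  m[d2 <= radius^2] <- fg
  m
}

disk_mask <- function(size = 128, radius = 30) {
  ctr <- (size + 1) / 2
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, `+`)
  matrix(as.integer(d2 <= radius^2), size, size)
}

random_mask <- function(nr = 32, nc = 32, p = 0.5) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}

# Brute-force P/R/F by explicit pixel iteration (independent of the
# vectorised implementation).
prf_oracle <- function(pred, truth) {
  tp <- np <- nt <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1L) np <- np + 1L
    if (truth[i] == 1L) nt <- nt + 1L
    if (pred[i] == 1L && truth[i] == 1L) tp <- tp + 1L
  }
  p <- if (np == 0L) 0 else tp / np
  r <- if (nt == 0L) 0 else tp / nt
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(p = p, r = r, f = f)
}

# A small constant-colour RGB scene for plumbing tests.
flat_rgb <- function(nr, nc, rgb) {
  a <- array(0, c(nr, nc, 3))
  for (ch in 1:3) a[, , ch] <- rgb[ch]
  raster_image(a, "RGB8")
}
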