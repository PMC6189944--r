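# Independent oracles used across the suite.  These deliberately use the
# slowest, most literal formulations (double loops, direct rotation) so
# they stay independent of the package's vectorized implementations.

# image moments by naive double loop over all pixels
naive_moments <- function(mask) {
  m <- c(m00 = 0, m10 = 0, m01 = 0, m11 = 0, m20 = 0, m02 = 0)
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] == 1) {
        x <- j - 1; y <- i - 1
        m <- m + c(1, x, y, x * y, x * x, y * y)
      }
    }
  }
  m
}

# ellipse membership by explicit rotate-then-scale of the test point
naive_inside <- function(roi, x, y) {
  px <- x - roi$cx; py <- y - roi$cy
  rx <- px * cos(-roi$angle) - py * sin(-roi$angle)
  ry <- px * sin(-roi$angle) + py * cos(-roi$angle)
  (rx / roi$a)^2 + (ry / roi$b)^2 <= 1 + 1e-9
}

# random sparse binary mask
random_mask <- function(h, w, p = 0.2) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# binary mask of a filled rotated ellipse (pixel-centre membership)
ellipse_mask <- function(h, w, cx, cy, a, b, angle) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  u <- (xs - cx) * cos(angle) + (ys - cy) * sin(angle)
  v <- -(xs - cx) * sin(angle) + (ys - cy) * cos(angle)
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), h, w)
}

# smallest angular difference between two undirected axes (radians)
axis_diff <- function(p1, p2) {
  d <- abs(p1 - p2) %% pi
  min(d, pi - d)
}
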