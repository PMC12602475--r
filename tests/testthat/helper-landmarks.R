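# Canonical right-knee landmark fixture: axis-aligned so the expected
# frames are the identity triad, making hand-derived expectations exact.
canonical_landmarks <- function(side = "right") {
  m <- if (side == "left") -1 else 1
  landmark_set(list(
    Lepi = c(m * 42, 0, 6),
    Mepi = c(-m * 42, 0, 6),
    Mppc = c(-m * 22, -27, -6),
    Lppc = c(m * 22, -27, -6),
    Chip = c(0, 0, 420),
    Ofem = c(0, 0, 0),
    Mctc = c(-m * 22, 0, -2),
    Lctc = c(m * 22, 0, -2),
    Cank = c(0, 0, -360),
    Otib = c(0, 0, 0)
  ), side = side)
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rot_axis <- kneesim:::rot_axis
  rot_axis(ax, stats::runif(1, -pi, pi))
}

rotate_landmarks <- function(lm, R, shift = c(0, 0, 0)) {
  pts <- lapply(lm$points, function(p) as.numeric(R %*% p) + shift)
  landmark_set(pts, side = lm$side)
}
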