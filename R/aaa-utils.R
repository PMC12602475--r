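# Small 3-vector helpers used throughout.  All positions are mm, all
# internal angles radians; degrees appear only at file/user boundaries.

v3 <- function(x, y = NULL, z = NULL) {
  if (is.null(y)) {
    x <- as.numeric(x)
    stopifnot(length(x) == 3L)
    return(x)
  }
  c(as.numeric(x), as.numeric(y), as.numeric(z))
}

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (!is.finite(n) || n < tol)
    stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Elementary rotation matrices (right-handed, column-vector convention).
rot_x <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3L, 3L)
}
rot_y <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3L, 3L)
}
rot_z <- function(t) {
  c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3L, 3L)
}

# Rotation about an arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, t) {
  a <- vunit(axis)
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
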