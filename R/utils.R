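# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-300) stop("cannot normalize zero-length ", what, call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle at the origin between two nonzero 3-vectors, in [0, pi].
vec_angle <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na < 1e-300 || nb < 1e-300) stop("zero-length ray in angle computation", call. = FALSE)
  acos(max(-1, min(1, sum(a * b) / (na * nb))))
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || anyNA(p)) stop(what, " must be a numeric 3-vector", call. = FALSE)
  p
}

as_points_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3L)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stop("points must have 3 columns", call. = FALSE)
  p
}

# Deterministic 31-ary rolling checksum mod (2^31 - 1) over a character
# string. Not cryptographic; used for config provenance and to detect
# accidental edits of the bundled catalog.
acu_checksum <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(utf8ToInt(x))
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%010d", h)
}
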