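# Internal helpers: conditions, small vector algebra, seeded evaluation.

stopSchema <- function(msg, call. = FALSE) {
  stop(structure(class = c("pianoSign_schema_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stopGeometry <- function(msg) {
  stop(structure(class = c("pianoSign_geometry_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stopStats <- function(msg) {
  stop(structure(class = c("pianoSign_stats_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12)
    stopGeometry("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## Rotation by `deg` degrees about unit axis (Rodrigues).
rotationAbout <- function(axis, deg) {
  u <- normalize(axis)
  th <- deg2rad(deg)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

isRotationMatrix <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3L))) < tol && abs(det(R) - 1) < tol
}

## Evaluate expr with a temporary RNG seed; restores the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Truncated-normal draw by rejection; bounds are hard anatomical limits.
rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

## FNV-1a hash of a character scalar, hex string; used to stamp outputs with
## the configuration they were produced under.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply, split to stay inside exact double arithmetic
    hLo <- h %% 65536
    hHi <- (h - hLo) / 65536
    h <- (hLo * m + ((hHi * m) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
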