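# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. All seeded package entry points funnel through this so
# they are pure functions of their seed.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Angle in degrees between two vectors.
angleDeg <- function(u, v) {
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cs))) * 180 / pi
}

# Rotate unit vector v by `deg` degrees in a random direction, rejecting
# directions that would make a component negative (absorbance must stay
# non-negative); falls back to clamping if no admissible direction is found.
rotateStainVector <- function(v, deg) {
  v <- v / sqrt(sum(v^2))
  a <- deg * pi / 180
  for (i in seq_len(60)) {
    u <- rnorm(3)
    u <- u - sum(u * v) * v
    n <- sqrt(sum(u^2))
    if (n < 1e-8) next
    u <- u / n
    w <- cos(a) * v + sin(a) * u
    if (all(w >= 0)) return(w)
  }
  w <- pmax(cos(a) * v + sin(a) * u, 0)
  w / sqrt(sum(w^2))
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# Bilinear upsampling of a coarse grid to n x n (used for smooth textures).
upsampleGrid <- function(g, n) {
  m <- nrow(g)
  pos <- (seq_len(n) - 0.5) / n * (m - 1) + 1
  i0 <- pmin(floor(pos), m - 1); f <- pos - i0
  rows <- g[i0, , drop = FALSE] * (1 - f) + g[i0 + 1, , drop = FALSE] * f
  t(t(rows[, i0, drop = FALSE]) * (1 - f) +
      t(rows[, i0 + 1, drop = FALSE]) * f)
}
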