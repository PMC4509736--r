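# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. With seed = NULL the global stream is used
# as-is (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive n independent substream seeds from one master seed. Used so that the
# stages of a detector chain (or the frames of a run) consume decoupled
# streams: changing the draw count in one stage does not shift the others.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Bilinear interpolation of V (length(xg) x length(yg), uniform ascending
# grids) at points (x, y). x beyond max(xg) yields `outside`; y is clamped
# by the caller (see psf_lookup for the domain contract).
bilinear <- function(xg, yg, V, x, y, outside = 0) {
  nx <- length(xg); ny <- length(yg)
  dx <- xg[2L] - xg[1L]; dy <- yg[2L] - yg[1L]
  fx <- (x - xg[1L]) / dx
  fy <- (y - yg[1L]) / dy
  ix <- pmin(pmax(floor(fx), 0), nx - 2L)
  iy <- pmin(pmax(floor(fy), 0), ny - 2L)
  tx <- pmin(pmax(fx - ix, 0), 1)
  ty <- pmin(pmax(fy - iy, 0), 1)
  i <- ix + 1L; j <- iy + 1L
  v <- (1 - tx) * (1 - ty) * V[cbind(i, j)] +
    tx * (1 - ty) * V[cbind(i + 1L, j)] +
    (1 - tx) * ty * V[cbind(i, j + 1L)] +
    tx * ty * V[cbind(i + 1L, j + 1L)]
  out <- x > xg[nx] + 1e-12
  if (any(out)) v[out] <- outside
  v
}

# Trapezoid weights for a uniform grid.
trap_weights <- function(x) {
  n <- length(x)
  w <- rep(x[2L] - x[1L], n)
  w[c(1L, n)] <- w[1L] / 2
  w
}

stop_arg <- function(...) stop(..., call. = FALSE)
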