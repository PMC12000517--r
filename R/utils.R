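# Internal numerical and RNG helpers.

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenvalue
# method; deterministic and dependency-free. Cached per order.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  if (n == 1L) {
    out <- list(x = 0, w = 2)
  } else {
    i <- seq_len(n - 1L)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- b
    J[cbind(i + 1L, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    out <- list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
  }
  .gl_cache[[key]] <- out
  out
}

# Nodes and weights for panelised Gauss-Legendre over [0, 1] given interior
# panel breakpoints. Returns list(t, w) ready for sum(w * f(t)).
panel_nodes <- function(breaks, order = 8L) {
  gl <- gauss_legendre(order)
  a <- breaks[-length(breaks)]
  b <- breaks[-1L]
  half <- (b - a) / 2
  mid <- (a + b) / 2
  t <- as.vector(outer(gl$x, half) + rep(mid, each = order))
  w <- as.vector(outer(gl$w, half))
  list(t = t, w = w)
}

# sin(x)/x, stable at 0; preserves dim() of the input.
sinc <- function(x) {
  out <- x
  out[] <- 1
  nz <- abs(x) > 1e-8
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# 2 J1(x)/x, the circular cross-section amplitude, stable at 0.
bessel_cs <- function(x) {
  out <- x
  out[] <- 1
  nz <- abs(x) > 1e-6
  out[nz] <- 2 * besselJ(x[nz], 1) / x[nz]
  out
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards (generators stay pure functions of seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Stable 31-adic string hash into [0, 2^31 - 2]; used to fan a single
# pipeline seed out into independent per-stage child seeds.
stable_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + stable_hash(stage)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
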