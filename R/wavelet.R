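#' Orthonormal wavelet filter pairs
#'
#' Returns the scaling (low-pass) and wavelet (high-pass) decomposition
#' filters for the supported families. The Daubechies-4 filter (8 taps, 4
#' vanishing moments) is the package default throughout; Haar is provided
#' mainly as an independently verifiable reference. Filters satisfy the
#' quadrature-mirror relation g[k] = (-1)^k h[L-1-k] and are orthonormal
#' (sum h^2 = 1, even shifts orthogonal).
#'
#' @param wavelet `"db4"` or `"haar"`.
#' @return list with numeric vectors `h` (low-pass) and `g` (high-pass).
#' @export
wt_filters <- function(wavelet = "db4") {
  h <- switch(wavelet,
    db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
            -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
            0.0328830116668852, -0.010597401785069032),
    haar = c(1, 1) / sqrt(2),
    stopf("unsupported wavelet: %s", wavelet)
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  list(h = h, g = g)
}

# One periodized analysis step: x (even length N) -> approximation and detail
# coefficients of length N/2. a[k] = sum_m h[m] x[(2(k-1)+m-1) mod N + 1].
dwt_step <- function(x, h, g) {
  N <- length(x)
  if (N %% 2L != 0L) stopf("periodized DWT step needs an even length, got %d", N)
  K <- N %/% 2L
  base <- 2L * (seq_len(K) - 1L)
  a <- numeric(K)
  d <- numeric(K)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% N + 1L
    xm <- x[idx]
    a <- a + h[m] * xm
    d <- d + g[m] * xm
  }
  list(a = a, d = d)
}

# Adjoint (synthesis) of dwt_step; exact inverse for orthonormal filters.
idwt_step <- function(a, d, h, g) {
  K <- length(a)
  N <- 2L * K
  x <- numeric(N)
  base <- 2L * (seq_len(K) - 1L)
  for (m in seq_along(h)) {
    idx <- (base + (m - 1L)) %% N + 1L
    x[idx] <- x[idx] + h[m] * a + g[m] * d
  }
  x
}

#' Periodized discrete wavelet transform
#'
#' Multi-level periodized (circular-boundary) orthonormal DWT. The transform
#' conserves energy exactly: `sum(a^2) + sum(d^2)` over all levels equals
#' `sum(x^2)`. The input length must be divisible by `2^level`.
#'
#' @param x numeric vector.
#' @param level decomposition depth (>= 1).
#' @param wavelet filter family, see [wt_filters()].
#' @return list with `a` (coarsest approximation) and `d` (list of detail
#'   vectors, finest first), plus the `level` and `wavelet` used.
#' @export
dwt_per <- function(x, level = 4L, wavelet = "db4") {
  if (level < 1L) stopf("`level` must be >= 1")
  if (length(x) %% 2L^level != 0L) {
    stopf("length %d is not divisible by 2^%d", length(x), level)
  }
  f <- wt_filters(wavelet)
  d <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a, f$h, f$g)
    a <- s$a
    d[[j]] <- s$d
  }
  list(a = a, d = d, level = level, wavelet = wavelet)
}

#' Inverse periodized discrete wavelet transform
#' @param w a decomposition from [dwt_per()].
#' @return the reconstructed numeric vector.
#' @export
idwt_per <- function(w) {
  f <- wt_filters(w$wavelet)
  a <- w$a
  for (j in rev(seq_len(w$level))) {
    a <- idwt_step(a, w$d[[j]], f$h, f$g)
  }
  a
}

#' Full wavelet-packet coefficients of a window
#'
#' Recursive periodized wavelet-packet analysis: both the approximation and
#' the detail branch are split at every level, yielding `2^level` leaf nodes
#' whose concatenated coefficients form an orthonormal transform of the input
#' (so total coefficient energy equals signal energy). This is the reference
#' implementation; [wpt_matrix()] precomputes the same linear map for speed.
#'
#' @param x numeric vector whose length is divisible by `2^level`.
#' @param level packet decomposition depth.
#' @param wavelet filter family.
#' @return numeric vector of length `length(x)`: leaf-node coefficients in
#'   natural (filter-bank) order.
#' @export
wpt_coefficients <- function(x, level = 3L, wavelet = "db4") {
  if (length(x) %% 2L^level != 0L) {
    stopf("length %d is not divisible by 2^%d", length(x), level)
  }
  f <- wt_filters(wavelet)
  rec <- function(v, lev) {
    if (lev == 0L) return(v)
    s <- dwt_step(v, f$h, f$g)
    c(rec(s$a, lev - 1L), rec(s$d, lev - 1L))
  }
  rec(x, as.integer(level))
}

#' Wavelet-packet transform matrix
#'
#' The `n x n` orthonormal matrix `W` such that `W %*% x` equals
#' [wpt_coefficients()]`(x)`. Cached per `(n, level, wavelet)` so that batch
#' feature extraction reduces to one matrix product per window set.
#'
#' @param n window length, divisible by `2^level`.
#' @param level packet depth.
#' @param wavelet filter family.
#' @return an `n x n` numeric matrix.
#' @export
wpt_matrix <- function(n, level = 3L, wavelet = "db4") {
  key <- paste(n, level, wavelet, sep = "|")
  if (!is.null(.semgwfm_cache[[key]])) return(.semgwfm_cache[[key]])
  if (n %% 2L^level != 0L) stopf("n = %d is not divisible by 2^%d", n, level)
  f <- wt_filters(wavelet)
  build <- function(m, lev) {
    if (lev == 0L) return(diag(m))
    K <- m %/% 2L
    H <- matrix(0, K, m)
    G <- matrix(0, K, m)
    base <- 2L * (seq_len(K) - 1L)
    for (mm in seq_along(f$h)) {
      idx <- (base + (mm - 1L)) %% m + 1L
      H[cbind(seq_len(K), idx)] <- H[cbind(seq_len(K), idx)] + f$h[mm]
      G[cbind(seq_len(K), idx)] <- G[cbind(seq_len(K), idx)] + f$g[mm]
    }
    sub <- build(K, lev - 1L)
    rbind(sub %*% H, sub %*% G)
  }
  W <- build(as.integer(n), as.integer(level))
  .semgwfm_cache[[key]] <- W
  W
}

#' Wavelet soft-threshold denoising of one channel
#'
#' Periodized DWT, per-channel universal threshold
#' `sigma * sqrt(2 log N)` with `sigma` estimated as `median(|d1|)/0.6745`
#' from the finest detail level, soft thresholding of all detail
#' coefficients, inverse transform. Signals whose length is not divisible by
#' `2^level` are padded by reflection and truncated after reconstruction.
#'
#' @param x numeric vector.
#' @param wavelet filter family.
#' @param level decomposition depth.
#' @return the denoised vector, same length as `x`.
#' @export
wavelet_denoise <- function(x, wavelet = "db4", level = 4L) {
  n <- length(x)
  block <- 2L^level
  pad <- (block - n %% block) %% block
  if (pad > 0L) {
    tail_ref <- rev(x)[seq_len(min(pad, n))]
    tail_ref <- rep_len(tail_ref, pad)
    x <- c(x, tail_ref)
  }
  w <- dwt_per(x, level = level, wavelet = wavelet)
  sigma <- stats::median(abs(w$d[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  soft <- function(v) sign(v) * pmax(abs(v) - thr, 0)
  w$d <- lapply(w$d, soft)
  y <- idwt_per(w)
  y[seq_len(n)]
}
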