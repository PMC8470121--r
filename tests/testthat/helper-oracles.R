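# Independent brute-force oracles, written as plain loops so they share no
# code path with the vectorised implementations they check.

oracle_frame <- function(x, L, I) {
  M <- floor((length(x) - L) / I) + 1
  lapply(seq_len(M), function(i) x[((i - 1) * I + 1):((i - 1) * I + L)])
}

oracle_frame_energy <- function(frames) {
  sapply(frames, function(f) {
    s <- 0
    for (v in f) s <- s + v * v
    s
  })
}

oracle_onset <- function(en, th, run = 4) {
  for (f in seq_len(length(en) - run + 1)) {
    if (all(en[f:(f + run - 1)] > th)) return(f)
  }
  NA_integer_
}

oracle_mav <- function(wins, denom = "printed") {
  vals <- sapply(wins, function(w) {
    n <- length(w)
    d <- if (denom == "printed") n - 1 else n
    sum(abs(w)) / d
  })
  mean(vals)
}

oracle_rms <- function(wins, denom = "printed") {
  vals <- sapply(wins, function(w) {
    n <- length(w)
    d <- if (denom == "printed") n - 1 else n
    sqrt(sum(w^2) / d)
  })
  mean(vals)
}

oracle_wa <- function(wins, th) {
  vals <- sapply(wins, function(w) {
    cnt <- 0
    for (i in seq_len(length(w) - 1)) {
      if (abs(w[i] - w[i + 1]) >= th) cnt <- cnt + 1
    }
    cnt
  })
  mean(vals)
}

# recursive packet energy via the exported reference transform, one window at
# a time (the feature path uses the cached matrix form instead)
oracle_ec1 <- function(wins, level = 3, log_floor = 1e-12) {
  e <- sapply(wins, function(w) sum(wpt_coefficients(w, level)^2))
  log10(max(mean(e), log_floor))
}

# small deterministic multichannel recording for plumbing tests
toy_recording <- function(n = 400, nch = 3, fs = 200, seed = 1) {
  set.seed(seed)
  semg_recording(matrix(rnorm(n * nch), ncol = nch), fs = fs)
}
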