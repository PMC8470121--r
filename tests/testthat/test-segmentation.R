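test_that("frame counts satisfy the sliding-window relation", {
  expect_identical(frame_count(20000, 64, 32), 624L)
  expect_identical(frame_count(64, 64, 32), 1L)
  expect_identical(frame_count(95, 64, 32), 1L)
  expect_error(frame_count(63, 64, 32), "shorter than a frame")
  set.seed(42)
  for (i in 1:200) {
    L <- sample(2:128, 1)
    I <- sample(seq_len(L), 1)
    N <- L + sample(0:5000, 1)
    M <- frame_count(N, L, I)
    expect_true((M - 1) * I + L <= N)
    expect_true(N < M * I + L)
  }
})

test_that("framing and frame energy match brute-force oracles", {
  set.seed(11)
  x <- rnorm(500)
  fr <- frame_signal(x, 64, 32)
  or <- oracle_frame(x, 64, 32)
  expect_equal(ncol(fr), length(or))
  expect_equal(fr[, 5], or[[5]])
  expect_equal(frame_energy(fr), oracle_frame_energy(or), tolerance = 1e-12)
  expect_equal(frame_energy(matrix(rep(2, 64), ncol = 1)), 256)
  expect_equal(frame_energy(matrix(c(1, 2, 3), ncol = 1)), 14)
  expect_equal(frame_energy(matrix(0, 64, 3)), rep(0, 3))
})

test_that("the adaptive threshold is the mean frame energy", {
  expect_equal(adaptive_threshold(c(1, 2, 3)), 2)
  expect_equal(adaptive_threshold(rep(5.5, 10)), 5.5)
  set.seed(3)
  e <- rnorm(1000, 5)
  expect_equal(adaptive_threshold(e), sum(e) / 1000, tolerance = 1e-12)
  expect_error(adaptive_threshold(numeric(0)), "empty")
})

test_that("onset detection finds the first qualifying frame run", {
  expect_identical(detect_onset(c(0, 0, 5, 5, 5, 5, 5), th = 1), 3L)
  expect_identical(detect_onset(c(0, 5, 5, 0, 5, 5, 5, 5), th = 1), 5L)
  expect_error(detect_onset(rep(0.5, 10), th = 1), class = "semgwfm_no_onset")
  expect_identical(detect_onset(c(0, 5, 5, 5, 0, 5), th = 1, run_length = 3), 2L)
  set.seed(21)
  for (i in 1:100) {
    en <- runif(30)
    th <- runif(1)
    got <- tryCatch(detect_onset(en, th), semgwfm_no_onset = function(e) NA_integer_)
    expect_identical(got, oracle_onset(en, th))
  }
})

test_that("the main feature segment is 2 s starting 0.5 s after onset", {
  rec <- semg_recording(matrix(seq_len(20000 * 2) / 1e5, ncol = 2), fs = 2000)
  out <- extract_main_segment(rec, FS = 1)
  expect_identical(out$bounds[c("SN", "MSN", "MEN")],
                   list(SN = 1L, MSN = 1001L, MEN = 5001L))
  expect_equal(n_samples(out$segment), 4000)
  expect_equal(out$segment$data[1, 1], rec$data[1001, 1])
  # boundary: the last frame whose segment fits succeeds, the next one fails
  edge <- extract_main_segment(rec, FS = 469)
  expect_equal(edge$bounds$MEN, 19977)
  expect_error(extract_main_segment(rec, FS = 470),
               class = "semgwfm_short_recording")
  expect_equal(n_samples(edge$segment), 2 * rec$fs)
})

test_that("denoising removes power-line interference and baseline offset", {
  fs <- 2000
  t <- seq_len(20000) / fs
  mains <- semg_recording(matrix(sin(2 * pi * 50 * t), ncol = 1), fs = fs)
  out <- denoise(mains, wavelet = NULL)
  expect_lt(sqrt(mean(out$data^2)) / sqrt(mean(mains$data^2)), 0.05)

  set.seed(8)
  sig <- rnorm(8192, sd = 0.1) + 1.0
  shifted <- denoise(semg_recording(matrix(sig, ncol = 1), fs = fs))
  expect_lt(abs(mean(shifted$data)), 0.01)

  silent <- denoise(semg_recording(matrix(0, 4096, 2), fs = fs))
  expect_equal(max(abs(silent$data)), 0)
  expect_error(denoise(semg_recording(matrix(rnorm(4096), ncol = 1), fs = 15)),
               "too low")
})

test_that("channel-summed onset detection recovers synthetic burst onsets", {
  hits <- 0L
  n_trials <- 40L
  profiles <- default_action_profiles()
  for (s in seq_len(n_trials)) {
    p <- profiles[[(s %% 6) + 1]]
    g <- generate_recording(p, sim_config(duration = 5),
                            seed = 1000 + s)
    ons <- detect_onset_recording(g$recording)
    if (abs((ons$FS - 1) * 32 + 1 - g$true_onset) <= 3 * 32) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.95)
})
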