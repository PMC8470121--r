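test_that("channel energies are absolute-amplitude sums over the region", {
  rec <- semg_recording(cbind(rep(0.5, 100), rep(-0.25, 100)), fs = 100)
  et <- channel_energies(rec)
  expect_equal(unname(et$energies), c(50, 25))
  expect_equal(et$total, 75)
  part <- channel_energies(rec, region = 1:10)
  expect_equal(unname(part$energies), c(5, 2.5))
  expect_error(channel_energies(rec, region = integer(0)), "empty")
  expect_error(channel_energies(rec, region = 50:150), "outside")
  # linearity: scaling one channel scales its energy
  set.seed(41)
  x <- rnorm(200)
  two <- semg_recording(cbind(x, 3 * x), fs = 100)
  e2 <- channel_energies(two)$energies
  expect_equal(unname(e2[2] / e2[1]), 3, tolerance = 1e-12)
})

test_that("channel weights reproduce the reference correlation table", {
  t2 <- table2_fixture()
  t3 <- table3_fixture()
  for (i in 1:6) {
    w <- channel_weights(t2[i, ])
    expect_lt(max(abs(w - t3[i, ])), 5e-4)
    expect_equal(sum(w), 8, tolerance = 1e-9)
  }
  expect_equal(unname(channel_weights(t2["action1", ])[1]), 0.8208,
               tolerance = 5e-5)
  expect_equal(unname(channel_weights(t2["action2", ])[3]), 2.9565,
               tolerance = 5e-5)
  expect_equal(unname(channel_weights(rep(4, 8))), rep(1, 8))
  expect_error(channel_weights(rep(0, 5)), class = "semgwfm_degenerate")
})

test_that("weights conserve their sum and ignore a common energy scale", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    e <- runif(n, 0, 100)
    w <- channel_weights(e)
    expect_equal(sum(w), n, tolerance = 1e-9 * n)
    expect_equal(channel_weights(e * runif(1, 0.01, 100)), w, tolerance = 1e-9)
  }
})

test_that("weighted fusion concatenates or sums scaled channel vectors", {
  f <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  rownames(f) <- c("CH1", "CH2")
  colnames(f) <- c("MAV", "RMS", "WA", "EC1")
  expect_equal(unname(apply_weights(f, c(2, 0.5), mode = "sum")),
               c(2, 0.5, 0, 0))
  cc <- apply_weights(f, c(2, 0.5), mode = "concat")
  expect_length(cc, 8)
  expect_equal(unname(cc), c(2, 0, 0, 0, 0, 0.5, 0, 0))
  expect_identical(names(cc)[1], "CH1_MAV")
  expect_equal(unname(apply_weights(f, c(1, 1), mode = "sum")), colSums(f),
               ignore_attr = TRUE)
  expect_equal(unname(apply_weights(f * 0, c(2, 0.5), mode = "concat")),
               rep(0, 8))
  expect_error(apply_weights(f, c(1, 2, 3)), "weights")
})

test_that("the dominant-gain channel earns the largest weight on synthetic bursts", {
  profiles <- default_action_profiles()
  hits <- 0L
  n_trials <- 24L
  for (s in seq_len(n_trials)) {
    p <- profiles[[(s %% 6) + 1]]
    g <- generate_recording(p, sim_config(duration = 5), seed = 500 + s)
    ons <- detect_onset_recording(g$recording)
    seg <- extract_main_segment(g$recording, ons$FS)
    w <- channel_weights(channel_energies(g$recording,
                                          seg$bounds$MSN:(seg$bounds$MEN - 1)))
    if (which.max(w) == which.max(g$gains_realized)) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("build_dataset assembles aligned fusion rows and reports exclusions", {
  man <- generate_dataset(sim_config(n_per_class = 2, duration = 5),
                          default_action_profiles(), seed = 77)
  ds <- build_dataset(man)
  expect_identical(dim(ds$X), c(12L, 32L))
  expect_identical(as.character(ds$y), manifest_labels(man)[ds$kept])
  expect_identical(nrow(ds$excluded), 0L)
  # identical recordings give identical rows
  rec <- generate_recording(default_action_profiles()[[1]],
                            sim_config(duration = 5), seed = 3, label = "y1")
  twin <- semg_manifest(list(list(label = "y1", recording = rec$recording),
                             list(label = "y1", recording = rec$recording)))
  dt <- build_dataset(twin)
  expect_equal(dt$X[1, ], dt$X[2, ])
  # a flat recording has no onset and is excluded with a reason
  flat <- semg_recording(matrix(0, 4000, 2), fs = 1000)
  mixed <- semg_manifest(list(list(label = "y1", recording = rec$recording),
                              list(label = "y2", recording = flat)))
  dm <- build_dataset(mixed)
  expect_identical(dm$kept, 1L)
  expect_match(dm$excluded$reason, "onset|run")
  sums <- build_dataset(twin, mode = "sum")
  expect_identical(ncol(sums$X), 4L)
})
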