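# small separable 3-class feature problem for fast SVM checks
gauss_problem <- function(n_per_class = 12, sep = 4, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(n_per_class * 2, sd = 0.5), ncol = 2), 2,
          centers[k, ], `+`)
  }))
  list(X = X, y = factor(rep(paste0("y", 1:3), each = n_per_class)))
}

test_that("config invariants are enforced", {
  expect_error(ga_config(pop_size = 4), ">= 8")
  expect_error(ga_config(P = 0), "0 < P")
  expect_error(ga_config(P = 0.4, sigma = 0.25), "3\\*sigma")
  expect_error(ga_config(pc = 1.2), "pc and pm")
  cfg <- ga_config(pop_size = 10)
  expect_s3_class(cfg, "ga_config")
})

test_that("population initialisation is bounded and seed-reproducible", {
  cfg <- ga_config(pop_size = 50, seed = 42)
  p1 <- init_population(cfg)
  p2 <- init_population(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 50)
  expect_true(all(p1$lc >= -5 & p1$lc <= 15))
  expect_true(all(p1$lg >= -15 & p1$lg <= 3))
  expect_true(all(is.na(p1$fit)))
})

test_that("cross-validated fitness separates signal from chance", {
  prob <- gauss_problem(12, sep = 5)
  folds <- make_folds(prob$y, 3, seed = 2)
  expect_equal(unname(table(folds)), rep(12, 3), ignore_attr = TRUE)
  fit <- svm_cv_accuracy(prob$X, prob$y, cost = 10, gamma = 0.5, folds)
  expect_gte(fit, 0.95)
  set.seed(7)
  chance <- replicate(5, {
    yr <- sample(prob$y)
    svm_cv_accuracy(prob$X, yr, cost = 10, gamma = 0.5, make_folds(yr, 3, seed = 2))
  })
  expect_lt(abs(mean(chance) - 1 / 3), 0.15)
  expect_error(svm_cv_accuracy(prob$X, factor(rep("y1", nrow(prob$X))),
                               1, 1, folds), "two classes")
  expect_error(make_folds(rep(c("a", "b"), 2), k = 5), "at least")
})

test_that("sorting and tiering follow the quartering rule", {
  set.seed(3)
  pop <- data.frame(lc = rnorm(10), lg = rnorm(10), fit = runif(10))
  st <- sort_and_tier(pop)
  expect_true(!is.unsorted(st$fit))
  expect_equal(unname(table(st$tier)), c(2, 2, 2, 4), ignore_attr = TRUE)
  big <- data.frame(lc = rnorm(2000), lg = rnorm(2000), fit = runif(2000))
  expect_equal(unname(table(sort_and_tier(big)$tier)), rep(500, 4),
               ignore_attr = TRUE)
  # ties leave a deterministic order
  tied <- data.frame(lc = c(2, 1, 1), lg = c(0, 1, 0), fit = c(0.5, 0.5, 0.5))
  expect_identical(sort_and_tier(tied)$lc, c(1, 1, 2))
  expect_identical(sort_and_tier(tied)$lg, c(0, 1, 0))
  expect_error(sort_and_tier(data.frame(lc = 1, lg = 1, fit = NA_real_)),
               "unevaluated")
})

test_that("tiered selection and refill keep the arithmetic of the scheme", {
  set.seed(4)
  pop <- data.frame(lc = rnorm(2000), lg = rnorm(2000), fit = runif(2000))
  st <- sort_and_tier(pop)
  sel <- tiered_select(st, P = 0.4, sigma = 0.2)
  expect_equal(nrow(sel), 200 + 300 + 400 + 500)
  expect_equal(sum(sel$tier == "good"), 500) # P + 3*sigma = 1: all good kept
  ref <- refill_population(sel, st)
  expect_equal(nrow(ref), 2000)
  # deficit 600 > Cgood 500: whole good tier + 100 from well
  refill_part <- ref[(nrow(sel) + 1):nrow(ref), ]
  expect_equal(sum(refill_part$tier == "good"), 500)
  expect_equal(sum(refill_part$tier == "well"), 100)
  # small-deficit branch draws from the good tier only
  sel2 <- st[st$fit >= sort(st$fit)[101], ][1:1900, ]
  ref2 <- refill_population(sel2, st)
  expect_equal(nrow(ref2), 2000)
  expect_true(all(ref2$tier[1901:2000] == "good"))
  expect_identical(refill_population(st, st)[, 1:3], st[, 1:3])
})

test_that("crossover blends within parental bounds and mutation respects clips", {
  set.seed(5)
  pop <- data.frame(lc = c(0, 10, 3, 3), lg = c(-10, -2, 1, 1),
                    fit = c(0.1, 0.2, 0.3, 0.4))
  crossed <- semgwfm:::crossover_population(pop, pc = 1, c_range = c(-5, 15),
                                            g_range = c(-15, 3))
  expect_true(all(crossed$lc[1:2] >= 0 & crossed$lc[1:2] <= 10))
  expect_true(all(is.na(crossed$fit[1:2])))
  expect_equal(crossed$lc[3:4], c(3, 3)) # identical parents blend to themselves
  same <- semgwfm:::crossover_population(pop, pc = 0, c_range = c(-5, 15),
                                         g_range = c(-15, 3))
  expect_identical(same, pop)
  mut <- semgwfm:::mutate_population(pop, pm = 1, c_range = c(-5, 15),
                                     g_range = c(-15, 3), mutation_scale = 5)
  expect_true(all(mut$lc >= -5 & mut$lc <= 15))
  expect_true(all(mut$lg >= -15 & mut$lg <= 3))
  keep <- semgwfm:::mutate_population(pop, pm = 0, c_range = c(-5, 15),
                                      g_range = c(-15, 3), mutation_scale = 5)
  expect_identical(keep, pop)
  # symmetric perturbation: mean shift of many mutations is near zero
  big <- data.frame(lc = rep(5, 5000), lg = rep(-6, 5000), fit = runif(5000))
  m <- semgwfm:::mutate_population(big, pm = 1, c_range = c(-100, 100),
                                   g_range = c(-100, 100), mutation_scale = 0.01)
  expect_lt(abs(mean(m$lc) - 5), 0.1)
})

test_that("evolution finds good hyperparameters deterministically", {
  prob <- gauss_problem(10, sep = 5)
  cfg <- ga_config(pop_size = 16, max_generations = 4, cv_folds = 3, seed = 11)
  r1 <- evolve(prob$X, prob$y, cfg)
  r2 <- evolve(prob$X, prob$y, cfg)
  expect_identical(r1$best_c, r2$best_c)
  expect_identical(r1$best_g, r2$best_g)
  expect_identical(r1$history, r2$history)
  expect_gte(r1$best_fitness, 0.9)
  expect_true(all(diff(r1$history$best) >= 0))
  zero_gen <- evolve(prob$X, prob$y,
                     ga_config(pop_size = 16, max_generations = 1,
                               cv_folds = 3, seed = 11))
  expect_equal(nrow(zero_gen$history), 1)
  early <- evolve(prob$X, prob$y,
                  ga_config(pop_size = 16, max_generations = 50, cv_folds = 3,
                            seed = 11, target_fitness = 0.5))
  expect_lt(nrow(early$history), 50)
  plain <- evolve_plain_ga(prob$X, prob$y, cfg)
  expect_gte(plain$best_fitness, 0.9)
})

test_that("final SVM training and evaluation are coherent", {
  prob <- gauss_problem(10, sep = 5)
  model <- train_svm(prob$X, prob$y, best_c = 10, best_g = 0.5)
  ev <- evaluate_model(model, prob$X, prob$y)
  expect_gte(ev$accuracy, 0.95)
  expect_equal(rowSums(ev$confusion), table(prob$y), ignore_attr = TRUE)
  expect_equal(sum(ev$confusion), length(prob$y))
  expect_named(ev$per_class, levels(prob$y))
  # tiny memorizable set with a large penalty is interpolated
  tiny <- list(X = rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(5, 5), c(6, 5)),
               y = factor(c("a", "a", "a", "a", "b", "b")))
  mt <- train_svm(tiny$X, tiny$y, best_c = 1e3, best_g = 1)
  expect_equal(as.character(predict(mt, tiny$X)), as.character(tiny$y))
  expect_error(train_svm(prob$X, rep("y1", nrow(prob$X)), 1, 1), "two classes")
  expect_error(evaluate_model(model, prob$X, rep("zz", nrow(prob$X))),
               "outside")
})
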