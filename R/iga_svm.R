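#' Genetic algorithm configuration
#'
#' Parameters of the improved genetic algorithm that tunes the RBF-SVM
#' penalty `c` and kernel parameter `g`. Individuals are encoded as real
#' pairs `(log2 c, log2 g)`; the defaults mirror the reference operating
#' point (population 2000, crossover 0.7, mutation 0.1, base selection
#' probability `P = 0.4` with tier increment `sigma = 0.2`, stopping at 50
#' generations, 5-fold cross-validated fitness).
#'
#' @param pop_size population size `C`.
#' @param pc crossover probability.
#' @param pm per-gene mutation probability.
#' @param P base selection probability of the lowest (bad) tier.
#' @param sigma tier increment: the four tiers bad/medium/well/good are
#'   selected with probabilities `P`, `P + sigma`, `P + 2 sigma`,
#'   `P + 3 sigma`; `P + 3 sigma` must not exceed 1.
#' @param max_generations generation budget.
#' @param target_fitness optional early-stop fitness (CV accuracy in `[0, 1]`).
#' @param c_range,g_range log2 search bounds for the penalty and kernel
#'   parameters.
#' @param cv_folds folds of the stratified cross-validated fitness.
#' @param seed integer seed; the whole evolution is deterministic given the
#'   seed and data.
#' @param mutation_scale standard deviation of the Gaussian mutation as a
#'   fraction of each gene's range.
#' @param tournament_size tournament size of the plain-GA baseline
#'   ([evolve_plain_ga()]).
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 2000L, pc = 0.7, pm = 0.1, P = 0.4,
                      sigma = 0.2, max_generations = 50L,
                      target_fitness = NULL, c_range = c(-5, 15),
                      g_range = c(-15, 3), cv_folds = 5L, seed = 1L,
                      mutation_scale = 0.1, tournament_size = 2L) {
  if (!is_count(pop_size) || pop_size < 8L) stopf("`pop_size` must be >= 8")
  if (P <= 0 || P >= 1 || sigma <= 0 || sigma >= 1) {
    stopf("need 0 < P < 1 and 0 < sigma < 1")
  }
  if (P + 3 * sigma > 1 + 1e-12) stopf("P + 3*sigma must be <= 1")
  if (pc < 0 || pc > 1 || pm < 0 || pm > 1) stopf("pc and pm must be in [0, 1]")
  if (diff(c_range) <= 0 || diff(g_range) <= 0) stopf("parameter ranges must be increasing")
  if (!is_count(cv_folds) || cv_folds < 2L) stopf("`cv_folds` must be >= 2")
  structure(list(pop_size = as.integer(pop_size), pc = pc, pm = pm, P = P,
                 sigma = sigma, max_generations = as.integer(max_generations),
                 target_fitness = target_fitness, c_range = c_range,
                 g_range = g_range, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), mutation_scale = mutation_scale,
                 tournament_size = as.integer(tournament_size)),
            class = "ga_config")
}

#' Initialise a GA population
#'
#' `pop_size` individuals with `(log2 c, log2 g)` drawn uniformly within the
#' configured ranges; fitness unset.
#'
#' @param config a [ga_config()].
#' @return a data.frame with columns `lc`, `lg` (log2 parameters) and `fit`
#'   (`NA` until evaluated).
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "ga_config"))
  C <- config$pop_size
  with_seed(config$seed, {
    data.frame(
      lc = stats::runif(C, config$c_range[1], config$c_range[2]),
      lg = stats::runif(C, config$g_range[1], config$g_range[2]),
      fit = NA_real_
    )
  })
}

#' Stratified cross-validation folds
#'
#' Assigns every sample to one of `k` folds so that each class is spread as
#' evenly as possible across folds. The assignment is fixed per run so that
#' all individuals of a GA run are scored on identical folds.
#'
#' @param y factor (or coercible) of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.factor(y)
  if (min(table(y)) < k) {
    stopf("smallest class has %d samples; need at least %d for %d-fold CV",
          min(table(y)), k, k)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated fitness of one (c, g) pair
#'
#' Mean held-out accuracy of a one-vs-one RBF-SVM with penalty `cost` and
#' kernel parameter `gamma` over the given stratified folds. This is the GA's
#' fitness function.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y class labels.
#' @param cost SVM penalty `c` (> 0).
#' @param gamma RBF kernel parameter `g` (> 0).
#' @param folds integer fold assignment from [make_folds()].
#' @return scalar accuracy in `[0, 1]`.
#' @export
svm_cv_accuracy <- function(X, y, cost, gamma, folds) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stopf("need at least two classes")
  correct <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "C-classification",
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

evaluate_population <- function(pop, X, y, folds) {
  todo <- which(is.na(pop$fit))
  for (i in todo) {
    pop$fit[i] <- svm_cv_accuracy(X, y, cost = 2^pop$lc[i],
                                  gamma = 2^pop$lg[i], folds = folds)
  }
  pop
}

#' Sort a population by fitness and assign tiers
#'
#' Orders individuals by ascending fitness (ties broken by `lc`, `lg`, then
#' original position, so the order is deterministic) and labels the four
#' tiers bad/medium/well/good. The three lower tiers each get
#' `floor(C / 4)` individuals; the remainder goes to the good (highest
#' fitness) tier.
#'
#' @param pop evaluated population (no `NA` fitness).
#' @return the population sorted ascending with an added `tier` factor.
#' @export
sort_and_tier <- function(pop) {
  if (anyNA(pop$fit)) stopf("population has unevaluated individuals")
  ord <- order(pop$fit, pop$lc, pop$lg, seq_len(nrow(pop)))
  pop <- pop[ord, , drop = FALSE]
  rownames(pop) <- NULL
  C <- nrow(pop)
  q <- C %/% 4L
  sizes <- c(bad = q, medium = q, well = q, good = C - 3L * q)
  pop$tier <- factor(rep(names(sizes), sizes),
                     levels = c("bad", "medium", "well", "good"))
  pop
}

#' Tiered selection
#'
#' From each tier, `floor(tier_size * tier_probability)` members are drawn
#' uniformly without replacement, with tier probabilities `P`, `P + sigma`,
#' `P + 2 sigma`, `P + 3 sigma` for bad/medium/well/good.
#'
#' @param pop a tiered population from [sort_and_tier()].
#' @param P,sigma selection parameters, see [ga_config()].
#' @return the selected subset of `pop` (its `Cnew` rows).
#' @export
tiered_select <- function(pop, P, sigma) {
  if (is.null(pop$tier)) stopf("population has no tiers; call sort_and_tier()")
  probs <- c(bad = P, medium = P + sigma, well = P + 2 * sigma,
             good = P + 3 * sigma)
  picks <- integer(0)
  for (tier in levels(pop$tier)) {
    idx <- which(pop$tier == tier)
    n_take <- floor(length(idx) * probs[[tier]])
    if (n_take > 0L) picks <- c(picks, sample(idx, n_take))
  }
  pop[picks, , drop = FALSE]
}

#' Elitist refill of a selected population
#'
#' Restores the population to size `C` after tiered selection. If the
#' deficit `C - Cnew` fits inside the good tier, that many individuals are
#' drawn at random from the good tier; otherwise the whole good tier is
#' reinserted and the rest is drawn from the well tier. Duplicates between
#' selection and refill are allowed (elites may enter twice).
#'
#' @param selected result of [tiered_select()].
#' @param pop the full tiered population the selection came from.
#' @return a population of exactly `nrow(pop)` rows.
#' @export
refill_population <- function(selected, pop) {
  C <- nrow(pop)
  deficit <- C - nrow(selected)
  if (deficit < 0L) stopf("selection larger than the population")
  if (deficit == 0L) return(selected)
  good <- pop[pop$tier == "good", , drop = FALSE]
  if (deficit <= nrow(good)) {
    extra <- good[sample(nrow(good), deficit), , drop = FALSE]
  } else {
    well <- pop[pop$tier == "well", , drop = FALSE]
    still <- deficit - nrow(good)
    if (still > nrow(well)) {
      stopf("refill deficit %d exceeds the good and well tiers", deficit)
    }
    extra <- rbind(good, well[sample(nrow(well), still), , drop = FALSE])
  }
  out <- rbind(selected, extra)
  rownames(out) <- NULL
  out
}

# Arithmetic-blend crossover over consecutive pairs, in log2 parameter space.
# Pairing follows population order: after tiered selection the population is
# fitness-blocked, so recombination is assortative (elites blend with elites).
# Children of a crossed pair get NA fitness; untouched pairs keep theirs.
# `n_apply` limits the operator to the first n_apply rows (the recombination
# pool), leaving rows beyond it untouched.
crossover_population <- function(pop, pc, c_range, g_range,
                                 n_apply = nrow(pop)) {
  n_pairs <- n_apply %/% 2L
  for (p in seq_len(n_pairs)) {
    i <- 2L * p - 1L
    j <- 2L * p
    if (stats::runif(1) < pc) {
      alpha <- stats::runif(1)
      a <- c(pop$lc[i], pop$lg[i])
      b <- c(pop$lc[j], pop$lg[j])
      child1 <- alpha * a + (1 - alpha) * b
      child2 <- (1 - alpha) * a + alpha * b
      pop$lc[i] <- min(max(child1[1], c_range[1]), c_range[2])
      pop$lg[i] <- min(max(child1[2], g_range[1]), g_range[2])
      pop$lc[j] <- min(max(child2[1], c_range[1]), c_range[2])
      pop$lg[j] <- min(max(child2[2], g_range[1]), g_range[2])
      pop$fit[c(i, j)] <- NA_real_
    }
  }
  pop
}

# Gaussian per-gene mutation in log2 space, scale = mutation_scale * range,
# clipped to bounds. Mutated individuals get NA fitness. `n_apply` as in
# crossover_population().
mutate_population <- function(pop, pm, c_range, g_range, mutation_scale,
                              n_apply = nrow(pop)) {
  C <- nrow(pop)
  hit_c <- stats::runif(C) < pm & seq_len(C) <= n_apply
  hit_g <- stats::runif(C) < pm & seq_len(C) <= n_apply
  if (any(hit_c)) {
    pop$lc[hit_c] <- pmin(pmax(
      pop$lc[hit_c] + stats::rnorm(sum(hit_c), 0, mutation_scale * diff(c_range)),
      c_range[1]), c_range[2])
  }
  if (any(hit_g)) {
    pop$lg[hit_g] <- pmin(pmax(
      pop$lg[hit_g] + stats::rnorm(sum(hit_g), 0, mutation_scale * diff(g_range)),
      g_range[1]), g_range[2])
  }
  pop$fit[hit_c | hit_g] <- NA_real_
  pop
}

#' Evolve SVM hyperparameters with the improved genetic algorithm
#'
#' Runs the championship-with-sorting loop: evaluate the population with the
#' cross-validated fitness, sort and tier, select per tier, recombine and
#' mutate the selected pool, and complete the population with intact
#' individuals drawn from the good (and, if needed, well) tier — the elitist
#' insertions are not subjected to the operators, so a core of elites reaches
#' the next evaluation unchanged. Stops when `target_fitness` is reached or
#' after `max_generations`. The best-ever individual is tracked outside the
#' population, so the reported best fitness is non-decreasing.
#'
#' @param X numeric training feature matrix.
#' @param y training class labels.
#' @param config a [ga_config()].
#' @return list with `best_c`, `best_g` (linear scale), `best_fitness`, and
#'   `history` (data.frame with per-generation `generation`, `best`
#'   best-so-far fitness, and `mean` population fitness).
#' @export
evolve <- function(X, y, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  folds <- make_folds(y, config$cv_folds, seed = derive_seed(config$seed, 1L))
  pop <- init_population(config)
  best <- list(lc = NA_real_, lg = NA_real_, fit = -Inf)
  hist_best <- numeric(0)
  hist_mean <- numeric(0)
  with_seed(derive_seed(config$seed, 2L), {
    for (gen in seq_len(max(1L, config$max_generations))) {
      pop <- evaluate_population(pop, X, y, folds)
      stopifnot(nrow(pop) == config$pop_size)
      i_best <- which.max(pop$fit)
      if (pop$fit[i_best] > best$fit) {
        best <- list(lc = pop$lc[i_best], lg = pop$lg[i_best],
                     fit = pop$fit[i_best])
      }
      hist_best <- c(hist_best, best$fit)
      hist_mean <- c(hist_mean, mean(pop$fit))
      if (!is.null(config$target_fitness) && best$fit >= config$target_fitness) break
      if (gen == config$max_generations) break
      pop <- sort_and_tier(pop)
      sel <- tiered_select(pop, config$P, config$sigma)
      n_sel <- nrow(sel)
      pop <- refill_population(sel, pop)
      pop$tier <- NULL
      # recombination and mutation act on the selected pool; the elitist
      # refill block joins the new population intact (survival of the fittest)
      pop <- crossover_population(pop, config$pc, config$c_range,
                                  config$g_range, n_apply = n_sel)
      pop <- mutate_population(pop, config$pm, config$c_range, config$g_range,
                               config$mutation_scale, n_apply = n_sel)
    }
  })
  list(best_c = 2^best$lc, best_g = 2^best$lg, best_fitness = best$fit,
       history = data.frame(generation = seq_along(hist_best),
                            best = hist_best, mean = hist_mean))
}

#' Plain tournament GA baseline
#'
#' The unimproved comparator: selection is by championship only — each of the
#' `C` slots of the next generation is filled with the fittest of
#' `tournament_size` individuals drawn at random — followed by the same
#' crossover and mutation operators as [evolve()]. Used to demonstrate the
#' benefit of the tiered scheme on a common problem.
#'
#' @inheritParams evolve
#' @return same structure as [evolve()].
#' @export
evolve_plain_ga <- function(X, y, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  folds <- make_folds(y, config$cv_folds, seed = derive_seed(config$seed, 1L))
  pop <- init_population(config)
  best <- list(lc = NA_real_, lg = NA_real_, fit = -Inf)
  hist_best <- numeric(0)
  hist_mean <- numeric(0)
  with_seed(derive_seed(config$seed, 2L), {
    for (gen in seq_len(max(1L, config$max_generations))) {
      pop <- evaluate_population(pop, X, y, folds)
      i_best <- which.max(pop$fit)
      if (pop$fit[i_best] > best$fit) {
        best <- list(lc = pop$lc[i_best], lg = pop$lg[i_best],
                     fit = pop$fit[i_best])
      }
      hist_best <- c(hist_best, best$fit)
      hist_mean <- c(hist_mean, mean(pop$fit))
      if (!is.null(config$target_fitness) && best$fit >= config$target_fitness) break
      if (gen == config$max_generations) break
      C <- nrow(pop)
      winners <- vapply(seq_len(C), function(i) {
        cand <- sample(C, config$tournament_size)
        cand[which.max(pop$fit[cand])]
      }, integer(1))
      pop <- pop[winners, , drop = FALSE]
      rownames(pop) <- NULL
      pop <- crossover_population(pop, config$pc, config$c_range, config$g_range)
      pop <- mutate_population(pop, config$pm, config$c_range, config$g_range,
                               config$mutation_scale)
    }
  })
  list(best_c = 2^best$lc, best_g = 2^best$lg, best_fitness = best$fit,
       history = data.frame(generation = seq_along(hist_best),
                            best = hist_best, mean = hist_mean))
}

#' Train the final RBF-SVM
#'
#' Fits a one-vs-one multiclass C-SVM with the optimised `(best_c, best_g)`
#' on the full training set.
#'
#' @param X training feature matrix.
#' @param y training labels.
#' @param best_c,best_g hyperparameters, e.g. from [evolve()].
#' @return list of class `semg_model` with the fitted classifier and its
#'   hyperparameters and class levels.
#' @export
train_svm <- function(X, y, best_c, best_g) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stopf("need at least two classes to train")
  fit <- e1071::svm(X, y, type = "C-classification", kernel = "radial",
                    cost = best_c, gamma = best_g, scale = FALSE)
  structure(list(fit = fit, best_c = best_c, best_g = best_g,
                 classes = levels(y)),
            class = "semg_model")
}

#' @export
predict.semg_model <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata)
}

#' Evaluate a trained model on a test set
#'
#' @param model a `semg_model` from [train_svm()].
#' @param XT test feature matrix.
#' @param YT test labels; every label must be one of the training classes.
#' @return list with `accuracy`, `per_class` (named per-class accuracy), and
#'   `confusion` (matrix, rows = actual, columns = predicted).
#' @export
evaluate_model <- function(model, XT, YT) {
  YT <- factor(YT, levels = model$classes)
  if (anyNA(YT)) stopf("test labels outside the training classes")
  pred <- factor(predict(model, XT), levels = model$classes)
  confusion <- table(actual = YT, predicted = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  per_class <- diag(confusion) / rowSums(confusion)
  list(accuracy = acc, per_class = per_class,
       confusion = unclass(confusion))
}
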