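#' Genetic algorithm configuration
#'
#' Settings for evolving the CNN's flattened weight vector. Defaults follow
#' the reference experiment grid: population 40, eight parents, mutation
#' probability 0.1.
#'
#' @param population_size chromosomes per generation (default 40).
#' @param num_parents elite parents kept each generation (default 8;
#'   must satisfy 2 <= num_parents <= population_size).
#' @param mutation_rate per-offspring probability of mutating exactly one
#'   gene (default 0.1); with `mutation_mode = "per_gene"` the per-gene
#'   probability instead.
#' @param mutation_range half-width of the uniform mutation increment
#'   (default 1).
#' @param generations number of generations to run.
#' @param batch_size images per fitness mini-batch (default 32).
#' @param init_dist `"uniform"` or `"normal"` population initialization.
#' @param seed integer seed; all randomness derives from it.
#' @param fitness_mode `"minibatch"` (cycle through the training set in a
#'   seeded shuffled order, one batch per generation) or `"fullbatch"`
#'   (evaluate on the whole training set every generation).
#' @param mutation_mode `"per_offspring"` (default) or `"per_gene"`.
#' @param keep_both_offspring keep both children of each crossover pair
#'   instead of the first only.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = 40L, num_parents = 8L,
                      mutation_rate = 0.1, mutation_range = 1,
                      generations = 100L, batch_size = 32L,
                      init_dist = c("uniform", "normal"), seed = 0L,
                      fitness_mode = c("minibatch", "fullbatch"),
                      mutation_mode = c("per_offspring", "per_gene"),
                      keep_both_offspring = FALSE) {
  init_dist <- match.arg(init_dist)
  fitness_mode <- match.arg(fitness_mode)
  mutation_mode <- match.arg(mutation_mode)
  if (num_parents < 2 || num_parents > population_size)
    stop("need 2 <= num_parents <= population_size")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must be in [0, 1]")
  if (generations < 0) stop("generations must be >= 0")
  if (mutation_range <= 0) stop("mutation_range must be positive")
  structure(list(population_size = as.integer(population_size),
                 num_parents = as.integer(num_parents),
                 mutation_rate = mutation_rate,
                 mutation_range = mutation_range,
                 generations = as.integer(generations),
                 batch_size = as.integer(batch_size),
                 init_dist = init_dist, seed = as.integer(seed),
                 fitness_mode = fitness_mode, mutation_mode = mutation_mode,
                 keep_both_offspring = isTRUE(keep_both_offspring)),
            class = "ga_config")
}

#' GA fitness: classification error rate on a batch
#'
#' (false positives + false negatives) / batch size, computed from the
#' network's predictions. Lower is fitter; the GA minimizes this directly.
#'
#' @param spec a `cnn_spec`.
#' @param weight_vec flat weight vector (the chromosome).
#' @param images list of image arrays (or an `image_dataset`).
#' @param labels integer 0/1 truth vector (taken from the dataset when
#'   `images` is an `image_dataset` and `labels` is missing).
#' @return error rate in \[0, 1\].
#' @export
ga_fitness <- function(spec, weight_vec, images, labels = NULL) {
  if (inherits(images, "image_dataset") && is.null(labels))
    labels <- images$meta$y
  imgs <- as_image_list(images)
  if (length(imgs) == 0) stop("fitness batch must be non-empty")
  stopifnot(length(labels) == length(imgs))
  w <- restore_weights(weight_vec, spec)
  pred <- cnn_predict(spec, w, imgs)
  mean(pred != labels)
}

#' Select the fittest members of a population
#'
#' Returns the `k` members with the lowest error rate, best first; ties
#' resolve to the lower index.
#'
#' @param population list with `members` (list of weight vectors) and
#'   `fitness` (aligned numeric error rates).
#' @param k number of parents.
#' @return list of `k` weight vectors, best first.
#' @export
select_parents <- function(population, k) {
  fit <- population$fitness
  if (is.null(fit) || anyNA(fit)) stop("population fitness not computed")
  if (k < 1 || k > length(population$members)) stop("k out of range")
  population$members[order(fit)[seq_len(k)]]   # order() is stable on ties
}

#' Single-point crossover of two chromosomes
#'
#' Swaps the tails of two equal-length parents at `point`: offspring 1 is
#' `p1[1:point]` followed by `p2[(point+1):L]`, and symmetrically for
#' offspring 2.
#'
#' @param p1,p2 numeric parent vectors of equal length L.
#' @param point cut index in `[1, L-1]`.
#' @return `list(o1, o2)` of offspring vectors.
#' @export
single_point_crossover <- function(p1, p2, point) {
  L <- length(p1)
  if (length(p2) != L) stop("parent length mismatch")
  if (point < 1 || point > L - 1) stop("crossover point out of range")
  head1 <- seq_len(point); tail1 <- (point + 1L):L
  list(c(p1[head1], p2[tail1]), c(p2[head1], p1[tail1]))
}

#' Mutate an offspring chromosome
#'
#' In `"per_offspring"` mode (default): with probability `rate`, exactly
#' one uniformly chosen gene receives a uniform(-range, +range) increment;
#' otherwise the offspring is returned unchanged. In `"per_gene"` mode
#' each gene independently receives an increment with probability `rate`.
#'
#' @param offspring numeric weight vector.
#' @param rate mutation probability in \[0, 1\].
#' @param range half-width of the uniform increment.
#' @param seed optional integer; when given, the draw is made under a
#'   temporary RNG state so the call is deterministic and side-effect free.
#' @param mode `"per_offspring"` or `"per_gene"`.
#' @return the (possibly) mutated vector.
#' @export
mutate_offspring <- function(offspring, rate, range, seed = NULL,
                             mode = c("per_offspring", "per_gene")) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, rate <= 1, range > 0)
  doit <- function() {
    if (mode == "per_offspring") {
      if (runif(1) < rate) {
        g <- sample.int(length(offspring), 1L)
        offspring[g] <- offspring[g] + runif(1, -range, range)
      }
    } else {
      hit <- which(runif(length(offspring)) < rate)
      if (length(hit))
        offspring[hit] <- offspring[hit] + runif(length(hit), -range, range)
    }
    offspring
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}

#' Advance a population by one generation
#'
#' Elitist generational replacement: the `num_parents` fittest members
#' survive unchanged; the remaining slots are filled by single-point
#' crossover of cyclically paired parents (1-2, 2-3, ...) at a random cut,
#' followed by mutation. Fitness of the new members is left unset (NA);
#' the caller evaluates it on the next batch. Uses the current RNG stream;
#' seed via the caller (see [train_ga()]).
#'
#' @param population list with `members`, `fitness`, `generation`.
#' @param config a `ga_config`.
#' @return the next-generation population (fitness NA except where
#'   inherited, generation incremented).
#' @export
evolve_generation <- function(population, config) {
  pop_n <- length(population$members)
  stopifnot(pop_n == config$population_size)
  parents <- select_parents(population, config$num_parents)
  L <- length(parents[[1]])
  members <- parents
  np <- length(parents)
  pair <- 0L
  while (length(members) < pop_n) {
    pair <- pair + 1L
    i <- ((pair - 1L) %% np) + 1L
    j <- (i %% np) + 1L
    point <- sample.int(L - 1L, 1L)
    off <- single_point_crossover(parents[[i]], parents[[j]], point)
    kids <- if (config$keep_both_offspring) off else off[1]
    for (kid in kids) {
      if (length(members) >= pop_n) break
      members[[length(members) + 1L]] <-
        mutate_offspring(kid, config$mutation_rate, config$mutation_range,
                         mode = config$mutation_mode)
    }
  }
  list(members = members,
       fitness = rep(NA_real_, pop_n),
       generation = population$generation + 1L)
}

#' Train the CNN with the genetic algorithm
#'
#' Initializes `population_size` random weight sets, then repeats for
#' `generations` rounds: evaluate every chromosome's error rate on the
#' current batch (a seeded shuffled mini-batch cycle through the training
#' set, or the full set), select the elite, and refill the population by
#' crossover and mutation. The reported solution is the best-ever member
#' by its recorded fitness (mini-batch fitness is noisy, so the final
#' generation's best need not be the overall best).
#'
#' @param spec a `cnn_spec`.
#' @param train_set an `image_dataset` (non-empty).
#' @param config a `ga_config`.
#' @return list of class `ga_result`: `best_weights` (flat vector),
#'   `best_fitness`, `best_fitness_history` (length `generations + 1`,
#'   including generation 0), and `final_population`.
#' @export
train_ga <- function(spec, train_set, config) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(train_set, "image_dataset"),
            inherits(config, "ga_config"))
  n <- length(train_set$images)
  if (n == 0) stop("training set is empty")
  labels <- train_set$meta$y
  with_seed(config$seed, {
    member_seeds <- sample.int(.Machine$integer.max - 1L, config$population_size)
    members <- lapply(member_seeds, function(s)
      flatten_weights(init_weights(spec, config$init_dist, seed = s), spec))
    next_batch <- make_batch_cycle(n, min(config$batch_size, n))
    batch_idx <- function() {
      if (config$fitness_mode == "fullbatch") seq_len(n) else next_batch()
    }
    eval_pop <- function(members, idx) {
      vapply(members, function(v)
        ga_fitness(spec, v, train_set$images[idx], labels[idx]), numeric(1))
    }
    idx <- batch_idx()
    population <- list(members = members, fitness = eval_pop(members, idx),
                       generation = 0L)
    best_i <- which.min(population$fitness)
    best <- list(vec = population$members[[best_i]],
                 fit = population$fitness[best_i])
    history <- numeric(config$generations + 1L)
    history[1] <- best$fit
    if (config$generations > 0) {
      for (g in seq_len(config$generations)) {
        elite_fit <- sort(population$fitness)[seq_len(config$num_parents)]
        population <- evolve_generation(population, config)
        idx <- batch_idx()
        if (config$fitness_mode == "fullbatch") {
          # elites survive unchanged and the evaluation set is fixed, so
          # their fitness carries over (evolve_generation places the
          # selected parents best-first at the head of the population)
          fresh <- setdiff(seq_len(config$population_size),
                           seq_len(config$num_parents))
          population$fitness <- c(elite_fit,
                                  eval_pop(population$members[fresh], idx))
        } else {
          population$fitness <- eval_pop(population$members, idx)
        }
        best_i <- which.min(population$fitness)
        if (population$fitness[best_i] <= best$fit) {
          best <- list(vec = population$members[[best_i]],
                       fit = population$fitness[best_i])
        }
        history[g + 1L] <- population$fitness[best_i]   # this generation's best
      }
    }
    structure(list(best_weights = best$vec, best_fitness = best$fit,
                   best_fitness_history = history,
                   final_population = population),
              class = "ga_result")
  })
}

# Closure yielding successive mini-batches of indices, reshuffling each
# epoch from the ambient RNG stream.
make_batch_cycle <- function(n, batch_size) {
  pool <- integer(0)
  function() {
    if (length(pool) < batch_size) pool <<- c(pool, sample.int(n))
    out <- pool[seq_len(batch_size)]
    pool <<- pool[-seq_len(batch_size)]
    out
  }
}
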