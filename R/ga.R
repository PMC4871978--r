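#' Chromosome encoding of wavelet-kernel hyperparameters
#'
#' A candidate parameter set is a 20-bit chromosome: bits 1-4 encode the
#' wavelet oscillation parameter `w` (1..16), bits 5-8 the scale `x`
#' (1..16), bits 9-12 the width `y` (1..16), and bits 13-20 the
#' hidden-neuron count (5..260).  Each field is the range minimum plus
#' the unsigned MSB-first value of its bit slice, so `0000 -> 1`,
#' `1111 -> 16`, `00000000 -> 5` and `11111111 -> 260`.
#'
#' @param chromosome An integer/logical vector of 20 bits (0/1).
#' @return `decode_chromosome()`: a list with integers `w`, `x`, `y`,
#'   `n_hidden`.
#' @examples
#' decode_chromosome(rep(0, 20))
#' encode_params(w = 15, x = 3, y = 10, n_hidden = 86)
#' @export
decode_chromosome <- function(chromosome) {
  chromosome <- check_chromosome(chromosome)
  list(
    w = 1L + bits_to_int(chromosome[1:4]),
    x = 1L + bits_to_int(chromosome[5:8]),
    y = 1L + bits_to_int(chromosome[9:12]),
    n_hidden = 5L + bits_to_int(chromosome[13:20])
  )
}

#' @rdname decode_chromosome
#' @param w,x,y Integers in 1..16.
#' @param n_hidden Integer in 5..260.
#' @return `encode_params()`: a length-20 integer vector of bits whose
#'   decode reproduces the inputs (the mapping is a bijection).
#' @export
encode_params <- function(w, x, y, n_hidden) {
  for (v in list(w = w, x = x, y = y)) {
    if (v < 1 || v > 16 || v != round(v)) {
      stop("kernel parameters must be integers in 1..16", call. = FALSE)
    }
  }
  if (n_hidden < 5 || n_hidden > 260 || n_hidden != round(n_hidden)) {
    stop("n_hidden must be an integer in 5..260", call. = FALSE)
  }
  c(int_to_bits(w - 1, 4), int_to_bits(x - 1, 4), int_to_bits(y - 1, 4),
    int_to_bits(n_hidden - 5, 8))
}

check_chromosome <- function(chromosome) {
  chromosome <- as.integer(chromosome)
  if (length(chromosome) != 20 || !all(chromosome %in% c(0L, 1L))) {
    stop("a chromosome is exactly 20 bits of 0/1", call. = FALSE)
  }
  chromosome
}

bits_to_int <- function(bits) {
  as.integer(sum(as.integer(bits) * 2^((length(bits) - 1):0)))
}

int_to_bits <- function(value, width) {
  as.integer(intToBits(value))[width:1]
}

#' Genetic-algorithm configuration
#'
#' @param population_size Individuals per generation (default 40).
#' @param generations Generation budget (default 50).
#' @param crossover_prob Probability of single-point crossover per
#'   parent pair (default 0.8).
#' @param mutation_prob Per-bit flip probability (default 0.02).
#' @param elitism_count Best individuals copied unchanged into the next
#'   generation (default 1; must be < population_size).
#' @param stall_generations Optional early stop after this many
#'   generations without improvement of the best fitness.
#' @param seed Integer seed driving the whole search.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 40, generations = 50,
                      crossover_prob = 0.8, mutation_prob = 0.02,
                      elitism_count = 1, stall_generations = NULL,
                      seed = 1L) {
  if (population_size < 2) stop("population_size must be >= 2", call. = FALSE)
  if (generations < 1) stop("generations must be >= 1", call. = FALSE)
  if (crossover_prob < 0 || crossover_prob > 1) {
    stop("crossover_prob must be in [0, 1]", call. = FALSE)
  }
  if (mutation_prob < 0 || mutation_prob > 1) {
    stop("mutation_prob must be in [0, 1]", call. = FALSE)
  }
  if (elitism_count < 0 || elitism_count >= population_size) {
    stop("elitism_count must be in [0, population_size)", call. = FALSE)
  }
  if (!is.null(stall_generations) && stall_generations < 1) {
    stop("stall_generations must be >= 1 or NULL", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         elitism_count = as.integer(elitism_count),
         stall_generations = stall_generations, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Training-accuracy fitness of a chromosome
#'
#' Decodes the chromosome, fits a center-subset wavelet-kernel ELM with
#' the decoded `w`, `x`, `y` and `K = n_hidden` centers (capped at the
#' number of training rows), and returns the training-set classification
#' accuracy as a fraction in \[0, 1\].  A training failure yields
#' fitness 0 with a warning rather than aborting the search.
#'
#' @param chromosome A 20-bit chromosome.
#' @param data Training rows (data frame).
#' @param outcome Label column name.
#' @param E Regulation coefficient passed to [wkelm()].
#' @param seed Seed for center selection (kept fixed across the search
#'   so fitness is a deterministic function of the chromosome).
#' @param features Optional feature column subset.
#' @return Training accuracy in \[0, 1\].
#' @export
ga_fitness <- function(chromosome, data, outcome = "status", E = 1,
                       seed = 1L, features = NULL) {
  p <- decode_chromosome(chromosome)
  n <- nrow(data)
  tryCatch({
    fit <- wkelm(data, outcome = outcome, features = features,
                 kernel = kernel_spec("wavelet", w = p$w, x = p$x, y = p$y),
                 variant = "center_subset", E = E,
                 n_hidden = min(p$n_hidden, n), seed = seed)
    mean(predict(fit, data) == data[[outcome]])
  }, error = function(e) {
    warning("fitness evaluation failed (", conditionMessage(e),
            "); returning 0", call. = FALSE)
    0
  })
}

#' Roulette-wheel parent selection
#'
#' Fitness-proportionate sampling with replacement; when every fitness
#' is zero (or the total is not finite) selection falls back to uniform.
#'
#' @param population A list of chromosomes.
#' @param fitnesses Numeric vector aligned with `population`.
#' @return A list of two selected chromosomes.
#' @export
ga_select_parents <- function(population, fitnesses) {
  stopifnot(length(population) == length(fitnesses), length(population) > 0)
  total <- sum(fitnesses)
  idx <- if (!is.finite(total) || total <= 0) {
    sample.int(length(population), 2, replace = TRUE)
  } else {
    sample.int(length(population), 2, replace = TRUE, prob = fitnesses)
  }
  population[idx]
}

#' Single-point crossover
#'
#' With probability `prob` the two parents are cut at a uniform point in
#' 1..19 and their tails swapped; otherwise the children are exact
#' copies of the parents.
#'
#' @param a,b Parent chromosomes (equal length).
#' @param prob Crossover probability.
#' @return A list of two child chromosomes.
#' @export
ga_crossover <- function(a, b, prob = 0.8) {
  a <- check_chromosome(a)
  b <- check_chromosome(b)
  if (stats::runif(1) < prob) {
    cut <- sample.int(19, 1)
    list(c(a[1:cut], b[(cut + 1):20]), c(b[1:cut], a[(cut + 1):20]))
  } else {
    list(a, b)
  }
}

#' Per-bit mutation
#'
#' Flips each bit independently with probability `prob`.
#'
#' @param chromosome A 20-bit chromosome.
#' @param prob Per-bit flip probability.
#' @return The mutated chromosome.
#' @export
ga_mutate <- function(chromosome, prob = 0.02) {
  chromosome <- check_chromosome(chromosome)
  flips <- stats::runif(length(chromosome)) < prob
  as.integer(xor(chromosome, flips))
}

# Ranking used for elites and the best-ever individual: higher fitness
# first; ties prefer fewer hidden neurons, then the lexicographically
# smaller bit string (the cheapest model wins).
ga_order <- function(population, fitnesses) {
  nh <- vapply(population, function(ch) decode_chromosome(ch)$n_hidden, 0L)
  lex <- vapply(population, paste, "", collapse = "")
  order(-fitnesses, nh, lex)
}

#' Genetic-algorithm search over wavelet-kernel ELM hyperparameters
#'
#' Runs the binary GA: a seeded random initial population of 20-bit
#' chromosomes; per generation, fitness evaluation ([ga_fitness()] =
#' training accuracy of a center-subset wavelet-kernel ELM), elitist
#' carry-over of the best individuals, then roulette selection,
#' single-point crossover and per-bit mutation to refill the
#' population.  The best individual ever seen is returned decoded; ties
#' are broken toward fewer hidden neurons.
#'
#' @param data Training rows (data frame).
#' @param outcome Label column name.
#' @param config A [ga_config()].
#' @param E Regulation coefficient for the fitness classifier.
#' @param features Optional feature column subset.
#' @return An object of class `wkelm_ga` with elements `best_params`
#'   (w, x, y, n_hidden), `best_chromosome`, `best_fitness`, `history`
#'   (tibble: generation, best, mean), and `evaluations`.
#' @examples
#' \donttest{
#' d <- simulate_parkinsons(n_samples = 80, effect_size = 2, seed = 1)
#' res <- ga_optimize(d, config = ga_config(population_size = 10,
#'                                          generations = 5, seed = 1))
#' res$best_params
#' }
#' @export
ga_optimize <- function(data, outcome = "status", config = ga_config(),
                        E = 1, features = NULL) {
  if (!inherits(config, "ga_config")) {
    stop("config must come from ga_config()", call. = FALSE)
  }
  n_pop <- config$population_size
  evaluate <- function(pop) {
    vapply(pop, ga_fitness, 0, data = data, outcome = outcome, E = E,
           seed = config$seed, features = features)
  }
  withr::with_seed(config$seed, {
    population <- replicate(n_pop, sample(0:1, 20, replace = TRUE),
                            simplify = FALSE)
    fitnesses <- evaluate(population)
    evaluations <- n_pop
    ord <- ga_order(population, fitnesses)
    best_chrom <- population[[ord[1]]]
    best_fit <- fitnesses[ord[1]]
    history <- list(tibble::tibble(generation = 0L, best = best_fit,
                                   mean = mean(fitnesses)))
    stall <- 0L
    for (gen in seq_len(config$generations)) {
      ord <- ga_order(population, fitnesses)
      elite <- population[ord[seq_len(config$elitism_count)]]
      children <- elite
      while (length(children) < n_pop) {
        parents <- ga_select_parents(population, fitnesses)
        pair <- ga_crossover(parents[[1]], parents[[2]],
                             prob = config$crossover_prob)
        pair <- lapply(pair, ga_mutate, prob = config$mutation_prob)
        children <- c(children, pair)
      }
      population <- children[seq_len(n_pop)]
      fitnesses <- evaluate(population)
      evaluations <- evaluations + n_pop
      ord <- ga_order(population, fitnesses)
      cand_chrom <- population[[ord[1]]]
      cand_fit <- fitnesses[ord[1]]
      improved <- cand_fit > best_fit ||
        (cand_fit == best_fit && better_tiebreak(cand_chrom, best_chrom))
      if (cand_fit > best_fit) stall <- 0L else stall <- stall + 1L
      if (improved) {
        best_chrom <- cand_chrom
        best_fit <- cand_fit
      }
      history <- c(history, list(tibble::tibble(
        generation = gen, best = best_fit, mean = mean(fitnesses))))
      if (!is.null(config$stall_generations) &&
          stall >= config$stall_generations) break
    }
    structure(
      list(best_params = decode_chromosome(best_chrom),
           best_chromosome = best_chrom,
           best_fitness = best_fit,
           history = dplyr::bind_rows(history),
           evaluations = evaluations,
           config = config, E = E),
      class = "wkelm_ga"
    )
  })
}

better_tiebreak <- function(a, b) {
  na <- decode_chromosome(a)$n_hidden
  nb <- decode_chromosome(b)$n_hidden
  if (na != nb) return(na < nb)
  paste(a, collapse = "") < paste(b, collapse = "")
}

#' @export
print.wkelm_ga <- function(x, ...) {
  p <- x$best_params
  cat(sprintf(
    "<wkelm_ga> best fitness %.4f at w = %d, x = %d, y = %d, n_hidden = %d\n",
    x$best_fitness, p$w, p$x, p$y, p$n_hidden))
  cat(sprintf("%d fitness evaluations over %d generations\n",
              x$evaluations, max(x$history$generation)))
  invisible(x)
}

#' Per-generation fitness history of a GA run
#'
#' @param x A [ga_optimize()] result.
#' @param ... Unused.
#' @return A tibble with columns `generation`, `best`, `mean`.
#' @method tidy wkelm_ga
#' @export
tidy.wkelm_ga <- function(x, ...) x$history

#' One-row summary of a GA run
#'
#' @param x A [ga_optimize()] result.
#' @param ... Unused.
#' @return A one-row tibble: decoded best parameters, best fitness,
#'   generations run and total fitness evaluations.
#' @method glance wkelm_ga
#' @export
glance.wkelm_ga <- function(x, ...) {
  res <- x
  p <- res$best_params
  tibble::tibble(
    w = p$w, x = p$x, y = p$y, n_hidden = p$n_hidden,
    best_fitness = res$best_fitness,
    generations = max(res$history$generation),
    evaluations = res$evaluations
  )
}
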