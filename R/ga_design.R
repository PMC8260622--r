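# Genetic-algorithm design of synthetic 5' UTRs. Starting from a
# seeded sample of 100 natural library members, sequences are evolved
# under a surrogate-predicted fitness by truncation parent selection,
# single-point crossover, per-nucleotide point mutation and an
# insertion-style shift mutation, with start-codon repair after every
# variation step and elitist plus-selection of survivors. Each run
# keeps its top 5 sequences subject to a minimum pairwise Hamming
# distance of 5 and a minimum fitness improvement of 0.05 over the
# best initial natural sequence, within at most 50 generations.

#' Genetic-algorithm configuration
#'
#' Population/selection/diversity parameters follow the screening
#' design: population 100, at most 50 generations, keep the top 5
#' sequences at pairwise Hamming distance >= 5 whose fitness beats the
#' best initial seed by >= 0.05 (on the fitness scale used for the
#' run). Variation-operator settings are standard evolutionary-search
#' defaults chosen for reliable optimization within the 50-generation
#' budget: parents are drawn from the `parent_pool` fittest
#' individuals, `n_offspring` children are bred per generation, and
#' survivors are the fittest `pop_size` of parents plus offspring
#' (elitist plus-selection, so the best fitness never decreases). All
#' are configurable.
#'
#' @param pop_size Population size (>= 2).
#' @param max_generations Generation cap.
#' @param n_keep Designs kept per run.
#' @param min_hamming Minimum pairwise Hamming distance among kept.
#' @param min_improvement Required fitness gain over the best initial
#'   seed.
#' @param mutation_rate Per-nucleotide substitution probability.
#' @param crossover_rate Per-offspring crossover probability.
#' @param shift_rate Expected number of segment-shift mutations per
#'   offspring (Poisson); set 0 to disable (e.g. for the
#'   two-generation model-test mode, which requires offspring near
#'   their seed).
#' @param parent_pool Number of fittest individuals parents are drawn
#'   from (truncation selection).
#' @param n_offspring Children bred per generation.
#' @param elitism_count Minimum number of best individuals guaranteed
#'   to survive; plus-selection implies this for any value below
#'   `pop_size`.
#' @param seed Integer seed.
#' @return List with class `ga_config`.
#' @export
ga_config <- function(pop_size = 100L, max_generations = 50L, n_keep = 5L,
                      min_hamming = 5L, min_improvement = 0.05,
                      mutation_rate = 0.01, crossover_rate = 0.5,
                      shift_rate = 0.5, parent_pool = 5L,
                      n_offspring = 150L, elitism_count = 2L, seed = 1L) {
  stopifnot(pop_size >= 2L, max_generations >= 1L, min_hamming >= 0L,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1, shift_rate >= 0,
            parent_pool >= 1L, parent_pool <= pop_size,
            n_offspring >= 1L, elitism_count >= 0L,
            elitism_count < pop_size)
  structure(list(pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 n_keep = as.integer(n_keep),
                 min_hamming = as.integer(min_hamming),
                 min_improvement = min_improvement,
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 shift_rate = shift_rate,
                 parent_pool = as.integer(parent_pool),
                 n_offspring = as.integer(n_offspring),
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b DNA strings of equal length.
#' @return Count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming distance requires equal-length sequences", call. = FALSE)
  }
  sum(seq_chars(a) != seq_chars(b))
}

#' Mutate a sequence at a per-nucleotide rate
#'
#' Each position is independently substituted with probability `rate`
#' to one of the three other bases; start codons introduced (or
#' pre-existing) are then repaired with [strip_augs()], preserving
#' length. Uses the current RNG stream.
#'
#' @param seq DNA string.
#' @param rate Per-nucleotide substitution probability.
#' @param repair Apply AUG repair afterwards (default TRUE).
#' @return Mutated sequence of equal length.
#' @export
mutate_seq <- function(seq, rate, repair = TRUE) {
  assert_dna(seq)
  stopifnot(rate >= 0, rate <= 1)
  chars <- seq_chars(seq)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1), USE.NAMES = FALSE)
  }
  out <- paste(chars, collapse = "")
  if (repair) out <- strip_augs(out)
  out
}

#' Segment-shift (insertion) mutation
#'
#' Removes the base at a random position and reinserts it at another
#' random position, shifting the intervening segment by one. Length
#' and base composition are preserved. This classic string-mutation
#' operator lets the search cross plateaus that point mutation alone
#' cannot (e.g. phase defects in periodic motifs). Uses the current
#' RNG stream.
#'
#' @param seq DNA string.
#' @param repair Apply AUG repair afterwards (default TRUE).
#' @return Shifted sequence of equal length.
#' @export
shift_seq <- function(seq, repair = TRUE) {
  chars <- seq_chars(seq)
  n <- length(chars)
  i <- sample.int(n, 1L)
  j <- sample.int(n, 1L)
  b <- chars[i]
  chars <- append(chars[-i], b, after = j - 1L)
  out <- paste(chars, collapse = "")
  if (repair) out <- strip_augs(out)
  out
}

#' Single-point crossover of two sequences
#'
#' Cut point is uniform on `1..L-1`; the child is `a[1:cut]` followed
#' by `b[(cut+1):L]`, with AUG repair applied (a start codon can form
#' at the junction). Uses the current RNG stream.
#'
#' @param a,b Equal-length DNA strings.
#' @param repair Apply AUG repair (default TRUE).
#' @return Child sequence of the same length.
#' @export
recombine <- function(a, b, repair = TRUE) {
  n <- nchar(a)
  if (n != nchar(b)) stop("recombine requires equal-length sequences",
                          call. = FALSE)
  cut <- sample.int(n - 1L, 1L)
  child <- paste0(substr(a, 1L, cut), substr(b, cut + 1L, n))
  if (repair) child <- strip_augs(child)
  child
}

#' Greedy fitness-ranked diverse subset
#'
#' Candidates are sorted by fitness descending (ties broken by
#' sequence lexicographic order) and accepted greedily iff their
#' Hamming distance to every previously accepted sequence is at least
#' `min_dist`, stopping at `k` or exhaustion.
#'
#' @param candidates data.frame with columns `sequence`, `fitness`.
#' @param k Maximum designs to keep.
#' @param min_dist Minimum pairwise Hamming distance.
#' @return Accepted subset of `candidates`, fitness-descending.
#' @export
diverse_top_k <- function(candidates, k = 5L, min_dist = 5L) {
  stopifnot(all(c("sequence", "fitness") %in% names(candidates)))
  candidates <- candidates[!duplicated(candidates$sequence), , drop = FALSE]
  ord <- order(-candidates$fitness, candidates$sequence)
  candidates <- candidates[ord, , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(candidates))) {
    if (length(accepted) >= k) break
    ok <- all(vapply(accepted, function(j)
      hamming(candidates$sequence[i], candidates$sequence[j]) >= min_dist,
      logical(1)))
    if (ok) accepted <- c(accepted, i)
  }
  out <- candidates[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evolve synthetic 5' UTRs under a fitness function
#'
#' One GA run. The initial population is a seeded sample of
#' `pop_size` sequences from `seed_pool` (standardized, AUG-free
#' members of one length). Each generation, `n_offspring` children
#' are bred from parents drawn uniformly from the `parent_pool`
#' fittest individuals: single-point crossover with probability
#' `crossover_rate`, per-nucleotide point mutation at
#' `mutation_rate`, a Poisson(`shift_rate`) number of segment-shift
#' mutations, then AUG repair. Survivors are the fittest `pop_size`
#' distinct sequences among parents and offspring (elitist
#' plus-selection), so the best fitness is non-decreasing. Fitness
#' values are memoized by sequence. After `max_generations`, the kept
#' designs are the fitness-ranked diverse subset ([diverse_top_k()])
#' of all evaluated sequences, filtered to fitness at least
#' `min_improvement` above the best initial seed.
#'
#' @param seed_pool Character vector of candidate seed sequences
#'   (length >= `pop_size`), or a record data.frame with a `sequence`
#'   column.
#' @param fitness_fn Function `sequence -> numeric fitness` (e.g. a
#'   surrogate-model predictor).
#' @param config A [ga_config()].
#' @return Object of class `ga_result`: `kept` (data.frame `sequence`,
#'   `fitness`, `generation`), `best_fitness_trajectory` (length
#'   `max_generations + 1`, element 1 = initial population),
#'   `initial_best`, `seed_ids`, `n_evaluated`, `config`.
#' @export
evolve <- function(seed_pool, fitness_fn, config = ga_config()) {
  if (is.data.frame(seed_pool)) {
    ids <- if ("id" %in% names(seed_pool)) seed_pool$id else
      paste0("seed", seq_len(nrow(seed_pool)))
    seed_pool <- setNames(seed_pool$sequence, ids)
  }
  if (is.null(names(seed_pool))) {
    names(seed_pool) <- paste0("seed", seq_along(seed_pool))
  }
  if (length(seed_pool) < config$pop_size) {
    stop("seed_pool smaller than pop_size", call. = FALSE)
  }
  if (length(unique(nchar(seed_pool))) != 1L) {
    stop("seed sequences must share one length", call. = FALSE)
  }

  memo <- new.env(parent = emptyenv())
  gen_found <- new.env(parent = emptyenv())
  current_gen <- 0L
  fitness_of <- function(s) {
    if (is.null(memo[[s]])) {
      f <- tryCatch(fitness_fn(s), error = function(e)
        stop("fitness_fn failed at generation ", current_gen, ": ",
             conditionMessage(e), call. = FALSE))
      memo[[s]] <- f
      gen_found[[s]] <- current_gen
    }
    memo[[s]]
  }

  withr::with_seed(config$seed, {
    pick <- sample.int(length(seed_pool), config$pop_size)
    pop <- unname(seed_pool[pick])
    seed_ids <- names(seed_pool)[pick]
    fit <- vapply(pop, fitness_of, numeric(1), USE.NAMES = FALSE)
    initial_best <- max(fit)
    trajectory <- numeric(config$max_generations + 1L)
    trajectory[1L] <- initial_best

    for (gen in seq_len(config$max_generations)) {
      current_gen <- gen
      parents <- order(-fit)[seq_len(config$parent_pool)]
      offspring <- character(config$n_offspring)
      for (i in seq_along(offspring)) {
        p1 <- pop[parents[sample.int(config$parent_pool, 1L)]]
        child <- if (runif(1) < config$crossover_rate) {
          p2 <- pop[parents[sample.int(config$parent_pool, 1L)]]
          recombine(p1, p2, repair = FALSE)
        } else p1
        child <- mutate_seq(child, config$mutation_rate, repair = FALSE)
        n_shift <- if (config$shift_rate > 0)
          stats::rpois(1L, config$shift_rate) else 0L
        if (n_shift > 0L) for (z in seq_len(n_shift)) {
          child <- shift_seq(child, repair = FALSE)
        }
        offspring[i] <- strip_augs(child)
      }
      off_fit <- vapply(offspring, fitness_of, numeric(1),
                        USE.NAMES = FALSE)
      all_pop <- c(offspring, pop)
      all_fit <- c(off_fit, fit)
      d <- !duplicated(all_pop)
      all_pop <- all_pop[d]
      all_fit <- all_fit[d]
      keep <- order(-all_fit)[seq_len(min(config$pop_size,
                                          length(all_pop)))]
      pop <- all_pop[keep]
      fit <- all_fit[keep]
      trajectory[gen + 1L] <- max(fit)
    }

    seqs <- ls(memo)
    all_eval <- data.frame(
      sequence = seqs,
      fitness = vapply(seqs, function(s) memo[[s]], numeric(1),
                       USE.NAMES = FALSE),
      generation = vapply(seqs, function(s) gen_found[[s]], integer(1),
                          USE.NAMES = FALSE),
      row.names = NULL, stringsAsFactors = FALSE
    )
    kept <- diverse_top_k(all_eval, k = config$n_keep,
                          min_dist = config$min_hamming)
    kept <- kept[kept$fitness >= initial_best + config$min_improvement, ,
                 drop = FALSE]
    rownames(kept) <- NULL
    structure(list(kept = kept, best_fitness_trajectory = trajectory,
                   initial_best = initial_best, seed_ids = seed_ids,
                   n_evaluated = nrow(all_eval), config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("ga_result:", nrow(x$kept), "kept designs;",
      x$n_evaluated, "sequences evaluated\n")
  cat(sprintf("  initial best %.4f -> final best %.4f\n",
              x$initial_best, max(x$best_fitness_trajectory)))
  invisible(x)
}
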