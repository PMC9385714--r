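#' Configuration of the classifier-guided in silico loop
#'
#' @param n_rounds Number of selection/recombination/mutation/
#'   classification rounds (default 100).
#' @param recombinant_fraction Fraction of each round's offspring
#'   created by pure recombination (default 0.8); the remainder are
#'   point mutants.
#' @param final_population Number of candidate offspring generated in
#'   the final round (default 12000), of which only those predicted
#'   neutral are returned.
#' @param ga A [ga_config()] providing tournament size, parent count,
#'   per-round population size and the mutation rate. The per-round
#'   parameters of the original runs are not public; set them
#'   explicitly for any quantitative comparison.
#' @param filter_each_round Retain only predicted-neutral offspring as
#'   each round's population (default), or defer filtering to the final
#'   round.
#' @param dedup_scope `"round"` (default) forbids duplicates within a
#'   round's offspring; `"history"` additionally forbids any sequence
#'   generated in an earlier round of the loop.
#' @return Object of class `guided_config`.
#' @export
guided_config <- function(n_rounds = 100L, recombinant_fraction = 0.8,
                          final_population = 12000L,
                          ga = ga_config(), filter_each_round = TRUE,
                          dedup_scope = c("round", "history")) {
  stopifnot(n_rounds >= 1L, recombinant_fraction > 0,
            recombinant_fraction < 1, final_population >= 1L,
            inherits(ga, "ga_config"))
  dedup_scope <- match.arg(dedup_scope)
  structure(list(n_rounds = as.integer(n_rounds),
                 recombinant_fraction = recombinant_fraction,
                 final_population = as.integer(final_population),
                 ga = ga, filter_each_round = filter_each_round,
                 dedup_scope = dedup_scope),
            class = "guided_config")
}

#' Classifier-guided tournament selection
#'
#' Samples `tournament_size` contestants without replacement; when at
#' least one contestant is predicted neutral the winner is drawn
#' uniformly among the predicted-neutral contestants, otherwise
#' uniformly among all contestants. Unlike RA-based tournaments, chosen
#' parents stay in the pool (sampling per tournament is independent).
#'
#' @param pop Character vector of sequences.
#' @param classifier A classifier with a [predict_neutral()] method.
#' @param cfg A [ga_config()] (uses `tournament_size`, `n_parents`).
#' @return Character vector of `n_parents` selected parents.
#' @export
guided_tournament_select <- function(pop, classifier, cfg) {
  stopifnot(length(pop) >= 1L)
  neutral <- predict_neutral(classifier, pop)
  parents <- character(cfg$n_parents)
  for (i in seq_len(cfg$n_parents)) {
    k <- min(cfg$tournament_size, length(pop))
    idx <- sample.int(length(pop), k)
    neu <- idx[neutral[idx]]
    pick <- if (length(neu) >= 1L) {
      neu[sample.int(length(neu), 1L)]
    } else {
      idx[sample.int(length(idx), 1L)]
    }
    parents[i] <- pop[pick]
  }
  parents
}

# Generate one round's offspring: recombinant_fraction by one-point
# crossover of random parent pairs, the rest by point mutation of a
# random parent or recombinant. Duplicates are avoided within `avoid`
# up to an attempt cap, after which the requirement is relaxed so the
# loop cannot stall on small sequence spaces.
.guided_offspring <- function(parents, n_offspring, cfg, avoid) {
  n_rec <- round(cfg$recombinant_fraction * n_offspring)
  n_mut <- n_offspring - n_rec
  seen <- avoid
  out <- character(n_offspring)
  origin <- character(n_offspring)
  cap <- cfg$ga$max_attempts_factor * max(n_offspring, 1L)
  attempts <- 0L
  got <- 0L
  while (got < n_rec) {
    attempts <- attempts + 1L
    idx <- sample.int(length(parents), 2L, replace = TRUE)
    child <- one_point_crossover(parents[idx[1L]], parents[idx[2L]])
    if (attempts <= cap && child %in% seen) next
    got <- got + 1L
    seen <- c(seen, child)
    out[got] <- child
    origin[got] <- "recombinant"
  }
  pool <- c(parents, out[seq_len(n_rec)])
  attempts <- 0L
  while (got < n_offspring) {
    attempts <- attempts + 1L
    child <- mutate_genotype(pool[sample.int(length(pool), 1L)],
                             cfg$ga$per_position_mutation_prob)
    if (attempts <= cap && child %in% seen) next
    got <- got + 1L
    seen <- c(seen, child)
    out[got] <- child
    origin[got] <- "point_mutant"
  }
  data.frame(sequence = out, origin = origin, stringsAsFactors = FALSE)
}

#' Run the fully in silico classifier-guided evolutionary loop
#'
#' Starting from a seed population, each round performs guided
#' tournament selection, generates offspring (80% pure recombinants,
#' 20% point mutants by default), classifies them, and (by default)
#' retains only the predicted-neutral offspring as the next round's
#' population. The final round generates `final_population` candidates
#' and returns only those predicted neutral. The mean Hamming distance
#' from the reference is tracked per round.
#'
#' @param start_pop Character vector of starting sequences (e.g. the
#'   neutral variants of the last experimental generation).
#' @param classifier A classifier with a [predict_neutral()] method.
#' @param cfg A [guided_config()].
#' @param reference Reference sequence for the Hamming-distance
#'   trajectory (defaults to the first starting sequence).
#' @return List of class `guided_run`: `final` (character vector, all
#'   predicted neutral), `trajectory` (data frame `round`, `pop_size`,
#'   `mean_hamming`, `median_hamming`, `fraction_neutral`), `extinct`
#'   (logical), `extinct_round`.
#' @export
run_guided_evolution <- function(start_pop, classifier, cfg = guided_config(),
                                 reference = start_pop[1L]) {
  stopifnot(length(start_pop) >= 1L, inherits(cfg, "guided_config"))
  pop <- start_pop
  history <- character(0)
  traj <- data.frame(round = integer(0), pop_size = integer(0),
                     mean_hamming = numeric(0), median_hamming = numeric(0),
                     fraction_neutral = numeric(0))
  extinct <- FALSE
  extinct_round <- NA_integer_
  final <- character(0)
  for (r in seq_len(cfg$n_rounds)) {
    parents <- guided_tournament_select(pop, classifier, cfg$ga)
    last <- r == cfg$n_rounds
    n_off <- if (last) cfg$final_population else cfg$ga$population_size
    avoid <- if (cfg$dedup_scope == "history") history else character(0)
    off <- .guided_offspring(parents, n_off, cfg, avoid)
    history <- unique(c(history, off$sequence))
    neutral <- predict_neutral(classifier, off$sequence)
    survivors <- off$sequence[neutral]
    d <- hamming(reference, off$sequence)
    traj <- rbind(traj, data.frame(
      round = r, pop_size = length(survivors),
      mean_hamming = if (length(survivors)) mean(d[neutral]) else NA_real_,
      median_hamming = if (length(survivors))
        stats::median(d[neutral]) else NA_real_,
      fraction_neutral = mean(neutral)))
    if (last) {
      final <- survivors
      if (length(final) == 0L) {
        extinct <- TRUE
        extinct_round <- r
      }
      break
    }
    next_pop <- if (cfg$filter_each_round) survivors else off$sequence
    if (length(next_pop) == 0L) {
      extinct <- TRUE
      extinct_round <- r
      break
    }
    pop <- next_pop
  }
  structure(list(final = final, trajectory = traj, extinct = extinct,
                 extinct_round = extinct_round, reference = reference,
                 config = cfg),
            class = "guided_run")
}

#' @export
print.guided_run <- function(x, ...) {
  cat("Classifier-guided in silico evolution:",
      nrow(x$trajectory), "round(s)\n")
  if (x$extinct) {
    cat("EXTINCT at round", x$extinct_round,
        "(no predicted-neutral offspring)\n")
  } else {
    last <- x$trajectory[nrow(x$trajectory), ]
    cat(sprintf(
      "final population: %d predicted-neutral variants, mean Hamming %.2f from reference\n",
      length(x$final), last$mean_hamming))
  }
  invisible(x)
}

#' Write the round-by-round log of a guided run
#'
#' @param run A [run_guided_evolution()] result.
#' @param path File path.
#' @param comments Optional provenance comment lines.
#' @export
write_guided_log <- function(run, path, comments = NULL) {
  write_tsv(run$trajectory, path, comments)
}
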