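#' Genetic-algorithm configuration
#'
#' Parameters of the in silico generation designers. Per-generation
#' values in the original experiments varied; the defaults here are
#' illustrative and every analysis should set them explicitly (e.g. from
#' a YAML config).
#'
#' @param tournament_size Number of variants drawn per tournament.
#' @param n_parents Number of parents selected per generation.
#' @param n_recombinants Number of pure recombinants (algorithm used from
#'   generation 6 onward).
#' @param n_mutants Number of point-mutated variants (same algorithm).
#' @param population_size Total offspring per generation.
#' @param per_position_mutation_prob Per-position substitution
#'   probability of the mutation operator; the default 1/35 yields one
#'   substitution per call on average for the 35-nt core.
#' @param n_controls Number of offspring slots overwritten with control
#'   genotypes.
#' @param max_attempts_factor Novelty search gives up after
#'   `max_attempts_factor * population_size` attempts.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(tournament_size = 10L, n_parents = 100L,
                      population_size = 1000L,
                      n_recombinants = round(0.8 * population_size),
                      n_mutants = population_size - n_recombinants,
                      per_position_mutation_prob = 1 / 35,
                      n_controls = 0L, max_attempts_factor = 100L) {
  stopifnot(tournament_size >= 1L, n_parents >= 1L,
            population_size >= n_recombinants + n_mutants,
            per_position_mutation_prob >= 0,
            per_position_mutation_prob <= 1,
            n_controls >= 0L)
  structure(list(tournament_size = as.integer(tournament_size),
                 n_parents = as.integer(n_parents),
                 n_recombinants = as.integer(n_recombinants),
                 n_mutants = as.integer(n_mutants),
                 population_size = as.integer(population_size),
                 per_position_mutation_prob = per_position_mutation_prob,
                 n_controls = as.integer(n_controls),
                 max_attempts_factor = as.integer(max_attempts_factor)),
            class = "ga_config")
}

#' Tournament selection
#'
#' Repeatedly samples `tournament_size` variants without replacement
#' from the remaining population, retains the variant with the highest
#' RA as a parent, and returns the losers to the population, until
#' `n_parents` parents are selected. A variant already chosen as parent
#' cannot be selected again. Ties in RA are broken uniformly at random.
#'
#' @param pop Data frame with columns `sequence` and `ra`.
#' @param cfg A [ga_config()].
#' @return Data frame of selected parents (subset of `pop` rows).
#' @export
tournament_select <- function(pop, cfg) {
  stopifnot(all(c("sequence", "ra") %in% names(pop)), nrow(pop) >= 1L)
  if (cfg$n_parents > nrow(pop)) {
    stop("cannot select ", cfg$n_parents, " parents from a population of ",
         nrow(pop))
  }
  remaining <- seq_len(nrow(pop))
  winners <- integer(cfg$n_parents)
  for (i in seq_len(cfg$n_parents)) {
    k <- min(cfg$tournament_size, length(remaining))
    contestants <- remaining[sample.int(length(remaining), k)]
    ra <- pop$ra[contestants]
    best <- contestants[which(ra == max(ra))]
    win <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    winners[i] <- win
    remaining <- remaining[remaining != win]
  }
  pop[winners, , drop = FALSE]
}

#' One-point crossover
#'
#' Cuts both parents at a position drawn uniformly from `1..L-1` (so
#' both children are true recombinants) and returns one of the two
#' children uniformly at random.
#'
#' @param p1,p2 Equal-length parent sequences.
#' @return Recombinant sequence.
#' @export
one_point_crossover <- function(p1, p2) {
  L <- nchar(p1)
  if (nchar(p2) != L) stop("parents differ in length")
  cut <- sample.int(L - 1L, 1L)
  children <- c(paste0(substr(p1, 1L, cut), substr(p2, cut + 1L, L)),
                paste0(substr(p2, 1L, cut), substr(p1, cut + 1L, L)))
  children[sample.int(2L, 1L)]
}

#' Random point mutation
#'
#' Each position mutates independently with probability
#' `per_position_mutation_prob` to one of the three other bases with
#' equal probability. The call may return the input unchanged when no
#' substitution is drawn; novelty is enforced downstream by
#' deduplication, not by forcing a substitution.
#'
#' @param g Genotype sequence.
#' @param prob Per-position substitution probability.
#' @return Mutated sequence.
#' @export
mutate_genotype <- function(g, prob = 1 / 35) {
  ch <- .chars(g)
  hit <- which(stats::runif(length(ch)) < prob)
  for (p in hit) ch[p] <- sample(setdiff(RNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

# Overwrite n_controls random offspring slots with control genotypes
# (recycled if fewer controls than slots). Controls may duplicate
# history by design: the wild type is carried in every generation.
.insert_controls <- function(gen, controls, n_controls) {
  if (n_controls == 0L || length(controls) == 0L) return(gen)
  n_controls <- min(n_controls, nrow(gen))
  slots <- sample.int(nrow(gen), n_controls)
  gen$sequence[slots] <- rep_len(controls, n_controls)
  gen$origin[slots] <- "control"
  gen
}

#' Design a generation: recombine-then-mutate algorithm
#'
#' The algorithm used for generations 2-5: after tournament selection,
#' two parents are repeatedly picked at random, recombined by one-point
#' crossover, and the chosen recombinant immediately undergoes the
#' random point mutation, until `population_size` novel offspring (not
#' in `history`, no within-generation duplicates) are collected. Control
#' genotypes then overwrite `n_controls` random slots.
#'
#' @param pop Source population, data frame with `sequence` and `ra`.
#' @param cfg A [ga_config()].
#' @param history Character vector of all previously assayed sequences.
#' @param controls Character vector of control genotypes (e.g. the WT).
#' @return Data frame with columns `sequence`, `origin`, `parent1`,
#'   `parent2`; parents selected are in `attr(, "parents")`.
#' @export
design_generation_v1 <- function(pop, cfg, history = character(0),
                                 controls = character(0)) {
  parents <- tournament_select(pop, cfg)
  seen <- c(history)
  out_seq <- character(cfg$population_size)
  out_p1 <- character(cfg$population_size)
  out_p2 <- character(cfg$population_size)
  got <- 0L
  attempts <- 0L
  cap <- cfg$max_attempts_factor * cfg$population_size
  while (got < cfg$population_size) {
    attempts <- attempts + 1L
    if (attempts > cap) {
      stop("could not assemble ", cfg$population_size,
           " novel offspring within ", cap, " attempts")
    }
    idx <- sample.int(nrow(parents), 2L, replace = TRUE)
    child <- one_point_crossover(parents$sequence[idx[1L]],
                                 parents$sequence[idx[2L]])
    child <- mutate_genotype(child, cfg$per_position_mutation_prob)
    if (child %in% seen) next
    got <- got + 1L
    seen <- c(seen, child)
    out_seq[got] <- child
    out_p1[got] <- parents$sequence[idx[1L]]
    out_p2[got] <- parents$sequence[idx[2L]]
  }
  gen <- data.frame(sequence = out_seq, origin = "point_mutant",
                    parent1 = out_p1, parent2 = out_p2,
                    stringsAsFactors = FALSE)
  gen <- .insert_controls(gen, controls, cfg$n_controls)
  attr(gen, "parents") <- parents
  gen
}

#' Design a generation: pure recombinants plus random mutants
#'
#' The algorithm used from generation 6 onward: after tournament
#' selection, `n_recombinants` novel pure recombinants are generated
#' from the parents (no substitution), then `n_mutants` novel variants
#' are created by applying the random point mutation to variants drawn
#' from the pool of parents and recombinants. Offspring are deduplicated
#' against `history` and within the generation; controls are inserted as
#' in [design_generation_v1()].
#'
#' @inheritParams design_generation_v1
#' @return Data frame with columns `sequence`, `origin` (one of
#'   `recombinant`, `point_mutant`, `control`), `parent1`, `parent2`.
#' @export
design_generation_v2 <- function(pop, cfg, history = character(0),
                                 controls = character(0)) {
  parents <- tournament_select(pop, cfg)
  seen <- c(history)
  cap <- cfg$max_attempts_factor *
    max(cfg$n_recombinants + cfg$n_mutants, 1L)
  rec_seq <- character(cfg$n_recombinants)
  rec_p1 <- character(cfg$n_recombinants)
  rec_p2 <- character(cfg$n_recombinants)
  got <- 0L
  attempts <- 0L
  while (got < cfg$n_recombinants) {
    attempts <- attempts + 1L
    if (attempts > cap) stop("novelty search exhausted among recombinants")
    idx <- sample.int(nrow(parents), 2L, replace = TRUE)
    child <- one_point_crossover(parents$sequence[idx[1L]],
                                 parents$sequence[idx[2L]])
    if (child %in% seen) next
    got <- got + 1L
    seen <- c(seen, child)
    rec_seq[got] <- child
    rec_p1[got] <- parents$sequence[idx[1L]]
    rec_p2[got] <- parents$sequence[idx[2L]]
  }
  pool <- c(parents$sequence, rec_seq)
  mut_seq <- character(cfg$n_mutants)
  mut_p1 <- character(cfg$n_mutants)
  got <- 0L
  attempts <- 0L
  while (got < cfg$n_mutants) {
    attempts <- attempts + 1L
    if (attempts > cap) stop("novelty search exhausted among point mutants")
    src <- pool[sample.int(length(pool), 1L)]
    child <- mutate_genotype(src, cfg$per_position_mutation_prob)
    if (child %in% seen) next
    got <- got + 1L
    seen <- c(seen, child)
    mut_seq[got] <- child
    mut_p1[got] <- src
  }
  gen <- data.frame(
    sequence = c(rec_seq, mut_seq),
    origin = rep(c("recombinant", "point_mutant"),
                 c(cfg$n_recombinants, cfg$n_mutants)),
    parent1 = c(rec_p1, mut_p1),
    parent2 = c(rec_p2, rep(NA_character_, cfg$n_mutants)),
    stringsAsFactors = FALSE)
  gen <- .insert_controls(gen, controls, cfg$n_controls)
  attr(gen, "parents") <- parents
  gen
}

#' Write a generation manifest as TSV
#'
#' @param gen Generation data frame from a designer.
#' @param generation_index Integer generation number.
#' @param path File path.
#' @param comments Optional provenance comment lines.
#' @export
write_generation_manifest <- function(gen, generation_index, path,
                                      comments = NULL) {
  gen$generation_index <- generation_index
  write_tsv(gen, path, comments)
}
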