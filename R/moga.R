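# Multi-objective (NSGA-II style) genetic search over network topologies:
# maximize mean validation accuracy, minimize total hidden-neuron count.

GENOME_SIZE_MAX <- c(256L, 255L, 255L)

random_genome <- function() {
  n_layers <- sample(1:3, 1)
  list(n_layers = n_layers,
       sizes = c(sample.int(256L, 1), sample.int(255L, 1), sample.int(255L, 1)),
       activations = sample(ACTIVATIONS, 3, replace = TRUE))
}

#' Decode a genome into a network topology
#'
#' Fixed-length encoding: three size genes and three activation genes plus
#' a layer count; genes beyond `n_layers` are inactive free-riders kept for
#' simple crossover and ignored here.
#'
#' @param g a genome (list with `n_layers`, `sizes`, `activations`).
#' @return An [ann_topology()].
#' @export
decode_genome <- function(g) {
  k <- g$n_layers
  ann_topology(g$sizes[seq_len(k)], g$activations[seq_len(k)])
}

genome_valid <- function(g) {
  g$n_layers %in% 1:3 && length(g$sizes) == 3 && length(g$activations) == 3 &&
    all(g$sizes >= 1) && all(g$sizes <= GENOME_SIZE_MAX) &&
    all(g$activations %in% ACTIVATIONS)
}

genome_key <- function(g) {
  k <- g$n_layers
  paste(c(g$sizes[seq_len(k)], g$activations[seq_len(k)]), collapse = "/")
}

uniform_crossover <- function(a, b) {
  pick <- function(x, y, m) ifelse(m, x, y)
  m_sz <- stats::runif(3) < 0.5
  m_ac <- stats::runif(3) < 0.5
  list(n_layers = if (stats::runif(1) < 0.5) a$n_layers else b$n_layers,
       sizes = as.integer(pick(a$sizes, b$sizes, m_sz)),
       activations = pick(a$activations, b$activations, m_ac))
}

mutate_genome <- function(g, rate) {
  if (stats::runif(1) < rate) g$n_layers <- sample(1:3, 1)
  for (j in 1:3) {
    if (stats::runif(1) < rate) g$sizes[j] <- sample.int(GENOME_SIZE_MAX[j], 1)
    if (stats::runif(1) < rate) g$activations[j] <- sample(ACTIVATIONS, 1)
  }
  g
}

# objectives: minimize (-accuracy, neurons). Returns ranks (1 = best front).
nondominated_sort <- function(obj) {
  n <- nrow(obj)
  dominates <- function(i, j) all(obj[i, ] <= obj[j, ]) && any(obj[i, ] < obj[j, ])
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n); r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    front <- remaining[vapply(remaining, function(i)
      !any(vapply(remaining, function(j) j != i && dominates(j, i), logical(1))),
      logical(1))]
    rank[front] <- r
    remaining <- setdiff(remaining, front)
  }
  rank
}

crowding_distance <- function(obj) {
  n <- nrow(obj); d <- rep(0, n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- obj[o[n], k] - obj[o[1], k]
    d[o[c(1, n)]] <- Inf
    if (rng > 0 && n > 2)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], k] - obj[o[1:(n - 2)], k]) / rng
  }
  d
}

#' Evolve a network topology with a multi-objective genetic algorithm
#'
#' NSGA-II style search over the topology space (1-3 hidden layers, sizes
#' 1-256 / 1-255, four activation functions): binary tournament selection on
#' (rank, crowding distance), uniform crossover, per-gene mutation within
#' bounds, elitist mu+lambda survival by nondominated sorting. A genome's
#' fitness is its mean validation accuracy over `fitness_reps` independent
#' [train_ann()] runs (cached per genome) against its total hidden-neuron
#' count. Deterministic per `seed`; training errors invalidate the genome
#' (worst fitness) instead of aborting the run.
#'
#' @param ds a `labeled_dataset`.
#' @param pop_size population size (>= 4).
#' @param generations number of generations.
#' @param fitness_reps training repetitions averaged per fitness evaluation.
#' @param crossover_rate,mutation_rate GA operator rates.
#' @param tournament_size tournament size for parent selection.
#' @param seed master seed.
#' @param split_policy passed to [train_ann()].
#' @param epochs,patience training budget per fitness evaluation (smaller
#'   than the final-evaluation budget; fitness only ranks topologies).
#' @param initial_pop optional list of `pop_size` genomes to seed the
#'   population with (default: random initialization).
#' @return A `moga_result`: `front` (data frame of nondominated genomes with
#'   `topology`, `accuracy`, `neurons`), `best` (the front's highest-accuracy
#'   [ann_topology()], ties to fewer neurons), `best_accuracy`, `history`
#'   (best accuracy per generation).
#' @export
evolve_topology <- function(ds, pop_size = 30, generations = 20,
                            fitness_reps = 3, crossover_rate = 0.9,
                            mutation_rate = 0.15, tournament_size = 3,
                            seed = 1, split_policy = "subject",
                            epochs = 120, patience = 10, initial_pop = NULL) {
  if (pop_size < 4) pds_error("parameter_error", "population must be >= 4")
  cache <- new.env(parent = emptyenv())
  eval_genome <- function(g, eval_seed) {
    key <- genome_key(g)
    if (!is.null(cache[[key]])) return(cache[[key]])
    acc <- tryCatch({
      topo <- decode_genome(g)
      accs <- vapply(seq_len(fitness_reps), function(r)
        train_ann(ds, topo, split_policy = split_policy,
                  seed = (eval_seed + r * 7919) %% .Machine$integer.max,
                  epochs = epochs, patience = patience)$val_accuracy,
        numeric(1))
      mean(accs)
    }, pdscribe_error = function(e) -1)
    res <- c(acc = acc, neurons = sum(g$sizes[seq_len(g$n_layers)]))
    cache[[key]] <- res
    res
  }

  withr::local_seed(seed)
  fitness_seed <- sample.int(.Machine$integer.max - 1e6, 1)
  pop <- if (is.null(initial_pop)) {
    replicate(pop_size, random_genome(), simplify = FALSE)
  } else {
    stopifnot(length(initial_pop) == pop_size, all(vapply(initial_pop, genome_valid, logical(1))))
    initial_pop
  }
  fit <- t(vapply(pop, eval_genome, numeric(2), eval_seed = fitness_seed))
  history <- numeric(generations)
  for (gen in seq_len(generations)) {
    obj <- cbind(-fit[, "acc"], fit[, "neurons"])
    rank <- nondominated_sort(obj)
    crowd <- unlist(lapply(split(seq_len(nrow(obj)), rank), function(ix) {
      stats::setNames(crowding_distance(obj[ix, , drop = FALSE]), ix)
    }))
    crowd <- crowd[as.character(seq_len(nrow(obj)))]
    tourn <- function() {
      cand <- sample.int(length(pop), tournament_size)
      cand[order(rank[cand], -crowd[cand])][1]
    }
    children <- vector("list", pop_size)
    for (i in seq_len(pop_size)) {
      p1 <- pop[[tourn()]]; p2 <- pop[[tourn()]]
      child <- if (stats::runif(1) < crossover_rate) uniform_crossover(p1, p2) else p1
      child <- mutate_genome(child, mutation_rate)
      stopifnot(genome_valid(child))
      children[[i]] <- child
    }
    child_fit <- t(vapply(children, eval_genome, numeric(2), eval_seed = fitness_seed))
    all_pop <- c(pop, children)
    all_fit <- rbind(fit, child_fit)
    all_obj <- cbind(-all_fit[, "acc"], all_fit[, "neurons"])
    all_rank <- nondominated_sort(all_obj)
    all_crowd <- unlist(lapply(split(seq_len(nrow(all_obj)), all_rank), function(ix) {
      stats::setNames(crowding_distance(all_obj[ix, , drop = FALSE]), ix)
    }))
    all_crowd <- all_crowd[as.character(seq_len(nrow(all_obj)))]
    keep <- order(all_rank, -all_crowd)[seq_len(pop_size)]
    pop <- all_pop[keep]; fit <- all_fit[keep, , drop = FALSE]
    history[gen] <- max(fit[, "acc"])
  }
  obj <- cbind(-fit[, "acc"], fit[, "neurons"])
  front_ix <- which(nondominated_sort(obj) == 1)
  # deduplicate genomes on the front
  front_ix <- front_ix[!duplicated(vapply(pop[front_ix], genome_key, ""))]
  front <- data.frame(
    topology = vapply(pop[front_ix], function(g) format_topology(decode_genome(g)), ""),
    accuracy = fit[front_ix, "acc"], neurons = fit[front_ix, "neurons"])
  best_ix <- front_ix[order(-fit[front_ix, "acc"], fit[front_ix, "neurons"])][1]
  structure(list(front = front, best = decode_genome(pop[[best_ix]]),
                 best_accuracy = fit[best_ix, "acc"],
                 history = history, final_population = pop),
            class = "moga_result")
}

#' @export
print.moga_result <- function(x, ...) {
  cat(sprintf("<moga_result> best %s (fitness accuracy %.4f); front of %d:\n",
              format_topology(x$best), x$best_accuracy, nrow(x$front)))
  print(x$front[order(-x$front$accuracy), ], row.names = FALSE)
  invisible(x)
}
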