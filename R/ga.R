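#' Genetic Algorithm configuration
#'
#' Third-phase baseline: population 8, 200 generations, roulette selection,
#' two-point crossover, mutation probability 0.3.
#'
#' @param population Even population size.
#' @param generations Number of generations (>= 1).
#' @param mutation_prob Per-individual mutation probability in `[0, 1]`.
#' @param elitism If `TRUE`, the generation's best individual survives
#'   unchanged (off by default: plain generational replacement).
#' @param seed Integer RNG seed, or `NULL`.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population = 8L, generations = 200L,
                      mutation_prob = 0.3, elitism = FALSE, seed = NULL) {
  if (population < 2L || population %% 2L != 0L) {
    stop("population must be even and >= 2")
  }
  if (mutation_prob < 0 || mutation_prob > 1) {
    stop("mutation_prob must be in [0, 1]")
  }
  structure(
    list(population = as.integer(population),
         generations = as.integer(generations),
         mutation_prob = mutation_prob, crossover = "two_point",
         selection = "roulette", elitism = elitism, seed = seed),
    class = "ga_config"
  )
}

#' Roulette-wheel parent selection
#'
#' Draws `k` parent indices with probability proportional to shifted
#' fitness `f - min(f) + delta`, so negative fitness values are legal.
#' When all fitnesses are equal the draw degenerates to uniform.
#'
#' @param fitnesses Numeric vector of fitness values.
#' @param k Number of parents to draw.
#' @param delta Small positive shift keeping the minimum selectable.
#' @return Integer vector of `k` parent indices (with replacement).
#' @export
roulette_select <- function(fitnesses, k, delta = 1e-9) {
  if (k < 1L) stop("k must be >= 1")
  if (!any(is.finite(fitnesses))) stop("need at least one finite fitness")
  w <- fitnesses - min(fitnesses) + delta
  if (sum(w) <= 0 || all(w == w[1L])) {
    w <- rep(1, length(fitnesses))
  }
  sample.int(length(fitnesses), size = k, replace = TRUE, prob = w)
}

# Re-thread a row's original residues through a child's gap pattern so the
# feasibility constraint (gap-strip recovers the input) holds after
# crossover. Surplus residue slots beyond the original length become gaps;
# missing residues are appended at the row end.
rethread_row <- function(pattern_row, residues) {
  slots <- which(pattern_row != "-")
  L <- length(residues)
  out <- rep("-", length(pattern_row))
  fill <- seq_len(min(length(slots), L))
  out[slots[fill]] <- residues[fill]
  if (L > length(slots)) out <- c(out, residues[(length(slots) + 1L):L])
  out
}

#' Two-point crossover of alignment matrices
#'
#' Two cut columns `c1 < c2` are chosen uniformly on the common (padded)
#' width; the children swap the column block `[c1, c2)`. Because swapping
#' gapped columns between different gap patterns breaks residue content,
#' each child row is repaired by re-threading the parent's original
#' residues through the child's gap pattern; children are then cleaned of
#' all-gap columns. If the common width is < 2 the parents are returned
#' unchanged.
#'
#' @param a,b Parent `bacterium` objects with the same number of rows.
#' @return List of two child `bacterium` objects.
#' @export
two_point_crossover <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("parents must have the same number of rows")
  res_a <- strsplit(gapstrip(as_strings(a)), "", fixed = TRUE)
  res_b <- strsplit(gapstrip(as_strings(b)), "", fixed = TRUE)
  m <- max(ncol(a), ncol(b))
  if (m < 2L) return(list(a, b))
  pad <- function(x) {
    if (ncol(x) < m) {
      cbind(unclass(x), matrix("-", nrow(x), m - ncol(x)))
    } else unclass(x)
  }
  ma <- pad(a); mb <- pad(b)
  cuts <- sort(sample.int(m + 1L, 2L) - 1L)   # 0..m, c1 < c2
  c1 <- cuts[1L]; c2 <- cuts[2L]
  block <- (c1 + 1L):c2
  child1 <- ma; child2 <- mb
  child1[, block] <- mb[, block]
  child2[, block] <- ma[, block]
  repair <- function(child, residues) {
    rows <- lapply(seq_len(nrow(child)),
                   function(i) rethread_row(child[i, ], residues[[i]]))
    clean_gap_columns(cuadra_list(rows, a))
  }
  list(repair(child1, res_a), repair(child2, res_b))
}

#' Gap-indel mutation
#'
#' With probability `p`, applies one random edit: a fair coin chooses gap
#' insertion (uniform row and position) or gap deletion (uniform existing
#' gap; falls back to insertion when the matrix holds no gaps). Otherwise
#' the individual is returned unchanged.
#'
#' @param bact A `bacterium`.
#' @param p Mutation probability in `[0, 1]`.
#' @return A `bacterium`.
#' @export
mutate <- function(bact, p) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (stats::runif(1) >= p) return(bact)
  delete <- stats::runif(1) < 0.5 && any(unclass(bact) == "-")
  if (delete) swim(bact, 1L) else tumble(bact, 1L)
}

#' Run the Genetic Algorithm baseline
#'
#' Per generation: the population is scored by the normalized BLOSUM
#' sum-of-pairs objective (no swarm interaction — that is a foraging
#' concept; cross-algorithm comparability comes from z-standardization),
#' parents are roulette-selected, paired for two-point crossover, children
#' are mutated and replace the population. The NFE counter follows the
#' per-matrix convention, with the first generation counted twice (initial
#' evaluation plus the first selection), so for population 8 the sequence
#' is 16, 24, 32, ...
#'
#' @param seqs A `seq_records` data frame or character vector (>= 2).
#' @param cfg A [ga_config()].
#' @param scoring A [scoring_config()]; normalization is forced on.
#' @param workers Parallel workers for the scoring pass.
#' @return A `run_trace` (fitness = normalized BLOSUM score; the
#'   `best_interaction` column is 0).
#' @export
run_ga <- function(seqs, cfg, scoring = scoring_config(normalize = TRUE),
                   workers = 1L) {
  if (inherits(seqs, "seq_records") && nrow(seqs) < 2L ||
      (is.character(seqs) && length(seqs) < 2L)) {
    stop("need at least 2 sequences")
  }
  scoring$normalize <- TRUE
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  S <- cfg$population
  base <- bacterium(seqs)
  pop <- lapply(seq_len(S), function(k) tumble(base, 1L))
  nfe <- 0
  t0 <- proc.time()[["elapsed"]]
  rows <- vector("list", cfg$generations)
  best_bact <- NULL
  best_fit <- -Inf
  for (gen in seq_len(cfg$generations)) {
    score_one <- function(i) blosum_score(pop[[i]], scoring)
    fit <- if (workers > 1L && .Platform$OS.type == "unix") {
      unlist(parallel::mclapply(seq_len(S), score_one, mc.cores = workers))
    } else {
      vapply(seq_len(S), score_one, numeric(1))
    }
    nfe <- record_nfe(nfe, "per_matrix", S)
    if (gen == 1L) nfe <- record_nfe(nfe, "per_matrix", S)  # first selection
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fit) {
      best_fit <- fit[gen_best]
      best_bact <- pop[[gen_best]]
    }
    rows[[gen]] <- data.frame(
      iteration = gen, best_fitness = fit[gen_best],
      best_blosum = fit[gen_best], best_interaction = 0, nfe = nfe,
      elapsed_s = proc.time()[["elapsed"]] - t0
    )
    parents <- roulette_select(fit, S)
    nxt <- vector("list", S)
    for (j in seq_len(S / 2L)) {
      kids <- two_point_crossover(pop[[parents[2L * j - 1L]]],
                                  pop[[parents[2L * j]]])
      nxt[[2L * j - 1L]] <- mutate(kids[[1L]], cfg$mutation_prob)
      nxt[[2L * j]] <- mutate(kids[[2L]], cfg$mutation_prob)
    }
    if (isTRUE(cfg$elitism)) nxt[[1L]] <- pop[[gen_best]]
    pop <- nxt
  }
  new_run_trace(do.call(rbind, rows), best = best_bact, algorithm = "ga",
                config = cfg)
}
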