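#' Scheme configuration for the foraging optimizers
#'
#' Collects every parameter of a run: chemotaxis intensity (`tumble` = gaps
#' inserted per bacterium per step), population size, iteration count,
#' `swim` (gaps deleted per step; 0 disables the swim process), the swarm
#' interaction parameters, the scoring configuration, the NFE bookkeeping
#' mode, the elitism count, and the RNG seed.
#'
#' @param tumble Gap insertions per bacterium per chemotaxis step.
#' @param population Number of bacteria (>= 2).
#' @param iterations Optimization iterations (>= 1).
#' @param swim Gap deletions per bacterium per step (0 = no swim).
#' @param swarm A [swarm_params()].
#' @param scoring A [scoring_config()].
#' @param nfe_mode NFE convention, see [record_nfe()].
#' @param elitism Number of best bacteria carried unchanged into the next
#'   iteration (elitist variant only).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param tumble_each_iter If `FALSE`, gaps are inserted only at
#'   initialization and iterations rescore without tumbling.
#' @param replace_count How many worst bacteria are replaced by copies of
#'   the best each iteration.
#' @return A list of class `scheme_config`.
#' @seealso [scheme_preset()] for the named schemes.
#' @export
scheme_config <- function(tumble, population, iterations, swim = 0L,
                          swarm = swarm_params(), scoring = scoring_config(),
                          nfe_mode = c("per_interaction", "per_matrix"),
                          elitism = 1L, seed = NULL,
                          tumble_each_iter = TRUE, replace_count = 1L) {
  nfe_mode <- match.arg(nfe_mode)
  if (population < 2L) stop("population must be >= 2")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (tumble < 0L || swim < 0L) stop("tumble and swim must be >= 0")
  structure(
    list(tumble = as.integer(tumble), population = as.integer(population),
         iterations = as.integer(iterations), swim = as.integer(swim),
         swarm = swarm, scoring = scoring, nfe_mode = nfe_mode,
         elitism = as.integer(elitism), seed = seed,
         tumble_each_iter = tumble_each_iter,
         replace_count = as.integer(replace_count)),
    class = "scheme_config"
  )
}

#' Named parameter schemes
#'
#' The experimental schemes: `A`-`D` vary chemotaxis intensity, population
#' and iterations with identical attraction/repulsion parameters
#' (`w_repel = 0.001`); `K` strengthens repulsion (`w_repel = 0.002`) and
#' enables the swim process (50 gap deletions) for the gap-deletion
#' variant; `dtp` is the elitist configuration (population 8, 200
#' iterations, tumble 100, swim 1, `w_repel = 1`, normalized scoring,
#' per-matrix NFE counting).
#'
#' @param name One of `"A"`, `"B"`, `"C"`, `"D"`, `"K"`, `"dtp"`.
#' @param seed Integer RNG seed for the run.
#' @param ... Overrides passed on to [scheme_config()] (e.g. `iterations`).
#' @return A `scheme_config`.
#' @examples
#' scheme_preset("K", seed = 1)$swim   # 50
#' @export
scheme_preset <- function(name = c("A", "B", "C", "D", "K", "dtp"),
                          seed = NULL, ...) {
  name <- match.arg(name)
  base <- switch(name,
    A = list(tumble = 100L, population = 22L, iterations = 100L, swim = 0L,
             swarm = swarm_params(w_repel = 0.001)),
    B = list(tumble = 160L, population = 44L, iterations = 200L, swim = 0L,
             swarm = swarm_params(w_repel = 0.001)),
    C = list(tumble = 180L, population = 88L, iterations = 400L, swim = 0L,
             swarm = swarm_params(w_repel = 0.001)),
    D = list(tumble = 330L, population = 120L, iterations = 800L, swim = 0L,
             swarm = swarm_params(w_repel = 0.001)),
    K = list(tumble = 200L, population = 120L, iterations = 33L, swim = 50L,
             swarm = swarm_params(w_repel = 0.002)),
    dtp = list(tumble = 100L, population = 8L, iterations = 200L, swim = 1L,
               swarm = swarm_params(w_repel = 1),
               scoring = scoring_config(normalize = TRUE),
               nfe_mode = "per_matrix", elitism = 1L)
  )
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(scheme_config, args)
}

new_run_trace <- function(iterations, best, algorithm, config) {
  structure(
    list(iterations = iterations, best = best, algorithm = algorithm,
         config = config),
    class = "run_trace"
  )
}

#' @export
print.run_trace <- function(x, ...) {
  df <- x$iterations
  cat(sprintf("run_trace: %s, %d iterations\n", x$algorithm, nrow(df)))
  cat(sprintf("  final best fitness %.4f (blosum %.4f, interaction %.4f)\n",
              df$best_fitness[nrow(df)], df$best_blosum[nrow(df)],
              df$best_interaction[nrow(df)]))
  cat(sprintf("  cumulative NFE %s, elapsed %.2f s\n",
              format(df$nfe[nrow(df)], big.mark = ","),
              df$elapsed_s[nrow(df)]))
  invisible(x)
}

init_population <- function(seqs, cfg) {
  base <- bacterium(seqs)
  lapply(seq_len(cfg$population), function(k) tumble(base, cfg$tumble))
}

run_engine <- function(seqs, cfg, variant, workers = 1L) {
  if (inherits(seqs, "seq_records") && nrow(seqs) < 2L ||
      (is.character(seqs) && length(seqs) < 2L)) {
    stop("need at least 2 sequences")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  elitist <- variant == "bfoadtp"
  S <- cfg$population
  pop <- init_population(seqs, cfg)
  elite_idx <- integer(0)
  nfe <- 0
  t0 <- proc.time()[["elapsed"]]
  rows <- vector("list", cfg$iterations)
  g_best <- list(fitness = -Inf, blosum = NA_real_, interaction = NA_real_,
                 bact = NULL)
  for (iter in seq_len(cfg$iterations)) {
    for (k in seq_len(S)) {
      if (elitist && k %in% elite_idx) next   # elites skip chemotaxis
      b <- pop[[k]]
      if (cfg$tumble_each_iter && cfg$tumble > 0L) b <- tumble(b, cfg$tumble)
      if (cfg$swim > 0L) b <- swim(b, cfg$swim)
      pop[[k]] <- clean_gap_columns(b)
    }
    tables <- fitness_table(pop, cfg$scoring, cfg$swarm, workers = workers)
    nfe <- record_nfe(nfe, cfg$nfe_mode, S)
    best_k <- which.max(tables$fitness)    # ties -> lowest index
    iter_best_bact <- pop[[best_k]]
    worst <- order(tables$fitness)[seq_len(min(cfg$replace_count, S - 1L))]
    worst <- setdiff(worst, c(best_k, if (elitist) elite_idx))
    if (elitist) {
      # global-best substitution: the reported best never worsens
      if (tables$fitness[best_k] > g_best$fitness) {
        g_best <- list(fitness = tables$fitness[best_k],
                       blosum = tables$blosum[best_k],
                       interaction = tables$interaction[best_k],
                       bact = pop[[best_k]])
      }
      rep_fit <- g_best$fitness
      rep_blo <- g_best$blosum
      rep_int <- g_best$interaction
    } else {
      rep_fit <- tables$fitness[best_k]
      rep_blo <- tables$blosum[best_k]
      rep_int <- tables$interaction[best_k]
    }
    # reproduction: worst replaced by copies of the iteration's best
    fit <- tables$fitness
    for (w in worst) {
      pop[[w]] <- pop[[best_k]]
      fit[w] <- fit[best_k]
    }
    if (elitist) {
      elite_idx <- order(-fit)[seq_len(min(cfg$elitism, S))]
    }
    rows[[iter]] <- data.frame(
      iteration = iter, best_fitness = rep_fit, best_blosum = rep_blo,
      best_interaction = rep_int, nfe = nfe,
      elapsed_s = proc.time()[["elapsed"]] - t0
    )
  }
  final_best <- if (elitist) g_best$bact else iter_best_bact
  new_run_trace(do.call(rbind, rows), best = final_best,
                algorithm = variant, config = cfg)
}

#' Run the base bacterial foraging optimizer
#'
#' Each iteration: every bacterium tumbles (inserts `cfg$tumble` random
#' gaps), is re-rectangularized and cleaned of all-gap columns, the
#' population is scored (BLOSUM sum-of-pairs plus swarm interaction), and
#' the worst bacterium is replaced by a copy of the best. The trace records
#' each iteration's best — there is no elitism, so the reported best may
#' worsen across iterations as gaps accumulate.
#'
#' @param seqs A `seq_records` data frame (or character vector of
#'   sequences), at least 2 sequences.
#' @param cfg A [scheme_config()] with `swim = 0`.
#' @param workers Parallel workers for the scoring pass; results are
#'   identical for any worker count.
#' @return A `run_trace`: `$iterations` data frame (`iteration`,
#'   `best_fitness`, `best_blosum`, `best_interaction`, `nfe`,
#'   `elapsed_s`), `$best` bacterium, `$algorithm`, `$config`.
#' @export
run_bfoa <- function(seqs, cfg, workers = 1L) {
  if (cfg$swim != 0L) stop("base variant requires swim = 0; see run_bfoad()")
  run_engine(seqs, cfg, "bfoa", workers)
}

#' Run the gap-deletion (swim) variant
#'
#' As [run_bfoa()], but after each tumble every bacterium swims: `cfg$swim`
#' random gaps are deleted (50 under scheme `K`) to counter gap saturation.
#'
#' @inheritParams run_bfoa
#' @param cfg A [scheme_config()] with `swim > 0`.
#' @return A `run_trace`.
#' @export
run_bfoad <- function(seqs, cfg, workers = 1L) {
  if (cfg$swim <= 0L) stop("gap-deletion variant requires swim > 0")
  run_engine(seqs, cfg, "bfoad", workers)
}

#' Run the elitist variant with normalized scoring
#'
#' As [run_bfoad()], plus: (i) the `cfg$elitism` best bacteria are carried
#' unchanged (no chemotaxis) into the next iteration; (ii) global-best
#' tracking — an iteration's best is discarded from the report if it is not
#' better than the best of any previous iteration, so the best-fitness
#' trace is monotone non-decreasing; (iii) NFE counted per alignment matrix
#' (`+ population` per iteration); (iv) BLOSUM scores normalized to mean
#' per-pair values.
#'
#' @inheritParams run_bfoa
#' @param cfg A [scheme_config()] with `scoring$normalize = TRUE`,
#'   `elitism >= 1` and `nfe_mode = "per_matrix"` (see
#'   `scheme_preset("dtp")`).
#' @return A `run_trace` whose `best_fitness` column is monotone
#'   non-decreasing.
#' @export
run_bfoadtp <- function(seqs, cfg, workers = 1L) {
  if (!isTRUE(cfg$scoring$normalize)) {
    stop("elitist variant requires normalized scoring")
  }
  if (cfg$elitism < 1L) stop("elitist variant requires elitism >= 1")
  if (cfg$nfe_mode != "per_matrix") {
    stop("elitist variant counts NFE per matrix")
  }
  run_engine(seqs, cfg, "bfoadtp", workers)
}
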