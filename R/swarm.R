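#' Swarm attraction/repulsion parameters
#'
#' Coefficients of the Gaussian cell-to-cell interaction: a negative
#' attraction well of depth `d_attr` and width `w_attr`, plus a positive
#' repulsion hill of height `h_repel` and width `w_repel`. Defaults are the
#' first-phase scheme values (`w_repel` varies by scheme: 0.001, 0.002,
#' or 1).
#'
#' @param d_attr Attraction depth (>= 0).
#' @param w_attr Attraction width (>= 0).
#' @param h_repel Repulsion height (>= 0).
#' @param w_repel Repulsion width (>= 0).
#' @return A list of class `swarm_params`.
#' @export
swarm_params <- function(d_attr = 0.1, w_attr = 0.002, h_repel = 0.1,
                         w_repel = 0.001) {
  vals <- c(d_attr = d_attr, w_attr = w_attr, h_repel = h_repel,
            w_repel = w_repel)
  if (any(vals < 0)) stop("swarm parameters must be >= 0")
  structure(as.list(vals), class = "swarm_params")
}

#' Coordinate of a bacterium for the interaction distance
#'
#' The swarm interaction is defined over squared distances between bacteria
#' in a P-dimensional space. For alignment matrices we use the minimal
#' embedding P = 1: a bacterium's coordinate is its (scalar) BLOSUM
#' sum-of-pairs score, so bacteria with similar alignment quality attract
#' and repel most strongly.
#'
#' @param blosum The bacterium's BLOSUM score (must already be computed).
#' @return Numeric vector of length 1.
#' @export
coordinate_of <- function(blosum) {
  if (length(blosum) != 1L || !is.finite(blosum)) {
    stop("bacterium is not scored: need one finite blosum value")
  }
  as.numeric(blosum)
}

#' Attraction and repulsion felt by one bacterium
#'
#' For bacterium `k` in a population with coordinates `coords`:
#' `attract = sum_i -d_attr * exp(-w_attr * D_ki)` and
#' `repel   = sum_i  h_repel * exp(-w_repel * D_ki)`, with
#' `D_ki` the squared Euclidean distance between coordinates. The sums run
#' over all `i` including `i = k` (the self-term contributes the constant
#' `-d_attr + h_repel`, which is harmless to ranking).
#'
#' @param k Bacterium index (1-based).
#' @param coords Numeric vector (P = 1) or matrix (rows = bacteria) of
#'   population coordinates.
#' @param p A [swarm_params()].
#' @return List with components `attract` (<= 0), `repel` (>= 0) and
#'   `interaction = attract + repel`.
#' @export
interaction <- function(k, coords, p) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1L)
  S <- nrow(coords)
  if (S < 1L) stop("empty population")
  if (k < 1L || k > S) stop("bacterium index out of range")
  D <- rowSums((coords - matrix(coords[k, ], S, ncol(coords),
                                byrow = TRUE))^2)
  attract <- sum(-p$d_attr * exp(-p$w_attr * D))
  repel <- sum(p$h_repel * exp(-p$w_repel * D))
  list(attract = attract, repel = repel, interaction = attract + repel)
}

#' Score tables for a population
#'
#' Fills the per-bacterium score tables: BLOSUM score, attraction,
#' repulsion, their sum (interaction), and total fitness
#' `fitness = blosum + attract + repel`. These tables are the shared
#' "notebooks" of the parallel design: each worker writes only its own
#' bacterium's slot, and the interaction pass starts only after all BLOSUM
#' slots are filled.
#'
#' @param bacteria List of rectangular `bacterium` objects.
#' @param cfg A [scoring_config()].
#' @param p A [swarm_params()].
#' @param workers Parallel workers for the BLOSUM pass.
#' @return A data frame of class `score_tables` with columns `blosum`,
#'   `attract`, `repel`, `interaction`, `fitness` (one row per bacterium).
#' @export
fitness_table <- function(bacteria, cfg, p, workers = 1L) {
  S <- length(bacteria)
  if (S < 1L) stop("empty population")
  score_one <- function(i) {
    tryCatch(blosum_score(bacteria[[i]], cfg),
             error = function(e) stop("bacterium ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (workers > 1L && .Platform$OS.type == "unix") {
    blosum <- unlist(parallel::mclapply(seq_len(S), score_one,
                                        mc.cores = workers))
  } else {
    blosum <- vapply(seq_len(S), score_one, numeric(1))
  }
  coords <- matrix(vapply(blosum, coordinate_of, numeric(1)), ncol = 1L)
  inter <- lapply(seq_len(S), interaction, coords = coords, p = p)
  attract <- vapply(inter, `[[`, numeric(1), "attract")
  repel <- vapply(inter, `[[`, numeric(1), "repel")
  structure(
    data.frame(blosum = blosum, attract = attract, repel = repel,
               interaction = attract + repel,
               fitness = blosum + attract + repel),
    class = c("score_tables", "data.frame")
  )
}

#' Advance the cumulative function-evaluation counter
#'
#' Two bookkeeping conventions are supported. `per_interaction` counts
#' every attraction and every repulsion term over all ordered bacterium
#' pairs (`+ 2 * S^2` per population evaluation) — the convention of the
#' base and gap-deletion variants. `per_matrix` counts one evaluation per
#' bacterium alignment matrix (`+ S`) — the convention of the elitist
#' variant and the GA.
#'
#' @param nfe Current cumulative count.
#' @param mode `"per_interaction"` or `"per_matrix"`.
#' @param S Population size (>= 1).
#' @return The updated cumulative count.
#' @examples
#' record_nfe(0, "per_matrix", 8)        # 8
#' record_nfe(0, "per_interaction", 1)   # 2
#' @export
record_nfe <- function(nfe, mode = c("per_interaction", "per_matrix"), S) {
  mode <- match.arg(mode)
  if (S < 1L) stop("population size must be >= 1")
  nfe + switch(mode, per_interaction = 2 * S * S, per_matrix = S)
}
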