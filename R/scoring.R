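#' Scoring configuration
#'
#' Bundles the substitution matrix and gap conventions used to score a
#' bacterium's pair list:
#' * residue vs residue: BLOSUM62 lookup;
#' * indel (exactly one gap): `-indel_penalty` (0.1 by default);
#' * gap vs gap: `gap_gap_score` (0 by default — double-gap pairs carry no
#'   information, and all-gap columns are removed anyway);
#' * `X` / `*`, and `N` under the DNA alphabet, are ambiguity codes scored
#'   0 (under the protein alphabet `N` is asparagine and uses the matrix).
#'
#' DNA inputs are scored with the same BLOSUM62 lookup on the `A,C,G,T`
#' letters (all valid amino-acid codes): one evaluator serves both genetic
#' and protein sets. `normalize = TRUE` reports the mean per-pair score
#' instead of the raw sum, which is scale-stable across alignment lengths.
#'
#' @param matrix_name Substitution matrix; only `"BLOSUM62"` is shipped.
#' @param indel_penalty Penalty subtracted for each residue-gap pair.
#' @param gap_gap_score Score of a gap-gap pair.
#' @param normalize Report mean per-pair score rather than the raw sum.
#' @param alphabet `"protein"` or `"dna"`; controls whether `N` is an
#'   ambiguity code (DNA) or asparagine (protein).
#' @return A list of class `scoring_config`, with the residue-pair lookup
#'   table precomputed in `$lookup`.
#' @export
scoring_config <- function(matrix_name = "BLOSUM62", indel_penalty = 0.1,
                           gap_gap_score = 0, normalize = FALSE,
                           alphabet = c("protein", "dna")) {
  matrix_name <- match.arg(matrix_name)
  alphabet <- match.arg(alphabet)
  if (indel_penalty < 0) stop("indel_penalty must be >= 0")
  blosum <- load_substitution_matrix(matrix_name)
  structure(
    list(matrix_name = matrix_name, indel_penalty = indel_penalty,
         gap_gap_score = gap_gap_score, normalize = normalize,
         alphabet = alphabet,
         lookup = build_pair_lookup(blosum, indel_penalty, gap_gap_score,
                                    alphabet)),
    class = "scoring_config"
  )
}

#' Load a substitution matrix shipped with the package
#'
#' Parses the plain-text NCBI-format matrix vendored under `extdata`.
#'
#' @param name Matrix name (`"BLOSUM62"`).
#' @return A symmetric numeric matrix with residue dimnames.
#' @export
load_substitution_matrix <- function(name = "BLOSUM62") {
  path <- system.file("extdata", paste0(name, ".txt"), package = "bfoalign",
                      mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  body <- do.call(rbind, strsplit(trimws(lines[-1L]), "\\s+"))
  mat <- apply(body[, -1L, drop = FALSE], 2L, as.numeric)
  dimnames(mat) <- list(body[, 1L], cols)
  stopifnot(isSymmetric(unname(mat)))
  mat
}

# Full character-pair score table including gap and ambiguity conventions,
# so scoring is a single vectorized lookup.
build_pair_lookup <- function(blosum, indel_penalty, gap_gap_score, alphabet) {
  ambig <- if (alphabet == "dna") c("N", "X", "*") else c("X", "*")
  chars <- c(rownames(blosum), "-")
  full <- matrix(NA_real_, length(chars), length(chars),
                 dimnames = list(chars, chars))
  full[rownames(blosum), colnames(blosum)] <- blosum
  full[ambig, ] <- 0
  full[, ambig] <- 0
  full["-", ] <- -indel_penalty
  full[, "-"] <- -indel_penalty
  full["-", "-"] <- gap_gap_score
  full
}

#' Score one aligned character pair
#'
#' @param a,b Single characters from the alphabet, a gap `-`, or an
#'   ambiguity code.
#' @param cfg A [scoring_config()].
#' @return The pair score (BLOSUM62 value, `-indel_penalty` for an indel,
#'   `gap_gap_score` for a double gap, 0 for ambiguity codes).
#' @examples
#' cfg <- scoring_config()
#' score_pair("A", "A", cfg)   # 4
#' score_pair("A", "-", cfg)   # -0.1
#' @export
score_pair <- function(a, b, cfg) {
  lk <- cfg$lookup
  if (!a %in% rownames(lk)) stop("character '", a, "' not in scoring matrix")
  if (!b %in% rownames(lk)) stop("character '", b, "' not in scoring matrix")
  lk[a, b]
}

#' BLOSUM sum-of-pairs score of a bacterium
#'
#' Sums [score_pair()] over the full column pair list of the alignment
#' matrix: every unordered pair of rows, every column. With
#' `cfg$normalize` the raw sum is divided by the number of pairs
#' (`ncol * choose(nrow, 2)`). Work can be split over parallel workers by
#' row pair; partial sums are accumulated in a fixed partition order, so
#' the result is bit-identical for any worker count.
#'
#' @param bact A rectangular `bacterium` with >= 2 rows.
#' @param cfg A [scoring_config()].
#' @param workers Number of parallel workers (forked; serial if 1 or on
#'   platforms without fork).
#' @return The (possibly normalized) sum-of-pairs score.
#' @export
blosum_score <- function(bact, cfg, workers = 1L) {
  n <- nrow(bact)
  if (n < 2L) stop("need at least 2 sequences to score")
  if (ncol(bact) == 0L) stop("degenerate alignment: zero-width matrix")
  mat <- unclass(bact)
  bad <- setdiff(unique(as.vector(mat)), rownames(cfg$lookup))
  if (length(bad)) stop("character '", bad[1L], "' not in scoring matrix")
  lk <- cfg$lookup
  pairs <- utils::combn(n, 2L)
  pair_sum <- function(j) sum(lk[cbind(mat[pairs[1L, j], ], mat[pairs[2L, j], ])])
  chunks <- seq_len(ncol(pairs))
  if (workers > 1L && .Platform$OS.type == "unix") {
    parts <- parallel::mclapply(chunks, pair_sum, mc.cores = workers)
  } else {
    parts <- lapply(chunks, pair_sum)
  }
  total <- sum(unlist(parts))           # fixed order: chunk index
  if (isTRUE(cfg$normalize)) total / (ncol(mat) * ncol(pairs)) else total
}
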