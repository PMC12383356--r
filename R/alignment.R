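#' Construct a bacterium (candidate alignment matrix)
#'
#' A bacterium is one candidate solution to the alignment problem: an
#' `n x m` character matrix whose rows are the gapped input sequences.
#' Ragged input rows are padded with trailing gaps ([cuadra()]), so the
#' result is always rectangular. Every matrix operator in the package
#' conserves each row's gap-stripped residue content.
#'
#' @param rows Character vector of (possibly gapped, possibly ragged)
#'   sequence strings, a `seq_records` data frame, or a character matrix
#'   of single characters.
#' @param ids Optional row ids; taken from `rows$id` for `seq_records`.
#' @return A character matrix of class `bacterium` (rows = sequences).
#' @examples
#' b <- bacterium(c("ACGT", "AC"))
#' as_strings(b)   # "ACGT" "AC--"
#' @export
bacterium <- function(rows, ids = NULL) {
  if (inherits(rows, "seq_records")) {
    ids <- rows$id
    rows <- rows$residues
  }
  if (is.matrix(rows)) {
    mat <- rows
  } else {
    if (!is.character(rows)) stop("rows must be strings or a character matrix")
    mat <- pad_to_matrix(strsplit(rows, "", fixed = TRUE))
  }
  if (!is.null(ids)) rownames(mat) <- ids
  class(mat) <- c("bacterium", class(mat))
  mat
}

pad_to_matrix <- function(rows_list) {
  m <- max(lengths(rows_list), 0L)
  mat <- matrix("-", nrow = length(rows_list), ncol = m)
  for (i in seq_along(rows_list)) {
    li <- length(rows_list[[i]])
    if (li) mat[i, seq_len(li)] <- rows_list[[i]]
  }
  mat
}

as_bacterium <- function(mat, template = NULL) {
  if (!is.null(template)) rownames(mat) <- rownames(template)
  class(mat) <- c("bacterium", "matrix", "array")
  mat
}

#' Gapped row strings of a bacterium
#' @param bact A `bacterium`.
#' @return Character vector of gapped row strings.
#' @export
as_strings <- function(bact) {
  unname(apply(unclass(bact), 1L, paste, collapse = ""))
}

#' Remove gap characters from strings
#' @param x Character vector of (gapped) sequence strings.
#' @return `x` with every `-` removed.
#' @export
gapstrip <- function(x) gsub("-", "", x, fixed = TRUE)

#' @export
print.bacterium <- function(x, ...) {
  s <- as_strings(x)
  cat(sprintf("bacterium: %d x %d alignment matrix\n", nrow(x), ncol(x)))
  show <- if (length(s) > 8L) c(utils::head(s, 8L), "...") else s
  cat(substr(show, 1L, 70L), sep = "\n")
  invisible(x)
}

#' Pad rows to a common length ("cuadra")
#'
#' Ensures all rows of the alignment matrix have the same length by filling
#' the shorter ones with trailing gaps. Idempotent on rectangular input;
#' residue order is never changed.
#'
#' @param bact A `bacterium`, or a character vector / list of possibly
#'   ragged row strings.
#' @return A rectangular `bacterium`.
#' @export
cuadra <- function(bact) {
  if (inherits(bact, "bacterium")) return(bact)  # matrices are rectangular
  bacterium(if (is.list(bact)) vapply(bact, paste, "", collapse = "") else bact)
}

cuadra_list <- function(rows_list, template = NULL) {
  as_bacterium(pad_to_matrix(rows_list), template)
}

#' Indices of all-gap columns
#'
#' @param bact A rectangular `bacterium`.
#' @return Integer vector (1-based) of columns consisting only of gaps.
#' @export
gap_column_indices <- function(bact) {
  if (ncol(bact) == 0L) return(integer(0))
  which(colSums(unclass(bact) == "-") == nrow(bact))
}

#' Remove all-gap columns
#'
#' Columns made entirely of gaps carry no pair information and are removed;
#' the relative order of the remaining columns is preserved. If every
#' column is all-gap the result is a legal zero-width matrix (scoring such
#' a degenerate alignment is an error).
#'
#' @param bact A rectangular `bacterium`.
#' @return A `bacterium` with no all-gap columns.
#' @export
clean_gap_columns <- function(bact) {
  idx <- gap_column_indices(bact)
  if (!length(idx)) return(bact)
  as_bacterium(unclass(bact)[, -idx, drop = FALSE], bact)
}

#' Chemotactic tumble: random gap insertion
#'
#' Inserts `num_gaps` gap characters, each at a uniformly chosen row and
#' uniformly chosen intra-row position (inclusive of both ends), then pads
#' back to rectangular. The input is not mutated; randomness comes from
#' R's global RNG, so a fixed seed gives identical output.
#'
#' @param bact A `bacterium`.
#' @param num_gaps Number of gaps to insert (>= 0).
#' @return A new `bacterium`.
#' @export
tumble <- function(bact, num_gaps) {
  if (num_gaps < 0L) stop("num_gaps must be >= 0")
  rows <- apply(unclass(bact), 1L, function(r) r, simplify = FALSE)
  n <- length(rows)
  for (g in seq_len(num_gaps)) {
    r <- sample.int(n, 1L)
    pos <- sample.int(length(rows[[r]]) + 1L, 1L) - 1L   # 0..len inclusive
    rows[[r]] <- append(rows[[r]], "-", after = pos)
  }
  cuadra_list(rows, bact)
}

#' Swim step: random gap deletion
#'
#' Deletes up to `num_deletions` gap characters, each chosen uniformly
#' among the existing gap positions (padding included); if fewer gaps
#' exist, all are removed. The matrix is then re-rectangularized and
#' cleaned of all-gap columns. Counters gap saturation of the alignment.
#'
#' @param bact A `bacterium`.
#' @param num_deletions Number of gaps to delete (>= 0).
#' @return A new `bacterium`.
#' @export
swim <- function(bact, num_deletions) {
  if (num_deletions < 0L) stop("num_deletions must be >= 0")
  mat <- unclass(bact)
  gap_pos <- which(mat == "-")          # column-major linear indices
  k <- min(num_deletions, length(gap_pos))
  if (k == 0L) return(clean_gap_columns(bact))
  drop <- if (length(gap_pos) == 1L) gap_pos else sample(gap_pos, k)
  keep <- matrix(TRUE, nrow(mat), ncol(mat))
  keep[drop] <- FALSE
  rows <- lapply(seq_len(nrow(mat)), function(i) mat[i, keep[i, ]])
  clean_gap_columns(cuadra_list(rows, bact))
}

#' All unordered residue pairs per column
#'
#' Builds the evaluable pair list: for every column of the matrix, all
#' `choose(n, 2)` unordered pairs of row characters. This list is the unit
#' of sum-of-pairs scoring.
#'
#' @param bact A rectangular `bacterium` with >= 2 rows.
#' @return A data frame with columns `a`, `b` (characters) and `column`
#'   (1-based column index), of `ncol * choose(nrow, 2)` rows.
#' @export
column_pairs <- function(bact) {
  n <- nrow(bact)
  if (n < 2L) stop("need at least 2 rows to form pairs")
  m <- ncol(bact)
  idx <- utils::combn(n, 2L)
  mat <- unclass(bact)
  data.frame(
    a = as.vector(mat[idx[1L, ], , drop = FALSE]),
    b = as.vector(mat[idx[2L, ], , drop = FALSE]),
    column = rep(seq_len(m), each = ncol(idx))
  )
}

#' Closed-form pairwise-comparison count
#'
#' Number of pairwise character evaluations needed to score `matrices`
#' alignment matrices of `n` sequences by `m` columns:
#' `matrices * m * choose(n, 2)`.
#'
#' @param n Number of sequences (>= 2).
#' @param m Alignment length (>= 1).
#' @param matrices Number of matrices (>= 1).
#' @return The total count, as a double (counts overflow 32-bit integers).
#' @examples
#' count_pairs(100, 100, 100)  # 49,500,000
#' @export
count_pairs <- function(n, m, matrices = 1) {
  if (n < 2 || m < 1 || matrices < 1) stop("need n >= 2, m >= 1, matrices >= 1")
  as.numeric(matrices) * as.numeric(m) * n * (n - 1) / 2
}

#' Wall-time estimate for pairwise evaluation
#'
#' Converts a pairwise-comparison count into an idealized evaluation time
#' under perfect linear scaling over parallel workers.
#'
#' @inheritParams count_pairs
#' @param ms_per_pair Cost of one pairwise evaluation, in milliseconds.
#' @param workers Number of parallel workers.
#' @return Time in seconds.
#' @examples
#' pair_eval_seconds(100, 100, 100) / 3600          # 13.75 h sequential
#' pair_eval_seconds(100, 100, 100, workers = 16) / 60  # ~52 min
#' @export
pair_eval_seconds <- function(n, m, matrices = 1, ms_per_pair = 1, workers = 1) {
  count_pairs(n, m, matrices) * ms_per_pair / 1000 / workers
}
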