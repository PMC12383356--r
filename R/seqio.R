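#' Read sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a data frame of sequence records.
#' Residues are case-folded to upper case (substitution-matrix lookups are
#' uppercase-keyed) and validated against the declared alphabet; the gap
#' character `-` and the ambiguity codes `N` (DNA) / `X` are always accepted.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"dna"`, `"protein"` or `"auto"`. With `"auto"`
#'   the file is classified as DNA iff the union of all residues is a subset
#'   of `{A,C,G,T,N,-}`, otherwise as protein.
#' @return A data frame of class `seq_records` with columns `id`,
#'   `description` and `residues`, one row per FASTA record, and attribute
#'   `alphabet` giving the resolved alphabet.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 first", "ACGT", ">s2", "AC-G"), fa)
#' read_fasta(fa, alphabet = "dna")
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, " (", conditionMessage(e), ")")
  )
  if (length(set) == 0L) {
    stop("FASTA format error: no records in ", path)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- gsub("\\s", "", toupper(as.character(set)))
  names(residues) <- NULL
  if (any(ids == "")) stop("FASTA format error: empty header in ", path)
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate record id '", ids[duplicated(ids)][1L], "'")
  }
  if (any(nchar(residues) == 0L)) {
    stop("FASTA format error: record '", ids[nchar(residues) == 0L][1L], "' has no residues")
  }
  recs <- new_seq_records(ids, desc, residues)
  resolved <- resolve_alphabet(recs, alphabet)
  validate_alphabet(recs, resolved)
  attr(recs, "alphabet") <- resolved
  recs
}

new_seq_records <- function(id, description, residues) {
  structure(
    data.frame(id = id, description = description, residues = residues,
               stringsAsFactors = FALSE),
    class = c("seq_records", "data.frame")
  )
}

ALPHABETS <- list(
  dna = c("A", "C", "G", "T", "N"),
  protein = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "J", "X")
)

resolve_alphabet <- function(records, alphabet) {
  if (alphabet != "auto") return(alphabet)
  chars <- unique(unlist(strsplit(records$residues, "", fixed = TRUE)))
  if (all(chars %in% c("A", "C", "G", "T", "N", "-"))) "dna" else "protein"
}

#' Validate record residues against an alphabet
#'
#' @param records A `seq_records` data frame.
#' @param alphabet `"dna"` or `"protein"`.
#' @return `records`, invisibly; errors if any residue falls outside the
#'   alphabet (plus `-`).
#' @export
validate_alphabet <- function(records, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  allowed <- c(ALPHABETS[[alphabet]], "-")
  for (i in seq_len(nrow(records))) {
    chars <- strsplit(records$residues[i], "", fixed = TRUE)[[1L]]
    bad <- setdiff(chars, allowed)
    if (length(bad)) {
      stop("invalid ", alphabet, " character '", bad[1L], "' in record '",
           records$id[i], "'")
    }
  }
  invisible(records)
}

#' Write sequence records to a FASTA file
#'
#' Round-trips with [read_fasta()]: ids and residues are preserved exactly
#' (line wrapping aside).
#'
#' @param records A `seq_records` data frame (or anything with `id`,
#'   `description`, `residues` columns).
#' @param path Output file path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (nrow(records) == 0L) {
    # degenerate but legal: an empty FASTA file
    cat("", file = path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(records$description == "", records$id,
                       paste(records$id, records$description))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a run trace to CSV
#'
#' Exports the per-iteration record of a run with the canonical column set
#' `iteration, best_fitness, blosum_score, interaction, nfe, elapsed_s`.
#'
#' @param trace A `run_trace` object (see [run_bfoa()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- trace$iterations
  out <- data.frame(
    iteration = df$iteration,
    best_fitness = df$best_fitness,
    blosum_score = df$best_blosum,
    interaction = df$best_interaction,
    nfe = df$nfe,
    elapsed_s = df$elapsed_s
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a run trace CSV written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @return A `run_trace` object (without a final alignment).
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  new_run_trace(
    data.frame(
      iteration = df$iteration,
      best_fitness = df$best_fitness,
      best_blosum = df$blosum_score,
      best_interaction = df$interaction,
      nfe = df$nfe,
      elapsed_s = df$elapsed_s
    ),
    best = NULL, algorithm = NA_character_, config = NULL
  )
}
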