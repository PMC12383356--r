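# shared helpers: random matrices and tiny families built in code

random_letters <- function(n, alphabet = "protein") {
  sample(bfoalign:::sim_letters(alphabet), n, replace = TRUE)
}

# random rectangular bacterium with a given gap fraction
random_bacterium <- function(n, m, gap_frac = 0.2, alphabet = "protein") {
  chars <- random_letters(n * m, alphabet)
  chars[stats::runif(n * m) < gap_frac] <- "-"
  bacterium(matrix(chars, nrow = n, ncol = m))
}

tiny_family <- function(seed = 11, n = 4, len = 30) {
  generate_family(family_spec(
    n_sequences = n, ancestor_length = len, alphabet = "protein",
    substitution_rate = 0.1, indel_rate = 0.05, seed = seed
  ))
}

# independent brute-force sum-of-pairs oracle: explicit loops over the
# column pair list, one score_pair call per pair
brute_force_sp <- function(bact, cfg) {
  pairs <- column_pairs(bact)
  total <- 0
  for (i in seq_len(nrow(pairs))) {
    total <- total + score_pair(pairs$a[i], pairs$b[i], cfg)
  }
  total
}

# literal scalar transcription of the interaction sums for one bacterium
brute_force_interaction <- function(k, coords, p) {
  attract <- 0
  repel <- 0
  for (i in seq_along(coords)) {
    d2 <- (coords[k] - coords[i])^2
    attract <- attract + (-p$d_attr * exp(-p$w_attr * d2))
    repel <- repel + p$h_repel * exp(-p$w_repel * d2)
  }
  c(attract = attract, repel = repel)
}
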