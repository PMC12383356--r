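Package: bfoalign
Title: Bacterial Foraging Optimization for Multiple Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A list-based, parallelizable implementation of the Bacterial
    Foraging Optimization Algorithm (BFOA) for the multiple sequence
    alignment problem, in three variants: the base chemotactic algorithm
    (gap-insertion tumbling), a gap-deletion variant with a swim step
    (BFOAd), and an elitist variant with normalized scoring and
    global-best tracking (BFOAdtp). Candidate alignments are scored by a
    BLOSUM62 sum-of-pairs objective with an indel penalty, combined with
    a Gaussian attraction-repulsion swarm interaction term. Includes a
    Genetic Algorithm baseline with roulette selection and repaired
    two-point crossover, a synthetic homologous sequence-family
    generator, convergence and z-score run analysis, NFE-to-threshold
    comparison, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
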