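# Generators: determinism, degenerate limits, moment fidelity, truth
# sidecars.

test_that("zero-mutation, zero-divergence spec yields identical sequences", {
  s <- simulateSequences(4, 100, theta_within = 0, d_between = 0, seed = 1)
  seqs <- as.character(panelSeqs(s$panel))
  expect_length(unique(seqs), 1)
})

test_that("sequence simulation is byte-identical under a fixed seed", {
  s1 <- simulateSequences(5, 200, 2, 0.05, seed = 7)
  s2 <- simulateSequences(5, 200, 2, 0.05, seed = 7)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  writeFastaPanel(s1$panel, f1); writeFastaPanel(s2$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
})

test_that("oversized mutation expectation is refused with a sizing error", {
  expect_error(simulateSequences(20, 10, theta_within = 50,
                                 d_between = 0, seed = 1),
               "exceeds alignment length")
})

test_that("between-clade divergence matches the requested d_between", {
  means <- vapply(1:100, function(s) {
    sim <- simulateSequences(5, 1000, theta_within = 0, d_between = 0.078,
                             seed = s)
    groupDivergence(sim$panel, "A", "B")[["mean"]]
  }, 0)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.078), 3 * se)
})

test_that("genotype simulation hits its limits and reproduces itself", {
  g0 <- simulateGenotypes(3, 4, 5, fst = 0, n_per_group = 200,
                          missing_rate = 0, seed = 3)
  # fst = 0: all groups draw from one frequency vector -> across-group
  # allele-frequency spread shrinks toward sampling noise
  fr <- g0$truth$realized$group_allele_freqs[[1]]
  expect_true(all(apply(fr, 2, function(col) diff(range(col))) < 1e-12))
  g1 <- simulateGenotypes(3, 6, 5, 0.3, 20, 0.1, seed = 11)
  g2 <- simulateGenotypes(3, 6, 5, 0.3, 20, 0.1, seed = 11)
  expect_identical(genotypeAlleles(g1$genotypes),
                   genotypeAlleles(g2$genotypes))
  expect_error(simulateGenotypes(2, 3, 4, fst = 1, n_per_group = 5,
                                 seed = 1))
})

test_that("structured genotypes carry group-private alleles", {
  hits <- vapply(1:100, function(s) {
    g <- simulateGenotypes(3, 12, 6, fst = 0.3, n_per_group = 15,
                           missing_rate = 0, seed = s)
    sum(privateAlleles(g$genotypes)$private_alleles) >= 1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("transect sampling follows the true cline and validates effort", {
  pos <- seq(0, 400, length.out = 9)
  st <- simulateTransect(pos, list(tr = c(center = 200, width = 60)),
                         n_per_locality = 5000, seed = 5)
  tr <- transectTraits(st$transect)$tr
  p_true <- clineValue(pos, c(center = 200, width = 60))
  expect_true(all(abs(tr$k / tr$n - p_true) <
                    3 * sqrt(p_true * (1 - p_true) / 5000) + 1e-3))
  expect_error(simulateTransect(pos, list(tr = c(center = 1, width = 1)),
                                n_per_locality = 0, seed = 1))
  # quantitative traits report per-locality moments
  sq <- simulateTransect(pos, list(q = c(center = 200, width = 60)),
                         trait_kind = c(q = "quantitative"),
                         n_per_locality = 30, sigma = 0.5, seed = 6)
  qt <- transectTraits(sq$transect)$q
  expect_equal(qt$kind, "quantitative")
  expect_true(all(is.finite(qt$mean)) && all(qt$sd > 0))
})

test_that("landscape grids have requested shape, unit range and determinism", {
  l1 <- simulateLandscape(12, 9, seed = 2)
  expect_equal(dim(gridValues(l1$environment)), c(12, 9))
  rd <- gridValues(l1$road_distance)
  expect_equal(range(rd), c(0, 1))
  l2 <- simulateLandscape(12, 9, seed = 2)
  expect_identical(gridValues(l1$environment), gridValues(l2$environment))
})

test_that("truth sidecars round-trip losslessly through JSON", {
  s <- simulateSequences(3, 50, 1, 0.02, seed = 9)
  p <- tempfile(fileext = ".truth.json")
  writeTruth(s$truth, p)
  back <- readTruth(p)
  expect_equal(back$spec$L, 50)
  expect_equal(back$spec$d_between, 0.02)
  expect_equal(back$spec$seed, 9)
  expect_equal(unlist(back$realized$mutations_per_group),
               unlist(s$truth$realized$mutations_per_group))
})
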