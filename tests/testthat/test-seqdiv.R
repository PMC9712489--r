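# Diversity statistics, neutrality tests, networks and divergence against
# hand values and independently coded oracles.

test_that("haplotype collapsing honours each identity rule", {
  p <- makePanel(c("AAA", "AAA", "AAT"))
  hn <- collapseHaplotypes(p)
  expect_equal(sort(hn@multiplicity), c(1L, 2L))
  expect_length(hn@haplos, 2)

  distinct <- randomPanel(6, 40, seed = 2)
  expect_equal(length(collapseHaplotypes(distinct)@haplos), 6)

  pn <- makePanel(c("AAN", "AAT"))
  expect_length(collapseHaplotypes(pn, "strict")@haplos, 2)
  expect_length(collapseHaplotypes(pn, "n_matches")@haplos, 1)
  expect_length(collapseHaplotypes(pn, "mask")@haplos, 1)
})

test_that("segregating sites match a naive column scan", {
  expect_equal(segregatingSites(makePanel(c("AAA", "AAT", "AAA"))), 1)
  expect_equal(segregatingSites(makePanel(rep("ACGT", 4))), 0)
  for (s in 1:50) {
    set.seed(s)
    n <- sample(3:8, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "N", "-"), 100, replace = TRUE,
                   prob = c(.3, .3, .15, .15, .05, .05)), collapse = ""), "")
    expect_equal(segregatingSites(makePanel(seqs)), oracleSegSites(seqs))
  }
})

test_that("theta_pi and pi match hand values and the brute-force pair loop", {
  p <- makePanel(c("AAAAAAAAAA", "AAAAAAAAAT"))
  expect_equal(thetaPi(p)[["estimate"]], 1)
  expect_equal(nucleotideDiversity(p)[["estimate"]], 0.1)

  same <- makePanel(rep("ACGTACGT", 4))
  expect_equal(unname(thetaPi(same)), c(0, 0))

  set.seed(42)
  seqs <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
          collapse = ""), "")
  or <- oraclePairwise(seqs)
  expect_equal(thetaPi(makePanel(seqs))[["estimate"]], or$theta_pi,
               tolerance = 1e-12)
  expect_equal(nucleotideDiversity(makePanel(seqs))[["estimate"]], or$pi,
               tolerance = 1e-12)
})

test_that("Watterson theta follows S / a1", {
  th <- wattersonTheta(5, 5)
  expect_equal(th[["estimate"]], 5 / (1 + 1/2 + 1/3 + 1/4), tolerance = 1e-12)
  expect_equal(th[["estimate"]], 2.4, tolerance = 1e-6)
  expect_equal(wattersonTheta(0, 10)[["estimate"]], 0)
  a1_oracle <- sum(1 / seq_len(682))
  expect_equal(wattersonTheta(682, 683)[["estimate"]], 682 / a1_oracle,
               tolerance = 1e-12)
})

test_that("Tajima's D is zero at the balance point and matches its oracle", {
  n <- 10; S <- 5
  a1 <- sum(1 / seq_len(n - 1))
  expect_equal(clinepop:::tajimasDFromSummary(n, S, S / a1), 0)
  for (s in 1:100) {
    set.seed(1000 + s)
    n <- sample(4:10, 1); L <- sample(20:50, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "T"), L, replace = TRUE,
                   prob = c(.6, .3, .1)), collapse = ""), "")
    D_pkg <- suppressWarnings(tajimasD(makePanel(seqs)))
    D_or <- oracleTajimaD(seqs)
    if (is.na(D_or)) expect_true(is.na(D_pkg))
    else expect_equal(D_pkg, D_or, tolerance = 1e-10)
  }
})

test_that("neutral coalescent panels bracket D = 0", {
  Ds <- vapply(1:120, function(s) {
    sim <- simulateSequences(25, 2000, theta_within = 5, d_between = 0,
                             groups = "A", seed = 2000 + s)
    suppressWarnings(tajimasD(sim$panel))
  }, 0)
  Ds <- Ds[is.finite(Ds)]
  expect_gt(quantile(Ds, 0.975), 0)
  expect_lt(quantile(Ds, 0.025), 0)
})

test_that("Ewens haplotype-count distribution is a proper distribution", {
  for (n in c(2, 10, 50, 200)) {
    lp <- ewensLogProbs(n, theta = 3.7)
    expect_lt(abs(sum(exp(lp)) - 1), 1e-10)
  }
})

test_that("Fu's Fs matches the exact Stirling oracle and flags degeneracy", {
  # K >= 1 is certain: S' = 1, Fs = +Inf, flagged
  fs_degenerate <- clinepop:::fusFSFromTheta(4, 1, 1)
  expect_identical(as.numeric(fs_degenerate), Inf)
  expect_identical(attr(fs_degenerate, "flag"), "degenerate")

  for (case in list(c(6, 2, 4), c(8, 1.3, 3), c(12, 0.7, 5),
                    c(10, 4.2, 9))) {
    n <- case[1]; th <- case[2]; k0 <- case[3]
    Sp <- oracleEwensTail(n, th, k0)
    fs_oracle <- log(Sp / (1 - Sp))
    expect_equal(as.numeric(clinepop:::fusFSFromTheta(n, th, k0)),
                 fs_oracle, tolerance = 1e-8)
  }
})

test_that("Fu's Fs stays finite in log space at large n", {
  expect_true(is.finite(clinepop:::fusFSFromTheta(700, 5, 40)))
  # log-space row agrees with direct-double Stirling magnitudes at n = 50
  lp <- ewensLogProbs(50, 2)
  st_direct <- oracleStirlingRow(50)
  rising <- prod(2 + 0:49)
  direct <- log(st_direct) + seq_len(50) * log(2) - log(rising)
  expect_equal(lp, direct, tolerance = 1e-8)
})

test_that("between-group divergence brackets and symmetry hold", {
  p <- makePanel(c("AAAA", "AAAT"), pops = c("A", "B"))
  expect_equal(unname(groupDivergence(p, "A", "B")), rep(0.25, 3))

  same <- makePanel(c("ACGT", "ACGT"), pops = c("A", "B"))
  expect_equal(unname(groupDivergence(same, "A", "B")), rep(0, 3))

  sim <- simulateSequences(6, 800, theta_within = 1.5, d_between = 0.06,
                           seed = 31)
  ab <- groupDivergence(sim$panel, "A", "B")
  ba <- groupDivergence(sim$panel, "B", "A")
  expect_equal(ab, ba)
  expect_true(ab[["min"]] <= ab[["mean"]] && ab[["mean"]] <= ab[["max"]])
})

test_that("strict-clock conversion is plain division with guarded rate", {
  expect_equal(clockTime(0.0779), 0.0779 / 0.021)
  expect_equal(clockTime(0.0779), 3.71, tolerance = 0.002)
  expect_equal(clockTime(0), 0)
  expect_equal(clockTime(0.021, 0.021), 1)
  expect_error(clockTime(0.05, rate = 0), "positive")
})

test_that("minimum spanning network keeps exactly the MST-supporting edges", {
  # triangle at distances 1, 1, 2: both unit edges kept, the long one not
  hn <- collapseHaplotypes(makePanel(c("AAA", "AAT", "ATA")))
  msn <- buildMSN(hn)
  e <- networkEdges(msn)
  expect_equal(sort(e$dist), c(1, 1, 2))
  expect_identical(e$in_mst[order(e$dist)], c(TRUE, TRUE, FALSE))

  chain <- buildMSN(collapseHaplotypes(makePanel(c("AAA", "AAT", "ATT"))))
  ec <- networkEdges(chain)
  expect_equal(sum(ec$in_mst), 2)
  expect_equal(sum(ec$dist[ec$in_mst]), 2)

  for (s in 1:10) {
    set.seed(300 + s)
    nh <- 8
    seqs <- unique(vapply(seq_len(nh), function(i)
      paste(sample(c("A", "T"), 7, replace = TRUE), collapse = ""), ""))
    net <- buildMSN(collapseHaplotypes(makePanel(seqs)))
    e <- networkEdges(net)
    dm <- matrix(0, length(seqs), length(seqs))
    for (r in seq_len(nrow(e))) {
      dm[e$from[r], e$to[r]] <- e$dist[r]
      dm[e$to[r], e$from[r]] <- e$dist[r]
    }
    orc <- oracleMSNEdges(dm)
    expect_identical(e$in_mst, orc$in_mst)
    # spanning + weight-minimal
    comp <- seq_along(seqs)
    for (r in which(e$in_mst)) {
      ca <- comp[e$from[r]]; cb <- comp[e$to[r]]
      comp[comp == cb] <- ca
    }
    expect_length(unique(comp), 1)
  }
})

test_that("diversity summary table is coherent per group", {
  sim <- simulateSequences(10, 600, theta_within = 3, d_between = 0.07,
                           seed = 17)
  tab <- diversityStats(sim$panel)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$H <= tab$n))
  expect_true(all(tab$pi >= 0) && all(tab$S >= 0))
  expect_equal(tab$theta_pi / 600, tab$pi, tolerance = 1e-9)
})
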