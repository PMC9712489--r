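# Microsatellite statistics against hand arithmetic and recount oracles.

test_that("heterozygosity matches hand arithmetic and a recount oracle", {
  # 10 diploids, allele freqs exactly {0.5, 0.5}: HE = (20/19) * 0.5
  a1 <- matrix(c(rep(1L, 5), rep(2L, 5)), ncol = 1)
  a2 <- matrix(c(rep(1L, 5), rep(2L, 5)), ncol = 1)
  colnames(a1) <- colnames(a2) <- "L01"
  gm <- GenotypeMatrix(a1, a2, pop = rep("P", 10))
  het <- heterozygosity(gm)
  expect_equal(het$HE, 20 / 19 * 0.5, tolerance = 1e-9)
  expect_equal(het$HO, 0)

  mono <- GenotypeMatrix(matrix(1L, 6, 1, dimnames = list(NULL, "L01")),
                         matrix(1L, 6, 1, dimnames = list(NULL, "L01")),
                         pop = rep("P", 6))
  hm <- heterozygosity(mono)
  expect_equal(hm$HO, 0)
  expect_equal(hm$HE, 0)

  g <- simulateGenotypes(2, 5, 4, 0.2, 25, missing_rate = 0.1, seed = 8)
  het <- heterozygosity(g$genotypes)
  al <- genotypeAlleles(g$genotypes)
  grp <- genotypeGroup(g$genotypes)
  for (r in sample(nrow(het), 6)) {
    rows <- which(grp == het$group[r])
    orc <- oracleHetero(al$a1[rows, het$locus[r]],
                        al$a2[rows, het$locus[r]])
    expect_equal(het$HO[r], orc$HO)
    expect_equal(het$HE[r], orc$HE)
  }
})

test_that("HWE exact test agrees with full enumeration on 2-allele tables", {
  # AA = 5, aa = 5, Aa = 0 (maximal heterozygote deficit)
  a1 <- matrix(c(rep(1L, 5), rep(2L, 5)), ncol = 1)
  a2 <- matrix(c(rep(1L, 5), rep(2L, 5)), ncol = 1)
  colnames(a1) <- colnames(a2) <- "L01"
  gm <- GenotypeMatrix(a1, a2, pop = rep("P", 10))
  res <- hweExact(gm, "population", "P", "L01")
  expect_equal(res$method, "enumeration")
  expect_equal(res$p, oracleHwe2(5, 0, 5), tolerance = 1e-12)

  # HWE-proportioned sample: p should be large
  nAA <- 25L; nAa <- 50L; naa <- 25L
  a1 <- matrix(c(rep(1L, nAA), rep(1L, nAa), rep(2L, naa)), ncol = 1)
  a2 <- matrix(c(rep(1L, nAA), rep(2L, nAa), rep(2L, naa)), ncol = 1)
  colnames(a1) <- colnames(a2) <- "L01"
  gmh <- GenotypeMatrix(a1, a2, pop = rep("P", 100))
  res_h <- hweExact(gmh, "population", "P", "L01")
  expect_gt(res_h$p, 0.5)
  expect_equal(res_h$p, oracleHwe2(nAA, nAa, naa), tolerance = 1e-10)

  mono <- GenotypeMatrix(matrix(1L, 5, 1, dimnames = list(NULL, "L01")),
                         matrix(1L, 5, 1, dimnames = list(NULL, "L01")),
                         pop = rep("P", 5))
  expect_equal(hweExact(mono, "population", "P", "L01")$p, 1)
})

test_that("HWE Monte Carlo converges to the enumeration p-value", {
  a1 <- matrix(c(rep(1L, 12), rep(1L, 6), rep(2L, 10)), ncol = 1)
  a2 <- matrix(c(rep(1L, 12), rep(2L, 6), rep(2L, 10)), ncol = 1)
  colnames(a1) <- colnames(a2) <- "L01"
  gm <- GenotypeMatrix(a1, a2, pop = rep("P", 28))
  p_enum <- hweExact(gm, "population", "P", "L01")$p
  mc <- hweExact(gm, "population", "P", "L01", n_steps = 1e5, seed = 4,
                 enum_limit = 0)
  expect_equal(mc$method, "mc")
  expect_lt(abs(mc$p - p_enum), 0.01)
})

test_that("Holm-Bonferroni reproduces the hand step-down", {
  res <- holmBonferroni(c(0.01, 0.04, 0.03))
  expect_equal(res$p_adj, c(0.03, 0.06, 0.06))
  expect_identical(res$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holmBonferroni(0.2)$p_adj, 0.2)
  expect_false(any(holmBonferroni(rep(1, 5))$reject))
  set.seed(5)
  p <- runif(12)
  expect_equal(holmBonferroni(p)$p_adj, oracleHolm(p))
})

test_that("allelic richness is exact at full size and matches resampling", {
  g <- simulateGenotypes(3, 4, 6, 0.25, 12, missing_rate = 0, seed = 21)
  gm <- g$genotypes
  # g = full gene count of the smallest group: equals observed count there
  ar_full <- allelicRichness(gm)
  by_locus <- split(ar_full, ar_full$locus)
  for (bl in by_locus) {
    i_min <- which.min(bl$genes)
    expect_equal(bl$RS[i_min], bl$A[i_min], tolerance = 1e-9)
  }
  # monotone non-decreasing in g
  r2 <- allelicRichness(gm, g = 2)$RS
  r8 <- allelicRichness(gm, g = 8)$RS
  r16 <- allelicRichness(gm, g = 16)$RS
  expect_true(all(r8 >= r2 - 1e-12) && all(r16 >= r8 - 1e-12))
  expect_error(allelicRichness(gm, g = 1), ">= 2")

  # Monte-Carlo subsampling oracle on one group-locus at g = 8
  al <- genotypeAlleles(gm)
  grp <- genotypeGroup(gm)
  rows <- which(grp == "G1")
  genes <- c(al$a1[rows, "L01"], al$a2[rows, "L01"])
  set.seed(99)
  n_res <- 1e5
  mc <- vapply(seq_len(n_res), function(i)
    length(unique(sample(genes, 8))), 0L)
  rs_pkg <- allelicRichness(gm, g = 8)
  rs_val <- rs_pkg$RS[rs_pkg$group == "G1" & rs_pkg$locus == "L01"]
  se <- sd(mc) / sqrt(n_res)
  expect_lt(abs(rs_val - mean(mc)), 3 * se + 1e-9)
})

test_that("private alleles match a set-difference oracle", {
  shared <- GenotypeMatrix(
    matrix(rep(c(1L, 2L), 8), 8, 2, dimnames = list(NULL, c("L1", "L2"))),
    matrix(rep(c(2L, 1L), 8), 8, 2, dimnames = list(NULL, c("L1", "L2"))),
    pop = rep(c("A", "B"), each = 4))
  rep_shared <- privateAlleles(shared)
  expect_equal(sum(rep_shared$private_alleles), 0)

  g <- simulateGenotypes(3, 12, 6, 0.3, 15, missing_rate = 0.05, seed = 13)
  gm <- g$genotypes
  rep_pkg <- privateAlleles(gm)
  al <- genotypeAlleles(gm)
  grp <- genotypeGroup(gm)
  groups <- unique(grp)
  # oracle: per group, alleles seen there and in no other group
  seen <- lapply(groups, function(gr) {
    rows <- which(grp == gr)
    out <- character(0)
    for (l in lociNames(gm)) {
      v <- c(al$a1[rows, l], al$a2[rows, l])
      out <- c(out, paste(l, unique(v[!is.na(v)]), sep = ":"))
    }
    out
  })
  names(seen) <- groups
  for (gr in groups) {
    others <- unlist(seen[setdiff(groups, gr)])
    priv_oracle <- setdiff(seen[[gr]], others)
    expect_equal(
      rep_pkg$private_alleles[rep_pkg$group == gr], length(priv_oracle))
  }
  # percentages recompute exactly from counts
  expect_equal(rep_pkg$private_alleles_pct,
               100 * rep_pkg$private_alleles / rep_pkg$alleles_genotyped)
  expect_equal(rep_pkg$populations_with_private_pct,
               100 * rep_pkg$populations_with_private /
                 rep_pkg$populations_total)
})

test_that("LD permutation test detects copies and respects its null", {
  g <- simulateGenotypes(1, 2, 4, 0, 40, missing_rate = 0, seed = 33)
  gm <- g$genotypes
  al <- genotypeAlleles(gm)
  dup <- GenotypeMatrix(cbind(al$a1, L03 = al$a1[, "L01"]),
                        cbind(al$a2, L03 = al$a2[, "L01"]),
                        pop = genotypePop(gm))
  res <- ldTest(dup, "population", "G1", "L01", "L03", n_perm = 99,
                seed = 2)
  expect_lte(res$p, 2 / 100)

  mono <- GenotypeMatrix(
    cbind(al$a1, L03 = 1L), cbind(al$a2, L03 = 1L),
    pop = genotypePop(gm))
  expect_true(is.na(ldTest(mono, "population", "G1", "L01", "L03",
                           n_perm = 19, seed = 1)$p))

  # type-I error close to nominal on independent loci
  rej <- vapply(1:200, function(s) {
    gi <- simulateGenotypes(1, 2, 3, 0, 30, missing_rate = 0,
                            seed = 5000 + s)
    ldTest(gi$genotypes, "population", "G1", "L01", "L02",
           n_perm = 99, seed = s)$p <= 0.05
  }, TRUE)
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("DAPC separates disjoint groups and rows sum to 100", {
  gm <- disjointGenotypes(12, 5)
  res <- suppressWarnings(dapcAssign(gm, "population", n_pc = 2, seed = 1))
  expect_equal(res$accuracy, 1)
  expect_equal(unname(rowSums(res$confusion)), c(100, 100))
  expect_equal(diag(res$confusion), c(A = 100, B = 100))
})
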