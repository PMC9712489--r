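# Microsatellite diversity and equilibrium statistics: observed / unbiased
# expected heterozygosity, exact Hardy-Weinberg tests (complete enumeration
# or an allele-swap Monte Carlo chain), Holm-Bonferroni correction,
# hypergeometric allelic-richness rarefaction, private-allele reporting,
# genotypic linkage-disequilibrium permutation tests, and DAPC-style
# assignment.

groupingLabels <- function(gm, grouping = c("group", "population")) {
  grouping <- match.arg(grouping)
  if (grouping == "group") genotypeGroup(gm) else genotypePop(gm)
}

#' Observed and unbiased expected heterozygosity
#'
#' Per locus and group: `H_O` is the fraction of heterozygotes among typed
#' individuals; `H_E` is Nei's unbiased expected heterozygosity
#' `(2n/(2n-1)) (1 - sum p_i^2)` with `n` typed diploids. All-missing
#' group-locus combinations yield `NA`.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param grouping `"group"` (morphotype) or `"population"`.
#' @return data.frame with columns `group`, `locus`, `n`, `A` (allele
#'   count), `HO`, `HE`.
#' @export
heterozygosity <- function(gm, grouping = c("group", "population")) {
  lab <- groupingLabels(gm, grouping)
  loci <- lociNames(gm)
  out <- expand.grid(group = unique(lab), locus = loci,
                     stringsAsFactors = FALSE)
  out$n <- out$A <- out$HO <- out$HE <- NA_real_
  for (r in seq_len(nrow(out))) {
    rows <- which(lab == out$group[r])
    l <- out$locus[r]
    a1 <- gm@a1[rows, l]; a2 <- gm@a2[rows, l]
    typed <- !is.na(a1)
    n <- sum(typed)
    out$n[r] <- n
    if (n == 0) next
    het <- mean(a1[typed] != a2[typed])
    p <- table(c(a1[typed], a2[typed])) / (2 * n)
    out$A[r] <- length(p)
    out$HO[r] <- het
    out$HE[r] <- if (n > 1) (2 * n / (2 * n - 1)) * (1 - sum(p^2)) else NA_real_
  }
  out[c("group", "locus", "n", "A", "HO", "HE")]
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the probability mass of genotype tables no more probable than the
#' observed one under the Levene distribution (random union of gametes).
#' Tables are enumerated completely when the table space does not exceed
#' `enum_limit`; otherwise an allele-swap Monte Carlo chain over allele
#' arrangements (whose stationary distribution is exactly the conditional
#' null) is run for `n_steps` with the given seed, and a naive Monte Carlo
#' standard error is attached.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param grouping `"group"` or `"population"`.
#' @param group Label of the group to test.
#' @param locus Locus name.
#' @param n_steps Monte Carlo steps (default 1e5).
#' @param seed Seed for the Monte Carlo chain.
#' @param enum_limit Maximum number of tables for complete enumeration.
#' @return List: `p` (p-value), `method` (`"enumeration"` or `"mc"`),
#'   `se` (MC standard error, 0 for enumeration), `n_tables` (enumeration
#'   only).
#' @export
hweExact <- function(gm, grouping = c("group", "population"), group, locus,
                     n_steps = 1e5, seed = 1, enum_limit = 1e6) {
  lab <- groupingLabels(gm, grouping)
  rows <- which(lab == group)
  a1 <- gm@a1[rows, locus]; a2 <- gm@a2[rows, locus]
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  if (length(a1) < 1) stop("no typed individuals")
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2) return(list(p = 1, method = "monomorphic", se = 0))
  ai <- match(a1, alleles); bi <- match(a2, alleles)
  obs <- genotypeCountTable(ai, bi, k)
  m <- alleleCountsFromTable(obs)
  lp_obs <- hweTableLogProb(obs)
  enum <- tryCatch(hweEnumerate(m, lp_obs, enum_limit),
                   condition = function(c) NULL)
  if (!is.null(enum))
    return(list(p = enum$p, method = "enumeration", se = 0,
                n_tables = enum$n_tables))
  mc <- hweMcmc(ai, bi, k, lp_obs, n_steps, seed)
  list(p = mc$p, method = "mc", se = mc$se)
}

genotypeCountTable <- function(ai, bi, k) {
  tab <- matrix(0L, k, k)
  for (x in seq_along(ai)) {
    i <- min(ai[x], bi[x]); j <- max(ai[x], bi[x])
    tab[i, j] <- tab[i, j] + 1L
  }
  tab
}

alleleCountsFromTable <- function(tab) {
  k <- nrow(tab)
  m <- integer(k)
  for (i in seq_len(k)) for (j in i:k) {
    m[i] <- m[i] + tab[i, j]
    m[j] <- m[j] + tab[i, j]
  }
  m
}

hweTableLogProb <- function(tab) {
  k <- nrow(tab)
  cells <- tab[upper.tri(tab, diag = TRUE)]
  n <- sum(cells)
  m <- alleleCountsFromTable(tab)
  h <- sum(tab[upper.tri(tab)])
  lgamma(n + 1) + sum(lgamma(m + 1)) + h * log(2) -
    lgamma(2 * n + 1) - sum(lgamma(cells + 1))
}

# complete enumeration of genotype tables with given allele-count margins;
# aborts (signalling a condition) past `limit` tables
hweEnumerate <- function(m, lp_obs, limit) {
  k <- length(m)
  env <- new.env()
  env$count <- 0L
  env$p_le <- 0
  env$tot <- 0
  tab <- matrix(0L, k, k)
  tol <- 1e-12
  recurse <- function(i, rem) {
    if (i > k) {
      env$count <- env$count + 1L
      if (env$count > limit) stop("enumeration limit exceeded")
      lp <- hweTableLogProb(tab)
      pr <- exp(lp)
      env$tot <- env$tot + pr
      if (lp <= lp_obs + tol) env$p_le <- env$p_le + pr
      return(invisible())
    }
    # distribute rem[i] copies of allele i over n_ii and n_ij (j > i)
    fill <- function(j, left) {
      if (j > k) {
        if (left == 0) recurse(i + 1, rem2())
        return(invisible())
      }
      if (j == i) {
        for (c in 0:(left %/% 2)) {
          tab[i, i] <<- c
          fill(j + 1, left - 2 * c)
        }
        tab[i, i] <<- 0L
      } else {
        for (c in 0:min(left, rem[j])) {
          tab[i, j] <<- c
          fill(j + 1, left - c)
        }
        tab[i, j] <<- 0L
      }
    }
    rem2 <- function() {
      r <- rem
      for (j in i:k) if (j > i) r[j] <- r[j] - tab[i, j]
      r
    }
    fill(i, rem[i])
  }
  recurse(1, m)
  list(p = env$p_le / env$tot, n_tables = env$count)
}

# Allele-swap Monte Carlo: the uniform distribution over arrangements of
# the 2n allele copies into n pairs induces exactly the Levene conditional
# distribution on tables; swapping allele copies between two pairs is a
# symmetric proposal with unit acceptance.
hweMcmc <- function(ai, bi, k, lp_obs, n_steps, seed) {
  withSeed(seed, {
    n <- length(ai)
    a <- ai; b <- bi                        # pair x: (a[x], b[x])
    tab <- genotypeCountTable(a, b, k)
    lp <- hweTableLogProb(tab)
    log2_ <- log(2)
    hits <- 0L
    tol <- 1e-9
    for (s in seq_len(n_steps)) {
      pr <- sample.int(n, 2)
      x <- pr[1]; y <- pr[2]
      # sequential removal / re-insertion keeps the incremental
      # log-probability exact even when the four cells coincide
      i <- min(a[x], b[x]); j <- max(a[x], b[x])
      lp <- lp + lgamma(tab[i, j] + 1)
      tab[i, j] <- tab[i, j] - 1L
      lp <- lp - lgamma(tab[i, j] + 1)
      if (i != j) lp <- lp - log2_
      i <- min(a[y], b[y]); j <- max(a[y], b[y])
      lp <- lp + lgamma(tab[i, j] + 1)
      tab[i, j] <- tab[i, j] - 1L
      lp <- lp - lgamma(tab[i, j] + 1)
      if (i != j) lp <- lp - log2_
      tmp <- b[x]; b[x] <- a[y]; a[y] <- tmp
      i <- min(a[x], b[x]); j <- max(a[x], b[x])
      lp <- lp + lgamma(tab[i, j] + 1)
      tab[i, j] <- tab[i, j] + 1L
      lp <- lp - lgamma(tab[i, j] + 1)
      if (i != j) lp <- lp + log2_
      i <- min(a[y], b[y]); j <- max(a[y], b[y])
      lp <- lp + lgamma(tab[i, j] + 1)
      tab[i, j] <- tab[i, j] + 1L
      lp <- lp - lgamma(tab[i, j] + 1)
      if (i != j) lp <- lp + log2_
      if (lp <= lp_obs + tol) hits <- hits + 1L
    }
    p <- hits / n_steps
    list(p = p, se = sqrt(p * (1 - p) / n_steps))
  })
}

#' Holm-Bonferroni step-down correction
#'
#' Monotone step-down adjusted p-values (via [stats::p.adjust]) and
#' rejection decisions at `alpha`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return data.frame with `p`, `p_adj`, `reject`.
#' @export
holmBonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  adj <- p.adjust(pvals, method = "holm")
  data.frame(p = pvals, p_adj = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Rarefied allelic richness
#'
#' Hypergeometric rarefaction to a common number of genes `g` (allele
#' copies): `R_S = sum_a [1 - C(2N - N_a, g) / C(2N, g)]` with `2N` typed
#' genes at the group-locus and `N_a` copies of allele `a`. `g` defaults,
#' per locus, to the smallest typed gene count across groups. At `g = 2N`,
#' `R_S` equals the observed allele count.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param grouping `"group"` or `"population"`.
#' @param g Rarefaction size in genes (>= 2); `NULL` for the per-locus
#'   minimum across groups.
#' @return data.frame with `group`, `locus`, `genes` (2N), `A`, `g`, `RS`.
#' @export
allelicRichness <- function(gm, grouping = c("group", "population"),
                            g = NULL) {
  if (!is.null(g) && g < 2) stop("rarefaction size g must be >= 2")
  lab <- groupingLabels(gm, grouping)
  loci <- lociNames(gm)
  groups <- unique(lab)
  out <- list()
  for (l in loci) {
    counts <- lapply(groups, function(gr) {
      rows <- which(lab == gr)
      v <- c(gm@a1[rows, l], gm@a2[rows, l])
      table(v[!is.na(v)])
    })
    genes <- vapply(counts, sum, 0)
    gl <- if (is.null(g)) min(genes) else g
    if (gl > min(genes))
      stop("g = ", gl, " exceeds the smallest typed gene count (",
           min(genes), ") at locus ", l)
    for (gi in seq_along(groups)) {
      cnt <- counts[[gi]]; N2 <- genes[gi]
      rs <- sum(1 - exp(lchoose(N2 - cnt, gl) - lchoose(N2, gl)))
      out[[length(out) + 1]] <-
        data.frame(group = groups[gi], locus = l, genes = N2,
                   A = length(cnt), g = gl, RS = rs)
    }
  }
  do.call(rbind, out)
}

#' Private-allele report
#'
#' An allele (locus-specific) is private to a group when it is observed in
#' exactly one group. Aggregated per group: populations total and with
#' private alleles (count, %), alleles genotyped and private (count, %),
#' and the mean within-group frequency of the private alleles.
#'
#' @param gm A [GenotypeMatrix-class] with >= 2 groups.
#' @return data.frame, one row per group, plus attribute
#'   `"private_list"`: data.frame of the individual private alleles
#'   (group, locus, allele, freq, populations).
#' @export
privateAlleles <- function(gm) {
  grp <- genotypeGroup(gm)
  pops <- genotypePop(gm)
  groups <- unique(grp)
  if (length(groups) < 2) stop("need >= 2 groups")
  loci <- lociNames(gm)
  # which groups carry each (locus, allele)
  occ <- list(); freq <- list()
  for (l in loci) {
    for (gr in groups) {
      rows <- which(grp == gr)
      v <- c(gm@a1[rows, l], gm@a2[rows, l]); v <- v[!is.na(v)]
      tt <- table(v)
      for (al in names(tt)) {
        key <- paste(l, al, sep = ":")
        occ[[key]] <- union(occ[[key]], gr)
        freq[[paste(key, gr, sep = ":")]] <- as.numeric(tt[al]) / length(v)
      }
    }
  }
  priv <- data.frame(group = character(0), locus = character(0),
                     allele = character(0), freq = numeric(0),
                     populations = character(0))
  for (key in names(occ)) if (length(occ[[key]]) == 1) {
    gr <- occ[[key]]
    parts <- strsplit(key, ":")[[1]]
    l <- parts[1]; al <- parts[2]
    carriers <- which(grp == gr &
      ((!is.na(gm@a1[, l]) & gm@a1[, l] == as.integer(al)) |
       (!is.na(gm@a2[, l]) & gm@a2[, l] == as.integer(al))))
    priv <- rbind(priv, data.frame(
      group = gr, locus = l, allele = al,
      freq = freq[[paste(key, gr, sep = ":")]],
      populations = paste(sort(unique(pops[carriers])), collapse = ";")))
  }
  out <- list()
  for (gr in groups) {
    rows <- which(grp == gr)
    pops_gr <- unique(pops[rows])
    keys_gr <- names(occ)[vapply(occ, function(o)
      gr %in% o, TRUE)]
    n_alleles <- length(keys_gr)
    pg <- priv[priv$group == gr, , drop = FALSE]
    pops_with <- unique(unlist(strsplit(pg$populations, ";")))
    out[[gr]] <- data.frame(
      group = gr,
      populations_total = length(pops_gr),
      populations_with_private = length(pops_with),
      populations_with_private_pct = 100 * length(pops_with) /
        length(pops_gr),
      alleles_genotyped = n_alleles,
      private_alleles = nrow(pg),
      private_alleles_pct = 100 * nrow(pg) / n_alleles,
      mean_private_freq = if (nrow(pg)) mean(pg$freq) else 0)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "private_list") <- priv
  res
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Log-likelihood-ratio G statistic on the two-locus genotype contingency
#' table within a group; the null is built by permuting one locus's
#' genotypes across the group's individuals (`n_perm` permutations,
#' seeded). `p = (#{G_perm >= G_obs} + 1) / (n_perm + 1)`.
#'
#' @param gm A [GenotypeMatrix-class].
#' @param grouping `"group"` or `"population"`.
#' @param group Group label.
#' @param locusA,locusB Locus names (both polymorphic in the group).
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed.
#' @return List: `G`, `p`, `n` (individuals typed at both loci); `NA`
#'   p-value when either locus is monomorphic or fewer than 2 usable
#'   individuals.
#' @export
ldTest <- function(gm, grouping = c("group", "population"), group,
                   locusA, locusB, n_perm = 999, seed = 1) {
  lab <- groupingLabels(gm, grouping)
  rows <- which(lab == group)
  gA <- paste(pmin(gm@a1[rows, locusA], gm@a2[rows, locusA]),
              pmax(gm@a1[rows, locusA], gm@a2[rows, locusA]))
  gB <- paste(pmin(gm@a1[rows, locusB], gm@a2[rows, locusB]),
              pmax(gm@a1[rows, locusB], gm@a2[rows, locusB]))
  ok <- !is.na(gm@a1[rows, locusA]) & !is.na(gm@a1[rows, locusB])
  gA <- gA[ok]; gB <- gB[ok]
  if (length(gA) < 2 || length(unique(gA)) < 2 || length(unique(gB)) < 2)
    return(list(G = NA_real_, p = NA_real_, n = length(gA)))
  gstat <- function(a, b) {
    tab <- table(a, b)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sel <- tab > 0
    2 * sum(tab[sel] * log(tab[sel] / E[sel]))
  }
  G_obs <- gstat(gA, gB)
  withSeed(seed, {
    hits <- 0L
    for (r in seq_len(n_perm)) {
      if (gstat(gA, sample(gB)) >= G_obs - 1e-12) hits <- hits + 1L
    }
    list(G = G_obs, p = (hits + 1) / (n_perm + 1), n = length(gA))
  })
}
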