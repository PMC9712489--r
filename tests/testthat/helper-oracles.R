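# Independent oracles and small fixture builders used across the suite.
# Each oracle is coded from first principles, separately from the package
# implementation it checks.

# quick panel from raw strings
makePanel <- function(seqs, pops = NULL, groups = NULL) {
  ids <- sprintf("s%02d", seq_along(seqs))
  if (is.null(pops)) pops <- rep("P1", length(seqs))
  SequencePanel(setNames(seqs, ids), pop = setNames(pops, ids),
                group = groups)
}

randomPanel <- function(n, L, seed, pops = NULL) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
  makePanel(seqs, pops = pops)
}

# naive column scan for segregating sites (gap = 5th state, N missing)
oracleSegSites <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  count <- 0L
  for (j in seq_len(ncol(mat))) {
    states <- character(0)
    for (i in seq_len(nrow(mat))) {
      ch <- mat[i, j]
      if (ch != "N") states <- union(states, ch)
    }
    if (length(states) >= 2) count <- count + 1L
  }
  count
}

# brute-force pairwise loop for theta_pi / pi (N and gap excluded per pair)
oraclePairwise <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  diffs <- valids <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 0L; v <- 0L
    for (s in seq_len(ncol(mat))) {
      a <- mat[i, s]; b <- mat[j, s]
      if (a %in% c("N", "-") || b %in% c("N", "-")) next
      v <- v + 1L
      if (a != b) d <- d + 1L
    }
    diffs <- c(diffs, d); valids <- c(valids, v)
  }
  list(theta_pi = mean(diffs), pi = mean(diffs / valids))
}

# Tajima's D coded from scratch (constants recomputed independently)
oracleTajimaD <- function(seqs) {
  n <- length(seqs)
  S <- oracleSegSites(seqs)
  if (S == 0 || n < 4) return(NA_real_)
  tp <- oraclePairwise(seqs)$theta_pi
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  (tp - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact unsigned Stirling numbers of the first kind via polynomial
# expansion of the rising factorial x(x+1)...(x+n-1); exact in doubles for
# n <= 18 or so, plenty for the n <= 12 oracle
oracleStirlingRow <- function(n) {
  coefs <- c(0, 1)                       # x
  if (n >= 2) for (m in 1:(n - 1)) {
    shifted <- c(0, coefs)               # * x
    coefs <- m * c(coefs, 0) + shifted   # * (x + m)
  }
  coefs[2:(n + 1)]                       # |s(n,k)|, k = 1..n
}

# exact Ewens tail probability Pr(K >= k0 | theta, n) for small n
oracleEwensTail <- function(n, theta, k0) {
  st <- oracleStirlingRow(n)
  rising <- prod(theta + 0:(n - 1))
  probs <- st * theta^seq_len(n) / rising
  sum(probs[k0:n])
}

# union of all minimum spanning trees: edge e belongs to some MST iff
# forcing e into the tree does not increase the Kruskal weight
oracleMSNEdges <- function(distmat) {
  nh <- nrow(distmat)
  pairs <- utils::combn(nh, 2)
  kruskal <- function(order_idx, forced = NULL) {
    comp <- seq_len(nh)
    w <- 0; used <- 0L
    join <- function(a, b) {
      ca <- comp[a]; cb <- comp[b]
      if (ca == cb) return(FALSE)
      comp[comp == cb] <<- ca
      TRUE
    }
    if (!is.null(forced)) {
      join(pairs[1, forced], pairs[2, forced])
      w <- w + distmat[pairs[1, forced], pairs[2, forced]]
      used <- 1L
    }
    for (e in order_idx) {
      if (used == nh - 1L) break
      if (join(pairs[1, e], pairs[2, e])) {
        w <- w + distmat[pairs[1, e], pairs[2, e]]
        used <- used + 1L
      }
    }
    w
  }
  wts <- apply(pairs, 2, function(p) distmat[p[1], p[2]])
  ord <- order(wts)
  w_min <- kruskal(ord)
  in_any <- vapply(seq_len(ncol(pairs)), function(e)
    kruskal(ord, forced = e) == w_min, TRUE)
  data.frame(from = pairs[1, ], to = pairs[2, ], in_mst = in_any)
}

# direct-count heterozygosity oracle for one group-locus
oracleHetero <- function(a1, a2) {
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  n <- length(a1)
  alleles <- unique(c(a1, a2))
  p <- vapply(alleles, function(al) sum(a1 == al) + sum(a2 == al), 0) /
    (2 * n)
  list(HO = sum(a1 != a2) / n,
       HE = (2 * n / (2 * n - 1)) * (1 - sum(p^2)))
}

# full enumeration of 2-allele HWE tables by heterozygote count
oracleHwe2 <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  mA <- 2 * nAA + nAa
  ma <- 2 * n - mA
  lprob <- function(h) {
    aa <- (mA - h) / 2; bb <- (ma - h) / 2
    lgamma(n + 1) + lgamma(mA + 1) + lgamma(ma + 1) + h * log(2) -
      lgamma(2 * n + 1) - lgamma(aa + 1) - lgamma(bb + 1) - lgamma(h + 1)
  }
  hs <- seq(mA %% 2, min(mA, ma), by = 2)
  lp <- vapply(hs, lprob, 0)
  p <- exp(lp) / sum(exp(lp))
  sum(p[lp <= lp[hs == nAa] + 1e-12])
}

# hand step-down Holm adjustment
oracleHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# simple two-group genotype fixture with disjoint fixed alleles
disjointGenotypes <- function(n_per_group = 10, n_loci = 4) {
  n <- 2 * n_per_group
  a1 <- matrix(rep(c(1L, 3L), each = n_per_group), n, n_loci)
  a2 <- matrix(rep(c(2L, 4L), each = n_per_group), n, n_loci)
  colnames(a1) <- colnames(a2) <- sprintf("L%02d", seq_len(n_loci))
  rownames(a1) <- rownames(a2) <- sprintf("i%03d", seq_len(n))
  GenotypeMatrix(a1, a2, pop = rep(c("A", "B"), each = n_per_group))
}
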