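# Mitochondrial diversity statistics, neutrality tests, haplotype networks
# and between-group divergence.
#
# Missing-data conventions (configurable where noted): sites with N are
# excluded pairwise for distances / pi / theta_pi; the alignment gap "-" is
# a fifth character state for segregating sites and haplotype identity but
# is excluded pairwise for p-distances.

# integer coding of the alignment: A,C,G,T,- -> 1..5; N -> NA
seqIntMatrix <- function(panel, gap_as_state = TRUE) {
  m <- alignmentMatrix(panel)
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, `-` = 5L, N = NA_integer_)
  out <- matrix(code[m], nrow(m), ncol(m))
  rownames(out) <- rownames(m)
  if (!gap_as_state) out[out == 5L] <- NA_integer_
  out
}

#' Count segregating sites
#'
#' Number of alignment columns with at least two distinct non-missing
#' states. The gap character `-` counts as a fifth state; `N` is missing.
#'
#' @param panel A [SequencePanel-class] with `n >= 2`.
#' @return Integer count of polymorphic columns.
#' @export
segregatingSites <- function(panel) {
  stopifnot(length(panel) >= 2)
  m <- seqIntMatrix(panel, gap_as_state = TRUE)
  sum(apply(m, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) >= 2
  }))
}

# per-pair difference counts and valid-site counts; N and gap excluded
# pairwise (distance convention). Returns list(diff, valid) as vectors over
# the C(n,2) pairs in combn order.
pairwiseDiffs <- function(panel) {
  m <- seqIntMatrix(panel, gap_as_state = FALSE)
  n <- nrow(m)
  np <- n * (n - 1) / 2
  dd <- numeric(np); vv <- numeric(np)
  idx <- 1L
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    block <- m[(i + 1):n, , drop = FALSE]
    cmp <- sweep(block, 2, xi, FUN = "!=")
    valid <- !is.na(cmp)
    nb <- nrow(block)
    dd[idx:(idx + nb - 1)] <- rowSums(cmp & valid, na.rm = TRUE)
    vv[idx:(idx + nb - 1)] <- rowSums(valid)
    idx <- idx + nb
  }
  list(diff = dd, valid = vv)
}

#' Mean pairwise differences (theta_pi) and nucleotide diversity (pi)
#'
#' `thetaPi` is the mean over all `C(n,2)` sequence pairs of the per-pair
#' difference count; `nucleotideDiversity` the analogous per-site quantity
#' using each pair's own valid-site denominator. Standard deviations follow
#' the classical variance of the mean-pairwise-difference estimator:
#' `Var(theta_pi) = b1*theta + b2*theta^2` with `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`; the per-site SD divides by `L`.
#'
#' @param panel A [SequencePanel-class] with `n >= 2`.
#' @return Named numeric vector `c(estimate, sd)`.
#' @export
thetaPi <- function(panel) {
  stopifnot(length(panel) >= 2)
  pd <- pairwiseDiffs(panel)
  n <- length(panel)
  est <- mean(pd$diff)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c(estimate = est, sd = sqrt(b1 * est + b2 * est^2))
}

#' @rdname thetaPi
#' @export
nucleotideDiversity <- function(panel) {
  stopifnot(length(panel) >= 2)
  pd <- pairwiseDiffs(panel)
  ok <- pd$valid > 0
  est <- mean(ifelse(ok, pd$diff / pd$valid, NA), na.rm = TRUE)
  tp <- thetaPi(panel)
  c(estimate = est, sd = unname(tp["sd"]) / alignmentLength(panel))
}

# Watterson a1 = sum 1/i, a2 = sum 1/i^2 over i = 1..n-1
wattersonA <- function(n) {
  i <- seq_len(n - 1)
  c(a1 = sum(1 / i), a2 = sum(1 / i^2))
}

#' Watterson's theta from segregating sites
#'
#' `theta_S = S / a1` with `a1 = sum_{i=1}^{n-1} 1/i`; its SD is
#' `sqrt(theta/a1 + a2 theta^2 / a1^2)` from `Var(S) = a1 theta + a2
#' theta^2`.
#'
#' @param S Number of segregating sites (>= 0).
#' @param n Number of sequences (>= 2).
#' @return Named numeric vector `c(estimate, sd)`.
#' @export
#' @examples
#' wattersonTheta(5, 5)   # a1 = 1/1+...+1/4 = 2.0833, theta = 2.4
wattersonTheta <- function(S, n) {
  stopifnot(n >= 2, S >= 0)
  a <- wattersonA(n)
  est <- S / a["a1"]
  c(estimate = unname(est),
    sd = unname(sqrt(est / a["a1"] + a["a2"] * est^2 / a["a1"]^2)))
}

#' Tajima's D
#'
#' `D = (theta_pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the 1989
#' normalizing constants computed from `n`. Undefined (NA with a warning)
#' when `S = 0` or `n < 4`.
#'
#' @param panel A [SequencePanel-class].
#' @return The D statistic (scalar, possibly `NA`).
#' @export
tajimasD <- function(panel) {
  n <- length(panel)
  if (n < 4) { warning("Tajima's D undefined for n < 4"); return(NA_real_) }
  S <- segregatingSites(panel)
  if (S < 1) { warning("Tajima's D undefined for S = 0"); return(NA_real_) }
  tp <- thetaPi(panel)[["estimate"]]
  tajimasDFromSummary(n, S, tp)
}

tajimasDFromSummary <- function(n, S, theta_pi) {
  a <- wattersonA(n); a1 <- a[["a1"]]; a2 <- a[["a2"]]
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# vectorized two-term log-sum-exp, tolerating -Inf entries
logAddExp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[m == -Inf] <- -Inf
  out
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n), via
# |s(m+1,k)| = m|s(m,k)| + |s(m,k-1)|, carried in log space.
logStirlingRow <- function(n) {
  row <- c(0, rep(-Inf, n - 1))            # |s(1,1)| = 1
  if (n == 1) return(row)
  for (m in seq_len(n - 1)) {
    shifted <- c(-Inf, row[seq_len(n - 1)])
    row <- logAddExp(log(m) + row, shifted)
  }
  row
}

#' Ewens sampling distribution of the number of haplotypes
#'
#' Log-probabilities `log Pr(K = k | theta, n)` for `k = 1..n` under the
#' Ewens sampling formula `Pr(K = k) = |s(n,k)| theta^k / (theta)_n`, with
#' unsigned Stirling numbers of the first kind and the rising factorial
#' `(theta)_n`, all carried in log space.
#'
#' @param n Sample size.
#' @param theta Positive scaled mutation parameter.
#' @return Numeric vector of length `n` of log-probabilities (sums to 1 on
#'   the natural scale).
#' @export
ewensLogProbs <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- logStirlingRow(n)
  k <- seq_len(n)
  log_rising <- sum(log(theta + 0:(n - 1)))
  ls + k * log(theta) - log_rising
}

#' Fu's Fs
#'
#' With `theta_hat = theta_pi`, `S' = Pr(K >= H_obs | theta_hat)` under the
#' Ewens sampling distribution and `Fs = ln(S'/(1 - S'))`. `S'` numerically
#' 0 or 1 yields signed infinity with an attribute flag; `theta_hat = 0`
#' yields `NA`.
#'
#' @param panel A [SequencePanel-class] (`n >= 2`).
#' @param haplotype_rule Haplotype identity rule passed to
#'   [collapseHaplotypes].
#' @return The Fs statistic; attribute `"flag"` set to `"degenerate"` when
#'   infinite.
#' @export
fusFS <- function(panel,
                  haplotype_rule = c("strict", "mask", "n_matches")) {
  n <- length(panel)
  stopifnot(n >= 2)
  th <- thetaPi(panel)[["estimate"]]
  if (th <= 0) { warning("Fu's Fs undefined for theta_pi = 0"); return(NA_real_) }
  H <- length(collapseHaplotypes(panel, match.arg(haplotype_rule))@haplos)
  fusFSFromTheta(n, th, H)
}

fusFSFromTheta <- function(n, theta, k_obs) {
  lp <- ewensLogProbs(n, theta)
  tail_lp <- lp[k_obs:n]
  mx <- max(tail_lp)
  logS <- mx + log(sum(exp(tail_lp - mx)))
  logS <- min(logS, 0)
  if (logS > -1e-10) {            # S' = 1 up to summation accuracy
    out <- Inf
  } else if (!is.finite(logS)) {
    out <- -Inf
  } else {
    # log(S'/(1-S')) computed stably from logS
    out <- logS - log(-expm1(logS))
  }
  if (!is.finite(out)) attr(out, "flag") <- "degenerate"
  out
}

#' Collapse a panel into haplotype classes
#'
#' Haplotypes are equivalence classes of identical strings. Three identity
#' rules are available for the ambiguity code `N`:
#' * `"strict"` (default): exact string equality with `N` as its own
#'   state, so `"AAN"` and `"AAT"` are different haplotypes;
#' * `"mask"`: alignment columns containing any `N` are masked panel-wide
#'   before comparing (Arlequin-style deterministic counts);
#' * `"n_matches"`: `N` matches any state; sequences are greedily merged
#'   into the first compatible class and the class representative
#'   accumulates observed bases, so `"AAN"` and `"AAT"` collapse to one.
#' The gap `-` is always a fifth character state.
#'
#' @param panel A [SequencePanel-class] (`n >= 1`).
#' @param rule `"strict"`, `"mask"` or `"n_matches"`.
#' @return A [HaplotypeNetwork-class] with nodes only (no edges); node
#'   strings are the (possibly masked) haplotype sequences.
#' @export
collapseHaplotypes <- function(panel,
                               rule = c("strict", "mask", "n_matches")) {
  rule <- match.arg(rule)
  stopifnot(length(panel) >= 1)
  m <- alignmentMatrix(panel)
  grp <- panelGroup(panel)
  if (rule %in% c("strict", "mask")) {
    mm <- m
    if (rule == "mask") {
      keep <- colSums(m == "N") == 0
      mm <- m[, keep, drop = FALSE]
    }
    key <- apply(mm, 1, paste, collapse = "")
    classes <- split(seq_len(nrow(m)), factor(key, levels = unique(key)))
    reps <- names(classes)
  } else {
    key <- apply(m, 1, paste, collapse = "")
    reps <- character(0)
    classes <- list()
    for (i in seq_len(nrow(m))) {
      s <- m[i, ]
      hit <- 0L
      for (j in seq_along(reps)) {
        r <- strsplit(reps[j], "")[[1]]
        ok <- all(r == s | r == "N" | s == "N")
        if (ok) {
          r[r == "N"] <- s[r == "N"]
          reps[j] <- paste(r, collapse = "")
          hit <- j; break
        }
      }
      if (hit) classes[[hit]] <- c(classes[[hit]], i)
      else { reps <- c(reps, paste(s, collapse = "")); classes <- c(classes, list(i)) }
    }
  }
  groups <- sort(unique(grp))
  cnt <- vapply(classes, function(ix)
    as.numeric(table(factor(grp[ix], levels = groups))),
    numeric(length(groups)))
  gc <- if (length(groups) == 1) matrix(cnt, ncol = 1) else t(cnt)
  colnames(gc) <- groups
  methods::new("HaplotypeNetwork",
               haplos = unname(reps),
               multiplicity = unname(vapply(classes, length, 1L)),
               groupCounts = gc,
               edges = data.frame(from = integer(0), to = integer(0),
                                  dist = numeric(0), in_mst = logical(0)))
}

#' Minimum spanning network over haplotypes
#'
#' Builds the complete Hamming-distance graph over the distinct haplotypes
#' and flags every edge that belongs to at least one minimum spanning tree
#' (the epsilon = 0 minimum-spanning-network convention): distance classes
#' are visited in increasing order and, within a class, all edges joining
#' components not yet connected at smaller distances are retained.
#'
#' @param network A [HaplotypeNetwork-class] from [collapseHaplotypes]
#'   (edges ignored).
#' @return The network with its complete edge table and `in_mst` flags.
#' @export
buildMSN <- function(network) {
  h <- network@haplos
  nh <- length(h)
  if (nh < 1) stop("need at least one haplotype")
  if (nh == 1) return(network)
  hm <- do.call(rbind, strsplit(h, ""))
  pairs <- combn(nh, 2)
  d <- apply(pairs, 2, function(p) sum(hm[p[1], ] != hm[p[2], ]))
  edges <- data.frame(from = pairs[1, ], to = pairs[2, ], dist = d,
                      in_mst = FALSE)
  comp <- seq_len(nh)
  for (dc in sort(unique(d))) {
    in_class <- which(edges$dist == dc)
    cross <- in_class[comp[edges$from[in_class]] !=
                        comp[edges$to[in_class]]]
    edges$in_mst[cross] <- TRUE
    for (e in cross) {                      # merge after flagging the class
      ca <- comp[edges$from[e]]; cb <- comp[edges$to[e]]
      if (ca != cb) comp[comp == cb] <- ca
    }
  }
  methods::new("HaplotypeNetwork", haplos = h,
               multiplicity = network@multiplicity,
               groupCounts = network@groupCounts, edges = edges)
}

#' Raw between-group sequence divergence
#'
#' Minimum, mean and maximum uncorrected p-distance over all cross-group
#' sequence pairs; per pair, differing sites are counted over the sites
#' valid in both sequences (`N` and `-` excluded pairwise). Contact-zone
#' exclusion is the caller's responsibility via the group labels.
#'
#' @param panel A [SequencePanel-class].
#' @param groupA,groupB Group labels (both non-empty in the panel).
#' @return Named numeric vector `c(min, mean, max)`.
#' @export
groupDivergence <- function(panel, groupA, groupB) {
  grp <- panelGroup(panel)
  ia <- which(grp == groupA); ib <- which(grp == groupB)
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  m <- seqIntMatrix(panel, gap_as_state = FALSE)
  dists <- numeric(0)
  skipped <- 0L
  for (i in ia) {
    blk <- m[ib, , drop = FALSE]
    cmp <- sweep(blk, 2, m[i, ], FUN = "!=")
    valid <- rowSums(!is.na(cmp))
    diffs <- rowSums(cmp, na.rm = TRUE)
    zero <- valid == 0
    skipped <- skipped + sum(zero)
    dists <- c(dists, diffs[!zero] / valid[!zero])
  }
  if (skipped) warning(skipped, " pair(s) with no comparable sites skipped")
  c(min = min(dists), mean = mean(dists), max = max(dists))
}

#' Strict-clock divergence-to-time conversion
#'
#' Converts a raw pairwise divergence into an age under a strict molecular
#' clock, `time = divergence / rate`. The conventional avian mitochondrial
#' rate is 0.021 (2.1% pairwise divergence) per million years.
#'
#' @param divergence Raw divergence (proportion, >= 0).
#' @param rate Divergence per million years (> 0); default 0.021.
#' @return Age in millions of years.
#' @export
#' @examples
#' clockTime(0.0779)   # ~3.71 Myr under the 2.1%/Myr clock
clockTime <- function(divergence, rate = 0.021) {
  if (rate <= 0) stop("clock rate must be positive")
  stopifnot(all(divergence >= 0))
  divergence / rate
}

#' Per-group diversity summary table
#'
#' One row per group: sample size `n`, segregating sites `S`, haplotype
#' count `H`, per-site nucleotide diversity `pi` (+- SD), Watterson
#' `theta_S` (+- SD), mean pairwise differences `theta_pi` (+- SD), Fu's
#' `FS` and Tajima's `D`. Optionally attaches simulation-based p-values for
#' the neutrality statistics (coalescent null under the fitted
#' `theta_pi`; two-tailed for D, lower-tail for Fs).
#'
#' @param panel A [SequencePanel-class].
#' @param by `"group"` or `"population"` grouping of the summary.
#' @param significance Add neutrality p-values by coalescent simulation.
#' @param n_sims Null simulations per group (default 10000).
#' @param seed Seed for the null simulations.
#' @return data.frame, one row per group.
#' @export
diversityStats <- function(panel, by = c("group", "population"),
                           significance = FALSE, n_sims = 10000,
                           seed = 1) {
  by <- match.arg(by)
  lab <- if (by == "group") panelGroup(panel) else panelPop(panel)
  out <- list()
  for (g in unique(lab)) {
    sub <- subsetPanel(panel, names(lab)[lab == g])
    n <- length(sub)
    if (n < 2) next
    S <- segregatingSites(sub)
    H <- length(collapseHaplotypes(sub)@haplos)
    tp <- thetaPi(sub); pi_ <- nucleotideDiversity(sub)
    ts <- wattersonTheta(S, n)
    D <- if (n >= 4 && S >= 1) tajimasD(sub) else NA_real_
    FS <- if (tp[["estimate"]] > 0) as.numeric(fusFS(sub)) else NA_real_
    row <- data.frame(group = g, n = n, S = S, H = H,
                      pi = pi_[["estimate"]], pi_sd = pi_[["sd"]],
                      theta_S = ts[["estimate"]], theta_S_sd = ts[["sd"]],
                      theta_pi = tp[["estimate"]], theta_pi_sd = tp[["sd"]],
                      FS = FS, D = D)
    if (significance && is.finite(D)) {
      pv <- neutralityNull(n, tp[["estimate"]], alignmentLength(sub),
                           D_obs = D, FS_obs = FS, n_sims = n_sims,
                           seed = childSeed(seed, match(g, unique(lab))))
      row$D_p <- pv[["D_p"]]; row$FS_p <- pv[["FS_p"]]
    }
    out[[g]] <- row
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# coalescent null distribution of D and Fs under theta (simulation-based
# p-values; two-tailed for D, lower-tail for Fs)
neutralityNull <- function(n, theta, L, D_obs, FS_obs, n_sims, seed) {
  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    Ds <- FSs <- rep(NA_real_, n_sims)
    for (r in seq_len(n_sims)) {
      sim <- coalescentGroup(n, L, theta, anc, bases)
      ids <- sprintf("s%d", seq_len(n))
      p <- SequencePanel(setNames(sim$seqs, ids),
                         pop = setNames(rep("x", n), ids))
      S <- segregatingSites(p)
      if (S >= 1) {
        tp <- thetaPi(p)[["estimate"]]
        Ds[r] <- tajimasDFromSummary(n, S, tp)
        if (tp > 0)
          FSs[r] <- fusFSFromTheta(n, tp,
                                   length(collapseHaplotypes(p)@haplos))
      }
    }
    c(D_p = mean(abs(Ds) >= abs(D_obs), na.rm = TRUE),
      FS_p = mean(FSs <= FS_obs, na.rm = TRUE))
  })
}
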