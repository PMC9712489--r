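# Discriminant analysis of principal components on microsatellite
# genotypes: allele-count encoding, PCA, a-score selection of the number of
# retained components, linear discriminant classification.

# individuals x alleles 0/1/2 count encoding; missing imputed by the
# group-blind overall mean (never the group mean, to avoid leaking labels)
alleleCountEncoding <- function(gm) {
  loci <- lociNames(gm)
  n <- nrow(gm@a1)
  cols <- list()
  for (l in loci) {
    alleles <- sort(unique(c(gm@a1[, l], gm@a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    for (al in alleles) {
      v <- (gm@a1[, l] == al) + (gm@a2[, l] == al)
      v[is.na(gm@a1[, l])] <- NA
      mu <- mean(v, na.rm = TRUE)
      v[is.na(v)] <- mu
      cols[[paste(l, al, sep = ".")]] <- v
    }
  }
  do.call(cbind, cols)
}

#' DAPC-style assignment of individuals to groups
#'
#' Individuals are encoded as allele-count vectors (0/1/2 per allele;
#' missing imputed by the overall allele-frequency mean), reduced by PCA,
#' and classified by linear discriminant analysis on the retained
#' components. When `n_pc` is missing it is chosen to maximize the a-score:
#' observed reassignment rate minus the mean reassignment rate over
#' permuted group labels (seeded).
#'
#' @param gm A [GenotypeMatrix-class].
#' @param grouping `"group"` or `"population"` (>= 2 groups, >= 2
#'   individuals per group).
#' @param n_pc Number of principal components to retain; `NULL` for
#'   a-score selection.
#' @param seed Seed for the a-score permutations.
#' @param n_perm Label permutations per candidate `n_pc` (default 10).
#' @return List: `confusion` (percent matrix, rows = actual groups),
#'   `counts` (raw confusion counts), `accuracy`, `n_pc`, `a_score`
#'   (selection trace or `NA`), `scores` (discriminant coordinates),
#'   `assigned` (predicted labels).
#' @export
dapcAssign <- function(gm, grouping = c("group", "population"),
                       n_pc = NULL, seed = 1, n_perm = 10) {
  lab <- groupingLabels(gm, grouping)
  stopifnot(length(unique(lab)) >= 2, all(table(lab) >= 2))
  X <- alleleCountEncoding(gm)
  keep <- apply(X, 2, function(v) var(v) > 0)
  X <- X[, keep, drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  pos <- which(pc$sdev > 1e-8)
  max_pc <- min(length(pos), nrow(X) - length(unique(lab)))
  safe_lda <- function(S, labels) {
    tryCatch(MASS::lda(S, grouping = labels), error = function(e) {
      # components constant within groups (perfect separation): a small
      # jitter relative to each component's overall spread restores the
      # pooled covariance without moving any boundary that matters
      sds <- pmax(apply(S, 2, sd) * 1e-3, 1e-9)
      jit <- sweep(matrix(rnorm(length(S)), nrow(S)), 2, sds, "*")
      MASS::lda(S + jit, grouping = labels)
    })
  }
  reassign <- function(npc, labels) {
    S <- pc$x[, seq_len(npc), drop = FALSE]
    fit <- safe_lda(S, labels)
    mean(stats::predict(fit, S)$class == labels)
  }
  ascore_trace <- NA
  if (is.null(n_pc)) {
    cand <- unique(round(seq(1, max_pc, length.out = min(max_pc, 12))))
    ascore_trace <- withSeed(seed, {
      vapply(cand, function(npc) {
        obs <- reassign(npc, lab)
        perm <- mean(vapply(seq_len(n_perm), function(i)
          reassign(npc, sample(lab)), 0))
        obs - perm
      }, 0)
    })
    names(ascore_trace) <- cand
    n_pc <- cand[which.max(ascore_trace)]
  } else if (n_pc > max_pc) {
    warning("n_pc exceeds usable rank; clipped to ", max_pc)
    n_pc <- max_pc
  }
  S <- pc$x[, seq_len(n_pc), drop = FALSE]
  fit <- safe_lda(S, lab)
  pred <- stats::predict(fit, S)
  groups <- sort(unique(lab))
  counts <- table(factor(lab, groups), factor(pred$class, groups))
  confusion <- 100 * sweep(counts, 1, rowSums(counts), "/")
  list(confusion = as.matrix(confusion), counts = as.matrix(counts),
       accuracy = mean(pred$class == lab), n_pc = n_pc,
       a_score = ascore_trace, scores = pred$x,
       assigned = as.character(pred$class))
}
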