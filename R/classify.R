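# Morphometric / environmental ordination and cross-validated discriminant
# classification. Complete-case analysis throughout (no imputation of
# missing trait values).

#' Principal components of a trait matrix
#'
#' Eigen-decomposition of the covariance (default) or correlation matrix
#' of complete cases. Loading vectors are oriented so that each one's
#' largest-magnitude entry is positive; trailing zero-variance components
#' are flagged for rank-deficient input.
#'
#' @param features Numeric data.frame or matrix (individuals x named
#'   traits); rows with any missing value are dropped.
#' @param scale_mode `"covariance"` (raw measurement units) or
#'   `"correlation"`.
#' @return List: `scores`, `loadings`, `variance_fraction` (sums to 1),
#'   `sdev`, `complete_rows` (row indices used), `zero_variance`
#'   (logical flags per component).
#' @export
pcaTraits <- function(features, scale_mode = c("covariance",
                                               "correlation")) {
  scale_mode <- match.arg(scale_mode)
  X <- as.matrix(features)
  cc <- complete.cases(X)
  if (sum(cc) < 2) stop("need >= 2 complete rows")
  X <- X[cc, , drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = scale_mode == "correlation")
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_fraction = vf,
       sdev = pc$sdev, complete_rows = which(cc),
       zero_variance = pc$sdev < 1e-10)
}

#' Cross-validated linear discriminant classification
#'
#' Linear discriminant analysis with pooled within-group covariance;
#' assignments are leave-one-out cross-validated by default (`MASS::lda`
#' with `CV = TRUE`), or k-fold. The confusion matrix is expressed as
#' percent of each actual group's rows; discriminant-axis scores and the
#' percent of between-group variance per axis are returned from a fit on
#' the full data. A singular pooled covariance is ridge-regularized with a
#' warning.
#'
#' @param features Numeric data.frame/matrix of continuous traits.
#' @param groups Group label per row (>= 2 groups; each group larger than
#'   the trait count).
#' @param scheme `"loo"` (leave-one-out) or an integer number of folds.
#' @param seed Seed (k-fold shuffling only).
#' @return List: `confusion` (percent), `counts`, `accuracy`, `scores`,
#'   `axis_variance_pct`, `assigned`, `used_rows`.
#' @export
ldaCrossval <- function(features, groups, scheme = "loo", seed = 1) {
  X <- as.matrix(features)
  cc <- complete.cases(X) & !is.na(groups)
  X <- X[cc, , drop = FALSE]
  g <- factor(groups[cc])
  stopifnot(nlevels(g) >= 2)
  if (any(table(g) <= ncol(X)))
    warning("some groups have no more members than traits; ",
            "estimates may be unstable")
  ridge_fit <- function(x, grouping, ...) {
    tryCatch(MASS::lda(x, grouping = grouping, ...),
             error = function(e) {
               warning("singular pooled covariance; ridge-regularized")
               MASS::lda(x + matrix(rnorm(length(x), 0, 1e-8), nrow(x)),
                         grouping = grouping, ...)
             })
  }
  if (identical(scheme, "loo")) {
    # explicit refits: the held-out row never touches its training fold
    assigned <- factor(rep(NA_character_, nrow(X)), levels = levels(g))
    for (i in seq_len(nrow(X))) {
      fit <- ridge_fit(X[-i, , drop = FALSE], g[-i])
      assigned[i] <- stats::predict(fit, X[i, , drop = FALSE])$class
    }
  } else {
    folds <- withSeed(seed, sample(rep_len(seq_len(scheme), nrow(X))))
    assigned <- factor(rep(NA_character_, nrow(X)), levels = levels(g))
    for (f in seq_len(scheme)) {
      tr <- folds != f
      fit <- ridge_fit(X[tr, , drop = FALSE], g[tr])
      assigned[!tr] <-
        stats::predict(fit, X[!tr, , drop = FALSE])$class
    }
  }
  fit_full <- ridge_fit(X, g)
  scores <- stats::predict(fit_full, X)$x
  counts <- table(g, factor(assigned, levels = levels(g)))
  confusion <- 100 * sweep(counts, 1, rowSums(counts), "/")
  list(confusion = as.matrix(confusion), counts = as.matrix(counts),
       accuracy = mean(assigned == g), scores = scores,
       axis_variance_pct = 100 * fit_full$svd^2 / sum(fit_full$svd^2),
       assigned = as.character(assigned), used_rows = which(cc))
}

#' Per-population frequency table of a binary trait
#'
#' Counts and frequencies of a scored (0/1 or logical) trait per
#' population — the mapping / cline `k/n` input format.
#'
#' @param trait Binary or 0/1-scored vector per individual (`NA` dropped
#'   per population).
#' @param population Population label per individual.
#' @return data.frame with `population`, `n`, `k`, `frequency`.
#' @export
frequencyMapTable <- function(trait, population) {
  stopifnot(length(trait) == length(population))
  tr <- as.numeric(trait)
  stopifnot(all(tr %in% c(0, 1) | is.na(tr)))
  out <- lapply(split(tr, population), function(v) {
    v <- v[!is.na(v)]
    data.frame(n = length(v), k = sum(v),
               frequency = if (length(v)) mean(v) else NA_real_)
  })
  res <- do.call(rbind, out)
  data.frame(population = names(out), res, row.names = NULL)
}
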