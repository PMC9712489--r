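# Distribution-model support procedures: plain-text raster IO, bias-aware
# pseudo-absence sampling, proximity thinning, tuning-grid enumeration,
# collinearity filtering, and permutation-importance backward selection
# around a pluggable model fitter.

#' Read / write an ESRI ASCII grid
#'
#' Minimal plain-text raster support: the six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed
#' by rows of cell values, top row first.
#'
#' @param path File path.
#' @return [readAsciiGrid]: a [RasterGrid-class]. [writeAsciiGrid]:
#'   `path`, invisibly.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[a-zA-Z]", trimws(lines[i]))) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  methods::new("RasterGrid", values = m, xll = xll, yll = yll,
               cellsize = hdr$cellsize)
}

#' @rdname readAsciiGrid
#' @param grid A [RasterGrid-class].
#' @param nodata Value written for `NA` cells.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  m <- grid@values
  m[is.na(m)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid@xll),
           sprintf("yllcorner %.10g", grid@yll),
           sprintf("cellsize %.10g", grid@cellsize),
           sprintf("nodata_value %.10g", nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Bias-weighted pseudo-absence sampling
#'
#' Draws `n_points` grid cells with probability proportional to the cell
#' weights (min-max rescaled to `[0, 1]` first if needed), then jitters
#' each point uniformly within its cell. For a distance-to-roads surface,
#' pass `weight = 1 - scaled distance` so points near roads are more
#' likely to be sampled.
#'
#' @param weight_grid A [RasterGrid-class] of sampling weights (at least
#'   one positive cell after rescaling).
#' @param n_points Number of points to draw.
#' @param seed Integer seed; draws are fully reproducible.
#' @return data.frame with `x`, `y` (grid coordinates), `row`, `col`
#'   (1-based cell indices, row 1 = top).
#' @export
biasSample <- function(weight_grid, n_points, seed) {
  w <- weight_grid@values
  w[is.na(w)] <- 0
  rng <- range(w)
  if (rng[1] < 0 || rng[2] > 1) {
    if (rng[2] > rng[1]) w <- (w - rng[1]) / (rng[2] - rng[1])
    else w[] <- 0
  }
  if (all(w <= 0)) stop("all sampling weights are zero")
  nr <- nrow(w); nc <- ncol(w)
  cs <- weight_grid@cellsize
  withSeed(seed, {
    cell <- sample.int(nr * nc, n_points, replace = TRUE, prob = as.vector(w))
    r <- (cell - 1L) %% nr + 1L
    cl <- (cell - 1L) %/% nr + 1L
    data.frame(
      x = weight_grid@xll + (cl - 1 + runif(n_points)) * cs,
      y = weight_grid@yll + (nr - r + runif(n_points)) * cs,
      row = r, col = cl)
  })
}

#' Proximity thinning of occurrence records
#'
#' Greedy thinning to a minimum pairwise separation: records are ranked
#' (specimen records preferred, then input order with a seeded random
#' tie-break within source class) and accepted whenever farther than
#' `min_km` from every already-accepted record (haversine distance).
#'
#' @param occ data.frame with `lon`, `lat` and optionally `source`
#'   (records with source `"specimen"` are preferentially retained).
#' @param min_km Minimum separation in km (default 10).
#' @param seed Seed for the within-class tie-break.
#' @return The retained subset of `occ` (original row order).
#' @export
thinOccurrences <- function(occ, min_km = 10, seed = 1) {
  n <- nrow(occ)
  if (n == 0) return(occ)
  pri <- if ("source" %in% names(occ))
    ifelse(occ$source == "specimen", 0, 1) else rep(1, n)
  ord <- withSeed(seed, order(pri, sample.int(n)))
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all(haversineKm(occ$lat[keep], occ$lon[keep],
                        occ$lat[i], occ$lon[i]) > min_km))
      keep <- c(keep, i)
  }
  occ[sort(keep), , drop = FALSE]
}

#' Enumerate a feature-class x smoothing tuning grid
#'
#' Cartesian product of every non-empty subset of the feature-class
#' universe with the smoothing (regularization-multiplier) sequence, in
#' deterministic order. With the conventional universe (linear, quadratic,
#' hinge) and smoothing 1 to 12 in steps of 0.5 this enumerates
#' `(2^3 - 1) * 23 = 161` cells.
#'
#' @param feature_universe Character vector of feature classes (non-empty
#'   subset universe), default `c("linear", "quadratic", "hinge")`.
#' @param smoothing Numeric vector of smoothing values, default
#'   `seq(1, 12, by = 0.5)`.
#' @return data.frame with `classes` (plus-separated feature subset) and
#'   `smoothing`.
#' @export
tuningGrid <- function(feature_universe = c("linear", "quadratic",
                                            "hinge"),
                       smoothing = seq(1, 12, by = 0.5)) {
  if (!length(feature_universe)) stop("empty feature-class universe")
  stopifnot(length(smoothing) >= 1)
  u <- feature_universe
  subsets <- unlist(lapply(seq_along(u), function(k)
    combn(u, k, paste, collapse = "+", simplify = FALSE)), use.names = FALSE)
  out <- expand.grid(classes = subsets, smoothing = smoothing,
                     stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(match(out$classes, subsets), out$smoothing), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative collinearity filter
#'
#' Repeatedly finds the most-correlated predictor pair with `|r|` above
#' the threshold and drops the member with the larger variance inflation
#' factor (computed against all currently retained predictors), until no
#' pair exceeds the threshold. Constant predictors are dropped first with
#' a warning.
#'
#' @param predictors data.frame/matrix of numeric predictors (>= 2).
#' @param r_threshold Absolute correlation threshold (default 0.8).
#' @return Character vector of retained predictor names.
#' @export
collinearityFilter <- function(predictors, r_threshold = 0.8) {
  X <- as.data.frame(predictors)
  stopifnot(ncol(X) >= 2)
  const <- vapply(X, function(v) var(v, na.rm = TRUE) == 0, TRUE)
  if (any(const)) {
    warning("dropping constant predictors: ",
            paste(names(X)[const], collapse = ", "))
    X <- X[!const]
  }
  vif <- function(j, Xr) {
    others <- Xr[setdiff(names(Xr), j)]
    if (!ncol(others)) return(1)
    r2 <- summary(lm(Xr[[j]] ~ ., data = others))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (ncol(X) < 2) break
    cm <- abs(cor(X, use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm) <= r_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- colnames(cm)[idx[1]]; b <- colnames(cm)[idx[2]]
    drop <- if (vif(a, X) >= vif(b, X)) a else b
    X <- X[setdiff(names(X), drop)]
  }
  names(X)
}

# ---- default penalized presence/pseudo-absence fitter ----------------------

# hinge basis: forward and reverse hinges at interior quantile knots
hingeBasis <- function(v, knots) {
  cbind(outer(v, knots, function(x, t) pmax(0, x - t)),
        outer(v, knots, function(x, t) pmax(0, t - x)))
}

buildFeatures <- function(X, classes, knots) {
  cls <- strsplit(classes, "+", fixed = TRUE)[[1]]
  out <- list()
  for (p in colnames(X)) {
    v <- X[, p]
    if ("linear" %in% cls) out[[paste0(p, "_lin")]] <- v
    if ("quadratic" %in% cls) out[[paste0(p, "_sq")]] <- v^2
    if ("hinge" %in% cls) {
      hb <- hingeBasis(v, knots[[p]])
      colnames(hb) <- paste0(p, "_h", seq_len(ncol(hb)))
      out[[paste0(p, "_hinge")]] <- hb
    }
  }
  do.call(cbind, out)
}

#' Default penalized logistic presence/pseudo-absence fitter
#'
#' The package's built-in fitter for [backwardSelect]: an L1-penalized
#' logistic regression (glmnet) of presence against the requested feature
#' expansion (linear, quadratic and hinge classes), with the penalty
#' proportional to the tuning cell's smoothing value. The fitter contract:
#' called as `fitter(data, features, cell)` and returning a list with
#' `loglik`, `K` (nonzero coefficients, the MaxEnt-AICc convention),
#' `n_presence`, and `predict(newdata)` giving presence probabilities.
#'
#' @param data data.frame with a 0/1 `presence` column and numeric
#'   predictor columns.
#' @param features Character vector of predictor names to use.
#' @param cell One row of [tuningGrid] (`classes`, `smoothing`).
#' @param lambda_base Penalty at smoothing 1 (default 0.005).
#' @return Fitted-model contract list (see Description).
#' @export
penalizedLogisticFitter <- function(data, features, cell,
                                    lambda_base = 0.005) {
  y <- data$presence
  X <- as.matrix(data[features])
  knots <- lapply(as.data.frame(X), function(v)
    unique(quantile(v, probs = seq(0.1, 0.9, 0.2), names = FALSE)))
  F <- buildFeatures(X, cell$classes, knots)
  lambda <- lambda_base * cell$smoothing
  fit <- glmnet::glmnet(F, y, family = "binomial", lambda = lambda,
                        standardize = TRUE)
  pred_feats <- colnames(F)
  predict_fun <- function(newdata) {
    Fn <- buildFeatures(as.matrix(newdata[features]), cell$classes, knots)
    as.numeric(stats::predict(fit, Fn[, pred_feats, drop = FALSE],
                              type = "response"))
  }
  p <- as.numeric(stats::predict(fit, F, type = "response"))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  K <- sum(as.numeric(coef(fit)) != 0)
  list(loglik = ll, K = K, n_presence = sum(y == 1),
       predict = predict_fun)
}

#' Permutation-importance backward selection
#'
#' The tuning/selection driver: per iteration, every tuning-grid cell is
#' fitted on the current predictor set and the AICc-best cell chosen
#' (AICc computed from the fitter's `loglik` and nonzero-coefficient `K`
#' with `n` = presence records); permutation importances are then computed
#' for each predictor as the drop in model log-likelihood when that
#' predictor's column is permuted (averaged over `n_perm` seeded
#' permutations, clipped at zero, normalized to sum to 100). While any
#' importance is below `importance_threshold` (percent), the
#' minimum-importance predictor is dropped and the procedure repeats.
#'
#' @param data data.frame with a 0/1 `presence` column and numeric
#'   predictors.
#' @param predictors Character vector of starting predictor names
#'   (default: all non-`presence` columns).
#' @param fitter Fitter honouring the [penalizedLogisticFitter] contract.
#' @param tuning data.frame from [tuningGrid].
#' @param importance_threshold Minimum tolerated permutation importance in
#'   percent (default 1).
#' @param n_perm Permutations per predictor (default 10).
#' @param seed Seed.
#' @return List with `trace` (per-iteration records: predictor set, chosen
#'   cell, AICc, importances, dropped predictor) and `final` (the last
#'   fitted model contract).
#' @export
backwardSelect <- function(data, predictors = NULL,
                           fitter = penalizedLogisticFitter,
                           tuning = tuningGrid(),
                           importance_threshold = 1, n_perm = 10,
                           seed = 1) {
  if (is.null(predictors))
    predictors <- setdiff(names(data), "presence")
  stopifnot(length(predictors) >= 1, "presence" %in% names(data))
  trace <- list()
  it <- 0L
  final <- NULL
  repeat {
    it <- it + 1L
    best <- NULL; best_cell <- NULL; best_aicc <- Inf
    for (ci in seq_len(nrow(tuning))) {
      cell <- tuning[ci, , drop = FALSE]
      f <- tryCatch(fitter(data, predictors, cell),
                    error = function(e) NULL)
      if (is.null(f)) next
      a <- suppressWarnings(aicc(f$loglik, f$K, f$n_presence))
      if (is.finite(a) && a < best_aicc) {
        best <- f; best_cell <- cell; best_aicc <- a
      }
    }
    if (is.null(best)) stop("all tuning cells failed")
    imp <- permutationImportance(best, data, predictors, n_perm,
                                 childSeed(seed, it))
    low <- imp < importance_threshold
    dropped <- NA_character_
    if (any(low) && length(predictors) > 1)
      dropped <- predictors[which.min(imp)]
    trace[[it]] <- list(predictors = predictors,
                        cell = best_cell, AICc = best_aicc,
                        importance = imp, dropped = dropped)
    final <- best
    if (is.na(dropped)) break
    predictors <- setdiff(predictors, dropped)
  }
  list(trace = trace, final = final)
}

# drop in model log-likelihood when one predictor's column is permuted,
# averaged over seeded permutations; normalized to sum to 100
permutationImportance <- function(model, data, predictors, n_perm, seed) {
  y <- data$presence
  loglik_of <- function(d) {
    p <- pmin(pmax(model$predict(d), 1e-12), 1 - 1e-12)
    sum(y * log(p) + (1 - y) * log1p(-p))
  }
  base_ll <- loglik_of(data)
  withSeed(seed, {
    drops <- vapply(predictors, function(pn) {
      mean(vapply(seq_len(n_perm), function(r) {
        d <- data
        d[[pn]] <- sample(d[[pn]])
        max(0, base_ll - loglik_of(d))
      }, 0))
    }, 0)
    tot <- sum(drops)
    if (tot <= 0) rep(100 / length(predictors), length(predictors)) |>
        setNames(predictors)
    else 100 * drops / tot
  })
}
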