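# Cline fitting: bounded parameterization, maximum likelihood by
# multi-start optimization, adaptive random-walk MCMC (covariance tuned in
# a discarded first phase, then three fixed-kernel chains), and AICc model
# selection over the 15 architectures.

# Full positional parameter layout used by the fast likelihood path:
# 1 center, 2 width, 3 deltaL, 4 tauL, 5 deltaR, 6 tauR, 7 pmin, 8 pmax,
# 9 sigma. Free parameters are a subset, bounded uniform, sampled through
# a logistic transform of unconstrained coordinates.
PAR_SLOTS <- c("center", "width", "deltaL", "tauL", "deltaR", "tauR",
               "pmin", "pmax", "sigma")

tailCode <- function(tail_config)
  match(tail_config, c("none", "right", "left", "mirror", "both")) - 1L

pspecBuild <- function(transect, trait, tail_config, scaling) {
  tr <- transect@traits[[trait]]
  if (is.null(tr)) stop("unknown trait: ", trait)
  x <- transect@localities$position_km
  keep <- !is.na(tr$n) & tr$n > 0
  x <- x[keep]
  span <- max(diff(range(x)), 1e-6)
  x0 <- min(x)
  quantitative <- tr$kind == "quantitative"
  if (quantitative) {
    obs <- tr$mean[keep]
    env <- range(c(obs - 2 * tr$sd[keep], obs + 2 * tr$sd[keep]))
    lo_p <- env[1] - diff(range(obs)); hi_p <- env[2] + diff(range(obs))
    if (lo_p == hi_p) { lo_p <- lo_p - 1; hi_p <- hi_p + 1 }
    sig_hi <- max(diff(env) / 2, 1e-6)
  } else {
    obs <- tr$k[keep] / tr$n[keep]
    lo_p <- 0; hi_p <- 1
    sig_hi <- NA_real_
  }
  nm <- c("center", "width")
  lo <- c(x0 - 0.5 * span, span * 1e-3)
  hi <- c(x0 + 1.5 * span, 10 * span)
  if (tail_config %in% c("left", "mirror", "both")) {
    nm <- c(nm, "deltaL", "tauL"); lo <- c(lo, 0, 1e-4); hi <- c(hi, span, 1)
  }
  if (tail_config %in% c("right", "both")) {
    nm <- c(nm, "deltaR", "tauR"); lo <- c(lo, 0, 1e-4); hi <- c(hi, span, 1)
  }
  if (scaling == "free") {
    nm <- c(nm, "pmin", "pgap")
    lo <- c(lo, lo_p, 1e-4); hi <- c(hi, hi_p, 1)
  }
  if (quantitative) {
    nm <- c(nm, "sigma"); lo <- c(lo, sig_hi * 1e-4); hi <- c(hi, sig_hi)
  }
  fixed <- c(center = NA, width = NA, deltaL = 0, tauL = 1, deltaR = 0,
             tauR = 1, pmin = 0, pmax = 1, sigma = NA)
  if (scaling == "observed") {
    fixed["pmin"] <- min(obs); fixed["pmax"] <- max(obs)
  } else if (scaling == "free") {
    fixed["pmin"] <- NA; fixed["pmax"] <- NA
  } else if (quantitative) {
    # fixed01 scaling is meaningful for frequencies only; for quantitative
    # traits it pins the asymptotes to the observed extremes instead
    fixed["pmin"] <- min(obs); fixed["pmax"] <- max(obs)
  }
  direct <- nm %in% PAR_SLOTS
  list(free = nm, lo = lo, hi = hi, fixed = fixed, hi_p = hi_p,
       fixed_num = unname(fixed),
       slot_idx = match(nm[direct], PAR_SLOTS), slot_src = which(direct),
       has_pgap = "pgap" %in% nm,
       i_pmin = match("pmin", nm), i_pgap = match("pgap", nm),
       mirror = tail_config == "mirror",
       tail_config = tail_config, scaling = scaling,
       quantitative = quantitative, span = span,
       x = x, n = tr$n[keep],
       k = if (!quantitative) tr$k[keep] else NULL,
       mean = if (quantitative) tr$mean[keep] else NULL,
       sd = if (quantitative) tr$sd[keep] else NULL)
}

# z (unconstrained) -> natural free values
zToFree <- function(z, ps) ps$lo + (ps$hi - ps$lo) * stats::plogis(z)

freeToZ <- function(v, ps) {
  u <- pmin(pmax((v - ps$lo) / (ps$hi - ps$lo), 1e-6), 1 - 1e-6)
  stats::qlogis(u)
}

# natural free values -> full positional parameter vector
freeToFull <- function(v, ps) {
  full <- ps$fixed_num
  full[ps$slot_idx] <- v[ps$slot_src]
  if (ps$has_pgap) {
    full[7] <- v[ps$i_pmin]
    full[8] <- full[7] + (ps$hi_p - full[7]) * v[ps$i_pgap]
  }
  if (ps$mirror) { full[5] <- full[3]; full[6] <- full[4] }
  full
}

clineShapeFast <- function(x, th, tc) {
  f <- stats::plogis(4 * (x - th[1]) / th[2])
  if (tc == 2L || tc == 3L || tc == 4L) {
    xl <- th[1] - th[3]
    sel <- x < xl
    if (any(sel)) {
      fl <- stats::plogis(4 * (xl - th[1]) / th[2])
      f[sel] <- fl^(1 - th[4]) * f[sel]^th[4]
    }
  }
  if (tc == 1L || tc == 3L || tc == 4L) {
    xr <- th[1] + th[5]
    sel <- x > xr
    if (any(sel)) {
      fr <- stats::plogis(4 * (xr - th[1]) / th[2])
      f[sel] <- 1 - (1 - fr)^(1 - th[6]) * (1 - f[sel])^th[6]
    }
  }
  f
}

makeLogLik <- function(ps) {
  tc <- tailCode(ps$tail_config)
  x <- ps$x
  if (!ps$quantitative) {
    k <- ps$k; n <- ps$n
    function(th) {
      p <- th[7] + (th[8] - th[7]) * clineShapeFast(x, th, tc)
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      sum(k * log(p) + (n - k) * log1p(-p))
    }
  } else {
    n <- ps$n; m <- ps$mean; s <- ps$sd
    ss0 <- ifelse(n > 1, (n - 1) * s^2, 0)
    function(th) {
      mu <- th[7] + (th[8] - th[7]) * clineShapeFast(x, th, tc)
      sigma <- th[9]
      if (!is.finite(sigma) || sigma <= 0) return(-Inf)
      sum(-n / 2 * log(2 * pi * sigma^2) -
            (ss0 + n * (m - mu)^2) / (2 * sigma^2))
    }
  }
}

# data-driven + random starting points on the z scale
clineStarts <- function(ps, n_starts, seed) {
  withSeed(seed, {
    obs <- if (ps$quantitative) ps$mean else ps$k / pmax(ps$n, 1)
    mid <- (min(obs) + max(obs)) / 2
    c0 <- ps$x[which.min(abs(obs - mid))]
    v0 <- setNames(numeric(length(ps$free)), ps$free)
    v0["center"] <- c0
    v0["width"] <- ps$span / 4
    if ("deltaL" %in% ps$free) { v0["deltaL"] <- ps$span / 10; v0["tauL"] <- 0.9 }
    if ("deltaR" %in% ps$free) { v0["deltaR"] <- ps$span / 10; v0["tauR"] <- 0.9 }
    if ("pmin" %in% ps$free) { v0["pmin"] <- min(obs); v0["pgap"] <- 0.95 }
    if ("sigma" %in% ps$free)
      v0["sigma"] <- max(mean(ps$sd, na.rm = TRUE), ps$hi[ps$free == "sigma"] / 10)
    z0 <- freeToZ(unname(v0), ps)
    starts <- list(z0, rep(0, length(ps$free)))
    while (length(starts) < n_starts)
      starts[[length(starts) + 1]] <- rnorm(length(ps$free), 0, 1.5)
    starts
  })
}

#' Maximum-likelihood cline fit (no posterior)
#'
#' Multi-start bounded optimization of the cline likelihood for one
#' architecture. Used by [modelSelect] to build the AICc table; use
#' [fitClineMCMC] for credible intervals.
#'
#' @param transect A [Transect-class].
#' @param trait Trait name.
#' @param tail_config Tail architecture (`none`, `right`, `left`,
#'   `mirror`, `both`).
#' @param scaling `fixed01`, `observed`, or `free`.
#' @param seed Seed (start-point jitter).
#' @param n_starts Number of optimization starts.
#' @return A [ClineFit-class] with empty posterior draws.
#' @export
fitClineML <- function(transect, trait, tail_config = "none",
                       scaling = "fixed01", seed = 1, n_starts = 5) {
  ps <- pspecBuild(transect, trait, tail_config, scaling)
  obj <- function(z) -.cpp_cline_loglik(ps, z)
  best <- NULL
  for (z0 in clineStarts(ps, n_starts, seed)) {
    o <- tryCatch({
      o1 <- optim(z0, obj, method = "Nelder-Mead",
                  control = list(maxit = 800))
      optim(o1$par, obj, method = "BFGS", control = list(maxit = 200))
    }, error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimization starts failed")
  full <- freeToFull(zToFree(best$par, ps), ps)
  K <- clineK(tail_config, scaling, ps$quantitative)
  nloc <- length(ps$x)
  AICc <- suppressWarnings(aicc(-best$value, K, nloc))
  methods::new("ClineFit", trait = trait,
               arch = list(tail_config = tail_config, scaling = scaling),
               params = setNames(full, PAR_SLOTS),
               maxLL = -best$value, K = as.numeric(K), AICc = AICc,
               draws = matrix(numeric(0), 0, 0),
               ci = matrix(NA_real_, 0, 2),
               diagnostics = list(convergence = best$convergence))
}

#' Bayesian cline fit by adaptive MCMC
#'
#' Phase 1: a single adaptive random-walk Metropolis chain (`n_adapt`
#' steps; the first half is discarded) estimates the proposal covariance,
#' with the step scale tuned toward an acceptance rate of 0.23. Phase 2:
#' `chains` independent fixed-kernel chains of `n_iter` steps each, using
#' the scaled (`2.38^2/d`) phase-1 covariance, started from overdispersed
#' draws of the phase-1 tail. Priors are uniform within scale-aware bounds
#' (center over the transect span +- half a span; width up to 10 spans;
#' tails up to a span; tau in (0,1]; sigma bounded by half the observed
#' data range). The ML point is the best-likelihood draw refined by local
#' optimization; intervals are central posterior quantiles; a split-chain
#' potential scale reduction factor is reported per parameter and flagged
#' (not fatal) above 1.1.
#'
#' @inheritParams fitClineML
#' @param n_adapt Phase-1 (adaptation) steps; default `1e6`.
#' @param n_iter Phase-2 steps per chain; default `3e6`.
#' @param chains Number of phase-2 chains (default 3).
#' @param keep Posterior draws retained per chain (thinning is derived).
#' @param ci_level Credible-interval level (default 0.95).
#' @return A [ClineFit-class] with posterior draws, credible intervals and
#'   convergence diagnostics.
#' @export
fitClineMCMC <- function(transect, trait, tail_config = "none",
                         scaling = "fixed01", seed = 1,
                         n_adapt = 1e6, n_iter = 3e6, chains = 3,
                         keep = 1000, ci_level = 0.95) {
  ps <- pspecBuild(transect, trait, tail_config, scaling)
  ll <- makeLogLik(ps)
  d <- length(ps$free)
  logpost <- function(z) {
    s <- stats::plogis(z)
    jac <- sum(log(ps$hi - ps$lo) + log(s) + log1p(-s))
    ll(freeToFull(ps$lo + (ps$hi - ps$lo) * s, ps)) + jac
  }
  withSeed(seed, {
    # cheap ML start
    obj <- function(z) -ll(freeToFull(zToFree(z, ps), ps))
    st <- tryCatch(
      optim(clineStarts(ps, 1, childSeed(seed, 99))[[1]], obj,
            method = "Nelder-Mead", control = list(maxit = 400))$par,
      error = function(e) rep(0, d))
    # ---- phase 1: batched adaptive chain (compiled kernel) ----
    z <- st
    if (!is.finite(logpost(z))) z <- rep(0, d)
    scale <- 0.3
    U <- diag(d) * 0.1
    batch <- 1000L
    n_batches <- max(2L, ceiling(n_adapt / batch))
    half_b <- floor(n_batches / 2)
    thin1 <- 5L
    hist1 <- list()
    best_z <- z; best_ll <- ll(freeToFull(zToFree(z, ps), ps))
    for (b in seq_len(n_batches)) {
      res <- .cpp_mh_chain(ps, z, U, scale, batch, thin1)
      z <- res$z
      rate <- res$accept / batch
      scale <- scale * exp((rate - 0.23) * 0.5)
      if (res$best_ll > best_ll) { best_ll <- res$best_ll; best_z <- res$best_z }
      hist1[[b]] <- res$draws
      if (b > 5) {                      # progressive covariance adaptation
        D <- do.call(rbind, hist1[max(1, b - 20):b])
        Sg <- cov(D) + diag(1e-8, d)
        U <- tryCatch(chol(Sg), error = function(e) U)
      }
    }
    tail_draws <- do.call(rbind, hist1[(half_b + 1):n_batches])
    zbar <- colMeans(tail_draws)
    Sig <- cov(tail_draws) + diag(1e-8, d)
    U2 <- tryCatch(chol(Sig), error = function(e) diag(sqrt(diag(Sig))))
    scale2 <- 2.38 / sqrt(d)
    # ---- phase 2: fixed-kernel chains ----
    thin <- max(1L, floor(n_iter / keep))
    draws <- vector("list", chains)
    acc2 <- numeric(chains)
    for (ch in seq_len(chains)) {
      z0 <- tail_draws[sample.int(nrow(tail_draws), 1), ] +
        rnorm(d, 0, 0.05)
      if (!is.finite(logpost(z0))) z0 <- zbar
      res <- .cpp_mh_chain(ps, z0, U2, scale2, n_iter, thin)
      if (res$best_ll > best_ll) { best_ll <- res$best_ll; best_z <- res$best_z }
      draws[[ch]] <- res$draws
      acc2[ch] <- res$accept / n_iter
    }
    # refine ML point from the best draw
    all_nat <- do.call(rbind, lapply(draws, function(m)
      t(apply(m, 1, function(z) zToFree(z, ps)))))
    lls <- apply(all_nat, 1, function(v) ll(freeToFull(v, ps)))
    zb <- freeToZ(all_nat[which.max(lls), ], ps)
    if (max(lls) > best_ll) { best_ll <- max(lls); best_z <- zb }
    o <- tryCatch(optim(best_z, obj, method = "Nelder-Mead",
                        control = list(maxit = 600)),
                  error = function(e) NULL)
    if (!is.null(o) && -o$value >= best_ll) {
      best_z <- o$par; best_ll <- -o$value
    }
    full_ml <- freeToFull(zToFree(best_z, ps), ps)
    # diagnostics + intervals on the natural scale of the free parameters
    rhat <- splitRhat(draws)
    alpha <- (1 - ci_level) / 2
    ci <- t(apply(all_nat, 2, quantile, probs = c(alpha, 1 - alpha)))
    rownames(ci) <- ps$free
    names(rhat) <- ps$free
    colnames(all_nat) <- ps$free
    w_ml <- full_ml[2]
    w_hi <- ps$hi[ps$free == "width"]
    flags <- character(0)
    if (median(all_nat[, "width"]) > 0.9 * w_hi || w_ml > 0.9 * w_hi)
      flags <- c(flags, "width_at_prior_bound")
    if (any(rhat > 1.1, na.rm = TRUE))
      flags <- c(flags, "non_convergence")
    K <- clineK(tail_config, scaling, ps$quantitative)
    methods::new("ClineFit", trait = trait,
                 arch = list(tail_config = tail_config, scaling = scaling),
                 params = setNames(full_ml, PAR_SLOTS),
                 maxLL = best_ll, K = as.numeric(K),
                 AICc = suppressWarnings(aicc(best_ll, K, length(ps$x))),
                 draws = all_nat, ci = ci,
                 diagnostics = list(rhat = rhat, accept = acc2,
                                    flags = flags))
  })
}

splitRhat <- function(draws) {
  seqs <- list()
  for (m in draws) {
    h <- floor(nrow(m) / 2)
    if (h < 2) next
    seqs <- c(seqs, list(m[1:h, , drop = FALSE]),
              list(m[(h + 1):(2 * h), , drop = FALSE]))
  }
  if (!length(seqs)) return(NA_real_)
  d <- ncol(seqs[[1]])
  vapply(seq_len(d), function(j) {
    ch <- vapply(seqs, function(m) c(mean(m[, j]), var(m[, j])),
                 numeric(2))
    W <- mean(ch[2, ])
    B <- var(ch[1, ]) * nrow(seqs[[1]])
    n <- nrow(seqs[[1]])
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

#' AICc model selection over the 15 cline architectures
#'
#' Fits every combination of 5 tail configurations (none, right, left,
#' mirror, both exponential tails) and 3 scalings (asymptotes fixed to
#' 0/1, fixed to the observed extremes, or free) by maximum likelihood and
#' ranks them by AICc. Individual model failures are recorded in the
#' table, not fatal. Optionally refits the winning architecture by MCMC
#' for credible intervals.
#'
#' @inheritParams fitClineML
#' @param mcmc Refit the AICc-best architecture with [fitClineMCMC].
#' @param n_adapt,n_iter,chains Passed to [fitClineMCMC] when
#'   `mcmc = TRUE`.
#' @return List: `best` (a [ClineFit-class]) and `table` (15-row
#'   data.frame with tail_config, scaling, K, maxLL, AICc, dAICc, ordered
#'   by AICc).
#' @export
modelSelect <- function(transect, trait, seed = 1, n_starts = 5,
                        mcmc = FALSE, n_adapt = 1e5, n_iter = 1e5,
                        chains = 3) {
  archs <- clineArchitectures()
  fits <- vector("list", nrow(archs))
  rows <- vector("list", nrow(archs))
  for (i in seq_len(nrow(archs))) {
    tc <- archs$tail_config[i]; sc <- archs$scaling[i]
    f <- tryCatch(
      fitClineML(transect, trait, tc, sc,
                 seed = childSeed(seed, i), n_starts = n_starts),
      error = function(e) NULL)
    fits[[i]] <- f
    rows[[i]] <- data.frame(
      tail_config = tc, scaling = sc,
      K = if (is.null(f)) NA_integer_ else f@K,
      maxLL = if (is.null(f)) NA_real_ else f@maxLL,
      AICc = if (is.null(f)) Inf else f@AICc,
      failed = is.null(f))
  }
  tab <- do.call(rbind, rows)
  tab$dAICc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  ord <- order(tab$AICc)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  best_i <- ord[1]
  best <- fits[[best_i]]
  if (mcmc)
    best <- fitClineMCMC(transect, trait, archs$tail_config[best_i],
                         archs$scaling[best_i],
                         seed = childSeed(seed, 1000),
                         n_adapt = n_adapt, n_iter = n_iter,
                         chains = chains)
  list(best = best, table = tab)
}
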