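# Geographic cline model: central sigmoid with optional exponential tails,
# trait scaling, and binomial / Gaussian likelihoods over an ordered
# transect.

#' Transect positions from geographic coordinates
#'
#' Cumulative great-circle distances along an ordered set of localities.
#' Each leg is a haversine distance (mean Earth radius 6371.0088 km) rounded
#' to the nearest 0.1 km before accumulation, so printed positions add up
#' exactly.
#'
#' @param lat,lon Numeric vectors of WGS84 decimal degrees, in transect
#'   order.
#' @return Numeric vector of positions in km, starting at 0.
#' @export
#' @examples
#' transectPositions(c(0, 0), c(0, 1))   # ~111.2 km apart on the equator
transectPositions <- function(lat, lon) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1)
  if (length(lat) == 1) return(0)
  legs <- haversineKm(lat[-length(lat)], lon[-length(lon)],
                      lat[-1], lon[-1])
  cumsum(c(0, round(legs, 1)))
}

haversineKm <- function(lat1, lon1, lat2, lon2) {
  R <- 6371.0088
  to_rad <- pi / 180
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlam / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# Central sigmoid in [0,1]: f(x) = (1 + tanh(2(x-c)/w))/2, equivalently the
# logistic 1/(1 + exp(-4(x-c)/w)).
clineSigmoid <- function(x, center, width) {
  stats::plogis(4 * (x - center) / width)
}

# Tailed shape F(x) in [0,1]. Tails replace the sigmoid beyond the
# attachment points c - deltaL / c + deltaR by a geometric interpolation
# f(x)^tau * f_att^(1-tau) (acting on 1-f on the right), which decays
# asymptotically exponentially at rate tau * 4/w, has log-slope at the
# attachment equal to tau times the sigmoid's own log-slope there, is
# monotone for tau in (0,1], and is identically the sigmoid when tau = 1.
clineShape <- function(x, params, tail_config = "none") {
  center <- params[["center"]]; width <- params[["width"]]
  f <- clineSigmoid(x, center, width)
  if (tail_config %in% c("left", "mirror", "both")) {
    dL <- params[["deltaL"]]; tL <- params[["tauL"]]
    xl <- center - dL
    sel <- x < xl
    if (any(sel)) {
      fl <- clineSigmoid(xl, center, width)
      f[sel] <- fl^(1 - tL) * clineSigmoid(x[sel], center, width)^tL
    }
  }
  if (tail_config %in% c("right", "mirror", "both")) {
    if (tail_config == "mirror") {
      dR <- params[["deltaL"]]; tR <- params[["tauL"]]
    } else {
      dR <- params[["deltaR"]]; tR <- params[["tauR"]]
    }
    xr <- center + dR
    sel <- x > xr
    if (any(sel)) {
      fr <- clineSigmoid(xr, center, width)
      f[sel] <- 1 - (1 - fr)^(1 - tR) *
        (1 - clineSigmoid(x[sel], center, width))^tR
    }
  }
  f
}

#' Evaluate a cline at transect positions
#'
#' The expected trait value `pmin + (pmax - pmin) * F(x)` where `F` is the
#' central sigmoid `(1 + tanh(2(x - c)/w))/2` with optional exponential
#' tails beyond the attachment distances (see Details in the package
#' vignette). With `tail_config = "none"` and `x = c` the value is
#' `(pmin + pmax)/2`.
#'
#' @param x Positions (km).
#' @param params Named numeric vector with `center`, `width` and, as the
#'   architecture requires, `pmin`, `pmax`, `deltaL`, `tauL`, `deltaR`,
#'   `tauR`. Missing `pmin`/`pmax` default to 0/1.
#' @param tail_config One of `"none"`, `"right"`, `"left"`, `"mirror"`,
#'   `"both"`.
#' @return Expected frequency (or trait mean) at each `x`.
#' @export
clineValue <- function(x, params, tail_config = "none") {
  pmin_ <- if ("pmin" %in% names(params)) params[["pmin"]] else 0
  pmax_ <- if ("pmax" %in% names(params)) params[["pmax"]] else 1
  pmin_ + (pmax_ - pmin_) * clineShape(x, params, tail_config)
}

#' Cline log-likelihood on a transect trait
#'
#' Frequency traits: product-binomial likelihood
#' `sum(k*log(p) + (n-k)*log(1-p))` with `p` clamped to
#' `[1e-9, 1 - 1e-9]`. Quantitative traits: Gaussian likelihood evaluated
#' from the per-locality sufficient statistics `(n, mean, sd)` with mean
#' `mu(x)` from [clineValue] and residual standard deviation
#' `params["sigma"]`. Localities with `n = 0` are skipped.
#'
#' @param transect A [Transect-class].
#' @param trait Trait name.
#' @param params Named parameter vector (see [clineValue]; quantitative
#'   traits additionally need `sigma`).
#' @param tail_config Tail architecture.
#' @return Log-likelihood (scalar).
#' @export
clineLogLik <- function(transect, trait, params, tail_config = "none") {
  tr <- transect@traits[[trait]]
  if (is.null(tr)) stop("unknown trait: ", trait)
  x <- transect@localities$position_km
  keep <- !is.na(tr$n) & tr$n > 0
  x <- x[keep]
  mu <- clineValue(x, params, tail_config)
  if (tr$kind == "frequency") {
    p <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
    k <- tr$k[keep]; n <- tr$n[keep]
    sum(k * log(p) + (n - k) * log1p(-p))
  } else {
    n <- tr$n[keep]; m <- tr$mean[keep]; s <- tr$sd[keep]
    sigma <- params[["sigma"]]
    if (!is.finite(sigma) || sigma <= 0) return(-Inf)
    ss <- ifelse(n > 1, (n - 1) * s^2, 0) + n * (m - mu)^2
    sum(-n / 2 * log(2 * pi * sigma^2) - ss / (2 * sigma^2))
  }
}

#' Small-sample corrected AIC
#'
#' `AICc = -2*maxLL + 2K + 2K(K+1)/(n - K - 1)`, with `n` the number of
#' localities carrying data. When `n <= K + 1` the correction is undefined
#' and `+Inf` is returned with a warning (model unusable at this sample
#' size).
#'
#' @param maxLL Maximum log-likelihood.
#' @param K Number of free parameters.
#' @param n Number of localities with data.
#' @return AICc value.
#' @export
#' @examples
#' aicc(-20, 4, 11)  # 54.6667
aicc <- function(maxLL, K, n) {
  if (n <= K + 1) {
    warning("AICc undefined for n <= K + 1; returning Inf")
    return(Inf)
  }
  -2 * maxLL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

# The 15 cline architectures: 5 tail configurations x 3 scalings.
clineArchitectures <- function() {
  expand.grid(tail_config = c("none", "right", "left", "mirror", "both"),
              scaling = c("fixed01", "observed", "free"),
              stringsAsFactors = FALSE)
}

# Free-parameter count of an architecture. center + width always free;
# tails add 2 per independent side (2 for mirror); free scaling adds 2;
# sigma adds 1 for quantitative traits.
clineK <- function(tail_config, scaling, quantitative = FALSE) {
  K <- 2L
  K <- K + switch(tail_config, none = 0L, right = 2L, left = 2L,
                  mirror = 2L, both = 4L)
  if (scaling == "free") K <- K + 2L
  if (quantitative) K <- K + 1L
  K
}
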