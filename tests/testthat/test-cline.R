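# Cline geometry, likelihood, AICc and fitting machinery.

test_that("transect positions follow rounded haversine legs", {
  # two equatorial points 1 degree apart: 2R sin(0.5 deg) ~ 111.2 km
  pos <- transectPositions(c(0, 0), c(0, 1))
  leg <- 2 * 6371.0088 * sin(pi / 360)
  expect_equal(pos, c(0, round(leg, 1)))
  expect_equal(transectPositions(40, -110), 0)
  lat <- c(42, 43.1, 44.5, 45.2); lon <- c(-116, -115, -113.5, -112)
  fwd <- transectPositions(lat, lon)
  rev_ <- transectPositions(rev(lat), rev(lon))
  expect_equal(rev(max(fwd) - fwd), rev_)
})

test_that("cline evaluation honours its sigmoid geometry and limits", {
  par <- c(center = 150, width = 40)
  expect_equal(clineValue(150, par), 0.5)
  expect_equal(clineValue(c(-1e6, 1e6), par), c(0, 1), tolerance = 1e-12)
  par2 <- c(center = 150, width = 40, pmin = 0.2, pmax = 0.8)
  expect_equal(clineValue(150, par2), 0.5)
  expect_equal(clineValue(1e6, par2), 0.8, tolerance = 1e-9)
  # tau = 1 tails reproduce the pure sigmoid exactly (any delta)
  x <- seq(-100, 400, by = 7)
  for (tc in c("left", "right", "mirror", "both")) {
    part <- c(center = 150, width = 40, deltaL = 0, tauL = 1,
              deltaR = 0, tauR = 1)
    expect_equal(clineValue(x, part, tc), clineValue(x, par),
                 tolerance = 1e-12)
    part2 <- c(center = 150, width = 40, deltaL = 35, tauL = 1,
               deltaR = 20, tauR = 1)
    expect_equal(clineValue(x, part2, tc), clineValue(x, par),
                 tolerance = 1e-12)
  }
})

test_that("tailed clines stay monotone and continuous", {
  x <- seq(-200, 500, by = 0.5)
  set.seed(14)
  for (i in 1:25) {
    par <- c(center = runif(1, 50, 250), width = runif(1, 10, 120),
             deltaL = runif(1, 0, 100), tauL = runif(1, 0.05, 1),
             deltaR = runif(1, 0, 100), tauR = runif(1, 0.05, 1))
    for (tc in c("none", "left", "right", "mirror", "both")) {
      v <- clineValue(x, par, tc)
      expect_true(all(diff(v) >= -1e-12))
      expect_true(all(v >= 0 & v <= 1))
      expect_lt(max(abs(diff(v))), 0.2)   # no jumps at attachment points
    }
  }
})

test_that("frequency log-likelihood equals the per-individual product", {
  st <- simulateTransect(seq(0, 300, by = 50),
                         list(tr = c(center = 160, width = 70)),
                         n_per_locality = 12, seed = 3)
  par <- c(center = 140, width = 60, pmin = 0, pmax = 1)
  ll <- clineLogLik(st$transect, "tr", par)
  tr <- transectTraits(st$transect)$tr
  x <- transectLocalities(st$transect)$position_km
  p <- pmin(pmax(clineValue(x, par), 1e-9), 1 - 1e-9)
  ll_brute <- 0
  for (i in seq_along(x)) {
    outcomes <- c(rep(1, tr$k[i]), rep(0, tr$n[i] - tr$k[i]))
    for (o in outcomes) ll_brute <- ll_brute + log(ifelse(o == 1, p[i],
                                                          1 - p[i]))
  }
  expect_equal(ll, ll_brute, tolerance = 1e-9)
  # all-zero successes stay finite under clamping
  flat <- st$transect
  ttr <- transectTraits(flat)$tr
  ttr$k[] <- 0
  flat@traits$tr <- ttr
  expect_true(is.finite(clineLogLik(flat, "tr",
                                    c(center = 150, width = 50))))
})

test_that("likelihood is invariant under the label-swap symmetry", {
  # relabelling successes as failures (k -> n-k), with the asymptotes
  # swapped to (1-pmax, 1-pmin) and the cline direction flipped by
  # reflecting localities about the center, leaves the likelihood intact
  st <- simulateTransect(seq(0, 300, by = 30),
                         list(tr = c(center = 150, width = 60)),
                         n_per_locality = 20, seed = 9)
  tr <- transectTraits(st$transect)$tr
  loc <- transectLocalities(st$transect)
  sw <- Transect(
    data.frame(name = rev(loc$name),
               position_km = 300 - rev(loc$position_km)),
    list(tr = list(kind = "frequency", n = rev(tr$n),
                   k = rev(tr$n - tr$k))))
  par <- c(center = 150, width = 60, pmin = 0.1, pmax = 0.7)
  par_sw <- c(center = 150, width = 60, pmin = 0.3, pmax = 0.9)
  expect_equal(clineLogLik(st$transect, "tr", par),
               clineLogLik(sw, "tr", par_sw), tolerance = 1e-9)
})

test_that("compiled likelihood agrees with the reference implementation", {
  st <- simulateTransect(seq(0, 400, length.out = 11),
                         list(tr = c(center = 180, width = 45)),
                         n_per_locality = 25, seed = 12)
  for (tc in c("none", "right", "mirror", "both")) {
    for (sc in c("fixed01", "observed", "free")) {
      ps <- clinepop:::pspecBuild(st$transect, "tr", tc, sc)
      set.seed(7)
      for (rep in 1:5) {
        z <- rnorm(length(ps$free))
        full <- clinepop:::freeToFull(clinepop:::zToFree(z, ps), ps)
        names(full) <- clinepop:::PAR_SLOTS
        expect_equal(clinepop:::.cpp_cline_loglik(ps, z),
                     clineLogLik(st$transect, "tr", full, tc),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("AICc arithmetic and guard behave", {
  expect_equal(aicc(-20, 4, 11), 54 + 2/3, tolerance = 1e-9)
  expect_equal(aicc(-12.5, 0, 8), 25)
  expect_warning(expect_equal(aicc(-5, 7, 8), Inf), "undefined")
  set.seed(2)
  for (i in 1:20) {
    LL <- rnorm(1, -30, 10); K <- sample(1:6, 1); n <- K + 1 + sample(2:9, 1)
    expect_equal(aicc(LL, K, n),
                 -2 * LL + 2 * K + 2 * K * (K + 1) / (n - K - 1))
  }
})

test_that("MCMC fitting is seed-deterministic and flags flat traits", {
  st <- simulateTransect(seq(0, 400, length.out = 11),
                         list(tr = c(center = 200, width = 50)),
                         n_per_locality = 30, seed = 4)
  f1 <- fitClineMCMC(st$transect, "tr", seed = 5, n_adapt = 6000,
                     n_iter = 6000, chains = 2, keep = 300)
  f2 <- fitClineMCMC(st$transect, "tr", seed = 5, n_adapt = 6000,
                     n_iter = 6000, chains = 2, keep = 300)
  expect_identical(clineDraws(f1), clineDraws(f2))
  expect_identical(clineParams(f1), clineParams(f2))

  flat <- st$transect
  trf <- transectTraits(flat)$tr
  trf$k <- round(trf$n / 2)
  flat@traits$tr <- trf
  ff <- fitClineMCMC(flat, "tr", seed = 6, n_adapt = 6000, n_iter = 6000,
                     chains = 2, keep = 300)
  expect_true("width_at_prior_bound" %in% ff@diagnostics$flags)
})

test_that("model selection covers all 15 architectures with nesting", {
  st <- simulateTransect(seq(0, 400, length.out = 11),
                         list(tr = c(center = 200, width = 50)),
                         n_per_locality = 30, seed = 8)
  ms <- modelSelect(st$transect, "tr", seed = 3)
  expect_equal(nrow(ms$table), 15)
  expect_equal(nrow(unique(ms$table[c("tail_config", "scaling")])), 15)
  expect_equal(ms$table$dAICc[1], 0)
  expect_false(any(ms$table$failed))
  # free scaling nests fixed01: maxLL can only improve
  for (tc in unique(ms$table$tail_config)) {
    ll_free <- ms$table$maxLL[ms$table$tail_config == tc &
                                ms$table$scaling == "free"]
    ll_fix <- ms$table$maxLL[ms$table$tail_config == tc &
                               ms$table$scaling == "fixed01"]
    expect_gte(ll_free, ll_fix - 1e-4)
  }
})

test_that("quantitative traits fit with a residual scale parameter", {
  st <- simulateTransect(seq(0, 400, length.out = 11),
                         list(q = c(center = 220, width = 60,
                                    pmin = 10, pmax = 30)),
                         trait_kind = c(q = "quantitative"),
                         n_per_locality = 25, sigma = 2, seed = 19)
  f <- fitClineMCMC(st$transect, "q", scaling = "free", seed = 7,
                    n_adapt = 2e4, n_iter = 2e4, chains = 2, keep = 500)
  ci <- clineCI(f)
  expect_true(ci["center", 1] < 220 & 220 < ci["center", 2])
  expect_true(ci["sigma", 1] < 3)
  expect_gt(clineParams(f)[["sigma"]], 0)
})
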