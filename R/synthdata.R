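# Seeded generators emulating the statistical structure of a two-clade
# contact-zone dataset: coalescent sequence panels with a deep between-group
# split, Balding-Nichols structured diploid genotypes, transects sampled
# under a true cline, and smooth landscape grids. Every generator returns
# its ground truth alongside the data and is bit-reproducible under a fixed
# seed.

GENERATOR_VERSION <- "1"

#' Simulate an aligned two-or-more-clade sequence panel
#'
#' Within each group, haplotypes descend from a common group ancestor along
#' a simulated Kingman coalescent genealogy; mutations are placed by a
#' Poisson process (rate `theta_within/2` per unit branch length) under the
#' infinite-sites convention: each mutation hits a site not previously
#' mutated within that group, so the per-site divergence stays
#' `mutation count / L`. Group ancestors differ from the first group's
#' ancestor at `Binomial(L, d_between)` fixed sites, emulating a deep
#' between-clade split with star-like within-clade diversity when
#' `theta_within` is small.
#'
#' @param n_per_group Sequences per group (>= 1).
#' @param L Alignment length in sites (>= 1).
#' @param theta_within Scaled mutation parameter per group (>= 0).
#' @param d_between Expected between-clade raw divergence, proportion of
#'   sites in `[0, 0.75]`.
#' @param groups Ordered character vector of group labels.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List with `panel` (a [SequencePanel-class]; populations equal
#'   groups) and `truth` (generating spec plus realized summaries:
#'   per-group mutation counts, realized ancestor divergence, genealogy
#'   total lengths).
#' @export
simulateSequences <- function(n_per_group, L, theta_within, d_between,
                              groups = c("A", "B"), seed) {
  stopifnot(L >= 1, d_between >= 0, d_between <= 0.75,
            theta_within >= 0, all(n_per_group >= 1))
  n_per_group <- rep_len(n_per_group, length(groups))
  # expected segregating mutations per group: theta * a1(n)
  a1 <- vapply(n_per_group, function(n)
    if (n > 1) sum(1 / seq_len(n - 1)) else 0, 0)
  if (any(theta_within * a1 > L))
    stop("expected mutation count (theta * a1 = ",
         sprintf("%.1f", max(theta_within * a1)),
         ") exceeds alignment length L = ", L,
         "; increase L or reduce theta_within")
  withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, L, replace = TRUE)
    anc <- list()
    anc[[groups[1]]] <- root
    div_real <- numeric(0)
    for (g in groups[-1]) {
      nmut <- rbinom(1, L, d_between)
      a <- root
      if (nmut > 0) {
        sites <- sample.int(L, nmut)
        a[sites] <- vapply(a[sites], function(b)
          sample(setdiff(bases, b), 1), "")
      }
      anc[[g]] <- a
      div_real[g] <- nmut / L
    }
    seqs <- character(0); ids <- character(0); pops <- character(0)
    tree_len <- numeric(length(groups)); names(tree_len) <- groups
    mut_count <- integer(length(groups)); names(mut_count) <- groups
    for (gi in seq_along(groups)) {
      g <- groups[gi]; n <- n_per_group[gi]
      sim <- coalescentGroup(n, L, theta_within, anc[[g]], bases)
      tree_len[g] <- sim$total_length
      mut_count[g] <- sim$n_mut
      ids_g <- sprintf("%s_%02d", g, seq_len(n))
      seqs <- c(seqs, setNames(sim$seqs, ids_g))
      ids <- c(ids, ids_g)
      pops <- c(pops, rep(g, n))
    }
    panel <- SequencePanel(seqs, pop = setNames(pops, ids))
    truth <- list(
      generator = "simulate_sequences", version = GENERATOR_VERSION,
      spec = list(n_per_group = n_per_group, L = L,
                  theta_within = theta_within, d_between = d_between,
                  groups = groups, seed = seed),
      realized = list(ancestor_divergence = as.list(div_real),
                      mutations_per_group = as.list(mut_count),
                      tree_length_per_group = as.list(tree_len)))
    list(panel = panel, truth = truth)
  })
}

# Kingman coalescent for one group: exponential waiting times, uniform
# pairwise merging; Poisson(theta/2 * branch length) mutations assigned to
# distinct sites (infinite sites within the group).
coalescentGroup <- function(n, L, theta, ancestor, bases) {
  if (n == 1 || theta == 0) {
    total <- 0
    if (n > 1) {
      k <- n
      while (k > 1) { total <- total + k * rexp(1, k * (k - 1) / 2); k <- k - 1 }
    }
    return(list(seqs = rep(paste(ancestor, collapse = ""), n),
                total_length = total, n_mut = 0L))
  }
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1) {
    k <- length(active)
    t <- t + rexp(1, k * (k - 1) / 2)
    pair <- sample(active, 2)          # RNG tie-break of topology
    parent[pair] <- nxt
    node_time[nxt] <- t
    active <- c(setdiff(active, pair), nxt)
    nxt <- nxt + 1L
  }
  root <- n_nodes
  blen <- numeric(n_nodes)
  nonroot <- seq_len(n_nodes - 1L)
  blen[nonroot] <- node_time[parent[nonroot]] - node_time[nonroot]
  total <- sum(blen)
  n_mut <- stats::rpois(1, theta / 2 * total)
  if (n_mut > L)
    stop("realized mutation count ", n_mut, " exceeds alignment length ",
         L, "; increase L or reduce theta_within")
  seq_mat <- matrix(rep(ancestor, n), nrow = n, byrow = TRUE)
  if (n_mut > 0) {
    sites <- sample.int(L, n_mut)            # without replacement
    carriers <- descendantTips(parent, n)
    mb <- sample(nonroot, n_mut, replace = TRUE, prob = blen[nonroot])
    for (j in seq_len(n_mut)) {
      tips <- carriers[[mb[j]]]
      old <- ancestor[sites[j]]
      seq_mat[tips, sites[j]] <- sample(setdiff(bases, old), 1)
    }
  }
  list(seqs = apply(seq_mat, 1, paste, collapse = ""),
       total_length = total, n_mut = as.integer(n_mut))
}

# tip sets subtended by each node (tips are nodes 1..n)
descendantTips <- function(parent, n) {
  n_nodes <- length(parent)
  out <- vector("list", n_nodes)
  for (i in seq_len(n)) out[[i]] <- i
  for (i in seq_len(n_nodes - 1L)) {       # children precede parents
    p <- parent[i]
    out[[p]] <- c(out[[p]], out[[i]])
  }
  lapply(out, sort)
}

#' Simulate Balding-Nichols structured diploid genotypes
#'
#' Per locus an ancestral allele-frequency vector is drawn uniformly on the
#' simplex; each group's frequency vector is Dirichlet with mean the
#' ancestral vector and concentration `(1 - fst)/fst` (the Balding-Nichols
#' model). Genotypes are two independent allele draws within group
#' (Hardy-Weinberg within group); cells are masked missing at
#' `missing_rate`. `fst = 0` is the no-differentiation limit (all groups
#' share the ancestral frequencies); `fst` is capped at 0.999.
#'
#' @param n_groups Number of groups.
#' @param n_loci Number of loci.
#' @param alleles_per_locus Alleles segregating at each locus.
#' @param fst Differentiation parameter in `[0, 1)`.
#' @param n_per_group Diploid individuals per group.
#' @param missing_rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `genotypes` (a [GenotypeMatrix-class]) and `truth`
#'   (spec plus realized per-group allele frequencies).
#' @export
simulateGenotypes <- function(n_groups, n_loci, alleles_per_locus, fst,
                              n_per_group, missing_rate = 0, seed) {
  stopifnot(fst >= 0, fst < 1, missing_rate >= 0, missing_rate < 1,
            n_groups >= 1, n_loci >= 1, alleles_per_locus >= 1)
  fst <- min(fst, 0.999)
  withSeed(seed, {
    groups <- sprintf("G%d", seq_len(n_groups))
    n_ind <- n_groups * n_per_group
    pop <- rep(groups, each = n_per_group)
    a1 <- matrix(NA_integer_, n_ind, n_loci)
    a2 <- matrix(NA_integer_, n_ind, n_loci)
    colnames(a1) <- colnames(a2) <- sprintf("L%02d", seq_len(n_loci))
    rownames(a1) <- rownames(a2) <- sprintf("ind%03d", seq_len(n_ind))
    freqs <- vector("list", n_loci); names(freqs) <- colnames(a1)
    for (l in seq_len(n_loci)) {
      anc <- rgamma(alleles_per_locus, 1); anc <- anc / sum(anc)
      fg <- matrix(0, n_groups, alleles_per_locus,
                   dimnames = list(groups, NULL))
      for (g in seq_len(n_groups)) {
        if (fst == 0) fg[g, ] <- anc
        else {
          conc <- (1 - fst) / fst
          d <- rgamma(alleles_per_locus, anc * conc)
          while (sum(d) == 0) d <- rgamma(alleles_per_locus, anc * conc)
          fg[g, ] <- d / sum(d)
        }
        rows <- which(pop == groups[g])
        a1[rows, l] <- sample.int(alleles_per_locus, length(rows),
                                  replace = TRUE, prob = fg[g, ])
        a2[rows, l] <- sample.int(alleles_per_locus, length(rows),
                                  replace = TRUE, prob = fg[g, ])
      }
      freqs[[l]] <- fg
    }
    if (missing_rate > 0) {
      mask <- matrix(runif(n_ind * n_loci) < missing_rate, n_ind, n_loci)
      a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
    }
    gm <- GenotypeMatrix(a1, a2, pop = pop)
    truth <- list(
      generator = "simulate_genotypes", version = GENERATOR_VERSION,
      spec = list(n_groups = n_groups, n_loci = n_loci,
                  alleles_per_locus = alleles_per_locus, fst = fst,
                  n_per_group = n_per_group, missing_rate = missing_rate,
                  seed = seed),
      realized = list(group_allele_freqs = lapply(freqs, function(m)
        as.data.frame(m))))
    list(genotypes = gm, truth = truth)
  })
}

#' Simulate a transect sampled under true clines
#'
#' Frequency traits: per-locality successes `k ~ Binomial(n, p(x))` under
#' the true cline. Quantitative traits: `n` per-individual values
#' `Normal(mu(x), sigma)`, reported as per-locality `n`, mean, sd.
#'
#' @param positions_km Strictly increasing locality positions.
#' @param true_params Named list of per-trait true parameter vectors (see
#'   [clineValue]); each may carry an attribute-free `tail_config` entry via
#'   `attr` or default `"none"`.
#' @param trait_kind Named character vector per trait:
#'   `"frequency"` or `"quantitative"`.
#' @param n_per_locality Sampling effort per locality (>= 1), recycled.
#' @param sigma Residual SD for quantitative traits.
#' @param seed Integer seed.
#' @return List with `transect` (a [Transect-class]) and `truth`.
#' @export
simulateTransect <- function(positions_km, true_params,
                             trait_kind = NULL, n_per_locality = 20,
                             sigma = 1, seed) {
  stopifnot(all(diff(positions_km) > 0), all(n_per_locality >= 1))
  nl <- length(positions_km)
  n_i <- rep_len(as.integer(n_per_locality), nl)
  if (is.null(trait_kind))
    trait_kind <- setNames(rep("frequency", length(true_params)),
                           names(true_params))
  withSeed(seed, {
    traits <- list()
    for (tn in names(true_params)) {
      pars <- true_params[[tn]]
      tc <- attr(pars, "tail_config")
      if (is.null(tc)) tc <- "none"
      mu <- clineValue(positions_km, pars, tc)
      if (trait_kind[[tn]] == "frequency") {
        k <- rbinom(nl, n_i, pmin(pmax(mu, 0), 1))
        traits[[tn]] <- list(kind = "frequency", n = n_i, k = k)
      } else {
        m <- s <- numeric(nl)
        for (i in seq_len(nl)) {
          v <- rnorm(n_i[i], mu[i], sigma)
          m[i] <- mean(v); s[i] <- if (n_i[i] > 1) sd(v) else 0
        }
        traits[[tn]] <- list(kind = "quantitative", n = n_i,
                             mean = m, sd = s)
      }
    }
    loc <- data.frame(name = sprintf("site%02d", seq_len(nl)),
                      lat = NA_real_, lon = NA_real_,
                      position_km = positions_km)
    tra <- methods::new("Transect", localities = loc, traits = traits)
    truth <- list(
      generator = "simulate_transect", version = GENERATOR_VERSION,
      spec = list(positions_km = positions_km,
                  true_params = lapply(true_params, as.list),
                  trait_kind = as.list(trait_kind),
                  n_per_locality = n_i, sigma = sigma, seed = seed))
    list(transect = tra, truth = truth)
  })
}

#' Simulate a smooth landscape grid pair
#'
#' A smooth spatially correlated random field for the environment and an
#' independent field min-max rescaled to `[0, 1]` standing in for distance
#' to roads. Fields are Gaussian white noise smoothed with a separable
#' Gaussian kernel.
#'
#' @param nx,ny Grid dimensions (>= 2).
#' @param seed Integer seed.
#' @param smooth Kernel standard deviation in cells.
#' @return List with `environment` and `road_distance`
#'   ([RasterGrid-class] objects on a unit-cell grid) and `truth`.
#' @export
simulateLandscape <- function(nx, ny, seed, smooth = 3) {
  stopifnot(nx >= 2, ny >= 2)
  withSeed(seed, {
    env <- smoothField(nx, ny, smooth)
    rd <- smoothField(nx, ny, smooth)
    rd <- (rd - min(rd)) / (max(rd) - min(rd))
    mk <- function(v) methods::new("RasterGrid", values = v,
                                   xll = 0, yll = 0, cellsize = 1)
    list(environment = mk(env), road_distance = mk(rd),
         truth = list(generator = "simulate_landscape",
                      version = GENERATOR_VERSION,
                      spec = list(nx = nx, ny = ny, seed = seed,
                                  smooth = smooth)))
  })
}

smoothField <- function(nx, ny, smooth) {
  pad <- ceiling(3 * smooth)
  z <- matrix(rnorm((nx + 2 * pad) * (ny + 2 * pad)),
              nx + 2 * pad, ny + 2 * pad)
  k <- dnorm(seq(-pad, pad), sd = smooth)
  k <- k / sum(k)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  out <- z[pad + seq_len(nx), pad + seq_len(ny)]
  (out - mean(out)) / sd(out)
}

#' Write a SyntheticTruth JSON sidecar
#'
#' Serializes the ground-truth record of a generator next to the dataset it
#' describes (`<path>.truth.json` convention). Round-trips losslessly via
#' [readTruth].
#'
#' @param truth Truth list as returned by the simulators.
#' @param path Output path (conventionally ending in `.truth.json`).
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
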