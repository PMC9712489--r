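#' @import methods
#' @importFrom stats aggregate coef complete.cases cor cov dnorm lm na.omit
#'   optim p.adjust prcomp quantile rbeta rbinom rexp rgamma rmultinom rnorm
#'   runif sd setNames var
#' @importFrom utils combn head read.csv write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib clinepop, .registration = TRUE
NULL

#' Aligned sequence panel with population and group labels
#'
#' Holds equal-length aligned haplotype sequences (alphabet `A,C,G,T,N,-`)
#' together with a per-individual population assignment and a
#' population-to-group (morphotype) map. The central container for the
#' mitochondrial analyses: diversity statistics, neutrality tests, haplotype
#' networks and between-group divergence.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal width; names are the
#'   individual identifiers (unique, required).
#' @slot pop Named character vector mapping individual id to population label.
#' @slot group Named character vector mapping population label to group
#'   (morphotype) label.
#' @exportClass SequencePanel
setClass("SequencePanel",
  representation(seqs = "ANY", pop = "character", group = "character"))

setValidity("SequencePanel", function(object) {
  msg <- character()
  s <- object@seqs
  if (!methods::is(s, "DNAStringSet"))
    return("seqs must be a DNAStringSet")
  if (length(s) > 0) {
    if (is.null(names(s)) || anyNA(names(s)) || any(names(s) == ""))
      msg <- c(msg, "all sequences must be named by individual id")
    if (anyDuplicated(names(s)))
      msg <- c(msg, sprintf("duplicate id: %s",
                            names(s)[anyDuplicated(names(s))]))
    if (length(unique(Biostrings::width(s))) > 1)
      msg <- c(msg, "sequences have unequal lengths (alignment error)")
    missing_pop <- setdiff(names(s), names(object@pop))
    if (length(missing_pop))
      msg <- c(msg, sprintf("ids without a population assignment: %s",
                            paste(head(missing_pop, 5), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Diploid multi-locus genotype matrix
#'
#' Unordered allele pairs (positive integer allele names) for individuals at
#' microsatellite loci, with missing data coded `NA` in both allele slots.
#' A cell is fully typed or fully missing.
#'
#' @slot a1,a2 Integer matrices (individuals x loci) holding the two alleles
#'   of each genotype; `NA` together when the cell is missing.
#' @slot pop Character vector of population labels, one per individual.
#' @slot group Named character vector mapping population to group label.
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(a1 = "matrix", a2 = "matrix", pop = "character",
                 group = "character"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!all(dim(object@a1) == dim(object@a2)))
    msg <- c(msg, "a1 and a2 must have identical dimensions")
  if (nrow(object@a1) != length(object@pop))
    msg <- c(msg, "pop must have one label per individual")
  half <- xor(is.na(object@a1), is.na(object@a2))
  if (any(half))
    msg <- c(msg, "half-missing genotype cells (one allele NA)")
  ok <- !is.na(object@a1)
  if (any(object@a1[ok] < 1L) || any(object@a2[!is.na(object@a2)] < 1L))
    msg <- c(msg, "allele names must be positive integers")
  if (length(msg)) msg else TRUE
})

#' Ordered transect of localities with per-locality trait data
#'
#' Localities ordered along a one-dimensional transect (positions in km),
#' carrying for each trait either binomial counts (`n`, `k`) for frequency
#' traits or per-locality moments (`n`, `mean`, `sd`) for quantitative
#' traits. The input container for geographic cline fitting.
#'
#' @slot localities A data.frame with columns `name`, `lat`, `lon`,
#'   `position_km` (non-decreasing).
#' @slot traits Named list; each element a list with `kind`
#'   (`"frequency"` or `"quantitative"`) and numeric vectors `n` plus either
#'   `k` or `mean`/`sd`, aligned with the localities.
#' @exportClass Transect
setClass("Transect",
  representation(localities = "data.frame", traits = "list"))

setValidity("Transect", function(object) {
  loc <- object@localities
  msg <- character()
  need <- c("name", "position_km")
  if (!all(need %in% names(loc)))
    msg <- c(msg, "localities need columns name and position_km")
  else if (is.unsorted(loc$position_km))
    msg <- c(msg, "position_km must be non-decreasing")
  for (tn in names(object@traits)) {
    tr <- object@traits[[tn]]
    if (!tr$kind %in% c("frequency", "quantitative")) {
      msg <- c(msg, sprintf("trait %s: unknown kind", tn)); next
    }
    if (length(tr$n) != nrow(loc))
      msg <- c(msg, sprintf("trait %s: n not aligned with localities", tn))
    if (tr$kind == "frequency") {
      if (any(tr$k < 0 | tr$k > tr$n, na.rm = TRUE))
        msg <- c(msg, sprintf("trait %s: k outside [0, n]", tn))
    } else if (any(tr$sd < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("trait %s: negative sd", tn))
  }
  if (length(msg)) msg else TRUE
})

#' Fitted geographic cline
#'
#' @slot trait Trait name the fit refers to.
#' @slot arch List with `tail_config` (none/right/left/mirror/both) and
#'   `scaling` (fixed01/observed/free) defining the architecture.
#' @slot params Named numeric vector of maximum-likelihood parameters.
#' @slot maxLL Maximum log-likelihood.
#' @slot K Number of free parameters of the architecture.
#' @slot AICc Corrected Akaike information criterion.
#' @slot draws Matrix of posterior draws (possibly 0-row when fitted by
#'   optimization only).
#' @slot ci Matrix of 95% credible intervals (rows = parameters).
#' @slot diagnostics List: split-chain potential scale reduction, acceptance
#'   rates, flags.
#' @exportClass ClineFit
setClass("ClineFit",
  representation(trait = "character", arch = "list", params = "numeric",
                 maxLL = "numeric", K = "numeric", AICc = "numeric",
                 draws = "matrix", ci = "matrix", diagnostics = "list"))

#' Haplotype network (nodes + Hamming-distance edges)
#'
#' @slot haplos Character vector of distinct haplotype strings.
#' @slot multiplicity Integer vector, copies of each haplotype; sums to n.
#' @slot groupCounts Matrix haplotypes x groups of per-group multiplicities.
#' @slot edges data.frame `from`, `to`, `dist`, `in_mst` for all pairs
#'   (complete graph), `in_mst` flagging the minimum-spanning-network subset.
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  representation(haplos = "character", multiplicity = "integer",
                 groupCounts = "matrix", edges = "data.frame"))

setValidity("HaplotypeNetwork", function(object) {
  msg <- character()
  if (length(object@haplos) != length(object@multiplicity))
    msg <- c(msg, "one multiplicity per haplotype required")
  if (nrow(object@edges) && any(object@edges$dist < 1))
    msg <- c(msg, "edge distances must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Plain-text raster grid (ESRI ASCII dialect)
#'
#' @slot values Numeric matrix (rows = grid rows, top row first); `NA` marks
#'   nodata cells.
#' @slot xll,yll Coordinates of the lower-left corner of the grid.
#' @slot cellsize Cell edge length.
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", xll = "numeric", yll = "numeric",
                 cellsize = "numeric"))

setValidity("RasterGrid", function(object) {
  if (object@cellsize <= 0) "cellsize must be positive" else TRUE
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "SequencePanel", function(object) {
  cat(sprintf("SequencePanel: %d sequences x %d sites, %d populations, %d groups\n",
              length(object@seqs),
              if (length(object@seqs)) Biostrings::width(object@seqs)[1] else 0L,
              length(unique(object@pop)), length(unique(object@group))))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d loci (%.1f%% missing), %d populations\n",
              nrow(object@a1), ncol(object@a1),
              100 * mean(is.na(object@a1)), length(unique(object@pop))))
})

setMethod("show", "Transect", function(object) {
  cat(sprintf("Transect: %d localities over %.1f km; traits: %s\n",
              nrow(object@localities),
              diff(range(object@localities$position_km)),
              paste(names(object@traits), collapse = ", ")))
})

setMethod("show", "ClineFit", function(object) {
  cat(sprintf("ClineFit [%s]: tails=%s scaling=%s  K=%d  maxLL=%.3f  AICc=%.3f\n",
              object@trait, object@arch$tail_config, object@arch$scaling,
              object@K, object@maxLL, object@AICc))
  cat("  params:", paste(sprintf("%s=%.4g", names(object@params),
                                 object@params), collapse = "  "), "\n")
})

setMethod("show", "HaplotypeNetwork", function(object) {
  cat(sprintf("HaplotypeNetwork: %d haplotypes, n=%d, %d MSN edges\n",
              length(object@haplos), sum(object@multiplicity),
              if (nrow(object@edges)) sum(object@edges$in_mst) else 0L))
})

setMethod("show", "RasterGrid", function(object) {
  cat(sprintf("RasterGrid: %d x %d cells, cellsize %.4g, origin (%.4g, %.4g)\n",
              nrow(object@values), ncol(object@values), object@cellsize,
              object@xll, object@yll))
})
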