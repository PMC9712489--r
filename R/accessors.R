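# Constructors and accessor generics for the core containers.

#' Construct a SequencePanel
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   equal-length aligned sequences over `A,C,G,T,N,-`.
#' @param pop Named character vector: individual id -> population label.
#' @param group Named character vector: population -> group (morphotype)
#'   label. Populations absent from `group` map to themselves.
#' @return A validated [SequencePanel-class] object.
#' @export
SequencePanel <- function(seqs, pop, group = NULL) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  pops <- unique(unname(pop))
  if (is.null(group)) group <- setNames(pops, pops)
  miss <- setdiff(pops, names(group))
  if (length(miss)) group <- c(group, setNames(miss, miss))
  methods::new("SequencePanel", seqs = seqs, pop = pop, group = group)
}

#' Construct a GenotypeMatrix
#'
#' @param a1,a2 Integer matrices individuals x loci (allele 1 / allele 2);
#'   `NA` for missing. Column names are locus names, row names individual ids.
#' @param pop Character vector of population labels per individual.
#' @param group Named character vector: population -> group label.
#' @return A validated [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(a1, a2, pop, group = NULL) {
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  pops <- unique(pop)
  if (is.null(group)) group <- setNames(pops, pops)
  miss <- setdiff(pops, names(group))
  if (length(miss)) group <- c(group, setNames(miss, miss))
  methods::new("GenotypeMatrix", a1 = a1, a2 = a2, pop = pop, group = group)
}

#' Construct a Transect
#'
#' @param localities data.frame with `name`, optional `lat`/`lon`, and
#'   `position_km` (computed from lat/lon via [transectPositions] when
#'   absent).
#' @param traits Named list of per-trait data; see [Transect-class].
#' @return A validated [Transect-class] object.
#' @export
Transect <- function(localities, traits = list()) {
  if (is.null(localities$position_km)) {
    localities$position_km <- transectPositions(localities$lat,
                                                localities$lon)
  }
  methods::new("Transect", localities = localities, traits = traits)
}

#' Number of sequences in a panel
#' @param x A SequencePanel.
#' @export
setMethod("length", "SequencePanel", function(x) length(x@seqs))

#' @rdname panelAccessors
#' @export
setGeneric("panelSeqs", function(x) standardGeneric("panelSeqs"))
#' @rdname panelAccessors
#' @export
setGeneric("panelPop", function(x) standardGeneric("panelPop"))
#' @rdname panelAccessors
#' @export
setGeneric("panelGroup", function(x) standardGeneric("panelGroup"))
#' @rdname panelAccessors
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' Accessors for SequencePanel
#'
#' `panelSeqs` returns the DNAStringSet; `panelPop` the id -> population
#' map; `panelGroup` the per-individual group label (population mapped
#' through the morphotype table); `alignmentLength` the alignment width.
#'
#' @param x A [SequencePanel-class].
#' @name panelAccessors
NULL

#' @rdname panelAccessors
setMethod("panelSeqs", "SequencePanel", function(x) x@seqs)
#' @rdname panelAccessors
setMethod("panelPop", "SequencePanel", function(x) x@pop[names(x@seqs)])
#' @rdname panelAccessors
setMethod("panelGroup", "SequencePanel", function(x)
  setNames(unname(x@group[x@pop[names(x@seqs)]]), names(x@seqs)))
#' @rdname panelAccessors
setMethod("alignmentLength", "SequencePanel", function(x)
  if (length(x@seqs)) Biostrings::width(x@seqs)[1] else 0L)

#' Character matrix view of a panel's alignment
#'
#' @param panel A [SequencePanel-class].
#' @return Character matrix, sequences in rows, sites in columns.
#' @export
alignmentMatrix <- function(panel) {
  m <- as.matrix(panel@seqs)
  rownames(m) <- names(panel@seqs)
  m
}

#' Subset a panel by individual ids
#'
#' @param panel A [SequencePanel-class].
#' @param ids Individual identifiers to keep.
#' @return A [SequencePanel-class] restricted to `ids`.
#' @export
subsetPanel <- function(panel, ids) {
  stopifnot(all(ids %in% names(panel@seqs)))
  methods::new("SequencePanel", seqs = panel@seqs[ids],
               pop = panel@pop[ids], group = panel@group)
}

#' @rdname genotypeAccessors
#' @export
setGeneric("genotypeAlleles", function(x) standardGeneric("genotypeAlleles"))
#' @rdname genotypeAccessors
#' @export
setGeneric("genotypePop", function(x) standardGeneric("genotypePop"))
#' @rdname genotypeAccessors
#' @export
setGeneric("genotypeGroup", function(x) standardGeneric("genotypeGroup"))
#' @rdname genotypeAccessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' Accessors for GenotypeMatrix
#'
#' `genotypeAlleles` returns `list(a1, a2)`; `genotypePop` / `genotypeGroup`
#' the per-individual population / group labels; `lociNames` the locus names.
#'
#' @param x A [GenotypeMatrix-class].
#' @name genotypeAccessors
NULL

#' @rdname genotypeAccessors
setMethod("genotypeAlleles", "GenotypeMatrix", function(x)
  list(a1 = x@a1, a2 = x@a2))
#' @rdname genotypeAccessors
setMethod("genotypePop", "GenotypeMatrix", function(x) x@pop)
#' @rdname genotypeAccessors
setMethod("genotypeGroup", "GenotypeMatrix", function(x)
  unname(x@group[x@pop]))
#' @rdname genotypeAccessors
setMethod("lociNames", "GenotypeMatrix", function(x) colnames(x@a1))

#' Localities and traits of a Transect
#' @param x A [Transect-class].
#' @export
setGeneric("transectLocalities",
           function(x) standardGeneric("transectLocalities"))
#' @rdname transectLocalities
setMethod("transectLocalities", "Transect", function(x) x@localities)

#' @rdname transectLocalities
#' @export
setGeneric("transectTraits", function(x) standardGeneric("transectTraits"))
#' @rdname transectLocalities
setMethod("transectTraits", "Transect", function(x) x@traits)

#' Parameters / AICc / draws of a ClineFit
#' @param x A [ClineFit-class].
#' @export
setGeneric("clineParams", function(x) standardGeneric("clineParams"))
#' @rdname clineParams
setMethod("clineParams", "ClineFit", function(x) x@params)
#' @rdname clineParams
#' @export
setGeneric("clineAICc", function(x) standardGeneric("clineAICc"))
#' @rdname clineParams
setMethod("clineAICc", "ClineFit", function(x) x@AICc)
#' @rdname clineParams
#' @export
setGeneric("clineDraws", function(x) standardGeneric("clineDraws"))
#' @rdname clineParams
setMethod("clineDraws", "ClineFit", function(x) x@draws)
#' @rdname clineParams
#' @export
setGeneric("clineCI", function(x) standardGeneric("clineCI"))
#' @rdname clineParams
setMethod("clineCI", "ClineFit", function(x) x@ci)

#' Values / extent of a RasterGrid
#' @param x A [RasterGrid-class].
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname gridValues
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' Network accessors
#' @param x A [HaplotypeNetwork-class].
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname networkEdges
setMethod("networkEdges", "HaplotypeNetwork", function(x) x@edges)
#' @rdname networkEdges
#' @export
setGeneric("networkHaplotypes",
           function(x) standardGeneric("networkHaplotypes"))
#' @rdname networkEdges
setMethod("networkHaplotypes", "HaplotypeNetwork", function(x)
  data.frame(haplotype = x@haplos, multiplicity = x@multiplicity))
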