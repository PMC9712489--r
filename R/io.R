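# Shared readers and writers: FASTA with assignment join, genotype CSV and
# Genepop dialect, transect CSV, network export. All outputs are
# plain-text and diff-able.

#' Read an aligned FASTA with an assignment table
#'
#' Loads a FASTA alignment and joins a CSV assignment table (columns `id`,
#' `population`, optional `group`, optional `in_contact_zone`) into a
#' validated [SequencePanel-class]. Lowercase bases are normalized to
#' uppercase; duplicate ids, length mismatches and missing assignments are
#' explicit errors.
#'
#' @param fasta_path Path to the FASTA alignment.
#' @param assignment_path Path to the assignment CSV.
#' @param drop_contact_zone Drop individuals flagged `in_contact_zone`.
#' @return A [SequencePanel-class].
#' @export
readFastaPanel <- function(fasta_path, assignment_path,
                           drop_contact_zone = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate id in FASTA: ",
         names(seqs)[duplicated(names(seqs))][1])
  asn <- read.csv(assignment_path, stringsAsFactors = FALSE)
  if (!all(c("id", "population") %in% names(asn)))
    stop("assignment table needs columns id, population")
  unmatched <- setdiff(names(seqs), asn$id)
  if (length(unmatched))
    stop("ids without assignment: ", paste(head(unmatched, 5),
                                           collapse = ", "))
  asn <- asn[match(names(seqs), asn$id), ]
  if (drop_contact_zone && "in_contact_zone" %in% names(asn)) {
    keep <- !isTRUE_vec(asn$in_contact_zone)
    seqs <- seqs[keep]; asn <- asn[keep, ]
  }
  group <- NULL
  if ("group" %in% names(asn)) {
    map <- unique(asn[c("population", "group")])
    if (anyDuplicated(map$population))
      stop("population mapped to more than one group")
    group <- setNames(map$group, map$population)
  }
  SequencePanel(setNames(toupper(as.character(seqs)), names(seqs)),
                pop = setNames(asn$population, asn$id), group = group)
}

isTRUE_vec <- function(v)
  v %in% c(TRUE, "TRUE", "true", "1", 1)

#' Write a panel's sequences as FASTA
#'
#' @param panel A [SequencePanel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFastaPanel <- function(panel, path) {
  Biostrings::writeXStringSet(panel@seqs, path, width = 70L)
  invisible(path)
}

#' Write a panel's assignment table as CSV
#'
#' @param panel A [SequencePanel-class].
#' @param path Output path.
#' @param in_contact_zone Optional character vector of contact-zone
#'   population labels to flag.
#' @return `path`, invisibly.
#' @export
writeAssignment <- function(panel, path, in_contact_zone = character(0)) {
  df <- data.frame(id = names(panel@seqs),
                   population = unname(panelPop(panel)),
                   group = unname(panelGroup(panel)))
  df$in_contact_zone <- df$population %in% in_contact_zone
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write diploid genotypes as CSV
#'
#' The CSV dialect: columns `id`, `population`, optional `group`, then two
#' columns per locus named `<locus>_a1` and `<locus>_a2`; `0` or blank
#' codes a missing allele (a cell must be fully typed or fully missing).
#'
#' @param path File path.
#' @return [readGenotypesCsv]: a [GenotypeMatrix-class].
#' @export
readGenotypesCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "population") %in% names(df)))
  acols <- grep("_a[12]$", names(df), value = TRUE)
  loci <- unique(sub("_a[12]$", "", acols))
  for (l in loci)
    if (!all(paste0(l, c("_a1", "_a2")) %in% names(df)))
      stop("odd allele columns for locus ", l)
  parse_col <- function(v) {
    v[v %in% c("", "0", 0)] <- NA
    out <- suppressWarnings(as.integer(v))
    if (any(is.na(out) & !is.na(v)))
      stop("non-integer allele value in genotype table")
    out
  }
  a1 <- sapply(loci, function(l) parse_col(df[[paste0(l, "_a1")]]))
  a2 <- sapply(loci, function(l) parse_col(df[[paste0(l, "_a2")]]))
  if (!is.matrix(a1)) { a1 <- matrix(a1, nrow = nrow(df)) ; a2 <- matrix(a2, nrow = nrow(df)) }
  colnames(a1) <- colnames(a2) <- loci
  rownames(a1) <- rownames(a2) <- df$id
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
    warning("half-typed genotype cells set to missing")
  }
  group <- NULL
  if ("group" %in% names(df)) {
    map <- unique(df[c("population", "group")])
    group <- setNames(map$group, map$population)
  }
  GenotypeMatrix(a1, a2, pop = df$population, group = group)
}

#' @rdname readGenotypesCsv
#' @param gm A [GenotypeMatrix-class].
#' @export
writeGenotypesCsv <- function(gm, path) {
  df <- data.frame(id = rownames(gm@a1), population = gm@pop,
                   group = genotypeGroup(gm))
  for (l in lociNames(gm)) {
    df[[paste0(l, "_a1")]] <- ifelse(is.na(gm@a1[, l]), 0L, gm@a1[, l])
    df[[paste0(l, "_a2")]] <- ifelse(is.na(gm@a2[, l]), 0L, gm@a2[, l])
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write genotypes in the Genepop dialect
#'
#' Classic Genepop layout: a title line, one locus name per line, then
#' `Pop` blocks of `id ,  aaabbb aaabbb ...` rows with 3-digit allele
#' codes (`000` = missing).
#'
#' @param path File path.
#' @return [readGenepop]: a [GenotypeMatrix-class] (populations named
#'   `pop1`, `pop2`, ... unless ids carry labels).
#' @export
readGenepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  body <- lines[-1]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no Pop line found")
  loci <- trimws(body[seq_len(pop_idx[1] - 1)])
  loci <- unlist(strsplit(paste(loci, collapse = ","), ","))
  loci <- trimws(loci); loci <- loci[nzchar(loci)]
  ids <- character(0); pops <- character(0)
  a1 <- NULL; a2 <- NULL
  bounds <- c(pop_idx, length(body) + 1L)
  for (p in seq_along(pop_idx)) {
    rows <- body[(bounds[p] + 1L):(bounds[p + 1L] - 1L)]
    for (r in rows) {
      parts <- strsplit(r, ",")[[1]]
      if (length(parts) != 2) stop("malformed Genepop row: ", r)
      id <- trimws(parts[1])
      calls <- strsplit(trimws(parts[2]), "\\s+")[[1]]
      if (length(calls) != length(loci))
        stop("ragged Genepop row (", length(calls), " loci, expected ",
             length(loci), "): ", id)
      code_w <- nchar(calls[1]) / 2
      x1 <- as.integer(substr(calls, 1, code_w))
      x2 <- as.integer(substr(calls, code_w + 1, 2 * code_w))
      x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
      miss <- is.na(x1) | is.na(x2)
      x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
      ids <- c(ids, id); pops <- c(pops, sprintf("pop%d", p))
      a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
    }
  }
  colnames(a1) <- colnames(a2) <- loci
  rownames(a1) <- rownames(a2) <- make.unique(ids)
  GenotypeMatrix(a1, a2, pop = pops)
}

#' @rdname readGenepop
#' @param gm A [GenotypeMatrix-class].
#' @param title Title line.
#' @export
writeGenepop <- function(gm, path, title = "clinepop export") {
  loci <- lociNames(gm)
  out <- c(title, loci)
  for (p in unique(gm@pop)) {
    out <- c(out, "Pop")
    for (i in which(gm@pop == p)) {
      calls <- vapply(loci, function(l) {
        x1 <- gm@a1[i, l]; x2 <- gm@a2[i, l]
        if (is.na(x1)) "000000"
        else sprintf("%03d%03d", x1, x2)
      }, "")
      out <- c(out, paste0(rownames(gm@a1)[i], " ,  ",
                           paste(calls, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a transect CSV
#'
#' Expected columns: `locality`, `lat`, `lon` (or a precomputed
#' `position_km`), then per trait either `<trait>_n` and `<trait>_k`
#' (frequency) or `<trait>_n`, `<trait>_mean`, `<trait>_sd`
#' (quantitative).
#'
#' @param path File path.
#' @return A [Transect-class].
#' @export
readTransectCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot("locality" %in% names(df))
  ncols <- grep("_n$", names(df), value = TRUE)
  traits <- list()
  for (nc in ncols) {
    tn <- sub("_n$", "", nc)
    if (paste0(tn, "_k") %in% names(df)) {
      traits[[tn]] <- list(kind = "frequency", n = df[[nc]],
                           k = df[[paste0(tn, "_k")]])
    } else if (paste0(tn, "_mean") %in% names(df)) {
      traits[[tn]] <- list(kind = "quantitative", n = df[[nc]],
                           mean = df[[paste0(tn, "_mean")]],
                           sd = df[[paste0(tn, "_sd")]])
    }
  }
  loc <- data.frame(name = df$locality,
                    lat = if ("lat" %in% names(df)) df$lat else NA_real_,
                    lon = if ("lon" %in% names(df)) df$lon else NA_real_)
  if ("position_km" %in% names(df)) loc$position_km <- df$position_km
  Transect(loc, traits)
}

#' Export a haplotype network
#'
#' Writes the edge list as CSV (`from`, `to`, `dist`, `in_mst`) and,
#' optionally, the full network in GML.
#'
#' @param network A [HaplotypeNetwork-class] with edges (see [buildMSN]).
#' @param csv_path Edge-list CSV path.
#' @param gml_path Optional GML path.
#' @return `csv_path`, invisibly.
#' @export
writeNetwork <- function(network, csv_path, gml_path = NULL) {
  write.csv(network@edges, csv_path, row.names = FALSE)
  if (!is.null(gml_path)) {
    nodes <- vapply(seq_along(network@haplos), function(i)
      sprintf("  node [ id %d label \"h%d\" multiplicity %d ]",
              i, i, network@multiplicity[i]), "")
    e <- network@edges[network@edges$in_mst, , drop = FALSE]
    edges <- vapply(seq_len(nrow(e)), function(i)
      sprintf("  edge [ source %d target %d weight %d ]",
              e$from[i], e$to[i], as.integer(e$dist[i])), "")
    writeLines(c("graph [", nodes, edges, "]"), gml_path)
  }
  invisible(csv_path)
}
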