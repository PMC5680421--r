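#' @include AllClasses.R
#' @importFrom utils read.csv write.csv read.delim write.table packageVersion
NULL

IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H",
           "V", "N", "-", "?")

# split "<individual>_<copy>" labels; individual ids are deme-qualified
# (e.g. "EbuW01_3"), so the deme is everything before the individual index
parseHapLabels <- function(labels, popmap = NULL) {
  copy <- suppressWarnings(as.integer(sub("^.*_", "", labels)))
  abort_if(any(is.na(copy) | !copy %in% 1:2),
           "haplotype labels must end in _<copy> with copy 1 or 2")
  individual <- sub("_[^_]+$", "", labels)
  if (!is.null(popmap)) {
    miss <- setdiff(individual, popmap$individual)
    abort_if(length(miss) > 0,
             paste("individuals missing from population map:",
                   paste(unique(miss), collapse = ", ")))
    deme <- popmap$population[match(individual, popmap$individual)]
  } else {
    deme <- sub("_[^_]+$", "", individual)
    deme[!grepl("_", individual)] <- individual[!grepl("_", individual)]
  }
  list(individual = individual, copy = copy, deme = deme)
}

#' Read a phased haplotype alignment
#'
#' FASTA (via Biostrings) or relaxed sequential PHYLIP. Sequence labels
#' follow \code{<individual>_<copy>}; the deme of each haplotype comes from
#' the population map when given, otherwise from the individual id prefix.
#' Ragged alignments, duplicate labels and non-IUPAC characters are
#' rejected with the offending record named.
#'
#' @param path input file.
#' @param format \code{"fasta"} or \code{"phylip"}.
#' @param popmap optional population map data.frame (see
#'   \code{\link{readPopmap}}).
#' @param locusId locus identifier (default: file name without extension).
#' @return a \code{\linkS4class{HaplotypeAlignment}}.
#' @export
readHaplotypeAlignment <- function(path, format = c("fasta", "phylip"),
                                   popmap = NULL, locusId = NULL) {
  format <- match.arg(format)
  abort_if(!file.exists(path), paste("no such file:", path))
  if (is.null(locusId)) locusId <- sub("\\.[^.]*$", "", basename(path))
  if (format == "fasta") {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    abort_if(!length(hdr), "no FASTA records found")
    labels <- sub("^>\\s*", "", lines[hdr])
    ends <- c(hdr[-1] - 1, length(lines))
    seqs <- vapply(seq_along(hdr), function(i)
      gsub("\\s", "", paste(lines[seq(hdr[i] + 1, ends[i])], collapse = "")),
      "")
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[lines != ""]
    head <- strsplit(lines[1], "\\s+")[[1]]
    abort_if(length(head) < 2, "phylip header must give counts")
    n <- as.integer(head[1])
    abort_if(length(lines) < n + 1, "phylip file truncated")
    parts <- strsplit(lines[seq(2, n + 1)], "\\s+")
    labels <- vapply(parts, `[`, "", 1)
    seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  }
  abort_if(anyDuplicated(labels) > 0,
           paste("duplicate labels:",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1) {
    bad <- labels[widths != widths[1]][1]
    stop("ragged alignment: record '", bad, "' has length ",
         widths[widths != widths[1]][1], " (expected ", widths[1], ")",
         call. = FALSE)
  }
  chars <- unique(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]])
  bad <- setdiff(chars, IUPAC)
  abort_if(length(bad) > 0,
           paste("non-IUPAC characters:", paste(bad, collapse = " ")))
  lab <- parseHapLabels(labels, popmap)
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  names(ss) <- labels
  new("HaplotypeAlignment", locusId = locusId, seqs = ss,
      individual = lab$individual, copy = lab$copy, deme = lab$deme)
}

#' Write an alignment as FASTA
#'
#' Labels are \code{<individual>_<copy>} (individual ids deme-qualified),
#' accepted unchanged by \code{\link{readHaplotypeAlignment}}.
#'
#' @param aln a \code{HaplotypeAlignment}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeHaplotypeAlignment <- function(aln, path) {
  seqs <- as.character(aln@seqs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", haplotypeLabels(aln), "\n", seqs), con, sep = "\n")
  invisible(path)
}

#' Read / write a population map
#'
#' Tab-separated columns \code{individual}, \code{population},
#' \code{species}, \code{lineage}. Each individual appears once; each
#' population belongs to one species, each species to one lineage.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readPopmap <- function(path) {
  pm <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "species", "lineage")
  abort_if(!all(need %in% names(pm)),
           paste("popmap must have columns:", paste(need, collapse = ", ")))
  abort_if(anyDuplicated(pm$individual) > 0, "duplicate individuals in popmap")
  abort_if(anyDuplicated(unique(pm[, c("population", "species")])$population) > 0,
           "a population maps to more than one species")
  abort_if(anyDuplicated(unique(pm[, c("species", "lineage")])$species) > 0,
           "a species maps to more than one lineage")
  pm
}

#' @rdname readPopmap
#' @param popmap data.frame to write.
#' @export
writePopmap <- function(popmap, path) {
  write.table(popmap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a diploid genotype CSV
#'
#' Comma-separated; first column \code{individual}, remaining columns one
#' SNP locus each with unordered calls like \code{A/G} (\code{NA} or
#' \code{./.} for missing).
#'
#' @param path CSV file.
#' @param popmap population map data.frame covering every individual.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @export
readGenotypesCsv <- function(path, popmap) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(names(d)[1] != "individual", "first column must be 'individual'")
  calls <- as.matrix(d[, -1, drop = FALSE])
  calls[calls %in% c("", "./.", "NA", "N/N")] <- NA
  rownames(calls) <- d$individual
  miss <- setdiff(d$individual, popmap$individual)
  abort_if(length(miss) > 0,
           paste("individuals missing from popmap:", paste(miss, collapse = ", ")))
  pm <- popmap[match(d$individual, popmap$individual), , drop = FALSE]
  rownames(pm) <- NULL
  new("GenotypeMatrix", calls = calls, popmap = pm)
}

#' @rdname readGenotypesCsv
#' @param gm \code{GenotypeMatrix} to write.
#' @export
writeGenotypesCsv <- function(gm, path) {
  d <- data.frame(individual = gm@popmap$individual, gm@calls,
                  check.names = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Minimal VCF reader (biallelic GT field only)
#'
#' Reads the GT subfield of a VCF into a \code{GenotypeMatrix}; loci with
#' more than one ALT allele are dropped with a warning.
#'
#' @param path VCF file (uncompressed).
#' @param popmap population map covering the VCF samples.
#' @return a \code{GenotypeMatrix}.
#' @export
readGenotypesVcf <- function(path, popmap) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  abort_if(!length(lines) || !startsWith(lines[1], "#CHROM"),
           "missing #CHROM header line")
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  samples <- hdr[-(1:9)]
  abort_if(!length(samples), "VCF has no sample columns")
  body <- strsplit(lines[-1], "\t")
  keep <- vapply(body, function(f) !grepl(",", f[5]), TRUE)
  if (!all(keep)) warning(sum(!keep), " multiallelic site(s) dropped")
  body <- body[keep]
  calls <- matrix(NA_character_, length(samples), length(body))
  ids <- character(length(body))
  for (k in seq_along(body)) {
    f <- body[[k]]
    ids[k] <- if (f[3] != ".") f[3] else paste0(f[1], ":", f[2])
    al <- c(f[4], f[5])
    gtIdx <- match("GT", strsplit(f[9], ":")[[1]])
    g <- vapply(f[-(1:9)], function(s) strsplit(s, ":")[[1]][gtIdx], "")
    a <- strsplit(g, "[/|]")
    calls[, k] <- vapply(a, function(x) {
      if (length(x) != 2 || any(x == ".")) return(NA_character_)
      b <- sort(al[as.integer(x) + 1])
      paste(b, collapse = "/")
    }, "")
  }
  dimnames(calls) <- list(samples, ids)
  miss <- setdiff(samples, popmap$individual)
  abort_if(length(miss) > 0,
           paste("individuals missing from popmap:", paste(miss, collapse = ", ")))
  pm <- popmap[match(samples, popmap$individual), , drop = FALSE]
  rownames(pm) <- NULL
  new("GenotypeMatrix", calls = calls, popmap = pm)
}

#' Read / write a floral trait table
#'
#' CSV columns \code{individual}, \code{population}, \code{flower}, then
#' one column per trait.
#'
#' @param path CSV file.
#' @return a \code{\linkS4class{TraitMatrix}}.
#' @export
readTraitsCsv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "flower")
  abort_if(!all(need %in% names(d)),
           paste("trait table must have columns:", paste(need, collapse = ", ")))
  new("TraitMatrix", data = d, traitNames = setdiff(names(d), need))
}

#' @rdname readTraitsCsv
#' @param tm \code{TraitMatrix} to write.
#' @export
writeTraitsCsv <- function(tm, path) {
  write.csv(tm@data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rooted tree in newick format
#'
#' @param path file, or a newick string.
#' @param popmap optional population map; tip labels
#'   (\code{<individual>_<copy>}) are then checked against it and unmapped
#'   labels reported.
#' @param requireBinary reject polytomies (default TRUE).
#' @return an \code{ape::phylo}.
#' @export
readTreeRooted <- function(path, popmap = NULL, requireBinary = TRUE) {
  tr <- if (file.exists(path)) ape::read.tree(path)
        else ape::read.tree(text = path)
  abort_if(is.null(tr), "could not parse newick input")
  abort_if(!ape::is.rooted(tr), "tree is unrooted; root it before use")
  abort_if(requireBinary && !ape::is.binary(tr),
           "tree contains polytomies (set requireBinary = FALSE to keep)")
  if (!is.null(popmap)) parseHapLabels(tr$tip.label, popmap)
  tr
}

#' @rdname readTreeRooted
#' @param tree phylo to write.
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# "# key=value" provenance header used by the CLI writers
reportHeader <- function(seed = NULL, config = NULL) {
  h <- paste0("# speciflow ", as.character(packageVersion("speciflow")))
  if (!is.null(seed)) h <- c(h, paste0("# seed=", seed))
  if (!is.null(config))
    h <- c(h, paste0("# config=", paste(names(config), unlist(config),
                                        sep = "=", collapse = ";")))
  h
}

writeReportTsv <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(reportHeader(seed, config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
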