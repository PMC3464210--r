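#' Write an inversion catalog to JSON
#' @param catalog an [InversionCatalog-class].
#' @param path output file.
#' @export
writeCatalogJSON <- function(catalog, path) {
  jsonlite::write_json(list(description = catalog@description,
                            inversions = catalog@inversions,
                            anchorAliases = catalog@anchorAliases),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an inversion catalog from JSON
#' @param path JSON file written by [writeCatalogJSON].
#' @return An [InversionCatalog-class].
#' @export
readCatalogJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  inversionCatalog(x$inversions,
                   anchorAliases = if (length(x$anchorAliases)) x$anchorAliases
                                   else data.frame(alias = character(), anchor = character()),
                   description = x$description)
}

#' Write a karyotype matrix to TSV
#'
#' Rows are taxa, columns inversion names, cells `standard`/`inverted`/
#' `unknown`.
#'
#' @param kmat a [KaryotypeMatrix-class].
#' @param path output file.
#' @export
writeKaryotypeTSV <- function(kmat, path) {
  st <- kmat@states
  st[is.na(st)] <- "unknown"
  df <- data.frame(taxon = rownames(st), st, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a karyotype matrix from TSV
#'
#' @param path TSV with a `taxon` column and one column per inversion.
#' @param catalog the [InversionCatalog-class] the columns refer to.
#' @param outgroup optional outgroup taxon label.
#' @return A [KaryotypeMatrix-class].
#' @export
readKaryotypeTSV <- function(path, catalog, outgroup = character(0)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  st <- as.matrix(df[, setdiff(names(df), "taxon"), drop = FALSE])
  rownames(st) <- df$taxon
  st[st == "unknown"] <- NA
  karyotypeMatrix(st, catalog, outgroup = outgroup)
}

#' Write encoded signed permutations to JSON
#' @param perms per-taxon list of per-arm [SignedPermutation-class] lists.
#' @param path output file.
#' @export
writePermsJSON <- function(perms, path) {
  x <- lapply(perms, function(k) lapply(k, permElements))
  jsonlite::write_json(x, path, digits = NA)
  invisible(path)
}

#' Read signed permutations from JSON
#' @param path file written by [writePermsJSON].
#' @return Per-taxon list of per-arm integer vectors.
#' @export
readPermsJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(x, function(k) lapply(k, as.integer))
}

#' Write breakpoint calls to BED and TSV
#'
#' BED intervals are 0-based half-open; the TSV adds support counts and the
#' reciprocal-call pairing.
#'
#' @param calls [GenomicRanges::GRanges] from [clusterAndCall].
#' @param bedPath,tsvPath output files (either may be `NULL`).
#' @export
writeCallsBED <- function(calls, bedPath = NULL, tsvPath = NULL) {
  if (!is.null(bedPath)) {
    x <- calls
    names(x) <- paste0("inv", x$inversion, "_", x$side)
    x$score <- x$support
    rtracklayer::export(x, bedPath, format = "BED")
  }
  if (!is.null(tsvPath)) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(calls)),
                     start0 = GenomicRanges::start(calls) - 1L,
                     end0 = GenomicRanges::end(calls),
                     inversion = calls$inversion, side = calls$side,
                     support = calls$support)
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(calls)
}

#' Write mate pairs to FASTQ
#'
#' Pair suffixes `/1` and `/2` follow the read names; qualities are constant
#' (error-free simulation).
#'
#' @param read1,read2 [Biostrings::DNAStringSet].
#' @param prefix output path prefix (`<prefix>_1.fq`, `<prefix>_2.fq`).
#' @export
writeFastqPair <- function(read1, read2, prefix) {
  f1 <- paste0(prefix, "_1.fq"); f2 <- paste0(prefix, "_2.fq")
  q1 <- Biostrings::BStringSet(strrep("I", Biostrings::width(read1)))
  q2 <- Biostrings::BStringSet(strrep("I", Biostrings::width(read2)))
  Biostrings::writeXStringSet(read1, f1, format = "fastq", qualities = q1)
  Biostrings::writeXStringSet(read2, f2, format = "fastq", qualities = q2)
  invisible(c(f1, f2))
}

#' Read a mate-pair FASTQ pair
#' @param prefix path prefix used by [writeFastqPair].
#' @return list with `read1`, `read2`.
#' @export
readFastqPair <- function(prefix) {
  list(read1 = Biostrings::readDNAStringSet(paste0(prefix, "_1.fq"), format = "fastq"),
       read2 = Biostrings::readDNAStringSet(paste0(prefix, "_2.fq"), format = "fastq"))
}

#' Write mapped reads as minimal SAM
#'
#' Unmapped and multi-mapping reads get flag 4; mapped reads carry flag 0/16
#' by strand.  CIGAR is full-length match (exact matching).
#'
#' @param mapped table from [mapReads].
#' @param reads the mapped [Biostrings::DNAStringSet].
#' @param refName,refLength reference name and length for the header.
#' @param path output file.
#' @export
writeSAM <- function(mapped, reads, refName, refLength, path) {
  rl <- Biostrings::width(reads)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", refName, as.integer(refLength))), con)
  flag <- ifelse(mapped$status != "unique", 4L, ifelse(mapped$strand == "-", 16L, 0L))
  posn <- ifelse(mapped$status == "unique", mapped$pos + 1L, 0L)
  rn <- ifelse(mapped$status == "unique", refName, "*")
  cig <- ifelse(mapped$status == "unique", paste0(rl, "M"), "*")
  seqs <- as.character(reads)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     mapped$id, flag, rn, posn,
                     ifelse(mapped$status == "unique", 60L, 0L), cig, seqs,
                     strrep("I", rl)), con)
  invisible(path)
}

#' Write scenario results to JSON and a text report
#'
#' @param result output of [bestScenario].
#' @param jsonPath,txtPath output files (either may be `NULL`).
#' @export
writeScenarioReport <- function(result, jsonPath = NULL, txtPath = NULL) {
  x <- lapply(result$scenarios, function(s) list(
    scenario = s@scenario, totalEvents = s@totalEvents,
    topologies = s@newick,
    origins = lapply(s@origins, as.list)))
  if (!is.null(jsonPath))
    jsonlite::write_json(list(winner = result$winner, scenarios = x),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(txtPath)) {
    con <- file(txtPath, "w")
    on.exit(close(con))
    writeLines(sprintf("winner: %s", result$winner), con)
    for (s in result$scenarios) {
      writeLines(sprintf("scenario %s: %d events, %d optimal topologies",
                         s@scenario, s@totalEvents, length(s@trees)), con)
      o <- s@origins[[1L]]
      multi <- names(o)[o > 1L]
      writeLines(sprintf("  origins>1: %s",
                         if (length(multi)) paste(multi, collapse = ", ") else "none"), con)
      writeLines(paste0("  ", s@newick), con)
    }
  }
  invisible(result)
}
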