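# Standard-format adapters: FASTA (Biostrings), BED6 (0-based half-open),
# newick (ape) and commented TSV tables. All readers validate and report the
# offending record; writers round-trip bit-exactly.

#' Read a FASTA file as a named character vector
#' @param path FASTA file
#' @return named character vector of upper-case sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#' @param sequences named character vector
#' @param path output file
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences))) stop("sequences must be named")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a 6-column BED file (0-based half-open)
#' @param path BED file
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{name}, \code{score}, \code{strand}
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad <- which(lengths(rows) < 6L)
  if (length(bad))
    stop("malformed BED record at line ", lineno[bad[1]],
         ": expected >= 6 tab-separated fields")
  start <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(rows, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end < start)
  if (length(bad))
    stop("malformed BED coordinates at line ", lineno[bad[1]])
  data.frame(chrom = vapply(rows, `[[`, "", 1), start = start, end = end,
             name = vapply(rows, `[[`, "", 4),
             score = suppressWarnings(as.numeric(vapply(rows, `[[`, "", 5))),
             strand = vapply(rows, `[[`, "", 6),
             stringsAsFactors = FALSE)
}

#' Write a 6-column BED file
#' @param bed data.frame with chrom, start, end, name, score, strand
#' @param path output file
#' @export
write_bed <- function(bed, path) {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  missing <- setdiff(need, names(bed))
  if (length(missing))
    stop("BED table lacks columns: ", paste(missing, collapse = ", "))
  utils::write.table(bed[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert BED-like small-RNA records to read records
#'
#' A BED row \code{te1 99 125 read1 0 -} becomes a read with 0-based start
#' 99, length 26 and strand \code{-}.
#'
#' @param bed data.frame from \code{\link{read_bed}}; sequences may ride in
#'   an optional \code{sequence} column
#' @return data.frame with \code{te_id}, \code{start}, \code{length},
#'   \code{strand}, \code{sequence}
#' @export
bed_to_reads <- function(bed) {
  data.frame(te_id = bed$chrom, start = bed$start,
             length = bed$end - bed$start, strand = bed$strand,
             sequence = if ("sequence" %in% names(bed)) bed$sequence
                        else NA_character_,
             stringsAsFactors = FALSE)
}

#' Read a newick tree
#' @param path newick file
#' @return \code{phylo}
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a newick tree
#' @param tree \code{phylo}
#' @param path output file
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' Write a TSV table with provenance header comments
#' @param x data.frame
#' @param path output file
#' @param comments character vector written as leading \code{#} lines
#' @export
write_tsv_table <- function(x, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by \code{\link{write_tsv_table}}
#' @param path TSV file
#' @return data.frame (header comments dropped)
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
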