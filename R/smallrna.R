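# Small-RNA evidence that a putative TE is recognized by host silencing:
# length classification into siRNA/piRNA, the sense/antisense 5'-overlap
# spectrum whose mode at 10 nt marks ping-pong amplification, and positional
# base composition (1U on sense primaries, 10A on antisense responders).

#' Classify a small RNA by length
#'
#' 21-23 nt reads are siRNAs, 24-29 nt reads are piRNAs, anything else is
#' \code{other} (boundaries inclusive).
#'
#' @param length read length(s) in nt
#' @return character vector of \code{"siRNA"}, \code{"piRNA"}, \code{"other"}
#' @export
classify_length <- function(length) {
  ifelse(length >= 21 & length <= 23, "siRNA",
  ifelse(length >= 24 & length <= 29, "piRNA", "other"))
}

#' Sense/antisense 5'-overlap spectrum and ping-pong z-score
#'
#' For every pair of a plus-strand and a minus-strand read on the same TE,
#' the overlap is (5' coordinate of the minus read) - (5' coordinate of the
#' plus read) + 1, where the minus read's 5' coordinate is its rightmost
#' base. Pairs whose overlap falls in \code{offsets} increment that offset's
#' count. The ping-pong z-score of offset 10 is its count standardized
#' against the mean and standard deviation of the remaining offsets.
#' Pairing is computed by cross-correlating the 5'-coordinate count vectors,
#' so all pairs are enumerated implicitly and read count is no complexity
#' concern.
#'
#' @param reads data.frame with columns \code{start} (0-based leftmost
#'   base), \code{length}, \code{strand} (+/-), for one TE; typically
#'   pre-filtered to piRNA lengths with \code{\link{classify_length}}
#' @param offsets overlap offsets tallied (default 1:25)
#' @param focal the signature offset for the z-score (default 10)
#' @return list of class \code{"overlap_spectrum"}: \code{counts} (named by
#'   offset), \code{z10}, \code{modal_offset} (NA when the spectrum is empty),
#'   \code{n_pairs_total}
#' @export
overlap_spectrum <- function(reads, offsets = 1:25, focal = 10L) {
  plus <- reads[reads$strand == "+", , drop = FALSE]
  minus <- reads[reads$strand == "-", , drop = FALSE]
  counts <- stats::setNames(numeric(length(offsets)), offsets)
  n_pairs_total <- as.numeric(nrow(plus)) * nrow(minus)
  if (nrow(plus) > 0L && nrow(minus) > 0L) {
    p5 <- plus$start
    m5 <- minus$start + minus$length - 1L
    tp <- table(p5)
    tm <- table(m5)
    for (i in seq_along(offsets)) {
      # overlap = m5 - p5 + 1 == offsets[i]  <=>  m5 == p5 + offsets[i] - 1
      want <- as.numeric(names(tp)) + offsets[i] - 1
      hit <- match(as.character(want), names(tm))
      ok <- !is.na(hit)
      counts[i] <- sum(as.numeric(tp[ok]) * as.numeric(tm[hit[ok]]))
    }
  }
  bg <- counts[names(counts) != as.character(focal)]
  z10 <- if (length(bg) > 1 && stats::sd(bg) > 0)
    (counts[[as.character(focal)]] - mean(bg)) / stats::sd(bg) else NA_real_
  modal <- if (sum(counts) > 0) offsets[which.max(counts)] else NA_integer_
  structure(list(counts = counts, z10 = z10, modal_offset = modal,
                 n_pairs_total = n_pairs_total),
            class = "overlap_spectrum")
}

#' @export
print.overlap_spectrum <- function(x, ...) {
  cat("5' overlap spectrum over offsets", names(x$counts)[1], "..",
      names(x$counts)[length(x$counts)], "\n")
  cat("  modal offset:", x$modal_offset, " z10:",
      if (is.na(x$z10)) "undefined" else sprintf("%.2f", x$z10), "\n")
  invisible(x)
}

#' Per-position base composition of small-RNA reads, by strand class
#'
#' Tallies A/C/G/T frequencies at each read position (1-based from the 5'
#' end, in read orientation; U appears as T in sequence space), separately
#' for sense (+) and antisense (-) reads. Reports the argmax position of T
#' among sense reads and of A among antisense reads -- under ping-pong
#' amplification these are positions 1 and 10.
#'
#' @param reads data.frame with columns \code{strand} and \code{sequence}
#' @param positions positions tallied (default 1:24)
#' @return list of class \code{"positional_composition"}: \code{sense} and
#'   \code{antisense} (4 x length(positions) frequency matrices),
#'   \code{t_argmax_sense}, \code{a_argmax_antisense}
#' @export
positional_composition <- function(reads, positions = 1:24) {
  if (nrow(reads) == 0L) stop("empty read set")
  bases <- c("A", "C", "G", "T")
  freq_mat <- function(seqs) {
    m <- matrix(NA_real_, 4, length(positions),
                dimnames = list(bases, positions))
    if (length(seqs) == 0L) return(m)
    for (j in seq_along(positions)) {
      p <- positions[j]
      ch <- toupper(substr(seqs, p, p))
      ch <- ch[ch %in% bases]
      if (length(ch)) m[, j] <- tabulate(match(ch, bases), 4L) / length(ch)
    }
    m
  }
  sense <- freq_mat(reads$sequence[reads$strand == "+"])
  anti <- freq_mat(reads$sequence[reads$strand == "-"])
  argmax <- function(m, base) {
    v <- m[base, ]
    if (all(is.na(v))) NA_integer_ else positions[which.max(v)]
  }
  structure(list(sense = sense, antisense = anti,
                 t_argmax_sense = argmax(sense, "T"),
                 a_argmax_antisense = argmax(anti, "A")),
            class = "positional_composition")
}
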