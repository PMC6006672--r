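# Codon-aware divergence statistics: Nei-Gojobori (1986) counting of
# synonymous/nonsynonymous sites and differences with Jukes-Cantor correction,
# Wright's effective number of codons, major-allele consensus building and
# pairwise identity. All sequence arguments are plain character strings over
# {A,C,G,T} (plus N/- where documented); coding frame starts at position 1.

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- toupper(names(gc))
  gc
}

.sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

.is_stop <- function(codon) {
  gc <- .genetic_code()
  unname(gc[codon] == "*")
}

#' Split a nucleotide string into codons
#' @param x character scalar, length a multiple of 3
#' @return character vector of codons
#' @keywords internal
.split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' Counts fractional synonymous (s) and nonsynonymous (n) sites of a sense
#' codon following Nei & Gojobori (1986). For each of the three positions the
#' three single-nucleotide neighbours are considered; neighbours that are stop
#' codons are excluded from the denominator, so s + n = 3 for every sense
#' codon after this renormalization.
#'
#' @param codon a 3-letter sense codon (standard genetic code)
#' @return named numeric vector \code{c(s = , n = )} with \code{s + n == 3}
#' @examples
#' syn_nonsyn_sites("TTT")  # s = 1/3, n = 8/3
#' syn_nonsyn_sites("GGG")  # s = 1,   n = 2
#' @export
syn_nonsyn_sites <- function(codon) {
  codon <- toupper(codon)
  gc <- .genetic_code()
  if (!codon %in% names(gc))
    stop("not a valid codon: ", codon)
  if (gc[codon] == "*")
    stop("stop codon has no synonymous/nonsynonymous site counts: ", codon)
  aa <- gc[codon]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    syn <- 0L
    nonstop <- 0L
    for (b in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (gc[mut] == "*") next
      nonstop <- nonstop + 1L
      if (gc[mut] == aa) syn <- syn + 1L
    }
    if (nonstop > 0L) s <- s + syn / nonstop
  }
  c(s = s, n = 3 - s)
}

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair: average over all orderings of the differing positions, excluding
# pathways that pass through a stop codon. Returns c(sd, nd, ok); ok = 0 when
# every pathway is blocked (pair then excluded from counting).
.codon_pair_diffs <- function(c1, c2) {
  gc <- .genetic_code()
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(diff_pos)
  if (d == 0L) return(c(sd = 0, nd = 0, ok = 1))
  perms <- .permutations(diff_pos)
  sd_tot <- 0
  nd_tot <- 0
  nvalid <- 0L
  for (i in seq_len(nrow(perms))) {
    cur <- c1
    sd_p <- 0L
    nd_p <- 0L
    blocked <- FALSE
    for (pos in perms[i, ]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (gc[nxt] == "*") { blocked <- TRUE; break }
      if (gc[nxt] == gc[cur]) sd_p <- sd_p + 1L else nd_p <- nd_p + 1L
      cur <- nxt
    }
    if (!blocked) {
      sd_tot <- sd_tot + sd_p
      nd_tot <- nd_tot + nd_p
      nvalid <- nvalid + 1L
    }
  }
  if (nvalid == 0L) return(c(sd = NA_real_, nd = NA_real_, ok = 0))
  c(sd = sd_tot / nvalid, nd = nd_tot / nvalid, ok = 1)
}

.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_len(n))
    out <- rbind(out, cbind(x[i], .permutations(x[-i])))
  out
}

# Lazily built lookup tables over the 61 sense codons: per-codon site counts
# and 61 x 61 pathway-averaged difference counts. Built once per session.
.codon_tables <- function() {
  if (!is.null(.codon_env$tables)) return(.codon_env$tables)
  sense <- .sense_codons()
  sites <- t(vapply(sense, syn_nonsyn_sites, numeric(2)))
  k <- length(sense)
  Sd <- matrix(0, k, k, dimnames = list(sense, sense))
  Nd <- matrix(0, k, k, dimnames = list(sense, sense))
  OK <- matrix(1, k, k, dimnames = list(sense, sense))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      r <- .codon_pair_diffs(sense[i], sense[j])
      Sd[i, j] <- Sd[j, i] <- r["sd"]
      Nd[i, j] <- Nd[j, i] <- r["nd"]
      OK[i, j] <- OK[j, i] <- r["ok"]
    }
  }
  .codon_env$tables <- list(sense = sense, sites = sites, Sd = Sd, Nd = Nd, OK = OK)
  .codon_env$tables
}

#' Nei-Gojobori (1986) pairwise dS and dN
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' aligned in-frame coding sequences and applies the Jukes-Cantor correction.
#' Differences within a codon pair are averaged over all orderings of the
#' differing positions; pathways passing through stop codons are excluded.
#' Codon pairs in which either codon contains a gap, an ambiguity character or
#' is a stop codon are excluded from counting (the count is reported in
#' \code{codons_excluded}).
#'
#' @param seq_a,seq_b aligned, equal-length nucleotide strings; length a
#'   multiple of 3, frame starting at the first base
#' @return an object of class \code{"ds_estimate"}: a list with fractional
#'   site counts \code{S}, \code{N}, difference counts \code{Sd}, \code{Nd},
#'   proportions \code{pS}, \code{pN}, Jukes-Cantor rates \code{dS},
#'   \code{dN} (\code{NA} and flagged when the proportion is saturated at
#'   >= 3/4), and \code{codons_used}/\code{codons_excluded}
#' @examples
#' ng86("TTTGGGTTTGGG", "TTCGGGTTTGGG")$dS  # -0.75 * log(0.5)
#' @export
ng86 <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences have different lengths (", nchar(seq_a), " vs ",
         nchar(seq_b), "); align them first")
  ca <- .split_codons(seq_a)
  cb <- .split_codons(seq_b)
  tab <- .codon_tables()
  usable <- ca %in% tab$sense & cb %in% tab$sense
  usable[usable] <- tab$OK[cbind(ca[usable], cb[usable])] == 1
  if (!any(usable))
    stop("no usable codon pairs (all contain gaps, ambiguity or stop codons)")
  ia <- ca[usable]; ib <- cb[usable]
  S <- (sum(tab$sites[ia, "s"]) + sum(tab$sites[ib, "s"])) / 2
  N <- (sum(tab$sites[ia, "n"]) + sum(tab$sites[ib, "n"])) / 2
  Sd <- sum(tab$Sd[cbind(ia, ib)])
  Nd <- sum(tab$Nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p <= 0) return(0)
    if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  }
  out <- list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
              dS = jc(pS), dN = jc(pN),
              dS_saturated = pS >= 3 / 4, dN_saturated = pN >= 3 / 4,
              codons_used = sum(usable), codons_excluded = sum(!usable))
  class(out) <- "ds_estimate"
  out
}

#' @export
print.ds_estimate <- function(x, ...) {
  cat("NG86 pairwise divergence (", x$codons_used, " codons used, ",
      x$codons_excluded, " excluded)\n", sep = "")
  cat(sprintf("  S = %.3f  Sd = %.3f  pS = %.4f  dS = %s\n", x$S, x$Sd, x$pS,
              if (x$dS_saturated) "saturated" else sprintf("%.4f", x$dS)))
  cat(sprintf("  N = %.3f  Nd = %.3f  pN = %.4f  dN = %s\n", x$N, x$Nd, x$pN,
              if (x$dN_saturated) "saturated" else sprintf("%.4f", x$dN)))
  invisible(x)
}

# Redundancy class (number of synonymous codons) per amino acid, from the
# standard code. Met and Trp (class 1) carry no usage information.
.aa_redundancy <- function() {
  gc <- .genetic_code()
  gc <- gc[gc != "*"]
  table(gc)
}

#' Wright's effective number of codons (ENC)
#'
#' Computes Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 where Fk is the mean codon
#' homozygosity of the amino acids with k synonymous codons, each estimated as
#' F = (n * sum(p^2) - 1) / (n - 1) from the codon counts of that amino acid.
#' Amino acids observed fewer than twice are excluded from their class mean;
#' if a whole redundancy class has no usable amino acid the estimate is
#' reported undefined with a reason rather than imputed. Nc is capped into
#' [20, 61]. Stop codons and codons containing non-ACGT characters are
#' skipped.
#'
#' @param cds in-frame coding sequence (length a multiple of 3)
#' @return object of class \code{"enc_estimate"}: list with \code{Nc},
#'   per-class mean homozygosities \code{F_bar}, \code{codons_counted},
#'   \code{defined} and \code{reason}
#' @export
effective_number_of_codons <- function(cds) {
  codons <- .split_codons(cds)
  gc <- .genetic_code()
  codons <- codons[codons %in% names(gc)]
  codons <- codons[gc[codons] != "*"]
  if (length(codons) == 0L)
    stop("no usable sense codons in coding sequence")
  aa <- gc[codons]
  red <- .aa_redundancy()
  class_sizes <- c("2" = 9, "3" = 1, "4" = 5, "6" = 3)
  F_hat <- tapply(codons, aa, function(cc) {
    n <- length(cc)
    if (n < 2L) return(NA_real_)
    p <- table(cc) / n
    (n * sum(p^2) - 1) / (n - 1)
  })
  F_bar <- sapply(names(class_sizes), function(k) {
    members <- names(red)[red == as.integer(k)]
    vals <- F_hat[names(F_hat) %in% members]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) NA_real_ else mean(vals)
  })
  out <- list(Nc = NA_real_, F_bar = F_bar,
              codons_counted = length(codons), defined = FALSE, reason = NA_character_)
  class(out) <- "enc_estimate"
  if (any(is.na(F_bar))) {
    out$reason <- paste0("no usable amino acid in redundancy class ",
                         paste(names(F_bar)[is.na(F_bar)], collapse = ","))
    return(out)
  }
  if (any(F_bar <= 0)) {
    out$reason <- "non-positive class homozygosity"
    return(out)
  }
  nc <- 2 + sum(class_sizes / F_bar)
  out$Nc <- min(61, max(20, nc))
  out$defined <- TRUE
  out
}

#' @export
print.enc_estimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("ENC: Nc = %.2f over %d codons\n", x$Nc, x$codons_counted))
  else
    cat("ENC: undefined (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Major-allele consensus of aligned TE copies
#'
#' Per alignment column, the most frequent base among A/C/G/T (gaps and N
#' ignored); columns where gaps form the majority are dropped; frequency ties
#' are broken toward the lexicographically smallest base. A kept column with
#' no A/C/G/T observation yields N.
#'
#' @param copies character vector of equal-length aligned sequences
#'   (alphabet A, C, G, T, N, -), or a character matrix with one row per copy
#' @return consensus sequence (character scalar)
#' @export
build_consensus <- function(copies) {
  m <- .as_copy_matrix(copies)
  n <- nrow(m)
  if (n == 0L) stop("no copies supplied")
  gap_major <- colSums(m == "-") > n / 2
  m <- m[, !gap_major, drop = FALSE]
  if (ncol(m) == 0L)
    stop("alignment is gap-majority at every column; no consensus")
  bases <- c("A", "C", "G", "T")
  cons <- apply(m, 2, function(col) {
    counts <- vapply(bases, function(b) sum(col == b), integer(1))
    if (all(counts == 0L)) return("N")
    bases[which.max(counts)]  # which.max takes the first = lexicographic min
  })
  paste(cons, collapse = "")
}

.as_copy_matrix <- function(copies) {
  if (is.matrix(copies)) {
    m <- toupper(copies)
  } else {
    copies <- toupper(copies)
    if (length(copies) == 0L) return(matrix(character(0), 0, 0))
    if (length(unique(nchar(copies))) != 1L)
      stop("copies have unequal lengths; align them first")
    m <- do.call(rbind, strsplit(copies, ""))
  }
  m
}

#' Pairwise identity of two aligned sequences
#'
#' Fraction of matching columns among comparable columns; a column is
#' comparable when both sequences carry an unambiguous base (A/C/G/T).
#'
#' @param a,b aligned, equal-length sequences
#' @return fraction in [0, 1]
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences have different lengths")
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  bases <- c("A", "C", "G", "T")
  comp <- va %in% bases & vb %in% bases
  if (!any(comp)) stop("no comparable columns (all gap or ambiguous)")
  mean(va[comp] == vb[comp])
}
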