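# Candidate TE classification and content characterization: the BLAST-hit
# decision tree, family clustering at the 90% identity rule, hit-count and
# relative-coverage filters, read-depth copy-number estimation, the
# insertion-frequency filter and N-corrected sliding-window densities.

#' Classify one candidate sequence from its BLAST hits
#'
#' Decision tree over the hit table of a single query, after filtering at the
#' e-value threshold: a single TE subject family means the candidate is a
#' previously known family; multiple TE subject families all in one
#' superfamily make it potentially novel within that superfamily; hits in a
#' single order but multiple superfamilies make it potentially novel within
#' the order; with no TE subjects, a candidate whose primary hit (lowest
#' e-value, ties broken by highest percent identity then subject id) is an
#' annotated or predicted gene is discarded; anything else -- including an
#' empty hit set -- is retained as unknown.
#'
#' @param hits data.frame with columns \code{query_id},
#'   \code{subject_family}, \code{subject_superfamily}, \code{subject_order},
#'   \code{e_value}, \code{pct_identity}, \code{is_te_subject},
#'   \code{nr_subject_kind} (rows for one query)
#' @param max_evalue e-value cutoff applied before classification
#' @return list of class \code{"candidate_class"}: \code{class} (one of
#'   \code{known_family}, \code{novel_in_superfamily}, \code{novel_in_order},
#'   \code{discarded_gene_like}, \code{unknown_retained}) and \code{subject}
#'   (the family/superfamily/order label, or NA)
#' @export
classify_candidate <- function(hits, max_evalue = 1e-8) {
  out <- function(class, subject = NA_character_)
    structure(list(class = class, subject = subject),
              class = "candidate_class")
  if (nrow(hits) == 0L) return(out("unknown_retained"))
  if (any(hits$e_value < 0)) stop("negative e-value")
  hits <- hits[hits$e_value <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(out("unknown_retained"))
  te <- hits[hits$is_te_subject, , drop = FALSE]
  if (nrow(te) > 0L) {
    fams <- unique(te$subject_family)
    if (length(fams) == 1L) return(out("known_family", fams))
    supfams <- unique(te$subject_superfamily)
    if (length(supfams) == 1L) return(out("novel_in_superfamily", supfams))
    orders <- unique(te$subject_order)
    if (length(orders) == 1L) return(out("novel_in_order", orders))
    return(out("unknown_retained"))
  }
  # no TE subjects: inspect the primary nr hit
  ord <- order(hits$e_value, -hits$pct_identity, hits$subject_family)
  primary <- hits[ord[1], ]
  if (!is.na(primary$nr_subject_kind) && primary$nr_subject_kind == "gene")
    return(out("discarded_gene_like", primary$subject_family))
  out("unknown_retained")
}

#' Single-linkage clustering of sequences into families
#'
#' Sequences are joined into one family whenever a chain of pairwise
#' identities above the threshold connects them (single linkage). Each
#' cluster's representative is its longest member, ties broken by
#' lexicographic id.
#'
#' @param sequences named character vector of (aligned, equal-length)
#'   sequences, or NULL when \code{identity} is supplied
#' @param identity_threshold identity above which two sequences are the same
#'   family (strict \code{>})
#' @param identity optional precomputed symmetric identity matrix with
#'   dimnames; computed with \code{\link{pairwise_identity}} otherwise
#' @return data.frame with columns \code{id}, \code{cluster},
#'   \code{representative}
#' @export
cluster_families <- function(sequences = NULL, identity_threshold = 0.90,
                             identity = NULL) {
  if (is.null(identity)) {
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
      stop("sequences must carry unique names")
    ids <- names(sequences)
    k <- length(ids)
    identity <- diag(1, k)
    dimnames(identity) <- list(ids, ids)
    if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k)
      identity[i, j] <- identity[j, i] <-
        pairwise_identity(sequences[[i]], sequences[[j]])
    lens <- nchar(gsub("[-N]", "", toupper(sequences)))
  } else {
    ids <- rownames(identity)
    lens <- if (is.null(sequences)) stats::setNames(rep(0L, length(ids)), ids)
            else stats::setNames(nchar(gsub("[-N]", "", toupper(sequences)))[match(ids, names(sequences))], ids)
  }
  k <- length(ids)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k)
    if (identity[i, j] > identity_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  root <- vapply(seq_len(k), find, integer(1))
  cluster <- match(root, unique(root))
  rep_of <- vapply(seq_len(max(cluster)), function(cl) {
    members <- ids[cluster == cl]
    members[order(-lens[members], members)][1]
  }, "")
  data.frame(id = ids, cluster = cluster, representative = rep_of[cluster],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Minimum-hit-count filter for a family
#'
#' A family is retained when it has at least \code{min_hits} repeat-mask hits
#' in at least one species (boundary inclusive).
#'
#' @param per_species_hit_counts non-negative counts, one per species
#' @param min_hits threshold (default 25)
#' @return logical keep flag
#' @export
hit_count_filter <- function(per_species_hit_counts, min_hits = 25L) {
  if (any(per_species_hit_counts < 0)) stop("negative hit count")
  max(per_species_hit_counts) >= min_hits
}

#' Estimate TE copy number from relative read depth
#'
#' Copy number = median per-base depth over the TE consensus divided by the
#' median depth of a single-copy reference chromosome. For elements whose
#' segments amplify independently (e.g. solo LTRs versus the LTR body), the
#' estimate is made per segment and the segment estimates averaged.
#'
#' @param profile a \code{coverage_profile} (list with \code{depth} and
#'   \code{baseline_median})
#' @param segments optional list of integer position vectors (1-based into
#'   \code{depth}) defining segments estimated separately then averaged
#' @return estimated copy number
#' @export
estimate_copy_number <- function(profile, segments = NULL) {
  if (length(profile$depth) == 0L) stop("empty coverage profile")
  if (is.null(profile$baseline_median) || profile$baseline_median <= 0)
    stop("baseline median depth must be > 0")
  if (is.null(segments))
    return(stats::median(profile$depth) / profile$baseline_median)
  ests <- vapply(segments, function(idx)
    stats::median(profile$depth[idx]) / profile$baseline_median, numeric(1))
  mean(ests)
}

#' Relative-coverage filter for a family
#'
#' A family is retained when at least \code{min_frac} of its positions have
#' depth at least \code{fold} times the single-copy baseline (both boundaries
#' inclusive). Note the filter as stated is calibrated against a 2-fold
#' baseline: a genuinely single-copy family in a homozygous line sits near
#' 1x relative coverage and is discarded by the default parameters; both
#' knobs are therefore configurable.
#'
#' @param profile a \code{coverage_profile}
#' @param fold coverage multiple of the baseline required (default 2)
#' @param min_frac minimum fraction of positions meeting it (default 0.8)
#' @return logical keep flag
#' @export
coverage_filter <- function(profile, fold = 2, min_frac = 0.8) {
  if (length(profile$depth) == 0L) stop("empty coverage profile")
  if (profile$baseline_median <= 0) stop("baseline median depth must be > 0")
  mean(profile$depth >= fold * profile$baseline_median) >= min_frac
}

#' Filter insertion calls by population frequency
#'
#' Retains insertion records whose estimated frequency is at least
#' \code{min_freq} (inclusive); in mostly inbred lines, true insertions are
#' expected at high frequency.
#'
#' @param calls data.frame with a \code{frequency} column in [0, 1]
#' @param min_freq threshold (default 0.5)
#' @return the retained rows
#' @export
insertion_frequency_filter <- function(calls, min_freq = 0.5) {
  if (nrow(calls) == 0L) return(calls)
  if (any(calls$frequency < 0 | calls$frequency > 1))
    stop("frequencies must be in [0, 1]")
  calls[calls$frequency >= min_freq, , drop = FALSE]
}

# Merge possibly overlapping 0-based half-open intervals (two-column matrix
# or data.frame with start/end), returning a data.frame sorted by start.
.merge_intervals <- function(start, end) {
  if (length(start) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# Total clipped overlap of merged intervals with [ws, we).
.overlap_bases <- function(iv, ws, we) {
  if (nrow(iv) == 0L) return(0L)
  sum(pmax(0L, pmin(iv$end, we) - pmax(iv$start, ws)))
}

.make_windows <- function(len, window, step) {
  starts <- seq(0L, max(0L, len - 1L), by = step)
  starts <- starts[starts < len]
  data.frame(start = starts, end = pmin(starts + window, len))
}

#' N-corrected sliding-window TE density
#'
#' Per window, density = TE bases / (window span - N bases in the window),
#' with overlapping mask intervals merged and overlaps clipped to the window.
#' Windows consisting entirely of Ns are flagged undefined (NA density).
#' Terminal windows shorter than the nominal size are included with their
#' actual span.
#'
#' @param mask_intervals BED-like data.frame (\code{chrom}, \code{start},
#'   \code{end}; 0-based half-open) of repeat-masked TE intervals
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param n_intervals BED-like data.frame of N (assembly-gap) runs
#' @param window,step window size and step in bp (defaults 1 Mb / 100 kb)
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{te_bases}, \code{n_bases}, \code{density}
#' @export
window_density <- function(mask_intervals, chrom_lengths,
                           n_intervals = NULL, window = 1e6L, step = 1e5L) {
  .check_bounds(mask_intervals, chrom_lengths, "mask interval")
  if (!is.null(n_intervals)) .check_bounds(n_intervals, chrom_lengths, "N interval")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    wins <- .make_windows(len, window, step)
    mi <- mask_intervals[mask_intervals$chrom == ch, , drop = FALSE]
    mi <- .merge_intervals(mi$start, mi$end)
    ni <- if (is.null(n_intervals)) data.frame(start = integer(0), end = integer(0))
          else {
            x <- n_intervals[n_intervals$chrom == ch, , drop = FALSE]
            .merge_intervals(x$start, x$end)
          }
    te_b <- mapply(function(s, e) .overlap_bases(mi, s, e), wins$start, wins$end)
    n_b <- mapply(function(s, e) .overlap_bases(ni, s, e), wins$start, wins$end)
    span <- wins$end - wins$start
    dens <- ifelse(span > n_b, te_b / (span - n_b), NA_real_)
    data.frame(chrom = ch, start = wins$start, end = wins$end,
               te_bases = as.integer(te_b), n_bases = as.integer(n_b),
               density = dens, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.check_bounds <- function(iv, chrom_lengths, what) {
  if (nrow(iv) == 0L) return(invisible())
  bad_chrom <- !iv$chrom %in% names(chrom_lengths)
  if (any(bad_chrom))
    stop(what, " on unknown chromosome: ", iv$chrom[which(bad_chrom)[1]])
  lens <- chrom_lengths[iv$chrom]
  bad <- iv$start < 0 | iv$end > lens | iv$start >= iv$end
  if (any(bad)) {
    i <- which(bad)[1]
    stop(what, " out of bounds: ", iv$chrom[i], ":", iv$start[i], "-",
         iv$end[i], " (chromosome length ", lens[i], ")")
  }
  invisible()
}

#' N-corrected sliding-window insertion density
#'
#' Insertions are assigned to windows by their midpoint; per window the count
#' is divided by (window span - N bases) and scaled to insertions per Mb.
#'
#' @param insertion_positions data.frame with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open insertion spans; point insertions may use
#'   end = start + 1)
#' @param chrom_lengths named integer vector
#' @param n_intervals BED-like data.frame of N runs (optional)
#' @param window,step window size and step in bp
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{n_insertions}, \code{n_bases}, \code{per_mb}
#' @export
insertion_density <- function(insertion_positions, chrom_lengths,
                              n_intervals = NULL, window = 1e6L,
                              step = 1e5L) {
  .check_bounds(insertion_positions, chrom_lengths, "insertion")
  if (!is.null(n_intervals)) .check_bounds(n_intervals, chrom_lengths, "N interval")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    wins <- .make_windows(len, window, step)
    ins <- insertion_positions[insertion_positions$chrom == ch, , drop = FALSE]
    mid <- floor((ins$start + ins$end) / 2)
    ni <- if (is.null(n_intervals)) data.frame(start = integer(0), end = integer(0))
          else {
            x <- n_intervals[n_intervals$chrom == ch, , drop = FALSE]
            .merge_intervals(x$start, x$end)
          }
    cnt <- mapply(function(s, e) sum(mid >= s & mid < e), wins$start, wins$end)
    n_b <- mapply(function(s, e) .overlap_bases(ni, s, e), wins$start, wins$end)
    span <- wins$end - wins$start
    per_mb <- ifelse(span > n_b, cnt / (span - n_b) * 1e6, NA_real_)
    data.frame(chrom = ch, start = wins$start, end = wins$end,
               n_insertions = as.integer(cnt), n_bases = as.integer(n_b),
               per_mb = per_mb, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
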