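# Synthetic-data generators: every input the downstream stages consume can be
# produced here with known ground truth, so the whole pipeline is testable
# without genome or SRA downloads.

#' Default species tree of the simulated five-species group
#'
#' Rooted, ultrametric topology ((((pse,per),mir),low),aff) in expected
#' substitutions per site. The pse-per root-to-root path is anchored at a
#' synonymous divergence of 0.018, the value typical of the most closely
#' related pair in the group; successively deeper splits sit at 3x, 6x and
#' 12x that depth (relative depths are what the classifier tests exercise;
#' absolute deep-node ages are placeholders).
#'
#' @return an \code{ape} \code{phylo} object with branch lengths
#' @export
species_tree_default <- function() {
  ape::read.tree(text = paste0(
    "((((pse:0.009,per:0.009):0.018,mir:0.027):0.027,",
    "low:0.054):0.054,aff:0.108);"))
}

#' Simulation configuration
#'
#' Bundles the knobs shared by the sequence-level simulators.
#'
#' @param seed integer seed; fixing it makes every simulator output
#'   byte-identical between runs
#' @param substitution_model \code{"JC69"} or \code{"K2P"}
#' @param kappa transition/transversion rate ratio (K2P only)
#' @param sequence_length_codons length of the simulated TE ORF, in codons
#' @param theta_per_site scaled mutation rate for the within-family copy
#'   coalescent
#' @param copy_number TE copies per species
#' @param coverage_depth_baseline mean single-copy read depth
#' @param noise_cv coefficient of variation of depth noise
#' @return a list of class \code{"simulation_config"}
#' @export
simulation_config <- function(seed = 1L, substitution_model = c("JC69", "K2P"),
                              kappa = 2, sequence_length_codons = 1000L,
                              theta_per_site = 0.01, copy_number = 10L,
                              coverage_depth_baseline = 30,
                              noise_cv = 0.1) {
  substitution_model <- match.arg(substitution_model)
  stopifnot(kappa > 0, sequence_length_codons >= 1, theta_per_site >= 0,
            copy_number >= 0, coverage_depth_baseline >= 0, noise_cv >= 0)
  structure(list(seed = as.integer(seed),
                 substitution_model = substitution_model, kappa = kappa,
                 sequence_length_codons = as.integer(sequence_length_codons),
                 theta_per_site = theta_per_site,
                 copy_number = as.integer(copy_number),
                 coverage_depth_baseline = coverage_depth_baseline,
                 noise_cv = noise_cv),
            class = "simulation_config")
}

#' Horizontal-transfer event descriptor
#'
#' @param donor,recipient tip labels of the species tree (must differ)
#' @param time_fraction fraction of the recipient's root-to-tip depth at
#'   which the transfer occurs (0 = present, approaching 1 = near the root)
#' @param family_id optional identifier carried along for bookkeeping
#' @return a list of class \code{"ht_event"}
#' @export
ht_event <- function(donor, recipient, time_fraction, family_id = NA_character_) {
  if (donor == recipient) stop("donor and recipient must differ")
  if (time_fraction < 0 || time_fraction >= 1)
    stop("time_fraction must be in [0, 1)")
  structure(list(family_id = family_id, donor = donor, recipient = recipient,
                 time_fraction = time_fraction), class = "ht_event")
}

.BASES <- c("A", "C", "G", "T")

.random_orf <- function(n_codons) {
  paste(sample(.sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Evolve a sequence (character vector of single bases) along one branch of
# length b expected substitutions/site under K2P, sampling each site from the
# transition probabilities. Transition rate alpha = kappa * beta; each of the
# two transversion targets has rate beta; alpha + 2 beta = b.
.evolve_branch_k2p <- function(seq_vec, b, kappa = 2) {
  L <- length(seq_vec)
  beta <- b / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta)
  e2 <- exp(-2 * (alpha + beta))
  p_ts <- 1 / 4 + e1 / 4 - e2 / 2
  p_tv <- 1 / 4 - e1 / 4
  ts_partner <- c(A = "G", C = "T", G = "A", T = "C")
  u <- stats::runif(L)
  out <- seq_vec
  hit_ts <- u < p_ts
  hit_tv1 <- !hit_ts & u < p_ts + p_tv
  hit_tv2 <- !hit_ts & !hit_tv1 & u < p_ts + 2 * p_tv
  out[hit_ts] <- ts_partner[seq_vec[hit_ts]]
  # the two transversion targets of each base, in fixed order
  tv1 <- c(A = "C", C = "A", G = "C", T = "A")
  tv2 <- c(A = "T", C = "G", G = "T", T = "G")
  out[hit_tv1] <- tv1[seq_vec[hit_tv1]]
  out[hit_tv2] <- tv2[seq_vec[hit_tv2]]
  out
}

.evolve_branch_jc <- function(seq_vec, b) {
  p_other <- (1 - exp(-4 * b / 3)) / 4
  L <- length(seq_vec)
  u <- stats::runif(L)
  change <- which(u < 3 * p_other)
  if (length(change)) {
    pick <- ceiling(stats::runif(length(change)) * 3)  # 1..3
    cur <- seq_vec[change]
    idx <- match(cur, .BASES)
    others <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                     nrow = 4, byrow = TRUE)
    seq_vec[change] <- others[cbind(idx, pick)]
  }
  seq_vec
}

.evolve <- function(seq_vec, b, model, kappa) {
  if (b <= 0) return(seq_vec)
  if (model == "JC69") .evolve_branch_jc(seq_vec, b)
  else .evolve_branch_k2p(seq_vec, b, kappa)
}

#' Evolve a TE family on a species tree, optionally with a horizontal transfer
#'
#' A random open reading frame of the configured codon length is placed at the
#' root and evolved down every branch under JC69 (or K2P). With an
#' \code{\link{ht_event}}, the recipient's lineage is re-grafted onto the
#' donor's lineage at \code{time_fraction} of the recipient's root-to-tip
#' depth, so the expected donor-recipient divergence is
#' 2 x time_fraction x depth while all other pairs keep their tree path
#' lengths.
#'
#' @param tree a rooted \code{phylo} with branch lengths (expected
#'   substitutions/site), e.g. \code{\link{species_tree_default}}
#' @param config a \code{\link{simulation_config}}
#' @param ht optional \code{\link{ht_event}}
#' @param root_sequence optional root ORF (overrides the random one)
#' @return list of class \code{"family_simulation"}: \code{sequences} (named
#'   character vector, one per tip), \code{root_sequence}, \code{ht}
#' @export
evolve_family_on_tree <- function(tree, config = simulation_config(),
                                  ht = NULL, root_sequence = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  set.seed(config$seed)
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  if (!is.null(ht)) {
    missing <- setdiff(c(ht$donor, ht$recipient), tree$tip.label)
    if (length(missing))
      stop("ht event references species not in the tree: ",
           paste(missing, collapse = ", "))
  }
  model <- config$substitution_model
  kappa <- config$kappa
  root_seq <- if (is.null(root_sequence)) .random_orf(config$sequence_length_codons)
              else toupper(root_sequence)
  root_vec <- strsplit(root_seq, "")[[1]]
  root <- ntip + 1L

  # node depths from the root, to locate the transfer point
  depth <- numeric(ntip + tree$Nnode)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge)))
    depth[ord$edge[k, 2]] <- depth[ord$edge[k, 1]] + ord$edge.length[k]

  split_edge <- NA_integer_; split_at <- NA_real_; tau <- NA_real_
  transfer_vec <- NULL
  if (!is.null(ht)) {
    rec_tip <- match(ht$recipient, tree$tip.label)
    don_tip <- match(ht$donor, tree$tip.label)
    tau <- ht$time_fraction * depth[rec_tip]
    target_depth <- depth[don_tip] - tau
    if (target_depth < 0)
      stop("transfer time predates the donor lineage")
    # walk the donor's root-to-tip path to find the edge holding target_depth
    node <- don_tip
    path_edges <- integer(0)
    while (node != root) {
      e <- which(ord$edge[, 2] == node)
      path_edges <- c(e, path_edges)
      node <- ord$edge[e, 1]
    }
    for (e in path_edges) {
      d0 <- depth[ord$edge[e, 1]]; d1 <- depth[ord$edge[e, 2]]
      if (target_depth >= d0 && target_depth <= d1) {
        split_edge <- e; split_at <- target_depth - d0
        break
      }
    }
  }

  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- root_vec
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    b <- ord$edge.length[k]
    if (!is.na(split_edge) && k == split_edge) {
      mid <- .evolve(seqs[[parent]], split_at, model, kappa)
      transfer_vec <- mid
      seqs[[child]] <- .evolve(mid, b - split_at, model, kappa)
    } else {
      seqs[[child]] <- .evolve(seqs[[parent]], b, model, kappa)
    }
  }
  if (!is.null(ht)) {
    rec_tip <- match(ht$recipient, tree$tip.label)
    seqs[[rec_tip]] <- .evolve(transfer_vec, tau, model, kappa)
  }
  tips <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(tips) <- tree$tip.label
  structure(list(sequences = tips, root_sequence = root_seq, ht = ht,
                 config = config), class = "family_simulation")
}

#' Simulate TE copies within one species under a Kingman coalescent
#'
#' Draws an n-sample coalescent genealogy, scatters mutations on its branches
#' as a Poisson process with total rate theta/2 per unit branch length
#' (theta = theta_per_site x sequence length), and applies them oldest-first
#' to a finite-sites copy of the consensus (a mutated site changes to one of
#' the three other bases; repeat hits at a site are allowed, approximating
#' infinite sites at low theta). With \code{expansion = TRUE}, external
#' (tip) branches are stretched by \code{expansion_factor}, skewing the site
#' frequency spectrum toward rare variants as after a copy-number expansion.
#'
#' @param consensus the family consensus sequence
#' @param n_copies number of copies (>= 2)
#' @param theta_per_site scaled mutation rate per site
#' @param seed integer seed (NULL to use the current RNG state)
#' @param expansion logical; stretch external branches
#' @param expansion_factor multiplier for external branch lengths
#' @return named character vector of \code{n_copies} sequences
#' @export
simulate_te_copies <- function(consensus, n_copies, theta_per_site,
                               seed = NULL, expansion = FALSE,
                               expansion_factor = 3) {
  if (n_copies < 2) stop("n_copies must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  theta_total <- theta_per_site * L

  gen <- .coalescent_segments(n_copies)
  dur <- gen$dur
  if (expansion) dur[gen$size == 1L] <- dur[gen$size == 1L] * expansion_factor
  mat <- matrix(rep(strsplit(consensus, "")[[1]], n_copies),
                nrow = n_copies, byrow = TRUE)
  total_len <- sum(dur)
  n_mut <- stats::rpois(1, theta_total / 2 * total_len)
  if (n_mut > 0 && theta_total > 0) {
    seg <- sample.int(length(dur), n_mut, replace = TRUE, prob = dur)
    site <- sample.int(L, n_mut, replace = TRUE)
    age <- gen$birth[seg] + stats::runif(n_mut) * dur[seg]
    ord <- order(age, decreasing = TRUE)  # oldest first
    for (m in ord) {
      tipset <- gen$tips[[seg[m]]]
      cur <- mat[tipset[1], site[m]]
      mat[tipset, site[m]] <- sample(setdiff(.BASES, cur), 1)
    }
  }
  out <- apply(mat, 1, paste, collapse = "")
  names(out) <- paste0("copy_", seq_len(n_copies))
  out
}

# Kingman coalescent genealogy as branch segments: each lineage alive over
# some interval, with its descendant tip set. Returns parallel vectors
# dur/birth/size and the list of tip sets.
.coalescent_segments <- function(n) {
  tips <- as.list(seq_len(n))
  birth_active <- rep(0, n)
  segs_tips <- list(); segs_dur <- numeric(0); segs_birth <- numeric(0)
  t <- 0
  while (length(tips) > 1L) {
    k <- length(tips)
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    for (i in pair) {
      segs_tips[[length(segs_tips) + 1L]] <- tips[[i]]
      segs_dur <- c(segs_dur, t - birth_active[i])
      segs_birth <- c(segs_birth, birth_active[i])
    }
    merged <- sort(c(tips[[pair[1]]], tips[[pair[2]]]))
    tips <- tips[-pair]
    birth_active <- birth_active[-pair]
    tips[[length(tips) + 1L]] <- merged
    birth_active <- c(birth_active, t)
  }
  list(tips = segs_tips, dur = segs_dur, birth = segs_birth,
       size = lengths(segs_tips), tmrca = t)
}

#' Simulate a per-base coverage profile with known true copy number
#'
#' Depths are lognormal with mean \code{true_copy_number x baseline_depth}
#' and the requested coefficient of variation; the single-copy baseline
#' (median depth of a reference chromosome) is recorded alongside.
#'
#' @param te_length length of the TE consensus in bp
#' @param true_copy_number ground-truth copy number (>= 0)
#' @param baseline_depth mean single-copy depth
#' @param noise_cv coefficient of variation of the depth noise (0 = exact)
#' @param seed integer seed
#' @param te_id identifier carried in the output
#' @return object of class \code{"coverage_profile"}: list with \code{te_id},
#'   numeric \code{depth}, and \code{baseline_median}
#' @export
simulate_coverage_profile <- function(te_length, true_copy_number,
                                      baseline_depth, noise_cv = 0.1,
                                      seed = NULL, te_id = "te") {
  if (te_length < 1) stop("te_length must be >= 1")
  if (true_copy_number < 0) stop("true_copy_number must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  m <- true_copy_number * baseline_depth
  if (m == 0) {
    depth <- rep(0, te_length)
  } else if (noise_cv == 0) {
    depth <- rep(m, te_length)
  } else {
    sdlog <- sqrt(log(1 + noise_cv^2))
    depth <- stats::rlnorm(te_length, meanlog = log(m) - sdlog^2 / 2,
                           sdlog = sdlog)
  }
  structure(list(te_id = te_id, depth = depth,
                 baseline_median = baseline_depth),
            class = "coverage_profile")
}

.revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", sapply(lapply(strsplit(x, ""), rev), paste,
                                  collapse = ""))
}

#' Simulate ping-pong-structured small-RNA reads
#'
#' Generates primary (sense) piRNAs whose 5' base is uridine (T in sequence
#' space) with probability \code{u1_freq} -- imposed by choosing read start
#' positions on the consensus, not by editing sequences -- and for each one an
#' antisense responder whose 5' end overlaps the sense 5' end by exactly
#' \code{offset} nucleotides, with the responder sequence the reverse
#' complement of the consensus. Any adenine bias at responder position
#' \code{offset} is therefore emergent from complementarity, never written in.
#' A fraction \code{background_frac} of all reads are uniform-position,
#' random-strand noise.
#'
#' @param consensus TE consensus sequence; a random 2-kb sequence if NULL
#' @param n_pairs number of ping-pong pairs before background replacement
#' @param offset 5'-overlap in nt (default 10, the ping-pong signature)
#' @param u1_freq probability that a primary read starts on a T
#' @param background_frac fraction of reads that are positional noise
#' @param length_range read lengths, sampled uniformly (piRNA-sized default)
#' @param seed integer seed
#' @param te_id identifier for the output records
#' @return data.frame with columns \code{te_id}, \code{start} (0-based
#'   leftmost base on the consensus), \code{length}, \code{strand} (+/-),
#'   \code{sequence} (read orientation)
#' @export
simulate_pingpong_reads <- function(consensus = NULL, n_pairs = 5000L,
                                    offset = 10L, u1_freq = 0.9,
                                    background_frac = 0.2,
                                    length_range = 24:29, seed = NULL,
                                    te_id = "te") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(consensus))
    consensus <- paste(sample(.BASES, 2000, replace = TRUE), collapse = "")
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  max_len <- max(length_range)
  if (offset < 1 || offset > min(length_range))
    stop("offset must be in 1..min(length_range)")
  cvec <- strsplit(consensus, "")[[1]]
  lo <- max_len - offset          # smallest sense 5' start (0-based)
  hi <- L - max_len               # largest
  if (hi <= lo) stop("consensus too short for the requested read lengths")
  cand <- lo:hi
  t_pool <- cand[cvec[cand + 1L] == "T"]
  nt_pool <- cand[cvec[cand + 1L] != "T"]
  if (length(t_pool) == 0L) stop("consensus has no T in the usable range")

  n_bg <- round(2 * n_pairs * background_frac)
  n_sig <- n_pairs - ceiling(n_bg / 2)
  n_bg <- 2L * (n_pairs - n_sig)

  rows <- list()
  if (n_sig > 0) {
    use_t <- stats::runif(n_sig) < u1_freq
    s0 <- integer(n_sig)
    s0[use_t] <- t_pool[sample.int(length(t_pool), sum(use_t), replace = TRUE)]
    if (any(!use_t))
      s0[!use_t] <- nt_pool[sample.int(length(nt_pool), sum(!use_t), replace = TRUE)]
    ls <- sample(length_range, n_sig, replace = TRUE)
    la <- sample(length_range, n_sig, replace = TRUE)
    r <- s0 + offset - 1L                 # antisense 5' (rightmost base)
    sa <- r - la + 1L                     # antisense leftmost base
    sense_seq <- substring(consensus, s0 + 1L, s0 + ls)
    anti_seq <- .revcomp(substring(consensus, sa + 1L, r + 1L))
    rows$sense <- data.frame(te_id = te_id, start = s0, length = ls,
                             strand = "+", sequence = sense_seq,
                             stringsAsFactors = FALSE)
    rows$anti <- data.frame(te_id = te_id, start = sa, length = la,
                            strand = "-", sequence = anti_seq,
                            stringsAsFactors = FALSE)
  }
  if (n_bg > 0) {
    lb <- sample(length_range, n_bg, replace = TRUE)
    sb <- vapply(lb, function(l) sample.int(L - l + 1L, 1L) - 1L, integer(1))
    strand <- sample(c("+", "-"), n_bg, replace = TRUE)
    seqs <- substring(consensus, sb + 1L, sb + lb)
    seqs[strand == "-"] <- .revcomp(seqs[strand == "-"])
    rows$bg <- data.frame(te_id = te_id, start = sb, length = lb,
                          strand = strand, sequence = seqs,
                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "consensus") <- consensus
  out
}

#' Simulate a BLAST-style hit table for one candidate sequence
#'
#' Produces the hit structures the candidate decision tree distinguishes:
#' a single known-family hit, multiple hits within one superfamily, multiple
#' superfamilies within one order, a gene-like candidate whose primary
#' (best e-value) hit is an annotated gene, or an orphan with no informative
#' hit.
#'
#' @param scenario one of \code{"known_single"}, \code{"multi_one_superfamily"},
#'   \code{"multi_one_order"}, \code{"gene_like"}, \code{"orphan"}
#' @param seed integer seed (jitters e-values/identities only)
#' @param query_id candidate identifier
#' @return data.frame with columns \code{query_id}, \code{subject_family},
#'   \code{subject_superfamily}, \code{subject_order}, \code{e_value},
#'   \code{pct_identity}, \code{is_te_subject}, \code{nr_subject_kind}
#' @export
simulate_hit_table <- function(scenario, seed = NULL, query_id = "cand_1") {
  scenarios <- c("known_single", "multi_one_superfamily", "multi_one_order",
                 "gene_like", "orphan")
  if (!scenario %in% scenarios)
    stop("unknown scenario: ", scenario, " (expected one of ",
         paste(scenarios, collapse = ", "), ")")
  if (!is.null(seed)) set.seed(seed)
  # listed order is hit rank: the first subject always gets the best e-value
  ev <- function(n) sort(10^(-stats::runif(n, 20, 60)))
  pid <- function(n) round(stats::runif(n, 86, 99), 1)
  row <- function(fam, supfam, ord, te, kind = NA_character_) {
    n <- length(fam)
    data.frame(query_id = query_id, subject_family = fam,
               subject_superfamily = supfam, subject_order = ord,
               e_value = ev(n), pct_identity = pid(n),
               is_te_subject = te, nr_subject_kind = kind,
               stringsAsFactors = FALSE)
  }
  switch(scenario,
    known_single = row("Gypsy10_Dpse", "Gypsy", "LTR", TRUE),
    multi_one_superfamily = row(c("Gypsy10_Dpse", "Gypsy3_Dper", "Gypsy7_Dmir"),
                                "Gypsy", "LTR", TRUE),
    multi_one_order = row(c("Gypsy10_Dpse", "Copia2_Dpse", "BEL1_Dper"),
                          c("Gypsy", "Copia", "BEL-Pao"), "LTR", TRUE),
    gene_like = row(c("XP_0012345_pred_gene", "hypothetical_protein_1"),
                    NA_character_, NA_character_, FALSE,
                    c("gene", "other")),
    orphan = row("uncharacterized_contig", NA_character_, NA_character_,
                 FALSE, "other"))
}

#' Simulate a genome mosaic of TE insertions and assembly gaps
#'
#' Places non-overlapping TE insertion intervals and runs of N (assembly
#' gaps) on a random background sequence. Truth intervals are 0-based
#' half-open.
#'
#' @param families family labels to draw insertion identities from
#' @param genome_length total genome length in bp
#' @param n_insertions number of TE insertions
#' @param n_gap_frac target fraction of N bases
#' @param seed integer seed
#' @param insert_length_range min/max insertion length in bp
#' @param chrom chromosome name used in the interval tables
#' @return list with \code{genome} (character scalar), \code{te_intervals}
#'   (BED-like data.frame: chrom, start, end, family, score, strand) and
#'   \code{n_intervals} (chrom, start, end)
#' @export
simulate_genome_mosaic <- function(families = c("fam1", "fam2", "fam3"),
                                   genome_length = 1e6L, n_insertions = 20L,
                                   n_gap_frac = 0.05, seed = NULL,
                                   insert_length_range = c(500L, 5000L),
                                   chrom = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  genome_length <- as.integer(genome_length)
  te_len <- if (n_insertions > 0)
    sample(insert_length_range[1]:insert_length_range[2], n_insertions,
           replace = TRUE) else integer(0)
  n_total <- round(n_gap_frac * genome_length)
  n_runs <- if (n_total > 0) sample(1:5, 1) else 0L
  gap_len <- if (n_runs > 0) {
    w <- as.vector(stats::rmultinom(1, n_total, rep(1 / n_runs, n_runs)))
    w[w > 0]
  } else integer(0)
  block_len <- c(te_len, gap_len)
  kind <- c(rep("te", length(te_len)), rep("gap", length(gap_len)))
  if (sum(block_len) > genome_length)
    stop("insertions and gaps exceed genome length (",
         sum(block_len), " > ", genome_length, ")")
  ordr <- sample(length(block_len))
  block_len <- block_len[ordr]; kind <- kind[ordr]
  free <- genome_length - sum(block_len)
  spacers <- as.vector(stats::rmultinom(1, free,
                                        rep(1 / (length(block_len) + 1),
                                            length(block_len) + 1)))
  start <- cumsum(c(0L, block_len)) + cumsum(spacers)
  start <- start[seq_along(block_len)]
  end <- start + block_len
  genome <- sample(.BASES, genome_length, replace = TRUE)
  te_rows <- which(kind == "te")
  gap_rows <- which(kind == "gap")
  for (g in gap_rows) genome[(start[g] + 1L):end[g]] <- "N"
  te_intervals <- data.frame(chrom = rep(chrom, length(te_rows)),
                             start = start[te_rows], end = end[te_rows],
                             family = if (length(te_rows))
                               sample(families, length(te_rows), replace = TRUE)
                             else character(0),
                             score = rep(0L, length(te_rows)),
                             strand = rep("+", length(te_rows)),
                             stringsAsFactors = FALSE)
  te_intervals <- te_intervals[order(te_intervals$start), , drop = FALSE]
  rownames(te_intervals) <- NULL
  n_intervals <- data.frame(chrom = rep(chrom, length(gap_rows)),
                            start = start[gap_rows], end = end[gap_rows],
                            stringsAsFactors = FALSE)
  n_intervals <- n_intervals[order(n_intervals$start), , drop = FALSE]
  rownames(n_intervals) <- NULL
  list(genome = paste(genome, collapse = ""), te_intervals = te_intervals,
       n_intervals = n_intervals)
}
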