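# Independent oracles, written from scratch against the published formulas so
# they share no code path with the package implementation.

oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- toupper(names(gc))
  gc
})

oracle_aa <- function(codon) unname(oracle_code[codon])

# Fractional synonymous sites of a codon: per position, the fraction of
# non-stop single-nucleotide neighbours that keep the amino acid.
oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0; tot <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_aa(mut) == "*") next
      tot <- tot + 1
      if (oracle_aa(mut) == oracle_aa(codon)) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  s
}

# Exhaustive mutational-pathway enumeration between two sense codons:
# recursively take every remaining differing position as the next step,
# dropping branches that pass through a stop codon; returns the mean
# synonymous/nonsynonymous step counts over surviving pathways.
oracle_pathways <- function(from, to) {
  walk <- function(cur, syn, non) {
    diff <- which(strsplit(cur, "")[[1]] != strsplit(to, "")[[1]])
    if (length(diff) == 0) return(list(c(syn = syn, non = non)))
    res <- list()
    for (pos in diff) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(to, pos, pos)
      if (oracle_aa(nxt) == "*") next
      step_syn <- oracle_aa(nxt) == oracle_aa(cur)
      res <- c(res, walk(nxt, syn + step_syn, non + !step_syn))
    }
    res
  }
  paths <- walk(from, 0, 0)
  if (length(paths) == 0) return(c(sd = NA_real_, nd = NA_real_))
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "syn"]), nd = mean(m[, "non"]))
}

# Full NG86 on two aligned coding sequences, assembled only from the oracle
# primitives above (codon pairs containing stops are skipped, as documented).
oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- N <- Sd <- Nd <- 0
  used <- 0
  for (i in seq_along(ca)) {
    if (oracle_aa(ca[i]) %in% c("*", NA) || oracle_aa(cb[i]) %in% c("*", NA))
      next
    p <- oracle_pathways(ca[i], cb[i])
    if (any(is.na(p))) next
    used <- used + 1
    sa <- oracle_syn_sites(ca[i]); sb <- oracle_syn_sites(cb[i])
    S <- S + (sa + sb) / 2
    N <- N + (3 - sa + 3 - sb) / 2
    Sd <- Sd + p["sd"]; Nd <- Nd + p["nd"]
  }
  list(S = S, N = N, Sd = unname(Sd), Nd = unname(Nd), codons_used = used)
}

random_sense_cds <- function(n_codons) {
  sense <- names(oracle_code)[oracle_code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Tajima's D from an alignment by direct evaluation of the 1989 formulas:
# pi from explicit pairwise sequence comparison, every constant written out.
oracle_tajima_d <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  diffs <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  pi <- mean(diffs)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Random small copy alignment with scattered variants, for oracle comparisons.
random_copy_alignment <- function(n_copies, len, n_variants) {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  m <- matrix(rep(base, n_copies), nrow = n_copies, byrow = TRUE)
  for (v in seq_len(n_variants)) {
    site <- sample(len, 1)
    carriers <- sample(n_copies, sample(n_copies - 1, 1))
    m[carriers, site] <- sample(setdiff(c("A", "C", "G", "T"), base[site]), 1)
  }
  apply(m, 1, paste, collapse = "")
}

# Independent neutral-coalescent Monte-Carlo for Tajima's D: explicit node
# records (times and descendant counts), mutations assigned per branch by a
# binomial split of a Poisson total, D evaluated with oracle constants.
oracle_coalescent_d <- function(n, theta, n_reps) {
  replicate(n_reps, {
    desc <- rep(1, n)
    t <- 0
    branch_len <- numeric(0)
    branch_desc <- numeric(0)
    alive_since <- rep(0, n)
    while (length(desc) > 1) {
      k <- length(desc)
      t <- t + rexp(1, k * (k - 1) / 2)
      idx <- sample(k, 2)
      branch_len <- c(branch_len, t - alive_since[idx])
      branch_desc <- c(branch_desc, desc[idx])
      desc <- c(desc[-idx], sum(desc[idx]))
      alive_since <- c(alive_since[-idx], t)
    }
    S <- rpois(1, theta / 2 * sum(branch_len))
    if (S == 0) return(NA_real_)
    k_mut <- sample(branch_desc, S, replace = TRUE, prob = branch_len)
    pi <- sum(k_mut * (n - k_mut)) / choose(n, 2)
    a1 <- sum(1 / (1:(n - 1)))
    a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (pi - S / a1) /
      sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  })
}

# Per-base brute-force recount of TE density in one window.
oracle_window_density <- function(te_intervals, n_intervals, ws, we) {
  pos <- ws:(we - 1)
  in_any <- function(iv) {
    hit <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(iv)))
      hit <- hit | (pos >= iv$start[i] & pos < iv$end[i])
    hit
  }
  te <- sum(in_any(te_intervals))
  nn <- if (is.null(n_intervals) || nrow(n_intervals) == 0) 0
        else sum(in_any(n_intervals))
  span <- we - ws
  list(te_bases = te, n_bases = nn,
       density = if (span > nn) te / (span - nn) else NA_real_)
}
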