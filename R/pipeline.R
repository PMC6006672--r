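# End-to-end orchestration on a simulated bundle: genes and TE families are
# evolved on the species tree (some TEs with injected horizontal transfers),
# pairwise dS is computed for both, families are classified against the genic
# quantiles, confirmed with the ENC-conditioned rule, checked for
# tree discordance, and summarized. Every artifact carries the seed and a
# config hash in a header comment.

#' Pipeline configuration
#'
#' Validated bundle of every threshold and simulation knob the pipeline
#' uses; unknown keys are rejected, as are thresholds outside their ranges.
#' Defaults equal the field-standard thresholds (2.5%/50% quantiles, 90%
#' identity, 25 hits, 2-fold/80% coverage, 50% insertion frequency, 1 Mb
#' windows with 100 kb steps).
#'
#' @param seed integer seed driving every stage
#' @param n_vertical_families TE families evolved without transfer
#' @param ht_events list of \code{\link{ht_event}} objects
#' @param n_genes nuclear genes simulated for the genic dS distribution
#' @param sequence_length_codons ORF length for genes and TE families
#' @param q_strong,q_median classifier quantiles
#' @param identity_threshold family clustering identity
#' @param min_hits,fold,min_frac,min_freq filter thresholds
#' @param window,step density window geometry in bp
#' @param run_popgen,run_smallrna include the polymorphism and ping-pong
#'   stages
#' @param out_dir directory for TSV artifacts (NULL = in-memory only)
#' @param ... rejected; catches unknown keys
#' @return list of class \code{"run_config"}
#' @export
run_config <- function(seed = 1L, n_vertical_families = 20L,
                       ht_events = list(), n_genes = 100L,
                       sequence_length_codons = 300L,
                       q_strong = 0.025, q_median = 0.5,
                       identity_threshold = 0.90, min_hits = 25L,
                       fold = 2, min_frac = 0.8, min_freq = 0.5,
                       window = 1e6L, step = 1e5L,
                       run_popgen = FALSE, run_smallrna = FALSE,
                       out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config keys: ", paste(names(extra), collapse = ", "))
  chk01 <- function(x, nm) if (x < 0 || x > 1)
    stop(nm, " must be in [0, 1], got ", x)
  chk01(q_strong, "q_strong"); chk01(q_median, "q_median")
  chk01(identity_threshold, "identity_threshold")
  chk01(min_frac, "min_frac"); chk01(min_freq, "min_freq")
  if (q_strong > q_median) stop("q_strong must not exceed q_median")
  if (min_hits < 0 || fold < 0 || window < 1 || step < 1)
    stop("thresholds out of range")
  if (n_genes < 2 || n_vertical_families < 0)
    stop("sample sizes out of range")
  for (e in ht_events) if (!inherits(e, "ht_event"))
    stop("ht_events must be a list of ht_event objects")
  structure(list(seed = as.integer(seed),
                 n_vertical_families = as.integer(n_vertical_families),
                 ht_events = ht_events, n_genes = as.integer(n_genes),
                 sequence_length_codons = as.integer(sequence_length_codons),
                 q_strong = q_strong, q_median = q_median,
                 identity_threshold = identity_threshold,
                 min_hits = as.integer(min_hits), fold = fold,
                 min_frac = min_frac, min_freq = min_freq,
                 window = as.integer(window), step = as.integer(step),
                 run_popgen = run_popgen, run_smallrna = run_smallrna,
                 out_dir = out_dir),
            class = "run_config")
}

# Polynomial rolling hash of the deparsed config (out_dir excluded), for
# artifact provenance headers.
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config), "out_dir")]),
                           collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.pair_label <- function(a, b) paste(sort(c(a, b)), collapse = "-")

# Pairwise dS of one family's per-species sequences; NA where saturated.
.pairwise_ds <- function(seqs) {
  sp <- names(seqs)
  pairs <- utils::combn(sp, 2)
  data.frame(species_a = pairs[1, ], species_b = pairs[2, ],
             species_pair = apply(pairs, 2, function(p) .pair_label(p[1], p[2])),
             ds = apply(pairs, 2, function(p) ng86(seqs[[p[1]]], seqs[[p[2]]])$dS),
             stringsAsFactors = FALSE)
}

#' Run the simulated end-to-end analysis
#'
#' Stages, in order: simulate nuclear genes on the species tree and build the
#' per-pair genic dS (and ENC) distributions; simulate vertical TE families
#' and families carrying the configured horizontal-transfer events; compute
#' per-pair TE dS; classify each family x pair against the genic quantiles;
#' confirm with the ENC-conditioned rule; build per-family NJ trees from the
#' dS matrices and flag Robinson-Foulds discordance with the species tree;
#' optionally run the within-family polymorphism and ping-pong stages; and
#' summarize. Deterministic given the config (all randomness flows from
#' \code{config$seed}); when \code{out_dir} is set every stage writes a TSV
#' carrying the seed and config hash.
#'
#' @param config a \code{\link{run_config}}
#' @param tree species tree (default \code{\link{species_tree_default}})
#' @return list of class \code{"run_report"}: \code{calls} (the
#'   \code{\link{htt_calls}} table), \code{summary}
#'   (from \code{\link{summarize_transfers}} plus stage counts),
#'   \code{genic}, \code{te_ds}, optional \code{popgen} and
#'   \code{smallrna} results, and \code{artifacts} (paths written)
#' @export
run_pipeline <- function(config, tree = species_tree_default()) {
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(config)
  log_lines <- character(0)
  logf <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
  }

  ntip <- length(tree$tip.label)
  L <- config$sequence_length_codons

  # stage 1: genic dS / ENC distributions per species pair
  genes <- lapply(seq_len(config$n_genes), function(i)
    evolve_family_on_tree(tree, simulation_config(
      seed = config$seed * 1000L + i, sequence_length_codons = L)))
  gene_ds <- do.call(rbind, lapply(seq_along(genes), function(i) {
    d <- .pairwise_ds(genes[[i]]$sequences)
    d$gene_id <- paste0("gene_", i)
    d$nc <- vapply(d$species_a, function(sp) {
      e <- effective_number_of_codons(genes[[i]]$sequences[[sp]])
      if (e$defined) e$Nc else NA_real_
    }, numeric(1))
    d
  }))
  logf("stage genic: %d genes -> %d pairwise dS values (%d undefined)",
       config$n_genes, nrow(gene_ds), sum(is.na(gene_ds$ds)))
  genic_by_pair <- lapply(split(gene_ds, gene_ds$species_pair), function(g)
    list(dist = genic_ds_distribution(g$ds, g$species_pair[1],
                                      config$q_strong, config$q_median),
         ds = g$ds, nc = g$nc))

  # stage 2: TE families (vertical + HT) and their pairwise dS
  n_ht <- length(config$ht_events)
  fam_ids <- c(paste0("fam_v", seq_len(config$n_vertical_families)),
               if (n_ht) paste0("fam_ht", seq_len(n_ht)))
  events <- c(vector("list", config$n_vertical_families), config$ht_events)
  fams <- lapply(seq_along(fam_ids), function(i)
    evolve_family_on_tree(tree, simulation_config(
      seed = config$seed * 1000L + 500000L + i,
      sequence_length_codons = L), ht = events[[i]]))
  names(fams) <- fam_ids
  te_ds <- do.call(rbind, lapply(fam_ids, function(f) {
    d <- .pairwise_ds(fams[[f]]$sequences)
    d$family_id <- f
    ev <- fams[[f]]$ht
    d$truth_ht <- if (is.null(ev)) FALSE
                  else d$species_pair == .pair_label(ev$donor, ev$recipient)
    d
  }))
  logf("stage te: %d families (%d with injected transfer) -> %d pairwise dS",
       length(fam_ids), n_ht, nrow(te_ds))

  # stages 3-5: classify, confirm, discordance
  te_ds$category <- NA_character_
  te_ds$enc_confirmed <- NA
  for (p in names(genic_by_pair)) {
    sel <- te_ds$species_pair == p
    te_ds$category[sel] <-
      as.character(classify_htt(te_ds$ds[sel], genic_by_pair[[p]]$dist))
  }
  for (i in which(te_ds$category == "strong")) {
    f <- te_ds$family_id[i]
    sp <- te_ds$species_a[i]
    enc <- effective_number_of_codons(fams[[f]]$sequences[[sp]])
    g <- genic_by_pair[[te_ds$species_pair[i]]]
    res <- enc_conditioned_test(te_ds$ds[i],
                                if (enc$defined) enc$Nc else NA_real_,
                                g$ds, g$nc)
    te_ds$enc_confirmed[i] <- res$confirmed
  }
  discord <- vapply(fam_ids, function(f) {
    d <- te_ds[te_ds$family_id == f, ]
    if (any(is.na(d$ds)) || ntip < 4) return(NA)
    m <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
    m[cbind(d$species_a, d$species_b)] <- d$ds
    m[cbind(d$species_b, d$species_a)] <- d$ds
    rf_discordance(nj_tree(m), tree)$discordant
  }, logical(1))
  te_ds$discordant <- discord[te_ds$family_id]
  calls <- htt_calls(te_ds$family_id, te_ds$species_pair, te_ds$ds,
                     factor(te_ds$category,
                            levels = c("strong", "potential", "none",
                                       "undefined")),
                     te_ds$enc_confirmed, te_ds$discordant)
  summ <- summarize_transfers(calls)
  summ$n_families <- length(fam_ids)
  summ$n_ht_injected <- n_ht
  summ$n_discordant_families <- sum(discord, na.rm = TRUE)
  truth_strong <- te_ds$truth_ht & te_ds$category == "strong"
  summ$ht_recovered <- unique(te_ds$family_id[truth_strong])
  logf("stage classify: %d strong, %d potential, %d none, %d undefined calls",
       sum(calls$category == "strong"), sum(calls$category == "potential"),
       sum(calls$category == "none"), sum(calls$category == "undefined"))

  out <- list(calls = calls, summary = summ, genic = genic_by_pair,
              te_ds = te_ds, log = NULL, artifacts = character(0))

  if (isTRUE(config$run_popgen)) {
    fam1 <- fams[[1]]
    cons <- fam1$sequences[[1]]
    copies <- simulate_te_copies(cons, n_copies = 10,
                                 theta_per_site = 0.005,
                                 seed = config$seed * 1000L + 900001L)
    ps <- tajimas_d(copies)
    null <- coalescent_null(ps$n, max(ps$theta_w, 1), n_reps = 500,
                            seed = config$seed * 1000L + 900002L)
    out$popgen <- list(summary = ps,
                       p = if (is.na(ps$tajima_d)) NA_real_
                           else tajima_p(ps$tajima_d, null))
    logf("stage popgen: n=%d S=%d D=%s", ps$n, ps$S,
         format(ps$tajima_d, digits = 3))
  }
  if (isTRUE(config$run_smallrna)) {
    reads <- simulate_pingpong_reads(fams[[1]]$sequences[[1]],
                                     n_pairs = 2000,
                                     seed = config$seed * 1000L + 900003L)
    pir <- reads[classify_length(reads$length) == "piRNA", ]
    out$smallrna <- list(spectrum = overlap_spectrum(pir),
                         composition = positional_composition(pir))
    logf("stage smallrna: modal offset %d, z10 %.2f",
         out$smallrna$spectrum$modal_offset, out$smallrna$spectrum$z10)
  }

  out$log <- log_lines
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c(paste0("seed=", config$seed), paste0("config_hash=", hash))
    paths <- c(
      genic_ds = file.path(config$out_dir, "genic_ds.tsv"),
      te_ds = file.path(config$out_dir, "te_ds.tsv"),
      htt_calls = file.path(config$out_dir, "htt_calls.tsv"),
      per_pair = file.path(config$out_dir, "summary_per_pair.tsv"),
      log = file.path(config$out_dir, "run_log.txt"))
    write_tsv_table(gene_ds, paths[["genic_ds"]], hdr)
    write_tsv_table(te_ds, paths[["te_ds"]], hdr)
    write_tsv_table(as.data.frame(calls), paths[["htt_calls"]], hdr)
    write_tsv_table(summ$per_pair, paths[["per_pair"]], hdr)
    writeLines(c(paste0("# ", hdr), log_lines), paths[["log"]])
    out$artifacts <- paths
  }
  class(out) <- "run_report"
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("tetransfer run:", x$summary$n_families, "families,",
      x$summary$n_ht_injected, "injected transfers\n")
  print(x$summary$per_pair)
  cat("strong in all pairs:",
      if (length(x$summary$strong_all_pairs))
        paste(x$summary$strong_all_pairs, collapse = ", ") else "none", "\n")
  invisible(x)
}
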