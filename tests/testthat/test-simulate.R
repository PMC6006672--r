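# Synthetic-data generators: calibration against closed-form expectations and
# structural ground truth.

test_that("default species tree is ultrametric with the anchored sister-pair depth", {
  tr <- species_tree_default()
  expect_setequal(tr$tip.label, c("pse", "per", "mir", "low", "aff"))
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["pse", "per"], 0.018)
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_true(all(abs(depths - depths[1]) < 1e-12))
})

test_that("family evolution is deterministic under a fixed config", {
  tr <- species_tree_default()
  cfg <- simulation_config(seed = 7, sequence_length_codons = 100)
  s1 <- evolve_family_on_tree(tr, cfg)
  s2 <- evolve_family_on_tree(tr, cfg)
  expect_identical(s1$sequences, s2$sequences)
})

test_that("zero-length branches give identical tip sequences", {
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  s <- evolve_family_on_tree(tr0, simulation_config(seed = 3,
                                                    sequence_length_codons = 50))
  expect_identical(s$sequences[["a"]], s$sequences[["b"]])
})

test_that("pairwise raw divergence matches the JC expectation on the tree path", {
  tr <- species_tree_default()
  sim <- evolve_family_on_tree(tr, simulation_config(
    seed = 11, sequence_length_codons = 3000))
  a <- strsplit(sim$sequences[["pse"]], "")[[1]]
  b <- strsplit(sim$sequences[["per"]], "")[[1]]
  p_obs <- mean(a != b)
  p_exp <- 3 / 4 * (1 - exp(-4 / 3 * 0.018))
  se <- sqrt(p_exp * (1 - p_exp) / 9000)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("K2P evolution matches its expected divergence and favours transitions", {
  tr2 <- ape::read.tree(text = "(a:0.05,b:0.05);")
  cfg <- simulation_config(seed = 13, substitution_model = "K2P", kappa = 8,
                           sequence_length_codons = 4000)
  sim <- evolve_family_on_tree(tr2, cfg)
  a <- strsplit(sim$sequences[["a"]], "")[[1]]
  b <- strsplit(sim$sequences[["b"]], "")[[1]]
  diff <- a != b
  p_exp <- 0.25 + 0.25 * exp(-4 * 0.1 / 10) - 0.5 * exp(-2 * 0.9 * 0.1)
  p_exp <- p_exp + 2 * (0.25 - 0.25 * exp(-4 * 0.1 / 10))  # ts + 2 tv
  se <- sqrt(p_exp * (1 - p_exp) / 12000)
  expect_lt(abs(mean(diff) - p_exp), 3 * se)
  is_ts <- (a %in% c("A", "G") & b %in% c("A", "G")) |
           (a %in% c("C", "T") & b %in% c("C", "T"))
  expect_gt(sum(diff & is_ts), sum(diff & !is_ts))  # kappa = 8 >> 1
})

test_that("an injected transfer collapses donor-recipient divergence to 2 tau", {
  tr <- species_tree_default()
  ht <- ht_event("pse", "low", time_fraction = 0.05)
  sim <- evolve_family_on_tree(tr, simulation_config(
    seed = 19, sequence_length_codons = 3000), ht = ht)
  a <- strsplit(sim$sequences[["pse"]], "")[[1]]
  b <- strsplit(sim$sequences[["low"]], "")[[1]]
  depth <- ape::node.depth.edgelength(species_tree_default())[1]
  d_exp <- 2 * 0.05 * depth
  p_exp <- 3 / 4 * (1 - exp(-4 / 3 * d_exp))
  se <- sqrt(p_exp * (1 - p_exp) / 9000)
  expect_lt(abs(mean(a != b) - p_exp), 3 * se)
  # far below the vertical expectation for that pair
  p_vert <- 3 / 4 * (1 - exp(-4 / 3 * ape::cophenetic.phylo(tr)["pse", "low"]))
  expect_lt(mean(a != b), p_vert / 3)
  # other pairs keep their tree paths: per-mir unaffected
  c1 <- strsplit(sim$sequences[["per"]], "")[[1]]
  c2 <- strsplit(sim$sequences[["mir"]], "")[[1]]
  p_pm <- 3 / 4 * (1 - exp(-4 / 3 * ape::cophenetic.phylo(tr)["per", "mir"]))
  expect_lt(abs(mean(c1 != c2) - p_pm), 3 * sqrt(p_pm * (1 - p_pm) / 9000))
})

test_that("a transfer naming an unknown species fails with the label", {
  tr <- species_tree_default()
  expect_error(
    evolve_family_on_tree(tr, simulation_config(seed = 1),
                          ht = ht_event("pse", "yakuba", 0.1)),
    "yakuba")
  expect_error(ht_event("pse", "pse", 0.1), "must differ")
  expect_error(ht_event("pse", "per", 1.0), "time_fraction")
})

test_that("copies are identical at theta 0 and require n >= 2", {
  cons <- random_sense_cds(50)
  cp <- simulate_te_copies(cons, 5, theta_per_site = 0, seed = 2)
  expect_true(all(cp == cons))
  expect_error(simulate_te_copies(cons, 1, 0.01), "n_copies")
})

test_that("segregating sites match the coalescent expectation theta * a1(n)", {
  set.seed(42)
  cons <- paste(rep("A", 500), collapse = "")
  S <- replicate(1000, {
    cp <- simulate_te_copies(cons, 10, 5 / 500)
    m <- do.call(rbind, strsplit(cp, ""))
    sum(apply(m, 2, function(x) length(unique(x)) > 1))
  })
  a1 <- sum(1 / (1:9))
  expect_lt(abs(mean(S) - 5 * a1), 3 * sd(S) / sqrt(length(S)))
})

test_that("the expansion flag skews Tajima's D negative", {
  set.seed(43)
  cons <- random_sense_cds(150)
  d_neutral <- replicate(150, tajimas_d(
    simulate_te_copies(cons, 8, 0.02))$tajima_d)
  d_expand <- replicate(150, tajimas_d(
    simulate_te_copies(cons, 8, 0.02, expansion = TRUE,
                       expansion_factor = 4))$tajima_d)
  expect_lt(mean(d_expand, na.rm = TRUE), mean(d_neutral, na.rm = TRUE))
  expect_lt(mean(d_expand, na.rm = TRUE), 0)
})

test_that("coverage profiles honour exact and degenerate parameter settings", {
  p0 <- simulate_coverage_profile(100, 5, 10, noise_cv = 0)
  expect_true(all(p0$depth == 50))
  expect_equal(p0$baseline_median, 10)
  pz <- simulate_coverage_profile(100, 0, 10, noise_cv = 0.2, seed = 1)
  expect_true(all(pz$depth == 0))
  pn <- simulate_coverage_profile(5000, 7, 10, noise_cv = 0.1, seed = 5)
  expect_equal(mean(pn$depth), 70, tolerance = 0.02)
  expect_equal(sd(pn$depth) / mean(pn$depth), 0.1, tolerance = 0.1)
})

test_that("hit-table scenarios have the structure their names promise", {
  known <- simulate_hit_table("known_single", seed = 1)
  expect_equal(sum(known$is_te_subject), 1L)
  msf <- simulate_hit_table("multi_one_superfamily", seed = 1)
  expect_gte(nrow(msf), 2L)
  expect_equal(length(unique(msf$subject_superfamily)), 1L)
  mor <- simulate_hit_table("multi_one_order", seed = 1)
  expect_equal(length(unique(mor$subject_order)), 1L)
  expect_gt(length(unique(mor$subject_superfamily)), 1L)
  gl <- simulate_hit_table("gene_like", seed = 1)
  expect_false(any(gl$is_te_subject))
  expect_equal(gl$nr_subject_kind[which.min(gl$e_value)], "gene")
  expect_error(simulate_hit_table("nonsense"), "unknown scenario")
})

test_that("genome mosaics have disjoint truth intervals and the target N fraction", {
  mz <- simulate_genome_mosaic(genome_length = 3e5, n_insertions = 15,
                               n_gap_frac = 0.05, seed = 6)
  iv <- mz$te_intervals
  expect_true(all(iv$end > iv$start))
  if (nrow(iv) > 1)
    expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  n_obs <- sum(strsplit(mz$genome, "")[[1]] == "N")
  expect_equal(n_obs / 3e5, 0.05, tolerance = 0.02)
  expect_equal(nchar(mz$genome), 3e5)
  # zero insertions -> empty truth set
  mz0 <- simulate_genome_mosaic(genome_length = 1e4, n_insertions = 0,
                                n_gap_frac = 0, seed = 7)
  expect_equal(nrow(mz0$te_intervals), 0L)
  expect_error(simulate_genome_mosaic(genome_length = 1e3, n_insertions = 50,
                                      n_gap_frac = 0, seed = 8),
               "exceed")
})

test_that("ping-pong simulator only imposes U1 via start choice, never by editing", {
  reads <- simulate_pingpong_reads(n_pairs = 500, u1_freq = 1,
                                   background_frac = 0, seed = 21)
  cons <- attr(reads, "consensus")
  # every read sequence is an exact (reverse-complemented for minus strand)
  # substring of the consensus
  ok <- vapply(seq_len(nrow(reads)), function(i) {
    sub <- substr(cons, reads$start[i] + 1, reads$start[i] + reads$length[i])
    if (reads$strand[i] == "-")
      sub <- tetransfer:::.revcomp(sub)
    sub == reads$sequence[i]
  }, logical(1))
  expect_true(all(ok))
  sense <- reads[reads$strand == "+", ]
  expect_true(all(substr(sense$sequence, 1, 1) == "T"))
})

test_that("pure background reads produce no modal ping-pong offset", {
  z <- vapply(1:15, function(s) {
    r <- simulate_pingpong_reads(n_pairs = 1500, background_frac = 1, seed = s)
    overlap_spectrum(r)$z10
  }, numeric(1))
  expect_gte(mean(abs(z) < 3), 0.9)
})

test_that("without a U1 bias the responder 10A signal vanishes", {
  r <- simulate_pingpong_reads(n_pairs = 5000, u1_freq = 0.25,
                               background_frac = 0, seed = 31)
  pc <- positional_composition(r)
  a10 <- pc$antisense["A", "10"]
  others <- pc$antisense["A", colnames(pc$antisense) != "10"]
  # within 3 binomial SEs of the background A frequency
  se <- sqrt(0.25 * 0.75 / 5000)
  expect_lt(abs(a10 - mean(others, na.rm = TRUE)), 3 * se + 0.02)
})
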