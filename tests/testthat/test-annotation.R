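# Candidate decision tree, clustering, filters, copy number and densities.

test_that("the decision tree maps each hit structure to its class", {
  expect_equal(classify_candidate(simulate_hit_table("known_single", 1))$class,
               "known_family")
  expect_equal(classify_candidate(simulate_hit_table("known_single", 1))$subject,
               "Gypsy10_Dpse")
  expect_equal(classify_candidate(simulate_hit_table("multi_one_superfamily", 1))$class,
               "novel_in_superfamily")
  expect_equal(classify_candidate(simulate_hit_table("multi_one_order", 1))$class,
               "novel_in_order")
  expect_equal(classify_candidate(simulate_hit_table("multi_one_order", 1))$subject,
               "LTR")
  expect_equal(classify_candidate(simulate_hit_table("gene_like", 1))$class,
               "discarded_gene_like")
  expect_equal(classify_candidate(simulate_hit_table("orphan", 1))$class,
               "unknown_retained")
})

test_that("classification is total, deterministic and row-order invariant", {
  set.seed(71)
  for (scen in c("known_single", "multi_one_superfamily", "multi_one_order",
                 "gene_like", "orphan")) {
    hits <- simulate_hit_table(scen, seed = 5)
    ref <- classify_candidate(hits)$class
    for (rep in 1:5) {
      shuffled <- hits[sample(nrow(hits)), , drop = FALSE]
      expect_equal(classify_candidate(shuffled)$class, ref)
    }
  }
  empty <- simulate_hit_table("known_single", 1)[0, ]
  expect_equal(classify_candidate(empty)$class, "unknown_retained")
})

test_that("the e-value threshold gates hits before classification", {
  hits <- simulate_hit_table("known_single", 1)
  hits$e_value <- 1e-5       # above the 1e-8 default cutoff
  expect_equal(classify_candidate(hits)$class, "unknown_retained")
  expect_equal(classify_candidate(hits, max_evalue = 1e-4)$class,
               "known_family")
})

test_that("TE families with multiple orders fall through to unknown", {
  hits <- rbind(simulate_hit_table("known_single", 1),
                transform(simulate_hit_table("known_single", 2),
                          subject_family = "Jockey1", subject_superfamily = "Jockey",
                          subject_order = "LINE"))
  expect_equal(classify_candidate(hits)$class, "unknown_retained")
})

test_that("single-linkage clustering at >90% identity picks longest representatives", {
  s95 <- c(x = paste(rep("A", 100), collapse = ""),
           y = paste(c(rep("A", 95), rep("T", 5)), collapse = ""))
  cl <- cluster_families(s95)
  expect_equal(length(unique(cl$cluster)), 1L)
  s85 <- c(x = paste(rep("A", 100), collapse = ""),
           y = paste(c(rep("A", 85), rep("T", 15)), collapse = ""))
  expect_equal(length(unique(cluster_families(s85)$cluster)), 2L)
  # chain: a~b 0.92, b~c 0.92, a~c 0.85 -> one cluster (single linkage)
  idm <- matrix(c(1, 0.92, 0.85,
                  0.92, 1, 0.92,
                  0.85, 0.92, 1), 3, 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  chain <- cluster_families(identity = idm)
  expect_equal(length(unique(chain$cluster)), 1L)
  # representative: longest member, ties by lexicographic id
  seqs <- c(b = paste(rep("A", 20), collapse = ""),
            a = paste(rep("A", 20), collapse = ""),
            c = paste(c(rep("A", 19), "T"), collapse = ""))
  cl3 <- cluster_families(seqs)   # c at 0.95 identity joins; lengths tie
  expect_equal(length(unique(cl3$cluster)), 1L)
  expect_true(all(cl3$representative == "a"))
  # boundary: exactly at the threshold is NOT the same family (strict >)
  id_eq <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
                  dimnames = list(c("p", "q"), c("p", "q")))
  expect_equal(length(unique(cluster_families(identity = id_eq)$cluster)), 2L)
})

test_that("hit-count filter is inclusive at the 25-hit boundary and monotone", {
  expect_true(hit_count_filter(c(30, 2, 0)))
  expect_false(hit_count_filter(c(24, 24, 24)))
  expect_true(hit_count_filter(25))
  expect_error(hit_count_filter(c(-1, 3)), "negative")
  set.seed(72)
  for (rep in 1:20) {
    counts <- sample(0:40, 4)
    if (hit_count_filter(counts)) expect_true(hit_count_filter(counts + 5))
  }
})

test_that("copy number is median depth over baseline, segment-averaged and scale-free", {
  pr <- list(te_id = "t", depth = rep(50, 200), baseline_median = 10)
  expect_equal(estimate_copy_number(pr), 5)
  seg <- list(te_id = "t", depth = c(rep(80, 100), rep(40, 300)),
              baseline_median = 10)
  expect_equal(estimate_copy_number(seg, segments = list(1:100, 101:400)), 6)
  # scale invariance
  pr2 <- list(te_id = "t", depth = pr$depth * 7, baseline_median = 70)
  expect_equal(estimate_copy_number(pr2), estimate_copy_number(pr))
  expect_error(estimate_copy_number(list(depth = 1:5, baseline_median = 0)),
               "baseline")
})

test_that("simulated coverage recovers the true copy number within 10%", {
  pr <- simulate_coverage_profile(3000, 7, 30, noise_cv = 0.1, seed = 12)
  est <- estimate_copy_number(pr)
  expect_lt(abs(est - 7) / 7, 0.10)
})

test_that("the coverage filter is inclusive at 80% and monotone in depth", {
  mk <- function(frac, n = 1000) list(
    depth = c(rep(25, round(frac * n)), rep(5, n - round(frac * n))),
    baseline_median = 10)
  expect_true(coverage_filter(mk(0.9)))
  expect_false(coverage_filter(mk(0.7)))
  expect_true(coverage_filter(mk(0.8)))
  p <- mk(0.7)
  expect_false(coverage_filter(p))
  p$depth <- p$depth + 100
  expect_true(coverage_filter(p))   # adding depth never flips keep -> discard
  expect_error(coverage_filter(list(depth = numeric(0), baseline_median = 1)),
               "empty")
})

test_that("insertion frequency filter keeps >= 50% inclusive", {
  calls <- data.frame(id = 1:4, frequency = c(0.5, 0.49, 1.0, 0))
  kept <- insertion_frequency_filter(calls)
  expect_equal(kept$id, c(1L, 3L))
  expect_equal(nrow(insertion_frequency_filter(calls[0, ])), 0L)
  expect_error(insertion_frequency_filter(data.frame(frequency = 1.2)),
               "frequencies")
})

test_that("window density applies the N correction exactly", {
  lens <- c(chr1 = 1e6L)
  te <- data.frame(chrom = "chr1", start = 0L, end = 100000L)
  wd <- window_density(te, lens, window = 1e6L, step = 1e6L)
  expect_equal(wd$density, 0.1)
  nn <- data.frame(chrom = "chr1", start = 500000L, end = 700000L)
  wd2 <- window_density(te, lens, nn, window = 1e6L, step = 1e6L)
  expect_equal(wd2$density, 1e5 / 8e5)
  # all-N window flagged undefined
  lens2 <- c(chr1 = 1000L)
  all_n <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  wd3 <- window_density(te[0, ], lens2, all_n, window = 1000L, step = 1000L)
  expect_true(is.na(wd3$density))
  expect_error(window_density(data.frame(chrom = "chr1", start = 0L,
                                         end = 2e6L), lens),
               "out of bounds")
  expect_error(window_density(data.frame(chrom = "chrX", start = 0L,
                                         end = 10L), lens),
               "unknown chromosome")
})

test_that("tiling windows conserve masked mass and match a per-base recount", {
  mz <- simulate_genome_mosaic(genome_length = 2e5, n_insertions = 12,
                               n_gap_frac = 0.04, seed = 31)
  lens <- c(chr1 = 2e5L)
  tiling <- window_density(mz$te_intervals, lens, mz$n_intervals,
                           window = 2e4L, step = 2e4L)
  expect_equal(sum(tiling$te_bases),
               sum(mz$te_intervals$end - mz$te_intervals$start))
  sliding <- window_density(mz$te_intervals, lens, mz$n_intervals,
                            window = 5e4L, step = 1e4L)
  for (i in sample(nrow(sliding), 6)) {
    o <- oracle_window_density(mz$te_intervals, mz$n_intervals,
                               sliding$start[i], sliding$end[i])
    expect_equal(sliding$te_bases[i], o$te_bases)
    expect_equal(sliding$n_bases[i], o$n_bases)
    expect_equal(sliding$density[i], o$density, tolerance = 1e-12)
  }
})

test_that("insertion density counts midpoints with the per-Mb N correction", {
  lens <- c(chr1 = 1e6L)
  ins0 <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0))
  d0 <- insertion_density(ins0, lens, window = 1e6L, step = 1e6L)
  expect_true(all(d0$n_insertions == 0))
  ins5 <- data.frame(chrom = "chr1", start = seq(1e5, 5e5, 1e5),
                     end = seq(1e5, 5e5, 1e5) + 100L)
  d5 <- insertion_density(ins5, lens, window = 1e6L, step = 1e6L)
  expect_equal(d5$per_mb, 5)
  nn <- data.frame(chrom = "chr1", start = 5e5L, end = 1e6L)
  dn <- insertion_density(ins5, lens, nn, window = 1e6L, step = 1e6L)
  expect_equal(dn$per_mb, 10)   # 5 / (1 Mb - 500 kb N) per Mb
})
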