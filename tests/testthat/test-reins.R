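test_that("catalog construction union-merges peaks across cell types", {
  peaks <- data.frame(tf_label = c("A", "A", "A", "B"),
                      cell_type = c("c1", "c2", "c1", "c1"),
                      chrom = "chr1",
                      start = c(10, 15, 100, 50),
                      end = c(20, 30, 110, 60), stringsAsFactors = FALSE)
  cat_ <- build_tf_catalog(peaks)
  expect_equal(cat_$tfs$A$start, c(10, 100))
  expect_equal(cat_$tfs$A$end, c(30, 110))
  expect_equal(nrow(cat_$tfs$B), 1L)
  # book-ended intervals coalesce under the half-open convention
  cat2 <- build_tf_catalog(data.frame(tf_label = "A", cell_type = "c1",
                                      chrom = "chr1", start = c(10, 20),
                                      end = c(20, 30)))
  expect_equal(cat2$tfs$A$start, 10)
  expect_equal(cat2$tfs$A$end, 30)
})

test_that("merged-catalog overlap counts equal per-CpG deduplicated counts
          on the raw multiset", {
  for (seed in 1:20) {
    inst <- random_overlap_instance(seed, max_cpgs = 300, max_tfs = 8,
                                    max_intervals = 30)
    merged <- catalog_from_list(inst$tfs)
    got <- overlap_counts(inst$positions, merged)
    want <- brute_overlap_counts(inst$positions, inst$tfs)
    expect_identical(unname(got), unname(want))
  }
})

test_that("overlap counting is half-open, deduplicated, zero-safe", {
  cat_ <- catalog_from_list(list(T1 = data.frame(chrom = "chr1",
                                                 start = c(10, 12),
                                                 end = c(20, 40))))
  hits <- overlap_counts(data.frame(chrom = "chr1", pos = c(15, 20, 40, 5)),
                         cat_)
  # pos 15 in both raw peaks counts once; 20 inside [10,40); 40 excluded
  expect_equal(unname(hits), 2L)
  expect_equal(unname(overlap_counts(
    data.frame(chrom = character(0), pos = numeric(0)), cat_)), 0L)
})

test_that("TFR is the percentage of the class overlapping the TF", {
  expect_equal(compute_tfr(2, 4), 50)
  expect_equal(compute_tfr(0, 478), 0)
  expect_equal(compute_tfr(478, 478), 100)
  expect_error(compute_tfr(0, 0), "empty CpG class")
  expect_error(compute_tfr(5, 4), "n_overlap")
  # exhaustive small counts against the defining formula
  for (tot in 1:20)
    expect_equal(compute_tfr(0:tot, tot), 100 * (0:tot) / tot)
})

test_that("RRT and log2(RRT) follow the ratio definition with a flagged
          pseudocount fallback", {
  r <- compute_rrt(2, 4, 1, 5)
  expect_equal(r$rrt, 2.5)
  expect_equal(r$log2_rrt, log(2.5) / log(2), tolerance = 1e-14)
  expect_false(r$pseudocount_used)
  r2 <- compute_rrt(3, 10, 6, 20)  # equal TFRs
  expect_equal(r2$rrt, 1)
  expect_equal(r2$log2_rrt, 0)
  r3 <- compute_rrt(0, 10, 5, 20)
  expect_true(r3$pseudocount_used)
  expect_equal(r3$rrt, (0.5 / 10) / (5.5 / 20))
  expect_true(is.finite(r3$log2_rrt))
})

test_that("per-TF Fisher test is the two-sided exact contingency p", {
  sig <- tf_significance(data.frame(n_hypo_overlap = 3, n_hypo_total = 4,
                                    n_hyper_overlap = 1, n_hyper_total = 4))
  expect_equal(sig$fisher_p, 34 / 70, tolerance = 1e-12)
  sig2 <- tf_significance(data.frame(n_hypo_overlap = c(5, 2),
                                     n_hypo_total = c(12, 9),
                                     n_hyper_overlap = c(5, 2),
                                     n_hyper_total = c(12, 9)))
  expect_equal(sig2$fisher_p, c(1, 1))
  set.seed(8)
  counts <- data.frame(n_hypo_overlap = sample(0:20, 30, TRUE),
                       n_hypo_total = 25, n_hyper_overlap = sample(0:15, 30,
                                                                   TRUE),
                       n_hyper_total = 18)
  sig3 <- tf_significance(counts)
  expect_true(all(sig3$adj_p >= sig3$fisher_p - 1e-15))
})

test_that("ranking is by log2(RRT) descending with documented tie-breaks", {
  rep_ <- data.frame(tf_label = c("X", "Y", "Z", "W"),
                     log2_rrt = c(0, 1, -3, 0),
                     fisher_p = c(0.2, 0.5, 0.9, 0.01))
  out <- rank_tfs(rep_)
  expect_equal(out$tf_label, c("Y", "W", "X", "Z"))
  expect_equal(out$rank, 1:4)
})

test_that("exchanging the hypo and hyper sets negates log2(RRT) and
          reverses the ranking", {
  set.seed(9)
  for (i in 1:20) {
    n_tf <- 6
    counts <- data.frame(
      n_hypo_overlap = sample(1:30, n_tf), n_hypo_total = 40,
      n_hyper_overlap = sample(1:20, n_tf), n_hyper_total = 25)
    fwd <- compute_rrt(counts$n_hypo_overlap, counts$n_hypo_total,
                       counts$n_hyper_overlap, counts$n_hyper_total)
    rev_ <- compute_rrt(counts$n_hyper_overlap, counts$n_hyper_total,
                        counts$n_hypo_overlap, counts$n_hypo_total)
    expect_equal(rev_$log2_rrt, -fwd$log2_rrt, tolerance = 1e-12)
    labs <- sprintf("TF%02d", seq_len(n_tf))
    p <- tf_significance(counts)$fisher_p
    r1 <- rank_tfs(data.frame(tf_label = labs, log2_rrt = fwd$log2_rrt,
                              fisher_p = p))
    r2 <- rank_tfs(data.frame(tf_label = labs, log2_rrt = rev_$log2_rrt,
                              fisher_p = p))
    if (!anyDuplicated(fwd$log2_rrt))
      expect_equal(r1$tf_label, rev(r2$tf_label))
  }
})

test_that("TFR, RRT and the Fisher odds ratio are invariant under
          duplicating every CpG membership", {
  counts <- data.frame(n_hypo_overlap = 7, n_hypo_total = 40,
                       n_hyper_overlap = 3, n_hyper_total = 25)
  single <- compute_rrt(counts$n_hypo_overlap, counts$n_hypo_total,
                        counts$n_hyper_overlap, counts$n_hyper_total)
  doubled <- compute_rrt(2 * counts$n_hypo_overlap, 2 * counts$n_hypo_total,
                         2 * counts$n_hyper_overlap,
                         2 * counts$n_hyper_total)
  expect_equal(doubled$rrt, single$rrt)
  expect_equal(compute_tfr(14, 80), compute_tfr(7, 40))
})

test_that("the full report equals a from-scratch brute-force recomputation", {
  sim <- simulate_all(preset_config("tiny", seed = 10))
  d <- suppressMessages(diff_methylation(sim$beta, sim$sample_sheet))
  sets <- diff_sets(d)
  cat_ <- build_tf_catalog(sim$tf_peaks)
  rep_ <- reins_report(d, sim$manifest, cat_)

  pos_of <- function(ids) {
    i <- match(ids, sim$manifest$probe_id)
    data.frame(chrom = sim$manifest$chrom[i], pos = sim$manifest$pos[i])
  }
  raw <- split(sim$tf_peaks[c("chrom", "start", "end")],
               sim$tf_peaks$tf_label)
  bho <- brute_overlap_counts(pos_of(sets$hypo), raw)
  bhr <- brute_overlap_counts(pos_of(sets$hyper), raw)
  i <- match(rep_$tf_label, names(raw))
  expect_equal(rep_$n_hypo_overlap, unname(bho[i]))
  expect_equal(rep_$n_hyper_overlap, unname(bhr[i]))
  expect_equal(rep_$tfr_hypo, 100 * unname(bho[i]) / length(sets$hypo))
  expect_equal(rep_$tfr_hyper, 100 * unname(bhr[i]) / length(sets$hyper))
  no_pseudo <- !rep_$pseudocount_used
  expect_equal(rep_$rrt[no_pseudo],
               (rep_$tfr_hypo / rep_$tfr_hyper)[no_pseudo])
})

test_that("multi-signature TFR reduces to the single-signature values and
          flags empty classes", {
  sim <- simulate_all(preset_config("tiny", seed = 12))
  d <- suppressMessages(diff_methylation(sim$beta, sim$sample_sheet))
  sets <- diff_sets(d)
  cat_ <- build_tf_catalog(sim$tf_peaks)
  rep_ <- reins_report(d, sim$manifest, cat_)
  pos_of <- function(ids) {
    i <- match(ids, sim$manifest$probe_id)
    data.frame(chrom = sim$manifest$chrom[i], pos = sim$manifest$pos[i])
  }
  sig <- list(osteo = list(hypo = pos_of(sets$hypo),
                           hyper = pos_of(sets$hyper)),
              copy = list(hypo = pos_of(sets$hypo),
                          hyper = pos_of(sets$hyper)),
              broken = list(hypo = pos_of(sets$hypo),
                            hyper = pos_of(character(0))))
  tf <- "TFP01"
  ms <- multi_signature_tfr(sig, cat_, tf)
  expect_equal(ms$tfr_hypo[1], rep_$tfr_hypo[rep_$tf_label == tf])
  expect_equal(ms$tfr_hyper[1], rep_$tfr_hyper[rep_$tf_label == tf])
  expect_equal(ms[1, -1], ms[2, -1], ignore_attr = TRUE)
  expect_equal(ms$flag[3], "empty_class")
  expect_true(is.na(ms$tfr_hypo[3]))
  expect_error(multi_signature_tfr(sig, cat_, "NOPE"), "not in catalog")
})

test_that("a TF whose peaks preferentially cover one signature's hypo CpGs
          stands out only there", {
  specs <- default_tf_specs(n_decoys = 2)
  specs$hypo_coverage_prob[1] <- 0.6   # planted TF now hypo-biased
  specs$hyper_coverage_prob[1] <- 0.15
  sim1 <- simulate_all(sim_config(seed = 13, n_probes = 3000L,
                                  tf_specs = specs, state_bias = NULL))
  set.seed(99)
  gt_pos <- function(sim, ids) {
    i <- match(ids, sim$manifest$probe_id)
    data.frame(chrom = sim$manifest$chrom[i], pos = sim$manifest$pos[i])
  }
  cat1 <- build_tf_catalog(sim1$tf_peaks)
  sigs <- list(
    planted = list(hypo = gt_pos(sim1, sim1$ground_truth$planted_hypo),
                   hyper = gt_pos(sim1, sim1$ground_truth$planted_hyper)),
    other = list(hypo = gt_pos(sim1, sample(sim1$manifest$probe_id, 100)),
                 hyper = gt_pos(sim1, sample(sim1$manifest$probe_id, 100))))
  ms <- multi_signature_tfr(sigs, cat1, "TFP01")
  expect_gt(ms$tfr_hypo[1], ms$tfr_hyper[1] + 20)
  expect_lt(abs(ms$tfr_hypo[2] - ms$tfr_hyper[2]), 15)
})
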