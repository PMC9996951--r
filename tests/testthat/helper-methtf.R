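# Shared fixtures and independent oracles (brute force / enumeration),
# deliberately written without reusing the package's overlap or testing
# machinery.

# O(n * m) all-pairs point-in-interval scan (half-open convention).
brute_point_hits <- function(chrom, pos, intervals) {
  vapply(seq_along(pos), function(i)
    any(intervals$chrom == chrom[i] &
          intervals$start <= pos[i] & pos[i] < intervals$end),
    logical(1))
}

brute_overlap_counts <- function(positions, tf_intervals) {
  vapply(tf_intervals, function(iv)
    sum(brute_point_hits(positions$chrom, positions$pos, iv)), integer(1))
}

# Random CpG-set / TF-catalog instance for overlap equivalence checks.
random_overlap_instance <- function(seed, max_cpgs = 2000, max_tfs = 50,
                                    max_intervals = 100) {
  set.seed(seed)
  chroms <- c("chr1", "chr2")
  n_cpg <- sample.int(max_cpgs, 1)
  n_tf <- sample.int(max_tfs, 1)
  positions <- data.frame(chrom = sample(chroms, n_cpg, replace = TRUE),
                          pos = sample.int(10000, n_cpg, replace = TRUE) - 1,
                          stringsAsFactors = FALSE)
  tfs <- lapply(seq_len(n_tf), function(k) {
    m <- sample.int(max_intervals, 1)
    s <- sample.int(10000, m, replace = TRUE) - 1
    w <- sample.int(60, m, replace = TRUE)
    data.frame(chrom = sample(chroms, m, replace = TRUE),
               start = s, end = s + w, stringsAsFactors = FALSE)
  })
  names(tfs) <- sprintf("TF%03d", seq_len(n_tf))
  list(positions = positions, tfs = tfs)
}

# Interval list -> TFBindingCatalog via the package's public constructor.
catalog_from_list <- function(tfs) {
  flat <- do.call(rbind, lapply(names(tfs), function(nm)
    cbind(tf_label = nm, tfs[[nm]], stringsAsFactors = FALSE)))
  build_tf_catalog(flat)
}

# Two-sided Fisher exact p for a 2x2 table by full enumeration of the
# hypergeometric pmf over the support, independent of fisher.test.
fisher_p_enumeration <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  pmf <- dhyper(support, r1, r2, c1)
  sum(pmf[pmf <= pmf[support == a] * (1 + 1e-7)])
}

# Minimal probe manifest from parallel vectors.
make_manifest <- function(probe_id, chrom, pos,
                          island_relation = "OpenSea",
                          gene = NA_character_, utr5 = FALSE) {
  n <- length(probe_id)
  mani <- data.frame(probe_id = probe_id, chrom = rep_len(chrom, n),
                     pos = pos,
                     island_relation = rep_len(island_relation, n),
                     stringsAsFactors = FALSE)
  gene <- rep_len(gene, n); utr5 <- rep_len(utr5, n)
  mani$gene_symbols <- lapply(seq_len(n), function(i)
    if (is.na(gene[i])) character(0) else gene[i])
  mani$region_flags <- lapply(seq_len(n), function(i)
    if (utr5[i]) "FiveUTR" else character(0))
  class(mani) <- c("ProbeManifest", "data.frame")
  mani
}

# Classified DiffMethTable from explicit hypo/hyper id sets over a probe
# universe (for context/reins tests that do not need real test statistics).
make_diff_table <- function(all_ids, hypo_ids, hyper_ids) {
  cls <- rep("ns", length(all_ids))
  cls[all_ids %in% hypo_ids] <- "hypo"
  cls[all_ids %in% hyper_ids] <- "hyper"
  d <- data.frame(probe_id = all_ids,
                  delta_m = ifelse(cls == "hypo", -1,
                                   ifelse(cls == "hyper", 1, 0)),
                  p = 1, adj_p = 1, class = cls, stringsAsFactors = FALSE)
  d$p[cls != "ns"] <- 1e-4
  d$adj_p[cls != "ns"] <- 1e-3
  class(d) <- c("DiffMethTable", "data.frame")
  d
}

# Paired two-condition sample sheet for n donors.
make_sheet <- function(n_donors = 3) {
  donors <- sprintf("d%d", seq_len(n_donors))
  data.frame(sample_id = c(paste0("ref_", donors), paste0("trt_", donors)),
             condition = rep(c("reference", "treatment"), each = n_donors),
             donor = rep(donors, 2), stringsAsFactors = FALSE)
}
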