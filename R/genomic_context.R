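# Where do differential CpGs fall? Enrichment of hypo-/hyper-methylated
# CpGs across CpG-island neighbourhood categories and chromatin-state
# segmentations, plus a per-state test of methylation shift between the two
# conditions.
#
# Normalisation follows the array-as-background convention: observed
# percentages are computed within each significance group, expected
# percentages from all probes on the supplied manifest.

#' Validate a chromatin-state segmentation
#'
#' Segmentation intervals must be non-overlapping within a chromosome (the
#' half-open convention makes adjacent segments sharing a boundary legal).
#' Violations are a hard error listing the offending intervals.
#'
#' @param seg Interval `data.frame` (`chrom`, `start`, `end`, `label`).
#' @return The segmentation, invisibly.
#' @export
validate_segmentation <- function(seg) {
  validate_intervals(seg, where = "segmentation")
  for (ch in unique(seg$chrom)) {
    sub <- seg[seg$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    bad <- which(sub$start[-1L] < sub$end[-nrow(sub)])
    if (length(bad)) {
      off <- paste0(ch, ":[", sub$start[bad], ",", sub$end[bad], ") overlaps [",
                    sub$start[bad + 1L], ",", sub$end[bad + 1L], ")")
      stop("segmentation: overlapping intervals on ", ch, ": ",
           paste(utils::head(off, 5L), collapse = "; "))
    }
  }
  invisible(seg)
}

# Shared engine: counts, group-normalised percentages, observed/expected
# ratios and per-category Fisher tests, for an arbitrary per-probe category
# assignment. Background = all probes on the manifest. The Fisher 2x2 for a
# category contrasts the significance group against the non-significant rest
# of the background: [[sig_in, sig_out], [rest_in, rest_out]].
context_enrichment_table <- function(category, probe_id, hypo_ids, hyper_ids,
                                     levels) {
  category <- factor(category, levels = levels)
  n_bg <- as.integer(table(category))
  in_hypo <- probe_id %in% hypo_ids
  in_hyper <- probe_id %in% hyper_ids
  n_hypo <- as.integer(table(category[in_hypo]))
  n_hyper <- as.integer(table(category[in_hyper]))
  tot_bg <- sum(n_bg)
  tot_hypo <- sum(n_hypo)
  tot_hyper <- sum(n_hyper)
  expected_pct <- 100 * n_bg / tot_bg
  pct_hypo <- if (tot_hypo) 100 * n_hypo / tot_hypo else rep(NA_real_,
                                                             length(n_bg))
  pct_hyper <- if (tot_hyper) 100 * n_hyper / tot_hyper else rep(NA_real_,
                                                                 length(n_bg))
  fisher_one <- function(n_sig, tot_sig) {
    vapply(seq_along(n_bg), function(i) {
      if (tot_sig == 0) return(NA_real_)
      rest_in <- n_bg[i] - n_sig[i]
      rest_out <- (tot_bg - n_bg[i]) - (tot_sig - n_sig[i])
      tab <- matrix(c(n_sig[i], tot_sig - n_sig[i], rest_in, rest_out),
                    nrow = 2L, byrow = TRUE)
      # fisher.test can exceed 1 by a rounding ulp
      min(stats::fisher.test(tab)$p.value, 1)
    }, numeric(1))
  }
  p_hypo <- fisher_one(n_hypo, tot_hypo)
  p_hyper <- fisher_one(n_hyper, tot_hyper)
  adj <- rep(NA_real_, 2L * length(n_bg))
  pall <- c(p_hypo, p_hyper)
  ok <- !is.na(pall)
  adj[ok] <- bh_adjust(pall[ok])
  out <- data.frame(
    category = levels,
    n_background = n_bg,
    n_hypo = n_hypo,
    n_hyper = n_hyper,
    expected_pct = expected_pct,
    pct_hypo = pct_hypo,
    pct_hyper = pct_hyper,
    ratio_hypo = ifelse(expected_pct > 0, pct_hypo / expected_pct, NA_real_),
    ratio_hyper = ifelse(expected_pct > 0, pct_hyper / expected_pct,
                         NA_real_),
    fisher_p_hypo = p_hypo,
    fisher_p_hyper = p_hyper,
    adj_p_hypo = adj[seq_along(n_bg)],
    adj_p_hyper = adj[length(n_bg) + seq_along(n_bg)],
    stringsAsFactors = FALSE)
  class(out) <- c("ContextEnrichment", "data.frame")
  out
}

check_probes_in_manifest <- function(ids, manifest) {
  miss <- setdiff(ids, manifest$probe_id)
  if (length(miss))
    stop("significant probe(s) missing from manifest: ",
         paste(utils::head(miss, 5L), collapse = ", "))
}

#' CpG-island context distribution of differential CpGs
#'
#' Distributes hypo- and hyper-methylated CpGs over the six island-relation
#' categories (island, north/south shore, north/south shelf, open sea).
#' Percentages are normalised within each significance group; the expected
#' distribution comes from all probes on the manifest (the array is the
#' background, not the genome). Each category gets a two-sided Fisher exact
#' test of the group against the non-significant remainder of the array,
#' with BH adjustment across the 6 x 2 tests.
#'
#' @param diff Classified `DiffMethTable`.
#' @param manifest `ProbeManifest` covering every significant probe.
#' @return A `ContextEnrichment` `data.frame`, one row per category.
#' @export
island_context_distribution <- function(diff, manifest) {
  sets <- diff_sets(diff)
  check_probes_in_manifest(c(sets$hypo, sets$hyper), manifest)
  context_enrichment_table(manifest$island_relation, manifest$probe_id,
                           sets$hypo, sets$hyper,
                           levels = ISLAND_CATEGORIES)
}

#' Chromatin-state enrichment of differential CpGs
#'
#' Same statistics as [island_context_distribution()], keyed by the state
#' label of the segmentation interval containing each probe. Probes outside
#' every segment are assigned to the category `"Unassigned"`.
#'
#' @param diff Classified `DiffMethTable`.
#' @param seg Segmentation intervals (BED4-style; validated non-overlapping).
#' @param manifest `ProbeManifest`.
#' @return A `ContextEnrichment` `data.frame`, one row per state.
#' @export
state_enrichment <- function(diff, seg, manifest) {
  validate_segmentation(seg)
  sets <- diff_sets(diff)
  check_probes_in_manifest(c(sets$hypo, sets$hyper), manifest)
  state <- point_interval_label(manifest$chrom, manifest$pos, seg)
  state[is.na(state)] <- "Unassigned"
  levels <- c(sort(unique(seg$label)),
              if (any(state == "Unassigned")) "Unassigned")
  context_enrichment_table(state, manifest$probe_id, sets$hypo, sets$hyper,
                           levels = levels)
}

#' Per-state methylation shift between conditions
#'
#' For each chromatin state, compares per-probe mean beta between the two
#' conditions over the probes assigned to that state, restricted to probes
#' whose absolute difference of condition means is at least `min_diff`
#' (default 0.001, i.e. a 0.1% methylation difference). The default test is
#' the two-sided Wilcoxon signed-rank over the probe-level pairs of
#' condition means; a paired t-test is available.
#'
#' @param beta Beta-value matrix, probes x samples.
#' @param sheet Sample sheet.
#' @param seg Segmentation intervals.
#' @param manifest `ProbeManifest` for probe coordinates.
#' @param min_diff Minimum absolute difference of per-probe condition mean
#'   beta for a probe to enter the test (default `0.001`).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return A `data.frame` with one row per state: `state`, `n_probes`
#'   (qualifying), `mean_beta_reference`, `mean_beta_treatment`,
#'   `delta_beta`, `p`. States with fewer than 10 qualifying probes are
#'   reported as `NA` with a warning.
#' @export
state_methylation_shift <- function(beta, sheet, seg, manifest,
                                    min_diff = 0.001,
                                    test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  validate_segmentation(seg)
  validate_sample_sheet(sheet)
  common <- intersect(rownames(beta), manifest$probe_id)
  mani <- manifest[match(common, manifest$probe_id), , drop = FALSE]
  b <- beta[common, , drop = FALSE]
  ref_ids <- sheet$sample_id[sheet$condition == "reference"]
  trt_ids <- sheet$sample_id[sheet$condition == "treatment"]
  mref <- rowMeans(b[, ref_ids, drop = FALSE], na.rm = TRUE)
  mtrt <- rowMeans(b[, trt_ids, drop = FALSE], na.rm = TRUE)
  delta <- mtrt - mref
  state <- point_interval_label(mani$chrom, mani$pos, seg)
  states <- sort(unique(seg$label))
  rows <- lapply(states, function(s) {
    in_state <- which(!is.na(state) & state == s)
    q <- in_state[abs(delta[in_state]) >= min_diff &
                    is.finite(delta[in_state])]
    if (length(q) < 10L) {
      warning("state ", s, ": only ", length(q),
              " qualifying probes (< 10); reported as NA", call. = FALSE)
      return(data.frame(state = s, n_probes = length(q),
                        mean_beta_reference = NA_real_,
                        mean_beta_treatment = NA_real_,
                        delta_beta = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    p <- if (test == "wilcoxon")
      stats::wilcox.test(mtrt[q], mref[q], paired = TRUE,
                         exact = FALSE)$p.value
    else
      stats::t.test(mtrt[q], mref[q], paired = TRUE)$p.value
    data.frame(state = s, n_probes = length(q),
               mean_beta_reference = mean(mref[q]),
               mean_beta_treatment = mean(mtrt[q]),
               delta_beta = mean(delta[q]), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
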