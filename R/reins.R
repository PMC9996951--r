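# TFR/RRT: rank transcription factors by the hypo- vs hyper-methylation
# bias of their binding sites.
#
# For a TF with binding-site catalog B and CpG classes Ho (hypo) and Hr
# (hyper):
#   TFR_hypo  = 100 * |{c in Ho : c overlaps B}| / |Ho|
#   TFR_hyper = 100 * |{c in Hr : c overlaps B}| / |Hr|
#   RRT       = TFR_hypo / TFR_hyper
# log2(RRT) > 0 marks a TF whose sites are preferentially de-methylated,
# < 0 preferentially methylated. A CpG inside several peaks of one TF
# counts once for that TF; TFs are counted independently.

#' Build a TF binding-site catalog
#'
#' Aggregates peak files per TF label across cell types by union: all
#' intervals for one TF are pooled and overlapping or book-ended intervals
#' are coalesced. Provenance (source file, cell type) is retained per TF.
#'
#' @param peaks Either a `data.frame` with columns `tf_label`, `cell_type`,
#'   `path` naming peak files to read, or one with columns `tf_label`,
#'   `cell_type`, `chrom`, `start`, `end` giving intervals directly.
#' @param dialect BED dialect passed to [read_bed()] when reading files.
#' @return A `TFBindingCatalog`: list with `tfs` (named list of merged,
#'   sorted interval `data.frame`s) and `provenance`.
#' @export
build_tf_catalog <- function(peaks, dialect = "narrowPeak") {
  stopifnot(is.data.frame(peaks), all(c("tf_label") %in% names(peaks)))
  if ("path" %in% names(peaks)) {
    recs <- lapply(seq_len(nrow(peaks)), function(i) {
      iv <- read_bed(peaks$path[i], dialect = dialect)
      if (!nrow(iv)) return(NULL)
      cbind(tf_label = peaks$tf_label[i], cell_type = peaks$cell_type[i],
            iv[c("chrom", "start", "end")], stringsAsFactors = FALSE)
    })
    flat <- do.call(rbind, recs)
    prov <- peaks[c("tf_label", "cell_type", "path")]
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
    if (!"cell_type" %in% names(peaks)) peaks$cell_type <- "unspecified"
    flat <- peaks[c("tf_label", "cell_type", "chrom", "start", "end")]
    prov <- unique(peaks[c("tf_label", "cell_type")])
    prov$path <- NA_character_
  }
  if (is.null(flat))
    flat <- data.frame(tf_label = character(0), cell_type = character(0),
                       chrom = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
  labels <- unique(peaks$tf_label)
  tfs <- list()
  for (tf in labels) {
    sub <- flat[flat$tf_label == tf, , drop = FALSE]
    if (!nrow(sub)) {
      warning("TF ", tf, ": no intervals; omitted from catalog",
              call. = FALSE)
      next
    }
    tfs[[tf]] <- merge_intervals(sub[c("chrom", "start", "end")])
  }
  structure(list(tfs = tfs, provenance = prov), class = "TFBindingCatalog")
}

# Union-merge: sort by (chrom, start) and coalesce overlapping/adjacent
# intervals, per chromosome.
merge_intervals <- function(iv) {
  validate_intervals(iv)
  out <- lapply(split(iv, iv$chrom), function(sub) {
    r <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1L,
                                          end = sub$end))
    data.frame(chrom = sub$chrom[1L],
               start = as.numeric(IRanges::start(r)) - 1,
               end = as.numeric(IRanges::end(r)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

#' @export
print.TFBindingCatalog <- function(x, ...) {
  cat("TFBindingCatalog:", length(x$tfs), "TFs,",
      sum(vapply(x$tfs, nrow, 0L)), "merged intervals\n")
  invisible(x)
}

#' Count CpGs overlapping each TF's binding sites
#'
#' A CpG (single-base point, 0-based) inside one or more intervals of a TF
#' counts once for that TF; counting is independent across TFs. Matches a
#' brute-force all-pairs scan exactly.
#'
#' @param positions `data.frame` with columns `chrom`, `pos` (0-based
#'   points).
#' @param catalog A `TFBindingCatalog`.
#' @return Named integer vector of per-TF counts.
#' @export
overlap_counts <- function(positions, catalog) {
  stopifnot(inherits(catalog, "TFBindingCatalog"))
  vapply(catalog$tfs, function(iv)
    sum(point_in_intervals(positions$chrom, positions$pos, iv)),
    integer(1))
}

#' TF relevance (TFR) percentage
#'
#' `100 * n_overlap / n_total`: the percentage of a CpG class (hypo- or
#' hyper-methylated) falling inside a TF's binding sites.
#'
#' @param n_overlap Count of CpGs of the class overlapping the TF.
#' @param n_total Total count of CpGs in the class (must be >= 1).
#' @return Percentage in `[0, 100]`. Vectorised.
#' @export
compute_tfr <- function(n_overlap, n_total) {
  if (any(n_total == 0)) stop("empty CpG class")
  if (any(n_overlap < 0 | n_overlap > n_total))
    stop("need 0 <= n_overlap <= n_total")
  100 * n_overlap / n_total
}

#' Relative relevance of a TF (RRT)
#'
#' `RRT = TFR_hypo / TFR_hyper`, with `log2(RRT)` as the reported
#' enrichment score. When either overlap count is zero, both TFRs are
#' recomputed with a Haldane-style +0.5 on both overlap counts (totals
#' unchanged) so the ratio stays finite and rankable; the pseudocount is
#' flagged in the output.
#'
#' @param n_hypo_overlap,n_hypo_total,n_hyper_overlap,n_hyper_total The
#'   four underlying counts (vectorised over TFs).
#' @return `data.frame` with `rrt`, `log2_rrt`, `pseudocount_used`.
#' @export
compute_rrt <- function(n_hypo_overlap, n_hypo_total,
                        n_hyper_overlap, n_hyper_total) {
  tfr_ho <- compute_tfr(n_hypo_overlap, n_hypo_total)
  tfr_hr <- compute_tfr(n_hyper_overlap, n_hyper_total)
  pseudo <- n_hypo_overlap == 0 | n_hyper_overlap == 0
  num <- ifelse(pseudo, 100 * (n_hypo_overlap + 0.5) / n_hypo_total,
                tfr_ho)
  den <- ifelse(pseudo, 100 * (n_hyper_overlap + 0.5) / n_hyper_total,
                tfr_hr)
  # log2 as a difference of logs so that exchanging the classes negates
  # log2_rrt exactly, bit for bit
  data.frame(rrt = num / den, log2_rrt = log2(num) - log2(den),
             pseudocount_used = pseudo)
}

#' Per-TF Fisher significance of the hypo/hyper overlap imbalance
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[n_hypo_overlap, n_hypo_total - n_hypo_overlap],
#'   [n_hyper_overlap, n_hyper_total - n_hyper_overlap]]`,
#' BH-adjusted across all TFs in the catalog.
#'
#' @param counts `data.frame` with columns `n_hypo_overlap`, `n_hypo_total`,
#'   `n_hyper_overlap`, `n_hyper_total` (one row per TF).
#' @return `data.frame` with `fisher_p`, `adj_p`.
#' @export
tf_significance <- function(counts) {
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tab <- matrix(c(counts$n_hypo_overlap[i],
                    counts$n_hypo_total[i] - counts$n_hypo_overlap[i],
                    counts$n_hyper_overlap[i],
                    counts$n_hyper_total[i] - counts$n_hyper_overlap[i]),
                  nrow = 2L, byrow = TRUE)
    min(stats::fisher.test(tab)$p.value, 1)
  }, numeric(1))
  data.frame(fisher_p = p, adj_p = bh_adjust(p))
}

#' Rank TFs by their methylation bias
#'
#' Sorts a TFR report by `log2_rrt` descending (most de-methylation-biased
#' first); ties are broken by `fisher_p` ascending, then `tf_label`
#' lexicographically. Adds a `rank` column.
#'
#' @param report A `TFRReport` `data.frame`.
#' @return The report sorted, with `rank` added.
#' @export
rank_tfs <- function(report) {
  o <- order(-report$log2_rrt, report$fisher_p, report$tf_label)
  report <- report[o, , drop = FALSE]
  report$rank <- seq_len(nrow(report))
  rownames(report) <- NULL
  report
}

#' Full TFR/RRT report for one differential-methylation signature
#'
#' Overlaps the hypo- and hyper-methylated CpG sets with every TF in the
#' catalog and assembles per-TF overlap counts, TFR percentages, RRT and
#' log2(RRT), two-sided Fisher p with BH adjustment across TFs, and rank.
#'
#' @param diff Classified `DiffMethTable` (or a list with `hypo`/`hyper`
#'   probe-id vectors).
#' @param manifest `ProbeManifest` providing probe coordinates.
#' @param catalog `TFBindingCatalog`.
#' @return A `TFRReport` `data.frame`, ranked, with columns `tf_label`,
#'   `n_hypo_overlap`, `n_hyper_overlap`, `tfr_hypo`, `tfr_hyper`, `rrt`,
#'   `log2_rrt`, `fisher_p`, `adj_p`, `pseudocount_used`, `rank`.
#' @export
reins_report <- function(diff, manifest, catalog) {
  sets <- if (is.data.frame(diff)) diff_sets(diff) else diff
  if (!length(sets$hypo) || !length(sets$hyper))
    stop("empty CpG class: both a hypo and a hyper set are required")
  check_probes_in_manifest(c(sets$hypo, sets$hyper), manifest)
  pos_of <- function(ids) {
    i <- match(ids, manifest$probe_id)
    data.frame(chrom = manifest$chrom[i], pos = manifest$pos[i],
               stringsAsFactors = FALSE)
  }
  n_ho <- overlap_counts(pos_of(sets$hypo), catalog)
  n_hr <- overlap_counts(pos_of(sets$hyper), catalog)
  counts <- data.frame(n_hypo_overlap = n_ho,
                       n_hypo_total = length(sets$hypo),
                       n_hyper_overlap = n_hr,
                       n_hyper_total = length(sets$hyper))
  rr <- compute_rrt(counts$n_hypo_overlap, counts$n_hypo_total,
                    counts$n_hyper_overlap, counts$n_hyper_total)
  sig <- tf_significance(counts)
  rep <- data.frame(tf_label = names(catalog$tfs),
                    n_hypo_overlap = n_ho,
                    n_hyper_overlap = n_hr,
                    tfr_hypo = compute_tfr(n_ho, length(sets$hypo)),
                    tfr_hyper = compute_tfr(n_hr, length(sets$hyper)),
                    rrt = rr$rrt,
                    log2_rrt = rr$log2_rrt,
                    fisher_p = sig$fisher_p,
                    adj_p = sig$adj_p,
                    pseudocount_used = rr$pseudocount_used,
                    stringsAsFactors = FALSE)
  rownames(rep) <- NULL
  rep <- rank_tfs(rep)
  attr(rep, "sort_key") <- "log2_rrt"
  class(rep) <- c("TFRReport", "data.frame")
  rep
}

#' TFR of one TF across several methylation signatures
#'
#' Computes `tfr_hypo` and `tfr_hyper` of a single TF for each of several
#' differential-methylation signatures (e.g. different tissues), the
#' multi-signature validation mode. A signature with an empty class is
#' flagged and reported as `NA`.
#'
#' @param signatures Named list; each element a list with `hypo` and
#'   `hyper` `data.frame`s of CpG positions (`chrom`, `pos`).
#' @param catalog `TFBindingCatalog`.
#' @param tf TF label present in the catalog.
#' @return `data.frame` with one row per signature: `signature`,
#'   `n_hypo`, `n_hyper`, `n_hypo_overlap`, `n_hyper_overlap`,
#'   `tfr_hypo`, `tfr_hyper`, `flag`.
#' @export
multi_signature_tfr <- function(signatures, catalog, tf) {
  if (!tf %in% names(catalog$tfs))
    stop("TF ", tf, " not in catalog")
  sub <- structure(list(tfs = catalog$tfs[tf],
                        provenance = catalog$provenance),
                   class = "TFBindingCatalog")
  rows <- lapply(names(signatures), function(nm) {
    sg <- signatures[[nm]]
    n_ho <- nrow(sg$hypo)
    n_hr <- nrow(sg$hyper)
    if (!n_ho || !n_hr)
      return(data.frame(signature = nm, n_hypo = n_ho, n_hyper = n_hr,
                        n_hypo_overlap = NA_integer_,
                        n_hyper_overlap = NA_integer_,
                        tfr_hypo = NA_real_, tfr_hyper = NA_real_,
                        flag = "empty_class", stringsAsFactors = FALSE))
    oh <- overlap_counts(sg$hypo, sub)[[1L]]
    or <- overlap_counts(sg$hyper, sub)[[1L]]
    data.frame(signature = nm, n_hypo = n_ho, n_hyper = n_hr,
               n_hypo_overlap = oh, n_hyper_overlap = or,
               tfr_hypo = compute_tfr(oh, n_ho),
               tfr_hyper = compute_tfr(or, n_hr),
               flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
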