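# Methylation-expression coupling: rank correlation between per-CpG
# methylation and the expression of the annotated gene, with optional
# restriction to 5'UTR CpGs and to robustly expressed genes, plus the
# Fisher test of hypo/hyper CpG association with RNAPII-interaction
# regions.

# All permutations of 1..n, one per row (n <= 9 in practice).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  prev <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(prev), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(prev) + seq_len(nrow(prev))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[prev], nrow(prev), n - 1L)
  }
  out
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of (average, for ties) ranks. The
#' p-value is exact for `n <= exact_max_n` with untied data, by full
#' enumeration of the permutation distribution of `|rho|`; otherwise the
#' standard large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df is used.
#' Incomplete pairs are dropped (pairwise-complete).
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @param exact_max_n Largest n for exact enumeration (default 9).
#' @return `list(rho, p, n, method)`; `rho` and `p` are `NA` when either
#'   vector is constant.
#' @export
spearman_cor <- function(x, y, exact_max_n = 9L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman_cor: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= exact_max_n && !ties) {
    perms <- all_permutations(n)
    cy <- ry - mean(ry)
    denom <- sqrt(sum((rx - mean(rx))^2) * sum(cy^2))
    rho_perm <- as.vector(matrix(rx[perms], nrow(perms), n) %*% cy) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, n = n, method = "exact_permutation"))
  }
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- min(1, max(2 * stats::pt(-abs(tt), df = n - 2),
                  .Machine$double.xmin))
  list(rho = rho, p = p, n = n, method = "t_approximation")
}

#' Correlate methylation of differential CpGs with gene expression
#'
#' Assembles (CpG, gene) pairs from the significant probes: `x` is the mean
#' M-value of the probe over the samples of `condition`, `y` the mean
#' expression of the annotated gene over the same samples. A CpG annotated
#' to several genes contributes one pair per gene; a gene with several
#' significant CpGs contributes one pair per CpG. With
#' `subset = "utr5_only"` only probes flagged `FiveUTR` are used. With
#' `expr_threshold_frac` set, only pairs whose gene mean expression exceeds
#' `frac * max(gene mean expression in the condition)` are kept (the
#' robust-expression filter; the maximum is over all genes on the
#' expression table). Inference is Spearman (or Pearson); a lowess smooth
#' (span 2/3) of the pairs is attached for plotting.
#'
#' @param diff Classified `DiffMethTable`.
#' @param m M-value matrix, probes x samples.
#' @param expr Expression matrix, genes x samples (same sample ids).
#' @param manifest `ProbeManifest` with `gene_symbols`/`region_flags`.
#' @param sheet Sample sheet.
#' @param condition `"treatment"` or `"reference"`.
#' @param subset `"all_significant"` or `"utr5_only"`.
#' @param expr_threshold_frac Optional fraction of the maximum gene mean
#'   expression (e.g. `1/3`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A `CorrelationResult` list: `rho`, `p`, `n`, `subset_tag`,
#'   `n_before_filter`, `n_removed_by_threshold`, `pairs` (`data.frame`),
#'   `lowess_curve`. When fewer than 3 pairs remain the result is `NA` with
#'   a warning.
#' @export
methylation_expression_correlation <- function(diff, m, expr, manifest,
                                               sheet,
                                               condition = c("treatment",
                                                             "reference"),
                                               subset = c("all_significant",
                                                          "utr5_only"),
                                               expr_threshold_frac = NULL,
                                               method = c("spearman",
                                                          "pearson")) {
  condition <- match.arg(condition)
  subset <- match.arg(subset)
  method <- match.arg(method)
  cond_samples <- sheet$sample_id[sheet$condition == condition]
  if (!length(cond_samples)) stop("no samples for condition ", condition)
  if (!all(cond_samples %in% colnames(m)) ||
      !all(cond_samples %in% colnames(expr)))
    stop("condition samples missing from methylation or expression matrix")
  sig <- diff$probe_id[diff$class != "ns"]
  mi <- match(sig, manifest$probe_id)
  if (anyNA(mi))
    stop("significant probe(s) missing from manifest: ",
         paste(utils::head(sig[is.na(mi)], 5L), collapse = ", "))
  if (subset == "utr5_only") {
    keep <- vapply(manifest$region_flags[mi],
                   function(f) "FiveUTR" %in% f, logical(1))
    sig <- sig[keep]; mi <- mi[keep]
  }
  genes <- manifest$gene_symbols[mi]
  pairs <- data.frame(
    probe_id = rep(sig, lengths(genes)),
    gene = unlist(genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  pairs <- pairs[pairs$gene %in% rownames(expr) &
                   pairs$probe_id %in% rownames(m), , drop = FALSE]
  na_result <- function(n_before, n_removed) {
    warning("fewer than 3 (CpG, gene) pairs; correlation reported as NA",
            call. = FALSE)
    structure(list(rho = NA_real_, p = NA_real_, n = nrow(pairs),
                   subset_tag = subset, n_before_filter = n_before,
                   n_removed_by_threshold = n_removed,
                   pairs = pairs, lowess_curve = NULL, method = method),
              class = "CorrelationResult")
  }
  gene_means <- rowMeans(expr[, cond_samples, drop = FALSE], na.rm = TRUE)
  n_before <- nrow(pairs)
  n_removed <- 0L
  if (!is.null(expr_threshold_frac) && nrow(pairs)) {
    thr <- expr_threshold_frac * max(gene_means, na.rm = TRUE)
    keep <- gene_means[pairs$gene] > thr
    n_removed <- sum(!keep)
    pairs <- pairs[keep, , drop = FALSE]
  }
  message("methylation_expression_correlation: ", n_before,
          " pairs assembled, ", n_removed, " removed by threshold, ",
          nrow(pairs), " used")
  if (nrow(pairs) < 3L) return(na_result(n_before, n_removed))
  x <- rowMeans(m[pairs$probe_id, cond_samples, drop = FALSE], na.rm = TRUE)
  y <- gene_means[pairs$gene]
  res <- if (method == "spearman") spearman_cor(x, y) else {
    ct <- stats::cor.test(x, y, method = "pearson")
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
         method = "pearson")
  }
  pairs$mean_m <- unname(x)
  pairs$mean_expr <- unname(y)
  lw <- stats::lowess(x, y, f = 2 / 3)
  structure(list(rho = res$rho, p = res$p, n = res$n, subset_tag = subset,
                 n_before_filter = n_before,
                 n_removed_by_threshold = n_removed,
                 pairs = pairs,
                 lowess_curve = data.frame(x = lw$x, y = lw$y),
                 method = res$method),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  cat("CorrelationResult (", x$subset_tag, ", ", x$method, "): rho = ",
      format(x$rho, digits = 4), ", p = ", format(x$p, digits = 4),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Association of differential CpGs with RNAPII-interaction regions
#'
#' Two-sided Fisher exact test of the 2x2 table with rows {hypo, hyper}
#' and columns {overlapping, not overlapping} an RNAPII (ChIA-PET) region;
#' overlap is point-in-interval under the half-open convention.
#'
#' @param diff Classified `DiffMethTable` with non-empty hypo and hyper
#'   sets.
#' @param regions Interval `data.frame` of RNAPII-interaction regions.
#' @param manifest `ProbeManifest`.
#' @return `list(table = 2x2 matrix, fisher_p = numeric)`.
#' @export
rnapii_overlap_test <- function(diff, regions, manifest) {
  sets <- diff_sets(diff)
  if (!length(sets$hypo) || !length(sets$hyper))
    stop("rnapii_overlap_test: both hypo and hyper sets must be non-empty")
  check_probes_in_manifest(c(sets$hypo, sets$hyper), manifest)
  ov_of <- function(ids) {
    i <- match(ids, manifest$probe_id)
    point_in_intervals(manifest$chrom[i], manifest$pos[i], regions)
  }
  ho <- ov_of(sets$hypo)
  hr <- ov_of(sets$hyper)
  tab <- matrix(c(sum(ho), sum(!ho), sum(hr), sum(!hr)), nrow = 2L,
                byrow = TRUE,
                dimnames = list(c("hypo", "hyper"),
                                c("overlapping", "not_overlapping")))
  list(table = tab, fisher_p = min(stats::fisher.test(tab)$p.value, 1))
}
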