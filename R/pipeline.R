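# End-to-end pipeline: diff -> island context -> state context & shift ->
# TFR/RRT -> expression link -> RNAPII association, with a machine-readable
# run manifest. Fail-fast: every input is read and validated before any
# output is written, so a stage error never leaves partial downstream
# files.

config_error <- function(...) {
  stop(structure(class = c("methtf_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Run the full analysis pipeline
#'
#' Reads a YAML (or list) configuration naming the input files, runs every
#' stage for which inputs are configured, writes one TSV per stage into
#' `outdir` plus a JSON run manifest recording the package version, the
#' configuration, input checksums and per-stage row counts. All stages are
#' deterministic, so re-running with the same configuration reproduces the
#' outputs byte-identically.
#'
#' Configuration keys: `beta`, `samples`, `manifest` (required);
#' `segmentation`, `peaks_manifest`, `expression`, `rnapii` (optional
#' stages); `outdir` (required); `alpha` (default 0.05), `paired` (default
#' true), `min_diff` (default 0.001), `expr_condition` (default
#' `treatment`), `expr_subset` (default `utr5_only`),
#' `expr_threshold_frac` (default 1/3), `seed` (recorded; no pipeline
#' stage is stochastic).
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param outdir Optional override of the configured output directory.
#' @return Invisibly, a named list of the written paths.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  if (!is.list(cfg)) config_error("invalid configuration")
  for (key in c("beta", "samples", "manifest"))
    if (is.null(cfg[[key]]))
      config_error("config: required input '", key, "' is missing")
  if (is.null(outdir)) outdir <- cfg$outdir
  if (is.null(outdir)) config_error("config: outdir is required")
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  paired <- if (is.null(cfg$paired)) TRUE else isTRUE(cfg$paired)
  min_diff <- if (is.null(cfg$min_diff)) 0.001 else cfg$min_diff
  expr_condition <- if (is.null(cfg$expr_condition)) "treatment" else
    cfg$expr_condition
  expr_subset <- if (is.null(cfg$expr_subset)) "utr5_only" else
    cfg$expr_subset
  expr_frac <- if (is.null(cfg$expr_threshold_frac)) 1 / 3 else
    cfg$expr_threshold_frac

  inputs <- c("beta", "samples", "manifest", "segmentation",
              "peaks_manifest", "expression", "rnapii")
  paths <- unlist(cfg[intersect(inputs, names(cfg))])
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    config_error("input file(s) not found: ", paste(missing, collapse = ", "))

  ## read everything up front (fail fast, no partial outputs)
  beta <- read_matrix(cfg$beta)
  sheet <- read_sample_sheet(cfg$samples)
  manifest <- read_probe_manifest(cfg$manifest)
  seg <- if (!is.null(cfg$segmentation)) {
    s <- read_bed(cfg$segmentation, dialect = "bed3plus")
    validate_segmentation(s)
    s
  }
  catalog <- if (!is.null(cfg$peaks_manifest)) {
    pm <- utils::read.delim(cfg$peaks_manifest, colClasses = "character")
    if (!all(c("tf_label", "cell_type", "path") %in% names(pm)))
      config_error("peaks manifest needs columns tf_label, cell_type, path")
    # relative peak paths resolve against the peaks manifest's directory
    rel <- !file.exists(pm$path)
    pm$path[rel] <- file.path(dirname(cfg$peaks_manifest), pm$path[rel])
    absent <- pm$path[!file.exists(pm$path)]
    if (length(absent))
      config_error("peak file(s) not found: ",
                   paste(absent, collapse = ", "))
    build_tf_catalog(pm)
  }
  expr <- if (!is.null(cfg$expression)) read_matrix(cfg$expression)
  rnapii <- if (!is.null(cfg$rnapii)) read_bed(cfg$rnapii)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  counts <- list()

  message("pipeline: differential methylation at adjusted p <= ", alpha,
          if (paired) " (paired design)" else " (unpaired design)")
  diff <- diff_methylation(beta, sheet, paired = paired, alpha = alpha)
  written$diff <- file.path(outdir, "diff.tsv")
  write_report(diff, written$diff)
  counts$diff <- nrow(diff)

  ic <- island_context_distribution(diff, manifest)
  written$island_context <- file.path(outdir, "island_context.tsv")
  write_report(ic, written$island_context)
  counts$island_context <- nrow(ic)

  if (!is.null(seg)) {
    sc <- state_enrichment(diff, seg, manifest)
    written$state_context <- file.path(outdir, "state_context.tsv")
    write_report(sc, written$state_context)
    counts$state_context <- nrow(sc)
    sh <- suppressWarnings(
      state_methylation_shift(beta, sheet, seg, manifest,
                              min_diff = min_diff))
    written$state_shift <- file.path(outdir, "state_shift.tsv")
    write_report(sh, written$state_shift)
    counts$state_shift <- nrow(sh)
  }

  if (!is.null(catalog)) {
    rr <- reins_report(diff, manifest, catalog)
    written$reins <- file.path(outdir, "reins.tsv")
    write_report(rr, written$reins)
    counts$reins <- nrow(rr)
  }

  if (!is.null(expr)) {
    m <- beta_to_m(beta)
    cr <- tryCatch(
      methylation_expression_correlation(
        diff, m, expr, manifest, sheet, condition = expr_condition,
        subset = expr_subset, expr_threshold_frac = expr_frac),
      warning = function(w) {
        message("exprlink: ", conditionMessage(w))
        suppressWarnings(methylation_expression_correlation(
          diff, m, expr, manifest, sheet, condition = expr_condition,
          subset = expr_subset, expr_threshold_frac = expr_frac))
      })
    el <- data.frame(subset = cr$subset_tag, method = cr$method,
                     rho = cr$rho, p = cr$p, n = cr$n,
                     n_before_filter = cr$n_before_filter,
                     n_removed_by_threshold = cr$n_removed_by_threshold,
                     stringsAsFactors = FALSE)
    written$exprlink <- file.path(outdir, "exprlink.tsv")
    write_report(el, written$exprlink)
    counts$exprlink <- cr$n
  }

  if (!is.null(rnapii)) {
    pt <- rnapii_overlap_test(diff, rnapii, manifest)
    po <- data.frame(class = rownames(pt$table),
                     overlapping = pt$table[, 1L],
                     not_overlapping = pt$table[, 2L],
                     fisher_p = pt$fisher_p, stringsAsFactors = FALSE)
    written$polii <- file.path(outdir, "polii.tsv")
    write_report(po, written$polii)
    counts$polii <- sum(pt$table)
  }

  manifest_json <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(
    list(tool = "methtf",
         version = as.character(utils::packageVersion("methtf")),
         config = cfg,
         thresholds = list(alpha = alpha, min_diff = min_diff,
                           expr_threshold_frac = expr_frac,
                           paired = paired),
         input_md5 = as.list(tools::md5sum(paths)),
         stage_rows = counts,
         seed = cfg$seed),
    manifest_json, auto_unbox = TRUE, digits = NA, null = "null",
    pretty = TRUE)
  written$run_manifest <- manifest_json
  invisible(written)
}
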