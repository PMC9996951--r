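# Synthetic inputs with planted, recoverable structure for every analysis
# stage: a paired three-donor, two-condition beta matrix with a minority of
# planted differential CpGs; island/shore/shelf/open-sea probe annotation; a
# fifteen-state chromatin segmentation; a TF peak catalog of decoys plus one
# planted methylation-biased TF; expression negatively coupled to the
# methylation of 5'UTR CpGs; and RNAPII-interaction regions preferentially
# covering hypo-methylated CpGs.
#
# Noise is added on the M (logit) scale and back-transformed so beta stays
# strictly inside (0, 1) without truncation artifacts. One seed drives the
# whole run; each output block reseeds at a fixed offset so adding a new
# block does not perturb the existing ones. Offsets are spaced by a large
# prime so that two runs with different (small) seeds never share a
# sub-stream.

sub_seed <- function(seed, block) {
  (as.integer(seed) + block * 1000003L) %% 2147483629L
}

CHROMHMM_STATES <- c("Active_Promoter", "Weak_Promoter", "Poised_Promoter",
                     "Strong_Enhancer_1", "Strong_Enhancer_2",
                     "Weak_Enhancer_1", "Weak_Enhancer_2", "Insulator",
                     "Txn_Transition", "Txn_Elongation", "Weak_Txn",
                     "Repressed", "Heterochrom_lo", "Repetitive_CNV_1",
                     "Repetitive_CNV_2")

#' Default TF peak specification
#'
#' One planted TF (`TFP01`) whose peaks cover hyper-methylated planted CpGs
#' with probability 0.6 versus 0.15 for hypo-methylated ones, among 20
#' decoy TFs with uniform 0.15 coverage everywhere.
#'
#' @param n_decoys Number of decoy TFs (default 20).
#' @return `data.frame` with columns `label`, `hypo_coverage_prob`,
#'   `hyper_coverage_prob`, `background_coverage_prob`.
#' @export
default_tf_specs <- function(n_decoys = 20L) {
  data.frame(
    label = c("TFP01", sprintf("TFD%02d", seq_len(n_decoys))),
    hypo_coverage_prob = c(0.15, rep(0.15, n_decoys)),
    hyper_coverage_prob = c(0.60, rep(0.15, n_decoys)),
    background_coverage_prob = rep(0.15, n_decoys + 1L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults emulate the study design the generator stands in for: three
#' donors, both conditions derived from each donor (paired), a minority of
#' planted differential CpGs with a beta-scale effect of 0.3, sample noise
#' of 0.03 on the logit scale, a fifteen-state segmentation and a planted
#' hyper-methylation-biased TF among uniform decoys. Planted
#' hyper-methylated CpGs are drawn into the `Insulator` state at three
#' times its genomic share.
#'
#' @param seed Integer seed; drives all randomness.
#' @param n_chrom,chrom_length Genome geometry (default 2 x 1e6 bp).
#' @param n_probes Number of CpG probes (default 10000).
#' @param island_props Named proportions over the six island-relation
#'   categories.
#' @param n_states Number of chromatin states (default 15).
#' @param n_segments_per_chrom Number of segmentation intervals per
#'   chromosome (default 120).
#' @param n_samples_per_condition Donors per condition (default 3, paired).
#' @param n_planted_diff Planted differential CpGs (default 200).
#' @param planted_hypo_frac Fraction of planted CpGs losing methylation
#'   (default 0.5).
#' @param delta_beta Beta-scale shift of planted CpGs (default 0.3).
#' @param beta_noise_sd Per-sample noise SD on the logit (M) scale
#'   (default 0.03).
#' @param donor_sd SD of the per-donor, per-probe offset shared by the two
#'   paired samples of a donor (default 0.3, logit scale).
#' @param tf_specs See [default_tf_specs()].
#' @param peak_width TF peak width in bp (default 20; narrow relative to
#'   the probe spacing so a peak targeted at one CpG rarely covers a
#'   neighbouring one).
#' @param gene_fraction Fraction of probes annotated to a (synthetic) gene
#'   (default 0.7).
#' @param utr5_fraction Fraction of gene-annotated probes flagged
#'   `FiveUTR` (default 0.3).
#' @param expr_intercept,expr_slope,expr_noise_sd Expression model for
#'   genes of 5'UTR planted CpGs:
#'   `expr = intercept - slope * (condition mean M) + N(0, noise)`,
#'   floored at 0. `expr_slope = 0` gives null coupling.
#' @param state_bias Optional `list(state =, group =, factor =)`: planted
#'   CpGs of `group` (`"hyper"` or `"hypo"`) land in `state` at `factor`
#'   times its genomic share. Default: hyper CpGs, `Insulator`, 3.
#' @param state_shift Optional `list(state =, delta =)`: add a bulk
#'   beta-scale shift to the treatment condition for every probe in the
#'   state (off by default; independent of the planted per-CpG signal).
#' @param rnapii_hypo_prob,rnapii_hyper_prob Coverage probabilities of
#'   planted CpGs by RNAPII-interaction regions (defaults 0.4 / 0.2).
#' @param rnapii_bg_n,rnapii_width Background RNAPII regions per chromosome
#'   and region width (defaults 300 / 1000 bp).
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 1e6,
                       n_probes = 10000L,
                       island_props = c(Island = 0.31, N_Shore = 0.12,
                                        S_Shore = 0.11, N_Shelf = 0.05,
                                        S_Shelf = 0.05, OpenSea = 0.36),
                       n_states = 15L,
                       n_segments_per_chrom = 120L,
                       n_samples_per_condition = 3L,
                       n_planted_diff = 200L,
                       planted_hypo_frac = 0.5,
                       delta_beta = 0.3,
                       beta_noise_sd = 0.03,
                       donor_sd = 0.3,
                       tf_specs = default_tf_specs(),
                       peak_width = 20L,
                       gene_fraction = 0.7,
                       utr5_fraction = 0.3,
                       expr_intercept = 12,
                       expr_slope = 2,
                       expr_noise_sd = 2,
                       state_bias = list(state = "Insulator",
                                         group = "hyper", factor = 3),
                       state_shift = NULL,
                       rnapii_hypo_prob = 0.4,
                       rnapii_hyper_prob = 0.2,
                       rnapii_bg_n = 300L,
                       rnapii_width = 1000L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$island_props, cfg$tf_specs$hypo_coverage_prob,
             cfg$tf_specs$hyper_coverage_prob,
             cfg$tf_specs$background_coverage_prob,
             cfg$planted_hypo_frac, cfg$rnapii_hypo_prob,
             cfg$rnapii_hyper_prob, cfg$gene_fraction, cfg$utr5_fraction)
  if (any(probs < 0 | probs > 1))
    stop("simulation config: probabilities must lie in [0, 1]")
  if (cfg$n_planted_diff > cfg$n_probes)
    stop("simulation config: n_planted_diff must not exceed n_probes")
  if (abs(sum(cfg$island_props) - 1) > 1e-6)
    stop("simulation config: island_props must sum to 1")
  if (cfg$delta_beta < 0 || cfg$delta_beta >= 1)
    stop("simulation config: delta_beta must lie in [0, 1)")
  if (cfg$n_samples_per_condition < 2L)
    stop("simulation config: need at least 2 samples per condition")
  if (cfg$n_states > length(CHROMHMM_STATES))
    stop("simulation config: at most ", length(CHROMHMM_STATES), " states")
  invisible(cfg)
}

# Beta-distribution parameters of baseline methylation per island category:
# island probes are mostly unmethylated, open-sea probes mostly methylated,
# shores/shelves intermediate.
baseline_beta_params <- list(
  Island = c(2, 10), N_Shore = c(3, 7), S_Shore = c(3, 7),
  N_Shelf = c(6, 4), S_Shelf = c(6, 4), OpenSea = c(10, 2))

#' Generate one complete synthetic data set
#'
#' Deterministic for a fixed `config$seed`. See [sim_config()] for the
#' generative model.
#'
#' @param config A `SimulationConfig` from [sim_config()].
#' @return A list with `manifest`, `sample_sheet`, `beta`, `segmentation`,
#'   `tf_peaks` (flat `data.frame`: `tf_label`, `cell_type`, `chrom`,
#'   `start`, `end`), `expression`, `rnapii`, `ground_truth`, `config`.
#' @export
simulate_all <- function(config) {
  validate_sim_config(config)
  seed <- as.integer(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  L <- config$chrom_length
  n <- config$n_probes

  ## --- segmentation (offset 2; needed before probe placement) ---
  set.seed(sub_seed(seed, 2L))
  states <- CHROMHMM_STATES[seq_len(config$n_states)]
  seg <- do.call(rbind, lapply(chroms, function(ch) {
    k <- config$n_segments_per_chrom
    lens <- stats::rexp(k)
    bounds <- round(cumsum(lens) / sum(lens) * L)
    start <- c(0, bounds[-k])
    keep <- bounds > start
    lab <- c(states, sample(states, k - length(states), replace = TRUE))
    lab <- sample(lab)
    data.frame(chrom = ch, start = start[keep], end = bounds[keep],
               label = lab[keep], stringsAsFactors = FALSE)
  }))
  rownames(seg) <- NULL

  ## --- probes: positions, categories, planted sets (offset 0) ---
  set.seed(sub_seed(seed, 0L))
  probe_id <- sprintf("cg%06d", seq_len(n))
  chrom <- sample(chroms, n, replace = TRUE)
  pos <- floor(stats::runif(n, 0, L))
  island <- sample(names(config$island_props), n, replace = TRUE,
                   prob = config$island_props)
  planted <- if (config$n_planted_diff > 0)
    sample.int(n, config$n_planted_diff) else integer(0)
  n_hypo <- round(config$planted_hypo_frac * length(planted))
  planted_hypo <- planted[seq_len(n_hypo)]
  planted_hyper <- setdiff(planted, planted_hypo)

  # Optional placement bias: planted CpGs of one group land in a chosen
  # state at `factor` times its genomic share.
  if (!is.null(config$state_bias) && length(planted)) {
    sb <- config$state_bias
    target <- planted_hyper
    if (identical(sb$group, "hypo")) target <- planted_hypo
    in_state <- seg[seg$label == sb$state, , drop = FALSE]
    w <- sum(in_state$end - in_state$start) / (config$n_chrom * L)
    p_in <- min(sb$factor * w, 1)
    go_in <- stats::runif(length(target)) < p_in
    idx_in <- target[go_in]
    if (length(idx_in)) {
      j <- sample.int(nrow(in_state), length(idx_in), replace = TRUE,
                      prob = in_state$end - in_state$start)
      chrom[idx_in] <- in_state$chrom[j]
      pos[idx_in] <- floor(stats::runif(length(idx_in), in_state$start[j],
                                        in_state$end[j]))
    }
    idx_out <- target[!go_in]
    while (length(idx_out)) {   # vectorised rejection: land outside state
      chrom[idx_out] <- sample(chroms, length(idx_out), replace = TRUE)
      pos[idx_out] <- floor(stats::runif(length(idx_out), 0, L))
      inside <- !is.na(point_interval_label(chrom[idx_out], pos[idx_out],
                                            in_state))
      idx_out <- idx_out[inside]
    }
  }

  # Gene model: a fraction of probes is annotated to its own synthetic
  # gene; a fraction of those carries the FiveUTR flag.
  has_gene <- stats::runif(n) < config$gene_fraction
  gene <- ifelse(has_gene, sprintf("g%06d", seq_len(n)), NA_character_)
  is_utr5 <- has_gene & stats::runif(n) < config$utr5_fraction
  manifest <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                         island_relation = island, stringsAsFactors = FALSE)
  manifest$gene_symbols <- lapply(seq_len(n), function(i)
    if (has_gene[i]) gene[i] else character(0))
  manifest$region_flags <- lapply(seq_len(n), function(i)
    if (!has_gene[i]) character(0) else if (is_utr5[i]) "FiveUTR" else
      "Body")
  class(manifest) <- c("ProbeManifest", "data.frame")

  ## --- beta matrix (offset 1) ---
  set.seed(sub_seed(seed, 1L))
  ab <- t(vapply(island, function(cat) baseline_beta_params[[cat]],
                 numeric(2)))
  beta0 <- stats::rbeta(n, ab[, 1L], ab[, 2L])
  beta0 <- pmin(pmax(beta0, 0.01), 0.99)
  beta_trt <- beta0
  beta_trt[planted_hypo] <- pmax(beta0[planted_hypo] - config$delta_beta,
                                 0.01)
  beta_trt[planted_hyper] <- pmin(beta0[planted_hyper] + config$delta_beta,
                                  0.99)
  if (!is.null(config$state_shift)) {
    ss <- config$state_shift
    in_s <- !is.na(point_interval_label(chrom, pos,
                                        seg[seg$label == ss$state, ,
                                            drop = FALSE]))
    beta_trt[in_s] <- pmin(pmax(beta_trt[in_s] + ss$delta, 0.01), 0.99)
  }
  logit2 <- function(b) log2(b / (1 - b))
  m_ref <- logit2(beta0)
  m_trt <- logit2(beta_trt)
  nd <- config$n_samples_per_condition
  donors <- sprintf("d%d", seq_len(nd))
  donor_eff <- matrix(stats::rnorm(n * nd, 0, config$donor_sd), n, nd)
  mk_samples <- function(m_cond, prefix) {
    sapply(seq_len(nd), function(j)
      m_cond + donor_eff[, j] + stats::rnorm(n, 0, config$beta_noise_sd))
  }
  m_mat <- cbind(mk_samples(m_ref, "ref"), mk_samples(m_trt, "trt"))
  beta_mat <- 1 / (1 + 2^(-m_mat))
  colnames(beta_mat) <- c(sprintf("ref_%s", donors),
                          sprintf("trt_%s", donors))
  rownames(beta_mat) <- probe_id
  sheet <- data.frame(sample_id = colnames(beta_mat),
                      condition = rep(c("reference", "treatment"),
                                      each = nd),
                      donor = rep(donors, 2L), stringsAsFactors = FALSE)

  ## --- TF peaks (offset 3) ---
  set.seed(sub_seed(seed, 3L))
  grp <- rep("background", n)
  grp[planted_hypo] <- "hypo"
  grp[planted_hyper] <- "hyper"
  half <- floor(config$peak_width / 2)
  tf_peaks <- do.call(rbind, lapply(seq_len(nrow(config$tf_specs)),
                                    function(k) {
    spec <- config$tf_specs[k, ]
    p <- c(background = spec$background_coverage_prob,
           hypo = spec$hypo_coverage_prob,
           hyper = spec$hyper_coverage_prob)[grp]
    # Two cell types with independent sub-draws whose union hits the
    # target coverage probability, exercising the union-merge rule.
    pc <- 1 - sqrt(1 - p)
    covered_a <- stats::runif(n) < pc
    covered_b <- stats::runif(n) < pc
    mk <- function(covered, cell) {
      idx <- which(covered)
      if (!length(idx)) return(NULL)
      data.frame(tf_label = spec$label, cell_type = cell,
                 chrom = chrom[idx],
                 start = pmax(pos[idx] - half, 0),
                 end = pos[idx] + (config$peak_width - half),
                 stringsAsFactors = FALSE)
    }
    rbind(mk(covered_a, "cellA"), mk(covered_b, "cellB"))
  }))
  rownames(tf_peaks) <- NULL

  ## --- expression (offset 4) ---
  set.seed(sub_seed(seed, 4L))
  gene_ids <- gene[has_gene]
  gene_probe <- which(has_gene)
  coupled <- has_gene & is_utr5 & seq_len(n) %in% planted
  base_expr <- stats::runif(length(gene_ids), 0, 20)
  expr <- matrix(NA_real_, length(gene_ids), 2L * nd,
                 dimnames = list(gene_ids, colnames(beta_mat)))
  m_cond <- cbind(matrix(m_ref, n, nd), matrix(m_trt, n, nd))
  for (j in seq_len(2L * nd)) {
    mu <- ifelse(coupled[gene_probe],
                 config$expr_intercept -
                   config$expr_slope * m_cond[gene_probe, j],
                 base_expr)
    expr[, j] <- pmax(mu + stats::rnorm(length(gene_ids), 0,
                                        config$expr_noise_sd), 0)
  }

  ## --- RNAPII-interaction regions (offset 5) ---
  set.seed(sub_seed(seed, 5L))
  hw <- floor(config$rnapii_width / 2)
  mk_regions <- function(idx, p) {
    hit <- idx[stats::runif(length(idx)) < p]
    if (!length(hit)) return(NULL)
    data.frame(chrom = chrom[hit], start = pmax(pos[hit] - hw, 0),
               end = pos[hit] + (config$rnapii_width - hw),
               label = NA_character_, stringsAsFactors = FALSE)
  }
  bg_regions <- do.call(rbind, lapply(chroms, function(ch) {
    s <- floor(stats::runif(config$rnapii_bg_n, 0, L - config$rnapii_width))
    data.frame(chrom = ch, start = s, end = s + config$rnapii_width,
               label = NA_character_, stringsAsFactors = FALSE)
  }))
  rnapii <- rbind(mk_regions(planted_hypo, config$rnapii_hypo_prob),
                  mk_regions(planted_hyper, config$rnapii_hyper_prob),
                  bg_regions)
  rownames(rnapii) <- NULL

  ground_truth <- list(
    planted_hypo = probe_id[planted_hypo],
    planted_hyper = probe_id[planted_hyper],
    planted_tf = config$tf_specs$label[
      config$tf_specs$hypo_coverage_prob !=
        config$tf_specs$hyper_coverage_prob],
    tf_specs = config$tf_specs,
    coupled_genes = gene[coupled],
    expr_slope = config$expr_slope,
    state_bias = config$state_bias,
    state_shift = config$state_shift,
    seed = seed)

  list(manifest = manifest, sample_sheet = sheet, beta = beta_mat,
       segmentation = seg, tf_peaks = tf_peaks, expression = expr,
       rnapii = rnapii, ground_truth = ground_truth, config = config)
}

#' Preset simulation configurations
#'
#' * `"tiny"`: 400 probes on one 200 kb chromosome, 40 planted CpGs, 1
#'   planted TF + 4 decoys; for fast unit and smoke tests.
#' * `"default"`: the full study-scale configuration of [sim_config()].
#' * `"null"`: 5000 probes, no planted signal anywhere (`delta_beta = 0`,
#'   no planted CpGs, no biased TF, no expression coupling).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A `SimulationConfig`.
#' @export
preset_config <- function(name, seed = 1L) {
  presets <- c("tiny", "default", "null")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "))
  switch(name,
    tiny = sim_config(seed = seed, n_chrom = 1L, chrom_length = 2e5,
                      n_probes = 400L, n_planted_diff = 40L,
                      n_segments_per_chrom = 60L,
                      tf_specs = default_tf_specs(n_decoys = 4L),
                      rnapii_bg_n = 50L),
    default = sim_config(seed = seed),
    null = sim_config(seed = seed, n_probes = 5000L, n_planted_diff = 0L,
                      delta_beta = 0, expr_slope = 0, state_bias = NULL,
                      tf_specs = within(default_tf_specs(n_decoys = 4L),
                                        hyper_coverage_prob <- 0.15)))
}

#' Write a synthetic fixture to disk
#'
#' Emits every format the readers consume: probe manifest TSV (positions
#' re-encoded 1-based, as in vendor manifests), beta matrix TSV, sample
#' sheet TSV, chromatin-state BED4, per-(TF, cell type) narrowPeak files
#' plus a peaks manifest TSV, expression TSV, RNAPII-region BED3, and the
#' ground truth as JSON.
#'
#' @param name Preset name (see [preset_config()]).
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed.
#' @return Invisibly, a named list of the written paths.
#' @export
emit_fixture <- function(name, outdir, seed = 1L) {
  cfg <- preset_config(name, seed = seed)
  sim <- simulate_all(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  paths <- list(
    manifest = file.path(outdir, "manifest.tsv"),
    beta = file.path(outdir, "beta.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    segmentation = file.path(outdir, "states.bed"),
    expression = file.path(outdir, "expr.tsv"),
    rnapii = file.path(outdir, "rnapii.bed"),
    peaks_manifest = file.path(outdir, "peaks_manifest.tsv"),
    ground_truth = file.path(outdir, "ground_truth.json"))

  mani <- sim$manifest
  out <- data.frame(probe_id = mani$probe_id, chrom = mani$chrom,
                    pos = mani$pos + 1,
                    island_relation = mani$island_relation,
                    gene_symbols = vapply(mani$gene_symbols, paste, "",
                                          collapse = ";"),
                    region_flags = vapply(mani$region_flags, paste, "",
                                          collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix_tsv(sim$beta, paths$beta, id_name = "probe_id")
  utils::write.table(sim$sample_sheet, paths$samples, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$segmentation, paths$segmentation, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_matrix_tsv(sim$expression, paths$expression, id_name = "gene")
  utils::write.table(sim$rnapii[c("chrom", "start", "end")], paths$rnapii,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  combos <- unique(sim$tf_peaks[c("tf_label", "cell_type")])
  # paths are relative to the fixture directory so that identical seeds
  # give byte-identical fixtures wherever they are written
  combos$path <- file.path("peaks",
                           sprintf("%s.%s.narrowPeak", combos$tf_label,
                                   combos$cell_type))
  for (i in seq_len(nrow(combos))) {
    sub <- sim$tf_peaks[sim$tf_peaks$tf_label == combos$tf_label[i] &
                          sim$tf_peaks$cell_type == combos$cell_type[i], ]
    np <- data.frame(sub$chrom, sub$start, sub$end,
                     sprintf("%s_peak%d", combos$tf_label[i],
                             seq_len(nrow(sub))),
                     0L, ".", 0, -1, -1, -1)
    utils::write.table(np, file.path(outdir, combos$path[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(combos, paths$peaks_manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- sim$ground_truth
  gt$tf_specs <- NULL
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
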