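---
title: "Linking DNA-methylation remodelling to transcription-factor activity"
author: "methtf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking DNA-methylation remodelling to transcription-factor activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtf)
```

## The problem

DNA methylation at a CpG dinucleotide can block a transcription factor
(TF) from binding its site. When a cell changes state — the motivating
case is mesenchymal stem cells (MSCs) differentiating into osteoblasts —
the genome-wide methylation profile is remodelled, and the *direction* of
that remodelling at a TF's binding sites is informative: a TF whose sites
are preferentially de-methylated is plausibly being licensed, one whose
sites are preferentially methylated plausibly silenced. `methtf`
implements that chain of reasoning as a pipeline: call differentially
methylated CpGs from a two-condition beta-value matrix, describe where
they fall in the genome, and rank TFs by the hypo- versus
hyper-methylation bias of their ChIP-seq binding-site catalog.

## Differential methylation

Array methylation arrives as beta-values, $\beta = M/(M+U) \in [0,1]$.
Beta-values are heteroscedastic (variance is compressed near 0 and 1), so
testing is done on M-values,

$$M = \log_2 \frac{\beta'}{1-\beta'}, \qquad
  \beta' = \min(\max(\beta, \varepsilon),\, 1-\varepsilon),$$

with `clip_epsilon` $\varepsilon = 10^{-3}$ by default: beta-values of
exactly 0 or 1 do occur on arrays and must not produce infinities. The
map is strictly increasing and antisymmetric around $\beta = 0.5$, and
`m_to_beta()` inverts it exactly on the unclipped range.

Per CpG we fit the two-condition comparison with a moderated t. The
default design is **donor-paired** — in the motivating design both
conditions derive from the same three donors, so the statistic is a
one-sample t on within-donor differences; an unpaired pooled-variance t
is available by flag. With thousands of probes and two residual degrees
of freedom each, per-probe variances are noisy; we shrink them toward a
pooled prior with an empirical-Bayes scheme estimated by method of
moments on the log residual variances: for $z_g = \log s^2_g$,

$$\mathrm{E}[z_g] = \log \sigma^2_g + \psi(d_g/2) - \log(d_g/2), \qquad
  \mathrm{Var}[z_g] = \psi'(d_g/2),$$

so the spread of the observed $z_g$ in excess of the $\chi^2$ sampling
noise identifies the prior degrees of freedom $d_0$ (via a Newton
inversion of the trigamma function), and the centre identifies the prior
variance $s_0^2$. The posterior variance
$(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ replaces $s^2_g$ and the t is
referred to $d_g + d_0$ degrees of freedom. When the excess spread is
zero or negative, $d_0$ is effectively infinite; it is capped at $10^6$
to represent that cleanly. `shrink = FALSE` gives the ordinary t-test,
which the test suite uses to check the reduction, and the moderated path
is cross-checked against an independent empirical-Bayes implementation
(limma) on heteroscedastic data.

P-values are adjusted by Benjamini–Hochberg (the ecosystem default where
the upstream report says only "adjusted p"; Holm and Bonferroni are
selectable), and probes with adjusted $p \le \alpha = 0.05$ are
classified `hypo` ($\Delta M < 0$, treatment minus reference) or `hyper`
($\Delta M > 0$). Effect sizes are reported both as $\Delta M$ (tested
scale) and $\Delta\beta$ (interpretable scale). Probes with missing
values are tested on the available samples and flagged; probes with
fewer than two usable values per condition get $p = 1$ and a flag rather
than being dropped, so row counts are conserved.

## Genomic context

Two context analyses share one normalisation convention: **the array is
the background, not the genome**. Observed percentages are computed
within each significance group (hypo, hyper), expected percentages from
all probes on the manifest, and the enrichment ratio is
observed/expected.

* `island_context_distribution()` distributes CpGs over the six
  island-relation categories (island, N/S shore, N/S shelf, open sea).
* `state_enrichment()` does the same over chromatin-state labels from a
  BED4 segmentation (validated non-overlapping; probes outside every
  segment fall in an `Unassigned` category so counts are conserved).

Each category gets a two-sided Fisher exact test contrasting the
significance group with the non-significant remainder of the array, with
BH adjustment across all (category × group) tests.

`state_methylation_shift()` asks a different question: did the bulk
methylation level of a state move between conditions? It compares
per-probe condition means of beta restricted to probes with
$|\Delta\beta| \ge$ `min_diff` $= 0.001$ (a 0.1% methylation
difference — below array noise, so the filter only removes exact-tie
degeneracies that would break a signed-rank test). The test is the
two-sided Wilcoxon signed-rank over probe-level pairs, chosen for
robustness since per-state beta distributions are strongly bimodal; a
paired t is available. The upstream analysis this follows did not name
its per-state test, so this is a documented default, not a claim about
the original. States with fewer than ten qualifying probes are reported
`NA` with a warning.

## TFR / RRT

The core statistic. For a TF with merged binding-site catalog $B$ and
CpG classes $\mathrm{Ho}$ (hypo) and $\mathrm{Hr}$ (hyper):

$$\mathrm{TFR}_{\mathrm{hypo}} =
  \frac{|\{c \in \mathrm{Ho} : c \text{ overlaps } B\}|}{|\mathrm{Ho}|}
  \times 100,
  \qquad
  \mathrm{TFR}_{\mathrm{hyper}} =
  \frac{|\{c \in \mathrm{Hr} : c \text{ overlaps } B\}|}{|\mathrm{Hr}|}
  \times 100,$$

$$\mathrm{RRT} = \frac{\mathrm{TFR}_{\mathrm{hypo}}}
                      {\mathrm{TFR}_{\mathrm{hyper}}}.$$

$\log_2 \mathrm{RRT} > 0$ marks a TF whose sites are preferentially
de-methylated during the transition, $< 0$ preferentially methylated.
TFs are ranked by $\log_2 \mathrm{RRT}$ descending, ties broken by
Fisher p then label. Design choices worth stating:

* **Aggregation across cell types is union-merge.** Peak files for one
  TF label are pooled and overlapping or book-ended intervals coalesced.
  The most inclusive reading of a multi-cell-type catalog; per-cell-type
  analysis is possible by giving each cell type its own label.
* **CpGs are points.** A probe is its cytosine coordinate (0-based); a
  CpG inside several peaks of one TF counts once; TFs count
  independently. Interval-probe semantics would need a documented probe
  length and changes nothing for peaks much wider than a probe.
* **Degenerate zeros get a flagged Haldane pseudocount.** If either
  overlap count is zero, both TFRs are recomputed with $+0.5$ on the
  overlap counts (totals unchanged) so $\log_2 \mathrm{RRT}$ stays
  finite and rankable; `pseudocount_used` marks those rows. Without it a
  TF with zero hyper-class overlaps would silently vanish from the
  ranking it should top.
* **Significance** is a two-sided Fisher exact test on
  $[[o_{ho}, n_{ho}-o_{ho}], [o_{hr}, n_{hr}-o_{hr}]]$, BH-adjusted
  across TFs. $\log_2$ is computed as a difference of logs so that
  exchanging the two classes negates the score exactly, bit for bit — a
  property the test suite asserts.
* The $p < 0.001$ convention for highlighting top TFs is a report
  annotation, never a filter; the full table is always written.

`multi_signature_tfr()` computes one TF's TFR pair across several
differential-methylation signatures (e.g. different tissues), the
validation mode in which a TF known to be differentially active across
tissues should flip its TFR imbalance.

## Methylation and expression

`spearman_cor()` computes $\rho$ as the Pearson correlation of average
ranks. For $n \le 9$ untied observations the p-value is exact, by full
enumeration of the $n!$ permutation distribution of $|\rho|$; otherwise
the standard $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation on $n-2$
degrees of freedom. `methylation_expression_correlation()` assembles
(CpG, gene) pairs from significant probes via the manifest annotation —
one pair per (CpG, gene) when a CpG maps to several genes, one pair per
CpG when a gene hosts several — optionally restricted to 5'UTR CpGs
and/or to robustly expressed genes (gene mean above a fraction, canonically
1/3, of the maximum gene mean within the analysed condition). The lowess
smooth attached to the result is descriptive only; inference is the rank
correlation. `rnapii_overlap_test()` is the companion contingency test of
hypo/hyper CpGs against RNAPII-interaction (ChIA-PET-style) regions.

## Coordinates and file formats

Everything in memory is 0-based, half-open `[start, end)`, matching BED;
vendor manifest positions (1-based) are shifted exactly once at read
time, and a point at an interval's `end` coordinate is outside it.
Strand is ignored: CpG methylation is symmetric across strands.
Chromosome names match by exact string equality after trimming — silent
`chr`-prefix normalisation hides input errors. Interval overlap is
delegated to IRanges internally, but the behavioural contract is the
brute-force all-pairs scan, and the tests enforce exact agreement on
hundreds of random instances. Report writers render floats with 15
significant digits so a write/read round trip preserves values within
1e-9, and row order is deterministic (TFR reports sort ascending by
`log2_rrt`).

## The synthetic-data generator

Real array data for the motivating study are not redistributable, so
validation is on synthetic data with *planted, recoverable* structure.
`sim_config()` defaults describe the emulated study:

| parameter | default | meaning |
|---|---|---|
| `n_probes` | 10,000 | CpGs on 2 × 1 Mb chromosomes |
| `n_samples_per_condition` | 3, paired | three donors, both conditions each |
| `n_planted_diff` | 200 | planted differential CpGs, 50/50 hypo/hyper |
| `delta_beta` | 0.3 | beta-scale shift of planted CpGs |
| `beta_noise_sd` | 0.03 | per-sample noise SD, logit scale |
| `donor_sd` | 0.3 | per-donor offset shared by paired samples |
| `tf_specs` | 1 + 20 | planted TF covers hyper CpGs at 0.6 vs 0.15; decoys uniform 0.15 |
| `peak_width` | 20 bp | narrow vs ~200 bp probe spacing |
| `state_bias` | Insulator ×3 | planted hyper CpGs drawn into one state at 3× its share |
| `expr_intercept/slope/noise` | 12 / 2 / 2 | expression of 5'UTR planted CpG genes: $12 - 2M +$ noise |

Baseline beta is a bimodal mixture keyed to island context (island
probes ~ Beta(2,10), open sea ~ Beta(10,2), shores/shelves
intermediate), reproducing the empirical U-shape of array beta
distributions. Noise and donor effects are added on the logit (M) scale
and back-transformed, so beta stays strictly inside (0,1) with no
truncation artifacts and the analysis-side M-values are exactly normal
around their means. The planted TF's peaks are placed directly over the
CpGs they are meant to cover, in two cell-type files whose independent
sub-draws union to the target coverage (exercising the union-merge
rule); peaks are 20 bp wide so a peak targeted at one CpG rarely covers
a neighbour by accident. Uncoupled gene expression is uniform on
(0, 20), commensurate with the coupled-gene scale so the
robust-expression filter bites without degenerating.

One seed drives a run; each output block (probes, beta, segmentation,
peaks, expression, RNAPII regions) reseeds at the run seed plus a fixed
offset, with offsets spaced by a large prime. That means adding a new
output block never perturbs existing ones, and — important when
estimating error rates over a family of consecutive seeds — two runs
with different seeds never share a sub-stream.

What the generator does **not** emulate: probe-level chemistry (type
I/II bias), spatially correlated methylation blocks, SNP-affected or
cross-reactive probes, sex chromosomes, cell-composition mixtures, and
expression-array normalisation artifacts. Passing tests therefore
demonstrate that the statistics recover planted structure under clean
noise at realistic sizes — not robustness to array artifacts, which
upstream preprocessing is assumed to have handled.

## Validation regimes and problem sizes

The test suite ties every statistical claim to a regime chosen to make
the check sharp at desk scale: exact-agreement checks (overlap counting
vs brute force, Fisher p vs hypergeometric enumeration over all 2×2
tables with $N \le 30$, permutation-exact Spearman) run on hundreds of
random instances; calibration checks use 50–100 seeded replicates of the
null generator (type-I rate of the moderated t within $0.05 \pm 0.02$;
permuted context labels within ratio $1.0 \pm 0.1$; null
expression-coupling p-rate within $0.05 \pm 0.03$); recovery checks use
100 seeded replicates of the default generator (planted TF last by
$\log_2$RRT in $\ge 95$, BH-significant in $\ge 90$; planted CpG
sensitivity $\ge 0.6$ at empirical FDR $\le 0.10$; negative 5'UTR
coupling detected in $\ge 90$). The end-to-end pipeline is additionally
required to be byte-deterministic: two runs over the same fixture
produce identical reports.

## Known limitations

* The moderated test assumes approximately normal M-value noise and a
  common two-group (optionally donor-blocked) design; no surrogate
  variables, batch terms or continuous covariates.
* TF catalogs are treated as fixed truth; peak-calling uncertainty and
  cell-type relevance weighting are out of scope (union-merge is
  deliberately inclusive).
* The per-TF Fisher test treats CpGs as independent; spatially
  correlated CpGs in one peak would make it anticonservative on real
  data.
* A probe maps to at most one chromatin state (segmentations are
  non-overlapping by contract), and probes in multiple *annotation*
  categories are not double-counted anywhere.
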