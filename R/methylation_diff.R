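# Differential methylation: beta -> M transformation, per-CpG moderated
# t-testing between two conditions (donor-paired by default), BH adjustment
# and hypo/hyper classification.

#' Transform beta-values to M-values
#'
#' `M = log2(beta' / (1 - beta'))` with `beta' = min(max(beta, eps), 1 - eps)`.
#' Clipping keeps M finite for the beta-values of exactly 0 or 1 that occur
#' on arrays. The map is strictly increasing on `[eps, 1 - eps]` and
#' antisymmetric around 0.5: `M(beta) = -M(1 - beta)`.
#'
#' @param beta Numeric vector or matrix of beta-values in `[0, 1]`
#'   (`NA` allowed and propagated).
#' @param clip_epsilon Clipping bound in `(0, 0.5)`; default `1e-3`.
#' @return M-values with the same shape as `beta`.
#' @export
beta_to_m <- function(beta, clip_epsilon = 1e-3) {
  if (!is.numeric(clip_epsilon) || length(clip_epsilon) != 1L ||
      clip_epsilon <= 0 || clip_epsilon >= 0.5)
    stop("clip_epsilon must be a single value in (0, 0.5)")
  v <- beta
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(v, clip_epsilon), 1 - clip_epsilon)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) out <- matrix(out, nrow = nrow(beta),
                                     dimnames = dimnames(beta))
  out
}

#' Inverse of [beta_to_m()]
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta-values `2^m / (1 + 2^m)`.
#' @export
m_to_beta <- function(m) {
  out <- 1 / (1 + 2^(-m))
  if (is.matrix(m)) out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  out
}

# Row-wise sample variances with NA handling (two-pass, vectorised).
row_vars <- function(x, n = rowSums(!is.na(x))) {
  mu <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - mu)^2, na.rm = TRUE)
  ifelse(n >= 2, ss / (n - 1), NA_real_)
}

# Newton solve of trigamma(x) = y, x > 0 (used by the variance shrinkage).
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:100) {
    f <- trigamma(x) - y
    step <- f / psigamma(x, 2L)
    xn <- x - step
    if (xn <= 0) xn <- x / 2
    if (abs(xn - x) < 1e-10 * x) { x <- xn; break }
    x <- xn
  }
  x
}

# Method-of-moments empirical-Bayes variance shrinkage on the log scale.
# log(s^2) for a chi^2_{df} variance has mean log(sigma^2) + digamma(df/2) -
# log(df/2) and variance trigamma(df/2); the excess spread of the observed
# log-variances over that sampling noise identifies the prior df d0, the
# centre identifies the prior variance s0^2.
squeeze_variances <- function(s2, df, max_prior_df = 1e6) {
  ok <- is.finite(s2) & df > 0 & s2 > 0
  if (sum(ok) < 2L)
    return(list(prior_df = 0, prior_var = NA_real_,
                post_var = s2, post_df = df))
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(dfo / 2))
  d0 <- if (!is.finite(excess) || excess <= 0) Inf else
    2 * trigamma_inverse(excess)
  d0 <- min(d0, max_prior_df)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  s2f <- ifelse(is.finite(s2) & df > 0, s2, 0)
  post <- (d0 * s02 + df * s2f) / (d0 + df)
  list(prior_df = d0, prior_var = s02, post_var = post, post_df = df + d0)
}

#' Moderated differential-methylation test
#'
#' Per-probe comparison of M-values between `treatment` and `reference`.
#' With `paired = TRUE` (the default, matching a design where both
#' conditions derive from the same donors) the statistic is a one-sample t
#' on within-donor differences; otherwise a pooled two-sample t. With
#' `shrink = TRUE` residual variances are shrunk toward a pooled prior
#' estimated by method of moments on log-variances (empirical Bayes), and
#' the t is referred to a t-distribution with `df + prior_df` degrees of
#' freedom. `shrink = FALSE` gives the ordinary (unmoderated) t-test.
#'
#' Probes with missing values are tested on the available samples and
#' flagged; probes with fewer than 2 usable values per condition (complete
#' pairs, for a paired design) receive `t = 0`, `p = 1` and flag
#' `"insufficient_n"`.
#'
#' @param m Numeric matrix of M-values, probes x samples, with `colnames`
#'   matching `sheet$sample_id`.
#' @param sheet Sample sheet `data.frame` (`sample_id`, `condition`,
#'   `donor`).
#' @param paired Logical; donor-blocked design (default `TRUE`).
#' @param shrink Logical; apply empirical-Bayes variance shrinkage
#'   (default `TRUE`).
#' @param max_prior_df Cap on the estimated prior degrees of freedom,
#'   representing an effectively infinite prior cleanly; default `1e6`.
#' @return A `data.frame` of class `DiffMethTable` with columns `probe_id`,
#'   `delta_m` (treatment minus reference), `t_stat`, `p`, `df_total`,
#'   `n_ref`, `n_trt`, `flag`.
#' @export
moderated_diff_test <- function(m, sheet, paired = TRUE, shrink = TRUE,
                                max_prior_df = 1e6) {
  stopifnot(is.matrix(m))
  validate_sample_sheet(sheet, paired = paired)
  if (!all(sheet$sample_id %in% colnames(m)))
    stop("M-value matrix is missing sample(s): ",
         paste(setdiff(sheet$sample_id, colnames(m)), collapse = ", "))
  ref_ids <- sheet$sample_id[sheet$condition == "reference"]
  trt_ids <- sheet$sample_id[sheet$condition == "treatment"]
  if (paired) {
    donors <- sheet$donor[match(ref_ids, sheet$sample_id)]
    trt_ids <- sheet$sample_id[sheet$condition == "treatment"][
      match(donors, sheet$donor[sheet$condition == "treatment"])]
    d <- m[, trt_ids, drop = FALSE] - m[, ref_ids, drop = FALSE]
    n <- rowSums(!is.na(d))
    effect <- rowMeans(d, na.rm = TRUE)
    s2 <- row_vars(d, n)
    df <- pmax(n - 1, 0)
    se_unit2 <- 1 / n
    n_ref <- n_trt <- n
  } else {
    mr <- m[, ref_ids, drop = FALSE]
    mt <- m[, trt_ids, drop = FALSE]
    n1 <- rowSums(!is.na(mr))
    n2 <- rowSums(!is.na(mt))
    v1 <- row_vars(mr, n1)
    v2 <- row_vars(mt, n2)
    effect <- rowMeans(mt, na.rm = TRUE) - rowMeans(mr, na.rm = TRUE)
    df <- pmax(n1 + n2 - 2, 0)
    s2 <- ifelse(df > 0,
                 (pmax(n1 - 1, 0) * ifelse(is.na(v1), 0, v1) +
                    pmax(n2 - 1, 0) * ifelse(is.na(v2), 0, v2)) / pmax(df, 1),
                 NA_real_)
    se_unit2 <- 1 / n1 + 1 / n2
    n_ref <- n1
    n_trt <- n2
  }

  usable <- if (paired) n_ref >= 2 else (n_ref >= 2 & n_trt >= 2)
  incomplete <- if (paired) n_ref < length(ref_ids) else
    (n_ref < length(ref_ids) | n_trt < length(trt_ids))

  if (shrink) {
    sq <- squeeze_variances(s2[usable], df[usable], max_prior_df)
    post_var <- s2
    post_df <- df
    post_var[usable] <- sq$post_var
    post_df[usable] <- sq$post_df
  } else {
    post_var <- s2
    post_df <- df
    sq <- list(prior_df = 0, prior_var = NA_real_)
  }

  t_stat <- rep(0, nrow(m))
  p <- rep(1, nrow(m))
  idx <- which(usable)
  tt <- effect[idx] / sqrt(post_var[idx] * se_unit2[idx])
  tt[effect[idx] == 0] <- 0
  pv <- 2 * stats::pt(-abs(tt), df = post_df[idx])
  pv <- pmax(pv, .Machine$double.xmin)
  pv <- pmin(pv, 1)
  t_stat[idx] <- tt
  p[idx] <- pv

  flag <- rep("", nrow(m))
  flag[incomplete] <- "partial_data"
  flag[!usable] <- "insufficient_n"

  out <- data.frame(probe_id = rownames(m),
                    delta_m = effect,
                    t_stat = t_stat,
                    p = p,
                    df_total = post_df,
                    n_ref = n_ref,
                    n_trt = n_trt,
                    flag = flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior_df") <- sq$prior_df
  attr(out, "prior_var") <- sq$prior_var
  class(out) <- c("DiffMethTable", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (the default), with Bonferroni and Holm available.
#' Output order matches input order; `adj_p >= p` elementwise.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @param method `"BH"`, `"bonferroni"` or `"holm"`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni", "holm")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Classify CpGs as hypo-, hyper-methylated or non-significant
#'
#' A probe is `hypo` when `adj_p <= alpha` and `delta_m < 0`, `hyper` when
#' `adj_p <= alpha` and `delta_m > 0`, otherwise `ns`. Counts are reported
#' via `message()`.
#'
#' @param table A `DiffMethTable` carrying `adj_p` and `delta_m`.
#' @param alpha Significance threshold on the adjusted p (default `0.05`).
#' @return The table with a `class` column added.
#' @seealso [diff_sets()] to extract the hypo/hyper probe-id sets.
#' @export
classify_cpgs <- function(table, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value in (0, 1)")
  if (is.null(table$adj_p)) stop("classify_cpgs: adj_p column is required")
  cls <- rep("ns", nrow(table))
  sig <- table$adj_p <= alpha & table$delta_m != 0
  cls[sig & table$delta_m < 0] <- "hypo"
  cls[sig & table$delta_m > 0] <- "hyper"
  table$class <- cls
  message("classify_cpgs: ", sum(cls != "ns"), " significant (",
          sum(cls == "hypo"), " hypo, ", sum(cls == "hyper"),
          " hyper) of ", nrow(table), " probes at adjusted p <= ", alpha)
  table
}

#' Extract hypo/hyper probe-id sets from a classified table
#'
#' @param table A classified `DiffMethTable` (with `class` column).
#' @return `list(hypo = , hyper = )` of probe-id character vectors.
#' @export
diff_sets <- function(table) {
  if (is.null(table$class)) stop("diff_sets: run classify_cpgs first")
  list(hypo = table$probe_id[table$class == "hypo"],
       hyper = table$probe_id[table$class == "hyper"])
}

#' Full differential-methylation stage
#'
#' Convenience wrapper: transforms beta to M, runs the moderated test,
#' attaches the beta-scale effect size (difference of per-condition mean
#' beta), adjusts p-values and classifies probes.
#'
#' @param beta Numeric matrix of beta-values, probes x samples.
#' @param sheet Sample sheet `data.frame`.
#' @param paired,shrink,alpha,clip_epsilon,adjust Passed through; see
#'   [moderated_diff_test()], [classify_cpgs()], [beta_to_m()],
#'   [bh_adjust()].
#' @return A classified `DiffMethTable` with columns `probe_id`,
#'   `delta_beta`, `delta_m`, `t_stat`, `p`, `adj_p`, `class` (plus
#'   bookkeeping columns).
#' @export
diff_methylation <- function(beta, sheet, paired = TRUE, alpha = 0.05,
                             clip_epsilon = 1e-3, shrink = TRUE,
                             adjust = "BH") {
  m <- beta_to_m(beta, clip_epsilon)
  tab <- moderated_diff_test(m, sheet, paired = paired, shrink = shrink)
  ref_ids <- sheet$sample_id[sheet$condition == "reference"]
  trt_ids <- sheet$sample_id[sheet$condition == "treatment"]
  tab$delta_beta <- rowMeans(beta[, trt_ids, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, ref_ids, drop = FALSE], na.rm = TRUE)
  tab$adj_p <- bh_adjust(tab$p, method = adjust)
  tab <- classify_cpgs(tab, alpha = alpha)
  cols <- c("probe_id", "delta_beta", "delta_m", "t_stat", "p", "adj_p",
            "class", "df_total", "n_ref", "n_trt", "flag")
  out <- tab[, cols]
  attr(out, "prior_df") <- attr(tab, "prior_df")
  attr(out, "alpha") <- alpha
  class(out) <- c("DiffMethTable", "data.frame")
  out
}
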