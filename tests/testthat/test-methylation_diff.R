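test_that("beta-to-M transformation hits its exact landmarks and round-trips", {
  expect_identical(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  # clipping at the boundaries, against direct high-precision evaluation
  expect_equal(beta_to_m(0, clip_epsilon = 0.001),
               log(0.001 / 0.999) / log(2), tolerance = 1e-14)
  expect_equal(beta_to_m(1, clip_epsilon = 0.001),
               -log(0.001 / 0.999) / log(2), tolerance = 1e-14)
  b <- seq(0.01, 0.99, by = 0.007)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  # antisymmetry around 0.5
  expect_equal(beta_to_m(b), -beta_to_m(1 - b), tolerance = 1e-12)
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  expect_error(beta_to_m(-0.1), "\\[0, 1\\]")
  expect_error(beta_to_m(0.5, clip_epsilon = 0.7), "clip_epsilon")
})

test_that("probes identical across conditions give t = 0, p = 1", {
  sheet <- make_sheet(3)
  m <- matrix(rep(c(1.5, -2, 0.25), each = 6), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), sheet$sample_id))
  for (paired in c(TRUE, FALSE)) {
    tab <- moderated_diff_test(m, sheet, paired = paired)
    expect_equal(tab$t_stat, c(0, 0, 0))
    expect_equal(tab$p, c(1, 1, 1))
  }
})

test_that("without shrinkage the moderated test reduces to the textbook
          t-test (paired and unpaired)", {
  set.seed(7)
  sheet <- make_sheet(4)
  m <- matrix(rnorm(100 * 8), nrow = 100,
              dimnames = list(sprintf("p%03d", 1:100), sheet$sample_id))
  ref <- sheet$sample_id[sheet$condition == "reference"]
  trt <- sheet$sample_id[sheet$condition == "treatment"]

  tab <- moderated_diff_test(m, sheet, paired = TRUE, shrink = FALSE)
  for (i in 1:100) {
    tt <- t.test(m[i, trt], m[i, ref], paired = TRUE)
    expect_equal(tab$t_stat[i], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-8)
    expect_equal(tab$delta_m[i], unname(tt$estimate), tolerance = 1e-8)
  }
  tab2 <- moderated_diff_test(m, sheet, paired = FALSE, shrink = FALSE)
  for (i in 1:100) {
    tt <- t.test(m[i, trt], m[i, ref], var.equal = TRUE)
    expect_equal(tab2$t_stat[i], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(tab2$p[i], tt$p.value, tolerance = 1e-8)
  }
})

test_that("moderated test agrees with an independent empirical-Bayes
          implementation", {
  skip_if_not_installed("limma")
  set.seed(11)
  n <- 500
  sheet <- make_sheet(3)
  sig <- sqrt(1 / rgamma(n, shape = 2, rate = 2))  # heteroscedastic truth
  m <- matrix(rnorm(n * 6, sd = rep(sig, 6)), nrow = n,
              dimnames = list(sprintf("p%04d", 1:n), sheet$sample_id))
  tab <- moderated_diff_test(m, sheet, paired = TRUE)
  donor <- factor(sheet$donor)
  cond <- factor(sheet$condition, c("reference", "treatment"))
  design <- stats::model.matrix(~ donor + cond)
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(attr(tab, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(tab$t_stat, fit$t[, "condtreatment"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(tab$p, fit$p.value[, "condtreatment"], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("p-values are calibrated on a null matrix", {
  set.seed(5)
  sheet <- make_sheet(3)
  m <- matrix(rnorm(2000 * 6), nrow = 2000,
              dimnames = list(sprintf("p%04d", 1:2000), sheet$sample_id))
  tab <- moderated_diff_test(m, sheet, paired = TRUE)
  frac <- mean(tab$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("missing values are tolerated and under-powered probes flagged", {
  sheet <- make_sheet(3)
  m <- matrix(rnorm(3 * 6), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), sheet$sample_id))
  m[2, "ref_d1"] <- NA            # one incomplete pair
  m[3, c("ref_d1", "ref_d2")] <- NA  # < 2 complete pairs
  tab <- moderated_diff_test(m, sheet, paired = TRUE)
  expect_equal(tab$flag, c("", "partial_data", "insufficient_n"))
  expect_equal(tab$p[3], 1)
  expect_equal(tab$t_stat[3], 0)
  expect_error(
    moderated_diff_test(m[, 1:3],
                        sheet[sheet$condition == "reference", ]),
    ">= 2 samples")
})

test_that("BH adjustment matches the hand-computed step-up and keeps order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("classification respects the alpha threshold and effect sign", {
  tab <- data.frame(probe_id = c("a", "b", "c"),
                    delta_m = c(-1.2, 0.8, -2),
                    p = c(1e-4, 1e-4, 0.05),
                    adj_p = c(0.04, 0.04, 0.06))
  out <- suppressMessages(classify_cpgs(tab, alpha = 0.05))
  expect_equal(out$class, c("hypo", "hyper", "ns"))
  expect_error(classify_cpgs(tab, alpha = 0), "alpha")
  expect_error(classify_cpgs(tab, alpha = 1.5), "alpha")
  # monotonicity: larger alpha never shrinks the significant set
  lo <- suppressMessages(classify_cpgs(tab, alpha = 0.045))
  hi <- suppressMessages(classify_cpgs(tab, alpha = 0.07))
  expect_true(all(which(lo$class != "ns") %in% which(hi$class != "ns")))
})

test_that("swapping condition labels swaps hypo and hyper exactly and
          negates the effect", {
  set.seed(21)
  sim <- simulate_all(preset_config("tiny", seed = 21))
  d1 <- suppressMessages(diff_methylation(sim$beta, sim$sample_sheet))
  flipped <- sim$sample_sheet
  flipped$condition <- ifelse(flipped$condition == "reference",
                              "treatment", "reference")
  d2 <- suppressMessages(diff_methylation(sim$beta, flipped))
  expect_equal(d2$delta_m, -d1$delta_m)
  expect_equal(d2$p, d1$p)
  s1 <- diff_sets(d1); s2 <- diff_sets(d2)
  expect_identical(s1$hypo, s2$hyper)
  expect_identical(s1$hyper, s2$hypo)
})

test_that("planted differential CpGs are recovered in the right direction", {
  sim <- simulate_all(sim_config(seed = 1, n_probes = 5000L,
                                 n_planted_diff = 200L,
                                 planted_hypo_frac = 0))
  d <- suppressMessages(diff_methylation(sim$beta, sim$sample_sheet))
  planted <- sim$ground_truth$planted_hyper
  called <- d$class[match(planted, d$probe_id)]
  expect_gte(mean(called == "hyper"), 0.6)
  # no planted probe called in the wrong direction
  expect_equal(sum(called == "hypo"), 0)
})
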