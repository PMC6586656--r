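test_that("candidate filtering applies strict thresholds row-wise", {
  tab <- data.frame(
    transcript_id = paste0("t", 1:6),
    tpm_control = c(300, 300, 300, 100, 300, 300),
    tpm_heat_shock = c(400, 400, 400, 120, 400, 400),
    log2fc = c(5, 1.0, 5, 5, 5, "oops"),
    padj = c(1e-6, 1e-6, 0.001, 1e-6, NA, 1e-6),
    stringsAsFactors = FALSE)
  expect_warning(out <- filter_de(tab), "missing padj")
  expect_equal(out$de_significant, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$abundant, c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$candidate, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(attr(out, "row_errors")$row, 6L)
})

test_that("filter_de flag counts equal brute-force row evaluation on generated tables", {
  for (cfgcase in list(c(155L, 23L), c(108L, 19L), c(40L, 0L))) {
    de <- gen_de_table(77L + cfgcase[1L], cfgcase[1L], cfgcase[2L])
    out <- suppressWarnings(filter_de(de))
    expect_equal(sum(out$candidate), cfgcase[2L])
    # brute-force row check
    manual <- abs(de$log2fc) > 1 & !is.na(de$padj) & de$padj < 0.001 &
      (de$tpm_control + de$tpm_heat_shock) / 2 > 200
    manual[is.na(manual)] <- FALSE
    expect_equal(out$candidate, manual)
    expect_equal(out$candidate, attr(de, "truth")$planted_pass)
  }
})

test_that("reference-gene QC discards the right samples for the right reasons", {
  tab <- data.frame(
    sample_id = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = "control",
    gene = rep(c("gapdh", "hsp70"), 4),
    cq = c(31, 20, 25, 21, 25, 22, NA, 23),
    minus_rt_cq = c(NA, NA, 28, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  qc <- qc_cq(tab)
  expect_equal(qc$discarded$sample_id, c("s1", "s2", "s4"))
  expect_equal(qc$discarded$reason,
               c("below_detection", "contaminated", "below_detection"))
  expect_equal(unique(qc$kept$sample_id), "s3")

  noref <- data.frame(sample_id = "s9", group = "control", gene = "hsp70",
                      cq = 22, minus_rt_cq = NA, stringsAsFactors = FALSE)
  expect_equal(qc_cq(noref)$discarded$reason, "missing_reference")
})

test_that("delta-Cq subtracts the reference and censors undetected targets", {
  tab <- data.frame(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    group = c("control", "control", "heat_shock", "heat_shock",
              "control", "control"),
    gene = rep(c("gapdh", "hsp70"), 3),
    cq = c(20, 25, 25, 20, 20, NA),
    minus_rt_cq = NA_real_, stringsAsFactors = FALSE)
  d <- delta_cq(tab)
  expect_equal(d$delta_cq[d$sample_id == "s1"], 5)
  expect_equal(d$delta_cq[d$sample_id == "s2"], -5)
  expect_true(d$censored[d$sample_id == "s3"])
})

test_that("the exact two-sided Mann-Whitney p matches complete enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$method, "exact")
  expect_equal(mw$U, 0)

  same <- mann_whitney(c(3, 1, 2), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)

  expect_error(mann_whitney(numeric(0), 1), "non-empty")

  set.seed(61)
  for (i in 1:40) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    # integer draws guarantee ties are exercised
    a <- sample(1:6, n, TRUE); b <- sample(1:6, m, TRUE)
    expect_equal(mann_whitney(a, b)$p_value, oracle_mw_p(a, b),
                 info = paste("case", i))
  }
})

test_that("exact and normal-approximation p-values agree for tie-free 6v6 draws", {
  set.seed(62)
  diffs <- replicate(500, {
    a <- rnorm(6); b <- rnorm(6)
    exact <- mann_whitney(a, b, exact_max_n = 12L)$p_value
    approx <- mann_whitney(a, b, exact_max_n = 0L)$p_value
    abs(exact - approx)
  })
  expect_lt(max(diffs), 0.02 + 1e-12)
})

test_that("the exact test holds its size under the null", {
  # With continuous data the p-value is discrete: the attained size at a
  # nominal alpha is the largest achievable rejection probability <= alpha,
  # derived here from the exact null distribution of U for 6 vs 6.
  n <- 6L
  r <- seq_len(2L * n)
  labelings <- combn(2L * n, n)
  u_null <- colSums(matrix(r[labelings], nrow = n)) - n * (n + 1) / 2
  dev <- abs(u_null - n * n / 2)
  p_null <- vapply(dev, function(d) mean(dev >= d - 1e-9), numeric(1))
  attained <- mean(p_null <= 0.05)

  set.seed(63)
  n_rep <- 10000L
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    a <- rnorm(n); b <- rnorm(n)
    if (mann_whitney(a, b)$p_value <= 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  se <- sqrt(attained * (1 - attained) / n_rep)
  expect_lt(abs(rate - attained), 3 * se)
  expect_lte(rate, 0.05)  # never anti-conservative
})

test_that("Holm adjustment is monotone and conservative, matching step-down arithmetic", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.03, 0.01, 0.04)), c(0.06, 0.03, 0.06))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # independent step-down arithmetic: sort, multiply by m-i+1, cummax, cap
  oracle_holm <- function(ps) {
    m <- length(ps)
    o <- order(ps)
    pmin(1, cummax((m - seq_len(m) + 1L) * ps[o]))[order(o)]
  }
  set.seed(64)
  for (i in 1:20) {
    ps <- runif(sample(2:8, 1))
    adj <- holm_adjust(ps)
    expect_true(all(adj >= ps))
    expect_true(all(adj <= 1))
    o <- order(ps)
    expect_true(all(diff(adj[o]) >= -1e-12))
    expect_equal(adj, oracle_holm(ps))
    # fixed point once every hypothesis is at the cap
    expect_equal(holm_adjust(rep(1, length(ps))), rep(1, length(ps)))
  }
})

test_that("the full qPCR pipeline reports per-gene tests with Holm-adjusted p", {
  cq <- gen_cq_table(65, n_per_group = 6L, effect_size = -6,
                     target_genes = c("frag_I", "frag_II"),
                     n_below_detection = 1L)
  res <- qpcr_analysis(cq)
  expect_equal(res$discarded$sample_id, attr(cq, "truth")$planted_bad)
  expect_equal(nrow(res$tests), 2L)
  expect_true(all(res$tests$p_holm >= res$tests$p_value))
  expect_true(all(res$tests$method == "exact"))
  expect_true(all(res$tests$p_holm < 0.05))
})
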