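test_that("generators are deterministic in their seed and leave the RNG alone", {
  expect_identical(gen_protein(3)$sequence, gen_protein(3)$sequence)
  expect_false(identical(gen_protein(3)$sequence, gen_protein(4)$sequence))
  expect_identical(gen_promoter(5, 100)$sequence, gen_promoter(5, 100)$sequence)
  expect_identical(gen_de_table(6, 30, 5), gen_de_table(6, 30, 5))
  expect_identical(gen_cq_table(7), gen_cq_table(7))

  set.seed(99); before <- runif(3)
  set.seed(99); invisible(gen_protein(3)); invisible(gen_de_table(6, 10, 2))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("planted proteins carry their truth sidecar and classify as planted", {
  p <- gen_protein(201, "inducible")
  tr <- attr(p, "truth")
  expect_equal(tr$type, "inducible")
  expect_true(all(tr$motifs$end >= tr$motifs$start))
  # the sidecar is sufficient to locate every planted motif
  atp <- tr$motifs[tr$motifs$name == "ATP", ]
  expect_equal(substr(p$sequence, atp$start, atp$end), "SEAYLGKE")
  expect_equal(classify_hsp70(profile_signatures(p))$inducibility,
               "heat_inducible")

  c2 <- gen_protein(202, "cognate")
  expect_equal(classify_hsp70(profile_signatures(c2))$inducibility,
               "cognate_like")
  n3 <- gen_protein(203, "noncytosolic")
  expect_equal(classify_hsp70(profile_signatures(n3))$localization,
               "non_cytosolic")
  expect_error(gen_protein(204, length = 100L), "320")
})

test_that("promoter fixtures plant exactly the requested elements", {
  pr <- gen_promoter(211, distances = c(60L, 300L),
                     classes = c("canonical", "hse_like"))
  tr <- attr(pr, "truth")
  hits <- find_hse(pr)
  expect_equal(nrow(hits), 2L)
  expect_equal(sort(hits$start), sort(tr$elements$start))
  expect_equal(hits$hse_class[order(hits$start)],
               tr$elements$class[order(tr$elements$start)])
  for (i in seq_len(nrow(hits))) {
    d <- upstream_distance(hits[i, ], tr$orf_start)
    expect_true(d %in% tr$elements$distance)
  }

  empty <- gen_promoter(212, distances = integer(0), length = 800L)
  expect_equal(nrow(find_hse(empty)), 0L)

  both <- gen_promoter(213, distances = c(40L, 200L), strands = c("+", "-"))
  h2 <- find_hse(both)
  expect_equal(sort(h2$start), sort(attr(both, "truth")$elements$start))
  expect_true(all(h2$hse_class == "canonical"))

  expect_error(gen_promoter(214, distances = 5000L, length = 1000L),
               "do not fit")
})

test_that("DE tables plant the exact pass count with all failure modes covered", {
  de <- gen_de_table(221, 108, 19)
  out <- suppressWarnings(filter_de(de))
  expect_equal(sum(out$candidate), 19L)
  fails <- out[!attr(de, "truth")$planted_pass, ]
  expect_true(any(abs(fails$log2fc) <= 1))
  expect_true(any(!is.na(fails$padj) & fails$padj >= 0.001))
  expect_true(any((fails$tpm_control + fails$tpm_heat_shock) / 2 <= 200))
  expect_true(any(is.na(fails$padj)))

  none <- gen_de_table(222, 20, 0)
  expect_equal(sum(suppressWarnings(filter_de(none))$candidate), 0L)
})

test_that("Cq tables give the planted effect the expected statistical power", {
  # strong induction: rejection at alpha = 0.01 in nearly every draw
  hits <- 0L
  for (s in 1:200) {
    cq <- gen_cq_table(s, n_per_group = 6L, effect_size = -6)
    res <- qpcr_analysis(cq)
    if (res$tests$p_value <= 0.01) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)

  # null effect: rejection rate compatible with the attained size at 0.05
  null_hits <- 0L
  for (s in 1:1000) {
    cq <- gen_cq_table(10000L + s, n_per_group = 6L, effect_size = 0)
    if (qpcr_analysis(cq)$tests$p_value <= 0.05) null_hits <- null_hits + 1L
  }
  expect_lt(null_hits / 1000, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))

  # planted QC failure is discarded, and only it
  cq <- gen_cq_table(223, n_below_detection = 1L)
  res <- qpcr_analysis(cq)
  expect_equal(res$discarded$sample_id, attr(cq, "truth")$planted_bad)
  expect_equal(res$discarded$reason, "below_detection")
})
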