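test_that("motif grammar handles wildcards, alternatives and errors", {
  nls <- parse_motif("KKXXXXXXXXXRRLRT")
  expect_length(nls$positions, 16L)
  expect_true(all(vapply(nls$positions[3:11], identical, logical(1), "X")))

  atp <- parse_motif("S(A)EAYLGK(G)E(A)")
  expect_length(atp$positions, 8L)
  expect_equal(atp$positions[[1]], c("A", "S"))
  expect_equal(atp$positions[[7]], c("G", "K"))
  expect_equal(atp$positions[[8]], c("A", "E"))

  expect_error(parse_motif("(A)SEAYL"), "leading")
  expect_error(parse_motif("S(AB)E"), "exactly one letter")
  expect_error(parse_motif("S()E"), "exactly one letter")
})

test_that("scan_motif finds planted motifs and respects mismatch identity", {
  set.seed(21)
  backbone <- random_protein_str(641)
  planted <- paste0(substr(backbone, 1, 130), "SEAYLGKE",
                    substr(backbone, 139, 641))
  rec <- make_protein_record(planted)
  atp_ind <- hsp70_signatures()[["ATP_inducible"]]
  hits <- scan_motif(rec, atp_ind)
  expect_true(any(hits$start == 131L & hits$end == 138L))

  # the cognate ATP motif is not a hit for the inducible pattern at 0 mm
  cog <- make_protein_record(paste0(substr(backbone, 1, 130), "ADAYLGTN",
                                    substr(backbone, 139, 641)))
  expect_equal(nrow(scan_motif(cog, atp_ind)), 0L)

  # all-wildcard pattern hits every window
  wild <- parse_motif("XXXX")
  short <- make_protein_record(random_protein_str(10))
  expect_equal(scan_motif(short, wild)$start, 1:7)

  # pattern longer than sequence yields no hits
  expect_equal(nrow(scan_motif(make_protein_record("MK"), atp_ind)), 0L)
})

test_that("scan_motif equals the naive set-membership oracle on random cases", {
  set.seed(22)
  for (i in 1:200) {
    pat <- random_pattern()
    s <- random_protein_str(sample(20:200, 1L))
    got <- scan_motif(make_protein_record(s), pat)$start
    expect_equal(got, oracle_scan(s, pat), info = paste("case", i))
  }
})

test_that("profiles of planted fixtures carry the planted signatures only", {
  ind <- gen_protein(101, "inducible")
  prof <- profile_signatures(ind)
  for (nm in c("IDLGTTYS", "ATP_inducible", "RARFEEM", "GPTIEEVD",
               "EEVD_tail", "Nterm_inducible", "NLS", "phosphate_binding")) {
    expect_gt(nrow(prof$hits[[nm]]), 0L)
  }
  expect_equal(nrow(prof$hits[["ATP_cognate"]]), 0L)
  expect_equal(nrow(prof$hits[["Nterm_cognate"]]), 0L)

  cog <- gen_protein(102, "cognate")
  prof2 <- profile_signatures(cog)
  expect_gt(nrow(prof2$hits[["ATP_cognate"]]), 0L)
  expect_gt(nrow(prof2$hits[["Nterm_cognate"]]), 0L)
  expect_equal(nrow(prof2$hits[["ATP_inducible"]]), 0L)

  # signature-free random sequence: verify each entry against the oracle
  set.seed(23)
  s <- random_protein_str(300)
  prof3 <- profile_signatures(make_protein_record(s))
  for (nm in names(prof3$hits)) {
    expect_equal(prof3$hits[[nm]]$start,
                 oracle_scan(s, hsp70_signatures()[[nm]]), info = nm)
  }
})

test_that("classification rules fire in order with conflict awareness", {
  ind <- classify_hsp70(profile_signatures(gen_protein(103, "inducible")))
  expect_true(ind$is_family_member)
  expect_equal(ind$localization, "cytosolic")
  expect_equal(ind$inducibility, "heat_inducible")
  expect_equal(ind$score, 3L)

  noncyt <- classify_hsp70(profile_signatures(gen_protein(104, "noncytosolic")))
  expect_equal(noncyt$localization, "non_cytosolic")

  # conflicting ATP-site evidence -> undetermined inducibility
  set.seed(24)
  s <- random_protein_str(400)
  s <- paste0("IDLGTTYS", substr(s, 9, 100), "NEPTAA",
              substr(s, 107, 200), "SEAYLGKE",
              substr(s, 209, 300), "ADAYLGTN", substr(s, 309, 400))
  both <- classify_hsp70(profile_signatures(make_protein_record(s)))
  expect_true(both$is_family_member)
  expect_equal(both$inducibility, "undetermined")
  expect_true(length(both$conflicts) > 0L)

  # non-family: fewer than 2 family signatures
  set.seed(25)
  rnd <- classify_hsp70(profile_signatures(
    make_protein_record(random_protein_str(200))))
  expect_false(rnd$is_family_member)
  expect_equal(rnd$inducibility, "undetermined")
})

test_that("planted types are fully recovered at zero mutation and recovery never improves with mutation", {
  recovered <- function(n, mutations) {
    types <- rep(c("inducible", "cognate", "noncytosolic"), length.out = n)
    hits <- 0L
    for (i in seq_len(n)) {
      p <- gen_protein(1000L + i + 7919L * mutations, types[i],
                       mutations = mutations)
      cls <- classify_hsp70(profile_signatures(p))
      want_ind <- if (types[i] == "cognate") "cognate_like" else "heat_inducible"
      want_loc <- switch(types[i], inducible = "cytosolic",
                         cognate = "cytosolic", noncytosolic = "non_cytosolic")
      if (cls$inducibility == want_ind && cls$localization == want_loc &&
          cls$is_family_member) {
        hits <- hits + 1L
      }
    }
    hits / n
  }
  expect_equal(recovered(60L, 0L), 1.0)
  r <- vapply(c(0L, 4L, 12L, 30L), function(m) recovered(30L, m), numeric(1))
  expect_true(all(diff(r) <= 0L + 1e-9))
})

test_that("domain mapping is exact under self-alignment and tracks indels", {
  ref_rec <- gen_protein(105)
  ref <- reference_model(ref_rec$sequence, "synthetic-ref")
  self <- map_domains(seq_record("self", ref$aa_sequence, "protein"), ref)
  expect_equal(self$domains$q_start, ref$domains$start)
  expect_equal(self$domains$q_end, ref$domains$end)
  expect_equal(self$domains$coverage, rep(1, 3))
  expect_false(self$low_identity)

  # two extra residues inserted after position 190 shift the NBD end to 392
  q <- paste0(substr(ref$aa_sequence, 1, 190), "GG",
              substr(ref$aa_sequence, 191, 641))
  md <- map_domains(seq_record("ins", q, "protein"), ref)
  expect_equal(md$domains$q_end[md$domains$domain == "NBD"], 392L)

  # a 298-residue fragment: partial NBD, absent CTD, no identity warning
  frag <- substr(ref$aa_sequence, 217, 514)
  mf <- map_domains(seq_record("frag", frag, "protein"), ref)
  expect_lt(mf$domains$coverage[mf$domains$domain == "NBD"], 1)
  expect_equal(mf$domains$coverage[mf$domains$domain == "CTD"], 0)
  expect_false(mf$low_identity)
})

test_that("region extraction matches reference coordinates", {
  ref_rec <- gen_protein(106)
  ref <- reference_model(ref_rec$sequence)
  full <- extract_region(ref_rec, 1, 641, ref)
  expect_equal(full$sequence, ref$aa_sequence)
  # literal slice lengths for query = reference
  set.seed(26)
  for (i in 1:25) {
    s <- sort(sample(641, 2L))
    expect_equal(extract_region(ref_rec, s[1], s[2], ref)$length,
                 s[2] - s[1] + 1L)
  }
  expect_error(extract_region(ref_rec, 514, 217, ref), "ref_start")
  expect_error(extract_region(ref_rec, 1, 700, ref), "exceeds")
})
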