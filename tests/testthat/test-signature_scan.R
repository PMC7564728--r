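sig <- parse_prosite(thaumatin_signature())

test_that("PROSITE parser compiles literals, classes and repeats", {
  p <- parse_prosite("C-Q-T-G-D-C-G-G")
  expect_length(p, 8L)
  expect_true(all(vapply(p, `[[`, character(1), "kind") == "literal"))
  expect_equal(attr(p, "min_len"), 8L)
  expect_equal(attr(p, "max_len"), 8L)

  expect_length(sig, 14L)
  expect_equal(attr(sig, "min_len"), 15L)
  expect_equal(attr(sig, "max_len"), 17L)
  # cross-check length bounds by brute-force expansion of repeat choices
  reps <- lapply(sig, function(el) seq.int(el$min_repeat, el$max_repeat))
  widths <- rowSums(expand.grid(reps))
  expect_equal(range(widths), c(15, 17))

  # attached and dash-separated repeat suffixes are equivalent
  p1 <- parse_prosite("G-x(1,2)-C")
  p2 <- parse_prosite("G-x-(1,2)-C")
  expect_equal(unclass(p1), unclass(p2), ignore_attr = TRUE)
})

test_that("PROSITE parser reports malformed patterns by position", {
  expect_error(parse_prosite("G-x("), "position 2")
  expect_error(parse_prosite("G-[GF"), "position 2")
  expect_error(parse_prosite("G-[]-C"), "empty class")
  expect_error(parse_prosite("G-x(3,2)"), "maximum 2 < minimum 3")
  expect_error(parse_prosite("G-{P}-C"), "unsupported")
  expect_error(parse_prosite("<G-C"), "unsupported|cannot parse")
  expect_error(parse_prosite("G--C"), "empty element")
  expect_error(parse_prosite("(2)-G"), "no preceding element")
})

test_that("signature scan finds the documented matches", {
  m <- scan_signature("AAAGAGACATGDCGGAACAAA", sig)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 4L)
  expect_equal(m$end, 18L)
  expect_equal(m$matched, "GAGACATGDCGGAAC")

  # shorter than min_len: no match even though the motif core is present
  expect_equal(nrow(scan_signature("CQTGDCGG", sig)), 0L)

  # the carbohydrate-binding motif can sit inside the signature
  m2 <- scan_signature("GAGACQTGDCGGAAC", sig)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(1L, 15L))
})

test_that("scanner agrees exactly with the brute-force matcher", {
  withr::local_seed(421)
  n_checked <- 0L
  for (case in 1:120) {
    pat <- try(parse_prosite(random_pattern_text()), silent = TRUE)
    if (inherits(pat, "try-error")) next
    s <- random_sequence(sample(5:60, 1))
    got <- scan_signature(s, pat)
    want <- brute_force_shortest(s, pat)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # all-expansions mode agrees with the full enumeration
    got_all <- scan_signature(s, pat, all_expansions = TRUE)
    want_all <- brute_force_scan(s, pat)
    expect_equal(got_all[order(got_all$start, got_all$end), c("start", "end")],
                 want_all, ignore_attr = TRUE)
    # every reported match length lies within the pattern bounds
    if (nrow(got_all)) {
      len <- got_all$end - got_all$start + 1L
      expect_true(all(len >= attr(pat, "min_len") & len <= attr(pat, "max_len")))
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("matched subsequence equals the protein slice at its coordinates", {
  withr::local_seed(77)
  for (i in 1:20) {
    d <- design_protein(sample(60:120, 1), 5, TRUE,
                        sample(c("none", "canonical", "variant"), 1))
    m <- scan_signature(d$sequence, sig)
    expect_equal(m$matched, substring(d$sequence, m$start, m$end))
  }
})

test_that("CBM detection distinguishes canonical, variant and absence", {
  r <- detect_cbm("AACQTGDCGGAA")
  expect_true(r$canonical)
  expect_false(r$variant)
  expect_equal(r$canonical_positions, 3L)

  r <- detect_cbm("AACQTGDCQGAA")
  expect_false(r$canonical)
  expect_true(r$variant)
  expect_equal(r$variant_positions, 3L)

  r <- detect_cbm("AACQTADCGGAA")
  expect_false(r$canonical)
  expect_false(r$variant)
  expect_length(r$canonical_positions, 0L)
})

test_that("e-value filter is inclusive at the cutoff", {
  hits <- data.frame(query_id = c("a", "b", "c"), subject_id = "s",
                     e_value = c(1e-30, 1e-10, 1e-9))
  expect_equal(filter_hits(hits, 1e-10)$query_id, c("a", "b"))
  expect_equal(filter_hits(hits, 1e-10, inclusive = FALSE)$query_id, "a")
  expect_equal(nrow(filter_hits(hits[0, ], 1e-10)), 0L)
  expect_equal(nrow(filter_hits(hits, 1)), 3L)
})

test_that("candidate funnel counts stages and collapses loci", {
  prot <- as_protein_table(
    c("g1.1", "g1.2", "g2.1", "g3.1", "g4.1"),
    c("MAAGAGACQTGDCGGAACAAAW",    # signature (locus g1, longer isoform)
      "MAAGAGACQTGDCGGAACAAA",     # signature (locus g1, shorter)
      "MGAGACATGDCGGAACKKKKK",     # signature (locus g2)
      "MAAAAAKKKKKWWWWAAAAAA",     # no signature
      "MGAGACATGDCGGAACAAAAA"))    # signature but fails e-value
  hits <- data.frame(query_id = prot$protein_id, subject_id = "dom",
                     e_value = c(1e-30, 1e-20, 1e-15, 1e-12, 1e-9))
  res <- candidate_funnel(prot, hits)
  rep <- res$report
  expect_equal(rep$n_input_hits, 5L)
  expect_equal(rep$n_after_evalue, 4L)
  expect_equal(rep$n_with_signature, 3L)
  expect_equal(rep$n_unique_loci, 2L)
  expect_equal(rep$retained_ids, c("g1.1", "g2.1"))
  expect_equal(res$tlps$protein_id, c("g1.1", "g2.1"))

  # equal-length isoforms: lexicographically smaller transcript id wins
  prot2 <- as_protein_table(c("g1.2", "g1.1"),
                            rep("MAAGAGACQTGDCGGAACAAA", 2))
  hits2 <- data.frame(query_id = prot2$protein_id, subject_id = "dom",
                      e_value = c(1e-30, 1e-30))
  expect_equal(candidate_funnel(prot2, hits2)$report$retained_ids, "g1.1")

  # hit referencing an unknown protein is an error
  expect_error(candidate_funnel(prot, data.frame(query_id = "nope",
                                                 subject_id = "d",
                                                 e_value = 1e-30)),
               "unknown protein")
})

test_that("funnel counts are monotone non-increasing on random genomes", {
  for (s in c(2, 5, 8)) {
    sim <- make_genome(n_true = 6, n_decoy = 6, n_isoform_extra = 4, seed = s)
    rep <- candidate_funnel(sim$proteome, sim$hits)$report
    expect_true(rep$n_input_hits >= rep$n_after_evalue)
    expect_true(rep$n_after_evalue >= rep$n_with_signature)
    expect_true(rep$n_with_signature >= rep$n_unique_loci)
  }
})
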