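test_that("CDS to protein length arithmetic", {
  expect_equal(protein_length_from_cds(522), 173L)
  expect_equal(protein_length_from_cds(1080), 359L)
  expect_equal(protein_length_from_cds(690), 229L)
  expect_error(protein_length_from_cds(523), "not divisible")
  expect_error(protein_length_from_cds(3), "too short")
})

test_that("gene model constructor enforces interval invariants", {
  expect_error(gene_model("g", "g.1", "1H", "+",
                          exons = rbind(c(10, 40), c(30, 60))),
               "overlapping")
  expect_error(gene_model("g", "g.1", "1H", "+", exons = rbind(c(10, 5))),
               "end < start")
  expect_error(gene_model("g", "g.1", "1H", "+", exons = rbind(c(1, 10))),
               "divisible by 3")
  expect_error(gene_model("g", "g.1", "1H", "+", exons = rbind(c(10, 21)),
                          cds = rbind(c(5, 10))), "outside exons")
  m <- gene_model("g", "g.1", "1H", "-", exons = rbind(c(50, 61), c(10, 21)))
  expect_equal(m$span, c(10L, 61L))
  expect_equal(m$exons[, 1], c(10L, 50L))  # sorted by genomic coordinate
})

test_that("exon-count classification maps counts to groups I-IV/other", {
  res <- classify_by_exons(c(a = 1L, b = 1L, c = 2L, d = 3L, e = 4L))
  expect_equal(res$sizes, c(I = 2L, II = 1L, III = 1L, IV = 1L))
  expect_equal(res$assignments$group, c("I", "I", "II", "III", "IV"))
  expect_equal(exon_group_label(5L), "other")
  expect_equal(sum(res$sizes), 5L)
})

test_that("protein positions map to the correct exon on both strands", {
  # two-exon gene, 90 bp of CDS in exon 1: codon 30 ends exon 1,
  # amino acid 40 starts at spliced nucleotide 118, i.e. exon 2
  plus <- gene_model("g", "g.1", "1H", "+",
                     exons = rbind(c(101, 190), c(301, 402)))
  expect_equal(map_protein_position_to_exon(plus, 30), 1L)
  expect_equal(map_protein_position_to_exon(plus, 31), 2L)
  expect_equal(map_protein_position_to_exon(plus, 40), 2L)
  expect_error(map_protein_position_to_exon(plus, 64), "beyond the CDS")

  # mirrored to the minus strand: exon 1 of the transcript is the
  # genomically-last interval, the ordinal is unchanged
  minus <- gene_model("g", "g.1", "1H", "-",
                      exons = rbind(c(101, 202), c(301, 390)))
  expect_equal(map_protein_position_to_exon(minus, 30), 1L)
  expect_equal(map_protein_position_to_exon(minus, 40), 2L)

  single <- gene_model("g", "g.1", "1H", "+", exons = rbind(c(1, 300)))
  for (pos in c(1, 50, 99)) {
    expect_equal(map_protein_position_to_exon(single, pos), 1L)
  }
})

test_that("exon mapping is consistent with splicing on synthetic models", {
  sim <- make_genome(n_true = 5, n_decoy = 0, n_isoform_extra = 0, seed = 13)
  sig <- parse_prosite(thaumatin_signature())
  for (tx in sim$truth$table$protein_id) {
    m <- sim$models[[tx]]
    seq <- sim$proteome$sequence[sim$proteome$protein_id == tx]
    expect_identical(splice_translate(m, sim$genome[[m$chromosome]]), seq)
    # the signature's start position maps to a valid exon ordinal
    hit <- scan_signature(seq, sig)
    ord <- map_protein_position_to_exon(m, hit$start[1])
    expect_true(ord >= 1L && ord <= nrow(m$exons))
  }
})

test_that("splice-variant summary counts, zero-variant genes and argmax", {
  df <- data.frame(gene_id = c("A", "B", "B", "B", "C"),
                   transcript_id = c("A.1", "B.1", "B.2", "B.3", "C.1"))
  s <- splice_variant_summary(df)
  expect_equal(s$per_gene$n_transcripts, c(1L, 3L, 1L))
  expect_equal(s$per_gene$n_additional_variants, c(0L, 2L, 0L))
  expect_equal(s$zero_variant_genes, c("A", "C"))
  expect_equal(s$max_gene, "B")
  expect_equal(s$max_transcripts, 3L)

  # all singletons: empty max report
  s2 <- splice_variant_summary(data.frame(gene_id = c("A", "B"),
                                          transcript_id = c("A.1", "B.1")))
  expect_true(is.na(s2$max_gene))

  # tie broken by lexicographically smallest gene id
  s3 <- splice_variant_summary(data.frame(
    gene_id = c("Z", "Z", "A", "A"),
    transcript_id = c("Z.1", "Z.2", "A.1", "A.2")))
  expect_equal(s3$max_gene, "A")

  # a gene with 14 transcripts, mirroring the most-spliced barley TLP locus
  big <- data.frame(gene_id = c(rep("G17", 14), "G1"),
                    transcript_id = c(paste0("G17.", 1:14), "G1.1"))
  expect_equal(splice_variant_summary(big)$max_transcripts, 14L)
})

test_that("chromosome distribution tallies and finds tandem candidates", {
  tab <- barley_tlp_table()
  res <- chromosome_distribution(tab)
  expect_equal(res$counts,
               c("1H" = 2L, "3H" = 3L, "4H" = 3L, "5H" = 8L, "7H" = 3L))
  expect_equal(sum(res$counts), 19L)
  # genes ordered by start within chromosome
  for (d in res$by_chromosome) expect_false(is.unsorted(d$start))
  # the 5H cluster near 8.6 Mb appears among tandem candidates
  expect_true(any(res$tandem_pairs$chromosome == "5H"))

  # explicit pair 10 kb apart
  two <- data.frame(gene_symbol = c("a", "b"), chromosome = "5H",
                    start = c(1e5, 1.2e5), end = c(1.1e5, 1.3e5))
  tp <- chromosome_distribution(two)$tandem_pairs
  expect_equal(nrow(tp), 1L)
  expect_equal(tp$gene_a, "a")
  # beyond the threshold: no call
  two$start[2] <- 2e6; two$end[2] <- 2.1e6
  expect_equal(nrow(chromosome_distribution(two)$tandem_pairs), 0L)

  empty <- chromosome_distribution(tab[0, ])
  expect_length(empty$counts, 0L)
})

test_that("GFF3 write/read round trip preserves gene models", {
  sim <- make_genome(n_true = 3, n_decoy = 1, n_isoform_extra = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(sim$models, f)
  back <- read_gene_models(f)
  expect_setequal(names(back), names(sim$models))
  for (tx in names(sim$models)) {
    expect_equal(back[[tx]]$exons, sim$models[[tx]]$exons)
    expect_equal(back[[tx]]$cds, sim$models[[tx]]$cds)
    expect_equal(back[[tx]]$strand, sim$models[[tx]]$strand)
    expect_equal(back[[tx]]$chromosome, sim$models[[tx]]$chromosome)
    expect_equal(back[[tx]]$gene_id, sim$models[[tx]]$gene_id)
  }
})
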