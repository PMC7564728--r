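sig <- parse_prosite(thaumatin_signature())

test_that("designed proteins self-verify against the analysis modules", {
  d <- design_protein(250, 16, with_signature = TRUE,
                      cbm_class = "canonical", seed = 1)
  expect_equal(nchar(d$sequence), 250L)
  expect_equal(count_cysteines(d$sequence), 16L)
  m <- scan_signature(d$sequence, sig)
  expect_gte(nrow(m), 1L)
  expect_equal(m$start[1], d$truth$signature_start)
  cbm <- detect_cbm(d$sequence)
  expect_true(cbm$canonical)
  expect_false(cbm$variant)

  v <- design_protein(200, 12, cbm_class = "variant", seed = 2)
  cv <- detect_cbm(v$sequence)
  expect_true(cv$variant)
  expect_false(cv$canonical)

  n <- design_protein(200, 12, cbm_class = "none", seed = 3)
  cn <- detect_cbm(n$sequence)
  expect_false(cn$canonical || cn$variant)
  expect_equal(nrow(scan_signature(n$sequence, sig)), 1L)

  neg <- design_protein(200, 12, with_signature = FALSE, seed = 4)
  expect_equal(nrow(scan_signature(neg$sequence, sig)), 0L)

  expect_identical(design_protein(120, 8, seed = 9)$sequence,
                   design_protein(120, 8, seed = 9)$sequence)
  expect_error(design_protein(250, 2, with_signature = TRUE, seed = 1),
               ">= 3 cysteines")
  expect_error(design_protein(18, 5, with_signature = TRUE, seed = 1),
               "too short")
})

test_that("planted truth holds across a seed sweep", {
  withr::local_seed(99)
  for (i in 1:15) {
    len <- sample(60:300, 1)
    ncys <- sample(3:20, 1)
    cls <- sample(c("none", "canonical", "variant"), 1)
    d <- design_protein(len, ncys, TRUE, cls)
    expect_equal(count_cysteines(d$sequence), ncys)
    m <- scan_signature(d$sequence, sig)
    expect_equal(nrow(m), 1L)  # exactly the planted occurrence
    expect_equal(m$start, d$truth$signature_start)
    expect_equal(m$end, d$truth$signature_end)
    cbm <- detect_cbm(d$sequence)
    expect_equal(cbm$canonical, cls == "canonical")
    expect_equal(cbm$variant, cls == "variant")
  }
})

test_that("gene models splice and translate back to their protein", {
  d <- design_protein(80, 6, seed = 5)
  for (exon_count in 1:4) {
    for (strand in c("+", "-")) {
      b <- build_gene_model(d$sequence, exon_count, "1H", 1001L, strand,
                            seed = exon_count * 10 + (strand == "-"))
      expect_equal(nrow(b$model$exons), exon_count)
      cds_len <- sum(b$model$cds[, 2] - b$model$cds[, 1] + 1L)
      expect_equal(cds_len, 3L * (nchar(d$sequence) + 1L))
      # embed the region in a chromosome and round-trip
      chrom <- paste0(strrep("N", 1000), b$gene_seq, strrep("N", 50))
      expect_identical(splice_translate(b$model, chrom), d$sequence)
      expect_equal(protein_length_from_cds(cds_len), nchar(d$sequence))
    }
  }
  # same seed, same model
  b1 <- build_gene_model(d$sequence, 3, "1H", 1L, "+", seed = 7)
  b2 <- build_gene_model(d$sequence, 3, "1H", 1L, "+", seed = 7)
  expect_identical(b1$gene_seq, b2$gene_seq)
  expect_identical(b1$model$exons, b2$model$exons)
})

test_that("synthetic genomes carry their recorded truth", {
  sim <- make_genome(n_true = 8, n_decoy = 5, n_isoform_extra = 6, seed = 31)
  tt <- sim$truth$table
  expect_equal(nrow(sim$proteome), 8 + 5 + 6)
  expect_setequal(tt$protein_id, sim$proteome$protein_id)
  for (i in seq_len(nrow(tt))) {
    seq <- sim$proteome$sequence[sim$proteome$protein_id == tt$protein_id[i]]
    expect_equal(count_cysteines(seq), tt$n_cysteine[i])
    m <- scan_signature(seq, sig)
    if (tt$has_signature[i]) {
      expect_equal(m$start[1], tt$signature_start[i])
    } else {
      expect_equal(nrow(m), 0L)
    }
    mod <- sim$models[[tt$protein_id[i]]]
    expect_equal(nrow(mod$exons), tt$exon_count[i])
    expect_equal(mod$chromosome, tt$chromosome[i])
    expect_identical(splice_translate(mod, sim$genome[[mod$chromosome]]), seq)
  }
  # decoys and planted ids are disjoint
  expect_length(intersect(sim$truth$decoy_ids,
                          tt$protein_id[tt$role != "decoy"]), 0L)
  # tandem cluster genes sit within the adjacency threshold
  feats <- data.frame(
    gene_symbol = vapply(sim$models, `[[`, character(1), "gene_id"),
    chromosome = vapply(sim$models, `[[`, character(1), "chromosome"),
    start = vapply(sim$models, function(m) m$span[1], integer(1)),
    end = vapply(sim$models, function(m) m$span[2], integer(1)))
  feats <- feats[!duplicated(feats$gene_symbol), ]
  cd <- chromosome_distribution(feats)
  called <- unique(c(cd$tandem_pairs$gene_a, cd$tandem_pairs$gene_b))
  expect_true(all(sim$truth$tandem_genes %in% called))
})

test_that("genome generation is deterministic and scales with its knobs", {
  a <- make_genome(n_true = 4, n_decoy = 3, n_isoform_extra = 2, seed = 55)
  b <- make_genome(n_true = 4, n_decoy = 3, n_isoform_extra = 2, seed = 55)
  expect_identical(a$proteome, b$proteome)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$hits, b$hits)

  none <- make_genome(n_true = 0, n_decoy = 3, n_isoform_extra = 0, seed = 1)
  r <- candidate_funnel(none$proteome, none$hits)$report
  expect_equal(r$n_unique_loci, 0L)
  expect_length(none$truth$expected_final, 0L)
})

test_that("alignments evolved on a tree behave like the Poisson model", {
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  # zero-length branches give identical sequences
  zero <- tree
  zero$edge.length[] <- 0
  aln0 <- evolve_alignment(zero, 50, seed = 1)
  expect_length(unique(aln0), 1L)

  expect_identical(evolve_alignment(tree, 100, seed = 3),
                   evolve_alignment(tree, 100, seed = 3))

  # law of large numbers: poisson distances approach path lengths
  star <- ape::read.tree(text = "(A:0.15,B:0.15,C:0.15);")
  L <- 10000
  aln <- evolve_alignment(star, L, seed = 11)
  d <- distance_matrix(aln, "poisson")
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    true_d <- 0.3
    p_exp <- 1 - exp(-true_d)
    se_p <- sqrt(p_exp * (1 - p_exp) / L)
    se_d <- se_p / (1 - p_exp)
    expect_lt(abs(d[pair[1], pair[2]] - true_d), 3 * se_d + 0.01)
  }
})

test_that("planted expression structure is recovered by clustering", {
  prof <- tlp_expression_profiles()
  exact <- make_expression(prof, noise_sd = 0, seed = 1)
  expect_equal(exact$matrix, unclass(prof)[, ], ignore_attr = TRUE)

  noisy <- make_expression(prof, noise_sd = 1, seed = 5)
  expect_true(all(noisy$matrix >= 0))
  expect_identical(make_expression(prof, noise_sd = 1, seed = 5)$matrix,
                   noisy$matrix)

  # embryo-high genes (8x fold) cluster together before joining others
  cl <- cluster_rows(log2_normalize(noisy$matrix))
  classes <- noisy$truth$class_labels
  ord_classes <- classes[cl$order]
  emb_pos <- which(ord_classes == "embryo_high")
  expect_equal(max(emb_pos) - min(emb_pos) + 1L, length(emb_pos))
})
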