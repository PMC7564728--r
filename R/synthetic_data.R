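# Ground-truthed synthetic fixtures: designed TLP proteins, back-translated
# gene models with introns, whole synthetic genomes (FASTA + GFF3 + hit
# table + truth), protein alignments evolved on known trees, and
# tissue-structured FPKM matrices.  Every generator is deterministic under a
# fixed seed and every artifact self-verifies against the analysis modules.

# background alphabet for designed proteins: the literal residues the
# thaumatin signature pins down (C, T, D) are excluded, so a signature or
# carbohydrate-binding motif can only occur where the generator planted it.
.design_alphabet <- function() {
  setdiff(amino_acids(extended = FALSE), c("C", "T", "D"))
}

# one concrete signature instance (always the 15-residue shortest
# expansion): G x [GF] x C x T [GA] D C x [GQ] x x C, with the spacer
# residues chosen to realize the requested carbohydrate-binding-motif class
.signature_instance <- function(cbm_class) {
  alpha <- .design_alphabet()
  r <- function() sample(alpha, 1L)
  x6 <- switch(cbm_class,
               canonical = "Q", variant = "Q",
               none = sample(setdiff(alpha, "Q"), 1L))
  x11 <- switch(cbm_class, canonical = "G", variant = "Q", none = r())
  p12 <- switch(cbm_class, canonical = "G", variant = "G", sample(c("G", "Q"), 1L))
  p8 <- switch(cbm_class, canonical = "G", variant = "G", sample(c("G", "A"), 1L))
  paste0(c("G", r(), sample(c("G", "F"), 1L), r(), "C", x6, "T", p8,
           "D", "C", x11, p12, r(), r(), "C"), collapse = "")
}

#' Design a protein with planted, verifiable properties
#'
#' Generates a random protein of the requested length with an exact number
#' of cysteines and, optionally, one embedded thaumatin-signature instance
#' whose core realizes the requested carbohydrate-binding-motif class
#' (`"canonical"` embeds CQTGDCGG, `"variant"` embeds CQTGDCQG, `"none"`
#' embeds a signature without either motif).  The background alphabet
#' excludes C, T and D, so the planted span is provably the only signature
#' match and the cysteine count is exact by construction.
#'
#' @param length protein length in residues (>= 25 when a signature is
#'   embedded).
#' @param n_cysteine exact cysteine count (>= 3 when a signature is
#'   embedded, since the signature itself contains three).
#' @param with_signature embed one signature instance.
#' @param cbm_class `"none"`, `"canonical"` or `"variant"`; ignored when
#'   `with_signature = FALSE`.
#' @param seed integer seed; the same seed reproduces the same protein.
#' @param protein_id identifier stored in the truth entry.
#' @return list with `sequence` and `truth` (a one-row data frame:
#'   `protein_id`, `has_signature`, `signature_start`, `signature_end`,
#'   `n_cysteine`, `cbm_class`).
#' @export
design_protein <- function(length, n_cysteine, with_signature = TRUE,
                           cbm_class = c("none", "canonical", "variant"),
                           seed = NULL, protein_id = "synthetic.1") {
  cbm_class <- match.arg(cbm_class)
  run <- function() {
    alpha <- .design_alphabet()
    chars <- sample(alpha, length, replace = TRUE)
    chars[1] <- "M"
    sig_start <- NA_integer_
    sig_end <- NA_integer_
    n_free <- n_cysteine
    if (with_signature) {
      if (n_cysteine < 3L) stop("a signature-bearing protein needs >= 3 cysteines")
      inst <- strsplit(.signature_instance(cbm_class), "", fixed = TRUE)[[1]]
      if (length < length(inst) + 8L) {
        stop("length ", length, " too short to embed the signature with flanks")
      }
      sig_start <- sample(seq.int(3L, length - length(inst) - 1L), 1L)
      sig_end <- sig_start + length(inst) - 1L
      chars[sig_start:sig_end] <- inst
      n_free <- n_cysteine - 3L
    }
    reserved <- c(1L, if (with_signature) sig_start:sig_end)
    open <- setdiff(seq_len(length), reserved)
    if (n_free > length(open)) stop("cannot place ", n_cysteine, " cysteines")
    if (n_free > 0L) chars[sample(open, n_free)] <- "C"
    list(sequence = paste(chars, collapse = ""),
         truth = data.frame(protein_id = protein_id,
                            has_signature = with_signature,
                            signature_start = sig_start,
                            signature_end = sig_end,
                            n_cysteine = n_cysteine,
                            cbm_class = if (with_signature) cbm_class else "none",
                            stringsAsFactors = FALSE))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# codon table: amino acid -> codons (standard nuclear code)
.codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Back-translate a protein into a gene model with introns
#'
#' The protein is back-translated codon by codon (uniform choice among
#' synonymous codons), a stop codon is appended, and the CDS is split at
#' `exon_count - 1` random nucleotide positions (not necessarily codon
#' boundaries).  Introns with canonical `GT...AG` ends are inserted between
#' the pieces.  On the minus strand the whole gene region is
#' reverse-complemented and the intervals mirrored, so extracting, splicing
#' and translating the model from the genomic sequence reproduces the
#' protein on either strand.
#'
#' @param sequence protein sequence (no stop).
#' @param exon_count number of exons (>= 1).
#' @param chromosome chromosome name.
#' @param start 1-based genomic start of the gene region.
#' @param strand `"+"` or `"-"`.
#' @param seed integer seed.
#' @param gene_id,transcript_id identifiers for the model.
#' @param intron_range min/max intron length (bp).
#' @return list with `model` (a [gene_model()]), `gene_seq` (plus-strand
#'   genomic sequence of the gene region), `end` (genomic end),
#'   `rel_cds` (CDS intervals in transcript orientation relative to the
#'   region, used to derive truncated isoforms).
#' @export
build_gene_model <- function(sequence, exon_count, chromosome, start,
                             strand = "+", seed = NULL,
                             gene_id = "gene1", transcript_id = "gene1.1",
                             intron_range = c(60L, 300L)) {
  stopifnot(exon_count >= 1L, strand %in% c("+", "-"))
  run <- function() {
    codons <- .codons_by_aa()
    aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
    cds <- vapply(aa, function(a) {
      cs <- codons[[a]]
      if (is.null(cs)) stop("cannot back-translate residue ", a)
      cs[sample.int(length(cs), 1L)]
    }, character(1), USE.NAMES = FALSE)
    cds <- paste0(paste(cds, collapse = ""),
                  sample(c("TAA", "TAG", "TGA"), 1L))
    L <- nchar(cds)
    cuts <- if (exon_count > 1L) sort(sample(seq_len(L - 1L), exon_count - 1L))
      else integer(0)
    piece_bounds <- cbind(c(1L, cuts + 1L), c(cuts, L))
    pieces <- substring(cds, piece_bounds[, 1], piece_bounds[, 2])
    introns <- if (exon_count > 1L) {
      vapply(seq_len(exon_count - 1L), function(i) {
        len <- sample(seq.int(intron_range[1], intron_range[2]), 1L)
        paste0("GT", paste(sample(c("A", "C", "G", "T"), len - 4L,
                                  replace = TRUE), collapse = ""), "AG")
      }, character(1))
    } else character(0)
    # transcript-orientation layout of the gene region
    rel <- matrix(0L, exon_count, 2L)
    offset <- 0L
    region <- character(0)
    for (i in seq_len(exon_count)) {
      w <- nchar(pieces[i])
      rel[i, ] <- c(offset + 1L, offset + w)
      region <- c(region, pieces[i])
      offset <- offset + w
      if (i < exon_count) {
        region <- c(region, introns[i])
        offset <- offset + nchar(introns[i])
      }
    }
    gene_len <- offset
    region <- paste(region, collapse = "")
    if (strand == "+") {
      genomic <- rel + start - 1L
      gene_seq <- region
    } else {
      genomic <- cbind(start + gene_len - rel[, 2], start + gene_len - rel[, 1])
      gene_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(region)))
    }
    model <- gene_model(gene_id, transcript_id, chromosome, strand,
                        exons = genomic, cds = genomic)
    list(model = model, gene_seq = gene_seq, end = start + gene_len - 1L,
         rel_cds = rel, gene_len = gene_len)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# genomic intervals of a transcript-orientation prefix of the CDS
.prefix_intervals <- function(rel_cds, prefix_nt, start, gene_len, strand) {
  out <- list()
  remaining <- prefix_nt
  for (i in seq_len(nrow(rel_cds))) {
    w <- rel_cds[i, 2] - rel_cds[i, 1] + 1L
    take <- min(w, remaining)
    if (take > 0L) {
      out[[length(out) + 1L]] <- c(rel_cds[i, 1], rel_cds[i, 1] + take - 1L)
      remaining <- remaining - take
    }
    if (remaining == 0L) break
  }
  rel <- do.call(rbind, out)
  if (strand == "+") rel + start - 1L
  else cbind(start + gene_len - rel[, 2], start + gene_len - rel[, 1])
}

#' Extract, splice and translate a gene model from genomic sequence
#'
#' The round-trip oracle for synthetic gene models: CDS intervals are
#' extracted from the chromosome sequence in genomic order, concatenated,
#' reverse-complemented for minus-strand models, and translated with the
#' standard code.  A trailing stop is stripped.
#'
#' @param model a `gene_model`.
#' @param chrom_seq chromosome sequence (character or `DNAString`).
#' @return the encoded protein sequence.
#' @export
splice_translate <- function(model, chrom_seq) {
  chrom_seq <- as.character(chrom_seq)
  cds <- paste(substring(chrom_seq, model$cds[, 1], model$cds[, 2]),
               collapse = "")
  dna <- Biostrings::DNAString(cds)
  if (model$strand == "-") dna <- Biostrings::reverseComplement(dna)
  prot <- as.character(Biostrings::translate(dna, no.init.codon = TRUE))
  sub("\\*$", "", prot)
}

#' Generate a ground-truthed synthetic genome
#'
#' Emulates the data structure mined by the identification pipeline: a set
#' of signature-bearing TLP loci (with extra truncated splice isoforms at
#' some loci), signature-free decoys (the invariant signature aspartate
#' mutated to lysine), a tandem-duplicated cluster on one chromosome, a
#' homology-hit table whose e-values straddle the cutoff, chromosome
#' sequences (gene regions embedded in `N` filler), GFF3-ready gene models
#' and a truth table.
#'
#' With the defaults (19 loci, 13 extra isoforms, i.e. 32 signature-bearing
#' transcripts, and 13 decoys) the planted structure mirrors the funnel of
#' the barley study: 32 candidate transcripts collapsing to 19 unique loci.
#'
#' @param n_true number of true TLP loci.
#' @param n_decoy number of signature-free decoy proteins.
#' @param n_isoform_extra extra (truncated) isoforms distributed over the
#'   true loci, so true transcripts = `n_true + n_isoform_extra`.
#' @param tandem_spec list with `chromosome`, `n` (cluster size) and
#'   `spacing` (bp between cluster genes); the remaining genes are spaced
#'   2 Mb apart, beyond the default 1 Mb adjacency threshold.
#' @param seed integer seed; byte-identical output under the same seed.
#' @return list with `proteome` (protein table: primaries, isoforms,
#'   decoys), `models` (named list of `gene_model`), `genome`
#'   (`DNAStringSet`), `hits` (hit table), `truth` (list: `table`
#'   (per-protein truth), `true_loci`, `expected_final` (longest isoform
#'   per true locus), `decoy_ids`, `tandem_genes`).
#' @export
make_genome <- function(n_true = 19L, n_decoy = 13L, n_isoform_extra = 13L,
                        tandem_spec = list(chromosome = "5H", n = 3L,
                                           spacing = 2e4),
                        seed = 1L) {
  stopifnot(n_true >= 0L, n_decoy >= 0L, n_isoform_extra >= 0L)
  withr::with_seed(seed, {
    chrom_pool <- c("1H", "3H", "4H", "5H", "7H")
    chroms <- if (n_true == 19L) {
      # the chromosome tally of the barley TLP family
      rep(c("1H", "3H", "4H", "5H", "7H"), c(2L, 3L, 3L, 8L, 3L))
    } else if (n_true > 0L) {
      sample(chrom_pool, n_true, replace = TRUE)
    } else character(0)
    # put tandem-cluster genes first on their chromosome
    chroms <- c(chroms[chroms == tandem_spec$chromosome],
                chroms[chroms != tandem_spec$chromosome])

    proteome <- list()
    truth_rows <- list()
    models <- list()
    gene_pos <- list()  # per chromosome: next free coordinate
    tandem_genes <- character(0)
    builds <- list()

    cbm_classes <- rep("none", n_true)
    if (n_true >= 2L) cbm_classes[1:2] <- c("canonical", "variant")
    exon_counts <- sample(1:4, n_true, replace = TRUE,
                          prob = c(10, 6, 2, 1) / 19)

    for (i in seq_len(n_true)) {
      locus <- sprintf("TLPsim%03d", i)
      tx <- paste0(locus, ".1")
      chr <- chroms[i]
      dp <- design_protein(length = sample(173:359, 1L),
                           n_cysteine = sample(10:24, 1L),
                           with_signature = TRUE,
                           cbm_class = cbm_classes[i],
                           protein_id = tx)
      on_tandem <- chr == tandem_spec$chromosome &&
        sum(chroms[seq_len(i)] == chr) <= tandem_spec$n
      spacing <- if (on_tandem) tandem_spec$spacing else 2e6
      pos <- if (is.null(gene_pos[[chr]])) 1e4 else gene_pos[[chr]] + spacing
      strand <- sample(c("+", "-"), 1L)
      bld <- build_gene_model(dp$sequence, exon_counts[i], chr, as.integer(pos),
                              strand, gene_id = locus, transcript_id = tx)
      gene_pos[[chr]] <- bld$end
      if (on_tandem) tandem_genes <- c(tandem_genes, locus)
      proteome[[tx]] <- data.frame(protein_id = tx, locus_id = locus,
                                   species_tag = "synthetic",
                                   sequence = dp$sequence, description = "",
                                   stringsAsFactors = FALSE)
      truth_rows[[tx]] <- cbind(dp$truth, locus_id = locus,
                                exon_count = exon_counts[i],
                                chromosome = chr, role = "primary",
                                stringsAsFactors = FALSE)
      models[[tx]] <- bld$model
      builds[[tx]] <- bld
    }

    # truncated extra isoforms at random loci (still signature-bearing)
    if (n_isoform_extra > 0L && n_true > 0L) {
      host <- sort(sample(seq_len(n_true), n_isoform_extra, replace = TRUE))
      iso_index <- integer(n_true) + 1L
      for (h in host) {
        locus <- sprintf("TLPsim%03d", h)
        primary_tx <- paste0(locus, ".1")
        iso_index[h] <- iso_index[h] + 1L
        tx <- paste0(locus, ".", iso_index[h])
        primary <- proteome[[primary_tx]]$sequence
        tr <- truth_rows[[primary_tx]]
        lo <- tr$signature_end + 5L
        hi <- nchar(primary) - 5L
        aa_iso <- if (lo >= hi) lo else sample(seq.int(lo, hi), 1L)
        iso_seq <- substr(primary, 1L, aa_iso)
        bld <- builds[[primary_tx]]
        m <- bld$model
        iv <- .prefix_intervals(bld$rel_cds, 3L * aa_iso, m$span[1],
                                bld$gene_len, m$strand)
        models[[tx]] <- gene_model(locus, tx, m$chromosome, m$strand,
                                   exons = iv, cds = iv)
        proteome[[tx]] <- data.frame(protein_id = tx, locus_id = locus,
                                     species_tag = "synthetic",
                                     sequence = iso_seq, description = "",
                                     stringsAsFactors = FALSE)
        truth_rows[[tx]] <- data.frame(protein_id = tx, has_signature = TRUE,
                                       signature_start = tr$signature_start,
                                       signature_end = tr$signature_end,
                                       n_cysteine = count_cysteines(iso_seq),
                                       cbm_class = tr$cbm_class,
                                       locus_id = locus,
                                       exon_count = nrow(iv),
                                       chromosome = m$chromosome,
                                       role = "isoform",
                                       stringsAsFactors = FALSE)
      }
    }

    # decoys: TLP-like but with the invariant signature aspartate mutated
    decoy_ids <- character(0)
    for (i in seq_len(n_decoy)) {
      locus <- sprintf("DECsim%03d", i)
      tx <- paste0(locus, ".1")
      dp <- design_protein(length = sample(173:359, 1L),
                           n_cysteine = sample(10:24, 1L),
                           with_signature = TRUE, cbm_class = "none",
                           protein_id = tx)
      seq <- dp$sequence
      d_pos <- dp$truth$signature_start + 8L  # the invariant aspartate
      substr(seq, d_pos, d_pos) <- "K"
      chr <- sample(chrom_pool, 1L)
      pos <- if (is.null(gene_pos[[chr]])) 1e4 else gene_pos[[chr]] + 2e6
      bld <- build_gene_model(seq, sample(1:4, 1L), chr, as.integer(pos),
                              sample(c("+", "-"), 1L),
                              gene_id = locus, transcript_id = tx)
      gene_pos[[chr]] <- bld$end
      proteome[[tx]] <- data.frame(protein_id = tx, locus_id = locus,
                                   species_tag = "synthetic",
                                   sequence = seq, description = "",
                                   stringsAsFactors = FALSE)
      truth_rows[[tx]] <- data.frame(protein_id = tx, has_signature = FALSE,
                                     signature_start = NA_integer_,
                                     signature_end = NA_integer_,
                                     n_cysteine = count_cysteines(seq),
                                     cbm_class = "none", locus_id = locus,
                                     exon_count = nrow(bld$model$exons),
                                     chromosome = chr, role = "decoy",
                                     stringsAsFactors = FALSE)
      models[[tx]] <- bld$model
      builds[[tx]] <- bld
      decoy_ids <- c(decoy_ids, tx)
    }

    # hit table: true transcripts always pass the e-value cutoff; half the
    # decoys also pass it, so the signature filter must reject them
    ids <- names(proteome)
    is_decoy <- ids %in% decoy_ids
    e_val <- numeric(length(ids))
    e_val[!is_decoy] <- 10^stats::runif(sum(!is_decoy), -50, -12)
    if (any(is_decoy)) {
      nd <- sum(is_decoy)
      pass <- seq_len(nd) <= ceiling(nd / 2)
      e_val[is_decoy] <- ifelse(pass, 10^stats::runif(nd, -30, -12),
                                10^stats::runif(nd, -9, -2))
    }
    hits <- data.frame(query_id = ids, subject_id = "TLP_domain",
                       e_value = e_val, stringsAsFactors = FALSE)

    # assemble chromosome sequences: gene regions embedded in N filler
    genome_chroms <- sort(unique(vapply(models, `[[`, character(1),
                                        "chromosome")))
    genome <- Biostrings::DNAStringSet(vapply(genome_chroms, function(chr) {
      mm <- models[vapply(models, function(m) m$chromosome == chr, logical(1))]
      # isoforms share their primary's region; emit each region once
      regions <- unique(do.call(rbind, lapply(names(mm), function(tx) {
        b <- builds[[tx]]
        if (is.null(b)) return(NULL)
        data.frame(start = b$model$span[1], end = b$end, seq = b$gene_seq,
                   stringsAsFactors = FALSE)
      })))
      regions <- regions[order(regions$start), , drop = FALSE]
      out <- character(0)
      at <- 1L
      for (i in seq_len(nrow(regions))) {
        out <- c(out, strrep("N", regions$start[i] - at), regions$seq[i])
        at <- regions$end[i] + 1L
      }
      paste(c(out, strrep("N", 500L)), collapse = "")
    }, character(1)))

    truth_table <- do.call(rbind, c(truth_rows, make.row.names = FALSE))
    proteome <- do.call(rbind, c(proteome, make.row.names = FALSE))
    true_loci <- sprintf("TLPsim%03d", seq_len(n_true))
    expected_final <- if (n_true > 0L) {
      vapply(true_loci, function(l) {
        d <- proteome[proteome$locus_id == l, ]
        d <- d[order(-nchar(d$sequence), d$protein_id), ]
        d$protein_id[1]
      }, character(1), USE.NAMES = FALSE)
    } else character(0)

    list(proteome = proteome, models = models, genome = genome, hits = hits,
         truth = list(table = truth_table, true_loci = true_loci,
                      expected_final = sort(expected_final),
                      decoy_ids = decoy_ids, tandem_genes = tandem_genes))
  })
}

#' Write a synthetic genome to standard files
#'
#' Writes `proteome.faa` (protein FASTA), `genome.fa` (chromosome FASTA),
#' `models.gff3`, `hits.tsv` and `truth.tsv` into a directory.
#'
#' @param sim output of [make_genome()].
#' @param dir output directory (created if missing).
#' @return named character vector of the file paths, invisibly.
#' @export
write_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteome = file.path(dir, "proteome.faa"),
             genome = file.path(dir, "genome.fa"),
             models = file.path(dir, "models.gff3"),
             hits = file.path(dir, "hits.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_protein_fasta(sim$proteome, paths["proteome"])
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_gene_models(sim$models, paths["models"])
  utils::write.table(sim$hits, paths["hits"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$table, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Evolve a gapless protein alignment on a known tree
#'
#' A uniform random root sequence evolves along the tree under a Poisson
#' substitution process: on a branch of length `b` each site receives a
#' Poisson(`b`) number of substitution events (expected substitutions per
#' site equal to the branch length), each replacing the residue with a
#' uniformly chosen different one.  No indels are introduced, so the tip
#' sequences form the alignment.
#'
#' @param tree a `phylo` tree with branch lengths (>= 0).
#' @param seq_length number of sites.
#' @param seed integer seed.
#' @return named character vector of tip sequences.
#' @export
evolve_alignment <- function(tree, seq_length, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0))
  aa <- amino_acids(extended = FALSE)
  withr::with_seed(seed, {
    tree <- stats::reorder(tree, "cladewise")
    n_tip <- length(tree$tip.label)
    n_nodes <- n_tip + tree$Nnode
    seqs <- vector("list", n_nodes)
    root <- tree$edge[1, 1]
    seqs[[root]] <- sample(aa, seq_length, replace = TRUE)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      s <- seqs[[parent]]
      k <- stats::rpois(seq_length, tree$edge.length[e])
      for (site in which(k > 0L)) {
        cur <- s[site]
        for (j in seq_len(k[site])) cur <- sample(setdiff(aa, cur), 1L)
        s[site] <- cur
      }
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(n_tip), function(i)
      paste(seqs[[i]], collapse = ""), character(1))
    names(out) <- tree$tip.label
    out
  })
}

#' Planted expression profiles emulating a tissue panel
#'
#' Mean-FPKM profiles over the eight-tissue barley panel (EMB, LEA, INF1,
#' INF2, ROO, NOD, CAR5, CAR15) with gene classes that mirror the observed
#' expression structure: embryo-high genes, developing-grain-high genes,
#' root/tiller-high genes and uniformly low genes.  High tissues sit at
#' `fold` times the baseline.
#'
#' @param n_embryo_high,n_grain_high,n_root_high,n_low class sizes.
#' @param base baseline mean FPKM.
#' @param fold fold elevation of the high tissues.
#' @return numeric matrix of planted means with a `class` attribute
#'   (character vector of per-gene class labels).
#' @export
tlp_expression_profiles <- function(n_embryo_high = 10L, n_grain_high = 2L,
                                    n_root_high = 3L, n_low = 4L,
                                    base = 5, fold = 8) {
  tissues <- c("EMB", "LEA", "INF1", "INF2", "ROO", "NOD", "CAR5", "CAR15")
  classes <- rep(c("embryo_high", "grain_high", "root_high", "low"),
                 c(n_embryo_high, n_grain_high, n_root_high, n_low))
  n <- length(classes)
  mat <- matrix(base, n, length(tissues),
                dimnames = list(sprintf("gene%02d", seq_len(n)), tissues))
  mat[classes == "embryo_high", "EMB"] <- base * fold
  mat[classes == "grain_high", c("CAR5", "CAR15")] <- base * fold
  mat[classes == "root_high", c("ROO", "NOD")] <- base * fold
  mat[classes == "low", ] <- base / 5
  attr(mat, "class_labels") <- classes
  mat
}

#' Generate a noisy FPKM matrix from planted profiles
#'
#' `FPKM = max(0, mean + Gaussian noise)`, truncated at zero since FPKM is
#' non-negative.
#'
#' @param profiles matrix of planted means (see
#'   [tlp_expression_profiles()]).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return list with `matrix` (the FPKM matrix) and `truth` (the planted
#'   means and class labels).
#' @export
make_expression <- function(profiles, noise_sd = 1, seed = 1L) {
  stopifnot(noise_sd >= 0)
  withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(length(profiles), 0, noise_sd),
                    nrow(profiles), ncol(profiles))
    mat <- unclass(profiles) + noise
    mat[mat < 0] <- 0
    attr(mat, "class_labels") <- NULL
    dimnames(mat) <- dimnames(profiles)
    list(matrix = mat,
         truth = list(profiles = profiles,
                      class_labels = attr(profiles, "class_labels")))
  })
}
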