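# GFF3-driven exon/intron analysis: gene-model container, CDS/protein
# length arithmetic, exon-count structure groups, mapping protein positions
# onto exons, splice-variant summaries and chromosome distribution.

#' Construct a gene model
#'
#' A chromosome-anchored transcript with ordered exon and CDS intervals.
#' All coordinates are 1-based inclusive (the GFF3 convention).  Intervals
#' must be sorted by genomic coordinate and non-overlapping, every CDS
#' segment must lie inside an exon, and the total CDS length must be
#' divisible by 3.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chromosome chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds two-column matrices (start, end) of genomic intervals;
#'   `cds` defaults to `exons`.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chromosome, strand,
                       exons, cds = exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- .as_interval_matrix(exons, "exons")
  cds <- .as_interval_matrix(cds, "cds")
  cds_len <- sum(cds[, 2] - cds[, 1] + 1L)
  if (cds_len %% 3L != 0L) {
    stop("total CDS length ", cds_len, " of ", transcript_id,
         " is not divisible by 3")
  }
  # every CDS segment inside some exon
  inside <- vapply(seq_len(nrow(cds)), function(i) {
    any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
  }, logical(1))
  if (!all(inside)) {
    stop("CDS interval(s) outside exons in ", transcript_id)
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chromosome = chromosome, strand = strand,
                 span = c(min(exons[, 1]), max(exons[, 2])),
                 exons = exons, cds = cds),
            class = "gene_model")
}

.as_interval_matrix <- function(x, what) {
  x <- matrix(as.integer(x), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(x) == 0L) stop(what, ": at least one interval required")
  if (any(x[, 2] < x[, 1])) stop(what, ": end < start")
  x <- x[order(x[, 1]), , drop = FALSE]
  if (nrow(x) > 1L && any(x[-1L, 1] <= x[-nrow(x), 2])) {
    stop(what, ": overlapping intervals")
  }
  x
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene model", x$transcript_id, "(gene", paste0(x$gene_id, ")"),
      "on", x$chromosome, x$strand, "\n")
  cat("  span ", x$span[1], "-", x$span[2], ", ", nrow(x$exons), " exon(s), CDS ",
      sum(x$cds[, 2] - x$cds[, 1] + 1L), " bp\n", sep = "")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses mRNA/transcript features with their child exon and CDS features
#' into `gene_model` objects.
#'
#' @param path path to a GFF3 file.
#' @return named list of `gene_model` objects (names are transcript ids).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx_ids <- gr$ID[is_tx]
  tx_parent <- vapply(gr$Parent[is_tx], function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  models <- lapply(seq_along(tx_ids), function(i) {
    id <- tx_ids[i]
    child <- vapply(gr$Parent, function(p) id %in% as.character(p), logical(1))
    ex <- gr[child & type == "exon"]
    cd <- gr[child & type == "CDS"]
    if (length(ex) == 0L) ex <- cd
    idx <- which(is_tx)[i]
    gene_model(gene_id = if (is.na(tx_parent[i])) id else tx_parent[i],
               transcript_id = id,
               chromosome = as.character(GenomicRanges::seqnames(gr[idx])),
               strand = as.character(GenomicRanges::strand(gr[idx])),
               exons = cbind(GenomicRanges::start(ex), GenomicRanges::end(ex)),
               cds = cbind(GenomicRanges::start(cd), GenomicRanges::end(cd)))
  })
  names(models) <- tx_ids
  models
}

#' Write gene models to a GFF3 file
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- lapply(models, function(m) {
    n_ex <- nrow(m$exons)
    n_cds <- nrow(m$cds)
    # GFF3 phase: residue of CDS consumed before each segment, in
    # transcript orientation
    widths <- m$cds[, 2] - m$cds[, 1] + 1L
    if (m$strand == "-") widths <- rev(widths)
    phase <- (3L - cumsum(c(0L, widths[-length(widths)])) %% 3L) %% 3L
    if (m$strand == "-") phase <- rev(phase)
    data.frame(
      seqnames = m$chromosome,
      start = c(m$span[1], m$exons[, 1], m$cds[, 1]),
      end = c(m$span[2], m$exons[, 2], m$cds[, 2]),
      strand = m$strand,
      type = c("mRNA", rep("exon", n_ex), rep("CDS", n_cds)),
      phase = c(rep(NA_integer_, 1L + n_ex), phase),
      ID = c(m$transcript_id,
             paste0(m$transcript_id, ".exon", seq_len(n_ex)),
             paste0(m$transcript_id, ".cds", seq_len(n_cds))),
      Parent = c(m$gene_id, rep(m$transcript_id, n_ex + n_cds)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$phase <- df$phase
  gr$ID <- df$ID
  gr$Parent <- df$Parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Protein length implied by a CDS length
#'
#' `aa = cds/3 - 1`: one codon encodes the stop and is removed.
#'
#' @param cds_length_bp CDS length(s) in bp; must be divisible by 3 and at
#'   least 6 (stop plus one residue).
#' @return integer protein length(s) in amino acids.
#' @export
protein_length_from_cds <- function(cds_length_bp) {
  if (any(cds_length_bp %% 3L != 0L)) {
    stop("CDS length not divisible by 3: ",
         paste(cds_length_bp[cds_length_bp %% 3L != 0L], collapse = ", "))
  }
  if (any(cds_length_bp < 6L)) {
    stop("CDS too short to encode a stop codon plus one residue")
  }
  as.integer(cds_length_bp / 3L - 1L)
}

#' Structure-group label for an exon count
#'
#' Exon counts 1-4 map to the Roman-numeral groups I-IV; anything larger is
#' labelled `"other"` so the classifier generalizes beyond families whose
#' members all have at most four exons.
#'
#' @param exon_count integer exon count(s).
#' @return character vector of labels.
#' @export
exon_group_label <- function(exon_count) {
  stopifnot(all(exon_count >= 1L))
  labels <- c("I", "II", "III", "IV")
  ifelse(exon_count <= 4L, labels[exon_count], "other")
}

#' Classify transcripts into exon-count structure groups
#'
#' @param x either a named list of `gene_model` objects or a named integer
#'   vector of exon counts (names are transcript ids).
#' @return list with `assignments` (data frame `transcript_id`,
#'   `exon_count`, `group`) and `sizes` (named integer vector of group
#'   sizes over the labels actually used).
#' @export
classify_by_exons <- function(x) {
  if (is.list(x) && all(vapply(x, inherits, logical(1), "gene_model"))) {
    counts <- vapply(x, function(m) nrow(m$exons), integer(1))
    ids <- vapply(x, `[[`, character(1), "transcript_id")
  } else {
    counts <- as.integer(x)
    ids <- if (!is.null(names(x))) names(x) else as.character(seq_along(x))
  }
  group <- exon_group_label(counts)
  sizes <- table(factor(group, levels = c("I", "II", "III", "IV", "other")))
  sizes <- sizes[sizes > 0]
  list(assignments = data.frame(transcript_id = ids, exon_count = counts,
                                group = group, stringsAsFactors = FALSE,
                                row.names = NULL),
       sizes = stats::setNames(as.integer(sizes), names(sizes)))
}

#' Map a protein position to its encoding exon
#'
#' Locates the exon (1-based ordinal in transcript orientation, i.e. counted
#' 5' to 3' of the mRNA) that encodes the first nucleotide of the codon for
#' a given amino-acid position.  Used, e.g., to ask in which exon the
#' thaumatin signature starts.
#'
#' @param model a `gene_model`.
#' @param aa_position 1-based amino-acid position; must not exceed the
#'   protein length (`cds/3 - 1`).
#' @return integer exon ordinal.
#' @export
map_protein_position_to_exon <- function(model, aa_position) {
  stopifnot(inherits(model, "gene_model"), aa_position >= 1L)
  cds_len <- model$cds[, 2] - model$cds[, 1] + 1L
  if (model$strand == "-") cds_len <- rev(cds_len)
  total <- sum(cds_len)
  if (3L * aa_position > total - 3L) {
    stop("amino-acid position ", aa_position, " beyond the CDS of ",
         model$transcript_id)
  }
  nt <- 3L * (aa_position - 1L) + 1L
  ordinal <- findInterval(nt - 1L, cumsum(cds_len)) + 1L
  # exon ordinal among CDS-bearing exons, in transcript orientation
  as.integer(ordinal)
}

#' Splice-variant summary
#'
#' Counts transcripts per gene and reports both "transcripts per gene" and
#' "additional variants" (transcripts beyond the first), the genes with no
#' additional variants, and the gene with the most variants (ties broken by
#' the lexicographically smallest gene id).
#'
#' @param x either a named list of `gene_model` objects or a data frame
#'   with columns `gene_id` and `transcript_id`.
#' @return list with `per_gene` (data frame `gene_id`, `n_transcripts`,
#'   `n_additional_variants`), `zero_variant_genes`, `max_gene` (NA when
#'   every gene is a singleton) and `max_transcripts`.
#' @export
splice_variant_summary <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- data.frame(
      gene_id = vapply(x, `[[`, character(1), "gene_id"),
      transcript_id = vapply(x, `[[`, character(1), "transcript_id"),
      stringsAsFactors = FALSE)
  }
  n <- tapply(x$transcript_id, x$gene_id, function(t) length(unique(t)))
  per_gene <- data.frame(gene_id = names(n),
                         n_transcripts = as.integer(n),
                         n_additional_variants = as.integer(n) - 1L,
                         stringsAsFactors = FALSE, row.names = NULL)
  per_gene <- per_gene[order(per_gene$gene_id), , drop = FALSE]
  zero <- per_gene$gene_id[per_gene$n_transcripts == 1L]
  if (all(per_gene$n_transcripts == 1L)) {
    max_gene <- NA_character_
    max_n <- NA_integer_
  } else {
    top <- per_gene[per_gene$n_transcripts == max(per_gene$n_transcripts), ]
    max_gene <- sort(top$gene_id)[1]
    max_n <- max(per_gene$n_transcripts)
  }
  list(per_gene = per_gene, zero_variant_genes = zero,
       max_gene = max_gene, max_transcripts = max_n)
}

#' Chromosome distribution and tandem-duplication candidates
#'
#' Tallies genes per chromosome, orders genes by start coordinate within
#' each chromosome, and reports consecutive same-chromosome genes whose
#' intervening gap is smaller than `adjacency_threshold` as candidate
#' tandem duplicates (localized gene duplications).
#'
#' @param features data frame with columns `gene_symbol` (or `gene_id`),
#'   `chromosome`, `start`, `end`.
#' @param adjacency_threshold maximum gap in bp between consecutive genes
#'   for an adjacency call; default 1 Mb.
#' @return list with `counts` (named integer vector per chromosome, sorted
#'   by chromosome name), `by_chromosome` (list of ordered gene data
#'   frames) and `tandem_pairs` (data frame `chromosome`, `gene_a`,
#'   `gene_b`, `gap_bp`).
#' @export
chromosome_distribution <- function(features, adjacency_threshold = 1e6) {
  empty_pairs <- data.frame(chromosome = character(0), gene_a = character(0),
                            gene_b = character(0), gap_bp = numeric(0),
                            stringsAsFactors = FALSE)
  if (nrow(features) == 0L) {
    return(list(counts = stats::setNames(integer(0), character(0)),
                by_chromosome = list(), tandem_pairs = empty_pairs))
  }
  gene_col <- if ("gene_symbol" %in% names(features)) "gene_symbol" else "gene_id"
  counts <- table(features$chromosome)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[order(names(counts))]
  by_chr <- lapply(split(features, features$chromosome), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  pairs <- lapply(by_chr, function(d) {
    if (nrow(d) < 2L) return(NULL)
    gap <- d$start[-1L] - d$end[-nrow(d)]
    keep <- gap < adjacency_threshold
    if (!any(keep)) return(NULL)
    data.frame(chromosome = d$chromosome[1],
               gene_a = d[[gene_col]][-nrow(d)][keep],
               gene_b = d[[gene_col]][-1L][keep],
               gap_bp = gap[keep], stringsAsFactors = FALSE)
  })
  pairs <- pairs[!vapply(pairs, is.null, logical(1))]
  tandem <- if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE))
    else empty_pairs
  list(counts = counts, by_chromosome = by_chr, tandem_pairs = tandem)
}
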