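# Readers and writers for the external formats the pipeline touches:
# protein FASTA (plain and aligned), TSV homology-hit tables and TSV
# annotation tables.  All tables are tab-separated; lines starting with '#'
# are comments.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, optionally extended with the
#' unknown-residue code `X`.
#'
#' @param extended if `TRUE` (default) include `X`.
#' @return character vector of one-letter codes.
#' @export
amino_acids <- function(extended = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (extended) c(aa, "X") else aa
}

# ambiguity / non-standard codes that may be mapped to X under permissive = TRUE
.aa_ambiguous <- c("B", "Z", "J", "U", "O")

#' Read a protein FASTA file into a protein table
#'
#' Each FASTA record becomes one row of a protein table (`protein_id`,
#' `locus_id`, `species_tag`, `sequence`, `description`).  The `protein_id`
#' is the first whitespace-delimited token of the header; the remainder of
#' the header is kept as `description`.  Sequences are upper-cased and a
#' single trailing stop (`*`) is stripped.
#'
#' By default `locus_id` is derived by removing a trailing isoform suffix
#' (`.<number>`) from the protein identifier, which matches the
#' `<locus>.<isoform>` convention of Ensembl Plants transcript accessions
#' (e.g. `HORVU7Hr1G122120.1`).  Supply `locus_map` to override.
#'
#' @param path path to a FASTA file.
#' @param species_tag species label stored with every record.
#' @param locus_map optional data frame with columns `protein_id`,
#'   `locus_id` assigning each protein to a genetic locus.
#' @param permissive if `TRUE`, ambiguity codes (B, Z, J, U, O) are mapped to
#'   `X` instead of being rejected.
#' @return data frame with one row per protein record, in file order.
#' @export
read_protein_fasta <- function(path, species_tag = NA_character_,
                               locus_map = NULL, permissive = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  as_protein_table(ids, seqs,
                   description = desc, species_tag = species_tag,
                   locus_map = locus_map, permissive = permissive)
}

#' Assemble and validate a protein table from ids and sequences
#'
#' @param protein_id character vector of unique protein identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param description free-text descriptions.
#' @param species_tag species label.
#' @param locus_map optional `protein_id` -> `locus_id` data frame.
#' @param permissive map ambiguity codes to `X` instead of rejecting.
#' @return validated protein table (data frame).
#' @export
as_protein_table <- function(protein_id, sequence, description = "",
                             species_tag = NA_character_, locus_map = NULL,
                             permissive = FALSE) {
  protein_id <- as.character(protein_id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(protein_id)) {
    dup <- unique(protein_id[duplicated(protein_id)])
    stop("duplicate protein identifier(s): ", paste(dup, collapse = ", "))
  }
  empty <- !nzchar(sequence)
  if (any(empty)) {
    stop("record(s) with empty sequence: ",
         paste(protein_id[empty], collapse = ", "))
  }
  if (permissive) {
    sequence <- vapply(sequence, function(s) {
      chartr(paste(.aa_ambiguous, collapse = ""),
             strrep("X", length(.aa_ambiguous)), s)
    }, character(1), USE.NAMES = FALSE)
  }
  bad <- vapply(sequence, function(s) {
    letters <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    paste(setdiff(letters, amino_acids()), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    stop("illegal character(s) '", bad[i], "' in record ", i,
         " (", protein_id[i], ")")
  }
  if (is.null(locus_map)) {
    locus_id <- sub("\\.[0-9]+$", "", protein_id)
  } else {
    stopifnot(all(c("protein_id", "locus_id") %in% names(locus_map)))
    locus_id <- locus_map$locus_id[match(protein_id, locus_map$protein_id)]
    if (anyNA(locus_id)) {
      stop("locus_map is missing protein(s): ",
           paste(protein_id[is.na(locus_id)], collapse = ", "))
    }
  }
  data.frame(protein_id = protein_id,
             locus_id = as.character(locus_id),
             species_tag = rep_len(as.character(species_tag), length(protein_id)),
             sequence = sequence,
             description = rep_len(as.character(description), length(protein_id)),
             stringsAsFactors = FALSE)
}

#' Write a protein table as FASTA
#'
#' Headers are `protein_id description` (description omitted when empty).
#' Reading the file back with [read_protein_fasta()] restores the table.
#'
#' @param proteins protein table as returned by [read_protein_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  headers <- ifelse(nzchar(proteins$description),
                    paste(proteins$protein_id, proteins$description),
                    proteins$protein_id)
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a tab-separated homology-hit table
#'
#' Expects at least three tab-separated columns per row: query identifier,
#' subject identifier, and e-value (decimal or scientific notation, e.g.
#' `1e-10` or `1.0E-10`).  Extra columns are ignored; `#` comment lines and
#' blank lines are skipped.  Such tables are the carrier for BLASTp output
#' consumed by the candidate funnel; the homology search itself is upstream
#' of this package.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `query_id`, `subject_id`, `e_value`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      e_value = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3L)) {
    stop("malformed hit-table row (fewer than 3 columns) at line ",
         which(keep)[which(n_col < 3L)[1]])
  }
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(ev)) {
    stop("unparseable e-value at line ", which(keep)[which(is.na(ev))[1]])
  }
  if (any(ev < 0)) {
    stop("negative e-value at line ", which(keep)[which(ev < 0)[1]])
  }
  data.frame(query_id = vapply(fields, `[[`, "", 1L),
             subject_id = vapply(fields, `[[`, "", 2L),
             e_value = ev, stringsAsFactors = FALSE)
}

#' Read a tab-separated annotation table
#'
#' Carrier for external per-protein predictions (subcellular localization,
#' signal peptide, transmembrane-helix count) produced by tools such as
#' Softberry, SignalP and TMHMM, which this package consumes but does not
#' run.  The file must have a header line naming at least `protein_id`;
#' optional columns `localization`, `signal_peptide` and `tm_count` default
#' to `"unknown"`, `"unknown"` and `0` when absent or empty.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `protein_id`, `localization`,
#'   `signal_peptide`, `tm_count`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(tab)) {
    stop("annotation table must have a 'protein_id' column")
  }
  if (anyDuplicated(tab$protein_id)) {
    dup <- unique(tab$protein_id[duplicated(tab$protein_id)])
    stop("duplicate protein_id in annotation table: ",
         paste(dup, collapse = ", "))
  }
  fill_chr <- function(x) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- "unknown"
    x
  }
  localization <- if ("localization" %in% names(tab))
    fill_chr(tab$localization) else rep("unknown", nrow(tab))
  signal_peptide <- if ("signal_peptide" %in% names(tab))
    fill_chr(tab$signal_peptide) else rep("unknown", nrow(tab))
  tm <- if ("tm_count" %in% names(tab)) tab$tm_count else rep(0L, nrow(tab))
  tm[is.na(tm)] <- 0L
  tm <- as.integer(tm)
  if (any(tm < 0L)) stop("negative tm_count in annotation table")
  data.frame(protein_id = as.character(tab$protein_id),
             localization = localization,
             signal_peptide = signal_peptide,
             tm_count = tm, stringsAsFactors = FALSE)
}

#' Read an FPKM expression matrix
#'
#' Genes in rows, tissues in columns; the first column holds gene labels and
#' the header line holds tissue labels.  Values must be non-negative.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene row names and tissue column names.
#' @export
read_fpkm_matrix <- function(path) {
  if (!file.exists(path)) stop("FPKM matrix not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) stop("non-numeric values in FPKM matrix")
  if (any(mat < 0)) stop("negative FPKM values are not allowed")
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled reference characteristics of the 19 barley TLP genes
#'
#' Published characterization of the barley (Morex reference genome) TLP
#' family HvTLP1-HvTLP19: transcript accession, CDS length, protein length,
#' isoelectric point, molecular weight, cysteine count, chromosomal
#' location, genomic span, exon count and external localization / signal
#' peptide / transmembrane annotations.  Shipped as a plain-text table in
#' `inst/extdata/barley_tlp_table1.tsv` and used as a reference input for
#' structure classification and chromosome-distribution analyses.
#'
#' @return data frame with one row per HvTLP gene.
#' @export
barley_tlp_table <- function() {
  path <- system.file("extdata", "barley_tlp_table1.tsv", package = "tlpminer",
                      mustWork = TRUE)
  utils::read.delim(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Reported TLP family sizes across four cereal genomes
#'
#' Number of signature-verified TLP genes identified in the barley,
#' Brachypodium, sorghum and rice reference genomes.  The sum is the number
#' of taxa entering the cross-species phylogeny.
#'
#' @return named integer vector.
#' @export
tlp_family_sizes <- function() {
  c(barley = 19L, brachypodium = 28L, sorghum = 35L, rice = 37L)
}
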