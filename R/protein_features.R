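# Physicochemical characterization of TLP proteins in the ExPASy ProtParam
# convention: average-mass molecular weight, Bjellqvist-pKa isoelectric
# point, cysteine census, small-TLP classification, and assembly of the
# per-gene feature table.

# average residue (monomer) masses in Daltons, ProtParam convention
.aa_mass_average <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.aa_mass_monoisotopic <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

.water_average <- 18.0153
.water_monoisotopic <- 18.010565

#' Count cysteine residues
#'
#' The cysteine census determines the small-TLP class (exactly 10 conserved
#' cysteines) and bounds the number of possible disulfide linkages.
#'
#' @param sequence amino-acid sequence string(s).
#' @return integer vector of cysteine counts.
#' @export
count_cysteines <- function(sequence) {
  vapply(sequence, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] == "C")
  }, integer(1), USE.NAMES = FALSE)
}

#' Protein molecular weight
#'
#' Sum of residue masses plus one water molecule, using average isotopic
#' masses by default (the ProtParam convention); monoisotopic masses are
#' available behind a flag.  The unknown residue `X` has no defined mass and
#' is an error unless `x_mass` supplies one.
#'
#' @param sequence a single amino-acid sequence string.
#' @param monoisotopic use monoisotopic instead of average masses.
#' @param x_mass optional mass (Da) to assign to `X` residues.
#' @return molecular weight in Daltons.  Use `round(mw/1000, 3)` for the
#'   conventional kDa report value.
#' @export
molecular_weight <- function(sequence, monoisotopic = FALSE, x_mass = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  masses <- if (monoisotopic) .aa_mass_monoisotopic else .aa_mass_average
  water <- if (monoisotopic) .water_monoisotopic else .water_average
  if (!is.null(x_mass)) masses <- c(masses, X = as.numeric(x_mass))
  unknown <- setdiff(unique(chars), names(masses))
  if (length(unknown)) {
    stop("no mass defined for residue(s): ", paste(unknown, collapse = ", "),
         if ("X" %in% unknown) " (supply x_mass to assign a mass to X)" else "")
  }
  sum(masses[chars]) + water
}

#' The Bjellqvist pKa set (ProtParam convention)
#'
#' Ionizable-group pKa values as used by ExPASy ProtParam: side chains
#' C 9.0, D 4.05, E 4.45, H 5.98, K 10.0, R 12.0, Y 10.0; generic termini
#' 7.50 (N) and 3.55 (C); position-specific adjustments for the N-terminal
#' backbone amine depending on the first residue, and for the side-chain pKa
#' of a C-terminal aspartate or glutamate.
#'
#' @return an object of class `pka_set`, a named list that can be edited and
#'   passed to [isoelectric_point()].
#' @export
pka_set_bjellqvist <- function() {
  structure(list(
    name = "Bjellqvist/ProtParam",
    side_chain = c(C = 9.0, D = 4.05, E = 4.45, H = 5.98,
                   K = 10.0, R = 12.0, Y = 10.0),
    n_terminus = 7.50,
    c_terminus = 3.55,
    n_terminus_by_residue = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36,
                              T = 6.82, V = 7.44, E = 7.70, G = 7.50),
    c_terminal_side_chain = c(D = 4.55, E = 4.75)
  ), class = "pka_set")
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch charge summed over all ionizable groups: the
#' N-terminal amine and the H/K/R side chains as bases, the C-terminal
#' carboxyl and the D/E/C/Y side chains as acids.  Strictly decreasing in
#' pH, which guarantees a unique isoelectric point.
#'
#' @param sequence a single amino-acid sequence string.
#' @param pH pH value(s).
#' @param pka a `pka_set`, by default [pka_set_bjellqvist()].
#' @return net charge at each `pH`.
#' @export
net_charge <- function(sequence, pH, pka = pka_set_bjellqvist()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = amino_acids()))
  first <- chars[1]
  last <- chars[length(chars)]

  nterm_pka <- pka$n_terminus
  if (first %in% names(pka$n_terminus_by_residue)) {
    nterm_pka <- pka$n_terminus_by_residue[[first]]
  }
  sc <- pka$side_chain
  acid_counts <- c(D = unname(counts["D"]), E = unname(counts["E"]),
                   C = unname(counts["C"]), Y = unname(counts["Y"]))
  acid_pka <- sc[names(acid_counts)]
  # a C-terminal D/E side chain gets its own pKa: split one instance off
  extra_acids <- numeric(0)
  if (last %in% names(pka$c_terminal_side_chain) && acid_counts[last] > 0) {
    acid_counts[last] <- acid_counts[last] - 1L
    extra_acids <- pka$c_terminal_side_chain[[last]]
  }
  base_counts <- c(H = unname(counts["H"]), K = unname(counts["K"]),
                   R = unname(counts["R"]))
  base_pka <- sc[names(base_counts)]

  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - nterm_pka)) +
      sum(base_counts / (1 + 10^(p - base_pka)))
    neg <- 1 / (1 + 10^(pka$c_terminus - p)) +
      sum(acid_counts / (1 + 10^(acid_pka - p))) +
      sum(1 / (1 + 10^(extra_acids - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' The pH at which the net charge of the protein crosses zero, located by
#' bisection on the interval \[0, 14\].  The charge model follows the ExPASy
#' ProtParam convention ([pka_set_bjellqvist()]); the pKa set is swappable.
#' The result depends only on residue composition and the terminal residues,
#' not on sequence order.
#'
#' @param sequence a single amino-acid sequence string.
#' @param pka a `pka_set`.
#' @param tol bisection interval width at convergence (pH units).
#' @return the isoelectric point at full precision; round to 2 decimals for
#'   the conventional report value.
#' @export
isoelectric_point <- function(sequence, pka = pka_set_bjellqvist(),
                              tol = 0.002) {
  lo <- 0
  hi <- 14
  z_lo <- net_charge(sequence, lo, pka)
  z_hi <- net_charge(sequence, hi, pka)
  if (z_lo <= 0) return(lo)
  if (z_hi >= 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Small-TLP classification
#'
#' TLPs carrying exactly 10 conserved cysteines are designated small TLPs;
#' the classical full-size class carries 16.
#'
#' @param n_cysteine cysteine count(s).
#' @return logical vector, `TRUE` for small TLPs.
#' @export
classify_small_tlp <- function(n_cysteine) {
  stopifnot(all(n_cysteine >= 0))
  n_cysteine == 10L
}

#' Assemble the per-gene TLP feature table
#'
#' Joins the retained proteins with their gene models and external
#' annotations into one row per TLP: lengths, isoelectric point, molecular
#' weight, cysteine count, carbohydrate-binding-motif flags, genomic
#' location, exon-count structure group and the small-TLP flag.  The CDS /
#' protein length invariant `aa = cds/3 - 1` is enforced.
#'
#' @param proteins protein table of the retained TLP set.
#' @param gene_models named list of `gene_model` objects (names are
#'   transcript identifiers covering every protein).
#' @param annotations optional annotation table
#'   (see [read_annotation_table()]); missing proteins get
#'   `"unknown"` labels and `tm_count` 0.
#' @param gene_symbols optional named character vector mapping
#'   `protein_id` to a display gene symbol; defaults to the protein id.
#' @return data frame sorted by gene symbol with the columns of a
#'   characterization table: `gene_symbol`, `accession`, `cds_length_bp`,
#'   `aa_length`, `pI`, `mw_kda`, `n_cysteine`, `chromosome`, `start`,
#'   `end`, `exon_count`, `structure_group`, `cbm_canonical`,
#'   `cbm_variant`, `localization`, `signal_peptide`, `tm_count`,
#'   `is_small_tlp`.
#' @export
assemble_feature_table <- function(proteins, gene_models, annotations = NULL,
                                   gene_symbols = NULL) {
  missing_models <- setdiff(proteins$protein_id, names(gene_models))
  if (length(missing_models)) {
    stop("no gene model for protein(s): ",
         paste(missing_models, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    id <- proteins$protein_id[i]
    seq <- proteins$sequence[i]
    model <- gene_models[[id]]
    cds_len <- sum(model$cds[, 2] - model$cds[, 1] + 1L)
    aa_len <- nchar(seq)
    expected <- protein_length_from_cds(cds_len)
    if (aa_len != expected) {
      stop("protein ", id, " length ", aa_len,
           " inconsistent with CDS length ", cds_len,
           " (expected ", expected, " aa)")
    }
    n_cys <- count_cysteines(seq)
    cbm <- detect_cbm(seq)
    data.frame(
      gene_symbol = if (!is.null(gene_symbols) && id %in% names(gene_symbols))
        gene_symbols[[id]] else id,
      accession = id,
      cds_length_bp = cds_len,
      aa_length = aa_len,
      pI = round(isoelectric_point(seq), 2),
      mw_kda = round(molecular_weight(seq) / 1000, 3),
      n_cysteine = n_cys,
      chromosome = model$chromosome,
      start = model$span[1],
      end = model$span[2],
      exon_count = nrow(model$exons),
      structure_group = exon_group_label(nrow(model$exons)),
      cbm_canonical = cbm$canonical,
      cbm_variant = cbm$variant,
      is_small_tlp = classify_small_tlp(n_cys),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(annotations)) {
    annotations <- data.frame(protein_id = character(0),
                              localization = character(0),
                              signal_peptide = character(0),
                              tm_count = integer(0), stringsAsFactors = FALSE)
  }
  j <- match(tab$accession, annotations$protein_id)
  tab$localization <- ifelse(is.na(j), "unknown", annotations$localization[j])
  tab$signal_peptide <- ifelse(is.na(j), "unknown", annotations$signal_peptide[j])
  tab$tm_count <- ifelse(is.na(j), 0L, annotations$tm_count[j])
  tab <- tab[order(tab$gene_symbol), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
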