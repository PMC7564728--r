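# PROSITE-style pattern engine and the candidate-selection funnel that turns
# a proteome plus a homology-hit table into the final signature-verified,
# one-per-locus TLP set.

#' The thaumatin family signature
#'
#' PROSITE-style expression of the thaumatin family signature that is
#' diagnostic of TLP / PR-5 proteins.  Literal cysteines, the invariant
#' threonine and aspartate, and two variable-length spacers give a matched
#' length between 15 and 17 residues.
#'
#' @return the signature as a pattern string, ready for [parse_prosite()].
#' @export
thaumatin_signature <- function() {
  "G-x-[GF]-x-C-x-T-[GA]-D-C-x-(1,2)-[GQ]-x-(2,3)-C"
}

#' Compile a PROSITE-style pattern
#'
#' Supported grammar: elements separated by `-`; an element is a single
#' amino-acid letter (literal), `x` (any residue) or a bracketed class such
#' as `[GF]`; a repeat suffix `(n)` or `(n,m)` may be attached to the
#' element or follow it as its own `-`-separated token (both `x(1,2)` and
#' `x-(1,2)` are accepted).  PROSITE anchors (`<`, `>`) and negated classes
#' (`{..}`) are not part of the subset and raise a parse error.
#'
#' @param pattern_text the pattern string.
#' @return an object of class `prosite_pattern`: a list of elements (each
#'   with `kind`, `residues`, `min_repeat`, `max_repeat`) with attributes
#'   `min_len`, `max_len` and `source_text`.
#' @export
parse_prosite <- function(pattern_text) {
  stopifnot(is.character(pattern_text), length(pattern_text) == 1L)
  text <- trimws(pattern_text)
  if (!nzchar(text)) stop("empty pattern")
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  elements <- list()
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (!nzchar(tok)) stop("empty element at position ", i)
    if (grepl("^\\(", tok)) {
      # standalone repeat token applying to the previous element
      rep_bounds <- .parse_repeat(tok, i)
      if (length(elements) == 0L) {
        stop("repeat token at position ", i, " has no preceding element")
      }
      last <- length(elements)
      if (elements[[last]]$min_repeat != 1L || elements[[last]]$max_repeat != 1L) {
        stop("double repeat specification at position ", i)
      }
      elements[[last]]$min_repeat <- rep_bounds[1]
      elements[[last]]$max_repeat <- rep_bounds[2]
      next
    }
    m <- regmatches(tok, regexec("^([A-WYZa-z]|\\[[A-Z]*\\])(\\(.*\\))?$", tok))[[1]]
    if (length(m) == 0L || m[2] == "") {
      if (grepl("[<>{}]", tok)) {
        stop("unsupported PROSITE syntax '", tok, "' at position ", i)
      }
      stop("cannot parse element '", tok, "' at position ", i)
    }
    core <- m[2]
    rep_bounds <- if (nzchar(m[3])) .parse_repeat(m[3], i) else c(1L, 1L)
    if (core == "x") {
      el <- list(kind = "any", residues = character(0))
    } else if (startsWith(core, "[")) {
      residues <- strsplit(substr(core, 2L, nchar(core) - 1L), "", fixed = TRUE)[[1]]
      if (length(residues) == 0L) stop("empty class at position ", i)
      bad <- setdiff(residues, amino_acids(extended = FALSE))
      if (length(bad)) {
        stop("unknown residue(s) ", paste(bad, collapse = ""),
             " in class at position ", i)
      }
      el <- list(kind = "class", residues = residues)
    } else if (core %in% amino_acids(extended = FALSE)) {
      el <- list(kind = "literal", residues = core)
    } else {
      stop("unknown character '", core, "' at position ", i)
    }
    el$min_repeat <- rep_bounds[1]
    el$max_repeat <- rep_bounds[2]
    elements[[length(elements) + 1L]] <- el
  }
  if (length(elements) == 0L) stop("pattern has no elements")
  min_len <- sum(vapply(elements, `[[`, integer(1), "min_repeat"))
  max_len <- sum(vapply(elements, `[[`, integer(1), "max_repeat"))
  structure(elements, min_len = min_len, max_len = max_len,
            source_text = text, class = "prosite_pattern")
}

.parse_repeat <- function(tok, pos) {
  m <- regmatches(tok, regexec("^\\(([0-9]+)(,([0-9]+))?\\)$", tok))[[1]]
  if (length(m) == 0L) stop("malformed repeat '", tok, "' at position ", pos)
  n <- as.integer(m[2])
  mx <- if (nzchar(m[4])) as.integer(m[4]) else n
  if (n < 1L) stop("repeat minimum must be >= 1 at position ", pos)
  if (mx < n) stop("repeat maximum ", mx, " < minimum ", n, " at position ", pos)
  c(n, mx)
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("PROSITE pattern:", attr(x, "source_text"), "\n")
  cat(length(x), "elements, matched length",
      attr(x, "min_len"), "-", attr(x, "max_len"), "\n")
  invisible(x)
}

.element_matches <- function(el, ch) {
  if (el$kind == "any") TRUE else ch %in% el$residues
}

# match pattern elements against chars starting at position `pos`;
# repeat counts are tried shortest-first (lexicographically over the repeat
# vector), so the first success is the shortest-expansion match for `pos`.
# Returns the end position(s): first success only, or all distinct ends when
# all = TRUE.
.match_at <- function(chars, pattern, pos, all = FALSE) {
  n <- length(chars)
  ends <- integer(0)
  recurse <- function(p, idx) {
    if (idx > length(pattern)) {
      ends <<- c(ends, p - 1L)
      return(!all)  # stop after first success unless enumerating all
    }
    el <- pattern[[idx]]
    q <- p
    for (r in seq_len(el$max_repeat)) {
      if (q > n || !.element_matches(el, chars[q])) {
        return(FALSE)
      }
      q <- q + 1L
      if (r >= el$min_repeat) {
        if (recurse(q, idx + 1L)) return(TRUE)
      }
    }
    FALSE
  }
  recurse(pos, 1L)
  unique(ends)
}

#' Scan a protein sequence for a compiled PROSITE-style pattern
#'
#' Every start position is examined and matches may overlap.  For a given
#' start, variable repeats are expanded shortest-first and the first valid
#' expansion is reported (one match per start, PROSITE convention); set
#' `all_expansions = TRUE` to report every distinct expansion instead.
#' Positions are 1-based inclusive.
#'
#' @param sequence a single amino-acid sequence string.
#' @param pattern a `prosite_pattern` from [parse_prosite()].
#' @param all_expansions report all valid expansions per start.
#' @return data frame with columns `start`, `end`, `matched` (the matched
#'   subsequence); zero rows when there is no match.
#' @export
scan_signature <- function(sequence, pattern, all_expansions = FALSE) {
  stopifnot(inherits(pattern, "prosite_pattern"),
            is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  min_len <- attr(pattern, "min_len")
  out_start <- integer(0)
  out_end <- integer(0)
  last_start <- length(chars) - min_len + 1L
  if (last_start >= 1L) {
    for (p in seq_len(last_start)) {
      ends <- .match_at(chars, pattern, p, all = all_expansions)
      if (length(ends)) {
        out_start <- c(out_start, rep.int(p, length(ends)))
        out_end <- c(out_end, ends)
      }
    }
  }
  matched <- if (length(out_start)) substring(sequence, out_start, out_end)
    else character(0)
  data.frame(start = out_start, end = out_end, matched = matched,
             stringsAsFactors = FALSE)
}

#' Scan every protein of a protein table
#'
#' @param proteins protein table (see [read_protein_fasta()]).
#' @param pattern a `prosite_pattern`; defaults to the thaumatin family
#'   signature.
#' @param all_expansions passed to [scan_signature()].
#' @return data frame with columns `protein_id`, `start`, `end`, `matched`.
#' @export
scan_proteome <- function(proteins, pattern = parse_prosite(thaumatin_signature()),
                          all_expansions = FALSE) {
  res <- lapply(seq_len(nrow(proteins)), function(i) {
    m <- scan_signature(proteins$sequence[i], pattern, all_expansions)
    if (nrow(m)) cbind(protein_id = proteins$protein_id[i], m,
                       stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Detect the carbohydrate-binding motif (CBM)
#'
#' Reports exact occurrences of the canonical carbohydrate-binding
#' octapeptide `CQTGDCGG` and of its `CQTGDCQG` variant (glycine-to-glutamine
#' substitution at the seventh position).  Positions are 1-based.
#'
#' @param sequence a single amino-acid sequence string.
#' @return list with elements `canonical` (logical), `variant` (logical),
#'   `canonical_positions`, `variant_positions` (integer vectors of match
#'   start positions).
#' @export
detect_cbm <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  find <- function(motif) {
    hits <- gregexpr(motif, sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  }
  canonical <- find("CQTGDCGG")
  variant <- find("CQTGDCQG")
  list(canonical = length(canonical) > 0L,
       variant = length(variant) > 0L,
       canonical_positions = canonical,
       variant_positions = variant)
}

#' Filter homology hits by e-value
#'
#' @param hits hit table (see [read_hit_table()]).
#' @param threshold e-value cutoff, default `1e-10`.
#' @param inclusive retain hits with `e_value <= threshold` (default); if
#'   `FALSE`, the comparison is strict.
#' @return the retained rows of `hits`.
#' @export
filter_hits <- function(hits, threshold = 1e-10, inclusive = TRUE) {
  stopifnot(is.numeric(threshold), threshold > 0)
  keep <- if (inclusive) hits$e_value <= threshold else hits$e_value < threshold
  hits[keep, , drop = FALSE]
}

#' Candidate-selection funnel for TLP identification
#'
#' Turns a proteome plus homology-hit table into the final signature-verified
#' TLP set, mirroring the identification pipeline: (1) retain hit proteins
#' passing the e-value cutoff; (2) retain those containing at least one
#' complete thaumatin-signature match; (3) collapse to one protein per
#' genetic locus, keeping the longest isoform (ties broken by the
#' lexicographically smallest transcript identifier).
#'
#' @param proteins protein table; its `locus_id` column assigns loci unless
#'   `locus_map` is supplied.
#' @param hits hit table; every `query_id` must exist in `proteins`.
#' @param pattern compiled signature pattern.
#' @param locus_map optional data frame (`protein_id`, `locus_id`).
#' @param evalue e-value cutoff (inclusive), default `1e-10`.
#' @return list with `tlps` (rows of `proteins` retained, sorted by
#'   `protein_id`) and `report`, a `funnel_report` with the stage counts
#'   `n_input_hits`, `n_after_evalue`, `n_with_signature`, `n_unique_loci`
#'   and the `retained_ids`.
#' @export
candidate_funnel <- function(proteins, hits,
                             pattern = parse_prosite(thaumatin_signature()),
                             locus_map = NULL, evalue = 1e-10) {
  query_ids <- unique(hits$query_id)
  unknown <- setdiff(query_ids, proteins$protein_id)
  if (length(unknown)) {
    stop("hit table references unknown protein(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(locus_map)) {
    locus <- locus_map$locus_id[match(proteins$protein_id, locus_map$protein_id)]
    if (anyNA(locus[proteins$protein_id %in% query_ids])) {
      stop("locus_map does not cover all hit proteins")
    }
  } else {
    locus <- proteins$locus_id
  }
  names(locus) <- proteins$protein_id

  pass_e <- unique(filter_hits(hits, threshold = evalue)$query_id)
  has_sig <- pass_e[vapply(pass_e, function(id) {
    s <- proteins$sequence[match(id, proteins$protein_id)]
    nrow(scan_signature(s, pattern)) > 0L
  }, logical(1))]

  retained <- character(0)
  if (length(has_sig)) {
    len <- nchar(proteins$sequence[match(has_sig, proteins$protein_id)])
    by_locus <- split(data.frame(id = has_sig, len = len,
                                 stringsAsFactors = FALSE),
                      locus[has_sig])
    retained <- vapply(by_locus, function(d) {
      d <- d[order(-d$len, d$id), , drop = FALSE]
      d$id[1]
    }, character(1))
    retained <- sort(unname(retained))
  }

  report <- structure(list(n_input_hits = length(query_ids),
                           n_after_evalue = length(pass_e),
                           n_with_signature = length(has_sig),
                           n_unique_loci = length(retained),
                           retained_ids = retained),
                      class = "funnel_report")
  tlps <- proteins[match(retained, proteins$protein_id), , drop = FALSE]
  rownames(tlps) <- NULL
  list(tlps = tlps, report = report)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("TLP candidate funnel\n")
  cat("  input hit proteins:     ", x$n_input_hits, "\n")
  cat("  pass e-value cutoff:    ", x$n_after_evalue, "\n")
  cat("  complete signature:     ", x$n_with_signature, "\n")
  cat("  unique loci (retained): ", x$n_unique_loci, "\n")
  invisible(x)
}
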