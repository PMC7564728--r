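---
title: "Mining and characterizing thaumatin-like protein gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and characterizing thaumatin-like protein gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlpminer)
```

## The problem

Thaumatin-like proteins (TLPs, the pathogenesis-related PR-5 family) are
cysteine-rich plant proteins involved in defense and in seed germination;
in barley, TLPs carrying the carbohydrate-binding octapeptide `CQTGDCGG`
interact with endosperm β-glucan and are of direct interest to malting
quality. Genome-wide surveys of this family follow a standard recipe:
collect homology hits against a TLP domain, verify each candidate carries
the complete thaumatin family signature, collapse transcript isoforms to
one gene model per locus, and then characterize the survivors —
physicochemically (length, pI, molecular weight, cysteines), structurally
(exon/intron architecture, chromosomal clustering), phylogenetically
(neighbor-joining over a protein alignment with bootstrap), and by
expression (tissue FPKM panels, RT-PCR during germination).

`tlpminer` implements that recipe as a tested pipeline. Steps that depend
on external predictors or search engines (BLASTp, Pfam/SMART, SignalP,
TMHMM, subcellular localization, MUSCLE alignment) are consumed as inputs
— a hit table, an annotation table, an aligned FASTA — never re-implemented
and never required to run.

## The signature engine

The thaumatin family signature is the PROSITE-style pattern

```
G-x-[GF]-x-C-x-T-[GA]-D-C-x(1,2)-[GQ]-x(2,3)-C
```

compiled by `parse_prosite()` into 14 elements with matched lengths 15–17.
The supported grammar is the subset this class of signatures needs:
literals, `x`, bracketed classes, and `(n)`/`(n,m)` repeats (both `x(1,2)`
and the dash-separated `x-(1,2)` spelling are accepted, since both appear
in the literature). PROSITE anchors (`<`, `>`) and negated classes
(`{..}`) are a deliberate parse error rather than being silently ignored.

`scan_signature()` examines every start position, so matches may overlap.
For a fixed start, variable repeats are expanded shortest-first
(lexicographically over the repeat vector) and the first valid expansion
is reported — one deterministic match per start, following the PROSITE
convention; `all_expansions = TRUE` enumerates every expansion instead.
All coordinates are 1-based inclusive, matching biological convention.
The engine is property-tested against an independent brute-force matcher
that enumerates all starts and all repeat combinations on randomized
patterns and sequences.

## The candidate funnel

`candidate_funnel()` orders the selection stages as the identification
pipeline draws them top-to-bottom: e-value filter, then signature
verification, then locus collapse. The e-value cutoff defaults to `1e-10`
and the comparison is inclusive (`<=`); the convention is configurable
because "cutoff" alone does not fix the boundary. Locus collapse keeps the
longest protein per locus; equal lengths are broken by the
lexicographically smallest transcript identifier, a choice made purely for
determinism. The four funnel counts are non-increasing by construction and
this invariant is tested.

## Physicochemical characterization

Molecular weight is the sum of average residue masses plus one water
(18.0153 Da), the ProtParam convention; monoisotopic masses sit behind a
flag. The isoelectric point uses the Bjellqvist pKa set as applied by
ProtParam — side chains C 9.0, D 4.05, E 4.45, H 5.98, K 10.0, R 12.0,
Y 10.0; generic termini 7.50/3.55; N-terminal backbone pKa adjusted by the
identity of the first residue, and the side-chain pKa of a C-terminal
Asp/Glu raised to 4.55/4.75. The pKa set is a named, swappable object
(`pka_set_bjellqvist()`) because different tools ship different tables and
reproducing a published table requires matching its convention. The net
charge `Z(pH)` is strictly decreasing, so bisection on `[0, 14]` has a
unique root; the interval is narrowed to 0.002 pH units, comfortably
below the 2-decimal reporting precision. `pI` depends only on composition
plus the two terminal residues, a property the suite verifies by shuffling
sequence interiors.

A small TLP is one with exactly 10 cysteines; the feature-table assembler
(`assemble_feature_table()`) enforces the `aa = cds/3 − 1` arithmetic
between each protein and its gene model, computes report-precision
roundings (MW to 3 decimals of kDa, pI to 2 decimals) only at the table
surface, and defaults missing external annotations to `"unknown"`/0
rather than failing.

## Gene structure

Gene models are 1-based inclusive interval sets (the GFF3 standard) read
and written through `rtracklayer`. Exon-count classification maps 1–4
exons to groups I–IV; counts above 4 are labelled `other` instead of
erroring so the classifier generalizes beyond families that happen to top
out at four exons. `map_protein_position_to_exon()` converts an
amino-acid position to spliced-CDS nucleotide offset `3(aa−1)+1` and reads
off the exon ordinal 5′→3′ of the transcript, i.e. in reverse genomic
order on the minus strand — this is how one asks "is the signature encoded
in the second exon".

Splice variants are reported both as transcripts-per-gene and as
additional-variants-beyond-the-first, since the phrase "splice variants"
is used both ways in the literature. Tandem-duplication candidates are
consecutive same-chromosome genes with an intervening gap below a
configurable threshold; the default of 1 Mb operationalizes "close
proximity on the same chromosome" and is deliberately coarse — it flags
candidates for inspection, it does not call duplication events.

The bundled reference table (`barley_tlp_table()`) transcribes the
published characterization of the 19-member barley family (HvTLP1–19).
Two quirks of that table are preserved rather than corrected: the text
total of single-exon genes disagrees with the table by one (the table is
treated as authoritative), and the HvTLP5 genomic span (~138 kb for a
2-exon gene) is anomalous but reproduced as printed.

## Phylogeny

Distances over an aligned protein set use pairwise deletion (columns with
a gap in either member of a pair are dropped for that pair) and either the
p-distance or its Poisson correction `d = −ln(1 − p)`; Poisson is the
default since it is the simplest standard correction for multiple hits,
and the original analysis does not record its distance settings. A pair
with no comparable sites, or `p = 1` under Poisson, is an error naming the
pair rather than a silent `Inf`.

Trees come from Saitou–Nei neighbor joining (via `ape::nj` behind the
`nj_tree()` surface); negative branch lengths, which NJ can produce on
non-additive input, are clamped to zero with a warning, matching how the
major GUI tools present such branches. On additive input the suite
requires exact topology recovery and path-length reproduction to 1e-9.

Bootstrap supports resample alignment columns with replacement; replicate
`r` is seeded `seed + r`, so results are reproducible under one root seed
and each replicate's resampling is independent of how many replicates are
requested. Supports are the percentage of replicate trees containing each
internal bipartition of the original tree.

`extract_groups()` is an explicit algorithmic stand-in for reading groups
off a drawn tree: cut the `k − 1` longest internal edges (extending into
terminal edges when the tree has fewer internal edges than cuts, e.g. for
`k` equal to the leaf count) and take leaf-containing components as
groups. Ties are broken by the lexicographically smallest leaf beneath the
edge. In degenerate geometries the cuts can isolate leafless internal
fragments and yield fewer than `k` groups; the function warns when that
happens. The nine groups of the published cross-species figure are a
visual judgment and are not an acceptance surface for this algorithm;
`k` is a user parameter.

## Expression

FPKM matrices are transformed as `log2(x + 1)`. The pseudo-count is
unavoidable — FPKM panels contain exact zeros — and 1 is chosen so that 0
maps to 0 and the transform is monotone; it is configurable. Row
clustering is agglomerative average linkage (UPGMA) on Euclidean
distances, the defaults of the MeV-style tools used for such heatmaps,
with Pearson-correlation distance behind a flag; merge heights are tested
against a brute-force average-linkage oracle. Per-row min–max scaling
(`scale_rows()`) exists for display only; tests assert on raw log2
values because the published figure does not state its normalization
mode.

RT-PCR quantification divides each band intensity by the reference-gene
(actin) intensity from the same sample, and `compare_groups()` applies
the classic pooled-variance two-sample t-test (`df = n_a + n_b − 2`,
two-sided, significance at 0.05), with Welch behind a flag. Degenerate
zero-variance input is an error, not a silent `NaN`.

## The synthetic-data generator

The generators exist so every pipeline stage can be tested against planted
truth without any database access.

`design_protein()` draws background residues from the 17-letter alphabet
that excludes C, T and D — the three residues the signature pins at fixed
offsets. The consequence is exactness: the planted span is provably the
only signature match, the carbohydrate-binding motif occurs only where
planted, and the cysteine count is exact by construction. This is a
deliberate trade of compositional realism for verifiable ground truth.
Protein lengths default to the 173–359 aa range and cysteine counts to
10–24, the observed extremes of the barley family. Decoys are built as
signature-bearing proteins whose invariant aspartate is mutated to lysine
— TLP-like sequences that fail verification, so precision tests exercise
the signature filter rather than trivial background rejection.

`build_gene_model()` back-translates with uniform synonymous-codon choice
(codon-usage realism is out of scope), splits the CDS at random points
that need not respect codon boundaries, and inserts `GT…AG` introns of
60–300 bp. Extracting, splicing and translating every generated model
from its chromosome sequence must reproduce the protein exactly, on both
strands — the round-trip oracle the suite runs over every generated gene.

`make_genome()` assembles loci into chromosomes (gene regions embedded in
`N` filler — intergenic composition is not modelled), places a tandem
cluster within the adjacency threshold while spacing other genes 2 Mb
apart, adds truncated isoforms that retain the signature, and emits a hit
table whose true transcripts draw e-values log-uniform in [1e-50, 1e-12]
while half the decoys also pass the 1e-10 cutoff. Its defaults — 19 true
loci, 13 extra isoforms (32 signature-bearing transcripts) and 13 decoys,
with the 19-locus chromosome tally {5H:8, 7H:3, 4H:3, 3H:3, 1H:2} — are
the multiplicity structure of the barley study, so the funnel's 32→19
collapse is exercised under the published conditions.

`evolve_alignment()` runs a Poisson substitution process (event count per
site ~ Poisson(branch length), each event replacing the residue with a
uniformly chosen different one) with no indels. For moderate branch
lengths the Poisson-corrected distance estimates the path length; at the
10,000-site law-of-large-numbers check the small residual bias of
back-substitution is covered by the 3-standard-error tolerance.
`tlp_expression_profiles()` plants the tissue structure seen in the
barley panel — embryo-high, developing-grain-high and root/tiller-high
classes at 8-fold over baseline across the eight tissues EMB, LEA, INF1,
INF2, ROO, NOD, CAR5, CAR15 — and `make_expression()` adds truncated
Gaussian noise.

What passing these tests shows is that the pipeline is correct on data
satisfying its assumptions; it does not show robustness to the ways real
proteomes differ — compositional bias, partial signatures, fragmented
gene models, mis-annotated CDS phases, or alignment error upstream of the
phylogeny.

## Problem sizes and determinism

The test suite works at desk scale by design: randomized pattern
equivalence over ~180 pattern/sequence pairs of length ≤ 60, NJ recovery
on 4–8 taxa, bootstrap with 100 replicates on 6-taxon alignments of 400
sites, synthetic genomes of up to 19 loci, and one 10,000-site
law-of-large-numbers check. Every stochastic step takes an explicit
integer seed and is wrapped so the global RNG is untouched; the same seed
reproduces byte-identical FASTA/GFF3 output.

The real-sequence checks (cysteine counts, MW, pI of the published
accessions) require the protein sequences retrieved from Ensembl Plants
by accession; the package does not bundle or download them. Placing them
at `inst/extdata/hvtlp_proteins.fa` activates those checks.

## Known limitations

- The pattern grammar is the subset the thaumatin signature needs; full
  PROSITE (anchors, negated classes, `>` inside brackets) is out of scope.
- pI values reproduce the ProtParam convention only to the extent the
  Bjellqvist table does; proteins dominated by unusual termini are
  reported at full precision but conventions differ between tools.
- Group extraction on trees with many tied edge lengths can return fewer
  than `k` groups (warned).
- The t-test applies to per-sample relative-expression ratios; it does
  not model gel-quantification error structure.
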