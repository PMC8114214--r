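---
title: "Methods and design of the immunopep analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the immunopep analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopep)
```

`immunopep` analyses MHC class I immunopeptidomes: the peptides eluted
from MHC-I molecules of a cell line, identified by LC-MS/MS, together
with the MHC-I allotypes that present them. The motivating system is the
Tasmanian devil and its two transmissible cancers (DFT1 and DFT2), where
a pan-β2m immunoaffinity capture pools the ligands of several allotypes
into one data set per cell line. This vignette documents the models and
procedures each stage implements, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical choices
made where conventions were genuinely open.

## Input model

The unit of observation is one identified peptide row in a search-engine
export: sequence, cell line, replicate, optional label-free intensity,
optional source-protein accessions. Rows are observations, not unique
peptides — the same sequence seen in two replicates (or two HPLC
fractions) is two rows. Sequences are uppercased and validated against
the 20 standard one-letter codes; rows containing anything else
(ambiguity codes, modification annotations) are rejected and counted
rather than silently coerced. Sequences are otherwise taken verbatim:
isoleucine and leucine are *not* collapsed, so leucine frequencies mean
what the upstream search engine reported. Intensity is optional because
presence/absence analyses do not need it; it becomes mandatory only for
allotype quantification.

## Repertoire statistics

"Unique" always means exact string equality of the peptide sequence
within a cell line, pooled across replicates; cross-cell-line overlaps
use the same pooled sets. The canonical MHC-I length window is 7–15
residues (inclusive; configurable). `summarize_repertoire()` reports the
raw percentage of unique sequences in the window and a display version
truncated toward zero to an integer — truncation, not half-up rounding,
because that is the convention the printed summary tables this output
mirrors actually follow, and the two differ for fractions above .5.
The raw percentage is always retained alongside.

Length distributions are computed per replicate and summarised as
mean ± SEM (SEM = sd/√n) across replicates, because replicate-to-replicate
variability is the relevant error for these bar charts; a pooled variant
is available. With a single replicate the SEM is reported as missing
rather than zero. Replicate reproducibility is the fraction of unique
7–15mers detected in exactly *k* of the declared replicates; the
fractions sum to 100% by construction. The overlap partition
(`venn_overlap()`) returns all 2^m − 1 disjoint regions for m cell lines
so region counts always sum to the union size.

`differential_source_proteins()` is the ordinary equal-variance
two-sample Student's t-test on log2 expression values per accession, with
the mean log2 difference as fold change and Benjamini–Hochberg
adjustment. The degenerate zero-variance case (which `stats::t.test()`
refuses) is handled explicitly: p = 1 when the group means are equal,
p = 0 otherwise. Non-positive raw intensities are excluded with a
warning before any log transform, and accessions with fewer than two
values per group are dropped.

## Consensus motifs

A position frequency matrix is built from unique sequences of exactly
length L, pooled across replicates; each row (position) sums to 1. pΩ is
defined as the C-terminal position of the peptide, whatever its length,
so 8mer and 9mer matrices are comparable at the anchor positions p3 and
pΩ. Consensus classes use half-open boundaries: dominant strictly above
0.30, strong in (0.20, 0.30], moderate in (0.10, 0.20]. Strictness at
0.30 follows the ">30%" convention for the dominant class; the interval
descriptions "20–30%" and "10–20%" are otherwise ambiguous at their
endpoints, and the half-open reading makes the three classes a partition
(a residue-position pair can carry exactly one class). Within a
position, residues sort by descending frequency with alphabetical
tie-break, so output ordering is deterministic.

Small/bulky usage follows the residue sets {A, D, G, N, P, S} (small)
and {F, H, K, R, Y} (bulky); the other nine residues deliberately count
toward neither. The denominator is the pooled residue occurrences over
unique peptides of each length — one 9mer contributes nine residue
tokens — with per-replicate computation and SEM when requested. Pooling
residues (rather than averaging per-peptide fractions) weights longer
peptides proportionally to their residue content and keeps the uniform
null exactly 6/20 and 5/20.

## Allotype quantification

Alpha-chain-derived peptides are assigned to allotype groups by exact
substring matching against the allele sequences: enzymatic digestion of
an intact alpha chain yields exact subsequences, so no mismatch
tolerance is introduced. Groups exist because some alleles (e.g. two
alleles one non-synonymous substitution apart) cannot be distinguished
by the observed peptides; a peptide matching several alleles of one
group is an ordinary assignment, while a peptide matching two *groups*
is ambiguous and excluded — fractional sharing would invent an
allocation rule the data cannot support. Within a replicate, the
normalization denominator is the total intensity of *all* peptides, so
group shares sum to at most 1 and ambiguous/unmatched material accounts
for the shortfall; the quantification is thereby invariant to uniform
rescaling of a replicate's intensities. The presence rule retains a
group only when detected in ≥ 3 of 4 replicates by default (both numbers
configurable). Pairwise group comparisons use the same Student's t-test
as the proteomics stage, on per-replicate normalized intensities.

## Pocket homology scoring

The B pocket (reference positions 7, 9, 24, 34, 45, 63, 66, 67, 70, 99)
and F pocket (77, 80, 81, 84, 94, 115, 122, 142, 145, 146 plus adjacent
residues) are fixed position sets on the mature-chain numbering of an
HLA-A*02:01-style reference; any alignment of query and subjects to that
reference defines the mapping of positions to residues. Adjacency is ±1
in reference numbering (configurable radius), applied to the F pocket by
default — it buffers small register differences between distantly
related alleles. Positions beyond the reference length are clipped at
mapping time.

The score of query q against subject s is the contact-weighted
similarity sum S(q, s) = Σ_p w(p)·M[q(p), s(p)]. The maximum alignment
score is interpreted as the query's self-score S(q, q), computed per
query and pocket; with a similarity matrix whose diagonal is row-maximal
this bounds the relative score by 1. A subject passes when
S(q, s) ≥ 0.93 · S(q, q) — the cut-off is inclusive, so a relative score
of exactly 0.93 is a hit. A gap at a pocket position contributes the
matrix's global minimum (weighted), so missing pocket residues penalise
rather than inflate relative scores (skipping positions would do the
opposite). The relative score is invariant to uniform positive rescaling
of the weights. Pockets are scored separately, matching how pocket-level
results are reported and interpreted.

Two inputs are configuration, not computation: the 20×20 similarity
matrix and the contact weights. The package ships a *synthetic*
PMBEC-style similarity matrix (`synthetic_similarity_matrix()`, also as
`inst/extdata/similarity_pmbec_style_synthetic.tsv`) built from
standardised physicochemical property scales through a Gaussian kernel —
symmetric, strictly row-maximal diagonal — and a uniform contact-weight
table. Both are stand-ins with the right structural properties;
experimentally derived matrices and structure-derived contact
probabilities should be supplied through `read_similarity_matrix()` and
`read_contact_weights()` when available. Motif transfer likewise
consumes a user-supplied allele→motif annotation table; the package
ranks and selects (top 3 passing matches by default) but does not
predict binding affinity itself.

Alignment is delegated: `scan_database()` accepts a precomputed multiple
alignment (aligned FASTA via `Biostrings::readAAStringSet()` works
directly), which is the right input for a real cross-species scan. When
none is supplied, each sequence is aligned pairwise to the reference
(global Needleman–Wunsch via `Biostrings::pairwiseAlignment`, BLOSUM62,
affine gap open 10 / extend 1) — adequate for closely related allele
sets and the synthetic tests, but a pairwise fallback cannot recover a
consistent column space for deeply diverged sequence families.

## The synthetic generator

`synthetic_config()` specifies, per cell line: the number of candidate
unique peptides, a length distribution over 7–15 (default dominated by
8/9mers, approximating observed MHC-I ligandomes), a motif mixture, a
per-replicate detection probability, and a log-normal intensity model.
The default mixture has one anchored component (weight 0.7) carrying a
leucine anchor at p3 and a hydrophobic pΩ preference (L/V/F/P at
0.35/0.25/0.20/0.10) over a uniform background, plus an unanchored
background component — the three default cell lines differ only in the
p3 anchor strength (0.45 in the fibroblast-like and DFT2-like lines,
0.35 in the DFT1-like line, making the pooled p3 leucine frequency land
in the dominant and strong class respectively) and in repertoire size.
The background amino-acid distribution is uniform by default because it
makes closed-form expectations exact in tests; a proteome-like
composition can be configured but is deliberately not the default.

Detection is Bernoulli per replicate; a candidate sequence detected in
no replicate is never observed, so the observed replicate-count
distribution is the conditional Binomial(n, p | ≥1) — the closed form
the reproducibility tests check against. Cross-line overlap is
controlled by explicit injection of a shared pool (a configured fraction
of each line's candidates) rather than by hoping for collisions, so
expected region counts are constructible. The alpha-chain digest
generator samples 7–25mer substrings of allele sequences and then scales
each group's intensity sum within each replicate to the planted
abundance fractions, keeping peptide-level log-normal variation within
groups; without that scaling the heavy-tailed intensities would make
planted shares unrecoverable at realistic peptide counts. The allele-set
generator emits equal-length, substitution-only sequences, so the
trivial column mapping is the correct alignment and ground truth for the
planted pocket-identical subject is exact.

What the generator does *not* emulate: modified residues, I/L ambiguity,
chromatographic or spectral noise, search-engine FDR structure,
length-dependent detectability, correlated detection between replicates,
and real allele phylogeny. Passing tests therefore demonstrate that the
statistics, classifications and scores are computed correctly under
controlled conditions — not that the biological conclusions would
survive those real-data complications.

## Problem sizes and determinism

The test suite and the acceptance script run at deliberately moderate
sizes chosen to make sampling noise small relative to every asserted
tolerance: 5,000 unique peptides for motif recovery (binomial SD ≈ 0.007
at f = 0.35, several SDs inside each class boundary), 10,000 sequences
for reproducibility (per-bin SD < 0.5 percentage points), 500 peptides
per replicate for allotype splits, 100 repetitions for seed-robust
claims (planted-anchor classification, planted top-hit recovery), and
databases of 50 subjects for pocket scans. All generators draw through
`withr::with_seed()`, so outputs are pure functions of the configuration
seed; the pipeline writes a manifest with a configuration hash and
per-stage record counts, and re-running with the same config and seed
reproduces outputs byte-for-byte.

## Known limitations

- No motif deconvolution: a pan-β2m capture mixes the ligands of all
  expressed allotypes, and the consensus motif is that mixture's
  marginal; per-allotype motifs would need mixture modelling (e.g.
  Gibbs-clustering approaches) that is out of scope here.
- Exact substring assignment cannot place peptides carrying
  polymorphisms absent from the supplied allele sequences; the allele
  universe is entirely configuration-driven.
- The shipped similarity matrix and uniform contact weights are
  synthetic defaults, structurally correct but not experimentally
  derived; pocket-scan *scores* are meaningful relative to these inputs,
  and real analyses should substitute measured ones.
- The pairwise alignment fallback assumes the reference is alignable to
  every sequence without ambiguity; supply a proper multiple alignment
  for diverged families.
- Display percentages truncate toward zero; use the raw `pct_7_15`
  column for arithmetic.
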