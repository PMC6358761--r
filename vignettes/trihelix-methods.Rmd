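---
title: "Methods: genome-wide characterization of a trihelix gene family"
author: "trihelixr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide characterization of a trihelix gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trihelixr)
```

# Scope and model

trihelixr re-implements, as a tested pipeline, the computational procedure
used in genome-wide characterizations of the plant trihelix (GT-factor)
transcription-factor family, whose DNA-binding region is the Myb/SANT-LIKE
domain. The stages are: (1) two-pass profile-based identification of family
members in a proteome, filtered at E-value < 0.01 and a complete-domain
coverage check; (2) a per-gene catalog (ORF and protein length, molecular
weight, isoelectric point, exon counts, chromosomal distribution);
(3) duplication analysis — tandem clusters within a 200-kb window,
MCScanX-style collinear blocks for segmental duplications, and
Nei–Gojobori (NG86) Ka/Ks per duplicated pair; (4) a Poisson-distance
neighbor-joining phylogeny with bootstrap supports and marker-anchored
subfamily classification (SIP1, GTγ, GT, SH4, GTδ); (5) promoter
extraction (1500 nt upstream) with IUPAC cis-element scanning and
shared-element intersection, plus ZOOPS EM motif discovery; and
(6) expression binning, group clustering and 2^-ΔΔCT qPCR quantification
with replicate t-tests.

A synthetic-data module generates every input with a ground-truth table so
that each stage can be verified end-to-end without downloads.

# Family identification

## Profile model

The domain model is a position-specific log-odds profile built from a
gapped seed alignment: per-position emission scores
`log2(((counts + pc·bg) / (total + pc)) / bg)` with a background-shaped
pseudocount (`pc = 1` by default) against uniform background frequencies.
Alignment columns with more than 50% gaps are excluded from the match
states, the usual profile-construction practice. Searching uses local
(Smith–Waterman-style) dynamic programming against the profile with affine
gap penalties (defaults 4 / 1 bits), implemented in C++; the score floor
is 0 and ties break deterministically toward the earliest alignment end.

A full profile-HMM implementation (forward algorithm, multi-domain
envelopes) is deliberately not reproduced: the identification logic
requires ranking and thresholding of per-sequence best hits, for which a
calibrated local profile alignment is the equivalent-in-kind analog.

## E-value calibration

Scores are calibrated by fitting a Gumbel distribution by maximum
likelihood to the best-hit scores of composition-preserving shuffles of
the searched sequences (or i.i.d. background draws). The E-value of a hit
is `dbSize · (1 − exp(−exp(−λ(s − μ))))` with `dbSize` the number of
proteome sequences, i.e. a per-sequence best-hit E-value. One thousand
decoys are used by default; the fit degenerates (and errors, advising more
decoys) if the score variance vanishes.

## Two passes

Pass 1 runs the seed profile at a permissive threshold (E < 1 by default);
the aligned hit segments, threaded onto model coordinates, rebuild a
species-specific profile which is recalibrated and run over the full
proteome in pass 2. Final members must satisfy E < 0.01 **and** span at
least 80% of the model positions — the coverage check operationalizes the
"complete domain" verification that the original procedure delegated to
domain-database lookups. Pass-1 candidates that fail pass 2 are dropped.
The permissive pass-1 threshold is a configuration knob, not a reproduction
target, because the published procedure does not state it.

# Catalog statistics

Protein length from an annotated ORF is `orf/3 − 1` (the stop codon
excluded). Molecular weight is the sum of average residue masses plus one
water, in kDa (ExPASy convention). The isoelectric point solves
`Q(pH) = 0` by bisection on pH 0–14 to `|Q| < 1e-4`, where `Q` sums
Henderson–Hasselbalch charges of D, E, C, Y, H, K, R and the termini under
Bjellqvist-style pKa values; the pKa table ships as an editable file
(`extdata/pka_bjellqvist.tsv`) because the published computation names the
tool but not its constants. Subcellular localization is always an input
annotation column, never predicted.

A transcription of the published 41-gene catalog ships as
`extdata/osmsl_table1.tsv`; summarizing it reproduces the printed
genome-wide numbers (41 genes / 43 transcripts, 23 genes on the first four
chromosomes, 29 nuclear proteins, 266–882 aa, 28.62–97.37 kDa,
pI 4.45–11.38). One printed row (OsMSL37) is internally inconsistent
(ORF 1492 bp with 483 aa; 1452 bp would be consistent); the table is
transcribed verbatim and the tests name this row as the sole exception.

# Duplication and Ka/Ks

*Tandem events.* Family genes on one chromosome are clustered whenever
consecutive members lie within 200 kb (start-to-start); clusters of two or
more genes emit one event per adjacent pair.

*Anchors and collinearity.* All-vs-all protein similarity uses local
alignment with BLOSUM62 and affine gaps (top 5 non-self matches above a
score threshold). Collinear blocks are longest chains of anchors whose
gene-rank gaps on both chromosomes are at most 25, in the same or inverted
orientation, with at least 5 anchors per block (MCScanX defaults, adopted
because the cited method's parameters are not stated); chains are
extracted greedily and each anchor is used in at most one block per
chromosome pair. Family pairs co-occurring in a block are segmental;
tandem takes precedence when both lines of evidence apply.

At whole-genome gene density, the rank-gap constraint suppresses scattered
single-domain matches between family members. The synthetic genome is far
denser in family genes than a real genome, so the pipeline additionally
filters anchors with the standard homolog criteria — alignment coverage of
at least half the shorter protein and at least 60% alignment identity —
which separates whole-gene duplicates from domain-only family similarity.
These filters are configuration options of `findAnchorPairs()`, disabled
by default.

*NG86 Ka/Ks.* Synonymous site counts per codon are the per-position
fractions of the three single-nucleotide changes that are synonymous,
averaged over the two sequences; substitutions creating stop codons count
as nonsynonymous, and pathways through stop codons are excluded from the
difference averaging over substitution orders (the original-method
conventions). Proportions are corrected with Jukes–Cantor,
`d = −(3/4)·ln(1 − (4/3)p)`; `p ≥ 3/4` flags the estimate saturated and
`Ks = 0` flags the ratio undefined rather than returning NaN. Within-pair
codon alignment aligns the translated proteins globally (BLOSUM62) and
back-threads codons, dropping gapped columns — standard practice, since
the published analysis does not state its aligner. Maximum-likelihood
(codeml-style) estimation is out of scope.

# Phylogeny and subfamilies

Distances are Poisson-corrected, `d = −ln(1 − p)`, with `p` the mismatch
proportion over mutually ungapped columns (pairwise deletion); saturated
pairs (`p = 1`) are capped at a finite distance (10) and flagged. The tree
is Saitou–Nei neighbor joining with a deterministic tie-break (earliest
minimal-Q pair in matrix order); negative branch lengths are clamped to
zero with the deficit moved to the sister edge, preserving path lengths.
Bootstrap resamples alignment columns with replacement and reports the
percentage of replicates containing each original bipartition.

The published tree-building settings pair a maximum-likelihood label with
Poisson correction and pairwise deletion — options that belong to distance
methods. The package therefore implements the printed parameters as
Poisson-distance NJ with bootstrap; ML tree search is out of scope. The
published subfamily sizes depend on the real cross-species sequence set
and are documentation examples, not reproduction targets.

Subfamily labels propagate from marker taxa: each gene takes the label of
the smallest bipartition side containing it whose markers are of exactly
one subfamily; if no pure side exists it falls back to the nearest marker
by patristic distance and is flagged ambiguous. The bundled convenience
aligner threads each sequence's best profile hit onto the model's match
positions (insertions dropped); it makes no parity claim against a
progressive multiple aligner, and pre-aligned input is equally accepted.

# Promoters, cis-elements and motifs

Promoters are the 1500 nt upstream of the annotated gene start
(reverse-complemented downstream window for minus-strand genes), truncated
with a flag at chromosome edges. IUPAC consensus scanning reports every
position whose bases fall in the consensus sets, on both strands by
default (reverse-strand hits in forward coordinates); whether the original
promoter scan counted the reverse strand is unstated, so both-strand
scanning is the documented default. The five-element library (GATABOX,
ACGTATERD1, GT1CONSENSUS, INRNTPSADB, GT1GMSCAM4, with their
light/dehydration annotations) ships as an editable TSV populated from the
corresponding PLACE records; no consensus is hard-coded. The
shared-element set is the strict intersection: elements matched at least
once in every promoter.

Motif discovery is a ZOOPS (zero-or-one occurrence per sequence) EM
mixture against an i.i.d. background: per-sequence posteriors over site
offsets, PWM and occurrence-probability updates with pseudocounts, random
restarts with the best log-likelihood kept, and a post-convergence phase
refinement that re-seeds EM from sites shifted by ±1–2 positions (EM
readily converges to a register shifted by a position; re-seeding corrects
it whenever the true register has higher likelihood). Successive motifs
are fitted after masking the previous motif's maximum-posterior sites.
This is a didactic stand-in for MEME: the published motif E-values require
MEME's E-value model and the real proteome and are not targets.

# Expression and qPCR

Expression values bin at the printed thresholds: `>6` extremely high,
`(4,6]` high, `(2,4]` medium, `(0,2]` low. The printed bins leave 0 itself
unclassified, so values `≤ 0` map to a distinct "none" category, keeping
the printed bins verbatim. Group structure uses average-linkage
agglomerative clustering of Euclidean distances cut to five groups,
mirroring the five published heatmap groups; the original heatmap tool's
exact settings are unknown, so group membership is not a reproduction
target. Rows are ordered by id before clustering, making the partition
deterministic and invariant to input order.

Relative quantification follows 2^-ΔΔCT: per replicate
ΔCt = Ct_target − Ct_reference; ΔΔCt is taken against the gene's mean
baseline ΔCt (the printed formula is scalar at time 0; replicate handling
is unstated, and mean-baseline subtraction is the conventional choice);
the reported fold change is 2^(−mean ΔΔCt), whose log is an unbiased
estimate of the true log2 fold change under Gaussian Ct noise.
Significance is a two-sample, equal-variance, two-sided Student's t-test
of replicate ΔCt values against baseline replicates, with stars at
p < 0.05 and p < 0.01; when both groups have zero variance the p-value is
1 for equal means (0 otherwise) instead of an error.

# The synthetic study system

`familyGenomeSpec()` fixes the simulated conditions: domain-bearing family
genes among background decoys, tandem clusters (chromosome, size, span),
segmental blocks (anchor count, per-site divergence) and promoter element
implants, all under one seed. Defaults mirror the verification conditions
used throughout: 20 family genes among 80 decoys for identification;
150-kb tandem clusters under the 200-kb rule; segmental blocks of 5–6
anchors at 5% CDS divergence; 1500-nt promoters; 300-codon pairs evolved
at dN/dS 0.2 for the purifying-selection checks; three qPCR replicates
with 0.2-cycle Gaussian well noise. Background residues are uniform over
the 20 amino acids / 4 nucleotides unless a frequency file is supplied —
the simplest testable default.

The seed domain is a synthetic trihelix-like alignment
(`syntheticSeedAlignment()`): a random consensus with conserved
tryptophans at regular spacing, diverged 15% per position. It is a
synthetic stand-in for a curated seed alignment and makes no claim of
sequence realism. The codon generator is a simplified acceptance-rejection
scheme on a nucleotide mutation process with transition bias: mutations
creating stops are rejected and nonsynonymous changes accepted with
relative probability ω — adequate for NG86 recovery tests, not a full
Goldman–Yang likelihood model. `branchLength` is the expected number of
proposed mutations per codon between the two sequences, so realized
divergence is below it whenever ω < 1.

Non-clustered genes are placed 250–500 kb apart so that only implanted
clusters satisfy the tandem rule; intron/exon structure is minimal (1–3
exons, 60–200 nt introns) and makes no claim to realistic gene-structure
statistics. What passing tests show is therefore algorithmic correctness
— recovery of implanted truth under the stated noise — not performance on
real genomes, where domain divergence, fragmented annotations, repeats and
compositional bias all add difficulty the generator does not emulate.

# Numerical choices and problem sizes

All randomness flows from one root seed; per-stage seeds are derived
deterministically and logged, and identical configuration plus seed yields
byte-identical artifacts. The test suite and the bundled analysis scripts
run at desk scale: 100-protein proteomes, ~30-gene genomes, 300-codon
pairs, 100 bootstrap replicates (the full published setting of 1000 is a
single argument away), chosen so the whole verification cycle completes in
minutes on a laptop. Bisection tolerance for pI is 1e-4 charge units; the
Gumbel fit solves its likelihood equation to 1e-10; EM stops at a
log-likelihood change below 1e-6 or 200 iterations.

# Known limitations

No profile-HMM parity (no forward-algorithm E-values, no multi-domain
envelopes); no ML/Bayesian phylogenetics; NG86 only (no codeml); the MSA
convenience is profile-anchored, not progressive; MEME parity is not
claimed; primer-efficiency correction and multi-reference qPCR
normalization are out of scope; cross-species synteny counts, published
subfamily sizes and published qPCR fold changes depend on external data or
figure-only values and are documented but not reproduced.
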