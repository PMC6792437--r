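---
title: "diazoscan: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{diazoscan: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

diazoscan quantifies heterotrophic bacterial diazotrophs (HBDs) — bacteria
outside the cyanobacteria that carry the nitrogen-fixation marker gene
*nifH* — in shotgun metagenomes, starting from assembled genomes or
genome bins (MAGs) and per-sample read sets. This vignette explains the
statistical procedures, the parameters that matter, and the choices made
where the design was genuinely open. Nothing stated here goes beyond what
the package's test suite and acceptance script themselves compute.

## Read recruitment and coverage statistics

Reads are recruited *competitively*: all reference scaffolds form one
collection and each read counts toward at most one reference, so
recruited-read fractions are comparable across populations and sum to at
most 1 per sample. The built-in mapper is a deterministic surrogate for a
short-read aligner: exact k-mer seeding (default `k = 21`) at staggered
read offsets, ungapped extension of the full read on both strands, and
acceptance thresholds of 95% identity over at least 90% of the read.
Ties between references that score equally are broken uniformly at random
under the run seed — the usual behaviour of competitive mappers, made
reproducible. Users who map externally can import SAM text instead
(`read_alignments()`); the profiling functions are agnostic to the mapper.
No MAPQ filter is applied at profiling; none is exposed as a default
because the upstream convention is unstated, but alignments can be
pre-filtered before profiling.

Per-position coverage gives three summaries:

* **mean coverage** — average read depth;
* **Q2Q3 mean coverage** — the mean over positions whose coverage lies
  between the first and third quartiles of the per-position distribution.
  Spikes of non-specific recruitment (conserved segments, repeats) inflate
  a few positions enormously; interquartile trimming removes them, and for
  a constant coverage vector the trimmed mean equals the plain mean.
  Quartiles use the linear-interpolation convention (`stats::quantile`
  type 7); positions strictly below Q1 or strictly above Q3 are excluded.
  The convention is pinned by a brute-force oracle in the tests because
  different profilers interpolate differently;
* **detection** — the fraction of positions covered at least once
  (`min_cov = 1` by default): breadth of coverage, robust to depth.

Relative abundance is defined as the recruited-read fraction of the
sample. The translation to absolute numbers assumes 5×10⁸ archaeal and
bacterial cells per litre of surface seawater, so a population at relative
abundance *a* corresponds to *a* · 5×10⁸ cells per litre; the square-root
transform provided for display tables compresses the dynamic range of
boxplots and is never used in testing.

## MAG quality and the MAG rule

Completion and redundancy come from single-copy core gene (SCG) counts: a
family present at least once adds to completion; copies beyond the first
add to redundancy (`100 · Σ max(0, c−1)/D`). The redundancy formula counts
extra copies explicitly because the upstream tool does not print its
definition; it can exceed 100% for badly contaminated bins and is flagged,
never clamped. SCG detection itself (HMM search) is out of scope — counts
arrive as annotation tables or synthetic truth. A bin is a MAG when
completion exceeds 70% **or** length exceeds 2 Mbp, both strict: the
length clause deliberately keeps large bins whose completion is
underestimated (fragmented genomes with missing marker loci).

## Dereplication

Independent co-assemblies of overlapping sample sets recover the same
population repeatedly. Two MAGs are redundant when

1. fragment-based ANI ≥ 99% — the smaller genome is cut into 1 kb
   fragments, each anchored in the larger genome by exact 15-mer seeding
   and aligned with a banded edit-distance extension (band 16); fragments
   at ≥ 80% identity over ≥ 80% of their length are retained, ANI is their
   mean identity and the aligned fraction is retained bases over the
   smaller genome;
2. the aligned fraction exceeds 75% of the smaller genome (strict); and
3. the Pearson correlation of the two MAGs' relative distributions across
   samples exceeds 0.9 (strict; an undefined correlation from a constant
   profile fails the criterion).

"Reached 99%" is read as ≥ 99.0 while the other two comparatives are
strict, mirroring the wording of the thresholds. Correlation is computed
on untransformed relative-abundance fractions; a coverage-based mode can
be obtained by passing a coverage matrix instead, since the correlation
operates on whatever per-sample profile is supplied. Groups are connected
components of the pair relation — transitively, as chains of
near-identical genomes belong to one population. Each group is represented
by the member with the largest completion − redundancy (bacteria/archaea)
or the longest member (eukarya); ties prefer the longer genome, then the
lexicographically smaller id, so selection is total and deterministic.
Pre-grouping by taxon is available purely as a comparison-count
optimization and never changes results for groups within one taxon.

## nifH screening

Candidate genes are translated in all six frames (literal codon table, no
initiator special-casing, stops as `*`, ambiguous codons as `X`) and each
frame is aligned locally against every reference protein (BLOSUM62, gap
open 11 / extend 1, a gap of length L costing 11 + L). The best
(frame, reference) pair is assessed by three independent checks, all of
which must pass:

* **E-value** `E = K·m·n·exp(−λS)` below 1e-50, with m the translated
  frame length and n the summed reference length. λ = 0.3176 and
  K = 0.134 are the shipped ungapped-approximation constants for BLOSUM62
  and are config-exposed: the threshold's purpose is to make chance
  high-scoring alignments (decoys) essentially impossible, which the
  specificity tests verify directly (0 of 500 shuffled decoys pass).
* **Top-hit label**: the best reference's description must contain
  "nitrogenase" (case-insensitive substring). The check runs within the
  supplied reference database; screening against a comprehensive public
  protein database is out of scope, so a curated, labelled refdb stands in
  for the top-hit-against-nr logic.
* **Motif**: the [4Fe-4S]-binding-site PROSITE pattern must occur
  somewhere in the best frame's full translation. Whether the upstream
  rule required the motif inside the aligned region only is unstated;
  the full-translation default is the more permissive reading and is
  config-independent. The curated PROSITE signature text is deliberately
  **not** hardcoded: it is a required pattern input, and the repository
  ships only a clearly-labelled synthetic stand-in
  (`C-x(2)-C-x(2)-C-x(3)-C`, a cysteine-spacing pattern of the 4Fe-4S
  type) that matches the bundled synthetic reference set.

The PROSITE engine is a direct backtracking matcher over parsed elements
(sets, negated sets, wildcards, fixed and variable repeats, terminal
anchors), verified against an independently constructed regular-expression
translation on randomized patterns. The Smith–Waterman engine is verified
against a naive dynamic-programming oracle.

Reads recruited by a confirmed gene are re-aligned with a local nucleotide
alignment (match +1, mismatch −1, gap −2); alignments shorter than 100 nt
are discarded and identity is matches over alignment columns. On reads
simulated at error rate e the mean identity recovers 100(1 − e) within
0.5 percentage points, so high observed identities (e.g. > 97%) indicate
homogeneous natural phylotypes rather than mapping artefacts.

## Primer auditing

A degenerate primer denotes the Cartesian product of its per-position
IUPAC sets. Scanning slides the primer over every window of the gene on
both strands and counts positions where the primer's base set and the gene
base's set do not intersect — equivalent to the minimum Hamming distance
over all expanded primer variants, which an oracle test confirms. Gene
ambiguity codes therefore count as compatible when any concrete base is
shared; this intersection rule is pinned as the package's convention. The
default compatibility threshold is 0 mismatches, because in-silico primer
audits treat any mismatch as potentially disqualifying; the threshold is
configurable to study near-misses. The bundled primer table is a labelled
synthetic example of the input format — real audits must supply the
published primer sequences of interest.

## Enrichment testing

Per population, Welch's unequal-variance t-test compares relative
abundances in a focal sample group (e.g. Pacific Ocean metagenomes)
against all remaining samples, with Welch–Satterthwaite degrees of
freedom and a two-sided p-value. Raw p-values are reported by default —
matching the convention of reporting unadjusted P — with
Benjamini–Hochberg step-up adjustment available. Tests run on raw
fractions, not square-root-normalized values (the transform is
display-only). When both groups have zero variance the test is undefined
(all-NA row) unless the means coincide, in which case p = 1 by convention.
Calibration is verified empirically: under the null the type-I error rate
at α = 0.05 lies in [0.03, 0.07] over 2000 simulations.

## The synthetic-community generator

The generator emulates the statistical structure the analysis assumes:

* genomes with i.i.d. bases at controlled GC — no codon structure, repeats
  or mobile elements;
* redundant variants by per-position substitution at a set rate (0.002 in
  the demo — ANI ≈ 99.8%, comfortably above the 99% threshold; the
  negative control at 0.02 sits at ANI ≈ 98 and must never merge);
* per-sample abundances drawn log-normal (sdlog = 1) and renormalized;
  redundant pairs share a base profile with multiplicative log-normal
  noise (sd 0.05), giving Pearson r safely above 0.9 across tens of
  samples. The log-normal is a modelling choice — real population
  abundance distributions are not specified by any upstream source — and
  sdlog = 1 gives the order-of-magnitude spread typical of marine
  communities;
* reads drawn multinomially with probability ∝ abundance × genome length,
  uniform start and strand, substitution errors only (indels default 0, so
  identity and ANI truths stay exact); the recorded truth abundance is the
  read-origin fraction, which is exactly what recruitment estimates;
* marker genes planted by reverse-translating reference proteins with
  uniform codon choice, so each positive has a known location and a known
  protein-level divergence.

What passing tests on these communities do **not** show: robustness to
indel-rich sequencing error, strain microdiversity below the variant-pair
level, chimeric assembly artefacts, GC-dependent coverage bias, or
conserved-region cross-mapping between unrelated taxa. The generator's
role is to verify the statistical machinery against exact truth, not to
certify performance on any particular instrument's error profile.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; 1-based only in
  SAM files.
* Quartiles: type-7 linear interpolation (above).
* Mapping ties: uniform over tied references under the run seed.
* ANI with zero retained fragments is reported as no-alignment
  (`ani = NA`, aligned fraction 0), which fails the redundancy predicate.
* Representative ties: score, then length, then id (above).
* All generators are byte-reproducible under a fixed seed; the pipeline
  derives per-stage seeds by stable hashing of stage names, so stages can
  be re-run individually without coupling their random streams.
* Problem sizes in the tests and acceptance script (20–50 kb genomes,
  10⁵-read samples, 9-protein reference set — the size of a
  nine-population HBD gene database, 500-case oracle sweeps) were chosen
  as the smallest sizes at which the statistical tolerances are
  comfortably non-trivial.

## Known limitations

* The built-in mapper is ungapped and substitution-oriented; indel-rich
  reads should be mapped externally and imported as SAM.
* Fragment ANI is calibrated for closely related genomes (the
  dereplication regime, ≥ 95% identity); it is not a general-purpose
  whole-genome aligner and reports no-alignment for distant pairs rather
  than a low ANI value.
* E-value constants are fixed ungapped approximations, not fitted to the
  gapped score distribution; the 1e-50 working threshold is far from the
  regime where the approximation matters, as the decoy tests confirm.
* SCG-based completion inherits the marker-collection granularity: a
  fragmented genome's completion is accurate only to roughly one contig's
  worth of markers.
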