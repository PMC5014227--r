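---
title: "Models and methods behind BACography"
author: "BACography authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind BACography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BACography)
```

# The problem

Very large plant genomes — barley's 5.1 Gb is the motivating case — have
historically been accessed through BAC libraries: hundreds of thousands of
~100-kb clones, screened by hybridization with gene-derived probes to find
the minority that carry genes, fingerprinted into physical-map contigs,
reduced to a minimal tiling path (MTP), and sequenced clone by clone. The
sequencing itself is only the start; turning ~15,000 BAC assemblies into
genome-scale statements requires a chain of computational steps:

1. **Where is each clone?** Assignment to a chromosome arm using
   flow-sorted arm sequence as targets.
2. **What genes does it carry?** Annotation against a predicted gene-model
   catalogue, with filters against short assembly nodes, weak alignments,
   and transposon-contaminated models.
3. **How does it relate to sequenced relatives?** Placement on a reference
   genome (e.g. rice) by vote over translated-alignment hits, and joining
   of two species' genetic maps through the clones.
4. **What does the genome look like along its axis?** Sliding-window
   landscapes of gene density (GD) and recombination frequency (RF), and
   the detection of regions that break the canonical Triticeae pattern —
   gene-dense islands inside recombination-suppressed interiors.
5. **Was the screening saturated?** Rarefaction of the probe-pool
   screening data and extrapolation to the asymptotic number of
   gene-bearing clones.
6. **How good are the assemblies?** N50/L50 summaries and cross-platform
   concordance.

BACography implements this chain as a tested R package, together with a
synthetic-data generator that reproduces the statistical structure the
analyses assume, so that every stage can be validated against known truth
without access to the original multi-gigabyte resource.

# The synthetic genome

`simulateGenome()` builds chromosomes from a `genomeSpec()`:

* **Arms and centromeric overlap.** Each chromosome has a short (S) and a
  long (L) arm. The two flow-sorted arm targets are cut from the same
  chromosome sequence so that they share exactly
  `centromereOverlapLen` bp around the centromere — emulating the physical
  reality that flow-sorted arm fractions overlap there. This overlap is
  what makes centromeric pseudo-targets (`4HC` and friends) detectable as
  k-mers shared by exactly the two arms of one chromosome.
* **Gene placement.** Genes are placed by thinning a uniform proposal
  against a piecewise-linear density that equals 1 at the centromere and
  rises to `distalEnrichment` at the telomeres. With
  `distalEnrichment = 1` placement is exactly uniform (the package tests
  verify this with a chi-square goodness-of-fit check). An optional
  *interior island* adds a uniform block of extra genes inside a stated
  interval — the synthetic analogue of the gene-dense,
  low-recombination interior regions observed on real 2H and 5H.
* **Genetic map.** The map is the cumulative integral of a bathtub-shaped
  recombination intensity: a low plateau (5% of the distal intensity) of
  width `mapSuppressionWidth` centred on the centromere, rising linearly
  to the arm ends, scaled so each chromosome spans `totalCm`. The map is
  strictly increasing, so cM/Mb ratios are well defined everywhere.
* **Repeat families.** A configurable number of repeat units are copied
  to random positions genome-wide. They give the classifier multi-target
  k-mers to discard, give the annotation stage the cross-locus matches
  that motivate the frequent-model filter, and make BAC inserts
  realistically repetitive.
* **Alphabet.** Uppercase ACGT only, GC content configurable
  (default 0.445, the value typical of Triticeae gene-bearing BACs).

## Reference study conditions

The `genomeSpec()` defaults are the package's fixed reference conditions,
chosen once for realism at desk scale: three chromosomes of 600-kb S and
800-kb L arms with a 120-kb centromeric overlap; 120 genes of 1.5 kb per
chromosome, 60% labelled high-confidence (HC), four-fold distal
enrichment; a 200-kb gene island (+60 genes) planted at 400–600 kb of
chromosome 2H, inside its 300-kb recombination-suppressed plateau; four
repeat families of 2 kb with eight copies each; 150 cM per chromosome.
The companion library defaults (350 clones, 50 ± 5 kb inserts, mean six
nodes per clone) give ~4.5× clone coverage — deliberately low redundancy,
as in an MTP, so that ordinary genes stay well below the frequent-model
threshold while repeat-carrying models exceed it.

The generator emulates the *statistical* structure of a real resource —
density gradients, map suppression, screening noise, shared repeats — not
its sequence-level detail: there is no read-level error model, no
quality-score simulation, no fingerprinting, and repeat families are exact
copies rather than diverged elements. Passing recovery tests therefore
demonstrates the correctness of the analysis chain under the stated
generative model, not performance on real noisy assemblies.

# Chromosome-arm classification

`buildKmerIndex()` implements discriminative k-mer classification. All
k-mers (default k = 19, canonicalized to the lexicographic minimum of
forward and reverse complement, since clone orientation is arbitrary) are
enumerated per target; ambiguous letters break enumeration. Three
filtering rules follow:

* within a target, k-mers with total count below `minKmerCount` are
  dropped (rare k-mers in read-derived targets are usually sequencing
  errors; for error-free synthetic targets the pipeline sets this to 1,
  since every genuine k-mer occurs once);
* a k-mer found in exactly one target is indexed under that target;
* a k-mer found in exactly the S and L arm targets of one chromosome — and
  nowhere else — is indexed under the chromosome's centromeric label
  (`2HC`); any other multi-target k-mer is discarded.

`classifyBac()` counts, per label, the query's k-mer occurrences found in
the index. With $h_1$ the best count and $h_2$ the runner-up, the
confidence is

$$c = \frac{h_1}{h_1 + h_2},$$

taken as 1 when $h_2 = 0$ and 0 when there are no hits. The assignment is
accepted only when $c$ *strictly* exceeds the threshold (default 0.75) and
$h_1 \ge 1$; ties for the top label are left unassigned. The strictness
matters: a 30-vs-10 split gives exactly 0.75 and is rejected. The
two-best-counts ratio is the minimal formula consistent with a [0, 1]
confidence for this family of classifiers; occurrence counting (rather
than distinct k-mers) is the default because it is robust for repetitive
inserts, with `countMode = "distinct"` available.

Whether a whole chromosome (sequenced unarmed, as 1H was) competes as a
single target against arm targets is a layout question, not an algorithmic
one: the index accepts any label set, and centromeric labels arise only
where an S/L pair exists.

# Annotation

Hits between assembly nodes and gene models arrive as 12-column tabular
alignment records (or from `matchGenesBuiltin()`, a deterministic
exact-seed/ungapped-extension matcher sufficient for synthetic sequence,
so no external aligner is needed in tests). Three filters apply, in the
order the analyses present them:

1. nodes shorter than 200 bp are ignored (`minNodeLen` applies to the
   node, not the alignment length);
2. hits with e-value above 1e-20 are dropped;
3. gene models hitting ten or more *distinct* BACs are excluded outright —
   these are overwhelmingly transposon-related and would otherwise drown
   the signal. The distinct-BAC count is taken after the first two
   filters.

Counting is distinct-model per BAC (a model on three nodes of one clone
counts once). Per-label unique counts are computed within the label and
the overall count across all clones, which is why per-label counts can sum
to more than the overall figure when a model spans arms — both numbers are
reported. GC content is (G+C)/(A+C+G+T) with ambiguous letters excluded
from numerator and denominator.

# Synteny

`voteBacs()` applies plurality voting: hits at or below the e-value cutoff
are tallied per subject chromosome, the plurality winner takes the clone,
and the position is the mean of the matched subject coordinates on the
winning chromosome. A tie leaves the clone unplaced — conservative, and
rare at realistic hit counts. `voteContigs()` repeats the scheme one level
up: each placed member clone casts one vote. Positions stay in the subject
map's units; nothing is converted implicitly.

`anchorJoin()` chains marker → map-A position, marker → BAC, BAC → map-B
position, keeping only chains whose linkage groups are orthologous per a
supplied table, and collapsing duplicate chains. `detectInversions()`
slides a Kendall rank correlation over windows of consecutive anchor pairs
and reports maximal runs of negative windows. The window size (10 pairs)
and minimum run (2) are this package's own defaults — published inversion
intervals come from visual inspection of dotplots, and no detection rule
exists to inherit — so reported intervals should be read as candidates for
inspection, and depend on anchor density.

# Landscapes and deviant regions

`windowStats()` advances windows (default 40 Mb every 2.5 Mb, the scale
appropriate to a real Triticeae chromosome; the synthetic pipeline scales
to 100 kb / 10 kb) from position 1 of each chromosome. A clone belongs to
every window containing its anchor point — point membership, since clones
are anchored to golden-path coordinates as points. Per window:

* the proportions of clones with 0, exactly 1, and ≥ 3 HC models;
* gene density GD = distinct HC models among the window's clones divided
  by the clone count;
* recombination frequency RF = (cM span of the window's clones) / (bp span
  in Mb) — the literal cM/Mb reading; a regression-slope alternative was
  considered and rejected as less transparent for sparse windows.

Windows with fewer than `minBacsPerWindow` clones report missing GD/RF and
are excluded from threshold computation. The last, partial window is
emitted and flagged.

`detectDeviantRegions()` makes the visual "gene-dense but
recombination-suppressed" call explicit and scale-free: thresholds are
genome-wide quantiles (defaults: GD at or above its 75th percentile, RF at
or below its 25th), qualifying windows are merged when overlapping or
adjacent, and regions supported by fewer than two windows are dropped
(with heavily overlapping windows, a genuine region always spans many).
Degenerate profiles (all windows identical) yield no regions rather than
all of them.

# Screening saturation

`accumulationCurve()` shuffles the order in which probe pools are applied
(default 10,000 permutations) and records the cumulative number of
distinct positive clones after each pool; the mean over shuffles is the
accumulation curve. Below nine pools an exhaustive enumeration over all
orderings is available and serves as the exact oracle in the tests.

`fitAsymptote()` extrapolates the curve to its limit. No canonical
functional form exists for this extrapolation, so two saturating models
are offered and the estimate always carries the model name:
negative-exponential $y = A(1 - e^{-bx})$ (default: monotone, concave,
finite asymptote — the minimal shape consistent with an accumulation
curve) and hyperbolic $y = Ax/(B + x)$. Fitting is
Levenberg–Marquardt least squares, unweighted by default with optional
1/sd² weights. Because genic probes find multi-gene clones more easily
than single-gene clones, the asymptote systematically *underestimates* the
true gene-bearing count; the package reproduces this bias in a test and
reports, never corrects, it.

# Assembly statistics

`n50l50()` follows the definitions customarily printed with BAC summary
tables, which are asymmetric: N50 is the length of the last node in the
smallest prefix holding *at least* half the total, while L50 is the
smallest number of nodes holding *more than* half. The two readings differ
on edge cases — for nodes `[50, 50]`, N50 = 50 but L50 = 2 — and both are
covered by worked examples in the tests; `mode = "conventional"` switches
both to ≥. Per-group tables average per-clone statistics unweighted within
groups, and the "All" row is recomputed from the pooled clone set rather
than from group means (the two agree as BAC-weighted means, an identity
the acceptance checks exploit).

`pairwiseCoverage()` measures cross-platform concordance as the fraction
of one assembly's bases lying in exact matches (≥ 100 bp, both strands) to
the other, merged over overlaps — a deliberate lower bound on
alignment-based coverage that needs no external aligner and is exact on
synthetic data. A clone pair is discarded as discordant only when *both*
directional coverages fall strictly below 33% — that level of mutual
disagreement indicates rearray error or cross-contamination rather than
assembly quality.

# Numerical and interface conventions

* Coordinates are 1-based and closed everywhere, the Bioconductor/IRanges
  convention, so package containers interoperate without translation.
* All randomness flows from explicit `seed` arguments; callers' RNG state
  is saved and restored. The pipeline derives per-stage seeds from one
  master seed.
* Canonical k-mers compare by ACGT lexicographic order, identical in every
  locale.
* Every emitted table starts with a comment line recording the package
  version and a hash of the configuration that produced it.
* Inter-stage data are plain TSV and FASTA; the only structured text
  formats are the k-mer index (magic string + version, rejected on
  mismatch) and JSON for configs, manifests and estimates.

# Problem sizes

The test-suite and acceptance computations run the full pipeline on the
reference conditions above (≈ 4 Mb of target sequence, 350 clones, 30
pools, 10,000 curve permutations) and smaller per-module fixtures; these
sizes were chosen so the entire validation cycle completes in minutes on a
single core while leaving every recovery margin wide (misassignment
≤ 2% required, ≈ 0% observed; asymptote within 10%, ≈ 1–2% observed).

# Known limitations

* The built-in matcher is exact-seeded and ungapped; it is a stand-in for
  a real aligner on synthetic data, not a general homology search.
* The inversion caller's parameters are heuristic (see above).
* The saturation extrapolation inherits the detectability bias of genic
  probes; treat asymptotes as lower bounds.
* Coverage percentages from exact matches underestimate alignment coverage
  on diverged sequence.
* The generator does not model sequencing error, assembly chimerism or
  diverged repeats; conclusions about real data should lean on the
  filters' design rationale, not the synthetic recovery rates.
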