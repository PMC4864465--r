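---
title: "Methods: detecting and profiling telomere fusion junctions"
author: "telofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and profiling telomere fusion junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay and its computational model

Telomere fusion PCR amplifies, at the single-molecule level, the covalent
junctions formed when a dysfunctional chromosome end is joined by
nonhomologous end-joining (NHEJ) either to a nontelomeric genomic locus
(*inter-chromosomal* fusion) or head-to-head to its sister chromatid
(*intra-chromosomal* fusion). Paired-end sequencing of the pooled amplicons
turns each fusion molecule into a cloud of read pairs. `telofuse` models the
downstream analysis in four stages, each with an explicit data contract:

1. **Reference model.** A subtelomeric reference is one sequence oriented
   from the amplification primer towards the telomere, annotated with three
   1-based landmarks: `primer_pos` (conventionally 1), `telomere_start` (the
   first base of the (TTAGGG)ₙ array) and optionally `cut_site`, the base
   immediately 5′ of the cleaved phosphodiester bond of a subtelomere-targeted
   nuclease. Committing to a single cut-site convention makes resection
   arithmetic unambiguous: resection = `landmark − breakpoint` for
   breakpoints centromeric of the landmark, zero at it, and a flag — not a
   negative number — telomeric of it. The default synthetic geometry places
   the cleavage site at coordinate 3024 with the repeat array starting 14 bp
   further at 3038, matching the geometry of a nuclease cutting immediately
   ahead of the repeat array roughly 3 kb from its primer.

2. **Fusion calling.** Read pairs are classified against the expected
   library geometry: *concordant* (one reference, opposing strands, inward
   facing, fragment within insert bounds estimated as mean ± 4 SD of proper
   pairs), *intra* (both mates on one subtelomeric reference in the same
   orientation — the geometric signature of a head-to-head junction),
   *inter* (exactly one subtelomeric mate), else *ambiguous*. The partition
   is exhaustive and exclusive, so class counts always sum to the pair
   count. Linkages pass a mapping-quality floor (default 1: the published
   filter wording "MAPQ ≥ 0" is vacuous as written, so the package drops
   multi-mappers by default and exposes the threshold) and are clustered by
   single linkage within a 500 bp window per (class, reference pair)
   stratum — smaller than the separation of distinct simulated events,
   larger than the insert-size spread that scatters a single molecule's
   mate positions.

3. **Junction resolution.** Soft-clipped reads crossing the junction carry
   both sides. For each such read the aligned block fixes side A; the
   junction-distal 20-mer of the clip is placed exactly on the partner
   reference, and exact prefix/suffix walks against the two reference flanks
   give `p` (bases explained by side A) and `s` (bases explained by side B).
   If `p + s ≥ L` (the window length) the junction admits `p + s − L + 1`
   consistent breakpoint placements, i.e. `p + s − L` nt of microhomology;
   otherwise the unexplained central run of 1–49 nt is an insertion, and
   ≥ 50 nt flags an unresolved complex event. This identity — microhomology
   equals placement ambiguity — is the package's scoring definition and is
   checked against an independent brute-force placement enumerator.

4. **Statistics.** Event counts convert to frequencies per diploid genome
   (6 pg ≈ 1 diploid genome, so `genomes = ng × 1000 / 6`); binned profiles
   (100 bp default) and chromatid classes (short < 1 kb, long > 2 kb from
   the primer) summarize the fusion architecture; χ², permutation, GC and
   Welch-*t* procedures quantify genomic context and strand asymmetry.

## Conventions the design had to fix

Several scoring conventions are genuinely underdetermined by the assay
literature; the package fixes each one explicitly and tests against the
choice.

**Microhomology is summed over both directions.** The overlap at a junction
can be counted from either side of the breakpoint. `telofuse` reports
`k_left + k_right`, the total slack of the breakpoint placement, because
that definition equals the number of consistent placements minus one and
therefore has an exact, assumption-free oracle (enumerate every split of the
junction sequence and count the consistent ones). A one-sided convention
would be a subset of the same computation.

**Breakpoints are left-aligned.** Inside a microhomology tract every
placement describes the same molecule; the caller and the simulator both
canonicalize to the leftmost placement (smallest side-A coordinate in the
canonical orientation: subtelomeric side first, forward strand; for
head-to-head junctions the telomeric breakpoint first). Determinism here is
what makes exact truth comparison meaningful.

**Insertions and microhomology are mutually exclusive.** A junction
carrying both is ambiguous to score — part of the "insertion" could be
attributed to either flank. The simulator never emits both at one junction
and additionally rejection-samples insertion boundaries so the first
inserted base does not extend flank A nor the last extend flank B;
otherwise `(bp_a, insertion, bp_b)` would not be the unique description of
the junction sequence and exact recovery would be ill-posed.

**Templated means the whole insertion has a local template.** Insertion
classification searches ±1 kb of both breakpoints on both strands for an
exact occurrence of the entire insertion (length ≥ 2; 1-nt insertions are
untemplated by definition, honouring the 2 nt similarity floor). A literal
"any ≥ 2 nt of the insertion matches" rule would classify essentially every
insertion as templated — all 16 dinucleotides occur in any ±1 kb window — so
full-length occurrence is the defensible operationalization of a
BLAST-style criterion at these insert sizes; `min_match` exposes a partial
threshold for users who want one. The reported template locus is the match
nearest a breakpoint.

**χ² without continuity correction.** The gene-coincidence test is the
standard 1-df Pearson statistic on (in-gene, out-of-gene) counts against an
expected fraction (default 0.418, a genome-wide RefSeq gene-content
estimate), cross-checked to 10⁻⁸ against `stats::chisq.test(correct =
FALSE)`; Yates correction is a flag. Type-I error is verified by simulation
on a synthetic genome whose gene coverage is exactly the expected fraction.

**Permutation nulls are uniform over reference space.** Feature-proximity
tests compare the observed fraction of junctions with a feature within
± *w* bp against `n_random` equal-sized uniform position sets, with the
add-one empirical p-value `(1 + #{null ≥ obs}) / (n_random + 1)`; the seed
is part of the reported result.

## What the simulator emulates, and what it does not

The generator reproduces the features of the assay that the pipeline's
correctness depends on: multiplex single-primer amplicons of 1–20 kb;
head-to-head intra-chromosomal fusions of asymmetric chromatids (long
breakpoint uniform in `[cut_site − 50, telomere_start + 200]`, short uniform
in `[primer + 200, 1000]`, so long > 2 kb pairs with short < 1 kb and the
100-bp binned profile is bimodal); telomere–genomic fusions truncated at a
sampled total length (the multiplex primer scheme for genomic partners is
not modelled); junction microhomology, drawn from a decaying distribution
over 0–8 nt and *realized* in the sequence by exhaustive enumeration of
breakpoint pairs whose junction ambiguity equals the requested value;
templated and untemplated insertions (< 50 bp) with rejection-sampled
boundaries; inward-facing read pairs at a target coverage
(`round(coverage · L / (2 · read_length))` pairs per amplicon) with normal
insert sizes; and per-base substitution errors, optionally strand-specific
for intra molecules (a higher "lagging" rate on centromeric-side bases
emulates the reduced proofreading of lagging-strand synthesis).

Deliberately out of scope: PCR chimeras and duplicates, indel sequencing
errors, quality-score profiles, real subtelomeric paralogy beyond the
optional homologous-family generator, and any empirical amplicon length
distribution beyond the 1–20 kb range (uniform sampling is a documented
placeholder). Passing round-trip tests therefore demonstrate that the
caller inverts the generator's (idealized) read model exactly — not that it
is robust to every artifact of real libraries.

Requested microhomology values that the windows of a particular random
reference cannot realize are redrawn from the distribution (bounded
retries, then an error), which is why the default distribution concentrates
its mass at 0–6 nt: inside an ~260 × 800 bp window pair the expected number
of breakpoint pairs realizing *m* nt falls by 4× per additional nucleotide
and values ≥ 9 are usually unrealizable. Exact-recovery tests for the full
0–10 nt range instead plant a homology tract at chosen breakpoints and use
explicit breakpoint overrides.

**Study design for round-trip recovery.** The recovery benchmark assigns
each simulated molecule its own synthetic subtelomeric end (a multiplexed
family of distinct references) with inter partners spread over a 1 Mb decoy
genome. With a single shared subtelomere, two intra molecules whose
breakpoints fall within the clustering window are *inherently* one event —
no caller could separate them — so per-molecule references are what make
"every truth molecule recovered as its own event" a well-posed claim. The
suite exercises 200 molecules (100 inter + 100 intra) at 30× with 2×100 bp
reads; module tests use 10–40 molecules.

## Numerical and robustness choices

* **Aligner.** Exact 20-mer seeds at three read offsets, candidate
  diagonals verified by ungapped comparison, best contiguous block under
  +1/−1 scoring (earliest maximal block on ties), terminal soft clips,
  MAPQ 60 for a uniquely best placement and 0 for ties. Seeds hitting more
  than 16 index positions (telomere repeat arrays) contribute a capped
  candidate sample — enough to detect the tie and assign MAPQ 0 without
  enumerating every repeat unit.
* **Junction votes.** Only uniquely anchored reads (MAPQ ≥ 1) vote; clip
  anchors with more than 50 exact hits, or whose best partner placement is
  tied, are discarded (reads wholly within the repeat array cannot place a
  junction). A consensus needs at least two agreeing reads
  (`min_votes = 2`) and at least one vote whose partner-side match spans a
  full 20-nt anchor — very short clips (10–19 nt) can match a decoy locus
  exactly and would otherwise vote consistently for it. Ties between
  equally supported descriptions break toward the left-aligned (smallest)
  coordinates.
* **Unresolvable junctions are reported as such.** A breakpoint deep inside
  the shared (TTAGGG)ₙ array has no uniquely mappable support; the event
  keeps its footprint, the junction stays unresolved, and resection
  reporting flags breakpoints at or beyond `telomere_start` as within the
  telomere repeats. This mirrors how such junctions can only be described
  qualitatively in the assay itself.
* **Degenerate inputs.** Empty linkage sets cluster to an empty event
  table; truth tables round-trip header-only; flanks shorter than a
  junction window truncate with a warning; an all-N GC window and a zero
  intra denominator are errors/flagged NA rather than silent zeros.

## Problem sizes

The shipped tests run the full pipeline at up to 200 molecules / ~460 k read
pairs (about a minute of CPU), 1,000-junction oracle sweeps, 200-replicate
type-I calibrations and 500-draw architecture checks; these sizes give
stable rates while keeping the whole suite in the minutes range on a single
core.

## Known limitations

* The built-in aligner is ungapped; indel-bearing reads soft-clip at the
  indel instead of aligning through it. Production data should be aligned
  externally and ingested as SAM/BAM.
* Complex fusions incorporating three or more loci are flagged (unexplained
  runs ≥ 50 nt) but not assembled; events are reported pairwise.
* Insertion classification is exact-match based; a templated insertion
  copied with even one substitution classifies as untemplated unless
  `min_match` is lowered.
* The mapping-quality model is three-valued in practice (0/60); thresholds
  between are meaningful only for externally aligned input.
* `validate_uniqueness` performs exhaustive local alignment against every
  reference and is intended for per-event auditing, not for whole-library
  sweeps over large reference sets.
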