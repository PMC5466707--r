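---
title: "From low-coverage RIL resequencing to bin maps, corrected assemblies and QTL"
author: "binmapper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From low-coverage RIL resequencing to bin maps, corrected assemblies and QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binmapper)
```

## The model

A recombinant inbred line (RIL) population descends from a cross of two
inbred parents by repeated selfing (single-seed descent). After g selfing
generations each line is a mosaic of the two parental genomes with
residual heterozygosity of about $0.5^g$ (F10, the default, leaves
roughly 0.2% of the genome heterozygous). Low-coverage resequencing
(~2x per line) observes, at each SNP that segregates between the parents,
a noisy draw of the line's local parental origin: with Poisson-distributed
read depth, a fraction $e^{-\lambda}$ of sites is missing entirely
(13.5% at 2x), and a truly heterozygous site is only recognized when both
alleles happen to be read.

The pipeline turns these observations into genotype tracks, breakpoints,
recombination bins, a genetic map, assembly corrections, and trait maps.
This vignette records the modelling choices behind each stage, their
tunable parameters, and what the simulator does and does not emulate.

## Sliding-window genotype calling

Windows span 15 consecutive *non-missing* observations of one line on one
chromosome. A window is labelled by the parental ratio: `a` when
$n_{P1}:n_{P2} \ge 11:4$, `b` when $\le 4:11$, `h` otherwise. Three
conventions complete the rule, which ratio thresholds alone leave open:

* **Missing and heterozygous observations.** Windows are formed over the
  non-missing sequence; heterozygous observations contribute 0.5 to each
  parental count (so counts always total 15), and windows with fewer than
  8 homozygous observations (`min_informative`) emit no label. At 2x
  depth a window of 15 observed SNPs almost always clears this floor.
* **Projection to SNPs.** Each SNP takes the majority label of the up to
  15 windows covering it; ties break toward the previous SNP's call, then
  toward `h`, then toward the leftmost covering window. SNPs covered by
  no labelled window — including missing observations — take the nearest
  called SNP's label. These tie-breaks are symmetric under swapping the
  two parents, a property the test suite asserts.
* **Sparse chromosomes.** A line/chromosome with fewer non-missing
  observations than one window gets a whole-chromosome majority call and
  is flagged low-confidence.

A breakpoint is the boundary between maximal runs of different calls, at
the floor of the mean of the two flanking SNP coordinates. Runs shorter
than `min_run = 5` SNPs are first absorbed into their longer neighbour:
at 2x coverage, isolated mislabelled stretches otherwise masquerade as
double crossovers. Absorption costs sensitivity to genuine segments
shorter than ~5 SNPs (~4 kb at default density), a deliberate trade.

## Bins and the linkage map

Breakpoint midpoints from all lines are aligned to a `min_interval`
= 20-kb grid (floor snapping; the spec-level convention that two
breakpoints at 149 and 151 kb share the 140–160-kb cell). A midpoint in
the first cell would floor-snap to 0 and emit no boundary at all, so it
is assigned to the first grid point instead — the transition is kept at
the end of one minimal interval. Each line's genotype per interval is
read from its own breakpoint-delimited run states, with the transition
placed at the snapped cut; a segment whose two cuts collide under
snapping vanishes. (Reading intervals by majority vote over their SNPs
was considered and rejected: when a transition sits mid-cell, both
flanking intervals inherit the same majority and a true bin boundary
silently disappears.) Adjacent intervals with identical genotype columns
merge into one bin; columns differing only in `h`/`-` symbols are treated
as distinct.

Bins act as markers. Between two genotype columns, the recombination
fraction r is the fraction of discordant homozygous calls among lines
informative in both (h and missing excluded; fewer than 10 jointly
informative lines leaves r undefined; r is capped at 0.4999). Distances
use the Kosambi map function $d = 25\,\ln\frac{1+2r}{1-2r}$ cM, applied
to the *observed* RIL recombination fraction: RIL fractions are inflated
roughly two-fold relative to single-meiosis fractions
($R = 2r/(1+2r)$), and published RIL bin maps conventionally report the
uncorrected distances. `ril_correct = TRUE` applies $r = R/(2-2R)$ first
for map lengths on the meiotic scale.

Linkage groups are connected components of the r < 0.25 graph
(single-linkage clustering); a bin linked to nothing becomes a singleton
group with a warning. Within a group, order follows the diameter path of
the minimum-spanning tree of the r graph when that path covers the group
(it does whenever the underlying structure is a chain), with physical
order as the fall-back and as the orientation seed. Full de-novo marker
ordering is out of scope: the physical assembly supplies a strong prior,
and the map's job is to confirm or contradict it.

Bins that contradict their physical position are flagged when r to both
physical neighbours exceeds 0.15 while some non-neighbour bin shows
r < 0.05; the proposed position is adjacent to the minimum-r partner.
Both thresholds are conventions (configurable), chosen far apart so the
rule fires only on unambiguous conflicts.

## Assembly anchoring, correction and gap filling

Unplaced scaffolds anchor next to the map bin with minimum r to any of
their bins (refused at r ≥ 0.25); orientation is resolved only with at
least two scaffold bins, from whether their partners' map positions rise
or fall along the scaffold. AGP output uses 100-N spacer gaps between
map-joined components. Corrections are block moves on the component
layout; applying an empty report is the identity, and every move is
accompanied by an old-to-new liftover table whose intervals tile the new
objects exactly.

Gap filling is deliberately conservative. A gap is any run of at least
10 N. Its two 500-bp flanks are located in the donor by exact 31-mer
seeds (taken at the flank's two ends and middle) followed by ungapped
extension scored as simple identity; a fill requires each flank to have
exactly one donor match at ≥ 95% identity, both on one donor sequence and
strand in concordant order, with the enclosed span between 0 (the flanks
may abut — the gap closes) and 5x the gap length. Anything else is
recorded as `unfilled_no_match`, `unfilled_ambiguous` or
`unfilled_discordant`, so every gap is accounted for. Filled bases are
lowercased; no other base changes case. All alignment parameters are
exposed as arguments; none of them is sensitive on clean donors, and on
an unrelated donor the seed stage alone guarantees zero fills.

## Trait mapping

Quantitative traits use a per-bin single-marker normal model. With lines
split by their homozygous bin genotype, $LOD = \frac{n}{2}\log_{10}
\frac{SS_0}{SS_1}$ and $PVE = 100(1 - SS_1/SS_0)$, where $SS_0$ is the
total and $SS_1$ the within-class sum of squares. Heterozygous and
no-call lines are excluded (they are under 1% of calls in an F10
population); bins with fewer than 10 informative lines are skipped. The
statistic is invariant to affine phenotype transforms and to relabelling
the parents, and the tests verify it against an independent least-squares
oracle at 10⁻⁹. QTL are called for LOD > 3.0 (the conventional fixed
threshold; `permutation_threshold()` offers a Churchill–Doerge
alternative, off by default), runs above threshold collapse to their
peak, and the support interval is the contiguous region within 1.5 LOD
of the peak. A `cofactors` argument residualizes the phenotype on named
bins first, a light-weight stand-in for composite interval mapping —
with bins this dense, interval positions between markers add little.

Qualitative (monogenic) traits map by co-segregation: for every bin,
count the lines whose homozygous genotype disagrees with the
class-to-parent assignment, under both polarities, keeping the better
one. The best bin minimizes mismatches (ties: smaller physical span,
then lower coordinate); the candidate region is the contiguous run of
bins holding that minimum, i.e. bounded by the nearest recombinant
evidence; and a 1:1 segregation chi-square over informative lines is
reported. Note an intrinsic granularity limit: a line whose crossover
falls between the causal locus and its bin's grid cut co-segregates with
the neighbouring bin instead, so point loci planted very near a bin edge
can show one apparent mismatch without any error in the machinery.

## The simulator

The generator reproduces the study design the pipeline assumes: 184
lines, nine chromosomes, 1.2 segregating SNPs per kb, F1 followed by 9
selfing rounds, 2x mean depth. Crossovers are Poisson per meiosis at 1
per Morgan with uniform positions and no interference — the simplest
model consistent with downstream Kosambi use; chromosome genetic lengths
derive from a genome-wide 4.63 cM/Mb ratio (a ~1928-cM map over a
~416-Mb genome). Sequencing error is an exposed knob defaulting to 0.
Reported coverage and genome size in such studies imply anywhere from
~1.7x to 2x per line; depth is therefore a parameter, not a constant.

Default fixtures use a 1/100-scale genome (~4.2 Mb, ~5000 SNPs, ~19 cM),
chosen so that the complete pipeline runs in seconds while bins still
respect the 20-kb grid; full-scale lengths are one argument away
(`default_chrom_lengths(scale = 1)`). The recovery studies in the test
suite and acceptance script run on this default population (one full
simulation plus 50 phenotype replicates for QTL localization; a 1-Mb
donor with ~18 gaps for the fill round-trip).

What the simulator does **not** emulate — and what passing tests
therefore do not certify on real data: reference/alignment artefacts and
genotyping error from the variant caller, crossover interference and
recombination hot/cold spots, segregation distortion, duplicated or
repetitive regions that confound flank matching beyond literal repeats,
and structural variation between the parents. The gap-filling fixtures
use uniform random sequence, whose 31-mer uniqueness is far better than
a real plant genome's; on real assemblies the ambiguous-match refusal
path will fire much more often.

## Numerical conventions and degenerate inputs

* Coordinates: SNPs and breakpoints 1-based (VCF convention); bins and
  gaps 0-based half-open (BED convention); FASTA/AGP per their standards.
* A zero-variance phenotype yields LOD = 0 everywhere by convention; a
  noise-free trait yields infinite LOD at its bin with PVE = 100.
* r is capped at 0.4999 so Kosambi stays finite; `kosambi_cM` and
  `kosambi_r` round-trip to 10⁻⁹ over r in [0, 0.49].
* Unestimable adjacencies (too few jointly informative lines) contribute
  0 cM to cumulative positions rather than propagating NA.
* All randomness flows from explicit seeds; identical configuration and
  seed reproduce byte-identical outputs, which the pipeline test asserts.

## Known limitations

Bins are never finer than the 20-kb grid, so breakpoints are localized to
one cell and map distances between near-adjacent bins are noise-limited
at n = 184 (sub-centimorgan adjacent distances carry ~±1 cM sampling
error each; summed map lengths are accordingly upward-biased unless
corrected). F2 designs (three genotype classes) are not supported —
qualitative mapping and the scan assume a near-homozygous population.
Scaffold ordering assumes the physical assembly is mostly right; the MST
path heuristic is a consistency check, not a de-novo ordering proof.
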