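---
title: "Measuring selective constraint on indel sizes in 5'UTRs with upstream ORFs"
author: "uORFindels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selective constraint on indel sizes in 5'UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uORFindels)
```

## The question and the model

Upstream open reading frames (uORFs) begin at an AUG located in the
5'UTR (a uAUG) and regulate translation of the main coding sequence.
Three configurations matter biologically and are treated separately
throughout this package:

* **strict** uORFs terminate within the 5'UTR;
* **overlapping** uORFs are out of frame with the main CDS and
  terminate inside it;
* **alternative** uORFs are in frame with the main CDS and share its
  stop codon, so their uAUG is an alternative initiation site producing
  an N-terminally extended protein.

An insertion or deletion whose length is not a multiple of three (a
*non-3n* indel) shifts the reading frame of everything downstream. If it
lands between a uAUG and the uORF's stop it scrambles the uORF peptide;
for overlapping and alternative uORFs it can corrupt translation of the
main protein itself. The hypothesis under test is that non-3n indels
*downstream* of uAUGs are removed by purifying selection, most strongly
for the overlapping and alternative configurations, while 3n indels and
indels upstream of the uAUG are comparatively free to accumulate.

### The R statistic

For one transcript, indels in the 5'UTR (pooled insertions and
deletions of length 1–100 nt, taken from a pairwise genomic alignment)
are split at a reference point — the first uAUG from the cap — into
downstream (d) and upstream (u) counts of each size class:

$$
R \;=\; \log_2
\frac{(N_{n3n,d} + c)\,/\,(N_{3n,d} + c)}
     {(N_{n3n,u} + c)\,/\,(N_{3n,u} + c)},
\qquad c = 0.5 .
$$

The upstream non-3n/3n ratio is the transcript's own background, which
controls for composition and mutational idiosyncrasies of 5'UTRs.
Without size preference R is 0; depletion of non-3n indels downstream
drives R below 0. The pseudocount keeps every term finite; the log base
only rescales R and cannot affect anything downstream of it (the ISI
uses only the rank order of R values, which we assert as a unit test).

### The Indel Selection Index

Counts per transcript are small (most 5'UTRs are a few hundred nt), so
R itself is noisy. The Indel Selection Index is the permutation
probability

$$
\mathrm{ISI} \;=\; \frac{\#\{R_\mathrm{shuffled} < R_\mathrm{observed}\}}{N_\mathrm{shuffles}},
$$

where each of the 1000 shuffles redraws every indel's location
independently and uniformly on the integer positions $\{0..L\}$ of the
5'UTR (lengths and size classes retained) and rescores R. A small ISI
means the observed configuration puts fewer non-3n indels downstream
than placement chance would. An indel exactly at the reference point
counts as downstream: a gap at the uAUG disrupts the element it starts.
Because R depends only on the four counts, the shuffle distribution is
a pair of independent binomials, and `exactIsi()` evaluates the index
in closed form; it is the oracle against which the Monte-Carlo
`computeIsi()` is tested.

**Tie handling.** The definition above is strict: shuffles that tie
with the observed R count as "not smaller". With few indels the tie
mass is substantial, which is why the *neutral* median ISI sits near
0.3 rather than 0.5 — a property of the index, not a bug, and the
reason all inference is made against an empirical neutral reference
rather than against 0.5. A `midp` tie rule (half the tie mass counted)
is provided for diagnostic use; it centres the null at 0.5 exactly.

### The neutral reference and matched comparisons

ISI depends on where the reference point sits: near either end of the
UTR one side's counts are dominated by the pseudocount and the index is
depressed. The neutral reference is therefore built empirically from
transcripts *without* any uAUG (group G0), placing an artificial
reference point at p% of each transcript's UTR length. Median neutral
ISI is flat for p in roughly 30–70% and drops toward both ends — the
shape the acceptance suite checks. A uORF group (Ga, Gs, Gv; multi-type
transcripts are excluded) is compared by a two-sided Mann–Whitney U
test against the G0 distribution at the group's median uAUG percent.
Because group position distributions are not points, single-percent
matching is only approximate; the tertile analysis (splitting Gv by
uAUG position into three equal parts, each matched separately) is the
standard follow-up, and per-group position spread is deliberately kept
moderate in the default generator (below).

Unequal group sizes are handled by a size-equalising bootstrap: 1000
resamples (with replacement) of each group at the size of the smallest
group (Ga), each compared against the group's fixed matched neutral
distribution; $F_{sig}$ is the fraction of resample P values below
0.05, and P-value distributions of different groups are compared by
two-sample Kolmogorov–Smirnov tests (computed on P; displayed, when
plotted, as $-\log_{10} P$, a monotone map that leaves the KS statistic
unchanged).

## The synthetic-evolution generator

Real inputs (two genomes, GTF annotations, a pairwise MAF, an ortholog
table) are large and external, so the package ships a generator that
emits complete, ground-truthed datasets in exactly those formats.
Design choices worth knowing:

* **Planted structure is guaranteed, not sampled-and-hoped.** 5'UTRs
  are built from an ATG-excluding sampler (a uniform base sampler that
  never completes the trinucleotide ATG, including across junctions),
  so a G0 UTR contains no uAUG at all and a non-G0 UTR contains exactly
  the planted one. The uORF body uses A-free codons (no stop codon and
  no ATG contains no A), which pins the first in-frame stop exactly
  where the type requires; the CDS embeds stop codons early in both
  off-frames (codon pairs ATA|AGG and CCT|AAC) so an overlapping uORF
  always terminates inside the CDS. The generator still verifies every
  transcript with the package's own scanner and never emits one that
  violates its planted class.
* **Defaults.** Group mixture 0.55/0.02/0.30/0.13 (G0/Ga/Gs/Gv);
  log-normal UTR lengths (median 300 nt, >90% under 1 kb, bounds
  30–3000 nt); Poisson(3) indels per transcript with
  truncated-geometric lengths on 1–100 nt (parameter 0.25, about 3/4
  non-3n); uAUG relative positions Beta-distributed with means 0.25
  (Gs), 0.55 (Ga), 0.60 (Gv). The Beta concentration (alpha+beta =
  180, sd about 0.03) keeps each group well represented by a single
  matched percent; wide spreads re-create the position-mismatch problem
  the tertile analysis exists for, and tests that exercise tertiles
  lower the concentration deliberately.
* **Selection model.** With strength $s$, each non-3n indel at or
  downstream of the uAUG in a selected group is removed with
  probability $s$ before the alignment is realized. $s$ multiplies the
  surviving downstream non-3n fraction by $1-s$, which is the
  recoverable signature.
* **Indel realization.** Each indel is realized as one gap run
  (insertion: gaps in the reference row; deletion: gaps in the other
  row), with at least one matched base between features so runs never
  merge. The recorded location is the first matched reference base 3'
  of the feature — the same convention the alignment scanner uses — so
  the pipeline on emitted files reproduces the truth catalogue exactly.
  Insertions and deletions are pooled everywhere: a pairwise alignment
  cannot polarize them without an outgroup.
* **What is *not* modelled:** substitutions (alignments are exact
  outside gaps), multi-exon genes in the emitted datasets (the
  coordinate machinery supports them and is unit-tested on multi-exon
  and minus-strand toys), Kozak context, non-AUG starts, and lineage
  assignment. Passing tests on this generator demonstrate the
  statistical machinery, not the biology of any real genome.

## Numerical and procedural choices

* Coordinates are 0-based half-open genomically and 0-based from the
  cap on the spliced transcript; minus-strand transcripts are oriented
  cap-to-3' at load time.
* A uORF must be at least 9 nt including its stop codon, for every
  type; an in-frame uAUG with an intervening stop before the TIS is a
  strict uORF; stop codons are TAA/TAG/TGA only.
* One transcript per gene, by one of three criteria: `random` (seeded),
  `longest_utr`, or `pure_utr` (5'UTR genomically disjoint from every
  other isoform's CDS of the same gene). Length ties break by
  transcript ID.
* Alignment quality: alignable exonic coverage must exceed 80% for each
  species symmetrically, and the whole 5'UTR must lie inside alignment
  blocks; gap runs over 100 nt are dropped (counted, not fatal); a gap
  aligned to a gap is a malformed-input error.
* R-value ties in the ISI are detected with an absolute tolerance of
  1e-9, well below the spacing of distinct R values for realistic
  counts.
* Mann–Whitney U uses exact small-sample enumeration when tie-free and
  the tie-corrected normal approximation otherwise (`wilcox.test`);
  two-sided throughout. Tertile sizes differ by at most one, remainder
  to the cap-proximal subgroups, position ties broken by transcript ID.
  No multiple-testing correction is applied across group comparisons.
* All randomness is seed-controlled: the generator, the shuffles, the
  bootstrap, and `runPipeline()` (which derives per-stage seeds from
  the single config seed) are bit-reproducible.

## Problem sizes used in the test suite

The shipped tests run the statistics at the scales the analysis is
designed for: the neutral sweep on 2000 uAUG-free transcripts at the
10–90% deciles with 1000 shuffles; calibration over 200 replicate null
datasets; and selection recovery over 20 seeded datasets of 2000 genes
(400 per uORF group, selection 0.8 on Ga and Gv), with 1000-resample
bootstraps. Smaller unit fixtures are built in code.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(
  groupCounts = c(G0 = 800, Ga = 400, Gs = 400, Gv = 400),
  selectionStrength = 0.8, selectedGroups = c("Ga", "Gv"), seed = 1)
sim <- simulateDataset(cfg)
res <- analyzeSimulation(sim, bootstrap = TRUE)
res$comparisons
res$bootstrap$summary
```

The same analysis driven through files (`emitDataset()` then
`runPipeline()`) writes every stage table, a plain-text report and a
`results.json`; `runPipeline()` accepts either a `simulate` block or
paths to GTF/FASTA/MAF/ortholog inputs.

## Known limitations

Single-percent neutral matching is approximate for groups with broad
uAUG position spread; insertions cannot be told from deletions; indels
larger than 100 nt are ignored rather than modelled; the strict-tie ISI
is conservative (its null median is below 0.5), which is harmless for
matched comparisons but means raw ISI values are not comparable across
transcripts with different indel counts; and pseudocount choice can, for
extreme count patterns, flip the sign of R, so sign stability across
pseudocounts is reported as an empirical diagnostic, not assumed.
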