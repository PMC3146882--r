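# uORFindels

Are frame-shifting indels selectively removed from 5'UTRs downstream of
upstream AUGs?

Upstream open reading frames (uORFs) start at an AUG inside the 5'UTR
(a uAUG) and tune translation of the main CDS. An insertion or deletion
whose length is not a multiple of three (a *non-3n* indel) shifts the
reading frame of everything downstream of it: inside a uORF it
scrambles the uORF peptide, and for uORFs that are in frame with the
main CDS (alternative initiation sites) or overlap it out of frame, it
can corrupt the main protein. `uORFindels` is a pipeline for molecular
evolutionary analysis of this constraint from two-species data:
transcript annotations (GTF) + genomes (FASTA), a pairwise alignment
(MAF) and a one-to-one ortholog table.

## The statistic

Indels (pooled insertions/deletions, 1–100 nt) in each 5'UTR are split
at the first uAUG into downstream (d) and upstream (u) counts per size
class, and summarised by a log ratio-of-ratios with pseudocount
c = 0.5:

    R = log2( ((N_n3n,d + c) / (N_3n,d + c)) /
              ((N_n3n,u + c) / (N_3n,u + c)) )

R = 0 under no size preference; R < 0 when non-3n indels are depleted
downstream. Because per-transcript counts are small, inference uses the
**Indel Selection Index**: the fraction of 1000 positional shuffles
(indel locations redrawn uniformly along the UTR) whose R falls below
the observed one. Transcript groups defined by uORF content —
G0 (no uAUG), Ga (only alternative), Gs (only strict), Gv (only
overlapping) — are compared against a neutral ISI reference built from
G0 transcripts with an artificial reference point at the group's median
uAUG percent (Mann–Whitney U), refined by a position-tertile analysis
of Gv and a size-equalising bootstrap (F_sig = fraction of resample
P values < 0.05; Kolmogorov–Smirnov between groups' P-value
distributions).

A bundled synthetic-evolution generator emits complete ground-truthed
datasets (FASTA + GTF + MAF + ortholog TSV) with planted uORFs and a
tunable purifying-selection strength `s` on downstream non-3n indels,
so every stage is testable end to end without downloads.

## Worked example

Simulate 2000 genes with selection s = 0.8 acting on the Ga and Gv
groups only, and run the group comparisons:

```r
library(uORFindels)
cfg <- simulationConfig(
  groupCounts = c(G0 = 800, Ga = 400, Gs = 400, Gv = 400),
  selectionStrength = 0.8, selectedGroups = c("Ga", "Gv"), seed = 1)
sim <- simulateDataset(cfg)
res <- analyzeSimulation(sim, bootstrap = TRUE)
res$comparisons
```

    group matchedPercent nGroup nNeutral medianGroupIsi medianNeutralIsi uStatistic   pValue significance
       Ga             55    349      757         0.0360            0.319      74114 1.98e-32          ***
       Gs             25    377      757         0.2300            0.252     133132 6.56e-02
       Gv             60    352      757         0.0905            0.344      80460 6.79e-27          ***

```r
res$bootstrap$summary
```

    group targetN nResamples  fSig
       Ga     349       1000 1.000
       Gs     349       1000 0.397
       Gv     349       1000 1.000

Reading: the two selected groups (Ga, Gv) sit far below their matched
neutral medians (ISI ~0.04–0.09 vs ~0.32–0.34, P < 1e-26), while the
unselected Gs group is indistinguishable from neutral (P = 0.066); with
sample sizes equalised to the Ga group, F_sig stays at 1.0 for the
selected groups. That is the signature of purifying selection on
frame-shifting indels downstream of uAUGs.

The same analysis can be driven from files: `emitDataset()` writes the
simulated FASTA/GTF/MAF/TSV set, and `runPipeline()` (or the wrapper
`inst/scripts/run_pipeline.R` with a YAML config) runs
load → select → classify → filter/extract indels → ISI → neutral
table → comparisons, writing stage TSVs, a report and `results.json`.

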