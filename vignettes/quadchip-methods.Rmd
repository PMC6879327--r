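---
title: "quadchip: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadchip: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadchip)
```

## The scientific question

The shelterin protein TRF2 binds double-stranded telomeric `TTAGGG`
repeats, but ChIP-Seq shows thousands of binding sites far from
telomeres. One mechanistic hypothesis is that extra-telomeric TRF2 is
recruited by potential G-quadruplex (PG4) motifs — runs of guanines that
can fold into four-stranded G4 structures. quadchip implements the
computational side of testing that hypothesis: locate PG4 motifs,
characterise ChIP-Seq peaks (replicate consistency, TSS proximity,
genomic features, telomeric content, FRiP, bin-level enrichment), and
ask whether PG4 motifs and peaks co-occur more often than
length-matched random regions would suggest. A G4-FID titration module
quantifies the biochemical side: how much protein displaces the
fluorescent probe thiazole orange from a folded G4 in solution.

All coordinates are 0-based half-open (BED convention) throughout; a
single convention eliminates off-by-one drift between modules.

## PG4 scanning

A PG4 pattern `G<g>L<min>-<max>` is `n_runs` G-tracts of at least
`run_len` guanines separated by loops of `loop_min`–`loop_max` bases;
the classic quadparser pattern is `G3L1-7`, and relaxing the loops to 12
or 15 admits longer-looped conformations. The scanner's conventions:

* **Tracts are maximal G-runs.** Excess guanines belong to the tract,
  never to a loop, so a hit's boundaries are reproducible.
* **Leftmost, lazy matching.** A hit starts at the earliest qualifying
  tract, chains the nearest following tracts whose intervening loops
  satisfy the length bounds, and ends at the last guanine of the final
  tract. Scanning resumes at the next base, so hits on a strand never
  overlap; a run of six tracts yields one hit over the first four.
* **Loops may contain guanines** (in sub-threshold runs); only loop
  *length* is constrained. `N` never matches, neither in tracts nor in
  loops, so assembly gaps cannot produce hits.
* **Strands are scanned independently.** The minus strand is scanned on
  the reverse complement and mapped back to plus coordinates; G-rich and
  C-rich strands are chemically distinct folding substrates, so
  overlapping plus/minus hits are both counted (coverage, used by the
  enrichment table, is the base-level union).
* **Zero-length loops are rejected** (`loop_min = 1`): two tracts
  without a loop are one tract.

```{r scan-example}
scan_pg4("GGGTTAGGGTTAGGGTTAGGG", g4_preset("G3L1-7"))
```

The test suite holds the scanner to a brute-force oracle that enumerates
every substring against the grammar on hundreds of random sequences, for
both `G3L1-7` and `G3L1-15`.

Telomeric reads are defined by content, not position: a read is
telomeric when it contains two tandem `TTAGGG` units on either strand
(`TTAGGGTTAGGG` or `CCCTAACCCTAA` as a substring).

## Peak analytics

**Replicate intersection.** Two replicate peak sets are intersected by
the min-start/max-end rule: wherever peaks from both replicates overlap,
one common peak spans from the smallest start to the largest end. The
rule is applied to connected components of the pooled interval-overlap
graph, so an overlap chain (rep1–rep2–rep1) merges into a single common
peak; components touching only one replicate emit nothing. Touching
half-open intervals do not overlap.

**TSS proximity.** A peak counts as within `d` of a transcription start
site when the minimum interval-to-point distance (0 if the TSS lies in
the peak, else the gap to the nearest *contained* base) is at most `d`.
Distances are measured from peak edges, not summits — peak callers do
not always report summits, and the edge convention needs no extra
inputs. Counts are non-decreasing in `d` by construction.

**Feature annotation** classifies each peak by its midpoint with fixed
priority promoter > downstream > exon > intron > intergenic. The
promoter half-width (default 1 kb around the TSS) and the downstream
window (default 5 kb past the transcript end, on the gene strand) are
parameters; the priority order makes the categories mutually exclusive.

**Sub-telomeric partition.** An interval or read is sub-telomeric when
any of its bases lies within the margin (default 0.5 Mb) of a chromosome
terminus. Per-chromosome partition tables conserve read totals by
construction.

**FRiP** (fraction of reads in peaks) assigns a read to a peak when its
midpoint (`pos + floor(length/2)`) falls inside; the midpoint rule is
unambiguous for reads straddling peak edges. Overlapping peaks are
merged first.

## Enrichment against length-matched random controls

For each observed peak, `sample_control_regions()` draws `n_per_peak`
(default 100) regions of exactly that peak's length: a chromosome is
chosen with probability proportional to its length, the start uniformly
among fitting positions, and draws are rejected when they overlap an
exclusion interval (by default the observed peaks, to avoid
contamination) or contain more than 10% `N`. A single integer seed makes
the draw reproducible and is recorded in every report.

Two 2×2 tables are then tested with Fisher's exact test (two-sided, the
sum of hypergeometric probabilities not exceeding that of the observed
table, with a 1e-7 relative tolerance on the comparison):

* **Motif-count enrichment** — row 1: (number of nonoverlapping PG4
  motifs in peaks, peak bases not covered by any motif); row 2: the same
  over the pooled controls. Counting uncovered bases keeps both margins
  well-defined counts while preserving the "motifs within regions"
  comparison.
* **Presence enrichment** — row 1: (peaks with ≥ 1 hit, peaks with
  none); row 2: the same over pooled controls.

Controls are pooled into a single table per pattern (one p-value per
pattern), not converted into per-peak empirical p-values. The odds ratio
is `(ad)/(bc)` with a 0.5 continuity correction when a cell is zero.
Degenerate margins (e.g. every region contains a motif) return `p = 1`
with a warning rather than an error.

**Bin-level enrichment.** The genome is divided into fixed bins (default
50 bp); reads are assigned to the bin holding their midpoint. Each bin's
ChIP count is tested against a one-sided binomial null with success
probability `(input_bin + 1) / (input_total + n_bins)` — a +1
pseudo-count so that input-empty bins are not automatically significant
— and Benjamini–Hochberg controls the FDR (default 5%) across bins. The
binomial-with-pseudo-count model and the BH correction are deliberate,
config-exposed choices: they are the simplest calibrated reading of
"significant enrichment over input".

## G4-FID titrations

With `FA1` the fluorescence area after probe addition and before any
titrant, displacement at titration point `x` is

$$\mathrm{TOD}_x = 100 - \frac{FA_x}{FA_1} \times 100,$$

the standard G4-FID ratio form: 0 at the baseline, 100 at complete
displacement, invariant under rescaling all areas. (A published variant
of this formula omits the division by `FA1`, which breaks its own
baseline condition `TOD(FA1) = 0`; the ratio form is the one consistent
with the assay's definition and with the wider G4-FID literature.)
Raw TOD values are kept for fitting — noise can push areas above the
baseline — and clamped to `[0, 100]` only for reporting.

`dc50()` interpolates the 50% crossing linearly between the bracketing
points of the isotonic (monotone non-decreasing) smooth of the TOD
curve; if the raw curve crosses 50% more than once, the first crossing
is used with a warning. The *indicative* dissociation constant comes
from a Levenberg–Marquardt least-squares fit of the Hill curve
$\mathrm{TOD}(c) = 100\,c^h/(c^h + K^h)$, initialised at `K` = the
interpolated DC50 and `h = 1`; the Hill midpoint convention for an
indicative affinity is this package's choice of a transparent,
reproducible estimator. On noiseless Hill data the two estimators agree
within 15% across `h` from 0.5 to 4, and at 2% multiplicative noise both
recover their truth within 10% in well over 90% of runs.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth
(`synthetic_spec()` + `generate_*()`), and every generator is a pure
function of the spec and its seed (per-stage seeds are derived from the
root seed by a stable string hash, so stages and replicates get
distinct, reproducible streams).

Defaults emulate a desk-scale TRF2-style experiment: two 50-kb
chromosomes, uniform base composition, 30 true peaks of 300 bp (the
sonicated fragment size), planted `G3L1-7` motifs at 2.5/kb inside peaks
versus 0.5/kb outside (a 5-fold excess), replicate endpoint jitter of
SD 15 bp (1/20 of the peak length) plus 5 decoy peaks per replicate,
10,000 reads of 36 bp with a 10-fold start-rate enrichment inside peaks,
and a 23% telomeric read fraction — the fraction reported for a genuine
telomere-binding factor. FID titrations default to a ladder spanning
0.25–4× the true DC50 with 2% multiplicative noise.

Design points worth knowing:

* Planted motifs are built literally from the pattern — four G-tracts
  with loops drawn over `{A, C, T}` — and planting sites are rejected
  unless guard windows flanking the motif are free of qualifying G-runs.
  This guarantees *ground-truth closure*: the scanner recovers every
  planted motif verbatim, which the tests assert.
* The background is i.i.d.; there is no higher-order Markov structure,
  GC isochores, repeat families, or mappability variation. Passing tests
  therefore demonstrate the machinery is correct and calibrated on
  homogeneous backgrounds, not that length-matching controls for every
  compositional confounder in real genomes (the enrichment module
  deliberately matches length only, as the analysis it implements did).
* Telomeric reads keep their genomic placements; only their sequence is
  replaced. FRiP and bin ground truth are therefore unaffected by the
  telomeric fraction.

## Calibration at desk scale

Two emulation limits deserve emphasis.

First, drawing 100 length-matched controls per peak "from across the
genome" is harmless at genome scale (in a 3-Gb genome the control
footprint is a few percent), but in a 100-kb synthetic genome 3,000
controls of 300 bp over-sample the background roughly tenfold; the
control draws are then strongly overlapping, the control totals are
under-dispersed relative to the sampling model implicit in Fisher's
test, and the null false-positive rate inflates (we measure ~0.10 at
nominal 0.05). The calibration study therefore keeps the control
footprint at ~10% of a 500-kb genome (10 peaks × 250 bp, 20 controls
each).

Second, planted in-peak motifs lie wholly inside their peak by
construction, whereas a control region clips background motifs at its
edges — a ~21-bp motif in a 250-bp window is lost about 8% of the time.
Comparing planted peaks against controls at *equal densities* is
therefore not an exact null. `simulate_enrichment(peaks_from =
"random")` builds the exact null instead: motifs are planted genome-wide
at one rate and the "observed" peak set is itself drawn by the control
sampler, so every edge and sampling artefact cancels and only the
contingency-table machinery is under test. Under that design the
fraction of p < 0.05 across 200 replicate simulations is 0.02–0.05 —
slightly conservative, as expected for a discrete exact test at ~6
motifs per peak set. The power test runs against the planted peaks at
the unchanged generator defaults.

## Problem sizes and numerical choices

The shipped tests use: 500 random 2-kb sequences for scanner–oracle
equivalence; every 2×2 table with total ≤ 40 for the Fisher sweep
against `stats::fisher.test`; 200 replicate simulations for null
calibration and 100 for power; 20 jitter-recovery simulations; 10,000
reads for the telomeric classifier; 100 noisy titrations for FID
recovery. These sizes give stable proportions while keeping a full run
of the suite in single-digit minutes on one core.

Other numerical conventions: rejection sampling budgets are explicit
(1,000 draws per control region, with an error naming the offending
peak); Hill fits are bounded (`K > 0`, `h > 0`) and error after 200
Levenberg–Marquardt iterations; `bh_fdr` is `stats::p.adjust`'s step-up
rule compared against a literal implementation in the tests; distance
ties between interval edges resolve to the nearest contained base
(`end − 1`, never the exclusive end).

## Known limitations

* The scanner implements the canonical perfect-tract grammar; bulged or
  imperfect quadruplexes and thermodynamic scores (G4Hunter-style) are
  out of scope.
* Enrichment controls match length only — no GC, repeat or mappability
  matching.
* The IDR value on peaks is consumed (as a filter column), never
  computed.
* Alignment, de-duplication and peak calling are upstream of this
  package: it starts from peaks and read placements.
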