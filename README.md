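# quadchip

G-quadruplex motif and telomeric repeat analytics for ChIP-Seq peaks.

The telomere-binding shelterin protein TRF2 occupies thousands of
binding sites far from telomeres, and one candidate recruitment signal
is the potential G-quadruplex (PG4) motif — four runs of guanines
separated by short loops, written `G3L1-15` for tracts of ≥ 3 G with
loops of 1–15 bases:

```
G{3,} N{1,15} G{3,} N{1,15} G{3,} N{1,15} G{3,}
```

quadchip implements the full desk-side analysis around that hypothesis:

* **PG4 scanning** — leftmost, nonoverlapping, both strands, maximal
  G-tracts, `N`-aware (`scan_pg4()`, `count_pg4()`), plus telomeric
  `TTAGGG`-repeat detection and read classification
  (`is_telomeric_read()`, `find_telomeric_tracts()`).
* **Peak analytics** — replicate intersection by the min-start/max-end
  rule (`common_peaks()`), TSS-proximity counts, genomic feature
  annotation (promoter/downstream/exon/intron/intergenic),
  sub-telomeric vs interstitial partition at a 0.5-Mb terminal margin,
  FRiP, and flagging of peaks carrying interstitial telomeric repeats.
* **Enrichment statistics** — for each peak, `n` random regions of
  identical length drawn genome-wide as controls
  (`sample_control_regions()`), then two Fisher's exact tests:
  motif counts vs non-motif bases in peaks against pooled controls, and
  peaks-with-motif vs peaks-without against controls
  (`motif_count_enrichment()`, `peak_presence_enrichment()`); plus
  50-bp-bin ChIP-vs-input enrichment under a binomial model with
  Benjamini–Hochberg FDR control (`bin_track()`, `bin_enrichment()`).
* **G4-FID titrations** — percentage thiazole-orange displacement
  `TOD = 100 − (FAx/FA1)·100`, interpolated DC50, and an indicative
  dissociation constant from a Hill fit
  `TOD(c) = 100·cʰ/(cʰ + Kʰ)` (`fid_analyze()`, `dc50()`, `fit_hill()`).
* **Synthetic data with known ground truth** — genomes with planted PG4
  motifs at controlled densities inside/outside peaks, jittered
  replicate peak sets with decoys, reads with a controlled telomeric
  fraction and in-peak enrichment, and noisy sigmoidal FID titrations
  (`synthetic_spec()`, `generate_*()`); `run_pipeline()` chains
  everything into one reproducible report.

Everything is tidyverse-native: data frames in, tibbles out, results as
small S3 objects with `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

A complete synthetic study at the default conditions (two 50-kb
chromosomes, 30 true peaks of 300 bp, planted `G3L1-7` motifs at 2.5/kb
inside peaks vs 0.5/kb outside, 23% telomeric reads):

```r
library(quadchip)

spec <- synthetic_spec(seed = 7)
sim <- generate_genome(spec)
reps <- generate_replicate_peaks(sim$peaks, spec)
common <- common_peaks(reps$rep1, reps$rep2)
nrow(common)
#> [1] 30

controls <- sample_control_regions(common, sim$genome, n_per_peak = 100,
                                   seed = 7, genome = sim$genome)
motif_count_enrichment(common, controls, sim$genome, spec$pattern, seed = 7)
#> <g4_enrichment: motif-count> pattern G3L1-7
#>          with without
#> peaks      23    8999
#> controls  486  945765
#> odds ratio 4.97, two-sided Fisher p = 1.36e-09
```

All 30 true peaks survive replicate jitter and intersect back into the
common set; PG4 motifs occur about five times more often per base inside
the peaks than in 3,000 pooled length-matched controls, and the
two-sided Fisher test rejects chance co-occurrence. The read-level and
titration-level measurements recover their generating parameters:

```r
reads <- generate_reads(sim$genome, sim$peaks, spec)
round(100 * mean(is_telomeric_read(reads$reads)), 1)  # generated at 23%
#> [1] 23.7
round(frip(reads$placements, sim$peaks), 3)           # 10-fold in-peak rate
#> [1] 0.473

series <- generate_fid_series(dc50_true = 2, hill = 1, noise_cv = 0.02, seed = 7)
fid_analyze(series)
#> <fid_fit> 9 titration points; DC50 = 1.954 eq; indicative Kd = 1.99, Hill h = 0.979
```

`vignettes/quadchip-methods.Rmd` documents the models, conventions and
every tunable parameter; `trf2_reported_stats()` and
`trf2_read_partition()` expose the transcribed published summary tables
that motivate the default study conditions.

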