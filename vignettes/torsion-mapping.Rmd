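---
title: "Mapping DNA torsion from psoralen crosslink sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping DNA torsion from psoralen crosslink sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionmap)
```

## The measurement model

Trimethylpsoralen (TMP) intercalates into double-stranded DNA and, under
365-nm light, forms interstrand crosslinks (ICLs). Intercalation unwinds
the helix, so underwound ((−) supercoiled) DNA takes up TMP more readily
and overwound ((+) supercoiled) DNA less readily; over the physiological
range the crosslinking rate responds approximately linearly to torsion.
Sequencing the crosslink positions (the 5′ end of read 1 of each
enriched fragment) therefore yields a genome-wide torsion-sensitive
signal.

The catch is that the raw ICL landscape is dominated by two
torsion-independent factors: the intercalator's DNA-sequence preference
and chromatin accessibility (nucleosomes exclude TMP; linkers and
nucleosome-free regions admit it). A torsion map therefore needs a
*zero-torsion baseline*: the ICL landscape of the same chromatin with
its torsion released but its protein landscape intact — obtained by
fixing cells, permeabilizing them, and relaxing torsion by restriction
digestion before crosslinking. The package's central computation is

$$\text{torsion signal} \;=\;
  \overline{\text{ICL}}_{\text{with torsion}}^{\,\text{(mean = 1)}}
  \;-\;
  \overline{\text{ICL}}_{\text{without torsion}}^{\,\text{(mean = 1)}}$$

per 10-bp bin, where each replicate is first normalized to a genome-wide
mean of one and replicates are then averaged per condition. Both
conditions share the same sequence preference and accessibility
structure, so the difference isolates torsion: **positive values mark
(−)/underwound DNA, negative values (+)/overwound DNA**. Purified-DNA
normalization (`sequence_normalize()`) exists for accessibility-style
views but is deliberately *not* part of `compute_torsion()` — the
sequence preference cancels in the subtraction.

## Pipeline conventions

* **Coordinates.** Everything internal is 0-based half-open (the
  BED/bedGraph convention); bin $k$ covers $[10k, 10k+10)$.
* **Missing versus zero.** Bins a bedGraph does not cover are 0 — every
  bin of the genome gets a value. Missingness (`NA`) is reserved for
  deliberate exclusion: blacklist masking, off-chromosome flanks, and
  per-row anchor exclusions. `NA` propagates through arithmetic and is
  excluded from means and composite statistics.
* **Normalization order.** Each replicate is normalized to mean 1 and
  replicates are then averaged (`normalize_first = TRUE`); the swapped
  order is available as a flag. Normalizing first makes the result
  invariant to each replicate's sequencing depth. Whether blacklisted
  bins enter the normalizing mean is configurable (`exclude` argument);
  the default includes all non-missing bins.
* **Duplicates.** Only the SAM duplicate flag is honoured;
  duplicate *marking* is an upstream responsibility.
* **Division.** Track ratios use a configurable pseudocount, default 0;
  zero denominators yield missing bins plus a warning count rather than
  an error.
* **Composites.** Anchored matrices reorient minus-strand rows so
  transcription runs left to right; gene-*pair* and loop composites use
  chromosomal left-to-right orientation instead (pass `strand = NA`).
  Length rescaling uses mean-preserving coverage-weighted averaging —
  never interpolation at sample points and never summing — so a constant
  region stays constant and the per-row body mean equals the source
  mean; this is what "preserving the signal amplitude" means here.
* **Peak/valley statistics.** The composite extremum near an anchor is
  located per group by argmax/argmin of the group's composite profile
  within a ±500-bp search window (configurable); each gene is then
  averaged over bins whose centers lie within ±20 bp of that position
  (4 bins at 10-bp binning), and the group mean ± SEM across genes is
  reported. Locating extrema per group rather than globally follows the
  reading that weakly and strongly expressed groups may peak at
  slightly different offsets; both choices are exposed.
* **Percentile groups.** Five quintile groups (breaks 20/40/60/80) by
  default, configurable. A record's percentile rank is the fraction of
  keys strictly below its own, so tied keys share a group and all-equal
  keys fall in the first.
* **Gene pairs.** Nearest neighbours are adjacent ORFs per chromosome in
  coordinate order; overlapping ORFs are skipped with a logged count. A
  pair is "purified" iff no annotation other than its two members
  overlaps the shared intergenic interval (flanking gaps are not
  tested — only the shared gap matters for intergenic torsion).
* **Loops.** Nested-loop refinement removes any loop strictly containing
  another (loops sharing one boundary count as nested iff the other
  boundary is strictly inside; identical duplicates are kept). Boundary
  snapping moves each boundary independently to the nearest ChIP peak
  strictly within 500 bp, leftmost on ties; loops that would invert are
  dropped with a logged count. The bundled peak caller (greedy local
  maxima with an exclusion radius, default height cutoff the 90th
  percentile, separation 250 bp) is a plain utility for boundary work,
  not a modelled ChIP caller.

## The synthetic-data generator

The generator implements the twin-supercoiled-domain model so the whole
pipeline can be validated without external data. Its default parameters
*are* the study conditions of the test and acceptance suites:

| parameter | default | meaning |
|---|---|---|
| genome | 4 × 300 kb, 10-bp bins | desk-scale yeast-like genome (~550–600 genes) |
| gene length | log-normal, median 1.4 kb (sdlog 0.45) | yeast ORF scale |
| intergenic gap | log-normal, median 400 bp (sdlog 0.6, floor 100 bp) | yeast gene density |
| expression $E$ | log-normal, mean 1 (sdlog 0.6) | arbitrary units; light tail (below) |
| accessibility | $a_0 = 0.5$, NFR bump 0.45 at −80 ± 60 bp, nucleosome term 0.24 | clipped to [0.02, 1] |
| nucleosome repeat $p$ | 160 bp, phasing decay 800 bp | damped cosine in gene bodies |
| torsion amplitudes | $T_{tss} = 0.25$, $T_{tes} = 0.25$, $c_{len} = 10^{-4}$/bp | scale with $E$; terminator term grows with gene length |
| torsion decay $\lambda_t$ | 750 bp | confines torsion to 1–2 kb of promoters/terminators |
| linear response $\kappa$ | 0.5 | rate factor $\max(0, 1 + \kappa t)$ |
| insulators | bound probability UNB 0, TFO/STM 1; hard truncation, leakage 0 | at divergent-pair gap midpoints |
| depth | 0.2 ICLs/kb × scale 1000 | Poisson mean 2 per bin per replicate |
| replicates | 2 with torsion, 3 without | mirrors the replicate structure of real designs |

The torsion field adds, per gene, $+T_{tss} E\, e^{-d/\lambda_t}$
upstream of the TSS and $-(T_{tes} + c_{len}\,\mathrm{size}) E\,
e^{-d/\lambda_t}$ downstream of the TES; contributions sum over genes,
so divergent pairs merge their (−) domains and convergent pairs their
(+) domains. For insulated divergent pairs each promoter's upstream tail
is truncated at the gap midpoint (a leakage fraction exists, default 0 —
the blocking efficiency of real insulators is not quantified, so hard
truncation is the simplest defensible default).

Emission is Poisson: $\text{rate}_\text{with} = D\, s\, a\,
\max(0, 1 + \kappa t)$, $\text{rate}_\text{without} = D\, s\, a$,
$\text{rate}_\text{purified} = D\, s$, with $s$ a smooth log-normal
sequence-preference field and each condition's $D$ set so its mean rate
matches the configured depth (as UV dosage is tuned to match crosslink
densities across conditions in the laboratory protocol).

Three default choices deserve their reasons:

* **Depth scale.** Physical working densities are ~0.1–0.25 ICLs/kb per
  library, but a real library pools crosslinks over very many genome
  equivalents. On a 1.2-Mb desk genome the scale factor (default 1000,
  giving Poisson mean 2 per bin) stands in for that pooling, so
  composite signal-to-noise is comparable to a genome-wide run while a
  full simulation takes ~3 s.
* **Expression tail.** The linear torsion response is only meaningful
  while $1 + \kappa t > 0$; rates are clipped at zero and clipped bins
  logged. A heavy-tailed expression law drives $\kappa t$ far below −1
  at the terminators of strong long genes, which distorts exactly the
  strongest-signal bins. The default light tail (sdlog 0.6) keeps the
  field essentially inside the linear regime (tens of clipped bins per
  genome).
* **Amplitude calibration.** `nuc_amp`, `nfr_amp`, `t_tss` and `kappa`
  are calibrated jointly so the with-torsion TSS composite has about 5×
  the peak-to-valley amplitude of the torsion signal — the regime in
  which the baseline subtraction operates, where accessibility dominates
  the raw signal and torsion is the residual.

**What the generator does *not* emulate:** mappability artifacts,
fragment-length and exonuclease chemistry, GC or crosslink-density
library biases, transcription-unit architecture beyond single ORFs
(no UTRs, introns, or overlapping transcripts), replication- or
cohesin-*generated* torsion, and topoisomerase kinetics. Passing tests
show the pipeline computes what it claims on data with the assumed
statistical structure; they do not validate those additional features of
real libraries.

## Validation conventions

* **Recovery correlation.** `field_recovery_correlation()` smooths both
  the recovered torsion track and the truth response field $\kappa t$
  with a 31-bin (310 bp) moving average — wide enough to average Poisson
  noise, narrow against the 750-bp decay length — and correlates them
  over bins where the truth magnitude exceeds the analytic noise floor
  of the smoothed difference track,
  $\sqrt{(1/n_w + 1/n_{wo})/D_{bin}} / \sqrt{k}$. At the default depth
  this yields $r > 0.8$, improving with depth.
* **Periodicity.** The nucleosome repeat is estimated as the lag of the
  first non-zero-lag local maximum of the autocorrelation of the
  mean-centered composite profile, resolution one bin (10 bp).
* **Insulation discrimination.** On noise-free truth fields, the scaled
  divergent-gap composite of unbound pairs is a single merged region
  (midgap attenuation $\approx e^{-\bar g/2\lambda_t} \cdot 2 / (1 +
  e^{-\bar g/\lambda_t}) \gtrsim 0.95$ relative to its maximum at the
  default ~400-bp gaps), while hard truncation pulls insulated pairs
  down to $\approx 0.75$. Counting contiguous runs above 0.85 of the
  profile maximum — midway between those two regimes — separates one
  plateau from two peaks.
* **Problem sizes.** Module tests run on 1–2 chromosome genomes of
  60–150 kb; acceptance-level checks use the full default conditions
  (4 × 300 kb, ≥300 genes). The complete suite runs in well under a
  minute.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_tmp_experiment(sim_params(), seed = 1)
torsion <- compute_torsion(sim$tracks$with, sim$tracks$without)

genes <- expression_from_mrna(sim$fixtures$mrna_plus,
                              sim$fixtures$mrna_minus, sim$truth$genes)
groups <- percentile_groups(genes$expression)
peak_valley_stats(torsion, genes, groups, anchor = "tss_peak")

res <- run_torsion_pipeline(sim, pipeline_config(out_dir = "out"))
```

## Known limitations

* Torsion is reported in arbitrary (depth-normalized difference) units;
  absolute calibration to physical torque or supercoiling density is out
  of scope, as is ICL-density estimation from the digested fraction.
* TSS/TES are proxied by ORF bounds; UTRs shift true anchors by up to a
  few hundred bp in real annotations.
* The single-pass greedy peak caller is intentionally plain; externally
  called peaks can be supplied wherever a `PeakSet`-style table is
  accepted.
* Single-end alignments are rejected rather than supported; bigWig
  output is not produced (bedGraph is the contract).
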