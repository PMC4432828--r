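---
title: "Bisulfite methylation analysis of genomes and repeat amplicons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bisulfite methylation analysis of genomes and repeat amplicons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmethr)
```

## The problem

Bisulfite treatment deaminates unmethylated cytosine to uracil, read as
thymine after PCR, while 5-methyl-cytosine is retained as cytosine. A
bisulfite sequencing experiment therefore turns methylation into a C-vs-T
signal, but three nuisance processes sit between the chemistry and a
methylation call:

* **under-conversion** — an unmethylated C that fails to convert and
  masquerades as methylated (rate $u$, calibrated on a fully unmethylated
  spike-in such as phage lambda DNA);
* **over-conversion** — a methylated C erroneously converted (rate $v$,
  usually negligible);
* **sampling** — each read reports one molecule from a heterogeneous cell
  population, so a site's methylation is a per-molecule Bernoulli draw, not a
  fixed state.

`bsmethr` implements two analysis tracks over this signal, driven end to end
by a synthetic read generator so that every stage can be verified against
known truth without any external data:

1. **genome scale** — conversion-efficiency QC from the spike-in, per-site
   methylation calls, cytosine-count summaries and methylation-frequency bin
   profiles, per-site Fisher differential testing guarded by a
   conversion-error "reality screen", gene annotation of differential sites,
   and flank extraction;
2. **repeat amplicons** — Alu and LINE-1 consensus amplicons amplified from
   bisulfite-converted DNA, analysed per read: CpG/TpG dinucleotide
   frequencies, distribution-shift chi-square tests, one- versus
   two-component Gaussian mixture detection of bidirectional methylation
   change, and CpG–TpG inverse-correlation checks.

## The generator

### Genomic reads

`generate_reference()` draws a first-order Markov sequence: base composition
is set by `gc_fraction` and the CpG dinucleotide rate is `cpg_factor` times
the independence baseline $(\mathrm{GC}/2)^2$. `cpg_factor = 1` reduces to
i.i.d. bases; values around 0.2–0.3 emulate mammalian CpG depletion. The
pipeline default is a 50 kb chromosome at GC 0.42 — a desk-scale stand-in, not
a genome.

`assign_methylome()` labels every cytosine on both strands with its context
by the standard three-base rule (CpG, CHG, CHH; H = A/C/T; a context
truncated by the sequence end, or interrupted by N, falls back to CHH) and
draws a Bernoulli state per site. `bisulfite_convert()` applies the chemistry
to one strand: unmethylated C becomes T with probability $1-u$, methylated C
with probability $v$; nothing else changes. The two strands of converted DNA
are no longer complementary, so the minus strand is converted on the reverse
complement (`convert_both_strands()`), making minus-strand conversions appear
as G→A from the plus strand.

Two read simulators exist deliberately:

* `simulate_genomic_reads()` slices a *frozen* converted genome — a single
  molecule resequenced. It is the right model for round-trip and coordinate
  tests (every read equals its truth slice exactly) and supports a paired
  mode, but per-site methylation across its reads is degenerate (a site is
  either retained or converted once and for all).
* `simulate_methylome_reads()` is **molecule-resolved**: every read draws
  fresh Bernoulli states and conversion events at the cytosines it covers, as
  in a real library where every read is a distinct cell's molecule. Per-site
  methylation percentages then centre on
  $100\,(p(1-v) + (1-p)u)$ with binomial read-sampling noise — the model the
  per-site analysis assumes. The pipeline, the per-site tests and the
  acceptance script use this simulator; two arms generated at the same $p$
  constitute a genuine null for differential testing.

### Amplicon reads

`simulate_amplicon_reads()` emulates bisulfite PCR of a repeat family
followed by long-read sequencing. Per molecule: a mixture component is drawn
(`weights`), then a per-molecule CpG methylation level from that component's
beta distribution (mean `levels[j]`, concentration `dispersion[j]`), then
independent per-CpG Bernoulli states at that level; non-CpG cytosines are
unmethylated, matching the repeat biology. Conversion applies per molecule.
Incomplete sequencing is emulated by truncating a fraction
(`1 - p_full_length`, default 0.3) of reads to a uniform length at or above
`min_observed_len` (default 60 b), which exercises the 100 b analysis filter.
The beta-Bernoulli per-molecule model is the simplest one producing the
unimodal and bimodal per-read CpG-frequency distributions the analysis is
designed to detect; no claim is made that real per-molecule levels are beta
distributed. A PCR bias against molecules with unmethylated CpGs in the
priming regions is available (`pcr_bias`) but off by default.

### What the generator does not emulate

Sequencing errors beyond conversion events, indels, quality-score structure,
chimeric/concatemer artifacts, repeat-family sequence divergence (all reads
derive from one consensus template), and genome-scale alignment ambiguity
(truth sidecars stand in for mapping). Passing tests therefore demonstrate
the correctness of the estimators under the stated model, not robustness to
these real-data features.

## The analyses and their parameters

### Conversion QC

`estimate_under_conversion()` implements the spike-in estimator: over all
reads placed on the spike-in, count reference-C positions read as C
(`c_c_matches`) and all covered reference-C positions (`c_coverage`); the
under-conversion rate is their ratio and the efficiency
$100(1-\hat{u})$. Only the strand a read derives from contributes positions —
conversion is strand-specific chemistry — and read N bases are excluded.
`qc_verdict()` passes a sample at `min_efficiency_percent` (default 95, the
efficiency an unmethylated spike-in is expected to certify; the boundary
passes).

### Per-site calls and differential sites

`call_sites()` increments a site's methylated count for a read base C and
unmethylated for T; other bases are ignored. Context comes from the
unconverted reference. `differential_sites()` then tests each shared site
with a two-sided Fisher exact test on the 2×2 table of counts across
samples, at `alpha = 0.01` per site with no multiple-testing correction by
default (a Benjamini–Hochberg option exists). Before testing, a site must
look methylated beyond conversion error in at least one sample: a one-sided
binomial tail test of `n_meth` against retention probability
`conversion_error = 0.05` at the same `alpha`. How exactly a conversion
error rate should gate a per-site Fisher test is underdetermined; this
screen is the simplest reading consistent with calibrating against an
external standard, and it is applied per sample with sites failing in both
samples never tested. The tested universe is the intersection of covered
sites; sites covered in only one sample are reported and excluded.

`c_count_summary()` expresses methylated and unmethylated CpG observations
as percentages of **all sequenced bases** (the denominator choice follows
the C-count definition used by genome-scale methylation summaries; covered
bases would be the alternative) plus their ratio.
`methylation_bin_profile()` bins sites by methylation percentage into
`[0,10), …, [90,100]` — the last bin closed — and reports each bin's share of
methylated observations.

`annotate_sites()` labels sites genic / proximal / intergenic with a 5 kb
proximity threshold measured to the nearest gene boundary base under
half-open arithmetic (boundary inclusive); a two-way label collapsing genic
and proximal reproduces the dichotomy "intergenic = farther than 5 kb".
`extract_flanks()` emits fixed 201 b (±100) windows, greedily skipping any
window that overlaps the previously emitted one — fixed-width windows are
preserved in preference to merging.

### Amplicon track

`locate_amplicon()` places the forward primer and the reverse complement of
the reverse primer on the consensus, trying both orientations (repeat
consensus amplicons are sometimes printed in reverse-primer orientation —
the shipped LINE-1 consensus is; the locator reports `orientation = "-"` and
maps coordinates back). In bisulfite space, primer matching is asymmetric:
a primer C at a primer-CpG must match C (designed against methylated
template); a primer C elsewhere also matches T; a primer T also matches a
convertible (non-CpG) consensus C; and on the reverse site a primer A
matches a consensus G outside a CpG dyad (bottom-strand conversion seen from
the top). The reverse site may overhang the consensus end by up to
`max_overhang = 2` bases, each counted as a mismatch — the shipped Alu
consensus is one base shorter than its nominal amplicon and needs exactly
this allowance. Fewest mismatches wins; ties go to the leftmost placement
and then to the printed orientation; more than `max_mismatches = 3` per
primer is "primer not found".

`semi_global_align()` is an affine-gap dynamic program (match +1, mismatch
−1, gap open −2, extension −0.5; a k-gap costs `open + k·ext`) with free end
gaps on the consensus only, so a read aligns end-to-end to a consensus
stretch; identity is matches over all aligned columns, gaps included. It is
used for QC/identity reporting — per-read dinucleotide counting deliberately
uses reads as sequenced, since the per-molecule methylation measure is
defined on the read, not on a consensus projection.

`per_read_dinucleotide()` counts CG and TG over all overlapping windows and
divides by $L-1$ windows. The alternative normalisation
$100\,n_{CG}/(n_{CG}+n_{TG})$ is reported alongside
(`cg_pct_of_cgtg`) since the per-sequence "frequency" could be read either
way; the per-length reading is the primary measure. Conversion turns CpG
into TpG, so $n_{CG}+n_{TG}$ at CpG positions is conserved for full-length
reads — a generator-verified invariant — and CpG and TpG frequencies
correlate negatively across reads, attenuated by native (non-conversion)
TpG content.

`tail_shift_test()` categorises per-read values by tail thresholds (two-tail
`low/high` or a single `split`) and tests the treated sample's counts
against expected counts from the control proportions by chi-square goodness
of fit. Because the control proportions are treated as known, the test is
calibrated only when the control (calibration) sample is deep relative to
the treated sample; with equal sizes the null rejection rate inflates by
roughly $(1 + n_t/n_c)$ on the statistic's scale. The type-I simulations in
the test suite therefore use a control about five times the treated size.

### Mixture detection

`gaussian_em()` fits a k-component univariate Gaussian mixture by EM
(k-means-style seeded initialisations, best of 10 restarts, relative
log-likelihood tolerance $10^{-8}$, at most 500 iterations, component SDs
floored at $10^{-4}$ of the data range; the log-likelihood trace is returned
and is non-decreasing). `fit_methylation_mixture()` compares the one- and
two-component fits. The default selector fits both model curves to the
relative-frequency histogram by least squares and applies the nested-model
extra-sum-of-squares F test — best-curve-fit selection on a frequency plot.
This choice is load-bearing: per-read CG% is quantised (integer CG counts
over a shared read length put much of the mass on exact lattice values), and
an information criterion on the raw values will happily pay for a
near-zero-SD component sitting on one lattice spike, selecting two
components on clearly unimodal data. The histogram F test is immune to the
lattice and separates the regimes by orders of magnitude; because its binned
residuals are correlated, its nominal calibration is optimistic, so the
two-component verdict requires strong evidence (`f_alpha = 0.001` —
well-separated mixtures land many orders of magnitude below it). AICc on raw
values remains available (`selection = "aicc"`) and is appropriate for
continuous input. Fewer than 20 values force k = 1; zero variance forces
k = 1 with a floored SD and a warning.

## Study conditions encoded in the default configuration

One configuration (`default_config()`) drives both pipelines; every applied
threshold is echoed into the run summary so no default is silent.

| parameter | default | meaning |
|---|---|---|
| `qc$under_conversion` | 0.05 | spike-in conversion failure rate; 95% efficiency |
| `global$p_cpg` | 0.75 → 0.85 | control/treated CpG methylation probability |
| `global$p_chg`, `p_chh` | 0.005 | residual non-CpG methylation |
| `global$alpha` | 0.01 | per-site Fisher and screen threshold |
| `global$conversion_error` | 0.05 | retention probability in the reality screen |
| `global$annotation_distance` | 5000 b | genic-proximity dichotomy |
| `global$flank_radius` | 100 b | 201 b flank windows |
| `amplicon$min_len` | 100 b | amplicon read filter |
| `amplicon$alu` | 1 comp. at 0.65 vs 0.3/0.7 mix at 0.35/0.9 | unimodal control, bidirectional treated |
| `amplicon$line1` | 0.45 vs 0.75 | mean shift, no bidirectionality |
| `amplicon$alu$tails` | {3.0, 6.5} % | low/high tails for the synthetic Alu scale |
| `amplicon$line1$tails` | split 1.5 % | single split for the synthetic LINE-1 scale |

The tail thresholds deserve a note. On real repeat data the corresponding
thresholds sit near 8–12% (Alu) and 7.5% (LINE-1) of dinucleotide windows,
reflecting the CpG density of real repeat copies. The shipped consensus
amplicons bound what synthetic reads can reach: the 219 b Alu consensus
carries 16 CpGs (at most $16/218 = 7.3\%$) and the 429 b LINE-1 consensus 10
(at most 2.3%). The synthetic thresholds were therefore derived once, before
any testing, from the closed-form read-level means
$100 \cdot n_{CpG}\,(\ell + (1-\ell)u)/(L-1)$ at the configured mixture
levels $\ell$: the Alu control centres near 4.9% with SD ≈ 1, giving tails at
3.0/6.5; the LINE-1 arms centre near 1.1% and 1.8%, giving a split at 1.5.
`tail_shift_test()` itself defaults to the real-data thresholds {8, 12}.

## Problem sizes

The test suite and acceptance checks run at desk scale, chosen so each
stochastic check sits at least ~3 standard errors inside its tolerance:
20–50 kb references, 6,000–12,000 reads of 100 b (≈ 20–40× cytosine
coverage), 1,500 amplicon molecules per arm, 20-seed repetitions for seed
sweeps, 300 replicates for type-I rates, and 10,000 reads for the
conversion-efficiency recovery (SE of the efficiency ≈ 0.04 percentage
points against a ±0.5 tolerance).

## Known limitations

* All amplicon reads derive from one consensus template; real repeat copies
  differ in sequence and CpG complement, which both widens the per-read
  distribution and shifts its scale.
* The reality screen's combination of conversion error with per-site Fisher
  testing is one defensible reading of an underdocumented procedure; other
  gates (e.g. subtracting expected error counts) would flag slightly
  different site sets.
* The goodness-of-fit form of the tail-shift test conditions on the control
  proportions; with shallow controls its p-values are optimistic (see
  above).
* Paired-end simulation models mate geometry only (no insert-size
  distribution, no overlapping-mate double counting guard beyond one count
  per read).
* `simulate_genomic_reads()`'s frozen-genome mode is intentionally
  single-molecule; use `simulate_methylome_reads()` whenever per-site
  fractions matter.
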