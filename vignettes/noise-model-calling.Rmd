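---
title: "Calling low-frequency cfDNA mutations with a robust amplicon noise model"
author: "amplicall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling low-frequency cfDNA mutations with a robust amplicon noise model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplicall)
```

## The problem

Circulating tumor DNA is a small fraction of the cell-free DNA in blood
plasma, so the mutations that matter clinically often sit at allele
frequencies of a percent or less. Deep multiplex amplicon sequencing can
reach the required depth cheaply, but at those frequencies the signal
competes directly with PCR and sequencing errors, which occur at
comparable rates. `amplicall` implements an end-to-end workflow for this
setting: quality trimming, panel-aware read assignment, pileup counting,
a per-amplicon robust noise model that separates mutations from error,
catalogue-based annotation, and longitudinal tracking across serial
samples of a patient.

## The noise model

Every non-reference allele observed at a position of an amplicon in a
sample is one *observation* with allele frequency $a = \text{count} /
\text{depth}$. Per amplicon, observations across all samples are
modelled on the logit scale:

$$\log\frac{a}{1-a} \;=\; \beta_0 + \beta_1 X_1 + \beta_2 X_2 + \epsilon$$

with $X_1$ the 1-based position on the amplicon and $X_2$ the sample.
The model rests on three assumptions about deep amplicon data:

1. the overwhelming majority of observations are PCR or sequencing
   errors, not mutations;
2. PCR error is, on average, position-stationary up to a smooth trend
   along the amplicon (captured by $\beta_1$);
3. sequencing error at a given position is equally likely in every
   sample, up to a sample-level offset (captured by $\beta_2$).

Because true mutations violate assumption 1 locally, the fit must not
chase them: the plane is estimated by a Huber M-estimator (tuning
constant 1.345) via iteratively reweighted least squares, so outlying
observations are down-weighted and the fitted surface describes the
*noise*. A mutation is then an observation whose residual $\epsilon$
exceeds the median of all residuals by at least 3 standard deviations
*and* whose allele frequency is at least 0.5% — the second rule encodes
the clinical reporting floor of the assay.

### Encoding the sample term

A scalar encoding of "which sample" would be meaningless, so $X_2$ is a
reference-coded factor: one offset per non-reference sample. With a
single sample the term drops out and the model degenerates gracefully to
intercept + position. A design with fewer observations than free
parameters is flagged unfittable and its observations are rejected with
reason `insufficient-data` rather than silently fitted.

### Pooled residual summary

"The median of all residuals" admits two readings: per amplicon, or
pooled over the panel. `amplicall` pools by default
(`pool_residuals = TRUE`): the noise assumptions above are panel-wide
properties of the chemistry, not of one amplicon, and pooling
stabilises the scale estimate for amplicons that yield few
observations. The per-amplicon reading remains available behind the
flag. Similarly, "standard deviations" is taken literally as the
unweighted sample SD of the residual vector; a MAD-based robust scale
is available via `robust_sd = TRUE`.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `end_q` | 15 | phred | leading/trailing base trim threshold |
| `window`, `window_q` | 4, 15 | bases, phred | sliding-window cut (mean quality) |
| `min_len` | 70 | bases | minimum surviving read length |
| `max_edit_frac` | 0.10 | — | edit-distance budget for assignment |
| `min_margin` | 2 | edits | best vs second-best amplicon gap (ambiguity filter) |
| `min_base_q` | 30 | phred | bases below this count neither as allele nor as depth |
| `min_depth` | 100 | reads | columns shallower than this yield no observations: their logit AFs are dominated by discreteness |
| `sd_threshold` | 3 | residual SDs | mutation call rule |
| `min_af` | 0.005 | fraction | clinical reporting floor |

The trimming thresholds, base-quality floor, residual rule and AF floor
are the published operating point of the assay; the assignment margin
replaces a general-purpose mapping-quality cutoff (see below) and the
depth floor is this package's own numerical guard.

### Read assignment instead of genome mapping

The original pipeline maps reads to the whole genome with `bwa mem` and
discards MAPQ < 13. With a known panel of a few dozen amplicons, the
quantity MAPQ measures — ambiguity of placement — reduces to a direct
comparison: a read is assigned to the amplicon with the smallest edit
distance (best substring match, both strands, seeded by 16-mers) only
if that distance is within 10% of the read length and the second-best
amplicon is at least 2 edits worse. The equivalence to a MAPQ cutoff is
approximate by construction; users who prefer the original mapping
stage can bypass this module entirely by supplying a bam-readcount
style per-position count table (`counts:` in the config).

### Primer masking

Primer-binding bases are synthetic oligonucleotide and cannot carry a
template variant, so the first and last `fwd/rev_primer_len` offsets of
each amplicon are excluded from counting by default
(`mask_primers = TRUE`). Whether the original analysis did this is not
documented; masking is configurable for that reason.

## Numerical choices

* **Logit at the boundary.** `logit_af()` clamps $a$ to at most
  $(\text{depth}-0.5)/\text{depth}$ so homozygous columns stay finite;
  no pseudocounts are used anywhere else. Zero-count positions are not
  observations by definition.
* **IRLS.** OLS start; scale re-estimated each iteration as
  MAD(residuals)/0.6745 with a $10^{-8}$ floor; convergence when the
  largest coefficient change is below $10^{-8}$, capped at 50
  iterations. Rank-deficient designs are reduced by QR pivoting with
  zero coefficients for aliased columns. Tukey bisquare is available
  behind `loss = "bisquare"`.
* **Standard errors.** The M-estimator covariance uses Huber's
  correction ($\sum\psi^2$ over $(\sum\psi')^2$ with the small-sample
  factor), not the naive weighted-LS formula, which is anti-conservative.
* **Residual SD floor.** Zero residual variance (e.g. an exact-plane
  toy input) floors the SD at $10^{-8}$ instead of dividing by zero.
* **Indels.** The count-table route accepts composite allele keys
  (`+SEQ`, `-N`) at their left-anchored position; the internal FASTQ
  route places reads ungapped and counts substitutions only, which is
  exact for the substitution-dominated error process the panel
  chemistry produces.
* **Minus-strand amplicons.** Offsets always count along the amplicon's
  own 5'→3' sequence; all reported alleles are converted to the genomic
  plus strand, so catalogue matching is strand-free.

## The synthetic-data module

The generators produce exactly the structure the model assumes: per
(sample, amplicon) depths drawn negative-binomially (mean 7500, size 2,
spreading the 1st–99th percentiles over roughly 500–21000, the spread
of a real multiplex run — a fixed depth can be requested instead), and
per-position error counts drawn binomially with

$$p = \mathrm{logit}^{-1}\!\big(\mathrm{logit}(b) + \beta_1^{true}\,
\text{offset} + s_{\text{sample}} + \mathcal N(0, \sigma_\epsilon^2)\big)$$

with defaults $b = 0.001$ (the order of post-Q30 substitution error),
$\beta_1^{true} = 0.005$ per base, $s \sim \mathcal N(0, 0.2^2)$,
$\sigma_\epsilon = 0.3$. Injected variants add independent binomial
counts at their true mutant allele fraction. The dilution-series
generator encodes the monoallelic arithmetic of mixing two cell-line
genotypes: at mix fraction $f$ the minor genotype's variants sit at MAF
$f/2$. Serial cohorts draw recurrent mutations (all time points) from a
log-normal centred on 2.25% MAF and sporadic ones (one time point) from
a lower distribution, both truncated to the reportable range; the
hotspot catalogue places its entries mid-amplicon, where primer design
puts them in the real assay.

What the generators do **not** emulate: UMI family structure,
polymerase-specific error spectra (the substitution bias is a generic
2:1 transition preference), primer-dimer artifacts, indel errors, and
correlated errors at homopolymers. A green test suite therefore shows
the pipeline is correct *under the model's own assumptions*; it cannot
certify performance on chemistry whose noise violates them.

### What the model's own noise admits at the detection limit

Worth stating plainly, because it bounds what simulation can show: at
depth 7500 and base error rate 0.001, an error position carries ~10
reads, so the binomial contribution to the logit residual (~0.36 SD)
adds to the prescribed observation noise (0.3), giving a pooled
residual SD around 0.5. A variant at 0.625% MAF then sits near $z
\approx 3.2$ against the median + 3 SD rule — detectable in most runs,
but not in ≥95% of them. The package's acceptance checks report this
honestly: the dilution series typically certifies reliable detection
one step higher (1.25% MAF) under these simulation conditions.

## Longitudinal definitions

A mutation key (chrom, pos, ref, alt) present in ≥2 samples of a
patient is *recurrent* — not necessarily consecutive samples, so a
mutation seen at time points 1 and 3 of 4 is recurrent; present in
exactly one sample it is *sporadic*. Single-sample patients get an
explicit unavailable sentinel rather than a forced label. Replicate
concordance is computed over mutations detected in both replicates by
default (how replicate scatter is usually plotted); a union mode
scoring absent calls as AF 0 is available. Recurrent-vs-sporadic AF
comparisons use the two-sample Wilcoxon rank-sum test.

## Problem sizes in the test suite

The suite simulates at the assay's own scale where it matters (43
amplicons, depth ~7500, 20-seed dilution batches, 100-seed
recovery/false-positive batches) and at toy scale (3–10 amplicons) for
unit semantics; a full run takes a few minutes on one core. These sizes
are the package's chosen trade-off between statistical resolution and a
test suite that runs everywhere.

## Known limitations

* No UMI-based error suppression; counting is read-based.
* No copy-number or fusion detection — the amplicon design cannot see
  them.
* No multiple-testing correction on the residual rule (none is applied
  by design; the catalogue filter is the specificity backstop).
* The assignment margin rule is an approximate, panel-aware stand-in
  for a mapping-quality cutoff; pathological panels with near-duplicate
  amplicons will push reads into the unassigned bin (by design).
* Annotation requires exact allele matches; a catalogue that records
  only positions will reject allele variants at shared hotspots.
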