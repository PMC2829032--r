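---
title: "Methods: the proBDNF/totBDNF stress biomarker and its companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the proBDNF/totBDNF stress biomarker and its companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probdnf)
```

## The biomarker model

Brain-derived neurotrophic factor (BDNF) is produced as a precursor
(proBDNF) and proteolytically processed to the mature growth factor. In the
teleost brain, acute stress shifts the pro/mature balance towards the
precursor, and the shift is large enough to classify individual animals.
The score is the precursor's share of total BDNF measured by Western-blot
densitometry:

$$\mathrm{score} = 100 \cdot \frac{\mathrm{proBDNF}}{\mathrm{proBDNF} + \mathrm{matBDNF}} \quad [\%]$$

Two properties make this a robust densitometry readout. First, it is a
ratio of two bands from the same lane, so any multiplicative lane effect
(loading, transfer, exposure) cancels exactly; normalising both bands by the
α-tubulin loading control leaves the score unchanged, which
`run_biomarker_pipeline()` exploits by scoring raw bands directly. Second,
it is bounded in [0, 100] and interpretable as a percentage.

### Threshold classification

An animal is called **positive** when its score *strictly* exceeds

$$T = \bar{x}_{\mathrm{ctl}} + k\, s_{\mathrm{ctl}},$$

the control mean plus $k$ standard deviations ($k = 1$ by default; the
`sd_mult` argument exposes it). Choices worth stating:

- **Sample SD** ($n-1$ denominator). Control groups are small (default 15
  animals), so the sample statistic is the conventional estimator.
- **Strict inequality, ties negative.** A score exactly at $T$ is negative;
  positivity means exceeding one SD, not reaching it.
- **One-sided rule.** Only elevated proBDNF is a positive call; the mature
  fraction is the complement (the two always sum to 100), so a depressed
  mature fraction is the same event viewed from the other side.
- **Per-tissue thresholds.** Brain and liver cohorts are never pooled; the
  pipeline refuses mixed-tissue input.

With the default control-brain population (mean 40%, SD 3 percentage
points), the cutoff sits at 43%: an animal scoring below 43% is, under this
test, certainly not stressed.

### Diagnostic performance

From the counts $a$ (stressed, positive), $b$ (control, positive), $c$
(stressed, negative), $d$ (control, negative):

| metric | formula |
|---|---|
| sensitivity | $100\,a/(a+c)$ |
| specificity | $100\,d/(d+b)$ |
| PPV | $100\,a/(a+b)$ |
| NPV | $100\,d/(c+d)$ |

A metric with a zero denominator is reported as **undefined** (`NA`), never
as 0, so degenerate cohorts (e.g. no positive calls) do not silently produce
misleading zeros. Display values are rounded to integer percent, half away
from zero, so 86.67 displays as 87 and 88.24 as 88; the exact values are
kept alongside. Note that whenever $c = 0$ and $d > 0$, sensitivity and NPV
are both 100 regardless of $b$ — the structure of a perfect exclusion test.

PPV depends on prevalence; the package reports the cohort-conditional value
and deliberately does not attempt a Bayesian prevalence adjustment, nor any
ROC optimisation of the multiplier $k$.

### Group statistics

The control-vs-stressed comparison uses the two-tailed homoscedastic
(pooled-variance) Student's t-test and one-way ANOVA; for two groups
$F = t^2$, an identity the test suite checks to $10^{-9}$. The Holm–Šidák
post-hoc (`holm_sidak_posthoc()`) applies Šidák-corrected pairwise
equal-variance t-tests in Holm step-down order; with two groups it reduces
to the plain t-test. Degenerate inputs (zero pooled or within-group
variance) raise classed errors rather than returning infinite statistics.

## The semiquantitative RT-PCR stage

Each transcript-variant band is normalised by the same lane's β-actin band,
then per variant the stressed/control **ratio of group means** of the
normalised values is computed and the group difference tested with the
homoscedastic t-test. The order matters and is normalise-then-average. Calls
are per-variant at α = 0.05 with **no multiple-testing correction by
default** — six variants are each reported at their nominal level, matching
how such panels are conventionally read; `correct = "holm"` is available
when familywise control is wanted. Direction is `"down"`/`"up"` for
significant ratios below/above 1 and `"unchanged"` otherwise; stars map
p < 0.05 to `*` and p < 0.01 to `**`.

## Gene-model conventions

- **Coordinates are 1-based inclusive** throughout, so
  `length = end − start + 1`; the shipped seabass BDNF fixture validates
  this convention (every exon length matches its printed value; the six
  exons span 14,810 bp ≈ 15 kb). GFF3 uses the same convention natively, so
  `read_gene_model_gff3()`/`write_gene_model_gff3()` round-trip without
  coordinate shifts.
- **Plus strand only.** The published coordinate set is single-stranded;
  motif scans report `+` hits only.
- **Splice validation checks the two intronic nucleotides only** (GT donor,
  AG acceptor). The longer genomic contexts are informative annotation, not
  part of the rule; the terminal exon has no donor and the initial exon no
  acceptor.
- **uATG scanning** walks codon-by-codon upstream from the main start:
  a candidate must be an ATG in frame (distance divisible by 3) with no
  in-frame stop codon in between. The scanner reports candidate extended
  N-termini only; whether a candidate yields a functional signal peptide is
  a prediction problem outside this package's scope, so signal-peptide
  length is always an explicit input elsewhere.
- **CRE scanning** is an exact Hamming scan of the canonical octamer
  `TGACGTCA` with at most 0–2 mismatches (default 1, which admits the
  near-consensus `TGAAGTCA`). Hits are ordered by position; the test suite
  cross-checks the scanner against both a naive enumeration oracle and
  `Biostrings::matchPattern()`.
- Nucleotide input is case-insensitive; characters outside `ACGTN` are
  rejected at parse time.

## Protein processing

`partition_precursor()` cuts a precursor into signal / propeptide / mature
segments from two inputs — the signal length and the 1-based mature start —
and guarantees the segments reconcatenate to the input. The seabass-style
organisation is 20 + 150 + 129 residues, with the mature start immediately
after the furin site. Motif scanners use leftmost-match tie-breaking:
`find_furin_site()` matches the minimal convertase consensus `R-X-[KR]-R`
(cleaving after the final arginine; the minimal motif is used because only
furin processing, not a specific extended motif, is established for this
substrate), and `find_ski1_site()` matches `RGLT` (cleaving after the
threonine). `RGLT` absence is the biologically expected outcome for teleost
proBDNF — fish lack the SKI-1 site that generates the mammalian 28 kDa
intermediate, leaving a two-band (pro + mature) system — so `NULL` from
`find_ski1_site()` is a result, not an error.

Molecular weights use **average** (not monoisotopic) residue masses plus one
water (18.0153 Da), reported in kDa, the convention under which calculated
masses are compared with gel-apparent ones; one decimal is the conventional
reporting precision. The test fixture for the full precursor is a
**synthetic** 299-residue sequence with the documented domain structure (it
is labelled as such); the deposited seabass transcript is not bundled, so
sequence-specific masses (e.g. the mature domain's 13.3 kDa) can only be
recomputed by users who supply that sequence themselves.

## What the synthetic-data generator emulates

`generate_densitometry_cohort()` draws each animal's latent pro-fraction
from its group's normal distribution truncated to (0.5, 99.5) (rejection
sampling; truncation keeps scores on the reporting scale and avoids
degenerate lanes) and converts it to three band intensities sharing one
log-normal lane factor with unit mean. Defaults, chosen once as the study
conditions the analysis assumes:

| parameter | brain | liver | rationale |
|---|---|---|---|
| control mean (%) | 40 | 42 | reported control means |
| control SD (pp) | 3 | 4 | brain: mean + 1SD must sit at the 43% cutoff, so SD = 43 − 40; liver: comparable spread, no cutoff constraint |
| stressed mean (%) | 52 | 42 | brain: far enough above 43 that all 15 stressed animals exceed it with probability > 0.99; liver: no stress effect |
| stressed SD (pp) | 2.5 | 4 | see above |
| n per group | 15 | 15 | cohort size of the densitometry design |
| lane-noise CV | 0.2 | 0.2 | typical blot-to-blot loading variation; makes normalisation meaningful but cancels from the score |

Because the tubulin band carries the same lane factor, the generator makes
loading-control normalisation *testable*: the score from raw bands equals
the score from normalised bands exactly, and the latent fraction is
recoverable from the bands to floating-point precision.

`generate_expression_panel()` uses the same multiplicative structure:
biological noise is log-normal with CV 0.15 (a generator decision — no
per-sample fluorescence values exist to calibrate against; 0.15 gives
essentially full power at n = 5 for a ×0.6 effect while keeping the null
type-I rate at its nominal level, which the acceptance suite verifies by
resimulation), and a second log-normal factor models template amount,
cancelled by β-actin normalisation. The default multipliers are 1 for
variants 1β (`"1beta"` in code — ASCII labels are used throughout), 1a, 1b
and the coding exon 2, and 0.6 for 1c and 1d, encoding down-regulation of
the second promoter cluster under acute stress.

`generate_test_locus()` builds a random genome around specified exons with
correct GT…AG intron boundaries and plants motifs at known positions,
recording an answer key; accidental exact copies of the CRE octamer in the
random fill are mutated away so exact scans recover the key exactly.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: gel-image artefacts (saturation, background,
smearing), duplicate-lane technical replication (the duplicate measurements
of the original design are collapsed to one value per animal), antibody
cross-reactivity, non-normal score distributions, and any correlation
between an animal's brain and liver measurements. Determinism is per
configuration: the same config and seed give byte-identical tables, and
generation does not disturb the caller's RNG stream.

## Problem sizes and numerical tolerances

The test suite simulates at sizes chosen to make Monte-Carlo error small
relative to the quantity checked: 1,000 animals for generator means
(±0.5 pp checks), 10,000 for the ~16% null exceedance of the mean + 1SD
rule (normal-theory oracle P(Z > 1) ≈ 0.159), 1,000 resimulated null panels
for type-I calibration (binomial 3·SE ≈ 0.021 around 0.05), and 1,000
random small cohorts for the confusion-matrix oracle. Exact identities
(score recovery, F = t², partition reconcatenation) are checked to between
1e-9 and 1e-12.

## Known limitations

- Thresholds assume approximately normal control scores; heavy-tailed
  controls would inflate the false-positive rate beyond the ~16% expected
  for a 1SD rule under the null.
- PPV/NPV are prevalence-conditional on the cohort composition.
- The gene-model tools validate and assemble a *given* exon structure; they
  do not discover exons (alignment-based discovery is out of scope).
- Signal peptides are not predicted; partitioning requires the signal
  length as input.
- The CRE scan covers the explicit consensus only, not general
  transcription-factor binding prediction.
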