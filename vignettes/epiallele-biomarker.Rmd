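---
title: "Epiallele analysis of a targeted bisulfite amplicon: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epiallele analysis of a targeted bisulfite amplicon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epihap)
```

## The assay and its read-out

`epihap` analyses a single targeted bisulfite amplicon — a 126 bp stretch
of the ONECUT2 gene body (chr18:55107668–55107793) carrying K = 8 CpG
sites — at single-molecule resolution. Bisulfite treatment deaminates
unmethylated cytosines to uracil (sequenced as T) while methylated CpG
cytosines stay C, so each sequencing read reports the joint methylation
state of all 8 CpGs on one DNA strand: an *epiallele* or methylation
haplotype. The analysis deliberately discards positional information and
bins each strand by *how many* of its 8 sites are methylated, giving a
9-bin spectrum per sample. The biomarker is the fraction of strands in
the top two bins — strands with 7 or 8 methylated sites. The premise,
which the package's group-comparison machinery quantifies, is that
near-fully methylated strands separate tumor from adjacent-normal tissue
better than any single CpG site does: single-site beta values mix signal
from all strand classes, while the 7–8 bin isolates the molecule
population that is specific to the tumor state.

Gene-body methylation at this locus is *positively* associated with
expression — the opposite of the canonical promoter relationship — which
is why the package pairs the methylation read-out with qPCR expression
quantification and an association model rather than treating methylation
as a silencing proxy.

## The packaged amplicon is a synthetic stand-in

The published assay defines the locus by coordinates and primers but does
not print the reference sequence. `default_amplicon()` therefore carries
a *synthetic* 126 bp reference, constructed to satisfy every constraint
the assay states: it is consistent with both printed primers before
bisulfite conversion, each primer's degenerate base (`Y` forward, `R`
reverse) sits on a CpG cytosine as the primer design requires, it
contains exactly 8 CpG dinucleotides, and it carries 10 non-CpG cytosines
so the conversion-rate filter has signal to work with. Probe ids
cg10835584 and cg24771804 are attached to interior sites 4 and 6; the
true site identities are not public, and nothing downstream depends on
the assignment. Analyses of real data should supply their own
`amplicon_spec()` with the genuine reference sequence.

## Read classification

`classify_read()` mirrors a noise-eliminating amplicon workflow with
five outcomes, applied in order:

1. **dimer** — reads shorter than `min_read_length` (default 40 nt) are
   primer-dimer artifacts.
2. **off_target** — the read is compared position-by-position to the
   fully converted reference with every reference cytosine position
   treated as a wildcard (C and T both acceptable there, because a
   cytosine's read base depends on its unknown methylation/conversion
   state); a mismatch fraction above `max_mismatch_frac` (default 0.10)
   over the non-wildcard positions marks mispriming products.
3. **low_conversion** — the bisulfite conversion rate is estimated over
   non-CpG reference cytosines (T = converted, C = escaped); reads below
   `min_conversion_rate` (default 0.95) would inflate methylation calls
   through conversion failure and are removed.
4. **ambiguous_cpg** — any CpG position reading neither C nor T is a
   no-call; such reads are excluded entirely rather than partially
   counted, which keeps the "x of 8 methylated sites" spectrum defined on
   complete strands only.
5. **retained** — everything else, with the per-site M/U pattern and its
   methylated-site count.

Thresholds are deliberate stand-ins: the vendor workflow the assay used
does not disclose its criteria, so the defaults here are conventional
bisulfite QC values, all exposed in `qc_thresholds()`.

Two design points deserve explanation. First, *primers are matched but
not trimmed*: in this assay two of the eight CpGs fall inside
primer-binding regions (that is why the primers carry degenerate bases),
so trimming would make those sites uncallable; the wildcard comparison
subsumes primer degeneracy instead. Second, *orientation handling*:
bisulfite conversion destroys strand complementarity, so a bottom-strand
read of the PCR product is the reverse complement of the converted top
strand — not a molecule matching the reverse-complement reference. Both
orientations are therefore evaluated by comparing the read and its
reverse complement against the forward converted reference, keeping the
lower-mismatch orientation. `reverse_strand_variant()` is still provided
for the genomic reverse strand's own coordinate system (site i maps to
K+1−i) and is tested as an involution.

Quality scores are read but unused by default; there is a `min_phred`
hook, off by default, since the workflow being modelled states no
base-quality rule.

## The synthetic cohort generator

`simulate_cohort()` provides the statistical structure the analysis
assumes, so every downstream stage is testable without patient data:

- Per-core highly-methylated fraction h ~ Beta(2, 38) for adjacent-normal
  cores (mean 0.05) and Beta(8, 12) for cancer cores (mean 0.40); h is
  split evenly between the 7- and 8-site bins and the remainder spread
  geometrically (ratio 0.5) over bins 0–6, so background tissue is
  dominated by unmethylated strands. These effect sizes are
  configuration, not estimates — the real-cohort AUCs cannot be recovered
  from published summaries, and with these defaults the analytic
  tumor-vs-normal AUC, P(h_cancer > h_normal) ≈ 0.9997, is *stronger*
  than the real-assay separation; the end-to-end checks compare the
  pipeline against the generating laws, not against published values.
- Default 3,000 reads per core (the assay context is ~1000× coverage of
  the amplicon, with observed per-core depths of a few thousand);
  conversion failure 0.01, inappropriate conversion of methylated
  cytosines 0.01, per-base substitution error 0.005, 2% dimers, 3%
  off-target reads. Reads are full amplicon length: there is no
  partial-coverage, PCR-duplicate, or strand-bias model.
- Aggressiveness labels (Gleason group 3–5, T3, EPE, SV, LN) are
  Bernoulli with logistic probability plogis(8·(h − c)), with midpoints c
  rising from 0.35 (Gleason) to 0.50 (LN) so rarer features demand higher
  methylation; PSA recurrence is independent of h, matching the null
  recurrence association the assay observed.
- Relative expression is (0.25 + 4.75·h)·exp(N(0, 0.3²)) — affine in the
  true fraction with multiplicative lognormal noise — and feeds the
  simulated qPCR plate.

Every generator is byte-identical under a fixed seed, and a truth table
records each read's pattern and contaminant status, each sample's
mixture, fraction, and expression.

What passing tests on this cohort do **not** show: robustness to
partial-length reads, within-sample strand bias, batch effects across
sequencing runs, or clinical-covariate structure beyond the label–score
link. The generator validates the *analysis*, not the assay chemistry.

## qPCR quantification

Standard curves are ordinary least-squares fits of Cq on log10(input)
over a serial dilution (≥ 3 levels required), with efficiency
E = (10^(−1/slope) − 1)·100% and absolute quantity
Q = 10^((Cq − intercept)/slope). Target quantities are normalised to
HPRT1 *per replicate* and then averaged — the summarisation order is
ambiguous in the source protocol ("replicates summarised as mean ± SD"),
and quantities-first was chosen because it keeps each replicate a
complete, self-normalised observation; averaging Cq first is the obvious
alternative and differs only at second order in the replicate noise.
Replicates with reference Cq above 35 (or no amplification) are dropped;
a core failing in all replicates is flagged `excluded` and omitted from
the association, and relative expression is the normalised value scaled
to the LNCaP calibrator (≡ 1). No cutoff is applied to the target gene;
an undetected target well contributes quantity 0 with a flag. Control
wells (no-template, no-RT) amplifying before cycle 40 fail the plate.
Curves are fitted per plate, reflecting run-to-run slope variation.

## COBRA digestion model

The modified COBRA assay digests bisulfite PCR amplicons with BstUI
(CGCG, site cg10835584) or BsiWI (CGTACG, cg24771804) and re-amplifies:
both recognition sequences survive bisulfite conversion only when their
CpG cytosines were methylated, so cutting reports methylation. The
source protocol never writes the digestion-rate formula; this module
states its model explicitly: under exponential amplification with
per-cycle factor f (2.0 ideal, or 1 + E/100 from a fitted curve), the
intact fraction is f^−(Cq_digested − Cq_undigested), clamped to (0, 1],
and methylation level = cut fraction = 1 − intact. A digested Cq more
than 0.5 cycles *below* the undigested Cq is flagged as assay
inconsistency rather than silently clamped. Replicate rows are converted
per replicate and then averaged. Relative methylation across a treatment
course is the ratio of cut fractions, which reproduces the
dip-and-recover trajectory of a demethylating-agent experiment.

## Methylation–expression association

Both variables are Yeo-Johnson transformed — the power family defined on
all reals, with the log branches as the λ→0 and λ→2 limits — with λ
fitted *independently* per variable by maximising the Gaussian profile
log-likelihood over [−5, 5] (tolerance 1e-6; a constant input returns
λ = 1 with a flag). On bounded methylation fractions the likelihood can
maximise at the interval boundary; this is accepted rather than widened,
since the transformation remains monotone and the fit is unaffected in
practice. The regressor defaults to the per-core *mean* methylation
level (mean of methylated-sites/8 over retained reads), with the 7–8
score as a config alternative; "robust linear regression" is implemented
as Huber M-estimation (tuning constant 1.345, MAD scale, IRLS to 1e-8 or
100 iterations), with Tukey's bisquare behind a switch. The reported R²
is the squared Pearson correlation between fitted and observed
transformed responses — the source analysis does not say which R²
definition it used, and squared correlation is the definition that stays
meaningful under M-estimation. No p-value is attached to the robust
slope by design.

## Statistical conventions

Group comparisons use the Mann-Whitney U test in pair-counting form
(ties count ½), two-sided throughout; p-values are exact for n1+n2 ≤ 16
without ties and otherwise use the normal approximation with tie and
continuity corrections. AUC = U/(n1·n2), identical to the trapezoid area
under the threshold-sweep ROC — the identity is asserted in the tests.
Per-bin spectrum comparisons are reported raw (Benjamini-Hochberg is
available but off by default, matching the primary analysis); the
7-and-8 bins are pooled for the headline score, with per-bin tests
provided alongside since the exact grouping is not fixed by the source.
A core needs 20 retained reads to be scored (configurable) — below the
smallest observed real-core depth, so only genuinely failed cores are
dropped.

## Problem sizes used in the checks

The packaged verification suite runs the complete pipeline on the
default synthetic study: 70 normal + 35 cancer cores at 3,000 reads per
core (about 315,000 reads classified end-to-end), exhaustive recovery of
all 256 patterns, a 5,000-read spectrum-recovery check, 10,000
null cohorts for Mann-Whitney calibration, and 100 cohort-level
replicates for the association slope sign. These sizes were chosen so
the whole suite completes in a few minutes on one core while leaving the
statistical checks enough resolution (binomial error ≤ 0.01 per spectrum
bin, calibration error ± 0.005).

## Known limitations

- Single amplicon only; no multi-locus panels, no general bisulfite
  alignment, no SAM/BAM.
- The packaged reference sequence is synthetic (see above); real-data use
  requires the genuine sequence.
- No AUC confidence intervals, survival analysis, or multivariable
  adjustment — the analysis surface is deliberately that of the source
  study.
- The simulator's noise model is per-base i.i.d.; structured errors
  (homopolymer slips, strand-specific damage) are out of scope.
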