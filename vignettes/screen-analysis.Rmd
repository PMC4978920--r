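---
title: "Scoring arrayed RNAi screens of p53-dependent transcription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring arrayed RNAi screens of p53-dependent transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53screen)
```

## The experimental design this package models

An arrayed siRNA screen plates one gene-specific siRNA pool per well and asks,
for each knockdown, whether the transcription of a small panel of p53 target
genes changes. The design has six measurement conditions per knockdown: three
readout transcripts — *CDKN1A*/p21 (pro-arrest), *BBC3*/puma (pro-apoptotic)
and *TP53* itself — each measured after vehicle (DMSO) or etoposide
treatment, the latter a topoisomerase-II poison that activates p53 through
DNA damage. Every well also measures *LMNA*/lamin A/C, a transcript assumed
unaffected by the perturbations, as the normalization denominator. Each plate
carries three dedicated control siRNAs: a nontargeting pool (no effect
expected), a *TP53* pool (all three readouts collapse) and an *MDM2* pool
(basal *CDKN1A* and *BBC3* rise, because MDM2 destabilizes p53 protein, while
*TP53* mRNA itself is untouched).

The package covers every computational stage of such a screen: RT-qPCR
quantification, normalization, hit calling, regulator classification,
secondary-screen validation, false-positive flagging, clustering, and
quality control — plus a seeded generator of synthetic screens so the whole
pipeline is testable without any laboratory data.

## From Ct values to expression ratios

qPCR reports a threshold cycle (Ct) per reaction. The relative standard
curve method converts Ct to a relative template quantity through an
ordinary-least-squares fit of Ct against $\log_{10}$(quantity) over a
dilution series:

$$\mathrm{Ct} = b_0 + b_1 \log_{10} Q, \qquad
  \hat{Q}(\mathrm{Ct}) = 10^{(\mathrm{Ct}-b_0)/b_1}, \qquad
  E = 10^{-1/b_1} - 1 .$$

A perfectly doubling reaction has $b_1 = -1/\log_{10} 2 \approx -3.32$ and
efficiency $E = 1$. `fit_standard_curve()` flags (but does not refuse) a
non-negative slope, which is chemically meaningless and usually indicates
swapped columns.

Three numerical choices here are deliberate:

* **Replicates are averaged on the quantity scale, not the Ct scale.** The
  standard-curve method reports in quantity space; averaging Ct values would
  average logarithms. At typical triplicate dispersion the difference is
  small but it should be fixed, not incidental.
* **A replicate Ct standard deviation above 0.5 cycles raises a QC flag, not
  an exclusion.** No exclusion rule is part of the screen design; flags keep
  the pipeline auditable without silently changing the data.
* **A missing or non-positive reference quantity yields a missing normalized
  value with a reason code**, never an error. Knockdowns that kill the well
  produce no LMNA signal, and one dead well must not abort a screen.

Normalized expression is the plain ratio target/reference per gene and
treatment, from the same well set — the per-sample design of the screen.

## Hit calling

For each of the six conditions the standard score is

$$z = \frac{X - \mu}{\theta},$$

with $\mu$ and $\theta$ the mean and standard deviation of normalized
expression across the screened library for that condition. Values strictly
outside $\pm\tau$ (default $\tau = 2$) are hits; a value exactly on the
boundary sits inside the window and is not a hit. Because knockdown reduces
the targeted transcript, a readout *reduced* by a knockdown ($z < -\tau$)
identifies the target as a **positive regulator** of that readout, and an
*increased* readout identifies a **negative regulator**.

Conventions worth stating explicitly:

* $\mu$ and $\theta$ are computed over **library wells only** by default.
  The dedicated control wells recur on every plate; including them would
  bias the location estimate toward the controls' (strong, known) phenotypes.
  Controls still *receive* z-scores against the library parameters, so their
  behavior can be read on the library scale. `include_controls = TRUE`
  exposes the other convention, since either reading of "across all siRNA
  experiments" is defensible.
* $\theta$ is the sample standard deviation ($n-1$), the screening-statistics
  convention; at $n \approx 589$ the difference from $n$ is negligible.
* Missing values never create hits and are excluded from $\mu$, $\theta$.

## Regulator categories

Hits map onto categories that mirror how screen results are conventionally
tabulated:

* **joint** — same-direction hits for both *CDKN1A* and *BBC3* within one
  treatment: a gene steering the whole p53 transcriptional program.
* **CDKN1A-specific / BBC3-specific** — a hit for one readout in a treatment
  where the partner readout is not a hit, for genes not joint in *any*
  treatment (joint status takes precedence across treatments). A gene whose
  two readouts move in *opposite* directions in the same treatment is
  neither joint nor specific — the partner readout is a hit, just inverted —
  and such profiles are left to the clustering stage.
* **TP53-specific** — a hit on the *TP53* readout, assigned independently of
  the other categories. A gene may therefore be simultaneously joint and
  TP53-specific; this is exactly the profile of a *TP53* knockdown, which
  collapses all three readouts.

Category tallies are reported in two conventions (`summary()`): *entries*
counts per-treatment table rows (a gene hit under both treatments counts
twice), *genes* counts unique symbols. Published hit tables typically use
the entry convention; both are provided so either can be reproduced.

## Secondary validation and false-positive flagging

A validation rescreen re-tests a subset of the library (conventionally in
the basal condition only) at a relaxed cut-off of 1 SD, with z-scores
computed within the rescreened pool. A primary CDKN1A/BBC3 regulator present
in the pool is *confirmed* when at least one of its category's readouts
passes $|z| > 1$ with matching direction; present-but-unconfirmed regulators
are putative false positives; absent genes remain untested. Two open design
points and the defaults chosen:

* **Direction agreement is required by default** (`require_direction`
  switch). A regulator "confirmed" by an opposite-direction excursion would
  be a coincidence, not a validation.
* **A joint regulator confirms on either readout.** Requiring both would
  make joint confirmation strictly harder than the single-readout rule
  applied to specific regulators, which the relaxed 1-SD design argues
  against.

Independently, any regulator whose expression value in an external
expression table equals exactly 0 is flagged: an siRNA cannot generate an
on-target phenotype by depleting a transcript the cell line does not
express. The join is case-insensitive on the gene symbol because public
expression tables vary in capitalization; the flag is deliberately kept even
for secondary-confirmed genes (both flags are reported — a reproducible
off-target effect is still not an on-target effect).

## Self-organizing map clustering

Stringent thresholds discard genes that behave *like* known regulators but
fall just inside the window. The package therefore clusters the full
six-dimensional expression profiles with a self-organizing map implemented
from scratch: a `rows x cols` grid of prototype vectors $w_i$ trained by
online competitive learning. For each presented profile $x$ the
best-matching unit (BMU) is the prototype at minimal Euclidean distance, and
every unit moves by

$$w_i \leftarrow w_i + \alpha(t)\, h(i, \mathrm{bmu}, t)\,(x - w_i),$$

with learning rate $\alpha$ decaying linearly (0.05 to 0.01) and a bubble
neighborhood $h \in \{0, 1\}$ whose radius starts at the 2/3 quantile of
inter-unit grid distances (hexagonal layout) and decays linearly to zero, so
late updates refine BMUs only. These defaults — grid 5 x 5, 100 passes over
the data, codebook initialized by sampling data rows without replacement,
rows presented in seeded random order — match the documented default
behavior of the classical R SOM implementation used in expression
profiling, so results are comparable to the field's common practice. "100
iterations" means 100 presentations of the full data set.

Properties the implementation guarantees (and the tests assert):

* Determinism given `seed`; every update is a convex combination, so the
  codebook never leaves the data bounding box.
* Assignment is an exhaustive nearest-unit search; ties break toward the
  lowest unit id (units numbered 1..25 row-major from the top-left).
* Genes with any missing condition are excluded from training and listed.
* Profiles enter as-is (normalized expression values), matching common
  practice for this readout; `scale = TRUE` exposes per-column z-scaling.

Cluster *memberships* of any particular published map are not a
reproduction target: with random initialization they depend on an unknown
seed. The grid size, training regime and the qualitative structure (e.g. a
cluster collecting TP53-knockdown-like profiles) are.

## Screen quality control

Two standard instruments:

* **Z'-factor**, $1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$, the assay
  window between positive controls (TP53 siRNA, which collapses the
  readouts) and negative controls (nontargeting). It is at most 1, and
  invariant under common affine rescaling.
* **Control-versus-average t-tests**: per control role and condition, the
  per-plate control means against the per-plate library means. The default
  is an unpaired Welch test (unequal variances, Welch–Satterthwaite df),
  because plate pairing is an assumption about the experimental structure
  that the data may not support; `paired = TRUE` exposes the by-plate
  pairing for designs where it holds.

## The synthetic generator

`simulate_screen()` produces the package's test bed. Values are

$$v_{g,c} = \mathrm{baseline}_c \cdot 2^{\mathrm{effect}_{g,c}} \cdot
  \mathrm{plate}_g \cdot \varepsilon_{g,c},$$

with $\varepsilon$ lognormal with unit mean and configured CV (qPCR ratio
errors are multiplicative, and this keeps values non-negative), and plate
factors $e^{N(0,\,\sigma_\mathrm{plate})}$. Defaults, chosen once as the
study conditions the generator emulates:

* **589 library genes over 8 plates** with one control well per role per
  plate; *TP53* itself is the first library gene, carrying a strong
  (−3 log2) self-knockdown effect on all readouts — the canonical internal
  sanity check that must score as a hit in all six conditions.
* **Baselines** (normalized expression): CDKN1A 1.0 → 3.0 and BBC3
  0.5 → 1.5 from DMSO to etoposide (p53 target induction), TP53 1.0 → 1.2
  (transcript nearly flat under drug; p53 activation is mostly
  post-translational). These are stand-in magnitudes of a plausible
  induction experiment, not measured values.
* **Planted regulators: 1.5% of the library per category** (joint positive,
  joint negative, CDKN1A-, BBC3-, TP53-specific; ~7.5% total), matching the
  per-category hit densities such screens report (~10 joint regulators per
  direction in a 589-gene library). This density matters statistically:
  planted effects inflate the per-condition SD, so far denser regulators
  shrink everyone's z-scores, and far sparser ones leave the SD at the
  noise floor where chance calls dominate.
* **Effect size 1.5 log2 units, noise CV 15%, plate SD 0.05** — planted
  regulators then sit near $|z| \approx 2.5$–3: detectable but not trivial.
  Effects apply in both treatments by default (`condition_of_effect`).
* **Controls**: nontargeting wells carry zero effect; TP53 controls −3 log2
  on all readouts, both treatments; MDM2 controls +1.5 log2 on basal CDKN1A
  and BBC3 only.
* With `emit_ct`, raw Ct triplicates are produced by inverting planted
  standard curves (slope $-1/\log_{10}2$, per-readout intercepts), with a
  5-point 4-fold dilution series embedded per readout — the dilution design
  is a configurable stand-in, since no particular series is canonical.
  At zero cycle noise, quantify → normalize → z-score provably reproduces
  the hit set of the directly emitted matrix.

What the generator does **not** model: siRNA off-target effects,
transfection-efficiency gradients, plate edge effects, readout-specific
amplification biases. Passing tests therefore demonstrate the pipeline's
statistical correctness under clean multiplicative noise, not robustness to
every artifact of real screens.

## Problem sizes and runtime choices

The test suite and the acceptance script run screens of 200–600 genes, 10–20
replicate simulations per stochastic claim, and SOM training of 10–100
passes — sizes at which every statistical assertion stabilizes while the
whole suite completes in well under a minute of compute. The recovery
operating point asserted in the tests (recall ≥ 0.9, precision ≥ 0.8 at the
default conditions, averaged over 20 seeds) is a property of the defaults
above, verified across independent seed blocks.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11)
sim <- simulate_screen(cfg)
zt <- compute_zscores(sim$matrix)
hits <- call_hits(zt, threshold = 2)
cl <- classify_regulators(hits, genes = sim$truth$genes)
summary(cl)

sec <- simulate_secondary(sim$truth, subset_size = 81, seed = 12)
cl <- validate_secondary(cl, sec, threshold = 1)

model <- train_som(sim$matrix, som_config(seed = 13))
clusters <- assign_clusters(model, sim$matrix)
head(summarize_clusters(clusters, sim$matrix, n_units = 25))

score_recovery(sim$truth, cl)[c("precision", "recall")]
```

## Known limitations

* No multiple-testing correction, B-score/median-polish plate normalization,
  or redundant-siRNA scoring — deliberately out of scope; the z-threshold
  design is the method being implemented.
* The ΔΔCt method and multi-reference geometric-mean normalization are not
  provided; quantification is the relative standard curve method only.
* Instrument-native qPCR export formats are not parsed; inputs are CSV/TSV.
* The classification rule set is treatment-resolved and deterministic; genes
  with opposite-direction readout pairs are intentionally left to the SOM
  stage rather than forced into a category.
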