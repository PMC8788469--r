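---
title: "Label-free semi-absolute quantification: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free semi-absolute quantification: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saquant)
library(dplyr)
```

## The problem

A shotgun LC-MS/MS experiment reports, per sample, how many MS/MS spectra
matched each peptide (spectral counts, SC) and how large each peptide's
precursor chromatographic peak was (XIC area). Neither is an amount.
Longer proteins yield more peptides, and every peptide ionizes with its
own efficiency, so raw signals are comparable neither across proteins nor
across laboratories. Semi-absolute quantification closes that gap in two
steps: a *relative abundance index* corrects each protein's signal for its
sequence properties, and a *transformation strategy* maps the unitless
index to fmol, either by regression against a spiked protein ladder of
known composition (a UPS2-like standard: 48 proteins, 8 at each of six
molar levels from 0.5 fmol to 50 pmol) or by assuming the summed signal
represents the total injected mass (the total protein approach, TPA).

## Relative abundance indices

With `SC_i` the summed spectral count of protein $i$ in a sample, `L_i`
its length in residues and `N_i^{obs}` its number of observable tryptic
peptides:

* $\mathrm{PAI}_i = n_i / N_i^{obs}$, where $n_i$ is the number of
  *distinct* peptide sequences observed with at least one spectrum.
* $\mathrm{emPAI}_i = 10^{\mathrm{PAI}_i} - 1$.
* $\mathrm{SAF}_i = SC_i / L_i$;
  $\mathrm{NSAF}_i = \mathrm{SAF}_i / \sum_j \mathrm{SAF}_j$, so NSAF sums
  to 1 per sample over the quantified non-contaminant proteins.
* $\mathrm{SUMnorm}_i = \big(\sum_p I_p\big) / L_i$ over the protein's
  peptide intensities $I_p$;
  $\mathrm{TOP3}_i$ = mean of the three largest $I_p$;
  $\mathrm{iBAQ}_i = \big(\sum_p I_p\big) / N_i^{obs}$.

The PAI numerator counts distinct peptide sequences while SAF counts
spectra: a deliberate distinction, since the two indices respond
differently to repeated fragmentation of the same peptide. Intensity
sums and means are taken on the *linear* scale after log-space
normalization; log10 intensities are convenient for filtering and
normalization, but protein-level aggregation is only meaningful on linear
areas.

XIC areas are log10-transformed and normalized by a log-space
median-ratio shift against a designated reference sample (the first
sample by default): for each sample the median of
$\log_{10} I - \log_{10} I^{ref}$ over peptides shared with the reference
is subtracted. The original workflow cites a local normalization whose
details are not restated there; median-ratio normalization is the
standard robust choice with the same intent (removing sample-wide
loading/instrument shifts), and the reference sample is configurable.

## Evidence filters

Applied per sample, before quantification (`filter_evidence()`):

1. **RT reproducibility** (XIC methods only): rows with a retention-time
   standard deviation above 20 s are removed. A peptide whose RT varies
   that much across its observations was likely mis-integrated. Counted
   evidence carries no chromatographic information, so spectral-counting
   methods ignore this filter, and an absent RT-SD passes.
2. **Shared peptides**: peptides mapping to more than one protein are
   removed for every method except iBAQ, whose definition keeps them; a
   shared peptide then contributes its full intensity to every protein it
   maps to (no apportioning — the method's source defines no split, and
   any split rule would be arbitrary).
3. **Minimum peptides**: XIC methods require at least two distinct
   peptide sequences per protein; spectral-counting methods keep
   single-peptide proteins. "Peptides" means distinct sequences, not
   spectra. The rule is evaluated per sample by default
   (`per_sample = FALSE` switches to experiment-wide), since whether the
   original rule was per-sample is not documented.

When shared peptides are retained (iBAQ), a row is removed by rule 3 only
if *every* protein it maps to fails the minimum — removing it because one
of its proteins is unquantifiable would discard evidence for the other.
A consequence is that a protein below the minimum can still appear in
filtered evidence through a shared row; it simply rides along as a
mapping. TOP3 with exactly two peptides uses the mean of two (with a
logged count) rather than dropping the protein: quantifiability is the
filter's decision, not the aggregator's.

Contaminant-flagged proteins pass identification filters but are excluded
from the NSAF and TPA denominators and outputs, so totals reflect the
sample rather than the laboratory.

## The standard of reference

`fit_calibration()` regresses $\log_{10}(\text{expected fmol})$ on
$\log_{10}(\text{observed abundance})$. Both choices are deliberate:

* **Log-log space.** The ladder spans five decades; untransformed least
  squares would be dominated entirely by the top level.
* **Expected on observed.** With expected amount as the response, the
  fitted line is a direct read-off: `apply_calibration()` computes
  $\hat a_i = 10^{m \log_{10}(\text{rel}_i) + a}$ with no inversion. The
  axis orientation and space are recorded in the model object.

Standards observed at zero or absent are excluded (never imputed — a zero
has no logarithm and a below-detection standard carries no calibration
information). Outliers are removed in a **single pass**: one OLS fit,
Cook's distance $D_i$, removal of points with $D_i > 3 \bar D$, one
refit. Iterating the removal would eventually hollow out the ladder;
the reference workflow removes its outliers once. An essentially exact
fit short-circuits to "no outliers", since Cook's distances there are
0/0 float noise. At least four usable standards are required — below
that, a two-parameter regression with outlier screening is meaningless,
matching the observation that runs detecting fewer than ~15 standards
preclude regression.

Replicate fits are pooled (`pool_reference()`) by refitting on the
**union of retained points**, not by averaging per-replicate slopes: the
union weights replicates by how many standards they actually detected,
and its r² is an honest pooled statistic. Per-replicate models remain
available.

## TPA and the mass ratio

$\text{conc}_i = \dfrac{\text{rel}_i}{\sum_j \text{rel}_j}\cdot
\dfrac{\text{total mass}}{MW_i}$ (mol), with $MW_i$ the average (not
monoisotopic) molecular weight — bulk mass in g/mol is what the formula
needs. By construction $\sum_i \text{conc}_i \cdot MW_i$ equals the total
injected mass, which is why the mass-ratio metric is exactly 1 on any TPA
table over all proteins: for TPA the ratio is a consistency identity, and
it is only informative on subsets (e.g. the spiked standards against
their known injected mass) or for the UPS2 strategy.

## Digestion and observable peptides

Trypsin cleaves C-terminal to K or R, not before proline (the proline
rule is on by default; configurable). An *observable* peptide is a fully
tryptic peptide (0 missed cleavages by default; the search-engine setting
of 1 is available) of length 7–30 residues — the usual detectability
window in emPAI/iBAQ practice; the window is not standardized anywhere,
so it is exposed as `digest_params()`. With more than 0 missed cleavages,
peptides are returned fully cleaved fragments first, then joins, each
block N→C. Average residue masses are a fixed, documented in-code table
(`residue_masses()`); molecular weight = residue sum + 18.0153 (one
water).

## Evaluation metrics

* **CV among replicates**: per protein, $100\,s/\bar x$ across replicate
  samples, with the $n-1$ standard deviation; summarized by the median.
* **CV among proteins**: standards are grouped by concentration decade
  ($\lfloor \log_{10} \text{fmol} \rfloor$); the CV across proteins of a
  decade is computed within each sample, each decade summarized by its
  median across samples, and the decades by their median. Pooling across
  samples *after* decade grouping is a choice (the alternative is exposed
  by computing per-sample); decades with fewer than two proteins are
  skipped and logged.
* **Bootstrap absolute error**: per (protein, sample),
  $100\,|\hat a - a| / a$; the pooled errors are resampled with
  replacement $B$ times and the median of each resample recorded,
  giving a point median and a 2.5–97.5 percentile interval. The original
  study's appendix does not restate the resampling scheme; resampling
  the pooled error set is the plainest reading, with $B$ and the seed
  configurable, and no pool size hard-coded.
* **Mass ratio** and **error against validation spikes** (four purified
  proteins at 51.9, 108.6, 181.8 and 342.6 fmol) as defined above; the
  bundled manifest attaches synthetic stand-in sequences, clearly
  labelled as such, not the biological ones.

## The synthetic data generator

`simulate_proteome()` draws random sequences over the 20-letter alphabet
with K+R at ~11% combined frequency, so tryptic peptide lengths are
realistic; background amounts are log-uniform over 10–1000 fmol, and the
standard ladder is 8 proteins at each of 0.5/5/50/500/5000/50000 fmol.
`simulate_evidence()` observes each observable peptide of each protein,
per sample:

* detection with probability
  $\mathrm{logit}^{-1}\big(s\,(\log_{10} f - \log_{10} f_{1/2})\big)$
  (defaults $f_{1/2} = 400$ fmol, $s = 3$): abundance-dependent dropout,
  chosen so roughly 28–34 of the 48 standards are detected per sample and
  the 0.5 fmol level is essentially never seen — the qualitative
  signature of real UPS2 runs at economical spike amounts;
* spectral count $\sim$ Poisson(0.5 per fmol per peptide), truncated to
  $\geq 1$ (a detected peptide has at least one spectrum) — per-peptide
  Poisson rather than a protein-level draw, so PAI (distinct peptides)
  and SAF (spectra) respond differently, as in real data;
* XIC area $= 10^4 \cdot f \cdot 10^{e_p + \varepsilon}$ with $e_p \sim
  N(0, 0.3^2)$ a per-peptide ionization efficiency *fixed across
  samples* (real peptides ionize consistently) and $\varepsilon \sim
  N(0, 0.2^2)$ per observation;
* RT-SD $\sim |N(3, 2^2)|$ s, with 2% of peptides forced above 20 s to
  exercise the filter; 5% of peptides are mapped to a second protein to
  exercise the shared-peptide rules.

The generator is deterministic given `seed` (the proteome uses `seed`,
the evidence `seed + 1`, so the two stages draw independent streams).
What it does **not** emulate: correlated peptide misidentification,
retention-time drift, in-source fragmentation, protein inference
ambiguity beyond two-way sharing, and the long-tailed ionization
heterogeneity of real peptides. Tests passing on this generator therefore
demonstrate correctness of the arithmetic and the calibration machinery
under a known truth — not instrument-level performance on real data,
whose published r² and CV figures come from deposited LC-MS/MS runs far
beyond desk scale.

## Numerical choices and problem sizes

Tolerances: NSAF unit sums and TPA mass conservation are exact algebra
and tested at $10^{-9}$; calibration identity recovery at $10^{-6}$.
Degenerate inputs error early and by name: all-equal predictors, all-zero
SAF, fewer than four usable standards, missing molecular weights. Ties in
TOP3 are broken by peptide sequence (no effect on the mean; it fixes the
reported order). Abundance tables serialize at 6 significant digits and
round-trip bit-exactly at that precision.

The test suite and the acceptance script size their simulations for a
single CPU: 20–60 background proteins and 1–2 samples in unit tests;
500 replicate calibrations for slope-recovery coverage; 20 end-to-end
replicates (60 background proteins, 25 standards over five decades,
$\sigma = 0.1$, no dropout) for the NSAF recovery error. Those sizes are
the package's own choice of a desk-scale experiment; the generator scales
to arbitrarily larger proteomes by configuration.

```{r example}
sim <- simulate_dataset(sim_config(n_background = 40, n_samples = 2, seed = 1))
nsaf <- quantify(sim$evidence, sim$proteins, "NSAF")
standards <- filter(sim$proteins, role == "standard")
model <- nsaf |>
  filter(sample_id == "S01") |>
  inner_join(select(standards, accession, expected_fmol), by = "accession") |>
  fit_calibration()
glance(model)
```

## Known limitations

* emPAI is reported on its own scale; the molar-fraction conversion of
  the original emPAI publication is out of scope.
* No match-between-runs: a peptide undetected in a sample is absent, not
  imputed.
* iBAQ's full-intensity sharing double-counts shared signal by design;
  with high shared fractions this inflates totals.
* The UPS2 strategy extrapolates outside the detected standard range;
  estimates beyond the ladder's observed span inherit the regression's
  leverage there.
* TPA accuracy is bounded by the assumption that assigned signal
  represents the injected mass; unassigned spectra bias it low in real
  data, which the generator does not model.
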