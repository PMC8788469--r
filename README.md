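# saquant

Label-free **semi-absolute protein quantification** for shotgun proteomics.

Label-free LC-MS/MS yields unitless signals — spectral counts and
extracted-ion-chromatogram (XIC) peak areas — that cannot be compared
across proteins without correcting for each protein's size and peptide
yield, and cannot be expressed in physical units (fmol, mol/g) without a
calibration assumption. `saquant` implements the complete workflow that
turns peptide-level evidence into absolute protein amounts:

* **Seven relative abundance indices.** Spectral-counting: PAI
  (observed / observable peptides), emPAI (`10^PAI − 1`), SAF (`SC/L`) and
  NSAF (`(SC/L)_i / Σ_j (SC/L)_j`, unit sum per sample). Intensity-based:
  SUMnorm (summed peptide XIC / residue count), TOP3 (mean of the three
  most intense peptides) and iBAQ (summed intensity / observable-peptide
  count).
* **Evidence filters** preceding quantification: retention-time-SD > 20 s
  removal and a ≥ 2-distinct-peptides rule for the XIC methods, and
  shared-peptide removal for every method except iBAQ.
* **Two relative → absolute transformation strategies.**
  *UPS2 standard of reference*: ordinary least squares of
  `log10(expected fmol)` on `log10(observed abundance)` for a spiked
  48-protein, six-level standard, with single-pass Cook's-distance outlier
  removal (`D_i > 3·mean(D)`) and pooling of bulk-replicate fits.
  *Total protein approach (TPA)*:
  `conc_i = (rel_i / Σ_j rel_j) · total mass / MW_i`.
* **Evaluation metrics**: calibration linearity (r²), CV among replicates,
  decade-wise CV among standard proteins, bootstrap median absolute error,
  absolute error against validation spikes of known fmol, and the total
  mass ratio `Σ conc_i · MW_i / total mass`.
* **In-silico tryptic digestion** (K/R cleavage, proline rule, missed
  cleavages, 7–30 aa observable window) supplying the PAI/iBAQ
  denominators and average molecular weights.
* **A synthetic spike-in generator** with an explicit observation model
  (logistic abundance-dependent peptide detection, truncated-Poisson
  spectral counts, lognormal intensities with fixed per-peptide
  ionization efficiency), so the entire workflow runs and is tested
  without any external data.

Everything is tibble-in / tibble-out and composes with the pipe; fitted
calibrations support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(saquant)
library(dplyr)

sim <- simulate_dataset(sim_config(seed = 42))       # 48 standards + 200 background
nsaf <- quantify(sim$evidence, sim$proteins, "NSAF") # unit-sum relative abundance

standards <- filter(sim$proteins, role == "standard")
models <- lapply(unique(nsaf$sample_id), function(s) {
  nsaf |>
    filter(sample_id == s) |>
    inner_join(select(standards, accession, expected_fmol), by = "accession") |>
    fit_calibration()
})
reference <- pool_reference(models)
reference
#> <calibration (log10-log10)>
#>   log10(fmol) = 0.7519 * log10(observed) + 5.2629
#>   r2 = 0.9763 on 167 points (7 outlier(s) removed: SYNUPS21, SYNUPS22, ...)

fmol <- apply_calibration(nsaf, reference)           # absolute amounts, fmol
glance(bootstrap_absolute_error(fmol, standards, B = 1000, seed = 1))
#> # A tibble: 1 × 5
#>   median_error_pct ci_low ci_high n_errors     B
#>              <dbl>  <dbl>   <dbl>    <int> <int>
#> 1             33.7   28.1    36.6      181  1000
```

The pooled standard of reference maps observed NSAF shares to fmol on the
log-log scale; a slope below 1 and r² ≈ 0.98 reflect the generator's
default detection dropout and count noise. The bootstrap median absolute
error summarizes how far the calibrated estimates sit from the known
spiked amounts, with a percentile interval over resampled medians.

One call runs every technique (7 methods × UPS2/TPA) and writes abundance
tables, calibration models and a metrics manifest:

```r
run_pipeline(run_config(sim = sim_config(seed = 42), out_dir = "run"))
```

A thin command-line wrapper with the same functionality ships in
`inst/cli/saquant.R`.

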