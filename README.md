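# hypoxiaDCE

Estimation of tumor hypoxic fraction and survival stratification from
dynamic contrast-enhanced MRI (DCE-MRI) parameter maps, for researchers
working on imaging biomarkers of hypoxia in cervical carcinoma and
related solid tumors.

## The problem and the model

Tumor hypoxia drives treatment resistance and poor survival in
locally-advanced cervical carcinoma, but direct hypoxia assays
(pimonidazole immunostaining, polarographic electrodes) are invasive.
DCE-MRI offers a routine, non-invasive alternative: fitting the Tofts
generalized pharmacokinetic model to voxel-wise contrast
concentration-time curves yields the volume transfer rate constant
K<sup>trans</sup> (min⁻¹, a perfusion/permeability surrogate and hence a
proxy for oxygen *supply*) and the fractional distribution volume
v<sub>e</sub> (dimensionless, a putative cell-density and oxygen
*consumption* surrogate). The tissue model driven by a bi-exponential
population arterial input function
C<sub>a</sub>(t) = A·e<sup>−Bt</sup> + C·e<sup>−Dt</sup> has the closed
form

&nbsp;&nbsp;&nbsp;&nbsp;C<sub>t</sub>(t) = K<sup>trans</sup> Σ<sub>i</sub>
M<sub>i</sub> (e<sup>−m_i t</sup> − e<sup>−k_ep t</sup>) / (k<sub>ep</sub>
− m<sub>i</sub>), &nbsp; k<sub>ep</sub> = K<sup>trans</sup>/v<sub>e</sub>,

which this package fits per voxel by bounded Levenberg–Marquardt least
squares. Murine (A = 2.55 mM, B = 0.080 s⁻¹, C = 1.20 mM, D = 0.0010 s⁻¹)
and human (A = 5.10 mM, B = 14.2 s⁻¹, C = 0.99 mM, D = 0.159 s⁻¹)
population AIFs are built in. Voxels with unphysiological v<sub>e</sub> > 1
mark necrosis, where the model assumptions fail.

Four threshold rules classify tumor voxels as hypoxic:

| strategy | hypoxic iff |
|---|---|
| `ktrans_only` (i) | K<sup>trans</sup> < K<sup>trans</sup><sub>0</sub> |
| `ve_only` (ii) | v<sub>e</sub> < v<sub>e0</sub> |
| `conjunction` (iii) | both inequalities hold |
| `weighted_sum` (iv) | K<sup>trans</sup>/K<sup>trans</sup><sub>0</sub> + v<sub>e</sub>/v<sub>e0</sub> < 1 |

The hypoxic fraction HF<sub>MRI</sub> is the hypoxic share of viable
(v<sub>e</sub> ≤ 1) tumor voxels. Thresholds are calibrated against
pimonidazole hypoxic fractions by maximizing an adapted, slope-sensitive
similarity statistic S(x, y) = 2·cov(x, y)/(var x + var y), which equals
1 only for perfect slope-1 agreement. Clinical cohorts are stratified by
the one-third/two-thirds rule (the 26 of 80 patients with the highest
HF<sub>MRI</sub> versus the remaining 54) and compared by Kaplan–Meier /
log-rank across a grid of thresholds, producing p-value curves and
surfaces. A synthetic phantom/cohort generator (concentric necrotic
core, hypoxic annulus, perfused periphery; proportional-hazards survival)
makes the whole pipeline testable without external data.

## Worked example

```r
library(hypoxiaDCE)

ph   <- simulate_phantom(phantom_spec(seed = 42))
rule <- hypoxia_rule("ktrans_only", k0trans = 0.015)
classify_voxels(ph$maps, rule)
#> Hypoxia image (64x64): hypoxic=412, normoxic=1280, unphysiological=112,
#>   outside_roi=2292; HF_MRI = 0.2435
```

Of the 1804 tumor voxels, 112 have v<sub>e</sub> > 1 (the necrotic core)
and are excluded; 412 of the 1692 viable voxels fall below
K<sup>trans</sup><sub>0</sub> = 0.015 min⁻¹, giving a hypoxic fraction of
0.24.

```r
pre <- simulate_preclinical_cohort(cohort_spec(n_tumors = 30, seed = 42))
calibrate_1d(pre$tumors, pre$maps, "ktrans_only")
#> Threshold calibration [ktrans_only]
#>   optimum: k0trans = 0.015 (similarity 0.9863)
#>   agreement at optimum: r2 = 0.973, slope = 0.976
```

The similarity sweep recovers the generator's threshold (0.015 min⁻¹)
from 30 tumors whose pimonidazole fractions carry σ = 0.05 noise, with a
near-slope-1 agreement at the optimum.

```r
cl <- simulate_clinical_cohort(cohort_spec(seed = 42))
stratify_cohort(cl$patients)
#> Cohort split on hf_mri: 26 high / 54 low
#>   DFS: log-rank chi-square = 11.119, p = 0.0008546
#>   OS: log-rank chi-square = 10.042, p = 0.00153
```

Patients in the high-HF third have significantly shorter disease-free
and overall survival, the qualitative behaviour the generator encodes.

The pipeline stages are also available as chained subcommands
(`simulate`, `fit`, `hf`, `calibrate`, `stratify`) through
`run_pipeline()` or the thin CLI wrapper in `inst/cli/hypoxiadce`,
reading a YAML config and writing NIfTI maps, CSV tables and JSON
results into a run directory with a manifest.

## Documentation

The methods vignette (`vignettes/hypoxia-dce-methods.Rmd`) describes the
model, the classification rules, the calibration and survival machinery,
the synthetic generator and its deliberate simplifications, and the
package's numerical choices and limitations.
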