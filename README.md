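# dynPET

Reconstruction-dependent quantification of dynamic cardiac ¹¹C-acetate PET,
end-to-end on synthetic data with known ground truth.

Dynamic ¹¹C-acetate PET quantifies myocardial perfusion and oxidative
metabolism through a 1-tissue-compartment model,

    dC_myo/dt = K1·C_P(t) − k2·C_myo(t),

where the uptake rate K1 (mL/min/mL) is proportional to perfusion and the
washout rate k2 (1/min) reflects oxidative metabolism, with the input
function C_P taken from an LV blood-pool ROI. Because ¹¹C decays with a
20-minute half-life, count statistics vary enormously across the 53-frame,
40-minute protocol (15 × 10 s, 15 × 30 s, 16 × 60 s, 7 × 120 s), and the
choice of reconstruction — FBP, or ordinary-Poisson OSEM with/without
time-of-flight (TOF) and point-spread-function (PSF) modelling,

    f_j^(k,q+1) = f_j^(k,q) / (Σ_{i∈S_q} A_ij) · Σ_{i∈S_q} A_ij · p_i / (Σ_l A_il f_l^(k,q) + r_i + s_i),

— could bias SUV and the kinetic parameters. dynPET implements the whole
chain so the question is testable: a 2D cardiac phantom with
1-tissue-compartment regional kinetics and ¹¹C decay, parallel-beam
projection with attenuation, normalization, TOF binning and PSF blur,
Poisson counts with randoms/scatter backgrounds, the four reconstruction
algorithms, ROI/TAC/SUV extraction, CV/contrast convergence analysis,
spillover-corrected kinetic fitting, and pairwise method-comparison
statistics (OLS regression, paired and Welch t-tests) over simulated
cohorts.

It is intended for researchers studying how reconstruction choices
propagate into semi-quantitative (SUV) and fully quantitative (K1, k2)
cardiac PET measures, and as a tested reference implementation of each
stage.

## Worked example

One simulated subject on a 64 × 64 grid (3 mm voxels), 60 angles, all four
reconstructions, spillover-corrected fits:

```r
library(dynPET)
cfg <- defaultExperimentConfig(nx = 64L, voxelSize = 3, scale = 0.9,
                               nAngles = 60L, seed = 1L)
cfg$projection$countScale <- 0.05
res <- runSubject(cfg, seed = 1L)
res$truthParams
#    K1    k2
# 0.507 0.312
res$fits
#   method    K1    k2   v_lv v_rv  rss converged
# 1    FBP 0.471 0.308 0.0665    0 16.1      TRUE
# 2   OSEM 0.468 0.306 0.0702    0 19.0      TRUE
# 3    TOF 0.483 0.309 0.0424    0 23.4      TRUE
# 4   TPSF 0.503 0.312 0.0207    0 29.1      TRUE
```

This subject's true myocardial kinetics were K1 = 0.507, k2 = 0.312 (drawn
from the cohort distribution at seed 1); every reconstruction recovers k2
within 2% and K1 within 8%, with the TOF-based methods closest — the fitted
spillover fractions (`v_lv`) absorb the residual blood-pool contamination
that the blurrier reconstructions leave in the myocardial ROI. Myocardial
SUV at the four protocol time points (dose 740 MBq, weight 70 kg):

```r
res$suvs[res$suvs$method == "TOF", c("time_min", "suv")]
#   time_min  suv
#          2 3.80
#          5 4.61
#         10 4.37
#         30 2.64
```

the characteristic acetate shape: rapid uptake, peak a few minutes post
injection, washout through the tricarboxylic-acid cycle.

Cohorts and the pairwise comparison tables come from `runCohort()`;
`convergenceStudy()` reproduces the CV/contrast and kinetic-parameter
convergence analyses against EM-equivalent iterations (iterations ×
subsets). A thin command-line wrapper lives at
`inst/scripts/run_experiment.R`.

## Layout

- `R/phantom.R` — frame schedules, input functions, phantom, dynamic truth
- `R/projector.R` — system operator, forward/back projection, subsets, counts
- `R/recon.R` — OP-OSEM, FBP, post-filter, decay-corrected activity
- `R/roi.R` — ROI masks, TACs, CV/contrast, SUV
- `R/kinetics.R` — 1-tissue-compartment solver, spillover model, fitting
- `R/compare.R` — regressions, t-tests, cohort reports
- `R/pipeline.R`, `R/study.R` — orchestration, config I/O, reference studies
- `vignettes/dynamic-pet-quantification.Rmd` — models, assumptions, design
  choices, limitations
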