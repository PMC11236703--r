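# primedG1

Single-cell analysis of Rb–E2F cell-cycle commitment dynamics and
phosphorylation-site-preference (PSP) kinetics.

## The scientific problem

Mammalian cells commit to division when E2F transcription factors escape
inhibition by the retinoblastoma protein (Rb). Time-lapse imaging of live
reporters shows that, before committing, cells can linger in a reversible
*primed* G1 state of intermediate E2F activity, associated with Rb that is
phosphorylated at some sites (such as T373) while still chromatin-bound,
and only later undergo the switch-like hyperphosphorylation that fully
releases E2F and starts S phase. Dissecting this requires a chain of
quantitative steps — per-cell image quantification, single-cell trace
classification and alignment, and kinetic modelling of site-specific
phosphorylation — that this package implements end to end, together with a
synthetic-data module that plants known ground truth so every step can be
validated without any raw imaging data.

Intended users: quantitative cell biologists and systems biologists
analysing single-cell reporter imaging of cell-cycle commitment, and
anyone needing a tested reference implementation of PSP-style kinetic
inference.

## The core model

Each Rb phosphosite is a two-state species. With phosphorylation rate α
(shared between sites when the kinases are non-selective) and
site-specific dephosphorylation rates β₁, β₂:

    dx/dt = α(1 − x) − β₁x
    dy/dt = α(1 − y) − β₂y

At equilibrium, eliminating α gives a one-parameter curve relating the
phosphorylated fractions of the two sites:

    y = x / (PSP_coeff + (1 − PSP_coeff)·x),   PSP_coeff = β₂/β₁

so the curvature of the single-cell scatter of (x, y) measures the
relative dephosphorylation rate of the two sites. `fit_psp()` fits this
curve to normalized phospho-fraction pairs inside the 0.1–0.9 window on
both axes. Supporting fits: exponential decay with replicate-level
errors (`fit_exp_decay()`), the dephosphorylation rate ratio with
first-order error propagation (`rate_ratio()`), Hill fits of
phosphorylation versus CDK2 activity (`fit_hill()`), and Deming
errors-in-variables regression (`deming_fit()`).

Around the model sit the imaging and trace layers: nuclear segmentation,
a 0.65–3.25 µm cytoplasmic sampling ring for the CDK2 translocation
reporter (activity = cytoplasmic median / nuclear mean), 15.6 µm
whole-cell regions with FISH foreground-pixel counting (1.3 µm top-hat
kernel), S-entry detection from the CRL4^Cdt2 degron reporter drop, fate
classification (S enter / E2F reverse / undecided), and trace alignment
at S entry stratified by G1 length.

## Worked example

```r
library(primedG1)

## paired phospho snapshots from the two-site model, planted PSP_coeff 4.61
snap <- simulate_phospho_snapshots(2000, beta_ratio = 4.61,
                                   noise_cv = 0.1, seed = 1)$snapshots
x <- normalize_phospho(snap$phospho_x, snap$total_rb, snap$s_phase)
y <- normalize_phospho(snap$phospho_y, snap$total_rb, snap$s_phase)
fit_psp(x[!snap$s_phase], y[!snap$s_phase])
#> PSP fit: coeff = 4.494 +/- 0.046 (s.e.), n = 1413 in window [0.1, 0.9]

## dephosphorylation time courses (planted half-lives 40 / 15 / 6 min)
d <- simulate_decay_experiment(seed = 1, plateau = 0)
# ... fit each site with fit_exp_decay(), then:
#> Exponential decay fit (3 replicates):
#>   k = 0.01655 +/- 0.00014 min^-1, half-life = 41.9 min
rate_ratio(fit_s807, fit_t373)
#> dephosphorylation preference (S807/S811 over T373): 6.72 +/- 0.24

## synthetic traces -> fate calls
sim <- simulate_traces(sim_config(seed = 1, n_cells = 100))
table(classify_fates(sim$traces)$fate)
#> E2F_reverse     S_enter   undecided
#>          30          57          13   (100% agreement with planted truth)
```

The fitted coefficient (4.49 ± 0.05) recovers the planted preference of
4.61 from 2,000 noisy cells; the 41.9 min half-life recovers the planted
40 min; and the 6.72-fold rate ratio recovers the planted 40/6 = 6.67.

A full pipeline run (`simulate → quantify → traces → psp`) with manifest
and fit reports:

```r
run_pipeline(run_config(seed = 1), "my_run")
```

or from a shell: `Rscript inst/cli/g1primed.R run --out my_run --seed 1`.

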