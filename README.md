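# rtici

Tumor–immune dynamics of combined radiotherapy (RT) and CTLA-4 immune
checkpoint inhibition (ICI), for quantitative-systems-pharmacology work on
treatment design: which patients benefit from adding CTLA-4 blockade
(tremelimumab) to radiation, how the irradiated share of the tumor burden
shapes control of distant (non-irradiated) lesions, and in which order the
two modalities should be given.  The intended users are modelers and
radiation-oncology methodologists running in-silico trials, not clinical
decision-makers.

## The model

Four compartments — irradiated viable tumor cells $T_I$, dying tumor cells
$I$, non-irradiated viable tumor cells $T_{NI}$, and circulating
lymphocytes $L$ — evolve between treatment events as

$$
\dot T_I = a T_I - \omega_1 \tfrac{T_I}{g + T_I + T_{NI}} L, \quad
\dot I = -r I, \quad
\dot T_{NI} = a T_{NI} - \omega_1 \tfrac{T_{NI}}{g + T_I + T_{NI}} L,
$$

$$
\dot L = \omega_2 (1 + \delta(t)) \tfrac{T_I + T_{NI}}{g + T_I + T_{NI}} L
 + \omega_3 \tfrac{I}{g + I} L + s - f L,
$$

where the drug efficacy $\delta(t) = \delta_0 e^{-\lambda (t - t_{dose})}$
decays from each administration with the tremelimumab half-life
($\lambda = \ln 2 / t_{1/2}$).  Each radiation fraction is an
instantaneous linear–quadratic kill:
$T_I \mapsto T_I e^{-\alpha_T D_T - \beta_T D_T^2}$ with the killed cells
moved to $I$, and $L \mapsto L e^{-\alpha_L D_L}$.  Lesion diameters
follow from cell counts through sphere volume at $10^9$ cells/cm³, and
responses are classified under RECIST 1.1 (monthly assessments over one
year).  The per-patient efficacy $\delta_0$ is calibrated so that a
simulated drug-only cohort reproduces the response rates reported for
tremelimumab monotherapy (CR 0%, PR 17.6%, SD 58.8%, PD 23.6%): a
response curve over fixed efficacies 0–99 is convolved with candidate
normal distributions and $(\mu, \sigma)$ is chosen by grid search.  The
methods vignette (`vignettes/tumor-immune-rt-ici.Rmd`) documents every
equation, assumption and numerical choice.

## Worked example

One virtual patient with a 5 cm total burden split evenly between an
irradiated and a distant lesion, treated with 5 × 8 Gy daily fractions
plus quarterly tremelimumab of efficacy 42:

```r
library(rtici)
p <- model_parameters()
patient <- burden_to_initial_state(diameter = 5, itf = 0.5,
                                   lymphocytes = p$s / p$f)
state0 <- system_state(patient$T_I, patient$I, patient$T_NI, patient$L)
schedule <- treatment_schedule(rt = rt_fractions(),
                               ici = ici_pharmacodynamics(delta0 = 42),
                               horizon = 365)
traj <- simulate_patient(state0, p, schedule)
subset(as.data.frame(traj), time_d %in% c(0, 91.25, 182.5, 365),
       select = c(time_d, diameter_irr_cm, diameter_nonirr_cm, L, delta_trem))
#>    time_d diameter_irr_cm diameter_nonirr_cm           L delta_trem
#> 1    0.00            3.97               3.97  4454545455      42.00
#> 14  91.25            0.26               4.69  5811615345      40.38
#> 17 182.50            0.28               4.96  8185208253      38.82
#> 23 365.00            0.27               4.91 10265154659      35.88
```

Radiation nearly eradicates the irradiated lesion (4.0 cm → 0.3 cm) while
the distant lesion first grows and is then held by the drug-expanded
lymphocyte pool ($L$ rises from 4.5 to 10.3 billion).  At the cohort
level:

```r
cohort <- sample_cohort(population_config(n_patients = 100, seed = 1), p)
sim <- simulate_cohort(cohort, p, schedule)
ev <- evaluate_cohort(sim, lesion = "sum")
summarize_response(ev$category, ev$best_change_pct)
#> RECIST summary over 100 evaluable patient(s)
#>   CR 0.0%  PR 38.0%  SD 0.0%  PD 62.0%   CBR 38.0%
```

The experiment drivers `run_modality_comparison()`, `run_itf_sweep()` and
`run_sequencing_sweep()` compare the four treatment arms, sweep the
irradiated tumor fraction, and sweep the RT-vs-drug start offset; all are
seeded, emit tidy tables with provenance blocks, and can be driven from a
shell through `inst/cli/rtici.R` (subcommands `calibrate`,
`simulate-cohort`, `modality-compare`, `itf-sweep`, `sequence-sweep`).

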