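# gpcrsel

Quantifying **efficacy-driven agonist selectivity** at G-protein-coupled
receptors.

Some drugs are selective for one receptor subtype not because they bind it
more tightly (affinity-driven selectivity) but because, once bound, they
activate it more strongly (efficacy-driven selectivity). Demonstrating the
second mechanism — as has been done for the muscarinic M4-preferring agonist
xanomeline — takes a specific quantitative toolchain, which this package
implements end to end:

1. **Radioligand binding** — one-site saturation
   (`Y = Bmax·[A]/([A]+K_A) + NS·[A]`), one/two-site competition
   (`Y = (Top−Bottom)·(f₁/(1+10^(log[B]−logIC50₁)) +
   (1−f₁)/(1+10^(log[B]−logIC50₂))) + Bottom`) and the Cheng–Prusoff
   conversion `K_i = IC50/(1+[A*]/K_d)`, all reported as pK values
   (−log₁₀ molar).
2. **Operational model of agonism** (Black–Leff) —
   `Y = Basal + (Em−Basal)/(1 + (10^{logK_A}+10^{log[A]})/(10^{logτ}·10^{log[A]}))`,
   with the agonist K_A constrainable to the binding-derived K_i and the
   efficacy τ corrected for receptor expression (τ_C, exploiting τ ∝ R_T).
3. **Ternary complex model** — exact mass-action equilibrium of ligand L,
   receptor R and G protein G (species R, G, L, LR, RG, LRG; cooperativity α
   = fold-increase in agonist affinity at the G-protein-bound receptor),
   used to predict radioligand displacement across a G-protein titration, to
   fit (pK_L, α, pK_G) globally, and to convert affinities to state free
   energies `ΔG = −RT·ln10·pK`, `ΔΔG = −RT·ln α`.
4. **Trajectory state metrics** — χ1-rotamer and Cα-distance threshold
   classifiers for MD-derived feature series (channel-open: N6.52 χ1 in
   (−50°, 100°); active: TM3–TM6 Cα(3.46–6.37) > 10 Å; TM6-outward:
   Cα(4.57–6.55) > 20.7 Å; vertical ligand tail: < 8.9 Å to the ECL2
   anchor), equilibration masking, 30-ns moving averages and per-simulation
   state frequencies.
5. **Group statistics** — percentile bootstrap 68% CIs of the mean and the
   two-sided Mann–Whitney U test (exact by enumeration for small samples
   without ties, tie/continuity-corrected normal approximation otherwise).
6. **Synthetic data** — seeded generators for all of the above (dose–response
   curves, binding curves, two-state Markov feature traces with known state
   labels) so every stage is verifiable against ground truth without any
   download.

## Worked example

Simulate a pERK-style concentration–response curve (τ = 10^0.5 ≈ 3.2, pK_A
= 7, 5% noise), fit the operational model with K_A fixed at the
binding-derived value, and correct the efficacy for receptor expression:

```r
library(gpcrsel)
spec <- dose_response_spec(basal = 2, em = 100, log_ka = -7, log_tau = 0.5,
                           conc_grid = seq(-10, -4, length.out = 8),
                           n_replicates = 3, noise_sd = 5, seed = 1)
fit <- fit_operational(generate_dose_response(spec), log_ka_fixed = -7)
fit
#> Operational model fit
#>   Basal 1.999 +/- 2.066, Em 95.82 +/- 5.058
#>  ligand log_ka log_ka_se log_ka_fixed   log_tau log_tau_se
#>  ligand     -7         0         TRUE 0.5860149 0.09386024

correct_efficacy_for_expression(fit$ligands$log_tau, fit$ligands$log_tau_se,
                                expression_target = 1800,   # fmol/mg
                                expression_reference = 650)
#> $log_tau_c     0.1439817   # log tau rescaled to the reference expression
#> $log_tau_c_se  0.09386024
```

The fitted logτ (0.59 ± 0.09) recovers the generating value 0.5; the
correction subtracts log₁₀(1800/650) because τ scales linearly with receptor
density.

Fit the ternary complex model to a simulated G-protein titration (truth:
pK_L = 6.9, log₁₀α = 3.3, pK_G = 8) and convert to free energies:

```r
g_ladder <- c(0, 1e-9, 1e-8, 1e-7)   # molar G protein per curve
curves <- lapply(g_ladder, function(g) {
  cv <- predict_competition_curve(ternary_model(6.9, 10^3.3, 8, 1e-10, g),
                                  radioligand_p_kd = 9.5,
                                  radioligand_conc = 10^-9.5,
                                  competitor_grid = seq(-11, -3, length.out = 10))
  set.seed(1 + round(1e10 * g))
  cv$signal <- cv$signal + rnorm(nrow(cv), 0, 0.02)
  cv
})
tfit <- fit_ternary(curves, g_ladder, r_tot = 1e-10,
                    radioligand_p_kd = 9.5, radioligand_conc = 10^-9.5)
tfit
#> Ternary complex model fit
#>   pK_L (low-affinity pKi)  = 6.916 +/- 0.02914
#>   log10 alpha              = 3.291 +/- 0.04578
#>   pK_G                     = 8.059 +/- 0.05735
#>   implied high-affinity pKi = 10.21
free_energies(tfit$model)
#> Binding free energies (kcal/mol, 310.15 K, 1 M standard state)
#>   L + R   -> LR  :   -9.815
#>   L + RG  -> LRG :  -14.485
#>   G + R   -> RG  :  -11.438
#>   G + LR  -> LRG :  -16.108
#>   coupling ddG   :   -4.670
```

The coupling energy −4.67 kcal/mol is −RT·ln α; the thermodynamic cycle
closes exactly (ΔG(L,R) + ΔG(G,LR) = ΔG(G,R) + ΔG(L,RG)). For the published
high-affinity pKi pair of a G-protein-bound receptor at two subtypes
(7.10 vs 10.42):

```r
affinity_fold_shift(7.10, 10.42)   # 2089.296  -> "more than 1,000-fold"
delta_delta_g(7.10, 10.42, 310.15) # -4.711596 -> ~5 kcal/mol
```

## Command line

Each stage writes provenance-stamped artifacts plus a JSON-lines manifest:

```sh
Rscript -e 'quit(status = gpcrsel::gpcrsel_cli())' simulate    --output-dir out --seed 1
Rscript -e 'quit(status = gpcrsel::gpcrsel_cli())' full-report --output-dir out --seed 1
```

Stages: `simulate`, `fit-saturation`, `fit-competition`, `fit-operational`,
`fit-ternary`, `traj-features`, `traj-states`, `compare-groups`,
`full-report`. Configuration is a JSON file (`--config cfg.json`) with one
block per stage; flags override it. Exit codes: 0 success, 2 config error,
3 data error, 4 numerical failure.

## Documentation

The methods vignette (`vignettes/gpcrsel-methods.Rmd`) describes the models,
their assumptions, the synthetic-data design, numerical choices and known
limitations.
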