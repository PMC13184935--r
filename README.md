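# memwash

Kinetic analysis of membrane-mediated potentiator washout.

Lipophilic channel potentiators — such as CFTR potentiators carrying
membrane-exposed alkyl substituents — reach and leave their binding site
through the lipid bilayer. When such a compound is washed out of a patch-clamp
experiment, the current decay reports not just protein unbinding but the
interplay of protein rebinding and membrane escape. `memwash` is for
pharmacologists and modellers who want to analyse that interplay
quantitatively: it implements the three-state (water / membrane /
protein-bound) washout model, generates realistic synthetic patch-clamp
traces, estimates potentiation and decay constants from traces, links washout
rates to substituent hydrophobicity, and demonstrates weighted-ensemble
rare-event rate estimation at desk scale.

## The model

With `B` the bound-ligand concentration, `M` the free membrane concentration,
`P_t` the total site concentration and `K_d = k_-a / k_a`, washout (drug-free
bath) follows

    dB/dt = k_a (P_t - B) M - k_-a B
    dM/dt = k_-a B - k_a (P_t - B) M - k_lw M

Two regimes bracket the behaviour:

* **Scenario 1, fast escape** (`k_lw >> k_a P_t`): exponential decay with the
  protein residence time `T = 1 / k_-a`.
* **Scenario 2, fast rebinding** (`k_a P_t >> k_lw`): non-exponential decay,
  well approximated by a single exponential with
  `T = P_t / (1.53 K_d k_lw)`.

Since the membrane exit rate scales with the hydrophobicity of the conjugated
R group as `k_lw ∝ 10^(-logP/2)`, scenario 2 predicts that washout rates of an
analog series collapse onto `rate = A · 10^(-logP/2)` with a single shared
constant `A` — a structure–kinetics law the package fits with a ratio loss and
summarizes with an `r²` on mean rates.

## Worked example

Run the end-to-end synthetic analysis: generate seeded replicate traces for
the isobutyl (C3), hexyl (C6) and decyl (C10) analogs at 5% noise, estimate
potentiation and washout constants per trace, and fit the logP rate law
across analogs.

```r
library(memwash)
report <- run_pipeline(pipeline_config(seed = 5))
print(report)
```

```
Synthetic washout analysis
    analog rgroup_logP n potentiation_mean potentiation_sd tau_mean_s tau_sd_s
  CFTRi-C3           2 7             2.940        0.005945      3.244  0.01042
  CFTRi-C6           3 3             1.742        0.001913     10.124  0.08930
 CFTRi-C10           5 4             2.522        0.002277     89.555  0.31998

logP rate model: rate = 3.222 * 10^(-logP/2) /s   (r2 = 0.996)
      name rgroup_logP mean_tau_s predicted_tau_s mean_rate predicted_rate tau_ratio
  CFTRi-C3           2      3.244           3.103   0.30830        0.32223    1.0452
  CFTRi-C6           3     10.124           9.814   0.09878        0.10190    1.0316
 CFTRi-C10           5     89.555          98.137   0.01117        0.01019    0.9125
```

Reading the output: the recovered fold-potentiations match the per-analog
presets (2.94, 1.74, 2.52); the fitted washout constants grow steeply with
chain length (3.2 s → 10.1 s → 89.6 s); and a single proportionality constant
`A = 3.22 /s` places all three mean rates within ~9% of the
`10^(-logP/2)` prediction (`r² = 0.996` on mean rates), the fast-rebinding
signature.

Individual pieces are available directly:

```r
p <- kinetic_params(k_a = 1e4, k_minus_a = 100, k_lw = 13, k_wl = 13000, P_t = 1)
classify_regime(p)                      # "scenario-2"
scenario2_tau(p)                        # 5.03 s
scenario2_prefactor(method = "full")$prefactor   # 1.53: recomputed, not assumed
```

A thin command-line front end ships in `inst/cli/memwash` with subcommands
`simulate`, `fit`, `link`, `we-demo`, `pipeline` and `config`.

## Learn more

The methods vignette (`vignettes/memwash-methods.Rmd`) documents the model
assumptions, the reconstruction of the 1.53 prefactor conditions, the
estimator conventions and their windows, the synthetic-data generator's
scope, the weighted-ensemble design choices, and known limitations.
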