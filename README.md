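# syntroscreen

Analysis pipeline for high-throughput growth-complementation screens that
detect **spontaneously syntrophic pairs of auxotrophic yeast strains** from
microplate OD600 readings, and for characterizing the resulting cocultures
with dual-fluorophore subpopulation tracking.

Most pairs of *S. cerevisiae* auxotrophs cannot cross-feed each other on
minimal medium; the rare pairs that can are found by co-inoculating every
pair of library strains at a 0.1 OD600 inoculum, reading plates at 0 h and
48 h, and asking which cocultures grow substantially better than either
constituent alone. The package provides:

- **plate I/O** — wide-matrix and long plate-reader exports (96/384-well),
  layout and strain tables, annotated result CSVs;
- **QC cascade** — blank correction, MAD-based replicate-spread flags,
  contamination detection with neighborhood warnings, positional-bias
  detection (edge effect + row/column median polish), and Z-factor
  activity-range gating,
  `Z = 1 − 3(σ_co + σ_mono)/|μ_co − μ_mono|`;
- **hit calling** — fold difference against the fittest constituent
  monoculture (`FC = ḡ_co / ḡ_mono`), two-sided Welch's *t*-test,
  Benjamini–Hochberg correction across the screen, hit rule
  `p_adj < 0.05 AND FC ≥ 1.5`, volcano export;
- **population dynamics** — per-strain fluorescence/OD calibration curves,
  2×2 linear unmixing of blue/red channel readings into per-strain ODs,
  proportion trajectories, and stability across serial passages;
- **synthetic data** — a screen simulator with planted syntrophic pairs,
  contamination, positional bias and leaky auxotrophs, plus an RK4
  cross-feeding ODE model, so every stage is testable with known truth.

## Worked example

The `analysis/` scripts run the whole pipeline on simulated screens.
`01_simulate_screen.R` generates a 24-strain strict-auxotroph library with
40 planted syntrophic pairs (effect 0.5 of carrying OD) and a 64-strain
null library; `02_screen_qc.R` and `03_hit_calling.R` then print:

```
wells: 1232
hard flags by filter:
  replicate_spread   79
  contamination      0
  positional_bias    72

cocultures tested: 44  (dropped: 232)
hits: 40   not called: 4   unique strains among hits: 23
planted-pair recall 1.000, precision 1.000
null screen: 2016 pairs tested, hit fraction 0.0000 (bound 0.0649)
```

Reading this: of 276 simulated cocultures, 232 are dropped — almost all by
the activity-range gate, because under the null model a coculture grows
exactly as well as its leakier partner, leaving no assay window (the same
mechanism that dominated dataset reduction in real screens). All 40
planted syntrophic pairs are recovered as hits with no false positives,
and on the 2,016-pair null screen the hit fraction stays within the
Monte-Carlo bound of the nominal false-discovery level.

`04_population_dynamics.R` unmixes simulated dual-channel trajectories
over the nine inoculation ratios (1:20 … 20:1, total OD 0.10) and checks
composition stability over two serial passages:

```
inoculation ratios: 9 series, mean |proportion error| 0.0051
serial passage: final proportion delta 0.0118 -> re-established
```

In code, the same flow is three calls:

```r
library(syntroscreen)
sim <- simulate_screen(screen_sim_params(n_strains = 12, seed = 1))
res <- run_screen(sim$tidy, sim$conditions)     # QC + hit calling
res$summary                                     # counts per call tier
```

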