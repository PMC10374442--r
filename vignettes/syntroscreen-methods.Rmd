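---
title: "Methods: detecting spontaneous syntrophy in coculture screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting spontaneous syntrophy in coculture screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntroscreen)
```

## The problem

Most pairs of *Saccharomyces cerevisiae* auxotrophs cannot grow together on
minimal medium: each partner lacks a nutrient the other would have to
supply, and in the typical case neither exports enough of it. A
high-throughput growth-complementation screen tests this systematically —
every auxotroph is co-inoculated pairwise with every other at a fixed total
inoculum (0.1 OD600 equivalents) in 384-well plates, and cell density is
read at 0 h and 48 h. A coculture is syntrophic when it grows substantially
better than either of its constituents alone. The signal is rare (a few
percent of pairs) and the data are noisy: robotic pinning introduces
position-dependent artifacts, some wells get contaminated, and a sizable
fraction of "auxotrophs" leak — they grow slowly on their own by 48 h,
erasing the window in which synergy could be seen. This package implements
the full analysis path from plate-reader exports to hit calls, plus the
fluorescence-based estimation of who is actually in a coculture over time.

## Growth metric and QC cascade

The growth value of a well is the blank-corrected OD gain
$g = \mathrm{OD}_{48} - \mathrm{OD}_{0} - \tilde{b}$, floored at zero,
where $\tilde{b}$ is the median OD gain of the blank wells on the same
plate. Subtracting the 0-h reading removes the inoculum; the plate-blank
median removes shared drift. No other normalization touches the values:
QC flags gate which wells enter hit calling, they never adjust data.

Four filters act in sequence:

* **Replicate spread.** Within a condition, a replicate is flagged when it
  deviates from the replicate median by more than $k \cdot 1.4826 \cdot
  \mathrm{MAD}$ with $k = 3$. The 1.4826 factor makes the MAD comparable
  to a Gaussian standard deviation; $k = 3$ is the conventional robust
  3-sigma rule. When the MAD is exactly zero (instrument-identical
  replicates) the rule degenerates and an absolute margin
  (`blank_margin`, 0.05 OD) is used instead. At $n = 4$ replicates this
  rule inherently flags about 5–6% of clean Gaussian replicates (the MAD
  is a noisy spread estimate at such small $n$); that, plus a few percent
  from the positional test below, is the false-flag budget the test suite
  asserts (10% of wells) on artifact-free simulations.
* **Contamination.** Blank wells growing past `blank_margin`, and
  strict-auxotroph monoculture wells that grow while their condition
  median does not, are flagged as contaminated. Because sealing-film
  handling spreads material locally, the 8-connected neighbors of a
  flagged well inherit a soft warning.
* **Positional bias.** Two per-plate tests on assay wells, either of which
  flags: an edge-vs-interior median gap exceeding `edge_bias_k` (3)
  scaled MADs of the interior, and per-well additive row+column effects
  fit by median polish exceeding the same multiple of the residual MAD.
  These are the two standard microplate artifacts (perimeter evaporation
  and seal handling; systematic row/column gradients); other detectors
  can be slotted behind the same flag interface. Plates whose assay wells
  carry fewer than two distinct conditions offer no contrast and are
  skipped with a warning.
* **Activity range.** For each pair assay the Z-factor
  $Z = 1 - 3(\sigma_{co} + \sigma_{mono}) / |\mu_{co} - \mu_{mono}|$
  is computed between the coculture replicates and those of its fittest
  constituent monoculture. Assays with $Z <$ `z_threshold` (0.5, the
  conventional excellent-assay cut) are dropped: a leaky, high-growing
  monoculture leaves no window in which a synergy could be measured. The
  fittest monoculture is used as the negative group because it is the
  reference the effect size is measured against; equal means return a
  $-\infty$ sentinel and the assay is dropped.

## Hit calling

For each surviving coculture the effect size is the fold difference
$\mathrm{FC} = \bar{g}_{co} / \max(\bar{g}_{mono}^{fit}, 10^{-3})$
against the fittest constituent monoculture (the $10^{-3}$ floor keeps
the ratio finite when the monoculture does not grow — which is the
interesting case — and is flagged whenever it binds). Significance comes
from a two-sided Welch's *t*-test between the two replicate groups, with
Welch–Satterthwaite degrees of freedom; when both groups have zero
variance, differing means give $p = 0$ and equal means $p = 1$, each with
a degeneracy flag. Raw *p*-values are Benjamini–Hochberg adjusted across
all tested cocultures of the run as one family (per-batch correction
would trade power for batch isolation the screen does not need).

A coculture is a **hit** when $p_{adj} < 0.05$ and
$\mathrm{FC} \ge 1.5$. A *near-hit* tier
($\mathrm{FC} \ge 1.5$, $0.05 \le p_{adj} < 0.10$) is reported but never
counted: borderline pairs are worth a second look (some of the screen's
reconstructed pairs sat just above the threshold) without changing any
headline count. The volcano export carries $\log_2 \mathrm{FC}$ and
$\ln p$ for both raw and adjusted *p* (captions in the field are
inconsistent about which is plotted; exporting both is cheaper than
guessing), with $p < 10^{-300}$ clamped before the log.

Auxotroph classification itself uses the strict rule: growth below 20% of
the prototrophic parent in minimal medium **and** at least 50% of the
parent on complete medium. The 20% boundary is strict (`<`) — "below a
fifth of the parent" reads as exclusive, and the choice is configurable;
50% on complete medium separates auxotrophy from general sickness, and is
likewise a configurable default since "grows well" carries no number.

## Subpopulation unmixing

Each strain of a characterized pair carries one fluorophore (blue,
ex400/em465, or red, ex560/em620). Per strain and channel, a calibration
line `intensity = slope * OD + background` is fit by ordinary least
squares to a nine-point monoculture dilution series (ODs 0.95 down to
0.05). Two-channel readings of a coculture then unmix through the
$2 \times 2$ linear system $A \cdot od = F - bg$; cross-channel slopes
default to zero because the two channels are spectrally well separated,
but measured crosstalk curves drop into the same matrix. Matrices with
condition number above $10^{12}$ are rejected by name. Negative unmixed
ODs are clipped to zero (noise near a vanishing subpopulation) and
logged; the blue proportion is defined only where the unmixed total is
positive. Total OD600 is carried alongside but not used to constrain the
solve — with two channels and two strains the system is exactly
determined, and the constraint would mix absorbance and fluorescence
error models.

Stability across serial passages (48 h growth, wash, dilute to total OD
0.10, regrow) is summarized by the absolute difference of the final blue
proportions, with "re-established" meaning a difference of at most
`stability_tolerance` (0.15 — an invented, configurable default; the
qualitative observation it encodes is that composition re-emerges, and
0.15 is wide enough to absorb replicate noise while rejecting a
collapsed community). The Pearson correlation of the two trajectories on
the common time grid is also computed, but it is only informative when
both passages traverse a real trend: a community re-inoculated at its
equilibrium composition produces a flat second trajectory whose
correlation with anything is noise. The analysis scripts therefore
report the final-proportion delta and the classification, not the
correlation, for near-equilibrium communities.

## The synthetic screen

The generator exists so that every stage has ground truth. Its defaults
are the conditions the pipeline is meant for: 384-well plates, 4
replicates per condition, 0.1 OD inoculum, 8 blanks per plate, 48-h
endpoint. Growth is generated as

* monoculture of strain $s$: $0.1 + \ell_s K$, with leakiness
  $\ell_s = 0$ for strict auxotrophs; about 27% of strains are leaky
  (uniform $\ell \in [0.1, 0.6]$), matching the leaky fraction the
  physical screen discovered in its library;
* coculture of $a, b$: $0.1 + \max(\ell_a, \ell_b) K$ — the null model
  says a coculture grows exactly as well as its leakier partner alone,
  which is what makes the activity-range gate necessary and realistic —
  unless the pair is planted syntrophic, in which case
  $0.1 + \sigma_{pair} K$ with effect $\sigma_{pair} \in (0, 1]$
  (default 0.5, ten times the multiplicative noise scale: a clear but
  not caricatured synergy);
* every reading is multiplied by lognormal noise (sdlog 0.05) and
  perturbed by additive read noise (sd 0.002 OD) so that blanks are
  noisy too; readings are floored at 0.

Positional bias is planted as an additive field on the 48-h reading
(edge offset plus row/column gradients). An additive field, rather than a
multiplicative one, is deliberate: most wells of a screen sit near zero
growth, where a multiplicative artifact would be invisible — and
undetectable by any method — while real seal-handling artifacts add
signal to non-growing wells. Contamination adds a uniform(0.2, 0.8) OD
boost to sampled wells; sampling can be restricted to wells where
contamination is detectable in principle (blanks and strict-auxotroph
monocultures), which is what the artifact-detection checks use, since a
contaminated coculture well is indistinguishable from growth.

The coculture dynamics model is explicitly phenomenological: two strains
grow logistically, each rate-limited (Monod form, half-saturation `Km`)
by the metabolite its partner exports, with export proportional to
biomass and consumption proportional to partner growth. It is integrated
with fixed-step RK4 (step 0.2 h; halving the step changes trajectories
by under $10^{-4}$ relative, which the suite asserts) — deterministic and
dependency-light, adequate for smooth logistic dynamics. It reproduces
the qualitative phenomenology that motivates the ratio experiments —
obligate dependence (no export, no growth), ratio-dependent lag,
convergence to a composition set by exchange rates rather than growth
rates, re-establishment after passage — and makes no claim of matching
any measured growth curve. No metabolite identity is modeled.

What passing tests on these simulations do **not** show: performance on
real plate-reader artifacts outside the two modeled classes (e.g.,
snake-path drift of a dispenser), non-lognormal noise, secondary
mutations accumulating during passaging, or growth-curve shapes beyond
the logistic family.

## Numerical conventions

* Well coordinates are 0-based row-major internally; canonical
  letter+number labels at all I/O boundaries; parsing is
  locale-independent (decimal point only) and missing cells are missing,
  never zero.
* Fittest-monoculture ties break toward the lexicographically smaller
  condition id (deterministic reruns).
* BH is applied in input order with stable ranking; the adjusted values
  are capped at 1.
* Unmixing solves the exact 2×2 system; round trips are exact to
  $10^{-9}$ in the tests.
* Every simulator accepts a seed and restores the caller's RNG state, so
  a fixed seed reproduces a dataset byte-identically without side
  effects on the session.

## Problem sizes

The validation suite runs a 64-strain null screen (2,016 pairwise
cocultures, 23 plates) for type-I control, a 24-strain screen with 40
planted pairs for power, 12-strain screens for artifact detection, and
72-h dynamics at 0.2-h resolution — sizes chosen so the full suite
exercises every code path on a laptop in about a minute while keeping
the Monte-Carlo bounds meaningful (the type-I bound is
$\alpha + 3\sqrt{\alpha/n}$ at $n \approx 2000$).

One deliberate asymmetry: on the null screen the type-I property is
measured with the activity-range gate disabled. Under the max-leak null
model the coculture and its fittest monoculture have *equal means by
construction*, so the gate — doing exactly its job — removes every null
pair and would leave the type-I property vacuously true. Disabling it is
the only way to test what the property is about, namely that Welch + BH
+ FC control false calls at the nominal level.

## Known limitations

* The positional-bias mechanism implements the two standard artifact
  classes; the flag *rate* of any particular physical screen depends on
  its raw data and cannot be reproduced from mechanism alone.
* Welch's test at $n = 4$ replicates has limited power for effects near
  the noise floor; the planted-effect recall figures are properties of
  the stated effect size (0.5) and do not transfer to weaker synergies.
* The near-zero growth regime concentrates mass at the floor (growth
  values clipped at 0), which makes the replicate-spread MAD degenerate
  more often than Gaussian theory suggests; the margin fallback handles
  this but is a blunter instrument.
* The stability classification compares endpoints only; communities that
  drift late, after the last common timepoint, are not distinguished.
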