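---
title: "Measuring biological efficiency and competition in two-crop mixtures"
author: "intercrop package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring biological efficiency and competition in two-crop mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intercrop)
```

## The measurement problem

A replacement-series intercropping trial grows two crops — in the system
that motivates this package, Italian ryegrass (IR) and a clover mixture
(C) as a winter catch crop — both in pure stands and together in one
mixture at fixed sown proportions, across sites, seasons and blocks.
Each experimental unit (one site-year) yields the quartet the whole
analysis rests on: pure-stand performances $S_{IR}, S_C$, in-mixture
performances $I_{IR}, I_C$, sown proportions $z_{IR}, z_C$
($z_{IR}+z_C=1$), and the days each crop occupies the field. The same
quartet can be formed on a dry-matter basis (t/ha) or a nitrogen-uptake
basis (kg/ha, uptake $=$ DMY $\times$ N concentration with t/ha
$\times$ g/kg $=$ kg/ha); the package runs both through one code path,
so basis symmetry is structural, not re-implemented.

## The index family and its anchors

The partial relative yield $r_i = I_i/(S_i z_i)$ compares a component's
mixture output with the sown share of its pure stand. Everything else is
algebra on the quartet:

* **Biological efficiency.** Total RYT $= r_{IR} + r_C$ (the land
  equivalent ratio); LEC $= r_{IR} r_C$; SPI
  $= I_{IR} + (S_{IR}/S_C) I_C$ in kg/ha of primary-crop equivalents;
  ATER $= (r_{IR} d_{IR} + r_C d_C)/T$; PYD
  $= 100(I_{IR}/S_{IR} + I_C/S_C - 1)$; LUE $= ($RYT$ + $ATER$/2)\cdot100$.
* **Competition.** Competitive ratio
  $CR_{IR} = [(I_{IR}/S_{IR})/(I_C/S_C)](z_C/z_{IR})$; aggressivity
  $A_{IR} = r_{IR} - r_C$; relative crowding coefficient
  $K_{IR} = I_{IR} z_C / ((S_{IR}-I_{IR}) z_{IR})$; actual yield loss
  $AYL_i = r_i - 1$; land saved $= 100 - 100/$RYT; competitive balance
  $C_b = \log[(I_{IR}/S_{IR})/(I_C/S_C)]$.

A useful anchor is the *competition-neutral* pair $I_i = S_i z_i$: both
partials are 1, so RYT $=$ ATER $= 2$, PYD $= 0$, LSAV $= 50$, and every
competition index sits at its no-effect value ($A = 0$, $C_b = 0$,
$K = 1$, $AYL = 0$). Note that RYT $= 2$ — not 1 — at this point:
replacement-series parity means each crop delivers its full pure-stand
equivalent on its share of the land.

### Choices the formulas leave open

Three definitional ambiguities recur in the applied literature; the
package fixes a default and exposes the alternative:

* **$C_b$ log base.** Natural log by default (`cb_log = "log10"`
  available). On the reference means below, $\ln$ gives 0.71 and
  $\log_{10}$ gives 0.31; reported values near 0.7 for this system pin
  the natural log.
* **LEC.** Default is the product of partial RYTs (sown proportions in
  the denominators); the raw ratio product
  $(I_{IR}/S_{IR})(I_C/S_C)$ — a factor $1/(z_{IR}z_C)$ smaller — is the
  `"raw_ratio_product"` variant. Only the default lands on the
  magnitude-1 scale of reported LEC values for 50:50 mixtures.
* **LUE.** Default `(RYT + ATER/2) * 100`, the reading consistent with
  reported LUE above 300% when RYT $=$ ATER $\approx 2.2$; the plain
  mean `((RYT + ATER)/2) * 100` is the `"conventional"` variant.
* **AYL sown shares.** $AYL_i = I_i/(S_i z_i) - 1$ uses the pair's sown
  proportions by default, but published AYL applications vary in the
  land-share convention they plug in (some values in the literature are
  only reproducible with an effective share of $z/2$, e.g. 0.25 per
  component in a 50:50 mixture). The share is therefore a per-call
  override (`ayl_z_ir`, `ayl_z_c`), never a silent assumption.

Identities are enforced *by construction*: the engine computes
$A_C = -A_{IR}$, $CR_C = 1/CR_{IR}$, and totals as sums/products of the
partial variables, so the invariants hold to the last bit rather than to
a tolerance.

### Degenerate inputs

Ratios fail at well-defined points and the engine flags rather than
throws, so batch runs keep going: $I = S$ makes an RCC denominator zero
(returns `Inf`), $I > S$ makes it negative (signed value plus a
dominance warning — the crowding interpretation is lost); a zero mixture
performance of one crop makes the other's CR infinite; $C_b$ and LSAV
are undefined at zero performances (reported as `NA` with the reason in
the `"issues"` attribute of the index set, all other indices still
computed).

## Aggregation order

`run_pipeline()` exposes both orders because they genuinely differ:

* `per_unit_mean` (default): one index set per unit, then an arithmetic
  mean per index, excluding (and counting) non-finite unit values. This
  matches the usual multi-environment-trial practice of averaging over
  site-years, and it is the order under which linear identities
  ($A_{IR} = -A_{C}$, additive totals) survive aggregation.
* `index_of_means`: average the quartet first, then compute once.

For linear indices the orders agree on balanced data. For the
hyperbolic RCC they can diverge without bound: one unit with
$I \to S$ sends that unit's RCC to infinity while barely moving the
mean quartet. This is exactly why trial-level RCC values reported from
per-unit averaging can sit far above the value recomputed from a table
of mean yields — a regression test encodes the mechanism. Multiplicative
identities ($CR$ and $RCC$ products) are guaranteed per unit only; an
arithmetic mean does not preserve them.

## Small-sample rank correlations

The cross-crop analysis correlates each C-side parameter (mixture DMY
and N uptake, and per-unit RYT, RCC, CR, A, AYL on both bases) with each
IR-side parameter across units. With only $n = 6$ site-years, the
t approximation to Spearman's $\rho$ is unreliable and the attainable
p-values form a coarse grid, so `spearman_exact()` enumerates all $n!$
permutations for $n \le 8$ (configurable) and reports the exact
two-sided $P(|\rho_{perm}| \ge |\rho_{obs}|)$, with midranks under ties.
At $n = 6$: the smallest attainable two-sided p is $2/720 = 0.0028$
($|\rho| = 1$), $|\rho| \ge 31/35 = 0.886$ gives $p = 0.0333 < 0.05$,
and $|\rho| \ge 29/35 = 0.829$ gives $p = 0.0583$, below 0.10 but not
0.05. The two significance tiers are bound accordingly: `**` for
$p < 0.05$ and `*` for $p < 0.10$ — the tier convention used in
small multi-environment trials where $0.05$ is often unattainable for
moderate effects. No multiplicity correction is applied across the
144 cells; the matrix is descriptive. Above the cutoff the usual
t approximation on $n-2$ degrees of freedom takes over.

## The synthetic trial generator

No public plot-level data exist for the motivating trial, so
`generate_trial()` emulates its design as the package's test bed: 3
sites $\times$ 2 seasons $\times$ 4 blocks (blocks per site are never
reported for such trials; 4 is a common RCBD choice and a free
parameter), pure stands around 5.06 (grass) and 4.03 (clover) t/ha,
50:50 sowing, late-August sowing to early-May harvest (so both crops
occupy the field for the full duration and ATER $=$ RYT). The mixture
means are set through the relative performances $\kappa_i$
($I_i = S_i z_i \kappa_i$ before noise), making $\kappa_i$ exactly the
expected partial RYT; the defaults 1.50 and 0.73 encode the strongly
complementary grass-dominant mixture the reference trial reports.
$\kappa$ accepts per-unit vectors, which is how tests plant a monotone
IR-up/C-down structure and obtain a known all-negative correlation
matrix.

Noise is multiplicative log-normal — yields are positive and field-trial
dispersion is naturally expressed as a CV — at two levels, both
defaulting to CV $= 0.10$ (typical forage-trial magnitudes; true
variance components are not recoverable from published means):
between units on the pure-stand means, and between blocks within a
unit (mean-1 noise). Because the between-unit draw scales a component's
$S$ and $I$ together, ratio indices vary across units only through the
within-block level; quadrat subsampling is folded into that CV rather
than modelled separately. Nitrogen concentrations (defaults 24 g/kg
grass, 32 g/kg clover — grasses dilute N more than legumes — CV 0.05)
are drawn independently of yield; real grass-legume data show
yield-N dilution coupling, so passing N-basis tests demonstrates
correct plumbing of the basis, not realism of N dynamics. Blocks are
pure noise (no block $\times$ treatment interaction), matching the RCBD
intent.

The generator returns its own ground truth (noise-free unit pairs and
their exact index sets on both bases), giving downstream stages a
bookkeeping oracle: with all CVs at zero the pipeline must reproduce the
closed-form index sets exactly, and with noise the per-unit-mean RYT
must be unbiased for $\kappa_{IR} + \kappa_C$ (verified over 500 seeded
replicates at CV 0.05; a ratio-of-block-means curvature bias of order
$CV^2/n_{blocks} \approx 10^{-3}$ is the only expected deviation).

What the generator does *not* emulate — weather and soil processes,
site fertility gradients, clover winter-kill, the internal
crimson/red clover split (the two clovers are one pooled component, as
every two-crop formula requires) — bounds what green tests mean for
real data: they certify the arithmetic, the data path and the
statistical machinery, not agronomic realism.

## Numerical conventions

Dates are ISO-8601; durations are exclusive day counts
(harvest $-$ sowing), a convention that never changes ATER when both
crops span the whole season. Unit means are plain arithmetic means of
block records (balanced designs make unit-mean and mean-of-block-means
identical to $10^{-12}$, and a test holds that). Nitrogen consistency
(`n_uptake = dmy * n_conc` when both are present) is enforced at
relative tolerance $10^{-6}$; units with incomplete N data are excluded
from the N basis with a warning, never imputed — the indices are ratios
and imputation would bias them invisibly. Problem sizes used by the
test suite (1000 random pairs for the identity/oracle sweep, 500
generator replicates for the recovery check, full enumeration up to
$n = 7$ against an independent oracle) were chosen to make Monte-Carlo
error negligible relative to the asserted tolerances.

## Worked reference unit

```{r}
fixture <- generate_table1_fixture()
pair <- build_stand_pairs(fixture, basis = "dmy")
round(c(ryt_c = ryt_partial(pair$idm_c, pair$sdm_c, pair$z_c),
        ryt_total = compute_index_set(pair)$ryt_total,
        cb = cb(pair)), 4)
```

The clover runs at 73% of its sown-share expectation while the system as
a whole delivers 2.23 pure-stand hectare-equivalents per hectare; the
positive $C_b$ says the grass is the advantaged competitor.

```{r}
run_pipeline(pair)
```
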