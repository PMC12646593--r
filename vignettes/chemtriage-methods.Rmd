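---
title: "Models and methods behind chemtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemtriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtriage)
```

# The problem

Assembling a chemical collection for cross-species toxicity screening
means reconciling three things: the physical chemistry that decides
whether a compound can even be dosed reproducibly in small-volume
bioassays, the practical logistics of buying and shipping it, and the
scientific goal of covering a diverse set of toxicity mechanisms without
redundancy. `chemtriage` implements that workflow end to end for tabular
chemical records, together with the dosimetry and baseline-toxicity
models needed to plan test concentrations, and a seeded synthetic
generator so the whole pipeline can be exercised without any external
data source.

# Speciation

Ionizable chemicals exist as a pH-dependent mixture of charge states.
Each acid or base group is treated as an independent two-state system:
an acid's deprotonated (-1) form carries relative weight
$10^{\,\mathrm{pH} - \mathrm{p}K_a}$ against its neutral form, a base's
protonated (+1) form $10^{\,\mathrm{p}K_a - \mathrm{pH}}$. With at most
two groups of each kind, the net-charge distribution over $-2\ldots+2$
is the convolution of the per-group distributions, normalized over all
microstates (`species_fractions()`). This is algebraically identical to
enumerating every protonation microstate, which is exactly what the test
suite's independent oracle does. All net-neutral microstates — including
zwitterions — are pooled into `f_neutral`, which is why zwitterionic
profiles need no special arithmetic, only a reporting flag.

Only the neutral species has appreciable vapor pressure, so the
ionization-corrected air–water distribution ratio is
$D_{aw}(\mathrm{pH}) = K_{aw} \cdot f_{neutral}$. The package accepts
$\log K_{aw}$ directly as a dimensionless input and leaves any
Henry-coefficient unit or temperature conversion to the caller, since
conventions differ between data sources.

pH defaults to 7.4 everywhere a pH is optional — the physiological value
at which the bioassay models are parameterized.

# Partition models

Neutral-species partition constants toward membrane lipid (liposomes),
serum albumin, and structural (muscle-type) protein are predicted from
$\log K_{ow}$ through configurable linear maps
(`linear_map_model()`). In production these slots would be filled by
LSER-based or consensus predictors; the shipped defaults
(`default_partition_models()`) are deliberately simple, documented
calibrations:

* liposome–water: $1.01 \log K_{ow} + 0.12$ — membrane lipid tracks
  octanol closely;
* albumin–water (neutral): $0.71 \log K_{ow} + 0.42$;
* albumin–water (anions): $0.30 \log K_{ow} + 2.00$ — anions bind serum
  albumin much more strongly than their hydrophobicity alone suggests,
  so the map is flatter with a high offset;
* structural protein–water: $0.76 \log K_{ow} - 0.46$ — weaker than
  albumin, as muscle proteins bind neutral organics less avidly.

The ionization-corrected distribution ratios are species-weighted sums
of per-species constants. Three species rules matter:

1. Charged species partition into membranes roughly an order of
   magnitude more weakly than the neutral species; `dlipw_at_ph()`
   applies a configurable `ion_offset` (default 1 log unit).
2. Cations are assumed to bind albumin like the neutral species; anions
   go through the dedicated anion map. For structural protein the anion
   term is further attenuated by `anion_attenuation` (default 1 log
   unit).
3. For hydrophilic chemicals ($\log K_{ow} < 2$) the albumin constant is
   fixed at 1.31. Whether that printed constant is a $\log_{10}$ value
   or the linear ratio is genuinely ambiguous in the sorption
   literature; the package reads it as $\log_{10} K_{BSA/w}$ (a linear
   ratio of 1.31 L/L would imply essentially no protein binding at all,
   which is implausible against measured data for weakly bound
   organics), and exposes `floor_scale = "linear"` for the other
   reading. The consequences for the freely dissolved fraction are
   discussed below.

$\log D_{lip/w}$ is clipped from below at $-1$, the empirical lowest
membrane distribution ratio; below it the narcosis QSAR is not valid in
any case.

# The in vitro mass balance

In serum-supplemented medium the relevant loss processes are binding to
medium proteins and lipids and uptake into cells; plastic binding is
negligible when serum is present (with one caveat for cations on
tissue-culture-treated plates, for which the package emits a warning
because treated surfaces are anionic and no binding constants exist).
The freely dissolved fraction is

$$f_{free} = \frac{1}{1 + D_{medium/w}\frac{V_{protein+lipid}}{V_{medium}}
  + D_{cell/w}\frac{V_{cell}}{V_{medium}}}$$

with $D_{medium/w}$ a volume-fraction-weighted combination of
$D_{BSA/w}$ and $D_{lip/w}$ and $D_{cell/w}$ of $D_{SP/w}$, $D_{lip/w}$,
and cell water. One subtlety deserves a note: the medium volume
fractions can be defined against the sorptive-phase volume or against
total medium volume. The defaults (0.3% protein, 0.007% lipid for 10%
fetal bovine serum; 3% protein, 0.5% lipid, 96.5% water for cells) only
balance when `d_medium_w()` uses sorptive-phase-normalized fractions
with the total sorptive volume applied as a separate multiplier in
`f_free()`, while the nominal-dose expression uses per-volume fractions
directly. Both paths are verified mutually consistent against an
explicit three-compartment mass-balance oracle at $10^{-12}$ in the test
suite. The cell term defaults to zero: at 10% serum, cellular uptake is
a negligible share of total mass unless a cell volume is supplied.

Baseline cytotoxicity is anchored to the critical membrane
concentration of 26 mmol per liter of membrane lipid for a 10%
proliferation-reduction endpoint, nearly invariant across cell types.
`ic10_free()` divides it by $D_{lip/w}$; `ic10_nominal_baseline()`
additionally scales up for medium and cell sorption. All public returns
are in mol/L, with the constant stored in its conventional mmol/L units
and converted explicitly.

## What the availability model can and cannot reproduce

A common rule of thumb states that chemicals with
$\log D_{lip/w} < 3$ are essentially fully dissolved in 10% serum
medium while those above 5 are almost completely bound. The second half
holds in this parameterization (the sweep in the acceptance suite
measures $f_{free} \le 0.033$ above 5). The first half cannot hold
exactly, for two arithmetic reasons worth stating plainly:

* at $\log D_{lip/w} = 3$ the medium lipid term alone gives
  $f_{free} = 1/(1 + 10^{3}\cdot 7\times10^{-5}) = 0.935$, independent
  of any protein-binding model;
* with the hydrophilic albumin floor read as $\log_{10}K = 1.31$
  ($K \approx 20$ L/L), the protein term bounds $f_{free}$ at about
  0.942 for *every* hydrophilic chemical.

So "fully dissolved" is accurate only in the loose visual sense
($f_{free} \gtrsim 0.9$). The acceptance suite keeps the strict
$f_{free} > 0.95$ assertion as stated and lets it fail rather than
weakening it; the package-level tests assert the properties the model
actually has (monotone decline of $f_{free}$ with hydrophobicity, the
bound-above-5 band, and $f_{free} > 0.9$ at the hydrophilic end).

# Baseline-toxicity QSARs

The narcosis model is $-\log_{10} EC = a\,\log D_{lip/w} + b$. Using
$D_{lip/w}$ rather than $K_{ow}$ as the descriptor lets the same model
cover ionizable chemicals. The registry (`species_registry()`) freezes
five coefficient sets: *C. elegans* (0.81, 1.15), *D. magna*
(0.82, 1.48), *D. rerio* (0.99, 0.78), *X. laevis* (0.61, 2.12,
$r^2 = 0.690$, $n = 22$), and *D. melanogaster* (0.83, 0.52,
$r^2 = 0.724$, $n = 11$). The fly model operates on feed concentration
(mol/L feed) and is typed accordingly so it is never pooled with
aqueous endpoints in cross-species summaries. De novo fitting
(`fit_baseline_qsar()`) is ordinary least squares via `stats::lm()`,
with $r^2$ computed directly from residuals.

The specificity ratio SR divides the predicted baseline effect
concentration by the experimental one. The classification cutoff
defaults to 10 with an inclusive boundary — the conventional value in
the narcosis literature, configurable since no universal standard
exists.

# ADME categories

Intrinsic hepatic clearance (µl/min/10⁶ cells) maps to
`no_metabolism` (= 0), `very_slow` (< 2.5), `intermediate`
([2.5, 10]), `fast` (> 10), and `rapid` (> 100), with the most specific
label reported and boundary values assigned to the closed side exactly
as the thresholds are written. The gap between 2.5 and 10 has no
conventional name; `intermediate` is this package's label. The plasma
unbound fraction classifies as `high_availability` at $F_u \ge 0.5$
(inclusive). Value provenance (human > rodent > predicted) is carried
on `adme_record()` for reporting but never alters the classification.

# The triage pipeline

Stage 1 (physicochemical) excludes volatile chemicals
($D_{aw} > 10^{-4}$), overly hydrophobic ones
($\log D_{lip/w}(7.4) > 4$), and those failing aqueous/DMSO stability —
all evaluated from the partition layer at the configured pH. Records
flagged `moa_exception` are retained despite breaches (when a mechanism
has no well-behaved representative) with the waived criteria recorded.
Stage 2 (logistics) excludes on purity (< 98%), cost (> 1000 €),
availability, restricted-substance status, and laboratory-safety
exclusion, recording *all* failing criteria per record. Stage 3
(diversity) ranks candidates within each toxicity group — human-exposome
presence first, then reference-compound status, then ascending cost,
identifier as the deterministic tie-break — and admits greedily while no
mechanism tag exceeds its per-group cap (default 2) and the group stays
within its target maximum (default 30). The priority formula is this
package's own construction; the field's practice states the priorities
without an algorithm.

Two honest limitations of the greedy stage are documented rather than
hidden. First, with overlapping tag sets a high-priority record can
block two single-tag records, so greedy admission can fall below the
exhaustive-search maximum; the test suite pins an explicit
counterexample, and asserts greedy–exhaustive equality on single-tag
instances, where the constraints form a partition matroid and greedy is
provably optimal. Second, for the same reason, loosening a stage-3 cap
is only guaranteed not to shrink the admitted set on single-tag pools;
the threshold filters of stages 1–2 are monotone unconditionally.

Missing data never imputes: records lacking the fields a stage needs
are excluded with reason `missing_data`, mirroring how triage of real
nominee lists treats gaps. Duplicate nominees are merged by identifier
precedence InChIKey > DTXSID > CAS > name before stage 1 — a stable,
chemistry-aware rule chosen here because merge behavior across source
lists is otherwise unspecified.

# The synthetic generator

`generate_chemicals()` draws pools that match the property structure
the pipeline assumes: truncated-normal $\log K_{ow}$ with mean 2.31 over
$[-4.63, 8.50]$ (sd 2.0, chosen so the central mass spans the typical
4–5 orders of magnitude of a diverse collection while both tails remain
populated); an ionization mixture of roughly 40% neutral-dominant
(≥ 75% neutral at pH 7.4), 30% strongly charged (≥ 80% ionized), and
30% intermediate, realized by placing pKa values far from or near 7.4;
15% of ionizable chemicals get a second group of the same kind.
Volatility, purity (exponential deficit below 100%, mean 1.2
percentage points), lognormal cost (median 200 €, log-sd 1.2), and the
logistics/annotation flags are drawn independently — the joint
distribution of real collections is not emulated, so passing tests show
the pipeline's logic is correct on property-matched marginals, not that
any particular real attrition rate is reproduced. Effect data
(`generate_effect_data()`) put lognormal noise on concentrations
(Gaussian on the $-\log_{10}$ scale, the standard assumption for effect
concentrations), with specifically acting chemicals shifted toward
higher potency by a configurable 2 log units — enough to give SR = 100
in the noise-free case.

Every generator call uses one seeded stream (`withr::with_seed`) and
records its seed, so all simulated results in the tests are exactly
reproducible.

# Problem sizes and numerical choices

The test suite uses $10^4$ draws for the speciation sum-to-one
property, 300 random profiles against the microstate oracle at
$10^{-10}$, 2,000-record pools for generator calibration (sample mean
within ±0.1 of the target), 200 replicate OLS fits at $n = 22$ and
noise sd 0.3 for parameter recovery (mean slope bias ≤ 0.05, 95% CI
coverage within [0.90, 0.99]), and 1,000 chemicals for specificity
classification accuracy (≥ 95%). Decision boundaries are recovered by
bisection to $10^{-9}$. Ties in pKa ordering are resolved by input
order; convolution over at most four two-state groups keeps speciation
exact in double precision without log-sum-exp machinery (weights stay
within $10^{\pm 14}$ of unity for pKa and pH in [0, 14]).

# Known limitations

* Partition predictions are linear in $\log K_{ow}$; LSER descriptors,
  sorption-isotherm nonlinearity, and temperature dependence are out of
  scope.
* The mass balance is equilibrium-only: no kinetics, no volatilization
  term (volatile chemicals are excluded upstream), no plastic binding.
* The greedy diversity stage is order-dependent by design (priority is
  part of the contract) and can be suboptimal in admitted count with
  overlapping mechanism tags.
* ADME classification applies to organic chemicals; metals and
  inorganics should be flagged out-of-domain rather than classified.
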