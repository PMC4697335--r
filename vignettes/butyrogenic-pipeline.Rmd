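---
title: "Models and methods: isotope tracing and stoichiometry of butyrogenic lysine fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: isotope tracing and stoichiometry of butyrogenic lysine fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(butyrtrace)
```

## The biological system

Gut anaerobes such as *Intestinimonas* can ferment L-lysine — and
fructoselysine, the Amadori (Maillard) adduct of glucose and lysine — to
butyrate, acetate and ammonia. Two routes produce butyrate simultaneously:

* the **lysine pathway**: lysine 2,3-aminomutase, β-lysine 5,6-aminomutase,
  3,5-diaminohexanoate dehydrogenase, the 3-keto-5-aminohexanoate cleavage
  enzyme (Kce), 3-aminobutyryl-CoA ammonia-lyase, butyryl-CoA dehydrogenase,
  butyryl-CoA:acetoacetate CoA transferase (AtoD-A), a thiolase, phosphate
  acetyltransferase and acetate kinase — ten enzymatic steps in the packaged
  model. Kce cleaves the carbon chain between C2 and C3: carbons 3–6 of
  lysine become butyrate C1–C4, while the C1–C2 fragment condenses with an
  acetyl-CoA into acetoacetate and is eventually released as acetate;
* the **acetyl-CoA pathway**: condensation of two acetyl-CoA to
  acetoacetyl-CoA, reduction via 3-hydroxybutyryl-CoA and crotonyl-CoA to
  butyryl-CoA, and CoA transfer to release butyrate.

The pathway is shipped as a declarative YAML resource
(`inst/extdata/pathway_af211.yaml`, `load_pathway()`): metabolites with
molecular formulas, reactions with stoichiometry, branch labels and explicit
carbon-to-carbon atom maps (1-based IUPAC numbering from the carboxyl or
anomeric carbon; for fructoselysine, positions 1–6 are the sugar moiety and
7–12 the lysine moiety). Loading validates carbon conservation of every atom
map and reachability of butyrate from each declared substrate. CoA
thioesters and phosphoesters are represented by their acyl carbon skeletons
and the element alphabet is fixed to C/H/O/N, because the fermentation
equations of interest are written over free acids; redox cofactors are
omitted, so only carbon is conserved reaction-by-reaction.

## Elemental balancing

`balance_equation()` solves the element-balance linear system with the
reference substrate fixed at coefficient 1, optionally after pinning further
coefficients (e.g. one acetate co-consumed per fructoselysine). Numerically
this is an SVD: the rank decides the solution-space dimension, which is
always reported.

* dimension 0: the unique solution is returned (the lysine system
  lysine + a H₂O → b butyrate + c acetate + d NH₃ is of this kind and
  yields 1 : 2 → 1 : 1 : 2);
* dimension 1 (the fructoselysine-alone system with lactate overflow): the
  family `x(t) = x0 + t·v` is intersected with the non-negative orthant and
  the **minimal non-negative all-integer member** (smallest total
  coefficient sum; candidates enumerated where any coefficient crosses an
  integer, default bound 50) is selected. This rule was chosen because it is
  the natural "smallest whole-molecule equation" convention and needs no
  extra constraints; for the fructoselysine system it gives
  1 fructoselysine + 2 H₂O → 2 butyrate + 2 NH₃ + 1 CO₂ + 1 lactate, which
  is in fact the *only* integer member of the feasible segment;
* dimension ≥ 2, or dimension 1 with no integer member: an ambiguity error
  naming the free direction. Elemental infeasibility and forced negative
  coefficients are likewise errors naming the violated elements/species.

Coefficients within 1e−7 of integers are snapped; all comparisons use
tolerances ≥ 1e−12 on matrices whose entries are small integers, far from
any conditioning trouble.

## The steady-state tracer model

NMR measurements of culture supernatants are end-point measurements, so the
model is an isotopic steady state, not a kinetic one. Label states are
positional: an n-carbon metabolite has 2ⁿ isotopomers (full enumeration is
cheap for n ≤ 12; no EMU decomposition is needed). Natural-abundance ¹³C
(1.1%) is ignored — quantification is relative to enriched positions.

Free parameters (`flux_config()`):

* `theta_lys` ∈ [0,1] — fraction of butyrate made directly on the lysine
  branch (default 1);
* `weights` — normalized source weights of a single well-mixed acetyl-CoA
  pool: `lysine_c1c2` (the substrate C1–C2 fragment released by thiolysis of
  Kce-derived acetoacetyl-CoA), `recycled` (see below),
  `exogenous_acetate`, `glycolysis`;
* `phi_acetate_release` — bookkeeping share of acetyl-CoA exported as
  acetate; it scales amounts, not label patterns.

The pool distribution x solves the linear fixed point
`x = Σ_s w_s · source_s(x)`; `propagate_labels()` iterates it to a max-norm
tolerance of 1e−10 (cap 10⁴ iterations; the contraction factor is
`w_recycled · (1 − theta_lys)`, so convergence is geometric). Butyrate is
`theta_lys`-weighted between the deterministic lysine-branch molecule
(substrate carbons 3–6) and the condensation molecule assembled from two
*independent* draws from x (well-mixed pool assumption; unit A → C1,C2,
unit B → C3,C4, each methyl landing at C2/C4). Acetate is x itself; lactate
derives from the sugar moiety (canonical hexose → 2 pyruvate atom map) and
is unlabelled for lysine substrates.

**The recycled source.** How methyl label from [6-¹³C]lysine reaches
butyrate C2 (and acetate C2) is mechanistically open: the CoA-transfer
exchange between butyryl-CoA and the acetoacetate pool (AtoD-A operating in
both directions, with thiolase cleaving acetoacetyl-CoA) can return
2-carbon halves of butyryl skeletons to the acetyl pool. We model
`recycled` as exactly that thiolytic exchange: with probability `theta_lys`
the returned unit is one of the two halves of a lysine-branch butyryl
molecule (substrate carbons 3,4 or 5,6, methyl at acetyl C2), otherwise it
is a unit of the condensation pool, i.e. a fresh draw from x — which is
what keeps the fixed point linear. This choice reproduces the full
experimentally observed isotopomer set from [6-¹³C]lysine ([4-¹³C]-,
[2-¹³C]-, [2,4-¹³C]butyrate *and* minor [2-¹³C]acetate). A structural
consequence worth knowing: under purely thiolytic recycling the
methyl-labelled share of the pool cannot exceed 1/2, so class patterns with
`p24 > p2` lie slightly outside the model surface and fit with a small
positive residual at the boundary.

Degenerate input: `w_recycled · (1 − theta_lys) ≥ 1` means the pool is a
closed loop with no label source and is rejected. (With `theta_lys > 0` the
recycled source itself carries substrate label, so `w_recycled = 1` alone is
not degenerate.)

`to_class_fractions()` marginalizes the 16-state butyrate distribution to
the three classes the HMBC procedure can see — C2 only, C4 only, C2&C4 — as
fractions of that three-class pool; mass labelled only at C1/C3 is reported
separately as `p_other` and excluded from the normalization, since the
cross-peak correction observes C2/C4 enrichment only.

`fit_flux_split()` does a grid search (default `theta` step 0.02, recycled
weight step 0.05) plus Nelder–Mead refinement over
(`theta_lys`, `w_recycled`), the remaining weight going to one declared
source. The three observed fractions carry two degrees of freedom, matching
the two parameters; degeneracies still occur (pure [4-¹³C]butyrate is
explained by *any* `theta_lys` once recycling is off), so near-ties are
detected and flagged `non_identifiable`, and among exact ties the fit
attributes labelled butyrate maximally to the lysine branch (largest
`theta_lys`, then smallest recycling weight) — the most parsimonious reading
when the condensation branch is invisible to the data.

The analytic solver is validated against an independent Monte-Carlo oracle
(direct molecule sampling written from the pathway chemistry, no shared
code) on randomized configurations at 10⁵ draws, within three binomial
standard errors per state.

## HMBC split/non-split correction

In an HMBC experiment without decoupling, a three-bond cross-peak (H-2↔C-4
or H-4↔C-2 of butyrate) is split by the large one-bond coupling exactly when
the carbon attached to the observed proton is also enriched. The two split
peaks therefore both measure the [2,4-¹³C] population, and their ratio
`f = h2c4_split / h4c2_split` calibrates away the differential sensitivity
(relaxation, coupling) of the two proton sides. `estimate_butyrate_fractions()`
multiplies the H-4-side non-split integral by `f` and normalizes:

```
p4  = h2c4_nonsplit / S,  p24 = h2c4_split / S,  p2 = f·h4c2_nonsplit / S,
S   = h2c4_nonsplit + h2c4_split + f·h4c2_nonsplit.
```

The direction of `f` (moving the H-4 side onto the H-2 scale) is arbitrary:
the output is invariant to any per-side rescaling, which is precisely the
property the factor exploits, and `p24` taken from the H-2 split integral
coincides with the H-4 choice after equalization. When both split integrals
are zero there is no doubly labelled population to calibrate on; fractions
are computed with `f = 1` and flagged `calibrated = FALSE`. All four
integrals zero is an error, as is a positive H-2 split with a zero H-4
split (the two measure the same population). Peak picking and integration
of the raw 2-D spectra are out of scope — integrals arrive already summed
over doublet components.

`assign_peaks()` matches 1-D ¹³C shifts against a packaged reference table
(lysine C-6 41.75, lysine C-2 57.19, butyrate C-2 42.33, butyrate C-4
15.95, acetate C-2 25.99 p.p.m.) with a user tolerance (default 0.2
p.p.m.), returning the nearest entry and an ambiguity flag when several
entries fall inside the tolerance.

## Carbon recovery, ammonia gap, specific activity

`carbon_recovery()` is the carbon-weighted product/substrate ratio of
concentration changes; it is degree-0 homogeneous in concentrations.
Ammonia is carbon-free; CO₂ counts one carbon when measured. Biomass carbon
is not estimated — recovery below 1 is read as assimilation plus unmeasured
products, and the ammonia shortfall relative to the balanced equation
(`ammonia_gap()`) quantifies the anabolic sequestration side of the same
story. Percentages are rounded to integers for display only.

`specific_activity()` implements the spectrophotometric unit chain
`ΔA·min⁻¹ / (ε · path) × volume / protein` with ε defaulting to
15.1 mM⁻¹cm⁻¹ (acetoacetyl-CoA at 310 nm), giving U mg⁻¹ with
U = µmol min⁻¹. Note that a 237 vs 71 U mg⁻¹ pair is a 3.34-fold ratio.

## Growth kinetics

`fit_gompertz()` uses Zwietering's modified Gompertz on the log-growth
scale, `y(t) = A·exp(−exp(μmax·e/A·(λ−t)+1))` with `y = ln(OD/OD0)`, so
`μmax` has units h⁻¹ and `λ` hours. Fitting is bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`, A, μ > 0, λ ≥ 0) with deterministic data-driven
starts: `A₀ = max y`, `μ₀` the steepest finite-difference slope, `λ₀` the
time-axis intercept of the tangent at the steepest point. Curves with
`max y < 0.05` are rejected as no-growth rather than fitted. Generation
time is `ln 2 / μmax`; note that a growth rate of 0.1 h⁻¹ corresponds to
6.93 h, so quoted pairs like 0.1 h⁻¹ / 7.5 h are mutually inconsistent
under any standard convention — the package takes the `ln 2 / μmax`
definition and pins no result to that pair.

## Synthetic data: what it does and does not emulate

The generators produce statistical stand-ins for the three kinds of raw
measurement, with a mandatory seed and byte-identical reruns:

* `sim_growth_timecourse()`: substrate depletion follows the Gompertz
  sigmoid normalized to complete consumption at the final time point
  (default 16.8 mM substrate over 48 h, μmax 0.1 h⁻¹, λ 5 h, 25 time
  points — the stationary-phase-in-two-days regime of the lysine
  fermentation); products track consumption times their equation
  coefficients, optionally damped per product to emulate anabolic losses;
  additive Gaussian noise truncated at zero. Product formation is rigidly
  coupled to substrate consumption — adequate for testing balance and
  recovery code, *not* a kinetic model of overflow metabolism.
* `sim_hmbc_integrals()`: the noiseless inverse of the correction formula
  with per-side attenuation factors; composed with
  `estimate_butyrate_fractions()` it is the identity on class fractions for
  any positive attenuation pair — the calibration-invariance property the
  method rests on.
* `sim_labeling_observation()`: tracer output perturbed by multiplicative
  lognormal noise (σ on the log scale) and renormalized. Renormalization
  damps the nominal σ on the dominant class (first-order factor
  `sqrt((1−p₄)² + p₂² + p₂₄²)`), which the distributional self-test checks.

Noise models (additive truncated Gaussian for concentrations and integrals,
multiplicative lognormal for fractions) are pragmatic choices — real
replicate data are summarized only as means ± s.d. — so passing tests
demonstrate correctness of the computational chain under those models, not
the field behaviour of real NMR or HPLC noise.

Validation problem sizes (chosen as comfortable for routine runs): 200
random HMBC round-trip cases; 20 random tracer configurations against a
10⁵-draw Monte-Carlo oracle; 50 seeded replicates for the noisy flux-split
(σ = 0.05) and Gompertz (σ = 0.02) recovery studies.

## Known limitations

* Steady-state labelling only; no time-resolved isotopomer dynamics, no
  ²H/¹⁵N tracing.
* The acetyl-CoA pool is a single well-mixed compartment; branch-local
  pools would need compartment-resolved data to identify.
* The sugar-moiety atom fate uses the canonical glycolytic map; it is not
  experimentally constrained here.
* Thermodynamics, ΔG, genome-scale modelling and flux-balance optimization
  are out of scope, as are spectral processing and raw vendor formats.
* `ammonia_gap()` treats assimilation as a lump; no biomass composition
  model is attempted.
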