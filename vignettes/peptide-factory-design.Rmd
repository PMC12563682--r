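---
title: "Designing a probiotic peptide factory with constraint-based models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a probiotic peptide factory with constraint-based models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemfac)
```

## The problem

Engineering a probiotic lactic acid bacterium to synthesize and secrete a
therapeutic peptide poses two coupled questions before any cloning starts:
which growth substrate best supports both biomass and product formation, and
how much peptide the host's metabolism can in principle deliver. Both are
questions about flux through a stoichiometric network, and both are answered
here with flux balance analysis (FBA): maximize an objective flux subject to
steady-state mass balance $S\,v = 0$ and flux bounds $lb \le v \le ub$, with
fluxes in mmol·gDW⁻¹·h⁻¹ and the usual sign convention that exchange fluxes
are negative for uptake. The biomass pseudo-reaction's flux is the specific
growth rate (h⁻¹).

`gemfac` implements that workflow end to end — model I/O, the LP engine,
gap-filling, sequence-driven pathway construction, carbon scans, validation
arithmetic, and dose-response fitting — together with a synthetic network
generator so that every stage runs and is tested at desk scale.

## The linear-programming engine

FBA problems are small but notoriously degenerate: many alternative optimal
flux vectors share one objective value. The engine is a two-phase
bounded-variable primal simplex (`solve_lp()`) using Bland's rule
throughout. Bland's rule costs iterations on large problems but is provably
finite under degeneracy and fully deterministic, which makes every solve
bit-reproducible — a property the test suite relies on. Only the objective
value and constraint satisfaction are contractual; individual fluxes of a
degenerate optimum are one vertex among many.

Correctness is established against an independent oracle,
`enumerate_lp_optimum()`, which enumerates every basic solution (all choices
of $n-m$ variables fixed at a bound, the rest solved from the square
system) and is therefore exact on networks of up to ~10 reactions. The
suite compares the two routes on hundreds of randomized programs, including
rank-deficient ones; agreement is required to $10^{-6}$. Steady-state
residuals of accepted solutions stay below $10^{-6}$ (observed:
$<10^{-13}$).

Numerical choices: pivot tolerance $10^{-9}$; phase-1 infeasibility
declared above $10^{-7}$ total artificial flux; bounds may be infinite
(unboundedness is reported, not an error). Ties in the ratio test break
toward the smallest variable index.

## The synthetic toy network

`make_toy_model()` emulates, at ~50 reactions, the structure that matters
for carbon-source reasoning in a fermentative bacterium:

* **PTS uptake.** Glucose enters by a phosphotransferase reaction consuming
  one phosphoenolpyruvate per hexose. The disaccharide (trehalose) route is
  stoichiometrically *exactly twice* the glucose route, so growth on
  trehalose at rate $r$ equals growth on glucose at $2r$ — an identity the
  tests check to $10^{-6}$ and the reason the disaccharide tops the molar
  growth ranking.
* **A redox-rich sugar alcohol.** Sorbitol enters via PTS and is oxidized by
  an NADP-linked dehydrogenase, delivering one NADPH per mole on top of
  glucose-equivalent carbon. Amino-acid synthesis is reductive (2 NADPH per
  residue), and on non-alcohol substrates NADPH must be bought via an
  ATP-driven transhydrogenase; the alcohol route therefore wins the peptide
  ranking when sources are compared at equal carbon delivery.
* **Fermentative sinks** (lactate; a lumped two-NADH ethanol route; acetate
  + formate with substrate-level ATP) give the LP the redox and energy
  flexibility real heterofermentative metabolism has.
* **Biomass** drains 0.5 of each of the 20 amino acids plus 20 ATP.

With these coefficients the optima are hand-derivable: growth per unit
uptake is $0.06\,U$ (glucose), $0.12\,U$ (trehalose) and $0.07\,U$
(sorbitol); the generator's manifest records them and the tests verify FBA
against them for several seeds. Randomness affects only dead-end decoy
reactions, so the optima are seed-independent; at the default glucose
uptake of 10 mmol·gDW⁻¹·h⁻¹ the model grows at 0.6 h⁻¹, a realistic
magnitude for a lactic acid bacterium.

What the toy does *not* emulate: genome-scale redundancy (thousands of
reactions with isozymes and alternative routes), realistic biomass
composition, maintenance ATP, or a curated medium. Passing tests on the toy
demonstrate the correctness of the algorithms, not quantitative predictions
for any real strain.

NAD(P)(H) metabolites deliberately carry no elemental formula. The
mass-balance checker (`check_mass_balance()`) therefore reports every lumped
redox reaction as *unchecked* rather than imbalanced — the same situation
automated draft reconstructions are in — while all formula-complete
reactions in the toy balance exactly. The checker is report-only by design:
a quality gate, not a validator that blocks model use.

## Gap-filling

`find_gapfill_set()` restores flux to the objective by adding candidates
from a user-supplied universal set. For at most `exact_below` (default 12)
candidates the search enumerates subsets by cardinality and is provably
minimal; beyond that an add-all-then-prune greedy pass (deletions attempted
in id order) yields a subset-minimal repair flagged `minimal = FALSE`. The
objective is plain cardinality — the natural choice when no cost data
exist; weighted variants would slot into the same enumeration. Two guards
keep the search honest: candidate ids must be disjoint from the model, and
exchange reactions are never auto-created, so a repair cannot smuggle in new
nutrients. The default success threshold of $10^{-3}$ h⁻¹ separates genuine
growth from numerical residue.

## Peptide pathway stoichiometry

For a peptide of $n$ residues (His6 tag included), synthesis is lumped into
one reaction consuming the residue composition, $k n$ ATP and
$k n - (n-1)$ water (hydrolysis water net of condensation water), with
$k$ = `atp_per_residue` defaulting to 4 — two ATP-equivalents for
amino-acid activation plus two GTP-equivalents for ribosomal elongation,
the textbook cost of protein synthesis. tRNA charging, initiation and
termination are lumped into $k$, which is exposed as a parameter rather
than hard-coded. Molecular weights use average (not monoisotopic) residue
masses, matching how ELISA-quantified expression titers are reported.

The sequence-derived mass of the LL-37–His6 construct is 5.316 kDa. The
validation module nevertheless takes the construct weight as an explicit
input (default 5.38 kDa) rather than deriving it, because the exact
expressed construct (initiator methionine, linkers) is a cloning detail the
sequence alone does not determine.

When the host model supplies residue formulas, the peptide metabolite gets
the composition-derived formula (sum of residues minus $n-1$ waters), and
the synthesis reaction passes the elemental balance check — a useful guard
against stoichiometry typos.

## Carbon scans and the two-stage trade-off

`carbon_scan()` closes all scanned carbon exchanges except the focal source,
limits its uptake, and maximizes biomass per cell. Product formation is
computed by a two-stage scheme: biomass is first maximized, then fixed at a
fraction (default 0.1) of that maximum while peptide export is maximized.
How growth and production are traded off is a genuinely open design choice
in this kind of analysis; making the fraction an explicit, recorded
parameter (`strategy` field of the result) keeps the choice visible and
reproducible. Setting the fraction to 0 gives the absolute production
ceiling, 1 the fully growth-coupled value, and production is non-increasing
in between — a property the tests assert.

Sources are compared at equal molar uptake by default (the natural axes of
an uptake-rate matrix); `normalize_carbon = TRUE` rescales each source's
rate to equal carbon delivery (hexose equivalents) for "per carbon"
comparisons. In the toy model the disaccharide leads the growth ranking at
equal molar rates, while the sugar alcohol leads the production ranking at
equal carbon — the two orderings the network was built to exhibit.

The yields follow their defining ratios: $Y_{Xs} = (X - X_0)/S$ with $X_0$
the biomass flux of the intermediate (pre-peptide) model, and $Y_p = P/S$.
$Y_{Xs}$ is labelled gDW/mmol as is conventional even though it is formed
from a flux ratio; the arithmetic is implemented exactly as defined. When no
intermediate model is supplied, $X_0 = 0$ with a warning.

## Validation arithmetic

Model output (a specific production flux) meets measurement (a molar
concentration) through two conversions: `mass_titer()` multiplies flux ×
biomass density × duration × molecular weight into g/L, and
`concentration_uM()` divides g/L by kDa into µM. Prediction accuracy is the
symmetric ratio $100 \cdot \min(p, o)/\max(p, o)$ — 100% iff the values
agree, decreasing with the log-ratio, and indifferent to which value is
larger. For the package's worked example, a predicted 0.16 mmol·gDW⁻¹·h⁻¹
at 5.38 kDa corresponds to 29.74 µM, which agrees with a measured
26.96 µM at 90.65%.

## Dose-response fitting

Cytotoxicity readouts (e.g. MTT absorbances) become percent viability via
`viability_percent()`; fitting works on inhibition ($100 -$ viability), so
the logistic's Bottom sits near 0% inhibition. The model is the
four-parameter logistic with the Hill slope fixed at 1 — the fixed-slope
form is the one the rest of the arithmetic assumes, and freeing the slope
is deliberately out of scope. Fitting is nonlinear least squares
(Levenberg–Marquardt via `minpack.lm`), with a deterministic
initialization: Bottom and Top just outside the observed response range
(starting exactly on the extremes makes the gradient singular for
noise-free curves) and logIC50 at the dose nearest the midpoint.

Two refusal rules mirror assay-reporting practice: if maximal inhibition
stays below 50% across the tested range, no IC50 is reported (the
"> max dose" convention), and a converged IC50 outside the tested dose
range is refused rather than extrapolated. Zero doses anchor the control
but cannot enter a log-dose fit and are excluded from it. On simulated
curves (two-fold dilution series from 50 µM, the standard assay layout) the
fit recovers a 15 µM truth exactly without noise and to a median error
of ~1–7% across seeds at 5% assay noise over 50 replicates, comfortably
inside the 10% the tests require.

## Problem sizes and determinism

The test and acceptance workloads are sized for interactive use: 100–150
randomized solver-vs-oracle programs of ≤ 8 reactions, full knockout and
subset-enumeration screens on the ~50-reaction toy model, 10-point uptake
grids, 1000 sequence pairs for mass additivity, and 50 replicate IC50 fits
— a few seconds each. Every random draw is seeded, generators restore the
caller's RNG state, and repeated runs are bit-identical.

## Known limitations

* The simplex is dense and refactorizes the basis each iteration — right
  for networks up to a few hundred reactions, not for genome-scale models
  with thousands, where a sparse LP backend would be substituted behind the
  same `solve_fba()` surface.
* SBML support covers the `fbc` subset this workflow needs (bounds,
  objective, gene associations, formulas/charges, subsystem notes); other
  SBML packages are out of scope.
* Flux distributions at degenerate optima are not unique; downstream
  consumers use objective values, never individual fluxes, and no
  flux-variability analysis is provided.
* FBA is steady-state: time-course quantities (titers over a cultivation)
  enter only through the explicit duration factor in `mass_titer()`.
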