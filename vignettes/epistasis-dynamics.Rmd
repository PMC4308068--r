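---
title: "Simulating epistasis dynamics in metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating epistasis dynamics in metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifba)
library(dplyr)
```

## The model

epifba simulates how genetic interactions among metabolic genes change with
the environment, using constraint-based modelling. A metabolic network is a
stoichiometric matrix $S$ (metabolites by reactions) with per-reaction flux
bounds $v_{lb} \le v \le v_{ub}$. Flux balance analysis (FBA) assumes steady
state and picks the flux distribution maximising a biomass objective:

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; v_{lb} \le v \le v_{ub},$$

where $c$ selects the biomass reaction. Uptake of a nutrient is a negative
flux through its exchange reaction (a column of $S$ with a single nonzero
entry); every "uptake level" in this package is the magnitude of that
negative flux.

FBA optima are usually non-unique. Because mutants here are defined
*relative to a wild-type flux distribution*, the wild type must be one
deterministic, representative optimum: geometric FBA. Our implementation
iterates (i) flux variability analysis (FVA) at the optimal objective within
the current bounding box, (ii) an L1 minimisation towards the per-reaction
range midpoints (linearised with split variables, so the whole pipeline
needs only an LP solver), and (iii) shrinking each reaction's box to the
interval spanned by the L1 solution and the midpoint. Step (iii) at least
halves every range width per iteration, giving geometric convergence; the
loop stops when the widest range falls below $\tau_{geo} = 10^{-6}$.
Reactions are processed in lexicographic id order inside the solver, which
together with the deterministic pivot rule below makes the result invariant
to reaction column order and bit-reproducible across runs.

## Environments at matched growth

The study design compares an abundant-glucose reference with nutrient-limited
perturbations *at the same growth rate*, so that differences in epistasis are
not growth-rate artefacts. For each perturbed condition the limiting
nutrient's minimal uptake supporting exactly
$f \times$ (reference growth) is found by an LP (growth is constrained by
*equality*, and minimality plus continuity of the max-growth curve then
pins wild-type growth to the target exactly); that uptake bound is frozen
and geometric FBA is re-run to get the condition's wild-type fluxes. The
default growth fraction is $f = 0.2$: roughly half the worst-case maximal
relative growth among the perturbations in the original genome-scale design,
low enough that every condition can reach it and high enough to stay
biologically plausible. A `max_growth` mode is also provided: uptake opened
to the allowed maximum, growth capped at the reference growth.

Two choices here were genuinely open:

* **What "unrestricted uptake" means.** A literally infinite uptake bound
  would let any low-yield carbon source reach the reference growth, which
  contradicts the well-known observation that poor substrates cannot support
  fast growth at realistic uptake capacities. We therefore open the limiting
  nutrient to a configurable `max_uptake` that defaults to the reference
  (glucose) uptake magnitude — "as abundant as glucose was". The same cap
  bounds the calibration LP, so a growth target beyond the nutrient's yield
  errors out with the achievable maximum.
* **Which other bounds change between conditions.** Only the limiting
  nutrient's exchange bound is modified; all other exchange bounds are
  inherited from the reference medium. Media details beyond the
  carbon/phosphate manipulation are exposed in the conditions YAML rather
  than hard-coded.

## Mutants and epistasis

A mutation in gene $g$ restricts every reaction associated with $g$ to at
most 50% of its wild-type flux, in the wild-type direction: with wild-type
flux $w_r$ the mutant bounds are $[\min(0, \tfrac12 w_r), \max(0, \tfrac12
w_r)]$ intersected with the original bounds. Three consequences are
deliberate:

* the cap is an inequality, not an equality pin — the only reading under
  which every mutant remains feasible;
* a wild-type-zero reaction is pinned to zero, so pathways unused in one
  environment become mutationally invisible there and load-bearing
  elsewhere — the mechanism behind condition-specific epistasis;
* a reaction shared by both genes of a double mutant (a complex) receives
  the identical cap once — uniform restriction across enzymes, no
  compounding. Gene-protein-reaction boolean structure is flattened to
  membership for the same reason.

Relative fitness is $W = $ mutant optimal growth / wild-type growth in the
same condition; an infeasible mutant is scored $W = 0$ (lethal) with a
warning. Epistasis of a pair is
$\varepsilon = W_{xy} - W_x W_y$, with an interaction "existing" when
$|\varepsilon| \ge 0.01$ (sensitivity analyses use 0.05). Differential
epistasis is $d\varepsilon = \varepsilon_{condition} -
\varepsilon_{reference}$ per pair, thresholded the same way; the
positive:negative imbalance among passing pairs is tested with a two-sided
exact binomial test against 0.5 (two-sided because direction is read from
the ratio itself). All percentage denominators use the full
$\binom{n}{2}$ pair universe of model genes.

Across $K$ conditions, a pair passing in exactly 1 condition is *dynamic*,
in all $K$ *stable*, otherwise *intermediate*; sign consistency is reported
separately (`sign_change`) and does not affect the class. Similarity between
two conditions is 100 × (pairs passing in both with equal sign) / (pairs
passing in either), undefined (flagged `NA`) on an empty union.

Condition-level covariates (essential-gene count, nonzero wild-type fluxes,
mean single-mutant fitness) are rank-correlated with the positive:negative
ratio using average-rank Spearman $\rho$; the p-value is an exact
permutation enumeration below $n = 9$ conditions and the usual
$t$ approximation otherwise. Essentiality is a *knockout* property (all of a
gene's reactions closed, growth below $10^{-6} \times$ reference growth) —
the 50% restriction mutants are a separate concept and deliberately not
reused here.

## Co-evolution tests

Given a per-gene evolutionary-rate table (dN/dS), the similarity statistic
for a pair set is the mean absolute rate difference (absolute, since signed
differences cancel). The null resamples the same number of random
distinct-gene pairs from the rate universe 10,000 times; the left-tail
empirical p-value uses the plus-one rule $p = (1 + \#\{null \le
obs\})/(1 + N)$, so it is never exactly zero and ties count against
rejection. Group comparisons use two-sided Welch t-tests (the
pooled-variance variant was the other candidate; Welch is the safer default
under unequal variances) with degenerate inputs flagged rather than tested.
Genes missing from the rate table are excluded pairwise with a logged count.

## The LP engine

No linear-programming package is part of this stack's dependency set, and
the two general-purpose simplex routines available in base-R adjacent
packages proved numerically fragile on degenerate stoichiometric LPs. The
package therefore carries a small dense two-phase simplex with Bland's
anti-cycling rule: entering variable = lowest eligible index, leaving row =
minimum ratio with ties broken by lowest basis index. Bland's rule gives
finite, deterministic termination — determinism the geometric-FBA
reproducibility guarantee builds on. General box bounds are handled by
variable shifting; variables fixed by `lb == ub` (knockouts) are eliminated
before the solve. Tolerances: feasibility $\tau_{feas} = 10^{-9}$ (three
orders of magnitude of headroom under the 0.01 epistasis threshold), pivot
tolerance $10^{-9}$, geometric-FBA convergence $\tau_{geo} = 10^{-6}$,
iteration caps that error loudly rather than return silently. In the test
suite the solver is checked against an independent brute-force
vertex-enumeration oracle on every bundled toy network (exact on their
small-integer stoichiometries). Unbounded LPs are treated as construction
errors: toy models must be capped.

## What the synthetic generator emulates — and what it does not

`make_fixture()` ships four exactly solvable motifs: a serial pathway
(within-pathway masking, $\varepsilon = +0.25$ at 50% restriction), a
parallel pair of redundant branches (synthetic sickness,
$\varepsilon = -0.5$), a shared two-gene complex
($\varepsilon = W - W^2 > 0$), and a two-carbon network whose
alternative-carbon pathway is flux-zero on glucose and load-bearing on a
low-yield (0.5) second source — planting one stable and one
condition-specific interaction. `make_random_network()` composes seeded
serial/parallel motifs behind a shared biomass drain that consumes one unit
of every motif product, making each motif an obligate bottleneck so designed
signs are provable; uptake caps are drawn from 5–15 arbitrary units.
`make_rates()` draws background rates uniformly on (0, 1) and gives each
planted co-evolving pair a shared base rate with Gaussian jitter
($\sigma = 0.01$ by default).

These toys validate the *machinery*, not the biology: they do not mimic a
genome-scale reconstruction's biomass composition, cofactor coupling,
reversible internal cycles, or realistic gene-reaction pleiotropy. Passing
tests show the pipeline computes the intended quantities exactly on networks
where the answer is provable; they do not by themselves reproduce
genome-scale percentages, which additionally depend on unpublished medium
bounds of the original reconstruction.

## Problem sizes and limitations

The bundled analyses run at desk scale: toy networks of 4–40 reactions,
20-seed generator sweeps, 200-repeat calibration of the resampling test at
1,000 resamples (10,000 in the single headline test). These sizes were
chosen so the full suite completes in well under a minute while every
quantity is still computed, never asserted.

Known limitations:

* Full genome-scale runs (hundreds of genes, $4 \times 10^5$ pairs, 17
  conditions) are supported by the same code paths plus the on-disk fitness
  cache, but the dense simplex makes them hours-long; a sparse solver would
  be the natural upgrade.
* No MILP, loopless, parsimonious or regulatory FBA variants; dynamic
  re-allocation effects discussed around this class of models are out of
  scope.
* The closeness statistic defaults to the within-component convention
  ($(n_c - 1)/\sum d$, averaged over nodes); a harmonic variant is available
  because the convention used by legacy network tools is not always
  documented. Average path length is over connected pairs only — note that
  on *disconnected* graphs adding a bridging edge can legitimately raise
  this average (it adds new, long connected pairs).
* The over-representation helper takes a user-supplied annotation map; no
  GO/KEGG content is bundled.

## A worked example

```{r example}
tc <- make_fixture("twocarbon")
ref <- build_reference(tc$model, "EX_GLC", 10)
alt <- build_condition(tc$model, ref, "EX_ETH", "fixed_fraction",
                       growth_fraction = 0.2, name = "alt_carbon")
alt$wildtype_growth # 0.2 x 10, exactly

rec_ref <- condition_epistasis(fitness_screen(ref))
rec_alt <- condition_epistasis(fitness_screen(alt))
differential_epistasis(rec_alt, rec_ref) |>
  filter(passes)
```

The planted alternative-carbon pathway pair (`g3`, `g4`) flips from
$\varepsilon = 0$ on glucose to $\varepsilon = +0.25$ on the alternative
carbon — a positive differential interaction created purely by the
environment switch.
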