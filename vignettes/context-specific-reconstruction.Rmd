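---
title: "Context-specific metabolic model reconstruction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific metabolic model reconstruction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgem)
```

## The problem

A genome-scale metabolic model (GEM) is a parts list: every reaction an
organism's genome can in principle catalyse, encoded as a
stoichiometric matrix $S$ with flux bounds and gene–protein–reaction
(GPR) rules. A given cell line expresses only a fraction of those
parts. Context-specific reconstruction asks: given a transcriptome,
which subnetwork of the template is actually operating — and does the
resulting model predict measurable phenotypes such as gene essentiality
or flux directionality?

`csgem` implements this loop end to end. This vignette records the
methods as implemented, the tunable parameters with their defaults and
rationale, the numerical choices, and what the bundled synthetic data
can and cannot demonstrate.

## Constraint-based simulation

Fluxes are modelled at steady state, $S v = 0$, $lb \le v \le ub$, with
boundary-condition species excluded from the balance (they exist only
to pad exchange reactions and are stripped by
`remove_boundary_metabolites()`). Exchange reactions follow the COBRA
sign convention: negative flux is uptake. FBA maximizes the biomass
pseudo-reaction; pFBA fixes that optimum and minimizes $\sum_j |v_j|$
on the reversibly-split network, where the L1 norm is linear. Flux
variability analysis (FVA) minimizes and maximizes each flux
individually; reactions whose range is $[0, 0]$ under fully open
exchanges are *blocked* and removed during preprocessing.

Tolerances: steady-state residual and blocked-reaction calls use
$10^{-6}$ (configurable); "open exchange" uptake is $-1000$ in the units
of the model's bounds. The fixtures use bounds of magnitude 10, so these
settings are comfortably scale-separated.

### The LP/MILP engine

Every operation above reduces to small dense linear programs, and the
extraction and gap-filling steps to binary MILPs. The package ships its
own two-phase revised simplex and depth-first branch-and-bound
(`solve_lp()`, `solve_milp()`), written for the regime this package
actually occupies: tens of variables, heterogeneous coefficient scales
(activation thresholds of $10^{-4}$ next to big-M rows), and a hard
requirement of bit-reproducibility. Three design points matter:

- the basis is refactorized with a fresh linear solve at every pivot,
  so roundoff never accumulates across iterations;
- the ratio test admits arbitrarily small positive pivot components
  (excluding them is how textbook tableau codes silently drift
  infeasible on big-M rows), and a strict Bland's-rule restart handles
  the rare numerically degenerate run;
- branch-and-bound certifies every candidate incumbent by re-solving
  with the binaries fixed at their rounded values. Without that step, a
  relaxation that parks an indicator at $v/M \approx 10^{-9}$ rounds to
  an infeasible "solution" — the classic big-M integrality leak.

Branching is deterministic (most fractional variable, lowest index on
ties, nearest-integer child first), so identical inputs always give
identical reconstructions with no solver seed.

## Transcript and reaction activity

Local thresholds are per-transcript quantiles across samples
(`type = 7`, linear interpolation, so thresholds are reproducible to
the bit); global thresholds are means of a local threshold set. TAS
formulas per strategy are log-ratios to a state-dependent reference
threshold; logarithms are base 2 (the fold-change convention; the base
is a parameter). Key decisions:

- **Branch boundaries** go to the certain states: $x \ge g_{max}$ is
  active, $x \le g_{min}$ inactive. In `localT1` at exactly
  $x = g_{max}$ the global branch applies.
- **The uncertainty band is clipped**, not rescaled, into $[-1, 1]$ —
  the minimal reading of "constrained between −1 and 1".
- **Zero expression** would give $\log 0 = -\infty$; unbounded branches
  floor it at −10 (configurable). A zero threshold caps the ratio at
  +10 symmetrically.
- **Monotonicity** holds within each branch and for the global
  strategy. Across branch switches the score can jump (the reference
  threshold changes discontinuously whenever $l(y)$ differs from the
  global thresholds); this is a property of the scoring scheme itself,
  and the test suite asserts exactly the piecewise form.

GPRs are parsed once into expression trees and evaluated numerically:
AND → min by default (a complex is limited by its scarcest subunit),
OR → max or sum. The AND function is exposed as a parameter because
both min and max readings appear in practice. Evaluation is direct on
the tree without DNF expansion; for `max` the two are equivalent, for
`sum` the tree reading avoids double-counting genes shared between
conjuncts. Genes missing from the expression data score 0 (neutral) and
are logged; reactions without a GPR score 0, are excluded from the
FASTCORE core and carry zero weight in tINIT.

## Extraction

**FASTCORE** follows the published LP7/LP10 scheme: LP7 activates as
many pending core reactions as possible (flux $\ge \varepsilon$), LP10
finds an L1-minimal mode through them, penalizing non-core flux;
reversible reactions are direction-flipped when the forward orientation
fails. The activation threshold is $\varepsilon = 10^{-4}$
(configurable); support detection uses $0.99\,\varepsilon$ for core
activation, and a much smaller cutoff ($\varepsilon \cdot 10^{-6}$) for
reading the support of the L1-minimal mode, which a vertex solution
leaves exactly sparse. Core reactions that are not flux-consistent in
the template are dropped with a warning rather than failing the run.

**tINIT** is implemented as a reaction-level MILP: maximize
$\sum_j w_j y_j$ with $w$ = RAS, subject to steady state, flux coupling
$v_j \le UB_j\, y_j$ and $v_j \ge \varepsilon\, y_j$, and protected
reactions (at minimum biomass) forced in. The activity coupling means
one witness flux distribution drives every included reaction, so the
output subnetwork is flux-consistent by construction. Task-list
protection beyond biomass is intentionally out of scope.

Both algorithms return a binary presence vector over the template;
`apply_presence()` knocks reactions out by zeroing bounds rather than
deleting them, so gap filling can re-enable them.

## Gap filling

The gap-filling MILP minimizes the number of activated candidates
subject to steady state on the fully split network ($v \ge 0$), big-M
indicator coupling, and a minimum flux through the objective reaction
$u$ ($\delta = 10^{-4} \cdot ub_u$). Notes on the formulation:

- The indicator pair is $v_k \le M y_k$ (flux forces the indicator on)
  with optional lower coupling $v_k \ge \delta y_k$ so selected
  candidates genuinely carry flux; the lower coupling is on by default.
- $M = 10^6$ by default, but each coupling row uses
  $\min(M, \text{capacity of the candidate})$ — valid because flux can
  never exceed the candidate's own bound sum, and far better
  conditioned.
- Splitting is applied to the *whole* network, not only exchanges:
  non-negativity of $v$ is meaningless while internal reversible
  reactions can run backwards.
- Two scenarios: *intracellular* (candidates = absent non-exchange
  reactions; exchanges keep template bounds — exchange availability is
  treated as a medium question, and the pipeline accordingly leaves
  exchanges open in a gap-filled model) and *medium* (enzyme content
  frozen; candidates are one uptake half per exchange, so the optimum
  is a minimal growth medium).
- Alternative optima are enumerated with integer cuts in non-decreasing
  cardinality (`enumerate_gapfill_solutions()`).

Infeasibility — no candidate set restores flux — is a regular result
(`"no_gapfill"`), not an error.

## Validation

Gene knockouts disable the reactions whose GPR evaluates false with
only that gene off; FBA then gives the mutant growth rate. A knockout
is lethal below 0.1% of wild-type growth or on infeasibility. The
lethality fraction is a parameter, reflecting that any such cutoff is a
choice; 0.001 is the default used throughout. Experimental truth comes
from CERES-style dependency scores discretized at thresholds from a
five-point grid on $[-1.5, -0.5]$. Genes absent from the model predict
non-essential and stay in the confusion matrix (genome-wide scoring);
restricting to model genes is a caller-side filter.

Agreement is scored with the multiclass Matthews correlation
coefficient computed from confusion counts; degenerate denominators
return 0. The implementation is cross-checked in the tests against the
independent covariance (Gorodkin) formulation. Predicted fluxes are
discretized at $\pm 10^{-6}$ into forward/reverse/null and compared on
the reaction intersection, with a user-supplied sign map reconciling
direction conventions.

Parameter importance fits OLS on one-hot encoded parameters with one
reference level absorbed per parameter. Percentiles that a strategy
does not use are a real design level (`"unused"`), not missing data. A
genuinely rank-deficient design — e.g. a mixed-strategy grid where
"p_gmin unused" coincides exactly with "strategy ≠ localT2" — raises an
error naming the collinear options rather than reporting arbitrary
coefficients; per-strategy grids are full-rank and are what the
pipeline fits.

## Flux analysis

Predicted fluxes are compressed with
$s(x) = a\,(1 + e^{x})^{-1} + 1$; the default $a = -2$ is the unique
value making $s$ odd and sign-preserving (algebraically
$\tanh(x/2)$), which is what downstream interpretation of flux signs
requires. Feature selection drops variance below $10^{-8}$ (on scaled
fluxes) and then ranks by one-way ANOVA p-value, ties broken by F
statistic then column order; the default of 200 kept features matches
common practice for downstream PCA/classification. PCA loadings are
summarized per pathway as the mean of $|w_r| / \max_{r'} |w_{r'}|$
within the component — the per-component normalization is chosen
because it makes the score invariant to rescaling a component's
loading vector. Cross-validation splits partition whole cell lines
into folds so replicate models of one line never straddle a
train/test boundary. PCA itself and any classifier are left to
standard numerics; only the bespoke pieces live here.

## Synthetic data and what the tests show

The generators (`make_toy_model()`, `synth_expression()`,
`random_toy_model()`) produce networks of 3–10 reactions with known
blocked sets, essential genes and minimal subnetworks, and log-normal
TPM matrices (background mean 10 TPM, $\sigma_{\log} = 0.5$, optional
dropout, planted active/inactive sets at 8-fold separation — a
separation chosen to represent clearly differential expression, not a
detection-limit case). Biomass reactions are single-metabolite sinks;
no attempt is made to mimic a realistic biomass composition.

Problem sizes were chosen so every optimality claim is checkable by
exhaustive enumeration: gap-filling candidate sets up to ~12 reactions,
tINIT subnetworks up to ~10, FASTCORE cores on designed fixtures
without the algorithm's known approximation pathologies. The full suite
runs in well under a minute. Passing these tests demonstrates
correctness of the formulations and algorithms at desk scale — it does
not demonstrate biological fidelity on real genome-scale models, where
expression noise, GPR curation gaps and biomass composition dominate,
and where the approximation behaviour of FASTCORE on pathological
topologies can differ from the clean fixtures used here.

## Known limitations

- The built-in simplex targets dense desk-scale problems; genome-scale
  models (thousands of reactions) need a sparse industrial LP/MILP
  solver behind the same interfaces.
- Essentiality uses the biomass objective only; metabolic-task
  essentiality is out of scope.
- The SBML layer covers the L3+fbc subset that COBRA-style models use
  (bounds, GPRs, objectives, boundary species, subsystem notes), not
  the full standard.
- localT1/localT2 scores are discontinuous at threshold boundaries by
  construction; analyses that need a continuous score should use the
  global strategy.
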