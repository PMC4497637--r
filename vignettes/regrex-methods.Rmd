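---
title: "Regularized least-squares extraction of context-specific metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized least-squares extraction of context-specific metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrex)
```

## The problem

A genome-scale metabolic model (GEM) collects every known biochemical
reaction of an organism, but in any particular context — a tissue, a cell
type, a condition — only a subset of those reactions is active. This
package extracts that context-specific subnetwork, together with a steady-
state flux distribution, from a GEM and a context-specific expression
profile, with no user-tuned thresholds, no reaction pre-classification and
no assumed objective function: the single free parameter (the
regularization weight) is selected automatically from the data.

## The model

Let $S$ be the stoichiometric matrix of the (consistent part of the) GEM
and $d \in [0,1]^n$ a per-reaction data vector obtained from expression
values. The fit solves

$$
\min_{v,\,\varepsilon,\,x}\;
\tfrac12\lVert\varepsilon\rVert_2^2 + \lambda\lVert v\rVert_1
\quad\text{s.t.}\quad
S v = 0,\qquad
v_i + \varepsilon_i = d_i \;\; (i \in \text{Data}),\qquad
0 \le v \le v_{\max},\qquad
|\varepsilon| \le \varepsilon_{\max},
$$

a LASSO-type problem constrained to the steady-state flux cone. Reversible
reactions are split into non-negative forward and reverse components (so
$\lVert v\rVert_1$ is a plain sum) and a binary $x_i$ per reversible
reaction selects which direction is tied to the data while the other is
forced to zero — without it, binding both directions to the same
non-negative data value would cancel the net flux. The result is a
mixed-integer quadratic program (MIQP). Reactions whose solved net flux
exceeds the activity threshold form the context model; the $\ell_1$ penalty
is what shrinks context-irrelevant fluxes exactly to zero.

Assumptions worth keeping in mind: expression is used as a (rough) proxy
for flux magnitude on a common $[0,1]$ scale; mass balance is the only
physical constraint (no thermodynamic loop law — stoichiometrically
balanced cycles can carry flux bounded only by the cap); and reactions
without gene association ("data orphans") are constrained only by mass
balance and the penalty.

## From expression to reaction data

Each gene is max-normalized across all considered contexts,
$d_{ij} = t_{ij} / \max_j t_{ij}$ (with $0/0 := 0$), which removes the
orders-of-magnitude between-gene scale differences of RNAseq data that
would otherwise bias the fit toward highly expressed genes. Missing cells
are *absent*, never zero — a zero would actively pull the associated flux
to zero, which is not what "unmeasured" means. Gene values are mapped to
reactions through the GPR rules with AND $\to$ min, OR $\to$ max over
defined genes; nodes whose children are all absent are absent. The original
method description cites the GPR formalism without fixing the aggregation;
min/max is the dominant convention in expression-integration methods and
keeps values in $[0,1]$, so it is the default here (and a documented choice
rather than a mathematical necessity).

## Choosing the regularization weight

$\lambda$ is selected by maximizing the Pearson correlation between the
matched fluxes (the data-tied direction for reversible reactions) and $d$:

1. a coarse pass over $\lambda = 0, 0.1, 0.2, \dots$ that stops at the
   first $\lambda$ whose solution is entirely below the activity threshold
   (cross-validation is not applicable: leaving reactions out would break
   the steady-state coupling);
2. a fine pass with step $0.01$ over one coarse step either side of the
   coarse correlation maximizer;
3. the overall maximizer wins; ties (which arise structurally — rescaling
   all fluxes in a linear pathway leaves the correlation unchanged) are
   broken toward the **larger** $\lambda$, i.e. the sparser model, in line
   with the method's motivation.

Correlations are declared *undefined* when the matched-flux spread is at or
below the activity-threshold scale (sample sd $\le 10^{-6}$): such a
solution is the all-zero model up to sub-threshold noise, and correlating
that noise with data would be meaningless. Undefined correlations never
win, which also guarantees that the selected $\lambda^\*$ always yields a
non-empty model. Grids are generated on integer indices (tenths,
hundredths) so no floating-point drift can skip or duplicate a grid point.

## Parameters

| parameter | default | units / scale | role |
|---|---|---|---|
| `flux_cap` | 1 | flux (arbitrary) | upper bound of every split flux; matches the $[0,1]$ data scale. It *replaces* the model's own bound magnitudes so fluxes and data are commensurable |
| `epsilon_max` | $\max d$ | data units | error bound; the smallest value keeping $v=0,\ \varepsilon=d$ feasible, so the solver can never report spurious infeasibility |
| `activity_tol` | $10^{-6}$ | flux | a reaction is active iff $|v_{\text{net}}| >$ this (strict) |
| `consistency_tol` | $10^{-6}$ | flux | blocked-reaction detection threshold in the FVA preprocessing |
| `time_limit` | 60 s | wall clock | per-MIQP budget; on expiry the best incumbent is returned and flagged |
| `lambda_max` | 10 | — | coarse-search guard; with data and fluxes bounded by 1, shrinkage must occur far earlier, so this only catches pathological inputs |

## Numerical design

* **Convex QP backend.** Every subproblem reduces, after substituting
  $\varepsilon_i = d_i - v_i$ on the selected direction, to a QP with a
  diagonal positive-semidefinite Hessian, one equality block ($S_{\rm
  split}v = 0$) and box bounds. It is solved with the dual active-set
  method of Goldfarb–Idnani (package `quadprog`). Zero Hessian entries are
  lifted by a ridge of $10^{-8}$ (the method requires positive
  definiteness); reported objectives are always recomputed with the exact
  objective, so the ridge bias on a returned value is below
  $n\,v_{\max}^2 \cdot 10^{-8}/2$, far inside every tolerance used.
  Linearly dependent rows of $S$ (e.g. closed loops) are dropped by a
  pivoted QR before the solve, and the full residual is re-checked
  afterwards so inconsistent systems still surface as infeasible.
* **FVA as regularized LPs.** Flux variability (used for blocked-reaction
  detection and for flux capacity) minimizes/maximizes one flux at a time.
  With no LP code in the dependency set, each LP is solved as a QP with a
  $10^{-10}$ ridge; by the exact-regularization property of linear programs
  this returns the least-norm LP optimum, so the optimal *value* is exact
  to solver precision at these problem scales.
* **Branch and bound for the binaries.** `solve_regrex()` resolves the
  direction binaries by depth-first branch and bound. At a node with
  undecided reactions, their data terms are dropped from the objective and
  their direction-exclusivity constraints relaxed; since each dropped term
  contributes $\ge 0$, the relaxed optimum is a valid lower bound. Nodes
  are pruned against the incumbent with $10^{-9}$ slack; branching prefers
  data-covered reversible reactions with large $d$, and the child agreeing
  with the relaxed fluxes is explored first. An initial incumbent comes
  from rounding the root relaxation. The search is deterministic (model
  reaction order everywhere); under a time limit, however, the returned
  *incumbent* may depend on hardware speed, which is why its status is
  reported separately from proven optimality. `enumerate_oracle()` is the
  independent ground truth: it fixes all $2^R$ assignments exhaustively
  (refusing $R > 12$) and shares nothing with the solver except the convex
  QP backend.
* **Degenerate inputs.** All-zero data terminates the coarse search at
  $\lambda = 0$; constant data yields undefined correlations and a
  diagnostic error from selection (there is nothing to correlate); an
  over-tightened `epsilon_max` below $\max d$ is the one way to make the
  problem infeasible, and is reported as such.

## The synthetic study fixtures

`make_toy_network()` builds an uptake $\to$ {parallel linear pathways}
$\to$ secretion network, one unique gene per internal reaction, with
requested numbers of reversible and GPR-less (orphan) reactions; it is
consistent by construction. `make_synthetic_expression()` lets each
context favor one pathway (cyclically by default): favored genes draw from
$N(\text{signal}, \text{noise\_sd})$, the rest from $N(0.1 \cdot
\text{signal}, \text{noise\_sd})$, clipped at zero because expression is
non-negative. This makes the cross-context max-normalization non-trivial
and gives an unambiguous ground truth: the favored pathway should be
recovered (sensitivity) and the other pathways' reactions excluded
(specificity).

What the generator deliberately does **not** emulate: realistic
transcriptome distributions (library-size effects, overdispersion,
correlated genes), incomplete GPR coverage patterns of real GEMs, or
networks with branching and cofactor coupling. Passing tests on these
fixtures therefore demonstrate the *optimization and selection machinery* —
not that expression is a good flux proxy in real tissues, which is a
property of data, not of code.

The test suite runs the solver-vs-oracle comparison on 100 random
instances of at most 12 reactions and 4 reversible reactions (the
enumeration cap keeps the oracle exact), and the recovery study on the
2-pathway, length-3 fixture with signal 1.0 and noise sd 0.05 over 50
seeds, where it checks median sensitivity and specificity of at least 0.95
at the selected $\lambda^\*$ and a strictly lower median specificity for
the unregularized $\lambda = 0$ fit — the structural argument for
regularization in miniature. These sizes were chosen to keep the whole
suite fast while leaving the enumeration oracle applicable.

## Cross-context analyses

Extracted models are compared structurally (Jaccard similarity of active
sets; core, exclusive and union sets; per-context z-scores of summed
similarities, using the sample standard deviation) and against the data
(Pearson correlation matrix of the normalized expression over the genes
mapped to model reactions; agreement between the two matrices by
Escoufier's RV coefficient on double-centered matrices — the source method
names the coefficient without a formula, and the standard definition is
used). Functionally, flux capacity (FVA max $-$ min under reset bounds of
magnitude 1) is averaged per subsystem or category (MFC) and ranked by its
coefficient of variation across contexts: low CV marks housekeeping
functions, high CV context-specific ones; core reactions with CV $= 0$
(within $10^{-6}$, absorbing LP round-off) form the robust set. Categorical
protein levels, when available, validate models by three one-sided
Mann-Whitney tests on per-context gene counts (high $>$ medium, medium $>$
low, high $>$ low), exact for small untied samples.

Two more documented readings of ambiguous definitions: the data-orphan
ratio divides active orphans by active data-covered reactions (not by all
active reactions), matching the source's phrasing; and the mean residual is
the mean absolute difference between matched fluxes and data over the data
set. The extracted submodel is *not* re-checked for FVA consistency by
default (the upstream procedure does not re-apply it), but
`extract_consistent_model()` can be applied to the submodel when a fully
consistent output is required.

## Known limitations

* The MIQP is solved exactly only as far as branch and bound finishes
  within the time limit; on large GEMs incumbents are expected instead of
  proven optima (and are labelled as such).
* Dense linear algebra in the QP backend: fine for curated and mid-size
  networks, not tuned for multi-thousand-reaction GEMs.
* No identifier translation (Ensembl/Entrez/HGNC); gene ids must already
  match between model and expression table.
* No thermodynamic loop-law constraints; capacity values of reactions in
  stoichiometrically balanced cycles reflect the bound cap, not
  thermodynamic feasibility.
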