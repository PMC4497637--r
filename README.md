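# regrex

Context-specific metabolic model extraction by ℓ₁-regularized least-squares
flux fitting.

A genome-scale metabolic model (GEM) describes every known reaction of an
organism, yet in a given tissue, cell type or condition only a subset of
those reactions is active. `regrex` extracts that subnetwork — and a
steady-state flux distribution — from a GEM plus a context-specific
expression profile, fully automatically: no expression thresholds, no
reaction pre-classification, no assumed biomass objective. It is aimed at
people doing constraint-based modeling (COBRA-style workflows) who want
unbiased, data-driven context models, e.g. across many tissues of a
multicellular organism.

## The method

With stoichiometric matrix *S* and a per-reaction data vector *d* (gene
expression max-normalized across contexts and mapped through GPR rules,
AND → min / OR → max), the fit solves

```
min_{v, ε, x}  ½‖ε‖₂² + λ‖v‖₁
s.t.  S·v = 0
      vᵢ + εᵢ = dᵢ          for data-covered reactions
      0 ≤ v ≤ v_max,  |ε| ≤ ε_max
```

a LASSO on the steady-state flux cone. Reversible reactions are split into
non-negative forward/reverse components and a binary xᵢ per reversible
reaction ties one direction to the data while the other is forced to zero,
making the problem a mixed-integer quadratic program (MIQP), solved here by
an exact branch-and-bound over the binaries with a convex-QP backend. The
ℓ₁ penalty shrinks context-irrelevant fluxes exactly to zero; reactions
with |v| > 10⁻⁶ form the extracted model. The weight λ is chosen by a
coarse (step 0.1, until total shrinkage) then fine (step 0.01) grid search
maximizing the Pearson correlation between fluxes and data, with ties
broken toward the sparser model.

Also included: FVA-based consistency reduction, model metrics (cardinality,
data-orphan ratio, flux–data correlation, mean residual), cross-context
comparisons (Jaccard matrices, z-scores, RV coefficient, core/exclusive
sets, flux capacity, mean flux capacity per subsystem with CV ranking,
robust-reaction detection, Mann-Whitney enrichment against categorical
protein levels), SBML L3 (fbc) / COBRA-JSON model I/O, and a synthetic
network+expression generator with known ground truth.

## Worked example

```r
library(regrex)

# a toy GEM: 2 parallel pathways of 3 reactions between an uptake and a
# secretion reaction; one reversible reaction, one reaction without GPR
model <- make_toy_network(n_parallel_pathways = 2, pathway_length = 3,
                          n_reversible = 1, n_orphan = 1, seed = 7)
# two contexts, each favoring one pathway (signal 1.0, noise sd 0.05)
expr  <- make_synthetic_expression(model, favored_pathway = 1, signal = 1,
                                   noise_sd = 0.05, n_contexts = 2, seed = 11)

res <- run_regrex(model, expr, "context_1")
res
#> Context-specific extraction for 'context_1'
#>   lambda* = 0.39 (23 lambdas evaluated)
#>   cardinality 5 | data-orphan ratio 1.5 | correlation NA | mean residual 0.435
res$context_model$active_set
#> [1] "R_uptake"  "P1_R1"     "P1_R2"     "P1_R3"     "R_secrete"
ground_truth_score(res$context_model, model, favored_pathway = 1)
#> sensitivity specificity
#>           1           1
```

The extracted model contains exactly the favored pathway plus the exchange
backbone: all of pathway 1 recovered (sensitivity 1), all of pathway 2
excluded (specificity 1). λ* = 0.39 is the largest weight on the
correlation plateau — the sparsest model explaining the data equally well;
the data-orphan ratio 1.5 reflects that 3 of the 5 active reactions (the
two exchanges and the GPR-less pathway reaction) carry no data, and the
per-model correlation is flagged undefined because the two data-covered
active reactions sit on one linear pathway and hence carry identical flux.
Re-running with `config = list(lambda = 0)` (no regularization) keeps
pathway 2 active at low flux: specificity drops to 0 — the case for
regularization in miniature.

Comparing the two contexts:

```r
res2 <- run_regrex(model, expr, "context_2")
report <- cross_context_report(list(context_1 = res$context_model,
                                    context_2 = res2$context_model), expr)
report
#> Cross-context report over 2 contexts
#>   mean off-diagonal Jaccard: 0.25
#>   RV(model structure, expression): 1
#>   core: 2 | total exclusive: 6 | union: 8
#>   robust core reactions: 2
```

The contexts share only the exchange backbone (Jaccard 0.25, core = 2
reactions, each pathway exclusive to its context), and the structural
similarity of the extracted models agrees perfectly with the expression
correlation structure (RV = 1).

A thin command line sits on top of the same functions
(`inst/cli/regrex.R`, subcommands `simulate`, `extract`, `analyze`):

```sh
Rscript inst/cli/regrex.R simulate --pathways 2 --length 3 --out demo
Rscript inst/cli/regrex.R extract --model demo/model.json \
    --expression demo/expression.tsv --context context_1 --out demo/models
Rscript inst/cli/regrex.R analyze --models demo/models \
    --expression demo/expression.tsv --out demo/report
```

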