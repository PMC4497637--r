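## Shared fixtures and independent oracles used across the test files.

## 3-reaction irreversible chain uptake -> A -> B -> secrete with unit bounds;
## with d = (1, 1, 1) the optimum is the scalar closed form
## v = (c, c, c), c = max(0, 1 - lambda), objective 1.5 (1 - c)^2 + 3 lambda c.
chain_model <- function() {
  S <- matrix(c(1, 0, -1, 1, 0, -1), nrow = 2,
              dimnames = list(c("A", "B"), c("r1", "r2", "r3")))
  metabolic_model(S, lb = c(0, 0, 0), ub = c(1, 1, 1),
                  rxn_ids = colnames(S), met_ids = rownames(S))
}

chain_data <- function(d = c(1, 1, 1)) {
  reaction_data("chain", stats::setNames(d, c("r1", "r2", "r3")))
}

chain_objective <- function(lambda) {
  cc <- max(0, 1 - lambda)
  1.5 * (1 - cc)^2 + 3 * lambda * cc
}

## Random small instance for oracle-equivalence testing: a toy network with
## at most 12 reactions and 4 reversible reactions, and data on a random
## reaction subset with values in [0, 1].
random_instance <- function(seed) {
  set.seed(seed)
  np <- sample(1:3, 1)
  pl <- sample(1:3, 1)
  ni <- np * pl
  nrev <- sample(0:min(4, ni), 1)
  model <- make_toy_network(np, pl, n_reversible = nrev, n_orphan = 0,
                            seed = seed)
  nd <- sample(seq_len(n_reactions(model)), 1)
  dset <- sample(model$rxn_ids, nd)
  d <- stats::setNames(rep(NA_real_, n_reactions(model)), model$rxn_ids)
  d[dset] <- stats::runif(nd)
  list(model = model,
       split = split_reversible(model),
       data = reaction_data("rand", d))
}

## Exact one-sided Mann-Whitney p-value by full permutation enumeration:
## the probability, over all C(n+m, n) group assignments of the pooled
## sample, that the U statistic of the first group is >= the observed one.
mw_enum_greater <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  u_obs <- u_stat(x, y)
  hits <- apply(idx, 2, function(ii) {
    u_stat(pooled[ii], pooled[-ii]) >= u_obs - 1e-12
  })
  mean(hits)
}

## RV coefficient computed independently, elementwise from the definition.
rv_direct <- function(A, B) {
  k <- nrow(A)
  center <- function(M) {
    out <- matrix(0, k, k)
    gm <- mean(M)
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        out[i, j] <- M[i, j] - mean(M[i, ]) - mean(M[, j]) + gm
      }
    }
    out
  }
  Ac <- center(A)
  Bc <- center(B)
  tr <- function(M) sum(diag(M))
  tr(Ac %*% Bc) / sqrt(tr(Ac %*% Ac) * tr(Bc %*% Bc))
}

## Solution sanity checks shared by several files: steady state, direction
## exclusivity, and the data-tying identity v + eps = d on the selected
## direction.
expect_valid_solution <- function(sol, split, data) {
  expect_lt(max(abs(split$S_split %*% sol$v_split)), 1e-6)
  if (length(split$rev_set) > 0) {
    prod <- sol$v_split[split$fwd_index[split$rev_set]] *
      sol$v_split[split$rev_index[split$rev_set]]
    expect_lt(max(prod), 1e-8)
  }
  d <- data$d[sol$data_set]
  expect_lt(max(abs(sol$matched_flux + sol$epsilon - d)), 1e-6)
  invisible(sol)
}
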