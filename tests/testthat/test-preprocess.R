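test_that("flux variability matches hand-solved LPs on elementary networks", {
  # dead-end consumer: nothing produces C downstream, so both reactions stall
  S <- matrix(c(1, 0, -1, 1), nrow = 2,
              dimnames = list(c("A", "C"), c("r1", "rdead")))
  m_dead <- metabolic_model(S, c(0, 0), c(1, 1), colnames(S), rownames(S))
  fva <- flux_variability(m_dead)
  expect_equal(fva$min, c(0, 0), tolerance = 1e-8)
  expect_equal(fva$max, c(0, 0), tolerance = 1e-8)

  # closed loop A -> B -> A with bounds [0, 1]: both reactions range (0, 1)
  S <- matrix(c(-1, 1, 1, -1), nrow = 2,
              dimnames = list(c("A", "B"), c("f", "b")))
  m_loop <- metabolic_model(S, c(0, 0), c(1, 1), colnames(S), rownames(S))
  fva <- flux_variability(m_loop)
  expect_equal(fva$min, c(0, 0), tolerance = 1e-8)
  expect_equal(fva$max, c(1, 1), tolerance = 1e-8)

  # uptake -> A -> secrete chain: flux equality forces every range to (0, 1)
  fva <- flux_variability(chain_model())
  expect_equal(fva$min, rep(0, 3), tolerance = 1e-8)
  expect_equal(fva$max, rep(1, 3), tolerance = 1e-8)
})

test_that("blocked-reaction detection respects the tolerance semantics", {
  S <- matrix(c(1, 0, -1, 1), nrow = 2,
              dimnames = list(c("A", "C"), c("r1", "rdead")))
  m_dead <- metabolic_model(S, c(0, 0), c(1, 1), colnames(S), rownames(S))
  expect_setequal(find_blocked_reactions(m_dead), c("r1", "rdead"))
  expect_length(find_blocked_reactions(chain_model()), 0)
  # a tolerance above the loop's flux bound classifies the loop as blocked
  S <- matrix(c(-1, 1, 1, -1), nrow = 2,
              dimnames = list(c("A", "B"), c("f", "b")))
  m_loop <- metabolic_model(S, c(0, 0), c(1, 1), colnames(S), rownames(S))
  expect_setequal(find_blocked_reactions(m_loop, tolerance = 2), c("f", "b"))
})

test_that("consistency extraction reaches a fixpoint and is idempotent", {
  # chain plus a two-step dead-end branch B -> X -> Y: both branch reactions
  # are blocked and must go, while the chain survives
  S <- matrix(0, 4, 5,
              dimnames = list(c("A", "B", "X", "Y"),
                              c("up", "ab", "out", "bx", "xy")))
  S["A", "up"] <- 1
  S["A", "ab"] <- -1; S["B", "ab"] <- 1
  S["B", "out"] <- -1
  S["B", "bx"] <- -1; S["X", "bx"] <- 1
  S["X", "xy"] <- -1; S["Y", "xy"] <- 1
  m <- metabolic_model(S, rep(0, 5), rep(1, 5), colnames(S), rownames(S))
  cons <- extract_consistent_model(m)
  expect_setequal(cons$rxn_ids, c("up", "ab", "out"))
  expect_setequal(cons$met_ids, c("A", "B"))  # orphan metabolites pruned
  expect_length(find_blocked_reactions(cons), 0)
  # idempotence
  cons2 <- extract_consistent_model(cons)
  expect_identical(cons2$rxn_ids, cons$rxn_ids)
  # fully blocked model errors
  S2 <- matrix(c(1, 0, -1, 1), nrow = 2)
  m2 <- metabolic_model(S2, c(0, 0), c(1, 1), c("r1", "r2"), c("A", "C"))
  expect_error(extract_consistent_model(m2), "all reactions are blocked")
})

test_that("max-normalization maps each gene onto [0, 1] with its max at 1", {
  v <- rbind(g1 = c(2, 4), g2 = c(0, 0), g3 = c(3, NA))
  colnames(v) <- c("c1", "c2")
  nm <- normalize_expression(expression_matrix(v))
  expect_equal(unname(nm$values["g1", ]), c(0.5, 1.0))
  expect_equal(unname(nm$values["g2", ]), c(0, 0))       # 0/0 := 0
  expect_equal(nm$values["g3", "c1"], 1.0)               # max over defined
  expect_true(is.na(nm$values["g3", "c2"]))              # absent stays absent

  # single context: every nonzero gene maps to exactly 1
  one <- normalize_expression(expression_matrix(
    matrix(c(5, 0.1, 0), dimnames = list(c("a", "b", "c"), "only"))))
  expect_equal(unname(one$values[, 1]), c(1, 1, 0))

  # scale invariance: rescaling a gene's row leaves its normalized row alone
  set.seed(1)
  v2 <- matrix(runif(20), 4, 5,
               dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  n1 <- normalize_expression(expression_matrix(v2))
  v2["g2", ] <- v2["g2", ] * 137.5
  n2 <- normalize_expression(expression_matrix(v2))
  expect_equal(n1$values, n2$values)
})

test_that("expression maps onto reactions through GPRs, leaving orphans", {
  m <- make_toy_network(2, 2, n_reversible = 0, n_orphan = 1, seed = 5)
  expr <- make_synthetic_expression(m, 1, signal = 1, noise_sd = 0,
                                    n_contexts = 2, seed = 1)
  rd <- map_expression_to_reactions(m, normalize_expression(expr), "context_1")
  orphan <- m$rxn_ids[!nzchar(m$gpr)]
  expect_true(all(is.na(rd$d[orphan])))            # no GPR -> no data
  expect_false(any(orphan %in% rd$data_set))
  with_gene <- setdiff(m$rxn_ids, orphan)
  expect_setequal(rd$data_set, with_gene)
  # single-gene GPRs pass the normalized value through
  expect_equal(unname(rd$d[intersect(with_gene, "P1_R1")]), 1)
  expect_error(map_expression_to_reactions(m, normalize_expression(expr),
                                           "nope"),
               "not present")
})

test_that("reversible splitting counts columns and reconstructs net flux", {
  m <- make_toy_network(1, 5, n_reversible = 2, n_orphan = 0, seed = 2)
  sp <- split_reversible(m, flux_cap = 1)
  n <- n_reactions(m)
  expect_equal(ncol(sp$S_split), n + 2)
  expect_true(all(sp$vmax_split == 1))
  expect_true(all(is.na(sp$rev_index[sp$irrev_set])))
  # reverse columns are the negated forward columns
  for (i in sp$rev_set) {
    expect_equal(sp$S_split[, sp$rev_index[i]], -sp$S_split[, sp$fwd_index[i]])
  }
  # any nonnegative split vector in the null space gives a balanced net flux
  set.seed(9)
  for (rep in 1:5) {
    v <- runif(ncol(sp$S_split))
    bal <- max(abs(sp$S_split %*% v))
    vn <- net_flux(sp, v)
    expect_equal(max(abs(as.matrix(m$S) %*% vn)), bal, tolerance = 1e-12)
  }
})
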