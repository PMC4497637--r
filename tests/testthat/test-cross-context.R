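test_that("Jaccard matrices are valid similarities with known entries", {
  J <- jaccard_matrix(list(a = c("a", "b", "c"), b = c("b", "c", "d")))
  expect_equal(J["a", "b"], 0.5)  # 2 shared / 4 in the union
  sets <- list(x = c("r1", "r2"), y = c("r1", "r2"), z = c("r9"))
  J2 <- jaccard_matrix(sets)
  expect_equal(J2["x", "y"], 1)
  expect_equal(J2["x", "z"], 0)
  expect_true(isSymmetric(unname(J2)))
  expect_equal(unname(diag(J2)), rep(1, 3))
  expect_true(all(J2 >= 0 & J2 <= 1))
  # randomized: symmetry, diagonal, range
  set.seed(3)
  for (rep in 1:10) {
    fam <- lapply(1:4, function(i) sample(letters, sample(0:10, 1)))
    names(fam) <- paste0("c", 1:4)
    J3 <- jaccard_matrix(fam)
    expect_true(isSymmetric(unname(J3)))
    expect_true(all(J3 >= 0 & J3 <= 1))
  }
  empty <- jaccard_matrix(list(a = character(0), b = character(0)))
  expect_equal(empty["a", "b"], 1)
  expect_true(attr(empty, "empty_pairs"))
})

test_that("context z-scores normalize row sums with the sample sd", {
  # build a symmetric matrix whose off-diagonal row sums are (2, 4, 6):
  # mean 4, sample sd 2 -> z = (-1, 0, 1)
  M <- matrix(c(1, 0, 2, 0, 1, 4, 2, 4, 1), 3, 3,
              dimnames = rep(list(c("a", "b", "c")), 2))
  expect_equal(rowSums(M) - diag(M), c(a = 2, b = 4, c = 6))
  expect_equal(context_zscores(M), c(a = -1, b = 0, c = 1))
  # equal off-diagonal entries: degenerate, all-zero z with flag
  E <- matrix(0.4, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  diag(E) <- 1
  z <- context_zscores(E)
  expect_equal(unname(z), rep(0, 3), ignore_attr = TRUE)
  expect_true(attr(z, "degenerate"))
  # permutation equivariance
  p <- c(3, 1, 2)
  expect_equal(context_zscores(M[p, p]), context_zscores(M)[p])
})

test_that("RV coefficient matches the direct double-centered formula", {
  set.seed(7)
  for (k in c(3, 5)) {
    A <- crossprod(matrix(rnorm(k * k), k))
    B <- crossprod(matrix(rnorm(k * k), k))
    expect_equal(rv_coefficient(A, B), rv_direct(A, B), tolerance = 1e-12)
    expect_equal(rv_coefficient(A, A), 1.0, tolerance = 1e-12)
    expect_equal(rv_coefficient(A, 3.7 * A), 1.0, tolerance = 1e-12)
    # invariance under simultaneous relabeling and positive scaling
    p <- sample(k)
    expect_equal(rv_coefficient(A[p, p], B[p, p]), rv_coefficient(A, B),
                 tolerance = 1e-12)
    expect_equal(rv_coefficient(2 * A, 0.1 * B), rv_coefficient(A, B),
                 tolerance = 1e-12)
  }
  # hand-checked 2x2 case: double-centering turns [[a,b],[b,a]] into
  # (a-b)/2 * [[1,-1],[-1,1]], so RV is 1 whenever both (a-b) share a sign
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  B <- matrix(c(1, 0.2, 0.2, 1), 2)
  expect_equal(rv_coefficient(A, B), 1.0, tolerance = 1e-12)
  expect_equal(rv_coefficient(A, -B), -1.0, tolerance = 1e-12)
})

test_that("core/exclusive/union sets satisfy the partition identity", {
  ce <- core_and_exclusive(list(a = c("a", "b"), b = c("a", "c")))
  expect_equal(ce$core, "a")
  expect_equal(ce$exclusive$a, "b")
  expect_equal(ce$exclusive$b, "c")
  expect_equal(ce$total_cardinality, 3)
  set.seed(11)
  for (rep in 1:10) {
    fam <- lapply(1:4, function(i) sample(letters, sample(1:15, 1)))
    names(fam) <- paste0("c", 1:4)
    ce <- core_and_exclusive(fam)
    shared2plus <- length(unique(unlist(fam))) - sum(lengths(ce$exclusive))
    expect_equal(sum(lengths(ce$exclusive)) + shared2plus,
                 ce$total_cardinality)
    expect_true(all(vapply(fam, function(s) all(ce$core %in% s), TRUE)))
  }
})

test_that("flux capacity is the FVA range under reset bounds", {
  m <- chain_model()
  cm <- structure(list(context_id = "c", submodel = m,
                       active_set = m$rxn_ids,
                       flux = stats::setNames(rep(0.5, 3), m$rxn_ids)),
                  class = "context_model")
  cap <- flux_capacity(cm, 1)
  expect_equal(unname(cap), rep(1, 3), tolerance = 1e-7)
  # homogeneity of degree 1 in the bound magnitude
  expect_equal(unname(flux_capacity(cm, 2)), rep(2, 3), tolerance = 1e-6)
  # a dead branch inside the submodel has zero capacity
  S <- matrix(0, 3, 4, dimnames = list(c("A", "B", "X"),
                                       c("up", "ab", "out", "ax")))
  S["A", "up"] <- 1; S["A", "ab"] <- -1; S["B", "ab"] <- 1
  S["B", "out"] <- -1; S["A", "ax"] <- -1; S["X", "ax"] <- 1
  m2 <- metabolic_model(S, rep(0, 4), rep(1, 4), colnames(S), rownames(S))
  cap2 <- flux_capacity(m2, 1)
  expect_equal(cap2[["ax"]], 0, tolerance = 1e-7)
})

test_that("mean flux capacity per group handles absences and singletons", {
  caps <- list(
    c1 = c(r1 = 1, r2 = 0, r3 = 0.5),
    c2 = c(r1 = 0.2, r2 = 0.2)
  )
  grouping <- c(r1 = "g", r2 = "g", r3 = "solo")
  mfc <- mfc_by_group(caps, grouping)
  expect_equal(mfc["g", "c1"], 0.5)        # mean of (1, 0)
  expect_equal(mfc["solo", "c1"], 0.5)     # singleton group = raw capacity
  expect_equal(mfc["solo", "c2"], 0)       # absent -> 0 with flag
  expect_true(attr(mfc, "absent")["solo", "c2"])
  expect_false(attr(mfc, "absent")["g", "c2"])
})

test_that("CV ranking orders groups and flags degenerate rows", {
  mfc <- rbind(constant = c(2, 2, 2, 2),
               onehot = c(1, 0, 0, 0),
               dead = c(0, 0, 0, 0))
  colnames(mfc) <- paste0("c", 1:4)
  rk <- cv_ranking(mfc)
  expect_equal(rk$group, c("constant", "onehot", "dead"))
  expect_equal(rk$cv[1], 0)
  # one-hot row over k contexts has CV = sqrt(k) with the sample sd
  expect_equal(rk$cv[2], sqrt(4), tolerance = 1e-12)
  expect_true(is.na(rk$cv[3]))             # zero mean: undefined, ranked last
  # permuting contexts leaves CVs unchanged
  rk2 <- cv_ranking(mfc[, c(3, 1, 4, 2)])
  expect_equal(rk2$cv, rk$cv)
})

test_that("robust core reactions have context-invariant capacity", {
  caps <- list(c1 = c(a = 1, b = 0.5, c = 0),
               c2 = c(a = 1, b = 0.7, c = 0))
  rob <- robust_reactions(caps, core = c("a", "b", "c"))
  expect_setequal(rob$robust, c("a", "c"))  # all-zero counts as invariant
  expect_gt(rob$cv[["b"]], 0)
})

test_that("Mann-Whitney enrichment matches exact and enumerated p-values", {
  # complete separation at n = m = 3: exactly 1 of C(6,3) = 20 orderings
  expect_equal(mann_whitney_greater(c(7, 8, 9), c(1, 2, 3)), 0.05)
  expect_equal(mw_enum_greater(c(7, 8, 9), c(1, 2, 3)), 0.05)
  # identical distributions: one-sided p >= 0.5
  expect_gte(mann_whitney_greater(c(1, 2, 3), c(1.1, 2.1, 2.9)), 0.4999)
  # exact p equals full permutation enumeration for untied samples, n, m <= 6
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    pool <- sample(1000, n + m) / 7  # distinct values, no ties
    x <- pool[1:n]; y <- pool[(n + 1):(n + m)]
    expect_equal(mann_whitney_greater(x, y), mw_enum_greater(x, y),
                 tolerance = 1e-12)
    # swapping the groups maps p to its complement (plus the atom at the
    # observed statistic) under the exact null
    u_atom <- mw_enum_greater(x, y) - (1 - mw_enum_greater(y, x))
    expect_gte(u_atom, -1e-12)
    expect_equal(mw_enum_greater(x, y) + mw_enum_greater(y, x),
                 1 + u_atom, tolerance = 1e-12)
  }
  expect_true(is.na(mann_whitney_greater(numeric(0), c(1, 2))))
})

test_that("the assembled cross-context report is internally consistent", {
  m <- make_toy_network(2, 3, n_reversible = 1, n_orphan = 0, seed = 7)
  expr <- make_synthetic_expression(m, 1, 1, 0.05, n_contexts = 2, seed = 11)
  r1 <- run_regrex(m, expr, "context_1")
  r2 <- run_regrex(m, expr, "context_2")
  models <- list(context_1 = r1$context_model, context_2 = r2$context_model)
  rep <- cross_context_report(models, expr)
  # contexts favoring different pathways share only the exchange backbone
  expect_lt(rep$jaccard["context_1", "context_2"], 1)
  expect_true(all(rep$core_set %in% r1$context_model$active_set))
  expect_true(all(rep$core_set %in% r2$context_model$active_set))
  expect_length(intersect(rep$exclusive_sets$context_1,
                          rep$exclusive_sets$context_2), 0)
  expect_true(all(rep$robust_set %in% rep$core_set))
  expect_true(rep$rv >= -1 && rep$rv <= 1)
  expect_equal(dim(rep$mfc)[2], 2)

  # enrichment wiring: genes of each model counted per level and context
  lv <- matrix("low", length(m$genes), 2,
               dimnames = list(m$genes, c("context_1", "context_2")))
  lv[paste0("g_P1_R", 1:3), "context_1"] <- "high"
  lv[paste0("g_P2_R", 1:3), "context_2"] <- "high"
  pt <- structure(list(gene_ids = rownames(lv), context_ids = colnames(lv),
                       level = lv), class = "protein_level_table")
  enr <- categorical_enrichment(models, pt)
  expect_equal(enr$counts["high", "context_1"],
               sum(paste0("g_P1_R", 1:3) %in% r1$context_model$submodel$genes))
  expect_named(enr$p_values, c("high_gt_medium", "medium_gt_low",
                               "high_gt_low"))
})
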