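test_that("coarse search walks the 0.1 grid until full shrinkage", {
  sp <- split_reversible(chain_model())
  co <- coarse_search(sp, chain_data())
  # closed form c = 1 - lambda reaches zero exactly at lambda = 1
  expect_equal(co$trace$lambda, seq(0, 1, by = 0.1))
  expect_equal(nrow(co$trace), 11L)
  expect_equal(co$trace$cardinality[1], 3L)
  expect_equal(co$trace$cardinality[11], 0L)
  # cardinality and the l1 norm are recorded for every evaluated lambda
  expect_false(anyNA(co$trace$cardinality))
  expect_equal(co$trace$l1_norm, 3 * pmax(0, 1 - co$trace$lambda),
               tolerance = 1e-6)
  # all-zero data: the unpenalized optimum is already all-zero
  co0 <- coarse_search(sp, chain_data(c(0, 0, 0)))
  expect_equal(co0$trace$lambda, 0)
})

test_that("fine grid has step 0.01, clips at zero and skips coarse points", {
  sp <- split_reversible(chain_model())
  coarse_grid <- seq(0, 1, by = 0.1)
  f <- fine_search(sp, chain_data(), center = 0.5, skip = coarse_grid)
  expect_equal(f$trace$lambda, setdiff(round(seq(0.40, 0.60, 0.01), 2),
                                       c(0.40, 0.50, 0.60)))
  f0 <- fine_search(sp, chain_data(), center = 0, skip = coarse_grid)
  expect_true(all(f0$trace$lambda >= 0))
  expect_equal(min(f0$trace$lambda), 0.01)
  f05 <- fine_search(sp, chain_data(), center = 0.05, skip = coarse_grid)
  expect_equal(range(f05$trace$lambda), c(0.01, 0.15))
})

test_that("lambda selection maximizes correlation with a sparse tie-break", {
  mk <- function(lambdas, corrs) {
    sols <- lapply(seq_along(lambdas), function(i) {
      structure(list(lambda = lambdas[i], correlation = corrs[i]),
                class = "regrex_solution")
    })
    names(sols) <- sprintf("%.2f", lambdas)
    list(trace = data.frame(lambda = lambdas, correlation = corrs,
                            cardinality = 1L, l1_norm = 1, objective = 0,
                            status = "optimal"),
         solutions = sols)
  }
  res <- select_lambda(mk(c(0.1, 0.2, 0.3), c(0.3, 0.5, 0.5)))
  expect_equal(res$lambda_star, 0.3)       # tie toward the sparser model
  res2 <- select_lambda(mk(c(0.1, 0.2), c(NA, 0.4)))
  expect_equal(res2$lambda_star, 0.2)      # undefined never wins
  expect_error(select_lambda(mk(c(0, 0.1), c(NA, NA))), "undefined")
})

test_that("end-to-end extraction is deterministic and matches manual stages", {
  m <- make_toy_network(2, 3, n_reversible = 1, n_orphan = 1, seed = 7)
  expr <- make_synthetic_expression(m, 1, signal = 1, noise_sd = 0.05,
                                    n_contexts = 2, seed = 11)
  r1 <- run_regrex(m, expr, "context_1", config = list(seed = 1))
  r2 <- run_regrex(m, expr, "context_1", config = list(seed = 1))
  expect_true(all(r1$search$trace$status == "optimal"))
  expect_equal(r1$search$lambda_star, r2$search$lambda_star)
  expect_identical(r1$context_model$active_set, r2$context_model$active_set)

  # orchestration equals calling the stages by hand
  cons <- extract_consistent_model(m)
  rd <- map_expression_to_reactions(cons, normalize_expression(expr),
                                    "context_1")
  sp <- split_reversible(cons)
  co <- coarse_search(sp, rd)
  defined <- which(!is.na(co$trace$correlation))
  center <- max(co$trace$lambda[
    defined[co$trace$correlation[defined] >=
            max(co$trace$correlation[defined]) - 1e-9]])
  fi <- fine_search(sp, rd, center, skip = co$trace$lambda)
  sel <- select_lambda(co, fi)
  expect_equal(r1$search$lambda_star, sel$lambda_star)
  expect_setequal(r1$context_model$active_set,
                  active_reactions(sel$best_solution))
})

test_that("explicit NULL config entries fall back to the defaults", {
  m <- make_toy_network(2, 3, n_reversible = 1, n_orphan = 0, seed = 5)
  expr <- make_synthetic_expression(m, 1, 1, 0.05, 2, seed = 5)
  # a caller-style config spelling every option out, with NULLs for "auto"
  full <- list(lambda = NULL, time_limit = 60, epsilon_max = NULL,
               flux_cap = 1, activity_tol = 1e-6, seed = 1L)
  r_full <- run_regrex(m, expr, "context_1", config = full)
  r_def <- run_regrex(m, expr, "context_1")
  expect_equal(r_full$search$lambda_star, r_def$search$lambda_star)
  expect_identical(r_full$context_model$active_set,
                   r_def$context_model$active_set)
  expect_error(run_regrex(m, expr, "context_1", config = list(lam = 1)),
               "unknown config option")
})

test_that("coarse l1 norms are non-increasing on convex instances", {
  # no reversible reactions: every grid point is a proven convex optimum
  m <- make_toy_network(3, 2, n_reversible = 0, n_orphan = 0, seed = 12)
  sp <- split_reversible(m)
  set.seed(12)
  d <- stats::setNames(rep(NA_real_, n_reactions(m)), m$rxn_ids)
  internal <- m$rxn_ids[grepl("^pathway_", m$subsystem)]
  d[internal] <- runif(length(internal))
  co <- coarse_search(sp, reaction_data("c", d))
  expect_true(all(diff(co$trace$l1_norm) <= 1e-8))
})
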