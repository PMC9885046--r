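test_that("a single-path chain carries the full uptake into growth", {
  toy <- generate_toy_model(toy_model_spec(chain_length = 3, branch_a = 0.5,
                                           branch_b = 0.5, uptake = 10))
  sol <- fba_optimize(toy$model)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 10, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes[c("T01", "T02", "T03")]), rep(10, 3),
               tolerance = 1e-8)
  expect_lt(mass_balance_residual(toy$model, sol), 1e-9)
})

test_that("branch fluxes split according to the biomass coefficients", {
  toy <- generate_toy_model(toy_model_spec(branch_a = 0.3, branch_b = 0.7,
                                           uptake = 10))
  sol <- fba_optimize(toy$model)
  expect_equal(unname(sol$fluxes["RP1"]), 3, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes["RP2"]), 7, tolerance = 1e-8)
  sf <- section_flux(sol, toy$reporters, toy$sections)
  expect_equal(unname(sf["Tryptophan"]), 3, tolerance = 1e-8)
  expect_equal(unname(sf["PheTyr"]), 7, tolerance = 1e-8)
  expect_equal(unname(sf["Input"]), 10, tolerance = 1e-8)
})

test_that("solver output matches the analytic optimum across the toy family", {
  withr::local_seed(901)
  for (rep in 1:10) {
    spec <- toy_model_spec(chain_length = sample(1:6, 1),
                           branch_a = stats::runif(1, 0.1, 2),
                           branch_b = stats::runif(1, 0.1, 2),
                           uptake = stats::runif(1, 1, 50))
    toy <- generate_toy_model(spec)
    sol <- fba_optimize(toy$model)
    expect_equal(sol$objective, toy$truth$growth, tolerance = 1e-8)
    expect_equal(unname(sol$fluxes["RP1"]),
                 unname(toy$truth$branch_fluxes["RP1"]), tolerance = 1e-8)
    expect_equal(unname(sol$fluxes["RP2"]),
                 unname(toy$truth$branch_fluxes["RP2"]), tolerance = 1e-8)
    expect_lt(mass_balance_residual(toy$model, sol), 1e-9)
  }
})

test_that("an infeasible model reports infeasible with empty fluxes", {
  S <- matrix(c(1), 1, 1, dimnames = list("a", "r1"))
  m <- stoich_model(S, lb = 1, ub = 2, objective = "r1")  # a accumulates
  sol <- fba_optimize(m)
  expect_identical(sol$status, "infeasible")
  expect_length(sol$fluxes, 0)
})

test_that("GPR deletion semantics follow the boolean rules", {
  toy <- generate_toy_model(toy_model_spec())
  m <- toy$model
  m$gpr["T01"] <- "g1 and g2"
  m$gpr["T02"] <- "g1 or g2"
  m$gpr["T03"] <- "(g1 and g2) or g3"
  m$genes <- union(m$genes, c("g1", "g2", "g3"))
  d <- delete_genes(m, "g1")
  expect_equal(unname(d$ub["T01"]), 0)        # AND loses a subunit
  expect_gt(unname(d$ub["T02"]), 0)           # OR keeps the isozyme
  expect_gt(unname(d$ub["T03"]), 0)           # g3 route survives
  d2 <- delete_genes(m, c("g1", "g3"))
  expect_equal(unname(d2$ub["T03"]), 0)       # both routes gone
  expect_error(delete_genes(m, "ghost"), "unknown gene")
})

test_that("isozyme pairs are never flagged essential; unique steps are", {
  toy <- generate_toy_model(toy_model_spec(isozymes = 2L))
  scan <- essentiality_scan(toy$model, toy$reporters, sections = toy$sections)
  expect_false("T02" %in% scan$essential)
  expect_false("T02b" %in% scan$essential)
  expect_true(all(c("T01", "T03", "T04", "RP1", "RP2") %in% scan$essential))
  # deleting either isozyme leaves growth at the analytic optimum
  for (iso in c("T02", "T02b"))
    expect_equal(fba_optimize(delete_reactions(toy$model, iso))$objective,
                 toy$truth$growth, tolerance = 1e-8)
})

test_that("gene-mode scans agree with reaction-mode scans on dedicated genes", {
  toy <- generate_toy_model(toy_model_spec(isozymes = 2L))
  rscan <- essentiality_scan(toy$model, toy$reporters)
  gscan <- essentiality_scan(toy$model, toy$reporters, by = "gene")
  expect_setequal(paste0("g_", rscan$essential), gscan$essential)
})

test_that("no single deletion ever increases growth", {
  toy <- generate_toy_model(toy_model_spec(isozymes = c(1L, 3L)))
  wt <- fba_optimize(toy$model)$objective
  scan <- essentiality_scan(toy$model, toy$reporters)
  expect_true(all(scan$table$growth <= wt + 1e-8))
})

test_that("efficiency constraints scale bounds on the signed flux side", {
  toy <- generate_toy_model(toy_model_spec())
  wt <- fba_optimize(toy$model)
  # forward reaction: upper bound becomes f * v
  m1 <- constrain_efficiency(toy$model, "T01", 0.5, wt)
  expect_equal(unname(m1$ub["T01"]), 5)
  expect_equal(fba_optimize(m1)$objective, 5, tolerance = 1e-8)
  # reverse-running exchange: lower bound scales, sign kept
  m2 <- constrain_efficiency(toy$model, "EX_A", 0.9, wt)
  expect_equal(unname(m2$lb["EX_A"]), -9)
  expect_equal(fba_optimize(m2)$objective, 9, tolerance = 1e-8)
  # f = 1 leaves the optimum unchanged
  m3 <- constrain_efficiency(toy$model, "T01", 1, wt)
  expect_equal(fba_optimize(m3)$objective, wt$objective, tolerance = 1e-8)
  # zero-flux reaction: warning, no-op
  toyiso <- generate_toy_model(toy_model_spec(isozymes = 2L))
  wtiso <- fba_optimize(toyiso$model)
  zero_rxn <- names(which(wtiso$fluxes[c("T02", "T02b")] == 0))[1]
  expect_warning(m4 <- constrain_efficiency(toyiso$model, zero_rxn, 0.5, wtiso),
                 "no wild-type flux")
  expect_equal(m4$ub, toyiso$model$ub)
})

test_that("growth is nondecreasing in the efficiency fraction", {
  toy <- generate_toy_model(toy_model_spec())
  wt <- fba_optimize(toy$model)
  growths <- vapply(c(0, 0.25, 0.5, 0.75, 0.9, 1), function(f)
    fba_optimize(constrain_efficiency(toy$model, "T02", f, wt))$objective,
    numeric(1))
  expect_true(all(diff(growths) >= -1e-8))
  expect_equal(growths[1], 0, tolerance = 1e-8)
  expect_equal(growths[length(growths)], wt$objective, tolerance = 1e-8)
})

test_that("section reporters must exist and exchanges/medium are identified", {
  toy <- generate_toy_model(toy_model_spec())
  sol <- fba_optimize(toy$model)
  expect_error(section_flux(sol, c(Input = "NOPE")), "Input")
  expect_equal(exchange_reactions(toy$model), "EX_A")
  expect_equal(model_medium(toy$model), c(EX_A = 10))
})
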