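test_that("reynolds number is rho u D / eta", {
  fl <- fluid_properties(3.5e-3, 1060)
  bc <- boundary_conditions(0.1)
  # direct arithmetic oracle from the flow conditions
  expect_equal(reynolds_number(fl, bc, 2.3e-3), 1060 * 0.1 * 2.3e-3 / 3.5e-3,
               tolerance = 1e-12)
  expect_equal(reynolds_number(fl, 0, 2.3e-3), 0)
  expect_equal(reynolds_number(fl, boundary_conditions(0.2), 2.3e-3),
               2 * reynolds_number(fl, bc, 2.3e-3), tolerance = 1e-12)
})

test_that("channel solve reproduces plane Poiseuille flow", {
  ch <- channel_case()
  m <- ch$mesh; f <- ch$field
  h <- 2.3e-3; U <- 0.1
  expect_true(f$converged)
  expect_lte(max(f$residual_history$momentum[f$iterations],
                 f$residual_history$continuity[f$iterations]), 1e-4)
  # analytic profile, L2 over the downstream half
  sel <- m$cell_centroid[, 1] > 12e-3
  ua <- 6 * U * m$cell_centroid[sel, 2] * (h - m$cell_centroid[sel, 2]) / h^2
  expect_lte(sqrt(sum((f$u[sel] - ua)^2) / sum(ua^2)), 0.02)
  # fully developed flow is self-preserving: outlet profile equals the
  # inlet profile within 1%
  xs <- sort(unique(round(m$cell_centroid[, 1], 12)))
  first <- m$cell_centroid[, 1] == xs[1]
  last <- m$cell_centroid[, 1] == xs[length(xs)]
  expect_lte(sqrt(sum((f$u[last] - f$u[first])^2) / sum(f$u[first]^2)), 0.01)
  # mass conservation between inlet and outlet fluxes
  pf <- patch_fluxes(f, m)
  expect_lte(abs(sum(pf)) / abs(pf[["inlet"]]), 1e-3)
  # monotone residual trend over the final 20% of iterations
  tail_it <- f$residual_history$momentum[
    seq(ceiling(0.8 * f$iterations), f$iterations)]
  expect_lte(tail_it[length(tail_it)], tail_it[1])
})

test_that("velocity is invariant under an outlet reference pressure shift", {
  m <- channel_mesh(2.3e-3, 11.5e-3, 40, 16)
  fl <- fluid_properties()
  cfg <- solver_config()
  f1 <- solve_steady(m, fl, boundary_conditions(
    outlet_reference_pressure = mmhg_to_pa(100)), cfg)
  f2 <- solve_steady(m, fl, boundary_conditions(
    outlet_reference_pressure = mmhg_to_pa(100) + 1000), cfg)
  expect_lte(max(abs(f1$u - f2$u)) / max(abs(f1$u)), 1e-10)
  expect_lte(max(abs(f1$v - f2$v)) / max(abs(f1$u)), 1e-10)
  # pressure output shifts by exactly the added constant
  p1 <- f1$p + f1$p_ref; p2 <- f2$p + f2$p_ref
  expect_equal(max(abs((p2 - p1) - 1000)), 0, tolerance = 1e-9)
})

test_that("residual norms vanish for the exact discrete Poiseuille field", {
  m <- channel_mesh(2.3e-3, 11.5e-3, 50, 20)
  fl <- fluid_properties()
  pf <- poiseuille_field(m, 0.1, fl)
  rn <- residual_norms(pf, m, fl, pf$bc)
  expect_lt(rn[["continuity"]], 1e-12)
  # a uniform velocity aimed into the closed wall is flagged by a large
  # momentum residual
  bad <- pf; bad$u <- rep(0, length(pf$u)); bad$v <- rep(0.1, length(pf$u))
  rb <- residual_norms(bad, m, fl, pf$bc)
  expect_gt(rb[["momentum"]], 1)
  # converged solver output satisfies its own contract
  ch <- channel_case()
  rs <- residual_norms(ch$field, ch$mesh, ch$fluid, ch$bc)
  expect_lte(rs[["continuity"]], 1e-4)
})

test_that("graft outlet flux fraction is grid converged within 2%", {
  cfg1 <- coarse_config()
  cfg2 <- coarse_config()
  cfg2$mesh$target_edge_length_mm <- cfg1$mesh$target_edge_length_mm / 1.4
  frac <- sapply(list(cfg1, cfg2), function(cfg) {
    cs <- run_case(60, cfg, keep_field = TRUE)
    pf <- patch_fluxes(cs$field, cs$mesh)
    pf[["outlet_graft"]] / abs(pf[["inlet"]])
  })
  expect_lt(abs(frac[2] - frac[1]) / frac[1], 0.02)
})

test_that("non-convergence raises a diagnostic error with the history", {
  m <- channel_mesh(2.3e-3, 11.5e-3, 30, 12)
  err <- tryCatch(
    solve_steady(m, fluid_properties(), boundary_conditions(),
                 solver_config(max_outer_iterations = 3)),
    error = function(e) e)
  expect_match(conditionMessage(err), "no convergence")
  expect_true(is.matrix(err$residual_history))
  expect_equal(nrow(err$residual_history), 3L)
})
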