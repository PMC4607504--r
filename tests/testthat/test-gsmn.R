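# Constraint-based layer: FBA/FVA against the vertex oracle, biomass
# rebalancing arithmetic, strain-parameter and glucose-uptake calibration.

net_lp <- function(net) kinetigrate:::.lp_from_net(net)

test_that("FBA solves the toy network and matches the vertex oracle", {
  gs <- fx_gsmn()
  f <- fba(gs$net, sense = "max")
  expect_equal(f$status, "optimal")
  lp <- net_lp(gs$net)
  # cap the open bounds so the polytope is bounded for enumeration
  ub <- pmin(lp$ub, 1500)
  V <- enumerate_vertices(lp$Aeq, lp$beq, lp$lb, ub)
  expect_gt(nrow(V), 0)
  obj <- as.numeric(colnames(gs$net$S) == gs$net$biomass_id)
  expect_equal(f$objective_value, max(V %*% obj), tolerance = 1e-6)
  # every flux distribution satisfies S v = 0 and the bounds
  v <- f$fluxes$flux
  expect_lt(max(abs(gs$net$S %*% v)), 1e-6)
  expect_true(all(v >= lp$lb - 1e-8 & v <= lp$ub + 1e-8))
})

test_that("FVA brackets FBA and detects a forced internal cycle", {
  gs <- fx_gsmn()
  f <- fba(gs$net, sense = "max")
  net <- set_bounds(gs$net, "BIOMASS", lb = f$objective_value,
                    ub = f$objective_value)
  rng <- fva(net)
  v <- f$fluxes$flux
  expect_true(all(rng$min <= v + 1e-6 & v <= rng$max + 1e-6))

  gc <- make_toy_gsmn(fixture_spec(cycle = TRUE))
  net2 <- set_bounds(gc$net, "BIOMASS", lb = 0.2, ub = 0.2)
  net2 <- set_bounds(net2, "EX_glc", ub = 0.525)
  rng2 <- fva(net2, c("CYC1", "CYC2", "GLYC"))
  cyc <- rng2[rng2$reaction %in% c("CYC1", "CYC2"), ]
  expect_true(all(cyc$max - cyc$min > 1))      # the loop is free to spin
  glyc <- rng2[rng2$reaction == "GLYC", ]
  expect_lt(glyc$max - glyc$min, 1e-6)         # the chain is pinned
})

test_that("fully determined chain gives min = max throughout", {
  S <- matrix(c(1, -1, 0, 0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("EX_A", "R", "EX_B")))
  net <- stoich_network(S, lb = c(3, 0, 0), ub = c(3, 10, 10))
  rng <- fva(net)
  expect_equal(rng$min, rng$max, tolerance = 1e-9)
  expect_equal(rng$min, rep(3, 3), tolerance = 1e-9)
})

test_that("biomass rebalancing follows the three-step conversion", {
  gs <- make_toy_gsmn()
  # identity: one component, 1000 umol/gDCW of a 1000 g/mol species
  n1 <- rebalance_biomass(gs$net, c(A = 1000), c(A = 1000))
  expect_equal(unname(n1$S["A", "BIOMASS"]), -1)
  # two equal-molar components with MW 100 and 300: weight fractions
  # 0.25/0.75, coefficients 2.5 and 2.5 mmol/gDCW
  n2 <- rebalance_biomass(gs$net, c(A = 700, ac = 700),
                          c(A = 100, ac = 300))
  expect_equal(unname(n2$S["A", "BIOMASS"]), -2.5)
  expect_equal(unname(n2$S["ac", "BIOMASS"]), -2.5)
  # mass closes exactly: sum coeff * MW = 1 g
  expect_equal(2.5 * 100 / 1000 + 2.5 * 300 / 1000, 1)
  # the rebalanced network stays feasible at the reference growth rate
  n2 <- set_bounds(n2, "BIOMASS", lb = 0.2, ub = 0.2)
  expect_equal(fba(n2, sense = "max")$status, "optimal")
  # missing molecular weight names the component
  expect_error(rebalance_biomass(gs$net, c(A = 1, zz = 1), c(A = 100)), "zz")
})

test_that("strain parameters are recovered from zero-noise synthetic omics", {
  fit <- fx_strain_fit()
  truth <- fx_spec()$strain
  for (p in c("o2_max_uptake", "atpm_flux", "gam_atp_stoich", "h_p")) {
    expect_lt(abs(fit$parameters[[p]] - truth[[p]]) / truth[[p]], 1e-3)
  }
  expect_lt(fit$residual, 1e-10)
  expect_equal(fit$parameters$h_p - fit$parameters$h_c, 1)
  # best-of-N residual is non-increasing in N
  expect_true(all(diff(cummin(fit$starts$objective)) <= 0))
})

test_that("perturbing measured exchange rates shifts fitted bounds the same way", {
  gs <- fx_gsmn()
  om <- fx_omics()$omics
  om2 <- om
  om2$exchange$mean <- om2$exchange$mean * 1.10
  fit2 <- fit_strain_parameters(gs$net, om2, n_starts = 4, seed = 2)
  base <- fx_strain_fit()$parameters
  # oxygen uptake data moved up 10%, so the fitted cap must move up
  expect_gt(fit2$parameters$o2_max_uptake, base$o2_max_uptake)
})

test_that("glucose-uptake calibration inverts a linear growth relation", {
  net <- linear_growth_net()
  fit <- fit_glucose_uptake(net, target_mu = 0.2, ci_bounds = c(0.1, 10))
  expect_equal(fit$glc_max_uptake, 2, tolerance = 1e-6)
  expect_lt(abs(fit$achieved_mu - 0.2), 1e-6)
  # interval excluding the solution reports the achievable range
  expect_error(fit_glucose_uptake(net, 0.2, ci_bounds = c(3, 4)),
               "achievable range")
})

test_that("inactive-reaction constraints behave as stated", {
  gs <- fx_gsmn()
  net <- set_bounds(gs$net, "EX_glc", ub = 0.525)
  f0 <- fba(net, sense = "max")
  # CYC-free network carries no flux on the extra connectors: constraining a
  # zero-flux reaction leaves the optimum unchanged
  gx <- make_toy_gsmn(fixture_spec(n_extra_connecting = 1))
  netx <- set_bounds(gx$net, "EX_glc", ub = 0.525)
  fx0 <- fba(netx, sense = "max")
  netx2 <- set_inactive_reactions(netx, c("XCONN1", "EX_waste1"))
  expect_equal(fba(netx2, sense = "max")$objective_value,
               fx0$objective_value, tolerance = 1e-8)
  # silencing an essential reaction makes the fixed-maintenance problem infeasible
  net2 <- set_inactive_reactions(net, "GLYC")
  expect_equal(fba(net2, sense = "max")$status, "infeasible")
  expect_error(set_inactive_reactions(net, "NOPE"), "unknown")
  expect_equal(f0$status, "optimal")
})
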