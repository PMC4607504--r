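# QP projection of measured central fluxes and connecting-flux closure.

prefit_toy <- function() {
  fx_get("prefit", function() prefit_exchange_bounds(fx_gsmn()$net, 0.2))
}

test_that("prefit shrinks the feasible set, is idempotent, and hits the
           stoichiometric minimum glucose uptake", {
  gs <- fx_gsmn()
  netp <- prefit_toy()
  # glucose uptake at growth 0.2 by yield arithmetic: biomass needs 2 A and
  # 6 atp per unit growth plus maintenance 1; respiration is capped at 0.5,
  # so 2 r_f + (8/4) * ... reduces to u = d + (r_f + r_r)/2 = 0.525
  expect_equal(unname(netp$lb["EX_glc"]), 0.525, tolerance = 1e-6)
  rng0 <- fva(set_bounds(gs$net, "BIOMASS", lb = 0.2, ub = 0.2))
  rng1 <- fva(netp)
  expect_true(all(rng1$min >= rng0$min - 1e-7 & rng1$max <= rng0$max + 1e-7))
  netp2 <- prefit_exchange_bounds(netp, 0.2)
  expect_equal(netp2$lb, netp$lb, tolerance = 1e-9)
  expect_equal(netp2$ub, netp$ub, tolerance = 1e-9)
})

test_that("a feasible MFA vector projects onto itself", {
  netp <- prefit_toy()
  truth <- fx_kin()$truth$fluxes
  qp <- fit_central_fluxes_qp(netp, truth)
  expect_equal(unname(attr(qp, "central")), unname(truth), tolerance = 1e-6)
  expect_lt(attr(qp, "qp_objective"), 1e-10)
})

test_that("hand least-squares projection onto a constraint line", {
  # two fluxes, v1 = v2 enforced by one balance row, target (1, 3):
  # projection onto the line v1 = v2 is (2, 2)
  S <- matrix(c(1, -1), 1, 2, dimnames = list("m", c("r1", "r2")))
  net <- stoich_network(S, lb = c(-10, -10), ub = c(10, 10))
  qp <- fit_central_fluxes_qp(net, c(r1 = 1, r2 = 3))
  expect_equal(unname(attr(qp, "central")), c(2, 2), tolerance = 1e-6)
})

test_that("QP objective beats any sampled feasible point", {
  netp <- prefit_toy()
  target <- c(GLYC = 0.6, FERM = 0.1, RESP = 0.45)   # deliberately off-space
  qp <- fit_central_fluxes_qp(netp, target)
  lp <- kinetigrate:::.lp_from_net(netp)
  V <- enumerate_vertices(lp$Aeq, lp$beq, lp$lb, pmin(lp$ub, 1500))
  set.seed(1)
  idx <- match(names(target), netp$rxns)
  for (i in 1:100) {
    w <- stats::runif(nrow(V)); w <- w / sum(w)
    feas <- as.numeric(t(V) %*% w)          # convex combination stays feasible
    obj <- sum((feas[idx] - target)^2)
    expect_gte(obj, attr(qp, "qp_objective") - 1e-8)
  }
})

test_that("unmapped MFA ids are reported", {
  expect_error(fit_central_fluxes_qp(prefit_toy(), c(NOPE = 1)), "NOPE")
})

test_that("orientation mapping flips signed estimates explicitly", {
  m <- apply_orientation(c(a = 1, b = -2), c(b = -1))
  expect_equal(unname(m), c(1, 2))
})

test_that("connecting fluxes close the mass balance of every kinetic metabolite", {
  gs <- fx_gsmn()
  truth <- fx_kin()$truth
  conn <- compute_connecting_fluxes(gs$net, truth$fluxes, gs$kinetic_mets, 0.2)
  ci <- stats::setNames(conn$c_i$c_i, conn$c_i$metabolite)
  # GSMN steady-state closure: sum_central s_ij f_j + c_i = 0
  Sc <- gs$net$S[gs$kinetic_mets, names(truth$fluxes), drop = FALSE]
  closure <- as.numeric(Sc %*% truth$fluxes) + ci
  expect_lt(max(abs(closure)), 1e-8)
  # ground-truth values from the fixture ledger
  expect_equal(ci, truth$c_gsmn, tolerance = 1e-8)
  # biomass is part of the connecting set by default
  expect_true("BIOMASS" %in% conn$details$reaction)
  # FVA uniqueness: connecting fluxes are pinned on this fixture
  expect_lt(max(conn$c_i$fva_range), 1e-6)
})

test_that("a metabolite touched only by central reactions has c_i = 0", {
  S <- matrix(c(1, -1, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("A", "B"), c("EX_A", "R1", "R2")))
  net <- stoich_network(S, lb = c(0, 0, 0), ub = c(2, 10, 10),
                        roles = list(growth = "EX_A"))
  conn <- compute_connecting_fluxes(net, c(R1 = 2, R2 = 2), "B",
                                    target_mu = 2)
  expect_equal(unname(conn$c_i$c_i), 0)
  expect_equal(unname(conn$c_i$n_connecting), 0L)
})

test_that("degenerate alternate optima do not move c_i", {
  truth <- fx_kin()$truth
  gs <- fx_gsmn()
  gc <- make_toy_gsmn(fixture_spec(cycle = TRUE))
  c1 <- compute_connecting_fluxes(gs$net, truth$fluxes, gs$kinetic_mets, 0.2)
  c2 <- compute_connecting_fluxes(gc$net, truth$fluxes, gc$kinetic_mets, 0.2)
  expect_equal(c1$c_i$c_i, c2$c_i$c_i, tolerance = 1e-6)
})

test_that("closure constants make the reference state an exact fixed point", {
  kin <- fx_kin()
  gs <- fx_gsmn()
  conn <- compute_connecting_fluxes(gs$net, kin$truth$fluxes,
                                    gs$kinetic_mets, 0.2)
  m <- install_connecting_fluxes(kin$model, conn, dilution_correction = TRUE)
  expect_lt(steady_state_residual(m, ref_state(m)), 1e-10)
  # without the correction the residual equals the dilution term exactly
  m0 <- install_connecting_fluxes(kin$model, conn, dilution_correction = FALSE)
  f <- assemble_odes(m0)
  d <- f(0, ref_state(m0))[[1]]
  expect_equal(d, -m0$mu * ref_state(m0), tolerance = 1e-10, ignore_attr = TRUE)
})
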