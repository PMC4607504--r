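# Maximal-rate determination, curve fitting, missing concentrations and
# steady-state stabilization.

test_that("vmax inversion: half-saturation, round trip, ground-truth recovery", {
  law <- rate_law("irreversible_MM", params = list(vmax = 99, Km_s = 0.4),
                  substrates = "s")
  expect_equal(vmax_from_flux(law, 1, c(s = 0.4)), 2)
  # defining identity: installing the result reproduces the flux exactly
  law$params$vmax <- vmax_from_flux(law, 1, c(s = 0.4))
  expect_equal(kinetigrate:::.eval_law(law, c(s = 0.4)), 1)
  # zero saturation routes to the missing-concentration path
  expect_error(vmax_from_flux(law, 1, c(s = 0)), "missing")

  kin <- fx_kin()
  conc <- stats::setNames(kin$model$metabolites$conc, kin$model$metabolites$id)
  for (id in names(kin$truth$fluxes)) {
    v <- vmax_from_flux(kin$model$reactions[[id]], kin$truth$fluxes[[id]], conc)
    expect_equal(v, unname(kin$truth$vmax[id]), tolerance = 1e-10)
  }
})

test_that("turnover and specific-activity conversions carry exact unit factors", {
  expect_equal(vmax_from_kcat(100, 0.1, 50), 100 * 3600 * 0.1 / 50000)
  expect_equal(vmax_from_kcat(100, 0.1, 50), 0.72)
  expect_equal(vmax_from_kcat(100, 0.2, 50), 2 * 0.72)
  expect_equal(vmax_from_kcat(1 / 3600, 50 * 1000, 50), 1)
  expect_equal(vmax_from_specific_activity(10, 2), 1.2)
  expect_equal(vmax_from_specific_activity(1000 / 60, 1), 1)
  # algebraic identity between the two routes: sa = kcat*60*1000/(mw*1e6)
  kcat <- 7; mw <- 35; E <- 0.3
  sa <- kcat * 60 / (mw * 1000) * 1000
  expect_equal(vmax_from_specific_activity(sa, E), vmax_from_kcat(kcat, E, mw))
  expect_error(vmax_from_kcat(-1, 1, 1), "> 0")
  expect_error(vmax_from_specific_activity(0, 1), "> 0")
})

test_that("noiseless Michaelis-Menten curves are recovered to 1e-4", {
  law <- rate_law("irreversible_MM", params = list(vmax = 10, Km_s = 0.5),
                  substrates = "s")
  s <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10)
  data <- tibble::tibble(s = s, velocity = 10 * s / (0.5 + s))
  fit <- fit_rate_law_params(law, data, c("Km_s", "vmax"), n_starts = 10,
                             seed = 3)
  expect_lt(abs(fit$params$Km_s - 0.5) / 0.5, 1e-4)
  expect_lt(abs(fit$params$vmax - 10) / 10, 1e-4)
  expect_true(all(diff(cummin(fit$starts$objective)) <= 0))
})

test_that("noisy recovery stays within 10% at 20+ points", {
  law <- rate_law("irreversible_MM", params = list(vmax = 10, Km_s = 0.5),
                  substrates = "s")
  set.seed(11)
  s <- rep(c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 40), 2)
  v <- 10 * s / (0.5 + s) * (1 + rnorm(length(s), 0, 0.05))
  fit <- fit_rate_law_params(law, tibble::tibble(s = s, velocity = v),
                             c("Km_s", "vmax"), n_starts = 8, seed = 4)
  expect_lt(abs(fit$params$Km_s - 0.5) / 0.5, 0.10)
  expect_lt(abs(fit$params$vmax - 10) / 10, 0.10)
})

test_that("two-stage concerted-inhibition protocol recovers L and n", {
  p <- list(vmax = 50, Km_icit = 0.03, Km_nadp = 0.005, Ki_pep = 0.6,
            L = 0.4, n = 1.2)
  law <- rate_law("ordered_bibi_MWC", params = p,
                  substrates = c("icit", "nadp"), modifiers = "pep")
  icit <- c(0.005, 0.01, 0.02, 0.04, 0.08, 0.15, 0.3)
  mk <- function(pep_fixed) {
    vel <- vapply(icit, function(ic)
      rate_ordered_bibi_mwc(ic, 0.1, pep_fixed, p), numeric(1))
    tibble::tibble(icit = icit, nadp = 0.1, pep = pep_fixed, velocity = vel)
  }
  fit <- fit_mwc_inhibition(law, mk(0),
                            dplyr::bind_rows(mk(0.2), mk(1), mk(5)),
                            stage1_params = c("Km_nadp", "vmax"),
                            n_starts = 8, seed = 5)
  expect_lt(abs(fit$params$L - 0.4) / 0.4, 1e-3)
  expect_lt(abs(fit$params$n - 1.2) / 1.2, 1e-3)
})

test_that("degenerate curve data is flagged non-identifiable", {
  law <- rate_law("irreversible_MM", params = list(vmax = 1, Km_s = 1),
                  substrates = "s")
  data <- tibble::tibble(s = c(1, 2, 3), velocity = c(2, 2, 2))
  expect_warning(fit <- fit_rate_law_params(law, data, "vmax", n_starts = 2),
                 "non-identifiable")
  expect_false(fit$identifiable)
})

test_that("consistent known concentrations give the identity adjustment", {
  kin <- fx_kin()
  sol <- solve_missing_concentrations(
    kin$model, reactions = names(kin$truth$fluxes), unknown_mets = character(),
    target_fluxes = kin$truth$fluxes, policy = "min_weight", n_starts = 2)
  expect_lt(sol$obj1, 1e-8)
  expect_true(all(abs(sol$vmax_adjust - 1) < 1e-4))
})

test_that("a masked concentration is recovered exactly", {
  kin <- fx_kin()
  m <- kin$model
  m$metabolites$conc[m$metabolites$id == "ac"] <- NA
  sol <- solve_missing_concentrations(
    m, reactions = names(kin$truth$fluxes), unknown_mets = "ac",
    target_fluxes = kin$truth$fluxes, policy = "min_weight", n_starts = 3)
  expect_equal(unname(sol$solved_concentrations["ac"]), 0.5, tolerance = 1e-5)
  expect_lt(sol$obj1, 1e-8)
})

test_that("a perturbed flux is absorbed by the minimal vmax factor", {
  kin <- fx_kin()
  m <- kin$model
  m$metabolites$conc[m$metabolites$id == "A"] <- NA
  target <- kin$truth$fluxes
  target["GLYC"] <- target["GLYC"] * 1.05
  sol <- solve_missing_concentrations(
    m, reactions = names(target), unknown_mets = "A",
    target_fluxes = target, policy = "min_weight", n_starts = 3)
  expect_lt(sol$obj1, 1e-8)
  expect_equal(unname(sol$solved_concentrations["A"]), 1.2, tolerance = 1e-3)
  # the glucose branch has no unknown concentration, so its factor is forced;
  # grid oracle: smallest |a-1| with a balanced equation is 1.05
  grid <- seq(0.8, 1.3, by = 0.005)
  conc <- stats::setNames(m$metabolites$conc, m$metabolites$id)
  conc["A"] <- 1.2
  resid <- vapply(grid, function(a) {
    law <- kin$model$reactions$GLYC
    law$a2 <- a
    (kinetigrate:::.eval_law(law, conc) - target[["GLYC"]])^2
  }, numeric(1))
  ok <- grid[resid < 1e-8]
  expect_equal(min(abs(ok - 1)), abs(1.05 - 1), tolerance = 1e-6)
  expect_equal(unname(sol$vmax_adjust["GLYC"]), 1.05, tolerance = 1e-3)
})

test_that("an already-stable state needs no adjustment", {
  kin <- fx_kin()
  sol <- stabilize_steady_state(kin$model, ref_state(kin$model),
                                list(c("FERM", "Km_A")))
  expect_equal(unname(sol$A), 1)
  expect_lt(sol$spectral_abscissa, 0)
})

test_that("the minimal stabilizing factor matches the hand-derived boundary", {
  m <- boundary_model()
  st <- c(m1 = 0, m2 = 0)
  expect_lt(steady_state_residual(m, st), 1e-12)
  # unstable as parameterized (det J < 0 at A = 1)
  J <- compute_jacobian(m, st)
  expect_equal(classify_stability(eigen(J)$values), "unstable")
  sol <- stabilize_steady_state(m, st, list(c("AUTO", "k")),
                                method = "minimal")
  expect_equal(unname(sol$A), 0.8, tolerance = 1e-4)
  expect_lte(sol$spectral_abscissa, 1e-8)
  # penalized variant also reaches stability and reports the norm
  sol2 <- stabilize_steady_state(m, st, list(c("AUTO", "k")))
  expect_lte(sol2$spectral_abscissa, 0)
  expect_gte(sol2$adjustment_norm, 0.2 - 1e-4)
})

test_that("stabilization refuses states off the fixed point and impossible bounds", {
  m <- boundary_model()
  expect_error(stabilize_steady_state(m, c(m1 = 1, m2 = 1),
                                      list(c("AUTO", "k"))), "not a steady state")
  # with bounds that exclude the boundary no factor can stabilize
  expect_error(stabilize_steady_state(m, c(m1 = 0, m2 = 0),
                                      list(c("AUTO", "k")),
                                      bounds = c(0.9, 2), method = "minimal"),
               "spectral abscissa")
})
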