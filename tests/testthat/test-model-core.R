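# Rate laws, ODE assembly and simulation of the kinetic model container.

test_that("irreversible Michaelis-Menten limits: zero substrate and saturation", {
  law <- rate_law("irreversible_MM", params = list(vmax = 3, Km_s = 0.5),
                  substrates = "s")
  expect_equal(kinetigrate:::.eval_law(law, c(s = 0)), 0)
  expect_equal(kinetigrate:::.eval_law(law, c(s = 1e6 * 0.5)), 3, tolerance = 1e-5)
})

test_that("mass action balances at detailed-balance concentrations", {
  law <- rate_law("mass_action", params = list(kf = 0.7, kr = 0.3),
                  substrates = "A", products = "B")
  expect_equal(kinetigrate:::.eval_law(law, c(A = 0.3, B = 0.7)), 0)
})

test_that("rates are linear in the maximal-rate adjustment factor", {
  kin <- fx_kin()
  st <- ref_state(kin$model)
  r1 <- evaluate_rates(kin$model, st)
  m2 <- kin$model
  m2$reactions$FERM$a2 <- 2
  r2 <- evaluate_rates(m2, st)
  expect_equal(r2[["FERM"]], 2 * r1[["FERM"]])
  expect_equal(r2[["GLYC"]], r1[["GLYC"]])
})

test_that("rate-law validation rejects non-positive binding constants", {
  expect_error(rate_law("irreversible_MM", params = list(vmax = 1, Km_s = 0),
                        substrates = "s"), "Km/Ki")
  expect_error(rate_ordered_bibi_mwc(1, 1, 0, params = list(
    vmax = 1, Km_icit = 0, Km_nadp = 1, Ki_pep = 1, L = 1, n = 1)), "> 0")
})

test_that("ordered bi-bi MWC law: no substrate, concerted limits, inhibition", {
  p <- list(vmax = 54.829, Km_icit = 0.029, Km_nadp = 0.005, Ki_pep = 1,
            L = 0.3709, n = 1.0048)
  expect_equal(rate_ordered_bibi_mwc(0, 1, 0.5, p), 0)
  # with L = 0 the concerted factor is 1 and the rate is the bare
  # ordered bi-bi value; at icit = Km_icit, nadp = Km_nadp that value is
  # vmax * (1*1) / (1 + 1 + 1) = vmax / 3 (worked symbolically)
  p0 <- p; p0$L <- 0
  expect_equal(rate_ordered_bibi_mwc(0.029, 0.005, 2, p0), 54.829 / 3,
               tolerance = 1e-12)
  # strictly decreasing in the allosteric inhibitor
  rates <- vapply(c(0, 0.2, 1, 5), function(pep)
    rate_ordered_bibi_mwc(0.029, 0.005, pep, p), numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_true(all(rates >= 0 & rates <= p$vmax))
  # concerted factor -> 0 as inhibitor -> infinity
  expect_lt(rate_ordered_bibi_mwc(0.029, 0.005, 1e7, p), 1e-5 * p$vmax)
})

test_that("dilution-only dynamics follow the closed form exp(-mu t)", {
  m <- dilution_only_model(mu = 0.2, m0 = 2)
  tr <- simulate_model(m, init = 2, t_end = 5)
  expect_equal(tr$m, 2 * exp(-0.2 * tr$time), tolerance = 1e-6)
  expect_equal(tr$m[nrow(tr)], 2 * exp(-1), tolerance = 1e-6)
  # monotone decay, no kinetics
  expect_true(all(diff(tr$m) < 0))
})

test_that("dilution conserves the summed concentration derivative exactly", {
  m <- chain_model()
  m$reactions$R1$params$kf <- 0
  m$reactions$R2$params$kf <- 0
  m$c[] <- 0
  f <- assemble_odes(m)
  for (st in list(c(A = 1, B = 2), c(A = 0.3, B = 0), c(A = 4, B = 4))) {
    d <- f(0, st)[[1]]
    expect_equal(sum(d), -m$mu * sum(st))
    expect_equal(d, -m$mu * st, ignore_attr = TRUE)
  }
})

test_that("hand-solved fixed point of the mass-action chain has zero derivative", {
  m <- chain_model()
  # dA/dt = -0.5 A + 0.6 - 0.1 A = 0 at A = 1;
  # dB/dt = 0.5 A - 0.2 B - 0.1 B = 0 at B = 5/3
  expect_lt(steady_state_residual(m, c(A = 1, B = 5 / 3)), 1e-12)
})

test_that("derivative at a supplied steady state is below tolerance", {
  kin <- fx_kin()
  expect_lt(steady_state_residual(kin$model, ref_state(kin$model)), 1e-6)
})

test_that("simulation converges back onto a nearby bistable fixed point", {
  bm <- fx_motif()
  for (which in c("low", "high")) {
    fp <- bm$fixed_points[which, ]
    tr <- simulate_model(bm$model, fp * 0.97, t_end = 400,
                         times = c(0, 400))
    final <- as.numeric(tr[nrow(tr), c("m1", "m2", "m3")])
    expect_equal(final, unname(fp), tolerance = 1e-5)
  }
})

test_that("negative concentrations are rejected, clipping only in rate evaluation", {
  kin <- fx_kin()
  st <- ref_state(kin$model)
  st["A"] <- -0.1
  expect_error(evaluate_rates(kin$model, st), "negative")
  r <- evaluate_rates(kin$model, st, clip = TRUE)
  expect_true(all(is.finite(r)))
})

test_that("unresolvable metabolite references are configuration errors", {
  mets <- metabolite_table(id = "A")
  rx <- list(R = rate_law("irreversible_MM", params = list(vmax = 1, Km_x = 1),
                          substrates = "x"))
  S <- matrix(0, 1, 1, dimnames = list("A", "R"))
  expect_error(kinetic_model(mets, rx, S), "unknown metabolite")
})
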