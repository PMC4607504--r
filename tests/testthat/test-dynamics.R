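# Steady-state search, Jacobians, stability classification, scanning and
# state comparison.

test_that("a linear relaxation system converges to its unique attractor", {
  m <- chain_model()
  ss <- find_steady_state(m, c(A = 4, B = 0.1), tol = 1e-8)
  expect_equal(unname(ss$conc), c(1, 5 / 3), tolerance = 1e-6)
  expect_lt(ss$residual_norm, 1e-8)
  expect_equal(ss$classification, "stable")
})

test_that("each basin of the bistable fixture returns its own fixed point", {
  bm <- fx_motif()
  lo <- find_steady_state(bm$model, c(0.5, 0.5, 0.5))
  hi <- find_steady_state(bm$model, c(9, 2, 1))
  expect_equal(unname(lo$conc), unname(bm$fixed_points["low", ]),
               tolerance = 1e-6)
  expect_equal(unname(hi$conc), unname(bm$fixed_points["high", ]),
               tolerance = 1e-6)
})

test_that("finite differences reproduce the analytic Jacobian of a linear system", {
  m <- boundary_model()
  ka <- (2.1 - 20 / 11) / 0.8
  A_true <- matrix(c(ka - 2 - 0.1, 1, 2, -1 - 0.1), 2, 2, byrow = TRUE)
  J <- compute_jacobian(m, c(m1 = 0.5, m2 = 0.5))
  expect_equal(unname(J), A_true, tolerance = 1e-4)
  # forward scheme agrees with an independent central-difference recomputation
  bm <- fx_motif()
  st <- bm$fixed_points["high", ]
  Jf <- compute_jacobian(bm$model, st)
  f <- assemble_odes(bm$model)
  eps <- 1e-6
  Jc <- matrix(0, 3, 3)
  for (j in 1:3) {
    up <- st; up[j] <- up[j] + eps
    dn <- st; dn[j] <- dn[j] - eps
    Jc[, j] <- (f(0, up)[[1]] - f(0, dn)[[1]]) / (2 * eps)
  }
  expect_equal(unname(Jf), Jc, tolerance = 1e-3)
})

test_that("a gradient-flow fixture yields a symmetric Jacobian", {
  # coupled mass-action exchange A <-> B has symmetric off-diagonal terms
  mets <- metabolite_table(id = c("A", "B"))
  rx <- list(EXC = rate_law("mass_action", params = list(kf = 0.4, kr = 0.4),
                            substrates = "A", products = "B"))
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "EXC"))
  m <- kinetic_model(mets, rx, S, c = c(A = 0, B = 0), mu = 0.1, rho_X = 1)
  J <- compute_jacobian(m, c(A = 1, B = 1))
  expect_equal(J[1, 2], J[2, 1], tolerance = 1e-5)
})

test_that("stability classification follows the declared rule", {
  expect_equal(classify_stability(c(-1, -2)), "stable")
  expect_equal(classify_stability(c(-1, 0.5)), "unstable")
  expect_equal(classify_stability(complex(real = c(0, 0), imaginary = c(2, -2))),
               "periodic")
  # zero real parts count as stable when mixed with negatives
  expect_equal(classify_stability(c(0, -3, -1e6)), "stable")
  expect_error(classify_stability(numeric(0)))
})

test_that("a monostable model scans to a single state with full basin count", {
  m <- chain_model()
  sc <- multistart_scan(m, n_starts = 30, seed = 5)
  expect_equal(length(sc$states), 1L)
  expect_equal(sum(sc$basin_counts) + sum(sc$failures), 30)
  expect_equal(sc$basin_counts[1], 30L)
})

test_that("the bistable fixture scans to exactly its two stable states", {
  bm <- fx_motif()
  sc <- multistart_scan(bm$model, n_starts = 200, seed = 7)
  expect_equal(length(sc$states), 2L)
  expect_true(all(sc$summary$classification == "stable"))
  found <- t(vapply(sc$states, `[[`, numeric(3), "conc"))
  ord <- order(found[, 1])
  expect_equal(unname(found[ord, ]),
               unname(bm$fixed_points[c("low", "high"), ]), tolerance = 1e-5)
  expect_true(all(sc$basin_counts > 10))    # both basins hit
})

test_that("two stable states persist across seeds", {
  bm <- fx_motif()
  for (seed in 1:10) {
    sc <- multistart_scan(bm$model, n_starts = 50, seed = seed)
    expect_equal(sum(sc$summary$classification == "stable"), 2L)
  }
})

test_that("scans are reproducible bit-for-bit under a fixed seed", {
  bm <- fx_motif()
  s1 <- multistart_scan(bm$model, n_starts = 40, seed = 9)
  s2 <- multistart_scan(bm$model, n_starts = 40, seed = 9)
  expect_identical(s1$summary, s2$summary)
  expect_identical(lapply(s1$states, `[[`, "conc"),
                   lapply(s2$states, `[[`, "conc"))
})

test_that("every reported state re-verifies residual and classification", {
  bm <- fx_motif()
  sc <- multistart_scan(bm$model, n_starts = 40, seed = 3)
  for (st in sc$states) {
    expect_lt(steady_state_residual(bm$model, st$conc), 1e-6)
    J <- compute_jacobian(bm$model, st$conc)
    expect_equal(classify_stability(eigen(J, only.values = TRUE)$values),
                 st$classification)
  }
})

test_that("classification matches long-horizon simulation behaviour", {
  bm <- fx_motif()
  for (which in c("low", "high")) {
    fp <- bm$fixed_points[which, ]
    tr <- simulate_model(bm$model, fp * (1 + 1e-3), t_end = 300,
                         times = c(0, 300))
    final <- as.numeric(tr[nrow(tr), colnames(bm$fixed_points)])
    expect_equal(final, unname(fp), tolerance = 1e-4)   # perturbation decays
  }
  # the saddle's unstable direction grows away from it
  mid <- bm$fixed_points["middle", ]
  tr <- simulate_model(bm$model, mid + c(1e-3, 0, 0), t_end = 300,
                       times = c(0, 300))
  expect_gt(abs(tr$m1[2] - mid["m1"]), 0.5)
})

test_that("state comparison reports percent changes and undefined baselines", {
  kin <- fx_kin()
  a <- ref_state(kin$model)
  cmp0 <- compare_states(kin$model, a, a)
  expect_true(all(cmp0$metabolites$percent_change == 0))
  expect_true(all(cmp0$fluxes$change == 0))
  b <- a; b["A"] <- a["A"] * 1.05
  cmp <- compare_states(kin$model, a, b)
  expect_equal(cmp$metabolites$percent_change[
    cmp$metabolites$metabolite == "A"], 5, tolerance = 1e-10)
  z <- a; z["ac"] <- 0
  cmpz <- compare_states(kin$model, z, a)
  row <- cmpz$metabolites[cmpz$metabolites$metabolite == "ac", ]
  expect_true(row$undefined)
  expect_true(is.na(row$percent_change))
})
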