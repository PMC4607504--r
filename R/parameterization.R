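# Parameterization: maximal rates from fluxes / turnover numbers / specific
# activities, least-squares rate-law fitting with multistart, solving for
# missing steady-state concentrations under minimal parameter adjustment,
# and eigenvalue stabilization of a reference steady state.
#
# Naming note: the literature uses clashing symbols for the multiplicative
# adjustment factors, so this package names them by what they touch:
# `vmax_adjust` (factor on a reaction's maximal rate, the `a2` slot of a
# rate law) and `param_adjust` (per-parameter factors, the `a1` slots).

#' Maximal rate from a steady-state flux
#'
#' Inverts the rate law at known concentrations: `vmax = flux / f([m]; {Km})`
#' where `f` is the law's saturation function (the rate at `vmax = 1`).
#' Installing the result reproduces the flux exactly at those
#' concentrations.
#'
#' @param law a [rate_law()] with a `vmax` parameter.
#' @param flux steady-state reaction flux, mmol/gDCW/h.
#' @param conc named concentration vector covering the law's references (mM).
#' @return `vmax` in mmol/gDCW/h.
#' @export
vmax_from_flux <- function(law, flux, conc) {
  if (is.null(law$params$vmax)) stop("law has no vmax parameter")
  unit <- law
  unit$params$vmax <- 1
  unit$a2 <- 1
  unit$a1["vmax"] <- 1
  sat <- .eval_law(unit, conc)
  if (abs(sat) < 1e-12) {
    stop("saturation function is zero at the supplied concentrations; ",
         "a required concentration is missing or zero (route through ",
         "solve_missing_concentrations)")
  }
  flux / sat
}

#' Maximal rate from a turnover number
#'
#' `vmax = kcat * 3600 * E / (mw * 1000)`: the 3600 converts 1/s to 1/h and
#' the molecular weight in kDa times 1000 converts mgProtein to mmol enzyme.
#'
#' @param kcat turnover number, 1/s.
#' @param enzyme_conc enzyme concentration, mgProtein/gDCW.
#' @param mw polypeptide molecular weight, kDa.
#' @return `vmax` in mmol/gDCW/h.
#' @export
vmax_from_kcat <- function(kcat, enzyme_conc, mw) {
  if (any(c(kcat, enzyme_conc, mw) <= 0)) stop("all inputs must be > 0")
  kcat * 3600 * enzyme_conc / (mw * 1000)
}

#' Maximal rate from a specific activity
#'
#' `vmax = sa * E * 60 / 1000`: 60 converts per-minute to per-hour, 1000
#' converts micromol to mmol.
#'
#' @param sa specific activity, micromol/mgProtein/min.
#' @param enzyme_conc enzyme concentration, mgProtein/gDCW.
#' @return `vmax` in mmol/gDCW/h.
#' @export
vmax_from_specific_activity <- function(sa, enzyme_conc) {
  if (any(c(sa, enzyme_conc) <= 0)) stop("all inputs must be > 0")
  sa * enzyme_conc * 60 / 1000
}

# evaluate a law at one data row (named concentrations) with candidate params
.law_with_params <- function(law, params) {
  for (nm in names(params)) law$params[[nm]] <- params[[nm]]
  law
}

#' Fit rate-law parameters to kinetic curve data
#'
#' Best-of-multistart least squares: minimizes the sum of squared vertical
#' distances between measured velocities and the rate law evaluated at each
#' assay's concentrations. Initial guesses are drawn uniformly from the
#' supplied sampling intervals; optimization runs on log-parameters so
#' positivity is structural. A two-stage allosteric protocol (fit the
#' uninhibited series for the Michaelis constants and maximal rate first,
#' then the concerted-inhibition parameters `L` and `n` jointly over all
#' inhibited series with stage-1 values fixed) is available by calling the
#' function twice, or through [fit_mwc_inhibition()].
#'
#' @param law a [rate_law()].
#' @param data tibble with one column per referenced metabolite
#'   concentration (mM) and a `velocity` column (law rate units).
#' @param free_params names of parameters to fit.
#' @param intervals named list of length-2 sampling intervals for the
#'   multistart draws (default `[0, 10]` for binding constants, `[0, 1000]`
#'   for `vmax`-like parameters).
#' @param n_starts number of independent initial guesses.
#' @param seed RNG seed.
#' @return list with `law` (updated), `params`, `residual`, `starts`
#'   (per-start objectives) and `identifiable` (FALSE when all velocities
#'   are equal).
#' @export
fit_rate_law_params <- function(law, data, free_params, intervals = NULL,
                                n_starts = 25, seed = 1) {
  stopifnot(nrow(data) >= length(free_params))
  if (is.null(intervals)) intervals <- list()
  for (p in free_params) {
    if (is.null(intervals[[p]])) {
      intervals[[p]] <- if (grepl("vmax|^k", p)) c(0, 1000) else c(0, 10)
    }
  }
  identifiable <- stats::sd(data$velocity) > 0
  if (!identifiable) warning("degenerate data: all velocities equal; fit is non-identifiable")
  obj <- function(logth) {
    th <- stats::setNames(as.list(exp(logth)), free_params)
    cand <- .law_with_params(law, th)
    pred <- vapply(seq_len(nrow(data)), function(i) {
      conc <- unlist(data[i, setdiff(names(data), "velocity")])
      .eval_law(cand, conc)
    }, numeric(1))
    sum((pred - data$velocity)^2)
  }
  set.seed(seed)
  fits <- lapply(seq_len(n_starts), function(s) {
    th0 <- vapply(free_params, function(p)
      max(stats::runif(1, intervals[[p]][1], intervals[[p]][2]), 1e-6), numeric(1))
    if (length(free_params) == 1) {
      f <- stats::optim(log(th0), obj, method = "Brent",
                        lower = log(1e-9), upper = log(1e9))
      f$par <- stats::setNames(f$par, free_params)
      return(f)
    }
    f <- stats::optim(log(th0), obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
    stats::optim(f$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-14))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  params <- stats::setNames(as.list(exp(best$par)), free_params)
  list(law = .law_with_params(law, params), params = params,
       residual = best$value,
       starts = tibble::tibble(start = seq_len(n_starts), objective = vals),
       identifiable = identifiable)
}

#' Two-stage fit of an allosterically inhibited rate law
#'
#' Stage 1 fits the binding/maximal-rate parameters on the uninhibited
#' series; stage 2 fits the concerted-transition parameters `L` and `n`
#' jointly over all inhibited series with stage-1 estimates held fixed.
#'
#' @param law a [rate_law()] (typically `ordered_bibi_MWC`).
#' @param uninhibited,inhibited data tibbles as in [fit_rate_law_params()].
#' @param stage1_params,stage2_params parameter names per stage.
#' @inheritParams fit_rate_law_params
#' @export
fit_mwc_inhibition <- function(law, uninhibited, inhibited,
                               stage1_params, stage2_params = c("L", "n"),
                               intervals = NULL, n_starts = 25, seed = 1) {
  s1 <- fit_rate_law_params(law, uninhibited, stage1_params,
                            intervals = intervals, n_starts = n_starts,
                            seed = seed)
  s2 <- fit_rate_law_params(s1$law, inhibited, stage2_params,
                            intervals = intervals, n_starts = n_starts,
                            seed = seed + 1)
  list(law = s2$law, stage1 = s1, stage2 = s2,
       params = c(s1$params, s2$params),
       residual = s2$residual)
}

# rates of selected reactions at the model's reference concentrations with
# overrides for unknown concentrations and adjustment factors
.rates_at_reference <- function(model, reactions, conc_override = NULL,
                                vmax_adjust = NULL, param_adjust = NULL) {
  conc <- stats::setNames(model$metabolites$conc, model$metabolites$id)
  if (!is.null(conc_override)) conc[names(conc_override)] <- conc_override
  if (any(is.na(conc))) conc[is.na(conc)] <- 0
  vapply(reactions, function(id) {
    law <- model$reactions[[id]]
    if (!is.null(vmax_adjust) && !is.na(vmax_adjust[id])) law$a2 <- vmax_adjust[[id]]
    if (!is.null(param_adjust)) {
      key <- paste0(id, ".")
      hit <- grep(key, names(param_adjust), fixed = TRUE, value = TRUE)
      for (h in hit) law$a1[sub(key, "", h, fixed = TRUE)] <- param_adjust[[h]]
    }
    if (id %in% model$inactive) 0 else .eval_law(law, conc, id)
  }, numeric(1))
}

#' Solve for missing steady-state concentrations with minimal adjustment
#'
#' Finds unknown steady-state metabolite concentrations (and, where needed,
#' multiplicative adjustments to maximal rates and binding constants) such
#' that every steady-state reaction equation of the subproblem balances its
#' target flux simultaneously — shared unknowns take a single value across
#' equations. The objective is `w1*obj1 + w2*obj2 + w3*obj3` with `obj1` the
#' summed squared flux residuals, `obj2` the squared deviation of the
#' maximal-rate factors from 1 and `obj3` that of the binding-constant
#' factors (all squared sums; a signed difference cannot be minimized).
#'
#' Two weight policies are provided. `"min_weight"` (problems whose factors
#' are unbounded): `w2 = 1`, `w3 = 0` and `w1` is set to the minimum value
#' for which the optimized `obj1` falls below `obj1_tol`, found by a
#' geometric/bisection line search. `"bounded"` (the large coupled problem):
#' `w1 = 1`, `w2 = w3 = 0` and the factors are box-constrained to
#' `factor_bounds` (default `[0, 4]`).
#'
#' @param model a `ccm_kinetic_model` whose metabolite table carries the
#'   known reference concentrations (`NA` = unknown).
#' @param reactions reaction ids whose steady-state equations participate.
#' @param unknown_mets metabolite ids to solve for.
#' @param target_fluxes named flux vector (mmol/gDCW/h) for `reactions`.
#' @param adjust_vmax reaction ids whose maximal-rate factor may move
#'   (default: all participating reactions).
#' @param adjust_params optional character vector `"<reaction>.<param>"` of
#'   binding constants allowed to move.
#' @param policy `"min_weight"` or `"bounded"`.
#' @param factor_bounds closed interval for the factors under `"bounded"`.
#' @param conc_upper upper bound for unknown concentrations (mM).
#' @param obj1_tol convergence requirement on the flux residual.
#' @param n_starts multistart count for the inner optimizer.
#' @param seed RNG seed.
#' @return a `ccm_adjustment_solution`: list with `solved_concentrations`,
#'   `vmax_adjust`, `param_adjust`, `weights`, `obj1`, `obj2`, `obj3`,
#'   `converged`.
#' @export
solve_missing_concentrations <- function(model, reactions, unknown_mets,
                                         target_fluxes,
                                         adjust_vmax = reactions,
                                         adjust_params = character(),
                                         policy = c("min_weight", "bounded"),
                                         factor_bounds = c(0, 4),
                                         conc_upper = 50, obj1_tol = 1e-8,
                                         n_starts = 5, seed = 1) {
  policy <- match.arg(policy)
  stopifnot(setequal(names(target_fluxes), reactions))
  target <- target_fluxes[reactions]
  nu <- length(unknown_mets); nv <- length(adjust_vmax); np <- length(adjust_params)
  unpack <- function(th) {
    list(conc = stats::setNames(th[seq_len(nu)], unknown_mets),
         va = if (nv) stats::setNames(th[nu + seq_len(nv)], adjust_vmax) else NULL,
         pa = if (np) stats::setNames(th[nu + nv + seq_len(np)], adjust_params) else NULL)
  }
  objs <- function(th) {
    z <- unpack(th)
    r <- .rates_at_reference(model, reactions, conc_override = z$conc,
                             vmax_adjust = z$va, param_adjust = z$pa)
    c(obj1 = sum((r - target)^2),
      obj2 = if (nv) sum((z$va - 1)^2) else 0,
      obj3 = if (np) sum((z$pa - 1)^2) else 0)
  }
  lower <- c(rep(1e-9, nu), rep(factor_bounds[1], nv + np))
  upper <- c(rep(conc_upper, nu), rep(factor_bounds[2], nv + np))
  if (policy == "min_weight") {
    # factors unconstrained under this policy (penalized, not bounded)
    lower[nu + seq_len(nv + np)] <- 1e-6
    upper[nu + seq_len(nv + np)] <- 100
  }
  run <- function(w) {
    set.seed(seed)
    best <- NULL
    for (s in seq_len(n_starts)) {
      th0 <- c(stats::runif(nu, 0.1, 5), rep(1, nv + np))
      if (s > 1) th0 <- th0 * exp(stats::rnorm(length(th0), 0, 0.2))
      th0 <- pmin(pmax(th0, lower), upper)
      f <- tryCatch(stats::optim(th0, function(th) {
        o <- objs(th)
        sum(w * o)
      }, method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 500, factr = 1e4)), error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
    }
    best
  }
  if (policy == "bounded") {
    w <- c(1, 0, 0)
    best <- run(w)
  } else {
    # minimum w1 for which obj1 converges below tolerance
    w1 <- 1
    best <- run(c(w1, 1, 0))
    while (objs(best$par)["obj1"] > obj1_tol && w1 < 1e12) {
      w1 <- w1 * 10
      best <- run(c(w1, 1, 0))
    }
    if (objs(best$par)["obj1"] <= obj1_tol && w1 > 1) {
      lo <- w1 / 10; hi <- w1
      for (i in 1:20) {
        mid <- sqrt(lo * hi)
        cand <- run(c(mid, 1, 0))
        if (objs(cand$par)["obj1"] <= obj1_tol) { hi <- mid; best <- cand }
        else lo <- mid
      }
      w1 <- hi
    }
    w <- c(w1, 1, 0)
  }
  if (is.null(best)) stop("no feasible solution found within bounds")
  o <- objs(best$par)
  if (o["obj1"] > obj1_tol * 10) {
    stop(sprintf("flux residual %.3g did not converge below %.1g; best factors: %s",
                 o["obj1"], obj1_tol,
                 paste(signif(unpack(best$par)$va, 4), collapse = ", ")))
  }
  z <- unpack(best$par)
  structure(list(solved_concentrations = z$conc, vmax_adjust = z$va,
                 param_adjust = z$pa, weights = w,
                 obj1 = unname(o["obj1"]), obj2 = unname(o["obj2"]),
                 obj3 = unname(o["obj3"]),
                 converged = o["obj1"] <= obj1_tol * 10),
            class = "ccm_adjustment_solution")
}

# apply stabilization factors A to the adjustable parameters, optionally
# rescaling each touched reaction's maximal rate so a reference state stays
# an exact fixed point
.apply_stabilization <- function(model, A, adjustable, state, compensate = TRUE) {
  conc <- .full_conc(model, stats::setNames(state, model$state_ids))
  conc[is.na(conc)] <- 0
  for (i in seq_along(adjustable)) {
    rx <- adjustable[[i]][1]; pm <- adjustable[[i]][2]
    law <- model$reactions[[rx]]
    r0 <- if (compensate) .eval_law(law, conc, rx) else NULL
    law$a1[pm] <- A[i]
    if (compensate) {
      r1 <- .eval_law(law, conc, rx)
      if (abs(r1) > 1e-12 && abs(r0) > 1e-12) law$a2 <- law$a2 * r0 / r1
    }
    model$reactions[[rx]] <- law
  }
  model
}

#' Stabilize a reference steady state by minimal parameter adjustment
#'
#' Multiplies selected literature-derived binding constants by factors
#' `A_i` (each constrained to `bounds`) so that the spectral abscissa
#' (largest real part of the Jacobian eigenvalues) at the reference state
#' becomes non-positive. Each touched reaction's maximal rate is rescaled in
#' tandem so the reference state remains an exact fixed point — otherwise
#' the spectrum would be evaluated off the fixed point. The objective
#' `max(Re(lambda)) + penalty * ||A - 1||` is non-smooth, so a derivative-free
#' Nelder-Mead search is run from the unadjusted point plus random
#' perturbations (`method = "penalized"`). `method = "minimal"` instead
#' bisects along the adjustment ray for the smallest `||A - 1||` achieving
#' stability, which on a one-parameter problem returns the critical
#' (stability-boundary) factor.
#'
#' @param model a `ccm_kinetic_model`.
#' @param state steady-state concentration vector (residual below `tol`).
#' @param adjustable list of `c(reaction_id, param_name)` pairs.
#' @param bounds closed interval for each `A_i`.
#' @param penalty weight on `||A - 1||` (L2 by default).
#' @param norm `"l2"` or `"l1"`.
#' @param method `"penalized"` or `"minimal"` (see above).
#' @param compensate rescale maximal rates to keep the state a fixed point.
#' @param n_starts,seed multistart controls.
#' @param tol residual tolerance for accepting `state`.
#' @return a `ccm_adjustment_solution` with fields `A`, `spectral_abscissa`,
#'   `adjustment_norm`, `model` (adjusted copy); errors if no `A` within
#'   bounds achieves stability, reporting the best abscissa found.
#' @export
stabilize_steady_state <- function(model, state, adjustable,
                                   bounds = c(0.5, 2), penalty = 0.01,
                                   norm = c("l2", "l1"),
                                   method = c("penalized", "minimal"),
                                   compensate = TRUE, n_starts = 6, seed = 1,
                                   tol = 1e-6) {
  norm <- match.arg(norm); method <- match.arg(method)
  state <- stats::setNames(as.numeric(state), model$state_ids)
  if (steady_state_residual(model, state) > tol) {
    stop("state is not a steady state of the model (residual above tol)")
  }
  nA <- length(adjustable)
  nfun <- function(x) if (norm == "l2") sqrt(sum(x^2)) else sum(abs(x))
  abscissa <- function(A) {
    m2 <- .apply_stabilization(model, A, adjustable, state, compensate)
    J <- compute_jacobian(m2, state)
    max(Re(eigen(J, only.values = TRUE)$values))
  }
  clamp <- function(A) pmin(pmax(A, bounds[1]), bounds[2])
  objfn <- function(A) {
    pen <- sum(pmax(bounds[1] - A, 0) + pmax(A - bounds[2], 0))
    if (pen > 0) return(1e6 * (1 + pen))
    abscissa(A) + penalty * nfun(A - 1)
  }
  set.seed(seed)
  sa0 <- abscissa(rep(1, nA))
  if (sa0 <= 0) {
    # no adjustment needed
    return(structure(list(
      A = stats::setNames(rep(1, nA), vapply(adjustable, paste, "", collapse = ".")),
      spectral_abscissa = sa0, spectral_abscissa_check = sa0,
      adjustment_norm = 0, model = model, method = method),
      class = "ccm_adjustment_solution"))
  }
  if (method == "minimal") {
    # direction: penalized solution (or the single coordinate) from 1
    dir <- if (nA == 1) {
      cand <- c(bounds[1], bounds[2])
      sa <- vapply(cand, abscissa, numeric(1))
      if (!any(sa <= 0)) stop(sprintf(
        "no A within bounds achieves stability; best spectral abscissa %.4g",
        min(sa)))
      if (sa[1] <= sa[2]) -1 else 1
    } else {
      p <- stabilize_steady_state(model, state, adjustable, bounds, penalty,
                                  norm, "penalized", compensate, n_starts, seed, tol)
      d <- p$A - 1
      if (nfun(d) == 0) return(p)
      d / max(abs(d))
    }
    # bisect t in [0, t_max] for the smallest t with abscissa(1 + t*dir) <= 0
    t_hi_lim <- min(ifelse(dir > 0, (bounds[2] - 1) / dir,
                           ifelse(dir < 0, (bounds[1] - 1) / dir, Inf)))
    lo <- 0; hi <- t_hi_lim
    if (abscissa(clamp(1 + hi * dir)) > 0) {
      stop(sprintf("no A along the adjustment ray achieves stability; best spectral abscissa %.4g",
                   abscissa(clamp(1 + hi * dir))))
    }
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (abscissa(clamp(1 + mid * dir)) <= 0) hi <- mid else lo <- mid
    }
    A <- clamp(1 + hi * dir)
  } else {
    starts <- c(list(rep(1, nA)), lapply(seq_len(max(0, n_starts - 1)), function(i)
      clamp(1 + stats::rnorm(nA, 0, 0.2))))
    fits <- lapply(starts, function(A0) {
      if (nA == 1) {
        stats::optim(A0, objfn, method = "Brent",
                     lower = bounds[1], upper = bounds[2])
      } else {
        stats::optim(A0, objfn, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
      }
    })
    vals <- vapply(fits, `[[`, numeric(1), "value")
    A <- clamp(fits[[which.min(vals)]]$par)
  }
  m2 <- .apply_stabilization(model, A, adjustable, state, compensate)
  # independent confirmation on a fresh Jacobian (central differences)
  J2 <- compute_jacobian(m2, state, epsilon = 1e-6, scheme = "central")
  sa2 <- max(Re(eigen(J2, only.values = TRUE)$values))
  sa1 <- abscissa(A)
  if (max(sa1, sa2) > 1e-8) {
    stop(sprintf("no A within bounds achieves max Re(lambda) <= 0; best spectral abscissa %.4g",
                 max(sa1, sa2)))
  }
  structure(list(A = stats::setNames(A, vapply(adjustable, paste, "", collapse = ".")),
                 spectral_abscissa = sa1,
                 spectral_abscissa_check = sa2,
                 adjustment_norm = nfun(A - 1), model = m2,
                 method = method),
            class = "ccm_adjustment_solution")
}
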