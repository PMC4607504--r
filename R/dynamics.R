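# Dynamical systems layer: steady-state location (root solve + stiff
# relaxation), finite-difference Jacobians, eigenvalue stability
# classification, multistart phase-space scanning and state comparison.

#' Locate a steady state from an initial guess
#'
#' Two-stage search: a damped Newton root solve of the algebraic system
#' `d[m]/dt = 0` first; if its residual does not reach `tol` (root solves on
#' these stiff systems often stall around 1e-1), the best iterate seeds a
#' long stiff integration that relaxes onto the attractor, followed by a
#' final Newton polish. The solve path taken is recorded.
#'
#' @param model a `ccm_kinetic_model`.
#' @param init nonnegative initial concentrations (mM).
#' @param tol residual tolerance, max-norm of the derivative (mM/h).
#' @param t_budget maximum model time (h) for the relaxation stage.
#' @param attractor if `TRUE` (the scan mode), a root that classifies as
#'   unstable is discarded and replaced by relaxing the *original* initial
#'   condition under the flow, so only attractors are reported — saddle
#'   points have measure-zero basins under the dynamics but not under a
#'   Newton iteration.
#' @return a `ccm_steady_state`: list with `conc`, `residual_norm`,
#'   `eigenvalues`, `classification`, `provenance`.
#' @export
find_steady_state <- function(model, init, tol = 1e-6, t_budget = 1e4,
                              attractor = FALSE) {
  if (any(init < 0)) stop("init must be >= 0")
  ids <- model$state_ids
  init <- stats::setNames(as.numeric(init), ids)
  f <- assemble_odes(model)
  rhs <- function(x) f(0, stats::setNames(pmax(x, 0), ids))[[1]]
  newton <- function(x0, maxit = 60) {
    x <- x0
    for (i in seq_len(maxit)) {
      fx <- rhs(x)
      if (max(abs(fx)) < tol) break
      J <- compute_jacobian(model, pmax(x, 0), epsilon = 1e-8)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      for (k in 1:20) {         # damping: accept only improving steps
        xn <- x + lam * step
        if (all(is.finite(xn)) &&
            max(abs(rhs(pmax(xn, 0)))) < max(abs(fx))) break
        lam <- lam / 2
      }
      if (k == 20) break
      x <- pmax(x + lam * step, 0)
    }
    x
  }
  relax_from <- function(x0) {
    # stiff relaxation under the flow, in doubling time chunks
    t <- 0; chunk <- 50
    while (t < t_budget) {
      tr <- tryCatch(
        simulate_model(model, x0, t_end = chunk, times = c(0, chunk)),
        error = function(e) NULL)
      if (is.null(tr)) break
      x0 <- pmax(stats::setNames(as.numeric(unlist(tr[nrow(tr), ids])), ids), 0)
      t <- t + chunk
      chunk <- min(chunk * 2, t_budget - t + 1)
      if (max(abs(rhs(x0))) < tol) break
    }
    x0
  }
  x <- newton(init)
  path <- "root"
  if (max(abs(rhs(x))) >= tol) {
    x0 <- relax_from(pmax(x, 0))
    x <- newton(x0, maxit = 20)
    if (max(abs(rhs(x))) > max(abs(rhs(x0)))) x <- x0
    path <- "root+relax"
  }
  res <- max(abs(rhs(x)))
  if (res >= tol) {
    stop(sprintf("steady-state search did not converge; best residual %.3g (tol %.1g)",
                 res, tol))
  }
  J <- compute_jacobian(model, x)
  ev <- eigen(J, only.values = TRUE)$values
  if (attractor && classify_stability(ev) == "unstable") {
    x2 <- newton(relax_from(init), maxit = 20)
    if (max(abs(rhs(x2))) < tol) {
      x <- x2
      path <- "flow-relax"
      J <- compute_jacobian(model, x)
      ev <- eigen(J, only.values = TRUE)$values
      res <- max(abs(rhs(x)))
    }
  }
  structure(list(conc = stats::setNames(pmax(x, 0), ids),
                 residual_norm = res,
                 eigenvalues = ev,
                 classification = classify_stability(ev),
                 provenance = list(init = init, path = path, tol = tol)),
            class = "ccm_steady_state")
}

#' @export
print.ccm_steady_state <- function(x, ...) {
  cat("<ccm_steady_state> ", x$classification, "; residual ",
      format(x$residual_norm), "; max Re(lambda) = ",
      format(max(Re(x$eigenvalues))), "\n", sep = "")
  invisible(x)
}

#' Finite-difference Jacobian of the ODE right-hand side
#'
#' `J_ij = (f_i(m + eps e_j) - f_i(m)) / eps` (forward scheme, default
#' perturbation 1e-10), or the symmetric central-difference variant.
#'
#' @param model a `ccm_kinetic_model`.
#' @param state concentration vector at which to differentiate.
#' @param epsilon perturbation size.
#' @param scheme `"forward"` or `"central"`.
#' @return dense numeric matrix, dimension = state length.
#' @export
compute_jacobian <- function(model, state, epsilon = 1e-10,
                             scheme = c("forward", "central")) {
  scheme <- match.arg(scheme)
  stopifnot(epsilon > 0)
  ids <- model$state_ids
  state <- stats::setNames(as.numeric(state), ids)
  f <- assemble_odes(model)
  g <- function(x) f(0, x)[[1]]
  n <- length(state)
  J <- matrix(0, n, n, dimnames = list(ids, ids))
  f0 <- if (scheme == "forward") g(state) else NULL
  for (j in seq_len(n)) {
    xp <- state; xp[j] <- xp[j] + epsilon
    if (scheme == "forward") {
      J[, j] <- (g(xp) - f0) / epsilon
    } else {
      xm <- state; xm[j] <- xm[j] - epsilon
      J[, j] <- (g(xp) - g(xm)) / (2 * epsilon)
    }
  }
  J
}

#' Classify a steady state from its eigenvalue spectrum
#'
#' Periodic is checked first (all real parts within the zero tolerance of
#' zero and at least one non-zero imaginary part), then unstable (any real
#' part above the tolerance); otherwise stable — eigenvalues with zero real
#' part count towards stability. The zero tolerance is relative to the
#' largest real-part magnitude in the spectrum, which spans many orders of
#' magnitude in these models.
#'
#' @param eigenvalues complex (or numeric) spectrum.
#' @param zero_tol relative tolerance for treating a real part as zero.
#' @return `"stable"`, `"unstable"` or `"periodic"`.
#' @export
classify_stability <- function(eigenvalues, zero_tol = 1e-6) {
  stopifnot(length(eigenvalues) > 0)
  re <- Re(eigenvalues); im <- Im(eigenvalues)
  scale <- max(abs(re), 1e-300)
  thr <- zero_tol * max(scale, 1)
  if (all(abs(re) <= thr) && any(abs(im) > 0)) return("periodic")
  if (any(re > thr)) return("unstable")
  "stable"
}

# relative L-infinity distance between two states
.rel_linf <- function(a, b) {
  max(abs(a - b) / pmax(abs(a), abs(b), 1e-6))
}

#' Multistart scan of the metabolic phase space
#'
#' Repeatedly draws initial concentration vectors uniformly from the scan
#' box, converges each to a steady state, classifies it, and de-duplicates
#' the converged states by relative L-infinity distance. Biomass is held
#' fixed during the scan (the biomass ODE decouples), matching the
#' equal-cell-volume comparison the experiment requires. Failed starts are
#' categorized and counted, never silently dropped.
#'
#' @param model a `ccm_kinetic_model`.
#' @param n_starts number of random initial conditions.
#' @param interval sampling box for every concentration (mM).
#' @param seed RNG seed.
#' @param dedup_tol relative L-infinity distance below which two converged
#'   states are the same.
#' @param tol steady-state residual tolerance.
#' @param max_failure_rate abort if more than this fraction of starts fails.
#' @return a `ccm_scan_result`: list with `states` (list of
#'   `ccm_steady_state`), `summary` tibble, `basin_counts`, `failures`,
#'   `n_starts`, `seed`, `interval`, `dedup_tol`.
#' @export
multistart_scan <- function(model, n_starts = 2000, interval = c(0, 10),
                            seed = 1, dedup_tol = 1e-4, tol = 1e-6,
                            max_failure_rate = 0.5) {
  set.seed(seed)
  n <- length(model$state_ids)
  states <- list()
  counts <- integer(0)
  failures <- c(no_convergence = 0L, integration_error = 0L)
  for (s in seq_len(n_starts)) {
    init <- stats::runif(n, interval[1], interval[2])
    ss <- tryCatch(find_steady_state(model, init, tol = tol, attractor = TRUE),
                   error = function(e) {
                     if (grepl("did not converge", conditionMessage(e)))
                       "no_convergence" else "integration_error"
                   })
    if (is.character(ss)) {
      failures[ss] <- failures[ss] + 1L
      if (sum(failures) > max_failure_rate * n_starts) {
        stop("more than ", 100 * max_failure_rate,
             "% of scan starts failed (", sum(failures), " of ", s, ")")
      }
      next
    }
    hit <- which(vapply(states, function(st)
      .rel_linf(st$conc, ss$conc) <= dedup_tol, logical(1)))
    if (length(hit)) {
      counts[hit[1]] <- counts[hit[1]] + 1L
    } else {
      states[[length(states) + 1L]] <- ss
      counts[length(states)] <- 1L
    }
  }
  if (!length(states)) stop("no scan start converged to a steady state")
  ord <- order(-counts)
  states <- states[ord]; counts <- counts[ord]
  summary <- tibble::tibble(
    state = seq_along(states),
    classification = vapply(states, `[[`, "", "classification"),
    basin_count = counts,
    residual = vapply(states, `[[`, numeric(1), "residual_norm"),
    max_re_lambda = vapply(states, function(s) max(Re(s$eigenvalues)), numeric(1)))
  structure(list(states = states, summary = summary, basin_counts = counts,
                 failures = failures, n_starts = n_starts, seed = seed,
                 interval = interval, dedup_tol = dedup_tol),
            class = "ccm_scan_result")
}

#' @export
print.ccm_scan_result <- function(x, ...) {
  cat("<ccm_scan_result> ", length(x$states), " distinct state(s) from ",
      x$n_starts, " starts (", sum(x$failures), " failures)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Compare two steady states metabolite-by-metabolite
#'
#' Percent change `100 * (b - a) / a` per metabolite and the accompanying
#' per-reaction flux change. Metabolites with a zero baseline are reported
#' as undefined (`NA` percent with a flag), not propagated as NaN.
#'
#' @param model the shared `ccm_kinetic_model`.
#' @param state_a,state_b `ccm_steady_state` objects (or named vectors);
#'   `state_a` is the baseline.
#' @return list of tibbles `metabolites` (id, conc_a, conc_b, percent_change,
#'   undefined) and `fluxes` (reaction, flux_a, flux_b, change).
#' @export
compare_states <- function(model, state_a, state_b) {
  a <- if (inherits(state_a, "ccm_steady_state")) state_a$conc else state_a
  b <- if (inherits(state_b, "ccm_steady_state")) state_b$conc else state_b
  ids <- model$state_ids
  a <- a[ids]; b <- b[ids]
  undef <- a == 0
  pc <- ifelse(undef, NA_real_, 100 * (b - a) / a)
  ra <- evaluate_rates(model, a)
  rb <- evaluate_rates(model, b)
  list(metabolites = tibble::tibble(metabolite = ids, conc_a = unname(a),
                                    conc_b = unname(b),
                                    percent_change = unname(pc),
                                    undefined = unname(undef)),
       fluxes = tibble::tibble(reaction = names(ra), flux_a = unname(ra),
                               flux_b = unname(rb),
                               change = unname(rb - ra)))
}
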