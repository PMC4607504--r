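# The kinetic model container and the ODE system
#   d[X]/dt      = mu * [X]
#   d[glc_ex]/dt = 0
#   d[m_i]/dt    = (sum_j s_ij r_j([m]) + c_i) * rho_X - mu * [m_i]
# State = non-cofactor, non-external metabolites; cofactors and external
# glucose are fixed parameters. c_i is the net steady-state flux of the
# connecting reactions of m_i, in mmol/gDCW/h; rho_X (gDCW/L) converts
# gDCW-normalized fluxes to concentration change in mM/h.

#' Build a metabolite table
#'
#' @param id metabolite ids.
#' @param name display names (default ids).
#' @param compartment `"cytoplasm"`, `"periplasm"` or `"external"`.
#' @param conc steady-state concentration in mM (`NA` = missing/unmeasured).
#' @param is_cofactor logical; defaults to membership in [ccm_cofactors()].
#' @return tibble with one row per metabolite.
#' @export
metabolite_table <- function(id, name = id, compartment = "cytoplasm",
                             conc = NA_real_, is_cofactor = id %in% ccm_cofactors()) {
  tb <- tibble::tibble(id = id, name = name,
                       compartment = compartment, conc = as.numeric(conc),
                       is_cofactor = is_cofactor)
  bad <- !is.na(tb$conc) & (!is.finite(tb$conc) | tb$conc < 0)
  if (any(bad)) stop("concentrations must be finite and >= 0: ",
                     paste(tb$id[bad], collapse = ", "))
  if (!all(tb$compartment %in% c("cytoplasm", "periplasm", "external"))) {
    stop("compartment must be cytoplasm, periplasm or external")
  }
  if (anyDuplicated(tb$id)) stop("duplicate metabolite ids")
  tb
}

#' Construct a kinetic model
#'
#' @param metabolites tibble from [metabolite_table()]; row order fixes the
#'   state-vector order.
#' @param reactions named list of [rate_law()] objects (names = reaction ids).
#' @param S stoichiometric matrix, metabolites x reactions (dimensionless
#'   counts); dimnames must match `metabolites$id` and `names(reactions)`.
#' @param c connecting-flux closure vector in mmol/gDCW/h, named by state
#'   metabolite id (default all zero).
#' @param mu specific growth rate in 1/h.
#' @param rho_X cell density in gDCW/L.
#' @param biomass_X biomass state (carried but decoupled; its ODE is
#'   autonomous).
#' @param inactive reaction ids held at exactly zero rate.
#' @return object of class `ccm_kinetic_model`.
#' @export
kinetic_model <- function(metabolites, reactions, S, c = NULL, mu = 0.2,
                          rho_X = 1, biomass_X = 1, inactive = character()) {
  stopifnot(is.list(reactions), length(reactions) > 0)
  if (is.null(names(reactions)) || anyDuplicated(names(reactions))) {
    stop("reactions must be a uniquely named list")
  }
  S <- as.matrix(S)
  if (!identical(rownames(S), metabolites$id) ||
      !identical(colnames(S), names(reactions))) {
    stop("dimnames of S must match metabolite ids (rows) and reaction ids (columns)")
  }
  state <- metabolites$id[!metabolites$is_cofactor &
                            metabolites$compartment != "external"]
  if (is.null(c)) c <- stats::setNames(rep(0, length(state)), state)
  if (!setequal(names(c), state)) stop("c must be named by the state metabolites")
  c <- c[state]
  if (any(!is.finite(c))) stop("connecting fluxes c must be finite")
  if (mu < 0) stop("mu must be >= 0")
  if (rho_X <= 0) stop("rho_X must be > 0")
  if (!all(inactive %in% names(reactions))) {
    stop("inactive reaction ids not in model: ",
         paste(setdiff(inactive, names(reactions)), collapse = ", "))
  }
  model <- structure(
    list(metabolites = metabolites, reactions = reactions, S = S, c = c,
         mu = mu, rho_X = rho_X, biomass_X = biomass_X,
         state_ids = state, inactive = inactive),
    class = "ccm_kinetic_model")
  # fail fast on unresolvable metabolite references
  refs <- unique(unlist(lapply(reactions, function(l) {
    c(l$substrates, l$products, l$modifiers)
  })))
  miss <- setdiff(refs, metabolites$id)
  if (length(miss)) stop("rate laws reference unknown metabolite(s): ",
                         paste(miss, collapse = ", "))
  model
}

#' @export
print.ccm_kinetic_model <- function(x, ...) {
  cat("<ccm_kinetic_model> ", length(x$state_ids), " state metabolites (",
      nrow(x$metabolites), " total), ", length(x$reactions), " reactions, mu = ",
      x$mu, " 1/h, rho_X = ", x$rho_X, " gDCW/L\n", sep = "")
  invisible(x)
}

#' State metabolite ids of a kinetic model
#' @param model a `ccm_kinetic_model`.
#' @export
state_ids <- function(model) model$state_ids

# full named concentration vector: state values + fixed cofactor/external
.full_conc <- function(model, state) {
  conc <- stats::setNames(model$metabolites$conc, model$metabolites$id)
  conc[model$state_ids] <- state
  conc
}

#' Evaluate all reaction rates at a concentration vector
#'
#' @param model a `ccm_kinetic_model`.
#' @param conc state concentration vector in mM (named or in state order).
#' @param clip clip negative concentrations to zero inside rate evaluation
#'   only (used by the stiff integrator; the state itself is never modified).
#' @return named flux vector in mmol/gDCW/h, one entry per reaction;
#'   inactive reactions evaluate to exactly 0.
#' @export
evaluate_rates <- function(model, conc, clip = FALSE) {
  if (length(conc) != length(model$state_ids)) {
    stop("conc must have one entry per state metabolite (",
         length(model$state_ids), ")")
  }
  if (is.null(names(conc))) names(conc) <- model$state_ids
  if (!clip && any(conc < 0)) stop("negative concentration in rate evaluation")
  if (clip) conc <- pmax(conc, 0)
  full <- .full_conc(model, conc[model$state_ids])
  full[is.na(full)] <- 0
  r <- vapply(names(model$reactions), function(id) {
    if (id %in% model$inactive) return(0)
    .eval_law(model$reactions[[id]], full, id)
  }, numeric(1))
  r
}

#' Assemble the ODE right-hand side of a kinetic model
#'
#' Returns the derivative function of the metabolite subsystem:
#' `d[m]/dt = (S r + c) * rho_X - mu * [m]` (mM/h). External glucose has
#' derivative identically zero by construction (it is not part of the state)
#' and cofactors are fixed parameters. Negative state entries produced by a
#' stiff integrator are clipped to zero in rate evaluation only and counted.
#'
#' @param model a `ccm_kinetic_model`.
#' @return function `(t, state, parms)` in [deSolve::lsoda()] form; the
#'   closure carries a clip counter readable via `attr(fn, "clips")()`.
#' @export
assemble_odes <- function(model) {
  Sst <- model$S[model$state_ids, , drop = FALSE]
  cc <- model$c
  mu <- model$mu
  rho <- model$rho_X
  n_clip <- 0L
  fn <- function(t, state, parms = NULL) {
    if (any(state < 0)) n_clip <<- n_clip + 1L
    r <- evaluate_rates(model, state, clip = TRUE)
    dm <- (as.numeric(Sst %*% r) + cc) * rho - mu * state
    list(dm)
  }
  attr(fn, "clips") <- function() n_clip
  fn
}

#' Steady-state residual of a concentration vector
#'
#' Max-norm of the derivative `d[m]/dt` at `conc`, in mM/h.
#' @inheritParams evaluate_rates
#' @export
steady_state_residual <- function(model, conc) {
  f <- assemble_odes(model)
  max(abs(f(0, stats::setNames(as.numeric(conc), model$state_ids))[[1]]))
}

#' Simulate a kinetic model with a stiff integrator
#'
#' Integrates the metabolite subsystem with [deSolve::lsoda()] (switches
#' automatically to a BDF method on stiff problems; the eigenvalue spread of
#' these systems reaches ~1e6).
#'
#' @param model a `ccm_kinetic_model`.
#' @param init nonnegative initial state concentrations (mM).
#' @param t_end end time (h).
#' @param times output time grid; default 201 points over `[0, t_end]`.
#' @param rtol,atol relative and absolute integration tolerances.
#' @return a `ccm_trajectory`: tibble with `time`, one column per state
#'   metabolite, and `biomass`; solver diagnostics in attributes.
#' @export
simulate_model <- function(model, init, t_end, times = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  if (any(init < 0)) stop("initial concentrations must be >= 0")
  if (length(init) != length(model$state_ids)) stop("init has wrong length")
  init <- stats::setNames(as.numeric(init), model$state_ids)
  if (is.null(times)) times <- seq(0, t_end, length.out = 201)
  fn <- assemble_odes(model)
  out <- deSolve::lsoda(y = init, times = times, func = fn,
                        rtol = rtol, atol = atol)
  diag <- attributes(out)
  tb <- tibble::as_tibble(as.data.frame(unclass(out)))
  tb$biomass <- model$biomass_X * exp(model$mu * tb$time)
  structure(tb, class = c("ccm_trajectory", class(tb)),
            istate = diag$istate, rstate = diag$rstate,
            clips = attr(fn, "clips")(),
            steps = if (!is.null(diag$istate)) diag$istate[3] else NA)
}
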