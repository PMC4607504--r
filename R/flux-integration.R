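# Projection of carbon-13 flux-analysis estimates onto the feasible flux
# space of the stoichiometric network, and computation of the per-metabolite
# connecting-reaction closure constants c_i that close the kinetic model.

#' Pre-fit exchange bounds at the target growth rate
#'
#' Fixes the growth flux, minimizes the glucose uptake rate and fixes it,
#' then from flux variability fixes the acetate secretion and oxygen uptake
#' rates at their minima (sequentially, in the given order). This selects
#' the minimal pathway and flux distribution towards the required growth
#' rate before the quadratic projection.
#'
#' @param net a strain-fitted, role-annotated `ccm_stoich_network`.
#' @param target_mu growth rate to impose (1/h).
#' @param order which of the secondary exchanges to minimize first.
#' @return the constrained network.
#' @export
prefit_exchange_bounds <- function(net, target_mu = 0.2,
                                   order = c("acetate_secretion", "oxygen_uptake")) {
  gr <- net$roles$growth %||% net$biomass_id
  glc <- net$roles$glucose_uptake
  net <- set_bounds(net, gr, lb = target_mu, ub = target_mu)
  s <- net$uptake_sign
  f <- fba(net, objective = stats::setNames(s, glc), sense = "min")
  if (f$status != "optimal") stop("infeasible at target growth rate ", target_mu)
  net <- set_bounds(net, glc, lb = flux_of(f, glc), ub = flux_of(f, glc))
  for (role in order) {
    id <- net$roles[[role]]
    if (is.null(id)) next
    rng <- fva(net, id)
    # "minimum rate": smallest magnitude of the exchange under its sign
    v <- if (role == "oxygen_uptake" && s < 0) rng$max else rng$min
    if (role == "oxygen_uptake" && s > 0) v <- rng$min
    net <- set_bounds(net, id, lb = v, ub = v)
  }
  net
}

#' Project measured central fluxes onto the feasible space (QP)
#'
#' Minimizes the squared Euclidean distance between the network flux vector,
#' restricted to the central (kinetic-model) reactions, and the mean
#' carbon-13 flux estimates, over `S v = 0` and the flux bounds. The
#' projection is the unique minimizer on the central coordinates whenever
#' the quadratic form restricted to them is positive definite on the
#' feasible affine hull; a vanishing ridge on the remaining coordinates
#' keeps the quadratic program strictly convex for the solver.
#'
#' @param net_prefit network returned by [prefit_exchange_bounds()].
#' @param mfa_means named flux vector (mmol/gDCW/h) over central reactions;
#'   signs must already follow the network orientation (see
#'   [apply_orientation()]).
#' @param ridge regularization weight on non-central coordinates.
#' @return a `ccm_flux_distribution` with attribute `central` (the fitted
#'   central flux vector) and `qp_objective` (squared distance attained).
#' @export
fit_central_fluxes_qp <- function(net_prefit, mfa_means, ridge = 1e-8) {
  net <- net_prefit
  miss <- setdiff(names(mfa_means), net$rxns)
  if (length(miss)) stop("MFA reaction id(s) not in network: ",
                         paste(miss, collapse = ", "))
  n <- length(net$rxns)
  central <- match(names(mfa_means), net$rxns)
  w <- rep(ridge, n)
  w[central] <- 1
  target <- rep(0, n)
  target[central] <- mfa_means
  lb <- pmax(net$lb, -1e6)
  ub <- pmin(net$ub, 1e6)
  # equalities: S v = 0 plus pinned fluxes (lb == ub); solve in the null
  # space of the equality system so degenerate feasible sets (down to a
  # single point) stay well-posed for the active-set QP solver
  fixed <- which(ub - lb < 1e-12)
  free <- setdiff(seq_len(n), fixed)
  E <- rbind(net$S, diag(n)[fixed, , drop = FALSE])
  d <- c(rep(0, length(net$mets)), lb[fixed])
  feas <- lp_solve(rep(0, n), E, d, lb, ub)
  if (feas$status != "optimal") stop("QP infeasible: equality system has no solution in bounds")
  v0 <- feas$x
  sv <- svd(E, nv = n)
  rank <- sum(sv$d > 1e-9 * max(sv$d, 1))
  N <- sv$v[, setdiff(seq_len(n), seq_len(rank)), drop = FALSE]
  if (ncol(N) == 0) {
    v <- stats::setNames(v0, net$rxns)
  } else {
    W <- diag(w, n)
    Dmat <- 2 * t(N) %*% W %*% N + diag(1e-10, ncol(N))
    dvec <- as.numeric(2 * t(N) %*% (w * (target - v0)))
    Amat <- t(rbind(N[free, , drop = FALSE], -N[free, , drop = FALSE]))
    bvec <- c(lb[free] - v0[free], v0[free] - ub[free])
    sol <- tryCatch(
      quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 0),
      error = function(e) stop("QP infeasible or ill-posed: ", conditionMessage(e)))
    v <- stats::setNames(v0 + as.numeric(N %*% sol$solution), net$rxns)
  }
  fd <- structure(list(
    fluxes = tibble::tibble(reaction = net$rxns, flux = v),
    objective_value = sum((v[central] - mfa_means)^2),
    status = "optimal"), class = "ccm_flux_distribution")
  attr(fd, "central") <- v[central]
  attr(fd, "qp_objective") <- fd$objective_value
  fd
}

#' Map signed MFA estimates onto network reaction orientation
#'
#' Carbon-13 net fluxes are reported against an arbitrary reference
#' direction; an explicit orientation map (+1/-1 per reaction) converts them
#' to the network's sign convention. Silent sign flips are the dominant
#' failure mode of flux integration, so the mapping is always explicit.
#'
#' @param mfa_means named flux vector.
#' @param orientation named vector of +1/-1 (default +1 for every reaction).
#' @export
apply_orientation <- function(mfa_means, orientation = NULL) {
  if (is.null(orientation)) return(mfa_means)
  o <- rep(1, length(mfa_means))
  names(o) <- names(mfa_means)
  o[names(orientation)] <- orientation
  mfa_means * o
}

#' Compute connecting-reaction fluxes and the closure constants c_i
#'
#' Fixes growth and the central fluxes, takes the minimal-total-flux
#' distribution of the whole network, and nets the fluxes of each kinetic
#' metabolite's connecting reactions (all network reactions involving the
#' metabolite that are not central). The biomass pseudo-reaction counts as a
#' connecting reaction by default, so its drain of kinetic-model metabolites
#' is part of `c_i`. A flux variability report over the connecting reactions
#' accompanies the result as the uniqueness check.
#'
#' @param net a `ccm_stoich_network` (strain-fitted; growth role set).
#' @param central_fluxes named flux vector over the central reactions.
#' @param kinetic_metabolite_ids network metabolite ids modelled kinetically.
#' @param target_mu growth rate to impose (1/h).
#' @param exclude_biomass drop the biomass pseudo-reaction from the
#'   connecting set.
#' @return a `ccm_connecting_fluxes`: list with `c_i` (tibble: metabolite,
#'   n_connecting, c_i, fva_range), `details` (per-metabolite tibble of
#'   reaction, coefficient, flux), `fva` and the full `fluxes` tibble.
#' @export
compute_connecting_fluxes <- function(net, central_fluxes, kinetic_metabolite_ids,
                                      target_mu = 0.2, exclude_biomass = FALSE) {
  gr <- net$roles$growth %||% net$biomass_id
  net <- set_bounds(net, gr, lb = target_mu, ub = target_mu)
  net <- set_bounds(net, names(central_fluxes),
                    lb = unname(central_fluxes), ub = unname(central_fluxes))
  fd <- fba(net, objective = "min_total_flux")
  if (fd$status != "optimal") {
    stop("infeasible after fixing central fluxes (inconsistent QP output?)")
  }
  v <- stats::setNames(fd$fluxes$flux, fd$fluxes$reaction)
  miss <- setdiff(kinetic_metabolite_ids, net$mets)
  if (length(miss)) stop("kinetic metabolite(s) not in network: ",
                         paste(miss, collapse = ", "))
  conn_all <- character(0)
  details <- list()
  ci <- vapply(kinetic_metabolite_ids, function(m) {
    rxns <- net$rxns[net$S[m, ] != 0]
    conn <- setdiff(rxns, names(central_fluxes))
    if (exclude_biomass) conn <- setdiff(conn, net$biomass_id)
    conn_all <<- union(conn_all, conn)
    details[[m]] <<- tibble::tibble(
      metabolite = m, reaction = conn,
      coefficient = net$S[m, conn], flux = v[conn])
    sum(net$S[m, conn] * v[conn])
  }, numeric(1))
  fva_tb <- if (length(conn_all)) fva(net, conn_all) else
    tibble::tibble(reaction = character(), min = numeric(), max = numeric())
  range_of <- stats::setNames(fva_tb$max - fva_tb$min, fva_tb$reaction)
  details <- dplyr::bind_rows(details)
  structure(list(
    c_i = tibble::tibble(
      metabolite = kinetic_metabolite_ids,
      n_connecting = vapply(kinetic_metabolite_ids, function(m)
        sum(details$metabolite == m), integer(1)),
      c_i = unname(ci),
      fva_range = vapply(kinetic_metabolite_ids, function(m) {
        rr <- details$reaction[details$metabolite == m]
        if (!length(rr)) 0 else max(range_of[rr])
      }, numeric(1))),
    details = details, fva = fva_tb,
    fluxes = fd$fluxes, target_mu = target_mu),
    class = "ccm_connecting_fluxes")
}

#' @export
print.ccm_connecting_fluxes <- function(x, ...) {
  cat("<ccm_connecting_fluxes> ", nrow(x$c_i), " kinetic metabolites, ",
      length(unique(x$details$reaction)), " connecting reactions; max FVA range ",
      format(max(c(0, x$c_i$fva_range))), "\n", sep = "")
  invisible(x)
}

#' Install closure constants into a kinetic model
#'
#' Sets the model's `c` vector from a connecting-flux computation. With
#' `dilution_correction = TRUE` the constants are shifted by
#' `mu * [m_i] / rho_X` (using the model's stored reference concentrations)
#' so that the reference state is an exact fixed point of the closed ODE
#' system; without it the ODE residual at the reference state equals the
#' dilution term exactly.
#'
#' @param model a `ccm_kinetic_model`.
#' @param cset a `ccm_connecting_fluxes` (or named numeric vector).
#' @param dilution_correction logical, see above.
#' @export
install_connecting_fluxes <- function(model, cset, dilution_correction = FALSE) {
  ci <- if (inherits(cset, "ccm_connecting_fluxes")) {
    stats::setNames(cset$c_i$c_i, cset$c_i$metabolite)
  } else cset
  ids <- state_ids(model)
  cc <- model$c   # metabolites outside the network keep their closure
  hit <- intersect(names(ci), ids)
  cc[hit] <- ci[hit]
  if (dilution_correction) {
    ref <- stats::setNames(model$metabolites$conc, model$metabolites$id)[hit]
    if (any(is.na(ref))) stop("dilution correction needs reference concentrations for all state metabolites")
    cc[hit] <- cc[hit] + model$mu * ref / model$rho_X
  }
  model$c <- cc
  model
}
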