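# Constraint-based layer: stoichiometric networks, FBA/FVA, biomass
# rebalancing, strain-specific reparameterization and glucose-uptake
# calibration. Reaction thermodynamics enter only through directionality:
# irreversible reactions have lower bound 0, reversible ones may be negative.

#' Construct a stoichiometric network
#'
#' @param S stoichiometric matrix (metabolites x reactions) with dimnames.
#' @param lb,ub flux bounds in mmol/gDCW/h, named by reaction id or in column
#'   order. Irreversible reactions must have `lb >= 0`.
#' @param biomass_id id of the biomass pseudo-reaction (1 gDCW per unit flux).
#' @param exchange_ids ids of exchange reactions.
#' @param objective named coefficient vector (default: biomass reaction = 1).
#' @param roles named list mapping functional roles (`growth`,
#'   `glucose_uptake`, `oxygen_uptake`, `acetate_secretion`, `atpm`, `atps`,
#'   `proton_p`, `proton_c`, `atp`) to reaction/metabolite ids; used by the
#'   strain-parameter machinery.
#' @param uptake_sign +1 if uptake exchange reactions carry positive flux
#'   into the network (the toy convention), -1 for the SBML convention where
#'   uptake is a negative exchange flux.
#' @return object of class `ccm_stoich_network`.
#' @export
stoich_network <- function(S, lb, ub, biomass_id = NULL, exchange_ids = character(),
                           objective = NULL, roles = list(), uptake_sign = 1) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S))) stop("S needs dimnames")
  rxns <- colnames(S)
  lb <- if (is.null(names(lb))) stats::setNames(lb, rxns) else lb[rxns]
  ub <- if (is.null(names(ub))) stats::setNames(ub, rxns) else ub[rxns]
  if (any(lb > ub)) stop("bounds must satisfy lb <= ub")
  orphan <- rownames(S)[rowSums(abs(S)) == 0]
  if (length(orphan)) stop("metabolite(s) in no reaction: ",
                           paste(orphan, collapse = ", "))
  if (is.null(objective)) {
    objective <- if (!is.null(biomass_id)) stats::setNames(1, biomass_id) else NULL
  }
  structure(list(S = S, lb = lb, ub = ub, mets = rownames(S), rxns = rxns,
                 biomass_id = biomass_id, exchange_ids = exchange_ids,
                 objective = objective, roles = roles,
                 uptake_sign = uptake_sign),
            class = "ccm_stoich_network")
}

#' @export
print.ccm_stoich_network <- function(x, ...) {
  cat("<ccm_stoich_network> ", length(x$mets), " metabolites x ",
      length(x$rxns), " reactions (", sum(x$lb < 0), " reversible)\n", sep = "")
  invisible(x)
}

#' Set flux bounds on a network
#' @param net a `ccm_stoich_network`.
#' @param id reaction id(s).
#' @param lb,ub new bounds (recycled); `NULL` leaves a side unchanged.
#' @export
set_bounds <- function(net, id, lb = NULL, ub = NULL) {
  miss <- setdiff(id, net$rxns)
  if (length(miss)) stop("unknown reaction id(s): ", paste(miss, collapse = ", "))
  if (!is.null(lb)) net$lb[id] <- lb
  if (!is.null(ub)) net$ub[id] <- ub
  net
}

#' Constrain reactions to zero flux
#'
#' Marks reactions as non-active under the modelled growth condition by
#' fixing both bounds to zero (e.g. the glyoxylate shunt and fumarate
#' reductases of glucose-limited aerobic growth).
#' @param net a `ccm_stoich_network`.
#' @param ids reaction ids to silence.
#' @export
set_inactive_reactions <- function(net, ids) {
  set_bounds(net, ids, lb = 0, ub = 0)
}

.lp_from_net <- function(net) {
  list(Aeq = net$S, beq = rep(0, length(net$mets)),
       lb = pmax(net$lb, -1e6), ub = pmin(net$ub, 1e6))
}

#' Flux balance analysis
#'
#' Solves the linear program `optimize c'v  s.t.  S v = 0, lb <= v <= ub`.
#' The special objective `"min_total_flux"` minimizes the L1 norm of the
#' flux vector (total sum of absolute fluxes, via forward/backward flux
#' splitting), which removes futile cycles from the reported distribution.
#'
#' @param net a `ccm_stoich_network`.
#' @param objective named coefficient vector, a single reaction id, or
#'   `"min_total_flux"`; defaults to the network objective.
#' @param sense `"max"` or `"min"` (ignored for `"min_total_flux"`).
#' @return a `ccm_flux_distribution`: list with `fluxes` (tibble of
#'   reaction/flux), `objective_value` and `status`. Infeasibility and
#'   unboundedness are reported in `status`, not thrown.
#' @export
fba <- function(net, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  objective <- objective %||% net$objective
  lp <- .lp_from_net(net)
  n <- length(net$rxns)
  if (identical(objective, "min_total_flux")) {
    # variables (v, p, q): v - p + q = 0, p,q >= 0, minimize sum(p + q)
    big <- pmax(abs(lp$lb), abs(lp$ub)) + 1
    Aeq <- rbind(cbind(lp$Aeq, matrix(0, nrow(lp$Aeq), 2 * n)),
                 cbind(diag(n), -diag(n), diag(n)))
    res <- lp_solve(c(rep(0, n), rep(1, 2 * n)), Aeq,
                    c(lp$beq, rep(0, n)),
                    c(lp$lb, rep(0, 2 * n)), c(lp$ub, big, big))
    v <- res$x[seq_len(n)]
  } else {
    if (is.character(objective)) objective <- stats::setNames(1, objective)
    cc <- rep(0, n)
    cc[match(names(objective), net$rxns)] <- objective
    res <- lp_solve(cc, lp$Aeq, lp$beq, lp$lb, lp$ub, maximize = sense == "max")
    v <- res$x
  }
  structure(list(
    fluxes = tibble::tibble(reaction = net$rxns,
                            flux = stats::setNames(v, net$rxns)),
    objective_value = res$objective, status = res$status),
    class = "ccm_flux_distribution")
}

#' @export
print.ccm_flux_distribution <- function(x, ...) {
  cat("<ccm_flux_distribution> status: ", x$status,
      ", objective: ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Extract the flux of one reaction from a flux distribution
#' @param fd a `ccm_flux_distribution`.
#' @param id reaction id.
#' @export
flux_of <- function(fd, id) {
  unname(fd$fluxes$flux[match(id, fd$fluxes$reaction)])
}

#' Flux variability analysis
#'
#' Minimum and maximum attainable flux of each queried reaction over the
#' feasible set (after any constraints of interest have been imposed as
#' bounds on `net`).
#'
#' @param net a `ccm_stoich_network`.
#' @param reaction_ids reactions to scan (default all).
#' @return tibble with `reaction`, `min`, `max`.
#' @export
fva <- function(net, reaction_ids = net$rxns) {
  miss <- setdiff(reaction_ids, net$rxns)
  if (length(miss)) stop("unknown reaction id(s): ", paste(miss, collapse = ", "))
  lp <- .lp_from_net(net)
  base <- lp_solve(rep(0, length(net$rxns)), lp$Aeq, lp$beq, lp$lb, lp$ub)
  if (base$status != "optimal") stop("FVA base problem is ", base$status)
  out <- lapply(reaction_ids, function(id) {
    cc <- rep(0, length(net$rxns))
    cc[match(id, net$rxns)] <- 1
    lo <- lp_solve(cc, lp$Aeq, lp$beq, lp$lb, lp$ub)
    hi <- lp_solve(cc, lp$Aeq, lp$beq, lp$lb, lp$ub, maximize = TRUE)
    tibble::tibble(reaction = id, min = lo$objective, max = hi$objective)
  })
  dplyr::bind_rows(out)
}

#' Rebalance the biomass reaction against a measured composition
#'
#' Replaces the stoichiometric coefficients of measured biomass components
#' and renormalizes so the reaction yields exactly 1 gDCW per unit flux.
#' Procedure: micromol/gDCW amounts -> molar fractions -> weight fractions
#' of the components' mass share of 1 gDCW -> back to mmol/gDCW through the
#' molecular weights. Coefficients of unmeasured components are unchanged.
#'
#' @param net a `ccm_stoich_network` with a biomass reaction.
#' @param composition named vector, micromol/gDCW per measured component
#'   (names are metabolite ids consumed by the biomass reaction).
#' @param molecular_weights named vector, g/mol.
#' @param mass_share mass fraction of 1 gDCW covered by the measured
#'   components (default 1).
#' @return the network with updated biomass stoichiometry.
#' @export
rebalance_biomass <- function(net, composition, molecular_weights,
                              mass_share = 1) {
  if (is.null(net$biomass_id)) stop("network has no biomass reaction")
  if (!length(composition)) stop("composition is empty")
  miss <- setdiff(names(composition), names(molecular_weights))
  if (length(miss)) stop("missing molecular weight for measured component(s): ",
                         paste(miss, collapse = ", "))
  mw <- molecular_weights[names(composition)]
  if (any(mw <= 0)) stop("molecular weights must be > 0")
  x <- composition / sum(composition)            # molar fraction
  w <- x * mw / sum(x * mw)                      # weight fraction
  coeff <- w * mass_share * 1000 / mw            # mmol/gDCW
  unk <- setdiff(names(composition), net$mets)
  if (length(unk)) stop("component(s) not in network: ", paste(unk, collapse = ", "))
  net$S[names(coeff), net$biomass_id] <- -coeff
  stopifnot(abs(sum(coeff * mw) / 1000 - mass_share) < 1e-12)
  net
}

#' Strain parameters of a stoichiometric network
#'
#' @param o2_max_uptake,glc_max_uptake maximum uptake bounds, mmol/gDCW/h.
#' @param atpm_flux non-growth-associated ATP maintenance flux (both bounds).
#' @param gam_atp_stoich growth-associated maintenance: mmol ATP consumed in
#'   the biomass reaction per gDCW.
#' @param h_p periplasmic proton stoichiometry of the ATP synthase reaction;
#'   the cytoplasmic count is `h_p - 1` (atomic balance fixes the difference
#'   at exactly one proton).
#' @return object of class `ccm_strain_parameters`.
#' @export
strain_parameters <- function(o2_max_uptake, glc_max_uptake = 1000,
                              atpm_flux = 0, gam_atp_stoich = 0, h_p = 4) {
  stopifnot(o2_max_uptake >= 0, glc_max_uptake >= 0, atpm_flux >= 0)
  structure(list(o2_max_uptake = o2_max_uptake,
                 glc_max_uptake = glc_max_uptake,
                 atpm_flux = atpm_flux, gam_atp_stoich = gam_atp_stoich,
                 h_p = h_p, h_c = h_p - 1),
            class = "ccm_strain_parameters")
}

#' Install strain parameters into a network copy
#'
#' Uses the network `roles` map: sets the oxygen and glucose uptake bounds,
#' fixes the ATP maintenance flux, writes the growth-associated ATP
#' stoichiometry into the biomass reaction and the proton stoichiometry into
#' the ATP synthase reaction (`h_p` periplasmic consumed, `h_p - 1`
#' cytoplasmic produced when the cytoplasmic proton is tracked).
#'
#' @param net a `ccm_stoich_network` with role annotations.
#' @param sp a `ccm_strain_parameters`.
#' @export
apply_strain_parameters <- function(net, sp) {
  r <- net$roles
  if (!is.null(r$oxygen_uptake)) {
    if (net$uptake_sign > 0) net <- set_bounds(net, r$oxygen_uptake, ub = sp$o2_max_uptake)
    else net <- set_bounds(net, r$oxygen_uptake, lb = -sp$o2_max_uptake)
  }
  if (!is.null(r$glucose_uptake)) {
    if (net$uptake_sign > 0) net <- set_bounds(net, r$glucose_uptake, ub = sp$glc_max_uptake)
    else net <- set_bounds(net, r$glucose_uptake, lb = -sp$glc_max_uptake)
  }
  if (!is.null(r$atpm)) net <- set_bounds(net, r$atpm, lb = sp$atpm_flux, ub = sp$atpm_flux)
  if (!is.null(r$atp) && !is.null(net$biomass_id)) {
    net$S[r$atp, net$biomass_id] <- -sp$gam_atp_stoich
  }
  if (!is.null(r$atps)) {
    if (!is.null(r$proton_p)) net$S[r$proton_p, r$atps] <- -sp$h_p
    if (!is.null(r$proton_c)) net$S[r$proton_c, r$atps] <- sp$h_p - 1
  }
  net
}

# predicted exchange fluxes at a fixed growth rate: minimize glucose uptake,
# fix it, then take the minimal-total-flux distribution
.predict_exchanges <- function(net, mu, exchange_ids) {
  gr <- net$roles$growth %||% net$biomass_id
  glc <- net$roles$glucose_uptake
  net <- set_bounds(net, gr, lb = mu, ub = mu)
  s <- net$uptake_sign
  f1 <- fba(net, objective = stats::setNames(s, glc), sense = "min")
  if (f1$status != "optimal") return(NULL)
  net <- set_bounds(net, glc, lb = flux_of(f1, glc), ub = flux_of(f1, glc))
  f2 <- fba(net, objective = "min_total_flux")
  if (f2$status != "optimal") return(NULL)
  stats::setNames(f2$fluxes$flux[match(exchange_ids, f2$fluxes$reaction)],
                  exchange_ids)
}

#' Fit strain-specific parameters to measured exchange rates
#'
#' Least-squares fit of the oxygen uptake bound, ATP maintenance flux,
#' growth-associated maintenance stoichiometry and ATP synthase proton
#' stoichiometry: for each measured dilution rate the growth flux is fixed,
#' glucose is left non-limiting (bound 1000), glucose uptake is minimized
#' and the predicted glucose/oxygen uptake and acetate secretion rates are
#' compared with the measurements. The objective is the sum of squared
#' vertical distances across all dilution rates; a multistart Nelder-Mead
#' search guards against local minima.
#'
#' @param net a role-annotated `ccm_stoich_network`.
#' @param omics a `ccm_omics_dataset` whose `exchange` table has columns
#'   `dilution`, `reaction`, `mean`.
#' @param n_starts number of random initial guesses.
#' @param seed RNG seed for the multistart draws.
#' @param ranges named list of sampling intervals (uniform) for
#'   `o2_max_uptake`, `atpm_flux`, `gam_atp_stoich`, `h_p`.
#' @return list with `parameters` (a `ccm_strain_parameters`), `residual`,
#'   `net` (copy with parameters installed) and `starts` (per-start tibble).
#' @export
fit_strain_parameters <- function(net, omics, n_starts = 120, seed = 1,
                                  ranges = list(o2_max_uptake = c(0, 5),
                                                atpm_flux = c(0, 5),
                                                gam_atp_stoich = c(0, 20),
                                                h_p = c(2, 6))) {
  ex <- omics$exchange
  stopifnot(all(c("dilution", "reaction", "mean") %in% names(ex)))
  dils <- sort(unique(ex$dilution))
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  obj <- function(th) {
    if (any(th < lo) || any(th > hi)) {
      return(1e6 + sum(pmax(lo - th, 0) + pmax(th - hi, 0)))
    }
    sp <- strain_parameters(o2_max_uptake = th[1], glc_max_uptake = 1000,
                            atpm_flux = th[2], gam_atp_stoich = th[3],
                            h_p = th[4])
    net2 <- apply_strain_parameters(net, sp)
    total <- 0
    for (d in dils) {
      sub <- ex[ex$dilution == d, ]
      pred <- .predict_exchanges(net2, d, sub$reaction)
      if (is.null(pred)) return(1e6)
      total <- total + sum((pred - sub$mean)^2)
    }
    total
  }
  set.seed(seed)
  starts <- matrix(stats::runif(4 * n_starts, lo, hi), ncol = 4, byrow = TRUE)
  colnames(starts) <- names(ranges)
  fits <- lapply(seq_len(n_starts), function(i) {
    th0 <- starts[i, ]
    f <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = 1500, reltol = 1e-14))
    # one restart from the incumbent tightens the simplex
    stats::optim(f$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 1500, reltol = 1e-14))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(vals >= 1e6)) {
    stop("all multistart fits were infeasible; per-start objectives: ",
         paste(signif(vals, 3), collapse = ", "))
  }
  best <- fits[[which.min(vals)]]
  th <- unname(best$par)
  sp <- strain_parameters(o2_max_uptake = th[1], glc_max_uptake = 1000,
                          atpm_flux = th[2], gam_atp_stoich = th[3], h_p = th[4])
  list(parameters = sp, residual = best$value,
       net = apply_strain_parameters(net, sp),
       starts = tibble::tibble(start = seq_len(n_starts), objective = vals))
}

#' Calibrate the glucose uptake bound to a target growth rate
#'
#' Finds the glucose uptake bound, within a confidence interval of measured
#' uptake rates, that minimizes the squared difference between the
#' FBA-maximal growth rate and `target_mu`. Growth is monotone in the bound,
#' so the minimizer is located by bisection.
#'
#' @param net a strain-fitted `ccm_stoich_network`.
#' @param target_mu target specific growth rate (1/h).
#' @param ci_bounds length-2 search interval for the uptake bound.
#' @param tol convergence tolerance on the achieved growth rate.
#' @return list with `glc_max_uptake`, `achieved_mu`, `net` (bound installed).
#' @export
fit_glucose_uptake <- function(net, target_mu = 0.2, ci_bounds, tol = 1e-9) {
  glc <- net$roles$glucose_uptake
  gr <- net$roles$growth %||% net$biomass_id
  mu_at <- function(b) {
    n2 <- if (net$uptake_sign > 0) set_bounds(net, glc, ub = b)
          else set_bounds(net, glc, lb = -b)
    f <- fba(n2, objective = gr, sense = "max")
    if (f$status != "optimal") -Inf else f$objective_value
  }
  lo <- min(ci_bounds); hi <- max(ci_bounds)
  mu_lo <- mu_at(lo); mu_hi <- mu_at(hi)
  if (target_mu < mu_lo - tol || target_mu > mu_hi + tol) {
    stop(sprintf(
      "target growth %.6g unreachable within ci_bounds; achievable range [%.6g, %.6g]",
      target_mu, mu_lo, mu_hi))
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mu_at(mid) < target_mu) lo <- mid else hi <- mid
    if (hi - lo < 1e-13 * max(1, hi)) break
  }
  b <- hi
  list(glc_max_uptake = b, achieved_mu = mu_at(b),
       net = if (net$uptake_sign > 0) set_bounds(net, glc, ub = b)
             else set_bounds(net, glc, lb = -b))
}
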