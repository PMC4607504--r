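# Pipeline orchestration: the full construction-integration-analysis chain
# on file-based inputs, with persisted, resumable intermediates.

#' Pipeline configuration
#'
#' @param network path to a reaction-table TSV (or SBML file).
#' @param omics_dir directory of omics TSV files ([write_omics()] layout).
#' @param kinetic_model path to a kinetic model YAML.
#' @param outdir output directory for stage results.
#' @param target_mu target growth rate (1/h).
#' @param network_dialect `"tsv"` or `"sbml"`.
#' @param n_starts_strain,n_starts_scan multistart counts for the strain
#'   fit and the phase-space scan.
#' @param scan_interval sampling box for the scan (mM).
#' @param seed root seed; per-stage seeds are derived deterministically.
#' @param stabilize_params list of `c(reaction, param)` pairs the
#'   stabilization stage may adjust (`NULL`: first binding constant of each
#'   reaction).
#' @return validated config (class `ccm_pipeline_config`).
#' @export
pipeline_config <- function(network, omics_dir, kinetic_model, outdir,
                            target_mu = 0.2, network_dialect = "tsv",
                            n_starts_strain = 120, n_starts_scan = 2000,
                            scan_interval = c(0, 10), seed = 1,
                            stabilize_params = NULL) {
  for (p in c(network, omics_dir, kinetic_model)) {
    if (!file.exists(p)) stop("path does not exist: ", p)
  }
  stopifnot(target_mu > 0, n_starts_strain >= 1, n_starts_scan >= 1)
  structure(list(network = network, omics_dir = omics_dir,
                 kinetic_model = kinetic_model, outdir = outdir,
                 target_mu = target_mu, network_dialect = network_dialect,
                 n_starts_strain = n_starts_strain,
                 n_starts_scan = n_starts_scan,
                 scan_interval = scan_interval, seed = seed,
                 stabilize_params = stabilize_params),
            class = "ccm_pipeline_config")
}

# deterministic per-stage seed derived from the root seed
.stage_seed <- function(seed, stage) {
  (seed * 1000003L + match(stage, c("strain", "glc", "qp", "conn", "param",
                                    "stabilize", "scan")) * 7919L) %% 2147483647L
}

#' Run the integrated modelling pipeline
#'
#' Executes, in order: biomass rebalancing, strain-parameter fitting,
#' glucose-uptake calibration, exchange-bound prefit, quadratic projection
#' of the measured central fluxes, connecting-flux/closure computation,
#' maximal-rate determination (with missing-concentration solving when the
#' metabolome has gaps), steady-state stabilization, multistart scanning and
#' state comparison. Each stage's outputs are persisted under
#' `config$outdir`; with `resume = TRUE` stages whose outputs exist are
#' reloaded instead of recomputed. Any failure halts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param resume reuse persisted stage outputs when present.
#' @return result bundle: list with the fitted network, closure constants,
#'   parameterized/stabilized model, scan result and state comparison.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage_file <- function(name) file.path(out, name)
  stage <- function(name, outputs, fn) {
    if (resume && all(file.exists(stage_file(outputs)))) {
      message("pipeline: reusing ", name)
      return(NULL)
    }
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  net <- load_network(config$network, config$network_dialect)
  omics <- read_omics(config$omics_dir)
  model <- read_kinetic_model(config$kinetic_model)

  # 1. biomass rebalancing (needs component molecular weights)
  bc <- omics$biomass_composition
  if (!is.null(bc) && "mw" %in% names(bc)) {
    comp <- stats::setNames(bc$umol_gdcw, bc$component)
    mw <- stats::setNames(bc$mw, bc$component)
    net <- rebalance_biomass(net, comp, mw)
  }

  # 2. strain parameters
  sfit <- stage("strain", "strain.tsv", function() {
    fit_strain_parameters(net, omics, n_starts = config$n_starts_strain,
                          seed = .stage_seed(config$seed, "strain"))
  })
  if (is.null(sfit)) {
    sp_tb <- read_tsv_prov(stage_file("strain.tsv"))
    sp <- strain_parameters(sp_tb$o2_max_uptake, sp_tb$glc_max_uptake,
                            sp_tb$atpm_flux, sp_tb$gam_atp_stoich, sp_tb$h_p)
    net <- apply_strain_parameters(net, sp)
  } else {
    sp <- sfit$parameters
    net <- sfit$net
    write_tsv_prov(tibble::as_tibble(unclass(sp)[c("o2_max_uptake",
      "glc_max_uptake", "atpm_flux", "gam_atp_stoich", "h_p")]),
      stage_file("strain.tsv"), stage = "strain", seed = config$seed,
      config = config)
  }

  # 3. glucose uptake bound at the target growth rate
  ex <- omics$exchange
  glc_id <- net$roles$glucose_uptake
  glc_meas <- ex$mean[ex$reaction == glc_id &
                        abs(ex$dilution - config$target_mu) < 1e-9]
  ci <- if (length(glc_meas)) c(0.5, 1.5) * glc_meas[1] else c(0, 100)
  gfit <- fit_glucose_uptake(net, config$target_mu, ci)
  net <- gfit$net

  # 4-5. prefit exchange bounds, then QP projection of measured fluxes
  netp <- prefit_exchange_bounds(net, config$target_mu)
  mfa <- stats::setNames(omics$fluxome$mean, omics$fluxome$reaction)
  mfa <- mfa[names(mfa) %in% netp$rxns]
  qp <- fit_central_fluxes_qp(netp, mfa)
  central <- attr(qp, "central")
  write_tsv_prov(qp$fluxes, stage_file("central_fluxes.tsv"), stage = "qp",
                 seed = config$seed, config = config)

  # 6. connecting fluxes / closure constants
  kin_mets <- intersect(state_ids(model), net$mets)
  conn <- compute_connecting_fluxes(net, central, kin_mets, config$target_mu)
  write_tsv_prov(conn$c_i, stage_file("connecting_fluxes.tsv"),
                 stage = "conn", seed = config$seed, config = config)

  # 7. parameterization: reference concentrations, missing values, vmax
  metab <- omics$metabolome
  ref <- stats::setNames(metab$conc, metab$metabolite)
  known <- names(ref)[!is.na(ref)]
  model$metabolites$conc[match(known, model$metabolites$id)] <- ref[known]
  missing_mets <- intersect(names(ref)[is.na(ref)], state_ids(model))
  flux_map <- central[intersect(names(model$reactions), names(central))]
  if (length(missing_mets)) {
    eqs <- names(model$reactions)[vapply(model$reactions, function(l)
      any(c(l$substrates, l$products, l$modifiers) %in% missing_mets),
      logical(1))]
    eqs <- intersect(eqs, names(flux_map))
    sol <- solve_missing_concentrations(model, eqs, missing_mets,
                                        flux_map[eqs])
    model$metabolites$conc[match(missing_mets, model$metabolites$id)] <-
      sol$solved_concentrations[missing_mets]
    for (id in names(sol$vmax_adjust %||% c())) {
      model$reactions[[id]]$a2 <- sol$vmax_adjust[[id]]
    }
  }
  conc_full <- stats::setNames(model$metabolites$conc, model$metabolites$id)
  for (id in names(flux_map)) {
    law <- model$reactions[[id]]
    if (!is.null(law$params$vmax)) {
      model$reactions[[id]]$params$vmax <-
        vmax_from_flux(law, flux_map[[id]], conc_full) / law$a2
    }
  }
  model <- install_connecting_fluxes(model, conn, dilution_correction = TRUE)
  write_kinetic_model(model, stage_file("model_parameterized.yaml"))

  # 8. stabilization of the reference state
  refstate <- conc_full[state_ids(model)]
  adj <- config$stabilize_params
  if (is.null(adj)) {
    adj <- list()
    for (id in names(model$reactions)) {
      kms <- grep("^K[mi]_", names(model$reactions[[id]]$params), value = TRUE)
      if (length(kms)) adj[[length(adj) + 1]] <- c(id, kms[1])
    }
  }
  stab <- stabilize_steady_state(model, refstate, adj,
                                 seed = .stage_seed(config$seed, "stabilize"))
  model <- stab$model
  write_kinetic_model(model, stage_file("model_stabilized.yaml"))

  # 9. multistart phase-space scan
  scan <- multistart_scan(model, n_starts = config$n_starts_scan,
                          interval = config$scan_interval,
                          seed = .stage_seed(config$seed, "scan"))
  write_scan_json(scan, stage_file("scan.json"))

  # 10. state comparison (reference-like state first)
  comparison <- NULL
  stable <- which(scan$summary$classification == "stable")
  if (length(stable) >= 2) {
    dref <- vapply(scan$states[stable], function(s)
      .rel_linf(s$conc, refstate), numeric(1))
    a <- stable[which.min(dref)]
    b <- setdiff(stable, a)[1]
    comparison <- compare_states(model, scan$states[[a]], scan$states[[b]])
    write_tsv_prov(comparison$metabolites, stage_file("state_comparison.tsv"),
                   stage = "compare", seed = config$seed, config = config)
  }

  list(net = net, strain = sp, glc_fit = gfit, qp = qp,
       connecting = conn, model = model, stabilization = stab,
       scan = scan, comparison = comparison)
}
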