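# File-based fixture bundle for exercising the full pipeline through the
# production readers: toy network TSV, omics TSV directory and a kinetic
# model YAML combining the network-matched central subnetwork with the
# bistable feedback motif.

#' Combine the toy kinetic model with the bistable motif
#'
#' Block-diagonal union of the network-matched central kinetic model
#' (metabolites `A`, `ac`) and the positive-feedback motif (`m1`..`m3`).
#' The combined system inherits the motif's bistability while the central
#' block remains anchored to the stoichiometric network, so the full
#' pipeline exercises closure, parameterization and the two-state scan at
#' once.
#'
#' @param mu growth rate (1/h).
#' @param high_state store the motif's high (rather than low) fixed point
#'   as the reference concentration.
#' @return list with `model`, `truth` (central ground-truth ledger) and
#'   `motif` (the [make_bistable_motif()] bundle).
#' @export
make_combined_kinetic <- function(mu = 0.2, high_state = TRUE) {
  kin <- make_toy_kinetic(mu)
  motif <- make_bistable_motif()
  mk <- kin$model; mm <- motif$model
  ref_m <- motif$fixed_points[if (high_state) "high" else "low", ]
  mm$metabolites$conc <- unname(ref_m[mm$metabolites$id])
  mets <- dplyr::bind_rows(mk$metabolites, mm$metabolites)
  reactions <- c(mk$reactions, mm$reactions)
  S <- matrix(0, nrow(mets), length(reactions),
              dimnames = list(mets$id, names(reactions)))
  S[rownames(mk$S), colnames(mk$S)] <- mk$S
  S[rownames(mm$S), colnames(mm$S)] <- mm$S
  cc <- c(mk$c, mm$c)
  model <- kinetic_model(mets, reactions, S, c = cc, mu = mu,
                         rho_X = mk$rho_X)
  list(model = model, truth = kin$truth, motif = motif)
}

#' Write a complete pipeline fixture bundle to disk
#'
#' Produces `network.tsv`, an `omics/` directory and `model.yaml` in the
#' dialects the production readers consume, all generated from the
#' ground-truth fixtures.
#'
#' @param dir target directory.
#' @param spec a [fixture_spec()].
#' @return list of paths (`network`, `omics_dir`, `kinetic_model`) plus the
#'   ground-truth ledger.
#' @export
make_pipeline_fixture <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- make_toy_gsmn(spec)
  comb <- make_combined_kinetic()
  so <- make_synthetic_omics(list(model = comb$model, truth = comb$truth),
                             gs, spec)
  omics <- so$omics
  # metabolome covers the full combined state (masking from the spec applies
  # to the central block only, handled inside make_synthetic_omics)
  net_path <- file.path(dir, "network.tsv")
  omics_dir <- file.path(dir, "omics")
  model_path <- file.path(dir, "model.yaml")
  write_network_tsv(gs$net, net_path)
  # biomass composition needs molecular weights for the rebalance stage
  omics$biomass_composition$mw <- 500
  write_omics(omics, omics_dir)
  write_kinetic_model(comb$model, model_path)
  list(network = net_path, omics_dir = omics_dir, kinetic_model = model_path,
       truth = so$truth, motif = comb$motif)
}
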