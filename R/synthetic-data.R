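# Synthetic fixtures: a toy stoichiometric network with enumerable LP
# optima, a matching toy kinetic model with known ground-truth parameters,
# a kinetic motif with analytically known bistability, and multi-omics
# tables generated from the ground truth. Everything is reproducible from
# (spec, seed) and exercises the production code paths end to end.

#' Specification of a synthetic fixture set
#'
#' @param seed RNG seed governing all stochastic parts of a fixture.
#' @param n_extra_connecting extra (zero-flux) connecting reactions to
#'   attach to the central carbon intermediate (0..5).
#' @param cycle add a futile two-reaction internal cycle (exercises flux
#'   variability detection).
#' @param noise_flux,noise_conc,noise_prot relative noise levels
#'   (multiplicative log-normal on fluxes so signs are kept; additive
#'   zero-truncated Gaussian on concentrations and protein levels).
#' @param mask_fraction fraction of metabolome entries reported as missing.
#' @param dilution_rates chemostat dilution rates (1/h) at which exchange
#'   rates are tabulated.
#' @param strain ground-truth strain parameters of the emulated culture.
#' @return list of class `ccm_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_extra_connecting = 0, cycle = FALSE,
                         noise_flux = 0, noise_conc = 0, noise_prot = 0,
                         mask_fraction = 0,
                         dilution_rates = c(0.1, 0.2, 0.3, 0.4, 0.5),
                         strain = strain_parameters(
                           o2_max_uptake = 0.5, glc_max_uptake = 1000,
                           atpm_flux = 1, gam_atp_stoich = 6, h_p = 4)) {
  stopifnot(n_extra_connecting >= 0, n_extra_connecting <= 5,
            noise_flux >= 0, noise_conc >= 0, noise_prot >= 0,
            mask_fraction >= 0, mask_fraction <= 1,
            all(dilution_rates > 0))
  structure(list(seed = seed, n_extra_connecting = n_extra_connecting,
                 cycle = cycle, noise_flux = noise_flux,
                 noise_conc = noise_conc, noise_prot = noise_prot,
                 mask_fraction = mask_fraction,
                 dilution_rates = dilution_rates, strain = strain),
            class = "ccm_fixture_spec")
}

#' Toy stoichiometric network with enumerable optima
#'
#' A minimal aerobic glucose network: glycolysis-like catabolism
#' (`GLYC: glc -> 2 A + 2 atp`), an acetate-overflow branch
#' (`FERM: A -> ac + atp`), respiration via proton pumping
#' (`RESP: A + o2 -> 8 h_p`) and ATP synthase (`ATPS: h_p-stoich protons ->
#' atp`), ATP maintenance, a biomass reaction (`2 A + GAM atp -> bio`) and
#' exchange reactions for glucose, oxygen, acetate and biomass. The central
#' subnetwork is `GLYC`, `FERM`, `RESP`; the kinetic-model metabolites are
#' `A` and `ac`. Uptake exchanges carry positive flux (toy convention).
#'
#' The polytope is small enough for [enumerate_vertices()], and FBA optima
#' are returned alongside for use as oracle anchors.
#'
#' @param spec a [fixture_spec()].
#' @return list with `net` (strain parameters of `spec$strain` installed),
#'   `central` (central reaction ids), `kinetic_mets`, and `optimum`
#'   (max-growth FBA objective at the ground-truth parameters).
#' @export
make_toy_gsmn <- function(spec = fixture_spec()) {
  mets <- c("glc", "A", "ac", "o2", "atp", "hext", "bio")
  rxn <- list(
    EX_glc  = c(glc = 1),
    GLYC    = c(glc = -1, A = 2, atp = 2),
    FERM    = c(A = -1, ac = 1, atp = 1),
    RESP    = c(A = -1, o2 = -1, hext = 8),
    ATPS    = c(hext = -4, atp = 1),
    EX_o2   = c(o2 = 1),
    EX_ac   = c(ac = -1),
    ATPM    = c(atp = -1),
    BIOMASS = c(A = -2, atp = -6, bio = 1),
    EX_bio  = c(bio = -1))
  if (spec$cycle) {
    mets <- c(mets, "cycB")
    rxn$CYC1 <- c(A = -1, cycB = 1)
    rxn$CYC2 <- c(cycB = -1, A = 1)
  }
  if (spec$n_extra_connecting > 0) {
    for (i in seq_len(spec$n_extra_connecting)) {
      wm <- paste0("waste", i)
      mets <- c(mets, wm)
      rxn[[paste0("XCONN", i)]] <- stats::setNames(c(-1, 1), c("A", wm))
      rxn[[paste0("EX_waste", i)]] <- stats::setNames(-1, wm)
    }
  }
  S <- matrix(0, length(mets), length(rxn), dimnames = list(mets, names(rxn)))
  for (id in names(rxn)) S[names(rxn[[id]]), id] <- rxn[[id]]
  lb <- stats::setNames(rep(0, length(rxn)), names(rxn))
  ub <- stats::setNames(rep(1000, length(rxn)), names(rxn))
  if (spec$cycle) ub[c("CYC1", "CYC2")] <- 10
  if (spec$n_extra_connecting > 0) {
    ub[grep("^XCONN|^EX_waste", names(ub))] <- 0.05
  }
  net <- stoich_network(
    S, lb, ub, biomass_id = "BIOMASS",
    exchange_ids = grep("^EX_|^ATPM$", names(rxn), value = TRUE),
    roles = list(growth = "BIOMASS", glucose_uptake = "EX_glc",
                 oxygen_uptake = "EX_o2", acetate_secretion = "EX_ac",
                 atpm = "ATPM", atps = "ATPS", proton_p = "hext",
                 atp = "atp"),
    uptake_sign = 1)
  net <- apply_strain_parameters(net, spec$strain)
  opt <- fba(net, sense = "max")
  list(net = net, central = c("GLYC", "FERM", "RESP"),
       kinetic_mets = c("A", "ac"), optimum = opt$objective_value)
}

#' Toy kinetic model matched to the toy network
#'
#' Kinetic mirror of the toy network's central subnetwork: `GLYC` is
#' irreversible Michaelis-Menten in external glucose (held constant),
#' `FERM` is reversible Michaelis-Menten between the carbon intermediate
#' `A` and intracellular acetate, and `RESP` is irreversible
#' Michaelis-Menten in `A`. Ground-truth parameters are chosen so the
#' model's steady state reproduces the toy network's flux distribution at
#' dilution 0.2 1/h exactly; closure constants carry the dilution
#' correction so the reference concentrations are an exact fixed point.
#'
#' @param mu growth rate (1/h); the ground truth is constructed at 0.2.
#' @return list with `model` (reference concentrations stored in the
#'   metabolite table) and `truth` (parameter ledger: vmax, Km, kcat, mw,
#'   enzyme levels, reference concentrations and central fluxes).
#' @export
make_toy_kinetic <- function(mu = 0.2) {
  fluxes <- c(GLYC = 0.525, FERM = 0.15, RESP = 0.5)  # toy net at d = 0.2
  conc <- c(A = 1.2, ac = 0.5)
  glc_ex <- 10
  Km <- list(GLYC = c(Km_glc_ex = 1),
             FERM = c(Km_A = 2, Km_ac = 3, Keq = 5),
             RESP = c(Km_A = 0.8))
  vmax <- c(
    GLYC = unname(fluxes["GLYC"] / (glc_ex / (1 + glc_ex))),
    FERM = unname(fluxes["FERM"] * (2 + conc["A"] + (2 / 3) * conc["ac"]) /
                    (conc["A"] - conc["ac"] / 5)),
    RESP = unname(fluxes["RESP"] / (conc["A"] / (0.8 + conc["A"]))))
  mets <- metabolite_table(
    id = c("A", "ac", "glc_ex"),
    compartment = c("cytoplasm", "cytoplasm", "external"),
    conc = c(conc, glc_ex = glc_ex))
  reactions <- list(
    GLYC = rate_law("irreversible_MM",
                    params = list(vmax = vmax[["GLYC"]], Km_glc_ex = 1),
                    substrates = "glc_ex"),
    FERM = rate_law("reversible_MM",
                    params = c(list(vmax = vmax[["FERM"]]), as.list(Km$FERM)),
                    substrates = "A", products = "ac"),
    RESP = rate_law("irreversible_MM",
                    params = list(vmax = vmax[["RESP"]], Km_A = 0.8),
                    substrates = "A"))
  S <- matrix(c(2, -1, -1,
                0, 1, 0,
                -1, 0, 0),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "ac", "glc_ex"), names(reactions)))
  # closure: GSMN connecting fluxes (biomass drain of A, acetate export)
  # plus the dilution correction that makes the reference an exact fixed point
  c_gsmn <- c(A = -2 * mu, ac = -fluxes[["FERM"]])
  cc <- c_gsmn + mu * conc / 1
  model <- kinetic_model(mets, reactions, S, c = cc, mu = mu, rho_X = 1)
  kcat <- c(GLYC = 100, FERM = 50, RESP = 30)       # 1/s
  mw <- c(GLYC = 50, FERM = 40, RESP = 60)          # kDa
  E <- vmax * mw * 1000 / (kcat * 3600)             # mgProtein/gDCW
  list(model = model,
       truth = list(vmax = vmax, Km = Km, kcat = kcat, mw = mw,
                    enzyme_conc = E, conc = conc, fluxes = fluxes,
                    c_gsmn = c_gsmn, c_installed = cc))
}

#' Bistable kinetic motif with closed-form fixed points
#'
#' Three-metabolite motif built on the anaplerotic-style positive-feedback
#' mechanism: an autocatalytic Hill reaction produces the feedback
#' metabolite `m1`, whose nullcline is a cubic engineered to have roots at
#' 1, 3 and 7 mM; two passive metabolites relax linearly downstream. The
#' system has exactly two stable fixed points and one saddle, all returned
#' in closed form, and both stable points lie inside the scan box `[0, 10]`.
#'
#' @param seed unused (the motif is fully deterministic); kept so fixture
#'   constructors share a signature.
#' @return list with `model`, `fixed_points` (matrix, one row per fixed
#'   point), `stability` (classification per fixed point) and the cubic
#'   roots.
#' @export
make_bistable_motif <- function(seed = NULL) {
  roots <- c(1, 3, 7)
  mu <- 0.2
  S1 <- sum(roots)
  S2 <- roots[1] * roots[2] + roots[1] * roots[3] + roots[2] * roots[3]
  S3 <- prod(roots)
  K2 <- S2                       # K^2 of the Hill law
  cin <- mu * S3 / S2            # constant influx to m1
  vmax <- mu * S1 - cin
  k12 <- 0.2; kd2 <- 0.5; c2 <- 0.1
  k23 <- 0.3; kd3 <- 0.4
  mets <- metabolite_table(id = c("m1", "m2", "m3"))
  reactions <- list(
    AUTO = rate_law("custom_from_catalogue",
                    params = list(law = "hill_activation", vmax = vmax,
                                  K = sqrt(K2), n = 2),
                    modifiers = "m1"),
    S12 = rate_law("custom_from_catalogue",
                   params = list(law = "linear_rate", k = k12),
                   modifiers = "m1"),
    D2 = rate_law("custom_from_catalogue",
                  params = list(law = "linear_rate", k = kd2),
                  modifiers = "m2"),
    S23 = rate_law("custom_from_catalogue",
                   params = list(law = "linear_rate", k = k23),
                   modifiers = "m2"),
    D3 = rate_law("custom_from_catalogue",
                  params = list(law = "linear_rate", k = kd3),
                  modifiers = "m3"))
  S <- matrix(0, 3, 5, dimnames = list(c("m1", "m2", "m3"), names(reactions)))
  S["m1", "AUTO"] <- 1
  S["m2", "S12"] <- 1; S["m2", "D2"] <- -1
  S["m3", "S23"] <- 1; S["m3", "D3"] <- -1
  cc <- c(m1 = cin, m2 = c2, m3 = 0)
  model <- kinetic_model(mets, reactions, S, c = cc, mu = mu, rho_X = 1)
  m2s <- (k12 * roots + c2) / (kd2 + mu)
  m3s <- k23 * m2s / (kd3 + mu)
  fp <- cbind(m1 = roots, m2 = m2s, m3 = m3s)
  rownames(fp) <- c("low", "middle", "high")
  list(model = model, fixed_points = fp,
       stability = c("stable", "unstable", "stable"), roots = roots)
}

#' Generate synthetic multi-omics tables from a ground-truth model
#'
#' Emulates a steady-state chemostat multi-omics campaign: the fluxome is
#' the kinetic model's steady-state central fluxes plus exchange-rate
#' curves predicted by the stoichiometric network at each dilution rate
#' under the ground-truth strain parameters; the metabolome is the
#' steady-state concentrations with a masked fraction reported missing; the
#' proteome is consistent with the ground-truth maximal rates through
#' `vmax = kcat [E]` and the unit conversions. Noise levels and masking
#' come from the fixture spec; the full ground-truth ledger is returned for
#' recovery tests.
#'
#' @param kin output of [make_toy_kinetic()] (or a compatible
#'   `list(model, truth)`).
#' @param net_fix output of [make_toy_gsmn()].
#' @param spec a [fixture_spec()].
#' @return list with `omics` (a `ccm_omics_dataset`) and `truth`.
#' @export
make_synthetic_omics <- function(kin, net_fix, spec = fixture_spec()) {
  model <- kin$model; truth <- kin$truth
  net <- net_fix$net
  ref <- stats::setNames(model$metabolites$conc, model$metabolites$id)
  state <- ref[model$state_ids]
  if (steady_state_residual(model, state) > 1e-6) {
    stop("ground-truth model is not at steady state")
  }
  set.seed(spec$seed)
  noise_mult <- function(x, s) if (s > 0) x * exp(stats::rnorm(length(x), 0, s)) else x
  noise_add <- function(x, s) if (s > 0) pmax(x + stats::rnorm(length(x), 0, s * pmax(x, 1e-12)), 0) else x
  central_flux <- evaluate_rates(model, state)
  fluxome <- tibble::tibble(
    reaction = names(central_flux),
    mean = noise_mult(unname(central_flux), spec$noise_flux),
    sd = spec$noise_flux * abs(unname(central_flux)),
    n = 4L)
  exch_ids <- c(net$roles$glucose_uptake, net$roles$oxygen_uptake,
                net$roles$acetate_secretion)
  exchange <- dplyr::bind_rows(lapply(spec$dilution_rates, function(d) {
    pred <- .predict_exchanges(net, d, exch_ids)
    if (is.null(pred)) stop("toy network infeasible at dilution ", d)
    tibble::tibble(dilution = d, reaction = exch_ids,
                   mean = noise_mult(unname(pred), spec$noise_flux),
                   sd = spec$noise_flux * abs(unname(pred)), n = 3L)
  }))
  conc <- noise_add(state, spec$noise_conc)
  masked <- rep(FALSE, length(conc))
  if (spec$mask_fraction > 0) {
    k <- max(1, round(spec$mask_fraction * length(conc)))
    masked[sample(length(conc), k)] <- TRUE
  }
  metabolome <- tibble::tibble(metabolite = names(conc),
                               conc = ifelse(masked, NA_real_, unname(conc)))
  E <- noise_add(truth$enzyme_conc, spec$noise_prot)
  proteome <- tibble::tibble(enzyme = names(E), conc = unname(E))
  omics <- omics_dataset(
    fluxome = fluxome, exchange = exchange, metabolome = metabolome,
    proteome = proteome,
    polypeptide_mw = tibble::tibble(enzyme = names(truth$mw),
                                    mw = unname(truth$mw)),
    biomass_composition = tibble::tibble(component = "A", umol_gdcw = 2000),
    dilution_rates = spec$dilution_rates)
  list(omics = omics, truth = c(truth, list(strain = spec$strain)))
}

#' Assemble a multi-omics dataset
#'
#' @param fluxome tibble `reaction`, `mean`, `sd`, `n` (mmol/gDCW/h).
#' @param exchange tibble `dilution`, `reaction`, `mean`, `sd`, `n`.
#' @param metabolome tibble `metabolite`, `conc` (mM; `NA` = missing).
#' @param proteome tibble `enzyme`, `conc` (mgProtein/gDCW).
#' @param polypeptide_mw tibble `enzyme`, `mw` (kDa).
#' @param biomass_composition tibble `component`, `umol_gdcw`.
#' @param dilution_rates numeric vector (1/h).
#' @return object of class `ccm_omics_dataset`.
#' @export
omics_dataset <- function(fluxome, exchange = NULL, metabolome = NULL,
                          proteome = NULL, polypeptide_mw = NULL,
                          biomass_composition = NULL, dilution_rates = numeric()) {
  if (!is.null(fluxome)) {
    stopifnot(all(fluxome$sd >= 0), all(fluxome$n >= 1))
  }
  if (!is.null(metabolome)) {
    ok <- is.na(metabolome$conc) | metabolome$conc >= 0
    if (!all(ok)) stop("metabolome concentrations must be >= 0 or NA")
  }
  structure(list(fluxome = fluxome, exchange = exchange,
                 metabolome = metabolome, proteome = proteome,
                 polypeptide_mw = polypeptide_mw,
                 biomass_composition = biomass_composition,
                 dilution_rates = dilution_rates),
            class = "ccm_omics_dataset")
}
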