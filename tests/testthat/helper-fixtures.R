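# Shared fixtures, memoised so expensive constructions (the multistart
# strain fit in particular) run once per test session.

.fx_cache <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

fx_spec <- function() fx_get("spec", function() fixture_spec())

fx_gsmn <- function() fx_get("gsmn", function() make_toy_gsmn(fx_spec()))

fx_kin <- function() fx_get("kin", function() make_toy_kinetic())

fx_omics <- function() fx_get("omics", function()
  make_synthetic_omics(fx_kin(), fx_gsmn(), fx_spec()))

fx_motif <- function() fx_get("motif", function() make_bistable_motif())

# the expensive zero-noise strain fit (shared by recovery tests)
fx_strain_fit <- function() fx_get("strain_fit", function()
  fit_strain_parameters(fx_gsmn()$net, fx_omics()$omics,
                        n_starts = 6, seed = 2))

# reference state of a kinetic model from its metabolite table
ref_state <- function(model) {
  stats::setNames(model$metabolites$conc, model$metabolites$id)[state_ids(model)]
}

# dilution-only model: one metabolite, no active kinetics
dilution_only_model <- function(mu = 0.2, m0 = 2) {
  mets <- metabolite_table(id = "m", conc = m0)
  rx <- list(NOOP = rate_law("mass_action", params = list(kf = 0),
                             substrates = "m"))
  S <- matrix(0, 1, 1, dimnames = list("m", "NOOP"))
  kinetic_model(mets, rx, S, c = c(m = 0), mu = mu, rho_X = 1)
}

# two-metabolite mass-action chain with hand-solved fixed point (1, 5/3)
chain_model <- function() {
  mets <- metabolite_table(id = c("A", "B"))
  rx <- list(
    R1 = rate_law("mass_action", params = list(kf = 0.5), substrates = "A",
                  products = "B"),
    R2 = rate_law("mass_action", params = list(kf = 0.2), substrates = "B"))
  S <- matrix(c(-1, 0, 1, -1), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("R1", "R2")))
  kinetic_model(mets, rx, S, c = c(A = 0.6, B = 0), mu = 0.1, rho_X = 1)
}

# linear two-variable fixture whose stability boundary sits at A = 0.8 on
# the AUTO rate constant (characteristic polynomial worked by hand:
# det J = (ka*A - 2.1)(-1.1) - 2 crosses zero at ka*A = 2.1 - 20/11)
boundary_model <- function() {
  ka <- (2.1 - 20 / 11) / 0.8
  mets <- metabolite_table(id = c("m1", "m2"))
  rx <- list(
    AUTO = rate_law("custom_from_catalogue",
                    params = list(law = "linear_rate", k = ka),
                    modifiers = "m1"),
    TR12 = rate_law("custom_from_catalogue",
                    params = list(law = "linear_rate", k = 2),
                    modifiers = "m1"),
    TR21 = rate_law("custom_from_catalogue",
                    params = list(law = "linear_rate", k = 1),
                    modifiers = "m2"))
  S <- matrix(c(1, -1, 1,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("AUTO", "TR12", "TR21")))
  kinetic_model(mets, rx, S, c = c(m1 = 0, m2 = 0), mu = 0.1, rho_X = 1)
}

# simple linear-growth network: GROW consumes 10 glc per unit biomass flux,
# so growth = 0.1 * glucose uptake
linear_growth_net <- function() {
  S <- matrix(c(1, -10, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("glc", "bio"), c("EX_glc", "GROW", "EX_bio")))
  stoich_network(S, lb = c(0, 0, 0), ub = c(1000, 1000, 1000),
                 biomass_id = "GROW", exchange_ids = c("EX_glc", "EX_bio"),
                 roles = list(growth = "GROW", glucose_uptake = "EX_glc"),
                 uptake_sign = 1)
}
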