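# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.ccm_flux_distribution <- function(x, ...) x$fluxes

#' @exportS3Method generics::glance
glance.ccm_flux_distribution <- function(x, ...) {
  tibble::tibble(objective_value = x$objective_value, status = x$status,
                 n_reactions = nrow(x$fluxes))
}

#' @exportS3Method generics::tidy
tidy.ccm_steady_state <- function(x, ...) {
  tibble::tibble(metabolite = names(x$conc), conc = unname(x$conc))
}

#' @exportS3Method generics::glance
glance.ccm_steady_state <- function(x, ...) {
  tibble::tibble(classification = x$classification,
                 residual_norm = x$residual_norm,
                 max_re_lambda = max(Re(x$eigenvalues)),
                 n_positive_re = sum(Re(x$eigenvalues) >
                                       1e-6 * max(abs(Re(x$eigenvalues)), 1)),
                 path = x$provenance$path)
}

#' @exportS3Method generics::tidy
tidy.ccm_scan_result <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$states), function(i) {
    s <- x$states[[i]]
    tibble::tibble(state = i, metabolite = names(s$conc),
                   conc = unname(s$conc),
                   classification = s$classification,
                   basin_count = x$basin_counts[i])
  }))
}

#' @exportS3Method generics::glance
glance.ccm_scan_result <- function(x, ...) {
  tibble::tibble(n_states = length(x$states),
                 n_stable = sum(x$summary$classification == "stable"),
                 n_starts = x$n_starts, n_failures = sum(x$failures),
                 seed = x$seed)
}

#' @exportS3Method generics::tidy
tidy.ccm_connecting_fluxes <- function(x, ...) x$c_i

#' @exportS3Method generics::tidy
tidy.ccm_adjustment_solution <- function(x, ...) {
  if (!is.null(x$A)) {
    return(tibble::tibble(parameter = names(x$A), factor = unname(x$A)))
  }
  dplyr::bind_rows(
    if (length(x$solved_concentrations))
      tibble::tibble(quantity = names(x$solved_concentrations),
                     kind = "concentration",
                     value = unname(x$solved_concentrations)),
    if (length(x$vmax_adjust))
      tibble::tibble(quantity = names(x$vmax_adjust), kind = "vmax_factor",
                     value = unname(x$vmax_adjust)),
    if (length(x$param_adjust))
      tibble::tibble(quantity = names(x$param_adjust), kind = "param_factor",
                     value = unname(x$param_adjust)))
}

#' Eigenvalue table of a steady state
#'
#' Spectrum formatted one eigenvalue per row with real and imaginary parts.
#' @param state a `ccm_steady_state`.
#' @export
eigenvalue_table <- function(state) {
  ev <- state$eigenvalues
  tibble::tibble(re = Re(ev), im = Im(ev),
                 magnitude = Mod(ev))
}
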