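# Rate-law library. Laws are data (kind + parameter map + participant roles)
# so a full reaction catalogue can be transcribed without code changes.
# Units convention throughout: concentrations mM, rates mmol/gDCW/h.

#' Metabolites treated as cofactors
#'
#' Cofactor pools are assumed balanced by the rest of metabolism (their net
#' rate of change is zero), so they are held at fixed concentrations and
#' excluded from the ODE state vector.
#' @return character vector of metabolite ids.
#' @export
ccm_cofactors <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "coa")
}

#' Construct a rate law
#'
#' @param kind one of `"mass_action"`, `"irreversible_MM"`, `"reversible_MM"`,
#'   `"ordered_bibi_MWC"`, `"custom_from_catalogue"`.
#' @param params named list of kinetic parameters. Numeric entries use the
#'   package units (`vmax` mmol/gDCW/h, `Km_*`/`Ki_*` mM, `L` and Hill
#'   exponent `n` dimensionless, mass-action `kf`/`kr` per-mM-per-h). For
#'   `custom_from_catalogue`, `params$law` names a catalogue entry or
#'   `params$expr` gives an expression in `s1..`, `p1..`, `m1..` and the
#'   remaining parameters.
#' @param substrates,products,modifiers metabolite ids with stoichiometric
#'   roles; repeat an id for multiplicity greater than one.
#' @param a1 named numeric vector of per-parameter multiplicative adjustment
#'   factors (defaults to 1 for every parameter).
#' @param a2 multiplicative adjustment factor on the maximal rate.
#' @return object of class `ccm_rate_law`.
#' @export
rate_law <- function(kind = c("mass_action", "irreversible_MM", "reversible_MM",
                              "ordered_bibi_MWC", "custom_from_catalogue"),
                     params = list(), substrates = character(),
                     products = character(), modifiers = character(),
                     a1 = NULL, a2 = 1) {
  kind <- match.arg(kind)
  stopifnot(is.list(params))
  num <- vapply(params, is.numeric, logical(1))
  p <- unlist(params[num])
  km <- grep("^K[mi]_|^K$", names(p), value = TRUE)
  if (any(p[km] <= 0)) stop("all Km/Ki parameters must be > 0")
  if (!is.null(p["vmax"]) && !is.na(p["vmax"]) && p[["vmax"]] < 0) {
    stop("vmax must be >= 0")
  }
  if ("L" %in% names(p) && p[["L"]] < 0) stop("allosteric L must be >= 0")
  if ("n" %in% names(p) && p[["n"]] <= 0) stop("Hill exponent n must be > 0")
  if (kind == "reversible_MM" &&
      (length(substrates) != 1 || length(products) != 1)) {
    stop("reversible_MM supports exactly one substrate and one product")
  }
  if (kind == "ordered_bibi_MWC" &&
      (length(substrates) != 2 || length(modifiers) < 1)) {
    stop("ordered_bibi_MWC needs substrates c(second, first-binding) and an inhibitor modifier")
  }
  if (!is.null(a1)) {
    stopifnot(!is.null(names(a1)), all(names(a1) %in% names(params)))
  }
  structure(
    list(kind = kind, params = params, substrates = substrates,
         products = products, modifiers = modifiers,
         a1 = a1 %||% stats::setNames(numeric(0), character(0)), a2 = a2),
    class = "ccm_rate_law")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# effective parameters after per-parameter (a1) adjustment
.law_params <- function(law) {
  p <- law$params
  for (nm in names(law$a1)) p[[nm]] <- p[[nm]] * law$a1[[nm]]
  p
}

.law_catalogue <- new.env(parent = emptyenv())

#' Register or fetch a catalogue rate law
#'
#' Catalogue laws make mechanisms that the built-in kinds cannot express
#' available by name. A law is a function `f(S, P, M, p)` of substrate,
#' product and modifier concentration vectors (in declared order) and the
#' effective parameter list, returning a rate in mmol/gDCW/h.
#'
#' @param name catalogue key.
#' @param fn law function, or `NULL` to fetch the registered law.
#' @export
law_catalogue <- function(name, fn = NULL) {
  if (is.null(fn)) {
    f <- .law_catalogue[[name]]
    if (is.null(f)) stop("unknown catalogue law: ", name)
    return(f)
  }
  assign(name, fn, envir = .law_catalogue)
  invisible(fn)
}

# built-in catalogue entries -------------------------------------------------

# Hill-type positive feedback: vmax * x^n / (K^n + x^n) on the first
# substrate (or first modifier when the product feeds back on itself).
.init_catalogue <- function() {
  law_catalogue("hill_activation", function(S, P, M, p) {
    x <- if (length(S)) S[1] else M[1]
    if (x <= 0) return(0)
    p$vmax * x^p$n / (p$K^p$n + x^p$n)
  })
  law_catalogue("linear_rate", function(S, P, M, p) {
    x <- if (length(S)) S[1] else M[1]
    p$k * x
  })
}

#' Ordered bi-bi rate law with concerted (MWC) allosteric inhibition
#'
#' Irreversible compulsory-order two-substrate mechanism in which the
#' first-binding substrate (nadp for isocitrate dehydrogenase) acts as an
#' essential activator, multiplied by the concerted-transition factor
#' `R = (1 + beta)^n / (L (1 + gamma)^n + (1 + beta)^n)` with
#' `beta = icit / Km_icit` and `gamma = pep / Ki_pep`. No icit-only binding
#' term appears in the denominator: the free enzyme is assumed unable to form
#' an icit complex, and the affinity factor of the nadp-enzyme complex for
#' icit is absorbed into `Km_icit`.
#'
#' @param icit,nadp,pep concentrations in mM (`pep` is the allosteric
#'   inhibitor).
#' @param params list with `vmax`, `Km_icit`, `Km_nadp`, `Ki_pep`, `L`
#'   (>= 0) and `n` (> 0).
#' @return rate in the units of `vmax`, within `[0, vmax]`.
#' @export
rate_ordered_bibi_mwc <- function(icit, nadp, pep, params) {
  p <- params
  for (nm in c("Km_icit", "Km_nadp", "Ki_pep")) {
    if (is.null(p[[nm]]) || p[[nm]] <= 0) stop(nm, " must be > 0")
  }
  if (p$L < 0) stop("L must be >= 0")
  if (pep < 0) stop("pep must be >= 0")
  sa <- icit / p$Km_icit
  sb <- nadp / p$Km_nadp
  core <- p$vmax * (sa * sb) / (1 + sb + sa * sb)
  beta <- icit / p$Km_icit
  gamma <- pep / p$Ki_pep
  R <- (1 + beta)^p$n / (p$L * (1 + gamma)^p$n + (1 + beta)^p$n)
  core * R
}

# evaluate one law at a full named concentration vector
.eval_law <- function(law, conc, id = "?") {
  refs <- c(law$substrates, law$products, law$modifiers)
  miss <- setdiff(refs, names(conc))
  if (length(miss)) {
    stop("reaction ", id, " references unknown metabolite(s): ",
         paste(miss, collapse = ", "))
  }
  S <- unname(conc[law$substrates])
  P <- unname(conc[law$products])
  M <- unname(conc[law$modifiers])
  p <- .law_params(law)
  a2 <- law$a2
  switch(law$kind,
    mass_action = {
      kf <- (p$kf %||% 0) * a2
      kr <- (p$kr %||% 0) * a2
      kf * prod(S) - kr * prod(P)
    },
    irreversible_MM = {
      if (any(S == 0)) return(0)
      p$vmax * a2 * prod(S / (unlist(p[paste0("Km_", law$substrates)]) + S))
    },
    reversible_MM = {
      s <- S[1]; pr <- P[1]
      Ks <- p[[paste0("Km_", law$substrates[1])]] %||% p$Km_s
      Kp <- p[[paste0("Km_", law$products[1])]] %||% p$Km_p
      p$vmax * a2 * (s - pr / p$Keq) / (Ks + s + (Ks / Kp) * pr)
    },
    ordered_bibi_MWC = {
      pp <- p
      pp$vmax <- p$vmax * a2
      pp$Km_icit <- p[[paste0("Km_", law$substrates[1])]]
      pp$Km_nadp <- p[[paste0("Km_", law$substrates[2])]]
      pp$Ki_pep <- p[[paste0("Ki_", law$modifiers[1])]]
      rate_ordered_bibi_mwc(S[1], S[2], M[1], pp)
    },
    custom_from_catalogue = {
      p$vmax <- if (!is.null(p$vmax)) p$vmax * a2 else NULL
      if (!is.null(p$k)) p$k <- p$k * a2
      if (!is.null(law$params$expr)) {
        env <- list2env(p[vapply(p, is.numeric, logical(1))])
        for (i in seq_along(S)) assign(paste0("s", i), S[i], envir = env)
        for (i in seq_along(P)) assign(paste0("p", i), P[i], envir = env)
        for (i in seq_along(M)) assign(paste0("m", i), M[i], envir = env)
        eval(parse(text = law$params$expr), envir = env)
      } else {
        law_catalogue(law$params$law)(S, P, M, p)
      }
    })
}
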