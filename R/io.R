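# Readers and writers. TSV dialect: UTF-8, tab-separated, mandatory header
# row, '.' decimal separator, '#'-prefixed provenance/comment lines.

.pkg_version <- function() {
  as.character(utils::packageVersion("kinetigrate"))
}

# tiny FNV-1a hash over a serialized object, for provenance headers
.obj_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.provenance <- function(stage, seed = NA, config = NULL) {
  sprintf("# kinetigrate %s | stage: %s | seed: %s | config: %s",
          .pkg_version(), stage,
          ifelse(is.na(seed), "-", format(seed)),
          if (is.null(config)) "-" else .obj_hash(config))
}

#' Write a table as provenance-stamped TSV
#' @param x data frame.
#' @param path output file.
#' @param stage,seed,config provenance fields for the header comment.
#' @export
write_tsv_prov <- function(x, path, stage = "export", seed = NA, config = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance(stage, seed, config), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-stamped TSV
#' @param path file path.
#' @export
read_tsv_prov <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      comment.char = "#",
                                      stringsAsFactors = FALSE))
}

# equation strings: "1 glc[e] + 2 atp[c] -> 2 A[c]", "<->" for reversible
.format_equation <- function(S, id) {
  col <- S[, id]
  lhs <- col[col < 0]; rhs <- col[col > 0]
  side <- function(v, sgn) {
    if (!length(v)) return("")
    paste(sprintf("%g %s", abs(unname(v)), names(v)), collapse = " + ")
  }
  paste(side(lhs), "->", side(rhs))
}

.parse_equation <- function(eq) {
  sides <- strsplit(eq, "<->|->")[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s, sgn) {
    s <- trimws(s)
    if (s == "") return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "\\+")[[1]])
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9.eE+-]+)?\\s*(\\S+)$", t))[[1]]
      coef <- if (m[2] == "") 1 else as.numeric(m[2])
      cur <- if (m[3] %in% names(out)) out[[m[3]]] else 0
      out[m[3]] <- sgn * coef + cur
    }
    out
  }
  c(parse_side(sides[1], -1), parse_side(sides[2], 1))
}

#' Write a stoichiometric network as a reaction-table TSV
#'
#' One row per reaction: `id`, `equation` (compartment-suffixed metabolite
#' ids), `lb`, `ub`. Biomass/exchange/role annotations are kept in `#!`
#' header directives so the file round-trips losslessly.
#'
#' @param net a `ccm_stoich_network`.
#' @param path output file.
#' @export
write_network_tsv <- function(net, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.provenance("network"), con)
  if (!is.null(net$biomass_id)) writeLines(paste0("#! biomass\t", net$biomass_id), con)
  if (length(net$exchange_ids)) {
    writeLines(paste0("#! exchange\t", paste(net$exchange_ids, collapse = ",")), con)
  }
  writeLines(paste0("#! uptake_sign\t", net$uptake_sign), con)
  for (r in names(net$roles)) {
    writeLines(paste0("#! role\t", r, "\t", net$roles[[r]]), con)
  }
  tb <- data.frame(id = net$rxns,
                   equation = vapply(net$rxns, function(id)
                     .format_equation(net$S, id), ""),
                   lb = unname(net$lb), ub = unname(net$ub))
  utils::write.table(tb, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stoichiometric network
#'
#' @param path file path.
#' @param dialect `"tsv"` (reaction-table dialect) or `"sbml"` (SBML Level 3
#'   with the flux-balance-constraints extension).
#' @return a `ccm_stoich_network`.
#' @export
load_network <- function(path, dialect = c("tsv", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "sbml") return(read_sbml_network(path))
  lines <- readLines(path, encoding = "UTF-8")
  directives <- grep("^#!", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  tb <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("id", "equation", "lb", "ub") %in% names(tb))) {
    stop("network TSV must have columns id, equation, lb, ub")
  }
  stoichs <- lapply(seq_len(nrow(tb)), function(i) {
    tryCatch(.parse_equation(tb$equation[i]),
             error = function(e) stop("line for reaction ", tb$id[i],
                                      ": cannot parse equation"))
  })
  mets <- unique(unlist(lapply(stoichs, names)))
  S <- matrix(0, length(mets), nrow(tb), dimnames = list(mets, tb$id))
  for (i in seq_len(nrow(tb))) S[names(stoichs[[i]]), i] <- stoichs[[i]]
  biomass <- NULL; exch <- character(); roles <- list(); usign <- 1
  for (d in directives) {
    f <- strsplit(sub("^#!\\s*", "", d), "\t")[[1]]
    if (f[1] == "biomass") biomass <- f[2]
    if (f[1] == "exchange") exch <- strsplit(f[2], ",")[[1]]
    if (f[1] == "uptake_sign") usign <- as.numeric(f[2])
    if (f[1] == "role") roles[[f[2]]] <- f[3]
  }
  stoich_network(S, stats::setNames(tb$lb, tb$id), stats::setNames(tb$ub, tb$id),
                 biomass_id = biomass, exchange_ids = exch, roles = roles,
                 uptake_sign = usign)
}

#' Read an SBML Level 3 (FBC) model into a stoichiometric network
#'
#' Minimal importer: species, reactions with reactant/product stoichiometry,
#' flux bounds from the flux-balance-constraints attributes (resolved
#' through the parameter list), reversibility mapped to a zero lower bound
#' when `reversible="false"` and no explicit bound is given, and the active
#' FBC objective. Compartment suffixes in species ids are preserved as-is.
#'
#' @param path SBML file.
#' @return a `ccm_stoich_network`.
#' @export
read_sbml_network <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  met_ids <- xml2::xml_attr(species, "id")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  ids <- xml2::xml_attr(rxns, "id")
  S <- matrix(0, length(met_ids), length(ids), dimnames = list(met_ids, ids))
  lb <- stats::setNames(rep(-1000, length(ids)), ids)
  ub <- stats::setNames(rep(1000, length(ids)), ids)
  for (i in seq_along(rxns)) {
    rx <- rxns[[i]]
    for (sr in xml2::xml_find_all(rx, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      if (!sp %in% met_ids) stop("reaction ", ids[i], " references undeclared metabolite ", sp)
      st <- xml2::xml_attr(sr, "stoichiometry")
      S[sp, i] <- S[sp, i] - as.numeric(if (is.na(st)) 1 else st)
    }
    for (sr in xml2::xml_find_all(rx, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      if (!sp %in% met_ids) stop("reaction ", ids[i], " references undeclared metabolite ", sp)
      st <- xml2::xml_attr(sr, "stoichiometry")
      S[sp, i] <- S[sp, i] + as.numeric(if (is.na(st)) 1 else st)
    }
    lbid <- xml2::xml_attr(rx, "lowerFluxBound")
    ubid <- xml2::xml_attr(rx, "upperFluxBound")
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    lb[i] <- if (!is.na(lbid)) pval[[lbid]] else if (rev) -1000 else 0
    ub[i] <- if (!is.na(ubid)) pval[[ubid]] else 1000
  }
  # keep only species that participate in a reaction (boundary species drop out)
  used <- rowSums(abs(S)) > 0
  S <- S[used, , drop = FALSE]
  objf <- xml2::xml_find_first(doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- NULL
  biomass <- NULL
  if (!inherits(objf, "xml_missing")) {
    biomass <- xml2::xml_attr(objf, "reaction")
    cf <- xml2::xml_attr(objf, "coefficient")
    objective <- stats::setNames(as.numeric(if (is.na(cf)) 1 else cf), biomass)
  }
  stoich_network(S, lb, ub, biomass_id = biomass,
                 exchange_ids = grep("^EX_", ids, value = TRUE),
                 objective = objective, uptake_sign = -1)
}

#' Write a kinetic model definition (YAML)
#'
#' Structured-text serialization of a kinetic model: metabolites, reactions
#' (law kind, parameters, participant roles, adjustment factors), non-zero
#' stoichiometric entries, closure constants, growth rate and cell density.
#' Round-trips losslessly through [read_kinetic_model()].
#'
#' @param model a `ccm_kinetic_model`.
#' @param path output file.
#' @export
write_kinetic_model <- function(model, path) {
  rx <- lapply(names(model$reactions), function(id) {
    l <- model$reactions[[id]]
    list(id = id, kind = l$kind, params = l$params,
         substrates = as.list(l$substrates), products = as.list(l$products),
         modifiers = as.list(l$modifiers),
         a1 = as.list(l$a1), a2 = l$a2)
  })
  Sent <- which(model$S != 0, arr.ind = TRUE)
  stoich <- lapply(seq_len(nrow(Sent)), function(k) {
    list(metabolite = rownames(model$S)[Sent[k, 1]],
         reaction = colnames(model$S)[Sent[k, 2]],
         coefficient = model$S[Sent[k, 1], Sent[k, 2]])
  })
  obj <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      as.list(model$metabolites[i, ])),
    reactions = rx, stoichiometry = stoich,
    c = as.list(model$c), mu = model$mu, rho_X = model$rho_X,
    biomass_X = model$biomass_X, inactive = as.list(model$inactive))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a kinetic model definition (YAML)
#' @param path file written by [write_kinetic_model()].
#' @return a `ccm_kinetic_model`.
#' @export
read_kinetic_model <- function(path) {
  obj <- yaml::read_yaml(path)
  mets <- dplyr::bind_rows(lapply(obj$metabolites, tibble::as_tibble))
  mets$conc <- as.numeric(mets$conc)
  reactions <- stats::setNames(lapply(obj$reactions, function(r) {
    rate_law(r$kind, params = r$params,
             substrates = unlist(r$substrates) %||% character(),
             products = unlist(r$products) %||% character(),
             modifiers = unlist(r$modifiers) %||% character(),
             a1 = if (length(r$a1)) unlist(r$a1) else NULL,
             a2 = r$a2 %||% 1)
  }), vapply(obj$reactions, `[[`, "", "id"))
  S <- matrix(0, nrow(mets), length(reactions),
              dimnames = list(mets$id, names(reactions)))
  for (e in obj$stoichiometry) S[e$metabolite, e$reaction] <- e$coefficient
  kinetic_model(mets, reactions, S, c = unlist(obj$c), mu = obj$mu,
                rho_X = obj$rho_X, biomass_X = obj$biomass_X %||% 1,
                inactive = unlist(obj$inactive) %||% character())
}

#' Write a simulated trajectory as TSV
#' @param traj a `ccm_trajectory`.
#' @param path output file.
#' @param ... passed to [write_tsv_prov()].
#' @export
write_trajectory_tsv <- function(traj, path, ...) {
  write_tsv_prov(as.data.frame(traj), path, stage = "trajectory", ...)
}

#' Write / read a multi-omics dataset as a directory of TSV files
#' @param omics a `ccm_omics_dataset`.
#' @param dir directory (created if needed).
#' @export
write_omics <- function(omics, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("fluxome", "exchange", "metabolome", "proteome",
                 "polypeptide_mw", "biomass_composition")) {
    if (!is.null(omics[[part]])) {
      write_tsv_prov(omics[[part]], file.path(dir, paste0(part, ".tsv")),
                     stage = paste0("omics/", part))
    }
  }
  writeLines(format(omics$dilution_rates, digits = 15),
             file.path(dir, "dilution_rates.txt"))
  invisible(dir)
}

#' @rdname write_omics
#' @export
read_omics <- function(dir) {
  rd <- function(part) {
    p <- file.path(dir, paste0(part, ".tsv"))
    if (file.exists(p)) read_tsv_prov(p) else NULL
  }
  omics_dataset(fluxome = rd("fluxome"), exchange = rd("exchange"),
                metabolome = rd("metabolome"), proteome = rd("proteome"),
                polypeptide_mw = rd("polypeptide_mw"),
                biomass_composition = rd("biomass_composition"),
                dilution_rates = as.numeric(readLines(
                  file.path(dir, "dilution_rates.txt"))))
}

#' Write a scan report as JSON
#'
#' States, spectra, classifications, basin counts, seed and settings, in a
#' machine-readable report.
#' @param scan a `ccm_scan_result`.
#' @param path output file.
#' @export
write_scan_json <- function(scan, path) {
  obj <- list(
    n_starts = scan$n_starts, seed = scan$seed, interval = scan$interval,
    dedup_tol = scan$dedup_tol, failures = as.list(scan$failures),
    states = lapply(seq_along(scan$states), function(i) {
      s <- scan$states[[i]]
      list(index = i, classification = s$classification,
           basin_count = scan$basin_counts[i],
           residual = s$residual_norm,
           conc = as.list(s$conc),
           eigenvalues_re = Re(s$eigenvalues),
           eigenvalues_im = Im(s$eigenvalues))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
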