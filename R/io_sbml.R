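# Minimal SBML Level 3 Version 1 + FBC v2 reader/writer on xml2.
#
# The writer emits the subset of SBML-FBC that constraint-based tools consume:
# compartments, species with chemical formulas, reactions with
# reactant/product stoichiometry, flux bounds as shared parameters, and an
# active maximization objective. Exchange reactions are tagged with SBO:0000627
# and the biomass reaction with SBO:0000629 so the designation survives the
# round trip.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBO_EXCHANGE <- "SBO:0000627"
SBO_BIOMASS <- "SBO:0000629"

write_model_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  num <- function(x) formatC(x, digits = 17, format = "g")

  # shared flux-bound parameters, one per distinct value
  vals <- sort(unique(c(net$reactions$lower_bound, net$reactions$upper_bound)))
  par_id <- function(v) paste0("fb_", match(v, vals))

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"", SBML_NS, "\" xmlns:fbc=\"", FBC_NS,
           "\" level=\"3\" version=\"1\" fbc:required=\"false\">"),
    paste0("  <model id=\"", esc(net$model_id), "\" fbc:strict=\"true\">"),
    "    <listOfCompartments>"
  )
  for (cid in unique(net$metabolites$compartment)) {
    lines <- c(lines, paste0("      <compartment id=\"", esc(cid),
                             "\" constant=\"true\"/>"))
  }
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    formula_attr <- if (is.na(m$formula)) "" else
      paste0(" fbc:chemicalFormula=\"", esc(m$formula), "\"")
    lines <- c(lines, paste0(
      "      <species id=\"", esc(m$id), "\" name=\"", esc(m$name),
      "\" compartment=\"", esc(m$compartment),
      "\" hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\"",
      " constant=\"false\"", formula_attr, "/>"))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (v in vals) {
    lines <- c(lines, paste0("      <parameter id=\"", par_id(v),
                             "\" value=\"", num(v),
                             "\" constant=\"true\"/>"))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    s <- net$stoichiometry[[r$id]]
    s <- s[s != 0]
    sbo <- if (r$id == net$biomass_reaction_id) {
      paste0(" sboTerm=\"", SBO_BIOMASS, "\"")
    } else if (r$is_exchange) {
      paste0(" sboTerm=\"", SBO_EXCHANGE, "\"")
    } else ""
    lines <- c(lines, paste0(
      "      <reaction id=\"", esc(r$id), "\" name=\"", esc(r$name),
      "\" reversible=\"", if (r$lower_bound < 0) "true" else "false",
      "\" fast=\"false\"", sbo,
      " fbc:lowerFluxBound=\"", par_id(r$lower_bound),
      "\" fbc:upperFluxBound=\"", par_id(r$upper_bound), "\">"))
    react <- s[s < 0]; prod <- s[s > 0]
    if (length(react)) {
      lines <- c(lines, "        <listOfReactants>")
      for (j in seq_along(react)) {
        lines <- c(lines, paste0(
          "          <speciesReference species=\"", esc(names(react)[j]),
          "\" stoichiometry=\"", num(-react[j]),
          "\" constant=\"true\"/>"))
      }
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>")
      for (j in seq_along(prod)) {
        lines <- c(lines, paste0(
          "          <speciesReference species=\"", esc(names(prod)[j]),
          "\" stoichiometry=\"", num(prod[j]),
          "\" constant=\"true\"/>"))
      }
      lines <- c(lines, "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(
    lines,
    "    </listOfReactions>",
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
    "        <fbc:listOfFluxObjectives>",
    paste0("          <fbc:fluxObjective fbc:reaction=\"",
           esc(net$objective_reaction_id), "\" fbc:coefficient=\"1\"/>"),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>"
  )
  writeLines(lines, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML file '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model, "xml_missing")) {
    stop("malformed SBML file '", path, "': no <model> element")
  }
  model_id <- xml2::xml_attr(model, "id")

  sp <- xml2::xml_find_all(model, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("malformed SBML file '", path, "': no species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    formula = xml2::xml_attr(sp, "fbc:chemicalFormula", ns = ns),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE
  )

  pars <- xml2::xml_find_all(model, ".//s:listOfParameters/s:parameter", ns)
  par_val <- as.numeric(xml2::xml_attr(pars, "value"))
  names(par_val) <- xml2::xml_attr(pars, "id")

  rx <- xml2::xml_find_all(model, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("malformed SBML file '", path, "': no reactions")
  rid <- xml2::xml_attr(rx, "id")
  sbo <- xml2::xml_attr(rx, "sboTerm")
  lb_ref <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns = ns)
  ub_ref <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns = ns)
  if (anyNA(lb_ref) || anyNA(ub_ref)) {
    bad <- rid[is.na(lb_ref) | is.na(ub_ref)]
    stop("reaction(s) without fbc flux bounds in '", path, "': ",
         paste(bad, collapse = ", "))
  }
  stoich <- vector("list", length(rx))
  for (i in seq_along(rx)) {
    s <- numeric(0)
    for (ref in xml2::xml_find_all(rx[[i]],
                                   "./s:listOfReactants/s:speciesReference",
                                   ns)) {
      s[xml2::xml_attr(ref, "species")] <-
        -as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(rx[[i]],
                                   "./s:listOfProducts/s:speciesReference",
                                   ns)) {
      m <- xml2::xml_attr(ref, "species")
      s[m] <- (if (m %in% names(s)) s[[m]] else 0) +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    stoich[[i]] <- s
  }
  names(stoich) <- rid
  n_species <- vapply(stoich, function(s) sum(s != 0), integer(1))
  is_exchange <- (!is.na(sbo) & sbo == SBO_EXCHANGE) |
    (startsWith(rid, "EX_") & n_species == 1L)
  rxns <- data.frame(
    id = rid,
    name = ifelse(is.na(xml2::xml_attr(rx, "name")), rid,
                  xml2::xml_attr(rx, "name")),
    lower_bound = unname(par_val[lb_ref]),
    upper_bound = unname(par_val[ub_ref]),
    is_exchange = is_exchange,
    stringsAsFactors = FALSE
  )

  obj_ref <- xml2::xml_find_first(
    model, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(obj_ref, "xml_missing")) {
    stop("model '", path, "' declares no flux objective")
  }
  objective_id <- xml2::xml_attr(obj_ref, "fbc:reaction", ns = ns)

  biomass_id <- rid[!is.na(sbo) & sbo == SBO_BIOMASS]
  if (!length(biomass_id)) biomass_id <- objective_id
  if (length(biomass_id) != 1L) {
    stop("model '", path, "' must designate exactly one biomass reaction")
  }

  metabolic_network(
    model_id = model_id,
    metabolites = mets,
    reactions = rxns,
    stoichiometry = stoich,
    biomass_reaction_id = biomass_id,
    objective_reaction_id = objective_id
  )
}
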