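## Model input/output.
##
## Two dialects:
##  * tabular — a reactions TSV (id, equation, lower, upper, gpr, subsystem,
##    kind) and a metabolites TSV (id, name, formula, charge, compartment),
##    plus a small key/value TSV carrying biomass/maintenance ids and
##    GAM/NGAM.  Files share a path prefix: <prefix>_reactions.tsv,
##    <prefix>_metabolites.tsv, <prefix>_model.tsv.
##  * sbml — SBML Level 3 Version 1 with the fbc version 2 package
##    (flux bounds as parameters, GPRs as fbc geneProductAssociations).

#' Read a constraint-based model
#'
#' @param path for \code{dialect = "sbml"} an SBML file; for
#'   \code{dialect = "tabular"} the path prefix of the three TSV files
#'   written by \code{\link{writeModel}}.
#' @param dialect \code{"sbml"} or \code{"tabular"}.
#' @return A \code{\linkS4class{MetabolicModel}}.
#' @seealso \code{\link{writeModel}}
#' @export
readModel <- function(path, dialect = c("sbml", "tabular")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") readModelTabular(path) else readModelSBML(path)
}

#' Write a constraint-based model
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param path output file (sbml) or path prefix (tabular).
#' @inheritParams readModel
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path, dialect = c("sbml", "tabular")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") writeModelTabular(model, path)
  else writeModelSBML(model, path)
  invisible(path)
}

tabularPaths <- function(prefix) {
  list(reactions = paste0(prefix, "_reactions.tsv"),
       metabolites = paste0(prefix, "_metabolites.tsv"),
       model = paste0(prefix, "_model.tsv"))
}

readModelTabular <- function(prefix) {
  p <- tabularPaths(prefix)
  for (f in unlist(p))
    if (!file.exists(f)) stop("missing model file: ", f)
  rxn <- utils::read.delim(p$reactions, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  met <- utils::read.delim(p$metabolites, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  kv <- utils::read.delim(p$model, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!all(c("key", "value") %in% names(kv)))
    stop("malformed model key/value file: ", p$model)
  getkv <- function(key) {
    v <- kv$value[kv$key == key]
    if (length(v) == 0L) NA_character_ else v[1]
  }
  rxn$gpr[is.na(rxn$gpr)] <- ""
  if (!is.null(rxn$subsystem)) rxn$subsystem[is.na(rxn$subsystem)] <- ""
  MetabolicModel(met, rxn,
                 biomassId = getkv("biomass_reaction"),
                 maintenanceId = getkv("maintenance_reaction"),
                 gam = as.numeric(getkv("gam")),
                 ngam = as.numeric(getkv("ngam")))
}

writeModelTabular <- function(model, prefix) {
  p <- tabularPaths(prefix)
  utils::write.table(model@reactions, p$reactions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model@metabolites, p$metabolites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  kv <- data.frame(
    key = c("biomass_reaction", "maintenance_reaction", "gam", "ngam"),
    value = c(model@biomassId, model@maintenanceId,
              as.character(model@gam), as.character(model@ngam)))
  utils::write.table(kv, p$model, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

## ---- SBML Level 3 + fbc ----------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

## SBML ids must match [A-Za-z_][A-Za-z0-9_]*; metabolite/reaction ids in
## model files follow the usual M_/R_/G_ prefix convention with '-' mangled.
sbmlId <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "__", id))

readModelSBML <- function(path) {
  if (!file.exists(path)) stop("missing model file: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)

  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing")) stop("not an SBML L3 document: ", path)

  ## species
  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  if (length(sp) == 0L) stop("SBML model has no species: ", path)
  unprefix <- function(x, pre) sub(paste0("^", pre), "", x)
  met <- data.frame(
    id = unprefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = as.integer(xml2::xml_attr(sp, "charge")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  met$name[is.na(met$name)] <- met$id[is.na(met$name)]

  ## flux-bound parameters
  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))

  ## gene products
  gps <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                            ns)
  gpmap <- stats::setNames(xml2::xml_attr(gps, "label"),
                           xml2::xml_attr(gps, "id"))

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0L) stop("SBML model has no reactions: ", path)
  rxn <- do.call(rbind, lapply(rx, function(r) {
    rid <- unprefix(xml2::xml_attr(r, "id"), "R_")
    getRefs <- function(which) {
      refs <- xml2::xml_find_all(r, paste0("./s:", which, "/s:speciesReference"),
                                 ns)
      if (length(refs) == 0L) return(numeric())
      stats::setNames(as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      unprefix(xml2::xml_attr(refs, "species"), "M_"))
    }
    lhs <- getRefs("listOfReactants")
    rhs <- getRefs("listOfProducts")
    lbid <- xml2::xml_attr(r, "lowerFluxBound")
    ubid <- xml2::xml_attr(r, "upperFluxBound")
    lower <- if (!is.na(lbid) && lbid %in% names(parval)) parval[[lbid]] else -1000
    upper <- if (!is.na(ubid) && ubid %in% names(parval)) parval[[ubid]] else 1000
    gpa <- xml2::xml_find_first(r, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      tree <- sbmlGPATree(xml2::xml_child(gpa), gpmap, ns)
      deparseGPR(tree)
    }
    fmt <- function(v) paste(
      ifelse(v == 1, names(v), paste(format(v, scientific = FALSE), names(v))),
      collapse = " + ")
    eq <- paste(fmt(lhs), if (lower < 0) "<=>" else "->", fmt(rhs))
    data.frame(id = rid, equation = trimws(eq), lower = lower, upper = upper,
               gpr = gpr, subsystem = "", stringsAsFactors = FALSE)
  }))

  ## objective -> biomass reaction
  objref <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  biomassId <- if (inherits(objref, "xml_missing")) NA_character_ else
    unprefix(xml2::xml_attr(objref, "reaction"), "R_")

  annotKv <- function(key) {
    nd <- xml2::xml_find_first(
      mdl, paste0(".//s:annotation//*[local-name() = '", key, "']"), ns)
    if (inherits(nd, "xml_missing")) NA_character_ else xml2::xml_text(nd)
  }
  MetabolicModel(met, rxn, biomassId = biomassId,
                 maintenanceId = annotKv("maintenanceReaction"),
                 gam = as.numeric(annotKv("gam")),
                 ngam = as.numeric(annotKv("ngam")))
}

sbmlGPATree <- function(node, gpmap, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lab <- unname(gpmap[ref])
    return(if (length(lab) == 0L || is.na(lab)) ref else lab)
  }
  kids <- xml2::xml_children(node)
  args <- lapply(kids, sbmlGPATree, gpmap = gpmap, ns = ns)
  if (nm == "and") list(op = "and", args = args)
  else if (nm == "or") list(op = "or", args = args)
  else stop("unsupported geneProductAssociation node: ", nm)
}

writeModelSBML <- function(model, path) {
  rxn <- model@reactions
  met <- model@metabolites
  S <- model@stoichiometry
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="model" fbc:strict="true">')
  w('    <annotation>')
  w('      <modelParameters xmlns="https://example.org/fluxfit">')
  if (!is.na(model@maintenanceId))
    w('        <maintenanceReaction>', esc(model@maintenanceId),
      '</maintenanceReaction>')
  if (!is.na(model@gam)) w('        <gam>', model@gam, '</gam>')
  if (!is.na(model@ngam)) w('        <ngam>', model@ngam, '</ngam>')
  w('      </modelParameters>')
  w('    </annotation>')

  comps <- unique(met$compartment)
  w('    <listOfCompartments>')
  for (cp in comps)
    w('      <compartment id="', cp, '" constant="true"/>')
  w('    </listOfCompartments>')

  w('    <listOfSpecies>')
  for (i in seq_len(nrow(met))) {
    extra <- ""
    if (!is.na(met$formula[i]))
      extra <- paste0(extra, ' fbc:chemicalFormula="', met$formula[i], '"')
    if (!is.na(met$charge[i]))
      extra <- paste0(extra, ' fbc:charge="', met$charge[i], '"')
    w('      <species id="', sbmlId("M_", met$id[i]), '" name="',
      esc(met$name[i]), '" compartment="', met$compartment[i],
      '" hasOnlySubstanceUnits="false" boundaryCondition="false" ',
      'constant="false"', extra, '/>')
  }
  w('    </listOfSpecies>')

  ## bound parameters, deduplicated by value
  vals <- sort(unique(c(rxn$lower, rxn$upper)))
  pid <- function(v) paste0("fb_", match(v, vals))
  w('    <listOfParameters>')
  for (v in vals)
    w('      <parameter id="', pid(v), '" value="',
      format(v, scientific = FALSE), '" constant="true"/>')
  w('    </listOfParameters>')

  w('    <listOfReactions>')
  for (j in seq_len(nrow(rxn))) {
    col <- S[, j]
    lhs <- which(col < 0)
    rhs <- which(col > 0)
    w('      <reaction id="', sbmlId("R_", rxn$id[j]),
      '" reversible="', tolower(rxn$lower[j] < 0),
      '" fast="false" fbc:lowerFluxBound="', pid(rxn$lower[j]),
      '" fbc:upperFluxBound="', pid(rxn$upper[j]), '">')
    if (length(lhs)) {
      w('        <listOfReactants>')
      for (i in lhs)
        w('          <speciesReference species="',
          sbmlId("M_", rownames(S)[i]), '" stoichiometry="',
          format(-col[i], scientific = FALSE), '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(rhs)) {
      w('        <listOfProducts>')
      for (i in rhs)
        w('          <speciesReference species="',
          sbmlId("M_", rownames(S)[i]), '" stoichiometry="',
          format(col[i], scientific = FALSE), '" constant="true"/>')
      w('        </listOfProducts>')
    }
    tree <- model@gprTrees[[rxn$id[j]]]
    if (!is.null(tree)) {
      w('        <fbc:geneProductAssociation>')
      writeGPANode(tree, w, indent = "          ")
      w('        </fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')

  if (length(model@genes)) {
    w('    <fbc:listOfGeneProducts>')
    for (g in model@genes)
      w('      <fbc:geneProduct fbc:id="', sbmlId("G_", g),
        '" fbc:label="', esc(g), '"/>')
    w('    </fbc:listOfGeneProducts>')
  }

  if (!is.na(model@biomassId)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    w('          <fbc:fluxObjective fbc:reaction="',
      sbmlId("R_", model@biomassId), '" fbc:coefficient="1"/>')
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  w('  </model>')
  w('</sbml>')
}

writeGPANode <- function(tree, w, indent) {
  if (is.character(tree)) {
    w(indent, '<fbc:geneProductRef fbc:geneProduct="',
      sbmlId("G_", tree), '"/>')
    return(invisible(NULL))
  }
  tag <- paste0("fbc:", tree$op)
  w(indent, "<", tag, ">")
  for (a in tree$args) writeGPANode(a, w, paste0(indent, "  "))
  w(indent, "</", tag, ">")
}
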