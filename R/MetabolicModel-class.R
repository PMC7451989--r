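#' MetabolicModel: a constraint-based metabolic network
#'
#' S4 container for a genome-scale (or toy) stoichiometric model: a sparse
#' stoichiometric matrix S (metabolites x reactions), flux bounds in
#' mmol/gDW/h, gene-protein-reaction (GPR) boolean associations, and the
#' biomass / ATP-maintenance bookkeeping used by flux balance analysis.
#' Growth-associated maintenance (GAM, mmol ATP/gDW) is part of the biomass
#' equation stoichiometry; non-growth-associated maintenance (NGAM, mmol
#' ATP/gDW/h) is encoded as the lower bound of the maintenance reaction.
#'
#' @slot stoichiometry sparse \code{Matrix} S, metabolites x reactions,
#'   with dimnames.
#' @slot reactions data.frame with columns \code{id}, \code{lower},
#'   \code{upper}, \code{gpr} (string form), \code{subsystem}, \code{kind}
#'   (one of metabolic, transport, exchange, sink, biomass, maintenance).
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{formula}, \code{charge}, \code{compartment}.
#' @slot genes character vector of gene ids.
#' @slot gprTrees named list of parsed GPR trees (NULL for no GPR).
#' @slot biomassId,maintenanceId reaction ids (\code{NA} if absent).
#' @slot gam,ngam maintenance ATP parameters (may be \code{NA}).
#'
#' @aliases MetabolicModel-class
#' @export
setClass("MetabolicModel",
  slots = c(
    stoichiometry = "Matrix",
    reactions = "data.frame",
    metabolites = "data.frame",
    genes = "character",
    gprTrees = "list",
    biomassId = "character",
    maintenanceId = "character",
    gam = "numeric",
    ngam = "numeric"
  )
)

REACTION_KINDS <- c("metabolic", "transport", "exchange", "sink",
                    "biomass", "maintenance")

setValidity("MetabolicModel", function(object) {
  S <- object@stoichiometry
  rxn <- object@reactions
  met <- object@metabolites
  msgs <- character()
  if (nrow(rxn) == 0L)
    msgs <- c(msgs, "model has no reactions")
  if (anyDuplicated(rxn$id))
    msgs <- c(msgs, "duplicated reaction ids")
  if (anyDuplicated(met$id))
    msgs <- c(msgs, "duplicated metabolite ids")
  if (!identical(dim(S), c(nrow(met), nrow(rxn))))
    msgs <- c(msgs, "stoichiometric matrix dimensions do not match")
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
    msgs <- c(msgs, "stoichiometric matrix dimnames do not match ids")
  if (any(rxn$lower > rxn$upper))
    msgs <- c(msgs, "reaction with lower bound above upper bound")
  if (!all(rxn$kind %in% REACTION_KINDS))
    msgs <- c(msgs, "unknown reaction kind")
  if (!is.na(object@biomassId) && !(object@biomassId %in% rxn$id))
    msgs <- c(msgs, "biomass reaction id not present")
  if (!is.na(object@maintenanceId) && !(object@maintenanceId %in% rxn$id))
    msgs <- c(msgs, "maintenance reaction id not present")
  one_met <- rxn$kind %in% c("exchange", "sink")
  if (any(one_met)) {
    nmet <- Matrix::colSums(S[, one_met, drop = FALSE] != 0)
    if (any(nmet != 1L))
      msgs <- c(msgs, "exchange/sink reaction touching != 1 metabolite")
  }
  gg <- unique(unlist(lapply(object@gprTrees, gprGenes)))
  if (length(setdiff(gg, object@genes)))
    msgs <- c(msgs,
              paste("GPR references unknown gene(s):",
                    paste(setdiff(gg, object@genes), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a MetabolicModel from component tables
#'
#' @param metabolites data.frame with columns \code{id} and optionally
#'   \code{name}, \code{formula}, \code{charge}, \code{compartment}.
#' @param reactions data.frame with columns \code{id}, \code{equation}
#'   (e.g. \code{"glc_c + atp_c -> g6p_c + adp_c"}; use \code{"<=>"} for
#'   reversible and a one-sided equation for exchange/sink reactions) and
#'   optionally \code{lower}, \code{upper}, \code{gpr}, \code{subsystem},
#'   \code{kind}. Missing bounds default to \code{[0, 1000]} for
#'   \code{"->"} equations and \code{[-1000, 1000]} for \code{"<=>"}.
#' @param biomassId,maintenanceId reaction ids (\code{NA} if absent).
#' @param gam,ngam maintenance ATP parameters. When \code{ngam} is given and
#'   a maintenance reaction exists, its lower bound is set to \code{ngam}.
#' @return A validated \code{\linkS4class{MetabolicModel}}.
#' @examples
#' mets <- data.frame(id = c("a_c", "b_c"))
#' rxns <- data.frame(id = c("EX_a", "R1", "EX_b"),
#'                    equation = c("a_c <=>", "a_c -> b_c", "b_c <=>"))
#' m <- MetabolicModel(mets, rxns)
#' @export
MetabolicModel <- function(metabolites, reactions,
                           biomassId = NA_character_,
                           maintenanceId = NA_character_,
                           gam = NA_real_, ngam = NA_real_) {
  biomassId <- as.character(biomassId)
  maintenanceId <- as.character(maintenanceId)
  gam <- as.numeric(gam)
  ngam <- as.numeric(ngam)
  metabolites <- normalizeMetTable(metabolites)
  rxn <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!all(c("id", "equation") %in% names(rxn)))
    stop("reactions table needs 'id' and 'equation' columns")
  if (nrow(rxn) == 0L)
    stop("model has no reactions")
  if (anyDuplicated(rxn$id))
    stop("duplicated reaction id: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))

  eqs <- lapply(seq_len(nrow(rxn)), function(i) {
    parseEquation(rxn$equation[i], rxn$id[i])
  })
  rev_eq <- vapply(eqs, `[[`, logical(1), "reversible")
  if (is.null(rxn$lower)) rxn$lower <- NA_real_
  if (is.null(rxn$upper)) rxn$upper <- NA_real_
  rxn$lower <- as.numeric(ifelse(is.na(rxn$lower),
                                 ifelse(rev_eq, -1000, 0), rxn$lower))
  rxn$upper <- as.numeric(ifelse(is.na(rxn$upper), 1000, rxn$upper))
  if (is.null(rxn$gpr)) rxn$gpr <- ""
  rxn$gpr[is.na(rxn$gpr)] <- ""
  if (is.null(rxn$subsystem)) rxn$subsystem <- ""

  ## stoichiometric matrix
  allmets <- metabolites$id
  trip <- do.call(rbind, lapply(seq_along(eqs), function(i) {
    st <- eqs[[i]]$stoich
    unknown <- setdiff(names(st), allmets)
    if (length(unknown))
      stop("reaction ", rxn$id[i], " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    data.frame(i = match(names(st), allmets), j = i, x = unname(st))
  }))
  S <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                            dims = c(length(allmets), nrow(rxn)),
                            dimnames = list(allmets, rxn$id))

  if (is.null(rxn$kind) || all(is.na(rxn$kind))) {
    rxn$kind <- inferReactionKinds(rxn$id, S, metabolites,
                                   biomassId, maintenanceId)
  } else {
    miss <- is.na(rxn$kind) | !nzchar(rxn$kind)
    if (any(miss))
      rxn$kind[miss] <- inferReactionKinds(rxn$id[miss],
                                           S[, miss, drop = FALSE],
                                           metabolites,
                                           biomassId, maintenanceId)
  }

  trees <- lapply(rxn$gpr, parseGPR)
  names(trees) <- rxn$id
  genes <- sort(unique(unlist(lapply(trees, gprGenes))))

  if (!is.na(ngam) && !is.na(maintenanceId) && maintenanceId %in% rxn$id)
    rxn$lower[rxn$id == maintenanceId] <- ngam

  rownames(rxn) <- NULL
  methods::new("MetabolicModel",
      stoichiometry = S,
      reactions = rxn[, c("id", "equation", "lower", "upper", "gpr",
                          "subsystem", "kind")],
      metabolites = metabolites,
      genes = genes,
      gprTrees = trees,
      biomassId = biomassId,
      maintenanceId = maintenanceId,
      gam = gam, ngam = ngam)
}

normalizeMetTable <- function(metabolites) {
  met <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  if (!"id" %in% names(met))
    stop("metabolites table needs an 'id' column")
  if (is.null(met$name)) met$name <- met$id
  if (is.null(met$formula)) met$formula <- NA_character_
  if (is.null(met$charge)) met$charge <- NA_integer_
  if (is.null(met$compartment))
    met$compartment <- compartmentOf(met$id)
  rownames(met) <- NULL
  met[, c("id", "name", "formula", "charge", "compartment")]
}

## "glc_c" -> "c"; ids without a compartment suffix map to "c"
compartmentOf <- function(ids) {
  comp <- sub(".*_([a-z][a-z0-9]?)$", "\\1", ids)
  ifelse(comp == ids, "c", comp)
}

## strip a trailing compartment tag: "glc_c" -> "glc"
speciesOf <- function(ids) sub("_([a-z][a-z0-9]?)$", "", ids)

## Parse "2 a_c + b_c -> c_c" into list(stoich = named numeric, reversible).
parseEquation <- function(eq, id = "?") {
  if (is.na(eq) || !nzchar(trimws(eq)))
    stop("reaction ", id, ": empty equation")
  rev <- grepl("<=>", eq, fixed = TRUE)
  sides <- strsplit(eq, "<=>|<?->", perl = TRUE)[[1]]
  if (length(sides) > 2L || !grepl("<=>|->", eq))
    stop("reaction ", id, ": cannot parse equation '", eq, "'")
  parseSide <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- strsplit(s, "\\s+\\+\\s+")[[1]]
    out <- numeric()
    for (tm in terms) {
      tm <- trimws(tm)
      mres <- regmatches(tm, regexec("^([0-9.]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S+)$", tm))[[1]]
      if (length(mres) == 0L)
        stop("reaction ", id, ": bad term '", tm, "'")
      coef <- if (nzchar(trimws(mres[2]))) as.numeric(mres[2]) else 1
      met <- mres[3]
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + coef
    }
    out
  }
  lhs <- parseSide(sides[1])
  rhs <- if (length(sides) == 2L) parseSide(sides[2]) else numeric()
  st <- -lhs
  for (metname in names(rhs))
    st[metname] <- (if (metname %in% names(st)) st[[metname]] else 0) + rhs[[metname]]
  st <- st[st != 0]
  if (length(st) == 0L)
    stop("reaction ", id, ": equation has empty net stoichiometry")
  list(stoich = st, reversible = rev)
}

## Kind inference: id-prefix conventions with a structural fallback.
inferReactionKinds <- function(ids, S, metabolites, biomassId, maintenanceId) {
  vapply(seq_along(ids), function(k) {
    id <- ids[k]
    if (!is.na(biomassId) && id == biomassId) return("biomass")
    if (!is.na(maintenanceId) && id == maintenanceId) return("maintenance")
    if (grepl("^EX_", id)) return("exchange")
    if (grepl("^(SINK_|DM_)", id)) return("sink")
    part <- rownames(S)[S[, k] != 0]
    comps <- unique(compartmentOf(part))
    if (length(comps) > 1L &&
        anyDuplicated(speciesOf(part)))
      return("transport")
    "metabolic"
  }, character(1))
}

## ---- accessors -------------------------------------------------------------

#' @describeIn MetabolicModel-class reaction table accessor
#' @param object,x a \code{MetabolicModel}.
#' @export
reactions <- function(x) x@reactions

#' @describeIn MetabolicModel-class metabolite table accessor
#' @export
metabolites <- function(x) x@metabolites

#' @describeIn MetabolicModel-class gene id accessor
#' @export
genes <- function(x) x@genes

#' @describeIn MetabolicModel-class sparse stoichiometric matrix accessor
#' @export
stoichiometry <- function(x) x@stoichiometry

#' @describeIn MetabolicModel-class biomass reaction id (\code{NA} if unset)
#' @export
biomassReaction <- function(x) x@biomassId

#' @describeIn MetabolicModel-class parsed GPR tree for one reaction
#' @param reaction a reaction id.
#' @export
gprTree <- function(x, reaction) {
  if (!reaction %in% x@reactions$id) stop("unknown reaction: ", reaction)
  x@gprTrees[[reaction]]
}

#' Set flux bounds on reactions
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param ids reaction ids.
#' @param lower,upper replacement bounds (recycled; \code{NA} keeps the
#'   current value).
#' @return The modified model.
#' @export
setBounds <- function(model, ids, lower = NA, upper = NA) {
  idx <- match(ids, model@reactions$id)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  lower <- rep_len(as.numeric(lower), length(idx))
  upper <- rep_len(as.numeric(upper), length(idx))
  keepl <- is.na(lower)
  keepu <- is.na(upper)
  model@reactions$lower[idx][!keepl] <- lower[!keepl]
  model@reactions$upper[idx][!keepu] <- upper[!keepu]
  if (any(model@reactions$lower > model@reactions$upper))
    stop("setBounds would leave lower > upper")
  model
}

setMethod("show", "MetabolicModel", function(object) {
  rxn <- object@reactions
  cat("MetabolicModel:", nrow(rxn), "reactions,",
      nrow(object@metabolites), "metabolites,",
      length(object@genes), "genes\n")
  tab <- table(factor(rxn$kind, levels = REACTION_KINDS))
  cat("  kinds:", paste(names(tab)[tab > 0], tab[tab > 0],
                        sep = "=", collapse = ", "), "\n")
  if (!is.na(object@biomassId))
    cat("  biomass:", object@biomassId,
        if (!is.na(object@gam)) sprintf("(GAM %.4g mmol ATP/gDW)", object@gam),
        "\n")
  if (!is.na(object@maintenanceId))
    cat("  maintenance:", object@maintenanceId,
        if (!is.na(object@ngam)) sprintf("(NGAM %.4g mmol ATP/gDW/h)",
                                         object@ngam), "\n")
})
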