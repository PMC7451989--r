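## Synthetic data with planted ground truth.
##
## The generator builds toy metabolic networks whose flux-coupling module
## structure is known by construction, and simulates pooled-fitness
## matrices with the statistical structure the analysis assumes:
## module-level conditional essentiality, per-gene Gaussian noise,
## mixed-genotype score attenuation, barcode mis-mapping, missing mutants,
## and an orphan reaction whose true gene appears only in the fitness data.

#' Generate a toy metabolic model with planted coupling structure
#'
#' Builds \code{nPathways} linear pathways, each a chain of irreversible
#' (optionally some reversible) reactions ending in a biomass precursor,
#' fed either from a shared hub metabolite or from per-pathway substrates,
#' plus substrate exchanges and a biomass reaction consuming one unit of
#' each precursor. Each chain reaction carries a single dedicated gene,
#' except planted orphan reactions (no GPR) and planted isozyme reactions
#' (an OR of two genes).
#'
#' The ground truth records the expected fully coupled modules under the
#' standard coupling protocol (per-precursor sinks added, exchanges opened,
#' aggregate biomass disabled): each pathway's chain components, its
#' precursor sink, and — when pathways have private substrates — the
#' pathway's transporter.
#'
#' @param nPathways number of linear pathways.
#' @param pathwayLength chain length per pathway (scalar or vector).
#' @param sharedHub feed all pathways from one hub metabolite (TRUE) or
#'   give each pathway its own substrate and transporter (FALSE).
#' @param orphanAt optional data.frame (\code{pathway}, \code{position})
#'   marking reactions that get no GPR; each receives a hidden true gene
#'   in the ground truth.
#' @param isozymeAt optional data.frame (\code{pathway}, \code{position})
#'   marking reactions carrying two isozyme genes (OR).
#' @param reversibleFraction fraction of interior chain reactions made
#'   reversible (default 0; reversibility removes exact full coupling
#'   through the loop, so the planted-partition guarantee holds at 0).
#' @param seed integer seed (only used when \code{reversibleFraction > 0}).
#' @return list with \code{model} (a
#'   \code{\linkS4class{MetabolicModel}}, growth-feasible by construction)
#'   and \code{truth}: \code{pathwayReactions}, \code{pathwayGenes},
#'   \code{modules} (expected fully coupled component sets),
#'   \code{orphans} (data.frame \code{reaction}, \code{gene}),
#'   \code{isozymes}, \code{precursors}.
#' @export
makeToyModel <- function(nPathways = 5, pathwayLength = 4,
                         sharedHub = TRUE, orphanAt = NULL,
                         isozymeAt = NULL, reversibleFraction = 0,
                         seed = 1) {
  if (nPathways < 1) stop("need at least one pathway")
  len <- rep_len(pathwayLength, nPathways)
  if (any(len < 1)) stop("pathway length must be >= 1")

  mets <- list(); rxns <- list()
  addMet <- function(id) mets[[length(mets) + 1L]] <<- data.frame(
    id = id, formula = "X", charge = 0L, stringsAsFactors = FALSE)
  addRxn <- function(id, eq, lower = 0, upper = 1000, gpr = "") {
    rxns[[length(rxns) + 1L]] <<- data.frame(
      id = id, equation = eq, lower = lower, upper = upper, gpr = gpr,
      stringsAsFactors = FALSE)
  }

  if (sharedHub) {
    addMet("sub_e"); addMet("hub_c")
    addRxn("EX_sub_e", "sub_e <=>", lower = -10)
    addRxn("HUBT", "sub_e -> hub_c", gpr = "gHUB")
  }

  old <- withSeed(seed); on.exit(restoreSeed(old))
  pathwayReactions <- list(); pathwayGenes <- list()
  modules <- list(); orphans <- list(); isozymes <- character()
  precursors <- character()

  for (p in seq_len(nPathways)) {
    chain <- character(); genesP <- character()
    if (!sharedHub) {
      sub_e <- sprintf("sub%d_e", p); sub_c <- sprintf("sub%d_c", p)
      addMet(sub_e); addMet(sub_c)
      addRxn(sprintf("EX_sub%d_e", p), paste(sub_e, "<=>"), lower = -10)
      tid <- sprintf("T%d", p)
      addRxn(tid, paste(sub_e, "->", sub_c), gpr = sprintf("gT%d", p))
      chain <- c(chain, tid); genesP <- c(genesP, sprintf("gT%d", p))
      prev <- sub_c
    } else {
      prev <- "hub_c"
    }
    for (i in seq_len(len[p])) {
      metNext <- if (i == len[p]) sprintf("prec%d_c", p)
                 else sprintf("m%d_%d_c", p, i)
      addMet(metNext)
      rid <- sprintf("R%d_%d", p, i)
      isOrphan <- !is.null(orphanAt) &&
        any(orphanAt$pathway == p & orphanAt$position == i)
      isIso <- !is.null(isozymeAt) &&
        any(isozymeAt$pathway == p & isozymeAt$position == i)
      gpr <- if (isOrphan) "" else if (isIso)
        sprintf("g%d_%da or g%d_%db", p, i, p, i) else sprintf("g%d_%d", p, i)
      rev <- reversibleFraction > 0 && i > 1 && i < len[p] &&
        stats::runif(1) < reversibleFraction
      addRxn(rid, paste(prev, if (rev) "<=>" else "->", metNext),
             lower = if (rev) -1000 else 0, gpr = gpr)
      chain <- c(chain, rid)
      if (isOrphan) {
        orphans[[length(orphans) + 1L]] <- data.frame(
          reaction = rid, gene = sprintf("orph%d_%d", p, i),
          pathway = p, stringsAsFactors = FALSE)
      } else if (isIso) {
        isozymes <- c(isozymes, sprintf("g%d_%da", p, i),
                      sprintf("g%d_%db", p, i))
      } else {
        genesP <- c(genesP, sprintf("g%d_%d", p, i))
      }
      prev <- metNext
    }
    prec <- sprintf("prec%d_c", p)
    precursors <- c(precursors, prec)
    pathwayReactions[[p]] <- chain
    pathwayGenes[[p]] <- genesP
    modules[[p]] <- sort(c(paste0(chain, "_f"), paste0("SINK_", prec, "_f")))
  }

  addRxn("BIOMASS", paste(paste(precursors, collapse = " + "), "->"))
  metTab <- do.call(rbind, mets)
  rxnTab <- do.call(rbind, rxns)
  model <- MetabolicModel(metTab, rxnTab, biomassId = "BIOMASS")
  fd <- fba(model)
  if (fd@status != "optimal" || fd@objective <= 0)
    stop("generated toy model is not growth-feasible")

  orphans <- if (length(orphans)) do.call(rbind, orphans)
    else data.frame(reaction = character(), gene = character(),
                    pathway = integer())
  list(model = model,
       truth = list(pathwayReactions = pathwayReactions,
                    pathwayGenes = pathwayGenes,
                    modules = modules,
                    orphans = orphans,
                    isozymes = isozymes,
                    precursors = precursors))
}

#' Prepare a model for coupling analysis (sinks in, biomass out)
#'
#' Standard coupling protocol: add per-precursor sinks (and any terminal
#' product sinks), open every exchange, disable the aggregate biomass
#' reaction so that modules attach to individual precursors, and split
#' into directional components.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param biomassComponents,terminalProducts metabolite ids receiving sinks
#'   (default: metabolites consumed by the biomass reaction).
#' @return A \code{\linkS4class{ComponentModel}}.
#' @export
couplingModel <- function(model,
                          biomassComponents = biomassPrecursors(model),
                          terminalProducts = character()) {
  model <- augmentWithSinks(model, biomassComponents, terminalProducts)
  if (!is.na(model@biomassId)) {
    keep <- model@reactions$id != model@biomassId
    model@reactions <- model@reactions[keep, , drop = FALSE]
    model@stoichiometry <- model@stoichiometry[, keep, drop = FALSE]
    model@gprTrees <- model@gprTrees[keep]
    model@biomassId <- NA_character_
  }
  splitReversible(model)
}

#' Metabolites consumed by the biomass reaction
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @return Character vector of biomass precursor metabolite ids.
#' @export
biomassPrecursors <- function(model) {
  if (is.na(model@biomassId)) return(character())
  col <- model@stoichiometry[, model@biomassId]
  rownames(model@stoichiometry)[col < 0]
}

#' Simulate a pooled mutant fitness matrix with planted structure
#'
#' For each experiment, each pathway module is essential with probability
#' \code{pEssential}; genes of an essential module draw their score from
#' \code{Normal(essentialMean, essentialSD)} (a strong fitness defect on
#' the log2 scale), all other scores from \code{Normal(0, neutralSD)};
#' per-gene noise \code{Normal(0, geneNoiseSD)} is added on top. Isozyme
#' genes are never essential (the partner isozyme covers the deletion).
#' A fraction of mutants carry mixed genotypes (wild-type plus disrupted
#' copies) and have their scores multiplied by \code{attenuation},
#' shrinking the apparent defect toward zero; a fraction are mis-mapped
#' and inherit another random gene's score trajectory; a fraction are
#' missing from the matrix entirely. Orphan genes (from the toy model's
#' ground truth) follow their pathway's essentiality pattern but are
#' absent from the model's GPRs — the target of cofitness-based candidate
#' ranking. Background genes pad the matrix to \code{nGenes}.
#'
#' @param toy result of \code{\link{makeToyModel}}.
#' @param nGenes total genes in the matrix (>= model mutant genes).
#' @param nExperiments number of pooled experiments.
#' @param pEssential per-experiment probability a module is essential.
#' @param essentialMean,essentialSD essential-effect distribution (log2).
#' @param neutralSD spread of neutral scores.
#' @param geneNoiseSD per-gene measurement noise.
#' @param mixedFraction,attenuation mixed-genotype mutant fraction and
#'   score attenuation factor in (0, 1].
#' @param mismappedFraction fraction of mutants with mis-mapped barcodes
#'   (they inherit another random gene's trajectory). Default 1%:
#'   mis-mapping is the rarest corruption mode in sequence-verified
#'   barcoded libraries, well below the mixed-genotype rate.
#' @param missingFraction fraction of mutants absent from the matrix.
#' @param anaerobicFraction fraction of experiments flagged anaerobic.
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @return list with \code{fitness} (a
#'   \code{\linkS4class{FitnessMatrix}}) and \code{truth} (the toy ground
#'   truth extended with \code{essential} indicator matrix, \code{mixed},
#'   \code{mismapped}, \code{missing}, \code{moduleGenes}).
#' @export
simulateFitness <- function(toy, nGenes = 200, nExperiments = 100,
                            pEssential = 0.3, essentialMean = -4,
                            essentialSD = 0.5, neutralSD = 0.3,
                            geneNoiseSD = 0.2, mixedFraction = 0.05,
                            attenuation = 0.2, mismappedFraction = 0.01,
                            missingFraction = 0.05,
                            anaerobicFraction = 0.25, seed = 1) {
  stopifnot(pEssential >= 0, pEssential <= 1,
            attenuation > 0, attenuation <= 1,
            mixedFraction >= 0, mixedFraction <= 1,
            missingFraction >= 0, missingFraction < 1)
  truth <- toy$truth
  nP <- length(truth$pathwayGenes)
  ## module gene sets as seen by the fitness data: chain genes + orphan gene
  moduleGenes <- lapply(seq_len(nP), function(p) {
    og <- truth$orphans$gene[truth$orphans$pathway == p]
    c(truth$pathwayGenes[[p]], og)
  })
  modelGenes <- unique(c(unlist(moduleGenes), truth$isozymes))
  if (nGenes < length(modelGenes))
    stop("nGenes smaller than the number of model mutant genes")
  bg <- sprintf("bg%04d", seq_len(nGenes - length(modelGenes)))
  geneIds <- c(modelGenes, bg)

  old <- withSeed(seed); on.exit(restoreSeed(old))
  expIds <- sprintf("exp%03d", seq_len(nExperiments))
  essential <- matrix(stats::rbinom(nP * nExperiments, 1, pEssential) == 1,
                      nP, nExperiments,
                      dimnames = list(paste0("module", seq_len(nP)), expIds))

  sc <- matrix(stats::rnorm(length(geneIds) * nExperiments, 0, neutralSD),
               length(geneIds), nExperiments,
               dimnames = list(geneIds, expIds))
  for (p in seq_len(nP)) {
    hit <- essential[p, ]
    gset <- moduleGenes[[p]]
    if (any(hit))
      sc[gset, hit] <- matrix(
        stats::rnorm(length(gset) * sum(hit), essentialMean, essentialSD),
        length(gset), sum(hit))
  }
  ## mixed genotypes attenuate the phenotype signal itself; measurement
  ## noise is added afterwards at full scale (otherwise attenuation would
  ## be a pure rescaling, invisible to correlation)
  nG <- length(geneIds)
  mixed <- sample(geneIds, round(mixedFraction * nG))
  sc[mixed, ] <- sc[mixed, , drop = FALSE] * attenuation
  sc <- sc + matrix(stats::rnorm(length(sc), 0, geneNoiseSD),
                    nrow(sc), ncol(sc))
  ## orphan genes are the planted recovery targets: the ground truth
  ## asserts they are present and correctly mapped, so they are exempt
  ## from the mis-mapping and missing-mutant draws (attenuation above
  ## still applies — a mixed-genotype orphan merely has a weaker signal)
  protected <- truth$orphans$gene
  mismapped <- sample(setdiff(geneIds, c(mixed, protected)),
                      round(mismappedFraction * nG))
  for (g in mismapped)
    sc[g, ] <- sc[sample(setdiff(geneIds, g), 1), ]
  missing <- sample(setdiff(geneIds, c(mixed, mismapped, protected)),
                    round(missingFraction * nG))
  sc <- sc[!rownames(sc) %in% missing, , drop = FALSE]

  md <- data.frame(experiment = expIds,
                   anaerobic = stats::runif(nExperiments) < anaerobicFraction,
                   medium = "synthetic-minimal")
  fm <- FitnessMatrix(sc, md)
  truth$essential <- essential
  truth$moduleGenes <- moduleGenes
  truth$mixed <- mixed
  truth$mismapped <- mismapped
  truth$missing <- missing
  list(fitness = fm, truth = truth)
}
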