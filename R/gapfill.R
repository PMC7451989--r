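#' Add reactions (and metabolites) to a model
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param newReactions data.frame in the format accepted by
#'   \code{\link{MetabolicModel}} (\code{id}, \code{equation}, optional
#'   bounds/gpr/subsystem/kind).
#' @param newMetabolites optional data.frame of metabolites not yet in the
#'   model.
#' @return The extended model.
#' @export
addReactions <- function(model, newReactions, newMetabolites = NULL) {
  met <- model@metabolites
  if (!is.null(newMetabolites)) {
    nm <- normalizeMetTable(newMetabolites)
    nm <- nm[!nm$id %in% met$id, , drop = FALSE]
    met <- rbind(met, nm)
  }
  old <- model@reactions
  new <- as.data.frame(newReactions, stringsAsFactors = FALSE)
  for (cn in setdiff(names(old), names(new))) new[[cn]] <- NA
  dup <- intersect(new$id, old$id)
  if (length(dup)) stop("reaction id(s) already present: ",
                        paste(dup, collapse = ", "))
  MetabolicModel(met, rbind(old, new[, names(old)]),
                 biomassId = model@biomassId,
                 maintenanceId = model@maintenanceId,
                 gam = model@gam, ngam = model@ngam)
}

GAPFILL_GROWTH <- 1e-3

#' Minimal-additions gap filling
#'
#' Given a model that cannot grow, finds a smallest set of candidate
#' reactions whose activation restores growth, by solving a mixed-integer
#' program: binary indicators gate the candidate fluxes and the indicator
#' sum is minimised subject to steady-state balance and a growth threshold.
#' The candidate pool may contain universal ("template") reactions or
#' secretion reactions (sinks/exchanges), mirroring the use of gap filling
#' to diagnose missing secretion routes.
#'
#' @param model a \code{\linkS4class{MetabolicModel}} with zero maximal
#'   growth (a growing model returns an empty addition set).
#' @param candidates data.frame of candidate reactions (as in
#'   \code{\link{addReactions}}).
#' @param newMetabolites metabolites referenced only by candidates.
#' @param growthThreshold minimum restored growth rate (1/h); strictly
#'   positive but small, so feasibility restoration is what is certified.
#' @return list with \code{status} (\code{"filled"}, \code{"already_growing"}
#'   or \code{"unfillable"}), \code{added} (character vector of candidate
#'   ids) and \code{size}.
#' @export
minAdditionsGapfill <- function(model, candidates, newMetabolites = NULL,
                                growthThreshold = GAPFILL_GROWTH) {
  base <- fba(model)
  if (base@status == "optimal" && base@objective >= growthThreshold)
    return(list(status = "already_growing", added = character(), size = 0L))

  ext <- addReactions(model, candidates, newMetabolites)
  rxn <- ext@reactions
  S <- as.matrix(ext@stoichiometry)
  nR <- nrow(rxn)
  candIdx <- match(candidates$id, rxn$id)
  nC <- length(candIdx)
  biomass <- match(ext@biomassId, rxn$id)
  if (is.na(biomass)) stop("model lacks a biomass reaction")

  ## columns: v (nR) then y (nC)
  nv <- nR + nC
  Arows <- list()
  dir <- character()
  rhs <- numeric()
  ## S v = 0
  Sv <- cbind(S, matrix(0, nrow(S), nC))
  Arows[[1]] <- Sv
  dir <- c(dir, rep("==", nrow(S)))
  rhs <- c(rhs, rep(0, nrow(S)))
  ## candidate gating: v_k - ub_k y_k <= 0 ; v_k - lb_k y_k >= 0
  gate <- matrix(0, 2 * nC, nv)
  for (k in seq_len(nC)) {
    j <- candIdx[k]
    gate[2 * k - 1, j] <- 1
    gate[2 * k - 1, nR + k] <- -rxn$upper[j]
    gate[2 * k, j] <- 1
    gate[2 * k, nR + k] <- -rxn$lower[j]
  }
  Arows[[2]] <- gate
  dir <- c(dir, rep(c("<=", ">="), nC))
  rhs <- c(rhs, rep(0, 2 * nC))
  ## growth requirement
  grow <- matrix(0, 1, nv)
  grow[1, biomass] <- 1
  Arows[[3]] <- grow
  dir <- c(dir, ">=")
  rhs <- c(rhs, growthThreshold)

  A <- do.call(rbind, Arows)
  lb <- c(pmin(rxn$lower, 0), rep(0, nC))
  lb[candIdx] <- pmin(rxn$lower[candIdx], 0)
  ub <- c(rxn$upper, rep(1, nC))
  ## non-candidate reactions keep their own bounds
  lb[seq_len(nR)] <- rxn$lower
  lb[candIdx] <- pmin(rxn$lower[candIdx], 0)
  obj <- c(rep(0, nR), rep(1, nC))

  res <- solveMILP(obj, A, dir, rhs, lb, ub,
                   binary = nR + seq_len(nC))
  if (res$status != "optimal")
    return(list(status = "unfillable", added = character(), size = NA_integer_))
  y <- res$x[nR + seq_len(nC)]
  added <- candidates$id[y > 0.5]
  list(status = "filled", added = added, size = length(added))
}

#' Design host/medium pairs that make a target reaction essential
#'
#' Model-enabled gene search (MEGS) host design: searches knockout sets (up
#' to \code{maxKnockouts} gene deletions) and a catalog of media for pairs
#' under which (a) the knockout host still grows, and (b) additionally
#' disabling the target reaction abolishes growth — i.e. the target is
#' conditionally essential, so a library clone complementing it can be
#' selected by growth.
#'
#' @param model host \code{\linkS4class{MetabolicModel}}.
#' @param target target reaction id.
#' @param mediaCatalog named list of media (see \code{\link{medium}}).
#' @param maxKnockouts maximum number of simultaneous gene deletions
#'   (exhaustive search; keep small).
#' @param growthThreshold minimum growth rate counting as "grows".
#' @param tol zero-growth tolerance for "abolished".
#' @return data.frame with columns \code{knockouts} (comma-separated gene
#'   ids, \code{""} for none) and \code{medium}; zero rows if no design
#'   exists.
#' @export
megsDesign <- function(model, target, mediaCatalog, maxKnockouts = 2,
                       growthThreshold = GAPFILL_GROWTH,
                       tol = ZERO_GROWTH_TOL) {
  if (!target %in% model@reactions$id)
    stop("target reaction not in model: ", target)
  if (is.null(names(mediaCatalog)))
    names(mediaCatalog) <- paste0("medium", seq_along(mediaCatalog))
  gs <- genes(model)
  koSets <- list(character())
  for (k in seq_len(min(maxKnockouts, length(gs))))
    koSets <- c(koSets, utils::combn(gs, k, simplify = FALSE))

  trees <- model@gprTrees
  out <- list()
  for (mname in names(mediaCatalog)) {
    mm <- applyMedium(model, mediaCatalog[[mname]])
    for (ko in koSets) {
      off <- names(trees)[!vapply(trees, evaluateGPR, logical(1),
                                  deleted = ko)]
      mk <- if (length(off)) setBounds(mm, off, 0, 0) else mm
      g1 <- fba(mk)
      if (g1@status != "optimal" || g1@objective < growthThreshold) next
      mk2 <- setBounds(mk, target, 0, 0)
      g2 <- fba(mk2)
      dead <- g2@status != "optimal" || g2@objective <= tol
      if (dead)
        out[[length(out) + 1L]] <- data.frame(
          knockouts = paste(ko, collapse = ","), medium = mname,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(knockouts = character(), medium = character())
}

#' Steady-state diagnosis of a metabolite node
#'
#' At a fixed growth rate, partitions the reactions touching a metabolite
#' into those whose flux is locked to a fixed ratio with biomass (their
#' variability at the fixed growth rate is a single point) and those free
#' to vary, and reports the net locked production the free reactions must
#' carry to keep the node at steady state. This reproduces the diagnosis of
#' an imbalanced node: if no free reaction can carry the balance, deleting
#' one of them (e.g. fumarase) leaves the model infeasible, and a secretion
#' route is the natural gap fill.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param metabolite metabolite id at the node.
#' @param growthRate growth rate (1/h) at which to fix the biomass flux.
#' @param tol width below which a flux range counts as locked.
#' @return list with \code{reactions} (data.frame: \code{id}, \code{min},
#'   \code{max}, \code{locked}, \code{contribution} — flux times the node
#'   stoichiometric coefficient, for locked reactions) and
#'   \code{balancingFlux}: net locked production of the metabolite
#'   (mmol/gDW/h) that unlocked reactions must remove.
#' @export
fumarateNodeReport <- function(model, metabolite, growthRate, tol = 1e-6) {
  met <- model@metabolites
  if (!metabolite %in% met$id) stop("unknown metabolite: ", metabolite)
  biomass <- model@biomassId
  if (is.na(biomass)) stop("model lacks a biomass reaction")
  S <- model@stoichiometry
  touching <- model@reactions$id[S[metabolite, ] != 0]

  ## Relax the node's own balance with virtual source/sink reactions, then
  ## fix growth and scan variability: reactions still flux-determined are
  ## locked to the biomass ratio by demands elsewhere in the network (their
  ## products feed biomass precursors); reactions whose determination came
  ## only from closing this node's balance become free. Without the
  ## relaxation, a sole free consumer would be (wrongly) classified as
  ## locked, since the node balance pins its flux too.
  virt <- data.frame(id = c(".node_src", ".node_snk"),
                     equation = c(paste("->", metabolite),
                                  paste(metabolite, "->")),
                     lower = 0, upper = 1000, gpr = "", subsystem = "",
                     kind = "sink", stringsAsFactors = FALSE)
  mrel <- addReactions(model, virt)
  mrel <- setBounds(mrel, biomass, growthRate, growthRate)
  rng <- fva(mrel, objective = biomass, fraction = 1.0,
             reactionIds = touching)
  coef <- as.numeric(S[metabolite, touching])
  locked <- (rng$max - rng$min) <= tol * pmax(1, abs(rng$max))
  contribution <- ifelse(locked, coef * (rng$min + rng$max) / 2, NA_real_)
  balancing <- sum(contribution[locked])
  list(reactions = data.frame(id = touching, min = rng$min, max = rng$max,
                              locked = locked,
                              contribution = contribution),
       balancingFlux = balancing)
}
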