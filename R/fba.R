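#' FluxDistribution: result of a flux balance analysis
#'
#' Holds an optimal steady-state flux vector (mmol/gDW/h) together with the
#' objective value (growth rate in 1/h for a biomass objective) and the
#' solver status. Infeasibility is a legitimate outcome (for example after
#' deleting an essential gene) and is represented rather than raised.
#'
#' @slot fluxes named numeric vector of reaction fluxes (length 0 when
#'   infeasible).
#' @slot objective numeric objective value (\code{NA} when infeasible).
#' @slot objectiveReaction id of the optimised reaction.
#' @slot status \code{"optimal"} or \code{"infeasible"}.
#' @export
setClass("FluxDistribution",
  slots = c(fluxes = "numeric", objective = "numeric",
            objectiveReaction = "character", status = "character"))

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution (", object@status, "): ",
      object@objectiveReaction, " = ",
      format(object@objective, digits = 6), "\n", sep = "")
  nz <- sum(abs(object@fluxes) > 1e-9)
  cat("  ", length(object@fluxes), "reactions,", nz, "carrying flux\n")
})

#' @describeIn FluxDistribution-class flux vector accessor
#' @param x a \code{FluxDistribution}.
#' @export
fluxes <- function(x) x@fluxes

#' @describeIn FluxDistribution-class objective value accessor
#' @export
objectiveValue <- function(x) x@objective

#' Flux balance analysis
#'
#' Maximises (or minimises) the flux through an objective reaction subject
#' to steady-state mass balance \eqn{S v = 0} and the model's flux bounds.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param objective objective reaction id; defaults to the biomass reaction.
#' @param constraints optional data.frame (\code{id}, \code{lower},
#'   \code{upper}) of extra bounds applied before solving — e.g. fixing
#'   lactate secretion to zero flux by giving it \code{lower = upper = 0}.
#' @param maximize direction of optimisation.
#' @return A \code{\linkS4class{FluxDistribution}}.
#' @examples
#' # see makeToyModel() for ready-made feasible models
#' @export
fba <- function(model, objective = biomassReaction(model),
                constraints = NULL, maximize = TRUE) {
  rxn <- model@reactions
  if (is.na(objective) || !objective %in% rxn$id)
    stop("objective reaction not in model: ", objective)
  if (!is.null(constraints))
    model <- setBounds(model, constraints$id,
                       constraints$lower, constraints$upper)
  rxn <- model@reactions
  S <- model@stoichiometry
  obj <- as.numeric(rxn$id == objective)
  res <- solveLP(obj, S, rep("==", nrow(S)), rep(0, nrow(S)),
                 lb = rxn$lower, ub = rxn$upper, maximize = maximize)
  if (res$status == "unbounded")
    stop("objective unbounded along reaction ", objective,
         "; check exchange bounds")
  if (res$status != "optimal")
    return(methods::new("FluxDistribution", fluxes = numeric(),
                        objective = NA_real_, objectiveReaction = objective,
                        status = "infeasible"))
  methods::new("FluxDistribution",
               fluxes = stats::setNames(res$x, rxn$id),
               objective = res$objval, objectiveReaction = objective,
               status = "optimal")
}

#' Flux variability analysis
#'
#' Computes, for each reaction, the minimum and maximum flux attainable
#' while holding the objective at a fraction of its optimum (default 1.0,
#' i.e. at the optimal growth rate).
#'
#' @inheritParams fba
#' @param fraction fraction of the FBA optimum the objective must retain.
#' @param reactionIds reactions to scan (default: all).
#' @return data.frame with columns \code{id}, \code{min}, \code{max}.
#' @export
fva <- function(model, objective = biomassReaction(model), fraction = 1.0,
                reactionIds = NULL, constraints = NULL) {
  opt <- fba(model, objective, constraints = constraints)
  if (opt@status != "optimal")
    stop("fva: model infeasible, no FBA optimum exists")
  if (!is.null(constraints))
    model <- setBounds(model, constraints$id,
                       constraints$lower, constraints$upper)
  rxn <- model@reactions
  S <- model@stoichiometry
  if (is.null(reactionIds)) reactionIds <- rxn$id
  idx <- match(reactionIds, rxn$id)
  if (anyNA(idx)) stop("unknown reaction(s): ",
                       paste(reactionIds[is.na(idx)], collapse = ", "))

  ## hold objective >= fraction * optimum as an extra row
  objRow <- as.numeric(rxn$id == objective)
  A <- rbind(as.matrix(S), objRow)
  dir <- c(rep("==", nrow(S)), ">=")
  rhs <- c(rep(0, nrow(S)), fraction * opt@objective)

  out <- data.frame(id = reactionIds, min = NA_real_, max = NA_real_)
  for (k in seq_along(idx)) {
    obj <- as.numeric(seq_len(nrow(rxn)) == idx[k])
    lo <- solveLP(obj, A, dir, rhs, rxn$lower, rxn$upper, maximize = FALSE)
    hi <- solveLP(obj, A, dir, rhs, rxn$lower, rxn$upper, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("fva: subproblem ", reactionIds[k], " returned ", lo$status,
           "/", hi$status)
    out$min[k] <- lo$objval
    out$max[k] <- hi$objval
  }
  out
}

ZERO_GROWTH_TOL <- 1e-9

#' In-silico gene essentiality screen
#'
#' Deletes each gene in turn, deactivates every reaction whose GPR
#' evaluates to inactive under that single deletion, and maximises biomass.
#' A gene is called essential (phenotype \code{NoGrowth}) when the maximal
#' biomass flux is zero (below \code{tol}) or the deletion model is
#' infeasible.
#'
#' @inheritParams fba
#' @param med optional medium applied before screening
#'   (see \code{\link{applyMedium}}).
#' @param geneIds genes to screen (default: all model genes).
#' @param tol zero-growth tolerance in 1/h.
#' @return data.frame with columns \code{gene}, \code{phenotype}
#'   (\code{"Growth"}/\code{"NoGrowth"}) and \code{growth} (residual rate).
#' @export
essentialityScreen <- function(model, med = NULL,
                               geneIds = genes(model),
                               constraints = NULL,
                               tol = ZERO_GROWTH_TOL) {
  if (!is.null(med)) model <- applyMedium(model, med)
  if (!is.null(constraints))
    model <- setBounds(model, constraints$id,
                       constraints$lower, constraints$upper)
  trees <- model@gprTrees
  out <- data.frame(gene = geneIds, phenotype = NA_character_,
                    growth = NA_real_)
  for (k in seq_along(geneIds)) {
    g <- geneIds[k]
    off <- names(trees)[!vapply(trees, evaluateGPR, logical(1), deleted = g)]
    mdel <- if (length(off)) setBounds(model, off, 0, 0) else model
    fd <- fba(mdel)
    growth <- if (fd@status == "optimal") fd@objective else 0
    out$growth[k] <- growth
    out$phenotype[k] <- if (growth <= tol) "NoGrowth" else "Growth"
  }
  out
}

#' Substrate uptake sweep
#'
#' Runs FBA over a grid of substrate uptake rates, reporting growth and a
#' set of tracked production fluxes (for instance ethanol secretion, with
#' lactate secretion fixed to zero via \code{constraints}). Grid points at
#' which the model is infeasible (e.g. maintenance ATP cannot be met at
#' zero uptake) are reported with zero growth.
#'
#' @inheritParams fba
#' @param substrate substrate exchange reaction id.
#' @param rates non-negative uptake rates (mmol/gDW/h).
#' @param tracked reaction ids whose fluxes to report alongside growth.
#' @return data.frame with columns \code{uptake}, \code{growth} and one
#'   column per tracked reaction.
#' @export
uptakeSweep <- function(model, substrate, rates, tracked = character(),
                        constraints = NULL) {
  if (any(rates < 0)) stop("uptake rates must be >= 0")
  if (!substrate %in% model@reactions$id)
    stop("unknown substrate exchange: ", substrate)
  out <- data.frame(uptake = rates, growth = NA_real_)
  for (tid in tracked) out[[tid]] <- NA_real_
  for (k in seq_along(rates)) {
    mk <- setBounds(model, substrate, lower = -rates[k])
    fd <- fba(mk, constraints = constraints)
    if (fd@status == "optimal") {
      out$growth[k] <- fd@objective
      for (tid in tracked) out[[tid]][k] <- fd@fluxes[[tid]]
    } else {
      out$growth[k] <- 0
      for (tid in tracked) out[[tid]][k] <- 0
    }
  }
  out
}

#' Compare predicted fluxes with measured fluxes
#'
#' Compares an FBA flux distribution against a measured flux table (for
#' example from isotope-tracer metabolic flux analysis). Fluxes are
#' oriented to the measured direction before comparison, so agreement is
#' judged on magnitudes; a prediction running against the measured
#' direction shows up as a negative fold-deviation and is flagged. Zero (or
#' tiny) predicted fluxes are reported at a floor value so they remain
#' representable on a log scale.
#'
#' @param fd a \code{\linkS4class{FluxDistribution}}.
#' @param measured named numeric vector of measured fluxes.
#' @param foldCutoff flag predictions deviating more than this factor.
#' @param floor magnitude floor for zero-flux predictions.
#' @return data.frame with columns \code{reaction}, \code{predicted},
#'   \code{measured}, \code{fold} (oriented predicted/measured) and
#'   \code{outlier}.
#' @export
compareToMFA <- function(fd, measured, foldCutoff = 2, floor = 1e-4) {
  shared <- intersect(names(fd@fluxes), names(measured))
  if (length(shared) == 0L) stop("no shared reaction ids")
  pred <- fd@fluxes[shared]
  meas <- measured[shared]
  sgn <- ifelse(meas >= 0, 1, -1)
  predo <- pred * sgn
  predo <- ifelse(abs(predo) < floor, floor, predo)  # zero-flux floor
  measo <- pmax(abs(meas), floor)
  fold <- predo / measo
  outlier <- fold > foldCutoff | fold < 1 / foldCutoff
  data.frame(reaction = shared, predicted = unname(pred),
             measured = unname(meas), fold = unname(fold),
             outlier = unname(outlier))
}
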