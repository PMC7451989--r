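#' ComponentModel: non-negative directional flux components
#'
#' Flux coupling analysis works on a network in which every reaction
#' carries non-negative flux: each reversible reaction is split into a
#' forward (\code{_f}) and a reverse (\code{_r}) component (the reverse
#' component's stoichiometry is the negated original), and irreversible
#' reactions become single components. Forced lower bounds are relaxed to
#' zero — coupling is a property of the flux cone, not of a particular
#' operating point.
#'
#' @slot stoichiometry dense numeric matrix, metabolites x components.
#' @slot components data.frame with columns \code{id} (e.g.
#'   \code{"FUM_f"}), \code{reaction} (original id), \code{direction}
#'   (\code{"f"}/\code{"r"}) and \code{upper} (component flux bound).
#' @slot model the originating \code{\linkS4class{MetabolicModel}}.
#' @export
setClass("ComponentModel",
  slots = c(stoichiometry = "matrix", components = "data.frame",
            model = "MetabolicModel"))

setMethod("show", "ComponentModel", function(object) {
  cat("ComponentModel:", ncol(object@stoichiometry), "components over",
      nrow(object@stoichiometry), "metabolites\n")
})

#' Split reversible reactions into directional components
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @return A \code{\linkS4class{ComponentModel}} with
#'   \code{#irreversible + 2 * #reversible} components.
#' @export
splitReversible <- function(model) {
  rxn <- model@reactions
  S <- as.matrix(model@stoichiometry)
  cols <- list(); comp <- list()
  for (j in seq_len(nrow(rxn))) {
    lo <- rxn$lower[j]; up <- rxn$upper[j]
    if (up > 0) {
      cols[[length(cols) + 1L]] <- S[, j]
      comp[[length(comp) + 1L]] <- data.frame(
        id = paste0(rxn$id[j], "_f"), reaction = rxn$id[j],
        direction = "f", upper = up, stringsAsFactors = FALSE)
    }
    if (lo < 0) {
      cols[[length(cols) + 1L]] <- -S[, j]
      comp[[length(comp) + 1L]] <- data.frame(
        id = paste0(rxn$id[j], "_r"), reaction = rxn$id[j],
        direction = "r", upper = -lo, stringsAsFactors = FALSE)
    }
    if (up <= 0 && lo >= 0)
      stop("reaction ", rxn$id[j], " admits no flux (bounds [",
           lo, ", ", up, "])")
  }
  comp <- do.call(rbind, comp)
  Sc <- do.call(cbind, cols)
  dimnames(Sc) <- list(rownames(S), comp$id)
  methods::new("ComponentModel", stoichiometry = Sc, components = comp,
               model = model)
}

#' Add per-metabolite sink reactions and open all exchanges
#'
#' Prepares a model for flux coupling analysis under a full in-silico
#' medium: every exchange reaction is opened to \code{[-1000, 1000]}, and
#' one sink reaction (\code{SINK_<met>}, bounds \code{[0, 1000]}) is added
#' per listed biomass component and per terminal pathway product, so that
#' pathways feeding individual biomass precursors form their own modules
#' instead of one aggregate biomass-coupled module.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param biomassComponents,terminalProducts metabolite ids to receive
#'   sinks.
#' @return The augmented model.
#' @export
augmentWithSinks <- function(model, biomassComponents = character(),
                             terminalProducts = character()) {
  mets <- unique(c(biomassComponents, terminalProducts))
  unknown <- setdiff(mets, model@metabolites$id)
  if (length(unknown))
    stop("unknown metabolite(s): ", paste(unknown, collapse = ", "))
  model <- openAllExchanges(model)
  if (length(mets)) {
    sinks <- data.frame(id = paste0("SINK_", mets),
                        equation = paste(mets, "->"),
                        lower = 0, upper = 1000, gpr = "",
                        subsystem = "", kind = "sink",
                        stringsAsFactors = FALSE)
    sinks <- sinks[!sinks$id %in% model@reactions$id, , drop = FALSE]
    if (nrow(sinks)) model <- addReactions(model, sinks)
  }
  model
}

## Shared LP skeleton for ratio programs over the flux cone
## {S w = 0, w >= 0}: normalise w_j = 1 (valid after scaling because all
## components are non-negative and coupling is scale-invariant), then
## min/max w_i.  Flux caps are deliberately absent: coupling is a property
## of the cone, and every cone ray scales into the capped polytope.
couplingLPContext <- function(cm) {
  S <- cm@stoichiometry
  A <- rbind(S, 0)
  list(A = A, n = ncol(S), jrow = nrow(S) + 1,
       dir = c(rep("==", nrow(S)), "=="),
       rhs = c(rep(0, nrow(S)), 1))
}

FCF_EPS <- 1e-6

#' Flux-ratio extremes and coupling class for a component pair
#'
#' Computes \eqn{R_{min}} and \eqn{R_{max}}, the extreme values of the flux
#' ratio \eqn{v_i / v_j} over the steady-state flux cone, by linear
#' programming after normalising \eqn{v_j = 1} (valid since all components
#' are non-negative), and classifies the pair: fully coupled (fixed
#' nonzero ratio), partially coupled (variable but bounded away from 0 and
#' infinity), directionally coupled (one reaction's activity forces the
#' other's), or uncoupled.
#'
#' @param cm a \code{\linkS4class{ComponentModel}}.
#' @param i,j component ids (\code{i != j}).
#' @param eps relative tolerance for ratio equality / zero.
#' @param context internal precomputed LP skeleton (for batch use).
#' @return list with \code{i}, \code{j}, \code{Rmin}, \code{Rmax}
#'   (\code{Inf} when the ratio is unbounded) and \code{class} (one of
#'   \code{"fully"}, \code{"partially"}, \code{"directional_i_to_j"},
#'   \code{"directional_j_to_i"}, \code{"uncoupled"}).
#' @export
couplingPair <- function(cm, i, j, eps = FCF_EPS, context = NULL) {
  ids <- cm@components$id
  ii <- match(i, ids); jj <- match(j, ids)
  if (is.na(ii) || is.na(jj)) stop("unknown component id")
  if (ii == jj) stop("i and j must differ")
  if (is.null(context)) context <- couplingLPContext(cm)
  A <- context$A
  A[context$jrow, ] <- 0
  A[context$jrow, jj] <- 1
  obj <- numeric(ncol(A)); obj[ii] <- 1
  lo <- solveLP(obj, A, context$dir, context$rhs, lb = 0, ub = Inf,
                maximize = FALSE)
  if (lo$status == "infeasible")
    stop("component ", j, " is blocked; prefilter blocked components first")
  hi <- solveLP(obj, A, context$dir, context$rhs, lb = 0, ub = Inf,
                maximize = TRUE)
  Rmin <- max(lo$objval, 0)
  Rmax <- if (hi$status == "unbounded") Inf else hi$objval
  cls <- classifyCoupling(Rmin, Rmax, eps)
  list(i = i, j = j, Rmin = Rmin, Rmax = Rmax, class = cls)
}

classifyCoupling <- function(Rmin, Rmax, eps = FCF_EPS) {
  pos <- Rmin > eps
  bounded <- is.finite(Rmax)
  if (pos && bounded && (Rmax - Rmin) <= eps * max(1, abs(Rmax))) "fully"
  else if (pos && bounded) "partially"
  else if (!pos && bounded) "directional_i_to_j"
  else if (pos && !bounded) "directional_j_to_i"
  else "uncoupled"
}

#' Identify blocked components
#'
#' One LP per component on the opened network: a component is blocked if
#' its maximal flux is (numerically) zero. Blocked components are removed
#' before pairwise coupling analysis.
#'
#' @param cm a \code{\linkS4class{ComponentModel}}.
#' @param tol flux threshold below which a component counts as blocked.
#' @return Character vector of blocked component ids.
#' @export
blockedComponents <- function(cm, tol = 1e-6) {
  S <- cm@stoichiometry
  n <- ncol(S)
  dirs <- rep("==", nrow(S))
  rhs <- rep(0, nrow(S))
  ## iteratively maximise the summed flux of still-unseen components
  ## (capped at 1 each); anything positive is unblocked, repeat until no
  ## progress, then confirm the remainder one LP at a time
  remaining <- seq_len(n)
  repeat {
    obj <- numeric(n); obj[remaining] <- 1
    r <- solveLP(obj, S, dirs, rhs, lb = 0, ub = 1, maximize = TRUE)
    if (r$status != "optimal") break
    pos <- remaining[r$x[remaining] > tol]
    if (length(pos) == 0L) break
    remaining <- setdiff(remaining, pos)
    if (length(remaining) == 0L) break
  }
  blocked <- character()
  for (k in remaining) {
    obj <- numeric(n); obj[k] <- 1
    r <- solveLP(obj, S, dirs, rhs, lb = 0, ub = 1, maximize = TRUE)
    if (r$status != "optimal" || r$objval <= tol)
      blocked <- c(blocked, cm@components$id[k])
  }
  blocked
}

#' Full flux coupling analysis: modules of coupled components
#'
#' Removes blocked components, builds the fully-coupled equivalence classes
#' (exploiting transitivity so each component is tested against one
#' representative per class), finds partially coupled pairs between
#' classes, and assembles modules: fully coupled modules are equivalence
#' classes of size two or more; partially coupled modules are maximal
#' groups connected by partial (plus full) coupling containing at least one
#' partially coupled pair.
#'
#' @inheritParams couplingPair
#' @param verbose print progress.
#' @return list with \code{modules} (list of lists: \code{id},
#'   \code{class}, \code{components}, \code{reactions}), \code{blocked}
#'   (ids removed by the prefilter) and \code{classes} (full-coupling
#'   classes including singletons).
#' @export
couplingAll <- function(cm, eps = FCF_EPS, verbose = FALSE) {
  blocked <- blockedComponents(cm)
  ids <- setdiff(cm@components$id, blocked)
  context <- couplingLPContext(cm)

  ## fully coupled classes by transitivity
  classes <- list()
  for (id in ids) {
    placed <- FALSE
    for (ci in seq_along(classes)) {
      rep1 <- classes[[ci]][1]
      cp <- couplingPair(cm, id, rep1, eps = eps, context = context)
      if (cp$class == "fully") {
        classes[[ci]] <- c(classes[[ci]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- id
    if (verbose && (length(classes) %% 25 == 0))
      message("  classes so far: ", length(classes))
  }

  ## partial edges between class representatives
  k <- length(classes)
  padj <- matrix(FALSE, k, k)
  if (k >= 2) {
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        cp <- couplingPair(cm, classes[[a]][1], classes[[b]][1],
                           eps = eps, context = context)
        if (cp$class == "partially") padj[a, b] <- padj[b, a] <- TRUE
      }
    }
  }

  modules <- list()
  ## partially coupled modules: connected components over partial edges
  seen <- rep(FALSE, k)
  for (a in seq_len(k)) {
    if (seen[a] || !any(padj[a, ])) next
    grp <- a
    queue <- a
    seen[a] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nbrs <- which(padj[cur, ] & !seen)
      seen[nbrs] <- TRUE
      grp <- c(grp, nbrs)
      queue <- c(queue, nbrs)
    }
    comps <- sort(unlist(classes[grp]))
    modules[[length(modules) + 1L]] <- list(
      class = "partially", components = comps,
      reactions = unique(componentReactions(cm, comps)))
  }
  ## fully coupled modules: classes of size >= 2
  for (cl in classes) {
    if (length(cl) < 2) next
    comps <- sort(cl)
    modules[[length(modules) + 1L]] <- list(
      class = "fully", components = comps,
      reactions = unique(componentReactions(cm, comps)))
  }
  ## deterministic module ids: sort by class then first component
  ord <- order(vapply(modules, `[[`, character(1), "class"),
               vapply(modules, function(m) m$components[1], character(1)))
  modules <- modules[ord]
  for (i in seq_along(modules)) modules[[i]]$id <- paste0("M", i)
  list(modules = modules, blocked = blocked, classes = classes)
}

componentReactions <- function(cm, componentIds) {
  cm@components$reaction[match(componentIds, cm@components$id)]
}

#' Map coupled-reaction modules to genes and mutants
#'
#' Module genes are the union of GPR genes over member reactions,
#' excluding reactions without a GPR and genes that are isozyme
#' alternatives (under a top-level OR) — an isozyme-bearing mutant's
#' phenotype is masked by the alternative enzyme, so it is uninformative
#' for module-level cofitness. The mutant set is the intersection with the
#' genes present in a fitness dataset.
#'
#' @param modules module list from \code{\link{couplingAll}}.
#' @param model the originating \code{\linkS4class{MetabolicModel}}.
#' @param fitnessGenes optional character vector of genes with fitness data.
#' @return The module list, each element gaining \code{genes} and (when
#'   \code{fitnessGenes} is given) \code{mutants}.
#' @export
mapModulesToGenes <- function(modules, model, fitnessGenes = NULL) {
  trees <- model@gprTrees
  lapply(modules, function(m) {
    gs <- character()
    for (r in m$reactions) {
      tree <- trees[[r]]
      if (is.null(tree)) next                       # orphan reaction
      iso <- gprIsozymeGenes(tree)
      gs <- c(gs, setdiff(gprGenes(tree), iso))
    }
    m$genes <- sort(unique(gs))
    if (!is.null(fitnessGenes))
      m$mutants <- intersect(m$genes, fitnessGenes)
    m
  })
}

#' Condition-dependent flux coupling
#'
#' Recomputes coupling under additional constraints (for example closing
#' the oxygen exchange to simulate anaerobiosis) and reports, for each
#' baseline module, the components newly fully coupled into it. Tightening
#' constraints can only shrink the flux cone, so baseline couplings are
#' preserved and couplings can only be gained.
#'
#' @param cm baseline \code{\linkS4class{ComponentModel}}.
#' @param constraints data.frame (\code{reaction}, \code{upper}) of new
#'   component flux caps applied to both directional components of each
#'   listed reaction (use \code{upper = 0} to disable a reaction).
#' @param baseline result of \code{\link{couplingAll}} on \code{cm}.
#' @inheritParams couplingPair
#' @return list with \code{additions} (named list: baseline module id ->
#'   character vector of newly coupled component ids),
#'   \code{conditionModules} (the recomputed module list) and
#'   \code{unavailable} (components removed or blocked by the condition;
#'   coupling is undefined for these, not lost).
#' @export
conditionCoupling <- function(cm, constraints, baseline, eps = FCF_EPS) {
  cm2 <- cm
  if (nrow(constraints)) {
    hit <- cm2@components$reaction %in% constraints$reaction
    newub <- constraints$upper[match(cm2@components$reaction[hit],
                                     constraints$reaction)]
    cm2@components$upper[hit] <- newub
  }
  keep <- cm2@components$upper > 0
  cm2@components <- cm2@components[keep, , drop = FALSE]
  cm2@stoichiometry <- cm2@stoichiometry[, keep, drop = FALSE]

  removed <- setdiff(cm@components$id, cm2@components$id)
  cond <- couplingAll(cm2, eps = eps)
  fullCond <- Filter(function(m) m$class == "fully", cond$modules)
  additions <- list()
  for (bm in Filter(function(m) m$class == "fully", baseline$modules)) {
    added <- character()
    for (cmzz in fullCond) {
      if (length(intersect(bm$components, cmzz$components)))
        added <- c(added, setdiff(cmzz$components, bm$components))
    }
    additions[[bm$id]] <- sort(unique(added))
  }
  list(additions = additions, conditionModules = cond$modules,
       unavailable = sort(unique(c(removed, cond$blocked))))
}

#' FBA on a component model
#'
#' Maximises a component's flux over the non-negative component cone with
#' component bounds — used to check that splitting preserves optima.
#'
#' @param cm a \code{\linkS4class{ComponentModel}}.
#' @param objectiveComponent component id to maximise.
#' @return list with \code{objval} and \code{status}.
#' @export
componentFBA <- function(cm, objectiveComponent) {
  S <- cm@stoichiometry
  k <- match(objectiveComponent, cm@components$id)
  if (is.na(k)) stop("unknown component: ", objectiveComponent)
  obj <- numeric(ncol(S)); obj[k] <- 1
  r <- solveLP(obj, S, rep("==", nrow(S)), rep(0, nrow(S)),
               lb = 0, ub = cm@components$upper, maximize = TRUE)
  list(objval = r$objval, status = r$status)
}
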