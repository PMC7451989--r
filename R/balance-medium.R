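#' Parse an elemental formula into element counts
#'
#' @param formula a Hill-style formula string such as \code{"C6H12O6"}.
#' @return Named numeric vector of element counts.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(formula) {
  if (is.na(formula) || !nzchar(formula))
    stop("empty or missing formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)",
                                       formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("unparseable formula: ", formula)
  out <- numeric()
  for (tk in toks) {
    el <- regmatches(tk, regexpr("^[A-Z][a-z]?", tk))
    n <- sub("^[A-Z][a-z]?", "", tk)
    cnt <- if (nzchar(n)) as.numeric(n) else 1
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) + cnt
  }
  out
}

#' Check mass and charge balance of model reactions
#'
#' Verifies that every metabolic and transport reaction conserves each
#' chemical element and net charge. Exchange, sink, biomass and maintenance
#' reactions are boundary or lumped reactions and are skipped. Proton or
#' water imbalances are reported like any other; nothing is auto-corrected.
#'
#' @param model a \code{\linkS4class{MetabolicModel}} whose participating
#'   metabolites carry formulas and charges.
#' @param tol absolute tolerance on residual element/charge counts.
#' @return data.frame with columns \code{reaction}, \code{quantity} (element
#'   symbol or \code{"charge"}) and \code{imbalance}; zero rows when the
#'   model is balanced.
#' @export
checkBalance <- function(model, tol = 1e-6) {
  rxn <- model@reactions
  met <- model@metabolites
  S <- model@stoichiometry
  check <- which(rxn$kind %in% c("metabolic", "transport"))
  out <- list()
  for (j in check) {
    col <- S[, j]
    idx <- which(col != 0)
    bal <- numeric()
    for (i in idx) {
      f <- met$formula[i]
      if (is.na(f) || !nzchar(f))
        stop("metabolite ", met$id[i], " lacks a formula (reaction ",
             rxn$id[j], ")")
      cnt <- parseFormula(f)
      for (el in names(cnt))
        bal[el] <- (if (el %in% names(bal)) bal[[el]] else 0) +
          col[i] * cnt[[el]]
    }
    chg <- met$charge[idx]
    if (!anyNA(chg))
      bal["charge"] <- sum(col[idx] * chg)
    bad <- names(bal)[abs(bal) > tol]
    if (length(bad))
      out[[length(out) + 1L]] <- data.frame(
        reaction = rxn$id[j], quantity = bad,
        imbalance = unname(bal[bad]), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(reaction = character(), quantity = character(),
                  imbalance = numeric())
}

#' Define a growth medium
#'
#' A medium is a set of exchange-reaction bounds in mmol/gDW/h. Uptake is a
#' negative lower bound on the exchange reaction.
#'
#' @param uptake named numeric vector: exchange reaction id -> maximum uptake
#'   rate (positive number; stored as lower bound \code{-uptake}).
#' @param bounds optional data.frame (\code{id}, \code{lower}, \code{upper})
#'   overriding both bounds explicitly.
#' @return A data.frame with columns \code{id}, \code{lower}, \code{upper}
#'   of class \code{"fluxfit_medium"}.
#' @examples
#' medium(c(EX_glc_e = 61.5, EX_o2_e = 0))
#' @export
medium <- function(uptake = numeric(), bounds = NULL) {
  out <- if (length(uptake))
    data.frame(id = names(uptake), lower = -unname(uptake),
               upper = 1000, stringsAsFactors = FALSE)
  else data.frame(id = character(), lower = numeric(), upper = numeric(),
                  stringsAsFactors = FALSE)
  if (!is.null(bounds)) {
    stopifnot(all(c("id", "lower", "upper") %in% names(bounds)))
    out <- rbind(out[!out$id %in% bounds$id, ],
                 bounds[, c("id", "lower", "upper")])
  }
  class(out) <- c("fluxfit_medium", class(out))
  out
}

#' Apply a medium to a model
#'
#' Sets the listed exchange-reaction bounds, closes uptake (lower bound 0)
#' for every exchange reaction not listed, and opens secretion (upper bound
#' 1000) on all exchange reactions, so any extracellular compound may be
#' secreted.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param med a medium from \code{\link{medium}}.
#' @return The constrained model.
#' @export
applyMedium <- function(model, med) {
  rxn <- model@reactions
  ex <- rxn$id[rxn$kind == "exchange"]
  bad <- setdiff(med$id, ex)
  if (length(bad))
    stop("medium entries are not exchange reactions: ",
         paste(bad, collapse = ", "))
  model <- setBounds(model, ex, lower = 0, upper = 1000)
  if (nrow(med))
    model <- setBounds(model, med$id, lower = med$lower, upper = med$upper)
  model
}

#' Fully open in-silico medium
#'
#' Opens every exchange reaction to \code{[-1000, 1000]}, allowing uptake or
#' excretion of any metabolite with a transporter — the configuration used
#' for flux coupling analysis.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @return The opened model.
#' @export
openAllExchanges <- function(model) {
  ex <- model@reactions$id[model@reactions$kind == "exchange"]
  setBounds(model, ex, lower = -1000, upper = 1000)
}
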