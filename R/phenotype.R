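#' Classify pooled growth phenotypes at a fitness cutoff
#'
#' A mutant is considered to have a growth phenotype when its fitness score
#' is above the cutoff. Across replicate experiments: \code{Growth} if all
#' available replicate scores are strictly above the cutoff, \code{NoGrowth}
#' if all are at or below it, \code{Inconsistent} if replicates disagree,
#' and \code{Unavailable} if the gene is absent or all replicate scores are
#' missing.
#'
#' @param x a \code{\linkS4class{FitnessMatrix}}.
#' @param replicates experiment ids of the replicate experiments.
#' @param cutoff fitness score cutoff (default -0.6).
#' @param geneIds genes to classify; defaults to all genes in \code{x}.
#'   Genes not present in \code{x} are \code{Unavailable}.
#' @return data.frame with columns \code{gene} and \code{phenotype}.
#' @export
classifyGrowth <- function(x, replicates, cutoff = -0.6,
                           geneIds = rownames(x)) {
  unknown <- setdiff(replicates, colnames(x))
  if (length(unknown))
    stop("unknown experiment id(s): ", paste(unknown, collapse = ", "))
  if (length(replicates) < 1L) stop("need at least one replicate")
  sc <- fitnessScores(x)[, replicates, drop = FALSE]
  pheno <- vapply(geneIds, function(g) {
    if (!g %in% rownames(sc)) return("Unavailable")
    v <- sc[g, ]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return("Unavailable")
    above <- v > cutoff
    if (all(above)) "Growth"
    else if (all(!above)) "NoGrowth"
    else "Inconsistent"
  }, character(1))
  data.frame(gene = geneIds, phenotype = unname(pheno),
             stringsAsFactors = FALSE)
}

#' Confusion table of essentiality predictions vs pooled phenotypes
#'
#' Crosses model predictions (\code{Growth}/\code{NoGrowth}, from
#' \code{\link{essentialityScreen}}) with experimental phenotype calls.
#' Genes with inconsistent or unavailable experimental phenotypes are
#' tallied separately and excluded from the agreement cells.
#'
#' @param predictions data.frame with columns \code{gene},
#'   \code{phenotype}.
#' @param phenotypes data.frame with columns \code{gene}, \code{phenotype}
#'   from \code{\link{classifyGrowth}}. Predicted genes missing from it
#'   are counted as unavailable.
#' @return An object of class \code{"confusionTable"}: a list of counts
#'   \code{GG}, \code{GNG}, \code{NGG}, \code{NGNG} (prediction first,
#'   experiment second), \code{GI}, \code{NGI} (inconsistent), and
#'   \code{unavailableG}, \code{unavailableNG}.
#' @export
confusion <- function(predictions, phenotypes) {
  ph <- stats::setNames(phenotypes$phenotype, phenotypes$gene)
  cnt <- c(GG = 0L, GNG = 0L, NGG = 0L, NGNG = 0L, GI = 0L, NGI = 0L,
           unavailableG = 0L, unavailableNG = 0L)
  for (k in seq_len(nrow(predictions))) {
    pred <- predictions$phenotype[k]
    g <- predictions$gene[k]
    exp <- if (g %in% names(ph)) ph[[g]] else "Unavailable"
    key <- switch(exp,
      Growth = if (pred == "Growth") "GG" else "NGG",
      NoGrowth = if (pred == "Growth") "GNG" else "NGNG",
      Inconsistent = if (pred == "Growth") "GI" else "NGI",
      Unavailable = if (pred == "Growth") "unavailableG" else "unavailableNG")
    cnt[key] <- cnt[key] + 1L
  }
  structure(as.list(cnt), class = "confusionTable")
}

#' @export
print.confusionTable <- function(x, ...) {
  cat("Predicted vs experimental growth phenotypes\n")
  cat(sprintf("  GG %d  GNG %d  GI %d  unavailable %d\n",
              x$GG, x$GNG, x$GI, x$unavailableG))
  cat(sprintf("  NGG %d  NGNG %d  NGI %d  unavailable %d\n",
              x$NGG, x$NGNG, x$NGI, x$unavailableNG))
  n <- x$GG + x$GNG + x$NGG + x$NGNG
  if (n > 0)
    cat(sprintf("  agreement %.2f%% (%d/%d consistent genes)\n",
                100 * (x$GG + x$NGNG) / n, x$GG + x$NGNG, n))
  invisible(x)
}

#' Prediction-error curve over a cutoff grid and optimal cutoff
#'
#' For each cutoff, classifies phenotypes, tallies false positives (model
#' predicts growth, data says no growth), false negatives (model predicts
#' no growth, data says growth) and inconsistent genes, and reports the
#' fractions over the consistently classified genes. The selected cutoff
#' minimises the total error (false positive fraction + false negative
#' fraction); ties resolve to the most negative cutoff.
#'
#' @inheritParams classifyGrowth
#' @param predictions data.frame with columns \code{gene},
#'   \code{phenotype} (model predictions).
#' @param grid numeric vector of cutoffs (default \code{seq(-3, 0, 0.01)}).
#' @return list with \code{curve} (data.frame: \code{cutoff}, \code{fp},
#'   \code{fn}, \code{inconsistent}, \code{total}) and \code{bestCutoff}.
#' @export
errorCurve <- function(x, replicates, predictions,
                       grid = seq(-3, 0, by = 0.01)) {
  if (length(grid) == 0L) stop("empty cutoff grid")
  grid <- sort(grid)
  curve <- data.frame(cutoff = grid, fp = NA_real_, fn = NA_real_,
                      inconsistent = NA_real_, total = NA_real_)
  for (k in seq_along(grid)) {
    ph <- classifyGrowth(x, replicates, cutoff = grid[k],
                         geneIds = predictions$gene)
    ct <- confusion(predictions, ph)
    ncons <- ct$GG + ct$GNG + ct$NGG + ct$NGNG
    ntot <- ncons + ct$GI + ct$NGI
    curve$fp[k] <- if (ncons > 0) ct$GNG / ncons else 0
    curve$fn[k] <- if (ncons > 0) ct$NGG / ncons else 0
    curve$inconsistent[k] <- if (ntot > 0) (ct$GI + ct$NGI) / ntot else 0
    curve$total[k] <- curve$fp[k] + curve$fn[k]
  }
  best <- grid[which.min(curve$total)]   # ties -> most negative (grid sorted)
  list(curve = curve, bestCutoff = best)
}

#' Chi-squared association between predictions and phenotypes
#'
#' Pearson chi-squared test (1 degree of freedom, no continuity
#' correction) on the 2x2 consistent-phenotype confusion table.
#'
#' @param ct a \code{"confusionTable"} from \code{\link{confusion}}, or a
#'   list with elements \code{GG}, \code{GNG}, \code{NGG}, \code{NGNG}.
#' @return list with \code{statistic} and \code{p.value}.
#' @export
associationTest <- function(ct) {
  m <- matrix(c(ct$GG, ct$GNG, ct$NGG, ct$NGNG), 2, 2, byrow = TRUE)
  if (any(m < 0) || sum(m) == 0) stop("invalid confusion counts")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal in confusion table")
  ht <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value))
}
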