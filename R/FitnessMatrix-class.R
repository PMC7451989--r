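#' FitnessMatrix: pooled mutant fitness scores
#'
#' A \code{SummarizedExperiment} subclass holding a gene x experiment
#' matrix of fitness scores — the average log2 change in abundance of a
#' gene's barcoded transposon mutant over a pooled growth experiment
#' (strongly negative means the mutant failed to grow) — in the
#' \code{"fitness"} assay, with per-experiment metadata (at least an
#' \code{anaerobic} flag and a \code{medium} label) in \code{colData}.
#' Missing entries (mutant absent or unscored) are \code{NA}.
#'
#' @aliases FitnessMatrix-class
#' @export
setClass("FitnessMatrix", contains = "SummarizedExperiment")

setValidity("FitnessMatrix", function(object) {
  msgs <- character()
  if (!"fitness" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "missing 'fitness' assay")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "duplicated experiment ids")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicated gene ids")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("anaerobic", "medium") %in% colnames(cd)))
    msgs <- c(msgs, "colData must provide 'anaerobic' and 'medium'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FitnessMatrix
#'
#' @param scores numeric matrix, genes (rows, locus tags) x experiments
#'   (columns), with \code{NA} for missing entries.
#' @param metadata data.frame with one row per experiment: columns
#'   \code{experiment} (matching \code{colnames(scores)}),
#'   \code{anaerobic} (logical) and \code{medium} (label).
#' @return A \code{\linkS4class{FitnessMatrix}}.
#' @examples
#' sc <- matrix(rnorm(6), 2, 3,
#'              dimnames = list(c("g1", "g2"), c("e1", "e2", "e3")))
#' md <- data.frame(experiment = colnames(sc),
#'                  anaerobic = c(TRUE, FALSE, TRUE), medium = "minimal")
#' FitnessMatrix(sc, md)
#' @export
FitnessMatrix <- function(scores, metadata) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("scores must have gene rownames and experiment colnames")
  metadata <- as.data.frame(metadata)
  if (!"experiment" %in% names(metadata))
    stop("metadata needs an 'experiment' column")
  idx <- match(colnames(scores), metadata$experiment)
  if (anyNA(idx))
    stop("metadata missing experiment(s): ",
         paste(colnames(scores)[is.na(idx)], collapse = ", "))
  cd <- S4Vectors::DataFrame(metadata[idx, setdiff(names(metadata),
                                                   "experiment"),
                                      drop = FALSE],
                             row.names = colnames(scores))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fitness = scores), colData = cd)
  methods::new("FitnessMatrix", se)
}

#' @describeIn FitnessMatrix-class fitness score matrix accessor
#' @param x a \code{FitnessMatrix}.
#' @export
fitnessScores <- function(x) SummarizedExperiment::assay(x, "fitness")

#' @describeIn FitnessMatrix-class experiment ids of the anaerobic subset
#' @export
anaerobicExperiments <- function(x) {
  colnames(x)[SummarizedExperiment::colData(x)$anaerobic]
}

#' Read a fitness matrix from TSV
#'
#' Expects a scores TSV (first column gene locus tags, remaining columns
#' experiments; non-numeric cells become \code{NA}) and a metadata TSV
#' with columns \code{experiment}, \code{anaerobic}, \code{medium}.
#'
#' @param path scores TSV path.
#' @param metadataPath metadata TSV path.
#' @return A \code{\linkS4class{FitnessMatrix}}.
#' @export
readFitness <- function(path, metadataPath) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(raw) < 2L) stop("fitness TSV needs gene + experiment columns")
  gene <- as.character(raw[[1]])
  if (anyDuplicated(gene))
    stop("duplicate gene row(s): ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  sc <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(sc) <- "double")   # non-numeric -> NA
  rownames(sc) <- gene
  md <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
  md$anaerobic <- as.logical(md$anaerobic)
  FitnessMatrix(sc, md)
}

#' Write a fitness matrix to TSV
#'
#' @param x a \code{\linkS4class{FitnessMatrix}}.
#' @param path scores TSV path.
#' @param metadataPath metadata TSV path.
#' @return \code{path}, invisibly.
#' @export
writeFitness <- function(x, path, metadataPath) {
  sc <- fitnessScores(x)
  df <- data.frame(gene = rownames(sc), sc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  md <- data.frame(experiment = rownames(cd), cd)
  utils::write.table(md, metadataPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
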