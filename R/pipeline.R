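#' Model summary and validation report
#'
#' Summarises a model in the taxonomy used to compare genome-scale
#' reconstructions: reactions excluding biomass and exchange reactions,
#' reactions with and without GPR associations, metabolic reactions
#' without GPR (metabolic further excludes transport), gene and metabolite
#' counts (both compartmented species and compartment-deduplicated unique
#' metabolites), plus the mass/charge balance check when formulas are
#' available.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param balance run \code{\link{checkBalance}} (requires formulas).
#' @return list of counts: \code{reactions}, \code{reactionsWithGPR},
#'   \code{reactionsWithoutGPR}, \code{metabolicWithoutGPR}, \code{genes},
#'   \code{metabolites}, \code{uniqueMetabolites}, and \code{imbalanced}
#'   (data.frame, when \code{balance} is TRUE).
#' @export
validateModel <- function(model, balance = TRUE) {
  rxn <- model@reactions
  counted <- rxn[!rxn$kind %in% c("biomass", "exchange"), , drop = FALSE]
  hasGPR <- nzchar(counted$gpr)
  out <- list(
    reactions = nrow(counted),
    reactionsWithGPR = sum(hasGPR),
    reactionsWithoutGPR = sum(!hasGPR),
    metabolicWithoutGPR = sum(!hasGPR & counted$kind == "metabolic"),
    genes = length(model@genes),
    metabolites = nrow(model@metabolites),
    uniqueMetabolites = length(unique(speciesOf(model@metabolites$id))))
  if (out$reactions == 0L)
    warning("model has no countable reactions")
  if (balance) {
    haveFormula <- !is.na(model@metabolites$formula)
    out$imbalanced <- if (all(haveFormula)) checkBalance(model)
      else data.frame(reaction = character(), quantity = character(),
                      imbalance = numeric())
  }
  out
}

#' Run the full model-driven fitness analysis pipeline
#'
#' Orchestrates the end-to-end analysis: in-silico gene essentiality on a
#' medium, growth-phenotype classification of pooled fitness data with an
#' error-minimising cutoff, confusion-table comparison and chi-squared
#' association, flux coupling analysis with sink augmentation, module ->
#' gene mapping, resampling-calibrated module cofitness, and candidate
#' ranking for every module containing a reaction without a GPR. All
#' stages are deterministic given \code{seed}.
#'
#' @param model a \code{\linkS4class{MetabolicModel}}.
#' @param fitness a \code{\linkS4class{FitnessMatrix}}.
#' @param replicates experiment ids used for phenotype classification.
#' @param med optional medium for the essentiality screen.
#' @param cutoffGrid fitness-cutoff grid for error minimisation.
#' @param nSamples,percentile null-threshold resampling parameters.
#' @param seed integer seed for all resampling.
#' @param outDir optional directory; when given, TSV/JSON reports are
#'   written (\code{essentiality.tsv}, \code{confusion.json},
#'   \code{error_curve.tsv}, \code{modules.tsv},
#'   \code{module_cofitness.tsv}, \code{candidates_<module>.tsv},
#'   \code{run_info.json}).
#' @return list with elements \code{essentiality}, \code{bestCutoff},
#'   \code{errorCurve}, \code{phenotypes}, \code{confusion},
#'   \code{association}, \code{modules}, \code{moduleCofitness},
#'   \code{candidates}.
#' @export
runPipeline <- function(model, fitness, replicates, med = NULL,
                        cutoffGrid = seq(-3, 0, by = 0.01),
                        nSamples = 10000, percentile = 95, seed = 1,
                        outDir = NULL) {
  ess <- essentialityScreen(model, med = med)
  predictions <- data.frame(gene = ess$gene, phenotype = ess$phenotype)

  ec <- errorCurve(fitness, replicates, predictions, grid = cutoffGrid)
  phen <- classifyGrowth(fitness, replicates, cutoff = ec$bestCutoff,
                         geneIds = predictions$gene)
  ct <- confusion(predictions, phen)
  assoc <- tryCatch(associationTest(ct), error = function(e) NULL)

  cm <- couplingModel(model)
  ca <- couplingAll(cm)
  modules <- mapModulesToGenes(ca$modules, model,
                               fitnessGenes = rownames(fitness))

  cof <- cofitness(fitness)
  pool <- intersect(genes(model), rownames(fitness))
  geneSets <- lapply(modules, function(m) {
    if (is.null(m$mutants)) m$genes else m$mutants
  })
  names(geneSets) <- vapply(modules, `[[`, character(1), "id")
  usable <- vapply(geneSets, function(g)
    length(intersect(g, rownames(cof$r))) >= 2, logical(1))
  mc <- if (any(usable))
    moduleCofitness(cof, geneSets[usable], pool = pool,
                    nSamples = nSamples, percentile = percentile,
                    seed = seed)
  else data.frame()

  ## candidate ranking for modules containing a reaction without a GPR
  trees <- model@gprTrees
  candidates <- list()
  for (m in modules) {
    orphan <- any(vapply(m$reactions, function(r)
      r %in% names(trees) && is.null(trees[[r]]), logical(1)))
    known <- intersect(m$genes, rownames(cof$r))
    if (orphan && length(known) >= 1)
      candidates[[m$id]] <- rankCandidates(cof, known)
  }

  res <- list(essentiality = ess, bestCutoff = ec$bestCutoff,
              errorCurve = ec$curve, phenotypes = phen, confusion = ct,
              association = assoc, modules = modules,
              moduleCofitness = mc, candidates = candidates)
  if (!is.null(outDir)) writePipelineReports(res, outDir, seed)
  res
}

writePipelineReports <- function(res, outDir, seed) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, f) utils::write.table(
    df, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(res$essentiality, "essentiality.tsv")
  wtsv(res$errorCurve, "error_curve.tsv")
  wtsv(res$phenotypes, "phenotypes.tsv")
  jsonlite::write_json(
    c(unclass(res$confusion),
      list(bestCutoff = res$bestCutoff,
           chisq = res$association$statistic,
           p.value = res$association$p.value)),
    file.path(outDir, "confusion.json"), auto_unbox = TRUE, digits = NA)
  modtab <- do.call(rbind, lapply(res$modules, function(m) data.frame(
    module = m$id, class = m$class,
    components = paste(m$components, collapse = ","),
    genes = paste(m$genes, collapse = ","),
    mutants = if (!is.null(m$mutants)) paste(m$mutants, collapse = ",")
              else "", stringsAsFactors = FALSE)))
  if (!is.null(modtab)) wtsv(modtab, "modules.tsv")
  if (nrow(res$moduleCofitness)) wtsv(res$moduleCofitness,
                                      "module_cofitness.tsv")
  for (mid in names(res$candidates))
    wtsv(utils::head(res$candidates[[mid]], 50),
         paste0("candidates_", mid, ".tsv"))
  jsonlite::write_json(
    list(seed = seed, solver = "fluxfit bounded simplex",
         lpTolerance = LP_TOL, fcfTolerance = FCF_EPS,
         package = as.character(utils::packageVersion("fluxfit"))),
    file.path(outDir, "run_info.json"), auto_unbox = TRUE)
  invisible(NULL)
}
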