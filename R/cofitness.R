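#' Pairwise cofitness (Pearson correlation of fitness profiles)
#'
#' Cofitness of two genes is the Pearson correlation between their fitness
#' score vectors across experiments, computed on pairwise-complete
#' observations. Pairs with fewer overlapping experiments than
#' \code{minOverlap} are set to \code{NA}, as are pairs involving a
#' zero-variance profile.
#'
#' @param x a \code{\linkS4class{FitnessMatrix}}.
#' @param experiments optional experiment ids restricting the columns
#'   (e.g. the anaerobic subset).
#' @param minOverlap minimum number of overlapping experiments for a
#'   defined correlation.
#' @return An object of class \code{"cofitnessMatrix"}: list with \code{r}
#'   (symmetric gene x gene correlation matrix, unit diagonal), \code{n}
#'   (pairwise overlap counts) and \code{flagged} (zero-variance genes).
#' @export
cofitness <- function(x, experiments = NULL, minOverlap = 10) {
  sc <- fitnessScores(x)
  if (!is.null(experiments)) {
    unknown <- setdiff(experiments, colnames(sc))
    if (length(unknown))
      stop("unknown experiment id(s): ", paste(unknown, collapse = ", "))
    sc <- sc[, experiments, drop = FALSE]
  }
  m <- t(sc)                       # experiments x genes
  n <- crossprod(!is.na(m))        # pairwise overlap counts
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
  sds <- apply(sc, 1, stats::sd, na.rm = TRUE)
  flagged <- rownames(sc)[is.na(sds) | sds == 0]
  r[n < minOverlap] <- NA
  if (length(flagged)) {
    r[flagged, ] <- NA
    r[, flagged] <- NA
  }
  diag(r) <- 1
  structure(list(r = r, n = n, flagged = flagged),
            class = "cofitnessMatrix")
}

#' @export
print.cofitnessMatrix <- function(x, ...) {
  cat("cofitnessMatrix:", nrow(x$r), "genes;",
      sum(is.na(x$r[upper.tri(x$r)])), "undefined pairs;",
      length(x$flagged), "zero-variance genes\n")
  invisible(x)
}

## mean cofitness over all unordered pairs within `genes` (NA pairs dropped)
averageCofitness <- function(cof, geneIds) {
  geneIds <- intersect(geneIds, rownames(cof$r))
  if (length(geneIds) < 2) return(NA_real_)
  sub <- cof$r[geneIds, geneIds, drop = FALSE]
  vals <- sub[upper.tri(sub)]
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Size-calibrated null threshold for average cofitness
#'
#' Samples \code{nSamples} random gene sets of size \code{k} (without
#' replacement within a set) from a gene pool — by default the model genes
#' present in the fitness data — computes each set's average pairwise
#' cofitness, and returns the chosen percentile (default the 95th) of that
#' null distribution. Percentiles use linear interpolation between order
#' statistics (\code{stats::quantile} type 7) so thresholds are exactly
#' reproducible given the seed.
#'
#' @param cof a \code{"cofitnessMatrix"} from \code{\link{cofitness}}.
#' @param k module size (number of genes).
#' @param pool character vector of pool gene ids.
#' @param nSamples number of random sets (the reference analysis uses
#'   100,000; 10,000 gives thresholds within about 0.01).
#' @param percentile percentile of the null distribution, in (0, 100).
#' @param seed integer seed for the sampling stream.
#' @return list with \code{k}, \code{threshold}, \code{nSamples},
#'   \code{percentile}, \code{seed}.
#' @export
nullThreshold <- function(cof, k, pool, nSamples = 100000, percentile = 95,
                          seed = 1) {
  pool <- intersect(pool, rownames(cof$r))
  if (k > length(pool))
    stop("module size k exceeds pool size (", length(pool), ")")
  if (k < 2) stop("k must be >= 2")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  idx <- match(pool, rownames(cof$r))
  rmat <- cof$r
  old <- withSeed(seed)
  on.exit(restoreSeed(old))
  G <- replicate(nSamples, idx[sample.int(length(idx), k)])  # k x nSamples
  pairs <- utils::combn(k, 2)
  tot <- numeric(nSamples)
  cnt <- numeric(nSamples)
  for (p in seq_len(ncol(pairs))) {
    v <- rmat[cbind(G[pairs[1, p], ], G[pairs[2, p], ])]
    ok <- !is.na(v)
    tot[ok] <- tot[ok] + v[ok]
    cnt <- cnt + ok
  }
  avg <- ifelse(cnt > 0, tot / cnt, NA)
  thr <- unname(stats::quantile(avg, percentile / 100, na.rm = TRUE,
                                type = 7))
  list(k = k, threshold = thr, nSamples = nSamples,
       percentile = percentile, seed = seed)
}

## localized seed handling: set the seed, return previous .Random.seed
withSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Average cofitness of gene modules against size-matched null thresholds
#'
#' @param cof a \code{"cofitnessMatrix"}.
#' @param modules named list of character vectors (module gene sets), e.g.
#'   the \code{genes} element of \code{\link{mapModulesToGenes}} output.
#' @param pool gene pool for the null (see \code{\link{nullThreshold}}).
#' @inheritParams nullThreshold
#' @return data.frame with columns \code{module}, \code{k},
#'   \code{avgCofitness}, \code{threshold}, \code{significant}
#'   (strictly above the threshold).
#' @export
moduleCofitness <- function(cof, modules, pool, nSamples = 100000,
                            percentile = 95, seed = 1) {
  if (is.null(names(modules)))
    names(modules) <- paste0("M", seq_along(modules))
  ks <- vapply(modules, function(g)
    length(intersect(g, rownames(cof$r))), integer(1))
  thr <- rep(NA_real_, length(modules))
  for (k in sort(unique(ks[ks >= 2]))) {
    t_k <- nullThreshold(cof, k, pool, nSamples, percentile, seed)$threshold
    thr[ks == k] <- t_k
  }
  avg <- vapply(modules, function(g) averageCofitness(cof, g), numeric(1))
  data.frame(module = names(modules), k = ks, avgCofitness = avg,
             threshold = thr,
             significant = !is.na(avg) & !is.na(thr) & avg > thr,
             row.names = NULL)
}

#' Rank candidate genes for a module by average cofitness
#'
#' Ranks every gene outside the module by the mean of its cofitness values
#' with the module's genes (missing pairs dropped from the mean) — the
#' procedure used to propose genes for reactions lacking a GPR: the
#' orphan reaction's true gene should correlate with the rest of its
#' pathway. Ties break by locus-tag order.
#'
#' @param cof a \code{"cofitnessMatrix"}.
#' @param moduleGenes character vector of known module genes.
#' @param pool candidate search pool (default: all genes in \code{cof}).
#' @return data.frame with columns \code{gene} and \code{meanCofitness},
#'   sorted non-increasing.
#' @export
rankCandidates <- function(cof, moduleGenes, pool = rownames(cof$r)) {
  moduleGenes <- intersect(moduleGenes, rownames(cof$r))
  if (length(moduleGenes) == 0L) stop("no module genes present in cofitness")
  cand <- setdiff(intersect(pool, rownames(cof$r)), moduleGenes)
  sub <- cof$r[cand, moduleGenes, drop = FALSE]
  mc <- rowMeans(sub, na.rm = TRUE)
  mc[is.nan(mc)] <- NA
  out <- data.frame(gene = cand, meanCofitness = unname(mc))
  out <- out[order(-out$meanCofitness, out$gene, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Low-cofitness outlier genes within a module
#'
#' For each module member, the mean cofitness with the other members,
#' ascending — the first rows are the poorly correlated genes that drag a
#' module's average down (polar effects, mixed genotypes, mis-mapped
#' barcodes).
#'
#' @param cof a \code{"cofitnessMatrix"}.
#' @param moduleGenes character vector of module genes (needs >= 3).
#' @return data.frame with columns \code{gene} and \code{meanWithinModule},
#'   ascending.
#' @export
outlierGenes <- function(cof, moduleGenes) {
  moduleGenes <- intersect(moduleGenes, rownames(cof$r))
  if (length(moduleGenes) < 3) stop("need at least 3 module genes")
  sub <- cof$r[moduleGenes, moduleGenes, drop = FALSE]
  diag(sub) <- NA
  mw <- rowMeans(sub, na.rm = TRUE)
  out <- data.frame(gene = moduleGenes, meanWithinModule = unname(mw))
  out <- out[order(out$meanWithinModule, out$gene), ]
  rownames(out) <- NULL
  out
}
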