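## Shared fixtures and independent oracles, built in code at test time.

## Anaerobic fermentation toy with real formulas: glucose -> 2 ethanol + 2 CO2
ethanolToyModel <- function(uptake = 10) {
  mets <- data.frame(
    id = c("glc_e", "glc_c", "eth_c", "eth_e", "co2_c", "co2_e", "bm_c"),
    formula = c("C6H12O6", "C6H12O6", "C2H6O", "C2H6O", "CO2", "CO2", "X"),
    charge = 0L)
  rxns <- data.frame(
    id = c("EX_glc_e", "GLCt", "FERM", "ETHt", "EX_eth_e", "CO2t",
           "EX_co2_e", "BIOMASS"),
    equation = c("glc_e <=>", "glc_e -> glc_c",
                 "glc_c -> 2 eth_c + 2 co2_c", "eth_c -> eth_e",
                 "eth_e <=>", "co2_c -> co2_e", "co2_e <=>", "bm_c ->"),
    lower = c(-uptake, 0, 0, 0, 0, 0, 0, 0), upper = 1000,
    gpr = c("", "gT", "gA and gB", "gE1 or gE2", "", "", "", ""))
  MetabolicModel(mets, rxns, biomassId = "BIOMASS")
}

## Minimal growth model: substrate -> precursor -> biomass, isozyme transport
growthToyModel <- function() {
  mets <- data.frame(id = c("s_e", "s_c", "p_c"))
  rxns <- data.frame(
    id = c("EX_s_e", "TS", "CONV", "BIO"),
    equation = c("s_e <=>", "s_e -> s_c", "s_c -> p_c", "p_c ->"),
    lower = c(-10, 0, 0, 0), upper = 1000,
    gpr = c("", "gT1 or gT2", "gC1 and gC2", ""))
  MetabolicModel(mets, rxns, biomassId = "BIO")
}

## Random small irreversible network for solver / coupling oracles.
## Layered topology guarantees some flux paths exist: source exchange ->
## layer reactions -> sink exchange, with random branches and merges.
randomNetwork <- function(seed, nMet = 5, nRxn = 8) {
  set.seed(seed)
  metIds <- sprintf("m%d_c", seq_len(nMet))
  rxn <- list()
  addr <- function(id, eq) rxn[[length(rxn) + 1L]] <<- data.frame(
    id = id, equation = eq, lower = 0, upper = 1000,
    stringsAsFactors = FALSE)
  addr("SRC", paste("->", metIds[1]))
  addr("SNK", paste(metIds[nMet], "->"))
  pick <- function(v) v[sample.int(length(v), 1L)]   # safe for length 1
  for (k in seq_len(nRxn)) {
    i <- pick(seq_len(nMet - 1))
    j <- pick((i + 1):nMet)
    extra <- if (stats::runif(1) < 0.3 && j < nMet)
      paste(" +", metIds[pick(j:nMet)]) else ""
    addr(sprintf("R%d", k),
         paste0(metIds[i], " -> ", metIds[j], extra))
  }
  mets <- data.frame(id = metIds)
  MetabolicModel(mets, do.call(rbind, rxn))
}

## Brute-force LP oracle: enumerate candidate vertices from all n-subsets of
## the active-constraint rows. Only for very small problems.
bruteForceLP <- function(obj, A, dir, rhs, lb, ub, maximize = FALSE) {
  n <- ncol(A)
  rows <- rbind(A, diag(n), diag(n))
  rhsall <- c(rhs, lb, ub)
  finite <- is.finite(rhsall)
  best <- NULL
  combs <- utils::combn(nrow(rows), n)
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    if (!all(finite[idx])) next
    M <- rows[idx, , drop = FALSE]
    if (abs(det(M)) < 1e-9) next
    x <- solve(M, rhsall[idx])
    ok <- all(A %*% x <= rhs + 1e-7 | dir != "<=") &&
      all(A %*% x >= rhs - 1e-7 | dir != ">=") &&
      all(abs(A %*% x - rhs) <= 1e-7 | dir != "==") &&
      all(x >= lb - 1e-7) && all(x <= ub + 1e-7)
    if (ok) {
      v <- sum(obj * x)
      if (is.null(best) || (maximize && v > best) ||
          (!maximize && v < best)) best <- v
    }
  }
  best
}

## Independent flux-ratio oracle: bounded Charnes-Cooper formulation with an
## explicit homogenising variable t and the component flux caps as rows --
## a different LP from the package's cone normalisation.
oracleCouplingPair <- function(cm, i, j) {
  S <- cm@stoichiometry
  n <- ncol(S)
  ids <- cm@components$id
  ii <- match(i, ids); jj <- match(j, ids)
  ub <- cm@components$upper
  ## variables: w_1..w_n, t
  A <- rbind(cbind(S, 0),
             as.numeric(seq_len(n + 1) == jj),
             cbind(diag(n), -ub))
  dir <- c(rep("==", nrow(S)), "==", rep("<=", n))
  rhs <- c(rep(0, nrow(S)), 1, rep(0, n))
  obj <- numeric(n + 1); obj[ii] <- 1
  lo <- fluxfit:::solveLP(obj, A, dir, rhs, lb = 0, ub = Inf,
                          maximize = FALSE)
  hi <- fluxfit:::solveLP(obj, A, dir, rhs, lb = 0, ub = Inf,
                          maximize = TRUE)
  if (lo$status == "infeasible") return(NULL)   # j blocked
  Rmin <- max(lo$objval, 0)
  Rmax <- if (hi$status == "unbounded") Inf else hi$objval
  list(Rmin = Rmin, Rmax = Rmax,
       class = fluxfit:::classifyCoupling(Rmin, Rmax))
}

## exhaustive gap-fill oracle over candidate subsets
bruteForceGapfill <- function(model, candidates, newMetabolites = NULL,
                              growthThreshold = 1e-3, maxSize = 3) {
  n <- nrow(candidates)
  for (size in 0:min(maxSize, n)) {
    for (sel in (if (size == 0) list(integer())
                 else utils::combn(n, size, simplify = FALSE))) {
      sub <- candidates[sel, , drop = FALSE]
      m2 <- if (nrow(sub)) addReactions(model, sub, newMetabolites)
            else model
      fd <- fba(m2)
      if (fd@status == "optimal" && fd@objective >= growthThreshold)
        return(list(size = size, added = sub$id))
    }
  }
  list(size = NA_integer_, added = character())
}
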