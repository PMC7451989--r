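test_that("FBA reproduces stoichiometric doubling on the fermentation toy", {
  m <- ethanolToyModel(uptake = 10)
  fd <- fba(m, objective = "EX_eth_e")
  expect_identical(fd@status, "optimal")
  expect_equal(objectiveValue(fd), 20)        # glc -> 2 eth
  expect_equal(unname(fluxes(fd)[["EX_glc_e"]]), -10)
  ## steady state and bounds hold
  resid <- as.vector(stoichiometry(m) %*% fluxes(fd))
  expect_lt(max(abs(resid)), 1e-6)
  rx <- reactions(m)
  expect_true(all(fluxes(fd) >= rx$lower - 1e-6 &
                  fluxes(fd) <= rx$upper + 1e-6))
})

test_that("FBA optimum matches vertex enumeration on random networks", {
  for (seed in 1:10) {
    m <- randomNetwork(seed, nMet = 4, nRxn = 6)
    fd <- fba(m, objective = "SNK")
    rx <- reactions(m)
    S <- as.matrix(stoichiometry(m))
    bv <- bruteForceLP(as.numeric(rx$id == "SNK"), S,
                       rep("==", nrow(S)), rep(0, nrow(S)),
                       rx$lower, rx$upper, maximize = TRUE)
    expect_equal(objectiveValue(fd), bv, tolerance = 1e-6)
  }
})

test_that("extra constraints can pin fluxes (e.g. no lactate secretion)", {
  m <- ethanolToyModel()
  fd <- fba(m, objective = "EX_eth_e",
            constraints = data.frame(id = "EX_glc_e", lower = -5, upper = -5))
  expect_equal(objectiveValue(fd), 10)
  ## pinning the only pathway to zero removes all product flux
  fd0 <- fba(m, objective = "EX_eth_e",
             constraints = data.frame(id = "FERM", lower = 0, upper = 0))
  expect_equal(objectiveValue(fd0), 0)
})

test_that("FVA collapses on determined chains and spreads over branches", {
  ## fully determined linear chain: min = max everywhere
  mets <- data.frame(id = c("a_e", "a_c", "b_c", "b_e"))
  rxns <- data.frame(id = c("EX_a_e", "T1", "C1", "T2", "EX_b_e"),
    equation = c("a_e <=>", "a_e -> a_c", "a_c -> b_c", "b_c -> b_e",
                 "b_e <=>"),
    lower = c(-10, 0, 0, 0, 0), upper = c(-10, 1000, 1000, 1000, 1000))
  chain <- MetabolicModel(mets, rxns)
  v <- fva(chain, objective = "EX_b_e")
  expect_equal(v$min, v$max, tolerance = 1e-7)
  ## two equivalent parallel branches carrying total 10: each in [0, 10]
  mets2 <- data.frame(id = c("a_e", "a_c", "b_c"))
  rxns2 <- data.frame(id = c("EX_a_e", "T1", "B1", "B2", "SINK_b_c"),
    equation = c("a_e <=>", "a_e -> a_c", "a_c -> b_c", "a_c -> b_c",
                 "b_c ->"),
    lower = c(-10, 0, 0, 0, 0), upper = 1000)
  par2 <- MetabolicModel(mets2, rxns2)
  v2 <- fva(par2, objective = "SINK_b_c")
  expect_equal(unlist(v2[v2$id == "B1", c("min", "max")]),
               c(min = 0, max = 10), tolerance = 1e-7)
  expect_equal(unlist(v2[v2$id == "B2", c("min", "max")]),
               c(min = 0, max = 10), tolerance = 1e-7)
})

test_that("FVA ranges match per-reaction brute-force oracle", {
  for (seed in 11:15) {
    m <- randomNetwork(seed, nMet = 4, nRxn = 5)
    opt <- objectiveValue(fba(m, objective = "SNK"))
    rx <- reactions(m)
    S <- as.matrix(stoichiometry(m))
    A <- rbind(S, as.numeric(rx$id == "SNK"))
    dir <- c(rep("==", nrow(S)), ">=")
    rhs <- c(rep(0, nrow(S)), opt)
    v <- fva(m, objective = "SNK")
    for (k in seq_len(nrow(rx))) {
      obj <- as.numeric(seq_len(nrow(rx)) == k)
      lo <- bruteForceLP(obj, A, dir, rhs, rx$lower, rx$upper, FALSE)
      hi <- bruteForceLP(obj, A, dir, rhs, rx$lower, rx$upper, TRUE)
      expect_equal(v$min[k], lo, tolerance = 1e-6)
      expect_equal(v$max[k], hi, tolerance = 1e-6)
    }
  }
})

test_that("essentiality screen honours GPR logic", {
  m <- growthToyModel()
  ess <- essentialityScreen(m)
  ph <- stats::setNames(ess$phenotype, ess$gene)
  ## isozyme behind an OR survives; complex subunits are essential
  expect_identical(ph[["gT1"]], "Growth")
  expect_identical(ph[["gT2"]], "Growth")
  expect_identical(ph[["gC1"]], "NoGrowth")
  expect_identical(ph[["gC2"]], "NoGrowth")
  ## a gene whose reactions are blocked anyway cannot be essential
  m2 <- addReactions(m, data.frame(id = "DEAD", equation = "p_c -> d_c",
                                   lower = 0, upper = 1000, gpr = "gD",
                                   subsystem = "", kind = "metabolic"),
                     newMetabolites = data.frame(id = "d_c"))
  ess2 <- essentialityScreen(m2, geneIds = "gD")
  expect_identical(ess2$phenotype, "Growth")
})

test_that("uptake sweep is non-decreasing and linear for a yield model", {
  m <- growthToyModel()
  sw <- uptakeSweep(m, "EX_s_e", rates = c(0, 1, 2, 5, 10))
  expect_equal(sw$growth[1], 0)
  expect_true(all(diff(sw$growth) >= -1e-9))
  ## closed-form yield line: growth = uptake (1:1 pathway, no maintenance)
  expect_equal(sw$growth, sw$uptake, tolerance = 1e-7)
  expect_error(uptakeSweep(m, "EX_s_e", rates = c(-1, 2)), ">= 0")
})

test_that("MFA comparison flags exactly the planted outliers", {
  m <- ethanolToyModel()
  fd <- fba(m, objective = "EX_eth_e")
  ## identical vectors: fold 1, nothing flagged
  self <- compareToMFA(fd, fluxes(fd)[abs(fluxes(fd)) > 1e-9])
  expect_true(all(abs(self$fold - 1) < 1e-9))
  expect_false(any(self$outlier))
  ## constructed table with 3 planted >2-fold entries
  meas <- fluxes(fd)[c("GLCt", "FERM", "ETHt", "EX_eth_e", "CO2t")]
  meas[c("FERM", "ETHt", "CO2t")] <- meas[c("FERM", "ETHt", "CO2t")] * 2.5
  cmp <- compareToMFA(fd, meas)
  expect_setequal(cmp$reaction[cmp$outlier], c("FERM", "ETHt", "CO2t"))
  ## predicted 4 vs measured 1 is an outlier; zero predictions hit the floor
  fd2 <- methods::new("FluxDistribution",
                      fluxes = c(R1 = 4, R2 = 0), objective = 1,
                      objectiveReaction = "R1", status = "optimal")
  cmp2 <- compareToMFA(fd2, c(R1 = 1, R2 = 1))
  expect_true(cmp2$outlier[cmp2$reaction == "R1"])
  expect_equal(cmp2$fold[cmp2$reaction == "R2"], 1e-4)
})
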