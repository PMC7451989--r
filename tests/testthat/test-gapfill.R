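test_that("gap filling finds minimum-cardinality additions", {
  m <- growthToyModel()
  ## already-growing model needs nothing
  gf0 <- minAdditionsGapfill(m, data.frame(id = "X", equation = "s_c -> p_c",
                                           lower = 0, upper = 1000))
  expect_identical(gf0$status, "already_growing")
  expect_identical(gf0$size, 0L)
  ## break the pathway: one 1-reaction fill beats the 2-reaction detour
  broken <- setBounds(m, "CONV", 0, 0)
  cand <- data.frame(id = c("ALT1", "ALT2a", "ALT2b"),
                     equation = c("s_c -> p_c", "s_c -> x_c", "x_c -> p_c"),
                     lower = 0, upper = 1000)
  gf <- minAdditionsGapfill(broken, cand,
                            newMetabolites = data.frame(id = "x_c"))
  expect_identical(gf$status, "filled")
  expect_identical(gf$added, "ALT1")
  ## with only the detour available, both reactions are needed
  gf2 <- minAdditionsGapfill(broken, cand[2:3, ],
                             newMetabolites = data.frame(id = "x_c"))
  expect_identical(sort(gf2$added), c("ALT2a", "ALT2b"))
  ## candidates that cannot restore growth
  gf3 <- minAdditionsGapfill(broken,
                             data.frame(id = "U", equation = "s_c -> s_e",
                                        lower = 0, upper = 1000))
  expect_identical(gf3$status, "unfillable")
})

test_that("gap-fill size equals exhaustive-search minimum on random cases", {
  set.seed(33)
  for (trial in 1:12) {
    m <- growthToyModel()
    broken <- setBounds(m, "CONV", 0, 0)
    nCand <- sample(4:8, 1)
    ## random candidate pool: mostly useless conversions through new
    ## metabolites, with a planted detour of random length 1-3
    newMets <- data.frame(id = sprintf("x%d_c", 1:4))
    detour <- sample(1:3, 1)
    hops <- c("s_c", sample(newMets$id, detour - 1), "p_c")
    cand <- data.frame(id = sprintf("D%d", seq_len(detour)),
                       equation = sprintf("%s -> %s", hops[-length(hops)],
                                          hops[-1]),
                       lower = 0, upper = 1000)
    extra <- nCand - detour
    if (extra > 0) {
      src <- sample(newMets$id, extra, replace = TRUE)
      dst <- sample(newMets$id, extra, replace = TRUE)
      keep <- src != dst
      if (any(keep))
        cand <- rbind(cand, data.frame(
          id = sprintf("junk%d", which(keep)),
          equation = sprintf("%s -> %s", src[keep], dst[keep]),
          lower = 0, upper = 1000))
    }
    gf <- minAdditionsGapfill(broken, cand, newMetabolites = newMets)
    bf <- bruteForceGapfill(broken, cand, newMetabolites = newMets)
    expect_identical(gf$size, as.integer(bf$size))
  }
})

test_that("secretion gap fill rescues a node imbalanced by biomass demand", {
  ## fumarate-like node: biomass-locked production exceeds locked
  ## consumption; fumarase is the only free consumer. Deleting it makes
  ## the model infeasible, and adding a secretion route (sink) repairs it.
  mets <- data.frame(id = c("sub_e", "sub_c", "prec_c", "fum_c", "q_c",
                            "w_c"))
  rxns <- data.frame(
    id = c("EX_sub_e", "TS", "R1", "R2", "FUMASE", "SINK_w_c", "BIOMASS"),
    equation = c("sub_e <=>", "sub_e -> sub_c",
                 "sub_c -> prec_c + 2 fum_c", "fum_c -> q_c",
                 "fum_c -> w_c", "w_c ->", "prec_c + 0.5 q_c ->"),
    lower = c(-100, 0, 0, 0, 0, 0, 0), upper = 1000,
    gpr = c("", "", "", "", "gFUM", "", ""))
  m <- MetabolicModel(mets, rxns, biomassId = "BIOMASS")
  ## fumarase mutant: no steady state
  ess <- essentialityScreen(m, geneIds = "gFUM")
  expect_identical(ess$phenotype, "NoGrowth")
  broken <- setBounds(m, "FUMASE", 0, 0)
  ## candidate pool: secretion (sink) reactions for internal metabolites
  cand <- data.frame(id = c("SINK_fum_c", "SINK_q_c"),
                     equation = c("fum_c ->", "q_c ->"),
                     lower = 0, upper = 1000)
  gf <- minAdditionsGapfill(broken, cand)
  ## either secretion route alone rebalances the node: a size-1 fill
  expect_identical(gf$size, 1L)
  expect_true(gf$added %in% c("SINK_fum_c", "SINK_q_c"))
  ## fumarate secretion specifically restores growth
  fixed <- addReactions(broken, cand[cand$id == "SINK_fum_c", ])
  expect_gt(objectiveValue(fba(fixed)), 1e-3)
})

test_that("node diagnosis separates biomass-locked from free reactions", {
  mets <- data.frame(id = c("sub_e", "sub_c", "prec_c", "fum_c", "q_c",
                            "w_c"))
  rxns <- data.frame(
    id = c("EX_sub_e", "TS", "R1", "R2", "FUMASE", "SINK_w_c", "BIOMASS"),
    equation = c("sub_e <=>", "sub_e -> sub_c",
                 "sub_c -> prec_c + 2 fum_c", "fum_c -> q_c",
                 "fum_c -> w_c", "w_c ->", "prec_c + 0.5 q_c ->"),
    lower = c(-100, 0, 0, 0, 0, 0, 0), upper = 1000)
  m <- MetabolicModel(mets, rxns, biomassId = "BIOMASS")
  ## locked production 2*mu, locked consumption 0.5*mu -> balance 1.5 at mu=1
  rep <- fumarateNodeReport(m, "fum_c", growthRate = 1)
  expect_equal(rep$balancingFlux, 1.5, tolerance = 1e-6)
  locked <- rep$reactions$id[rep$reactions$locked]
  expect_setequal(locked, c("R1", "R2"))
  expect_false("FUMASE" %in% locked)
  ## node on a free side branch (no biomass-locked reactions): zero balance
  mets2 <- data.frame(id = c("s_e", "s_c", "p_c", "w_c", "v_c"))
  rxns2 <- data.frame(id = c("EX_s_e", "TS", "CONV", "W1", "W2",
                             "SINK_v_c", "BIO"),
    equation = c("s_e <=>", "s_e -> s_c", "s_c -> p_c", "s_c -> w_c",
                 "w_c -> v_c", "v_c ->", "p_c ->"),
    lower = c(-10, 0, 0, 0, 0, 0, 0), upper = 1000)
  m2 <- MetabolicModel(mets2, rxns2, biomassId = "BIO")
  rep2 <- fumarateNodeReport(m2, "w_c", growthRate = 1)
  expect_true(all(!rep2$reactions$locked))
  expect_equal(rep2$balancingFlux, 0, tolerance = 1e-6)
})

test_that("conditional-essentiality design recovers the planted knockout", {
  ## target CONV has a bypass; only deleting the bypass gene makes the
  ## target essential, which exhaustive single-knockout search must find
  m <- growthToyModel()
  m2 <- addReactions(m, data.frame(id = "BYP", equation = "s_c -> p_c",
                                   lower = 0, upper = 1000, gpr = "gB",
                                   subsystem = "", kind = "metabolic"))
  medcat <- list(minimal = medium(c(EX_s_e = 10)))
  des <- megsDesign(m2, "CONV", medcat, maxKnockouts = 1)
  expect_identical(des$knockouts, "gB")
  expect_identical(des$medium, "minimal")
  ## target already essential: the empty knockout set qualifies
  des0 <- megsDesign(m, "CONV", medcat, maxKnockouts = 1)
  expect_true("" %in% des0$knockouts)
})
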