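test_that("reversible splitting produces the expected components", {
  mets <- data.frame(id = c("a_c", "b_c"))
  rxns <- data.frame(id = c("IN", "R1", "OUT"),
                     equation = c("-> a_c", "a_c <=> b_c", "b_c ->"),
                     lower = c(0, -500, 0), upper = c(1000, 800, 1000))
  m <- MetabolicModel(mets, rxns)
  cm <- splitReversible(m)
  expect_identical(nrow(cm@components), 4L)   # 2 irreversible + 2*1 reversible
  expect_setequal(cm@components$id, c("IN_f", "R1_f", "R1_r", "OUT_f"))
  r1f <- cm@components[cm@components$id == "R1_f", ]
  r1r <- cm@components[cm@components$id == "R1_r", ]
  expect_equal(r1f$upper, 800)
  expect_equal(r1r$upper, 500)
  ## reverse component stoichiometry is the negated original
  expect_equal(cm@stoichiometry[, "R1_r"], -cm@stoichiometry[, "R1_f"])
})

test_that("splitting preserves the FBA optimum", {
  for (seed in 21:25) {
    m <- randomNetwork(seed)
    opt <- objectiveValue(fba(m, objective = "SNK"))
    cm <- splitReversible(m)
    expect_equal(componentFBA(cm, "SNK_f")$objval, opt, tolerance = 1e-7)
  }
})

test_that("consecutive chain components are fully coupled at ratio 1", {
  mets <- data.frame(id = c("a_c", "b_c", "c_c"))
  rxns <- data.frame(id = c("IN", "R1", "R2", "OUT"),
                     equation = c("-> a_c", "a_c -> b_c", "b_c -> c_c",
                                  "c_c ->"),
                     lower = 0, upper = 1000)
  cm <- splitReversible(MetabolicModel(mets, rxns))
  cp <- couplingPair(cm, "R1_f", "R2_f")
  expect_identical(cp$class, "fully")
  expect_equal(cp$Rmin, 1, tolerance = 1e-6)
  expect_equal(cp$Rmax, 1, tolerance = 1e-6)
})

test_that("a branch point yields directional coupling", {
  ## A -> B with B -> C and B -> D: flux through B->C forces A->B but not
  ## conversely
  mets <- data.frame(id = c("a_c", "b_c", "c_c", "d_c"))
  rxns <- data.frame(id = c("IN", "AB", "BC", "BD", "OUTC", "OUTD"),
                     equation = c("-> a_c", "a_c -> b_c", "b_c -> c_c",
                                  "b_c -> d_c", "c_c ->", "d_c ->"),
                     lower = 0, upper = 1000)
  cm <- splitReversible(MetabolicModel(mets, rxns))
  cp <- couplingPair(cm, "BC_f", "AB_f")
  expect_identical(cp$class, "directional_i_to_j")
  cp2 <- couplingPair(cm, "AB_f", "BC_f")
  expect_identical(cp2$class, "directional_j_to_i")
  ## the two parallel branches are uncoupled
  cp3 <- couplingPair(cm, "BC_f", "BD_f")
  expect_identical(cp3$class, "uncoupled")
  ## blocked j is an error directing to the prefilter
  mets2 <- data.frame(id = c("a_c", "x_c"))
  rxns2 <- data.frame(id = c("IN", "DEADEND", "OUT"),
                      equation = c("-> a_c", "a_c -> x_c", "a_c ->"),
                      lower = 0, upper = 1000)
  cm2 <- splitReversible(MetabolicModel(mets2, rxns2))
  expect_error(couplingPair(cm2, "IN_f", "DEADEND_f"), "blocked")
})

test_that("ratio intervals are reciprocal under argument swap", {
  for (seed in 31:35) {
    cm <- splitReversible(randomNetwork(seed))
    unblocked <- setdiff(cm@components$id, blockedComponents(cm))
    if (length(unblocked) < 2) next
    pick <- utils::combn(unblocked, 2)[, 1:min(5, choose(length(unblocked), 2)),
                                       drop = FALSE]
    for (k in seq_len(ncol(pick))) {
      a <- couplingPair(cm, pick[1, k], pick[2, k])
      b <- couplingPair(cm, pick[2, k], pick[1, k])
      ## Rmin(i,j) = 1/Rmax(j,i), with 0 <-> Inf
      expect_equal(a$Rmin, if (is.finite(b$Rmax) && b$Rmax > 0) 1 / b$Rmax
                           else 0, tolerance = 1e-5)
      expect_equal(b$Rmin, if (is.finite(a$Rmax) && a$Rmax > 0) 1 / a$Rmax
                           else 0, tolerance = 1e-5)
    }
  }
})

test_that("full coupling behaves as an equivalence relation", {
  ## 5-reaction linear pathway: one fully coupled module of size 5 (+ sink)
  mets <- data.frame(id = sprintf("m%d_c", 1:5))
  eqs <- c("-> m1_c", sprintf("m%d_c -> m%d_c", 1:4, 2:5), "m5_c ->")
  rxns <- data.frame(id = c("IN", sprintf("R%d", 1:4), "OUT"),
                     equation = eqs, lower = 0, upper = 1000)
  cm <- splitReversible(MetabolicModel(mets, rxns))
  ca <- couplingAll(cm)
  expect_length(ca$modules, 1L)
  expect_identical(ca$modules[[1]]$class, "fully")
  expect_length(ca$modules[[1]]$components, 6L)
  ## pairwise symmetry and transitivity on the module members
  comps <- ca$modules[[1]]$components
  for (k in 1:4) {
    i <- sample(comps, 1); j <- sample(setdiff(comps, i), 1)
    expect_identical(couplingPair(cm, i, j)$class, "fully")
    expect_identical(couplingPair(cm, j, i)$class, "fully")
  }
})

test_that("pairwise classes match the independent Charnes-Cooper oracle", {
  for (seed in 41:46) {
    cm <- splitReversible(randomNetwork(seed, nMet = 4, nRxn = 6))
    unblocked <- setdiff(cm@components$id, blockedComponents(cm))
    pairs <- utils::combn(unblocked, 2)
    context <- fluxfit:::couplingLPContext(cm)
    for (k in seq_len(ncol(pairs))) {
      got <- couplingPair(cm, pairs[1, k], pairs[2, k], context = context)
      want <- oracleCouplingPair(cm, pairs[1, k], pairs[2, k])
      expect_identical(got$class, want$class)
      expect_equal(got$Rmin, want$Rmin, tolerance = 1e-5)
      if (is.finite(want$Rmax)) {
        expect_equal(got$Rmax, want$Rmax, tolerance = 1e-5)
      } else {
        expect_identical(got$Rmax, Inf)
      }
    }
  }
})

test_that("module partition is invariant to component enumeration order", {
  toy <- makeToyModel(nPathways = 3, pathwayLength = 3)
  cm <- couplingModel(toy$model)
  ca1 <- couplingAll(cm)
  perm <- rev(seq_len(ncol(cm@stoichiometry)))
  cm2 <- cm
  cm2@stoichiometry <- cm2@stoichiometry[, perm]
  cm2@components <- cm2@components[perm, ]
  ca2 <- couplingAll(cm2)
  mods1 <- lapply(Filter(function(m) m$class == "fully", ca1$modules),
                  function(m) sort(m$components))
  mods2 <- lapply(Filter(function(m) m$class == "fully", ca2$modules),
                  function(m) sort(m$components))
  expect_setequal(mods1, mods2)
})

test_that("per-precursor sinks split the aggregate biomass module", {
  toy <- makeToyModel(nPathways = 3, pathwayLength = 3)
  m <- toy$model
  ## without sinks, coupling through the intact biomass reaction welds all
  ## pathways into one module
  noSinks <- splitReversible(openAllExchanges(m))
  caNo <- couplingAll(noSinks)
  fullNo <- Filter(function(x) x$class == "fully", caNo$modules)
  expect_length(fullNo, 1L)
  expect_true(all(unlist(lapply(toy$truth$pathwayReactions, paste0, "_f"))
                  %in% fullNo[[1]]$components))
  ## with per-precursor sinks (and biomass retired) the module splits
  withSinks <- couplingModel(m)
  caYes <- couplingAll(withSinks)
  fullYes <- Filter(function(x) x$class == "fully", caYes$modules)
  expect_length(fullYes, 3L)
})

test_that("module gene mapping excludes isozymes and orphan reactions", {
  toy <- makeToyModel(nPathways = 2, pathwayLength = 3,
                      orphanAt = data.frame(pathway = 1, position = 2),
                      isozymeAt = data.frame(pathway = 2, position = 1))
  ca <- couplingAll(couplingModel(toy$model))
  mods <- mapModulesToGenes(Filter(function(m) m$class == "fully",
                                   ca$modules),
                            toy$model, fitnessGenes = c("g1_1", "g2_2"))
  byFirst <- vapply(mods, function(m) m$components[1], character(1))
  m1 <- mods[[grep("R1_1", byFirst)]]
  m2 <- mods[[grep("R2_1", byFirst)]]
  ## orphan reaction contributes no gene
  expect_setequal(m1$genes, c("g1_1", "g1_3"))
  ## isozyme genes are excluded from the module set
  expect_setequal(m2$genes, c("g2_2", "g2_3"))
  expect_identical(m1$mutants, "g1_1")
  expect_identical(m2$mutants, "g2_2")
})

test_that("tightening constraints only adds couplings", {
  ## oxygen-dependent bypass: closing O2 couples the anaerobic branch in
  mets <- data.frame(id = c("s_e", "o2_e", "s_c", "o2_c", "i1_c", "p_c"))
  rxns <- data.frame(
    id = c("EX_s_e", "EX_o2_e", "TS", "TO2", "R1", "R2ana", "R2aer", "BIO"),
    equation = c("s_e <=>", "o2_e <=>", "s_e -> s_c", "o2_e -> o2_c",
                 "s_c -> i1_c", "i1_c -> p_c", "i1_c + o2_c -> p_c",
                 "p_c ->"),
    lower = c(-10, -10, 0, 0, 0, 0, 0, 0), upper = 1000)
  m <- MetabolicModel(mets, rxns, biomassId = "BIO")
  cm <- couplingModel(m)
  base <- couplingAll(cm)
  cc <- conditionCoupling(cm, data.frame(reaction = "EX_o2_e", upper = 0),
                          base)
  mainMod <- Filter(function(x) "R1_f" %in% x$components,
                    Filter(function(x) x$class == "fully", base$modules))
  expect_length(mainMod, 1L)
  expect_true("R2ana_f" %in% cc$additions[[mainMod[[1]]$id]])
  ## baseline full couplings among still-available components are preserved
  for (bm in Filter(function(x) x$class == "fully", base$modules)) {
    live <- setdiff(bm$components, cc$unavailable)
    if (length(live) < 2) next
    stillThere <- any(vapply(cc$conditionModules, function(x)
      all(live %in% x$components), logical(1)))
    expect_true(stillThere)
  }
  ## no constraint change: no additions
  cc0 <- conditionCoupling(cm, data.frame(reaction = character(),
                                          upper = numeric()), base)
  expect_true(all(lengths(cc0$additions) == 0))
})
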