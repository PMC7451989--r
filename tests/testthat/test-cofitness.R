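simFM <- function(sc) {
  md <- data.frame(experiment = colnames(sc),
                   anaerobic = FALSE, medium = "m")
  FitnessMatrix(sc, md)
}

test_that("cofitness is Pearson correlation with unit diagonal", {
  set.seed(21)
  base <- stats::rnorm(50)
  sc <- rbind(g1 = base,
              g2 = 2 * base + 1,              # affine image: r = 1
              g3 = -base,                     # r = -1
              g4 = stats::rnorm(50))
  colnames(sc) <- sprintf("e%02d", 1:50)
  cof <- cofitness(simFM(sc))
  expect_equal(diag(cof$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cof$r["g1", "g2"], 1, tolerance = 1e-12)
  expect_equal(cof$r["g1", "g3"], -1, tolerance = 1e-12)
  expect_equal(cof$r, t(cof$r))
  expect_true(all(abs(cof$r) <= 1 + 1e-12))
  ## per-gene affine transforms leave cofitness unchanged
  sc2 <- sc
  sc2["g4", ] <- 3 * sc2["g4", ] - 7
  cof2 <- cofitness(simFM(sc2))
  expect_equal(cof$r, cof2$r, tolerance = 1e-12)
})

test_that("sampled correlation concentrates around the true value", {
  ## bivariate normal with rho = 0.7 across n = 492 experiments
  set.seed(77)
  n <- 492
  z1 <- stats::rnorm(n)
  z2 <- 0.7 * z1 + sqrt(1 - 0.49) * stats::rnorm(n)
  sc <- rbind(gA = z1, gB = z2)
  colnames(sc) <- sprintf("e%03d", seq_len(n))
  cof <- cofitness(simFM(sc))
  expect_lt(abs(cof$r["gA", "gB"] - 0.7), 0.06)
})

test_that("low overlap and zero variance yield missing correlations", {
  sc <- rbind(g1 = c(stats::rnorm(12), rep(NA, 8)),
              g2 = c(rep(NA, 8), stats::rnorm(12)),
              g3 = rep(1, 20),
              g4 = stats::rnorm(20))
  colnames(sc) <- sprintf("e%02d", 1:20)
  cof <- cofitness(simFM(sc), minOverlap = 10)
  expect_true(is.na(cof$r["g1", "g2"]))     # only 4 shared experiments
  expect_false(is.na(cof$r["g1", "g4"]))
  expect_identical(cof$flagged, "g3")       # zero variance
  expect_true(all(is.na(cof$r["g3", c("g1", "g2", "g4")])))
  ## experiment subsetting restricts the columns used
  cofSub <- cofitness(simFM(sc), experiments = sprintf("e%02d", 1:12))
  expect_true(is.na(cofSub$r["g2", "g4"]))  # g2 has 4 values there
  expect_error(cofitness(simFM(sc), experiments = "eXX"),
               "unknown experiment")
})

test_that("null thresholds: degenerate case, monotonicity, reproducibility", {
  ## identical fitness vectors: every sampled average is 1
  sc <- matrix(rep(stats::rnorm(30), each = 12), 12, 30,
               dimnames = list(sprintf("g%02d", 1:12),
                               sprintf("e%02d", 1:30)))
  cofSame <- cofitness(simFM(sc))
  tau <- nullThreshold(cofSame, k = 3, pool = rownames(sc),
                       nSamples = 500, seed = 4)
  expect_equal(tau$threshold, 1, tolerance = 1e-12)
  ## i.i.d. null: averaging more pairs shrinks the upper tail
  set.seed(31)
  sc2 <- matrix(stats::rnorm(200 * 100), 200, 100,
                dimnames = list(sprintf("g%03d", 1:200),
                                sprintf("e%03d", 1:100)))
  cof <- cofitness(simFM(sc2))
  t3 <- nullThreshold(cof, 3, rownames(sc2), nSamples = 10000, seed = 8)
  t10 <- nullThreshold(cof, 10, rownames(sc2), nSamples = 10000, seed = 8)
  expect_gt(t3$threshold, t10$threshold)
  ## bit-reproducible given the seed; different seeds differ
  t3b <- nullThreshold(cof, 3, rownames(sc2), nSamples = 10000, seed = 8)
  expect_identical(t3$threshold, t3b$threshold)
  t3c <- nullThreshold(cof, 3, rownames(sc2), nSamples = 10000, seed = 9)
  expect_false(identical(t3$threshold, t3c$threshold))
  ## reduced-sample run close to a larger run
  tBig <- nullThreshold(cof, 3, rownames(sc2), nSamples = 100000, seed = 8)
  expect_lt(abs(t3$threshold - tBig$threshold), 0.01)
  expect_error(nullThreshold(cof, 500, rownames(sc2)), "pool")
})

test_that("module averages and significance flags are computed per size", {
  set.seed(41)
  shared <- stats::rnorm(60)
  sc <- rbind(a1 = shared + stats::rnorm(60, 0, 0.3),
              a2 = shared + stats::rnorm(60, 0, 0.3),
              a3 = shared + stats::rnorm(60, 0, 0.3),
              matrix(stats::rnorm(40 * 60), 40, 60,
                     dimnames = list(sprintf("bg%02d", 1:40), NULL)))
  colnames(sc) <- sprintf("e%02d", 1:60)
  cof <- cofitness(simFM(sc))
  ## two genes with known r: average equals that r
  r12 <- cof$r["a1", "a2"]
  mc <- moduleCofitness(cof, list(pair = c("a1", "a2"),
                                  trio = c("a1", "a2", "a3"),
                                  null3 = c("bg01", "bg02", "bg03")),
                        pool = rownames(sc), nSamples = 2000, seed = 2)
  expect_equal(mc$avgCofitness[mc$module == "pair"], r12)
  expect_true(mc$significant[mc$module == "trio"])
  expect_false(mc$significant[mc$module == "null3"])
})

test_that("candidate ranking places a module-matched profile first", {
  set.seed(51)
  shared <- stats::rnorm(80)
  sc <- rbind(m1 = shared + stats::rnorm(80, 0, 0.2),
              m2 = shared + stats::rnorm(80, 0, 0.2),
              m3 = shared + stats::rnorm(80, 0, 0.2),
              hit = shared + stats::rnorm(80, 0, 0.2),
              matrix(stats::rnorm(30 * 80), 30, 80,
                     dimnames = list(sprintf("bg%02d", 1:30), NULL)))
  colnames(sc) <- sprintf("e%02d", 1:80)
  cof <- cofitness(simFM(sc))
  rk <- rankCandidates(cof, c("m1", "m2", "m3"))
  expect_identical(rk$gene[1], "hit")
  expect_false(any(c("m1", "m2", "m3") %in% rk$gene))
  expect_true(all(diff(rk$meanCofitness) <= 1e-12))
  ## invariant to module gene ordering
  rk2 <- rankCandidates(cof, c("m3", "m1", "m2"))
  expect_identical(rk, rk2)
  ## a gene equal to a member correlates near the internal average
  internal <- fluxfit:::averageCofitness(cof, c("m1", "m2", "m3"))
  expect_lt(abs(rk$meanCofitness[1] - internal), 0.1)
})

test_that("outlier genes surface the poorly correlated member", {
  set.seed(61)
  shared <- stats::rnorm(70)
  sc <- rbind(m1 = shared + stats::rnorm(70, 0, 0.2),
              m2 = shared + stats::rnorm(70, 0, 0.2),
              m3 = shared + stats::rnorm(70, 0, 0.2),
              polar = -shared + stats::rnorm(70, 0, 0.2))
  colnames(sc) <- sprintf("e%02d", 1:70)
  cof <- cofitness(simFM(sc))
  out <- outlierGenes(cof, c("m1", "m2", "m3", "polar"))
  expect_identical(out$gene[1], "polar")
  expect_lt(out$meanWithinModule[1], 0)
  expect_error(outlierGenes(cof, c("m1", "m2")), "at least 3")
})
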