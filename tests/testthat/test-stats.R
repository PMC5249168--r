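mkSeries <- function(states, restype = "PHE", condition = "solution",
                     copy = "A") {
  new("RotamerStateSeries", chain = "A", resno = 1L, restype = restype,
      condition = condition, chainCopy = copy, states = as.integer(states))
}

test_that("distributions count, pool and window correctly", {
  d <- buildDistribution(mkSeries(c(1, 1, 2, 2)), testLib)
  expect_equal(probabilities(d), c(0.5, 0.5, 0, 0))
  pooled <- buildDistribution(list(mkSeries(c(1, 1), copy = "A1"),
                                   mkSeries(c(2, 2), copy = "A2")),
                              testLib)
  expect_equal(probabilities(pooled), c(0.5, 0.5, 0, 0))
  expect_identical(nFrames(pooled), 4L)
  lastHalf <- buildDistribution(mkSeries(c(1, 1, 1, 2, 2, 2)), testLib,
                                window = "lastHalf")
  expect_equal(probabilities(lastHalf), c(0, 1, 0, 0))
  expect_error(buildDistribution(mkSeries(1:2), testLib,
                                 window = integer(0)), "empty")
  expect_error(buildDistribution(list(mkSeries(1), mkSeries(1, restype = "SER")),
                                 testLib), "share")
})

test_that("overlap coefficient matches hand-computed values and its
           L1 identity", {
  expect_equal(overlapCoefficient(c(0.6, 0.4, 0), c(0.2, 0.3, 0.5)), 0.5)
  expect_equal(overlapCoefficient(c(1, 0), c(0, 1)), 0)
  expect_equal(overlapCoefficient(c(0.3, 0.7), c(0.3, 0.7)), 1)
  expect_error(overlapCoefficient(c(1, 0), c(1, 0, 0)), "length")
  set.seed(3)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    p <- runif(n); p <- p / sum(p)
    q <- runif(n); q <- q / sum(q)
    oc <- overlapCoefficient(p, q)
    expect_gte(oc, 0); expect_lte(oc, 1)
    expect_equal(1 - oc, sum(abs(p - q)) / 2, tolerance = 1e-12)
    expect_equal(oc, overlapCoefficient(q, p))
    expect_identical(oc == 1, isTRUE(all.equal(p, q, tolerance = 1e-12)))
  }
})

test_that("KL divergence has the closed-form values and Gibbs bound", {
  expect_equal(klDivergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), log(2))
  expect_warning(inf <- klDivergence(c(0.7, 0.3), c(1, 0)), "infinite")
  expect_identical(inf, Inf)
  expect_true(is.finite(klDivergence(c(0.7, 0.3), c(1, 0),
                                     pseudocount = 1e-3)))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(4); p <- p / sum(p)
    q <- runif(4); q <- q / sum(q)
    expect_gte(klDivergence(p, q), 0)
  }
})

test_that("configurational entropy has its closed forms and extremes", {
  kT <- 0.0019872 * 300
  expect_equal(confEntropy(c(1, 0, 0)), 0)
  expect_equal(confEntropy(rep(0.2, 5)), kT * log(5), tolerance = 1e-12)
  expect_equal(confEntropy(rep(1 / 3, 3)), 0.655, tolerance = 1e-3)
  expect_equal(deltaEntropy(rep(0.2, 5), c(1, 0, 0, 0, 0)), -kT * log(5))
  expect_equal(deltaEntropy(c(1, 0, 0, 0, 0), rep(0.2, 5)), kT * log(5))
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    p <- runif(n); p <- p / sum(p)
    expect_lte(confEntropy(p), confEntropy(rep(1 / n, n)) + 1e-12)
    expect_equal(deltaEntropy(p, rev(p)), -deltaEntropy(rev(p), p))
  }
})

test_that("likelihood score normalizes by the per-residue null model", {
  mkDist <- function(p, rt) new("RotamerDistribution", chain = "A",
                                resno = 1L, restype = rt,
                                condition = "solution", probabilities = p,
                                nFrames = 100L)
  uni <- mkDist(rep(0.25, 4), "PHE")
  expect_equal(likelihoodScore(list(uni), 3L), 1)
  delta <- mkDist(c(0, 0, 1, 0), "PHE")
  expect_equal(likelihoodScore(list(delta), 3L), 4)
  two <- list(mkDist(c(0.8, 0.1, 0.05, 0.05), "PHE"),
              mkDist(c(0.3, 0.4, 0.3), "SER"))
  expect_equal(likelihoodScore(two, c(1L, 1L)), (3.2 + 0.9) / 2)
  expect_warning(likelihoodScore(two, c(1L, NA)), "excluded")
  expect_equal(likelihoodQuotient(3.42, 2.49), 1.37, tolerance = 5e-3)
  expect_equal(likelihoodQuotient(2, 4), 0.5)
  expect_error(likelihoodQuotient(1, 0), "zero")
})

test_that("X-ray agreement uses the two dominant sampled rotamers", {
  mkDist <- function(p) new("RotamerDistribution", chain = "A", resno = 1L,
                            restype = "PHE", condition = "crystal",
                            probabilities = p, nFrames = 1000L)
  d <- mkDist(c(0.5, 0.3, 0.15, 0.05))
  expect_true(rotamerAgreement(d, 1L))
  expect_true(rotamerAgreement(d, 2L))
  expect_false(rotamerAgreement(d, 3L))
  # zero-probability bins are never "dominant", even when fewer than two
  # states were visited
  expect_false(rotamerAgreement(mkDist(c(1, 0, 0, 0)), 2L))
  # ties for second place are all included
  expect_true(rotamerAgreement(mkDist(c(0.5, 0.25, 0.25, 0)), 3L))
  # tolerance mode: X-ray chis must match a dominant state's modal angles
  modal <- modalChis(testLib, "PHE")
  expect_true(rotamerAgreement(d, xrayChis = modal[1, ] + 10,
                               library = testLib, mode = "tolerance"))
  expect_false(rotamerAgreement(d, xrayChis = modal[4, ],
                                library = testLib, mode = "tolerance"))
})

test_that("region classification reproduces the worked examples", {
  expect_identical(as.character(classifyRegion(0.83, -0.10)), "I")
  expect_identical(as.character(classifyRegion(0.32, -1.06)), "III")
  expect_identical(as.character(classifyRegion(0.06, -0.36)), "II")
  # boundaries are inclusive toward "unchanged"
  expect_identical(as.character(classifyRegion(0.5, 0.5)), "I")
  expect_identical(as.character(classifyRegion(0.5, -0.51)), "IV")
  expect_identical(as.character(classifyRegion(0.49, 0.51)), "III")
})

test_that("statistics agree with direct enumeration on toy distributions",
{
  # independent oracle: plain arithmetic on 3-4 state vectors
  cases <- list(list(p = c(0.5, 0.5, 0), q = c(0.25, 0.25, 0.5)),
                list(p = c(0.1, 0.2, 0.3, 0.4), q = c(0.4, 0.3, 0.2, 0.1)),
                list(p = c(1, 0, 0), q = c(0, 1, 0)))
  kT <- 0.0019872 * 300
  for (cs in cases) {
    p <- cs$p; q <- cs$q
    expect_equal(overlapCoefficient(p, q), sum(pmin(p, q)),
                 tolerance = 1e-12)
    sOf <- function(v) -sum(ifelse(v > 0, v * log(v), 0))
    expect_equal(deltaEntropy(p, q), kT * (sOf(q) - sOf(p)),
                 tolerance = 1e-12)
    if (all(q[p > 0] > 0))
      expect_equal(klDivergence(p, q),
                   sum(p[p > 0] * log(p[p > 0] / q[p > 0])),
                   tolerance = 1e-12)
  }
})

test_that("two-segment bounds are tight for stationary identical halves
           and bracket from below for pooled estimates", {
  s <- mkSeries(rep(c(1, 2), 50))
  cS <- mkSeries(rep(c(1, 2), 50), condition = "crystal")
  su <- segmentUncertainty(list(s), list(cS), testLib, statistic = "oc")
  expect_equal(su$bounds$low, su$bounds$high)
  expect_equal(su$bounds$low, 1)
  # enumerated small cases: the pooled OC never undercuts the lower bound
  set.seed(8)
  for (i in 1:10) {
    a <- mkSeries(sample(1:3, 40, replace = TRUE))
    b <- mkSeries(sample(1:3, 40, replace = TRUE), condition = "crystal")
    su <- segmentUncertainty(list(a), list(b), testLib, statistic = "oc")
    full <- overlapCoefficient(buildDistribution(a, testLib),
                               buildDistribution(b, testLib))
    expect_gte(full, su$bounds$low - 1e-12)
  }
  expect_error(segmentUncertainty(list(mkSeries(1L)), list(mkSeries(1L)),
                                  testLib), "2 frames")
})

test_that("set summaries aggregate with population SD and recompute under
           an independent oracle", {
  comp <- data.frame(
    chain = "A", resno = 1:3, resname = c("GLN", "SER", "THR"),
    contacting = c(TRUE, FALSE, FALSE), exposed = c(TRUE, TRUE, FALSE),
    n_states = c(9L, 3L, 3L), oc = c(0.4, 0.8, 0.5),
    tds = c(-0.6, -0.1, 0), agree_solution = c(TRUE, FALSE, TRUE),
    agree_crystal = c(TRUE, TRUE, TRUE),
    p_xray_solution = c(0.5, 0.3, 0.2), p_xray_crystal = c(0.9, 0.4, 0.1))
  sm <- suppressWarnings(summarizeSets(comp))
  allRow <- sm[sm$residue_set == "all", ]
  expect_identical(allRow$n_residues, 2L)  # exposed only
  expect_equal(allRow$mean_oc, 0.6)
  expect_equal(allRow$sd_oc, 0.2)  # population SD
  expect_equal(allRow$likelihood_solution, (0.5 * 9 + 0.3 * 3) / 2)
  expect_equal(allRow$likelihood_quotient,
               allRow$likelihood_crystal / allRow$likelihood_solution)
  contRow <- sm[sm$residue_set == "cont", ]
  expect_identical(contRow$n_residues, 1L)
  expect_equal(contRow$sd_oc, 0)
  expect_equal(contRow$pct_agreement_solution, 100)
})

test_that("residue composition is normalized and ordered by state count", {
  ann <- data.frame(resname = c("GLN", "GLN", "SER", "THR", "ARG"),
                    contacting = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    exposed = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    rotameric = TRUE)
  comp <- residueComposition(ann, testLib)
  cont <- comp[comp$set == "cont", ]
  expect_equal(cont$frequency[cont$resname == "GLN"], 0.5)
  expect_equal(sum(cont$frequency), 1)
  expect_false("non-cont" %in%
                 residueComposition(ann[ann$contacting, ], testLib)$set)
})

test_that("KL and OC rank residues in opposite directions", {
  set.seed(9)
  kls <- ocs <- numeric(30)
  for (i in 1:30) {
    p <- runif(5); p <- p / sum(p)
    q <- runif(5); q <- q / sum(q)
    ocs[i] <- overlapCoefficient(p, q)
    kls[i] <- klDivergence(p, q, pseudocount = 1e-4)
  }
  expect_lt(cor(ocs, kls, method = "spearman"), 0)
})
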