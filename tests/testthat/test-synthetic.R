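test_that("the generator is deterministic and respects zero noise", {
  w <- c(0, 1, 0, 0, 0)
  sp <- ensembleSpec("LEU", w, noiseSD = 0, nFrames = 50)
  a <- generateTorsionTrajectory(sp, testLib, seed = 123)
  b <- generateTorsionTrajectory(sp, testLib, seed = 123)
  expect_identical(frames(a$trajectory), frames(b$trajectory))
  modal <- modalChis(testLib, "LEU")
  expect_true(all(frames(a$trajectory) ==
                    matrix(modal[2, ], 50, 2, byrow = TRUE)))
  expect_identical(a$states, rep(2L, 50))
  c <- generateTorsionTrajectory(sp, testLib, seed = 124)
  expect_identical(frames(c$trajectory), frames(a$trajectory))  # no noise
})

test_that("generated angles stay in (-180, 180] and wells stay separable", {
  sp <- ensembleSpec("ARG", rep(1 / 34, 34), noiseSD = 15, nFrames = 2000)
  f <- frames(generateTorsionTrajectory(sp, testLib, seed = 5)$trajectory)
  expect_true(all(f > -180 & f <= 180))
})

test_that("empirical state frequencies match the mixture weights", {
  wells <- wellSeparatedStates(testLib, "GLN", minSep = 50)[1:2]
  w <- rep(0, nStates(testLib, "GLN")); w[wells] <- c(0.7, 0.3)
  n <- 10000
  sim <- generateTorsionTrajectory(
    ensembleSpec("GLN", w, noiseSD = 8, nFrames = n), testLib, seed = 21)
  st <- states(assignSeries(sim$trajectory, testLib))
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(mean(st == wells[1]) - 0.7), 3 * se)
  expect_lt(abs(mean(st == wells[2]) - 0.3), 3 * se)
  # mixture weight validation
  expect_error(ensembleSpec("GLN", c(0.5, 0.4)), "sum to 1")
  expect_error(generateTorsionTrajectory(
    ensembleSpec("SER", c(0.5, 0.5)), testLib), "3 states")
})

test_that("condition pairs carry exact closed-form truths", {
  mk <- function(w, cond) ensembleSpec("LEU", w, nFrames = 10,
                                       condition = cond)
  same <- generateConditionPair(mk(c(0.3, 0.7, 0, 0, 0), "solution"),
                                mk(c(0.3, 0.7, 0, 0, 0), "crystal"),
                                testLib)
  expect_equal(same$ocTrue, 1)
  expect_equal(same$tdsTrue, 0)
  kT <- 0.0019872 * 300
  froz <- generateConditionPair(mk(rep(0.2, 5), "solution"),
                                mk(c(1, 0, 0, 0, 0), "crystal"), testLib)
  expect_equal(froz$tdsTrue, -kT * log(5))
  expect_equal(froz$tdsTrue, -0.959, tolerance = 1e-3)
  shift <- generateConditionPair(mk(c(0.6, 0.4, 0, 0, 0), "solution"),
                                 mk(c(0.2, 0.3, 0.5, 0, 0), "crystal"),
                                 testLib)
  expect_equal(shift$ocTrue, 0.5)
})

test_that("pipeline-recovered OC and TdS converge to the truths", {
  wells <- wellSeparatedStates(testLib, "GLN", minSep = 50)[1:3]
  wS <- rep(0, 9); wS[wells] <- c(0.5, 0.3, 0.2)
  wC <- rep(0, 9); wC[wells] <- c(0.8, 0.2, 0)
  err <- vapply(c(100, 10000), function(n) {
    pr <- generateConditionPair(
      ensembleSpec("GLN", wS, nFrames = n, condition = "solution"),
      ensembleSpec("GLN", wC, nFrames = n, condition = "crystal"),
      testLib, seed = 31)
    dS <- buildDistribution(assignSeries(pr$solution$trajectory, testLib),
                            testLib)
    dC <- buildDistribution(assignSeries(pr$crystal$trajectory, testLib),
                            testLib)
    abs(overlapCoefficient(dS, dC) - pr$ocTrue)
  }, numeric(1))
  expect_lt(err[2], err[1] + 1e-9)
  expect_lt(err[2], 0.02)
})

test_that("sticky Markov sampling keeps the stationary distribution", {
  wells <- wellSeparatedStates(testLib, "LEU", minSep = 50)[1:2]
  w <- rep(0, 5); w[wells] <- c(0.6, 0.4)
  sim <- generateTorsionTrajectory(
    ensembleSpec("LEU", w, nFrames = 20000, stickiness = 0.9), testLib,
    seed = 77)
  expect_lt(abs(mean(sim$states == wells[1]) - 0.6), 0.05)
  # sticky chains really are autocorrelated
  sticky <- mean(sim$states[-1] == sim$states[-20000])
  expect_gt(sticky, 0.9)
})
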