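test_that("two-state builder encodes the telegraph model", {
  net <- figNet()
  expect_equal(unname(stoichiometry(net)["bind", ]), c(-1, 1, 0))
  expect_equal(unname(stoichiometry(net)["unbind", ]), c(1, -1, 0))
  expect_equal(
    unname(propensities(net, c(g_free = 0, g_bound = 1, m = 2), figParams)),
    c(0, 1, 0, 2)
  )
  expect_equal(unname(initialState(net)), c(1, 0, 0))
})

test_that("closed-form mean and Fano verify against the master equation", {
  mf <- twoStateMeanFano(0.5, 1, 10, 1)
  expect_equal(mf[["mean"]], 20 / 3)
  expect_equal(mf[["fano"]], 7 / 3)
  # brute-force oracle across a random parameter grid
  set.seed(31)
  for (k in 1:20) {
    p <- exp(runif(3, log(0.1), log(10)))
    mf <- twoStateMeanFano(p[1], 1, p[2], p[3])
    pdf <- twoStateStationaryPDF(p[1], 1, p[2], p[3], mMax = 150)
    expect_lt(abs(attr(pdf, "mean") - mf[["mean"]]) / mf[["mean"]], 1e-6)
    expect_lt(abs(attr(pdf, "fano") - mf[["fano"]]) / mf[["fano"]], 1e-6)
  }
})

test_that("two-state limits behave", {
  # no repression: Poisson with mean r/gamma
  mf <- twoStateMeanFano(1e-9, 1, 4, 2)
  expect_equal(mf[["mean"]], 2, tolerance = 1e-8)
  expect_equal(mf[["fano"]], 1, tolerance = 1e-8)
  # vanishing transcription: empty distribution
  mf2 <- twoStateMeanFano(0.5, 1, 1e-12, 1)
  expect_equal(mf2[["mean"]], 0, tolerance = 1e-10)
  expect_equal(mf2[["fano"]], 1, tolerance = 1e-10)
})

test_that("four-state transitions hop between exactly two indicators", {
  net <- fourStatePromoter(fourStateExample, conc = 1)
  S <- stoichiometry(net)
  expect_true(all(rowSums(S) == 0))
  expect_true(all(apply(S, 1, function(x) sum(x != 0)) == 2))
  expect_true(all(apply(S, 1, function(x) sort(x[x != 0])) == c(-1, 1)))
})

test_that("four-state steady state solves the master equation", {
  # symmetric rates: uniform occupancy
  psym <- c(
    kb = 1, ku = 1, ka = 1, ki = 1, eta_ab = 1, eta_ib = 1,
    eta_ba = 1, eta_ua = 1
  )
  expect_equal(unname(fourStateSteadyState(psym, 1)), rep(0.25, 4))
  set.seed(7)
  for (k in 1:10) {
    p <- randomFourState()
    conc <- 10^runif(1, -1, 1)
    pi <- fourStateSteadyState(p, conc)
    expect_true(all(pi > 0))
    expect_equal(sum(pi), 1)
    # independent oracle 1: leading eigenvector of the transition matrix
    Q <- diffGillespie:::fourStateQ(p, conc)
    ev <- eigen(t(Q))
    i0 <- which.min(abs(ev$values))
    piEig <- Re(ev$vectors[, i0])
    piEig <- piEig / sum(piEig)
    expect_lt(max(abs(pi - piEig)), 1e-8)
    # independent oracle 2: matrix-tree (Kirchhoff) stationary vector
    piK <- diffGillespie:::kirchhoffSteadyState(p, conc)
    expect_lt(max(abs(pi - piK)), 1e-8)
  }
})

test_that("detailed-balance parameters give Boltzmann occupancies", {
  # eta_ab * eta_ua == eta_ib * eta_ba -> equilibrium
  p <- c(
    kb = 0.02, ku = 1.5, ka = 0.7, ki = 2, eta_ab = 3, eta_ib = 2,
    eta_ba = 4.5, eta_ua = 3
  )
  expect_equal(nonequilibriumDrive(p), 0)
  conc <- 2
  pi <- fourStateSteadyState(p, conc)
  # equilibrium: every edge satisfies detailed balance individually
  Q <- diffGillespie:::fourStateQ(p, conc)
  for (i in 1:4) {
    for (j in 1:4) {
      if (Q[i, j] > 0) {
        expect_equal(pi[i] * Q[i, j], pi[j] * Q[j, i],
          tolerance = 1e-10,
          ignore_attr = TRUE
        )
      }
    }
  }
})

test_that("vanishing activator concentrates mass on the unbound states", {
  p <- fourStateExample
  pi <- fourStateSteadyState(p, conc = 1e-9)
  expect_lt(pi[["s1"]] + pi[["s2"]], 1e-6)
  # odds between the unbound states reduce to ka/ki
  expect_equal(pi[["s3"]] / pi[["s0"]], p[["ka"]] / p[["ki"]],
    tolerance = 1e-4
  )
})

test_that("long exact runs converge to the stationary occupancy", {
  p <- fourStateExample
  conc <- 1.3
  pi <- fourStateSteadyState(p, conc)
  net <- fourStatePromoter(p, conc)
  fs <- ensembleFinalStates(net, p,
    T = 2e4, nTraj = 200, seed = 13
  )
  ta <- attr(fs, "timeavg")
  est <- colMeans(ta)
  se <- apply(ta, 2, sd) / sqrt(nrow(ta))
  expect_true(all(abs(est - pi) < 4 * pmax(se, 1e-4)))
})

test_that("meanProductionRate reads out the ON occupancy", {
  # states ordered (s0, s1, s2, s3); transcription runs in s2 and s3
  expect_equal(meanProductionRate(c(1, 0, 0, 0), 10), 0)
  expect_equal(meanProductionRate(c(0.5, 0.5, 0, 0), 10), 0)
  expect_equal(meanProductionRate(c(0, 0.5, 0.25, 0.25), 10), 5)
  expect_equal(meanProductionRate(rep(0.25, 4), 2), 1)
  expect_error(meanProductionRate(c(0.5, 0.5, 0.5, 0), 1), "normalized")
})
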