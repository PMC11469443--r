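test_that("waitingTime matches the exact update and its derivative", {
  expect_equal(waitingTime(3, 1)$tau, 0)
  expect_equal(waitingTime(2, exp(-2))$tau, 1)
  # analytic derivative vs central finite difference
  h <- 1e-4
  fd <- (waitingTime(2 + h, exp(-2))$tau - waitingTime(2 - h, exp(-2))$tau) /
    (2 * h)
  expect_lt(abs(waitingTime(2, exp(-2))$dtau_dR - fd) / abs(fd), 1e-6)
  expect_error(waitingTime(2, 0), "0, 1")
})

test_that("softIndex interpolates the cumulative selection", {
  # r=(2,3,5): q=(0.2,0.5); u'=0.35 at 1/a=200 -> sigma(30)+sigma(-30)
  expect_equal(softIndex(c(2, 3, 5), 0.35, a = 1 / 200), 2, tolerance = 1e-6)
  # boundary draw contributes exactly one half
  expect_equal(softIndex(c(2, 3, 5), 0.2, a = 1 / 200), 1.5 + stats::plogis(-60))
  # sharp limit recovers the exact integer index
  expect_equal(softIndex(c(2, 3, 5), 0.35, a = 1e-9), 2)
  expect_equal(softIndex(c(2, 3, 5), 0.75, a = 1e-9), 3)
})

test_that("softStoichWeights approximate the Kronecker delta", {
  w <- softStoichWeights(2, 3, b = 1 / 20)
  expect_equal(w, c(exp(-20), 1, exp(-20)))
  # sharp limit with integer index is one-hot
  expect_equal(softStoichWeights(2, 3, b = 1e-6), c(0, 1, 0))
  # half-integer index weights neighbours symmetrically
  w2 <- softStoichWeights(1.5, 4, b = 1 / 20)
  expect_equal(w2[1], w2[2])
  expect_lt(w2[3], w2[2])
})

test_that("a single smoothed step matches the exact step in the sharp limit", {
  net <- figNet()
  sharp <- smoothingParams(a = 1e-9, b = 1e-4)
  set.seed(8)
  for (k in 1:20) {
    st0 <- c(g_free = 1, g_bound = 0, m = rpois(1, 5))
    u <- runif(1)
    up <- runif(1)
    ex <- stepExact(net, st0, 0, figParams, u, up)
    # skip draws sitting on a cumulative boundary
    q <- cumsum(propensities(net, st0, figParams)) /
      totalRate(propensities(net, st0, figParams))
    if (min(abs(up - q)) < 1e-6) next
    dg <- dgaStep(net, st0, 0, figParams, sharp, u, up)
    expect_lt(abs(dg$iprime - ex$reaction), 1e-4)
    expect_lt(max(abs(dg$state - ex$state)), 1e-3)
    # rate floor (1e-10) shifts the effective total rate minutely
    expect_equal(dg$t, ex$t, tolerance = 1e-8)
  }
})

test_that("limit equivalence holds at default smoothing off the boundaries", {
  net <- figNet()
  sm <- smoothingParams() # 1/a = 200, 1/b = 20
  set.seed(9)
  for (k in 1:50) {
    st0 <- c(g_free = 1, g_bound = 0, m = rpois(1, 5))
    r <- propensities(net, st0, figParams)
    q <- cumsum(r)[-4] / sum(r)
    up <- runif(1)
    if (min(abs(up - q)) < 10 * sm@a) next
    ex <- stepExact(net, st0, 0, figParams, 0.5, up)
    dg <- dgaStep(net, st0, 0, figParams, sm, 0.5, up)
    expect_lt(abs(dg$iprime - ex$reaction), 1e-4)
    expect_lt(max(abs(dg$state - ex$state)), 1e-3)
  }
})

test_that("the compiled stepper replays the pure-R stepper exactly", {
  net <- figNet()
  b <- simulateDGA(net, figParams,
    T = 5, nTraj = 2,
    config = dgaConfig(recordNoise = TRUE, nTraj = 2), seed = 12
  )
  for (A in 1:2) {
    nr <- b@noiseRecord[[A]]
    st <- initialState(net)
    t <- 0
    for (k in seq_len(nrow(nr))) {
      stp <- dgaStep(net, st, t, figParams, smoothingParams(), nr[k, 1], nr[k, 2])
      st <- stp$state
      t <- stp$t
    }
    expect_equal(unname(st), unname(finalStates(b)[A, ]), tolerance = 1e-10)
    expect_equal(t, b@elapsedTimes[A], tolerance = 1e-10)
  }
})

test_that("smoothed batches are bit-reproducible and flag overruns", {
  b1 <- simulateDGA(figNet(), figParams, T = 10, nTraj = 20, seed = 3)
  b2 <- simulateDGA(figNet(), figParams, T = 10, nTraj = 20, seed = 3)
  expect_identical(finalStates(b1), finalStates(b2))
  expect_identical(b1@elapsedTimes, b2@elapsedTimes)
  expect_identical(occupancy(b1), occupancy(b2))
  expect_true(all(b1@elapsedTimes >= 10))
  expect_warning(
    simulateDGA(figNet(), figParams,
      T = 100, nTraj = 10,
      config = dgaConfig(maxSteps = 10, nTraj = 10), seed = 1
    ),
    "maxSteps"
  )
})

test_that("soft occupancy rows are normalized", {
  b <- simulateDGA(figNet(), figParams, T = 50, nTraj = 100, seed = 6)
  expect_true(all(abs(rowSums(occupancy(b)) - 1) < 1e-6))
  bf <- simulateDGA(fourStatePromoter(fourStateExample, 1), fourStateExample,
    T = 200, nTraj = 50, seed = 6
  )
  expect_true(all(abs(rowSums(occupancy(bf)) - 1) < 1e-6))
})

test_that("a one-reaction birth process reproduces the Poisson mean", {
  b <- simulateDGA(birthNetwork(), c(k = 2), T = 10, nTraj = 2000, seed = 5)
  m <- snapshotStates(b)[, "m"]
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - 20), 4 * se)
  # exact-SSA cross-check under the same conditions
  fs <- ensembleFinalStates(birthNetwork(), c(k = 2), T = 10, nTraj = 2000, seed = 6)
  expect_lt(abs(mean(m) - mean(fs[, "m"])), 4 * se * sqrt(2))
})

test_that("pathwise gradients are exact derivatives of the smoothed map", {
  # short chains: compiled Jacobian vs central finite differences
  net <- figNet()
  x0 <- c(g_free = 1, g_bound = 0, m = 3)
  cfg <- dgaConfig(maxSteps = 15, nTraj = 5)
  b <- suppressWarnings(simulateDGA(net, figParams,
    x0 = x0, T = 1e9,
    config = cfg, nTraj = 5, seed = 4, gradients = TRUE,
    gradientMode = "full", jacobianClip = Inf
  ))
  for (pn in names(figParams)) {
    h <- 1e-7 * figParams[[pn]]
    up <- figParams
    up[pn] <- up[pn] + h
    dn <- figParams
    dn[pn] <- dn[pn] - h
    fu <- suppressWarnings(simulateDGA(net, up,
      x0 = x0, T = 1e9, config = cfg,
      nTraj = 5, seed = 4
    ))
    fd <- suppressWarnings(simulateDGA(net, dn,
      x0 = x0, T = 1e9, config = cfg,
      nTraj = 5, seed = 4
    ))
    FD <- (finalStates(fu) - finalStates(fd)) / (2 * h)
    expect_lt(max(abs(b@jacFinal[, , pn] - FD)), 1e-4)
  }
})

test_that("one-step state gradient matches finite differences at defaults", {
  net <- figNet()
  x0 <- c(g_free = 1, g_bound = 0, m = 0)
  cfg <- dgaConfig(maxSteps = 1, nTraj = 1)
  b <- suppressWarnings(simulateDGA(net, figParams,
    x0 = x0, T = 1e9,
    config = cfg, nTraj = 1, seed = 21, gradients = TRUE,
    gradientMode = "full", jacobianClip = Inf
  ))
  h <- 1e-5 * figParams[["r"]]
  up <- figParams
  up["r"] <- up["r"] + h
  dn <- figParams
  dn["r"] <- dn["r"] - h
  fu <- suppressWarnings(simulateDGA(net, up,
    x0 = x0, T = 1e9, config = cfg,
    nTraj = 1, seed = 21
  ))
  fd <- suppressWarnings(simulateDGA(net, dn,
    x0 = x0, T = 1e9, config = cfg,
    nTraj = 1, seed = 21
  ))
  FD <- (finalStates(fu)[1, "m"] - finalStates(fd)[1, "m"]) / (2 * h)
  expect_lt(
    abs(b@jacFinal[1, "m", "r"] - FD) / max(abs(FD), 1e-8), 1e-3
  )
})

test_that("gradient of the birth-rate mean is the horizon", {
  # d E[m(T)] / dk = T for a pure birth process
  b <- simulateDGA(birthNetwork(), c(k = 2),
    T = 10, nTraj = 2000, seed = 5,
    gradients = TRUE, gradientMode = "full", jacobianClip = Inf
  )
  g <- gradientOf(b, "m", "mean", source = "readout")
  # the per-trajectory derivative is T/(k tau) with tau the length-biased
  # horizon-crossing interval; its reciprocal is heavy-tailed, so the
  # ensemble mean converges slowly and the check is correspondingly loose
  expect_lt(abs(g[["k"]] - 10) / 10, 0.15)
  # a parameter appearing in no rate law has exactly zero gradient
  S <- matrix(1L, 1, 1, dimnames = list("birth", "m"))
  net <- reactionNetwork(S, list(rateLaw("k")),
    parameters = c("k", "idle"),
    initialState = c(m = 0)
  )
  b2 <- simulateDGA(net, c(k = 2, idle = 1),
    T = 5, nTraj = 50, seed = 2,
    gradients = TRUE
  )
  g2 <- gradientOf(b2, "m", "mean")
  expect_identical(g2[["idle"]], 0)
})

test_that("smoothing sweep reports gradient accuracy and divergence", {
  sw <- sweepSmoothing(birthDeathNetwork(), c(k = 5, gamma = 1), "m",
    oneOverA = c(50, 200), oneOverB = c(10, 20), T = 20, nTraj = 200,
    seed = 2
  )
  expect_equal(nrow(sw), 4)
  expect_true(all(is.finite(sw$jsd_over_entropy)))
  expect_true(all(sw$jsd_over_entropy >= 0))
})

test_that("batch CSV export round-trips the headline fields", {
  dir <- withr::local_tempdir()
  b <- simulateDGA(figNet(), figParams, T = 10, nTraj = 10, seed = 3)
  p <- exportBatchCSV(b, file.path(dir, "batch.csv"))
  df <- read.csv(p)
  expect_equal(nrow(df), 10)
  expect_true(all(c("m", "elapsed", "occ_g_free") %in% names(df)))
})
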