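test_that("stepExact implements the direct method", {
  net <- figNet()
  # single live reaction is always chosen
  S <- matrix(c(0L, 0L, 1L), 3, 1, dimnames = list(
    c("a", "b", "c"), "m"
  ))
  net3 <- reactionNetwork(
    S, list(rateLaw("k1"), rateLaw("k2"), rateLaw("k3")),
    initialState = c(m = 0)
  )
  st <- stepExact(net3, c(m = 0), 0, c(k1 = 0, k2 = 0, k3 = 5),
    u = 0.3, uprime = 0.99
  )
  expect_equal(st$reaction, 3L)
  # waiting time: R = 2, u = exp(-2) -> tau = 1
  st2 <- stepExact(birthNetwork(), c(m = 0), 0, c(k = 2),
    u = exp(-2),
    uprime = 0.5
  )
  expect_equal(st2$tau, 1)
  # cumulative selection: r = (2,5,3), u' = 0.35 -> reaction 2
  expect_equal(diffGillespie:::exactIndex(c(2, 5, 3), 0.35), 2L)
  expect_equal(diffGillespie:::exactIndex(c(2, 5, 3), 0.15), 1L)
  expect_equal(diffGillespie:::exactIndex(c(2, 5, 3), 0.95), 3L)
})

test_that("pure-death trajectories absorb after exactly m0 events", {
  tr <- simulateExact(deathNetwork(5), c(gamma = 1), T = 1e3, seed = 4)
  expect_equal(sum(!is.na(tr$reaction)), 5)
  expect_equal(tail(tr$m, 1), 0)
  expect_true(attr(tr, "absorbed"))
})

test_that("exact simulation is bit-reproducible for a fixed seed", {
  tr1 <- simulateExact(figNet(), figParams, T = 20, seed = 11)
  tr2 <- simulateExact(figNet(), figParams, T = 20, seed = 11)
  expect_identical(tr1, tr2)
  f1 <- ensembleFinalStates(figNet(), figParams, T = 20, nTraj = 50, seed = 3)
  f2 <- ensembleFinalStates(figNet(), figParams, T = 20, nTraj = 50, seed = 3)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_false(identical(
    as.numeric(f1),
    as.numeric(ensembleFinalStates(figNet(), figParams,
      T = 20, nTraj = 50,
      seed = 4
    ))
  ))
})

test_that("waiting times pool to mean 1/R at fixed total rate", {
  # pure birth keeps R = k constant
  tr <- simulateExact(birthNetwork(), c(k = 2), T = 2000, seed = 7)
  waits <- diff(tr$time[-1])
  n <- length(waits)
  se <- sd(waits) / sqrt(n)
  expect_lt(abs(mean(waits) - 1 / 2), 4 * se)
})

test_that("reaction selection frequencies match propensity fractions", {
  r <- c(2, 5, 3)
  set.seed(42)
  u <- runif(1e5)
  idx <- vapply(u, function(x) diffGillespie:::exactIndex(r, x), 0L)
  tab <- tabulate(idx, 3)
  p <- chisq.test(tab, p = r / sum(r))$p.value
  expect_gt(p, 0.001)
})

test_that("exact states remain integer-valued and nonnegative", {
  fs <- ensembleFinalStates(figNet(), figParams, T = 50, nTraj = 100, seed = 2)
  expect_true(all(fs == round(fs)))
  expect_true(all(fs >= 0))
  expect_true(all(fs[, "g_free"] + fs[, "g_bound"] == 1))
})

test_that("exact two-state ensemble reproduces the stationary mean and Fano", {
  mf <- twoStateMeanFano(0.5, 1, 10, 1)
  fs <- ensembleFinalStates(figNet(), figParams, T = 500, nTraj = 2000, seed = 5)
  m <- fs[, "m"]
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - mf[["mean"]]), 3 * se)
  fano <- var(m) / mean(m)
  expect_lt(abs(fano - mf[["fano"]]) / mf[["fano"]], 0.15)
  # time-averaged occupancy attribute matches the stationary ON fraction
  occ <- colMeans(attr(fs, "timeavg"))
  expect_lt(abs(occ[["g_free"]] - 1 / 1.5), 0.02)
})

test_that("trajectory and ensemble exports write well-formed CSV", {
  dir <- withr::local_tempdir()
  tr <- simulateExact(birthNetwork(), c(k = 2), T = 5, seed = 1)
  p1 <- exportTrajectoryCSV(tr, file.path(dir, "traj.csv"))
  df <- read.csv(p1)
  expect_true(all(c("trajectory_id", "time", "reaction", "m") %in% names(df)))
  fs <- ensembleFinalStates(birthNetwork(), c(k = 2), T = 5, nTraj = 10, seed = 1)
  p2 <- exportTrajectoryCSV(fs, file.path(dir, "ens.csv"))
  expect_equal(nrow(read.csv(p2)), 10)
})
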