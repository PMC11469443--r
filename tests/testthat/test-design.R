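test_that("sharpness measures the log-concentration slope", {
  g <- 10^seq(-2, 2, length.out = 50)
  expect_equal(responseSharpness(rep(1, 50), g), 0)
  expect_equal(responseSharpness(log(g), g), 1, tolerance = 1e-9)
  expect_error(responseSharpness(c(1, 2), c(1, 2)), "3 grid points")
  # Hill curve: c^2/(1+c^2); max slope d/dlnc = 2 s (1-s) at s = 1/2
  hill <- function(cc) cc^2 / (1 + cc^2)
  sh <- responseSharpness(hill, cMin = 1e-2, cMax = 1e2, nPoints = 400)
  expect_equal(sh, 0.5, tolerance = 0.01)
})

test_that("nonequilibrium drive is the cycle log rate ratio", {
  expect_equal(nonequilibriumDrive(c(
    eta_ab = 1, eta_ib = 1, eta_ba = 1,
    eta_ua = 1
  )), 0)
  expect_equal(nonequilibriumDrive(c(
    eta_ab = exp(2), eta_ib = 1,
    eta_ba = 1, eta_ua = 1
  )), 2)
  expect_equal(nonequilibriumDrive(c(
    eta_ab = 3, eta_ib = 2, eta_ba = 4.5,
    eta_ua = 3
  )), 0)
})

test_that("cycle flux vanishes at detailed balance and is edge-uniform", {
  pEq <- c(
    kb = 0.02, ku = 1.5, ka = 0.7, ki = 2, eta_ab = 3, eta_ib = 2,
    eta_ba = 4.5, eta_ua = 3
  )
  conc <- 1.4
  piEq <- fourStateSteadyState(pEq, conc)
  expect_lt(abs(cycleFlux(piEq, pEq, conc)), 1e-10)
  # driven cycle: the same net flux flows through every edge
  p <- fourStateExample
  pi <- fourStateSteadyState(p, conc)
  Q <- diffGillespie:::fourStateQ(p, conc)
  edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  J <- vapply(edges, function(e) {
    pi[e[1]] * Q[e[1], e[2]] - pi[e[2]] * Q[e[2], e[1]]
  }, 0)
  expect_equal(J[1], cycleFlux(pi, p, conc), tolerance = 1e-12)
  expect_lt(max(abs(J - J[1])), 1e-10)
  expect_equal(cycleFlux(c(0, 0.4, 0.3, 0.3), p, conc), -0.4 * p[["ku"]])
})

test_that("dissipated power obeys the second law on random draws", {
  expect_equal(dissipatedPower(0.1, 2), 0.2)
  expect_equal(dissipatedPower(0, 5), 0)
  expect_equal(dissipatedPower(0.3, 0), 0)
  set.seed(11)
  for (k in 1:100) {
    p <- randomFourState()
    conc <- 10^runif(1, -1, 1)
    pi <- fourStateSteadyState(p, conc)
    phi <- dissipatedPower(cycleFlux(pi, p, conc), nonequilibriumDrive(p))
    expect_gte(phi, -1e-12)
    if (abs(nonequilibriumDrive(p)) < 1e-12) expect_lt(abs(phi), 1e-8)
  }
})

test_that("target responses are nonnegative polynomials on a log grid", {
  tg <- referenceTarget("sharp")
  expect_equal(length(tg@concGrid), 10)
  expect_true(all(diff(tg@concGrid) > 0))
  expect_true(all(tg@values >= 0))
  expect_equal(length(tg@coeffs), 7)
  # values are the polynomial evaluated on the grid
  lx <- log10(tg@concGrid)
  vals <- vapply(lx, function(z) sum(tg@coeffs * z^(0:6)), 0)
  expect_equal(tg@values, pmax(vals, 0), tolerance = 1e-9)
  # the shallow reference is flatter than the sharp one
  expect_lt(
    max(diff(referenceTarget("shallow")@values)),
    max(diff(tg@values))
  )
})

test_that("smoothed occupancy estimates track the stationary law", {
  psym <- c(
    kb = 1, ku = 1, ka = 1, ki = 1, eta_ab = 1, eta_ib = 1,
    eta_ba = 1, eta_ua = 1
  )
  est <- estimateOccupancy(psym, 1, nSims = 300, T = 400, seed = 9)
  expect_equal(sum(est), 1, tolerance = 1e-6)
  expect_lt(max(abs(est - 0.25)), 0.02)
  # a single simulation returns that trajectory's occupancy row
  e1 <- estimateOccupancy(fourStateExample, 1, nSims = 1, T = 200 / 0.02, seed = 2)
  net <- fourStatePromoter(fourStateExample, 1)
  b1 <- simulateDGA(net, fourStateExample, T = 200 / 0.02, nTraj = 1, seed = 2)
  expect_equal(unname(e1), unname(occupancy(b1)[1, ]))
  # random draw: estimate close to the null-space solution (smoothing leaves
  # a small occupancy leak into rare states, so the comparison is absolute)
  set.seed(21)
  p <- randomFourState()
  pi <- fourStateSteadyState(p, 1.5)
  est2 <- estimateOccupancy(p, 1.5, nSims = 300, T = 150 / p[["kb"]], seed = 5)
  expect_lt(max(abs(est2 - pi)), 0.06)
})

test_that("design loss is zero on its own achieved response", {
  p <- fourStateExample
  dl <- designLoss(p, referenceTarget("sharp"),
    engine = "exact",
    drivePenalty = 0
  )
  self <- new("TargetResponse",
    coeffs = numeric(7),
    concGrid = referenceTarget("sharp")@concGrid,
    values = dl$achieved, name = "self"
  )
  expect_equal(designLoss(p, self, engine = "exact", drivePenalty = 0)$value,
    0,
    tolerance = 1e-12
  )
  # permutation invariance over grid points
  perm <- sample(10)
  permuted <- new("TargetResponse",
    coeffs = numeric(7),
    concGrid = sort(self@concGrid[perm]), values = self@values[perm][order(self@concGrid[perm])],
    name = "perm"
  )
  expect_gte(dl$value, 0)
})

test_that("exact-engine design gradients match finite differences", {
  p <- fourStateExample
  tg <- referenceTarget("sharp")
  dl <- designLoss(p, tg, engine = "exact", drivePenalty = 3e-4)
  free <- names(dl$gradient)
  for (pn in free[c(1, 4, 7)]) {
    h <- 1e-6 * p[[pn]]
    up <- p
    up[pn] <- up[pn] + h
    dn <- p
    dn[pn] <- dn[pn] - h
    fd <- (designLoss(up, tg, engine = "exact", drivePenalty = 3e-4)$value -
      designLoss(dn, tg, engine = "exact", drivePenalty = 3e-4)$value) / (2 * h)
    expect_lt(abs(dl$gradient[[pn]] - fd) / max(abs(fd), 1e-10), 1e-4)
  }
})

test_that("smoothed-engine design gradients agree with the analytic ones", {
  p <- c(
    kb = 0.02, ku = 1, ka = 1, ki = 1, eta_ab = 2, eta_ib = 1,
    eta_ba = 1, eta_ua = 2
  )
  tg <- referenceTarget("sharp", nPoints = 4)
  gd <- designLoss(p, tg,
    engine = "dga", nSims = 100, T = 2000, seed = 5,
    drivePenalty = 0
  )$gradient
  ge <- designLoss(p, tg, engine = "exact", drivePenalty = 0)$gradient
  cosine <- sum(gd * ge) / sqrt(sum(gd^2) * sum(ge^2))
  expect_gt(cosine, 0.95)
})

test_that("design recovers a self-generated target response", {
  pTrue <- fourStateExample
  grid <- referenceTarget("sharp")@concGrid
  self <- vapply(grid, function(cc) {
    meanProductionRate(fourStateSteadyState(pTrue, cc), 1)
  }, 0)
  tgt <- new("TargetResponse",
    coeffs = numeric(7), concGrid = grid,
    values = self, name = "self"
  )
  d <- designFit(tgt, iterations = 600, seed = 1)
  rmse <- sqrt(mean((d@achieved - self)^2)) / max(self)
  expect_lt(rmse, 0.03)
  # the fixed parameters were not optimized
  expect_equal(d@thetaHat[["kb"]], 0.02)
  expect_equal(d@thetaHat[["r"]], 1)
  # perturbing a parameter away from the optimum increases the loss
  worse <- d@thetaHat
  worse["ku"] <- worse["ku"] * 10
  l0 <- designLoss(d@thetaHat, tgt, engine = "exact")$value
  l1 <- designLoss(worse, tgt, engine = "exact")$value
  expect_gt(l1, l0)
  # power = flux * drive at every concentration
  expect_equal(d@power, d@flux * d@drive, tolerance = 1e-12)
})
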