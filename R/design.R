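#' @include dga.R promoters.R
NULL

#' Construct a target dose-response curve
#'
#' Builds a [TargetResponse-class] from 6th-degree polynomial coefficients
#' in log10 concentration, evaluated on a log-spaced concentration grid.
#'
#' @param coeffs numeric(7) polynomial coefficients, constant term first.
#' @param cMin,cMax concentration range (defaults 1e-2, 1e2).
#' @param nPoints grid size (default 10).
#' @param name label.
#' @return a [TargetResponse-class].
#' @export
targetResponse <- function(coeffs, cMin = 1e-2, cMax = 1e2, nPoints = 10,
                           name = "custom") {
  grid <- 10^seq(log10(cMin), log10(cMax), length.out = nPoints)
  lx <- log10(grid)
  vals <- as.numeric(vapply(lx, function(z) sum(coeffs * z^(0:6)), 0))
  vals <- pmax(vals, 0)
  new("TargetResponse",
    coeffs = coeffs, concGrid = grid, values = vals,
    name = name
  )
}

#' Reference design targets of differing sharpness
#'
#' Two shipped dose-response targets emulating developmental-boundary
#' specification: logistic curves in log10 concentration of differing
#' steepness (and maximal level), sampled on the standard 10-point grid and
#' re-encoded as 6th-degree polynomial fits (the functional form is a
#' convenience; results do not hinge on it). \code{"shallow"} has logistic
#' slope 2.3 per decade, i.e. an effective Hill coefficient of about one,
#' which a single-binding-site promoter can reach at (or near) equilibrium;
#' \code{"sharp"} has slope 3.5 per decade (effective Hill coefficient
#' about 1.5), beyond the equilibrium bound for one binding site and
#' therefore demanding a driven, dissipative promoter cycle.
#'
#' @param which "shallow" or "sharp".
#' @param r transcription rate the response is scaled to (default 1).
#' @param cMin,cMax,nPoints grid specification.
#' @return a [TargetResponse-class].
#' @examples
#' referenceTarget("sharp")@values
#' @export
referenceTarget <- function(which = c("shallow", "sharp"), r = 1,
                            cMin = 1e-2, cMax = 1e2, nPoints = 10) {
  which <- match.arg(which)
  slope <- if (which == "sharp") 3.5 else 2.3
  amp <- if (which == "sharp") 0.85 * r else 0.7 * r
  grid <- 10^seq(log10(cMin), log10(cMax), length.out = nPoints)
  lx <- log10(grid)
  vals <- amp * stats::plogis(slope * lx)
  deg <- min(6, nPoints - 1) # degree 6 needs at least 7 grid points
  fit <- lm(vals ~ poly(lx, deg, raw = TRUE))
  coeffs <- c(as.numeric(coef(fit)), rep(0, 6 - deg))
  coeffs[!is.finite(coeffs)] <- 0
  obj <- targetResponse(coeffs,
    cMin = cMin, cMax = cMax, nPoints = nPoints,
    name = which
  )
  obj
}

#' Smoothed-simulation estimate of promoter-state occupancy
#'
#' Runs \code{nSims} smoothed trajectories of the four-state promoter at
#' one activator concentration and averages the per-trajectory soft
#' time-in-state fractions, \eqn{\hat\pi_s = n^{-1}\sum_A w_{sA}}. The
#' estimate sums to one and is differentiable in the promoter parameters at
#' fixed seed.
#'
#' @param params four-state parameters (see [fourStatePromoter()]).
#' @param conc activator concentration.
#' @param nSims number of trajectories (default 600).
#' @param T horizon (default \code{200 / kb}).
#' @param smoothing a [SmoothingParams-class].
#' @param seed master seed.
#' @param gradients also return the occupancy Jacobian.
#' @return named probability 4-vector; with \code{gradients = TRUE}, the
#'   Jacobian (4 x parameters) is attached as attribute \code{"jacobian"}.
#' @export
estimateOccupancy <- function(params, conc, nSims = 600,
                              T = 200 / params[["kb"]],
                              smoothing = smoothingParams(), seed = 1,
                              gradients = FALSE) {
  stopifnot(nSims >= 1)
  net <- fourStatePromoter(params, conc)
  b <- simulateDGA(net, params,
    T = T, nTraj = nSims, smoothing = smoothing,
    seed = seed, gradients = gradients
  )
  pi <- colMeans(occupancy(b))
  if (gradients) {
    J <- apply(b@jacOccupancy, c(2, 3), mean)
    attr(pi, "jacobian") <- J
  }
  pi
}

# exact pi and d pi / d theta via the linearized null-space solve
fourStatePiGrad <- function(params, conc, free) {
  Q <- fourStateQ(params, conc)
  A <- t(Q)
  A[4, ] <- 1
  pi <- solve(A, c(0, 0, 0, 1))
  J <- matrix(0, 4, length(free), dimnames = list(names(pi), free))
  for (p in free) {
    dp <- params
    # each edge rate is a product of parameters: dQ/dp = Q-edge / p
    dQ <- fourStateQGradParam(params, conc, p)
    dA <- t(dQ)
    dA[4, ] <- 0
    J[, p] <- solve(A, -dA %*% pi)
  }
  rownames(J) <- c("s0", "s1", "s2", "s3")
  list(pi = setNames(pi, c("s0", "s1", "s2", "s3")), jac = J)
}

# derivative of the rate matrix w.r.t. one parameter (rates are products of
# parameters, so each entry's derivative is entry/param when param occurs)
fourStateQGradParam <- function(params, conc, p) {
  edges <- list(
    c("s0", "s1", "kb"), c("s1", "s0", "ku"),
    c("s3", "s2", "kb eta_ba"), c("s2", "s3", "ku eta_ua"),
    c("s0", "s3", "ka"), c("s3", "s0", "ki"),
    c("s1", "s2", "ka eta_ab"), c("s2", "s1", "ki eta_ib")
  )
  Q <- fourStateQ(params, conc)
  dQ <- matrix(0, 4, 4, dimnames = dimnames(Q))
  for (e in edges) {
    ps <- strsplit(e[3], " ")[[1]]
    if (p %in% ps) {
      dQ[e[1], e[2]] <- Q[e[1], e[2]] / params[[p]]
    }
  }
  diag(dQ) <- -rowSums(dQ)
  dQ
}

#' Design loss for a target dose-response
#'
#' Sum over the concentration grid of the squared gap between the model's
#' mean production rate \eqn{r(\pi_2 + \pi_3)} and the target,
#' \eqn{L = \sum_i (\langle\hat{\bar r}\rangle_i - \langle\bar r\rangle_i)^2}.
#' The transcription rate \code{r} is assumed known (it only scales the
#' output) and the binding rate \code{kb} is held at 0.02 (equivalently,
#' time is measured in units of 1/kb). Engine \code{"exact"} evaluates the
#' occupancies by the null-space solve with analytic gradients;
#' \code{"dga"} uses batches of smoothed simulations with pathwise
#' gradients ([estimateOccupancy()]).
#'
#' @param params full four-state parameter vector.
#' @param target a [TargetResponse-class].
#' @param r known transcription rate.
#' @param free parameter names the gradient is computed for.
#' @param engine "exact" or "dga".
#' @param nSims,T,smoothing,seed smoothed-engine settings.
#' @param drivePenalty weight of a small \eqn{\Delta\mu^2} regularizer.
#'   The dose-response constrains only rate ratios, so the optimum is a
#'   degenerate manifold; the penalty selects its least-dissipative point
#'   (the minimal nonequilibrium drive compatible with the target), which is
#'   the biophysically parsimonious circuit. Set to 0 to disable.
#' @return list with \code{value}, \code{gradient}, \code{achieved}.
#' @export
designLoss <- function(params, target, r = 1,
                       free = c(
                         "ku", "ka", "ki", "eta_ab", "eta_ib",
                         "eta_ba", "eta_ua"
                       ),
                       engine = c("exact", "dga"), nSims = 600,
                       T = 200 / params[["kb"]],
                       smoothing = smoothingParams(), seed = 1,
                       drivePenalty = 3e-4) {
  engine <- match.arg(engine)
  grid <- target@concGrid
  if (length(grid) != length(target@values)) stop("grid/values mismatch")
  value <- 0
  grad <- setNames(numeric(length(free)), free)
  achieved <- numeric(length(grid))
  for (i in seq_along(grid)) {
    if (engine == "exact") {
      pg <- fourStatePiGrad(params, grid[i], free)
      pi <- pg$pi
      Jon <- pg$jac["s2", ] + pg$jac["s3", ]
    } else {
      pi <- estimateOccupancy(params, grid[i],
        nSims = nSims, T = T,
        smoothing = smoothing, seed = seed + (i - 1) * 1000,
        gradients = TRUE
      )
      J <- attr(pi, "jacobian")
      Jon <- (J["s2", ] + J["s3", ])[free]
    }
    rhat <- r * (pi[["s2"]] + pi[["s3"]])
    achieved[i] <- rhat
    resid <- rhat - target@values[i]
    value <- value + resid^2
    grad <- grad + 2 * resid * r * Jon
  }
  if (drivePenalty > 0) {
    dmu <- nonequilibriumDrive(params)
    value <- value + drivePenalty * dmu^2
    for (nm in c("eta_ab", "eta_ua", "eta_ib", "eta_ba")) {
      if (nm %in% free) {
        sgn <- if (nm %in% c("eta_ab", "eta_ua")) 1 else -1
        grad[[nm]] <- grad[[nm]] +
          2 * drivePenalty * dmu * sgn / params[[nm]]
      }
    }
  }
  list(value = value, gradient = grad, achieved = achieved)
}

#' Gradient-based design of the four-state promoter
#'
#' Fits the seven free promoter parameters (\code{ku}, \code{ka},
#' \code{ki} and the four eta multipliers; \code{kb} and \code{r} are
#' fixed) so that the steady-state dose-response matches a target curve,
#' using ADAM in log space. Whatever engine drives the optimization, the
#' reported achieved curve, sharpness and thermodynamic budget (drive
#' \eqn{\Delta\mu}, cycle flux J and power \eqn{\Phi = J\Delta\mu}) are
#' recomputed with the exact steady-state solver, which removes Monte-Carlo
#' noise from the reported results.
#'
#' @param target a [TargetResponse-class].
#' @param theta0 named starting values of the seven free parameters
#'   (default: all 1, i.e. a detailed-balance start).
#' @param r known transcription rate (default 1).
#' @param kb fixed binding rate (default 0.02).
#' @param engine "exact" (default) or "dga" inner loop.
#' @param lr,iterations,seed optimizer settings (the exact engine is cheap,
#'   so the default allows a long run).
#' @param nSims,T,smoothing smoothed-engine settings.
#' @param drivePenalty see [designLoss()].
#' @param verbose print progress.
#' @return a [DesignResult-class].
#' @export
designFit <- function(target, theta0 = NULL, r = 1, kb = 0.02,
                      engine = c("exact", "dga"), lr = 0.15,
                      iterations = 2000, seed = 1, nSims = 600, T = NULL,
                      smoothing = smoothingParams(), drivePenalty = 3e-4,
                      verbose = FALSE) {
  engine <- match.arg(engine)
  free <- c("ku", "ka", "ki", "eta_ab", "eta_ib", "eta_ba", "eta_ua")
  if (is.null(theta0)) theta0 <- setNames(rep(1, 7), free)
  if (is.null(T)) T <- 200 / kb
  lossFn <- function(theta, seed) {
    params <- c(kb = kb, theta[free])
    designLoss(params, target,
      r = r, free = free, engine = engine,
      nSims = nSims, T = T, smoothing = smoothing, seed = seed,
      drivePenalty = drivePenalty
    )
  }
  fit <- fitParameters(lossFn, theta0,
    lr = lr, iterations = iterations,
    seed = seed, ci = FALSE, verbose = verbose
  )
  thetaHat <- c(kb = kb, fit@thetaHat[free], r = r)
  grid <- target@concGrid
  piList <- lapply(grid, function(cc) fourStateSteadyState(thetaHat, cc))
  achieved <- vapply(piList, function(p) meanProductionRate(p, r), 0)
  dmu <- nonequilibriumDrive(thetaHat)
  flux <- vapply(seq_along(grid), function(i) {
    cycleFlux(piList[[i]], thetaHat, grid[i])
  }, 0)
  pw <- flux * dmu
  # reported power: value at the response midpoint concentration
  mid <- which.min(abs(achieved - (min(achieved) + max(achieved)) / 2))
  sharp <- responseSharpness(
    function(cc) {
      meanProductionRate(fourStateSteadyState(thetaHat, cc), r)
    },
    cMin = min(grid), cMax = max(grid), nPoints = 50
  )
  new("DesignResult",
    thetaHat = thetaHat, achieved = achieved, lossTrace = fit@lossTrace,
    sharpness = sharp, drive = dmu, flux = flux, power = pw,
    powerMid = pw[mid], target = target, engine = engine
  )
}

setMethod("show", "DesignResult", function(object) {
  cat(sprintf(
    "DesignResult ('%s' target, %s engine): final loss %.3g\n",
    object@target@name, object@engine, tail(object@lossTrace, 1)
  ))
  cat(sprintf(
    "  sharpness %.3f, drive %.3f, power(midpoint) %.3g\n",
    object@sharpness, object@drive, object@powerMid
  ))
})

#' Sharpness of a dose-response curve
#'
#' \eqn{\max_c [c]\, d\langle\bar r\rangle/d[c]}, i.e. the maximal
#' derivative with respect to log concentration, estimated by centered
#' differences in \eqn{\ln[c]} over interior grid points.
#'
#' @param response numeric vector of responses on \code{conc}, or a function
#'   of concentration (then evaluated on a dense grid).
#' @param conc concentration grid (>= 3 points) when \code{response} is a
#'   vector.
#' @param cMin,cMax,nPoints dense-grid specification when \code{response}
#'   is a function.
#' @return scalar sharpness.
#' @examples
#' g <- 10^seq(-2, 2, length.out = 50)
#' responseSharpness(log(g), g) # == 1
#' @export
responseSharpness <- function(response, conc = NULL, cMin = 1e-2, cMax = 1e2,
                              nPoints = 50) {
  if (is.function(response)) {
    conc <- 10^seq(log10(cMin), log10(cMax), length.out = nPoints)
    response <- vapply(conc, response, 0)
  }
  if (length(conc) < 3) stop("need at least 3 grid points")
  lc <- log(conc)
  n <- length(conc)
  d <- (response[3:n] - response[1:(n - 2)]) / (lc[3:n] - lc[1:(n - 2)])
  max(d)
}

#' Nonequilibrium drive of the promoter cycle
#'
#' \eqn{\Delta\mu = \ln(\eta_{ab}\eta_{ua} / (\eta_{ib}\eta_{ba}))}: the
#' log ratio of clockwise to counterclockwise rate products around the
#' four-state cycle. Zero if and only if detailed balance holds.
#'
#' @param params four-state parameters (only the etas are used).
#' @return scalar drive (in units of kT).
#' @examples
#' nonequilibriumDrive(c(eta_ab = exp(2), eta_ib = 1, eta_ba = 1, eta_ua = 1))
#' @export
nonequilibriumDrive <- function(params) {
  p <- unlist(params)
  log(p[["eta_ab"]] * p[["eta_ua"]] / (p[["eta_ib"]] * p[["eta_ba"]]))
}

#' Cycle flux of the four-state promoter
#'
#' Net steady-state probability current around the cycle, measured on the
#' binding edge: \eqn{J = \pi_0 k_b [c] - \pi_1 k_u}. At steady state the
#' same net flux flows through every edge of the cycle.
#'
#' @param pi normalized probability 4-vector (s0..s3).
#' @param params four-state parameters (\code{kb}, \code{ku} used).
#' @param conc activator concentration.
#' @return scalar flux.
#' @export
cycleFlux <- function(pi, params, conc) {
  if (abs(sum(pi) - 1) > 1e-6) stop("pi must be normalized")
  p <- unlist(params)
  pi[[1]] * p[["kb"]] * conc - pi[[2]] * p[["ku"]]
}

#' Dissipated power
#'
#' Generalized Ohm's law for the promoter cycle: \eqn{\Phi = J \Delta\mu}.
#' Nonnegative for any steady state (flux and drive share sign), zero iff
#' the cycle satisfies detailed balance.
#'
#' @param J cycle flux.
#' @param deltaMu nonequilibrium drive.
#' @return scalar power.
#' @examples
#' dissipatedPower(0.1, 2) # 0.2
#' @export
dissipatedPower <- function(J, deltaMu) {
  J * deltaMu
}
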