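#' @include network.R
NULL

#' Smoothing hyperparameters
#'
#' Convenience constructor taking the inverse scales the smoothed stepper is
#' usually quoted in. Defaults \code{1/a = 200} (sigmoid steepness of the
#' reaction selection) and \code{1/b = 20} (Gaussian width of the soft
#' stoichiometry update): small enough to track the exact algorithm closely,
#' large enough for numerically stable gradients.
#'
#' @param one_over_a inverse sigmoid scale (> 0).
#' @param one_over_b inverse Gaussian width (> 0).
#' @param a,b alternatively, the scales themselves.
#' @return a [SmoothingParams-class].
#' @examples
#' smoothingParams() # defaults 1/a = 200, 1/b = 20
#' @export
smoothingParams <- function(one_over_a = 200, one_over_b = 20,
                            a = 1 / one_over_a, b = 1 / one_over_b) {
  new("SmoothingParams", a = a, b = b)
}

setMethod("show", "SmoothingParams", function(object) {
  cat(sprintf(
    "SmoothingParams: 1/a = %g (sigmoid), 1/b = %g (Gaussian)\n",
    1 / object@a, 1 / object@b
  ))
})

#' Runtime configuration for the differentiable simulator
#'
#' @param maxSteps events cap per trajectory (default 1e6); an overrun is
#'   flagged on the batch and triggers a warning when it affects more than
#'   1\% of trajectories.
#' @param rateFloor small rate added to the total rate inside divisions
#'   (default 1e-10); a raw total rate below it marks the state absorbing.
#' @param clampNonnegative smoothly clamp species at zero after each update
#'   (softplus, sharpness 1000) so gradients survive undershoots.
#' @param nTraj default ensemble size.
#' @param recordNoise store all uniform draws for replay.
#' @return a [DGAConfig-class].
#' @export
dgaConfig <- function(maxSteps = 1e6, rateFloor = 1e-10,
                      clampNonnegative = TRUE, nTraj = 2000,
                      recordNoise = FALSE) {
  new("DGAConfig",
    maxSteps = maxSteps, rateFloor = rateFloor,
    clampNonnegative = clampNonnegative, nTraj = nTraj,
    recordNoise = recordNoise
  )
}

setMethod("show", "DGAConfig", function(object) {
  cat(sprintf(
    "DGAConfig: nTraj = %g, maxSteps = %g, rateFloor = %g, clamp = %s\n",
    object@nTraj, object@maxSteps, object@rateFloor,
    object@clampNonnegative
  ))
})

#' Differentiable waiting time
#'
#' \eqn{\tau = -\ln(u)/R}: identical to the exact algorithm's waiting time
#' (this part of the Gillespie update is already smooth), with derivative
#' \eqn{\partial\tau/\partial R = \ln(u)/R^2}.
#'
#' @param R total rate (> 0).
#' @param u uniform draw in (0, 1].
#' @return list with \code{tau} and \code{dtau_dR}.
#' @examples
#' waitingTime(2, exp(-2))$tau # 1
#' @export
waitingTime <- function(R, u) {
  if (any(u <= 0) || any(u > 1)) stop("u must lie in (0, 1]")
  stopifnot(R > 0)
  list(tau = -log(u) / R, dtau_dR = log(u) / R^2)
}

#' Smooth reaction-index selection
#'
#' Soft version of the direct method's categorical draw. With cumulative
#' propensity fractions \eqn{q_i = \sum_{j \le i} r_j / R} (the cumulative
#' form is what reduces to the exact algorithm in the sharp limit), the
#' real-valued index is
#' \deqn{i' = 1 + \sum_{i=1}^{N-1} \sigma\big((u' - q_i)/a\big),}
#' with \eqn{\sigma} the logistic function. As \eqn{a \to 0}, \eqn{i'}
#' approaches the exact integer index whenever \eqn{u'} is off the
#' boundaries \eqn{q_i}.
#'
#' @param r propensity vector (total > 0).
#' @param uprime uniform draw in (0, 1).
#' @param a sigmoid scale, or a [SmoothingParams-class].
#' @return real-valued index in (1, N).
#' @examples
#' softIndex(c(2, 3, 5), 0.35, a = 1 / 200) # ~2
#' @export
softIndex <- function(r, uprime, a = smoothingParams()) {
  if (is(a, "SmoothingParams")) a <- a@a
  R <- totalRate(r)
  stopifnot(R > 0)
  N <- length(r)
  if (N == 1) {
    return(1)
  }
  q <- cumsum(r)[-N] / R
  1 + sum(stats::plogis((uprime - q) / a))
}

#' Soft stoichiometry weights
#'
#' Gaussian replacement of the Kronecker delta selecting the fired
#' reaction's stoichiometry row: \eqn{w_i = \exp(-(i' - i)^2 / b)}. The
#' state update becomes \eqn{x \leftarrow x + \sum_i w_i S_{i\cdot}}; as
#' \eqn{b \to 0} with integer \eqn{i'} this recovers the one-hot exact
#' update.
#'
#' @param iprime real-valued index from [softIndex()].
#' @param N number of reactions (>= 1).
#' @param b Gaussian width, or a [SmoothingParams-class].
#' @return numeric weight vector of length N.
#' @examples
#' softStoichWeights(2, 3, b = 1 / 20)
#' @export
softStoichWeights <- function(iprime, N, b = smoothingParams()) {
  if (is(b, "SmoothingParams")) b <- b@b
  stopifnot(N >= 1)
  exp(-(iprime - seq_len(N))^2 / b)
}

# smooth nonnegativity clamp (softplus, sharpness k); value only
smoothClamp <- function(x, k = 1e3) {
  z <- k * x
  ifelse(z > 30, x, ifelse(z < -30, exp(z) / k, log1p(exp(z)) / k))
}

# two-sided smooth clamp to [0, 1] for promoter indicator species: a single
# promoter copy's state occupancies are bounded by construction, and keeping
# them bounded blocks runaway mass creation from soft selection near
# cumulative-fraction ties
smoothClamp01 <- function(x, k = 1e3) {
  1 - smoothClamp(1 - smoothClamp(x, k), k)
}

#' One smoothed Gillespie step
#'
#' Reference (pure-R) implementation of a single step of the differentiable
#' stepper: waiting time from the total rate, soft index selection, Gaussian
#' stoichiometry weights, then the smooth nonnegativity clamp. The batched
#' simulator [simulateDGA()] performs exactly these operations in compiled
#' code; this function is the readable contract used by the equivalence
#' tests.
#'
#' @param network a [ReactionNetwork-class].
#' @param state numeric species vector (real-valued allowed).
#' @param t current time.
#' @param params named parameter values.
#' @param smoothing a [SmoothingParams-class].
#' @param u,uprime uniform draws.
#' @param config a [DGAConfig-class] (rate floor and clamp settings).
#' @return list with \code{state}, \code{t}, \code{iprime}, \code{tau},
#'   \code{weights}; or \code{absorbed = TRUE} when the total rate falls
#'   below the rate floor.
#' @export
dgaStep <- function(network, state, t, params, smoothing = smoothingParams(),
                    u, uprime, config = dgaConfig()) {
  r <- propensities(network, state, params)
  R <- totalRate(r)
  if (R < config@rateFloor) {
    return(list(state = state, t = t, absorbed = TRUE))
  }
  Reff <- R + config@rateFloor
  tau <- -log(u) / Reff
  N <- length(r)
  iprime <- if (N == 1) 1 else 1 + sum(stats::plogis((uprime - cumsum(r)[-N] / Reff) / smoothing@a))
  w <- softStoichWeights(iprime, N, smoothing@b)
  state2 <- as.numeric(state) + as.numeric(t(stoichiometry(network)) %*% w)
  if (config@clampNonnegative) {
    ind <- speciesNames(network) %in% indicatorSpecies(network)
    state2[ind] <- smoothClamp01(state2[ind])
    state2[!ind] <- smoothClamp(state2[!ind])
  }
  names(state2) <- speciesNames(network)
  list(
    state = state2, t = t + tau, iprime = iprime, tau = tau,
    weights = w, absorbed = FALSE
  )
}

#' Simulate a batch of smoothed trajectories
#'
#' Runs the differentiable Gillespie stepper for \code{nTraj} trajectories
#' under independent RNG substreams until each trajectory's time exceeds the
#' horizon (the final step may overshoot) or the step cap is hit. Soft
#' state occupancancy is accumulated along the way: at each step the clamped
#' indicator species are normalized to sum one, weighted by the step
#' duration, and finally divided by the total elapsed time, so each
#' occupancy row sums to one.
#'
#' With \code{gradients = TRUE} the simulator also propagates forward-mode
#' pathwise sensitivities: holding the noise draws fixed, the derivative of
#' every smooth operation (waiting time, soft index, Gaussian weights,
#' clamp, occupancy) with respect to each kinetic parameter is chained
#' through the run, yielding exact Jacobians of the final states and
#' occupancies for this realization of the noise. These are the
#' common-random-numbers gradients used by all fitting routines.
#'
#' @param network a [ReactionNetwork-class].
#' @param params named parameter values.
#' @param x0 initial state (real values allowed): a single species vector
#'   used for every trajectory, or an \code{nTraj x nSpecies} matrix giving
#'   each trajectory its own start (e.g. a dispersed stationary ensemble).
#' @param T horizon (> 0).
#' @param smoothing a [SmoothingParams-class].
#' @param config a [DGAConfig-class].
#' @param nTraj ensemble size (defaults to \code{config@nTraj}).
#' @param seed master seed; fixed seed gives a bit-identical batch.
#' @param gradients propagate parameter sensitivities.
#' @param gradientMode how deep state feedback recurses in the sensitivity
#'   propagation. \code{"full"} is the exact derivative of the smoothed map;
#'   at sharp smoothing scales that map is chaotic along a trajectory
#'   (sigmoid-derivative spikes of height 1/(4a) repeatedly amplify the
#'   accumulated state sensitivity), so per-trajectory derivatives explode
#'   and their ensemble mean is useless. \code{"local"} keeps only the
#'   explicit parameter dependence in the selection channel (stable, but
#'   blind to purely state-mediated pathways such as a binding rate acting
#'   on transcript counts through promoter occupancy).
#'   \code{"truncated"} (default) adds exactly one order of state feedback
#'   on top of \code{"local"} without closing the recursion loop, keeping
#'   the estimator stable while capturing one-step-mediated pathways. See
#'   the methods vignette.
#' @param gradKernelWidth inverse width \code{1/a_grad} of the selection
#'   derivative kernel: the sigmoid-derivative spikes used in the Jacobian
#'   propagation are widened (mass-conserving) to this scale while the
#'   simulated values keep the sharp scale \code{a}. \code{NULL} (default)
#'   uses the value scale.
#' @param jacobianClip elementwise bound applied to the per-trajectory state
#'   sensitivities after every step (exploding-gradient guard; \code{Inf}
#'   disables).
#' @param gradWindow trailing time window over which sensitivities
#'   accumulate (truncated backpropagation through time). \code{Inf}
#'   differentiates the whole trajectory; a finite window differentiates a
#'   surrogate in which the parameters act only during the last
#'   \code{gradWindow} time units, which preserves the location of loss
#'   minima (residual-weighted gradients still vanish exactly where the
#'   residuals do) while keeping the chain short enough to be stable.
#' @return a [TrajectoryBatch-class].
#' @examples
#' net <- twoStatePromoter(0.5, 1, 10, 1)
#' b <- simulateDGA(net, c(konR = 0.5, koffR = 1, r = 10, gamma = 1),
#'   T = 20, nTraj = 100, seed = 1
#' )
#' colMeans(finalStates(b))
#' @rdname simulateDGA
#' @export
setMethod("simulateDGA", "ReactionNetwork", function(network, params,
                                                     x0 = initialState(network),
                                                     T = 100,
                                                     smoothing = smoothingParams(),
                                                     config = dgaConfig(),
                                                     nTraj = config@nTraj,
                                                     seed = 1,
                                                     gradients = FALSE,
                                                     gradientMode = c(
                                                       "truncated", "local",
                                                       "full"
                                                     ),
                                                     gradKernelWidth = NULL,
                                                     jacobianClip = 10,
                                                     gradWindow = Inf) {
  stopifnot(T > 0, nTraj >= 1)
  gradientMode <- match.arg(gradientMode)
  modeCode <- c(local = 0L, truncated = 1L, full = 2L)[[gradientMode]]
  aGrad <- if (is.null(gradKernelWidth)) smoothing@a else 1 / gradKernelWidth
  cn <- netToC(network, params)
  ind <- match(indicatorSpecies(network), speciesNames(network)) - 1L
  # x0 may be one state for all trajectories or one row per trajectory
  x0m <- if (is.matrix(x0)) {
    stopifnot(nrow(x0) == nTraj, ncol(x0) == nSpecies(network))
    x0
  } else {
    matrix(as.numeric(x0), nTraj, nSpecies(network), byrow = TRUE)
  }
  res <- cpp_simulate_dga(
    cn$S, cn$form, cn$p1, cn$p2, cn$sp, cn$mult, cn$theta,
    x0m, T, smoothing@a, smoothing@b, config@rateFloor,
    config@maxSteps, as.integer(nTraj), as.numeric(seed),
    as.integer(ind), config@clampNonnegative, gradients,
    config@recordNoise, modeCode, aGrad, jacobianClip, gradWindow
  )
  nS <- nSpecies(network)
  P <- length(cn$theta)
  K <- length(ind)
  fin <- res$final
  colnames(fin) <- speciesNames(network)
  ro <- res$readout
  colnames(ro) <- speciesNames(network)
  sn <- res$snapshot
  colnames(sn) <- speciesNames(network)
  occ <- res$occupancy
  if (K > 0) {
    occ <- occ[, seq_len(K), drop = FALSE]
    colnames(occ) <- indicatorSpecies(network)
  } else {
    occ <- matrix(numeric(0), nrow = nTraj, ncol = 0)
  }
  jf <- jr <- js <- jo <- je <- NULL
  if (gradients) {
    jf <- array(res$jac_final,
      dim = c(nTraj, nS, P),
      dimnames = list(NULL, speciesNames(network), parameterNames(network))
    )
    jr <- array(res$jac_readout,
      dim = c(nTraj, nS, P),
      dimnames = list(NULL, speciesNames(network), parameterNames(network))
    )
    js <- array(res$jac_snapshot,
      dim = c(nTraj, nS, P),
      dimnames = list(NULL, speciesNames(network), parameterNames(network))
    )
    if (K > 0) {
      jo <- array(res$jac_occ,
        dim = c(nTraj, max(K, 1), P)
      )[, seq_len(K), , drop = FALSE]
      dimnames(jo) <- list(
        NULL, indicatorSpecies(network),
        parameterNames(network)
      )
    }
    je <- matrix(res$jac_time, nrow = nTraj, ncol = P)
    colnames(je) <- parameterNames(network)
  }
  nOver <- sum(res$overrun)
  if (nOver > 0.01 * nTraj) {
    warning(sprintf(
      "%d of %d trajectories hit maxSteps before reaching the horizon",
      nOver, nTraj
    ))
  }
  theta <- setNames(cn$theta, parameterNames(network))
  new("TrajectoryBatch",
    finalStates = fin, readoutStates = ro, snapshotStates = sn,
    elapsedTimes = res$elapsed,
    occupancy = occ, nSteps = res$nsteps, overrun = res$overrun,
    jacFinal = jf, jacReadout = jr, jacSnapshot = js, jacOccupancy = jo,
    jacElapsed = je,
    noiseRecord = if (config@recordNoise) res$noise else list(),
    parameters = theta, seed = as.numeric(seed), horizon = T
  )
})

#' @rdname batch-accessors
#' @export
setMethod("finalStates", "TrajectoryBatch", function(x) x@finalStates)
#' @rdname batch-accessors
#' @export
setMethod("readoutStates", "TrajectoryBatch", function(x) x@readoutStates)
#' @rdname batch-accessors
#' @export
setMethod("snapshotStates", "TrajectoryBatch", function(x) x@snapshotStates)
#' @rdname batch-accessors
#' @export
setMethod("occupancy", "TrajectoryBatch", function(x) x@occupancy)
#' @rdname batch-accessors
#' @export
setMethod("elapsedTimes", "TrajectoryBatch", function(x) x@elapsedTimes)

setMethod("show", "TrajectoryBatch", function(object) {
  cat(sprintf(
    "TrajectoryBatch: %d trajectories, %d species, horizon %g\n",
    nrow(object@finalStates), ncol(object@finalStates), object@horizon
  ))
  cat(sprintf(
    "  gradients: %s; overruns: %d\n",
    if (is.null(object@jacFinal)) "no" else "yes", sum(object@overrun)
  ))
})

#' Pathwise gradient of a batch summary statistic
#'
#' Differentiates a scalar summary of a [TrajectoryBatch-class] with respect
#' to the kinetic parameters using the stored forward sensitivities (the
#' reparameterized, common-random-numbers estimator: noise held fixed,
#' derivatives flow through the smoothed waiting time, index selection and
#' state update). Supported summaries of one species' final abundances:
#' the ensemble \code{"mean"}, \code{"sd"} / \code{"var"} (sample versions,
#' denominator n - 1) and raw \code{"moment"} of a given order. Occupancy
#' column means are differentiated with \code{statistic = "occupancy"}.
#'
#' @param batch a [TrajectoryBatch-class] simulated with
#'   \code{gradients = TRUE}.
#' @param species species name (ignored for \code{"occupancy"}).
#' @param statistic one of "mean", "sd", "var", "moment", "occupancy".
#' @param order moment order for \code{statistic = "moment"}.
#' @param state indicator species name for \code{statistic = "occupancy"}.
#' @param source which horizon statistic to differentiate: the unbiased
#'   \code{"snapshot"} at time T (default), the smooth interpolated
#'   \code{"readout"} (finite-difference consistent across step-count
#'   changes), or the raw \code{"final"} states (one soft update past the
#'   horizon).
#' @return named gradient vector over parameters, with attribute
#'   \code{"value"} carrying the summary itself. Non-finite entries raise an
#'   error naming the parameter (increase a or b if this happens).
#' @rdname gradientOf
#' @export
setMethod("gradientOf", "TrajectoryBatch", function(batch, species = NULL,
                                                    statistic = c(
                                                      "mean", "sd", "var",
                                                      "moment", "occupancy"
                                                    ),
                                                    order = 1, state = NULL,
                                                    source = c(
                                                      "snapshot", "readout",
                                                      "final"
                                                    )) {
  statistic <- match.arg(statistic)
  source <- match.arg(source)
  if (statistic == "occupancy") {
    if (is.null(batch@jacOccupancy)) {
      stop("batch was simulated without gradients")
    }
    w <- batch@occupancy[, state]
    g <- apply(batch@jacOccupancy[, state, , drop = FALSE], 3, mean)
    val <- mean(w)
  } else {
    if (is.null(batch@jacFinal)) stop("batch was simulated without gradients")
    xs <- switch(source,
      snapshot = batch@snapshotStates[, species],
      readout = batch@readoutStates[, species],
      final = batch@finalStates[, species]
    )
    J <- switch(source,
      snapshot = batch@jacSnapshot[, species, , drop = FALSE],
      readout = batch@jacReadout[, species, , drop = FALSE],
      final = batch@jacFinal[, species, , drop = FALSE]
    )
    dim(J) <- dim(J)[c(1, 3)]
    n <- length(xs)
    if (statistic == "mean") {
      val <- mean(xs)
      g <- colMeans(J)
    } else if (statistic == "moment") {
      val <- mean(xs^order)
      g <- colMeans(order * xs^(order - 1) * J)
    } else {
      v <- var(xs)
      ctr <- xs - mean(xs)
      gv <- 2 / (n - 1) * colSums(ctr * J) # centering term vanishes
      if (statistic == "var") {
        val <- v
        g <- gv
      } else {
        val <- sqrt(v)
        g <- gv / (2 * sqrt(v))
      }
    }
  }
  names(g) <- names(batch@parameters)
  bad <- !is.finite(g)
  if (any(bad)) {
    stop(sprintf(
      "non-finite gradient for parameter '%s'; consider larger smoothing scales a or b",
      paste(names(g)[bad], collapse = ", ")
    ))
  }
  structure(g, value = val)
})

#' Export a trajectory batch to CSV
#'
#' Writes final states (and occupancies, when present) with a trajectory id
#' column.
#'
#' @param batch a [TrajectoryBatch-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
exportBatchCSV <- function(batch, path) {
  df <- data.frame(
    trajectory_id = seq_len(nrow(batch@finalStates)),
    as.data.frame(batch@finalStates),
    elapsed = batch@elapsedTimes
  )
  if (ncol(batch@occupancy) > 0) {
    occ <- as.data.frame(batch@occupancy)
    names(occ) <- paste0("occ_", colnames(batch@occupancy))
    df <- cbind(df, occ)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Hyperparameter sweep for the smoothing scales
#'
#' Grid sweep over the inverse smoothing scales, reporting for each pair the
#' finite-difference relative error of the pathwise gradient of the mean
#' (the numerical-stability criterion: scales should be as small as
#' possible while gradients stay accurate) and the divergence-to-entropy
#' ratio against an exact-ensemble reference.
#'
#' @param network a [ReactionNetwork-class].
#' @param params named parameter values.
#' @param species species whose ensemble mean is differentiated.
#' @param oneOverA,oneOverB grids of inverse scales.
#' @param T,nTraj simulation settings (kept deliberately small; this is a
#'   diagnostic, not a production run).
#' @param seed master seed.
#' @return data.frame with columns \code{one_over_a}, \code{one_over_b},
#'   \code{grad_fd_rel_error}, \code{jsd_over_entropy}.
#' @export
sweepSmoothing <- function(network, params, species,
                           oneOverA = c(50, 100, 200, 400),
                           oneOverB = c(5, 10, 20, 40),
                           T = 50, nTraj = 200, seed = 1) {
  exact <- ensembleFinalStates(network, params,
    T = T, nTraj = nTraj,
    seed = seed + 1
  )
  pExact <- empiricalPDF(exact[, species])
  rows <- list()
  pn <- parameterNames(network)[1]
  for (ia in oneOverA) {
    for (ib in oneOverB) {
      sm <- smoothingParams(ia, ib)
      b <- simulateDGA(network, params,
        T = T, nTraj = nTraj, seed = seed,
        smoothing = sm, gradients = TRUE
      )
      g <- gradientOf(b, species, "mean")[pn]
      h <- 1e-3 * params[[pn]]
      up <- dn <- params
      up[pn] <- up[pn] + h
      dn[pn] <- dn[pn] - h
      fup <- mean(finalStates(simulateDGA(network, up,
        T = T, nTraj = nTraj,
        seed = seed, smoothing = sm
      ))[, species])
      fdn <- mean(finalStates(simulateDGA(network, dn,
        T = T, nTraj = nTraj,
        seed = seed, smoothing = sm
      ))[, species])
      fd <- (fup - fdn) / (2 * h)
      relerr <- abs(g - fd) / max(abs(fd), 1e-12)
      ratio <- jsdOverEntropy(empiricalPDF(finalStates(b)[, species]), pExact)
      rows[[length(rows) + 1]] <- data.frame(
        one_over_a = ia, one_over_b = ib,
        grad_fd_rel_error = as.numeric(relerr),
        jsd_over_entropy = ratio
      )
    }
  }
  do.call(rbind, rows)
}
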