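#' @import methods
#' @importFrom stats sd var setNames coef lm optim rnorm runif quantile
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib diffGillespie, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Reaction network with smooth, parameterized rate laws
#'
#' A \code{ReactionNetwork} bundles a stoichiometric matrix (one row per
#' reaction, one column per species) with an ordered list of rate laws and
#' the names of the kinetic parameters they reference. Rate laws are
#' restricted to smooth products so that simulated trajectories are
#' differentiable with respect to every parameter: each propensity is
#'
#' \deqn{r_i(x) = \theta_{p_1} \cdot \theta_{p_2} \cdot c \cdot x_s}
#'
#' where the second parameter \eqn{\theta_{p_2}}, the external scalar
#' \eqn{c} (for instance an activator concentration, an input that is never
#' optimized), and the single species factor \eqn{x_s} are each optional.
#' This covers the three supported forms: constant, proportional to one
#' species, and constant times an external scalar.
#'
#' Promoter states are encoded as one indicator species per state (exactly
#' one indicator equals 1 in exact simulation; the differentiable simulator
#' keeps them real-valued and renormalizes when accumulating occupancy).
#' The \code{indicators} slot names those species.
#'
#' @slot stoichiometry integer matrix, reactions in rows, species in columns.
#' @slot rateLaws list of rate laws as returned by [rateLaw()].
#' @slot speciesNames character vector of species labels.
#' @slot parameterNames ordered character vector of kinetic parameter labels.
#' @slot reactionNames character vector of reaction labels.
#' @slot extScalars named numeric vector of external scalar inputs.
#' @slot indicators character vector naming promoter-state indicator species.
#' @slot initialState default initial abundances (named numeric).
#'
#' @seealso [reactionNetwork()], [twoStatePromoter()], [fourStatePromoter()]
#' @export
setClass("ReactionNetwork",
  representation(
    stoichiometry = "matrix",
    rateLaws = "list",
    speciesNames = "character",
    parameterNames = "character",
    reactionNames = "character",
    extScalars = "numeric",
    indicators = "character",
    initialState = "numeric"
  )
)

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  S <- object@stoichiometry
  if (nrow(S) != length(object@rateLaws)) {
    msg <- c(msg, sprintf(
      "stoichiometry has %d rows but %d rate laws are defined",
      nrow(S), length(object@rateLaws)
    ))
  }
  if (ncol(S) != length(object@speciesNames)) {
    msg <- c(msg, "stoichiometry column count must match speciesNames")
  }
  if (length(object@reactionNames) != nrow(S)) {
    msg <- c(msg, "reactionNames length must match reaction count")
  }
  if (any(abs(S) > 10)) {
    msg <- c(msg, "stoichiometric entries must lie in [-10, 10]")
  }
  if (any(S != round(S))) {
    msg <- c(msg, "stoichiometric entries must be integers")
  }
  for (i in seq_along(object@rateLaws)) {
    rl <- object@rateLaws[[i]]
    if (!all(rl$params %in% object@parameterNames)) {
      msg <- c(msg, sprintf(
        "rate law %d references unknown parameter '%s'", i,
        paste(setdiff(rl$params, object@parameterNames), collapse = ", ")
      ))
    }
    if (!is.na(rl$species) && !(rl$species %in% object@speciesNames)) {
      msg <- c(msg, sprintf("rate law %d references unknown species", i))
    }
    if (!is.na(rl$scalar) && !(rl$scalar %in% names(object@extScalars))) {
      msg <- c(msg, sprintf("rate law %d references unknown external scalar", i))
    }
  }
  if (!all(object@indicators %in% object@speciesNames)) {
    msg <- c(msg, "indicators must name existing species")
  }
  if (length(object@initialState) != ncol(S)) {
    msg <- c(msg, "initialState length must match species count")
  }
  if (length(msg)) msg else TRUE
})

#' Smoothing hyperparameters of the differentiable simulator
#'
#' Holds the two hyperparameters of the smoothed Gillespie stepper: the
#' sigmoid steepness scale \code{a} used in reaction selection and the
#' Gaussian width \code{b} used in the soft stoichiometry update. Smaller
#' values approximate the exact algorithm more closely but eventually make
#' gradients numerically unstable. Defaults are \code{1/a = 200},
#' \code{1/b = 20}.
#'
#' @slot a sigmoid steepness scale (dimensionless, > 0).
#' @slot b squared-index Gaussian width (dimensionless, > 0).
#' @seealso [smoothingParams()]
#' @export
setClass("SmoothingParams", representation(a = "numeric", b = "numeric"))

setValidity("SmoothingParams", function(object) {
  if (length(object@a) != 1 || length(object@b) != 1 ||
    !is.finite(object@a) || !is.finite(object@b) ||
    object@a <= 0 || object@b <= 0) {
    "a and b must be finite positive scalars"
  } else {
    TRUE
  }
})

#' Runtime configuration of the differentiable simulator
#'
#' @slot maxSteps cap on reaction events per trajectory; overruns are flagged,
#'   never silent.
#' @slot rateFloor small positive rate added to the total rate inside
#'   divisions to prevent blow-ups near absorbing states; a raw total rate
#'   below this value terminates the trajectory as absorbing.
#' @slot clampNonnegative apply the smooth (softplus) nonnegativity clamp
#'   after every state update.
#' @slot nTraj default ensemble size.
#' @slot recordNoise store every uniform draw (for replay tests; memory-heavy
#'   on long runs).
#' @seealso [dgaConfig()]
#' @export
setClass("DGAConfig",
  representation(
    maxSteps = "numeric", rateFloor = "numeric",
    clampNonnegative = "logical", nTraj = "numeric", recordNoise = "logical"
  )
)

setValidity("DGAConfig", function(object) {
  msg <- character()
  if (object@maxSteps < 1) msg <- c(msg, "maxSteps must be >= 1")
  if (object@rateFloor < 0) msg <- c(msg, "rateFloor must be >= 0")
  if (object@nTraj < 1) msg <- c(msg, "nTraj must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ensemble of smoothed trajectories with a differentiability contract
#'
#' Result container of [simulateDGA()]. For a fixed seed every field is a
#' smooth function of the kinetic parameters; when gradients were requested,
#' the Jacobians of the final states and of the soft state occupancies with
#' respect to the parameters (pathwise, common-random-numbers derivatives)
#' are stored alongside.
#'
#' @slot finalStates real-valued matrix, trajectories in rows, species in
#'   columns (state after the final smoothed update, which may overshoot the
#'   horizon).
#' @slot snapshotStates the state at exactly the horizon in the exact-SSA
#'   sense: the state whose dwell interval covers time T (no post-horizon
#'   update included). This is the unbiased statistics surface and the
#'   default everywhere summary moments are computed.
#' @slot readoutStates smooth surrogate snapshot: the snapshot state
#'   linearly time-interpolated toward the post-crossing state. Continuous
#'   in the parameters even where a trajectory's step count changes (the
#'   snapshot is not), so this is the field finite-difference gradient
#'   checks are run on; at low copy numbers the interpolation shrinks the
#'   ensemble variance, which is why it is not the default statistic.
#' @slot elapsedTimes per-trajectory total simulated time (>= the horizon
#'   unless the step cap was hit; the last step may overshoot).
#' @slot occupancy per-trajectory soft time-in-state fractions over the
#'   indicator species (rows sum to 1).
#' @slot nSteps number of smoothed reaction events per trajectory.
#' @slot overrun flag per trajectory: step cap reached before the horizon.
#' @slot jacFinal array (trajectories x species x parameters) or NULL.
#' @slot jacReadout Jacobian of the readout states, same shape.
#' @slot jacSnapshot pathwise Jacobian of the snapshot states (boundary
#'   terms from step-count changes are not part of this derivative).
#' @slot jacOccupancy array (trajectories x states x parameters) or NULL.
#' @slot jacElapsed matrix (trajectories x parameters) or NULL.
#' @slot noiseRecord list of per-trajectory matrices of the uniform draws
#'   (u, u') actually used, when recording was requested.
#' @slot parameters the kinetic parameters the batch was simulated at.
#' @slot seed master seed of the per-trajectory substreams.
#' @slot horizon simulation horizon.
#' @export
setClass("TrajectoryBatch",
  representation(
    finalStates = "matrix", readoutStates = "matrix",
    snapshotStates = "matrix",
    elapsedTimes = "numeric", occupancy = "matrix",
    nSteps = "numeric", overrun = "logical", jacFinal = "ANY",
    jacReadout = "ANY", jacSnapshot = "ANY", jacOccupancy = "ANY",
    jacElapsed = "ANY", noiseRecord = "list",
    parameters = "numeric", seed = "numeric", horizon = "numeric"
  )
)

#' Discrete probability distribution on integer support
#'
#' @slot support ordered integer bins.
#' @slot probs nonnegative probabilities summing to one.
#' @seealso [empiricalPDF()], [pdfEntropy()], [jsDivergence()]
#' @export
setClass("DiscretePDF", representation(support = "integer", probs = "numeric"))

setValidity("DiscretePDF", function(object) {
  msg <- character()
  if (length(object@support) != length(object@probs)) {
    msg <- c(msg, "support and probs must have equal length")
  }
  if (any(object@probs < 0)) msg <- c(msg, "probabilities must be >= 0")
  if (abs(sum(object@probs) - 1) > 1e-9) {
    msg <- c(msg, "probabilities must sum to 1 (tolerance 1e-9)")
  }
  if (is.unsorted(object@support, strictly = TRUE)) {
    msg <- c(msg, "support must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a gradient-based parameter fit
#'
#' @slot thetaHat named numeric vector of estimated parameters (the iterate
#'   with the lowest recorded loss).
#' @slot lossTrace per-iteration loss values.
#' @slot ci matrix of per-parameter confidence intervals, columns
#'   \code{lower}/\code{upper}, computed from the loss curvature exactly as
#'   the asymmetric interval \eqn{[\hat\theta - \delta, \hat\theta + 1.96\delta]}
#'   with \eqn{\delta} the inverse second derivative (see
#'   [confidenceInterval()]).
#' @slot ciStandard same but with the symmetric half-width
#'   \eqn{1.96\sqrt{2/\mathrm{curvature}}}.
#' @slot seeds list recording the master seed and the per-iteration seeds.
#' @slot converged logical; FALSE when the divergence guard aborted the run.
#' @slot settings list of optimizer settings used.
#' @export
setClass("FitResult",
  representation(
    thetaHat = "numeric", lossTrace = "numeric", ci = "matrix",
    ciStandard = "matrix", seeds = "list", converged = "logical",
    settings = "list"
  )
)

#' Synthetic benchmark datasets for the two-state promoter
#'
#' Ground-truth parameter draws together with steady-state moment targets
#' computed by exact Gillespie ensembles (never by the smoothed simulator).
#'
#' @slot trueParams data.frame of the generating parameters, one row per set
#'   (for multi-condition data the per-condition binding rates live in
#'   \code{targets}).
#' @slot targets data.frame with columns \code{set}, (\code{condition},
#'   \code{konR} when multi-condition), \code{mean}, \code{sd}, \code{fano}.
#' @slot conditions number of repressor-concentration conditions per set.
#' @slot seed generation seed.
#' @export
setClass("SyntheticDataset",
  representation(
    trueParams = "data.frame", targets = "data.frame",
    conditions = "numeric", seed = "numeric"
  )
)

#' Target dose-response curve for promoter design
#'
#' A desired input-output relation: mean mRNA production rate as a function
#' of activator concentration, represented as a 6th-degree polynomial in
#' log10 concentration evaluated on a log-spaced grid.
#'
#' @slot coeffs 7 polynomial coefficients (constant term first) in
#'   log10 concentration.
#' @slot concGrid strictly increasing positive concentrations (default 10
#'   log-spaced points).
#' @slot values desired mean production rates at the grid points (>= 0).
#' @slot name label of the target.
#' @seealso [targetResponse()], [referenceTarget()], [designFit()]
#' @export
setClass("TargetResponse",
  representation(
    coeffs = "numeric", concGrid = "numeric", values = "numeric",
    name = "character"
  )
)

setValidity("TargetResponse", function(object) {
  msg <- character()
  if (length(object@coeffs) != 7) msg <- c(msg, "coeffs must have length 7")
  if (length(object@concGrid) != length(object@values)) {
    msg <- c(msg, "concGrid and values must have equal length")
  }
  if (any(object@concGrid <= 0) ||
    is.unsorted(object@concGrid, strictly = TRUE)) {
    msg <- c(msg, "concGrid must be strictly increasing and positive")
  }
  if (any(object@values < 0)) msg <- c(msg, "target values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of a four-state promoter design run
#'
#' @slot thetaHat fitted promoter parameters (full set, including the fixed
#'   \code{kb} and \code{r}).
#' @slot achieved achieved mean production rate per grid concentration
#'   (exact steady-state evaluation).
#' @slot lossTrace per-iteration design loss.
#' @slot sharpness max over concentration of \eqn{[c]\,d\langle\bar r\rangle/d[c]}.
#' @slot drive nonequilibrium drive \eqn{\Delta\mu}.
#' @slot flux cycle flux J per grid concentration.
#' @slot power dissipated power \eqn{\Phi = J\Delta\mu} per grid
#'   concentration.
#' @slot powerMid power at the response midpoint concentration (the reported
#'   scalar).
#' @slot target the [TargetResponse-class] that was fitted.
#' @slot engine "exact" or "dga" inner loop.
#' @export
setClass("DesignResult",
  representation(
    thetaHat = "numeric", achieved = "numeric", lossTrace = "numeric",
    sharpness = "numeric", drive = "numeric", flux = "numeric",
    power = "numeric", powerMid = "numeric", target = "TargetResponse",
    engine = "character"
  )
)
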