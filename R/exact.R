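#' @include network.R
NULL

#' One exact Gillespie step
#'
#' The direct method: with total rate \eqn{R = \sum_i r_i}, the waiting time
#' is \eqn{\tau = -\ln(u)/R} and the fired reaction is the smallest index
#' \eqn{i'} whose cumulative propensity fraction exceeds \eqn{u'}. The state
#' is advanced by the corresponding stoichiometry row. Both uniform draws
#' are explicit arguments so the step is a pure function, reusable under
#' common random numbers.
#'
#' @param network a [ReactionNetwork-class].
#' @param state numeric species vector.
#' @param t current time.
#' @param params named parameter values.
#' @param u,uprime uniform draws in (0, 1].
#' @return list with \code{state}, \code{t}, \code{reaction} (integer index),
#'   \code{tau}; or a list with \code{absorbed = TRUE} and the unchanged
#'   state when the total rate is zero.
#' @examples
#' net <- twoStatePromoter(0.5, 1, 10, 1)
#' stepExact(net, initialState(net), 0,
#'   params = c(konR = 0.5, koffR = 1, r = 10, gamma = 1),
#'   u = 0.5, uprime = 0.9
#' )
#' @export
stepExact <- function(network, state, t, params, u, uprime) {
  stopifnot(u > 0, u <= 1, uprime > 0, uprime <= 1)
  r <- propensities(network, state, params)
  R <- totalRate(r)
  if (R == 0) {
    return(list(state = state, t = t, reaction = NA_integer_, absorbed = TRUE))
  }
  tau <- -log(u) / R
  i <- exactIndex(r, uprime)
  state2 <- state + stoichiometry(network)[i, ]
  list(
    state = state2, t = t + tau, reaction = i, tau = tau,
    absorbed = FALSE
  )
}

# smallest i with cumulative fraction > u'
exactIndex <- function(r, uprime) {
  q <- cumsum(r) / sum(r)
  unname(which(q > uprime)[1])
}

#' Simulate one exact trajectory
#'
#' Runs the exact Gillespie direct method to the horizon and returns the
#' full event record. The trajectory is piecewise constant; the last
#' recorded event time is <= the horizon. Bit-exactly reproducible for a
#' fixed seed. When the total rate hits zero the state is absorbing and
#' holds to the horizon.
#'
#' @param network a [ReactionNetwork-class].
#' @param params named parameter values.
#' @param x0 initial state (defaults to the network's).
#' @param T simulation horizon (> 0).
#' @param seed integer seed.
#' @param maxEvents cap on recorded events.
#' @return data.frame with columns \code{time}, \code{reaction} (NA for the
#'   initial row) and one column per species; attribute \code{absorbed}.
#' @rdname simulateExact
#' @export
setMethod("simulateExact", "ReactionNetwork", function(network, params,
                                                       x0 = initialState(network),
                                                       T = 100, seed = 1,
                                                       maxEvents = 1e6) {
  stopifnot(T > 0)
  cn <- netToC(network, params)
  res <- cpp_simulate_exact_events(
    cn$S, cn$form, cn$p1, cn$p2, cn$sp, cn$mult, cn$theta,
    as.numeric(x0), T, as.numeric(seed), maxEvents
  )
  out <- data.frame(time = res$time, reaction = res$reaction)
  states <- res$states
  colnames(states) <- speciesNames(network)
  out <- cbind(out, as.data.frame(states))
  attr(out, "absorbed") <- res$absorbed
  out
})

#' Exact-ensemble final states at a fixed horizon
#'
#' Simulates \code{nTraj} independent exact trajectories (independent
#' counter-derived RNG substreams of one master seed) and returns each
#' trajectory's state at time \code{T}, plus the time-averaged state over
#' \code{[0, T]} as attribute \code{"timeavg"} (for indicator species this
#' is the exact state occupancy).
#'
#' @param network a [ReactionNetwork-class].
#' @param params named parameter values.
#' @param x0 initial state.
#' @param T horizon.
#' @param nTraj ensemble size (>= 1).
#' @param seed master seed.
#' @param maxEvents per-trajectory event cap.
#' @return numeric matrix (nTraj x nSpecies) of final states with attributes
#'   \code{timeavg} (matrix), \code{nevents}, \code{absorbed}.
#' @examples
#' net <- twoStatePromoter(0.5, 1, 10, 1)
#' fs <- ensembleFinalStates(net, c(konR = 0.5, koffR = 1, r = 10, gamma = 1),
#'   T = 50, nTraj = 200, seed = 1
#' )
#' mean(fs[, "m"])
#' @rdname ensembleFinalStates
#' @export
setMethod("ensembleFinalStates", "ReactionNetwork", function(network, params,
                                                             x0 = initialState(network),
                                                             T = 100,
                                                             nTraj = 2000,
                                                             seed = 1,
                                                             maxEvents = 1e8) {
  stopifnot(T > 0, nTraj >= 1)
  cn <- netToC(network, params)
  res <- cpp_simulate_exact(
    cn$S, cn$form, cn$p1, cn$p2, cn$sp, cn$mult, cn$theta,
    as.numeric(x0), T, as.integer(nTraj), as.numeric(seed), maxEvents
  )
  fin <- res$final
  colnames(fin) <- speciesNames(network)
  ta <- res$timeavg
  colnames(ta) <- speciesNames(network)
  structure(fin,
    timeavg = ta, nevents = res$nevents,
    absorbed = res$absorbed
  )
})

#' Export a trajectory or ensemble summary to CSV
#'
#' @param x a trajectory data.frame from [simulateExact()] or a final-state
#'   matrix from [ensembleFinalStates()].
#' @param path output CSV path.
#' @param id trajectory id recorded in the file.
#' @return \code{path}, invisibly.
#' @export
exportTrajectoryCSV <- function(x, path, id = 1L) {
  if (is.matrix(x)) {
    df <- data.frame(trajectory_id = seq_len(nrow(x)), as.data.frame(x))
  } else {
    df <- data.frame(trajectory_id = id, x)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
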