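#' @include network.R
NULL

#' Two-state (telegraph) promoter model
#'
#' Builds the classic repressed-promoter network: the gene toggles between a
#' transcriptionally active state (indicator species \code{g_free}) and a
#' repressor-bound, silent state (\code{g_bound}); mRNA \code{m} is
#' transcribed at rate \code{r} only while free and degrades at rate
#' \code{gamma}. Reactions, in declared order: repressor bind
#' (\code{konR * g_free}), unbind (\code{koffR * g_bound}), transcribe
#' (\code{r * g_free}), degrade (\code{gamma * m}). Time is conventionally
#' measured in units of the unbinding rate (\code{koffR = 1}).
#'
#' @param konR repressor binding rate (> 0).
#' @param koffR repressor unbinding rate (> 0, the time unit).
#' @param r transcription rate (> 0).
#' @param gamma mRNA degradation rate constant (> 0).
#' @param m0 initial mRNA abundance (real values allowed in the smoothed
#'   simulator; warm-starting near the stationary mean shortens transients).
#' @return a [ReactionNetwork-class] starting in the free state.
#' @examples
#' net <- twoStatePromoter(konR = 0.5, koffR = 1, r = 10, gamma = 1)
#' net
#' @export
twoStatePromoter <- function(konR = 0.5, koffR = 1, r = 10, gamma = 1,
                             m0 = 0) {
  stopifnot(konR > 0, koffR > 0, r > 0, gamma > 0)
  S <- matrix(
    c(
      -1, +1, 0, # bind: free -> bound
      +1, -1, 0, # unbind
      0, 0, +1, # transcribe
      0, 0, -1 # degrade
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(
      c("bind", "unbind", "transcribe", "degrade"),
      c("g_free", "g_bound", "m")
    )
  )
  reactionNetwork(
    S,
    rateLaws = list(
      rateLaw("konR", species = "g_free"),
      rateLaw("koffR", species = "g_bound"),
      rateLaw("r", species = "g_free"),
      rateLaw("gamma", species = "m")
    ),
    parameters = c("konR", "koffR", "r", "gamma"),
    indicators = c("g_free", "g_bound"),
    initialState = c(g_free = 1, g_bound = 0, m = m0)
  )
}

#' Closed-form stationary mean and Fano factor of the two-state promoter
#'
#' From the stationary solution of the two-state master equation:
#' \deqn{\langle m \rangle = \frac{r}{\gamma}\,
#'   \frac{k_{off}}{k_{on}+k_{off}}, \qquad
#'   f = 1 + \frac{r\, k_{on}}{(k_{on}+k_{off})(k_{on}+k_{off}+\gamma)}.}
#' With no repression (\eqn{k_{on} \to 0}) the distribution is Poisson
#' (mean \eqn{r/\gamma}, Fano 1). These formulas are cross-checked against
#' the truncated master-equation solver [twoStateStationaryPDF()] in the
#' test suite before they are used as oracles anywhere.
#'
#' @param konR,koffR,r,gamma two-state rates (> 0).
#' @return named numeric vector with \code{mean}, \code{fano}, \code{sd}.
#' @examples
#' twoStateMeanFano(0.5, 1, 10, 1) # mean 6.667, fano 2.333
#' @export
twoStateMeanFano <- function(konR, koffR, r, gamma) {
  stopifnot(konR > 0, koffR > 0, r > 0, gamma > 0)
  m <- (r / gamma) * koffR / (konR + koffR)
  f <- 1 + r * konR / ((konR + koffR) * (konR + koffR + gamma))
  c(mean = m, fano = f, sd = sqrt(f * m))
}

#' Truncated master-equation stationary distribution (two-state promoter)
#'
#' Brute-force oracle: solves the stationary chemical master equation on the
#' truncated state space \{free, bound\} x \{0, .., mMax\} by direct linear
#' solve of \eqn{Q^T \pi = 0} with normalization. Returns the marginal mRNA
#' distribution.
#'
#' @param konR,koffR,r,gamma two-state rates.
#' @param mMax mRNA truncation (increase until the tail mass is negligible).
#' @return a [DiscretePDF-class] over m = 0..mMax with attributes
#'   \code{mean}, \code{var}, \code{fano}.
#' @export
twoStateStationaryPDF <- function(konR, koffR, r, gamma, mMax = 150) {
  nm <- mMax + 1
  n <- 2 * nm # index: state g (0 free, 1 bound) x m
  idx <- function(g, m) g * nm + m + 1
  Q <- matrix(0, n, n)
  for (g in 0:1) {
    for (m in 0:mMax) {
      i <- idx(g, m)
      rates <- list()
      if (g == 0) {
        rates[[length(rates) + 1]] <- c(idx(1, m), konR)
        if (m < mMax) rates[[length(rates) + 1]] <- c(idx(0, m + 1), r)
      } else {
        rates[[length(rates) + 1]] <- c(idx(0, m), koffR)
      }
      if (m > 0) rates[[length(rates) + 1]] <- c(idx(g, m - 1), gamma * m)
      for (rr in rates) {
        Q[i, rr[1]] <- Q[i, rr[1]] + rr[2]
        Q[i, i] <- Q[i, i] - rr[2]
      }
    }
  }
  A <- t(Q)
  A[n, ] <- 1 # replace one balance row by normalization
  bvec <- c(rep(0, n - 1), 1)
  pi <- solve(A, bvec)
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)
  pm <- pi[idx(0, 0:mMax)] + pi[idx(1, 0:mMax)]
  mu <- sum((0:mMax) * pm)
  v <- sum((0:mMax)^2 * pm) - mu^2
  structure(new("DiscretePDF", support = 0:mMax, probs = pm / sum(pm)),
    mean = mu, var = v, fano = v / mu
  )
}

#' Four-state nonequilibrium promoter model
#'
#' Promoter cycle with an activator (concentration \code{c}) that can bind
#' in both the OFF and ON chromatin states: s0 = OFF/unbound, s1 =
#' OFF/bound, s2 = ON/bound, s3 = ON/unbound. Transitions (indicator-species
#' hops, one per reaction):
#' \itemize{
#'   \item binding: s0 -> s1 at \code{c * kb}; s3 -> s2 at
#'     \code{c * eta_ba * kb}
#'   \item unbinding: s1 -> s0 at \code{ku}; s2 -> s3 at \code{eta_ua * ku}
#'   \item activation: s0 -> s3 at \code{ka}; s1 -> s2 at
#'     \code{eta_ab * ka}
#'   \item inactivation: s3 -> s0 at \code{ki}; s2 -> s1 at
#'     \code{eta_ib * ki}
#' }
#' The eta multipliers encode how binding modifies switching and vice
#' versa; detailed balance holds iff
#' \code{eta_ab * eta_ua == eta_ib * eta_ba} (zero nonequilibrium drive).
#' mRNA is not simulated: production is read out from the ON occupancies
#' via [meanProductionRate()].
#'
#' @param params named numeric vector (or list) with \code{kb}, \code{ku},
#'   \code{ka}, \code{ki}, \code{eta_ab}, \code{eta_ib}, \code{eta_ba},
#'   \code{eta_ua}, all > 0. The transcription rate \code{r} is carried
#'   separately because it only scales the readout.
#' @param conc activator concentration (> 0).
#' @return a [ReactionNetwork-class] starting in s0.
#' @examples
#' p <- c(
#'   kb = 0.02, ku = 1, ka = 1, ki = 1, eta_ab = 2, eta_ib = 1,
#'   eta_ba = 1, eta_ua = 2
#' )
#' net <- fourStatePromoter(p, conc = 1)
#' fourStateSteadyState(p, conc = 1)
#' @export
fourStatePromoter <- function(params, conc) {
  params <- unlist(params)
  need <- c("kb", "ku", "ka", "ki", "eta_ab", "eta_ib", "eta_ba", "eta_ua")
  stopifnot(all(need %in% names(params)), all(params[need] > 0), conc > 0)
  sp <- c("s0", "s1", "s2", "s3")
  edges <- list( # from, to, rate-law
    list("s0", "s1", rateLaw("kb", species = "s0", scalar = "c")),
    list("s1", "s0", rateLaw("ku", species = "s1")),
    list("s3", "s2", rateLaw(c("kb", "eta_ba"), species = "s3", scalar = "c")),
    list("s2", "s3", rateLaw(c("ku", "eta_ua"), species = "s2")),
    list("s0", "s3", rateLaw("ka", species = "s0")),
    list("s3", "s0", rateLaw("ki", species = "s3")),
    list("s1", "s2", rateLaw(c("ka", "eta_ab"), species = "s1")),
    list("s2", "s1", rateLaw(c("ki", "eta_ib"), species = "s2"))
  )
  S <- matrix(0L, length(edges), 4, dimnames = list(
    vapply(edges, function(e) paste0(e[[1]], "_to_", e[[2]]), ""), sp
  ))
  for (i in seq_along(edges)) {
    S[i, edges[[i]][[1]]] <- -1L
    S[i, edges[[i]][[2]]] <- +1L
  }
  reactionNetwork(
    S,
    rateLaws = lapply(edges, `[[`, 3),
    parameters = need,
    extScalars = c(c = conc),
    indicators = sp,
    initialState = c(s0 = 1, s1 = 0, s2 = 0, s3 = 0)
  )
}

# 4x4 transition-rate matrix Q (rows = from, Q[i,j] = rate i->j) of the
# four-state promoter at concentration conc
fourStateQ <- function(params, conc) {
  p <- unlist(params)
  Q <- matrix(0, 4, 4, dimnames = list(
    c("s0", "s1", "s2", "s3"),
    c("s0", "s1", "s2", "s3")
  ))
  Q["s0", "s1"] <- conc * p[["kb"]]
  Q["s1", "s0"] <- p[["ku"]]
  Q["s3", "s2"] <- conc * p[["eta_ba"]] * p[["kb"]]
  Q["s2", "s3"] <- p[["eta_ua"]] * p[["ku"]]
  Q["s0", "s3"] <- p[["ka"]]
  Q["s3", "s0"] <- p[["ki"]]
  Q["s1", "s2"] <- p[["eta_ab"]] * p[["ka"]]
  Q["s2", "s1"] <- p[["eta_ib"]] * p[["ki"]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Exact steady state of the four-state promoter
#'
#' Solves \eqn{Q^T \pi = 0}, \eqn{\sum_s \pi_s = 1} by direct linear solve;
#' the chain is irreducible for positive rates so the solution is unique and
#' strictly positive.
#'
#' @param params four-state parameters (see [fourStatePromoter()]).
#' @param conc activator concentration.
#' @return probability 4-vector named s0..s3.
#' @export
fourStateSteadyState <- function(params, conc) {
  Q <- fourStateQ(params, conc)
  A <- t(Q)
  A[4, ] <- 1
  pi <- solve(A, c(0, 0, 0, 1))
  if (any(!is.finite(pi))) stop("steady-state solve failed")
  setNames(pmax(pi, 0) / sum(pmax(pi, 0)), rownames(Q))
}

# independent oracle: stationary vector via the matrix-tree (Kirchhoff)
# theorem, pi_s proportional to the cofactor of the Laplacian L = -Q^T
kirchhoffSteadyState <- function(params, conc) {
  Q <- fourStateQ(params, conc)
  L <- -t(Q)
  w <- vapply(1:4, function(s) det(L[-s, -s, drop = FALSE]), 0)
  setNames(abs(w) / sum(abs(w)), rownames(Q))
}

#' Mean mRNA production rate of the four-state promoter
#'
#' \eqn{\langle\bar r\rangle = r\,(\pi_2 + \pi_3)}: transcription proceeds
#' at rate r in either ON state.
#'
#' @param pi probability 4-vector over s0..s3 (must sum to 1 within 1e-6).
#' @param r transcription rate.
#' @return scalar mean production rate.
#' @examples
#' meanProductionRate(c(0, 0, 0.5, 0.5), r = 10) # 5
#' @export
meanProductionRate <- function(pi, r) {
  if (abs(sum(pi) - 1) > 1e-6) {
    stop("pi must be normalized (sum within 1e-6 of 1)")
  }
  r * (pi[[3]] + pi[[4]])
}
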