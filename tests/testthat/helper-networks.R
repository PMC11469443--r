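# shared small fixtures, built in code

birthNetwork <- function(k0 = 2) {
  S <- matrix(1L, 1, 1, dimnames = list("birth", "m"))
  reactionNetwork(S, list(rateLaw("k")), initialState = c(m = 0))
}

deathNetwork <- function(m0 = 5) {
  S <- matrix(-1L, 1, 1, dimnames = list("death", "m"))
  reactionNetwork(S, list(rateLaw("gamma", species = "m")),
    initialState = c(m = m0)
  )
}

birthDeathNetwork <- function() {
  S <- matrix(c(1L, -1L), 2, 1, dimnames = list(c("birth", "death"), "m"))
  reactionNetwork(S, list(rateLaw("k"), rateLaw("gamma", species = "m")),
    initialState = c(m = 0)
  )
}

figParams <- c(konR = 0.5, koffR = 1, r = 10, gamma = 1)
figNet <- function() twoStatePromoter(0.5, 1, 10, 1)

fourStateExample <- c(
  kb = 0.02, ku = 2, ka = 0.5, ki = 1.5,
  eta_ab = 4, eta_ib = 0.8, eta_ba = 2, eta_ua = 3
)

# draw positive four-state parameters, kb fixed
randomFourState <- function() {
  c(
    kb = 0.02,
    setNames(
      exp(runif(7, log(0.2), log(5))),
      c("ku", "ka", "ki", "eta_ab", "eta_ib", "eta_ba", "eta_ua")
    )
  )
}
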