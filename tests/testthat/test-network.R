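test_that("propensities evaluate the smooth rate laws", {
  net <- figNet()
  r <- propensities(net, c(g_free = 1, g_bound = 0, m = 0), figParams)
  expect_equal(unname(r), c(0.5, 0, 10, 0))
  # bound state with two transcripts
  r2 <- propensities(net, c(g_free = 0, g_bound = 1, m = 2), figParams)
  expect_equal(unname(r2), c(0, 1, 0, 2))
  # linear law: gamma * m
  expect_equal(
    unname(propensities(deathNetwork(), c(m = 5), c(gamma = 1))), 5
  )
  # all species factors zero, no constant laws -> zero vector
  r3 <- propensities(net, c(g_free = 0, g_bound = 0, m = 0), figParams)
  expect_equal(unname(r3), rep(0, 4))
})

test_that("propensities are homogeneous of degree one in a single rate", {
  net <- figNet()
  st <- c(g_free = 1, g_bound = 0, m = 3)
  r1 <- propensities(net, st, figParams)
  p2 <- figParams
  p2["r"] <- 2 * p2["r"]
  r2 <- propensities(net, st, p2)
  expect_equal(r2[["transcribe"]], 2 * r1[["transcribe"]])
  expect_equal(r2[-3], r1[-3])
})

test_that("propensity errors name the problem", {
  net <- figNet()
  expect_error(
    propensities(net, c(1, 0, 0), c(konR = 1, koffR = 1, r = 1)),
    "gamma"
  )
  expect_error(propensities(net, c(1, 0), figParams), "species")
})

test_that("totalRate sums and bounds the propensities", {
  expect_equal(totalRate(c(0.5, 0, 10, 0)), 10.5)
  expect_equal(totalRate(rep(0, 3)), 0)
  expect_equal(totalRate(c(1, 1, 1)), 3)
  expect_error(totalRate(numeric(0)))
  for (i in 1:10) {
    r <- runif(5)
    expect_gte(totalRate(r), max(r))
  }
})

test_that("validateNetwork reports structural issues without throwing", {
  expect_equal(nrow(validateNetwork(figNet())), 0)
  # unreferenced parameter
  S <- matrix(1L, 1, 1, dimnames = list("birth", "m"))
  net <- reactionNetwork(S, list(rateLaw("k")),
    parameters = c("k", "unused"),
    initialState = c(m = 0)
  )
  iss <- validateNetwork(net)
  expect_true(any(grepl("unused", iss$message)))
  # consuming reaction without a matching species factor can go negative
  S2 <- matrix(-1L, 1, 1, dimnames = list("drain", "m"))
  net2 <- reactionNetwork(S2, list(rateLaw("k")), initialState = c(m = 0))
  iss2 <- validateNetwork(net2)
  expect_true(any(iss2$what == "negativity"))
})

test_that("network accessors expose the definition", {
  net <- figNet()
  expect_equal(nReactions(net), 4)
  expect_equal(nSpecies(net), 3)
  expect_equal(speciesNames(net), c("g_free", "g_bound", "m"))
  expect_setequal(parameterNames(net), names(figParams))
  expect_equal(indicatorSpecies(net), c("g_free", "g_bound"))
  expect_equal(unname(stoichiometry(net)["bind", ]), c(-1, 1, 0))
})

test_that("network specifications round-trip losslessly through YAML and JSON", {
  net <- fourStatePromoter(fourStateExample, conc = 1.7)
  for (ext in c("yaml", "json")) {
    path <- file.path(withr::local_tempdir(), paste0("net.", ext))
    writeNetwork(net, path)
    back <- readNetwork(path)
    expect_equal(stoichiometry(back), stoichiometry(net))
    expect_equal(rateLaws(back), rateLaws(net))
    expect_equal(externalScalars(back), externalScalars(net))
    expect_equal(indicatorSpecies(back), indicatorSpecies(net))
    expect_equal(initialState(back), initialState(net))
    p <- propensities(net, initialState(net), fourStateExample)
    expect_equal(propensities(back, initialState(back), fourStateExample), p)
  }
})
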