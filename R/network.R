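#' @include AllGenerics.R
NULL

#' Construct a rate law
#'
#' Rate laws are smooth products of up to two named kinetic parameters, an
#' optional external scalar input (e.g. an activator concentration, which is
#' an input and never optimized) and an optional single species factor:
#' \eqn{r_i(x) = \theta_{p_1}\theta_{p_2}\, c \, x_s}. The three supported
#' forms are \code{"constant"} (parameters only),
#' \code{"proportional"} (times one species abundance) and
#' \code{"scaled_constant"} (times an external scalar); a proportional law
#' may additionally carry a scalar. Every law evaluates to a nonnegative
#' real for nonnegative states and positive parameters, and is smooth in
#' both, which is what makes the simulator differentiable.
#'
#' @param params character, one or two kinetic parameter names whose product
#'   enters the rate.
#' @param species optional species name: propensity is proportional to that
#'   species' abundance.
#' @param scalar optional external scalar name (looked up in the network's
#'   \code{extScalars}).
#' @return a rate-law list with elements \code{params}, \code{species},
#'   \code{scalar}, \code{form}.
#' @examples
#' rateLaw("gamma", species = "m") # degradation gamma * m
#' rateLaw("kb", scalar = "c") # concentration-scaled binding
#' @export
rateLaw <- function(params, species = NA_character_, scalar = NA_character_) {
  stopifnot(is.character(params), length(params) %in% 1:2)
  form <- if (!is.na(species)) {
    "proportional"
  } else if (!is.na(scalar)) {
    "scaled_constant"
  } else {
    "constant"
  }
  list(
    params = params, species = as.character(species),
    scalar = as.character(scalar), form = form
  )
}

#' Construct a reaction network
#'
#' @param stoichiometry reaction-by-species integer matrix (row i encodes how
#'   reaction i changes each species).
#' @param rateLaws list of rate laws ([rateLaw()]), one per reaction.
#' @param species character vector of species names (defaults to
#'   stoichiometry column names).
#' @param parameters ordered character vector of kinetic parameter names
#'   (defaults to the union referenced by the rate laws).
#' @param reactions reaction names (defaults to stoichiometry row names).
#' @param extScalars named numeric vector of external scalar inputs.
#' @param indicators names of promoter-state indicator species (exactly one
#'   equals 1 in exact simulation).
#' @param initialState default initial abundances.
#' @return a validated [ReactionNetwork-class].
#' @examples
#' net <- reactionNetwork(
#'   stoichiometry = matrix(c(1, -1), 2, 1,
#'     dimnames = list(c("birth", "death"), "m")
#'   ),
#'   rateLaws = list(rateLaw("k"), rateLaw("gamma", species = "m"))
#' )
#' propensities(net, state = c(m = 5), params = c(k = 2, gamma = 1))
#' @export
reactionNetwork <- function(stoichiometry, rateLaws, species = NULL,
                            parameters = NULL, reactions = NULL,
                            extScalars = numeric(), indicators = character(),
                            initialState = NULL) {
  stoichiometry <- as.matrix(stoichiometry)
  if (is.null(species)) species <- colnames(stoichiometry)
  if (is.null(species)) {
    species <- paste0("x", seq_len(ncol(stoichiometry)))
  }
  if (is.null(reactions)) reactions <- rownames(stoichiometry)
  if (is.null(reactions)) {
    reactions <- paste0("r", seq_len(nrow(stoichiometry)))
  }
  if (is.null(parameters)) {
    parameters <- unique(unlist(lapply(rateLaws, `[[`, "params")))
  }
  if (is.null(initialState)) {
    initialState <- setNames(numeric(length(species)), species)
  }
  if (is.null(names(initialState))) names(initialState) <- species
  dimnames(stoichiometry) <- list(reactions, species)
  new("ReactionNetwork",
    stoichiometry = stoichiometry, rateLaws = rateLaws,
    speciesNames = species, parameterNames = parameters,
    reactionNames = reactions, extScalars = extScalars,
    indicators = indicators, initialState = initialState
  )
}

#' @rdname network-accessors
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@speciesNames)
#' @rdname network-accessors
#' @export
setMethod("parameterNames", "ReactionNetwork", function(x) x@parameterNames)
#' @rdname network-accessors
#' @export
setMethod("reactionNames", "ReactionNetwork", function(x) x@reactionNames)
#' @rdname network-accessors
#' @export
setMethod("stoichiometry", "ReactionNetwork", function(x) x@stoichiometry)
#' @rdname network-accessors
#' @export
setMethod("rateLaws", "ReactionNetwork", function(x) x@rateLaws)
#' @rdname network-accessors
#' @export
setMethod("nReactions", "ReactionNetwork", function(x) nrow(x@stoichiometry))
#' @rdname network-accessors
#' @export
setMethod("nSpecies", "ReactionNetwork", function(x) ncol(x@stoichiometry))
#' @rdname network-accessors
#' @export
setMethod("indicatorSpecies", "ReactionNetwork", function(x) x@indicators)
#' @rdname network-accessors
#' @export
setMethod("initialState", "ReactionNetwork", function(x) x@initialState)
#' @rdname network-accessors
#' @export
setMethod("externalScalars", "ReactionNetwork", function(x) x@extScalars)

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf(
    "ReactionNetwork: %d reactions, %d species\n",
    nReactions(object), nSpecies(object)
  ))
  cat("  species:   ", paste(object@speciesNames, collapse = ", "), "\n")
  cat("  parameters:", paste(object@parameterNames, collapse = ", "), "\n")
  for (i in seq_along(object@rateLaws)) {
    rl <- object@rateLaws[[i]]
    terms <- paste(rl$params, collapse = "*")
    if (!is.na(rl$scalar)) terms <- paste0(terms, "*[", rl$scalar, "]")
    if (!is.na(rl$species)) terms <- paste0(terms, "*", rl$species)
    cat(sprintf("  %-12s rate = %s\n", object@reactionNames[i], terms))
  }
  if (length(object@indicators)) {
    cat("  indicators:", paste(object@indicators, collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Evaluate reaction propensities
#'
#' Computes the propensity vector \eqn{r(x)} of a network at a given state.
#' Where the rate laws are smooth, the result is differentiable with respect
#' to both parameters and state; each propensity is nonnegative.
#'
#' @param network a [ReactionNetwork-class].
#' @param state named or ordered numeric vector of species abundances.
#' @param params named numeric vector supplying every referenced parameter
#'   with a positive value.
#' @return numeric vector of propensities, one per reaction, named by
#'   reaction.
#' @examples
#' net <- twoStatePromoter(konR = 0.5, koffR = 1, r = 10, gamma = 1)
#' propensities(net, c(g_free = 1, g_bound = 0, m = 0),
#'   params = c(konR = 0.5, koffR = 1, r = 10, gamma = 1)
#' )
#' @rdname propensities
#' @export
setMethod(
  "propensities", "ReactionNetwork",
  function(network, state, params) {
    if (length(state) != nSpecies(network)) {
      stop(sprintf(
        "state has length %d but the network has %d species",
        length(state), nSpecies(network)
      ))
    }
    if (is.null(names(state))) names(state) <- network@speciesNames
    r <- numeric(nReactions(network))
    for (i in seq_len(nReactions(network))) {
      rl <- network@rateLaws[[i]]
      missing <- setdiff(rl$params, names(params))
      if (length(missing)) {
        stop(sprintf(
          "missing parameter value for '%s'",
          paste(missing, collapse = ", ")
        ))
      }
      v <- prod(params[rl$params])
      if (!is.na(rl$scalar)) v <- v * network@extScalars[[rl$scalar]]
      if (!is.na(rl$species)) v <- v * state[[rl$species]]
      r[i] <- max(v, 0)
    }
    setNames(r, network@reactionNames)
  }
)

#' Total reaction rate
#'
#' Sum of the propensity vector, \eqn{R = \sum_i r_i}: the rate of the
#' pooled Poisson process from which waiting times are drawn.
#'
#' @param r numeric vector of propensities (length >= 1, finite,
#'   nonnegative).
#' @return scalar total rate.
#' @examples
#' totalRate(c(0.5, 0, 10, 0)) # 10.5
#' @export
totalRate <- function(r) {
  if (length(r) < 1) stop("propensity vector must have at least one entry")
  if (any(!is.finite(r))) stop("propensities must be finite")
  if (any(r < 0)) stop("propensities must be nonnegative")
  sum(r)
}

#' Diagnose a reaction network
#'
#' Reports (never throws) structural issues: shape mismatches, parameters
#' declared but referenced by no rate law, and reactions that can drive a
#' species negative from a reachable state (a reaction that consumes a
#' species without its propensity vanishing when that species is exhausted).
#'
#' @param network a [ReactionNetwork-class].
#' @return data.frame with columns \code{severity}, \code{what},
#'   \code{message}; zero rows when the network is clean.
#' @rdname validateNetwork
#' @export
setMethod("validateNetwork", "ReactionNetwork", function(network) {
  issues <- list()
  add <- function(severity, what, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, what = what, message = message,
      stringsAsFactors = FALSE
    )
  }
  S <- network@stoichiometry
  if (nrow(S) != length(network@rateLaws)) {
    add(
      "error", "shape",
      sprintf(
        "%d stoichiometry rows vs %d rate laws", nrow(S),
        length(network@rateLaws)
      )
    )
  }
  used <- unique(unlist(lapply(network@rateLaws, `[[`, "params")))
  for (p in setdiff(network@parameterNames, used)) {
    add("warning", "parameters", sprintf("parameter '%s' is never referenced", p))
  }
  for (i in seq_len(min(nrow(S), length(network@rateLaws)))) {
    rl <- network@rateLaws[[i]]
    consumed <- which(S[i, ] < 0)
    for (s in consumed) {
      guard <- !is.na(rl$species) && rl$species == network@speciesNames[s]
      if (!guard) {
        add(
          "warning", "negativity",
          sprintf(
            "reaction '%s' consumes '%s' but its rate law has no matching species factor: species can go negative",
            network@reactionNames[i], network@speciesNames[s]
          )
        )
      }
    }
  }
  if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(
      severity = character(), what = character(),
      message = character(), stringsAsFactors = FALSE
    )
  }
})

# --- internal: marshal a network + parameter values for the C++ core -------
netToC <- function(network, params) {
  missing <- setdiff(network@parameterNames, names(params))
  if (length(missing)) {
    stop(sprintf(
      "missing parameter value for '%s'",
      paste(missing, collapse = ", ")
    ))
  }
  theta <- as.numeric(params[network@parameterNames])
  nR <- nReactions(network)
  form <- integer(nR)
  p1 <- integer(nR)
  p2 <- integer(nR)
  sp <- integer(nR)
  mult <- numeric(nR)
  for (i in seq_len(nR)) {
    rl <- network@rateLaws[[i]]
    p1[i] <- match(rl$params[1], network@parameterNames) - 1L
    p2[i] <- if (length(rl$params) == 2) {
      match(rl$params[2], network@parameterNames) - 1L
    } else {
      -1L
    }
    form[i] <- if (!is.na(rl$species)) 1L else 0L
    sp[i] <- if (!is.na(rl$species)) {
      match(rl$species, network@speciesNames) - 1L
    } else {
      -1L
    }
    mult[i] <- if (!is.na(rl$scalar)) network@extScalars[[rl$scalar]] else 1
  }
  list(
    S = matrix(as.integer(network@stoichiometry), nrow = nR),
    form = form, p1 = p1, p2 = p2, sp = sp, mult = mult, theta = theta
  )
}

# --- YAML / JSON serialization ---------------------------------------------

networkToList <- function(network) {
  list(
    species = as.list(network@speciesNames),
    parameters = as.list(network@parameterNames),
    ext_scalars = as.list(network@extScalars),
    indicators = as.list(network@indicators),
    initial_state = as.list(network@initialState),
    reactions = lapply(seq_len(nReactions(network)), function(i) {
      rl <- network@rateLaws[[i]]
      out <- list(
        name = network@reactionNames[i],
        stoichiometry = as.list(as.integer(network@stoichiometry[i, ])),
        params = as.list(rl$params)
      )
      if (!is.na(rl$species)) out$species <- rl$species
      if (!is.na(rl$scalar)) out$scalar <- rl$scalar
      out
    })
  )
}

networkFromList <- function(x) {
  species <- unlist(x$species)
  reactions <- vapply(x$reactions, `[[`, "", "name")
  S <- do.call(rbind, lapply(x$reactions, function(r) {
    unlist(r$stoichiometry)
  }))
  dimnames(S) <- list(reactions, species)
  laws <- lapply(x$reactions, function(r) {
    rateLaw(unlist(r$params),
      species = if (is.null(r$species)) NA_character_ else r$species,
      scalar = if (is.null(r$scalar)) NA_character_ else r$scalar
    )
  })
  ext <- if (length(x$ext_scalars)) {
    unlist(x$ext_scalars)
  } else {
    numeric()
  }
  init <- unlist(x$initial_state)
  reactionNetwork(S, laws,
    species = species, parameters = unlist(x$parameters),
    reactions = reactions, extScalars = ext,
    indicators = as.character(unlist(x$indicators)),
    initialState = init
  )
}

#' Read and write network specifications
#'
#' Networks round-trip losslessly through a YAML (or JSON) document with a
#' species list and one block per reaction giving its stoichiometry row and
#' rate law.
#'
#' @param network a [ReactionNetwork-class].
#' @param path file path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return \code{readNetwork} returns a [ReactionNetwork-class];
#'   \code{writeNetwork} returns \code{path} invisibly.
#' @export
writeNetwork <- function(network, path) {
  x <- networkToList(network)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  networkFromList(x)
}
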