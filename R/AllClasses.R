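#' StateSpace: an ordered discrete character alphabet
#'
#' Holds the ordered list of state symbols for a K-state character.
#' The DNA default is `A, C, G, T` in that fixed order.
#'
#' @slot labels character vector of unique state symbols; `K = length(labels)`.
#' @export
setClass("StateSpace", representation(labels = "character"))

setValidity("StateSpace", function(object) {
  labs <- object@labels
  if (length(labs) < 2L) return("a state space needs K >= 2 states")
  if (anyDuplicated(labs)) return("state labels must be unique")
  if (any(!nzchar(labs))) return("state labels must be non-empty")
  TRUE
})

#' The four-state DNA alphabet (A, C, G, T)
#' @return a [StateSpace-class].
#' @export
dnaStateSpace <- function() new("StateSpace", labels = c("A", "C", "G", "T"))

#' A generic K-state alphabet labelled 0, 1, ...
#' @param K integer number of states (>= 2).
#' @return a [StateSpace-class].
#' @export
mkStateSpace <- function(K) {
  new("StateSpace", labels = as.character(seq_len(K) - 1L))
}

#' @describeIn StateSpace-class number of states K.
#' @param x,object a `StateSpace`.
#' @export
setMethod("length", "StateSpace", function(x) length(x@labels))

#' State symbols of a StateSpace
#' @param x a [StateSpace-class].
#' @return character vector of symbols in fixed order.
#' @export
stateLabels <- function(x) x@labels

setMethod("show", "StateSpace", function(object) {
  cat("StateSpace with", length(object@labels), "states:",
      paste(object@labels, collapse = " "), "\n")
})

#' SubstitutionModel: a reversible substitution model with rate mixture
#'
#' A general time-reversible model over a K-state alphabet: symmetric
#' exchangeabilities for unordered state pairs, equilibrium frequencies
#' \eqn{\pi}, and an among-site rate mixture built from a discrete-gamma
#' distribution plus an optional invariant-sites class. The rate matrix is
#' scaled so the mean substitution rate at equilibrium is 1, making branch
#' lengths expected substitutions per site.
#'
#' @slot stateSpace the [StateSpace-class].
#' @slot rates numeric vector of K(K-1)/2 exchangeabilities for unordered
#'   pairs in row-major upper-triangle order (DNA: AC, AG, AT, CG, CT, GT).
#' @slot freqs equilibrium frequencies, summing to 1.
#' @slot gammaShape gamma shape alpha (`NA` for no rate heterogeneity).
#' @slot pInv proportion of invariant sites in `[0, 1)`.
#' @slot nGammaCat number of discrete gamma categories.
#' @seealso [substitutionModel()], [jcModel()], [mkModel()],
#'   [transitionMatrix()], [rateMixture()]
#' @export
setClass("SubstitutionModel", representation(
  stateSpace = "StateSpace",
  rates = "numeric",
  freqs = "numeric",
  gammaShape = "numeric",
  pInv = "numeric",
  nGammaCat = "integer"
))

setValidity("SubstitutionModel", function(object) {
  K <- length(object@stateSpace)
  npair <- K * (K - 1L) / 2L
  if (length(object@rates) != npair) {
    return(sprintf("need %d exchangeabilities for K = %d states", npair, K))
  }
  if (any(!is.finite(object@rates)) || any(object@rates < 0)) {
    return("exchangeabilities must be finite and non-negative")
  }
  if (all(object@rates == 0)) return("exchangeabilities cannot all be zero")
  if (length(object@freqs) != K) {
    return(sprintf("need %d frequencies for K = %d states", K, K))
  }
  if (any(!is.finite(object@freqs)) || any(object@freqs <= 0)) {
    return("equilibrium frequencies must be finite and positive")
  }
  if (abs(sum(object@freqs) - 1) > 1e-12) {
    return("equilibrium frequencies must sum to 1 (within 1e-12)")
  }
  if (length(object@gammaShape) != 1L ||
      (!is.na(object@gammaShape) && object@gammaShape <= 0)) {
    return("gammaShape must be a single positive value or NA")
  }
  if (length(object@pInv) != 1L || !is.finite(object@pInv) ||
      object@pInv < 0 || object@pInv >= 1) {
    return("pInv must lie in [0, 1)")
  }
  if (length(object@nGammaCat) != 1L || object@nGammaCat < 1L) {
    return("nGammaCat must be a positive integer")
  }
  if (object@nGammaCat > 1L && is.na(object@gammaShape)) {
    return("gammaShape must be given when nGammaCat > 1")
  }
  TRUE
})

setMethod("show", "SubstitutionModel", function(object) {
  K <- length(object@stateSpace)
  cat(sprintf("SubstitutionModel over %d states (%s)\n", K,
              paste(stateLabels(object@stateSpace), collapse = " ")))
  cat("  exchangeabilities:",
      paste(format(object@rates, digits = 4), collapse = " "), "\n")
  cat("  frequencies:      ",
      paste(format(object@freqs, digits = 4), collapse = " "), "\n")
  if (is.na(object@gammaShape)) {
    cat("  rate heterogeneity: none")
  } else {
    cat(sprintf("  gamma shape %.4g with %d categories",
                object@gammaShape, object@nGammaCat))
  }
  cat(sprintf(", pInv = %.4g\n", object@pInv))
})

#' PatternClass: the (steps, observed set, downpass set) bin of a pattern
#'
#' A pattern class is the set of all tip patterns on a fixed tree that share
#' a parsimony step count `s`, an observed state set `t`, and a root Fitch
#' downpass state set `d` (with `d` a nonempty subset of `t`).
#'
#' @slot steps non-negative integer parsimony step count.
#' @slot observed integer bitmask of the states seen at the tips.
#' @slot downpass integer bitmask of the root downpass state set.
#' @slot stateSpace the [StateSpace-class] the masks refer to.
#' @seealso [classifyPattern()]
#' @export
setClass("PatternClass", representation(
  steps = "integer",
  observed = "integer",
  downpass = "integer",
  stateSpace = "StateSpace"
))

setValidity("PatternClass", function(object) {
  if (object@steps < 0L) return("steps must be non-negative")
  if (object@downpass == 0L) return("downpass set cannot be empty")
  if (bitwAnd(object@downpass, object@observed) != object@downpass) {
    return("downpass set must be a subset of the observed set")
  }
  if (object@steps < maskSize(object@observed) - 1L) {
    return("steps cannot be smaller than |observed| - 1")
  }
  TRUE
})

setMethod("show", "PatternClass", function(object) {
  cat(sprintf("PatternClass: %d step(s), observed {%s}, downpass {%s}\n",
              object@steps,
              stateSetLabels(object@observed, object@stateSpace),
              stateSetLabels(object@downpass, object@stateSpace)))
})

#' ClassTable: per-node conditional pattern-class probabilities
#'
#' The dynamic-programming lookup table at one tree node: for every feasible
#' class `(s, t, d)` of the node's subtree and every ancestral state `a` at
#' the node, the probability that the subtree generates a pattern of that
#' class given the ancestor was in state `a`. For each fixed `a` the entries
#' sum to 1 (the subtree must produce some outcome).
#'
#' @slot nodeId integer node identifier.
#' @slot stateSpace the [StateSpace-class].
#' @slot probs numeric array `K x nTD x (smax+1)`: ancestral state, feasible
#'   (t, d) pair index, steps + 1.
#' @slot tdPairs integer matrix of the feasible (t, d) mask pairs indexing
#'   the second dimension.
#' @seealso [initLeafTable()], [combineNode()], [classTableEntry()]
#' @export
setClass("ClassTable", representation(
  nodeId = "integer",
  stateSpace = "StateSpace",
  probs = "array",
  tdPairs = "matrix"
))

setMethod("show", "ClassTable", function(object) {
  nz <- sum(object@probs != 0)
  cat(sprintf("ClassTable at node %d: K = %d, %d (t,d) pairs, steps 0..%d, %d nonzero entries\n",
              object@nodeId, dim(object@probs)[1], dim(object@probs)[2],
              dim(object@probs)[3] - 1L, nz))
})

#' ClassDistribution: root-level pattern-class probabilities
#'
#' The probability, for a single randomly evolving character, of each
#' pattern class `(s, t, d)` on the fixed tree, marginalised over root
#' states with the equilibrium frequencies and mixed over rate categories.
#' Probabilities sum to 1.
#'
#' @slot table data.frame with columns `steps`, `observedMask`,
#'   `downpassMask`, `observed`, `downpass` (rendered symbol strings) and
#'   `probability`, sorted by (steps, observedMask, downpassMask).
#' @slot stateSpace the [StateSpace-class].
#' @slot nTips number of tips of the tree the distribution refers to.
#' @slot note character description of how it was produced.
#' @seealso [classProbabilities()], [enumerateClassProbs()],
#'   [binDistribution()], [probConstant()]
#' @export
setClass("ClassDistribution", representation(
  table = "data.frame",
  stateSpace = "StateSpace",
  nTips = "integer",
  note = "character"
))

setValidity("ClassDistribution", function(object) {
  tab <- object@table
  need <- c("steps", "observedMask", "downpassMask", "probability")
  if (!all(need %in% names(tab))) {
    return(paste("table must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(tab) && any(tab$probability < -1e-12)) {
    return("class probabilities must be non-negative")
  }
  TRUE
})

setMethod("show", "ClassDistribution", function(object) {
  tab <- object@table
  cat(sprintf("ClassDistribution over %d classes (%d-tip tree, K = %d)\n",
              nrow(tab), object@nTips, length(object@stateSpace)))
  cat(sprintf("  total probability: %.12f\n", sum(tab$probability)))
  if (nzchar(object@note)) cat("  ", object@note, "\n", sep = "")
  print(utils::head(tab[, c("steps", "observed", "downpass", "probability")], 8L))
  if (nrow(tab) > 8L) cat("  ...", nrow(tab) - 8L, "more classes\n")
})

#' @describeIn ClassDistribution-class the class table as a data.frame.
#' @param x a `ClassDistribution`.
#' @param row.names,optional,... passed on conventions of the generic; unused.
#' @export
as.data.frame.ClassDistribution <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  x@table
}

#' Number of pattern classes with nonzero support
#' @param x a [ClassDistribution-class].
#' @export
setMethod("length", "ClassDistribution", function(x) nrow(x@table))

#' Look up the probability of one pattern class
#'
#' @param dist a [ClassDistribution-class].
#' @param steps parsimony step count.
#' @param observed observed state set: bitmask, or character label like "AC".
#' @param downpass downpass state set, same conventions.
#' @return the class probability (0 when the class has no support).
#' @export
classProbability <- function(dist, steps, observed, downpass = observed) {
  if (is.character(observed)) {
    observed <- stateSet(strsplit(observed, "")[[1]], dist@stateSpace)
  }
  if (is.character(downpass)) {
    downpass <- stateSet(strsplit(downpass, "")[[1]], dist@stateSpace)
  }
  tab <- dist@table
  hit <- tab$steps == steps & tab$observedMask == observed &
    tab$downpassMask == downpass
  if (!any(hit)) return(0)
  sum(tab$probability[hit])
}
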