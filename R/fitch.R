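## Fitch preliminary-phase ("downpass") parsimony over bitmask state sets.
## Only the downpass is implemented: it is all that is needed to define
## pattern classes, since a class is (steps, observed set, root downpass set).

#' Fitch downpass over a tree for one tip pattern
#'
#' Runs the preliminary (downpass) phase of Fitch's unordered parsimony
#' algorithm as a postorder traversal. A leaf's downpass state set is the
#' singleton of its observed state with 0 steps accrued; at an internal node
#' the downpass set is the intersection of the children's sets when that is
#' nonempty (no step added), otherwise their union (one step added). The
#' total step count at the root is the parsimony length of the pattern.
#'
#' @param tree a validated `phylo` object.
#' @param tipStates the pattern: a vector of 1-based state indices (or state
#'   labels when `space` is given) named by tip label, or unnamed in tip
#'   order; exactly one state per leaf (no missing or ambiguous data).
#' @param space optional [StateSpace-class] used to translate character
#'   state labels and to bound the state indices.
#' @return a list with elements `downpass` (integer bitmask per node),
#'   `observed` (bitmask of tip states per subtree), `steps` (accrued steps
#'   per node), `totalSteps`, `rootDownpass` and `rootObserved`.
#' @examples
#' tr <- parseNewickTree("((a:0.1,b:0.2):0.05,c:0.3);")
#' fitchDownpass(tr, c(a = 1L, b = 2L, c = 1L))$totalSteps
#' @export
fitchDownpass <- function(tree, tipStates, space = NULL) {
  ti <- treeIndex(tree)
  st <- resolveTipStates(ti, tipStates, space)
  res <- fitchDownpassIdx(ti, st)
  list(downpass = res$downpass, observed = res$observed, steps = res$steps,
       totalSteps = res$steps[ti$root],
       rootDownpass = res$downpass[ti$root],
       rootObserved = res$observed[ti$root])
}

#' Classify a tip pattern into its pattern class
#'
#' Returns the [PatternClass-class] of a pattern on the fixed tree: the
#' parsimony step count `s`, the observed state set `t` (union of tip
#' states), and the root downpass state set `d` from [fitchDownpass()].
#'
#' @inheritParams fitchDownpass
#' @return a [PatternClass-class].
#' @examples
#' tr <- parseNewickTree("(a:0.1,b:0.2);")
#' classifyPattern(tr, c(a = "A", b = "C"), dnaStateSpace())
#' @export
classifyPattern <- function(tree, tipStates, space = NULL) {
  ti <- treeIndex(tree)
  st <- resolveTipStates(ti, tipStates, space)
  if (is.null(space)) space <- mkStateSpace(max(2L, max(st)))
  res <- fitchDownpassIdx(ti, st)
  new("PatternClass",
      steps = res$steps[ti$root],
      observed = res$observed[ti$root],
      downpass = res$downpass[ti$root],
      stateSpace = space)
}

## tipStates (named/unnamed, indices or labels) -> integer vector in tip order
resolveTipStates <- function(ti, tipStates, space = NULL) {
  if (is.character(tipStates)) {
    if (is.null(space)) stop("a StateSpace is required for character states")
    v <- match(tipStates, stateLabels(space))
    if (anyNA(v)) {
      stop("unknown state label(s): ",
           paste(unique(tipStates[is.na(v)]), collapse = ", "))
    }
    names(v) <- names(tipStates)
    tipStates <- v
  }
  nm <- names(tipStates)
  tipStates <- as.integer(tipStates)
  names(tipStates) <- nm
  if (!is.null(names(tipStates)) && any(nzchar(names(tipStates)))) {
    idx <- match(ti$labels, names(tipStates))
    if (anyNA(idx)) {
      stop("no state assigned to leaf/leaves: ",
           paste(ti$labels[is.na(idx)], collapse = ", "))
    }
    tipStates <- tipStates[idx]
  }
  if (length(tipStates) != ti$nTips) {
    stop("need exactly one state per leaf")
  }
  if (anyNA(tipStates) || any(tipStates < 1L)) {
    stop("every leaf must be assigned a valid state index (>= 1)")
  }
  if (!is.null(space) && any(tipStates > length(space))) {
    stop("state index out of range for the given state space")
  }
  tipStates
}

## core single-pattern downpass on an indexed tree
fitchDownpassIdx <- function(ti, tipStates) {
  M <- ti$nNodes
  downpass <- integer(M)
  observed <- integer(M)
  steps <- integer(M)
  for (n in ti$postorder) {
    if (ti$isLeaf[n]) {
      downpass[n] <- bitwShiftL(1L, tipStates[n] - 1L)
      observed[n] <- downpass[n]
    } else {
      a <- ti$children[n, 1]; b <- ti$children[n, 2]
      inter <- bitwAnd(downpass[a], downpass[b])
      if (inter != 0L) {
        downpass[n] <- inter
        steps[n] <- steps[a] + steps[b]
      } else {
        downpass[n] <- bitwOr(downpass[a], downpass[b])
        steps[n] <- steps[a] + steps[b] + 1L
      }
      observed[n] <- bitwOr(observed[a], observed[b])
    }
  }
  list(downpass = downpass, observed = observed, steps = steps)
}

## Vectorised downpass over many patterns at once.
## patterns: nTips x nPat integer matrix of state indices (tip order).
## Returns steps, observed mask and downpass mask at the root, per pattern.
fitchAll <- function(ti, patterns) {
  nPat <- ncol(patterns)
  M <- ti$nNodes
  dp <- vector("list", M)
  st <- vector("list", M)
  rootObs <- integer(nPat)
  for (n in ti$postorder) {
    if (ti$isLeaf[n]) {
      dp[[n]] <- bitwShiftL(1L, patterns[n, ] - 1L)
      st[[n]] <- integer(nPat)
    } else {
      a <- ti$children[n, 1]; b <- ti$children[n, 2]
      inter <- bitwAnd(dp[[a]], dp[[b]])
      un <- bitwOr(dp[[a]], dp[[b]])
      hit <- inter != 0L
      dp[[n]] <- ifelse(hit, inter, un)
      st[[n]] <- st[[a]] + st[[b]] + !hit
    }
  }
  for (i in seq_len(ti$nTips)) {
    rootObs <- bitwOr(rootObs, bitwShiftL(1L, patterns[i, ] - 1L))
  }
  list(steps = st[[ti$root]], observed = rootObs,
       downpass = dp[[ti$root]])
}

## Sankoff 0/1-cost parsimony, vectorised over patterns: an independent
## check on the Fitch step counts.  cost[a, pattern] = minimal changes in
## the tree when the root is forced to state a.
sankoffSteps <- function(ti, patterns, K) {
  nPat <- ncol(patterns)
  cost <- vector("list", ti$nNodes)
  for (n in ti$postorder) {
    if (ti$isLeaf[n]) {
      m <- matrix(Inf, K, nPat)
      m[cbind(patterns[n, ], seq_len(nPat))] <- 0
      cost[[n]] <- m
    } else {
      a <- ti$children[n, 1]; b <- ti$children[n, 2]
      cost[[n]] <- sankoffChild(cost[[a]], K) + sankoffChild(cost[[b]], K)
    }
  }
  apply(cost[[ti$root]], 2, min)
}

## min_i (cost[i,] + [i != a]) for each parent state a, with 0/1 costs:
## pmin(own cost, overall min + 1)
sankoffChild <- function(costMat, K) {
  best <- apply(costMat, 2, min)
  out <- costMat
  for (a in seq_len(K)) out[a, ] <- pmin(costMat[a, ], best + 1)
  out
}
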