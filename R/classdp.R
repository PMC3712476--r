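## Pattern-class probability dynamic program.
##
## For the subtree rooted at node n, Q[a, (t,d), s] is the probability that
## the subtree generates a pattern with s parsimony steps, observed state
## set t and Fitch downpass state set d, conditional on ancestral state a at
## n.  Leaves are initialised with Q[x, ({x},{x}), 0] = 1.  At an internal
## node the table combines the children's tables through the two ways a
## downpass set can form: intersection (no extra step) and union (one extra
## step).  The child tables enter through a pruning-style contribution
## C[a] = sum_i P(i | a, edge) Q_child[i], so the combine is a convolution
## over step counts for each feasible (t,d) x (t,d) child pair.  Root-level
## class probabilities X(s,t,d) marginalise the root table over pi.

## ---- internal array DP -----------------------------------------------------

## leaf table as a dense array K x nTD x 1
leafArray <- function(td, K) {
  arr <- array(0, dim = c(K, td$nTD, 1L))
  for (x in seq_len(K)) {
    m <- bitwShiftL(1L, x - 1L)
    arr[x, td$index[m, m], 1L] <- 1
  }
  arr
}

## combine two child arrays across their edges' transition matrices
combineArrays <- function(QA, QB, PA, PB, td) {
  K <- dim(QA)[1]
  sA1 <- dim(QA)[3]; sB1 <- dim(QB)[3]
  CA <- array(PA %*% matrix(QA, nrow = K), dim = dim(QA))
  CB <- array(PB %*% matrix(QB, nrow = K), dim = dim(QB))
  Qn <- array(0, dim = c(K, td$nTD, sA1 + sB1))
  actA <- which(apply(CA, 2, function(m) any(m != 0)))
  actB <- which(apply(CB, 2, function(m) any(m != 0)))
  for (jA in actA) {
    CAj <- matrix(CA[, jA, ], nrow = K)
    nzA <- which(colSums(CAj != 0) > 0)
    for (jB in actB) {
      tgt <- td$tgt[jA, jB]
      dlt <- td$delta[jA, jB]
      CBj <- matrix(CB[, jB, ], nrow = K)
      for (sA in nzA) {
        idx <- (sA + dlt):(sA + dlt + sB1 - 1L)
        Qn[, tgt, idx] <- Qn[, tgt, idx] + CAj[, sA] * CBj
      }
    }
  }
  Qn
}

## full postorder sweep at a single rate multiplier; returns the root array
dpRootArray <- function(ti, eg, td, rate) {
  K <- eg$K
  tabs <- vector("list", ti$nNodes)
  for (n in ti$postorder) {
    if (ti$isLeaf[n]) {
      tabs[[n]] <- leafArray(td, K)
    } else {
      a <- ti$children[n, 1]; b <- ti$children[n, 2]
      PA <- transitionMatrixFromEigen(eg, rate * ti$edgeLen[a])
      PB <- transitionMatrixFromEigen(eg, rate * ti$edgeLen[b])
      tabs[[n]] <- combineArrays(tabs[[a]], tabs[[b]], PA, PB, td)
      tabs[a] <- list(NULL)
      tabs[b] <- list(NULL)
    }
  }
  tabs[[ti$root]]
}

## root array + pi -> sorted per-class data.frame
classFrameFromArray <- function(rootArr, freqs, td, space) {
  K <- length(freqs)
  nTD <- dim(rootArr)[2]; S1 <- dim(rootArr)[3]
  ## X[(t,d), s] = sum_a pi_a Q[a, (t,d), s]
  X <- matrix(colSums(freqs * matrix(rootArr, nrow = K)), nrow = nTD)
  nz <- which(X != 0, arr.ind = TRUE)
  if (!nrow(nz)) {
    return(data.frame(steps = integer(0), observedMask = integer(0),
                      downpassMask = integer(0), observed = character(0),
                      downpass = character(0), probability = numeric(0)))
  }
  out <- data.frame(
    steps = nz[, 2] - 1L,
    observedMask = td$pairs[nz[, 1], "t"],
    downpassMask = td$pairs[nz[, 1], "d"],
    probability = X[nz]
  )
  out <- out[order(out$steps, out$observedMask, out$downpassMask), ]
  out$observed <- stateSetLabels(out$observedMask, space)
  out$downpass <- stateSetLabels(out$downpassMask, space)
  rownames(out) <- NULL
  out[, c("steps", "observedMask", "downpassMask",
          "observed", "downpass", "probability")]
}

## ---- exported operations ---------------------------------------------------

#' Initialise the class lookup table of a leaf
#'
#' For a leaf there is no opportunity for evolution within the node, so for
#' each possible state `x` the table puts probability 1 on the class
#' `(0, {x}, {x})` conditional on ancestral state `x`, and 0 elsewhere.
#'
#' @param tree a validated `phylo` object.
#' @param nodeId a leaf node id (`1..N`, ape numbering).
#' @param space a [StateSpace-class].
#' @return a [ClassTable-class].
#' @export
initLeafTable <- function(tree, nodeId, space = dnaStateSpace()) {
  ti <- treeIndex(tree)
  nodeId <- as.integer(nodeId)
  if (nodeId < 1L || nodeId > ti$nNodes) stop("no such node: ", nodeId)
  if (!ti$isLeaf[nodeId]) {
    stop("node ", nodeId, " is internal; leaf tables exist only for leaves")
  }
  K <- length(space)
  td <- tdPairsFor(K)
  new("ClassTable", nodeId = nodeId, stateSpace = space,
      probs = leafArray(td, K), tdPairs = td$pairs)
}

#' Read one entry of a class table
#'
#' @param table a [ClassTable-class].
#' @param steps parsimony steps `s` in the subtree.
#' @param observed observed state set `t` (bitmask).
#' @param downpass downpass state set `d` (bitmask).
#' @param a ancestral state index at the node (1-based); when missing, the
#'   full length-K vector over ancestral states is returned.
#' @return probability (or vector over `a`); 0 for infeasible classes.
#' @export
classTableEntry <- function(table, steps, observed, downpass, a = NULL) {
  td <- tdPairsFor(length(table@stateSpace))
  s1 <- steps + 1L
  if (s1 < 1L || s1 > dim(table@probs)[3]) {
    return(if (is.null(a)) numeric(dim(table@probs)[1]) else 0)
  }
  if (observed < 1L || downpass < 1L ||
      bitwAnd(downpass, observed) != downpass) {
    return(if (is.null(a)) numeric(dim(table@probs)[1]) else 0)
  }
  j <- td$index[observed, downpass]
  if (is.na(j)) return(if (is.null(a)) numeric(dim(table@probs)[1]) else 0)
  v <- table@probs[, j, s1]
  if (is.null(a)) v else v[a]
}

#' Pruning-style contribution of a child subtree
#'
#' The probability that the child subtree displays the class
#' `(steps, observed, downpass)` given that the parent node is in state `a`:
#' \eqn{C = \sum_i P(i \mid a, e) \, Q_{s,t,d,i}(\mathrm{child})}, the
#' class-level analogue of one step of Felsenstein's pruning algorithm.
#'
#' @param childTable the child's [ClassTable-class].
#' @param steps,observed,downpass the child class (masks as integers).
#' @param a parent state index (1-based); when `NULL` the vector over all
#'   parent states is returned.
#' @param P the child's edge transition matrix at the current rate category.
#' @return probability (or length-K vector over `a`).
#' @export
childContribution <- function(childTable, steps, observed, downpass, a = NULL,
                              P) {
  q <- classTableEntry(childTable, steps, observed, downpass)
  v <- as.numeric(P %*% q)
  if (is.null(a)) v else v[a]
}

## shared machinery of the I and U terms: sum child-class pairs filtered by
## the formation rule.  type = 0 -> intersection, 1 -> union.
iuTerm <- function(type, steps, observed, downpass, tableA, tableB, PA, PB) {
  K <- nrow(PA)
  td <- tdPairsFor(K)
  sA1 <- dim(tableA@probs)[3]; sB1 <- dim(tableB@probs)[3]
  CA <- array(PA %*% matrix(tableA@probs, nrow = K), dim = dim(tableA@probs))
  CB <- array(PB %*% matrix(tableB@probs, nrow = K), dim = dim(tableB@probs))
  out <- numeric(K)
  for (jA in seq_len(td$nTD)) {
    for (jB in seq_len(td$nTD)) {
      tA <- td$pairs[jA, "t"]; dA <- td$pairs[jA, "d"]
      tB <- td$pairs[jB, "t"]; dB <- td$pairs[jB, "d"]
      if (bitwOr(tA, tB) != observed) next
      inter <- bitwAnd(dA, dB)
      if (type == 0L) {
        if (inter != downpass || inter == 0L) next
        sSum <- steps
      } else {
        if (inter != 0L || bitwOr(dA, dB) != downpass) next
        sSum <- steps - 1L
      }
      if (sSum < 0L) next
      for (sA in 0:min(sSum, sA1 - 1L)) {
        sB <- sSum - sA
        if (sB > sB1 - 1L) next
        out <- out + CA[, jA, sA + 1L] * CB[, jB, sB + 1L]
      }
    }
  }
  out
}

#' Intersection term of the class DP
#'
#' Probability mass of the class `(steps, observed, downpass)` at a node,
#' conditional on each ancestral state, restricted to the outcomes in which
#' the node's downpass set formed as a *nonempty intersection* of the
#' children's downpass sets. Both children's downpass sets must then be
#' supersets of `downpass`, no step is added, and the children's step counts
#' sum to `steps`; the children's observed sets must jointly cover
#' `observed`, and the states each child's downpass carries beyond
#' `downpass` must be disjoint between the children (otherwise the
#' intersection would be larger than `downpass`).
#'
#' @param steps,observed,downpass the target class at the parent node
#'   (masks as integers).
#' @param tableA,tableB the children's [ClassTable-class] tables.
#' @param PA,PB the children's edge transition matrices.
#' @return length-K numeric vector over the parent's ancestral state.
#' @seealso [unionTerm()], [combineNode()]
#' @export
intersectionTerm <- function(steps, observed, downpass, tableA, tableB,
                             PA, PB) {
  iuTerm(0L, steps, observed, downpass, tableA, tableB, PA, PB)
}

#' Union term of the class DP
#'
#' Probability mass of the class `(steps, observed, downpass)` at a node,
#' conditional on each ancestral state, restricted to the outcomes in which
#' the node's downpass set formed as a *union* of disjoint nonempty child
#' downpass sets (the Fitch case adding one step): the child downpass sets
#' partition `downpass` into two nonempty parts, the children's steps sum to
#' `steps - 1`, and the children's observed sets jointly cover `observed`.
#' Zero whenever `|downpass| < 2`, since two disjoint nonempty sets cannot
#' union to a singleton.
#'
#' @inheritParams intersectionTerm
#' @return length-K numeric vector over the parent's ancestral state.
#' @export
unionTerm <- function(steps, observed, downpass, tableA, tableB, PA, PB) {
  iuTerm(1L, steps, observed, downpass, tableA, tableB, PA, PB)
}

#' Combine two child class tables into the parent's table
#'
#' Fills the parent's Q table over all feasible `(s, t, d, a)` as the sum of
#' the intersection and union terms, implemented as a step-count convolution
#' over all feasible child (t, d) pairs. For each ancestral state `a` the
#' resulting entries sum to 1.
#'
#' @param tableA,tableB the children's [ClassTable-class] tables.
#' @param PA,PB the children's edge transition matrices at the current rate.
#' @param nodeId id to record on the resulting table.
#' @return the parent's [ClassTable-class].
#' @export
combineNode <- function(tableA, tableB, PA, PB, nodeId = NA_integer_) {
  space <- tableA@stateSpace
  td <- tdPairsFor(length(space))
  new("ClassTable", nodeId = as.integer(nodeId), stateSpace = space,
      probs = combineArrays(tableA@probs, tableB@probs, PA, PB, td),
      tdPairs = td$pairs)
}

#' Marginalise a root class table over root states
#'
#' Converts the root's conditional table into unconditional class
#' probabilities \eqn{X(s,t,d) = \sum_a \pi_a Q_{s,t,d,a}(\rho)}.
#'
#' @param rootTable the root [ClassTable-class].
#' @param freqs equilibrium frequencies (summing to 1), or a
#'   [SubstitutionModel-class] whose frequencies are used.
#' @param nTips number of tips (recorded on the result; inferred from the
#'   table's step range when missing).
#' @return a [ClassDistribution-class].
#' @export
rootClassProbabilities <- function(rootTable, freqs, nTips = NA_integer_) {
  if (is(freqs, "SubstitutionModel")) freqs <- freqs@freqs
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("equilibrium frequencies must sum to 1")
  }
  space <- rootTable@stateSpace
  td <- tdPairsFor(length(space))
  if (is.na(nTips)) nTips <- dim(rootTable@probs)[3]
  tab <- classFrameFromArray(rootTable@probs, freqs, td, space)
  new("ClassDistribution", table = tab, stateSpace = space,
      nTips = as.integer(nTips), note = "single-category root table")
}

#' Pattern-class probabilities on a tree under a substitution model
#'
#' The main entry point: runs the class dynamic program over the tree once
#' per rate category of the model's mixture (see [rateMixture()]), computing
#' for every pattern class `(s, t, d)` — parsimony steps, observed state
#' set, root Fitch downpass set — the probability that a single randomly
#' evolving character falls in that class. Category distributions are mixed
#' by their weights after classification; the rate-0 invariant category
#' contributes mass only to constant classes.
#'
#' @param tree a validated rooted binary `phylo` with branch lengths.
#' @param model a [SubstitutionModel-class].
#' @return a [ClassDistribution-class]; probabilities sum to 1.
#' @examples
#' tr <- parseNewickTree("((a:0.1,b:0.2):0.05,c:0.3);")
#' classProbabilities(tr, jcModel())
#' @export
classProbabilities <- function(tree, model) {
  ti <- treeIndex(tree)
  space <- model@stateSpace
  K <- length(space)
  td <- tdPairsFor(K)
  eg <- modelEigen(model)
  mix <- rateMixture(model)
  acc <- NULL
  for (r in seq_len(nrow(mix))) {
    rootArr <- dpRootArray(ti, eg, td, mix$rate[r])
    acc <- if (is.null(acc)) mix$weight[r] * rootArr else {
      acc + mix$weight[r] * rootArr
    }
  }
  tab <- classFrameFromArray(acc, model@freqs, td, space)
  new("ClassDistribution", table = tab, stateSpace = space,
      nTips = ti$nTips,
      note = sprintf("class DP over %d rate categories", nrow(mix)))
}

## per-node Q tables at a single rate (used by normalization checks/tests)
nodeTablesAtRate <- function(tree, model, rate) {
  ti <- treeIndex(tree)
  td <- tdPairsFor(length(model@stateSpace))
  eg <- modelEigen(model)
  tabs <- vector("list", ti$nNodes)
  for (n in ti$postorder) {
    if (ti$isLeaf[n]) {
      tabs[[n]] <- leafArray(td, eg$K)
    } else {
      a <- ti$children[n, 1]; b <- ti$children[n, 2]
      PA <- transitionMatrixFromEigen(eg, rate * ti$edgeLen[a])
      PB <- transitionMatrixFromEigen(eg, rate * ti$edgeLen[b])
      tabs[[n]] <- combineArrays(tabs[[a]], tabs[[b]], PA, PB, td)
    }
  }
  tabs
}
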