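## Independent brute-force and Monte-Carlo machinery: per-pattern pruning
## likelihoods, exhaustive class enumeration, character simulation, seeded
## random fixtures.  None of this shares code with the class DP; it exists
## to validate it.

#' Likelihood of a single tip pattern (Felsenstein pruning)
#'
#' Computes the probability of one tip pattern at a fixed rate multiplier by
#' the pruning algorithm: postorder partial likelihoods conditioned on each
#' ancestral state, marginalised at the root with the equilibrium
#' frequencies. With `rate = NULL` the likelihood is mixed over the model's
#' full rate mixture.
#'
#' @param tree a validated `phylo` object.
#' @param model a [SubstitutionModel-class].
#' @param pattern tip states as in [fitchDownpass()].
#' @param rate a single rate multiplier, or `NULL` to mix over
#'   [rateMixture()].
#' @return the pattern probability.
#' @examples
#' tr <- parseNewickTree("(a:0.1,b:0.2);")
#' pruningSiteProbability(tr, jcModel(), c(a = "A", b = "C"))
#' @export
pruningSiteProbability <- function(tree, model, pattern, rate = 1) {
  ti <- treeIndex(tree)
  st <- resolveTipStates(ti, pattern, model@stateSpace)
  eg <- modelEigen(model)
  if (is.null(rate)) {
    mix <- rateMixture(model)
    return(sum(mix$weight * vapply(mix$rate, function(r) {
      pruneOne(ti, eg, model@freqs, st, r)
    }, numeric(1))))
  }
  pruneOne(ti, eg, model@freqs, st, rate)
}

pruneOne <- function(ti, eg, freqs, st, rate) {
  K <- eg$K
  L <- vector("list", ti$nNodes)
  for (n in ti$postorder) {
    if (ti$isLeaf[n]) {
      v <- numeric(K)
      v[st[n]] <- 1
      L[[n]] <- v
    } else {
      a <- ti$children[n, 1]; b <- ti$children[n, 2]
      PA <- transitionMatrixFromEigen(eg, rate * ti$edgeLen[a])
      PB <- transitionMatrixFromEigen(eg, rate * ti$edgeLen[b])
      L[[n]] <- as.numeric(PA %*% L[[a]]) * as.numeric(PB %*% L[[b]])
    }
  }
  sum(freqs * L[[ti$root]])
}

## Vectorised pruning over all patterns in `patterns` (nTips x nPat) at one
## rate.  Returns the likelihood of every pattern.
pruneAll <- function(ti, eg, freqs, patterns, rate) {
  K <- eg$K
  nPat <- ncol(patterns)
  L <- vector("list", ti$nNodes)
  for (n in ti$postorder) {
    if (ti$isLeaf[n]) {
      m <- matrix(0, K, nPat)
      m[cbind(patterns[n, ], seq_len(nPat))] <- 1
      L[[n]] <- m
    } else {
      a <- ti$children[n, 1]; b <- ti$children[n, 2]
      PA <- transitionMatrixFromEigen(eg, rate * ti$edgeLen[a])
      PB <- transitionMatrixFromEigen(eg, rate * ti$edgeLen[b])
      L[[n]] <- (PA %*% L[[a]]) * (PB %*% L[[b]])
    }
  }
  colSums(freqs * L[[ti$root]])
}

## all K^N patterns as an nTips x K^N matrix of 1-based state indices
allPatterns <- function(nTips, K) {
  nPat <- K^nTips
  m <- matrix(0L, nrow = nTips, ncol = nPat)
  j <- seq_len(nPat) - 1L
  for (i in seq_len(nTips)) {
    m[i, ] <- (j %/% K^(i - 1L)) %% K + 1L
  }
  m
}

#' Exhaustive pattern-class distribution by enumeration
#'
#' The independent oracle for [classProbabilities()]: iterates every one of
#' the `K^N` tip patterns, computes its probability by pruning (mixed over
#' the rate mixture) and its class by the Fitch downpass, and accumulates
#' probability per class. Exact up to floating point; total mass is 1.
#'
#' @param tree a validated `phylo` object.
#' @param model a [SubstitutionModel-class].
#' @param cap maximum number of pattern-times-rate-category evaluations
#'   (default 1e7); larger instances are refused with a pointer to
#'   [simulateCharacters()].
#' @return a [ClassDistribution-class].
#' @export
enumerateClassProbs <- function(tree, model, cap = 1e7) {
  ti <- treeIndex(tree)
  K <- length(model@stateSpace)
  mix <- rateMixture(model)
  if (K^ti$nTips * nrow(mix) > cap) {
    stop(sprintf(
      "enumeration over K^N = %d^%d patterns exceeds the cap (%g); use simulateCharacters() instead",
      K, ti$nTips, cap))
  }
  eg <- modelEigen(model)
  patterns <- allPatterns(ti$nTips, K)
  probs <- numeric(ncol(patterns))
  for (r in seq_len(nrow(mix))) {
    probs <- probs + mix$weight[r] * pruneAll(ti, eg, model@freqs,
                                              patterns, mix$rate[r])
  }
  cls <- fitchAll(ti, patterns)
  key <- paste(cls$steps, cls$observed, cls$downpass)
  agg <- rowsum(probs, key)
  parts <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  tab <- data.frame(
    steps = as.integer(parts[, 1]),
    observedMask = as.integer(parts[, 2]),
    downpassMask = as.integer(parts[, 3]),
    probability = as.numeric(agg)
  )
  tab <- tab[order(tab$steps, tab$observedMask, tab$downpassMask), ]
  tab$observed <- stateSetLabels(tab$observedMask, model@stateSpace)
  tab$downpass <- stateSetLabels(tab$downpassMask, model@stateSpace)
  rownames(tab) <- NULL
  new("ClassDistribution",
      table = tab[, c("steps", "observedMask", "downpassMask",
                      "observed", "downpass", "probability")],
      stateSpace = model@stateSpace, nTips = ti$nTips,
      note = sprintf("exhaustive enumeration of %d^%d patterns", K, ti$nTips))
}

#' Simulate characters along the tree
#'
#' Draws `nSites` independent characters: for each site a rate category is
#' drawn by mixture weight, a root state from the equilibrium frequencies,
#' and states evolve down every edge by sampling from the corresponding
#' transition-matrix row. Fully reproducible given `seed` (R's default
#' Mersenne-Twister stream; the caller's RNG state is preserved).
#'
#' @param tree a validated `phylo` object.
#' @param model a [SubstitutionModel-class].
#' @param nSites number of characters to simulate.
#' @param seed integer seed.
#' @return integer matrix `nTips x nSites` of 1-based state indices, with
#'   tip labels as row names; one column per simulated character.
#' @export
simulateCharacters <- function(tree, model, nSites, seed) {
  stopifnot(nSites >= 1)
  ti <- treeIndex(tree)
  K <- length(model@stateSpace)
  eg <- modelEigen(model)
  mix <- rateMixture(model)
  withSeed(seed, {
    cat <- sample.int(nrow(mix), nSites, replace = TRUE, prob = mix$weight)
    states <- matrix(0L, nrow = ti$nNodes, ncol = nSites)
    states[ti$root, ] <- sample.int(K, nSites, replace = TRUE,
                                    prob = model@freqs)
    ## preorder = reverse postorder: parents before children
    for (n in rev(ti$postorder)) {
      if (n == ti$root) next
      Ps <- lapply(seq_len(nrow(mix)), function(r) {
        transitionMatrixFromEigen(eg, mix$rate[r] * ti$edgeLen[n])
      })
      parent <- parentOf(ti, n)
      pState <- states[parent, ]
      for (r in seq_len(nrow(mix))) {
        for (a in seq_len(K)) {
          idx <- which(cat == r & pState == a)
          if (length(idx)) {
            states[n, idx] <- sample.int(K, length(idx), replace = TRUE,
                                         prob = Ps[[r]][a, ])
          }
        }
      }
    }
    out <- states[seq_len(ti$nTips), , drop = FALSE]
    rownames(out) <- ti$labels
    out
  })
}

parentOf <- function(ti, n) {
  hit <- which(ti$children == n, arr.ind = TRUE)
  hit[1, 1]
}

## evaluate `expr` under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a seeded random (tree, model) fixture
#'
#' Draws a random rooted binary tree with exponential branch lengths and a
#' random valid reversible model, fully determined by `seed`. Intended for
#' property-style validation of the class DP against the enumeration oracle.
#'
#' @param nLeaves number of tips.
#' @param K number of states (4 = DNA GTR; other values use a symmetric-ish
#'   random model over a generic alphabet).
#' @param seed integer seed.
#' @param blMean mean of the exponential branch-length distribution
#'   (default 0.1 expected substitutions per site).
#' @param gamma draw a gamma shape and use 4 rate categories (default TRUE).
#' @param pInv proportion of invariant sites for the fixture model.
#' @return list with elements `tree` (phylo) and `model`
#'   ([SubstitutionModel-class]).
#' @export
generateFixture <- function(nLeaves, K = 4L, seed, blMean = 0.1,
                            gamma = TRUE, pInv = 0) {
  withSeed(seed, {
    tree <- ape::rtree(nLeaves, rooted = TRUE,
                       br = function(n) stats::rexp(n, rate = 1 / blMean))
    tree$tip.label <- paste0("t", seq_len(nLeaves))
    npair <- K * (K - 1L) / 2L
    rates <- stats::runif(npair, 0.5, 2)
    freqs <- stats::rgamma(K, shape = 5)
    freqs <- freqs / sum(freqs)
    shape <- if (gamma) stats::runif(1, 0.3, 2) else NA_real_
    model <- substitutionModel(
      rates = rates, freqs = freqs, gammaShape = shape, pInv = pInv,
      nGammaCat = if (gamma) 4L else 1L,
      stateSpace = if (K == 4L) dnaStateSpace() else mkStateSpace(K))
    list(tree = tree, model = model)
  })
}

#' Export a simulated character matrix as FASTA
#'
#' Writes one sequence per leaf, mapping state indices to the state-space
#' symbols (a plain uncompressed FASTA file).
#'
#' @param states integer matrix as returned by [simulateCharacters()].
#' @param space the [StateSpace-class] providing symbols.
#' @param file output path.
#' @return the path, invisibly.
#' @export
exportFasta <- function(states, space, file) {
  labs <- stateLabels(space)
  seqs <- lapply(seq_len(nrow(states)), function(i) labs[states[i, ]])
  seqinr::write.fasta(seqs, names = rownames(states), file.out = file)
  invisible(file)
}
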