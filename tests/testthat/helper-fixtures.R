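## Shared test fixtures and comparison helpers.

cherryTree <- function(e1 = 0.1, e2 = 0.2) {
  parseNewickTree(sprintf("(a:%g,b:%g);", e1, e2))
}

threeLeafTree <- function() {
  parseNewickTree("((a:0.1,b:0.2):0.05,c:0.3);")
}

balancedFourTree <- function() {
  parseNewickTree("((a:0.1,b:0.15):0.05,(c:0.2,d:0.1):0.07);")
}

## an arbitrary fixed valid GTR model used across tests
gtrTestModel <- function(gammaShape = NA_real_, pInv = 0, nGammaCat = 4L) {
  substitutionModel(rates = c(1.2, 3.1, 0.8, 1.1, 3.5, 1.0),
                    freqs = c(0.31, 0.18, 0.22, 0.29),
                    gammaShape = gammaShape, pInv = pInv,
                    nGammaCat = nGammaCat)
}

## max absolute per-class difference between two ClassDistributions,
## treating classes absent from one side as probability 0
maxClassDiff <- function(d1, d2) {
  a <- as.data.frame(d1)
  b <- as.data.frame(d2)
  mg <- merge(a, b, by = c("steps", "observedMask", "downpassMask"),
              all = TRUE)
  px <- mg$probability.x
  py <- mg$probability.y
  px[is.na(px)] <- 0
  py[is.na(py)] <- 0
  max(abs(px - py))
}

## brute-force transition probability by truncated series exp(Qt), used as
## an oracle independent of the eigendecomposition route
seriesTransitionMatrix <- function(model, t, terms = 60L) {
  eg <- PatternClassProb:::modelEigen(model)
  Q <- eg$Q
  K <- nrow(Q)
  P <- diag(K)
  term <- diag(K)
  for (k in seq_len(terms)) {
    term <- term %*% (Q * t) / k
    P <- P + term
  }
  P
}

## mean-of-bin gamma category rates by numerical quadrature (oracle for the
## closed-form incomplete-moment discretization)
quadratureGammaRates <- function(alpha, ncat) {
  b <- qgamma(seq(0, 1, length.out = ncat + 1L), shape = alpha, rate = alpha)
  vapply(seq_len(ncat), function(k) {
    integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
              lower = b[k], upper = b[k + 1L],
              rel.tol = 1e-12)$value * ncat
  }, numeric(1))
}

## swap the children of one internal node of a phylo tree (branch rotation)
rotateNode <- function(tree, node) {
  rows <- which(tree$edge[, 1] == node)
  stopifnot(length(rows) == 2L)
  tree$edge[rows, ] <- tree$edge[rev(rows), ]
  tree$edge.length[rows] <- tree$edge.length[rev(rows)]
  tree
}
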