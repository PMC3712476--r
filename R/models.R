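#' Construct a reversible substitution model
#'
#' Builds a [SubstitutionModel-class] from GTR exchangeabilities, equilibrium
#' frequencies, and the among-site rate mixture parameters. The instantaneous
#' rate matrix is normalised so that the expected substitution rate at
#' equilibrium is 1 (\eqn{-\sum_a \pi_a q_{aa} = 1}); branch lengths are then
#' expected substitutions per site at relative rate 1 and rate-category
#' multipliers scale them.
#'
#' @param rates K(K-1)/2 exchangeabilities, upper-triangle order
#'   (DNA: AC, AG, AT, CG, CT, GT).
#' @param freqs K equilibrium frequencies summing to 1.
#' @param gammaShape gamma shape parameter alpha, or `NA` for no
#'   gamma rate heterogeneity.
#' @param pInv proportion of invariant sites, in `[0, 1)`.
#' @param nGammaCat number of discrete gamma categories (default 4).
#' @param stateSpace a [StateSpace-class]; default DNA.
#' @return a validated [SubstitutionModel-class].
#' @examples
#' m <- substitutionModel(rates = c(1, 2, 1, 1, 2, 1),
#'                        freqs = c(0.3, 0.2, 0.2, 0.3),
#'                        gammaShape = 0.5, pInv = 0.1)
#' @export
substitutionModel <- function(rates, freqs, gammaShape = NA_real_, pInv = 0,
                              nGammaCat = 4L, stateSpace = dnaStateSpace()) {
  if (any(!is.finite(c(rates, freqs, pInv))) ||
      (!is.na(gammaShape) && !is.finite(gammaShape))) {
    stop("model parameters must be finite")
  }
  if (is.na(gammaShape)) nGammaCat <- 1L
  new("SubstitutionModel", stateSpace = stateSpace,
      rates = as.numeric(rates), freqs = as.numeric(freqs),
      gammaShape = as.numeric(gammaShape), pInv = as.numeric(pInv),
      nGammaCat = as.integer(nGammaCat))
}

#' Jukes-Cantor model (equal rates and frequencies, K states)
#'
#' @param K number of states (default 4).
#' @inheritParams substitutionModel
#' @return a [SubstitutionModel-class].
#' @export
jcModel <- function(K = 4L, gammaShape = NA_real_, pInv = 0, nGammaCat = 4L) {
  space <- if (K == 4L) dnaStateSpace() else mkStateSpace(K)
  substitutionModel(rates = rep(1, K * (K - 1) / 2),
                    freqs = rep(1 / K, K),
                    gammaShape = gammaShape, pInv = pInv,
                    nGammaCat = nGammaCat, stateSpace = space)
}

#' Symmetric Mk model over K states
#'
#' Equal exchangeabilities and equal frequencies, as used for morphological
#' characters; identical to [jcModel()] but with a generic alphabet.
#'
#' @inheritParams jcModel
#' @export
mkModel <- function(K, gammaShape = NA_real_, pInv = 0, nGammaCat = 4L) {
  substitutionModel(rates = rep(1, K * (K - 1) / 2),
                    freqs = rep(1 / K, K),
                    gammaShape = gammaShape, pInv = pInv,
                    nGammaCat = nGammaCat, stateSpace = mkStateSpace(K))
}

## Scaled rate matrix and its spectral decomposition.  Reversibility makes
## diag(sqrt(pi)) Q diag(1/sqrt(pi)) symmetric, so the eigendecomposition is
## stable and P(t) = U exp(Lambda t) U^-1 with real eigenvalues.
modelEigen <- function(model) {
  K <- length(model@stateSpace)
  pi <- model@freqs
  ## fill the symmetric exchangeability matrix row-major:
  ## (1,2),(1,3),...,(2,3),... = AC,AG,AT,CG,CT,GT for DNA
  R <- matrix(0, K, K)
  k <- 0L
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      k <- k + 1L
      R[i, j] <- model@rates[k]
      R[j, i] <- model@rates[k]
    }
  }
  Q <- R %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       U = diag(1 / sp) %*% e$vectors,
       Uinv = t(e$vectors) %*% diag(sp),
       Q = Q, K = K)
}

#' Transition probability matrix for one edge
#'
#' Computes \eqn{P(i \mid a, r \cdot \ell)}, the probability that state `a`
#' at the parent evolves to state `i` at the child across an edge of length
#' `edgeLength` at rate multiplier `rate`, by spectral decomposition of the
#' normalised rate matrix. Rows index the ancestral state and sum to 1.
#'
#' @param model a [SubstitutionModel-class].
#' @param edgeLength non-negative branch length (expected substitutions per
#'   site at rate 1).
#' @param rate non-negative rate multiplier (default 1).
#' @return a K x K row-stochastic matrix; exactly the identity when
#'   `rate * edgeLength == 0`.
#' @examples
#' transitionMatrix(jcModel(), 0.1)
#' @export
transitionMatrix <- function(model, edgeLength, rate = 1) {
  if (!is.finite(edgeLength) || edgeLength < 0) {
    stop("edgeLength must be finite and non-negative")
  }
  if (!is.finite(rate) || rate < 0) stop("rate must be finite and non-negative")
  eg <- modelEigen(model)
  transitionMatrixFromEigen(eg, edgeLength * rate)
}

transitionMatrixFromEigen <- function(eg, t) {
  if (t == 0) return(diag(eg$K))
  P <- eg$U %*% (exp(eg$values * t) * eg$Uinv)
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

## Mean rate within each of `ncat` equal-probability bins of a mean-1 gamma
## distribution (shape = rate = alpha), via the incomplete-moment identity
## E[X; X <= b] = P(Gamma(alpha+1, alpha) <= b) for a mean-1 gamma.
discreteGammaRates <- function(alpha, ncat) {
  if (ncat == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1L),
                     shape = alpha, rate = alpha)
  p <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  r <- (p[-1L] - p[-(ncat + 1L)]) * ncat
  r / mean(r)
}

#' Discrete rate mixture of a model
#'
#' Expands the gamma + invariant-sites parameters into discrete rate
#' categories: `nGammaCat` equal-probability gamma bins, each represented by
#' its within-bin mean rate and carrying weight `(1 - pInv) / nGammaCat`,
#' plus one rate-0 category of weight `pInv` when `pInv > 0`. Gamma rates
#' are rescaled by `1 / (1 - pInv)` so the mixture's mean rate is exactly 1.
#'
#' @param model a [SubstitutionModel-class].
#' @return data.frame with columns `rate` and `weight`; weights sum to 1.
#' @examples
#' rateMixture(jcModel(gammaShape = 0.5, pInv = 0.2))
#' @export
rateMixture <- function(model) {
  pInv <- model@pInv
  ncat <- model@nGammaCat
  if (ncat > 1L && (is.na(model@gammaShape) || model@gammaShape <= 0)) {
    stop("gammaShape must be positive when nGammaCat > 1")
  }
  gRates <- if (ncat == 1L) 1 else discreteGammaRates(model@gammaShape, ncat)
  out <- data.frame(rate = gRates / (1 - pInv),
                    weight = rep((1 - pInv) / ncat, ncat))
  if (pInv > 0) {
    out <- rbind(data.frame(rate = 0, weight = pInv), out)
  }
  out
}
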