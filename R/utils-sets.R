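## Bitmask state-set helpers. A state set over a K-state alphabet is an
## integer in [0, 2^K) with bit i-1 set iff state i is in the set.

#' Build a state-set bitmask from state labels
#'
#' State sets (the observed set of a subtree, a Fitch downpass set) are
#' represented as integer bitmasks over the ordered state alphabet.
#'
#' @param labels character vector of state symbols, e.g. `c("A", "C")`.
#' @param space a [StateSpace-class] giving the ordered alphabet.
#' @return integer bitmask.
#' @examples
#' stateSet(c("A", "G"), dnaStateSpace())
#' @export
stateSet <- function(labels, space = dnaStateSpace()) {
  idx <- match(labels, stateLabels(space))
  if (anyNA(idx)) {
    stop("unknown state label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  maskFromStates(idx)
}

#' Render a state-set bitmask as concatenated sorted symbols
#'
#' @param mask integer bitmask (or vector of them).
#' @param space a [StateSpace-class].
#' @return character vector, e.g. `"ACG"`.
#' @export
stateSetLabels <- function(mask, space = dnaStateSpace()) {
  labs <- stateLabels(space)
  vapply(mask, function(m) {
    paste(labs[statesInMask(m)], collapse = "")
  }, character(1))
}

## states (1-based indices) -> mask
maskFromStates <- function(states) {
  as.integer(sum(bitwShiftL(1L, as.integer(states) - 1L)))
}

## mask -> sorted 1-based state indices
statesInMask <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L)
}

maskSize <- function(mask) {
  vapply(mask, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:30)) != 0L),
         integer(1))
}

## all nonempty submasks of `mask`, ascending
submasksOf <- function(mask) {
  bits <- statesInMask(mask)
  k <- length(bits)
  if (k == 0L) return(integer(0))
  out <- integer(2^k - 1L)
  for (i in seq_len(2^k - 1L)) {
    sel <- bits[bitwAnd(i, bitwShiftL(1L, 0:(k - 1L))) != 0L]
    out[i] <- maskFromStates(sel)
  }
  sort(out)
}

## Feasible (t, d) pairs for a K-state alphabet: all masks with
## {} != d <= t <= S.  3^K - 2^K pairs (65 for K = 4).  Cached per K together
## with the pairwise combination table used by the DP: for child pairs
## (tA,dA) x (tB,dB), the parent class has t = tA|tB and, following the Fitch
## downpass, d = dA&dB with no extra step when the intersection is nonempty,
## else d = dA|dB with one extra step.
.tdCache <- new.env(parent = emptyenv())

tdPairsFor <- function(K) {
  key <- as.character(K)
  if (!is.null(.tdCache[[key]])) return(.tdCache[[key]])
  full <- bitwShiftL(1L, K) - 1L
  tmasks <- seq_len(full)
  pairs <- do.call(rbind, lapply(tmasks, function(t) {
    cbind(t = t, d = submasksOf(t))
  }))
  nTD <- nrow(pairs)
  index <- matrix(NA_integer_, nrow = full, ncol = full) # [t, d]
  index[cbind(pairs[, "t"], pairs[, "d"])] <- seq_len(nTD)
  tgt <- matrix(NA_integer_, nTD, nTD)
  delta <- matrix(NA_integer_, nTD, nTD)
  for (jA in seq_len(nTD)) {
    for (jB in seq_len(nTD)) {
      t <- bitwOr(pairs[jA, "t"], pairs[jB, "t"])
      inter <- bitwAnd(pairs[jA, "d"], pairs[jB, "d"])
      if (inter != 0L) {
        d <- inter
        delta[jA, jB] <- 0L
      } else {
        d <- bitwOr(pairs[jA, "d"], pairs[jB, "d"])
        delta[jA, jB] <- 1L
      }
      tgt[jA, jB] <- index[t, d]
    }
  }
  res <- list(pairs = pairs, index = index, tgt = tgt, delta = delta,
              nTD = nTD, K = as.integer(K))
  .tdCache[[key]] <- res
  res
}
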