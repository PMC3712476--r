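## Downstream uses of the class distribution: marginal model-adequacy
## binning with a chi-squared check, and ascertainment-bias quantities.

#' Bin a class distribution for marginal model-adequacy testing
#'
#' Aggregates the raw `(s, t, d)` class probabilities into coarser bins:
#' `"raw"` keeps every class; `"steps_observed"` sums over all downpass
#' state sets, leaving `(s, t)` bins (the grouping used by marginal
#' adequacy tests); `"steps_nstates"` further collapses the observed set to
#' its size, leaving `(s, |t|)` bins. Optional per-group step pools merge
#' runs of step counts (e.g. "7-20" within the two-state group) so every
#' bin keeps a usable expected count.
#'
#' @param dist a [ClassDistribution-class].
#' @param grouping one of `"raw"`, `"steps_observed"`, `"steps_nstates"`.
#' @param stepPools optional named list: names are group labels (the
#'   rendered observed set for `"steps_observed"`, the state count as a
#'   character for `"steps_nstates"`), each element a list of `c(lo, hi)`
#'   step ranges to pool within that group. Ranges within a group must be
#'   disjoint.
#' @param nSites optional number of sites; adds an `expected` count column
#'   (`probability * nSites`).
#' @return data.frame with columns `label`, `probability` and optionally
#'   `expected`; probabilities sum to the input's total mass.
#' @examples
#' tr <- parseNewickTree("(a:0.1,b:0.2);")
#' binDistribution(classProbabilities(tr, jcModel()), "steps_nstates")
#' @export
binDistribution <- function(dist,
                            grouping = c("raw", "steps_observed",
                                         "steps_nstates"),
                            stepPools = NULL, nSites = NULL) {
  grouping <- match.arg(grouping)
  tab <- dist@table
  group <- switch(grouping,
    raw = paste0(tab$steps, " {", tab$observed, "} {", tab$downpass, "}"),
    steps_observed = tab$observed,
    steps_nstates = as.character(maskSize(tab$observedMask))
  )
  steps <- tab$steps
  if (grouping == "raw") {
    out <- data.frame(label = group, probability = tab$probability)
  } else {
    if (!is.null(stepPools)) checkPools(stepPools)
    stepLab <- as.character(steps)
    if (!is.null(stepPools)) {
      for (g in names(stepPools)) {
        for (rg in stepPools[[g]]) {
          hit <- group == g & steps >= rg[1] & steps <= rg[2]
          stepLab[hit] <- paste0(rg[1], "-", rg[2])
        }
      }
    }
    key <- paste0(stepLab, " steps, ",
                  if (grouping == "steps_nstates") paste0(group, " state(s)")
                  else paste0("{", group, "}"))
    agg <- rowsum(tab$probability, key, reorder = FALSE)
    ## deterministic order: by group then first step in the bin
    firstStep <- rowsum(as.numeric(steps), key, reorder = FALSE)[, 1] /
      rowsum(rep(1, length(key)), key, reorder = FALSE)[, 1]
    grpOf <- tapply(group, key, function(x) x[1])[rownames(agg)]
    ord <- order(grpOf, firstStep[rownames(agg)])
    out <- data.frame(label = rownames(agg)[ord],
                      probability = agg[ord, 1])
  }
  rownames(out) <- NULL
  if (!is.null(nSites)) out$expected <- out$probability * nSites
  out
}

checkPools <- function(stepPools) {
  for (g in names(stepPools)) {
    rgs <- stepPools[[g]]
    if (!length(rgs)) next
    m <- do.call(rbind, rgs)
    if (any(m[, 1] > m[, 2])) stop("malformed step pool in group ", g)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(m) > 1L && any(m[-1, 1] <= m[-nrow(m), 2])) {
      stop("overlapping step pools in group ", g)
    }
  }
  invisible(TRUE)
}

#' Chi-squared goodness-of-fit between observed and expected counts
#'
#' Pearson's statistic \eqn{\sum (O - E)^2 / E} with `df = bins - 1` and the
#' upper-tail chi-squared p-value. Both arguments must be counts on the same
#' scale: multiplying observed and expected by a common factor scales the
#' statistic by that factor, so probabilities must be converted to counts
#' before calling.
#'
#' @param observed,expected equal-length numeric vectors of counts;
#'   all expected counts must be positive (pool sparse bins first).
#' @return an object of class `htest` with `statistic`, `parameter` (df)
#'   and `p.value`.
#' @export
chi2GoodnessOfFit <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("observed and expected must have the same length")
  }
  if (any(!is.finite(observed)) || any(!is.finite(expected))) {
    stop("counts must be finite")
  }
  if (any(expected <= 0)) {
    stop("zero or negative expected count; pool sparse bins before testing")
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(
    statistic = c("X-squared" = stat),
    parameter = c(df = df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE),
    method = "Chi-squared goodness-of-fit test on pattern-class counts",
    data.name = deparse(substitute(observed))
  ), class = "htest")
}

#' Probability of a constant pattern
#'
#' The total probability of the constant classes (parsimony steps 0,
#' equivalently a singleton observed set): the quantity needed for
#' variable-sites (Mkv-type) ascertainment-bias corrections.
#'
#' @param dist a [ClassDistribution-class].
#' @return probability in `[0, 1]`.
#' @export
probConstant <- function(dist) {
  sum(dist@table$probability[dist@table$steps == 0L])
}

#' Probability of a variable pattern
#'
#' `1 - probConstant(dist)`: the normalising constant of a
#' conditional-on-variable (Mkv) likelihood.
#'
#' @inheritParams probConstant
#' @export
probVariable <- function(dist) {
  1 - probConstant(dist)
}

#' Probability of a parsimony-uninformative pattern
#'
#' A pattern is parsimony-uninformative (for unordered characters) when at
#' most one state occurs in more than one tip; its parsimony score is then
#' the same on every tree. This tree-independent count criterion is distinct
#' from membership in any fixed-tree `(s, t, d)` class. The probability is
#' computed by enumeration: over all `K^N` patterns when that fits under
#' `cap`, otherwise (for `K = 2`) over the `2N + 2` qualifying patterns
#' directly; each qualifying pattern's probability comes from the pruning
#' algorithm mixed over the rate mixture.
#'
#' @param tree a validated `phylo` object.
#' @param model a [SubstitutionModel-class].
#' @param cap enumeration cap as in [enumerateClassProbs()].
#' @return probability in `[0, 1]`.
#' @export
probParsimonyUninformative <- function(tree, model, cap = 1e7) {
  ti <- treeIndex(tree)
  K <- length(model@stateSpace)
  N <- ti$nTips
  mix <- rateMixture(model)
  eg <- modelEigen(model)
  mixedPrune <- function(patterns) {
    p <- numeric(ncol(patterns))
    for (r in seq_len(nrow(mix))) {
      p <- p + mix$weight[r] * pruneAll(ti, eg, model@freqs, patterns,
                                        mix$rate[r])
    }
    p
  }
  if (K^N * nrow(mix) <= cap) {
    patterns <- allPatterns(N, K)
    counts <- apply(patterns, 2, tabulate, nbins = K)
    uninf <- colSums(counts >= 2L) <= 1L
    return(sum(mixedPrune(patterns[, uninf, drop = FALSE])))
  }
  if (K == 2L) {
    ## constant patterns plus every single-off pattern
    pats <- matrix(1L, nrow = N, ncol = 2L + 2L * N)
    pats[, 2L] <- 2L
    col <- 2L
    for (i in seq_len(N)) {
      col <- col + 1L
      pats[i, col] <- 2L
      col <- col + 1L
      pats[, col] <- 2L
      pats[i, col] <- 1L
    }
    return(sum(mixedPrune(pats)))
  }
  stop(sprintf(
    "instance too large for enumeration (K^N = %d^%d); only K = 2 has a direct route",
    K, N))
}

#' Expected pattern-class site counts for the 40-taxon mammal RAG1 data set
#'
#' The packaged validation table for a classic marginal model-adequacy
#' analysis of 730-base RAG1 sequences from 40 mammal species: for 25 bins
#' defined by parsimony step count (some pooled into ranges) and number of
#' observed states, the expected number of sites per 730-site data set as
#' estimated (i) by relative pattern frequencies in a 100,000-site
#' simulation study (Waddell and colleagues' approach) and (ii) by the
#' class dynamic program under the same tree and model.
#'
#' @return data.frame with columns `steps` (character; single values or
#'   pooled ranges like `"7-20"`), `nStates`, `simExpected`, `dpExpected`.
#' @export
rag1ClassCounts <- function() {
  path <- system.file("extdata", "rag1_class_counts.tsv",
                      package = "PatternClassProb", mustWork = TRUE)
  utils::read.delim(path, colClasses = c("character", "integer",
                                         "numeric", "numeric"))
}
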