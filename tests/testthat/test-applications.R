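test_that("binning conserves probability under every grouping", {
  fx <- generateFixture(6, K = 4, seed = 101)
  d <- classProbabilities(fx$tree, fx$model)
  total <- sum(as.data.frame(d)$probability)
  for (g in c("raw", "steps_observed", "steps_nstates")) {
    b <- binDistribution(d, g)
    expect_equal(sum(b$probability), total, tolerance = 1e-12)
  }
  ## raw grouping with nSites = 1 is the identity on the distribution
  raw <- binDistribution(d, "raw", nSites = 1)
  expect_equal(raw$probability, as.data.frame(d)$probability)
  expect_equal(raw$expected, raw$probability)
})

test_that("a cherry bins into (0 steps, 1 state) and (1 step, 2 states)", {
  d <- classProbabilities(cherryTree(), jcModel())
  b <- binDistribution(d, "steps_nstates")
  expect_equal(nrow(b), 2L)
  expect_setequal(b$label, c("0 steps, 1 state(s)", "1 steps, 2 state(s)"))
  expect_equal(sum(b$probability), 1, tolerance = 1e-12)
})

test_that("step pools merge ranges and reject overlap", {
  fx <- generateFixture(7, K = 4, seed = 102)
  d <- classProbabilities(fx$tree, fx$model)
  pooled <- binDistribution(d, "steps_nstates",
                            stepPools = list(`2` = list(c(3, 6)),
                                             `3` = list(c(4, 6))))
  expect_true(any(grepl("3-6 steps, 2 state", pooled$label)))
  expect_equal(sum(pooled$probability), 1, tolerance = 1e-12)
  expect_error(
    binDistribution(d, "steps_nstates",
                    stepPools = list(`2` = list(c(1, 4), c(3, 6)))),
    "overlap")
})

test_that("chi-squared statistic, df and p behave as defined", {
  E <- c(10, 20, 30, 40)
  perfect <- chi2GoodnessOfFit(E, E)
  expect_equal(unname(perfect$statistic), 0)
  expect_equal(unname(perfect$parameter), 3L)
  expect_equal(perfect$p.value, 1)
  expect_error(chi2GoodnessOfFit(c(1, 2), c(1, 2, 3)), "same length")
  expect_error(chi2GoodnessOfFit(c(1, 2), c(1, 0)), "pool")
  ## counts, not probabilities: common rescaling scales the statistic
  O <- c(12, 18, 33, 37)
  g1 <- chi2GoodnessOfFit(O, E)
  g10 <- chi2GoodnessOfFit(10 * O, 10 * E)
  expect_equal(unname(g10$statistic), 10 * unname(g1$statistic))
})

test_that("chi-squared test holds its nominal size under the null", {
  tab <- rag1ClassCounts()
  E <- tab$dpExpected * 100000 / 730
  p <- E / sum(E)
  nrep <- 2000
  rejections <- 0L
  set.seed(2024)
  for (i in seq_len(nrep)) {
    O <- as.numeric(stats::rmultinom(1, size = round(sum(E)), prob = p))
    g <- chi2GoodnessOfFit(O, round(sum(E)) * p)
    if (g$p.value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / nrep
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / nrep))
})

test_that("constant and variable probabilities are complements", {
  fx <- generateFixture(6, K = 4, seed = 103, pInv = 0.3)
  d <- classProbabilities(fx$tree, fx$model)
  expect_equal(probConstant(d) + probVariable(d), 1)
  expect_gte(probConstant(d), 0.3) # the invariant category is constant
  ## zero-length tree: everything constant
  tr0 <- parseNewickTree("((a:0,b:0):0,c:0);")
  d0 <- classProbabilities(tr0, jcModel())
  expect_equal(probConstant(d0), 1, tolerance = 1e-12)
  expect_equal(probVariable(d0), 0, tolerance = 1e-12)
  ## cherry closed form: sum_x sum_a pi_a P(x|a,t)^2, which by
  ## reversibility + Chapman-Kolmogorov is sum_x pi_x P(x|x, 2t)
  m <- gtrTestModel()
  dch <- classProbabilities(cherryTree(0.2, 0.2), m)
  expect_equal(probConstant(dch),
               sum(m@freqs * diag(transitionMatrix(m, 0.4))),
               tolerance = 1e-12)
  ## long-branch cherry under JC approaches 3/4 variable
  dlong <- classProbabilities(cherryTree(50, 50), jcModel())
  expect_equal(probVariable(dlong), 0.75, tolerance = 1e-6)
})

test_that("parsimony-uninformative probability matches brute force", {
  ## every 2-leaf pattern is uninformative
  expect_equal(probParsimonyUninformative(cherryTree(), jcModel()), 1,
               tolerance = 1e-12)
  ## zero-length tree: only constant patterns arise, all uninformative
  tr0 <- parseNewickTree("((a:0,b:0):0,(c:0,d:0):0);")
  expect_equal(probParsimonyUninformative(tr0, jcModel(K = 2)), 1,
               tolerance = 1e-12)
  ## random 6-leaf DNA fixture: equals the filtered full enumeration
  fx <- generateFixture(6, K = 4, seed = 104)
  full <- probParsimonyUninformative(fx$tree, fx$model)
  ## independent route: sum pruning over patterns failing the count test
  ti <- PatternClassProb:::treeIndex(fx$tree)
  eg <- PatternClassProb:::modelEigen(fx$model)
  pats <- PatternClassProb:::allPatterns(6, 4)
  mix <- rateMixture(fx$model)
  probs <- numeric(ncol(pats))
  for (r in seq_len(nrow(mix))) {
    probs <- probs + mix$weight[r] *
      PatternClassProb:::pruneAll(ti, eg, fx$model@freqs, pats, mix$rate[r])
  }
  keep <- apply(pats, 2, function(x) sum(tabulate(x, 4) >= 2L) <= 1L)
  expect_equal(full, sum(probs[keep]), tolerance = 1e-12)
  ## K = 2 direct route agrees with full enumeration on a binary fixture
  fb <- generateFixture(8, K = 2, seed = 105)
  expect_equal(probParsimonyUninformative(fb$tree, fb$model),
               probParsimonyUninformative(fb$tree, fb$model, cap = 10),
               tolerance = 1e-12)
})

test_that("the packaged class-count table is internally consistent", {
  tab <- rag1ClassCounts()
  expect_equal(nrow(tab), 25L)
  expect_equal(sum(tab$simExpected), 729.7, tolerance = 1e-9)
  expect_equal(sum(tab$dpExpected), 730.01, tolerance = 1e-9)
  expect_true(all(tab$nStates %in% 1:4))
})
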