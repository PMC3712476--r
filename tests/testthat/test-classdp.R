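test_that("leaf tables have one unit entry per ancestral state", {
  tr <- threeLeafTree()
  tab <- initLeafTable(tr, 1L, dnaStateSpace())
  for (x in 1:4) {
    m <- bitwShiftL(1L, x - 1L)
    v <- classTableEntry(tab, 0L, m, m)
    expect_equal(v, as.numeric(seq_len(4) == x))
  }
  ## per-a normalization: exactly one unit entry per ancestral state
  expect_equal(rowSums(matrix(tab@probs, nrow = 4)), rep(1, 4))
  expect_error(initLeafTable(tr, 4L, dnaStateSpace()), "internal")
})

test_that("child contribution of a leaf is a transition probability", {
  tr <- cherryTree()
  leaf <- initLeafTable(tr, 1L, dnaStateSpace())
  P <- transitionMatrix(gtrTestModel(), 0.23)
  for (x in 1:4) {
    m <- bitwShiftL(1L, x - 1L)
    expect_equal(childContribution(leaf, 0L, m, m, P = P), P[, x])
    ## no one-step class exists at a leaf
    expect_equal(childContribution(leaf, 1L, m, m, P = P), rep(0, 4))
  }
})

test_that("cherry intersection and union terms match closed forms", {
  tr <- cherryTree(0.1, 0.2)
  m <- gtrTestModel()
  PA <- transitionMatrix(m, 0.1)
  PB <- transitionMatrix(m, 0.2)
  tabA <- initLeafTable(tr, 1L, dnaStateSpace())
  tabB <- initLeafTable(tr, 2L, dnaStateSpace())
  mA <- stateSet("A"); mC <- stateSet("C"); mAC <- stateSet(c("A", "C"))
  ## constant class: both children state-A leaves, intersection {A}
  expect_equal(intersectionTerm(0L, mA, mA, tabA, tabB, PA, PB),
               PA[, 1] * PB[, 1])
  expect_equal(unionTerm(0L, mA, mA, tabA, tabB, PA, PB), rep(0, 4))
  ## two-state class: only the union route, two leaf assignments
  expect_equal(unionTerm(1L, mAC, mAC, tabA, tabB, PA, PB),
               PA[, 1] * PB[, 2] + PA[, 2] * PB[, 1])
  expect_equal(intersectionTerm(1L, mAC, mAC, tabA, tabB, PA, PB),
               rep(0, 4))
  ## |d| = 1 union is impossible; intersection with d != t is infeasible here
  expect_equal(unionTerm(1L, mAC, mA, tabA, tabB, PA, PB), rep(0, 4))
  ## combineNode = I + U entrywise
  comb <- combineNode(tabA, tabB, PA, PB)
  for (s in 0:1) {
    for (td in list(c(mA, mA), c(mAC, mAC), c(mAC, mA), c(mAC, mC))) {
      expect_equal(
        classTableEntry(comb, s, td[1], td[2]),
        intersectionTerm(s, td[1], td[2], tabA, tabB, PA, PB) +
          unionTerm(s, td[1], td[2], tabA, tabB, PA, PB))
    }
  }
  ## cherry table supports only (0,{x},{x}) and (1,{x,y},{x,y})
  arr <- comb@probs
  expect_equal(sum(arr != 0) , 4 * 4 + 6 * 4)
})

test_that("per-ancestral-state table mass is 1 at every internal node", {
  fx <- generateFixture(7, K = 4, seed = 21)
  tabs <- PatternClassProb:::nodeTablesAtRate(fx$tree, fx$model, rate = 1.37)
  for (n in seq_along(tabs)) {
    mass <- rowSums(matrix(tabs[[n]], nrow = 4))
    expect_equal(mass, rep(1, 4), tolerance = 1e-9)
  }
})

test_that("root marginalization with zero-length edges is the frequency vector", {
  tr <- cherryTree(0, 0)
  d <- classProbabilities(tr, jcModel())
  tab <- as.data.frame(d)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$probability, rep(0.25, 4))
  expect_equal(tab$steps, rep(0L, 4))
  expect_error(
    rootClassProbabilities(initLeafTable(tr, 1L, dnaStateSpace()),
                           c(0.5, 0.2, 0.2, 0.2)),
    "sum to 1")
})

test_that("DP equals the enumeration oracle on seeded fixtures", {
  ## K = 4 with GTR+Gamma across tree sizes, and K = 2 up to 10 leaves
  for (n in 2:7) {
    fx <- generateFixture(n, K = 4, seed = 300 + n)
    expect_lt(maxClassDiff(classProbabilities(fx$tree, fx$model),
                           enumerateClassProbs(fx$tree, fx$model)), 1e-10)
  }
  for (n in c(4, 10)) {
    fx <- generateFixture(n, K = 2, seed = 400 + n)
    expect_lt(maxClassDiff(classProbabilities(fx$tree, fx$model),
                           enumerateClassProbs(fx$tree, fx$model)), 1e-10)
  }
  ## and with invariant sites in the mixture
  fx <- generateFixture(5, K = 4, seed = 500, pInv = 0.25)
  expect_lt(maxClassDiff(classProbabilities(fx$tree, fx$model),
                         enumerateClassProbs(fx$tree, fx$model)), 1e-10)
})

test_that("class distribution support obeys the feasibility bounds", {
  fx <- generateFixture(6, K = 4, seed = 31)
  tab <- as.data.frame(classProbabilities(fx$tree, fx$model))
  expect_true(all(bitwAnd(tab$downpassMask, tab$observedMask) ==
                    tab$downpassMask))
  sizes <- PatternClassProb:::maskSize(tab$observedMask)
  dsizes <- PatternClassProb:::maskSize(tab$downpassMask)
  expect_true(all(tab$steps >= sizes - 1L))
  expect_true(all(tab$steps >= dsizes - 1L))
  expect_true(all(tab$steps <= 5L))
  expect_true(all(tab$probability >= 0))
  expect_equal(sum(tab$probability), 1, tolerance = 1e-9)
})

test_that("constant-class probabilities equal pruning of constant patterns", {
  fx <- generateFixture(8, K = 4, seed = 41, pInv = 0.1)
  d <- classProbabilities(fx$tree, fx$model)
  labs <- stateLabels(fx$model@stateSpace)
  for (x in seq_along(labs)) {
    pat <- setNames(rep(x, 8), fx$tree$tip.label)
    expect_equal(
      classProbability(d, 0L, bitwShiftL(1L, x - 1L)),
      pruningSiteProbability(fx$tree, fx$model, pat, rate = NULL),
      tolerance = 1e-12)
  }
})

test_that("the class distribution is invariant to branch rotation", {
  fx <- generateFixture(6, K = 4, seed = 51)
  tr <- fx$tree
  d0 <- classProbabilities(tr, fx$model)
  for (node in 6L + seq_len(tr$Nnode)) {
    expect_lt(maxClassDiff(d0, classProbabilities(rotateNode(tr, node),
                                                  fx$model)), 1e-12)
  }
})

test_that("degenerate and single-category mixtures behave as expected", {
  tr <- balancedFourTree()
  expect_error(jcModel(pInv = 1), "pInv")
  dHigh <- classProbabilities(tr, jcModel(pInv = 0.999))
  expect_gte(probConstant(dHigh), 0.999)
  m1 <- gtrTestModel()
  expect_lt(maxClassDiff(classProbabilities(tr, m1),
                         enumerateClassProbs(tr, m1)), 1e-12)
})
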