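test_that("pruning matches direct summation on a cherry", {
  tr <- cherryTree(0.13, 0.41)
  m <- gtrTestModel()
  P1 <- transitionMatrix(m, 0.13)
  P2 <- transitionMatrix(m, 0.41)
  pi <- m@freqs
  direct <- sum(pi * P1[, 1] * P2[, 2]) # pattern a=A, b=C
  expect_equal(pruningSiteProbability(tr, m, c(a = "A", b = "C")), direct,
               tolerance = 1e-14)
  ## constant pattern on zero-length edges under JC
  tr0 <- cherryTree(0, 0)
  expect_equal(pruningSiteProbability(tr0, jcModel(), c(a = "A", b = "A")),
               0.25, tolerance = 1e-15)
})

test_that("pattern probabilities sum to 1 over all patterns", {
  fx <- generateFixture(5, K = 4, seed = 61, pInv = 0.15)
  ti <- PatternClassProb:::treeIndex(fx$tree)
  eg <- PatternClassProb:::modelEigen(fx$model)
  pats <- PatternClassProb:::allPatterns(5, 4)
  mix <- rateMixture(fx$model)
  mixed <- numeric(ncol(pats))
  for (r in seq_len(nrow(mix))) {
    perCat <- PatternClassProb:::pruneAll(ti, eg, fx$model@freqs, pats,
                                          mix$rate[r])
    expect_equal(sum(perCat), 1, tolerance = 1e-12) # per rate category
    mixed <- mixed + mix$weight[r] * perCat
  }
  expect_equal(sum(mixed), 1, tolerance = 1e-12)
})

test_that("enumeration refuses instances beyond its cap", {
  fx <- generateFixture(20, K = 4, seed = 62)
  expect_error(enumerateClassProbs(fx$tree, fx$model), "cap")
})

test_that("simulation is seed-reproducible and respects limits", {
  fx <- generateFixture(6, K = 4, seed = 71)
  s1 <- simulateCharacters(fx$tree, fx$model, 200, seed = 9)
  s2 <- simulateCharacters(fx$tree, fx$model, 200, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulateCharacters(fx$tree, fx$model, 200, seed = 10)
  expect_false(identical(s1, s3))
  ## zero-length tree: every simulated site is constant
  tr0 <- parseNewickTree("((a:0,b:0):0,(c:0,d:0):0);")
  s0 <- simulateCharacters(tr0, jcModel(), 500, seed = 3)
  expect_true(all(apply(s0, 2, function(x) length(unique(x)) == 1L)))
})

test_that("a long-branch cherry approaches independent uniform tips", {
  tr <- cherryTree(50, 50)
  s <- simulateCharacters(tr, jcModel(), 100000, seed = 17)
  pConst <- mean(s[1, ] == s[2, ])
  se <- sqrt(0.25 * 0.75 / 100000)
  expect_lt(abs(pConst - 0.25), 4 * se)
})

test_that("empirical class frequencies track DP probabilities", {
  fx <- generateFixture(6, K = 4, seed = 81)
  d <- classProbabilities(fx$tree, fx$model)
  n <- 20000
  s <- simulateCharacters(fx$tree, fx$model, n, seed = 5)
  ti <- PatternClassProb:::treeIndex(fx$tree)
  cls <- PatternClassProb:::fitchAll(ti, s)
  key <- paste(cls$steps, cls$observed, cls$downpass)
  counts <- table(key)
  tab <- as.data.frame(d)
  tab$key <- paste(tab$steps, tab$observedMask, tab$downpassMask)
  ## every simulated class exists in the DP support
  expect_true(all(names(counts) %in% tab$key))
  for (i in which(tab$probability * n >= 5)) {
    obs <- if (tab$key[i] %in% names(counts)) counts[[tab$key[i]]] else 0
    p <- tab$probability[i]
    expect_lt(abs(obs / n - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("fixtures are deterministic in their seed", {
  f1 <- generateFixture(7, K = 4, seed = 91)
  f2 <- generateFixture(7, K = 4, seed = 91)
  expect_identical(writeNewickTree(f1$tree), writeNewickTree(f2$tree))
  expect_identical(f1$model@rates, f2$model@rates)
  expect_identical(f1$model@freqs, f2$model@freqs)
})

test_that("simulated matrices export as readable FASTA", {
  fx <- generateFixture(4, K = 4, seed = 92)
  s <- simulateCharacters(fx$tree, fx$model, 30, seed = 1)
  f <- tempfile(fileext = ".fasta")
  exportFasta(s, fx$model@stateSpace, f)
  back <- ape::read.FASTA(f)
  expect_equal(sort(names(back)), sort(rownames(s)))
  expect_equal(unique(lengths(back)), 30L)
})
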