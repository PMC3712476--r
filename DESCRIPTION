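Package: PatternClassProb
Title: Probabilities of Parsimony Pattern Classes on a Phylogeny
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes, by a postorder dynamic program, the probability that a
    discrete character evolving on a fixed rooted binary phylogeny under a
    reversible substitution model (GTR+I+Gamma or symmetric Mk) falls into
    each pattern class, where a class is defined by the parsimony step count,
    the set of states observed at the tips, and the Fitch downpass state set
    at the root. Downstream applications include marginal model-adequacy
    binning with a chi-squared goodness-of-fit check and ascertainment-bias
    quantities (constant, variable and parsimony-uninformative pattern
    probabilities). An independent brute-force oracle (Felsenstein pruning
    over all patterns) and a seeded character simulator are included for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, ape, seqinr, optparse
Suggests: testthat (>= 3.0.0), phangorn, Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
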