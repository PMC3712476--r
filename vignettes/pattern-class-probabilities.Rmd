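---
title: "Computing pattern-class probabilities on a fixed phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing pattern-class probabilities on a fixed phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PatternClassProb)
```

## The problem

Felsenstein's pruning algorithm gives the probability of one particular tip
pattern arising on a phylogeny under a substitution model. Several
applications instead need the probability of a whole *class* of patterns:

* **Marginal model-adequacy tests** bin the observed characters by their
  parsimony step count and the set of states they display, then compare
  observed bin counts to their model-expected counts. The classical way to
  obtain expected counts — simulating on the order of 100,000 characters and
  counting — does not scale well and carries Monte-Carlo noise.
* **Ascertainment-bias corrections** (conditioning on a character being
  variable, as in the Mkv model, or parsimony-informative, as in corrections
  for morphological matrices that were scored only at varying characters)
  need the total probability of the constant, variable or uninformative
  pattern sets.

With \(K\) states and \(N\) tips there are \(K^N\) patterns, so exhaustive
enumeration is only viable on small trees. This package computes class
probabilities *exactly* by a dynamic program whose cost is polynomial in
\(N\), and retains the exhaustive enumeration as an independent oracle to
validate the dynamic program on small instances.

## Pattern classes

Fix a rooted, fully resolved (binary) tree with branch lengths. For one tip
pattern, run the preliminary phase of Fitch's parsimony algorithm (the
*downpass*): a leaf's state set is the singleton of its observed state with
0 steps; at an internal node the set is the intersection of the children's
sets when that is nonempty (no step added), otherwise their union (one step
added). The step total at the root is the parsimony length of the pattern.

The **class** of a pattern is the triple \((s, t, d)\):

* \(s\): the parsimony step count,
* \(t\): the set of states observed at the tips,
* \(d\): the downpass state set at the root (always a nonempty subset of
  \(t\)).

Binning by \((s,t)\) — i.e. summing classes over all \(d\) — gives exactly
the bins used by marginal adequacy tests; \(d\) is carried because it is
what makes the recursion below self-contained.

## The dynamic program

For the subtree rooted at node \(n\), let \(Q_{s,t,d,a}(n)\) be the
probability that the subtree generates a pattern of class \((s,t,d)\),
conditional on the ancestral state at \(n\) being \(a\). At a leaf,
\(Q_{0,\{x\},\{x\},x} = 1\) for each state \(x\) and every other entry is 0:
there is no opportunity for evolution within a leaf.

At an internal node with children \(A\) and \(B\), each child's table first
passes through its edge in pruning style,
\[
C_{s',t',d'}(a) \;=\; \sum_i P(i \mid a,\, e)\; Q_{s',t',d',i}(\text{child}),
\]
where \(P(i \mid a, e)\) is the transition probability across the child's
edge. The parent's entry is then the sum of two terms, reflecting the two
ways a downpass set forms:

* **Intersection** (no step added): over all child classes with
  \(t_A \cup t_B = t\), \(d_A \cap d_B = d \ne \emptyset\) and
  \(s_A + s_B = s\). Equivalently, writing \(d_A = d \cup g_A\), the extra
  downpass states \(g_A, g_B \subseteq t - d\) must be disjoint between the
  children — any shared extra state would survive into the intersection and
  enlarge it — and the children's observed sets beyond \(d\) must jointly
  cover \(t\).
* **Union** (one step added): over all child classes with
  \(t_A \cup t_B = t\), \(d_A \cap d_B = \emptyset\),
  \(d_A \cup d_B = d\) (both nonempty, so the second child's downpass is
  determined by subtraction, \(d_B = d - d_A\)) and \(s_A + s_B = s - 1\).
  No union term exists when \(|d| = 1\).

After the postorder sweep, class probabilities come from marginalising the
root table over root states with the equilibrium frequencies:
\(X(s,t,d) = \sum_a \pi_a\, Q_{s,t,d,a}(\rho)\).

One design point deserves a note. The constraint system above can be
parameterised by "extra observed" sets \(c_A = t_A - d\) and "extra
downpass" sets \(g_A = d_A - d\); we define \(c_A\) relative to the
*parent's* target downpass \(d\) (states observed in the child's subtree
beyond \(d\)), which makes \(g_A \subseteq c_A\) hold and all summation
ranges consistent. The implementation does not iterate these
\(g/c\) sets explicitly: it iterates all feasible child \((t,d)\) pairs —
there are \(3^K - 2^K\) of them (65 for DNA), precomputed once per alphabet
together with the resulting parent \((t,d)\) and step increment — and
convolves over step counts. The two views are algebraically identical; the
exported `intersectionTerm()`/`unionTerm()` expose the decomposition
entry-by-entry, and the enumeration oracle arbitrates correctness of the
whole construction.

### Rate mixtures

Gamma-distributed rate heterogeneity and invariant sites are handled by
running the DP once per rate category and mixing the *root-level*
distributions by the category weights. Mixing after classification is the
only coherent choice: a pattern's class is a function of the tip pattern
alone, not of the rate that generated it. The rate-0 invariant category's
transition matrices are identities, so it contributes mass only to constant
classes — no special-casing is needed.

## Models and their parameters

* **Exchangeabilities and frequencies.** GTR with \(K(K-1)/2\)
  exchangeabilities (DNA order AC, AG, AT, CG, CT, GT) and positive
  frequencies summing to 1. `mkModel(K)`/`jcModel()` give the symmetric
  equal-frequency special case.
* **Normalisation.** The rate matrix is scaled so
  \(-\sum_a \pi_a q_{aa} = 1\): branch lengths are expected substitutions
  per site at relative rate 1, and the simulator, the oracle and the DP all
  share this convention.
* **Gamma discretization** (`gammaShape`, `nGammaCat`, default 4): equal
  probability bins represented by their within-bin mean rate, the common
  default in phylogenetics, computed in closed form via the
  incomplete-moment identity of the gamma distribution (and cross-checked
  against numerical quadrature and `phangorn::discrete.gamma` in the
  tests).
* **Invariant sites** (`pInv` in \([0,1)\)): a rate-0 category of weight
  `pInv`; the gamma rates are rescaled by \(1/(1-p_{\mathrm{inv}})\) so the
  mixture's mean rate stays exactly 1. `pInv = 1` is rejected as degenerate.
* **Transition probabilities** by eigendecomposition of the similarity
  transform \(\Pi^{1/2} Q\, \Pi^{-1/2}\), which reversibility makes
  symmetric; a truncated-series matrix exponential serves as the oracle in
  the tests. A zero-length (or rate-0) edge returns the exact identity.

## Numerical choices

* Plain double precision, no log-space scaling: class masses are sums of
  products with at most one multiplication per tree level, far from
  underflow at the scales targeted here (tens to a few hundred tips).
  Per-node rescaling would be the remedy if much larger trees were ever
  needed.
* State sets are integer bitmasks; the feasible \((t,d)\) catalogue and the
  pairwise combination table (which pair of child \((t,d)\)'s yields which
  parent \((t,d)\) and whether a step is added) are precomputed once per
  alphabet size and cached.
* Summation order is fixed (ascending steps, then observed mask, then
  downpass mask), so outputs are deterministic and the command-line tool is
  byte-stable across runs.
* Structurally impossible classes are never stored; conservation
  (\(\sum X = 1\), and per-ancestral-state table mass 1 at every node) is
  asserted in the tests at 1e-9.

## Validation design

Three independent routes check the DP:

1. **Exhaustive enumeration** (`enumerateClassProbs()`): all \(K^N\)
   patterns, each scored by Felsenstein pruning and classified by the Fitch
   downpass. Agreement is required to 1e-10 per class on seeded random
   fixtures (20 DNA fixtures with 2–7 tips under random GTR+Γ, 10 binary
   fixtures up to 10 tips). The enumeration cap defaults to \(10^7\)
   pattern-category evaluations.
2. **Monte-Carlo simulation** (`simulateCharacters()`): 100,000 seeded
   characters on a 10-tip fixture; every class with expected count at least
   5 must fall within 4 binomial standard errors of its DP probability.
   This mirrors how simulation-based expected counts were classically
   obtained.
3. **Parsimony cross-checks**: Fitch step counts equal the Sankoff
   0/1-cost minimum over all \(4^6\) patterns on random 6-leaf trees, and
   all results are invariant to swapping any node's children (branch
   rotation).

The packaged table `rag1ClassCounts()` records, for a classic 40-taxon
mammal RAG1 data set (730 sites), the expected sites per pattern-class bin
from a 100,000-site simulation study alongside the exact expectations from
the class DP under the same tree and model. Scaling both columns to counts
per 100,000 sites (×100000/730 — applied to both columns symmetrically,
since the two columns are expectations for the same 730-site alignment) and
comparing them with `chi2GoodnessOfFit()` gives χ² ≈ 20.9 on 24 degrees of
freedom (p ≈ 0.64): the simulation-based and analytical expectations are
statistically indistinguishable. The df convention is bins − 1; no
parameters are treated as estimated. The per-class probabilities of that
analysis are *not* recomputable here because the underlying tree and fitted
model parameters are not distributed with the table; the equivalence of the
DP with its oracles is established on the seeded fixtures instead.

## What the synthetic fixtures do and do not emulate

`generateFixture()` draws random rooted binary topologies, exponential
branch lengths with mean 0.1 substitutions/site (a typical interior-branch
scale in empirical nucleotide trees), GTR exchangeabilities uniform on
[0.5, 2], Dirichlet-like frequencies concentrated near 1/4, and gamma
shapes uniform on [0.3, 2] — realistic ranges for nucleotide data. They are
*iid*-site models on correct trees: passing validation on them demonstrates
the algebra of the DP, not robustness to model misspecification,
among-lineage heterogeneity, or alignment error in real data. Missing and
ambiguous tip states are out of scope throughout (every leaf carries
exactly one state).

## Ascertainment-bias quantities

* `probConstant()` / `probVariable()`: the constant classes are exactly the
  \(s = 0\) classes, so both come directly from the distribution; these are
  the normalising constants for conditional-on-variable (Mkv-type)
  likelihoods.
* `probParsimonyUninformative()`: a pattern is uninformative (unordered
  parsimony) when at most one state occurs in more than one tip — a
  *tree-independent* count criterion. Class membership \((s,t,d)\) on a
  fixed tree cannot decide it: an informative pattern can attain
  \(s = |t|-1\) on a favourable topology, so no mapping from classes to
  informativeness exists. The probability is therefore computed by
  enumeration — over all \(K^N\) patterns within the cap, or directly over
  the \(2N+2\) qualifying patterns for binary characters — with each
  pattern scored by pruning. A DP-based route for large multistate trees is
  deliberately left unimplemented rather than guessed.

## Problem sizes

The default validation suite uses exhaustive oracles up to \(4^7\) patterns
and one 40-tip GTR+I+Γ computation (about 2 s); the full DP scales
comfortably to hundreds of tips. These sizes were chosen to make the
exhaustive cross-checks exact while keeping the suite quick to run.
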