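#' Parse a rooted, fully resolved Newick tree
#'
#' Reads a Newick string (or file) into an `ape::phylo` object and validates
#' it for use with the pattern-class machinery: the tree must be rooted and
#' strictly bifurcating, every non-root edge must carry a finite non-negative
#' branch length (expected substitutions per site), and tip labels must be
#' unique and non-empty. Square-bracket comments are stripped; quoted labels
#' are supported by the underlying parser. A root edge length, if present,
#' is ignored.
#'
#' @param text Newick string (with terminating semicolon).
#' @param file path to a file containing one Newick tree; exactly one of
#'   `text`/`file` must be given.
#' @return a validated `phylo` object.
#' @examples
#' tr <- parseNewickTree("((a:0.1,b:0.2):0.05,c:0.3);")
#' @export
parseNewickTree <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`")
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text) # strip comments
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || inherits(phy, "multiPhylo")) {
    phy <- if (inherits(phy, "multiPhylo") && length(phy) == 1L) phy[[1]] else NULL
  }
  if (is.null(phy)) stop("could not parse Newick input")
  validateTree(phy)
  phy
}

#' Write a tree back to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeNewickTree <- function(tree, file = NULL, digits = 15L) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Validate a tree for pattern-class computations
#'
#' Checks that `tree` is a rooted, strictly bifurcating `phylo` with finite
#' non-negative branch lengths on all non-root edges and unique, non-empty
#' tip labels. Zero-length branches are allowed (the transition matrix is
#' then the identity). Called for its side effect of stopping with an
#' informative error; returns the tree invisibly.
#'
#' @param tree a `phylo` object.
#' @export
validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  N <- length(tree$tip.label)
  if (N < 2L) stop("tree must have at least 2 tips")
  deg <- tabulate(tree$edge[, 1], nbins = N + tree$Nnode)
  bad <- which(deg > 2L)
  if (length(bad) || !ape::is.rooted(tree)) {
    node <- if (length(bad)) bad[1] else N + 1L
    stop(sprintf(
      "unsupported topology: node %d has %d children; a rooted, fully resolved (binary) tree is required",
      node, max(deg[node], 3L)))
  }
  internalBad <- which(deg == 1L)
  if (length(internalBad)) {
    stop(sprintf("unsupported topology: node %d has 1 child", internalBad[1]))
  }
  if (is.null(tree$edge.length)) {
    stop("branch lengths are required on all non-root edges")
  }
  if (length(tree$edge.length) != nrow(tree$edge) ||
      any(!is.finite(tree$edge.length))) {
    i <- which(!is.finite(tree$edge.length))[1]
    stop(sprintf("missing or non-finite branch length on the edge to node %d",
                 if (is.na(i)) -1L else tree$edge[i, 2]))
  }
  if (any(tree$edge.length < 0)) {
    i <- which(tree$edge.length < 0)[1]
    stop(sprintf("negative branch length on the edge to node %d",
                 tree$edge[i, 2]))
  }
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip label")
  if (anyDuplicated(labs)) {
    stop("duplicate tip label(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  invisible(tree)
}

## Internal indexed form of a phylo tree.  Node ids follow ape numbering
## (tips 1..N, root N+1, further internals N+2..2N-1).  `children` keeps the
## Newick ("first child"/"second child") order; results must be invariant to
## swapping it.
treeIndex <- function(tree) {
  validateTree(tree)
  N <- length(tree$tip.label)
  M <- N + tree$Nnode
  children <- matrix(NA_integer_, nrow = M, ncol = 2L)
  edgeLen <- rep(NA_real_, M)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    slot <- if (is.na(children[p, 1])) 1L else 2L
    children[p, slot] <- ch
    edgeLen[ch] <- tree$edge.length[i]
  }
  root <- N + 1L
  ## iterative postorder (children before parents, first child subtree first)
  post <- integer(M)
  k <- 0L
  stack <- root
  out <- integer(M)   # reverse-postorder accumulation
  o <- 0L
  while (length(stack)) {
    n <- stack[length(stack)]
    stack <- stack[-length(stack)]
    o <- o + 1L
    out[o] <- n
    if (!is.na(children[n, 1])) {
      ## push first child first so the reversed sequence traverses the
      ## first-child subtree before the second
      stack <- c(stack, children[n, 1], children[n, 2])
    }
  }
  post <- rev(out)
  list(nTips = N, nNodes = M, root = root, children = children,
       edgeLen = edgeLen, labels = tree$tip.label, postorder = post,
       isLeaf = seq_len(M) <= N)
}

#' Postorder node sequence of a tree
#'
#' Returns node ids (ape numbering: tips `1..N`, root `N+1`) in postorder:
#' every child precedes its parent, the first-child subtree is traversed
#' before the second, and the root comes last. Deterministic for a given
#' tree.
#'
#' @param tree a validated `phylo` object.
#' @return integer vector of length `2N - 1`.
#' @export
postorderNodes <- function(tree) {
  treeIndex(tree)$postorder
}
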