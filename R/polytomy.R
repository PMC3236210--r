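# Random polytomy resolution. Each polytomy is broken by repeatedly
# joining two randomly chosen children under a new internal node whose
# branch length is drawn uniformly on (0, eps_max * the shorter of the two
# child branches]; the grouped child branches are shortened by the same
# amount, so all root-to-tip path lengths are conserved exactly. This is a
# deliberately simple randomization, not a Bayesian polytomy resolver.

phylo_to_rlist <- function(phy) {
  ntip <- length(phy$tip.label)
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  build <- function(node, len) {
    kid_edges <- children[[as.character(node)]]
    if (is.null(kid_edges)) {
      list(label = phy$tip.label[node], len = len, children = NULL)
    } else {
      list(label = NULL, len = len,
           children = lapply(kid_edges, function(e) {
             build(phy$edge[e, 2], phy$edge.length[e])
           }))
    }
  }
  build(ntip + 1L, 0)
}

rlist_resolve <- function(node, eps_max) {
  if (is.null(node$children)) return(node)
  while (length(node$children) > 2L) {
    pick <- sample.int(length(node$children), 2L)
    c1 <- node$children[[pick[1]]]
    c2 <- node$children[[pick[2]]]
    delta <- runif(1, 0, eps_max * min(c1$len, c2$len))
    c1$len <- c1$len - delta
    c2$len <- c2$len - delta
    joined <- list(label = NULL, len = delta, children = list(c1, c2))
    node$children[pick] <- NULL
    node$children <- c(node$children, list(joined))
  }
  node$children <- lapply(node$children, rlist_resolve, eps_max = eps_max)
  node
}

rlist_to_newick <- function(node) {
  fmt <- function(n) {
    if (is.null(n$children)) {
      sprintf("%s:%.12g", n$label, n$len)
    } else {
      sprintf("(%s):%.12g",
              paste(vapply(n$children, fmt, character(1)), collapse = ","), n$len)
    }
  }
  sprintf("(%s);", paste(vapply(node$children, fmt, character(1)), collapse = ","))
}

#' Randomly resolve polytomies into binary trees
#'
#' Produces a distribution of fully dichotomous trees from a tree that may
#' contain polytomies. Each polytomy is independently resolved by random
#' sequential joining; new internal branches receive a length drawn
#' uniformly on `(0, eps_max * min(child branch lengths)]`, and the joined
#' child branches are shortened to conserve every root-to-tip depth.
#' Already-binary trees are returned unchanged.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param n_resolutions Number of resolved trees to produce (default 100).
#' @param seed Optional integer seed.
#' @param eps_max Cap on the new internal branch length, as a fraction of
#'   the shorter of the two joined child branches (default 0.5).
#' @return A `multiPhylo` list of strictly binary trees.
#' @export
resolve_polytomies <- function(tree, n_resolutions = 100, seed = NULL,
                               eps_max = 0.5) {
  stopifnot(inherits(tree, "phylo"), n_resolutions >= 1,
            eps_max > 0, eps_max <= 1)
  if (is.null(tree$edge.length)) abort("Tree must have branch lengths.")
  if (!is.null(seed)) set.seed(seed)
  if (ape::is.binary(tree)) {
    out <- rep(list(tree), n_resolutions)
  } else {
    rl <- phylo_to_rlist(tree)
    out <- lapply(seq_len(n_resolutions), function(i) {
      ape::read.tree(text = rlist_to_newick(rlist_resolve(rl, eps_max)))
    })
  }
  class(out) <- "multiPhylo"
  out
}
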