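# Phylogeny input for row-aligned composites. Trees are read with ape;
# the leaf order used for figure rows is an explicit depth-first traversal
# of the edge table (left-to-right as written in the Newick string).

#' Read a rooted tree from Newick
#'
#' @param tree a Newick file path, a Newick string, or an ape `phylo`
#'   object (returned unchanged).
#' @return an ape `phylo`; duplicate leaf labels are an error.
#' @export
read_tree <- function(tree) {
  phy <- if (inherits(tree, "phylo")) {
    tree
  } else if (is.character(tree) && length(tree) == 1L) {
    if (grepl("(", tree, fixed = TRUE)) {
      out <- tryCatch(ape::read.tree(text = tree), error = function(e) NULL)
      if (is.null(out)) stop("unparseable Newick string", call. = FALSE)
      out
    } else {
      if (!file.exists(tree)) stop("tree file not found: ", tree, call. = FALSE)
      out <- tryCatch(ape::read.tree(tree), error = function(e) NULL)
      if (is.null(out)) stop("unparseable Newick in ", tree, call. = FALSE)
      out
    }
  } else {
    stop("tree must be a phylo object, a Newick string, or a file path",
         call. = FALSE)
  }
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("unparseable Newick input", call. = FALSE)
  }
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup) > 0L) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  phy
}

#' Depth-first leaf order of a tree
#'
#' Traverses the tree depth-first, visiting children left to right exactly
#' as written in the Newick string, and returns the tip labels in the order
#' encountered. This order dictates the row order of every tree-aligned
#' panel.
#'
#' @inheritParams read_tree
#' @return character vector of leaf labels.
#' @examples
#' leaf_order("((A,B),C);")  # A B C
#' @export
leaf_order <- function(tree) {
  phy <- read_tree(tree)
  ntip <- length(phy$tip.label)
  if (ntip == 1L) return(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])  # children in edge-table order
  root <- ntip + 1L
  out <- integer()
  stack <- root
  while (length(stack) > 0L) {
    node <- stack[1L]; stack <- stack[-1L]
    if (node <= ntip) {
      out <- c(out, node)
    } else {
      stack <- c(kids[[as.character(node)]], stack)
    }
  }
  phy$tip.label[out]
}

# node layout of a rectangular tree panel: x in [0, 1] (root left, tips
# right), y = the figure row position of each tip
tree_layout <- function(phy, tip_y, use_branch_lengths = FALSE) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  parent <- integer(nnode); parent[phy$edge[, 2]] <- phy$edge[, 1]
  elen <- stats::setNames(rep(1, nrow(phy$edge)), phy$edge[, 2])
  if (use_branch_lengths && !is.null(phy$edge.length)) {
    elen <- stats::setNames(phy$edge.length, phy$edge[, 2])
  }
  y <- numeric(nnode)
  y[seq_len(ntip)] <- tip_y[phy$tip.label]
  x <- numeric(nnode)
  # post-order for y (mean of children), pre-order distance for x
  post <- function(node) {
    if (node <= ntip) return(invisible())
    for (k in kids[[as.character(node)]]) post(k)
    y[node] <<- mean(y[kids[[as.character(node)]]])
  }
  post(root)
  pre <- function(node, d) {
    x[node] <<- d
    if (node > ntip) {
      for (k in kids[[as.character(node)]]) pre(k, d + elen[[as.character(k)]])
    }
  }
  pre(root, 0)
  if (!use_branch_lengths) {
    # cladogram: align every tip at the right edge
    depth <- max(x)
    h <- numeric(nnode)  # levels above the deepest descendant tip
    lev <- function(node) {
      if (node <= ntip) return(0)
      1 + max(vapply(kids[[as.character(node)]], lev, numeric(1)))
    }
    for (i in seq_len(nnode)) h[i] <- lev(i)
    x <- (max(h) - h) / max(max(h), 1)
  } else {
    x <- x / max(x, 1e-12)
  }
  list(x = x, y = y, parent = parent, root = root, ntip = ntip, kids = kids)
}
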