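# Unrooted binary phylogenies carrying genomes at their nodes. Internal
# representation is a plain adjacency list; every internal node has degree
# 3, so any internal node can serve as the root of a traversal ("rerooting"
# is choosing that node). Newick import/export goes through ape.

#' Construct a gene-order phylogeny
#'
#' @param edges Two-column integer matrix of node-id pairs (one row per
#'   branch; \code{n_nodes - 1} rows).
#' @param lengths Branch lengths in expected rearrangement events.
#' @param labels Character vector of node labels (length \code{n_nodes}).
#' @param is_leaf Logical vector marking leaves.
#' @param genomes Optional list of [genome()] objects per node id
#'   (\code{NULL} entries for unknown internal genomes).
#' @param root Optional node id used as traversal root.
#' @return Object of class \code{"gene_tree"}.
#' @export
gene_tree <- function(edges, lengths, labels, is_leaf, genomes = NULL,
                      root = NA_integer_) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  nn <- length(labels)
  stopifnot(nrow(edges) == nn - 1L, length(lengths) == nrow(edges),
            length(is_leaf) == nn, !anyDuplicated(labels))
  if (is.null(genomes)) genomes <- vector("list", nn)
  stopifnot(length(genomes) == nn)
  adj <- rep(list(integer(0L)), nn)
  alen <- rep(list(numeric(0L)), nn)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b); alen[[a]] <- c(alen[[a]], lengths[e])
    adj[[b]] <- c(adj[[b]], a); alen[[b]] <- c(alen[[b]], lengths[e])
  }
  deg <- lengths(adj)
  if (any(deg[is_leaf] != 1L)) stop("leaves must have degree 1")
  structure(list(edges = edges, len = as.numeric(lengths),
                 labels = as.character(labels), is_leaf = as.logical(is_leaf),
                 genomes = genomes, adj = adj, adj_len = alen,
                 root = as.integer(root)),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene tree: %d leaves, %d internal nodes, %d genomes attached>\n",
              sum(x$is_leaf), sum(!x$is_leaf),
              sum(!vapply(x$genomes, is.null, TRUE))))
  invisible(x)
}

node_id <- function(tree, x) {
  if (is.character(x)) {
    id <- match(x, tree$labels)
    if (is.na(id)) stop("unknown node label: ", x)
    return(id)
  }
  id <- as.integer(x)
  if (is.na(id) || id < 1L || id > length(tree$labels)) stop("bad node id")
  id
}

tree_leaves <- function(tree) which(tree$is_leaf)
tree_internal_nodes <- function(tree) which(!tree$is_leaf)

#' Re-root a tree at an internal node
#'
#' The tree is undirected; rerooting selects the internal node from which
#' recursions (likelihood pruning, simulation) proceed. Topology and
#' branch lengths are untouched.
#'
#' @param tree A [gene_tree()].
#' @param target Internal node label or id.
#' @return The tree with its \code{root} set.
#' @export
reroot <- function(tree, target) {
  id <- node_id(tree, target)
  if (tree$is_leaf[id]) stop("cannot root at a leaf")
  tree$root <- id
  tree
}

# BFS from `root`: visitation order, parent ids (0 at root), and the
# length of the edge to the parent.
tree_traversal <- function(tree, root) {
  nn <- length(tree$labels)
  parent <- integer(nn); plen <- numeric(nn)
  ord <- integer(nn)
  ord[1L] <- root; parent[root] <- 0L
  k <- 1L; i <- 1L
  while (i <= k) {
    v <- ord[i]
    nb <- tree$adj[[v]]; ln <- tree$adj_len[[v]]
    for (t in seq_along(nb)) {
      w <- nb[t]
      if (w != parent[v] && w != root) {
        k <- k + 1L; ord[k] <- w
        parent[w] <- v; plen[w] <- ln[t]
      }
    }
    i <- i + 1L
  }
  list(order = ord, parent = parent, plen = plen)
}

#' Summed DCJ distance over all branches (tree score)
#'
#' @param tree A [gene_tree()] with genomes at every node.
#' @return Integer score; the refinement loop's convergence functional.
#' @export
tree_score <- function(tree) {
  miss <- vapply(tree$genomes, is.null, TRUE)
  if (any(miss)) stop("tree score needs a genome at every node")
  sum(vapply(seq_len(nrow(tree$edges)), function(e) {
    dcj_distance(tree$genomes[[tree$edges[e, 1L]]],
                 tree$genomes[[tree$edges[e, 2L]]])
  }, 0L))
}

#' Pairwise leaf-to-leaf path lengths
#'
#' @param tree A [gene_tree()].
#' @return Symmetric matrix of summed branch lengths, leaf labels as
#'   dimnames.
#' @export
leaf_distances <- function(tree) {
  lv <- tree_leaves(tree)
  nn <- length(tree$labels)
  out <- matrix(0, length(lv), length(lv),
                dimnames = list(tree$labels[lv], tree$labels[lv]))
  for (i in seq_along(lv)) {
    tt <- tree_traversal(tree, lv[i])
    depth <- numeric(nn)
    for (v in tt$order[-1L]) depth[v] <- depth[tt$parent[v]] + tt$plen[v]
    out[i, ] <- depth[lv]
  }
  (out + t(out)) / 2
}

#' Convert a gene tree to an ape "phylo" object
#'
#' @param tree A [gene_tree()].
#' @return An \code{ape::phylo} (unrooted, basal trichotomy at the
#'   traversal root).
#' @export
tree_to_phylo <- function(tree) {
  lv <- tree_leaves(tree)
  iv <- tree_internal_nodes(tree)
  ro <- if (!is.na(tree$root)) tree$root else iv[1L]
  tt <- tree_traversal(tree, ro)
  L <- length(lv)
  map <- integer(length(tree$labels))
  map[lv] <- seq_len(L)
  inext <- L + 2L
  map[ro] <- L + 1L
  for (v in tt$order[-1L]) {
    if (!tree$is_leaf[v]) { map[v] <- inext; inext <- inext + 1L }
  }
  kids <- tt$order[-1L]
  edge <- cbind(map[tt$parent[kids]], map[kids])
  structure(list(edge = edge, edge.length = tt$plen[kids],
                 tip.label = tree$labels[lv], Nnode = length(iv),
                 node.label = tree$labels[c(ro, setdiff(tt$order[!tree$is_leaf[tt$order]], ro))]),
            class = "phylo")
}

#' Build a gene tree from an ape "phylo" object
#'
#' Rooted binary input is unrooted first (the algorithms assume every
#' internal node has degree 3). Missing internal labels are filled with
#' \code{A1, A2, ...}; missing branch lengths default to 1 event.
#'
#' @param phy An \code{ape::phylo}.
#' @param genomes Optional named list of leaf [genome()]s (names matched
#'   to tip labels).
#' @return A [gene_tree()].
#' @export
phylo_to_tree <- function(phy, genomes = NULL) {
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  L <- length(phy$tip.label)
  nn <- L + phy$Nnode
  labels <- c(phy$tip.label, phy$node.label)
  if (length(labels) < nn) labels <- c(labels, rep("", nn - length(labels)))
  blank <- !nzchar(labels) | is.na(labels)
  labels[blank] <- paste0("A", seq_len(sum(blank)))
  lens <- phy$edge.length
  if (is.null(lens)) lens <- rep(1, nrow(phy$edge))
  gl <- vector("list", nn)
  if (!is.null(genomes)) {
    idx <- match(phy$tip.label, names(genomes))
    if (anyNA(idx)) stop("genomes missing for some tips")
    gl[seq_len(L)] <- genomes[idx]
  }
  gene_tree(phy$edge, lens, labels, seq_len(nn) <= L, gl, root = L + 1L)
}

#' Read a Newick tree with its leaf genomes
#'
#' @param newick Path to (or text of) a Newick tree.
#' @param genomes Named list of leaf genomes, or path to a GRAPPA-style
#'   genome file ([read_genomes()]).
#' @return A [gene_tree()] with leaf genomes attached.
#' @export
read_gene_tree <- function(newick, genomes = NULL) {
  phy <- if (file.exists(newick)) ape::read.tree(newick)
         else ape::read.tree(text = newick)
  if (is.character(genomes) && length(genomes) == 1L) {
    genomes <- read_genomes(genomes)
  }
  phylo_to_tree(phy, genomes)
}

#' Write a gene tree as Newick
#'
#' @param tree A [gene_tree()].
#' @param path Output path; with \code{NULL}, the Newick string is
#'   returned.
#' @export
write_gene_tree <- function(tree, path = NULL) {
  phy <- tree_to_phylo(tree)
  if (is.null(path)) ape::write.tree(phy) else ape::write.tree(phy, file = path)
}

#' Estimate branch lengths from pairwise leaf distances
#'
#' Fits nonnegative branch lengths to the matrix of pairwise DCJ distances
#' between leaf genomes by least squares on the fixed topology. Used when
#' true per-branch event counts are unknown.
#'
#' @param tree A [gene_tree()] with leaf genomes.
#' @return The tree with \code{len} replaced by fitted lengths.
#' @export
estimate_edge_lengths <- function(tree) {
  if (!requireNamespace("phangorn", quietly = TRUE)) {
    stop("branch-length estimation needs the phangorn package")
  }
  lv <- tree_leaves(tree)
  gs <- tree$genomes[lv]
  if (any(vapply(gs, is.null, TRUE))) stop("all leaf genomes are required")
  L <- length(lv)
  dm <- matrix(0, L, L, dimnames = list(tree$labels[lv], tree$labels[lv]))
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      dm[i, j] <- dm[j, i] <- dcj_distance(gs[[i]], gs[[j]])
    }
  }
  phy <- tree_to_phylo(tree)
  fit <- phangorn::nnls.tree(stats::as.dist(dm), phy, method = "unrooted")
  # carry fitted lengths back by matching split edges via node mapping
  tr2 <- phylo_to_tree(fit, genomes = NULL)
  tr2$genomes <- tree$genomes[match(tr2$labels, tree$labels)]
  tr2$labels <- tr2$labels
  tr2
}
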