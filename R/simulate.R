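# Benchmark data generator: random unrooted binary trees (uniform
# topology; branch lengths either uniform-with-fluctuation per edge or
# exponential rescaled to a target diameter), inversion evolution from an
# identity root, and the true genome recorded at every node.

#' Simulation configuration
#'
#' @param n Gene count (genomes are circular signed permutations of
#'   \code{1..n}).
#' @param leaves Number of leaves.
#' @param model Branch-length model: \code{"uniform"} draws each edge's
#'   expected event count uniformly in
#'   \code{[rate_per_edge*n*(1-fluctuation), rate_per_edge*n*(1+fluctuation)]};
#'   \code{"lin_moret"} draws exponential edge weights and rescales them so
#'   the largest leaf-to-leaf expected-event path equals \code{diameter*n}
#'   (more unbalanced branch lengths).
#' @param rate_per_edge Expected events per edge as a fraction of \code{n}
#'   (uniform model).
#' @param fluctuation Relative half-width of the per-edge rate (uniform
#'   model), in \code{[0, 1)}.
#' @param diameter Expected events along the longest leaf-to-leaf path as
#'   a multiple of \code{n} (lin_moret model).
#' @param seed Optional random seed.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n = 100L, leaves = 10L,
                       model = c("uniform", "lin_moret"),
                       rate_per_edge = 0.12, fluctuation = 0.5,
                       diameter = 0.6, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n >= 3L, leaves >= 3L, rate_per_edge >= 0,
            fluctuation >= 0, fluctuation < 1, diameter > 0)
  structure(list(n = as.integer(n), leaves = as.integer(leaves),
                 model = model, rate_per_edge = rate_per_edge,
                 fluctuation = fluctuation, diameter = diameter,
                 seed = seed),
            class = "sim_config")
}

# Uniform unrooted binary leaf-labeled topology by sequential attachment:
# each new leaf subdivides a uniformly chosen existing edge, which makes
# all (2k-5)!! topologies equally likely.
random_topology <- function(leaves) {
  nn <- 2L * leaves - 2L
  labels <- c(paste0("L", seq_len(leaves)),
              paste0("A", seq_len(leaves - 2L)))
  is_leaf <- seq_len(nn) <= leaves
  first_int <- leaves + 1L
  edges <- rbind(c(first_int, 1L), c(first_int, 2L), c(first_int, 3L))
  if (leaves > 3L) {
    for (k in 4L:leaves) {
      w <- leaves + k - 2L
      e <- sample.int(nrow(edges), 1L)
      xy <- edges[e, ]
      edges <- rbind(edges[-e, , drop = FALSE],
                     c(xy[1L], w), c(w, xy[2L]), c(w, k))
    }
  }
  list(edges = edges, labels = labels, is_leaf = is_leaf)
}

#' Draw a random phylogeny for simulation
#'
#' Topology is uniform over unrooted binary leaf-labeled trees; branch
#' lengths (expected inversion events) follow the configured model.
#'
#' @param cfg A [sim_config()].
#' @return A [gene_tree()] with branch lengths but no genomes.
#' @export
random_tree <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  topo <- random_topology(cfg$leaves)
  ne <- nrow(topo$edges)
  if (cfg$model == "uniform") {
    lo <- cfg$rate_per_edge * cfg$n * (1 - cfg$fluctuation)
    hi <- cfg$rate_per_edge * cfg$n * (1 + cfg$fluctuation)
    lens <- runif(ne, lo, hi)
  } else {
    lens <- rexp(ne)
    tr0 <- gene_tree(topo$edges, lens, topo$labels, topo$is_leaf)
    dia <- max(leaf_distances(tr0))
    lens <- lens * (cfg$diameter * cfg$n) / dia
  }
  gene_tree(topo$edges, lens, topo$labels, topo$is_leaf,
            root = cfg$leaves + 1L)
}

#' Evolve genomes along a tree by inversions
#'
#' The traversal root receives the identity genome; along each branch,
#' \code{round(branch length)} inversions with uniformly drawn endpoints
#' are applied to the parent's genome. All node genomes are recorded.
#'
#' @param tree A [gene_tree()] with branch lengths (expected events).
#' @param cfg A [sim_config()] (supplies \code{n}).
#' @return Object of class \code{"sim_dataset"}: \code{tree} (with every
#'   genome filled in), \code{events} (realized inversion count per edge,
#'   ordered as \code{tree$edges}), \code{root}, \code{cfg}.
#' @export
evolve <- function(tree, cfg) {
  n <- cfg$n
  ro <- if (!is.na(tree$root)) tree$root else tree_internal_nodes(tree)[1L]
  tt <- tree_traversal(tree, ro)
  tree$genomes[[ro]] <- genome(seq_len(n), name = tree$labels[ro])
  events <- numeric(length(tree$labels))
  for (v in tt$order[-1L]) {
    k <- round(tt$plen[v])
    g <- tree$genomes[[tt$parent[v]]]
    if (k > 0) {
      for (s in seq_len(k)) {
        ij <- sort(sample.int(n, 2L, replace = TRUE))
        g <- apply_inversion(g, ij[1L], ij[2L])
      }
    }
    g$name <- tree$labels[v]
    tree$genomes[[v]] <- g
    events[v] <- k
  }
  edge_events <- integer(nrow(tree$edges))
  for (e in seq_len(nrow(tree$edges))) {
    a <- tree$edges[e, 1L]; b <- tree$edges[e, 2L]
    child <- if (tt$parent[b] == a) b else a
    edge_events[e] <- events[child]
  }
  structure(list(tree = tree, events = edge_events, root = ro, cfg = cfg),
            class = "sim_dataset")
}

#' Simulate a full benchmark dataset
#'
#' Draws a tree with [random_tree()] and evolves genomes with [evolve()]
#' under one seed.
#'
#' @param cfg A [sim_config()].
#' @return A \code{"sim_dataset"}.
#' @export
simulate_dataset <- function(cfg) {
  tr <- random_tree(cfg)   # sets the seed when cfg$seed is given
  evolve(tr, cfg)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<simulated dataset: %d genes, %d leaves, %s model, %d total events>\n",
              x$cfg$n, x$cfg$leaves, x$cfg$model, sum(x$events)))
  invisible(x)
}

#' Observable part of a simulated dataset
#'
#' Returns the tree with internal genomes removed — what an inference
#' method is allowed to see (leaf genomes, topology, branch lengths).
#'
#' @param ds A \code{"sim_dataset"}.
#' @return A [gene_tree()].
#' @export
observed_tree <- function(ds) {
  tr <- ds$tree
  tr$genomes[tree_internal_nodes(tr)] <- list(NULL)
  tr
}

#' True internal genomes of a simulated dataset
#'
#' @param ds A \code{"sim_dataset"}.
#' @return Named list of [genome()]s, one per internal node label.
#' @export
true_ancestors <- function(ds) {
  iv <- tree_internal_nodes(ds$tree)
  setNames(ds$tree$genomes[iv], ds$tree$labels[iv])
}
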