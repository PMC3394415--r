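# Likelihood stage: posterior probability of every candidate gene
# adjacency at a target internal node, from a two-state (present/absent)
# Markov model of adjacency evolution, followed by greedy assembly of the
# maximum-probability circular genome.
#
# Model: one inversion on a circular n-gene genome breaks 2 of its n
# adjacencies, so a present adjacency survives one event with probability
# 1 - 2/n; an absent adjacency is created with the matching stationary
# gain (2/n)/(2n-3), i.e. a freed extremity picks its new partner
# uniformly. Closing the two-state chain over t expected events per branch
# (t need not be an integer) gives
#   P(present -> present) = pi + (1 - pi) * g^t
#   P(absent  -> present) = pi * (1 - g^t)
# with g = 1 - 2/n - (2/n)/(2n-3) and stationary prior pi = 1/(2n-2).
# Both required limits hold: t = 0 is the identity and t -> Inf relaxes
# every adjacency to the prior. Adjacencies are treated independently in
# the recursion; their dependence (each extremity has exactly one partner)
# enters only at assembly.

adjacency_transition <- function(t, n) {
  a <- 2 / n
  b <- a / (2 * n - 3)
  pi0 <- 1 / (2 * n - 2)
  g <- (1 - a - b)^max(t, 1e-8)
  list(pp = pi0 + (1 - pi0) * g, ap = pi0 * (1 - g), prior = pi0)
}

#' Posterior probabilities of gene adjacencies at an internal node
#'
#' Re-roots the tree at the target node and runs, for every adjacency
#' observed in at least one leaf, a two-state pruning recursion from the
#' leaves up: each leaf contributes an indicator of whether it carries the
#' adjacency, each branch the transition probabilities of the adjacency
#' evolution model, and the root combines the likelihood with the
#' stationary prior. Unobserved adjacencies implicitly sit at the prior
#' \code{1/(2n-2)}.
#'
#' @param tree A [gene_tree()] whose leaves carry genomes and whose branch
#'   lengths are expected rearrangement events.
#' @param target Internal node label or id.
#' @return Data frame (class \code{"adjacency_posteriors"}) with columns
#'   \code{u}, \code{v}, \code{posterior}; attributes \code{n},
#'   \code{prior}, \code{target}.
#' @export
adjacency_posteriors <- function(tree, target) {
  tree <- reroot(tree, target)
  lv <- tree_leaves(tree)
  gs <- tree$genomes[lv]
  if (any(vapply(gs, is.null, TRUE))) stop("every leaf needs a genome")
  n <- length(gs[[1L]]$genes)
  lm <- lapply(gs, function(g) adjacency_matching(g$genes))
  names(lm) <- as.character(lv)

  pairs <- unique(do.call(rbind, lapply(lm, matching_to_pairs)))
  cu <- pairs[, 1L]; cv <- pairs[, 2L]
  m <- nrow(pairs)

  tt <- tree_traversal(tree, tree$root)
  nn <- length(tree$labels)
  L <- vector("list", nn)
  for (v in rev(tt$order)) {
    if (tree$is_leaf[v]) {
      pres <- lm[[as.character(v)]][cu] == cv
      L[[v]] <- cbind(as.numeric(pres), as.numeric(!pres))
    } else {
      kids <- tt$order[tt$parent[tt$order] == v & tt$order != tree$root]
      M <- matrix(1, m, 2L)
      for (k in kids) {
        tr <- adjacency_transition(tt$plen[k], n)
        Lk <- L[[k]]
        M <- M * cbind(tr$pp * Lk[, 1L] + (1 - tr$pp) * Lk[, 2L],
                       tr$ap * Lk[, 1L] + (1 - tr$ap) * Lk[, 2L])
      }
      M <- M / pmax(M[, 1L] + M[, 2L], 1e-300)
      L[[v]] <- M
      L[kids] <- list(NULL)
    }
  }
  pi0 <- 1 / (2 * n - 2)
  Lr <- L[[tree$root]]
  post <- pi0 * Lr[, 1L] / pmax(pi0 * Lr[, 1L] + (1 - pi0) * Lr[, 2L], 1e-300)
  out <- data.frame(u = cu, v = cv, posterior = post)
  attr(out, "n") <- n
  attr(out, "prior") <- pi0
  attr(out, "target") <- tree$labels[tree$root]
  class(out) <- c("adjacency_posteriors", "data.frame")
  out
}

#' Assemble the maximum-probability circular genome from posteriors
#'
#' Greedy maximum-weight matching: candidate adjacencies are visited by
#' decreasing posterior (ties by vertex ids); one is accepted when both
#' extremities are still free and accepting it would not close a circular
#' chromosome before all genes are linked (the final edge is exempt).
#' Should the explicit candidates run out first, assembly continues over
#' the implicit ones: every adjacency absent from all leaves carries the
#' same stationary prior, so the greedy rule there reduces to joining the
#' remaining path ends lowest-id-first.
#'
#' @param posteriors An [adjacency_posteriors()] data frame (or any data
#'   frame with columns \code{u}, \code{v}, \code{posterior}).
#' @param n Gene count.
#' @return A single circular [genome()].
#' @export
assemble_ml_genome <- function(posteriors, n) {
  u <- as.integer(posteriors$u); v <- as.integer(posteriors$v)
  p <- as.numeric(posteriors$posterior)
  ord <- order(-p, u, v)
  n2 <- 2L * n
  oend <- integer(n2)
  oend[seq(1L, n2, 2L)] <- seq(2L, n2, 2L)
  oend[seq(2L, n2, 2L)] <- seq(1L, n2, 2L)
  used <- logical(n2)
  med <- integer(n2)
  chosen <- 0L
  take <- function(a, b) {
    e1 <- oend[a]; e2 <- oend[b]
    oend[e1] <<- e2; oend[e2] <<- e1
    used[c(a, b)] <<- TRUE
    med[a] <<- b; med[b] <<- a
    chosen <<- chosen + 1L
  }
  for (i in ord) {
    if (chosen == n) break
    a <- u[i]; b <- v[i]
    if (used[a] || used[b]) next
    if (oend[a] == b && chosen < n - 1L) next
    take(a, b)
  }
  if (chosen == n - 1L) {
    # single open path left: its closure is the unique valid completion
    free <- which(!used)
    take(free[1L], free[2L])
  }
  if (chosen < n) {
    # remaining pairs all sit at the prior: greedy = lowest-id pairing
    while (chosen < n) {
      free <- which(!used)
      a <- free[1L]
      b <- free[free != a & (oend[a] != free | chosen == n - 1L)][1L]
      take(a, b)
    }
  }
  genome_of(med, n)
}

#' Maximum-likelihood ancestral genome at one internal node
#'
#' Convenience wrapper: [adjacency_posteriors()] followed by
#' [assemble_ml_genome()].
#'
#' @inheritParams adjacency_posteriors
#' @return \code{list(genome =, posteriors =)}.
#' @export
ml_ancestral <- function(tree, target) {
  post <- adjacency_posteriors(tree, target)
  list(genome = assemble_ml_genome(post, attr(post, "n")), posteriors = post)
}
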