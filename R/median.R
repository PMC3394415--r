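# Three-genome DCJ median: user-facing wrapper around the compiled branch
# and bound, plus the exhaustive enumeration oracle used in tests.

validate_fixed <- function(fixed, n) {
  if (is.null(fixed) || length(fixed) == 0L) {
    return(matrix(integer(0L), 0L, 2L))
  }
  fixed <- matrix(as.integer(fixed), ncol = 2L)
  if (any(fixed < 1L) || any(fixed > 2L * n)) {
    stop("fixed adjacency vertex out of range")
  }
  verts <- as.vector(t(fixed))
  if (anyDuplicated(verts)) {
    stop("fixed adjacencies are incompatible: vertex reused")
  }
  if (any((fixed[, 1L] + 1L) %/% 2L == (fixed[, 2L] + 1L) %/% 2L)) {
    stop("cannot fix the two extremities of one gene")
  }
  fixed
}

#' Solve the three-genome DCJ median problem
#'
#' Finds a circular genome minimizing the summed DCJ distance to three
#' input genomes, by branch and bound on the multiple breakpoint graph.
#' Adequate subgraphs (vertex pairs joined by parallel genome edges) are
#' committed without branching; adjacencies supplied in \code{fixed} are
#' first forced into every matching by edge surgery, constraining the
#' search to medians that contain them.
#'
#' @param g1,g2,g3 [genome()] objects (or signed vectors) over one gene set.
#' @param fixed Optional two-column matrix of extremity-vertex pairs (see
#'   [gene_pair_adjacency()]) forced into the median; must form a partial
#'   matching.
#' @param budget Branch-and-bound node limit; when exhausted the best
#'   median found so far is returned with \code{optimal = FALSE}.
#' @param adequate Eager-commitment policy for adequate pairs:
#'   \code{"pairs"} commits every >= 2-parallel pair (default),
#'   \code{"triples"} only 3-parallel pairs, \code{"off"} none (pure
#'   branch and bound; parallel edges still steer the branching order).
#' @return Object of class \code{"median_result"}: \code{median} (genome),
#'   \code{score} (summed DCJ distance to the three inputs), \code{cycles}
#'   (\code{3n - score}), \code{optimal}, \code{nodes}.
#' @examples
#' res <- solve_median(c(1, 2, 3), c(1, 2, -3), c(1, 3, 2))
#' res$median$genes  # 1 2 3
#' @export
solve_median <- function(g1, g2, g3, fixed = NULL, budget = 1e7,
                         adequate = c("pairs", "triples", "off")) {
  adequate <- match.arg(adequate)
  gs <- lapply(list(g1, g2, g3), as_genome)
  n <- length(gs[[1L]]$genes)
  if (any(vapply(gs, function(g) length(g$genes), 0L) != n)) {
    stop("genomes are over different gene sets")
  }
  ms <- lapply(gs, function(g) adjacency_matching(g$genes))
  fixed <- validate_fixed(fixed, n)
  mode <- c(off = 0L, triples = 1L, pairs = 2L)[[adequate]]
  res <- .median_bb(ms[[1L]], ms[[2L]], ms[[3L]], fixed, budget, mode)
  med <- genome_of(res$match, n)
  score <- sum(vapply(gs, function(g) dcj_distance(g, med), 0L))
  structure(list(median = med, score = score, cycles = 3L * n - score,
                 optimal = res$optimal, nodes = res$nodes),
            class = "median_result")
}

#' @export
print.median_result <- function(x, ...) {
  cat(sprintf("<median: score %d (%s), %g nodes>\n", x$score,
              if (x$optimal) "optimal" else "budget exhausted", x$nodes))
  print(x$median)
  invisible(x)
}

# all permutations of a vector (rows), lexicographic in input order
all_perms <- function(x) {
  if (length(x) <= 1L) return(matrix(x, nrow = 1L))
  do.call(rbind, lapply(seq_along(x), function(i) {
    cbind(x[i], all_perms(x[-i]), deparse.level = 0L)
  }))
}

# every circular signed genome on n genes, one canonical writing per row
all_circular_genomes <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  per <- all_perms(2:n)
  sg <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n - 1L)))
  k <- nrow(per) * nrow(sg)
  out <- matrix(1L, k, n)
  r <- 1L
  for (i in seq_len(nrow(per))) {
    for (j in seq_len(nrow(sg))) {
      out[r, 2:n] <- per[i, ] * sg[j, ]
      r <- r + 1L
    }
  }
  out
}

#' Exhaustive three-genome median (test oracle)
#'
#' Enumerates every circular signed genome on \code{n <= 6} genes and
#' scores it directly; independent of the branch-and-bound path.
#'
#' @inheritParams solve_median
#' @param all Also return every optimal median (list of genomes).
#' @return A \code{"median_result"}; with \code{all = TRUE} it carries an
#'   \code{all_medians} list.
#' @export
brute_force_median <- function(g1, g2, g3, all = FALSE) {
  gs <- lapply(list(g1, g2, g3), as_genome)
  n <- length(gs[[1L]]$genes)
  if (n > 6L) stop("exhaustive enumeration refused for n > 6")
  if (any(vapply(gs, function(g) length(g$genes), 0L) != n)) {
    stop("genomes are over different gene sets")
  }
  cand <- all_circular_genomes(n)
  cm <- t(apply(cand, 1L, adjacency_matching))
  ms <- lapply(gs, function(g) adjacency_matching(g$genes))
  cyc <- .score_matchings(cm, ms[[1L]], ms[[2L]], ms[[3L]])
  scores <- 3L * n - cyc
  ties <- which(scores == min(scores))
  # same deterministic tie order as the branch and bound: canonically
  # smallest genome (positive orientation preferred at the first difference)
  keys <- 2L * abs(cand[ties, , drop = FALSE]) + (cand[ties, , drop = FALSE] < 0L)
  i <- ties[do.call(order, as.data.frame(keys))[1L]]
  out <- structure(list(median = genome(cand[i, ]),
                        score = scores[i], cycles = cyc[i],
                        optimal = TRUE, nodes = nrow(cand)),
                   class = "median_result")
  if (all) {
    out$all_medians <- lapply(which(scores == scores[i]),
                              function(k) genome(cand[k, ]))
  }
  out
}
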