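# Signed circular genomes and their breakpoint-graph encoding.
#
# Gene i owns two extremity vertices: tail 2i-1 and head 2i. Reading +i
# enters at the tail and exits at the head; -i the other way round. An
# adjacency joins the exit vertex of one gene to the entry vertex of the
# next, so a circular genome of n genes is exactly a perfect matching on
# the 2n extremities:
#   i  followed by  j  -> edge (2i,   2j-1)
#   i  followed by -j  -> edge (2i,   2j)
#  -i  followed by  j  -> edge (2i-1, 2j-1)
#  -i  followed by -j  -> edge (2i-1, 2j)
# with the wrap-around adjacency from the last gene back to the first.

validate_genes <- function(genes) {
  if (length(genes) == 0L) stop("a genome needs at least one gene")
  if (anyNA(genes) || any(genes == 0L)) {
    stop("gene identifiers must be nonzero integers")
  }
  n <- length(genes)
  tab <- tabulate(abs(genes), nbins = max(abs(genes)))
  if (any(tab > 1L)) {
    dup <- which(tab > 1L)[1L]
    stop(sprintf("gene %d appears %d times", dup, tab[dup]))
  }
  if (max(abs(genes)) != n) {
    mis <- which(tab == 0L)[1L]
    stop(sprintf("gene %d is missing", mis))
  }
  invisible(genes)
}

#' Construct a signed circular genome
#'
#' A genome over the gene set \code{1..n} is an ordering of the genes in
#' which each gene carries an orientation (its sign). Only circular
#' unichromosomal genomes are supported: the written order is understood to
#' close back on itself, so any rotation, and the full reversal with all
#' signs flipped, denote the same molecule.
#'
#' @param genes Integer vector of signed gene identifiers; each of
#'   \code{1..n} must appear exactly once (in absolute value).
#' @param name Optional text label.
#' @param canonical If \code{TRUE}, store the canonical writing: rotated so
#'   gene 1 comes first, flipped so it reads forward.
#' @return An object of class \code{"genome"}.
#' @examples
#' g <- genome(c(1, 4, 2, -3, 5))
#' adjacencies_of(g)
#' @seealso [adjacencies_of()], [genome_of()], [apply_inversion()],
#'   [dcj_distance()]
#' @export
genome <- function(genes, name = "", canonical = FALSE) {
  genes <- as.integer(genes)
  validate_genes(genes)
  if (canonical) genes <- canonical_genes(genes)
  structure(list(name = as.character(name)[1L], genes = genes,
                 circular = TRUE),
            class = "genome")
}

as_genome <- function(x) {
  if (inherits(x, "genome")) x else genome(x)
}

#' @export
print.genome <- function(x, ...) {
  nm <- if (nzchar(x$name)) paste0(" '", x$name, "'") else ""
  cat(sprintf("<circular genome%s, %d genes>\n", nm, length(x$genes)))
  cat(paste(x$genes, collapse = " "), "\n")
  invisible(x)
}

# Canonical writing of a circular signed gene order: rotate gene 1 to the
# front; if it reads backwards, reverse-and-negate (same circle read the
# other way round) and rotate again.
canonical_genes <- function(genes) {
  n <- length(genes)
  p <- which(abs(genes) == 1L)
  if (p > 1L) genes <- genes[c(p:n, seq_len(p - 1L))]
  if (genes[1L] < 0L) {
    genes <- -rev(genes)
    genes <- genes[c(n, seq_len(n - 1L))]
  }
  genes
}

#' Canonical form of a genome
#'
#' @param g A [genome()].
#' @return The same genome rewritten canonically (gene 1 first, forward).
#' @export
canonical_genome <- function(g) {
  g <- as_genome(g)
  g$genes <- canonical_genes(g$genes)
  g
}

#' Test whether two circular genomes denote the same molecule
#'
#' @param a,b [genome()] objects (or signed vectors).
#' @return Logical.
#' @export
genomes_equal <- function(a, b) {
  identical(canonical_genes(as_genome(a)$genes),
            canonical_genes(as_genome(b)$genes))
}

# Perfect matching on {1..2n} induced by the gene order: m[u] is the
# partner of extremity u.
adjacency_matching <- function(genes) {
  n <- length(genes)
  exit <- ifelse(genes > 0L, 2L * genes, -2L * genes - 1L)
  entry <- ifelse(genes > 0L, 2L * genes - 1L, -2L * genes)
  u <- exit
  v <- entry[c(seq_len(n)[-1L], 1L)]
  m <- integer(2L * n)
  m[u] <- v
  m[v] <- u
  m
}

matching_to_pairs <- function(m) {
  u <- which(seq_along(m) < m & m > 0L)
  cbind(u = u, v = m[u])
}

pairs_to_matching <- function(pairs, n) {
  m <- integer(2L * n)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs < 1L) || any(pairs > 2L * n)) {
    stop("adjacency vertex out of range")
  }
  for (r in seq_len(nrow(pairs))) {
    u <- pairs[r, 1L]; v <- pairs[r, 2L]
    if (u == v) stop("an adjacency cannot join a vertex to itself")
    if (m[u] != 0L || m[v] != 0L) stop("vertex used by more than one adjacency")
    m[u] <- v; m[v] <- u
  }
  m
}

#' Adjacency set (breakpoint-graph edges) of a genome
#'
#' Gene \code{i} contributes extremity vertices \code{2i-1} (tail) and
#' \code{2i} (head); each immediate neighbour pair of genes in the circular
#' order contributes one edge between the facing extremities. The n edges
#' form a perfect matching on \code{1..2n}.
#'
#' @param genome A [genome()] or signed integer vector.
#' @return Integer matrix with columns \code{u}, \code{v} (one row per
#'   adjacency, \code{u < v}).
#' @examples
#' adjacencies_of(genome(c(1, 4, 2, -3, 5)))
#' @export
adjacencies_of <- function(genome) {
  g <- as_genome(genome)
  matching_to_pairs(adjacency_matching(g$genes))
}

# Decompose a perfect matching on 2n extremities into circular
# chromosomes; returns a list of signed gene vectors.
decompose_matching <- function(m) {
  n2 <- length(m)
  visited <- logical(n2)
  cycles <- list()
  for (s in seq_len(n2)) {
    if (visited[s] || m[s] == 0L) next
    genes <- integer(0L)
    v <- s
    repeat {
      gi <- (v + 1L) %/% 2L
      if (v %% 2L == 1L) {        # entered at tail: read forward
        genes <- c(genes, gi)
        ex <- v + 1L
      } else {                    # entered at head: read backward
        genes <- c(genes, -gi)
        ex <- v - 1L
      }
      visited[v] <- TRUE
      visited[ex] <- TRUE
      v <- m[ex]
      if (v == s) break
    }
    cycles[[length(cycles) + 1L]] <- genes
  }
  cycles
}

#' Reconstruct a genome from a set of adjacencies
#'
#' Inverse of [adjacencies_of()]. The matching is traversed alternately
#' along gene extremity pairs and adjacency edges; a valid single circular
#' genome corresponds to one cycle covering all genes.
#'
#' @param edges Either a two-column vertex-pair matrix or a matching vector
#'   of length \code{2n} (\code{edges[u]} = partner of \code{u}).
#' @param n Gene count.
#' @param multiple What to do when the matching decomposes into more than
#'   one circular chromosome: \code{"error"} (default) or \code{"list"},
#'   which returns \code{list(n_cycles=, cycles=)} with one signed gene
#'   vector per chromosome.
#' @return A canonical [genome()] (single cycle), or the multi-cycle report.
#' @export
genome_of <- function(edges, n, multiple = c("error", "list")) {
  multiple <- match.arg(multiple)
  if (is.matrix(edges)) {
    m <- pairs_to_matching(edges, n)
  } else {
    m <- as.integer(edges)
    if (length(m) != 2L * n) stop("matching vector must have length 2n")
  }
  if (any(m == 0L)) stop("not a perfect matching: unmatched vertex")
  if (any(m[m] != seq_along(m))) stop("not a valid matching")
  cyc <- decompose_matching(m)
  if (length(cyc) == 1L) {
    return(genome(canonical_genes(cyc[[1L]])))
  }
  if (multiple == "error") {
    stop(sprintf("matching decomposes into %d circular chromosomes",
                 length(cyc)))
  }
  list(n_cycles = length(cyc), cycles = cyc)
}

#' Apply an inversion to a genome
#'
#' Reverses the segment between positions \code{i} and \code{j} of the
#' current writing and flips its signs, transforming \code{1,2,...,n} into
#' \code{1,...,i-1,-j,...,-i,j+1,...,n}.
#'
#' @param genome A [genome()].
#' @param i,j Positions with \code{1 <= i <= j <= n}.
#' @return The rearranged genome.
#' @export
apply_inversion <- function(genome, i, j) {
  g <- as_genome(genome)
  n <- length(g$genes)
  if (i < 1L || j > n || i > j) stop("inversion positions out of range")
  g$genes[i:j] <- -rev(g$genes[i:j])
  g
}

# Alternating cycles in the union of two perfect matchings on the same
# vertex set.
count_cycles <- function(ma, mb) {
  visited <- logical(length(ma))
  cc <- 0L
  for (s in seq_along(ma)) {
    if (visited[s]) next
    cc <- cc + 1L
    v <- s
    repeat {
      visited[v] <- TRUE
      w <- ma[v]
      visited[w] <- TRUE
      v <- mb[w]
      if (v == s) break
    }
  }
  cc
}

#' DCJ (cycle) distance between two genomes
#'
#' \code{d = n - c}, where \code{c} is the number of alternating cycles in
#' the union of the two genomes' adjacency matchings. For circular genomes
#' this is the minimum number of double-cut-and-join operations needed to
#' transform one into the other; a single inversion is one such operation.
#'
#' @param a,b [genome()] objects over the same gene set.
#' @return Nonnegative integer distance.
#' @examples
#' dcj_distance(genome(1:3), genome(c(1, 2, -3)))  # 1
#' @export
dcj_distance <- function(a, b) {
  a <- as_genome(a); b <- as_genome(b)
  if (length(a$genes) != length(b$genes)) {
    stop("genomes are over different gene sets")
  }
  n <- length(a$genes)
  n - count_cycles(adjacency_matching(a$genes), adjacency_matching(b$genes))
}

#' Draw a uniform random signed circular genome
#'
#' @param n Gene count.
#' @param canonical Return the canonical writing (default TRUE).
#' @return A [genome()].
#' @export
random_genome <- function(n, canonical = TRUE) {
  genes <- sample.int(n) * sample(c(1L, -1L), n, replace = TRUE)
  genome(genes, canonical = canonical)
}

#' Encode a signed gene pair as an adjacency
#'
#' \code{gene_pair_adjacency(a, b)} is the extremity pair for "\code{a}
#' immediately followed by \code{b}" in reading order, e.g. \code{3, -5}
#' joins the head of gene 3 to the head of gene 5.
#'
#' @param a,b Signed gene identifiers.
#' @return Length-2 integer vector of extremity vertices.
#' @export
gene_pair_adjacency <- function(a, b) {
  u <- if (a > 0L) 2L * a else -2L * a - 1L
  v <- if (b > 0L) 2L * b - 1L else -2L * b
  c(as.integer(u), as.integer(v))
}
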