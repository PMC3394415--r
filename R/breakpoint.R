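# Multiple breakpoint graphs: three (or more) perfect matchings on a
# shared extremity vertex set. The median solver's state; the R-level
# operations here (adequate-pair detection, shrinking, adjacency fixing)
# mirror the compiled search's preprocessing and are used directly by the
# tests and the public API.

#' Build a multiple breakpoint graph
#'
#' Superimposes the adjacency matchings of three or more genomes on the
#' shared vertex set \code{1..2n}.
#'
#' @param x List of [genome()] objects (or signed gene vectors), or — with
#'   \code{type = "matchings"} — a list of matching vectors of length
#'   \code{2n} (\code{m[u]} = partner of vertex \code{u}).
#' @param type Whether \code{x} holds genomes or raw matchings.
#' @return Object of class \code{"mbg"} with fields \code{n},
#'   \code{matchings} and an \code{active} vertex mask (vertices removed by
#'   [shrink_mbg()] become inactive).
#' @examples
#' m <- mbg(list(c(1, 2, 3), c(1, 2, -3), c(1, 3, 2)))
#' detect_adequate_pairs(m)
#' @export
mbg <- function(x, type = c("genomes", "matchings")) {
  if (inherits(x, "mbg")) return(x)
  type <- match.arg(type)
  stopifnot(is.list(x), length(x) >= 3L)
  if (type == "matchings") {
    ms <- lapply(x, as.integer)
    for (m in ms) {
      if (any(m < 1L) || any(m[m] != seq_along(m)) || any(m == seq_along(m))) {
        stop("not a valid perfect matching")
      }
    }
  } else {
    ms <- lapply(x, function(g) adjacency_matching(as_genome(g)$genes))
  }
  n2 <- length(ms[[1L]])
  if (n2 %% 2L || any(lengths(ms) != n2)) {
    stop("matchings must share one even-sized vertex set")
  }
  structure(list(n = n2 %/% 2L, matchings = ms, active = rep(TRUE, n2)),
            class = "mbg")
}

#' @export
print.mbg <- function(x, ...) {
  cat(sprintf("<multiple breakpoint graph: %d genes, %d matchings, %d active vertices>\n",
              x$n, length(x$matchings), sum(x$active)))
  invisible(x)
}

# multiplicity of edge (u,v) across the matchings
edge_multiplicity <- function(x, u, v) {
  sum(vapply(x$matchings, function(m) m[u] == v, TRUE))
}

#' Detect size-2 adequate subgraphs of an MBG
#'
#' A vertex pair \code{{u, v}} joined by at least two parallel genome edges
#' is an adequate subgraph of the smallest kind: choosing median edge
#' \code{(u, v)} immediately closes at least 2 >= 3/2 alternating cycles,
#' so some optimal median contains it and the pair can be shrunk away.
#' Pairs sharing a vertex are resolved greedily by descending multiplicity,
#' ties by lowest vertex id.
#'
#' @param x An [mbg()] (or list of genomes).
#' @return Integer matrix of vertex-disjoint pairs (columns \code{u},
#'   \code{v}), zero rows when none exist.
#' @export
detect_adequate_pairs <- function(x) {
  x <- mbg(x)
  act <- x$active
  ed <- do.call(rbind, lapply(x$matchings, function(m) {
    u <- which(act & seq_along(m) < m & m > 0L)
    cbind(u, m[u])
  }))
  empty <- matrix(integer(0L), 0L, 2L, dimnames = list(NULL, c("u", "v")))
  if (is.null(ed) || nrow(ed) == 0L) return(empty)
  key <- (ed[, 1L] - 1L) * (2L * x$n) + ed[, 2L]
  cnt <- table(key)
  keep <- as.integer(names(cnt))[cnt >= 2L]
  if (!length(keep)) return(empty)
  u <- (keep - 1L) %/% (2L * x$n) + 1L
  v <- keep - (u - 1L) * (2L * x$n)
  mult <- as.integer(cnt[as.character(keep)])
  ord <- order(-mult, u, v)
  used <- logical(2L * x$n)
  sel <- ord[vapply(ord, function(i) {
    ok <- !used[u[i]] && !used[v[i]]
    if (ok) used[c(u[i], v[i])] <<- TRUE
    ok
  }, TRUE)]
  cbind(u = u[sel], v = v[sel])
}

#' Shrink one median edge out of an MBG
#'
#' Commits edge \code{(u, v)} to the median: every matching that contains
#' it is credited one closed alternating cycle and loses the edge; every
#' other matching has its edges \code{(u, a)}, \code{(v, b)} rewired to
#' \code{(a, b)}. Vertices \code{u} and \code{v} leave the vertex set.
#'
#' @param x An [mbg()].
#' @param edge Length-2 vertex pair.
#' @return \code{list(mbg =, cycles_gained =)}.
#' @export
shrink_mbg <- function(x, edge) {
  x <- mbg(x)
  u <- as.integer(edge[1L]); v <- as.integer(edge[2L])
  if (u == v) stop("cannot shrink a self-loop")
  if (!x$active[u] || !x$active[v]) {
    stop("edge endpoints absent from the current vertex set")
  }
  gained <- 0L
  for (g in seq_along(x$matchings)) {
    m <- x$matchings[[g]]
    if (m[u] == v) {
      gained <- gained + 1L
    } else {
      a <- m[u]; b <- m[v]
      m[a] <- b; m[b] <- a
    }
    m[u] <- 0L; m[v] <- 0L
    x$matchings[[g]] <- m
  }
  x$active[c(u, v)] <- FALSE
  list(mbg = x, cycles_gained = gained)
}

#' Force an adjacency into every matching of an MBG
#'
#' Edge surgery that makes \code{{i, j}} an adequate pair: matchings
#' already containing edge \code{(i, j)} are untouched; in every other
#' matching the incident edges \code{(i, a)} and \code{(j, b)} are removed
#' and \code{(i, j)}, \code{(a, b)} created. Afterwards all genome edges
#' at \code{i} and \code{j} are parallel, so any median search on the
#' modified graph must contain \code{(i, j)}.
#'
#' @param x An [mbg()].
#' @param adj Length-2 vertex pair; must not be the two extremities of one
#'   gene.
#' @return The modified [mbg()].
#' @export
fix_adjacency <- function(x, adj) {
  x <- mbg(x)
  i <- as.integer(adj[1L]); j <- as.integer(adj[2L])
  if (i == j) stop("cannot fix a self-loop")
  if ((i + 1L) %/% 2L == (j + 1L) %/% 2L) {
    stop("cannot fix the two extremities of one gene (would force a 1-gene circle)")
  }
  if (!x$active[i] || !x$active[j]) stop("adjacency endpoints absent")
  for (g in seq_along(x$matchings)) {
    m <- x$matchings[[g]]
    if (m[i] == j) next
    a <- m[i]; b <- m[j]
    m[i] <- j; m[j] <- i
    m[a] <- b; m[b] <- a
    x$matchings[[g]] <- m
  }
  x
}
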