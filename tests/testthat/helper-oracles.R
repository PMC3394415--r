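# Independent test oracles, kept deliberately naive.

adj_matching <- function(g) medianmix:::adjacency_matching(as_genome(g)$genes)
as_genome <- medianmix:::as_genome

# Minimum number of DCJ operations between two genomes, by breadth-first
# search over perfect matchings: one operation replaces edges (p,q),(r,s)
# by (p,r),(q,s) or (p,s),(q,r). Multichromosomal intermediates allowed.
bfs_dcj <- function(a, b) {
  ma <- adj_matching(a); mb <- adj_matching(b)
  key <- function(m) paste(m, collapse = ",")
  target <- key(mb)
  if (key(ma) == target) return(0L)
  seen <- new.env(hash = TRUE)
  assign(key(ma), TRUE, envir = seen)
  frontier <- list(ma)
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- list()
    for (m in frontier) {
      us <- which(seq_along(m) < m)
      ne <- length(us)
      for (i in seq_len(ne - 1L)) {
        for (j in (i + 1L):ne) {
          p <- us[i]; q <- m[p]; r <- us[j]; s <- m[r]
          for (w in 1:2) {
            m2 <- m
            if (w == 1L) { m2[p] <- r; m2[r] <- p; m2[q] <- s; m2[s] <- q }
            else         { m2[p] <- s; m2[s] <- p; m2[q] <- r; m2[r] <- q }
            k2 <- key(m2)
            if (k2 == target) return(d)
            if (!exists(k2, envir = seen, inherits = FALSE)) {
              assign(k2, TRUE, envir = seen)
              nxt[[length(nxt) + 1L]] <- m2
            }
          }
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) stop("BFS exhausted without reaching target")
  }
}

# hand-built star-like tree with four leaves carrying given genomes
quartet_tree <- function(genomes, lens = rep(1, 5)) {
  # leaves 1..4, internal 5 (joins 1,2) and 6 (joins 3,4)
  gene_tree(edges = rbind(c(5, 1), c(5, 2), c(5, 6), c(6, 3), c(6, 4)),
            lengths = lens,
            labels = c("a", "b", "c", "d", "X", "Y"),
            is_leaf = c(rep(TRUE, 4), FALSE, FALSE),
            genomes = c(genomes, list(NULL, NULL)))
}

# total log-probability of a genome under a posterior table (prior for
# adjacencies outside the table), used by the assembly quality check
genome_logprob <- function(g, post, n) {
  m <- adj_matching(g)
  u <- which(seq_along(m) < m)
  key <- (u - 1L) * 2L * n + m[u]
  pkey <- (pmin(post$u, post$v) - 1L) * 2L * n + pmax(post$u, post$v)
  p <- post$posterior[match(key, pkey)]
  p[is.na(p)] <- 1 / (2 * n - 2)
  sum(log(pmax(p, 1e-12)))
}
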