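# The mixture stage: repeatedly fix random subsets of the
# likelihood-proposed adjacencies in constrained median searches, count
# how often each non-fixed adjacency reappears in the median output, fix
# the best-supported fraction in a final constrained median, and sweep the
# whole tree until its score converges.

#' Mixture configuration
#'
#' @param fix_fraction Fraction of the likelihood genome's adjacencies
#'   randomly fixed in each replicate median (midpoint of the tested
#'   70--75\% range).
#' @param selection_percentage Fraction of adjacencies, ranked by
#'   occurrence, fixed in the final median. \code{NULL} (default) lets
#'   [run_experiment()] choose 0.70 for closely related genomes (per-edge
#'   rate <= 24\% of n, or tree diameter <= 3) and 0.75 otherwise;
#'   standalone calls fall back to 0.70. Values outside the tested
#'   0.65--0.85 band trigger a warning.
#' @param replicates Number of randomized median replicates; around 100
#'   the occurrence ranking reaches a steady state.
#' @param high_prob_threshold Adjacencies whose posterior exceeds this are
#'   treated as correct and fixed in every replicate.
#' @param seed Optional random seed (top-level entry points apply it once).
#' @param node_budget Branch-and-bound node limit per median call.
#' @param max_sweeps Tree-refinement sweep limit.
#' @param rank_once Rank each node's adjacencies only in the first sweep
#'   and reuse the table afterwards (cheaper variant).
#' @return A list of class \code{"mixture_config"}.
#' @export
mixture_config <- function(fix_fraction = 0.72, selection_percentage = NULL,
                           replicates = 100L, high_prob_threshold = 0.90,
                           seed = NULL, node_budget = 1e6,
                           max_sweeps = 20L, rank_once = FALSE) {
  stopifnot(fix_fraction >= 0, fix_fraction <= 1, replicates >= 1L,
            high_prob_threshold >= 0, high_prob_threshold <= 1,
            node_budget > 0, max_sweeps >= 1L)
  if (!is.null(selection_percentage)) {
    stopifnot(selection_percentage >= 0, selection_percentage <= 1)
    if (selection_percentage < 0.65 || selection_percentage > 0.85) {
      warning("selection percentage outside the tested 0.65-0.85 range")
    }
  }
  structure(list(fix_fraction = fix_fraction,
                 selection_percentage = selection_percentage,
                 replicates = as.integer(replicates),
                 high_prob_threshold = high_prob_threshold,
                 seed = seed, node_budget = node_budget,
                 max_sweeps = as.integer(max_sweeps),
                 rank_once = isTRUE(rank_once)),
            class = "mixture_config")
}

# posterior of each adjacency of `pairs` under `posteriors` (0 if absent)
lookup_posterior <- function(pairs, posteriors, n) {
  key <- (pmin(pairs[, 1L], pairs[, 2L]) - 1L) * 2L * n +
    pmax(pairs[, 1L], pairs[, 2L])
  pkey <- (pmin(posteriors$u, posteriors$v) - 1L) * 2L * n +
    pmax(posteriors$u, posteriors$v)
  p <- posteriors$posterior[match(key, pkey)]
  p[is.na(p)] <- 0
  p
}

#' Rank likelihood-proposed adjacencies by recurrence in random medians
#'
#' Runs \code{replicates} constrained median computations of the target
#' node against its three neighbour genomes. In each replicate the
#' high-posterior adjacencies are always fixed, plus a uniform random
#' sample of the remaining likelihood-genome adjacencies up to
#' \code{round(fix_fraction * n)} in total; every likelihood adjacency
#' left unfixed is eligible, and its count increments when the median
#' output contains it.
#'
#' @param neighbors List of three [genome()]s (the target's neighbours:
#'   leaves or current internal estimates).
#' @param ml_genome The likelihood-assembled ancestral [genome()] whose
#'   adjacencies are being screened.
#' @param posteriors An [adjacency_posteriors()] table for the target.
#' @param cfg A [mixture_config()]; \code{cfg$seed}, when set, is applied
#'   once at entry.
#' @return Data frame of class \code{"occurrence_table"}: columns
#'   \code{u}, \code{v}, \code{posterior}, \code{count}, \code{eligible};
#'   attributes \code{n} and \code{budget_exhausted} (replicate count
#'   whose median search hit the node budget).
#' @export
rank_adjacencies <- function(neighbors, ml_genome, posteriors, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  stopifnot(length(neighbors) == 3L)
  ml_genome <- as_genome(ml_genome)
  n <- length(ml_genome$genes)
  mladj <- adjacencies_of(ml_genome)
  mlpost <- lookup_posterior(mladj, posteriors, n)
  quota <- min(round(cfg$fix_fraction * n), n - 1L)
  always <- which(mlpost > cfg$high_prob_threshold)
  if (length(always) > quota) {
    # the fixed set per replicate is always the configured fraction; keep
    # the highest-posterior ones when the threshold over-selects
    always <- always[order(-mlpost[always])][seq_len(quota)]
  }
  counts <- integer(n)
  eligible <- integer(n)
  nonopt <- 0L
  pool <- setdiff(seq_len(n), always)
  k_extra <- quota - length(always)
  for (r in seq_len(cfg$replicates)) {
    fix_idx <- c(always, pool[sample.int(length(pool), k_extra)])
    res <- solve_median(neighbors[[1L]], neighbors[[2L]], neighbors[[3L]],
                        fixed = mladj[fix_idx, , drop = FALSE],
                        budget = cfg$node_budget)
    if (!res$optimal) nonopt <- nonopt + 1L
    mm <- adjacency_matching(res$median$genes)
    free <- setdiff(seq_len(n), fix_idx)
    eligible[free] <- eligible[free] + 1L
    hit <- mm[mladj[free, 1L]] == mladj[free, 2L]
    counts[free[hit]] <- counts[free[hit]] + 1L
  }
  out <- data.frame(u = mladj[, 1L], v = mladj[, 2L], posterior = mlpost,
                    count = counts, eligible = eligible)
  attr(out, "n") <- n
  attr(out, "budget_exhausted") <- nonopt
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Fix the best-supported adjacencies and solve the final median
#'
#' Sorts the likelihood adjacencies by occurrence rate
#' \code{count/eligible} (always-fixed adjacencies, never eligible, rank
#' at rate 1; ties broken by posterior, then vertex ids), walks down the
#' list keeping the top \code{round(selection_percentage * n)} mutually
#' compatible ones, and solves the median of the three neighbours with
#' that set fixed.
#'
#' @param table An \code{"occurrence_table"} from [rank_adjacencies()].
#' @param cfg A [mixture_config()]; a \code{NULL} selection percentage
#'   falls back to 0.70 here.
#' @param neighbors List of three [genome()]s.
#' @return A \code{"median_result"} with the fixed adjacency matrix
#'   attached as \code{$fixed}.
#' @export
select_and_finalize <- function(table, cfg, neighbors) {
  n <- attr(table, "n")
  sel <- cfg$selection_percentage
  if (is.null(sel)) sel <- 0.70
  rate <- ifelse(table$eligible > 0L, table$count / table$eligible, 1)
  ord <- order(-rate, -table$posterior, table$u, table$v)
  k <- min(round(sel * n), n)
  used <- logical(2L * n)
  pick <- integer(0L)
  for (i in ord) {
    if (length(pick) == k) break
    a <- table$u[i]; b <- table$v[i]
    if (used[a] || used[b]) next
    used[c(a, b)] <- TRUE
    pick <- c(pick, i)
  }
  fixed <- cbind(table$u[pick], table$v[pick])
  res <- solve_median(neighbors[[1L]], neighbors[[2L]], neighbors[[3L]],
                      fixed = fixed, budget = cfg$node_budget)
  res$fixed <- fixed
  res
}

# local score of node v against its current neighbour genomes
local_score <- function(tree, v) {
  sum(vapply(tree$adj[[v]], function(w) {
    dcj_distance(tree$genomes[[v]], tree$genomes[[w]])
  }, 0L))
}

#' Infer all ancestral genomes by iterative tree refinement
#'
#' Every internal node is initialized with its likelihood-assembled
#' genome; sweeps then revisit each internal node and recompute its genome
#' as a (constrained, for the mixture method) median of its three current
#' neighbour genomes, accepting the update when the local median score
#' does not increase. Sweeps stop when the tree score (summed DCJ distance
#' over all branches) no longer decreases.
#'
#' @param tree A [gene_tree()] with genomes at the leaves and branch
#'   lengths in expected events.
#' @param cfg A [mixture_config()]; \code{cfg$seed}, when set, is applied
#'   once at entry.
#' @param method \code{"mixture"} (randomized adjacency fixing, the
#'   default), \code{"median"} (unconstrained medians — direct
#'   optimization), or \code{"ml"} (stop after the likelihood stage).
#' @return \code{list(genomes =, tree_score =, sweeps =, converged =)}
#'   with \code{genomes} a named list over internal node labels.
#' @export
refine_tree <- function(tree, cfg = mixture_config(),
                        method = c("mixture", "median", "ml")) {
  method <- match.arg(method)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg$seed <- NULL                       # RNG stream now owned by this call
  iv <- tree_internal_nodes(tree)
  post <- vector("list", length(tree$labels))
  mlg <- vector("list", length(tree$labels))
  for (v in iv) {
    post[[v]] <- adjacency_posteriors(tree, v)
    mlg[[v]] <- assemble_ml_genome(post[[v]], attr(post[[v]], "n"))
    tree$genomes[[v]] <- mlg[[v]]
  }
  result <- function(score, sweeps, converged) {
    list(genomes = setNames(tree$genomes[iv], tree$labels[iv]),
         tree_score = score, sweeps = sweeps, converged = converged)
  }
  if (method == "ml") return(result(tree_score(tree), 0L, TRUE))

  tables <- vector("list", length(tree$labels))
  score <- tree_score(tree)
  converged <- FALSE
  sweeps <- 0L
  for (sweep in seq_len(cfg$max_sweeps)) {
    sweeps <- sweep
    for (v in iv) {
      nbrs <- tree$genomes[tree$adj[[v]]]
      if (method == "median") {
        res <- solve_median(nbrs[[1L]], nbrs[[2L]], nbrs[[3L]],
                            budget = cfg$node_budget)
      } else {
        if (is.null(tables[[v]]) || !cfg$rank_once) {
          tables[[v]] <- rank_adjacencies(nbrs, mlg[[v]], post[[v]], cfg)
        }
        res <- select_and_finalize(tables[[v]], cfg, nbrs)
      }
      if (res$score <= local_score(tree, v)) {
        res$median$name <- tree$labels[v]
        tree$genomes[[v]] <- res$median
      }
    }
    new_score <- tree_score(tree)
    if (new_score >= score) { converged <- TRUE; break }
    score <- new_score
  }
  result(score, sweeps, converged)
}
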