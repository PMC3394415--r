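fig2 <- list(c(1, 2, 3), c(1, 2, -3), c(1, 3, 2))

test_that("median solver reproduces the worked example and trivial cases", {
  res <- solve_median(fig2[[1]], fig2[[2]], fig2[[3]])
  expect_equal(res$median$genes, c(1, 2, 3))
  expect_equal(res$score, 3)
  expect_true(res$optimal)

  g <- random_genome(8)
  res <- solve_median(g, g, g)
  expect_equal(res$score, 0)
  expect_true(genomes_equal(res$median, g))

  bf <- brute_force_median(fig2[[1]], fig2[[2]], fig2[[3]])
  expect_equal(bf$median$genes, c(1, 2, 3))
  expect_equal(bf$score, 3)
  expect_error(brute_force_median(genome(1:7), genome(1:7), genome(1:7)),
               "refused")
})

test_that("branch and bound matches exhaustive enumeration", {
  set.seed(10)
  for (i in 1:60) {
    gs <- replicate(3, random_genome(5), simplify = FALSE)
    bf <- brute_force_median(gs[[1]], gs[[2]], gs[[3]])
    for (mode in c("pairs", "triples", "off")) {
      s <- solve_median(gs[[1]], gs[[2]], gs[[3]], adequate = mode)
      expect_true(s$optimal)
      expect_equal(s$score, bf$score)
      # returned median is a valid genome achieving the claimed score
      expect_equal(sum(vapply(gs, dcj_distance, 0L, b = s$median)), s$score)
    }
  }
  for (i in 1:10) {
    gs <- replicate(3, random_genome(6), simplify = FALSE)
    expect_equal(solve_median(gs[[1]], gs[[2]], gs[[3]])$score,
                 brute_force_median(gs[[1]], gs[[2]], gs[[3]])$score)
  }
})

test_that("fixed adjacencies constrain the search correctly", {
  set.seed(11)
  for (i in 1:25) {
    gs <- replicate(3, random_genome(5), simplify = FALSE)
    bf <- brute_force_median(gs[[1]], gs[[2]], gs[[3]], all = TRUE)
    opt_adj <- adjacencies_of(bf$median)

    # fixing one adjacency of an optimal median keeps the optimum
    s1 <- solve_median(gs[[1]], gs[[2]], gs[[3]],
                       fixed = opt_adj[sample(5, 1), , drop = FALSE])
    expect_equal(s1$score, bf$score)

    # fixing all its adjacencies returns exactly that median
    sall <- solve_median(gs[[1]], gs[[2]], gs[[3]], fixed = opt_adj)
    expect_equal(sall$score, bf$score)
    expect_true(genomes_equal(sall$median, bf$median))

    # an adjacency in no optimal median can only raise the score
    all_opt_match <- vapply(bf$all_medians, adj_matching, integer(10))
    # pick a pair absent from every optimal median (if any exists)
    found <- NULL
    for (u in 1:9) for (v in (u + 1):10) {
      if ((u + 1) %/% 2 == (v + 1) %/% 2) next
      if (!any(all_opt_match[u, ] == v)) { found <- c(u, v); break }
    }
    if (!is.null(found)) {
      s2 <- solve_median(gs[[1]], gs[[2]], gs[[3]],
                         fixed = matrix(found, 1))
      expect_gte(s2$score, bf$score)
    }
  }

  # monotone: more constraints never help
  set.seed(12)
  for (i in 1:15) {
    gs <- replicate(3, random_genome(6), simplify = FALSE)
    f2 <- adjacencies_of(random_genome(6))[1:2, ]
    s1 <- solve_median(gs[[1]], gs[[2]], gs[[3]], fixed = f2[1, , drop = FALSE])
    s2 <- solve_median(gs[[1]], gs[[2]], gs[[3]], fixed = f2)
    expect_gte(s2$score, s1$score)
  }

  expect_error(solve_median(fig2[[1]], fig2[[2]], fig2[[3]],
                            fixed = rbind(c(1, 4), c(4, 6))),
               "vertex reused")
  expect_error(solve_median(fig2[[1]], fig2[[2]], fig2[[3]],
                            fixed = rbind(c(3, 4))),
               "extremities of one gene")
})

test_that("node budget returns a valid best-so-far flagged non-optimal", {
  set.seed(13)
  gs <- replicate(3, random_genome(30), simplify = FALSE)
  s <- solve_median(gs[[1]], gs[[2]], gs[[3]], budget = 500, adequate = "off")
  expect_false(s$optimal)
  expect_equal(length(s$median$genes), 30)
  expect_equal(sum(vapply(gs, dcj_distance, 0L, b = s$median)), s$score)
})
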