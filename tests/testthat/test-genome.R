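test_that("breakpoint-graph encoding follows the extremity rules", {
  # worked circular example: 1,4,2,-3,5
  e <- adjacencies_of(genome(c(1, 4, 2, -3, 5)))
  want <- rbind(c(1, 10), c(2, 7), c(3, 8), c(4, 6), c(5, 9))
  expect_equal(e[order(e[, 1]), ], want, ignore_attr = TRUE)

  # identity genome: (2,3),(4,5),...,(2n,1)
  n <- 7
  e <- adjacencies_of(genome(seq_len(n)))
  want <- cbind(c(1, seq(2, 2 * n - 2, 2)), c(2 * n, seq(3, 2 * n - 1, 2)))
  expect_equal(e[order(e[, 1]), ], want[order(want[, 1]), ],
               ignore_attr = TRUE)

  # mixed signs, derived by the four rules: 1,2,-3 -> (2,3),(4,6),(5,1)
  e <- adjacencies_of(genome(c(1, 2, -3)))
  expect_equal(e[order(e[, 1]), ], rbind(c(1, 5), c(2, 3), c(4, 6)),
               ignore_attr = TRUE)

  # validation names the offending gene
  expect_error(genome(c(1, 2, 2)), "gene 2 appears 2 times")
  expect_error(genome(c(1, 2, 4)), "gene 3 is missing")
  expect_error(genome(c(1, 0, 2)), "nonzero")
})

test_that("genome reconstruction inverts adjacency extraction", {
  g <- genome_of(rbind(c(10, 1), c(2, 7), c(3, 8), c(4, 6), c(5, 9)), 5)
  expect_true(genomes_equal(g, c(1, 4, 2, -3, 5)))

  set.seed(1)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    g <- random_genome(n)
    expect_true(genomes_equal(genome_of(adjacencies_of(g), n), g))
  }

  # matching that decomposes into several circular chromosomes
  rep3 <- genome_of(rbind(c(2, 1), c(4, 3), c(6, 5)), 3, multiple = "list")
  expect_equal(rep3$n_cycles, 3)
  expect_error(genome_of(rbind(c(2, 1), c(4, 3), c(6, 5)), 3),
               "3 circular chromosomes")

  # every valid genome yields a perfect matching (degree exactly 1)
  set.seed(2)
  for (i in 1:50) {
    m <- medianmix:::adjacency_matching(random_genome(sample(3:25, 1))$genes)
    expect_true(all(m[m] == seq_along(m)) && all(m != seq_along(m)))
  }
})

test_that("inversions follow the signed-reversal formula", {
  expect_equal(apply_inversion(genome(1:5), 3, 5)$genes, c(1, 2, -5, -4, -3))
  g <- genome(c(2, -4, 1, 3))
  expect_equal(apply_inversion(g, 2, 2)$genes, c(2, 4, 1, 3))
  # full reversal of a circular genome is the same molecule
  expect_true(genomes_equal(apply_inversion(genome(1:3), 1, 3), 1:3))
  expect_error(apply_inversion(genome(1:5), 0, 2), "out of range")
  expect_error(apply_inversion(genome(1:5), 4, 6), "out of range")

  # an inversion moves a genome by at most one DCJ step
  set.seed(3)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    g <- random_genome(n)
    ij <- sort(sample.int(n, 2, replace = TRUE))
    h <- apply_inversion(g, ij[1], ij[2])
    d <- dcj_distance(g, h)
    expect_lte(d, 1)
    if (!genomes_equal(g, h)) expect_equal(d, 1)
  }
})

test_that("DCJ distance is the cycle distance and behaves as a metric", {
  expect_equal(dcj_distance(genome(1:3), genome(1:3)), 0)
  expect_equal(dcj_distance(genome(1:3), genome(c(1, 2, -3))), 1)
  expect_error(dcj_distance(genome(1:3), genome(1:4)), "different gene sets")

  set.seed(4)
  for (i in 1:60) {
    n <- sample(4:6, 1)
    a <- random_genome(n); b <- random_genome(n); c3 <- random_genome(n)
    dab <- dcj_distance(a, b)
    expect_equal(dab, dcj_distance(b, a))
    expect_lte(dab, n - 1)
    expect_lte(dab, dcj_distance(a, c3) + dcj_distance(c3, b))
    expect_equal(dcj_distance(a, a), 0)
  }
})

test_that("formula distance equals the breadth-first-search DCJ oracle", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(4:5, 1)
    a <- random_genome(n); b <- random_genome(n)
    expect_equal(dcj_distance(a, b), bfs_dcj(a, b))
  }
})

test_that("canonical form identifies rotations and reflections", {
  g <- c(1, -4, 3, -2)
  rot <- c(3, -2, 1, -4)
  refl <- -rev(g)
  expect_true(genomes_equal(g, rot))
  expect_true(genomes_equal(g, refl))
  expect_equal(canonical_genome(genome(c(-3, -2, -1)))$genes, c(1, 2, 3))
  expect_false(genomes_equal(g, c(1, 4, 3, -2)))
})
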