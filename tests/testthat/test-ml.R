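test_that("no-evolution limit: posteriors are indicators of the shared genome", {
  g <- genome(c(1, -3, 2, 5, -4))
  tr <- quartet_tree(list(g, g, g, g), lens = rep(0, 5))
  post <- adjacency_posteriors(tr, "X")
  m <- adj_matching(g)
  pres <- m[post$u] == post$v
  expect_true(all(post$posterior[pres] > 1 - 1e-6))
  expect_true(all(post$posterior[!pres] < 1e-6))
  expect_true(genomes_equal(assemble_ml_genome(post, 5), g))
})

test_that("an adjacency in every leaf outranks one in a single leaf", {
  g <- genome(1:6)
  h <- apply_inversion(g, 2, 3)   # breaks (2,3) and (6,7), creates (2,6),(3,7)
  tr <- quartet_tree(list(g, g, g, h), lens = rep(0.5, 5))
  post <- adjacency_posteriors(tr, "X")
  p_all <- post$posterior[post$u == 8 & post$v == 9]    # adjacency in all 4
  p_one <- post$posterior[post$u == 2 & post$v == 6]    # adjacency in h only
  expect_gt(p_all, p_one)
  expect_gt(p_all, 0.5)
})

test_that("infinite-branch limit relaxes every posterior to the prior", {
  n <- 10
  set.seed(16)
  gs <- replicate(4, random_genome(n), simplify = FALSE)
  tr <- quartet_tree(gs, lens = rep(50 * n, 5))
  post <- adjacency_posteriors(tr, "X")
  expect_true(all(abs(post$posterior - 1 / (2 * n - 2)) < 1e-3))
})

test_that("assembly is greedy, cycle-safe and always yields one circle", {
  # indicator posteriors reproduce the genome
  g <- genome(c(2, -1, 4, 3, -5))
  adj <- adjacencies_of(g)
  post <- data.frame(u = adj[, 1], v = adj[, 2], posterior = 1)
  expect_true(genomes_equal(assemble_ml_genome(post, 5), g))

  # a premature two-gene circle ranked on top must be skipped
  post <- data.frame(u = c(2, 1, 4, 6, 8),
                     v = c(3, 4, 5, 7, 1),
                     posterior = c(0.99, 0.98, 0.9, 0.8, 0.7))
  out <- assemble_ml_genome(post, 4)
  m <- adj_matching(out)
  expect_equal(m[2], 3)
  expect_false(m[1] == 4)   # (1,4) would have closed genes {1,2} early
  expect_s3_class(out, "genome")

  # arbitrary posterior tables still produce a valid single circle
  set.seed(17)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    k <- sample(n:(3 * n), 1)
    u <- sample(2 * n, k, replace = TRUE)
    v <- sample(2 * n, k, replace = TRUE)
    keep <- u != v & (u + 1) %/% 2 != (v + 1) %/% 2
    post <- data.frame(u = pmin(u, v)[keep], v = pmax(u, v)[keep],
                       posterior = runif(sum(keep)))
    out <- assemble_ml_genome(post, n)
    expect_s3_class(out, "genome")
    expect_equal(sort(abs(out$genes)), 1:n)
  }
})

test_that("assembled genome beats random genomes in total log-probability", {
  set.seed(18)
  cfg <- sim_config(n = 8, leaves = 6, rate_per_edge = 0.15, seed = 18)
  ds <- simulate_dataset(cfg)
  post <- adjacency_posteriors(observed_tree(ds), "A1")
  g <- assemble_ml_genome(post, 8)
  lp <- genome_logprob(g, post, 8)
  rand_lp <- replicate(1000, genome_logprob(random_genome(8), post, 8))
  expect_true(all(lp >= rand_lp))
})

test_that("posteriors recover true ancestral adjacencies at low rates", {
  cfg <- sim_config(n = 50, leaves = 10, rate_per_edge = 0.05, seed = 19)
  ds <- simulate_dataset(cfg)
  truth <- true_ancestors(ds)
  ok <- vapply(c("A1", "A3"), function(nm) {
    post <- adjacency_posteriors(observed_tree(ds), nm)
    topn <- head(order(-post$posterior), 50)
    mt <- adj_matching(truth[[nm]])
    mean(mt[post$u[topn]] == post$v[topn])
  }, 0.0)
  expect_true(all(ok >= 0.9))
})

test_that("posteriors commute with gene relabeling", {
  set.seed(20)
  n <- 8
  gs <- replicate(4, random_genome(n), simplify = FALSE)
  tr <- quartet_tree(gs, lens = c(2, 3, 1, 2, 4))
  post <- adjacency_posteriors(tr, "X")

  # relabel genes by a permutation (orientation preserved)
  sig <- sample.int(n)
  vmap <- integer(2 * n)
  vmap[2 * (1:n) - 1] <- 2 * sig - 1
  vmap[2 * (1:n)] <- 2 * sig
  relab <- function(g) genome(sign(g$genes) * sig[abs(g$genes)])
  tr2 <- quartet_tree(lapply(gs, relab), lens = c(2, 3, 1, 2, 4))
  post2 <- adjacency_posteriors(tr2, "X")

  k1 <- paste(pmin(vmap[post$u], vmap[post$v]),
              pmax(vmap[post$u], vmap[post$v]))
  k2 <- paste(post2$u, post2$v)
  expect_setequal(k1, k2)
  expect_equal(post2$posterior[match(k1, k2)], post$posterior,
               tolerance = 1e-12)
})
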