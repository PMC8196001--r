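chain_data <- function(n = 2000, seed = 1) {
  set.seed(seed)
  z <- rbinom(n, 2, 0.49)
  x <- 0.6 * z + rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.9 * x))
  data.frame(z = z, x = x, y = y)
}

chain_specs <- node_specs(c("z", "x", "y"),
                          c("gaussian", "gaussian", "bernoulli"),
                          no_parents = "z")

test_that("gaussian node score equals the closed-form normal likelihood minus penalty", {
  set.seed(21)
  n <- 400
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  sp <- node_specs(c("a", "b"), "gaussian")
  s <- node_score("a", character(0), d, sp)
  sigma2 <- mean((d$a - mean(d$a))^2) # MLE variance
  ll <- sum(dnorm(d$a, mean(d$a), sqrt(sigma2), log = TRUE))
  expect_equal(as.numeric(s), ll - (2 / 2) * log(n), tolerance = 1e-10)
  expect_equal(attr(s, "k"), 2)
})

test_that("adding an independent parent lowers the BIC score almost always", {
  worse <- vapply(1:100, function(r) {
    set.seed(3000 + r)
    d <- data.frame(a = rnorm(500), junk = rnorm(500))
    sp <- node_specs(c("a", "junk"), "gaussian")
    as.numeric(node_score("a", "junk", d, sp)) <
      as.numeric(node_score("a", character(0), d, sp))
  }, logical(1))
  expect_gte(sum(worse), 90)
})

test_that("a duplicated parent is flagged collinear and does not change the score", {
  set.seed(31)
  d <- data.frame(a = rnorm(300), p = rnorm(300))
  d$p2 <- d$p
  sp <- node_specs(c("a", "p", "p2"), "gaussian")
  s1 <- node_score("a", "p", d, sp)
  s2 <- node_score("a", c("p", "p2"), d, sp)
  expect_equal(as.numeric(s2), as.numeric(s1), tolerance = 1e-10)
  expect_match(attr(s2, "flag"), "collinear")
  expect_error(node_score("a", "a", d, sp), "own parent")
})

test_that("perfect separation in a logistic node yields a finite flagged score", {
  d <- data.frame(y = rep(c(0, 1), each = 30),
                  x = c(rnorm(30, -5), rnorm(30, 5)))
  sp <- node_specs(c("y", "x"), c("bernoulli", "gaussian"))
  s <- node_score("y", "x", d, sp)
  expect_true(is.finite(as.numeric(s)))
  expect_match(attr(s, "flag"), "separation")
})

test_that("independent nodes yield the empty network in most searches", {
  set.seed(41)
  d <- data.frame(a = rnorm(1000), b = rnorm(1000),
                  c = rbinom(1000, 1, 0.4))
  sp <- node_specs(c("a", "b", "c"),
                   c("gaussian", "gaussian", "bernoulli"))
  cache <- new.env(parent = emptyenv())
  empty <- vapply(1:100, function(s) {
    res <- search_once(d, sp, seed = s, cache = cache)
    sum(res$adj) == 0
  }, logical(1))
  expect_gte(sum(empty), 90)
})

test_that("strongly linked nodes are always connected (either orientation)", {
  set.seed(51)
  n <- 800
  a <- rnorm(n)
  d <- data.frame(a = a, b = 0.9 * a + rnorm(n, 0, sqrt(1 - 0.81)))
  sp <- node_specs(c("a", "b"), "gaussian")
  cache <- new.env(parent = emptyenv())
  for (s in 1:20) {
    res <- search_once(d, sp, seed = s, cache = cache)
    expect_true(res$adj["a", "b"] || res$adj["b", "a"])
  }
})

test_that("single-node data give the empty network", {
  d <- data.frame(a = rnorm(50))
  sp <- node_specs("a", "gaussian")
  res <- search_once(d, sp, seed = 1)
  expect_equal(sum(res$adj), 0)
})

test_that("every returned structure is acyclic, respects constraints and beats the empty DAG", {
  d <- chain_data(n = 600, seed = 61)
  cache <- new.env(parent = emptyenv())
  empty_score <- sum(vapply(c("z", "x", "y"), function(nd)
    as.numeric(node_score(nd, character(0), d, chain_specs)), numeric(1)))
  for (s in 1:15) {
    res <- search_once(d, chain_specs, seed = s, cache = cache)
    expect_true(bilicausal:::.is_acyclic(res$adj))
    expect_equal(sum(res$adj[, "z"]), 0) # genotype node stays parentless
    expect_gte(res$score, empty_score)
  }
})

test_that("consensus thresholds nest and a single search is its own consensus", {
  d <- chain_data(n = 500, seed = 71)
  net_half <- consensus(d, chain_specs, n_searches = 30, threshold = 0.5,
                        seed = 3)
  net_full <- consensus(d, chain_specs, n_searches = 30, threshold = 1.0,
                        seed = 3)
  e_half <- net_half$edge_freq[net_half$edge_freq$consensus,
                               c("from", "to")]
  e_full <- net_full$edge_freq[net_full$edge_freq$consensus,
                               c("from", "to")]
  expect_true(all(paste(e_full$from, e_full$to) %in%
                    paste(e_half$from, e_half$to)))
  one <- consensus(d, chain_specs, n_searches = 1, seed = 9)
  single <- search_once(d, chain_specs, seed = 10)
  expect_equal(one$consensus, single$adj)
})

test_that("the consensus network recovers the variant -> exposure -> outcome chain", {
  d <- chain_data(n = 2000, seed = 81)
  net <- consensus(d, chain_specs, n_searches = 100, threshold = 0.5,
                   seed = 5)
  expect_true(net$consensus["z", "x"])
  expect_true(net$consensus["x", "y"])
  expect_false(net$consensus["z", "y"])
})
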