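two_cliques <- function() {
  pos <- t(utils::combn(paste0("p", 1:4), 2))
  neg <- t(utils::combn(paste0("n", 1:4), 2))
  edges <- data.frame(from = c(pos[, 1], neg[, 1]),
                      to = c(pos[, 2], neg[, 2]))
  val <- c(stats::setNames(rep("positive", 4), paste0("p", 1:4)),
           stats::setNames(rep("negative", 4), paste0("n", 1:4)))
  make_graph(edges, val)
}

bipartite_pm <- function(k = 3) {
  edges <- expand.grid(from = paste0("p", 1:k), to = paste0("n", 1:k),
                       stringsAsFactors = FALSE)
  val <- c(stats::setNames(rep("positive", k), paste0("p", 1:k)),
           stats::setNames(rep("negative", k), paste0("n", 1:k)))
  make_graph(edges, val)
}

test_that("attribute scores map to -m/0/+m and reject unknown labels", {
  expect_equal(unname(valence_scores(c("positive", "neutral", "negative"), 2)),
               c(2, 0, -2))
  expect_error(valence_scores("meh"), "unknown attribute")
  expect_error(valence_scores("positive", m = 0))
})

test_that("edge-endpoint tau hits +1/-1 on perfectly sorted graphs", {
  expect_equal(edge_endpoint_tau(two_cliques())$tau, 1)
  g <- bipartite_pm()
  res <- edge_endpoint_tau(g)
  # independent check on the symmetrized endpoint vectors
  s <- c(p1 = 1, p2 = 1, p3 = 1, n1 = -1, n2 = -1, n3 = -1)
  el <- igraph::as_edgelist(g)
  x <- s[c(el[, 1], el[, 2])]
  y <- s[c(el[, 2], el[, 1])]
  expect_equal(res$tau, oracle_tau(x, y))
  expect_equal(res$tau, -1)
})

test_that("edge tau is invariant to m, orientation, and edge order", {
  sim <- simulate_survey(survey_config(n_participants = 15, h = 0.6,
                                       seed = 81))
  fit <- forma_mentis(sim$associations, sim$ratings)
  g <- fit$graph
  t1 <- edge_endpoint_tau(g, m = 1)$tau
  expect_equal(edge_endpoint_tau(g, m = 7.5)$tau, t1)
  gp <- igraph::permute(g, sample(igraph::vcount(g)))
  class(gp) <- class(g)
  expect_equal(edge_endpoint_tau(gp)$tau, t1)
  expect_error(edge_endpoint_tau(make_graph(
    data.frame(from = c("a", "b"), to = c("b", "c")),
    c(a = "neutral", b = "neutral", c = "neutral"))), "one attribute")
})

test_that("node-neighborhood tau matches hand-built configurations", {
  expect_equal(node_neighborhood_tau(two_cliques())$tau, 1)
  # star: + center with - leaves -> perfect anti-alignment
  star <- make_graph(data.frame(from = rep("c", 4), to = paste0("l", 1:4)),
                     c(c = "positive",
                       stats::setNames(rep("negative", 4), paste0("l", 1:4))))
  res <- node_neighborhood_tau(star)
  x <- c(1, -1, -1, -1, -1)
  y <- c(-1, 1, 1, 1, 1)
  expect_equal(res$tau, oracle_tau(x, y))
  expect_equal(res$tau, -1)
})

test_that("random attributes give near-zero mixing on a fixed graph", {
  set.seed(82)
  base <- igraph::sample_gnm(300, 1200)
  igraph::V(base)$name <- paste0("w", 1:300)
  taus_e <- numeric(25)
  taus_n <- numeric(25)
  for (i in 1:25) {
    g <- igraph::set_vertex_attr(
      base, "valence",
      value = sample(c("positive", "neutral", "negative"), 300, TRUE))
    g <- igraph::set_vertex_attr(g, "rated", value = TRUE)
    class(g) <- c("fmn_graph", class(g))
    taus_e[i] <- edge_endpoint_tau(g)$tau
    taus_n[i] <- node_neighborhood_tau(g)$tau
  }
  expect_lt(abs(mean(taus_e)), 0.02)
  expect_lt(abs(mean(taus_n)), 0.03)
})

test_that("null ensembles preserve degrees and attributes and reproduce", {
  sim <- simulate_survey(survey_config(n_participants = 12, h = 0.7,
                                       seed = 83))
  fit <- forma_mentis(sim$associations, sim$ratings)
  g <- fit$graph
  null1 <- configuration_null_ensemble(g, "edge", n_realisations = 8,
                                       seed = 5)
  null2 <- configuration_null_ensemble(g, "edge", n_realisations = 8,
                                       seed = 5)
  expect_identical(null1$null_taus, null2$null_taus)
  null3 <- configuration_null_ensemble(g, "edge", n_realisations = 8,
                                       seed = 6)
  expect_false(identical(null1$null_taus, null3$null_taus))
  expect_equal(null1$n_realisations, 8L)
  expect_true(all(abs(null1$null_taus) <= 1))
  expect_equal(null1$percentile_of_observed,
               100 * mean(null1$null_taus < null1$tau_observed))
  expect_error(
    configuration_null_ensemble(make_graph(
      data.frame(from = "a", to = "b"),
      c(a = "positive", b = "negative"))),
    "too constrained")
})

test_that("aura contrasts compare target words against the any-aura group", {
  # negative words with a negative aura carry high arousal, the rest low
  k <- 8
  neg <- paste0("neg", 1:(2 * k))
  hubs <- c("hubneg", "hubpos")
  edges <- rbind(
    data.frame(from = "hubneg", to = neg[1:k]),
    data.frame(from = "hubpos", to = neg[(k + 1):(2 * k)]),
    data.frame(from = neg[1:k], to = rep("hubneg2", k)),
    data.frame(from = neg[(k + 1):(2 * k)], to = rep("hubpos2", k)))
  val <- c(stats::setNames(rep("negative", 2 * k), neg),
           hubneg = "negative", hubpos = "positive",
           hubneg2 = "negative", hubpos2 = "positive")
  g <- make_graph(unique(edges), val)
  # neg[1:k] have only negative neighbors; neg[k+1..] only positive ones
  norms <- data.frame(word = neg,
                      valence_mean = rep(2, 2 * k),
                      arousal_mean = c(rep(5, k), rep(1, k)))
  res <- aura_contrast(g, norms, "negative", "negative", measure = "arousal")
  expect_identical(res$direction, "A > B")
  expect_lt(res$p_value, 0.1)
  expect_equal(res$n_B, 2 * k)
  # identical measure values -> p = 1, no signal
  flat <- norms
  flat$arousal_mean <- 3
  res2 <- aura_contrast(g, flat, "negative", "negative", measure = "arousal")
  expect_equal(res2$p_value, 1)
  expect_identical(res2$direction, "none")
  # disjoint norms report zero overlap
  expect_error(aura_contrast(g, data.frame(word = "zzz", valence_mean = 1),
                             "negative", "negative"), "overlap 0")
})
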