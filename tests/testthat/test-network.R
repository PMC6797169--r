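test_that("edges count distinct participants, once per pair, no self-loops", {
  # same participant repeats an association: counted once
  f1 <- make_assoc("p1", "life", r1 = "sun", r2 = "joy", r3 = "sun")
  g1 <- build_network(f1)
  expect_equal(igraph::ecount(g1), 2)
  expect_true(all(igraph::E(g1)$weight == 1))
  # two participants sharing one association: weight 2
  f2 <- rbind(make_assoc("p1", "school", r1 = "study"),
              make_assoc("p2", "school", r1 = "study"))
  class(f2) <- c("fmn_associations", "data.frame")
  g2 <- build_network(f2)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::E(g2)$weight, 2L)
  # reverse orientation merges into the same undirected edge
  f3 <- rbind(make_assoc("p1", "a", r1 = "b"), make_assoc("p2", "b", r1 = "a"))
  class(f3) <- c("fmn_associations", "data.frame")
  expect_equal(igraph::E(build_network(f3))$weight, 2L)
  # response equal to its cue is skipped
  f4 <- make_assoc("p1", "echo", r1 = "echo", r2 = "other")
  g4 <- build_network(f4)
  expect_equal(igraph::ecount(g4), 1)
  expect_false(igraph::any_loop(g4))
})

test_that("network build is invariant to form order and bounded by responses", {
  sim <- simulate_survey(survey_config(n_participants = 12, seed = 51))
  forms <- sim$associations
  g <- build_network(forms)
  perm <- forms[sample(nrow(forms)), , drop = FALSE]
  class(perm) <- c("fmn_associations", "data.frame")
  g2 <- build_network(perm)
  el <- function(x) {
    e <- igraph::as_data_frame(x, "edges")
    e[order(e$from, e$to), ]
  }
  expect_equal(el(g), el(g2), ignore_attr = TRUE)
  n_responses <- sum(!is.na(forms$r1)) + sum(!is.na(forms$r2)) +
    sum(!is.na(forms$r3))
  expect_lte(sum(igraph::E(g)$weight), n_responses)
})

test_that("node attributes come from the lexicon, unrated words flagged neutral", {
  ratings <- make_ratings(rep(sprintf("p%02d", 1:20), 2),
                          rep(c("sun", "war"), each = 20),
                          c(rep(5, 20), rep(1, 20)))
  lex <- build_lexicon(ratings)
  forms <- make_assoc("p1", "sun", r1 = "war", r2 = "unseen")
  g <- build_network(forms, lex)
  v <- igraph::V(g)
  expect_identical(igraph::vertex_attr(g, "valence", "sun"), "positive")
  expect_identical(igraph::vertex_attr(g, "valence", "war"), "negative")
  expect_identical(igraph::vertex_attr(g, "valence", "unseen"), "neutral")
  expect_false(igraph::vertex_attr(g, "rated", "unseen"))
})

test_that("filtering keeps supported edges, drops isolates, and composes", {
  edges <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"))
  val <- c(a = "positive", b = "neutral", c = "negative", d = "neutral")
  g <- make_graph(edges, val, weights = c(1, 2, 3))
  expect_equal(igraph::ecount(filter_network(g, 1)), 3)
  f2 <- filter_network(g, 2)
  expect_equal(igraph::ecount(f2), 2)
  expect_false("a" %in% igraph::V(f2)$name)
  # threshold composition: filter(filter(g, a), b) == filter(g, max(a, b))
  f23 <- filter_network(f2, 3)
  f3 <- filter_network(g, 3)
  expect_equal(sort(igraph::V(f23)$name), sort(igraph::V(f3)$name))
  expect_equal(igraph::graph_attr(f23, "filter_level"), 3)
  # fully filtered-out network is allowed and flagged
  empty <- filter_network(make_graph(edges, val), 2)
  expect_equal(igraph::vcount(empty), 0)
  expect_true(igraph::graph_attr(empty, "empty"))
})

test_that("aura fractions and polarity follow the neighbor counts", {
  edges <- data.frame(from = rep("hub", 3), to = c("n1", "n2", "n3"))
  val <- c(hub = "neutral", n1 = "positive", n2 = "positive", n3 = "negative")
  g <- make_graph(edges, val)
  a <- compute_aura(g, "hub")
  expect_equal(a$frac_positive, 2 / 3)
  expect_equal(a$frac_negative, 1 / 3)
  expect_equal(a$frac_neutral, 0)
  expect_identical(a$aura, "positive")
  expect_equal(a$degree, 3)
  # positive/negative tie -> neutral even though no neutral neighbor exists
  tie <- make_graph(data.frame(from = c("x", "x"), to = c("p", "n")),
                    c(x = "neutral", p = "positive", n = "negative"))
  expect_identical(compute_aura(tie, "x")$aura, "neutral")
  # all-neutral neighborhood
  allneu <- make_graph(data.frame(from = "x", to = "y"),
                       c(x = "positive", y = "neutral"))
  expect_identical(compute_aura(allneu, "x")$aura, "neutral")
  expect_equal(compute_aura(allneu, "x")$frac_neutral, 1)
  expect_error(compute_aura(g, "ghost"), "not in network")
})

test_that("majority rule differs from polarity when neutral dominates", {
  edges <- data.frame(from = rep("w", 4), to = c("a", "b", "c", "d"))
  val <- c(w = "neutral", a = "neutral", b = "neutral", c = "positive",
           d = "negative")
  g <- make_graph(edges, val)
  expect_identical(compute_aura(g, "w", rule = "majority")$aura, "neutral")
  # polarity rule ties positive vs negative -> neutral here too
  expect_identical(compute_aura(g, "w", rule = "polarity")$aura, "neutral")
  skewed <- make_graph(
    data.frame(from = rep("w", 3), to = c("a", "b", "c")),
    c(w = "neutral", a = "neutral", b = "neutral", c = "positive"))
  expect_identical(compute_aura(skewed, "w", rule = "majority")$aura, "neutral")
  expect_identical(compute_aura(skewed, "w", rule = "polarity")$aura, "positive")
})

test_that("aura table rows sum to one and relabelling flips polarity", {
  sim <- simulate_survey(survey_config(n_participants = 10, seed = 61))
  fit <- forma_mentis(sim$associations, sim$ratings)
  tab <- aura_table(fit$graph)
  expect_equal(tab$frac_positive + tab$frac_neutral + tab$frac_negative,
               rep(1, nrow(tab)))
  # duplicate request yields duplicate identical rows
  two <- aura_table(fit$graph, rep(tab$word[1], 2))
  expect_equal(two[1, ], two[2, ], ignore_attr = TRUE)
  expect_error(aura_table(fit$graph, "not-a-word"), "not-a-word")
  # global + <-> - swap flips every non-neutral aura label
  g2 <- fit$graph
  swap <- c(positive = "negative", neutral = "neutral", negative = "positive")
  g2 <- igraph::set_vertex_attr(g2, "valence",
                                value = unname(swap[igraph::V(g2)$valence]))
  tab2 <- aura_table(g2, tab$word)
  expect_identical(tab2$aura, unname(swap[tab$aura]))
  expect_equal(tab2$frac_positive, tab$frac_negative)
})

test_that("exports round-trip exactly, including non-ASCII tokens", {
  edges <- data.frame(from = c("università", "università"),
                      to = c("perché", "studio"))
  val <- c("università" = "positive", "perché" = "neutral",
           studio = "negative")
  g <- make_graph(edges, val, weights = c(2, 1))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(g, gml, "graphml")
  back <- import_network(gml)
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  ord <- match(igraph::V(g)$name, igraph::V(back)$name)
  expect_identical(igraph::V(back)$valence[ord], igraph::V(g)$valence)
  expect_true(igraph::isomorphic(g, back))
  eid <- igraph::get_edge_ids(back, c("università", "perché"))
  expect_equal(igraph::E(back)$weight[eid], 2L)

  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".csv")
  export_network(g, ep, "edgelist")
  export_network(g, np, "nodes")
  back2 <- import_network(edge_path = ep, node_path = np)
  expect_setequal(igraph::V(back2)$name, igraph::V(g)$name)
  ord2 <- match(igraph::V(g)$name, igraph::V(back2)$name)
  expect_identical(igraph::V(back2)$valence[ord2], igraph::V(g)$valence)
  expect_true(igraph::isomorphic(g, back2))
})

test_that("empty and larger networks survive the export round trip", {
  sim <- simulate_survey(survey_config(n_participants = 15, seed = 71))
  fit <- forma_mentis(sim$associations, sim$ratings)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(fit$graph, gml, "graphml")
  back <- import_network(gml)
  expect_equal(igraph::vcount(back), igraph::vcount(fit$graph))
  expect_equal(igraph::ecount(back), igraph::ecount(fit$graph))
  ord <- match(igraph::V(fit$graph)$name, igraph::V(back)$name)
  expect_identical(igraph::V(back)$valence[ord], igraph::V(fit$graph)$valence)
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(fit$graph)$weight))
  # zero-edge network still exports a valid file
  empty <- filter_network(fit$graph, 10000)
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, gml2, "graphml")
  expect_equal(igraph::ecount(import_network(gml2)), 0)
})
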