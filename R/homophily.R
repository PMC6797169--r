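#' Numeric scores for valence attributes
#'
#' Maps attributes to arbitrary scores -m / 0 / +m (negative / neutral /
#' positive). Since the mixing statistics are rank-based, any m > 0 gives
#' identical correlations; m = 1 is the conventional choice.
#'
#' @param attributes character vector of `"positive"`, `"neutral"`,
#'   `"negative"`.
#' @param m positive scale of the score.
#' @return numeric vector of scores.
#' @export
valence_scores <- function(attributes, m = 1) {
  stopifnot(m > 0)
  ok <- attributes %in% c("positive", "neutral", "negative")
  if (!all(ok)) stop("unknown attribute: ", attributes[!ok][1])
  c(positive = m, neutral = 0, negative = -m)[attributes]
}

#' Edge-endpoint valence mixing (assortativity by Kendall tau)
#'
#' Measures emotional homophily across links: pairs the valence scores of
#' every edge's two endpoints and computes Kendall tau-b. Because edges
#' are undirected, each edge contributes both orientations by default
#' (symmetrization), which removes the arbitrary endpoint ordering; a
#' seeded single-orientation mode is available for sensitivity checks.
#' Edge weights are ignored: each unique association counts once
#' (`weighted = TRUE` replicates each edge by its weight).
#'
#' @param g an `fmn_graph`.
#' @param m score scale (any m > 0 gives the same tau).
#' @param symmetrize contribute both orientations per edge (default) or a
#'   single random orientation.
#' @param weighted replicate edges by weight.
#' @param seed RNG seed for the single-orientation mode.
#' @return list with `tau`, `p_value`, `n` (number of pairs).
#' @export
edge_endpoint_tau <- function(g, m = 1, symmetrize = TRUE, weighted = FALSE,
                              seed = NULL) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) < 2) stop("need at least 2 edges")
  s <- valence_scores(igraph::V(g)$valence, m)
  names(s) <- igraph::V(g)$name
  if (length(unique(igraph::V(g)$valence)) < 2) {
    stop("tau undefined: all nodes share one attribute")
  }
  rep_n <- if (weighted) igraph::E(g)$weight else rep(1L, nrow(el))
  a <- rep(el[, 1], rep_n)
  b <- rep(el[, 2], rep_n)
  if (symmetrize) {
    x <- s[c(a, b)]
    y <- s[c(b, a)]
  } else {
    if (!is.null(seed)) {
      flip <- with_seed(seed, stats::runif(length(a)) < 0.5)
    } else {
      flip <- stats::runif(length(a)) < 0.5
    }
    x <- s[ifelse(flip, b, a)]
    y <- s[ifelse(flip, a, b)]
  }
  kt <- kendall_tau(x, y, p_method = "normal")
  list(tau = kt$tau, p_value = kt$p_value, n = kt$n)
}

#' Node-neighborhood valence clustering (Kendall tau)
#'
#' Pairs each non-isolated node's own valence score with the unweighted
#' mean score of its neighbors and computes Kendall tau-b; a positive tau
#' indicates that words tend to sit in neighborhoods (auras) of their own
#' valence.
#'
#' @inheritParams edge_endpoint_tau
#' @return list with `tau`, `p_value`, `n` (number of nodes used).
#' @export
node_neighborhood_tau <- function(g, m = 1) {
  deg <- igraph::degree(g)
  use <- which(deg > 0)
  if (length(use) < 2) stop("need at least 2 non-isolated nodes")
  s <- valence_scores(igraph::V(g)$valence, m)
  if (length(unique(s[use])) < 2) {
    stop("tau undefined: all nodes share one attribute")
  }
  adj <- igraph::as_adj_list(g)
  nb_mean <- vapply(use, function(i) mean(s[as.integer(adj[[i]])]), 0)
  kt <- kendall_tau(s[use], nb_mean, p_method = "normal")
  list(tau = kt$tau, p_value = kt$p_value, n = length(use))
}

#' Attribute-preserving configuration-model null ensemble
#'
#' Compares an observed mixing statistic with its distribution under a
#' null model that fixes every node's degree and valence attribute but
#' randomizes which nodes are linked: each realisation rewires the simple
#' graph by degree-preserving double-edge swaps (10 x |E| swap trials per
#' realisation, swaps creating self-loops or multi-edges rejected) and
#' recomputes the statistic. The observed value's percentile among the
#' null taus is the recommended basis for inference; the mean of
#' per-realisation p-values is reported for completeness only.
#'
#' @param g an `fmn_graph` (simple, >= 2 edges).
#' @param statistic `"edge"` ([edge_endpoint_tau()]) or `"node"`
#'   ([node_neighborhood_tau()]).
#' @param n_realisations number of null networks.
#' @param seed integer seed; the ensemble is bit-reproducible given the
#'   seed.
#' @param swaps_per_edge swap trials per edge per realisation.
#' @param m score scale.
#' @param keep_graphs retain the rewired graphs in the result (element
#'   `realisations`; `NULL` otherwise).
#' @return object of class `fmn_null`: list with `statistic`,
#'   `tau_observed`, `p_observed`, `null_taus`, `null_mean`, `null_p_mean`,
#'   `percentile_of_observed` (percent of null taus strictly below the
#'   observed), `n_realisations`, `seed`.
#' @export
configuration_null_ensemble <- function(g, statistic = c("edge", "node"),
                                        n_realisations = 50L, seed = 1L,
                                        swaps_per_edge = 10L, m = 1,
                                        keep_graphs = FALSE) {
  statistic <- match.arg(statistic)
  ne <- igraph::ecount(g)
  if (ne < 2) stop("graph too constrained to rewire (fewer than 2 edges)")
  stat_fun <- switch(statistic,
                     edge = function(x) edge_endpoint_tau(x, m = m),
                     node = function(x) node_neighborhood_tau(x, m = m))
  obs <- stat_fun(g)
  null_taus <- numeric(n_realisations)
  null_ps <- numeric(n_realisations)
  graphs <- if (keep_graphs) vector("list", n_realisations)
  with_seed(seed, {
    for (i in seq_len(n_realisations)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                     niter = swaps_per_edge * ne))
      if (keep_graphs) graphs[[i]] <- gr
      r <- stat_fun(gr)
      null_taus[i] <- r$tau
      null_ps[i] <- r$p_value
    }
  })
  structure(list(statistic = statistic, tau_observed = obs$tau,
                 realisations = graphs,
                 p_observed = obs$p_value, null_taus = null_taus,
                 null_mean = mean(null_taus), null_p_mean = mean(null_ps),
                 percentile_of_observed = 100 * mean(null_taus < obs$tau),
                 n_realisations = as.integer(n_realisations),
                 seed = as.integer(seed)),
            class = "fmn_null")
}

#' @export
print.fmn_null <- function(x, ...) {
  cat(sprintf(
    "Configuration-model null (%s tau, %d realisations, seed %d)\n",
    x$statistic, x$n_realisations, x$seed))
  cat(sprintf("  observed tau %.4f (p = %.3g)\n", x$tau_observed, x$p_observed))
  cat(sprintf("  null mean tau %.4f, mean null p %.3g\n",
              x$null_mean, x$null_p_mean))
  cat(sprintf("  observed at percentile %.1f of the null ensemble\n",
              x$percentile_of_observed))
  invisible(x)
}

#' Contrast external valence/arousal across aura-defined word groups
#'
#' Tests whether words of a given valence attribute that carry a
#' particular aura differ, in externally normed valence or arousal, from
#' all words of that attribute (any aura). Group A = words with
#' `target_attribute` whose aura equals `aura_condition`; group B = all
#' words with `target_attribute` (A included, as in the any-aura
#' comparison). The external measure is compared with the two-group
#' Kruskal-Wallis test.
#'
#' @param g an `fmn_graph`.
#' @param norms data.frame from [read_norms()].
#' @param target_attribute `"positive"`, `"neutral"` or `"negative"`.
#' @param aura_condition aura label defining group A.
#' @param measure `"valence"` or `"arousal"` (requires `arousal_mean` in
#'   the norms).
#' @param rule aura rule passed to [compute_aura()].
#' @return list with `target_attribute`, `aura_condition`, `measure`,
#'   `n_A`, `n_B`, `statistic`, `p_value`, `direction` (`"A > B"`,
#'   `"A < B"`, or `"none"` by group medians).
#' @export
aura_contrast <- function(g, norms, target_attribute, aura_condition,
                          measure = c("valence", "arousal"),
                          rule = c("polarity", "majority")) {
  measure <- match.arg(measure)
  rule <- match.arg(rule)
  col <- if (measure == "valence") "valence_mean" else "arousal_mean"
  if (!col %in% names(norms)) stop("norms lack column ", col)
  deg <- igraph::degree(g)
  cand <- igraph::V(g)$name[igraph::V(g)$valence == target_attribute & deg > 0]
  overlap <- intersect(cand, norms$word)
  if (length(overlap) == 0) {
    stop("no overlap between target words and norms (overlap 0)")
  }
  auras <- vapply(overlap, function(w) compute_aura(g, w, rule = rule)$aura, "")
  a_words <- overlap[auras == aura_condition]
  b_words <- overlap
  if (length(a_words) < 2 || length(b_words) < 2) {
    stop("comparison group too small after norm intersection (n_A = ",
         length(a_words), ", n_B = ", length(b_words), ")")
  }
  xa <- norms[[col]][match(a_words, norms$word)]
  xb <- norms[[col]][match(b_words, norms$word)]
  kw <- kruskal_two(xa, xb, exact = FALSE)
  med_a <- stats::median(xa)
  med_b <- stats::median(xb)
  direction <- if (med_a > med_b) "A > B" else if (med_a < med_b) "A < B" else "none"
  list(target_attribute = target_attribute, aura_condition = aura_condition,
       measure = measure, n_A = length(a_words), n_B = length(b_words),
       statistic = kw$statistic, p_value = kw$p_value, direction = direction)
}

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
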