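#' Fit a forma mentis network from survey forms
#'
#' The one-stop constructor: cleans the association and rating forms
#' (token normalization, warm-up removal, blank-fraction rejection),
#' builds the valence lexicon by the against-the-rest Kruskal-Wallis
#' procedure, and assembles the word-association network with node valence
#' attributes and participant-count edge weights.
#'
#' @param associations `fmn_associations` data.frame (see
#'   [read_association_forms()]).
#' @param ratings `fmn_ratings` data.frame (see [read_rating_forms()]).
#' @param map optional normalization map (variant -> canonical).
#' @param max_blank_frac blank-fraction rejection threshold (forms with a
#'   larger blank fraction are discarded, per task).
#' @param warmup_k leading response slots blanked per association form.
#' @param alpha per-word significance level of the valence classifier.
#' @param min_participants edge-weight filter; 1 keeps idiosyncratic
#'   (single-participant) associations.
#' @param population label stored in the network metadata.
#' @return object of class `forma_mentis`: list with `graph` (an
#'   `fmn_graph`), `lexicon` (an `fmn_lexicon`), `cleaning` (rejection
#'   logs), `call` and the cleaning/classification parameters.
#' @examples
#' sim <- simulate_survey(survey_config(n_participants = 20, seed = 42))
#' fit <- forma_mentis(sim$associations, sim$ratings)
#' fit
#' @export
forma_mentis <- function(associations, ratings, map = NULL,
                         max_blank_frac = 0.25, warmup_k = 3L, alpha = 0.1,
                         min_participants = 1L, population = "survey") {
  cleaned <- clean_survey(associations, ratings, map = map,
                          max_blank_frac = max_blank_frac,
                          warmup_k = warmup_k)
  lexicon <- build_lexicon(cleaned$ratings, alpha = alpha)
  graph <- build_network(cleaned$associations, lexicon,
                         population = population)
  if (min_participants > 1) graph <- filter_network(graph, min_participants)
  structure(list(graph = graph, lexicon = lexicon,
                 cleaning = cleaned[c("association_log", "rating_log",
                                      "rejected_overlap")],
                 params = list(max_blank_frac = max_blank_frac,
                               warmup_k = warmup_k, alpha = alpha,
                               min_participants = as.integer(min_participants),
                               population = population),
                 call = match.call()),
            class = "forma_mentis")
}

#' @export
print.forma_mentis <- function(x, ...) {
  g <- x$graph
  cat("Forma mentis network (", x$params$population, ")\n", sep = "")
  cat(sprintf("  %d words, %d associations (filter level %d)\n",
              igraph::vcount(g), igraph::ecount(g),
              igraph::graph_attr(g, "filter_level")))
  counts <- table(factor(igraph::V(g)$valence,
                         levels = c("positive", "neutral", "negative")))
  cat(sprintf("  node valence: %d positive, %d neutral, %d negative\n",
              counts[["positive"]], counts[["neutral"]], counts[["negative"]]))
  invisible(x)
}

#' @export
summary.forma_mentis <- function(object, ...) {
  g <- object$graph
  ee <- tryCatch(edge_endpoint_tau(g), error = function(e) NULL)
  nn <- tryCatch(node_neighborhood_tau(g), error = function(e) NULL)
  out <- list(
    n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
    filter_level = igraph::graph_attr(g, "filter_level"),
    valence_counts = table(factor(igraph::V(g)$valence,
                                  levels = c("positive", "neutral",
                                             "negative"))),
    rejected_association_forms = sum(object$cleaning$association_log$rejected),
    rejected_rating_forms = sum(object$cleaning$rating_log$rejected),
    pooled_skewness = object$lexicon$skew$pearson_skewness,
    edge_endpoint_tau = if (is.null(ee)) NA_real_ else ee$tau,
    node_neighborhood_tau = if (is.null(nn)) NA_real_ else nn$tau)
  class(out) <- "summary.forma_mentis"
  out
}

#' @export
print.summary.forma_mentis <- function(x, ...) {
  cat(sprintf("Nodes %d, edges %d (filter level %d)\n", x$n_nodes,
              x$n_edges, x$filter_level))
  cat(sprintf("Valence: %d positive, %d neutral, %d negative\n",
              x$valence_counts[["positive"]], x$valence_counts[["neutral"]],
              x$valence_counts[["negative"]]))
  cat(sprintf("Rejected forms: %d association, %d rating\n",
              x$rejected_association_forms, x$rejected_rating_forms))
  cat(sprintf("Pooled rating skewness %.3f\n", x$pooled_skewness))
  cat(sprintf("Mixing: edge-endpoint tau %.4f, node-neighborhood tau %.4f\n",
              x$edge_endpoint_tau, x$node_neighborhood_tau))
  invisible(x)
}

#' Plot aura fractions
#'
#' Stacked barplot of the positive / neutral / negative neighbor fractions
#' of the given words (default: the 10 highest-degree words), the
#' bar-chart view of the aura summary table.
#'
#' @param x a `forma_mentis` object.
#' @param words words to display.
#' @param ... passed to [graphics::barplot()].
#' @return the aura table, invisibly.
#' @export
plot.forma_mentis <- function(x, words = NULL, ...) {
  g <- x$graph
  if (is.null(words)) {
    deg <- igraph::degree(g)
    words <- igraph::V(g)$name[order(-deg)][seq_len(min(10, sum(deg > 0)))]
  }
  tab <- aura_table(g, words)
  m <- t(as.matrix(tab[, c("frac_negative", "frac_neutral", "frac_positive")]))
  colnames(m) <- tab$word
  graphics::barplot(m, col = c("firebrick", "grey80", "forestgreen"),
                    las = 2, ylab = "fraction of neighbors",
                    legend.text = c("negative", "neutral", "positive"), ...)
  invisible(tab)
}
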