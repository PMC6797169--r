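#' Build a forma mentis network
#'
#' Constructs the undirected word-association network: for every non-blank
#' response r to cue c, an edge {c, r} links the two words, weighted by the
#' number of *distinct participants* producing that association in either
#' orientation (repeated mentions by one participant count once).
#' Responses equal to their cue are skipped (no self-loops). Node valence
#' attributes are copied from the lexicon; words never rated get attribute
#' `"neutral"` with `rated = FALSE`.
#'
#' @param associations cleaned `fmn_associations` data.frame (non-empty).
#' @param lexicon an `fmn_lexicon`, or `NULL` to mark every node unrated
#'   neutral.
#' @param population free-text label stored as graph metadata.
#' @return an [igraph][igraph::igraph-package] graph of class
#'   `c("fmn_graph", "igraph")` with node attributes `valence`, `rated`,
#'   edge attribute `weight`, and graph attributes `population` and
#'   `filter_level` (1 = unfiltered).
#' @export
build_network <- function(associations, lexicon = NULL, population = "survey") {
  if (!inherits(associations, "fmn_associations")) {
    stop("associations must be fmn_associations")
  }
  long <- data.frame(
    participant = rep(associations$participant, 3),
    cue = rep(associations$cue, 3),
    response = c(associations$r1, associations$r2, associations$r3),
    stringsAsFactors = FALSE
  )
  long <- long[!is.na(long$response) & long$response != long$cue, , drop = FALSE]
  if (nrow(long) == 0) stop("no non-blank associations to build a network from")
  a <- pmin(long$cue, long$response)
  b <- pmax(long$cue, long$response)
  key <- paste(a, b, sep = "\r")
  uniq <- !duplicated(paste(long$participant, key, sep = "\r"))
  w <- table(key[uniq])
  pair <- strsplit(names(w), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(pair, `[`, "", 1),
                      to = vapply(pair, `[`, "", 2),
                      weight = as.integer(w), stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- .apply_lexicon_attributes(g, lexicon)
  g <- igraph::set_graph_attr(g, "population", population)
  g <- igraph::set_graph_attr(g, "filter_level", 1L)
  class(g) <- c("fmn_graph", class(g))
  g
}

.apply_lexicon_attributes <- function(g, lexicon) {
  nodes <- igraph::V(g)$name
  valence <- rep("neutral", length(nodes))
  rated <- rep(FALSE, length(nodes))
  if (!is.null(lexicon)) {
    stopifnot(inherits(lexicon, "fmn_lexicon"))
    hit <- match(nodes, lexicon$words$word)
    found <- !is.na(hit)
    valence[found] <- lexicon$words$attribute[hit[found]]
    rated[found] <- lexicon$words$rated[hit[found]]
  }
  g <- igraph::set_vertex_attr(g, "valence", value = valence)
  igraph::set_vertex_attr(g, "rated", value = rated)
}

#' Filter a network by participant support
#'
#' Keeps only edges produced by at least `min_participants` distinct
#' participants and drops nodes left isolated. `min_participants = 1`
#' returns the network unchanged (aside from metadata).
#'
#' @param g an `fmn_graph`.
#' @param min_participants minimum edge weight kept.
#' @return filtered `fmn_graph`; `filter_level` metadata records the
#'   threshold, and an `empty` graph attribute flags a fully filtered-out
#'   network.
#' @export
filter_network <- function(g, min_participants = 2L) {
  stopifnot(min_participants >= 1)
  cls <- class(g)
  drop <- igraph::E(g)[igraph::E(g)$weight < min_participants]
  g2 <- igraph::delete_edges(g, drop)
  g2 <- igraph::delete_vertices(g2, igraph::V(g2)[igraph::degree(g2) == 0])
  g2 <- igraph::set_graph_attr(g2, "filter_level",
                               max(as.integer(min_participants),
                                   igraph::graph_attr(g, "filter_level")))
  g2 <- igraph::set_graph_attr(g2, "empty", igraph::vcount(g2) == 0)
  class(g2) <- cls
  g2
}

#' Valence aura of a word
#'
#' The aura of a word summarizes the valence of its immediate neighbors:
#' the fractions of positive, neutral and negative neighbors (unweighted
#' by default -- each neighbor counts once) and a polarity label. Under the
#' default `"polarity"` rule the label is negative when the word has more
#' negative than positive neighbors, positive when more positive than
#' negative, and neutral on a tie (neutral neighbors never decide
#' polarity). The `"majority"` rule instead takes the most frequent of the
#' three attributes, ties resolved to neutral.
#'
#' @param g an `fmn_graph`.
#' @param word a node name with degree >= 1.
#' @param rule `"polarity"` (default) or `"majority"`.
#' @param weighted if `TRUE`, neighbors are counted with their edge
#'   weights.
#' @return list with `word`, `frac_positive`, `frac_neutral`,
#'   `frac_negative`, `aura`, `degree`.
#' @export
compute_aura <- function(g, word, rule = c("polarity", "majority"),
                         weighted = FALSE) {
  rule <- match.arg(rule)
  if (!word %in% igraph::V(g)$name) stop("word not in network: ", word)
  nb <- igraph::neighbors(g, word)
  if (length(nb) == 0) stop("word is isolated: ", word)
  val <- igraph::vertex_attr(g, "valence", nb)
  wts <- if (weighted) {
    nb_names <- igraph::V(g)$name[nb]
    eids <- igraph::get_edge_ids(
      g, as.vector(rbind(rep(word, length(nb)), nb_names)))
    igraph::E(g)$weight[eids]
  } else {
    rep(1, length(nb))
  }
  tot <- sum(wts)
  cnt <- c(positive = sum(wts[val == "positive"]),
           neutral = sum(wts[val == "neutral"]),
           negative = sum(wts[val == "negative"]))
  aura <- if (rule == "polarity") {
    if (cnt[["negative"]] > cnt[["positive"]]) "negative"
    else if (cnt[["positive"]] > cnt[["negative"]]) "positive"
    else "neutral"
  } else {
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) == 1) top else "neutral"
  }
  list(word = word, frac_positive = cnt[["positive"]] / tot,
       frac_neutral = cnt[["neutral"]] / tot,
       frac_negative = cnt[["negative"]] / tot,
       aura = aura, degree = length(nb))
}

#' Aura table for a set of words
#'
#' One [compute_aura()] row per requested word, in the given order;
#' suitable for bar-chart export of neighbor-valence fractions per cue.
#'
#' @param g an `fmn_graph`.
#' @param words character vector of node names (default: all non-isolated
#'   nodes).
#' @inheritParams compute_aura
#' @return data.frame with columns `word`, `frac_positive`, `frac_neutral`,
#'   `frac_negative`, `aura`, `degree`.
#' @export
aura_table <- function(g, words = NULL, rule = c("polarity", "majority"),
                       weighted = FALSE) {
  rule <- match.arg(rule)
  if (is.null(words)) {
    words <- igraph::V(g)$name[igraph::degree(g) > 0]
  }
  missing <- setdiff(words, igraph::V(g)$name)
  if (length(missing)) {
    stop("words not in network: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(words, function(w) {
    as.data.frame(compute_aura(g, w, rule = rule, weighted = weighted),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export / import a forma mentis network
#'
#' `format = "graphml"` writes a single GraphML file carrying node
#' attributes and edge weights. `format = "edgelist"` writes a TSV of
#' `from`, `to`, `weight`; `format = "nodes"` writes the node table CSV
#' (`word`, `valence`, `rated`). `import_network()` reconstructs the graph
#' from GraphML, or from an edge list plus node table. Round trips
#' preserve nodes, attributes and weights exactly, including non-ASCII
#' tokens (UTF-8 throughout).
#'
#' @param g an `fmn_graph`.
#' @param path output path.
#' @param format one of `"graphml"`, `"edgelist"`, `"nodes"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(g, path, format = c("graphml", "edgelist", "nodes")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    el <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(el[c("from", "to", "weight")], path, sep = "\t",
                       row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    nt <- data.frame(word = igraph::V(g)$name,
                     valence = igraph::V(g)$valence,
                     rated = igraph::V(g)$rated, stringsAsFactors = FALSE)
    utils::write.csv(nt, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname export_network
#' @param edge_path,node_path paths written with formats `"edgelist"` and
#'   `"nodes"`.
#' @export
import_network <- function(path = NULL, edge_path = NULL, node_path = NULL) {
  if (!is.null(path)) {
    g <- igraph::read_graph(path, format = "graphml")
    igraph::V(g)$name <- igraph::V(g)$name # ensure attribute materialized
    g <- igraph::set_vertex_attr(g, "rated", value = as.logical(igraph::V(g)$rated))
  } else {
    if (is.null(edge_path) || is.null(node_path)) {
      stop("need either a graphml path or edge_path + node_path")
    }
    el <- utils::read.table(edge_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            fileEncoding = "UTF-8", comment.char = "")
    nt <- utils::read.csv(node_path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = nt)
    g <- igraph::set_vertex_attr(g, "valence", value = nt$valence)
    g <- igraph::set_vertex_attr(g, "rated", value = as.logical(nt$rated))
  }
  g <- igraph::set_edge_attr(g, "weight",
                             value = as.integer(igraph::E(g)$weight))
  if (is.null(igraph::graph_attr(g, "filter_level"))) {
    g <- igraph::set_graph_attr(g, "filter_level", 1L)
  }
  class(g) <- c("fmn_graph", class(g))
  g
}
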