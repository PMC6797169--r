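# Independent oracles, deliberately naive: plain loops and first-principles
# formulas, no shared code with the package internals.

# Kendall tau-b by O(n^2) pair counting.
oracle_tau <- function(x, y) {
  n <- length(x)
  conc <- 0
  disc <- 0
  tie_x <- 0
  tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0) tie_x <- tie_x + 1
      if (dy == 0) tie_y <- tie_y + 1
      if (dx != 0 && dy != 0) {
        if (sign(dx) == sign(dy)) conc <- conc + 1 else disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tie_x) * (n0 - tie_y))
}

# Mid-ranks from first principles (sort positions, ties averaged).
oracle_midranks <- function(v) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    below <- sum(v < v[i])
    tied <- sum(v == v[i])
    out[i] <- below + (tied + 1) / 2
  }
  out
}

# Two-group Kruskal-Wallis H via hand-computed rank sums + tie correction.
oracle_kw <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- oracle_midranks(pooled)
  r1 <- sum(r[seq_along(x)])
  r2 <- sum(r[-seq_along(x)])
  h <- 12 / (n * (n + 1)) * (r1^2 / length(x) + r2^2 / length(y)) -
    3 * (n + 1)
  tie_sizes <- as.vector(table(pooled))
  corr <- 1 - sum(tie_sizes^3 - tie_sizes) / (n^3 - n)
  if (corr == 0) return(0)
  h / corr
}

# All permutations of 1..n (for exact-p enumeration checks).
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    t(apply(sub, 1, function(row) append(row, n, after = pos - 1)))
  }))
}

# All multisets of `size` values drawn from `values` (combinations with
# repetition), as rows.
oracle_multisets <- function(values, size) {
  idx <- utils::combn(length(values) + size - 1, size)
  t(apply(idx, 2, function(col) values[col - seq_len(size) + 1]))
}

# Small hand-built association forms data.frame with the package's classes.
make_assoc <- function(participant, cue, r1 = NA, r2 = NA, r3 = NA) {
  df <- data.frame(participant = participant, cue = cue, r1 = r1, r2 = r2,
                   r3 = r3, stringsAsFactors = FALSE)
  class(df) <- c("fmn_associations", "data.frame")
  df
}

make_ratings <- function(participant, word, rating) {
  df <- data.frame(participant = participant, word = word,
                   rating = as.integer(rating), stringsAsFactors = FALSE)
  class(df) <- c("fmn_ratings", "data.frame")
  df
}

# Hand-built graph: edge data.frame + per-node valence.
make_graph <- function(edges, valence, weights = NULL) {
  if (is.null(weights)) weights <- rep(1L, nrow(edges))
  g <- igraph::graph_from_data_frame(
    data.frame(edges, weight = as.integer(weights)), directed = FALSE,
    vertices = data.frame(name = names(valence), valence = unname(valence),
                          rated = TRUE, stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "filter_level", 1L)
  class(g) <- c("fmn_graph", class(g))
  g
}
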