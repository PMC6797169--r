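#' Two-group Kruskal-Wallis test
#'
#' Tie-corrected Kruskal-Wallis H statistic for exactly two groups, with a
#' chi-squared (df = 1) p-value. When the smaller group has fewer than 5
#' observations and full enumeration is feasible (at most `max_enum`
#' assignments), an exact permutation p-value is computed instead by
#' enumerating every assignment of group labels to the pooled sample.
#'
#' H = (12 / (N(N+1))) * sum(R_g^2 / n_g) - 3(N+1), divided by the tie
#' correction 1 - sum(t^3 - t) / (N^3 - N), where R_g are group rank sums
#' over the pooled mid-ranks and t runs over tie-group sizes.
#'
#' @param x,y numeric vectors, the two groups (each non-empty).
#' @param exact `"auto"` (exact when `min(n) < 5` and feasible), `TRUE`
#'   (force exact; errors if infeasible), or `FALSE` (chi-squared only).
#' @param max_enum maximum number of label assignments enumerated in exact
#'   mode.
#' @return list with `statistic`, `p_value`, `n` (total), `n_x`, `n_y`,
#'   and `method` (`"chisq"` or `"exact"`).
#' @examples
#' kruskal_two(c(1, 2, 3), c(4, 5, 6))
#' @export
kruskal_two <- function(x, y, exact = "auto", max_enum = 1e5) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  h <- .kw_statistic(c(x, y), n1)
  nmin <- min(n1, n2)
  feasible <- choose(n, nmin) <= max_enum
  do_exact <- if (identical(exact, "auto")) (nmin < 5L && feasible) else isTRUE(exact)
  if (isTRUE(exact) && !feasible) {
    stop("exact enumeration infeasible: choose(", n, ", ", nmin, ") > max_enum")
  }
  if (do_exact) {
    p <- .kw_exact_p(c(x, y), n1, h)
    method <- "exact"
  } else {
    p <- if (is.na(h)) NA_real_ else stats::pchisq(h, df = 1, lower.tail = FALSE)
    method <- "chisq"
  }
  list(statistic = h, p_value = p, n = n, n_x = n1, n_y = n2, method = method)
}

# H on the pooled vector where the first n1 elements form group 1.
# Returns 0 when every observation is tied (no information).
.kw_statistic <- function(pooled, n1) {
  n <- length(pooled)
  r <- rank(pooled)
  ties <- table(pooled)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) return(0)
  r1 <- sum(r[seq_len(n1)])
  r2 <- sum(r) - r1
  n2 <- n - n1
  h <- 12 / (n * (n + 1)) * (r1^2 / n1 + r2^2 / n2) - 3 * (n + 1)
  h / tie_corr
}

# Exact permutation p: proportion of group-1 index sets whose H is >= the
# observed H (within numerical tolerance).
.kw_exact_p <- function(pooled, n1, h_obs) {
  n <- length(pooled)
  nmin <- min(n1, n - n1)
  idx <- utils::combn(n, nmin)
  r <- rank(pooled)
  ties <- table(pooled)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr == 0) return(1)
  nmax <- n - nmin
  rtot <- sum(r)
  rs <- colSums(matrix(r[idx], nrow = nmin))
  h_all <- (12 / (n * (n + 1)) * (rs^2 / nmin + (rtot - rs)^2 / nmax) -
    3 * (n + 1)) / tie_corr
  mean(h_all >= h_obs - 1e-12)
}
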