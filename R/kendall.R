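#' Kendall tau-b rank correlation with tie correction
#'
#' Computes the tie-corrected Kendall tau-b between two numeric vectors,
#' together with a two-sided p-value. For small samples (`n <= 8`) an exact
#' p-value can be obtained by full enumeration of all permutations of `y`;
#' otherwise the normal approximation with the standard tie-corrected
#' variance is used.
#'
#' tau-b = (C - D) / sqrt((n0 - t_x)(n0 - t_y)) where C and D are the
#' concordant and discordant pair counts, n0 = n(n-1)/2 and t_x, t_y are the
#' tied-pair counts within each vector. Pairs tied in either coordinate are
#' neither concordant nor discordant.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @param p_method `"auto"` (exact when `n <= 8`, else normal), `"normal"`,
#'   `"exact"` (full permutation enumeration; only for `n <= 8`), or
#'   `"none"` to skip the p-value.
#' @return A list with elements `tau`, `p_value`, `n`, `concordant`,
#'   `discordant`, and `method` (the p-value method used).
#' @examples
#' kendall_tau(1:5, c(2, 1, 4, 3, 5))
#' @export
kendall_tau <- function(x, y, p_method = c("auto", "normal", "exact", "none")) {
  p_method <- match.arg(p_method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  ux <- length(unique(x))
  uy <- length(unique(y))
  if (ux == 1L && uy == 1L) {
    stop("tau is undefined when both vectors are constant")
  }

  cd <- .pair_counts(x, y)
  n0 <- n * (n - 1) / 2
  tx <- sum(choose(tabulate(match(x, unique(x))), 2))
  ty <- sum(choose(tabulate(match(y, unique(y))), 2))
  denom <- sqrt((n0 - tx) * (n0 - ty))
  if (denom == 0) stop("tau is undefined: one vector is constant")
  tau <- (cd$concordant - cd$discordant) / denom

  p <- switch(p_method,
    none = NA_real_,
    exact = {
      if (n > 8L) stop("exact p-value only available for n <= 8")
      .kendall_exact_p(x, y, tau)
    },
    normal = .kendall_normal_p(x, y, cd$concordant - cd$discordant),
    auto = if (n <= 8L) .kendall_exact_p(x, y, tau) else
      .kendall_normal_p(x, y, cd$concordant - cd$discordant)
  )
  used <- if (p_method == "auto") (if (n <= 8L) "exact" else "normal") else p_method
  list(tau = tau, p_value = p, n = n,
       concordant = cd$concordant, discordant = cd$discordant,
       method = used)
}

# Concordant/discordant counts. Two routes giving identical results:
# a contingency-table scan when both vectors take few distinct values
# (score data, where n can be large), and blocked O(n^2) sign counting
# otherwise. Both are exact.
.pair_counts <- function(x, y) {
  ux <- sort(unique(x))
  uy <- sort(unique(y))
  if (length(ux) * length(uy) <= 10000L) {
    # index into the sorted unique values: distinct doubles can collide when
    # coerced to character, so never build the table on the raw values
    ix <- match(x, ux)
    iy <- match(y, uy)
    tab <- table(factor(ix, levels = seq_along(ux)),
                 factor(iy, levels = seq_along(uy)))
    return(.pair_counts_table(tab))
  }
  conc <- 0
  disc <- 0
  block <- 512L
  n <- length(x)
  for (start in seq(1L, n - 1L, by = block)) {
    idx <- start:min(start + block - 1L, n - 1L)
    for (i in idx) {
      rest <- (i + 1L):n
      s <- sign(x[rest] - x[i]) * sign(y[rest] - y[i])
      conc <- conc + sum(s > 0)
      disc <- disc + sum(s < 0)
    }
  }
  list(concordant = conc, discordant = disc)
}

.pair_counts_table <- function(tab) {
  tab <- matrix(as.numeric(tab), nrow = nrow(tab), ncol = ncol(tab))
  r <- nrow(tab)
  c <- ncol(tab)
  # cum[i, j] = sum of tab[1:i, 1:j]
  cum <- tab
  if (r > 1) for (i in 2:r) cum[i, ] <- cum[i, ] + cum[i - 1, ]
  if (c > 1) for (j in 2:c) cum[, j] <- cum[, j] + cum[, j - 1]
  total <- cum[r, c]
  cm <- function(i, j) if (i < 1 || j < 1) 0 else cum[i, j]
  conc <- 0
  disc <- 0
  for (i in seq_len(r)) {
    for (j in seq_len(c)) {
      nij <- tab[i, j]
      if (nij == 0) next
      lower_left <- cm(i - 1, j - 1)
      upper_right <- total - cm(i, c) - cm(r, j) + cum[i, j]
      upper_left <- cm(i - 1, c) - cm(i - 1, j)
      lower_right <- cm(r, j - 1) - cm(i, j - 1)
      conc <- conc + nij * (lower_left + upper_right)
      disc <- disc + nij * (upper_left + lower_right)
    }
  }
  # each unordered pair counted from both of its cells
  list(concordant = conc / 2, discordant = disc / 2)
}

# Normal approximation with the tie-corrected variance of C - D
# (Kendall 1970); continuity correction omitted, two-sided.
.kendall_normal_p <- function(x, y, s) {
  n <- length(x)
  tx <- tabulate(match(x, unique(x)))
  ty <- tabulate(match(y, unique(y)))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  if (var_s <= 0) return(NA_real_)
  z <- s / sqrt(var_s)
  2 * stats::pnorm(-abs(z))
}

# Exact two-sided p by enumerating all n! permutations of y and counting
# |tau_perm| >= |tau_obs| (with a numerical tolerance on the comparison).
.kendall_exact_p <- function(x, y, tau_obs) {
  n <- length(x)
  perms <- .all_permutations(n)
  n0 <- n * (n - 1) / 2
  tx <- sum(choose(tabulate(match(x, unique(x))), 2))
  ty <- sum(choose(tabulate(match(y, unique(y))), 2))
  denom <- sqrt((n0 - tx) * (n0 - ty))
  sx <- sign(outer(x, x, "-"))
  hits <- 0L
  target <- abs(tau_obs) - 1e-12
  for (k in seq_len(nrow(perms))) {
    yp <- y[perms[k, ]]
    sy <- sign(outer(yp, yp, "-"))
    s <- sum(sx * sy) / 2
    if (abs(s / denom) >= target) hits <- hits + 1L
  }
  hits / nrow(perms)
}

.all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}
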