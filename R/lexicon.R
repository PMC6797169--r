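#' Pool valence ratings per word
#'
#' Collects every participant's rating of each word into one pooled sample
#' per word. A blank rating expresses neutrality and contributes the value
#' 3; each (participant, word) pair contributes exactly one value.
#'
#' @param ratings an `fmn_ratings` data.frame (cleaned).
#' @return named list: word -> integer vector of pooled ratings.
#' @export
pool_ratings <- function(ratings) {
  if (!inherits(ratings, "fmn_ratings")) stop("ratings must be fmn_ratings")
  if (anyDuplicated(ratings[c("participant", "word")])) {
    stop("duplicate rating for the same (participant, word)")
  }
  vals <- ratings$rating
  vals[is.na(vals)] <- 3L
  split(vals, ratings$word)
}

#' Pearson's skewness coefficient
#'
#' `3 * (mean - median) / sigma` with `sigma` the population (divide-by-n)
#' standard deviation; `sd_type = "sample"` switches to the n-1 divisor.
#'
#' @param scores numeric vector, length >= 2.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return the signed skewness coefficient.
#' @export
pearson_skewness <- function(scores, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  scores <- as.numeric(scores)
  if (length(scores) < 2) stop("need at least 2 scores")
  if (anyNA(scores)) stop("missing values are not allowed")
  s <- stats::sd(scores)
  if (sd_type == "population") {
    n <- length(scores)
    s <- s * sqrt((n - 1) / n)
  }
  if (s == 0) stop("skewness undefined: zero standard deviation")
  3 * (mean(scores) - stats::median(scores)) / s
}

#' Classify one word's valence against the rest
#'
#' The against-the-rest decision rule: a two-group Kruskal-Wallis test
#' compares the word's pooled ratings with the pooled ratings of every
#' other word. If `p < alpha` and the word's median is below the rest's,
#' the word is negative; if `p < alpha` and its median is above, positive;
#' otherwise neutral. No multiple-testing correction is applied by
#' default, matching the per-word `alpha` design; `correct = "BH"` is
#' available at the lexicon level.
#'
#' @param word_ratings numeric vector, the word's pooled ratings.
#' @param rest_ratings numeric vector, pooled ratings of all other words.
#' @param alpha per-word significance level (default 0.1).
#' @param exact passed to [kruskal_two()].
#' @return list with `attribute` (`"positive"`, `"neutral"`, or
#'   `"negative"`), `statistic`, `p_value`, `n`, `alpha`, and the two group
#'   medians.
#' @export
classify_word_valence <- function(word_ratings, rest_ratings, alpha = 0.1,
                                  exact = "auto") {
  if (length(word_ratings) == 0 || length(rest_ratings) == 0) {
    stop("both rating groups must be non-empty")
  }
  kw <- kruskal_two(word_ratings, rest_ratings, exact = exact)
  med_w <- stats::median(word_ratings)
  med_r <- stats::median(rest_ratings)
  attribute <- "neutral"
  if (!is.na(kw$p_value) && kw$p_value < alpha) {
    if (med_w < med_r) attribute <- "negative"
    if (med_w > med_r) attribute <- "positive"
  }
  list(attribute = attribute, statistic = kw$statistic, p_value = kw$p_value,
       n = kw$n, alpha = alpha, median_word = med_w, median_rest = med_r)
}

#' Build a valence lexicon from rating forms
#'
#' Pools ratings per word, classifies every word against the union of all
#' other words' ratings at level `alpha`, and computes distribution
#' diagnostics (pooled mean/median/sd and Pearson skewness) on the full
#' pooled score distribution.
#'
#' Internally the against-the-rest tests share one global ranking of the
#' pooled scores -- the combined sample of (word, rest) is the whole pool
#' for every word -- so the per-word H statistics are identical to calling
#' [classify_word_valence()] word by word, at a fraction of the cost.
#' Exact permutation p-values (small groups) fall back to the per-word
#' route.
#'
#' @param ratings an `fmn_ratings` data.frame (cleaned).
#' @param alpha per-word significance level.
#' @param correct `"none"` (default, per-word alpha) or `"BH"` for a
#'   Benjamini-Hochberg corrected decision at level `alpha`.
#' @return object of class `fmn_lexicon`: list with `words` (data.frame
#'   `word`, `n_raters`, `mean`, `median`, `attribute`, `kw_statistic`,
#'   `p_value`, `rated`), `skew` (pooled mean/median/sd and
#'   `pearson_skewness`), `alpha`, `correct`.
#' @export
build_lexicon <- function(ratings, alpha = 0.1, correct = c("none", "BH")) {
  correct <- match.arg(correct)
  pools <- pool_ratings(ratings)
  if (length(pools) < 2) stop("need at least 2 distinct rated words")
  words <- names(pools)
  all_scores <- unlist(pools, use.names = FALSE)
  n_tot <- length(all_scores)
  r_global <- rank(all_scores)
  word_of <- rep(seq_along(pools), lengths(pools))
  ties <- table(all_scores)
  tie_corr <- 1 - sum(ties^3 - ties) / (n_tot^3 - n_tot)
  rank_sums <- vapply(split(r_global, word_of), sum, 0)
  rtot <- sum(r_global)
  n_w <- lengths(pools)

  stat <- numeric(length(pools))
  pval <- numeric(length(pools))
  med_w <- vapply(pools, stats::median, 0)
  for (i in seq_along(pools)) {
    n1 <- n_w[i]
    n2 <- n_tot - n1
    if (tie_corr == 0) {
      stat[i] <- 0
      pval[i] <- 1
      next
    }
    r1 <- rank_sums[i]
    h <- (12 / (n_tot * (n_tot + 1)) *
            (r1^2 / n1 + (rtot - r1)^2 / n2) - 3 * (n_tot + 1)) / tie_corr
    stat[i] <- h
    if (min(n1, n2) < 5 && choose(n_tot, min(n1, n2)) <= 1e5) {
      rest <- all_scores[word_of != i]
      pval[i] <- kruskal_two(pools[[i]], rest, exact = "auto")$p_value
    } else {
      pval[i] <- stats::pchisq(h, df = 1, lower.tail = FALSE)
    }
  }
  med_rest <- vapply(seq_along(pools), function(i) {
    stats::median(all_scores[word_of != i])
  }, 0)
  pdec <- if (correct == "BH") stats::p.adjust(pval, "BH") else pval
  attribute <- rep("neutral", length(pools))
  sig <- !is.na(pdec) & pdec < alpha
  attribute[sig & med_w > med_rest] <- "positive"
  attribute[sig & med_w < med_rest] <- "negative"

  tab <- data.frame(word = words, n_raters = as.integer(n_w),
                    mean = vapply(pools, mean, 0), median = med_w,
                    attribute = attribute, kw_statistic = stat,
                    p_value = pval, rated = TRUE,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  pop_sd <- stats::sd(all_scores) * sqrt((n_tot - 1) / n_tot)
  skew <- list(mean = mean(all_scores), median = stats::median(all_scores),
               sd = pop_sd,
               pearson_skewness = if (pop_sd > 0)
                 3 * (mean(all_scores) - stats::median(all_scores)) / pop_sd
               else NA_real_)
  structure(list(words = tab, skew = skew, alpha = alpha, correct = correct),
            class = "fmn_lexicon")
}

#' @export
print.fmn_lexicon <- function(x, ...) {
  counts <- table(factor(x$words$attribute,
                         levels = c("positive", "neutral", "negative")))
  cat("Valence lexicon:", nrow(x$words), "words",
      sprintf("(%d positive, %d neutral, %d negative), alpha = %g\n",
              counts[["positive"]], counts[["neutral"]], counts[["negative"]],
              x$alpha))
  cat(sprintf("Pooled scores: mean %.3f, median %g, Pearson skewness %.3f\n",
              x$skew$mean, x$skew$median, x$skew$pearson_skewness))
  invisible(x)
}

#' Cross-validate lexicon means against external norms
#'
#' Kendall tau-b between the lexicon's mean valence scores and an external
#' norm table's mean valence, over the overlapping vocabulary.
#'
#' @param lexicon an `fmn_lexicon`.
#' @param norms data.frame from [read_norms()].
#' @return list with `tau`, `p_value`, `n_overlap`.
#' @export
cross_validate <- function(lexicon, norms) {
  stopifnot(inherits(lexicon, "fmn_lexicon"))
  common <- intersect(lexicon$words$word, norms$word)
  if (length(common) < 2) stop("fewer than 2 overlapping words with norms")
  x <- lexicon$words$mean[match(common, lexicon$words$word)]
  y <- norms$valence_mean[match(common, norms$word)]
  kt <- kendall_tau(x, y, p_method = if (length(common) <= 8) "exact" else "normal")
  list(tau = kt$tau, p_value = kt$p_value, n_overlap = length(common))
}

#' Export a lexicon as CSV
#'
#' Writes the per-word table (word, n_raters, mean, median, attribute,
#' kw_statistic, p_value, rated) as UTF-8 CSV; [import_lexicon()] reads it
#' back.
#'
#' @param lexicon an `fmn_lexicon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "fmn_lexicon"))
  utils::write.csv(lexicon$words, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname export_lexicon
#' @export
import_lexicon <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  structure(list(words = tab, skew = NULL, alpha = NA_real_,
                 correct = "none"),
            class = "fmn_lexicon")
}
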