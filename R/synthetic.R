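#' Configuration for a synthetic survey
#'
#' Describes a simulated free-association + valence-rating study with
#' known ground truth. Participants each see `n_cues` cue words
#' (`n_fixed_cues` of them common to everyone, the rest drawn at random
#' per participant) and produce `responses_per_cue` associative responses
#' per cue; separately they rate every vocabulary word on the 1-5 scale.
#' The vocabulary is partitioned into planted positive / neutral /
#' negative pools; `h` controls emotional homophily at the response level
#' (probability that a response is drawn from the cue's own pool rather
#' than the whole vocabulary).
#'
#' Default rating distributions over scores 1..5: positive pool
#' (0, 0, .1, .4, .5), neutral (.05, .2, .5, .2, .05), negative
#' (.5, .4, .1, 0, 0) -- skewed pools that are clearly separable with ~30
#' raters per word but leave classification nontrivial with few.
#'
#' @param n_participants number of simulated participants.
#' @param pool_sizes integer vector `c(positive, neutral, negative)` pool
#'   sizes (each >= 0, at least two words in total).
#' @param n_cues cues per participant; `n_fixed_cues` of them fixed.
#' @param n_fixed_cues number of cues shared by all participants.
#' @param responses_per_cue response slots per cue.
#' @param h homophily strength in `[0, 1]`.
#' @param blank_prob probability that any response or rating cell is left
#'   blank.
#' @param rating_probs list with elements `positive`, `neutral`,
#'   `negative`, each a probability vector over scores 1..5.
#' @param seed integer seed; all generated artifacts are deterministic
#'   given the config.
#' @return object of class `survey_config`.
#' @export
survey_config <- function(n_participants = 100L,
                          pool_sizes = c(positive = 30L, neutral = 30L,
                                         negative = 30L),
                          n_cues = 50L, n_fixed_cues = 10L,
                          responses_per_cue = 3L,
                          h = 0.5, blank_prob = 0.05,
                          rating_probs = list(
                            positive = c(0, 0, .1, .4, .5),
                            neutral = c(.05, .2, .5, .2, .05),
                            negative = c(.5, .4, .1, 0, 0)),
                          seed = 1L) {
  pool_sizes <- as.integer(pool_sizes)
  names(pool_sizes) <- c("positive", "neutral", "negative")
  stopifnot(n_participants >= 1, all(pool_sizes >= 0), sum(pool_sizes) >= 2,
            n_cues >= 1, n_fixed_cues >= 0, n_fixed_cues <= n_cues,
            responses_per_cue >= 1, h >= 0, h <= 1,
            blank_prob >= 0, blank_prob <= 1)
  n_cues <- min(as.integer(n_cues), sum(pool_sizes))
  n_fixed_cues <- min(as.integer(n_fixed_cues), n_cues)
  for (p in c("positive", "neutral", "negative")) {
    pr <- rating_probs[[p]]
    stopifnot(length(pr) == 5, all(pr >= 0), abs(sum(pr) - 1) < 1e-9)
  }
  structure(list(n_participants = as.integer(n_participants),
                 pool_sizes = pool_sizes, n_cues = n_cues,
                 n_fixed_cues = n_fixed_cues,
                 responses_per_cue = as.integer(responses_per_cue),
                 h = h, blank_prob = blank_prob,
                 rating_probs = rating_probs, seed = as.integer(seed)),
            class = "survey_config")
}

#' Generate the planted vocabulary
#'
#' Synthetic tokens tagged by pool (`pos001`, `neu001`, `neg001`, ...)
#' plus the ground truth: each word's planted attribute and planted mean
#' rating (the expectation of its pool's rating distribution).
#'
#' @param config a `survey_config`.
#' @return list with `vocabulary` (character) and `truth` (data.frame
#'   `word`, `attribute`, `planted_mean`; attributes `h` and `seed`).
#' @export
generate_vocabulary <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  pools <- config$pool_sizes
  mk <- function(tag, n) if (n > 0) sprintf("%s%03d", tag, seq_len(n)) else character(0)
  words <- c(mk("pos", pools[["positive"]]), mk("neu", pools[["neutral"]]),
             mk("neg", pools[["negative"]]))
  attribute <- rep(c("positive", "neutral", "negative"), pools)
  planted_mean <- vapply(attribute, function(a) {
    sum(config$rating_probs[[a]] * (1:5))
  }, 0)
  truth <- data.frame(word = words, attribute = attribute,
                      planted_mean = planted_mean, stringsAsFactors = FALSE)
  attr(truth, "h") <- config$h
  attr(truth, "seed") <- config$seed
  list(vocabulary = words, truth = truth)
}

#' Generate synthetic rating forms
#'
#' Every participant rates every vocabulary word: the rating is drawn from
#' the word's pool distribution, blanked with probability `blank_prob`
#' (blanks read as neutral when pooled).
#'
#' @param config a `survey_config`.
#' @param truth data.frame from [generate_vocabulary()].
#' @return an `fmn_ratings` data.frame.
#' @export
generate_rating_forms <- function(config, truth) {
  stopifnot(inherits(config, "survey_config"))
  with_seed(config$seed + 1000003L, {
    np <- config$n_participants
    nw <- nrow(truth)
    rating <- integer(np * nw)
    for (i in seq_len(nw)) {
      pr <- config$rating_probs[[truth$attribute[i]]]
      rating[seq(i, by = nw, length.out = np)] <-
        sample.int(5L, np, replace = TRUE, prob = pr)
    }
    blank <- stats::runif(np * nw) < config$blank_prob
    rating[blank] <- NA_integer_
    df <- data.frame(
      participant = rep(sprintf("p%04d", seq_len(np)), each = nw),
      word = rep(truth$word, np),
      rating = rating, stringsAsFactors = FALSE)
    class(df) <- c("fmn_ratings", "data.frame")
    df
  })
}

#' Generate synthetic association forms
#'
#' For each (participant, cue, slot): with probability `blank_prob` the
#' slot is blank; otherwise with probability `h` the response is drawn
#' uniformly from the cue's own valence pool (excluding the cue itself),
#' and with probability `1 - h` uniformly from the whole vocabulary
#' (excluding the cue). Cue lists are the fixed cues plus a per-participant
#' random draw of the remaining cues, in scrambled presentation order.
#'
#' @param config a `survey_config`.
#' @param truth data.frame from [generate_vocabulary()].
#' @return an `fmn_associations` data.frame.
#' @export
generate_association_forms <- function(config, truth) {
  stopifnot(inherits(config, "survey_config"))
  vocab <- truth$word
  by_pool <- split(truth$word, truth$attribute)
  with_seed(config$seed + 2000003L, {
    rows <- vector("list", config$n_participants)
    fixed <- vocab[seq_len(config$n_fixed_cues)]
    for (p in seq_len(config$n_participants)) {
      extra <- sample(setdiff(vocab, fixed),
                      config$n_cues - config$n_fixed_cues)
      cues <- sample(c(fixed, extra))
      resp <- matrix(NA_character_, length(cues), 3)
      for (ci in seq_along(cues)) {
        cue <- cues[ci]
        own <- setdiff(by_pool[[truth$attribute[match(cue, truth$word)]]], cue)
        any_word <- setdiff(vocab, cue)
        for (slot in seq_len(min(config$responses_per_cue, 3L))) {
          if (stats::runif(1) < config$blank_prob) next
          src <- if (length(own) > 0 && stats::runif(1) < config$h) own else any_word
          resp[ci, slot] <- src[sample.int(length(src), 1L)]
        }
      }
      rows[[p]] <- data.frame(participant = sprintf("p%04d", p), cue = cues,
                              r1 = resp[, 1], r2 = resp[, 2], r3 = resp[, 3],
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    class(df) <- c("fmn_associations", "data.frame")
    df
  })
}

#' Generate a pseudo norm table from ground truth
#'
#' External-norm stand-in on the 1-9 scale typical of affective norm
#' datasets: each word's normed valence is an affine map of its planted
#' mean rating plus Gaussian noise; arousal is higher for extreme-valence
#' pools. Useful for exercising cross-validation and aura contrasts
#' without external data.
#'
#' @param config a `survey_config`.
#' @param truth data.frame from [generate_vocabulary()].
#' @param noise_sd standard deviation of the rating noise.
#' @return data.frame with `word`, `valence_mean`, `arousal_mean`.
#' @export
generate_norms <- function(config, truth, noise_sd = 0.3) {
  with_seed(config$seed + 3000003L, {
    valence <- 1 + (truth$planted_mean - 1) * 2 +
      stats::rnorm(nrow(truth), 0, noise_sd)
    arousal <- 3 + 2 * abs(truth$planted_mean - 3) / 2 +
      stats::rnorm(nrow(truth), 0, noise_sd)
    data.frame(word = truth$word, valence_mean = valence,
               arousal_mean = arousal, stringsAsFactors = FALSE)
  })
}

#' Simulate a full survey
#'
#' Bundles [generate_vocabulary()], [generate_association_forms()],
#' [generate_rating_forms()] and [generate_norms()]. The generated forms
#' pass the io module's validation unchanged and, written with
#' [write_forms()], round-trip through the real parsers.
#'
#' @param config a `survey_config`.
#' @return list with `config`, `truth`, `associations`, `ratings`,
#'   `norms`.
#' @export
simulate_survey <- function(config = survey_config()) {
  v <- generate_vocabulary(config)
  list(config = config, truth = v$truth,
       associations = generate_association_forms(config, v$truth),
       ratings = generate_rating_forms(config, v$truth),
       norms = generate_norms(config, v$truth))
}

#' End-to-end parameter recovery experiment
#'
#' Runs the full pipeline (clean, lexicon, network, homophily) on
#' simulated surveys over a grid of homophily strengths and seeds, and
#' reports, per cell: the fraction of planted valence labels recovered by
#' the lexicon, the observed edge-endpoint tau, and (optionally) the
#' observed tau's percentile in a configuration-model null ensemble.
#'
#' @param h_grid numeric vector of homophily strengths.
#' @param seeds integer vector of seeds (one simulated study per (h,
#'   seed)).
#' @param config template `survey_config`; its `h` and `seed` are
#'   overridden cell by cell.
#' @param n_realisations null-ensemble size per cell (0 skips the null).
#' @return data.frame with columns `h`, `seed`, `label_accuracy`,
#'   `tau_observed`, `null_mean`, `null_percentile`, `n_nodes`, `n_edges`.
#' @export
recovery_experiment <- function(h_grid = c(0, 0.4, 0.8), seeds = 1:10,
                                config = survey_config(),
                                n_realisations = 0L) {
  cells <- expand.grid(h = h_grid, seed = seeds)
  out <- lapply(seq_len(nrow(cells)), function(k) {
    cfg <- config
    cfg$h <- cells$h[k]
    cfg$seed <- as.integer(cells$seed[k])
    sim <- simulate_survey(cfg)
    fit <- forma_mentis(sim$associations, sim$ratings)
    lex <- fit$lexicon$words
    truth <- sim$truth
    acc <- mean(lex$attribute[match(truth$word, lex$word)] == truth$attribute,
                na.rm = TRUE)
    tau <- edge_endpoint_tau(fit$graph)$tau
    nm <- NA_real_
    np <- NA_real_
    if (n_realisations > 0) {
      null <- configuration_null_ensemble(fit$graph, "edge",
                                          n_realisations = n_realisations,
                                          seed = cfg$seed)
      nm <- null$null_mean
      np <- null$percentile_of_observed
    }
    data.frame(h = cfg$h, seed = cfg$seed, label_accuracy = acc,
               tau_observed = tau, null_mean = nm, null_percentile = np,
               n_nodes = igraph::vcount(fit$graph),
               n_edges = igraph::ecount(fit$graph))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
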