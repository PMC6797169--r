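#' Run the full survey-to-results pipeline
#'
#' Reads forms, cleans them, builds the lexicon and both unfiltered and
#' filtered networks, and writes every artifact to an output directory:
#' rejection logs (JSON), lexicon CSV, GraphML networks, aura table CSV,
#' homophily JSON (observed taus + configuration-null summaries) and,
#' when norms are supplied, aura-contrast JSON; plus a manifest recording
#' the config and seed so a rerun reproduces every stochastic output
#' bit-exactly.
#'
#' @param config named list (or path to a YAML/JSON file readable by
#'   [read_run_config()]) with elements: `associations`, `ratings` (paths),
#'   optional `norms`, `map`, and parameters `max_blank_frac` (0.25),
#'   `warmup_k` (3), `alpha` (0.1), `filter_level` (2), `m` (1),
#'   `n_realisations` (50), `seed` (required), `aura_rule` ("polarity"),
#'   `contrast` (logical; requires `norms`), `out_dir` (required).
#' @return the output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  defaults <- list(max_blank_frac = 0.25, warmup_k = 3L, alpha = 0.1,
                   filter_level = 2L, m = 1, n_realisations = 50L,
                   aura_rule = "polarity", contrast = FALSE,
                   population = "survey")
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  for (k in c("associations", "ratings", "seed", "out_dir")) {
    if (is.null(config[[k]])) stop("config is missing required key: ", k)
  }
  if (isTRUE(config$contrast) && is.null(config$norms)) {
    stop("aura contrast requested but no 'norms' path configured")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)

  associations <- read_association_forms(config$associations)
  ratings <- read_rating_forms(config$ratings)
  map <- if (!is.null(config$map)) read_normalization_map(config$map)
  norms <- if (!is.null(config$norms)) read_norms(config$norms)

  fit <- forma_mentis(associations, ratings, map = map,
                      max_blank_frac = config$max_blank_frac,
                      warmup_k = config$warmup_k, alpha = config$alpha,
                      min_participants = 1L,
                      population = config$population)
  jsonlite::write_json(fit$cleaning, outp("cleaning_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  export_lexicon(fit$lexicon, outp("lexicon.csv"))
  export_network(fit$graph, outp("network_unfiltered.graphml"), "graphml")
  filtered <- filter_network(fit$graph, config$filter_level)
  export_network(filtered, outp("network_filtered.graphml"), "graphml")
  analysis_graph <- fit$graph

  utils::write.csv(aura_table(analysis_graph, rule = config$aura_rule),
                   outp("aura_table.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")

  homophily <- lapply(c(edge = "edge", node = "node"), function(st) {
    null <- configuration_null_ensemble(analysis_graph, st,
                                        n_realisations = config$n_realisations,
                                        seed = as.integer(config$seed),
                                        m = config$m)
    unclass(null)
  })
  jsonlite::write_json(homophily, outp("homophily.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (isTRUE(config$contrast)) {
    contrasts <- list()
    for (attrb in c("negative", "positive")) {
      for (meas in intersect(c("valence", "arousal"),
                             sub("_mean", "", names(norms)[-1]))) {
        key <- paste(attrb, meas, sep = "_")
        contrasts[[key]] <- tryCatch(
          aura_contrast(analysis_graph, norms, attrb, attrb, measure = meas,
                        rule = config$aura_rule),
          error = function(e) list(error = conditionMessage(e)))
      }
    }
    jsonlite::write_json(contrasts, outp("aura_contrast.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (!is.null(norms)) {
    cv <- tryCatch(cross_validate(fit$lexicon, norms),
                   error = function(e) list(error = conditionMessage(e)))
    jsonlite::write_json(cv, outp("cross_validation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(config = config[setdiff(names(config), "out_dir")],
                   seed = as.integer(config$seed),
                   n_nodes_unfiltered = igraph::vcount(fit$graph),
                   n_edges_unfiltered = igraph::ecount(fit$graph),
                   n_nodes_filtered = igraph::vcount(filtered),
                   n_edges_filtered = igraph::ecount(filtered),
                   config_hash = config_hash(config))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' @rdname run_pipeline
#' @param path YAML (needs the yaml package) or JSON config file.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

# Stable fingerprint of a config: serialize deterministically and hash.
config_hash <- function(config) {
  config <- config[order(names(config))]
  txt <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
  # small polynomial rolling hash over the code points; dependency-free,
  # stable across platforms
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 67108859
  sprintf("%08x", h)
}

#' Write a simulated survey to disk
#'
#' Emits the association and rating forms (TSV, the same layout the
#' readers expect), the pseudo-norm table, the ground truth and the config
#' (JSON) into a directory.
#'
#' @param sim result of [simulate_survey()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_survey <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_forms(sim$associations, file.path(dir, "associations.tsv"))
  write_forms(sim$ratings, file.path(dir, "ratings.tsv"))
  utils::write.table(sim$norms, file.path(dir, "norms.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
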