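#' Read free-association survey forms
#'
#' Parses a delimited file of continuous free-association responses. Each
#' row is one (participant, cue) presentation with up to three response
#' slots; row order within a participant records the presentation order of
#' cues, which downstream cleaning (warm-up removal) relies on. Blank cells
#' are kept as explicit `NA` so blank fractions stay computable.
#'
#' Expected columns (header required): `participant`, `cue`, `r1`, `r2`,
#' `r3`.
#'
#' @param path path to a delimited text file (UTF-8).
#' @param sep field delimiter; tab by default.
#' @return A data.frame of class `fmn_associations` with columns
#'   `participant`, `cue`, `r1`, `r2`, `r3` (character; `NA` = blank),
#'   rows in file order.
#' @export
read_association_forms <- function(path, sep = "\t") {
  rows <- .read_delim_rows(path, sep, c("participant", "cue", "r1", "r2", "r3"))
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  dup <- duplicated(df[c("participant", "cue")])
  if (any(dup)) {
    d <- df[dup, ][1, ]
    stop(sprintf("duplicate (participant, cue) pair in %s: (%s, %s)",
                 path, d$participant, d$cue))
  }
  if (any(!is.na(df$cue) & df$cue == "")) stop("empty cue token in ", path)
  if (nrow(df) > 0 && anyNA(df$cue)) stop("blank cue in ", path)
  class(df) <- c("fmn_associations", "data.frame")
  df
}

#' Read valence rating forms
#'
#' Parses a delimited file of 1-5 Likert valence ratings. Blank ratings are
#' kept as `NA`; they are interpreted as neutral (a score of 3) only when
#' ratings are pooled, not at read time.
#'
#' Expected columns (header required): `participant`, `word`, `rating`.
#'
#' @inheritParams read_association_forms
#' @return A data.frame of class `fmn_ratings` with columns `participant`,
#'   `word` (character) and `rating` (integer in 1..5 or `NA`).
#' @export
read_rating_forms <- function(path, sep = "\t") {
  rows <- .read_delim_rows(path, sep, c("participant", "word", "rating"))
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(df) > 0 && (anyNA(df$word) || any(df$word == ""))) {
    stop("blank word in ", path)
  }
  rating <- suppressWarnings(as.integer(df$rating))
  bad <- !is.na(df$rating) & (is.na(rating) | rating < 1L | rating > 5L)
  if (any(bad)) {
    stop(sprintf("invalid rating %s in %s (must be 1-5 or blank)",
                 df$rating[bad][1], path))
  }
  df$rating <- rating
  dup <- duplicated(df[c("participant", "word")])
  if (any(dup)) {
    d <- df[dup, ][1, ]
    stop(sprintf("duplicate rating for (participant, word) in %s: (%s, %s)",
                 path, d$participant, d$word))
  }
  class(df) <- c("fmn_ratings", "data.frame")
  df
}

#' Read an external affective norm table
#'
#' Reads a table of per-word mean valence (and optionally mean arousal)
#' from an external norm dataset. Any table with columns `word`,
#' `valence_mean` and optionally `arousal_mean` is accepted. Words are
#' lowercased; exact duplicate rows are dropped, conflicting duplicates are
#' an error.
#'
#' @inheritParams read_association_forms
#' @param sep field delimiter; `","` and `"\t"` are typical.
#' @return data.frame with columns `word`, `valence_mean` and, when
#'   present in the file, `arousal_mean`.
#' @export
read_norms <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8", comment.char = "")
  if (!all(c("word", "valence_mean") %in% names(df))) {
    stop("norm table ", path, " must declare columns 'word' and 'valence_mean'")
  }
  keep <- intersect(c("word", "valence_mean", "arousal_mean"), names(df))
  df <- df[keep]
  df$word <- tolower(df$word)
  df <- unique(df)
  if (anyDuplicated(df$word)) {
    w <- df$word[duplicated(df$word)][1]
    stop("conflicting duplicate norm entries for word '", w, "' in ", path)
  }
  num_cols <- setdiff(keep, "word")
  for (cc in num_cols) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(!is.finite(df[[cc]]))) stop("non-finite ", cc, " in ", path)
  }
  rownames(df) <- NULL
  df
}

#' Read a token-normalization map
#'
#' Two-column delimited file mapping raw token variants to canonical forms
#' (e.g. plural to singular, multi-word responses to a single word).
#' Canonical tokens must be lowercase and the map must be idempotent:
#' applying it to its own canonical forms changes nothing.
#'
#' @inheritParams read_association_forms
#' @return named character vector: `names` are variants, values canonical.
#' @export
read_normalization_map <- function(path, sep = "\t") {
  rows <- .read_delim_rows(path, sep, c("variant", "canonical"))
  map <- stats::setNames(rows$canonical, rows$variant)
  validate_normalization_map(map)
}

#' @rdname read_normalization_map
#' @param map named character vector (variant -> canonical).
#' @export
validate_normalization_map <- function(map) {
  if (length(map) == 0) return(map)
  if (anyNA(map) || anyNA(names(map))) stop("normalization map has blanks")
  if (any(map != tolower(map))) stop("canonical tokens must be lowercase")
  hit <- map %in% names(map)
  if (any(map[hit] != unname(map[match(map[hit], names(map))]))) {
    stop("normalization map is not idempotent")
  }
  if (anyDuplicated(names(map))) stop("duplicate variants in normalization map")
  map
}

# Strict row-wise delimited parser: exact column count per row, errors name
# file and line. Empty cells become NA.
.read_delim_rows <- function(path, sep, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) {
    out <- rep(list(character(0)), length(cols))
    names(out) <- cols
    return(out)
  }
  header <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  if (!identical(header, cols)) {
    stop(sprintf("%s line 1: expected header %s, found %s",
                 path, paste(cols, collapse = sep), lines[[1]]))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  parsed <- strsplit(body, sep, fixed = TRUE)
  out <- rep(list(character(length(parsed))), length(cols))
  names(out) <- cols
  for (i in seq_along(parsed)) {
    f <- parsed[[i]]
    # strsplit drops trailing empty fields; pad back up to the column count
    if (length(f) < length(cols)) f <- c(f, rep("", length(cols) - length(f)))
    if (length(f) != length(cols)) {
      stop(sprintf("%s line %d: expected %d fields, found %d",
                   path, i + 1L, length(cols), length(f)))
    }
    for (j in seq_along(cols)) out[[j]][i] <- f[j]
  }
  for (j in seq_along(out)) out[[j]][out[[j]] == ""] <- NA_character_
  out
}

#' Write association or rating forms
#'
#' Inverse of [read_association_forms()] / [read_rating_forms()]: writes
#' the same tab-delimited layout with blanks as empty cells, so cleaned
#' forms round-trip byte-identically.
#'
#' @param forms an `fmn_associations` or `fmn_ratings` data.frame.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_forms <- function(forms, path, sep = "\t") {
  df <- as.data.frame(forms)
  cells <- lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  lines <- c(paste(names(df), collapse = sep),
             if (nrow(df) > 0) do.call(paste, c(cells, sep = sep)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}
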