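#' Lowercase and normalize survey tokens
#'
#' Applies the token cleaning step: every cue and response (or rated word)
#' is lowercased and then passed through the user-supplied normalization
#' map (variant -> canonical, e.g. `"muscles" -> "muscle"`). Tokens absent
#' from the map pass through lowercased; blanks are untouched. The
#' operation is idempotent provided the map is (which
#' [validate_normalization_map()] enforces).
#'
#' @param forms an `fmn_associations` or `fmn_ratings` data.frame.
#' @param map named character vector (variant -> canonical), or `NULL` for
#'   lowercasing only.
#' @return forms of the same class with normalized tokens.
#' @export
normalize_tokens <- function(forms, map = NULL) {
  if (!is.null(map)) map <- validate_normalization_map(map)
  norm1 <- function(tok) {
    out <- tolower(tok)
    if (!is.null(map) && length(map)) {
      hit <- match(out, names(map))
      out[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
    }
    out
  }
  token_cols <- intersect(c("cue", "r1", "r2", "r3", "word"), names(forms))
  for (cc in token_cols) forms[[cc]] <- norm1(forms[[cc]])
  forms
}

#' Discard forms with too many blank responses
#'
#' A participant's form is rejected when its fraction of blank cells
#' exceeds `max_blank_frac` (strictly greater; the threshold itself is
#' kept). For association forms the cell count is (number of cues seen) x
#' (3 response slots); for rating forms it is the number of words rated.
#'
#' @param forms an `fmn_associations` or `fmn_ratings` data.frame.
#' @param max_blank_frac rejection threshold in `[0, 1]`; a form is dropped
#'   iff blank cells / total cells > `max_blank_frac`.
#' @return list with `kept` (forms of the input class) and `log` (one row
#'   per participant: `participant`, `n_cells`, `n_blank`, `blank_frac`,
#'   `rejected`).
#' @export
discard_incomplete_forms <- function(forms, max_blank_frac = 0.25) {
  stopifnot(max_blank_frac >= 0, max_blank_frac <= 1)
  cls <- class(forms)
  if (inherits(forms, "fmn_associations")) {
    cell_cols <- c("r1", "r2", "r3")
  } else if (inherits(forms, "fmn_ratings")) {
    cell_cols <- "rating"
  } else {
    stop("forms must be fmn_associations or fmn_ratings")
  }
  participants <- unique(forms$participant)
  n_cells <- integer(length(participants))
  n_blank <- integer(length(participants))
  for (i in seq_along(participants)) {
    sub <- forms[forms$participant == participants[i], cell_cols, drop = FALSE]
    n_cells[i] <- nrow(sub) * length(cell_cols)
    if (n_cells[i] == 0) stop("form with zero cells: ", participants[i])
    n_blank[i] <- sum(vapply(sub, function(col) sum(is.na(col)), 0L))
  }
  frac <- ifelse(n_cells > 0, n_blank / n_cells, NA_real_)
  rejected <- frac > max_blank_frac
  log <- data.frame(participant = participants, n_cells = n_cells,
                    n_blank = n_blank, blank_frac = frac,
                    rejected = rejected, stringsAsFactors = FALSE)
  kept <- forms[forms$participant %in% participants[!rejected], , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- cls
  list(kept = kept, log = log)
}

#' Blank out warm-up associates
#'
#' Replaces each participant's first `k` response tokens -- in presentation
#' order (cue order as recorded in the form, response slots r1, r2, r3
#' within each cue) -- with blanks, to strip warm-up responses that mostly
#' echo the task instructions. Cues themselves are unchanged, and the
#' blanked cells still count toward the blank fraction if rejection is
#' applied afterwards.
#'
#' @param forms an `fmn_associations` data.frame.
#' @param k number of leading response slots to blank per participant.
#' @return forms with warm-up responses blanked.
#' @export
drop_warmup_associates <- function(forms, k = 3L) {
  stopifnot(k >= 0)
  if (!inherits(forms, "fmn_associations")) {
    stop("forms must be fmn_associations")
  }
  if (k == 0 || nrow(forms) == 0) return(forms)
  for (p in unique(forms$participant)) {
    rows <- which(forms$participant == p)
    blanked <- 0L
    for (r in rows) {
      for (slot in c("r1", "r2", "r3")) {
        if (blanked >= k) break
        forms[r, slot] <- NA_character_
        blanked <- blanked + 1L
      }
      if (blanked >= k) break
    }
  }
  forms
}

#' Clean survey forms end to end
#'
#' Applies the full cleaning pipeline in a fixed order: lowercase +
#' normalization map, then warm-up removal (association forms only), then
#' blank-fraction rejection -- so cells blanked as warm-up count toward the
#' rejection rule, the conservative ordering.
#'
#' @param associations `fmn_associations` data.frame.
#' @param ratings `fmn_ratings` data.frame.
#' @param map optional normalization map.
#' @param max_blank_frac blank-fraction rejection threshold.
#' @param warmup_k warm-up response slots blanked per association form.
#' @return list with cleaned `associations`, `ratings`, per-task rejection
#'   logs (`association_log`, `rating_log`) and `rejected_overlap`, the
#'   participants rejected in both tasks (the two tasks are filtered
#'   independently).
#' @export
clean_survey <- function(associations, ratings, map = NULL,
                         max_blank_frac = 0.25, warmup_k = 3L) {
  associations <- normalize_tokens(associations, map)
  ratings <- normalize_tokens(ratings, map)
  associations <- drop_warmup_associates(associations, warmup_k)
  a <- discard_incomplete_forms(associations, max_blank_frac)
  r <- discard_incomplete_forms(ratings, max_blank_frac)
  overlap <- intersect(a$log$participant[a$log$rejected],
                       r$log$participant[r$log$rejected])
  list(associations = a$kept, ratings = r$kept,
       association_log = a$log, rating_log = r$log,
       rejected_overlap = overlap)
}
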