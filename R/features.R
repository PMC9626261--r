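#' Bigram cell codecs for pitch and rhythm statistics
#'
#' Melodic transitions are encoded with the extended pitch class
#' representation: a transition from pitch `p_prev` to pitch `p` (semitone
#' integers, MIDI convention) maps to a cell `(q_prev, q)` with
#' `q_prev = p_prev mod 12` and `q = (q_prev + p - p_prev) mod 36`. The
#' encoding is independent of pitch register and distinguishes signed
#' intervals from -17 to +17 semitones; +18 and -18 fall in the same cell.
#' The pitch table has 12 x 36 = 432 cells. Rhythm transitions are pairs of
#' metrical positions on a 48-unit bar grid, giving a 48 x 48 = 2304-cell
#' table.
#'
#' Cells are indexed 1..D in row-major order (`q_prev * 36 + q + 1` for
#' pitch, `b_prev * 48 + b + 1` for rhythm), and `*_cell_pair()` inverts the
#' index exactly.
#'
#' @param p_prev,p Integer pitches in semitones of the earlier and later note.
#' @param b_prev,b Integer metrical positions in `0..47` (0 = downbeat; 12 =
#'   second beat of 4/4).
#' @param index Integer cell index in `1..432` (pitch) or `1..2304` (rhythm).
#' @return `pitch_bigram_cell()` / `rhythm_bigram_cell()` return integer cell
#'   indices; `pitch_cell_pair()` / `rhythm_cell_pair()` return a tibble with
#'   the row/column pair of each index; `pitch_cell_labels()` /
#'   `rhythm_cell_labels()` return the column labels used in style tables.
#' @examples
#' pitch_bigram_cell(60, 62) # q' = 0, q = 2 -> cell 3
#' rhythm_bigram_cell(0, 12)
#' @name bigram_codec
NULL

#' @rdname bigram_codec
#' @export
pitch_bigram_cell <- function(p_prev, p) {
  if (any(p_prev != round(p_prev)) || any(p != round(p)))
    abort("pitches must be integer semitones")
  qp <- p_prev %% 12
  q <- (qp + p - p_prev) %% 36
  as.integer(qp * 36 + q + 1)
}

#' @rdname bigram_codec
#' @export
rhythm_bigram_cell <- function(b_prev, b) {
  if (any(b_prev < 0 | b_prev > 47 | b < 0 | b > 47))
    abort("metrical positions must lie in 0..47")
  as.integer(b_prev * 48 + b + 1)
}

#' @rdname bigram_codec
#' @export
pitch_cell_pair <- function(index) {
  stopifnot(all(index >= 1 & index <= 432))
  i0 <- as.integer(index) - 1L
  tibble(q_prev = i0 %/% 36L, q = i0 %% 36L)
}

#' @rdname bigram_codec
#' @export
rhythm_cell_pair <- function(index) {
  stopifnot(all(index >= 1 & index <= 2304))
  i0 <- as.integer(index) - 1L
  tibble(b_prev = i0 %/% 48L, b = i0 %% 48L)
}

#' @rdname bigram_codec
#' @export
pitch_cell_labels <- function() {
  pr <- pitch_cell_pair(1:432)
  sprintf("q'%d_q%d", pr$q_prev, pr$q)
}

#' @rdname bigram_codec
#' @export
rhythm_cell_labels <- function() {
  pr <- rhythm_cell_pair(1:2304)
  sprintf("b'%d_b%d", pr$b_prev, pr$b)
}

style_meta_cols <- c("song_id", "year", "n_events")

new_style_tbl <- function(theta, song_id, year, n_events, kind, labels) {
  colnames(theta) <- labels
  out <- dplyr::bind_cols(
    tibble(song_id = as.character(song_id),
           year = as.integer(year),
           n_events = as.double(n_events)),
    as_tibble(theta)
  )
  attr(out, "feature_kind") <- kind
  class(out) <- c("style_tbl", class(out))
  out
}

#' Style tables: per-song probability vectors
#'
#' A style table is a tibble with one row per song: identifier columns
#' `song_id`, `year`, `n_events` (the total event count behind the vector,
#' used as evidence weight in clustering), followed by D probability columns
#' that sum to one in every row. `style_theta()` extracts the probability
#' matrix, `style_counts()` the implied count matrix
#' (`theta * n_events`), and `style_feature_kind()` the declared feature kind.
#'
#' @param styles A style table as returned by the featurizers or
#'   [sample_ddmm_dataset()].
#' @return `style_theta()` and `style_counts()` return numeric matrices with
#'   one row per song; `style_feature_kind()` a string.
#' @name style_tbl
NULL

#' @rdname style_tbl
#' @export
style_theta <- function(styles) {
  m <- as.matrix(styles[, setdiff(names(styles), style_meta_cols), drop = FALSE])
  rownames(m) <- styles$song_id
  m
}

#' @rdname style_tbl
#' @export
style_counts <- function(styles) {
  style_theta(styles) * styles$n_events
}

#' @rdname style_tbl
#' @export
style_feature_kind <- function(styles) {
  attr(styles, "feature_kind") %||% "unknown"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse and validate a note-event table
#'
#' Validates a table of melody note events, snaps onsets declared on a finer
#' grid to the 48-unit bar grid, drops events whose onset cannot be expressed
#' at that resolution (with a warning), orders events by `(bar, position)`
#' within each song, and flags songs left with fewer than two notes (no
#' bigram can be formed from them).
#'
#' Input songs are assumed already transposed to C major / A minor; no key
#' detection is performed.
#'
#' @param notes A data frame with columns `song_id`, `year`, `pitch`
#'   (integer semitones, MIDI convention), `bar` (non-negative integer) and
#'   `position` (integer onset position within the bar).
#' @param resolution Units per bar in which `position` is expressed
#'   (default 48). Positions are rescaled to the 48-unit grid; onsets that do
#'   not land exactly on it are excluded.
#' @return A tibble of surviving note events sorted by song, bar and
#'   position, with attributes `dropped` (number of off-grid events removed)
#'   and `unusable` (song ids with fewer than two surviving notes).
#' @examples
#' notes <- tibble::tibble(song_id = "s1", year = 2000L,
#'                         pitch = c(60L, 62L), bar = 0L, position = c(0L, 12L))
#' parse_note_table(notes)
#' @export
parse_note_table <- function(notes, resolution = 48) {
  req <- c("song_id", "year", "pitch", "bar", "position")
  miss <- setdiff(req, names(notes))
  if (length(miss) > 0)
    abort(paste0("note table is missing column(s): ", paste(miss, collapse = ", ")))
  bad_pitch <- which(!is.finite(notes$pitch) | notes$pitch != round(notes$pitch))
  if (length(bad_pitch) > 0)
    abort(sprintf("non-integer pitch at row(s) %s", paste(head(bad_pitch, 5), collapse = ", ")))
  if (any(notes$bar < 0)) abort("bar indices must be non-negative")
  if (any(notes$position < 0 | notes$position >= resolution))
    abort(sprintf("positions must lie in 0..%d at the declared resolution", resolution - 1L))

  pos48 <- notes$position * 48 / resolution
  on_grid <- abs(pos48 - round(pos48)) < 1e-9
  n_drop <- sum(!on_grid)
  if (n_drop > 0)
    warn(sprintf("%d event(s) with onsets not expressible on the 48-unit grid were excluded", n_drop))
  out <- notes[on_grid, req]
  out$position <- as.integer(round(pos48[on_grid]))
  out <- out %>%
    as_tibble() %>%
    mutate(song_id = as.character(.data$song_id), year = as.integer(.data$year)) %>%
    arrange(.data$song_id, .data$bar, .data$position)

  sizes <- table(out$song_id)
  unusable <- names(sizes)[sizes < 2]
  if (length(unusable) > 0)
    inform(sprintf("%d song(s) have fewer than 2 usable notes and will be skipped by featurizers", length(unusable)))
  attr(out, "dropped") <- n_drop
  attr(out, "unusable") <- unusable
  out
}

bigram_styles <- function(notes, cell_fun, value_col, D, labels, kind) {
  unusable <- attr(notes, "unusable") %||% character()
  notes <- notes %>% filter(!.data$song_id %in% unusable)
  if (nrow(notes) == 0) abort("no usable songs in the note table")
  notes <- arrange(notes, .data$song_id, .data$bar, .data$position)
  ids <- unique(notes$song_id)
  vals <- notes[[value_col]]
  by_song <- split(seq_len(nrow(notes)), factor(notes$song_id, levels = ids))
  counts <- matrix(0, length(ids), D)
  years <- integer(length(ids))
  for (j in seq_along(ids)) {
    rows <- by_song[[j]]
    if (length(rows) < 2) abort(sprintf("song %s has fewer than 2 notes", ids[j]))
    v <- vals[rows]
    idx <- cell_fun(v[-length(v)], v[-1])
    counts[j, ] <- tabulate(idx, nbins = D)
    years[j] <- notes$year[rows[1]]
  }
  tot <- rowSums(counts)
  new_style_tbl(counts / tot, ids, years, tot, kind, labels)
}

#' Featurize melodies into bigram style vectors
#'
#' Computes per-song pitch or rhythm bigram probability vectors from a parsed
#' note table. All consecutive note pairs contribute a bigram: rests and bar
#' boundaries do not break adjacency. A song of L notes therefore yields
#' exactly L - 1 bigram counts, which are normalized into the style vector.
#'
#' @param notes A note table, ideally from [parse_note_table()]. Songs
#'   flagged unusable there are skipped.
#' @return A style table (see [style_tbl]) with 432 (pitch) or 2304 (rhythm)
#'   probability columns.
#' @seealso [bigram_codec] for the cell encodings.
#' @examples
#' notes <- parse_note_table(tibble::tibble(
#'   song_id = "s1", year = 1999L,
#'   pitch = c(60L, 62L, 64L), bar = 0L, position = c(0L, 12L, 24L)))
#' s <- pitch_bigram_styles(notes)
#' sum(style_theta(s))
#' @export
pitch_bigram_styles <- function(notes) {
  bigram_styles(notes, pitch_bigram_cell, "pitch", 432L, pitch_cell_labels(),
                "pitch_bigram")
}

#' @rdname pitch_bigram_styles
#' @export
rhythm_bigram_styles <- function(notes) {
  bigram_styles(notes, rhythm_bigram_cell, "position", 2304L, rhythm_cell_labels(),
                "rhythm_bigram")
}

#' Featurize token sequences into unigram style vectors
#'
#' Converts per-song token sequences over a fixed, ordered vocabulary into
#' unigram probability vectors: `theta_i` = (count of token i) / (sequence
#' length). This is the representation used for lexicalized audio features
#' (e.g. timbre/harmony lexicons) of popular-music corpora.
#'
#' @param sequences A data frame with columns `song_id`, `year` and `tokens`,
#'   where `tokens` is either a list column of character vectors or a
#'   character column of whitespace-separated tokens.
#' @param vocabulary Ordered character vector of allowed tokens; defines the
#'   columns of the result.
#' @return A style table with `length(vocabulary)` probability columns.
#' @examples
#' seqs <- tibble::tibble(song_id = "s1", year = 1980L, tokens = "a a b")
#' unigram_styles(seqs, vocabulary = c("a", "b"))
#' @export
unigram_styles <- function(sequences, vocabulary) {
  req <- c("song_id", "year", "tokens")
  miss <- setdiff(req, names(sequences))
  if (length(miss) > 0)
    abort(paste0("sequence table is missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(vocabulary)) abort("vocabulary has duplicated tokens")
  toks <- sequences$tokens
  if (!is.list(toks)) toks <- strsplit(as.character(toks), "\\s+")
  D <- length(vocabulary)
  counts <- matrix(0, nrow(sequences), D)
  for (j in seq_along(toks)) {
    tj <- toks[[j]]
    tj <- tj[nzchar(tj)]
    if (length(tj) == 0)
      abort(sprintf("song %s has an empty token sequence", sequences$song_id[j]))
    hit <- match(tj, vocabulary)
    if (anyNA(hit))
      abort(sprintf("token '%s' in song %s is outside the declared vocabulary",
                    tj[which(is.na(hit))[1]], sequences$song_id[j]))
    counts[j, ] <- tabulate(hit, nbins = D)
  }
  tot <- rowSums(counts)
  new_style_tbl(counts / tot, sequences$song_id, sequences$year, tot,
                "unigram", vocabulary)
}
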