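test_that("note tables are parsed, ordered, snapped and filtered", {
  notes <- tibble::tibble(song_id = "s1", year = 2000L,
                          pitch = c(62L, 60L), bar = c(0L, 0L),
                          position = c(12L, 0L))
  out <- parse_note_table(notes)
  expect_equal(nrow(out), 2)
  expect_equal(out$pitch, c(60L, 62L)) # reordered by (bar, position)

  # onsets on a finer declared grid: exact multiples snap, others are dropped
  fine <- tibble::tibble(song_id = "s2", year = 2000L,
                         pitch = c(60L, 61L, 62L), bar = 0L,
                         position = c(0L, 1L, 48L))
  expect_warning(out2 <- parse_note_table(fine, resolution = 144),
                 "excluded")
  expect_equal(out2$position, c(0L, 16L))
  expect_equal(attr(out2, "dropped"), 1L)

  # single-note songs cannot produce bigrams
  single <- tibble::tibble(song_id = c("a", "b", "b"), year = 2000L,
                           pitch = 60L, bar = 0L, position = c(0L, 0L, 12L))
  expect_message(out3 <- parse_note_table(single), "fewer than 2")
  expect_equal(attr(out3, "unusable"), "a")

  expect_error(parse_note_table(notes[, -3]), "missing column")
  expect_error(
    parse_note_table(tibble::tibble(song_id = "x", year = 1L, pitch = 60.5,
                                    bar = 0L, position = 0L)),
    "non-integer pitch")
})

test_that("extended pitch class encoding distinguishes signed intervals up to 17", {
  for (p0 in 48:59) {
    for (d in 1:17) {
      expect_false(pitch_bigram_cell(p0, p0 + d) == pitch_bigram_cell(p0, p0 - d))
    }
    expect_identical(pitch_bigram_cell(p0, p0 + 18), pitch_bigram_cell(p0, p0 - 18))
  }
  # register invariance: transposing both notes by octaves keeps the cell
  expect_identical(pitch_bigram_cell(60, 67), pitch_bigram_cell(72, 79))
})

test_that("cell index and (row, col) pair round-trip exactly over all cells", {
  pp <- pitch_cell_pair(1:432)
  expect_identical(as.integer(pp$q_prev * 36 + pp$q + 1), 1:432)
  expect_true(all(pp$q_prev >= 0 & pp$q_prev <= 11))
  expect_true(all(pp$q >= 0 & pp$q <= 35))
  rp <- rhythm_cell_pair(1:2304)
  expect_identical(as.integer(rp$b_prev * 48 + rp$b + 1), 1:2304)
  expect_length(pitch_cell_labels(), 432)
  expect_length(rhythm_cell_labels(), 2304)
})

test_that("pitch bigram vectors count consecutive transitions in extended pitch class", {
  notes <- parse_note_table(tibble::tibble(
    song_id = "s", year = 1990L, pitch = c(60L, 62L), bar = 0L,
    position = c(0L, 12L)))
  s <- pitch_bigram_styles(notes)
  th <- drop(style_theta(s))
  expect_equal(unname(th[pitch_bigram_cell(60, 62)]), 1)
  expect_equal(sum(th > 0), 1)
  expect_equal(s$n_events, 1)

  # +18 and -18 semitone intervals share one cell
  expect_identical(pitch_bigram_cell(60, 78), pitch_bigram_cell(60, 42))

  # L notes yield exactly L - 1 bigrams
  tri <- parse_note_table(tibble::tibble(
    song_id = "s", year = 1990L, pitch = c(60L, 62L, 64L), bar = 0L,
    position = c(0L, 12L, 24L)))
  s3 <- pitch_bigram_styles(tri)
  expect_equal(s3$n_events, 2)
  expect_equal(unname(sort(drop(style_theta(s3))[drop(style_theta(s3)) > 0])),
               c(0.5, 0.5))
  expect_error(pitch_bigram_styles(notes[1, ]), "fewer than 2")
})

test_that("rhythm bigram vectors use metrical positions; bar lines do not break adjacency", {
  notes <- parse_note_table(tibble::tibble(
    song_id = "s", year = 1990L, pitch = 60L, bar = c(0L, 0L),
    position = c(0L, 12L)))
  th <- drop(style_theta(rhythm_bigram_styles(notes)))
  expect_equal(unname(th[rhythm_bigram_cell(0, 12)]), 1)

  # consecutive downbeats across a bar boundary form a (0, 0) bigram
  across <- parse_note_table(tibble::tibble(
    song_id = "s", year = 1990L, pitch = 60L, bar = c(0L, 1L),
    position = c(0L, 0L)))
  th2 <- drop(style_theta(rhythm_bigram_styles(across)))
  expect_equal(unname(th2[rhythm_bigram_cell(0, 0)]), 1)

  long <- parse_note_table(tibble::tibble(
    song_id = "s", year = 1990L, pitch = 60L, bar = 0:4,
    position = rep(c(0L, 24L, 12L, 36L, 6L), 1)))
  expect_equal(rhythm_bigram_styles(long)$n_events, 4)
})

test_that("unigram vectors normalize token counts over a fixed vocabulary", {
  seqs <- tibble::tibble(song_id = "s", year = 1980L, tokens = "a a b")
  s <- unigram_styles(seqs, vocabulary = c("a", "b"))
  expect_equal(unname(drop(style_theta(s))), c(2 / 3, 1 / 3))

  mono <- unigram_styles(tibble::tibble(song_id = "s", year = 1L, tokens = "a a"),
                         c("a", "b"))
  expect_equal(unname(drop(style_theta(mono))), c(1, 0))

  vocab35 <- sprintf("T%02d", 1:35)
  s35 <- unigram_styles(tibble::tibble(song_id = "s", year = 1L,
                                       tokens = "T01 T05 T35"), vocab35)
  expect_equal(ncol(style_theta(s35)), 35)

  expect_error(unigram_styles(tibble::tibble(song_id = "s", year = 1L,
                                             tokens = "a z"), c("a", "b")),
               "'z'")
  expect_error(unigram_styles(tibble::tibble(song_id = "s", year = 1L,
                                             tokens = ""), c("a", "b")),
               "empty")
})

test_that("featurizers are pure and always emit unit-sum non-negative vectors", {
  notes <- parse_note_table(tibble::tibble(
    song_id = rep(c("a", "b"), each = 5), year = 2001L,
    pitch = c(60L, 64L, 67L, 65L, 62L, 55L, 59L, 60L, 62L, 64L),
    bar = rep(c(0L, 0L, 0L, 1L, 1L), 2),
    position = rep(c(0L, 12L, 24L, 0L, 24L), 2)))
  s1 <- pitch_bigram_styles(notes)
  s2 <- pitch_bigram_styles(notes)
  expect_identical(s1, s2)
  th <- style_theta(s1)
  expect_true(all(th >= 0))
  expect_equal(unname(rowSums(th)), rep(1, nrow(th)), tolerance = 1e-9)
  r <- rhythm_bigram_styles(notes)
  expect_equal(unname(rowSums(style_theta(r))), rep(1, 2), tolerance = 1e-9)
})
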