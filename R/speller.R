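# Scanning-speller paradigm: layout, condition phrases, cue event stream.

SPELLER_CHARS <- c(LETTERS, as.character(0:8), " ")
PHRASE_TEXT <- "HELLO IM FINE"
CONTROL_TEXT <- strrep("O", 13)

#' Default 6 x 6 speller layout
#'
#' Builds the character matrix of the scanning speller: the 26 letters A-Z in
#' row-major order, then the digits 0-8, with the space character in the last
#' cell. Cell coordinates are zero-based `(column, row)` pairs with `A` at
#' `(0, 0)` (top-left).
#'
#' @return An object of class `speller_layout`: a list with `grid` (6 x 6
#'   character matrix, rows top to bottom) and `cells` (tibble with columns
#'   `char`, `col`, `row`).
#' @examples
#' lay <- speller_layout()
#' lay$grid
#' @export
speller_layout <- function() {
  grid <- matrix(SPELLER_CHARS, nrow = 6, ncol = 6, byrow = TRUE)
  idx0 <- seq_along(SPELLER_CHARS) - 1L
  cells <- tibble::tibble(
    char = SPELLER_CHARS,
    col = idx0 %% 6L,
    row = idx0 %/% 6L
  )
  structure(list(grid = grid, cells = cells), class = "speller_layout")
}

#' @export
print.speller_layout <- function(x, ...) {
  cat("<speller_layout> 6 x 6 matrix\n")
  print(x$grid, quote = FALSE)
  invisible(x)
}

layout_cell <- function(layout, char) {
  i <- match(char, layout$cells$char)
  if (anyNA(i)) {
    abort(sprintf(
      "character(s) not in speller layout: %s",
      paste(unique(char[is.na(i)]), collapse = ", ")
    ))
  }
  layout$cells[i, ]
}

#' Target phrase for an experimental condition
#'
#' The three study conditions use 13-character phrases: the control condition
#' repeats the letter `O` thirteen times; the phrase condition spells
#' `"HELLO IM FINE"`; the random condition is a seeded permutation of the
#' characters of that phrase.
#'
#' @param condition One of `"control"`, `"phrase"`, `"random"`.
#' @param seed Integer seed; required (and only used) for `"random"`.
#' @return A 13-character string.
#' @examples
#' plan_condition("control")
#' plan_condition("random", seed = 7)
#' @export
plan_condition <- function(condition, seed = NULL) {
  condition <- match.arg(condition, c("control", "phrase", "random"))
  switch(condition,
    control = CONTROL_TEXT,
    phrase = PHRASE_TEXT,
    random = {
      if (is.null(seed)) abort("`seed` is required for the random condition")
      chars <- strsplit(PHRASE_TEXT, "")[[1]]
      withr::with_seed(seed, paste(sample(chars), collapse = ""))
    }
  )
}

#' Selector timing of the scanning speller
#'
#' The selector bar dwells a fixed time on each column (left to right), then on
#' each row (bottom to top); after every selection it pauses before resuming.
#' The cued movement is expected at the midpoint of the target cell's dwell,
#' i.e. `midpoint_offset_s` after cue onset. `lead_in_s` is quiet recording
#' time before the first sweep so that pre-cue epochs fit.
#'
#' @param dwell_s Seconds the selector spends per column/row. Default 2.
#' @param pause_s Seconds paused after each selection. Default 2.
#' @param midpoint_offset_s Expected movement time after cue onset. Default 1.
#' @param lead_in_s Seconds of recording before the first sweep. Default 5.
#' @return An object of class `timing_spec`.
#' @export
timing_spec <- function(dwell_s = 2, pause_s = 2, midpoint_offset_s = 1,
                        lead_in_s = 5) {
  stopifnot(dwell_s > 0, pause_s > 0, midpoint_offset_s > 0, lead_in_s >= 0)
  if (midpoint_offset_s > dwell_s) {
    abort("`midpoint_offset_s` must not exceed `dwell_s`")
  }
  structure(
    list(dwell_s = dwell_s, pause_s = pause_s,
         midpoint_offset_s = midpoint_offset_s, lead_in_s = lead_in_s),
    class = "timing_spec"
  )
}

#' Simulate a spelling session's cue events
#'
#' Emits the column/row onset (cue) stream for one phrase under constant-dwell
#' scanning. For each character the selector sweeps the columns left to right;
#' the column cue fires the moment the bar enters the target column. After the
#' column selection and a pause, the rows are swept bottom to top and the row
#' cue fires on entry into the target row. Each cue is one trial, so a
#' 13-character phrase yields 26 trials.
#'
#' @param phrase Character string; every character must be in `layout`.
#' @param layout A [speller_layout()].
#' @param timing A [timing_spec()].
#' @param condition Optional condition label carried into the event table.
#' @return A tibble with columns `onset_s`, `type` (`"column"`/`"row"`),
#'   `target_char`, `trial_idx` (0-based), `condition`.
#' @examples
#' ev <- simulate_session("HELLO IM FINE")
#' nrow(ev) # 26
#' @export
simulate_session <- function(phrase, layout = speller_layout(),
                             timing = timing_spec(),
                             condition = NA_character_) {
  chars <- strsplit(phrase, "")[[1]]
  if (length(chars) == 0) abort("`phrase` is empty")
  cells <- layout_cell(layout, chars)
  t <- timing$lead_in_s
  onsets <- numeric(2 * length(chars))
  types <- character(2 * length(chars))
  for (i in seq_along(chars)) {
    col <- cells$col[i]
    row <- cells$row[i]
    # column sweep, left to right
    onsets[2 * i - 1] <- t + col * timing$dwell_s
    types[2 * i - 1] <- "column"
    t <- t + (col + 1) * timing$dwell_s + timing$pause_s
    # row sweep, bottom to top (row 5 scanned first)
    row_pos <- 5 - row
    onsets[2 * i] <- t + row_pos * timing$dwell_s
    types[2 * i] <- "row"
    t <- t + (row_pos + 1) * timing$dwell_s + timing$pause_s
  }
  tibble::tibble(
    onset_s = onsets,
    type = types,
    target_char = rep(chars, each = 2),
    trial_idx = seq_along(onsets) - 1L,
    condition = condition
  )
}
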