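#' Well addresses on a 384-well plate
#'
#' Wells are addressed by a row letter A--P and a 1-based column number
#' 1--24, following plate-reader convention. `parse_well()` accepts both
#' zero-padded and bare column numbers ("B07" and "B7" are the same well);
#' `format_well()` produces the canonical zero-padded form used everywhere
#' in this package.
#'
#' @param x character vector of well addresses.
#' @return `parse_well()`: a data.frame with columns `row` (character),
#'   `column` (integer) and `well` (canonical address). `format_well()`:
#'   a character vector of canonical addresses.
#' @examples
#' parse_well(c("A1", "B07", "P24"))
#' format_well("p", 3)
#' @export
parse_well <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^([A-Pa-p])([0-9]{1,2})$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    screen_abort(
      sprintf("invalid well address(es): %s (expected row A-P, column 1-24)",
              paste(unique(x[bad]), collapse = ", ")),
      "rnaiscreen_address_error")
  }
  row <- toupper(vapply(m, `[`, character(1), 2L))
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  oob <- col < 1L | col > 24L
  if (any(oob)) {
    screen_abort(
      sprintf("well column out of range 1-24: %s",
              paste(unique(x[oob]), collapse = ", ")),
      "rnaiscreen_address_error")
  }
  data.frame(row = row, column = col, well = sprintf("%s%02d", row, col),
             stringsAsFactors = FALSE)
}

#' @rdname parse_well
#' @param row row letters A--P.
#' @param column column numbers 1--24.
#' @export
format_well <- function(row, column) {
  row <- toupper(as.character(row))
  column <- as.integer(column)
  if (any(!row %in% LETTERS[1:16]) || any(column < 1L | column > 24L)) {
    screen_abort("well coordinates outside the 16x24 plate",
                 "rnaiscreen_address_error")
  }
  sprintf("%s%02d", row, column)
}

#' @rdname parse_well
#' @export
canonical_well <- function(x) parse_well(x)$well

#' All 384 canonical well addresses
#'
#' Row-major order: A01..A24, B01..B24, ..., P01..P24.
#' @return character vector of length 384.
#' @export
plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:16], 1:24, function(r, c) sprintf("%s%02d", r, c))))
}

well_row <- function(w) substr(w, 1L, 1L)
well_col <- function(w) as.integer(substr(w, 2L, 3L))
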