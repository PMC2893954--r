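#' Parse 384-well plate addresses
#'
#' Converts letter+number well addresses (rows A-P, columns 1-24) into
#' 0-based row/column indices. User-facing text is always 1-based
#' ("C3" = row C, column 3); internal indices are 0-based.
#'
#' @param x character vector of well addresses such as "A1", "C3", "P24".
#' @return A data.frame with columns \code{well} (canonical text),
#'   \code{row} and \code{col} (0-based integer indices).
#' @examples
#' parseWellAddress(c("A1", "C3", "P24"))
#' @export
parseWellAddress <- function(x) {
  if (!is.character(x) || length(x) == 0)
    stop("well address must be a non-empty character vector")
  m <- regmatches(x, regexec("^([A-Pa-p])0*([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed well address: ", paste(x[bad], collapse = ", "))
  row <- match(toupper(vapply(m, `[`, "", 2L)), LETTERS) - 1L
  col <- as.integer(vapply(m, `[`, "", 3L)) - 1L
  if (any(col < 0L | col > 23L))
    stop("column out of range 1-24: ", paste(x[col < 0L | col > 23L], collapse = ", "))
  data.frame(well = formatWellAddress(row, col), row = row, col = col,
             stringsAsFactors = FALSE)
}

#' Format 0-based plate indices as well addresses
#'
#' @param row,col 0-based integer indices (row 0-15, column 0-23).
#' @return character vector of canonical addresses ("C3" style).
#' @examples
#' formatWellAddress(2, 2) # "C3"
#' @export
formatWellAddress <- function(row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(is.na(row) | row < 0L | row > 15L))
    stop("row index out of range 0-15")
  if (any(is.na(col) | col < 0L | col > 23L))
    stop("column index out of range 0-23")
  paste0(LETTERS[row + 1L], col + 1L)
}

#' All 384 well addresses in row-major order
#'
#' @return character vector "A1", "A2", ..., "P24".
#' @export
allWellAddresses <- function() {
  as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
}
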