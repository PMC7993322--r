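#' Plate well labels and indices
#'
#' Microplate wells are addressed in the plate-reader convention: rows are
#' letters (A, B, ...), columns are 1-based numbers, so the top-left well of
#' a 96-well plate is "A1" and the bottom-right is "H12". Internally wells
#' are numbered 1..n in row-major order (A1, A2, ..., A12, B1, ...).
#'
#' @param rows,cols Plate geometry (8 x 12 for a 96-well plate, 4 x 6 for a
#'   24-well plate).
#' @return `well_labels()` returns a character vector of length `rows * cols`
#'   in row-major order.
#' @examples
#' well_labels(2, 3)
#' well_to_index(c("A1", "B12"), 8, 12)
#' index_to_well(c(1, 96), 8, 12)
#' @export
well_labels <- function(rows = 8, cols = 12) {
  stopifnot(rows >= 1, cols >= 1, rows <= 26)
  as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0)))
}

#' @rdname well_labels
#' @param label Character vector of A1-style labels.
#' @return `well_to_index()` returns 1-based row-major integer indices.
#' @export
well_to_index <- function(label, rows = 8, cols = 12) {
  m <- stringr::str_match(label, "^([A-Z])([0-9]+)$")
  if (anyNA(m[, 1])) {
    abort(paste0("invalid well label(s): ",
                 paste(label[is.na(m[, 1])], collapse = ", ")))
  }
  r <- match(m[, 2], LETTERS)
  c <- as.integer(m[, 3])
  if (any(r > rows) || any(c > cols) || any(c < 1)) {
    abort("well label outside plate geometry")
  }
  (r - 1L) * cols + c
}

#' @rdname well_labels
#' @param index 1-based row-major well indices.
#' @export
index_to_well <- function(index, rows = 8, cols = 12) {
  index <- as.integer(index)
  if (any(index < 1 | index > rows * cols, na.rm = TRUE)) {
    abort("well index outside plate geometry")
  }
  r <- (index - 1L) %/% cols + 1L
  c <- (index - 1L) %% cols + 1L
  paste0(LETTERS[r], c)
}

#' Build a plate of culture wells
#'
#' One row per well, holding the true state of the culture: optical density
#' (OD600), working volume (constant across a grow/dilute cycle under the
#' constant-volume exchange convention), the intrinsic exponential growth
#' constant `k` (1/h), and a fluorescence expression factor (signal per unit
#' OD). An OD of 0 marks a sterile (no-bacteria) well; it is absorbing under
#' growth and never triggers dilution.
#'
#' @param plate Plate label.
#' @param od0 Initial OD per well, recycled to `rows * cols`.
#' @param volume_ul Working volume in microlitres (> 0).
#' @param k Intrinsic growth constant, 1/hour (>= 0), recycled.
#' @param expression_factor Fluorescence per unit OD (>= 0), recycled.
#' @param rows,cols Plate geometry.
#' @return A tibble with columns `plate`, `well`, `od`, `volume_ul`, `k`,
#'   `expression_factor`.
#' @examples
#' culture_plate("P1", od0 = 0.1, k = 0.7)
#' @export
culture_plate <- function(plate = "P1", od0 = 0.05, volume_ul = 175,
                          k = 0.7, expression_factor = 1000,
                          rows = 8, cols = 12) {
  n <- rows * cols
  od0 <- rep_len(od0, n)
  if (any(od0 < 0)) abort("od0 must be >= 0")
  if (any(volume_ul <= 0)) abort("volume_ul must be > 0")
  k <- rep_len(k, n)
  if (any(k < 0)) abort("k must be >= 0")
  expression_factor <- rep_len(expression_factor, n)
  if (any(expression_factor < 0)) abort("expression_factor must be >= 0")
  tibble(
    plate = plate,
    well = well_labels(rows, cols),
    od = od0,
    volume_ul = rep_len(volume_ul, n),
    k = k,
    expression_factor = expression_factor
  )
}
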