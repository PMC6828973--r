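#' Electrode grid layout
#'
#' Describes a rectangular HDEMG electrode grid as used over the lumbar
#' paraspinal muscles: 13 rows x 5 columns of electrodes with 8 mm
#' inter-electrode distance and one electrode absent from one corner (the
#' absent corner gives the grid a directional reference). Rows run along the
#' muscle fibre direction (cranio-caudal); by default row 1 is the caudal
#' edge of the grid.
#'
#' @param n_rows,n_cols Number of electrode rows and columns.
#' @param ied_mm Inter-electrode distance in mm.
#' @param missing_corner Integer `c(row, col)` of the absent electrode, which
#'   must be one of the four corners, or `NULL` for a complete grid.
#' @param orientation `"caudal_row_first"` (row 1 at the caudal grid edge,
#'   the default) or `"cranial_row_first"`.
#'
#' @return An object of class `grid_layout`.
#' @examples
#' lay <- grid_layout()
#' n_electrodes(lay) # 64
#' @export
grid_layout <- function(n_rows = 13L, n_cols = 5L, ied_mm = 8,
                        missing_corner = c(n_rows, n_cols),
                        orientation = c("caudal_row_first", "cranial_row_first")) {
  orientation <- match.arg(orientation)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 2L || n_cols < 1L)
    stop("grid must have at least 2 rows and 1 column")
  if (!is.null(missing_corner)) {
    missing_corner <- as.integer(missing_corner)
    if (length(missing_corner) != 2L)
      stop("missing_corner must be c(row, col) or NULL")
    corners <- rbind(c(1L, 1L), c(1L, n_cols), c(n_rows, 1L), c(n_rows, n_cols))
    if (!any(corners[, 1] == missing_corner[1] & corners[, 2] == missing_corner[2]))
      stop("missing_corner must be one of the four corner coordinates")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, ied_mm = ied_mm,
         missing_corner = missing_corner, orientation = orientation),
    class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  mc <- if (is.null(x$missing_corner)) "none" else
    paste0("(", x$missing_corner[1], ",", x$missing_corner[2], ")")
  cat(sprintf("HDEMG grid: %d x %d electrodes, IED %g mm, missing corner %s, %s\n",
              x$n_rows, x$n_cols, x$ied_mm, mc, x$orientation))
  cat(sprintf("  %d electrodes -> %d bipolar channels\n",
              n_electrodes(x), nrow(enumerate_bipolar_channels(x))))
  invisible(x)
}

#' Number of physical electrodes in a layout
#' @param layout A [grid_layout()].
#' @return Integer electrode count.
#' @export
n_electrodes <- function(layout) {
  layout$n_rows * layout$n_cols - as.integer(!is.null(layout$missing_corner))
}

# Map (row, col) lattice positions to monopolar signal column indices.
# Electrodes are numbered column-major (all rows of column 1, then column 2,
# ...), skipping the missing corner; NA marks the absent electrode.
electrode_index_map <- function(layout) {
  m <- matrix(NA_integer_, layout$n_rows, layout$n_cols)
  k <- 0L
  for (cc in seq_len(layout$n_cols)) {
    for (rr in seq_len(layout$n_rows)) {
      if (!is.null(layout$missing_corner) &&
          rr == layout$missing_corner[1] && cc == layout$missing_corner[2]) next
      k <- k + 1L
      m[rr, cc] <- k
    }
  }
  m
}

# Anatomical y (mm from the caudal grid edge) of an electrode row index.
.row_y_mm <- function(row, layout) {
  if (layout$orientation == "caudal_row_first") (row - 1) * layout$ied_mm
  else (layout$n_rows - row) * layout$ied_mm
}

#' Enumerate single-differential (bipolar) channels of a grid
#'
#' Bipolar channels are formed from adjacent electrode pairs along columns
#' (the cranio-caudal fibre direction), excluding pairs that touch the missing
#' corner. The default 13 x 5 grid with one absent corner electrode yields 59
#' channels on a 12 x 5 bipolar lattice. The difference is taken caudal minus
#' cranial. Enumeration order is deterministic: column-major, caudal to
#' cranial within each column.
#'
#' @param layout A [grid_layout()].
#' @return A data.frame with one row per bipolar channel: `channel` (index in
#'   enumeration order), `lat_row`/`lat_col` (position on the bipolar lattice,
#'   `lat_row` counted from the caudal edge), `elec_caudal`/`elec_cranial`
#'   (monopolar signal column indices), and `x_mm`/`y_mm` (channel midpoint,
#'   origin at the caudal-medial grid corner).
#' @examples
#' nrow(enumerate_bipolar_channels(grid_layout())) # 59
#' @export
enumerate_bipolar_channels <- function(layout) {
  stopifnot(inherits(layout, "grid_layout"))
  emap <- electrode_index_map(layout)
  out <- vector("list", layout$n_cols)
  for (cc in seq_len(layout$n_cols)) {
    rows <- seq_len(layout$n_rows - 1L)
    lo <- emap[rows, cc]; hi <- emap[rows + 1L, cc]
    keep <- !is.na(lo) & !is.na(hi)
    y_lo <- .row_y_mm(rows, layout); y_hi <- .row_y_mm(rows + 1L, layout)
    d <- data.frame(
      lat_col = cc,
      row_pair_lo = rows, row_pair_hi = rows + 1L,
      elec_caudal = ifelse(y_lo < y_hi, lo, hi),
      elec_cranial = ifelse(y_lo < y_hi, hi, lo),
      x_mm = (cc - 1) * layout$ied_mm,
      y_mm = (y_lo + y_hi) / 2)[keep, , drop = FALSE]
    out[[cc]] <- d
  }
  out <- do.call(rbind, out)
  # lattice row counted from the caudal edge (1-based)
  out$lat_row <- as.integer(round(out$y_mm / layout$ied_mm + 0.5))
  # order column-major, caudal to cranial
  out <- out[order(out$lat_col, out$lat_row), ]
  out$channel <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("channel", "lat_row", "lat_col", "row_pair_lo", "row_pair_hi",
          "elec_caudal", "elec_cranial", "x_mm", "y_mm")]
}

#' Anatomical position of a bipolar channel
#'
#' Midpoint of the channel's two electrodes, in mm, origin at the
#' caudal-medial corner of the grid (x across columns, y along the
#' cranio-caudal axis).
#'
#' @param channels One or more rows of the table returned by
#'   [enumerate_bipolar_channels()].
#' @param layout The [grid_layout()] the channels belong to.
#' @return A two-column matrix (`x_mm`, `y_mm`).
#' @export
channel_anatomical_position <- function(channels, layout) {
  stopifnot(inherits(layout, "grid_layout"))
  cbind(x_mm = (channels$lat_col - 1) * layout$ied_mm,
        y_mm = (channels$lat_row - 0.5) * layout$ied_mm)
}
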