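#' Construct a localisation table
#'
#' A localisation table holds one row per detected fluorophore position, with
#' planar coordinates in a consistent length unit (nm for experimental data,
#' arbitrary units for simulations) and an optional channel label.
#'
#' @param x,y Numeric coordinate vectors of equal length.
#' @param channel Optional channel labels (recycled if length 1).
#' @param image_id Identifier of the source image.
#' @return A `data.frame` of class `kna_locs` with columns `x`, `y` and
#'   optionally `channel`, carrying an `image_id` attribute.
#' @export
localisation_table <- function(x, y, channel = NULL, image_id = "image") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("all coordinates must be finite")
  tab <- data.frame(x = x, y = y)
  if (!is.null(channel)) tab$channel <- rep_len(channel, nrow(tab))
  attr(tab, "image_id") <- image_id
  class(tab) <- c("kna_locs", "data.frame")
  tab
}

#' @export
print.kna_locs <- function(x, ...) {
  cat(sprintf("Localisation table '%s': %d localisations\n",
              image_id(x), nrow(x)))
  if (nrow(x) > 0) print(head(as.data.frame(x)), ...)
  invisible(x)
}

#' @rdname localisation_table
#' @param table A `kna_locs` object.
#' @export
image_id <- function(table) {
  id <- attr(table, "image_id")
  if (is.null(id)) "image" else id
}

#' Rectangular observation window
#'
#' @param xmin,xmax,ymin,ymax Window limits (same units as the coordinates).
#'   All four boundaries are closed.
#' @return An object of class `kna_window`.
#' @export
kna_window <- function(xmin, xmax, ymin, ymax) {
  if (!(xmax > xmin) || !(ymax > ymin))
    stop("kna_window requires xmax > xmin and ymax > ymin")
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "kna_window")
}

#' @export
print.kna_window <- function(x, ...) {
  cat(sprintf("Window [%g, %g] x [%g, %g]\n", x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

window_area <- function(w) (w$xmax - w$xmin) * (w$ymax - w$ymin)

#' Read a localisation table from delimited text
#'
#' SMLM exporters disagree on column headers ("x [nm]" from ThunderSTORM-style
#' tables, plain "x" elsewhere); the `column_map` argument names the columns to
#' use. Rows with non-finite coordinates are dropped and counted.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named list/character vector mapping the fields `x`, `y`
#'   and optionally `channel` to column names in the file.
#' @param delimiter Field delimiter (default comma).
#' @param image_id Identifier for the image; defaults to the file name.
#' @return A `kna_locs` table. The number of dropped rows is available as
#'   `attr(, "n_dropped")`.
#' @export
read_localisations <- function(path, column_map = c(x = "x", y = "y"),
                               delimiter = ",", image_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = delimiter, check.names = FALSE,
                  stringsAsFactors = FALSE)
  column_map <- as.list(column_map)
  for (field in c("x", "y")) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw))
      stop(sprintf("column '%s' mapped to field '%s' not found in %s",
                   if (is.null(col)) "<unmapped>" else col, field, path))
  }
  x <- suppressWarnings(as.numeric(raw[[column_map$x]]))
  y <- suppressWarnings(as.numeric(raw[[column_map$y]]))
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no rows with finite coordinates in ", path)
  channel <- NULL
  if (!is.null(column_map$channel) && column_map$channel %in% names(raw))
    channel <- raw[[column_map$channel]][keep]
  if (is.null(image_id)) image_id <- basename(path)
  tab <- localisation_table(x[keep], y[keep], channel = channel,
                            image_id = image_id)
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Write a localisation table to CSV
#'
#' The canonical on-disk format is UTF-8 CSV with a header; a read/write/read
#' round trip reproduces coordinates exactly.
#'
#' @param table A `kna_locs` table.
#' @param path Output path.
#' @export
write_localisations <- function(table, path) {
  df <- as.data.frame(table)
  # full-precision decimal representation so the round trip is bit-exact
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Crop a localisation table to a window
#'
#' Retains points with `xmin <= x <= xmax` and `ymin <= y <= ymax` (all
#' boundaries closed). Cropping is idempotent.
#'
#' @param table A `kna_locs` table.
#' @param win A `kna_window`.
#' @return The cropped table (possibly empty).
#' @export
crop_to_window <- function(table, win) {
  stopifnot(inherits(win, "kna_window"))
  keep <- table$x >= win$xmin & table$x <= win$xmax &
          table$y >= win$ymin & table$y <= win$ymax
  out <- table[keep, , drop = FALSE]
  attr(out, "image_id") <- image_id(table)
  class(out) <- class(table)
  rownames(out) <- NULL
  out
}
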