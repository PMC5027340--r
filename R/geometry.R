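#' Build a regular multielectrode-array geometry
#'
#' Constructs the electrode grid of a planar multielectrode array (MEA):
#' channel coordinates, Moore (8-connected) neighbor lists and a
#' triangulation that splits every grid cell into two triangles. The default
#' device emulated elsewhere in the package is a 128-channel flexible array
#' arranged 16 x 8 with 2.7 mm interelectrode distance and a bipolar
#' stimulation site at the upper-left corner.
#'
#' Channel ids are 0-based and row-major (`channel_id = row * cols + col`),
#' coordinates are in mm with `x_mm = col * pitch_mm`, `y_mm = row * pitch_mm`.
#'
#' @param rows,cols Grid dimensions; both must be >= 2 so that 2-D triangles
#'   exist.
#' @param pitch_mm Interelectrode spacing in mm (default 2.7).
#' @param bad_channels Integer vector of 0-based channel ids excluded from
#'   analysis (default none).
#' @return An object of class `mea_geometry`: a list with `channels`
#'   (data.frame `channel_id,row,col,x_mm,y_mm`), `neighbors` (list of
#'   0-based neighbor id vectors, Moore connectivity), `triangles`
#'   (integer matrix, one row per triangle, 0-based vertex ids),
#'   `pitch_mm`, `rows`, `cols`, `stim_channels` (the two upper-left
#'   electrodes used as the bipolar pacing site) and `bad_channels`.
#' @examples
#' g <- make_geometry(16, 8, 2.7)
#' nrow(g$channels)   # 128
#' @export
make_geometry <- function(rows, cols, pitch_mm = 2.7, bad_channels = integer()) {
  if (length(rows) != 1 || length(cols) != 1 || is.na(rows) || is.na(cols) ||
      rows < 2 || cols < 2) {
    stop_invalid("rows and cols must both be >= 2 (got %s x %s): a 1-D array has no 2-D triangles",
                 toString(rows), toString(cols))
  }
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1 || is.na(pitch_mm) || pitch_mm <= 0) {
    stop_invalid("pitch_mm must be a positive scalar")
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  row_idx <- rep(seq_len(rows) - 1L, each = cols)
  col_idx <- rep(seq_len(cols) - 1L, times = rows)
  channels <- data.frame(
    channel_id = row_idx * cols + col_idx,
    row = row_idx,
    col = col_idx,
    x_mm = col_idx * pitch_mm,
    y_mm = row_idx * pitch_mm
  )

  id_of <- function(r, c) r * cols + c
  offsets <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                   dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  neighbors <- vector("list", rows * cols)
  for (i in seq_len(rows * cols)) {
    r <- row_idx[i]; c <- col_idx[i]
    nr <- r + offsets[, "dr"]; nc <- c + offsets[, "dc"]
    keep <- nr >= 0L & nr < rows & nc >= 0L & nc < cols
    neighbors[[i]] <- sort(id_of(nr[keep], nc[keep]))
  }

  # two triangles per grid cell: lower-left and upper-right split
  n_cells <- (rows - 1L) * (cols - 1L)
  tri <- matrix(0L, nrow = 2L * n_cells, ncol = 3L)
  k <- 0L
  for (r in seq_len(rows - 1L) - 1L) {
    for (c in seq_len(cols - 1L) - 1L) {
      k <- k + 1L
      tri[k, ] <- c(id_of(r, c), id_of(r, c + 1L), id_of(r + 1L, c))
      k <- k + 1L
      tri[k, ] <- c(id_of(r, c + 1L), id_of(r + 1L, c + 1L), id_of(r + 1L, c))
    }
  }
  colnames(tri) <- c("v1", "v2", "v3")

  bad_channels <- as.integer(bad_channels)
  if (length(bad_channels) && (any(bad_channels < 0L) ||
                               any(bad_channels >= rows * cols))) {
    stop_invalid("bad_channels outside 0..%d", rows * cols - 1L)
  }

  structure(list(
    channels = channels,
    neighbors = neighbors,
    triangles = tri,
    pitch_mm = pitch_mm,
    rows = rows,
    cols = cols,
    stim_channels = c(id_of(0L, 0L), id_of(0L, 1L)),
    bad_channels = bad_channels
  ), class = "mea_geometry")
}

#' @export
print.mea_geometry <- function(x, ...) {
  cat(sprintf("MEA geometry: %d x %d grid, %d channels, pitch %.2f mm, %d triangles\n",
              x$rows, x$cols, nrow(x$channels), x$pitch_mm, nrow(x$triangles)))
  if (length(x$bad_channels)) {
    cat("  bad channels:", toString(x$bad_channels), "\n")
  }
  invisible(x)
}

# 1-based position index for a 0-based channel id
chan_index <- function(geometry, channel_id) match(channel_id, geometry$channels$channel_id)

#' Write / read an array geometry as CSV
#'
#' The on-disk format is a plain CSV with header
#' `channel_id,row,col,x_mm,y_mm`. Neighbor and triangle topology are
#' reconstructed from the grid on read, so the file stays minimal.
#'
#' @param geometry An `mea_geometry`.
#' @param path File path.
#' @return `read_geometry_csv` returns an `mea_geometry`.
#' @export
write_geometry_csv <- function(geometry, path) {
  utils::write.csv(geometry$channels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) {
  if (!file.exists(path)) stop_format("geometry file not found: %s", path)
  df <- utils::read.csv(path)
  need <- c("channel_id", "row", "col", "x_mm", "y_mm")
  if (!all(need %in% names(df))) {
    stop_format("geometry CSV missing columns: %s",
                toString(setdiff(need, names(df))))
  }
  rows <- max(df$row) + 1L; cols <- max(df$col) + 1L
  if (nrow(df) != rows * cols) {
    stop_format("geometry CSV is not a complete %d x %d grid", rows, cols)
  }
  pitch <- if (cols > 1) max(df$x_mm) / (cols - 1L) else max(df$y_mm) / (rows - 1L)
  g <- make_geometry(rows, cols, pitch)
  if (!isTRUE(all.equal(g$channels[order(g$channels$channel_id), need],
                        df[order(df$channel_id), need],
                        check.attributes = FALSE, tolerance = 1e-8))) {
    stop_format("geometry CSV coordinates are not a regular row-major grid")
  }
  g
}
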