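#' Labelled 3D marker trajectories
#'
#' Container for the raw input of the toolkit: time series of labelled 3D
#' marker positions, in millimetres, at a fixed frame rate. Missing samples
#' (markers occluded in a frame) are carried as `NA` and tracked in a
#' per-frame, per-marker presence mask; they are never interpolated.
#'
#' @param positions numeric array `frames x markers x 3` (mm), or a list of
#'   `frames x 3` matrices (one per marker). `NA` marks missing samples; a
#'   sample is missing if any of its three coordinates is `NA`.
#' @param marker_ids character vector of marker labels, one per marker.
#' @param frame_rate recording rate in Hz (> 0).
#' @return object of class `marker_trajectory_set` with elements
#'   `positions` (array, `NA` where absent), `marker_ids`, `frame_rate`,
#'   and `present` (frames x markers logical mask).
#' @examples
#' pos <- array(rnorm(10 * 3 * 3), dim = c(10, 3, 3))
#' trj <- marker_trajectory_set(pos, c("a", "b", "c"), frame_rate = 500)
#' trj
#' @export
marker_trajectory_set <- function(positions, marker_ids, frame_rate) {
  if (is.list(positions)) {
    stopifnot(length(positions) == length(marker_ids))
    nf <- nrow(positions[[1]])
    arr <- array(NA_real_, dim = c(nf, length(positions), 3))
    for (m in seq_along(positions)) arr[, m, ] <- as.matrix(positions[[m]])
    positions <- arr
  }
  stopifnot(is.array(positions), length(dim(positions)) == 3,
            dim(positions)[3] == 3)
  if (dim(positions)[1] < 1) stop("need at least one frame")
  if (dim(positions)[2] < 1) stop("need at least one marker")
  if (dim(positions)[2] != length(marker_ids))
    stop("marker_ids length must match the marker dimension")
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    stop("frame_rate must be a single positive number")
  present <- apply(!is.na(positions), c(1, 2), all)
  dimnames(present) <- NULL
  # a partially-NA sample is treated as absent outright
  for (k in 1:3) positions[, , k][!present] <- NA_real_
  if (any(!is.finite(positions[, , 1][present])) ||
      any(!is.finite(positions[, , 2][present])) ||
      any(!is.finite(positions[, , 3][present])))
    stop("non-finite coordinates in present samples")
  dimnames(positions) <- list(NULL, marker_ids, c("X", "Y", "Z"))
  structure(list(positions = positions, marker_ids = marker_ids,
                 frame_rate = frame_rate, present = present),
            class = "marker_trajectory_set")
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  d <- dim(x$positions)
  miss <- sum(!x$present)
  cat(sprintf(
    "Marker trajectories: %d frames x %d markers @ %g Hz (%d missing samples)\n",
    d[1], d[2], x$frame_rate, miss))
  cat("  markers:", paste(x$marker_ids, collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(trj) dim(trj$positions)[1]

# positions of one frame as markers x 3 matrix (rows may contain NA)
frame_positions <- function(trj, frame, marker_ids = trj$marker_ids) {
  idx <- match(marker_ids, trj$marker_ids)
  if (anyNA(idx)) stop("unknown marker ids: ",
                       paste(marker_ids[is.na(idx)], collapse = ", "))
  x <- trj$positions[frame, idx, , drop = FALSE]
  matrix(x, nrow = length(idx), ncol = 3,
         dimnames = list(marker_ids, c("X", "Y", "Z")))
}

#' Read marker trajectories from CSV
#'
#' Reads the flat tracking-export dialect used throughout the package:
#' a `frame` column followed by per-marker coordinate triplets headed
#' `<marker>_X`, `<marker>_Y`, `<marker>_Z`. Blank cells are missing
#' samples. The frame rate is not stored in the file and must be supplied.
#'
#' @param path CSV file path.
#' @param frame_rate recording rate in Hz.
#' @return a [marker_trajectory_set()].
#' @seealso [write_marker_csv()]
#' @export
read_marker_csv <- function(path, frame_rate) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty trajectory CSV: ", path)
  if (names(df)[1] != "frame") stop("first column must be 'frame'")
  cols <- names(df)[-1]
  ok <- grepl("_[XYZ]$", cols)
  if (!all(ok)) stop("malformed coordinate columns: ",
                     paste(cols[!ok], collapse = ", "))
  ids <- unique(sub("_[XYZ]$", "", cols))
  nf <- nrow(df)
  pos <- array(NA_real_, dim = c(nf, length(ids), 3))
  for (m in seq_along(ids)) {
    for (k in 1:3) {
      col <- paste0(ids[m], "_", c("X", "Y", "Z")[k])
      if (!col %in% cols) stop("missing column: ", col)
      pos[, m, k] <- as.numeric(df[[col]])
    }
  }
  marker_trajectory_set(pos, ids, frame_rate)
}

#' Write marker trajectories to CSV
#'
#' @param trj a [marker_trajectory_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_marker_csv()]
#' @export
write_marker_csv <- function(trj, path) {
  nf <- n_frames(trj)
  out <- data.frame(frame = seq_len(nf))
  for (m in seq_along(trj$marker_ids)) {
    for (k in 1:3) {
      out[[paste0(trj$marker_ids[m], "_", c("X", "Y", "Z")[k])]] <-
        trj$positions[, m, k]
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
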