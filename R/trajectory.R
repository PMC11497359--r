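#' Construct a trajectory window
#'
#' A trajectory window holds time-ordered coordinate frames aligned to the
#' atom order of a [parse_structure()] structure, plus optional per-frame
#' orthorhombic box lengths.
#'
#' @param coords Either a 3-D array of dimension `n_atoms x 3 x n_frames` or a
#'   list of `n_atoms x 3` matrices (Angstrom).
#' @param times_ps Numeric vector of frame times in picoseconds, strictly
#'   increasing, one per frame.
#' @param box Optional box: either three lengths (Angstrom, constant over the
#'   trajectory) or an `n_frames x 3` matrix.
#' @param atom_ids Optional integer vector of atom ids in frame row order.
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function(coords, times_ps, box = NULL, atom_ids = NULL) {
  if (is.list(coords)) {
    na <- nrow(coords[[1]])
    if (!all(vapply(coords, nrow, 1L) == na)) {
      stop("Every frame must have the same atom count.", call. = FALSE)
    }
    coords <- array(unlist(coords, use.names = FALSE), dim = c(na, 3L, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nf <- dim(coords)[3]
  times_ps <- as.numeric(times_ps)
  if (length(times_ps) != nf) {
    stop("times_ps must have one entry per frame.", call. = FALSE)
  }
  if (nf > 1L && any(diff(times_ps) <= 0)) {
    stop("Frame times must be strictly increasing.", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("Coordinates must be finite.", call. = FALSE)
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(as.numeric(box), nrow = nf, ncol = 3L, byrow = TRUE)
    box <- as.matrix(box)
    stopifnot(nrow(box) == nf, ncol(box) == 3L)
    if (any(box <= 0)) stop("Box lengths must be positive.", call. = FALSE)
  }
  structure(
    list(coords = coords, times_ps = times_ps, box = box,
         atom_ids = if (is.null(atom_ids)) seq_len(dim(coords)[1]) else as.integer(atom_ids)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames x ", dim(x$coords)[1], " atoms, t = ",
      min(x$times_ps), "..", max(x$times_ps), " ps",
      if (!is.null(x$box)) " (periodic)", "\n", sep = "")
  invisible(x)
}

#' @rdname new_trajectory
#' @param traj A `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as a coordinate matrix
#'
#' @param traj A `trajectory`.
#' @param i Frame index.
#' @return An `n_atoms x 3` matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  traj$coords[, , i, drop = TRUE]
}

#' Drop frames before an equilibration boundary
#'
#' @param traj A `trajectory`.
#' @param equilibration_ps Time in ps; frames with `time < equilibration_ps`
#'   are removed.
#' @return A `trajectory` restricted to `time >= equilibration_ps`.
#' @export
trim_equilibration <- function(traj, equilibration_ps) {
  keep <- traj$times_ps >= equilibration_ps
  if (!any(keep)) {
    stop("No frames at or after the equilibration boundary (",
         equilibration_ps, " ps).", call. = FALSE)
  }
  new_trajectory(
    traj$coords[, , keep, drop = FALSE],
    traj$times_ps[keep],
    box = if (is.null(traj$box)) NULL else traj$box[keep, , drop = FALSE],
    atom_ids = traj$atom_ids
  )
}

#' Convert between trajectories and tidy frame tables
#'
#' The plain-text exchange format for trajectories is a long table with one
#' row per atom per frame and columns `frame`, `time_ps`, `atom_id`, `x`,
#' `y`, `z` (Angstrom), optionally `box_x`, `box_y`, `box_z`.
#'
#' @param table A data frame in the frame-table layout, or a path to a
#'   CSV/TSV file in that layout.
#' @return `as_trajectory()` returns a `trajectory`;
#'   `trajectory_table()` returns a tibble.
#' @export
as_trajectory <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    table <- readr::read_csv(table, show_col_types = FALSE, comment = "#")
  }
  table <- tibble::as_tibble(table)
  stopifnot(all(c("frame", "time_ps", "atom_id", "x", "y", "z") %in% names(table)))
  table <- dplyr::arrange(table, .data$frame, .data$atom_id)
  frames <- split(table, table$frame)
  ids <- frames[[1]]$atom_id
  if (!all(vapply(frames, function(f) identical(f$atom_id, ids), TRUE))) {
    stop("All frames must contain the same atom ids.", call. = FALSE)
  }
  coords <- array(
    unlist(lapply(frames, function(f) cbind(f$x, f$y, f$z)), use.names = FALSE),
    dim = c(length(ids), 3L, length(frames))
  )
  times <- vapply(frames, function(f) f$time_ps[1], 1)
  box <- NULL
  if (all(c("box_x", "box_y", "box_z") %in% names(table))) {
    box <- t(vapply(frames, function(f) c(f$box_x[1], f$box_y[1], f$box_z[1]), numeric(3)))
  }
  new_trajectory(coords, times, box = box, atom_ids = ids)
}

#' @rdname as_trajectory
#' @param traj A `trajectory`.
#' @export
trajectory_table <- function(traj) {
  nf <- n_frames(traj)
  na <- dim(traj$coords)[1]
  out <- tibble::tibble(
    frame = rep(seq_len(nf), each = na),
    time_ps = rep(traj$times_ps, each = na),
    atom_id = rep(traj$atom_ids, nf),
    x = as.vector(traj$coords[, 1, ]),
    y = as.vector(traj$coords[, 2, ]),
    z = as.vector(traj$coords[, 3, ])
  )
  if (!is.null(traj$box)) {
    out$box_x <- rep(traj$box[, 1], each = na)
    out$box_y <- rep(traj$box[, 2], each = na)
    out$box_z <- rep(traj$box[, 3], each = na)
  }
  out
}

#' @rdname as_trajectory
#' @param path Output path for `write_frame_table()`.
#' @export
write_frame_table <- function(traj, path) {
  readr::write_csv(trajectory_table(traj), path)
  invisible(path)
}

# match each grid time to the index (into sorted `times`) of its nearest
# time; ties are resolved to the earlier frame
.nearest_frame <- function(grid, times) {
  lo <- findInterval(grid, times)
  lo[lo < 1L] <- 1L
  hi <- pmin(lo + 1L, length(times))
  ifelse(abs(grid - times[lo]) <= abs(times[hi] - grid), lo, hi)
}
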