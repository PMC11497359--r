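#' Read single-cell migration tracks
#'
#' Ingests the delimited tables exported by image-tracking tools: one row per
#' cell per time point with columns `cell_id`, `t` (minutes), `x`, `y`
#' (micrometres). The aliases `t_min`, `x_um`, `y_um` and an optional
#' `condition` column are accepted. Rows are grouped by cell and sorted by
#' time; a duplicate timestamp within one cell is an error, and cells with
#' fewer than two samples are dropped with a warning.
#'
#' @param table A data frame, or a path to a CSV/TSV file with a header.
#' @return A tibble of class `cell_tracks` with columns `cell_id`, `t_min`,
#'   `x_um`, `y_um` (and `condition` when present), sorted by cell and time.
#' @export
read_tracks <- function(table) {
  if (is.character(table) && length(table) == 1L) {
    raw <- readr::read_delim(
      table,
      delim = if (grepl("\\.tsv$", table)) "\t" else ",",
      col_types = readr::cols(.default = readr::col_character()),
      comment = "#"
    )
  } else {
    raw <- tibble::as_tibble(table)
  }
  nm <- names(raw)
  pick <- function(cands) {
    hit <- intersect(cands, nm)
    if (length(hit) == 0L) {
      stop("Track table is missing a column named one of: ",
           paste(cands, collapse = ", "), call. = FALSE)
    }
    hit[1]
  }
  out <- tibble::tibble(
    cell_id = as.character(raw[[pick(c("cell_id", "cell", "track_id"))]]),
    t_min = raw[[pick(c("t", "t_min", "time", "time_min"))]],
    x_um = raw[[pick(c("x", "x_um"))]],
    y_um = raw[[pick(c("y", "y_um"))]]
  )
  if ("condition" %in% nm) out$condition <- as.character(raw$condition)
  for (col in c("t_min", "x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("Non-numeric ", col, " value '", out[[col]][bad],
           "' at data row ", bad, ".", call. = FALSE)
    }
    out[[col]] <- v
  }
  out <- dplyr::arrange(out, .data$cell_id, .data$t_min)
  dup <- out |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::filter(duplicated(.data$t_min)) |>
    dplyr::ungroup()
  if (nrow(dup) > 0L) {
    stop("Duplicate timestamp(s) within cell '", dup$cell_id[1],
         "' at t = ", dup$t_min[1], " min.", call. = FALSE)
  }
  short <- out |>
    dplyr::count(.data$cell_id) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(short) > 0L) {
    warning("Dropping ", nrow(short), " cell(s) with fewer than 2 samples: ",
            paste(utils::head(short$cell_id, 5), collapse = ", "),
            call. = FALSE)
    out <- out[!out$cell_id %in% short$cell_id, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("No usable tracks.", call. = FALSE)
  structure(out, class = c("cell_tracks", class(tibble::tibble())))
}

.one_track <- function(track) {
  track <- tibble::as_tibble(track)
  stopifnot(all(c("t_min", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < 2L) stop("A track needs at least 2 samples.", call. = FALSE)
  if (any(diff(track$t_min) <= 0)) {
    track <- dplyr::arrange(track, .data$t_min)
    if (any(diff(track$t_min) <= 0)) {
      stop("Track times must be strictly increasing.", call. = FALSE)
    }
  }
  track
}

#' Track kinematics: distances, velocity, persistence
#'
#' `accumulated_distance()` is the total path length (sum of consecutive step
#' lengths); `euclidean_distance()` the straight-line distance between first
#' and last position; `track_velocity()` the accumulated distance divided by
#' the elapsed time (micrometres per minute, the image-tracking convention);
#' `directional_persistence()` the ratio Euclidean/accumulated, a
#' directionality index of 1 for perfectly straight motion and 0 for a net
#' return to the origin (`NA` for a track that never moves).
#'
#' @param track A data frame with columns `t_min`, `x_um`, `y_um` for one
#'   cell.
#' @return A single number.
#' @export
accumulated_distance <- function(track) {
  track <- .one_track(track)
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' @rdname accumulated_distance
#' @export
euclidean_distance <- function(track) {
  track <- .one_track(track)
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

#' @rdname accumulated_distance
#' @export
track_velocity <- function(track) {
  track <- .one_track(track)
  dur <- track$t_min[nrow(track)] - track$t_min[1]
  if (dur <= 0) stop("Track duration must be positive.", call. = FALSE)
  accumulated_distance(track) / dur
}

#' @rdname accumulated_distance
#' @export
directional_persistence <- function(track) {
  acc <- accumulated_distance(track)
  if (acc == 0) return(NA_real_)
  euclidean_distance(track) / acc
}

#' Per-cell kinematic summary of a track set
#'
#' @param tracks A `cell_tracks` tibble (or any long table with `cell_id`,
#'   `t_min`, `x_um`, `y_um` and optionally `condition`).
#' @return A tibble of class `track_stats` with one row per cell and columns
#'   `cell_id` (and `condition`), `n_samples`, `duration_min`,
#'   `velocity_um_min`, `accumulated_um`, `euclidean_um`, `persistence`.
#' @export
track_stats <- function(tracks) {
  tracks <- tibble::as_tibble(tracks)
  grp <- intersect(c("condition", "cell_id"), names(tracks))
  out <- tracks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        n_samples = nrow(d),
        duration_min = max(d$t_min) - min(d$t_min),
        velocity_um_min = track_velocity(d),
        accumulated_um = accumulated_distance(d),
        euclidean_um = euclidean_distance(d),
        persistence = directional_persistence(d)
      )
    }) |>
    dplyr::ungroup()
  structure(out, class = c("track_stats", class(tibble::tibble())))
}

#' Condition-level summary of track statistics
#'
#' @param stats A `track_stats` tibble with a `condition` column.
#' @return One row per condition: cell count, median velocity, mean and
#'   median persistence, median accumulated and Euclidean distances.
#' @export
summarise_conditions <- function(stats) {
  stopifnot("condition" %in% names(stats))
  stats |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      median_velocity_um_min = stats::median(.data$velocity_um_min),
      mean_persistence = mean(.data$persistence, na.rm = TRUE),
      median_persistence = stats::median(.data$persistence, na.rm = TRUE),
      median_accumulated_um = stats::median(.data$accumulated_um),
      median_euclidean_um = stats::median(.data$euclidean_um),
      .groups = "drop"
    )
}

#' Mann-Whitney U test for two independent samples
#'
#' Computes the U statistic of each sample from midranks (ties count 0.5 per
#' pair) and a two-sided p-value: exact when the combined sample size is at
#' most 12 and tie-free, otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param a,b Numeric samples.
#' @return An object of class `mwu_test`: a list with `u_a`, `u_b`,
#'   `statistic` (`min(u_a, u_b)`), `p_value`, `n_a`, `n_b`, `exact`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("Both samples must be non-empty.", call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  ties <- any(duplicated(c(a, b)))
  exact <- (n_a + n_b) <= 12L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
  structure(
    list(u_a = u_a, u_b = u_b, statistic = min(u_a, u_b), p_value = p,
         n_a = n_a, n_b = n_b, exact = exact,
         method = if (exact) "exact" else "normal approximation (tie/continuity corrected)"),
    class = "mwu_test"
  )
}

#' @export
print.mwu_test <- function(x, ...) {
  cat("Mann-Whitney U test (two-sided, ", x$method, ")\n",
      "U_a = ", x$u_a, ", U_b = ", x$u_b,
      " (n_a = ", x$n_a, ", n_b = ", x$n_b, "), p = ",
      format.pval(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Pairwise Mann-Whitney comparisons across conditions
#'
#' @param stats A `track_stats` tibble with a `condition` column.
#' @param variable Column of `stats` to compare (default
#'   `"velocity_um_min"`).
#' @return A tibble with one row per unordered condition pair: `group_a`,
#'   `group_b`, `u_a`, `u_b`, `p_value`, `exact`.
#' @export
compare_conditions <- function(stats, variable = "velocity_um_min") {
  stopifnot("condition" %in% names(stats), variable %in% names(stats))
  conds <- unique(stats$condition)
  if (length(conds) < 2L) {
    stop("Need at least two conditions to compare.", call. = FALSE)
  }
  pairs <- utils::combn(conds, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1, i]; gb <- pairs[2, i]
    t <- mann_whitney_u(
      stats[[variable]][stats$condition == ga],
      stats[[variable]][stats$condition == gb]
    )
    tibble::tibble(group_a = ga, group_b = gb, u_a = t$u_a, u_b = t$u_b,
                   p_value = t$p_value, exact = t$exact)
  })
}
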