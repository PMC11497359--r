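#' Per-domain RMSD time series
#'
#' Computes the root-mean-square deviation of one named domain over a
#' trajectory. Frames before the equilibration boundary are discarded; the
#' reference is the first retained frame (or a caller-chosen time). Each frame
#' is superposed onto the reference using only the domain's selected atoms,
#' so the series reports internal deformation of that domain, not rigid-body
#' motion.
#'
#' @param traj A [new_trajectory()] object aligned to `structure`.
#' @param structure A `structure_model`.
#' @param map A `domain_map`.
#' @param domain Domain label in `map`.
#' @param atom_selection Atom selection for the fit and the deviation; see
#'   [select_atoms()]. Default `"calpha"`.
#' @param equilibration_ps Equilibration period discarded from the front of
#'   the trajectory (default 3000 ps, i.e. 3 ns).
#' @param superpose If `FALSE`, skip the rigid fit and report raw deviation
#'   from the reference frame (useful for ground-truth checks).
#' @param reference_time_ps Optional reference time; default the first
#'   post-equilibration frame.
#' @return A tibble of class `rmsd_series` with columns `domain`, `time_ps`,
#'   `rmsd_A`; the reference time is in `attr(, "reference_time_ps")`.
#' @export
domain_rmsd_series <- function(traj, structure, map, domain,
                               atom_selection = "calpha",
                               equilibration_ps = 3000,
                               superpose = TRUE,
                               reference_time_ps = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(structure, "structure_model"))
  if (dim(traj$coords)[1] != nrow(structure)) {
    stop("Trajectory and structure disagree on atom count.", call. = FALSE)
  }
  sel <- select_atoms(structure, atom_selection)
  dom <- assign_residue_domain(map, sel$chain, sel$residue_id)
  idx <- match(sel$atom_id[!is.na(dom) & dom == domain], structure$atom_id)
  if (length(idx) == 0L) {
    stop("Selection is empty for domain '", domain, "'.", call. = FALSE)
  }
  keep <- which(traj$times_ps >= equilibration_ps)
  if (length(keep) < 1L) {
    stop("No frames after the equilibration period.", call. = FALSE)
  }
  times <- traj$times_ps[keep]
  ref_i <- if (is.null(reference_time_ps)) keep[1] else {
    keep[.nearest_frame(reference_time_ps, times)]
  }
  ref <- traj$coords[idx, , ref_i, drop = TRUE]
  vals <- vapply(keep, function(f) {
    x <- traj$coords[idx, , f, drop = TRUE]
    if (superpose) kabsch_superpose(x, ref)$rmsd else .raw_rmsd(x, ref)
  }, 1)
  out <- tibble::tibble(domain = domain, time_ps = times, rmsd_A = vals)
  structure(out,
            reference_time_ps = traj$times_ps[ref_i],
            atom_selection = atom_selection,
            class = c("rmsd_series", class(out)))
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each residue about its mean position,
#' after removing overall rigid-body motion. A two-pass procedure is used:
#' frames are first superposed onto the first post-equilibration frame and
#' averaged; all frames are then re-superposed onto that mean structure, the
#' mean is recomputed, and fluctuations are measured about it. Residue RMSF
#' is the root of the mean squared fluctuation over the residue's selected
#' atoms.
#'
#' @inheritParams domain_rmsd_series
#' @param superpose If `FALSE`, fluctuations are measured in the raw frame
#'   coordinates (no alignment).
#' @return A tibble of class `rmsf_profile` with columns `chain`,
#'   `residue_id`, `residue_name`, `rmsf_A`.
#' @export
residue_rmsf <- function(traj, structure, atom_selection = "calpha",
                         equilibration_ps = 3000, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"), inherits(structure, "structure_model"))
  sel <- select_atoms(structure, atom_selection)
  idx <- match(sel$atom_id, structure$atom_id)
  keep <- which(traj$times_ps >= equilibration_ps)
  if (length(keep) < 2L) {
    stop("RMSF needs at least two post-equilibration frames.", call. = FALSE)
  }
  nf <- length(keep)
  X <- traj$coords[idx, , keep, drop = FALSE]

  if (superpose) {
    ref <- X[, , 1]
    for (pass in 1:2) {
      m <- matrix(0, nrow(ref), 3L)
      for (f in seq_len(nf)) {
        m <- m + kabsch_superpose(X[, , f], ref)$fitted
      }
      ref <- m / nf
    }
    msf <- numeric(nrow(ref))
    for (f in seq_len(nf)) {
      fit <- kabsch_superpose(X[, , f], ref)$fitted
      msf <- msf + rowSums((fit - ref)^2)
    }
    msf <- msf / nf
  } else {
    m <- apply(X, c(1, 2), mean)
    msf <- rowSums(apply(X, 3, function(fr) rowSums((fr - m)^2))) / nf
  }

  tibble::tibble(
    chain = sel$chain, residue_id = sel$residue_id,
    residue_name = sel$residue_name, msf = msf
  ) |>
    dplyr::group_by(.data$chain, .data$residue_id, .data$residue_name) |>
    dplyr::summarise(rmsf_A = sqrt(mean(.data$msf)), .groups = "drop") |>
    structure(
      atom_selection = atom_selection,
      alignment = if (superpose) "two-pass mean structure" else "none",
      class = c("rmsf_profile", class(tibble::tibble()))
    )
}

#' Domain-wise Tukey box statistics of an RMSF profile
#'
#' Residue RMSF values are assigned to their domain and summarised as Tukey
#' five-number box statistics: hinge-based quartiles, whiskers at the most
#' extreme values within 1.5 x IQR of the hinges, values beyond the whiskers
#' listed as outliers. Residues outside every domain are ignored; domains
#' with no residues in the profile are dropped with a warning.
#'
#' @param profile An `rmsf_profile`.
#' @param map A `domain_map`.
#' @return A tibble of class `domain_box_stats` with columns `domain`, `n`,
#'   `median`, `q1`, `q3`, `whisker_low`, `whisker_high` (Angstrom) and an
#'   `outliers` list column of `(chain, residue_id, rmsf_A)` tibbles.
#' @export
domain_rmsf_distribution <- function(profile, map) {
  stopifnot(inherits(map, "domain_map"))
  if (nrow(profile) == 0L) stop("Empty RMSF profile.", call. = FALSE)
  prof <- dplyr::mutate(
    tibble::as_tibble(profile),
    domain = assign_residue_domain(map, .data$chain, .data$residue_id)
  ) |>
    dplyr::filter(!is.na(.data$domain))
  missing <- setdiff(unique(map$domain), unique(prof$domain))
  if (length(missing) > 0L) {
    warning("No profile residues in domain(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- prof |>
    dplyr::group_by(.data$domain) |>
    dplyr::group_modify(function(d, key) {
      fn <- stats::fivenum(d$rmsf_A)
      iqr <- fn[4] - fn[2]
      lo_lim <- fn[2] - 1.5 * iqr
      hi_lim <- fn[4] + 1.5 * iqr
      inside <- d$rmsf_A >= lo_lim & d$rmsf_A <= hi_lim
      tibble::tibble(
        n = nrow(d),
        median = fn[3], q1 = fn[2], q3 = fn[4],
        whisker_low = min(d$rmsf_A[inside]),
        whisker_high = max(d$rmsf_A[inside]),
        outliers = list(d[!inside, c("chain", "residue_id", "rmsf_A")])
      )
    }) |>
    dplyr::ungroup()
  structure(out, class = c("domain_box_stats", class(tibble::tibble())))
}

#' Time-averaged RMSD matrix over a set of systems
#'
#' Summarises one RMSD series per (focal compound, co-compound) system into
#' its time average, laid out as the long form of a compound x compound
#' matrix. Diagonal cells (`co` equal to `focal`, or `NA`) are
#' single-compound systems; off-diagonal cells are binary mixtures.
#'
#' @param systems A data frame with columns `focal`, `co` and a list column
#'   `series` of `rmsd_series` tibbles (or any tibble with an `rmsd_A`
#'   column).
#' @return A tibble of class `rmsd_matrix` with columns `focal`, `co`,
#'   `mean_rmsd_A`, `n_frames`, `diagonal`.
#' @export
rmsd_summary_matrix <- function(systems) {
  systems <- tibble::as_tibble(systems)
  stopifnot(all(c("focal", "co", "series") %in% names(systems)))
  systems <- dplyr::mutate(
    systems,
    co = dplyr::coalesce(as.character(.data$co), as.character(.data$focal))
  )
  if (anyDuplicated(systems[c("focal", "co")])) {
    dup <- systems[duplicated(systems[c("focal", "co")]), ]
    stop("Duplicate system cell: (", dup$focal[1], ", ", dup$co[1], ").",
         call. = FALSE)
  }
  out <- systems |>
    dplyr::mutate(
      mean_rmsd_A = purrr::map_dbl(.data$series, ~ mean(.x$rmsd_A)),
      n_frames = purrr::map_int(.data$series, nrow),
      diagonal = .data$focal == .data$co
    ) |>
    dplyr::select("focal", "co", "mean_rmsd_A", "n_frames", "diagonal")
  structure(out, class = c("rmsd_matrix", class(tibble::tibble())))
}
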