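#' Define a ligand set
#'
#' A ligand set names which atoms of the structure belong to which ligand
#' species and copy. `ligand_set()` takes an explicit membership table;
#' `ligands_from_structure()` builds one from `HETATM` records, treating each
#' (residue name, chain, residue id) group as one copy of the species named
#' by its residue name.
#'
#' @param members A data frame with columns `species`, `copy`, `atom_id`.
#' @return A tibble of class `ligand_set`.
#' @export
ligand_set <- function(members) {
  members <- tibble::as_tibble(members)
  stopifnot(all(c("species", "copy", "atom_id") %in% names(members)))
  members <- dplyr::mutate(
    members,
    species = as.character(.data$species),
    copy = as.integer(.data$copy),
    atom_id = as.integer(.data$atom_id)
  )
  if (anyDuplicated(members$atom_id)) {
    stop("Ligand copies must be disjoint atom groups.", call. = FALSE)
  }
  if (nrow(members) == 0L) stop("Empty ligand set.", call. = FALSE)
  structure(members, class = c("ligand_set", class(tibble::tibble())))
}

#' @rdname ligand_set
#' @param structure A `structure_model` whose `HETATM` records are the
#'   ligand atoms.
#' @param species Optional character vector of residue names to keep
#'   (default: all `HETATM` residue names except water `HOH`).
#' @export
ligands_from_structure <- function(structure, species = NULL) {
  het <- structure[structure$record == "HETATM", , drop = FALSE]
  if (is.null(species)) species <- setdiff(unique(het$residue_name), "HOH")
  het <- het[het$residue_name %in% species, , drop = FALSE]
  if (nrow(het) == 0L) stop("No ligand atoms found.", call. = FALSE)
  het |>
    dplyr::group_by(.data$residue_name) |>
    dplyr::mutate(copy = dplyr::dense_rank(paste(.data$chain, .data$residue_id))) |>
    dplyr::ungroup() |>
    dplyr::transmute(species = .data$residue_name, copy = .data$copy,
                     atom_id = .data$atom_id) |>
    ligand_set()
}

#' Mass-weighted centre of mass of one residue
#'
#' @param structure A `structure_model`.
#' @param chain,residue_id Residue address.
#' @param coords Optional `n_atoms x 3` frame matrix in structure atom order;
#'   defaults to the structure's own coordinates.
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @return Length-3 numeric vector (Angstrom).
#' @export
residue_com <- function(structure, chain, residue_id, coords = NULL,
                        weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  rows <- which(structure$chain == chain & structure$residue_id == residue_id)
  if (length(rows) == 0L) {
    stop("Residue ", chain, ":", residue_id, " not in structure.", call. = FALSE)
  }
  xyz <- if (is.null(coords)) {
    as.matrix(structure[rows, c("x", "y", "z")])
  } else {
    coords[rows, , drop = FALSE]
  }
  w <- if (weighting == "mass") structure$mass[rows] else rep(1, length(rows))
  as.numeric(colSums(xyz * w) / sum(w))
}

# group centres of mass: coords (n x 3), group integer vector (1..G), w masses
.group_com <- function(coords, group, w) {
  sw <- rowsum(w, group)
  cbind(
    rowsum(coords[, 1] * w, group) / sw,
    rowsum(coords[, 2] * w, group) / sw,
    rowsum(coords[, 3] * w, group) / sw
  )
}

# squared minimum-image distances between every row of a (R x 3) and b (L x 3);
# box = NULL for the non-periodic case, else 3 lengths (orthorhombic)
.pair_dist2 <- function(a, b, box = NULL) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], `-`)
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

#' Transient contact count of one residue in one frame
#'
#' Counts, per ligand species, the number of ligand copies whose centre of
#' mass lies strictly within `cutoff_nm` of the residue's centre of mass.
#' Under periodic boundaries the minimum-image convention is applied
#' (orthorhombic boxes).
#'
#' @inheritParams residue_com
#' @param ligands A `ligand_set`.
#' @param cutoff_nm Distance cutoff in nanometres (default 0.7, i.e. 7
#'   Angstrom); the comparison is strict (`< cutoff`).
#' @param box Optional three box lengths in Angstrom; `NULL` disables
#'   periodicity.
#' @return Named integer vector, one count per species.
#' @export
transient_contact_count <- function(structure, chain, residue_id, ligands,
                                    coords = NULL, cutoff_nm = 0.7,
                                    box = NULL,
                                    weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  stopifnot(cutoff_nm > 0)
  rc <- matrix(residue_com(structure, chain, residue_id, coords, weighting), 1, 3)
  li <- match(ligands$atom_id, structure$atom_id)
  if (anyNA(li)) stop("Ligand atom ids not found in structure.", call. = FALSE)
  xyz <- if (is.null(coords)) as.matrix(structure[, c("x", "y", "z")]) else coords
  w <- if (weighting == "mass") structure$mass[li] else rep(1, length(li))
  grp <- as.integer(factor(paste(ligands$species, ligands$copy)))
  lcom <- .group_com(xyz[li, , drop = FALSE], grp, w)
  spec <- tapply(ligands$species, grp, `[`, 1)
  d2 <- .pair_dist2(rc, lcom, box)
  hit <- d2[1, ] < (cutoff_nm * 10)^2
  counts <- tapply(hit, spec, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out[sort(unique(ligands$species))]
}

#' Transient contact-number series and averages
#'
#' Evaluates the per-residue, per-species transient contact count C_i(t) on a
#' fixed time grid and its time average. The grid is anchored at the
#' equilibration boundary: t_k = equilibration + k * interval, for every k
#' with t_k not after the last frame; each grid time is mapped to the nearest
#' stored post-equilibration frame (ties to the earlier frame). The average
#' contact number of residue i is the arithmetic mean of its count series
#' over the grid.
#'
#' @param traj A `trajectory` aligned to `structure`.
#' @param structure A `structure_model` containing protein and ligand atoms.
#' @param ligands A `ligand_set`.
#' @param residues Optional tibble `(chain, residue_id)` restricting the
#'   analysis; default every `ATOM`-record residue.
#' @param interval_ps Grid spacing in ps (default 100).
#' @param equilibration_ps Equilibration period in ps (default 3000); no
#'   frame before it contributes.
#' @param cutoff_nm Contact cutoff in nm (default 0.7), strict inequality.
#' @param periodic Apply the minimum-image convention using the trajectory's
#'   per-frame box; default `TRUE` when the trajectory carries a box.
#' @param weighting Centre-of-mass weighting, `"mass"` or `"geometric"`.
#' @return An object of class `contact_series`: a list with `counts` (tibble
#'   `time_ps`, `chain`, `residue_id`, `species`, `count`), `averages`
#'   (tibble `chain`, `residue_id`, `residue_name`, `species`,
#'   `avg_contacts`), `copies` (copies per species) and `params`.
#' @export
contact_series <- function(traj, structure, ligands, residues = NULL,
                           interval_ps = 100, equilibration_ps = 3000,
                           cutoff_nm = 0.7, periodic = NULL,
                           weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(traj, "trajectory"), inherits(ligands, "ligand_set"))
  if (interval_ps <= 0) stop("interval_ps must be positive.", call. = FALSE)
  if (cutoff_nm <= 0) stop("cutoff_nm must be positive.", call. = FALSE)
  if (is.null(periodic)) periodic <- !is.null(traj$box)
  if (periodic && is.null(traj$box)) {
    stop("periodic = TRUE but the trajectory has no box.", call. = FALSE)
  }
  if (dim(traj$coords)[1] != nrow(structure)) {
    stop("Trajectory and structure disagree on atom count.", call. = FALSE)
  }

  t_max <- max(traj$times_ps)
  if (t_max < equilibration_ps) {
    stop("Trajectory does not extend past the equilibration period.",
         call. = FALSE)
  }
  grid <- seq(equilibration_ps, t_max, by = interval_ps)
  post <- which(traj$times_ps >= equilibration_ps)
  frame_of <- post[.nearest_frame(grid, traj$times_ps[post])]

  prot <- structure$record == "ATOM"
  if (is.null(residues)) {
    residues <- dplyr::distinct(
      structure[prot, c("chain", "residue_id", "residue_name")]
    )
  } else {
    residues <- tibble::as_tibble(residues)
    residues$residue_name <- structure$residue_name[
      match(paste(residues$chain, residues$residue_id),
            paste(structure$chain, structure$residue_id))
    ]
  }
  res_key <- paste(structure$chain, structure$residue_id)
  want_key <- paste(residues$chain, residues$residue_id)
  pa <- which(prot & res_key %in% want_key)
  if (length(pa) == 0L) stop("No protein atoms in the residue set.", call. = FALSE)
  rgrp <- match(res_key[pa], want_key)
  rw <- if (weighting == "mass") structure$mass[pa] else rep(1, length(pa))

  li <- match(ligands$atom_id, structure$atom_id)
  if (anyNA(li)) stop("Ligand atom ids not found in structure.", call. = FALSE)
  lw <- if (weighting == "mass") structure$mass[li] else rep(1, length(li))
  lgrp <- as.integer(factor(paste(ligands$species, ligands$copy)))
  lspec <- as.character(tapply(ligands$species, lgrp, `[`, 1))
  species <- sort(unique(ligands$species))
  spec_i <- match(lspec, species)
  cut2 <- (cutoff_nm * 10)^2

  nR <- nrow(residues)
  nS <- length(species)
  counts <- array(0L, dim = c(nR, nS, length(grid)))
  for (g in seq_along(grid)) {
    fr <- traj$coords[, , frame_of[g], drop = TRUE]
    rcom <- .group_com(fr[pa, , drop = FALSE], rgrp, rw)
    lcom <- .group_com(fr[li, , drop = FALSE], lgrp, lw)
    box <- if (periodic) traj$box[frame_of[g], ] else NULL
    hit <- .pair_dist2(rcom, lcom, box) < cut2
    counts[, , g] <- t(rowsum(t(hit) + 0L, spec_i))
  }

  counts_tbl <- tibble::tibble(
    time_ps = rep(grid, each = nR * nS),
    chain = rep(residues$chain, times = nS * length(grid)),
    residue_id = rep(residues$residue_id, times = nS * length(grid)),
    species = rep(rep(species, each = nR), times = length(grid)),
    count = as.integer(counts)
  )
  averages <- tibble::tibble(
    chain = rep(residues$chain, times = nS),
    residue_id = rep(residues$residue_id, times = nS),
    residue_name = rep(residues$residue_name, times = nS),
    species = rep(species, each = nR),
    avg_contacts = as.vector(apply(counts, c(1, 2), mean))
  )
  copies <- vapply(species, function(s) {
    length(unique(ligands$copy[ligands$species == s]))
  }, 1L)

  structure(
    list(
      counts = counts_tbl,
      averages = averages,
      copies = copies,
      params = list(
        cutoff_nm = cutoff_nm, interval_ps = interval_ps,
        equilibration_ps = equilibration_ps, periodic = periodic,
        weighting = weighting, grid_times_ps = grid
      )
    ),
    class = "contact_series"
  )
}

#' @export
print.contact_series <- function(x, ...) {
  cat("<contact_series> ", length(x$params$grid_times_ps), " grid frames x ",
      dplyr::n_distinct(paste(x$averages$chain, x$averages$residue_id)),
      " residues; species: ",
      paste(sprintf("%s (%d copies)", names(x$copies), x$copies), collapse = ", "),
      "\n  cutoff ", x$params$cutoff_nm, " nm, interval ",
      x$params$interval_ps, " ps, equilibration ",
      x$params$equilibration_ps, " ps\n", sep = "")
  invisible(x)
}

#' Domain contact number
#'
#' The domain contact number is the sum of the average contact numbers of the
#' domain's residues. Because one ligand copy can touch several residues at
#' once, it may exceed the number of copies present.
#'
#' @param series A `contact_series`.
#' @param map A `domain_map`.
#' @param domain Domain label; `NULL` for all domains.
#' @param species Species name; `NULL` for all species.
#' @return A tibble with columns `domain`, `species`, `c_domain` (one row per
#'   combination); with both `domain` and `species` given, a single number.
#' @export
domain_contact_number <- function(series, map, domain = NULL, species = NULL) {
  stopifnot(inherits(series, "contact_series"), inherits(map, "domain_map"))
  av <- series$averages |>
    dplyr::mutate(domain = assign_residue_domain(map, .data$chain, .data$residue_id)) |>
    dplyr::filter(!is.na(.data$domain))
  if (!is.null(domain)) av <- av[av$domain %in% domain, , drop = FALSE]
  if (!is.null(species)) av <- av[av$species %in% species, , drop = FALSE]
  out <- av |>
    dplyr::group_by(.data$domain, .data$species) |>
    dplyr::summarise(c_domain = sum(.data$avg_contacts), .groups = "drop")
  if (length(domain) == 1L && length(species) == 1L) {
    return(if (nrow(out) == 1L) out$c_domain else 0)
  }
  out
}

#' Competition matrix of domain contact numbers
#'
#' Tabulates, for one domain, the domain contact number of each focal species
#' alone (diagonal) and in binary mixtures (off-diagonal), with an
#' increase/decrease annotation relative to the focal species' single-species
#' value.
#'
#' @param systems A data frame with columns `focal`, `co` (`NA` or equal to
#'   `focal` for single-species systems) and a list column `series` of
#'   `contact_series` objects. In mixtures, only the focal species' contacts
#'   enter its row.
#' @param map A `domain_map`.
#' @param domain Domain label.
#' @return A tibble of class `competition_matrix` with columns `focal`, `co`,
#'   `c_domain`, `diagonal`, `annotation` (`"diagonal"`, `"increase"`,
#'   `"decrease"`, `"unchanged"` or `NA` when the diagonal is missing).
#' @export
competition_matrix <- function(systems, map, domain) {
  systems <- tibble::as_tibble(systems)
  stopifnot(all(c("focal", "co", "series") %in% names(systems)))
  systems <- dplyr::mutate(
    systems,
    focal = as.character(.data$focal),
    co = dplyr::coalesce(as.character(.data$co), as.character(.data$focal))
  )
  if (anyDuplicated(systems[c("focal", "co")])) {
    stop("Duplicate (focal, co) system pair.", call. = FALSE)
  }
  out <- systems |>
    dplyr::mutate(
      c_domain = purrr::map2_dbl(.data$series, .data$focal, function(s, sp) {
        domain_contact_number(s, map, domain = domain, species = sp)
      }),
      diagonal = .data$focal == .data$co
    ) |>
    dplyr::select("focal", "co", "c_domain", "diagonal")
  diag_val <- out$c_domain[out$diagonal][match(out$focal, out$focal[out$diagonal])]
  missing_diag <- unique(out$focal[!out$diagonal & is.na(diag_val)])
  if (length(missing_diag) > 0L) {
    warning("No single-species system for: ",
            paste(missing_diag, collapse = ", "),
            "; change annotations suppressed for those rows.", call. = FALSE)
  }
  out$annotation <- dplyr::case_when(
    out$diagonal ~ "diagonal",
    is.na(diag_val) ~ NA_character_,
    out$c_domain > diag_val ~ "increase",
    out$c_domain < diag_val ~ "decrease",
    TRUE ~ "unchanged"
  )
  structure(out, domain = domain,
            class = c("competition_matrix", class(tibble::tibble())))
}

#' Contact profile by amino-acid type
#'
#' Mean average contact number per residue type (3-letter code), alongside
#' the global mean over all residues, per species. Types whose mean exceeds
#' the global mean are contact-preferred.
#'
#' @param series A `contact_series`.
#' @return A tibble with columns `species`, `residue_name`, `n_residues`,
#'   `mean_avg_contacts`, `global_mean`, `above_average`.
#' @export
amino_acid_type_profile <- function(series) {
  stopifnot(inherits(series, "contact_series"))
  series$averages |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(global_mean = mean(.data$avg_contacts)) |>
    dplyr::group_by(.data$species, .data$residue_name, .data$global_mean) |>
    dplyr::summarise(
      n_residues = dplyr::n(),
      mean_avg_contacts = mean(.data$avg_contacts),
      .groups = "drop"
    ) |>
    dplyr::mutate(above_average = .data$mean_avg_contacts > .data$global_mean) |>
    dplyr::select("species", "residue_name", "n_residues",
                  "mean_avg_contacts", "global_mean", "above_average")
}

#' Contact hotspot residues
#'
#' Residues whose average contact number exceeds the across-residue mean by
#' more than `k` standard deviations (per species).
#'
#' @param series A `contact_series`.
#' @param k Threshold in standard deviations above the mean (default 1;
#'   `k = 0` selects everything strictly above the mean).
#' @param species Optional species filter.
#' @return A tibble with columns `species`, `chain`, `residue_id`,
#'   `residue_name`, `avg_contacts`, `threshold`.
#' @export
hotspot_residues <- function(series, k = 1, species = NULL) {
  stopifnot(inherits(series, "contact_series"), k >= 0)
  av <- series$averages
  if (!is.null(species)) av <- av[av$species %in% species, , drop = FALSE]
  av |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(threshold = mean(.data$avg_contacts) +
                    k * stats::sd(.data$avg_contacts)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$avg_contacts > .data$threshold) |>
    dplyr::select("species", "chain", "residue_id", "residue_name",
                  "avg_contacts", "threshold")
}

#' Write average contacts into the B-factor column of a PDB file
#'
#' Every atom of residue i carries that residue's average contact number in
#' the B-factor column (6.2F, so precision 0.01), which lets any molecular
#' viewer colour the protein surface by contact occupancy. Residues without
#' an average (including ligand atoms) get 0; values above 999.99 are
#' clipped with a warning.
#'
#' @param structure A `structure_model`.
#' @param series A `contact_series` computed on that structure.
#' @param species Species whose averages are written.
#' @param path Optional output path.
#' @return PDB text (invisibly when `path` is given).
#' @export
write_bfactor_pdb <- function(structure, series, species, path = NULL) {
  stopifnot(inherits(series, "contact_series"))
  av <- series$averages[series$averages$species == species, , drop = FALSE]
  if (nrow(av) == 0L) {
    stop("Species '", species, "' not present in the contact series.",
         call. = FALSE)
  }
  b <- av$avg_contacts[
    match(paste(structure$chain, structure$residue_id),
          paste(av$chain, av$residue_id))
  ]
  b[is.na(b)] <- 0
  write_structure(structure, path = path, bfactor = b)
}
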