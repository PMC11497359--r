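#' Lattice pseudo-protein with a domain map
#'
#' Builds a toy protein with one CA atom per residue placed on a cubic
#' lattice (non-collinear by construction for 3 or more residues, so rigid
#' superposition is well defined) together with a valid domain map. All
#' analysis stages accept it in place of a real structure.
#'
#' @param n_residues Number of residues (one atom each).
#' @param spacing_A Lattice spacing in Angstrom (default 10).
#' @param domain_splits Named list of interval lists, e.g.
#'   `list(D1 = list(c(1, 25)), D2 = list(c(26, 50)))`; default a single
#'   domain `"D1"` covering everything.
#' @param chain Chain identifier (default `"A"`).
#' @param residue_names Residue type per residue, recycled (default `"ALA"`).
#' @param box_A Optional three box lengths attached to the structure.
#' @param center_in_box Centre the lattice in the box (default `TRUE` when a
#'   box is given).
#' @return A list with `structure` (a `structure_model`) and `map` (a
#'   `domain_map`).
#' @export
make_lattice_protein <- function(n_residues, spacing_A = 10,
                                 domain_splits = NULL, chain = "A",
                                 residue_names = "ALA", box_A = NULL,
                                 center_in_box = !is.null(box_A)) {
  stopifnot(n_residues >= 1, spacing_A > 0)
  side <- ceiling(n_residues^(1 / 3))
  i <- seq_len(n_residues) - 1L
  xyz <- cbind(i %% side, (i %/% side) %% side, i %/% (side * side)) * spacing_A
  if (center_in_box && !is.null(box_A)) {
    xyz <- sweep(xyz, 2, box_A / 2 - colMeans(xyz), `+`)
  }
  atoms <- tibble::tibble(
    record = "ATOM",
    atom_id = seq_len(n_residues),
    name = "CA",
    residue_name = rep_len(residue_names, n_residues),
    chain = chain,
    residue_id = seq_len(n_residues),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = "C"
  )
  str <- new_structure_model(atoms, box = box_A)
  if (is.null(domain_splits)) {
    domain_splits <- list(D1 = list(c(1, n_residues)))
  }
  map <- build_domain_map(purrr::imap(domain_splits, function(rng, nm) {
    list(domain = nm, chain = chain, ranges = rng)
  }))
  bad <- domain_residues_outside(map, n_residues, chain)
  if (bad) {
    stop("domain_splits reference residues outside 1..", n_residues, ".",
         call. = FALSE)
  }
  list(structure = str, map = map)
}

domain_residues_outside <- function(map, n_residues, chain) {
  any(map$chain == chain & (map$start < 1L | map$end > n_residues))
}

# append one single-atom ligand copy per (species, copy) to a structure
.add_point_ligands <- function(structure, species, n_copies) {
  base_id <- max(structure$atom_id)
  lig <- tidyr::expand_grid(species = species, copy = seq_len(n_copies))
  atoms <- tibble::tibble(
    record = "HETATM",
    atom_id = base_id + seq_len(nrow(lig)),
    name = "C1",
    residue_name = lig$species,
    chain = "L",
    residue_id = seq_len(nrow(lig)),
    x = 0, y = 0, z = 0,
    element = "C"
  )
  list(
    structure = new_structure_model(rbind(
      tibble::as_tibble(structure)[names(atoms)], atoms
    ), box = attr(structure, "box")),
    ligands = ligand_set(tibble::tibble(
      species = lig$species, copy = lig$copy, atom_id = atoms$atom_id
    ))
  )
}

#' Simulate ligand copies diffusing around a static protein
#'
#' Appends `n_copies` single-atom ligand copies per species to the structure
#' and generates frames in which the protein is static and each copy is
#' redrawn independently every frame. In `"uniform"` mode positions are
#' i.i.d. uniform in the box, so the expected average contact number of any
#' residue follows the analytic occupancy law
#' `E = n_copies * (4/3) * pi * r^3 / V` with `r` the contact cutoff. In
#' `"tethered"` mode the first copy of the first species is instead placed
#' within `tether_r_A` of a chosen residue's centre of mass on a fixed,
#' evenly spaced fraction `tether_fraction` of the frames.
#'
#' @param structure A `structure_model` (typically from
#'   [make_lattice_protein()]) carrying a box.
#' @param species Character vector of species names.
#' @param n_copies Copies per species (default 10).
#' @param n_frames Number of frames.
#' @param dt_ps Frame spacing in ps (default 100).
#' @param t0_ps Time of the first frame (default 0).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param mode `"uniform"` or `"tethered"`.
#' @param tether_chain,tether_residue Tether residue address.
#' @param tether_r_A Tether radius in Angstrom (default 2).
#' @param tether_fraction Fraction of frames spent bound (default 1).
#' @return A list with `structure` (protein + ligand atoms), `ligands` (a
#'   `ligand_set`) and `trajectory`.
#' @export
simulate_ligand_diffusion <- function(structure, species = "LIG",
                                      n_copies = 10, n_frames = 100,
                                      dt_ps = 100, t0_ps = 0, seed = 1,
                                      mode = c("uniform", "tethered"),
                                      tether_chain = NULL,
                                      tether_residue = NULL,
                                      tether_r_A = 2, tether_fraction = 1) {
  mode <- match.arg(mode)
  box <- attr(structure, "box")
  if (is.null(box)) stop("The structure must carry a box.", call. = FALSE)
  aug <- .add_point_ligands(structure, species, n_copies)
  np <- nrow(structure)
  nl <- nrow(aug$ligands)
  prot_xyz <- as.matrix(tibble::as_tibble(structure)[, c("x", "y", "z")])

  bound_frames <- integer(0)
  tether_com <- NULL
  if (mode == "tethered") {
    if (is.null(tether_chain) || is.null(tether_residue)) {
      stop("Tethered mode needs tether_chain and tether_residue.", call. = FALSE)
    }
    tether_com <- residue_com(structure, tether_chain, tether_residue)
    # deterministic evenly-spread schedule with exactly floor(f * n) bound
    # frames, so the realised bound fraction matches the request
    k <- seq_len(n_frames)
    bound_frames <- which(floor(tether_fraction * k) >
                            floor(tether_fraction * (k - 1)))
  }

  coords <- withr::with_seed(seed, {
    arr <- array(0, dim = c(np + nl, 3L, n_frames))
    for (f in seq_len(n_frames)) {
      lig <- cbind(stats::runif(nl, 0, box[1]),
                   stats::runif(nl, 0, box[2]),
                   stats::runif(nl, 0, box[3]))
      if (f %in% bound_frames) {
        # rejection-free: uniform direction, radius ~ r * u^(1/3)
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        lig[1, ] <- tether_com + u * tether_r_A * stats::runif(1)^(1 / 3)
      }
      arr[, , f] <- rbind(prot_xyz, lig)
    }
    arr
  })
  traj <- new_trajectory(
    coords, t0_ps + (seq_len(n_frames) - 1L) * dt_ps,
    box = box, atom_ids = aug$structure$atom_id
  )
  list(structure = aug$structure, ligands = aug$ligands, trajectory = traj)
}

#' Simulate harmonic per-residue fluctuations
#'
#' Each residue oscillates sinusoidally about its reference position with a
#' prescribed amplitude along a fixed random direction and a random phase.
#' Frames sample an integer number of oscillation periods uniformly, so the
#' time-averaged squared displacement is exactly `A^2 / 2` and the
#' ground-truth RMSF of residue i is `A_i / sqrt(2)`. By default every
#' residue gets its own integer frequency, which makes the residues'
#' displacements mutually orthogonal over the sampled window — the
#' fluctuation field then carries no coherent rigid-body component beyond
#' the generic 6-degree-of-freedom share removed by superposition.
#'
#' @param structure A `structure_model` (one-atom residues recommended).
#' @param amplitudes_A Amplitude per residue in Angstrom, recycled.
#' @param n_frames Number of frames.
#' @param dt_ps Frame spacing (default 10 ps).
#' @param t0_ps Time of the first frame (default 0).
#' @param cycles Whole oscillation periods covered by the frames, recycled
#'   per residue; default one distinct frequency per residue (residue i gets
#'   `i + 2` cycles).
#' @param seed Integer seed for directions and phases.
#' @return A `trajectory`.
#' @export
simulate_harmonic_fluctuations <- function(structure, amplitudes_A,
                                           n_frames, dt_ps = 10, t0_ps = 0,
                                           cycles = NULL, seed = 1) {
  stopifnot(all(amplitudes_A >= 0), n_frames >= 2)
  res <- dplyr::distinct(tibble::as_tibble(structure)[, c("chain", "residue_id")])
  nres <- nrow(res)
  amp <- rep_len(amplitudes_A, nres)
  ref <- as.matrix(tibble::as_tibble(structure)[, c("x", "y", "z")])
  rgrp <- match(paste(structure$chain, structure$residue_id),
                paste(res$chain, res$residue_id))
  cyc <- if (is.null(cycles)) seq_len(nres) + 2L else rep_len(cycles, nres)
  withr::with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * nres), nres, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    phase <- stats::runif(nres, 0, 2 * pi)
    coords <- array(0, dim = c(nrow(ref), 3L, n_frames))
    for (f in seq_len(n_frames)) {
      th <- 2 * pi * cyc * (f - 1L) / n_frames + phase
      disp <- dirs * (amp * sin(th))
      coords[, , f] <- ref + disp[rgrp, , drop = FALSE]
    }
    new_trajectory(coords, t0_ps + (seq_len(n_frames) - 1L) * dt_ps,
                   box = attr(structure, "box"),
                   atom_ids = structure$atom_id)
  })
}

#' Simulate isotropic Gaussian positional jitter
#'
#' Every atom is displaced independently each frame by isotropic Gaussian
#' noise of standard deviation `sigma_A` per axis; the ground-truth RMSF of
#' a one-atom residue is `sigma_A * sqrt(3)`.
#'
#' @inheritParams simulate_harmonic_fluctuations
#' @param sigma_A Per-axis displacement standard deviation in Angstrom.
#' @return A `trajectory`.
#' @export
simulate_gaussian_jitter <- function(structure, sigma_A, n_frames,
                                     dt_ps = 10, t0_ps = 0, seed = 1) {
  stopifnot(sigma_A >= 0, n_frames >= 2)
  ref <- as.matrix(tibble::as_tibble(structure)[, c("x", "y", "z")])
  withr::with_seed(seed, {
    coords <- array(
      rep(as.vector(ref), n_frames) +
        stats::rnorm(length(ref) * n_frames, 0, sigma_A),
      dim = c(nrow(ref), 3L, n_frames)
    )
    new_trajectory(coords, t0_ps + (seq_len(n_frames) - 1L) * dt_ps,
                   box = attr(structure, "box"),
                   atom_ids = structure$atom_id)
  })
}

#' Simulate rigid-body motion of a structure
#'
#' Every frame is a rigid transform of the reference coordinates, so the
#' superposed RMSD is 0 by construction and the unsuperposed RMSD of a pure
#' translation equals its length.
#'
#' @param structure A `structure_model`.
#' @param translations `n_frames x 3` matrix of translations (Angstrom).
#' @param angles_deg Optional rotation angle per frame (degrees) about
#'   `axis`, applied about the centroid before translating.
#' @param axis Rotation axis (default z).
#' @param dt_ps Frame spacing (default 100 ps).
#' @param t0_ps Time of the first frame (default 0).
#' @return A `trajectory`.
#' @export
simulate_rigid_motion <- function(structure, translations,
                                  angles_deg = NULL, axis = c(0, 0, 1),
                                  dt_ps = 100, t0_ps = 0) {
  translations <- as.matrix(translations)
  stopifnot(ncol(translations) == 3L)
  nf <- nrow(translations)
  if (is.null(angles_deg)) angles_deg <- rep(0, nf)
  stopifnot(length(angles_deg) == nf)
  axis <- axis / sqrt(sum(axis^2))
  ref <- as.matrix(tibble::as_tibble(structure)[, c("x", "y", "z")])
  ctr <- colMeans(ref)
  coords <- array(0, dim = c(nrow(ref), 3L, nf))
  for (f in seq_len(nf)) {
    th <- angles_deg[f] * pi / 180
    K <- matrix(c(0, axis[3], -axis[2],
                  -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    coords[, , f] <- sweep(sweep(ref, 2, ctr) %*% t(R), 2, ctr + translations[f, ], `+`)
  }
  new_trajectory(coords, t0_ps + (seq_len(nf) - 1L) * dt_ps,
                 box = attr(structure, "box"), atom_ids = structure$atom_id)
}

#' Simulate persistent random-walk cell tracks
#'
#' Cells move at constant speed with turning angles drawn from a wrapped
#' Cauchy distribution of concentration `persistence`: `persistence = 0`
#' gives an unbiased random walk (uniform turning), `persistence = 1`
#' perfectly straight motion. Sampling every `dt_min` minutes mimics
#' time-lapse imaging of randomly migrating cells.
#'
#' @param n_tracks Number of cells (default 40, a typical per-well count).
#' @param n_steps Steps per track (default 19, i.e. 20 samples: 8 h at
#'   25-min framing).
#' @param dt_min Sampling interval in minutes (default 25).
#' @param speed_um_min Constant step speed in micrometres/minute (default
#'   0.5).
#' @param persistence Directional persistence parameter in `[0, 1]`.
#' @param seed Integer seed.
#' @param condition Optional condition label column value.
#' @return A `cell_tracks` tibble.
#' @export
simulate_persistent_random_walk <- function(n_tracks = 40, n_steps = 19,
                                            dt_min = 25, speed_um_min = 0.5,
                                            persistence = 0.5, seed = 1,
                                            condition = NULL) {
  stopifnot(persistence >= 0, persistence <= 1, n_steps >= 1)
  step <- speed_um_min * dt_min
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_len(n_tracks), function(i) {
      th0 <- stats::runif(1, -pi, pi)
      turns <- if (persistence >= 1) {
        rep(0, n_steps - 1L)
      } else {
        # wrapped Cauchy via its inverse-CDF-style tangent transform
        u <- stats::runif(n_steps - 1L)
        2 * atan(((1 - persistence) / (1 + persistence)) * tan(pi * (u - 0.5)))
      }
      th <- cumsum(c(th0, turns))
      x <- c(0, cumsum(step * cos(th)))
      y <- c(0, cumsum(step * sin(th)))
      tibble::tibble(
        cell_id = sprintf("cell_%03d", i),
        t_min = (seq_len(n_steps + 1L) - 1L) * dt_min,
        x_um = x, y_um = y
      )
    })
    if (!is.null(condition)) out$condition <- condition
    structure(out, class = c("cell_tracks", class(tibble::tibble())))
  })
}
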