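# Shared fixture builders and independent oracles for the test suite.

# one PDB ATOM line with full control over the fields
pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     occ = 1, b = 0, element = "C", record = "ATOM",
                     altloc = " ", icode = " ") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resid, icode,
          x, y, z, occ, b, element)
}

# independent scalar double-loop contact oracle: counts ligand copies with
# COM strictly within cutoff_A of each residue COM (optionally min-image)
brute_contact_counts <- function(structure, coords, ligands, cutoff_A,
                                 box = NULL) {
  str_tbl <- tibble::as_tibble(structure)
  res <- unique(str_tbl[str_tbl$record == "ATOM", c("chain", "residue_id")])
  copies <- unique(ligands[, c("species", "copy")])
  out <- matrix(0L, nrow(res), nrow(copies))
  mi_dist <- function(a, b) {
    d <- a - b
    if (!is.null(box)) {
      for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
    }
    sqrt(sum(d^2))
  }
  com_of <- function(rows) {
    w <- str_tbl$mass[rows]
    colSums(coords[rows, , drop = FALSE] * w) / sum(w)
  }
  for (i in seq_len(nrow(res))) {
    ri <- which(str_tbl$chain == res$chain[i] &
                  str_tbl$residue_id == res$residue_id[i] &
                  str_tbl$record == "ATOM")
    rc <- com_of(ri)
    for (j in seq_len(nrow(copies))) {
      lr <- which(str_tbl$atom_id %in% ligands$atom_id[
        ligands$species == copies$species[j] & ligands$copy == copies$copy[j]
      ])
      if (mi_dist(rc, com_of(lr)) < cutoff_A) out[i, j] <- 1L
    }
  }
  # per-residue, per-species totals
  spec <- copies$species
  res$counts <- lapply(seq_len(nrow(res)), function(i) {
    tapply(out[i, ], spec, sum)
  })
  res
}

# independent rigid-fit oracle: random rotation sampling plus local
# refinement of a rotation vector, never calling kabsch_superpose()
brute_force_min_rmsd <- function(mobile, reference, n_grid = 4000) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  rotmat <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    a <- v / th
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(v) {
    sqrt(mean(rowSums((P %*% t(rotmat(v)) - Q)^2)))
  }
  best <- c(0, 0, 0); best_val <- obj(best)
  for (i in seq_len(n_grid)) {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    th <- 2 * acos(abs(q[1]))
    axis <- q[2:4] / max(sqrt(sum(q[2:4]^2)), 1e-12)
    v <- axis * th
    val <- obj(v)
    if (val < best_val) { best <- v; best_val <- val }
  }
  stats::optim(best, obj, method = "BFGS",
               control = list(reltol = 1e-14))$value
}

# rigidly transform every frame of a trajectory by one rotation+translation
transform_trajectory <- function(traj, rotation, translation) {
  coords <- traj$coords
  for (f in seq_len(dim(coords)[3])) {
    coords[, , f] <- sweep(coords[, , f] %*% t(rotation), 2, translation, `+`)
  }
  new_trajectory(coords, traj$times_ps, box = traj$box,
                 atom_ids = traj$atom_ids)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# brute-force exact two-sided Mann-Whitney p by enumerating all subset
# assignments of the pooled sample (tie-free inputs only)
brute_mwu_exact_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(n, na)
  us <- apply(sets, 2, function(ix) sum(rank(pool)[ix]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# build a small two-system fixture bundle on disk and return its config
make_bundle <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lp <- make_lattice_protein(
    16, spacing_A = 8, box_A = c(70, 70, 70),
    domain_splits = list(D1 = list(c(1, 8)), D2 = list(c(9, 16)))
  )
  mk_system <- function(species, seed, n_copies) {
    sim <- simulate_ligand_diffusion(lp$structure, species = species,
                                     n_copies = n_copies, n_frames = 30,
                                     seed = seed)
    tag <- paste(species, collapse = "_")
    write_structure(sim$structure, file.path(dir, paste0(tag, ".pdb")))
    write_frame_table(sim$trajectory, file.path(dir, paste0(tag, ".csv")))
    tag
  }
  t1 <- mk_system("XXX", seed = 71, n_copies = 5)
  t2 <- mk_system(c("XXX", "YYY"), seed = 72, n_copies = 5)
  for (cond in c("ctrl", "dose")) {
    readr::write_csv(
      simulate_persistent_random_walk(
        10, persistence = ifelse(cond == "ctrl", 0.3, 0.7),
        seed = 73, condition = cond
      ),
      file.path(dir, paste0(cond, ".csv"))
    )
  }
  yaml::write_yaml(list(
    domains = list(
      list(domain = "D1", chain = "A", start = 1, end = 8),
      list(domain = "D2", chain = "A", start = 9, end = 16)
    ),
    systems = list(
      list(focal = "XXX", structure = paste0(t1, ".pdb"),
           trajectory = paste0(t1, ".csv")),
      list(focal = "XXX", co = "YYY", structure = paste0(t2, ".pdb"),
           trajectory = paste0(t2, ".csv"))
    ),
    tracks = list(
      list(condition = "ctrl", path = "ctrl.csv"),
      list(condition = "dose", path = "dose.csv")
    ),
    params = list(equilibration_ps = 0),
    output_dir = "report"
  ), file.path(dir, "run.yaml"))
  file.path(dir, "run.yaml")
}

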