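# a two-residue protein with multi-atom residues for COM checks
com_structure <- function() {
  new_structure_model(tibble::tibble(
    record = "ATOM",
    atom_id = 1:4,
    name = c("N", "CA", "CA", "CB"),
    residue_name = c("GLY", "GLY", "ALA", "ALA"),
    chain = "A",
    residue_id = c(1L, 1L, 2L, 2L),
    x = c(0, 2, 10, 11), y = 0, z = 0,
    element = c("C", "C", "C", "H")
  ))
}

test_that("residue centre of mass is the mass-weighted mean", {
  s <- com_structure()
  # equal masses at 0 and 2 -> midpoint
  expect_equal(residue_com(s, "A", 1), c(1, 0, 0))
  # masses 12.011 and 1.008 at 10 and 11
  expect_equal(residue_com(s, "A", 2)[1],
               (12.011 * 10 + 1.008 * 11) / (12.011 + 1.008))
  # geometric mode ignores mass
  expect_equal(residue_com(s, "A", 2, weighting = "geometric"), c(10.5, 0, 0))
  expect_error(residue_com(s, "A", 9), "not in structure")
})

test_that("multi-atom residue COM matches the direct mass-weighted sum", {
  set.seed(41)
  atoms <- tibble::tibble(
    record = "ATOM", atom_id = 1:7,
    name = c("N", "CA", "C", "O", "CB", "OG", "HG"),
    residue_name = "SER", chain = "A", residue_id = 1L,
    x = rnorm(7), y = rnorm(7), z = rnorm(7),
    element = c("N", "C", "C", "O", "C", "O", "H")
  )
  s <- new_structure_model(atoms)
  manual <- colSums(as.matrix(atoms[, c("x", "y", "z")]) * s$mass) / sum(s$mass)
  expect_equal(residue_com(s, "A", 1), unname(manual), tolerance = 1e-10)
})

test_that("the contact cutoff is a strict inequality", {
  lp <- make_lattice_protein(1)
  aug <- trajmetrics:::.add_point_ligands(lp$structure, "LIG", 1)
  place <- function(d) {
    co <- aug$structure
    co$x[2] <- lp$structure$x[1] + d
    co$y[2] <- lp$structure$y[1]
    co$z[2] <- lp$structure$z[1]
    as.matrix(tibble::as_tibble(co)[, c("x", "y", "z")])
  }
  count_at <- function(d) {
    transient_contact_count(aug$structure, "A", 1, aug$ligands,
                            coords = place(d), cutoff_nm = 0.7)[["LIG"]]
  }
  expect_equal(count_at(0), 1L)      # coincident COMs
  expect_equal(count_at(6.999), 1L)  # just inside
  expect_equal(count_at(7.0), 0L)    # exactly at 0.7 nm: excluded
  expect_equal(count_at(7.001), 0L)
})

test_that("vectorised counts equal the scalar double-loop oracle exactly", {
  lp <- make_lattice_protein(12, spacing_A = 7,
                             box_A = c(60, 60, 60))
  sim <- simulate_ligand_diffusion(lp$structure, species = c("AAA", "BBB"),
                                   n_copies = 4, n_frames = 25, seed = 42)
  cs <- contact_series(sim$trajectory, sim$structure, sim$ligands,
                       equilibration_ps = 0)
  for (g in c(1, 7, 25)) {
    fr <- sim$trajectory$coords[, , g]
    oracle <- brute_contact_counts(sim$structure, fr, sim$ligands,
                                   cutoff_A = 7, box = c(60, 60, 60))
    got <- cs$counts[cs$counts$time_ps == cs$params$grid_times_ps[g], ]
    for (i in seq_len(nrow(oracle))) {
      for (sp in c("AAA", "BBB")) {
        expect_identical(
          got$count[got$residue_id == oracle$residue_id[i] &
                      got$species == sp],
          as.integer(oracle$counts[[i]][[sp]])
        )
      }
    }
  }
})

test_that("a permanently tethered ligand gives average contact number 1", {
  lp <- make_lattice_protein(9, spacing_A = 20, box_A = c(120, 120, 120))
  sim <- simulate_ligand_diffusion(
    lp$structure, n_copies = 1, n_frames = 60, seed = 43,
    mode = "tethered", tether_chain = "A", tether_residue = 5,
    tether_fraction = 1
  )
  cs <- contact_series(sim$trajectory, sim$structure, sim$ligands,
                       equilibration_ps = 0)
  expect_equal(
    cs$averages$avg_contacts[cs$averages$residue_id == 5], 1
  )
})

test_that("a half-time tether gives average contact number 1/2 on the grid", {
  lp <- make_lattice_protein(9, spacing_A = 40, box_A = c(200, 200, 200))
  sim <- simulate_ligand_diffusion(
    lp$structure, n_copies = 1, n_frames = 100, seed = 44,
    mode = "tethered", tether_chain = "A", tether_residue = 5,
    tether_fraction = 0.5
  )
  cs <- contact_series(sim$trajectory, sim$structure, sim$ligands,
                       equilibration_ps = 0)
  avg <- cs$averages$avg_contacts[cs$averages$residue_id == 5]
  # bound on exactly half the frames; unbound frames are uniform in a large
  # box, so accidental contacts are rare but possible
  expect_gte(avg, 0.5)
  expect_lt(avg, 0.52)
})

test_that("no grid time before the equilibration boundary contributes", {
  # ligand sits on the residue before 3000 ps and far away afterwards
  lp <- make_lattice_protein(2, spacing_A = 30)
  aug <- trajmetrics:::.add_point_ligands(lp$structure, "LIG", 1)
  ref <- as.matrix(tibble::as_tibble(aug$structure)[, c("x", "y", "z")])
  times <- seq(0, 6000, by = 100)
  coords <- array(0, dim = c(nrow(ref), 3, length(times)))
  for (f in seq_along(times)) {
    fr <- ref
    fr[3, ] <- if (times[f] < 3000) ref[1, ] else ref[1, ] + c(1000, 0, 0)
    coords[, , f] <- fr
  }
  traj <- new_trajectory(coords, times, atom_ids = aug$structure$atom_id)
  cs <- contact_series(traj, aug$structure, aug$ligands,
                       equilibration_ps = 3000)
  expect_true(all(cs$params$grid_times_ps >= 3000))
  expect_equal(max(cs$averages$avg_contacts), 0)
  # with equilibration 0 the early contacts do show up
  cs0 <- contact_series(traj, aug$structure, aug$ligands, equilibration_ps = 0)
  expect_gt(max(cs0$averages$avg_contacts), 0.4)
})

test_that("domain contact numbers are additive over residue partitions", {
  lp <- make_lattice_protein(
    12, spacing_A = 7, box_A = c(60, 60, 60),
    domain_splits = list(D1 = list(c(1, 6)), D2 = list(c(7, 12)))
  )
  sim <- simulate_ligand_diffusion(lp$structure, n_copies = 5, n_frames = 40,
                                   seed = 45)
  cs <- contact_series(sim$trajectory, sim$structure, sim$ligands,
                       equilibration_ps = 0)
  whole <- make_lattice_protein(12, domain_splits = list(ALL = list(c(1, 12))))$map
  c_all <- domain_contact_number(cs, whole, "ALL", "LIG")
  c_split <- domain_contact_number(cs, lp$map, "D1", "LIG") +
    domain_contact_number(cs, lp$map, "D2", "LIG")
  expect_identical(c_all, c_split)
  # and equals the direct sum of the averages
  expect_identical(c_all, sum(cs$averages$avg_contacts))
})

test_that("one ligand touching several residues pushes C_domain past the copy count", {
  # 4 residues packed within the cutoff of a single permanently-bound copy
  lp <- make_lattice_protein(4, spacing_A = 3)
  aug <- trajmetrics:::.add_point_ligands(lp$structure, "LIG", 1)
  ref <- as.matrix(tibble::as_tibble(aug$structure)[, c("x", "y", "z")])
  ref[5, ] <- colMeans(ref[1:4, ])
  coords <- array(rep(ref, 5), dim = c(5, 3, 5))
  traj <- new_trajectory(coords, seq(0, 400, by = 100),
                         atom_ids = aug$structure$atom_id)
  cs <- contact_series(traj, aug$structure, aug$ligands, equilibration_ps = 0)
  cd <- domain_contact_number(cs, lp$map, "D1", "LIG")
  expect_equal(cd, 4)          # 4 x per-residue average of 1
  expect_gt(cd, 1)             # exceeds the single copy present
})

test_that("counts never decrease when the cutoff grows", {
  lp <- make_lattice_protein(10, spacing_A = 8, box_A = c(50, 50, 50))
  sim <- simulate_ligand_diffusion(lp$structure, n_copies = 6, n_frames = 30,
                                   seed = 46)
  cuts <- c(0.3, 0.5, 0.7, 1.0, 1.5)
  series <- lapply(cuts, function(cc) {
    contact_series(sim$trajectory, sim$structure, sim$ligands,
                   equilibration_ps = 0, cutoff_nm = cc)$counts$count
  })
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(series[[i]] >= series[[i - 1]]))
  }
})

test_that("translating ligands by a full box vector leaves periodic counts unchanged", {
  lp <- make_lattice_protein(8, spacing_A = 9, box_A = c(55, 55, 55))
  sim <- simulate_ligand_diffusion(lp$structure, n_copies = 5, n_frames = 20,
                                   seed = 47)
  cs <- contact_series(sim$trajectory, sim$structure, sim$ligands,
                       equilibration_ps = 0)
  shifted <- sim$trajectory
  lig_rows <- match(sim$ligands$atom_id, sim$structure$atom_id)
  shifted$coords[lig_rows, 1, ] <- shifted$coords[lig_rows, 1, ] + 55
  shifted$coords[lig_rows, 3, ] <- shifted$coords[lig_rows, 3, ] - 2 * 55
  cs2 <- contact_series(shifted, sim$structure, sim$ligands,
                        equilibration_ps = 0)
  expect_identical(cs$counts$count, cs2$counts$count)
})

test_that("amino-acid-type profiles compare type means to the global mean", {
  lp <- make_lattice_protein(6, spacing_A = 30,
                             residue_names = c("ALA", "GLY", "ALA",
                                               "GLY", "GLY", "GLY"))
  aug <- trajmetrics:::.add_point_ligands(lp$structure, "LIG", 1)
  ref <- as.matrix(tibble::as_tibble(aug$structure)[, c("x", "y", "z")])
  ref[7, ] <- ref[1, ]  # parked on an ALA residue
  coords <- array(rep(ref, 4), dim = c(7, 3, 4))
  traj <- new_trajectory(coords, seq(0, 300, 100),
                         atom_ids = aug$structure$atom_id)
  cs <- contact_series(traj, aug$structure, aug$ligands, equilibration_ps = 0)
  prof <- amino_acid_type_profile(cs)
  ala <- prof[prof$residue_name == "ALA", ]
  expect_gt(ala$mean_avg_contacts, ala$global_mean)
  expect_true(ala$above_average)
  # direct averaging oracle
  expect_equal(
    ala$mean_avg_contacts,
    mean(cs$averages$avg_contacts[cs$averages$residue_name == "ALA"])
  )
  # single-type degenerate case: type mean equals global mean
  lp1 <- make_lattice_protein(4, spacing_A = 30)
  aug1 <- trajmetrics:::.add_point_ligands(lp1$structure, "LIG", 1)
  tr1 <- simulate_rigid_motion(aug1$structure, matrix(0, 3, 3))
  cs1 <- contact_series(tr1, aug1$structure, aug1$ligands,
                        equilibration_ps = 0, periodic = FALSE)
  prof1 <- amino_acid_type_profile(cs1)
  expect_equal(prof1$mean_avg_contacts, prof1$global_mean)
})

test_that("hotspot extraction follows the mean + k*sd rule", {
  mk_series <- function(avgs) {
    structure(list(
      counts = tibble::tibble(),
      averages = tibble::tibble(
        chain = "A", residue_id = seq_along(avgs), residue_name = "ALA",
        species = "LIG", avg_contacts = avgs
      ),
      copies = c(LIG = 1L),
      params = list(grid_times_ps = 0)
    ), class = "contact_series")
  }
  # uniform: nothing exceeds mean + k*sd for k > 0
  expect_equal(nrow(hotspot_residues(mk_series(rep(0.4, 10)), k = 1)), 0L)
  # one residue at 10x the rest
  avgs <- c(rep(0.1, 9), 1)
  hs <- hotspot_residues(mk_series(avgs), k = 1)
  expect_equal(hs$residue_id, 10L)
  expect_equal(hs$threshold, mean(avgs) + sd(avgs))
  # k = 0: everything strictly above the mean
  hs0 <- hotspot_residues(mk_series(c(0.1, 0.2, 0.3, 0.4)), k = 0)
  expect_equal(hs0$residue_id, c(3L, 4L))
})

test_that("average contacts round-trip through the B-factor column", {
  lp <- make_lattice_protein(20, spacing_A = 4, box_A = c(40, 40, 40))
  sim <- simulate_ligand_diffusion(lp$structure, n_copies = 8, n_frames = 37,
                                   seed = 48)
  cs <- contact_series(sim$trajectory, sim$structure, sim$ligands,
                       equilibration_ps = 0)
  txt <- write_bfactor_pdb(sim$structure, cs, "LIG")
  back <- parse_structure(txt)
  av <- cs$averages
  for (i in seq_len(nrow(av))) {
    got <- back$bfactor[back$record == "ATOM" &
                          back$chain == av$chain[i] &
                          back$residue_id == av$residue_id[i]]
    expect_lt(max(abs(got - av$avg_contacts[i])), 0.0051)
  }
  # ligand atoms (no average) carry zero
  expect_true(all(back$bfactor[back$record == "HETATM"] == 0))
  # all-zero series writes "0.00" everywhere
  cs0 <- cs
  cs0$averages$avg_contacts <- 0
  back0 <- parse_structure(write_bfactor_pdb(sim$structure, cs0, "LIG"))
  expect_true(all(back0$bfactor == 0))
})

test_that("competition matrices annotate changes against the diagonal", {
  mk_series <- function(avg) {
    structure(list(
      counts = tibble::tibble(),
      averages = tibble::tibble(chain = "A", residue_id = 1L,
                                residue_name = "ALA", species = "X",
                                avg_contacts = avg),
      copies = c(X = 1L),
      params = list(grid_times_ps = 0)
    ), class = "contact_series")
  }
  map <- build_domain_map(tibble::tibble(domain = "D", chain = "A",
                                         start = 1, end = 1))
  systems <- tibble::tibble(
    focal = c("X", "X"), co = c(NA, "Y"),
    series = list(mk_series(2.0), mk_series(1.0))
  )
  cm <- competition_matrix(systems, map, "D")
  expect_equal(cm$annotation, c("diagonal", "decrease"))
  expect_equal(cm$c_domain, c(2, 1))
  # single system: 1x1 diagonal matrix
  cm1 <- competition_matrix(systems[1, ], map, "D")
  expect_equal(nrow(cm1), 1L)
  expect_equal(cm1$annotation, "diagonal")
  # missing diagonal suppresses annotations with a warning
  expect_warning(
    cm2 <- competition_matrix(systems[2, ], map, "D"),
    "single-species"
  )
  expect_true(is.na(cm2$annotation))
  expect_error(competition_matrix(systems[c(2, 2), ], map, "D"), "Duplicate")
})
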