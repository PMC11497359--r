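# trajmetrics

Tidy R toolkit for two analyses that pair up in studies of
endocrine-disrupting chemicals acting on cell-adhesion receptors:

1. **Protein–ligand contact occupancy and domain stability from MD
   trajectories.** Given a structure, a named-domain partition (chain +
   residue ranges) and trajectory frames for a protein with 1–3 ligand
   species in multiple copies, the package computes per-domain RMSD
   (Kabsch superposition on the domain's own atoms), per-residue RMSF with
   domain-wise Tukey box statistics, and a contact statistic: the
   *transient contact number* C_i(t) — the number of ligand copies whose
   centre of mass lies strictly within 0.7 nm of residue *i*'s centre of
   mass, evaluated every 100 ps after a 3 ns equilibration — its time
   average ⟨C_i⟩, and the *domain contact number*
   C_domain = Σ_{i ∈ domain} ⟨C_i⟩. Domain contact numbers for compounds
   alone versus in binary mixtures are tabulated as competition matrices
   (increase/decrease annotations against the single-compound diagonal),
   and ⟨C_i⟩ can be written into the B-factor column of a PDB file to
   colour contact hotspots in any molecular viewer.
2. **Single-cell migration kinematics.** From time-lapse tracking tables
   (cell id, t, x, y): velocity (accumulated distance / elapsed time,
   µm/min), accumulated and Euclidean distances, directional persistence
   (Euclidean/accumulated ∈ [0, 1]), condition summaries and pairwise
   Mann–Whitney comparisons.

Every stage has a synthetic generator with an analytically known answer
(uniform ligand diffusion obeys the occupancy law
E⟨C_i⟩ = M·(4/3)πr³/V; harmonic fluctuation of amplitude A gives RMSF
A/√2; Gaussian jitter σ gives σ√3; rigid motion gives superposed RMSD 0;
persistent random walks have exact speed and tunable persistence), so the
whole pipeline is testable without an MD engine or a microscope.

The package is aimed at computational structural biologists doing
contact/occupancy analysis of multi-copy ligand simulations, and at cell
biologists quantifying random-migration assays.

## Worked example

```r
library(trajmetrics)

# a 50-residue toy protein with two domains, plus 10 copies of one ligand
# species diffusing in a periodic 137 A box
lp  <- make_lattice_protein(50, spacing_A = 10, box_A = c(137, 137, 137),
                            domain_splits = list(core = list(c(1, 25)),
                                                 rim  = list(c(26, 50))))
sim <- simulate_ligand_diffusion(lp$structure, species = "AOH",
                                 n_copies = 10, n_frames = 2000, seed = 42)
cs  <- contact_series(sim$trajectory, sim$structure, sim$ligands,
                      equilibration_ps = 0)
cs
#> <contact_series> 2000 grid frames x 50 residues; species: AOH (10 copies)
#>   cutoff 0.7 nm, interval 100 ps, equilibration 0 ps

domain_contact_number(cs, lp$map)
#> # A tibble: 2 x 3
#>   domain species c_domain
#>   <chr>  <chr>      <dbl>
#> 1 core   AOH        0.136
#> 2 rim    AOH        0.13
```

The two domain contact numbers sit near the occupancy-law expectation for
unbound ligands (25 residues × 10 × (4/3)π·7³ / 137³ ≈ 0.140 per domain):
nothing binds in this fixture, so contacts are pure volume sampling. A
tethered fixture or a real trajectory concentrates ⟨C_i⟩ on the bound
residues instead, which `hotspot_residues()` and `write_bfactor_pdb()`
then pick out.

Migration kinematics with a two-condition comparison:

```r
tracks <- dplyr::bind_rows(
  simulate_persistent_random_walk(40, persistence = 0.3, seed = 1,
                                  condition = "control"),
  simulate_persistent_random_walk(40, persistence = 0.7, seed = 2,
                                  condition = "treated"))
st <- track_stats(tracks)
summarise_conditions(st)
#> # A tibble: 2 x 7
#>   condition n_cells median_velocity_um_min mean_persistence median_persistence
#> 1 control        40                    0.5            0.316              0.297
#> 2 treated        40                    0.5            0.437              0.395

compare_conditions(st, "persistence")
#> # A tibble: 1 x 6
#>   group_a group_b   u_a   u_b p_value exact
#> 1 control treated   549  1051  0.0159 FALSE
```

Both conditions move at the constructed 0.5 µm/min; the more persistent
walk shows the higher directionality ratio, and the Mann–Whitney test
(U_a + U_b = 40·40 = 1600) flags the difference.

`run_pipeline()` (or the CLI at `inst/cli/trajmetrics.R`, subcommands
`simulate | stability | contacts | tracks | report`) orchestrates all
stages from a YAML config into tidy CSV reports plus a checksummed
manifest; `autoplot()` methods and `plot_domain_rmsf()` draw the series,
matrices, box statistics and track roses.

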